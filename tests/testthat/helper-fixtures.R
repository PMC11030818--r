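# fixtures are built in code; nothing is read from disk except what the
# tests themselves write to tempfiles

site_key <- function(d) {
  paste(d$protein_id, d$residue, d$position, d$modification)
}

make_site_table <- function(m, protein_id = NULL, position = NULL,
                            modification = "crotonyl") {
  n <- nrow(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  tab <- tibble::tibble(
    protein_id = protein_id %||% sprintf("P%03d", seq_len(n)),
    residue = "K",
    position = position %||% as.integer(seq_len(n) * 10L),
    modification = modification
  )
  for (j in seq_len(ncol(m))) tab[[colnames(m)[j]]] <- m[, j]
  tab
}

make_sheet <- function(groups, n_rep) {
  tibble::tibble(
    sample_id = as.vector(vapply(
      groups, function(g) paste0(g, "_", seq_len(n_rep)), character(n_rep)
    )),
    group = rep(groups, each = n_rep),
    replicate_index = rep(seq_len(n_rep), length(groups))
  )
}

# random site table with optional missingness; column names follow the sheet
random_site_table <- function(n_sites, sheet, missing_rate = 0) {
  m <- matrix(
    exp(rnorm(n_sites * nrow(sheet), log(1e6), 1)),
    nrow = n_sites
  )
  if (missing_rate > 0) {
    m[runif(length(m)) < missing_rate] <- NA_real_
    # keep at least one observed value per row
    bad <- rowSums(!is.na(m)) == 0
    m[bad, 1] <- exp(rnorm(sum(bad), log(1e6), 1))
  }
  colnames(m) <- sheet$sample_id
  make_site_table(m)
}

`%||%` <- rlang::`%||%`
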
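intensity_matrix <- function(tab, samples) {
  m <- as.matrix(tab[samples])
  storage.mode(m) <- "double"
  m
}

row_mean_na <- function(m) rowMeans(m, na.rm = TRUE)

row_sd_na <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  sqrt(out)
}

#' Centralize site intensities into relative quantitative values
#'
#' Each site's intensity in each sample is divided by the arithmetic mean of
#' that site's non-missing intensities across all samples, so that every
#' site's relative values average to exactly 1. This removes the arbitrary
#' overall intensity scale of a site (ionization efficiency, peptide length)
#' while preserving between-sample structure. Missing cells stay missing;
#' rows with no observed cell are dropped with a message.
#'
#' @param table a site intensity tibble (see [read_site_table()]).
#' @return a relative-quant tibble with the same keys and sample columns plus
#'   a logical `protein_normalized` column (`FALSE` until
#'   [protein_normalize()] is applied).
#' @export
centralize <- function(table) {
  samples <- sample_cols(table)
  m <- intensity_matrix(table, samples)
  observed <- rowSums(!is.na(m))
  if (any(observed == 0)) {
    inform(sprintf(
      "dropping %d row(s) with no observed intensity", sum(observed == 0)
    ))
    table <- table[observed > 0, , drop = FALSE]
    m <- m[observed > 0, , drop = FALSE]
  }
  rel <- m / row_mean_na(m)
  out <- table
  out[samples] <- as_tibble(rel)
  out$protein_normalized <- FALSE
  select(
    out, any_of(c(SITE_KEY_COLS, "protein_normalized")), all_of(samples)
  )
}

#' Normalize site relative values by host-protein abundance
#'
#' Divides each site's relative value by the relative value of its host
#' protein in the same sample, removing the part of a modification signal
#' that merely tracks protein expression. The protein table is itself
#' centralized first. Cells whose protein value is unavailable (protein
#' absent from the table, or missing in that sample) keep the unnormalized
#' value; such rows are flagged `protein_normalized = FALSE`. A protein
#' relative value of exactly 0 makes the site cell missing (logged).
#'
#' @param sites a relative-quant tibble from [centralize()].
#' @param proteins a raw protein intensity tibble (see
#'   [read_protein_table()]); it is centralized internally.
#' @return the normalized relative-quant tibble.
#' @export
protein_normalize <- function(sites, proteins) {
  samples <- sample_cols(sites)
  psamples <- sample_cols(proteins, key_cols = "protein_id")
  common <- intersect(samples, psamples)

  pm <- intensity_matrix(proteins, psamples)
  keep <- rowSums(!is.na(pm)) > 0
  proteins <- proteins[keep, , drop = FALSE]
  pm <- pm[keep, , drop = FALSE]
  prel <- pm / row_mean_na(pm)
  colnames(prel) <- psamples
  rownames(prel) <- proteins$protein_id

  sm <- intensity_matrix(sites, samples)
  idx <- match(sites$protein_id, proteins$protein_id)

  norm_ok <- matrix(FALSE, nrow(sm), ncol(sm))
  zero_cells <- 0L
  for (j in seq_along(samples)) {
    s <- samples[j]
    if (!s %in% common) next
    pv <- prel[idx, s]
    have_site <- !is.na(sm[, j])
    usable <- !is.na(pv) & have_site
    zero <- usable & pv == 0
    zero_cells <- zero_cells + sum(zero)
    sm[zero, j] <- NA_real_
    div <- usable & !zero
    sm[div, j] <- sm[div, j] / pv[div]
    norm_ok[, j] <- !have_site | div
  }
  if (zero_cells > 0) {
    inform(sprintf(
      "%d cell(s) set missing: protein relative value was 0", zero_cells
    ))
  }
  if (length(common) < length(samples)) {
    norm_ok[, !samples %in% common] <- FALSE
  }

  out <- sites
  out[samples] <- as_tibble(sm)
  # a row counts as normalized only if no observed cell fell back
  out$protein_normalized <- rowSums(!norm_ok) == 0
  out
}

contrast_groups <- function(contrast) {
  if (length(contrast) != 2) {
    config_error("contrast must be (numerator group, denominator group)")
  }
  as.character(contrast)
}

#' Per-site fold change between two groups
#'
#' The fold change of a site for contrast (A, B) is the mean of the site's
#' relative values over the A samples divided by the mean over the B samples
#' (ratio of group means, not mean of pairwise ratios). Sites lacking an
#' observed value in either group get `NA`.
#'
#' @param relq a relative-quant tibble.
#' @param contrast character vector `c(numerator_group, denominator_group)`.
#' @param sheet the sample sheet.
#' @return a tibble of site keys plus `fc`.
#' @export
fold_change <- function(relq, contrast, sheet) {
  g <- contrast_groups(contrast)
  a <- intersect(sample_cols(relq), group_samples(sheet, g[1]))
  b <- intersect(sample_cols(relq), group_samples(sheet, g[2]))
  ma <- intensity_matrix(relq, a)
  mb <- intensity_matrix(relq, b)
  mean_a <- row_mean_na(ma)
  mean_b <- row_mean_na(mb)
  mean_a[rowSums(!is.na(ma)) == 0] <- NA_real_
  mean_b[rowSums(!is.na(mb)) == 0] <- NA_real_
  relq |>
    select(all_of(SITE_KEY_COLS)) |>
    mutate(fc = mean_a / mean_b)
}

paired_ratio_matrix <- function(relq, contrast, sheet) {
  g <- contrast_groups(contrast)
  sa <- sheet[sheet$group == g[1], ]
  sb <- sheet[sheet$group == g[2], ]
  shared <- intersect(sa$replicate_index, sb$replicate_index)
  shared <- sort(shared)
  a_ids <- sa$sample_id[match(shared, sa$replicate_index)]
  b_ids <- sb$sample_id[match(shared, sb$replicate_index)]
  keep <- a_ids %in% names(relq) & b_ids %in% names(relq)
  a_ids <- a_ids[keep]
  b_ids <- b_ids[keep]
  if (length(a_ids) == 0) {
    config_error("no replicate-paired samples shared between the two groups")
  }
  ma <- intensity_matrix(relq, a_ids)
  mb <- intensity_matrix(relq, b_ids)
  zero_den <- !is.na(mb) & mb == 0
  if (any(zero_den)) {
    inform(sprintf(
      "%d replicate pair(s) excluded: denominator relative value was 0",
      sum(zero_den)
    ))
    mb[zero_den] <- NA_real_
  }
  ma / mb
}

#' Coefficient of variation of replicate-paired ratios
#'
#' For contrast (A, B), samples are paired across groups by their
#' `replicate_index` and a per-site ratio A_r / B_r is formed for every pair
#' with both values observed. The CV is the sample standard deviation (n - 1
#' denominator) of these ratios divided by their mean; it serves as the
#' significance index of the differential call. Fewer than 2 usable pairs
#' give `NA`. Pairs whose denominator is 0 are excluded with a message.
#'
#' @inheritParams fold_change
#' @return a tibble of site keys plus `cv` and `n_ratio_pairs`.
#' @export
cv_statistic <- function(relq, contrast, sheet) {
  r <- paired_ratio_matrix(relq, contrast, sheet)
  n_pairs <- rowSums(!is.na(r))
  cv <- row_sd_na(r) / row_mean_na(r)
  cv[n_pairs < 2] <- NA_real_
  relq |>
    select(all_of(SITE_KEY_COLS)) |>
    mutate(cv = cv, n_ratio_pairs = as.integer(n_pairs))
}

#' Call differential PTM sites
#'
#' Combines the fold change and the replicate-ratio CV under the strict
#' threshold rules: a site is `up` when fc > `fc_up` and CV < `cv_max`,
#' `down` when fc < `fc_down` and CV < `cv_max`, `undetermined` when the fold
#' change is undefined or fewer than 2 usable ratio pairs exist, and `ns`
#' otherwise. All inequalities are strict, so a fold change sitting exactly
#' on a cutoff is not significant.
#'
#' @inheritParams fold_change
#' @param thresholds a [threshold_config()] with mode `"label_free"` or
#'   `"tmt"`.
#' @return a tibble of site keys plus `fc`, `cv`, `n_ratio_pairs`,
#'   `direction`.
#' @export
call_differential_sites <- function(relq, contrast, sheet, thresholds) {
  if (!inherits(thresholds, "threshold_config")) {
    config_error("thresholds must be a threshold_config")
  }
  if (!thresholds$mode %in% c("label_free", "tmt")) {
    config_error("site calling needs mode 'label_free' or 'tmt'")
  }
  fc_tab <- fold_change(relq, contrast, sheet)
  cv_tab <- cv_statistic(relq, contrast, sheet)
  calls <- inner_join(fc_tab, cv_tab, by = SITE_KEY_COLS)
  calls |>
    mutate(direction = dplyr::case_when(
      is.na(.data$fc) | .data$n_ratio_pairs < 2 ~ "undetermined",
      .data$fc > thresholds$fc_up & .data$cv < thresholds$cv_max ~ "up",
      .data$fc < thresholds$fc_down & .data$cv < thresholds$cv_max ~ "down",
      TRUE ~ "ns"
    ))
}

#' Aggregate site-level calls to proteins
#'
#' A protein is counted as upregulated when it carries at least one
#' upregulated site, and downregulated when it carries at least one
#' downregulated site; a protein can appear in both directions. Protein
#' counts per direction are therefore never larger than site counts.
#'
#' @param calls output of [call_differential_sites()].
#' @return a tibble with one row per protein that carries any site call:
#'   `protein_id`, `n_sites_up`, `n_sites_down`, `protein_direction_up`,
#'   `protein_direction_down`.
#' @export
aggregate_sites_to_proteins <- function(calls) {
  calls |>
    group_by(.data$protein_id) |>
    summarise(
      n_sites_up = sum(.data$direction == "up"),
      n_sites_down = sum(.data$direction == "down"),
      .groups = "drop"
    ) |>
    mutate(
      protein_direction_up = .data$n_sites_up >= 1,
      protein_direction_down = .data$n_sites_down >= 1
    )
}

#' Volcano-style plot of site calls
#'
#' Log2 fold change against replicate-ratio CV, coloured by call direction.
#'
#' @param calls output of [call_differential_sites()].
#' @param thresholds optional [threshold_config()] to draw cutoff lines.
#' @return a ggplot object.
#' @export
plot_site_calls <- function(calls, thresholds = NULL) {
  p <- calls |>
    filter(!is.na(.data$fc), !is.na(.data$cv)) |>
    ggplot2::ggplot(ggplot2::aes(
      x = log2(.data$fc), y = .data$cv, colour = .data$direction
    )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "log2 fold change", y = "CV of replicate ratios",
      colour = "call"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p +
      ggplot2::geom_hline(yintercept = thresholds$cv_max, linetype = 2) +
      ggplot2::geom_vline(
        xintercept = log2(c(thresholds$fc_down, thresholds$fc_up)),
        linetype = 2
      )
  }
  p
}
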
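pkg_version <- function() {
  as.character(utils::packageVersion("ptmlipidr"))
}

provenance_header <- function(seed = NULL, thresholds = NULL,
                              extra = character()) {
  h <- c(paste0("ptmlipidr ", pkg_version()))
  if (!is.null(seed)) h <- c(h, paste0("seed: ", seed))
  if (!is.null(thresholds)) {
    h <- c(h, sprintf(
      "thresholds: mode=%s fc_up=%g fc_down=%g cv_max=%g vip_min=%g abs_log2fc_min=%g rescue_up=%g rescue_down=%g",
      thresholds$mode, thresholds$fc_up, thresholds$fc_down,
      thresholds$cv_max, thresholds$vip_min, thresholds$abs_log2fc_min,
      thresholds$rescue_up, thresholds$rescue_down
    ))
  }
  c(h, extra)
}

log_stage <- function(...) {
  message("[ptmlipidr] ", sprintf(...))
}

#' Direction summary of a calls table
#'
#' Counts per call direction plus each differential direction's share of
#' all differential calls.
#'
#' @param calls a site- or metabolite-calls tibble with a `direction`
#'   column.
#' @param digits decimals for percentages.
#' @return a tibble with `direction`, `n`, `pct_of_all_differential` (NA
#'   for non-differential rows).
#' @export
report_summary <- function(calls, digits = 2) {
  n_diff <- sum(calls$direction %in% c("up", "down"))
  counts <- calls |>
    group_by(.data$direction) |>
    summarise(n = n(), .groups = "drop")
  counts |>
    mutate(pct_of_all_differential = ifelse(
      .data$direction %in% c("up", "down") & n_diff > 0,
      pct(.data$n, n_diff, digits), NA_real_
    ))
}

#' Run the PTM differential pipeline on files
#'
#' Reads a site table, optional protein table and a sample sheet;
#' centralizes, optionally protein-normalizes, calls differential sites,
#' aggregates to proteins, and writes `calls.tsv`, `proteins.tsv` and
#' `summary.tsv` into `out_dir`. Every output carries a provenance header
#' (tool version, seed, thresholds). Outputs are byte-identical across runs
#' with the same inputs and configuration.
#'
#' @param sites_path site table path.
#' @param sheet_path sample sheet path.
#' @param contrast `c(numerator_group, denominator_group)`.
#' @param proteins_path optional protein table path; when given, sites are
#'   protein-normalized.
#' @param mode `"label_free"` or `"tmt"`.
#' @param thresholds optional [threshold_config()]; defaults to the mode's
#'   defaults.
#' @param dialect site-table dialect, see [read_site_table()].
#' @param out_dir output directory (created if absent).
#' @param seed recorded in output headers (the chain is deterministic).
#' @return invisibly, a list with `calls`, `proteins`, `summary`.
#' @export
run_ptm_diff <- function(sites_path, sheet_path, contrast,
                         proteins_path = NULL,
                         mode = c("label_free", "tmt"),
                         thresholds = NULL,
                         dialect = "generic",
                         out_dir = ".", seed = 20221124) {
  mode <- match.arg(mode)
  thresholds <- thresholds %||% threshold_config(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sheet <- read_sample_sheet(sheet_path)
  sites <- read_site_table(sites_path, dialect = dialect)
  log_stage("read %d sites, %d samples", nrow(sites), nrow(sheet))

  relq <- centralize(sites)
  log_stage("centralized: %d rows retained", nrow(relq))
  if (!is.null(proteins_path)) {
    proteins <- read_protein_table(proteins_path)
    relq <- protein_normalize(relq, proteins)
    log_stage(
      "protein-normalized: %d/%d rows fully normalized",
      sum(relq$protein_normalized), nrow(relq)
    )
  }

  calls <- call_differential_sites(relq, contrast, sheet, thresholds)
  prot <- aggregate_sites_to_proteins(calls)
  summ <- report_summary(calls)
  log_stage(
    "calls: %d up, %d down, %d ns, %d undetermined",
    sum(calls$direction == "up"), sum(calls$direction == "down"),
    sum(calls$direction == "ns"), sum(calls$direction == "undetermined")
  )

  hdr <- provenance_header(
    seed, thresholds, paste0("contrast: ", contrast[1], " vs ", contrast[2])
  )
  write_table(calls, file.path(out_dir, "calls.tsv"), hdr)
  write_table(prot, file.path(out_dir, "proteins.tsv"), hdr)
  write_table(summ, file.path(out_dir, "summary.tsv"), hdr)
  invisible(list(calls = calls, proteins = prot, summary = summ))
}

#' Run OPLS-DA with VIP and permutation validation on files
#'
#' Writes `scores.tsv` (per-sample predictive and orthogonal scores),
#' `vip.tsv` and `permutation.tsv` into `out_dir`.
#'
#' @param table_path metabolite table path.
#' @param sheet_path sample sheet path.
#' @param contrast `c(numerator_group, denominator_group)`.
#' @param k_ortho orthogonal components (default 1).
#' @param n_perm permutations (default 200).
#' @param seed seed for fold assignment and permutations.
#' @param out_dir output directory.
#' @return invisibly, a list with `model`, `vip`, `permutation`.
#' @export
run_opls <- function(table_path, sheet_path, contrast, k_ortho = 1,
                     n_perm = 200, seed = 20221124, out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- read_sample_sheet(sheet_path)
  tab <- read_metabolite_table(table_path)
  prep <- preprocess_metabolites(tab, sheet, contrast)
  fit <- fit_opls_da(prep$X, prep$y, k_ortho)
  fit$variables <- prep$metabolite_id
  vip <- vip_scores(fit)
  perm <- permutation_test(prep$X, prep$y, k_ortho, n_perm, seed = seed)
  log_stage(
    "OPLS-DA: R2Y=%.3f Q2=%.3f p(Q2)=%.4g",
    fit$R2Y, perm$observed_q2, perm$p_value_q2
  )

  hdr <- provenance_header(
    seed,
    extra = c(
      paste0("contrast: ", contrast[1], " vs ", contrast[2]),
      paste0("k_ortho: ", k_ortho), paste0("n_perm: ", n_perm)
    )
  )
  scores <- tibble(
    sample_id = prep$sample_id,
    group = ifelse(prep$y > 0, contrast[1], contrast[2]),
    t_pred = fit$t
  )
  if (fit$k_ortho > 0) scores$t_ortho1 <- fit$t_ortho[, 1]
  write_table(scores, file.path(out_dir, "scores.tsv"), hdr)
  write_table(vip, file.path(out_dir, "vip.tsv"), hdr)
  perm_tab <- tibble(
    statistic = c("R2Y", "Q2"),
    observed = c(perm$observed_r2y, perm$observed_q2),
    p_value = c(perm$p_value_r2y, perm$p_value_q2),
    n_perm = n_perm
  )
  write_table(perm_tab, file.path(out_dir, "permutation.tsv"), hdr)
  invisible(list(model = fit, vip = vip, permutation = perm))
}

#' Run two-group metabolite differential calling on files
#'
#' Calls differential metabolites under the chosen criterion and writes
#' `metab_calls.tsv` and `class_summary.tsv` (including the phospholipid
#' and lysophospholipid composite rows) into `out_dir`.
#'
#' @inheritParams run_opls
#' @param criterion `"vip"` (runs OPLS-DA internally) or `"ratio"`.
#' @param thresholds optional [threshold_config()] (metabolite mode
#'   defaults).
#' @param k_ortho orthogonal components for the VIP criterion.
#' @return invisibly, a list with `calls` and `class_summary`.
#' @export
run_metab_diff <- function(table_path, sheet_path, contrast,
                           criterion = c("vip", "ratio"),
                           thresholds = NULL, k_ortho = 1,
                           seed = 20221124, out_dir = ".") {
  criterion <- match.arg(criterion)
  thresholds <- thresholds %||% threshold_config("metabolite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- read_sample_sheet(sheet_path)
  tab <- read_metabolite_table(table_path)

  vip <- NULL
  if (criterion == "vip") {
    prep <- preprocess_metabolites(tab, sheet, contrast)
    fit <- fit_opls_da(prep$X, prep$y, k_ortho)
    fit$variables <- prep$metabolite_id
    vip <- vip_scores(fit)
  }
  calls <- call_differential_metabolites(
    tab, contrast, sheet, thresholds, criterion = criterion, vip = vip
  )
  summ <- class_summary(calls, by = "class", composites = lipid_composites())
  log_stage(
    "metabolite calls: %d up, %d down of %d",
    sum(calls$direction == "up"), sum(calls$direction == "down"),
    nrow(calls)
  )

  hdr <- provenance_header(
    seed, thresholds,
    c(paste0("contrast: ", contrast[1], " vs ", contrast[2]),
      paste0("criterion: ", criterion))
  )
  write_table(calls, file.path(out_dir, "metab_calls.tsv"), hdr)
  write_table(summ, file.path(out_dir, "class_summary.tsv"), hdr)
  invisible(list(calls = calls, class_summary = summ))
}

#' Run the three-group rescue analysis on files
#'
#' Writes `recovery.tsv` and `recovery_class_summary.tsv` (class summary of
#' the recovered metabolites, direction taken from the stress-vs-control
#' step) into `out_dir`.
#'
#' @inheritParams run_metab_diff
#' @param groups `c(control, stress, rescue)` labels.
#' @return invisibly, a list with `recovery` and `class_summary`.
#' @export
run_rescue <- function(table_path, sheet_path, groups, thresholds = NULL,
                       seed = 20221124, out_dir = ".") {
  thresholds <- thresholds %||% threshold_config("metabolite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- read_sample_sheet(sheet_path)
  tab <- read_metabolite_table(table_path)
  rec <- recovery_analysis(tab, sheet, groups, thresholds)
  log_stage("recovered %d of %d metabolites", sum(rec$recovered), nrow(rec))

  rec_calls <- rec |>
    filter(.data$recovered) |>
    mutate(direction = .data$dir_cs_vs_ctrl)
  summ <- class_summary(
    rec_calls, by = "class", composites = lipid_composites()
  )

  hdr <- provenance_header(
    seed, thresholds,
    paste0("groups: ", paste(groups, collapse = ", "))
  )
  write_table(rec, file.path(out_dir, "recovery.tsv"), hdr)
  write_table(summ, file.path(out_dir, "recovery_class_summary.tsv"), hdr)
  invisible(list(recovery = rec, class_summary = summ))
}

#' Write a simulated experiment to disk
#'
#' Writes the tables of [simulate_ptm_experiment()] or
#' [simulate_metabolite_experiment()] plus the ground-truth TSV into
#' `out_dir`, with provenance headers recording the seed.
#'
#' @param sim a `ptm_simulation` or `metab_simulation`.
#' @param out_dir output directory.
#' @param seed the seed used to generate `sim` (recorded in headers).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, out_dir = ".", seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(seed)
  files <- character()
  if (inherits(sim, "ptm_simulation")) {
    write_table(sim$sites, file.path(out_dir, "sites.tsv"), hdr)
    write_table(sim$proteins, file.path(out_dir, "proteins.tsv"), hdr)
    write_table(sim$sheet, file.path(out_dir, "sheet.tsv"), hdr)
    write_table(sim$truth, file.path(out_dir, "truth.tsv"), hdr)
    files <- file.path(out_dir,
                       c("sites.tsv", "proteins.tsv", "sheet.tsv", "truth.tsv"))
  } else if (inherits(sim, "metab_simulation")) {
    write_table(sim$table, file.path(out_dir, "metabolites.tsv"), hdr)
    write_table(sim$sheet, file.path(out_dir, "sheet.tsv"), hdr)
    write_table(sim$truth, file.path(out_dir, "truth.tsv"), hdr)
    files <- file.path(out_dir, c("metabolites.tsv", "sheet.tsv", "truth.tsv"))
  } else {
    config_error("sim must be a ptm_simulation or metab_simulation")
  }
  invisible(files)
}

#' Read a pipeline TSV, skipping provenance headers
#'
#' @param path path to a TSV written by the pipeline.
#' @return a tibble.
#' @export
read_report_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
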
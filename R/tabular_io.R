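#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate select filter arrange group_by ungroup summarise
#'   across left_join inner_join bind_rows rename n all_of any_of distinct pull
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats sd phyper p.adjust setNames rnorm rbinom runif median
#' @importFrom utils head
NULL

# column names that identify a PTM site; everything else in a site table is a
# sample column
SITE_KEY_COLS <- c("protein_id", "residue", "position", "modification")

format_error <- function(msg) {
  abort(msg, class = "ptmlipidr_format_error")
}

config_error <- function(msg) {
  abort(msg, class = "ptmlipidr_config_error")
}

#' Sample columns of a wide intensity table
#'
#' @param x a site, protein or metabolite table.
#' @param key_cols identifier columns to exclude.
#' @return character vector of sample column names, in table order.
#' @export
sample_cols <- function(x, key_cols = NULL) {
  if (is.null(key_cols)) {
    key_cols <- intersect(
      c(SITE_KEY_COLS, "protein_normalized", "metabolite_id", "name",
        "lipid_class"),
      names(x)
    )
  }
  setdiff(names(x), key_cols)
}

detect_delim <- function(path) {
  lines <- readLines(path, n = 50L)
  header <- lines[!startsWith(lines, "#")][1]
  if (is.na(header)) format_error(paste0("no header line in ", path))
  if (grepl("\t", header)) "\t" else ","
}

#' Read a sample sheet
#'
#' The sheet maps samples to groups and replicate pairs. It must contain
#' columns `sample_id`, `group` and `replicate_index`; an optional `channel`
#' column carries TMT reporter labels. Comma or tab delimiters are
#' auto-detected from the header line. Unknown columns are dropped with a
#' warning; row order is preserved.
#'
#' @param path path to a delimited text file.
#' @return a tibble with columns `sample_id`, `group`, `replicate_index` and,
#'   when present in the file, `channel`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  delim <- detect_delim(path)
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE, comment = "#"
  )
  required <- c("sample_id", "group", "replicate_index")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    format_error(paste0(
      "sample sheet is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  keep <- c(required, intersect("channel", names(raw)))
  extra <- setdiff(names(raw), keep)
  if (length(extra) > 0) {
    warn(paste0(
      "ignoring unknown sample sheet column(s): ",
      paste(extra, collapse = ", ")
    ))
  }
  sheet <- raw |>
    select(all_of(keep)) |>
    mutate(
      sample_id = as.character(.data$sample_id),
      group = as.character(.data$group),
      replicate_index = as.integer(.data$replicate_index)
    )
  validate_sample_sheet(sheet)
  sheet
}

#' Validate a sample sheet
#'
#' Checks the invariants a sheet must satisfy: unique sample ids, positive
#' replicate indices, replicate indices unique within each group.
#'
#' @param sheet a sample-sheet tibble.
#' @return the sheet, invisibly, if valid.
#' @export
validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id) > 0) {
    format_error("duplicated sample_id in sample sheet")
  }
  if (any(is.na(sheet$replicate_index)) || any(sheet$replicate_index < 1)) {
    format_error("replicate_index must be a positive integer")
  }
  dup <- sheet |>
    dplyr::count(.data$group, .data$replicate_index) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    format_error("replicate_index values must be unique within a group")
  }
  invisible(sheet)
}

coerce_intensity_cols <- function(tab, key_cols, what) {
  samples <- setdiff(names(tab), key_cols)
  if (length(samples) == 0) {
    format_error(paste0("no intensity columns found in ", what, " table"))
  }
  tab <- mutate(tab, across(all_of(samples), as.numeric))
  vals <- unlist(tab[samples], use.names = FALSE)
  if (any(vals < 0, na.rm = TRUE)) {
    format_error(paste0("negative intensity in ", what, " table"))
  }
  tab
}

#' Read a site-level modified-peptide intensity table
#'
#' Two dialects are accepted. `generic` expects columns `protein_id`,
#' `residue`, `position`, `modification` followed by one intensity column per
#' sample; empty cells or `NA` encode missing values. `maxquant_sites` expects
#' the MaxQuant sites-table columns `Protein`, `Amino acid`, `Position` plus
#' `Intensity <sample>` columns; intensities of exactly 0 are converted to
#' missing, following the MaxQuant convention that a zero denotes
#' non-detection rather than a true zero.
#'
#' @param path path to a tab-delimited file.
#' @param dialect `"generic"` or `"maxquant_sites"`.
#' @param modification modification tag to assign to every row when the
#'   dialect carries none (`maxquant_sites` only).
#' @return a site intensity tibble keyed by
#'   (`protein_id`, `residue`, `position`, `modification`).
#' @export
read_site_table <- function(path, dialect = c("generic", "maxquant_sites"),
                            modification = "mod") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  # parse everything as character and convert numerics with strtod so that
  # 17-digit renderings round-trip bit-exactly
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#",
                         col_types = readr::cols(.default = "c"))
  if (dialect == "maxquant_sites") {
    needed <- c("Protein", "Amino acid", "Position")
    if (!all(needed %in% names(raw))) {
      format_error(paste0(
        "maxquant_sites dialect requires columns: ",
        paste(needed, collapse = ", ")
      ))
    }
    int_cols <- grep("^Intensity ", names(raw), value = TRUE)
    if (length(int_cols) == 0) {
      format_error("no 'Intensity <sample>' columns found")
    }
    tab <- tibble(
      protein_id = as.character(raw$Protein),
      residue = as.character(raw[["Amino acid"]]),
      position = raw$Position,
      modification = modification
    )
    for (col in int_cols) {
      v <- as.numeric(raw[[col]])
      v[!is.na(v) & v == 0] <- NA_real_
      tab[[sub("^Intensity ", "", col)]] <- v
    }
  } else {
    missing <- setdiff(SITE_KEY_COLS, names(raw))
    if (length(missing) > 0) {
      format_error(paste0(
        "site table is missing required column(s): ",
        paste(missing, collapse = ", ")
      ))
    }
    tab <- raw |>
      mutate(
        protein_id = as.character(.data$protein_id),
        residue = as.character(.data$residue),
        modification = as.character(.data$modification)
      )
  }
  pos <- suppressWarnings(as.numeric(tab$position))
  if (any(is.na(pos)) || any(pos < 1) || any(pos != floor(pos))) {
    format_error("position must be a positive integer")
  }
  tab$position <- as.integer(pos)
  tab <- coerce_intensity_cols(tab, SITE_KEY_COLS, "site")
  if (anyDuplicated(tab[SITE_KEY_COLS]) > 0) {
    format_error("duplicated site keys in site table")
  }
  select(tab, all_of(SITE_KEY_COLS), dplyr::everything())
}

#' Read a protein-level intensity table
#'
#' Expects a `protein_id` column followed by one intensity column per sample.
#'
#' @inheritParams read_site_table
#' @return a protein intensity tibble keyed by `protein_id`.
#' @export
read_protein_table <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  # parse everything as character and convert numerics with strtod so that
  # 17-digit renderings round-trip bit-exactly
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#",
                         col_types = readr::cols(.default = "c"))
  if (!"protein_id" %in% names(raw)) {
    format_error("protein table is missing required column: protein_id")
  }
  tab <- mutate(raw, protein_id = as.character(.data$protein_id))
  tab <- coerce_intensity_cols(tab, "protein_id", "protein")
  if (anyDuplicated(tab$protein_id) > 0) {
    format_error("duplicated protein_id in protein table")
  }
  tab
}

#' Read a metabolite peak-area table
#'
#' Expects a `metabolite_id` column, an optional display `name` and an
#' optional `lipid_class` annotation, followed by one peak-area column per
#' sample. Negative areas are a format error; missing values are allowed.
#'
#' @inheritParams read_site_table
#' @return a metabolite tibble keyed by `metabolite_id`.
#' @export
read_metabolite_table <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  # parse everything as character and convert numerics with strtod so that
  # 17-digit renderings round-trip bit-exactly
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#",
                         col_types = readr::cols(.default = "c"))
  if (!"metabolite_id" %in% names(raw)) {
    format_error("metabolite table is missing required column: metabolite_id")
  }
  key_cols <- intersect(c("metabolite_id", "name", "lipid_class"), names(raw))
  tab <- raw |>
    mutate(across(all_of(key_cols), as.character))
  tab <- coerce_intensity_cols(tab, key_cols, "metabolite")
  if (anyDuplicated(tab$metabolite_id) > 0) {
    format_error("duplicated metabolite_id in metabolite table")
  }
  tab
}

#' Write a table as tab-delimited text
#'
#' Writes any of the pipeline's tables (sample sheet, site, protein,
#' metabolite, calls, summaries) as TSV with stable column order and
#' round-trip-exact decimal rendering, so that `write_table()` followed by the
#' matching reader reproduces the table bit for bit. Missing values are
#' written as `NA`.
#'
#' @param x a tibble.
#' @param path output path.
#' @param header_lines optional character vector of comment lines (without
#'   the leading `#`) written before the header, e.g. run provenance.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, header_lines = NULL) {
  # render doubles with 17 significant digits so read-back is bit-exact
  x <- mutate(x, across(
    dplyr::where(is.double),
    function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  ))
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), path)
    readr::write_tsv(x, path, na = "NA", append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(x, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Threshold configuration for differential calling
#'
#' Bundles every cutoff the calling rules use. The defaults encode the three
#' regimes: label-free PTM data (fold change > 1.3 up, < 0.77 down, CV < 0.1),
#' TMT PTM data (1.2 / 0.833, looser because isobaric labeling compresses
#' reporter ratios toward 1, CV < 0.1), and metabolite data
#' (VIP >= 1 with |log2 FC| >= 1, or the plain ratio rule >= 1.5 / <= 0.67;
#' rescue reversal at >= 1.5 / <= 0.67). PTM fold-change and CV cutoffs are
#' strict inequalities; metabolite cutoffs are inclusive.
#'
#' @param mode `"label_free"`, `"tmt"` or `"metabolite"`; selects defaults.
#' @param fc_up,fc_down ratio cutoffs (up > 1, down in (0,1)).
#' @param cv_max maximum coefficient of variation of replicate ratios.
#' @param vip_min minimum VIP score (metabolite VIP mode).
#' @param abs_log2fc_min minimum |log2 fold change| (metabolite VIP mode).
#' @param rescue_up,rescue_down reversal cutoffs for the three-group rescue
#'   analysis.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(mode = c("label_free", "tmt", "metabolite"),
                             fc_up = NULL, fc_down = NULL, cv_max = NULL,
                             vip_min = NULL, abs_log2fc_min = NULL,
                             rescue_up = NULL, rescue_down = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    label_free = list(fc_up = 1.3, fc_down = 0.77, cv_max = 0.1,
                      vip_min = 1, abs_log2fc_min = 1,
                      rescue_up = 1.5, rescue_down = 0.67),
    tmt = list(fc_up = 1.2, fc_down = 0.833, cv_max = 0.1,
               vip_min = 1, abs_log2fc_min = 1,
               rescue_up = 1.5, rescue_down = 0.67),
    metabolite = list(fc_up = 1.5, fc_down = 0.67, cv_max = 0.1,
                      vip_min = 1, abs_log2fc_min = 1,
                      rescue_up = 1.5, rescue_down = 0.67)
  )
  cfg <- list(
    mode = mode,
    fc_up = fc_up %||% defaults$fc_up,
    fc_down = fc_down %||% defaults$fc_down,
    cv_max = cv_max %||% defaults$cv_max,
    vip_min = vip_min %||% defaults$vip_min,
    abs_log2fc_min = abs_log2fc_min %||% defaults$abs_log2fc_min,
    rescue_up = rescue_up %||% defaults$rescue_up,
    rescue_down = rescue_down %||% defaults$rescue_down
  )
  if (!(cfg$fc_down < 1 && 1 < cfg$fc_up)) {
    config_error("need fc_down < 1 < fc_up")
  }
  if (!(cfg$rescue_down < 1 && 1 < cfg$rescue_up)) {
    config_error("need rescue_down < 1 < rescue_up")
  }
  if (cfg$cv_max <= 0) config_error("cv_max must be positive")
  if (cfg$vip_min < 0 || cfg$abs_log2fc_min < 0) {
    config_error("vip_min and abs_log2fc_min must be non-negative")
  }
  structure(cfg, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config> mode:", x$mode, "\n")
  cat(sprintf("  fold change: up > %g, down < %g (strict, PTM modes)\n",
              x$fc_up, x$fc_down))
  cat(sprintf("  CV maximum: %g\n", x$cv_max))
  cat(sprintf("  VIP mode: VIP >= %g & |log2FC| >= %g\n",
              x$vip_min, x$abs_log2fc_min))
  cat(sprintf("  rescue reversal: >= %g or <= %g\n",
              x$rescue_up, x$rescue_down))
  invisible(x)
}

#' Read a flat key:value configuration file
#'
#' Lines of the form `key: value` (or `key = value`); blank lines and lines
#' starting with `#` are ignored. Values that parse as numbers are returned
#' numeric.
#'
#' @param path path to the config file.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:=]+)[:=](.*)$", ln))[[1]]
    if (length(m) != 3) format_error(paste0("malformed config line: ", ln))
    key <- trimws(m[2])
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Samples belonging to a group
#'
#' @param sheet a sample sheet.
#' @param group group label.
#' @return character vector of sample ids.
#' @export
group_samples <- function(sheet, group) {
  ids <- sheet$sample_id[sheet$group == group]
  if (length(ids) == 0) {
    config_error(paste0("group not present in sample sheet: ", group))
  }
  ids
}
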
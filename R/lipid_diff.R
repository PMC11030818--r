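#' Round half-up to a fixed number of decimals
#'
#' Commercial rounding (0.5 always rounds away from zero for positive
#' input), used for reported percentages; base `round()` rounds half to
#' even, which does not reproduce conventionally reported percentages.
#'
#' @param x numeric vector (non-negative use case).
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  v <- x * scale
  # guard against representation error just below an exact half
  floor(v + 0.5 + 1e-9 * pmax(1, abs(v))) / scale
}

#' Percentage of a count pair, rounded half-up
#'
#' @param numerator,denominator counts.
#' @param digits reported decimal places.
#' @return `100 * numerator / denominator`, rounded half-up.
#' @export
pct <- function(numerator, denominator, digits = 2) {
  round_half_up(100 * numerator / denominator, digits)
}

#' Per-metabolite fold change between two groups
#'
#' Ratio of raw peak-area group means (numerator over denominator) and its
#' log2. Metabolites with an undefined ratio (denominator mean 0, or no
#' observed value in a group) are excluded with a message.
#'
#' @param table a metabolite tibble.
#' @param contrast `c(numerator_group, denominator_group)`.
#' @param sheet the sample sheet.
#' @return a tibble with `metabolite_id`, any `name`/`lipid_class` columns,
#'   `ratio` and `log2fc`.
#' @export
metabolite_fold_change <- function(table, contrast, sheet) {
  g <- contrast_groups(contrast)
  a <- intersect(sample_cols(table), group_samples(sheet, g[1]))
  b <- intersect(sample_cols(table), group_samples(sheet, g[2]))
  ma <- intensity_matrix(table, a)
  mb <- intensity_matrix(table, b)
  mean_a <- row_mean_na(ma)
  mean_b <- row_mean_na(mb)
  mean_a[rowSums(!is.na(ma)) == 0] <- NA_real_
  mean_b[rowSums(!is.na(mb)) == 0] <- NA_real_
  ratio <- mean_a / mean_b
  ratio[!is.na(mean_b) & mean_b == 0] <- NA_real_
  bad <- is.na(ratio)
  if (any(bad)) {
    inform(sprintf(
      "excluding %d metabolite(s) with undefined fold change", sum(bad)
    ))
  }
  keys <- intersect(c("metabolite_id", "name", "lipid_class"), names(table))
  table |>
    select(all_of(keys)) |>
    mutate(ratio = ratio, log2fc = log2(ratio)) |>
    filter(!bad)
}

# class vocabulary, longest prefix first so LPC wins over PC
LIPID_CLASSES <- c("LPC", "LPE", "LPA", "PC", "PE", "PI", "PA", "TG", "SM")

#' Classify a metabolite into a lipid class
#'
#' An explicit class annotation wins; otherwise the display name is matched
#' against the class vocabulary by longest prefix (so "LPC 18:0" is LPC, not
#' PC). Names matching no class are `"other"`.
#'
#' @param name character vector of display names.
#' @param annotation optional character vector of class annotations (`NA`
#'   where absent).
#' @return character vector of classes.
#' @export
classify_lipid <- function(name, annotation = NULL) {
  out <- rep("other", length(name))
  for (cl in LIPID_CLASSES[order(-nchar(LIPID_CLASSES))]) {
    hit <- out == "other" & startsWith(name, cl)
    out[hit] <- cl
  }
  if (!is.null(annotation)) {
    use <- !is.na(annotation) & nzchar(annotation)
    out[use] <- annotation[use]
  }
  out
}

#' Call differential metabolites
#'
#' Two explicit criteria are supported and never guessed. `"vip"` follows
#' the multivariate rule: up when VIP >= `vip_min` and log2 fold change
#' >= `abs_log2fc_min`, down when VIP >= `vip_min` and log2 fold change
#' <= -`abs_log2fc_min`. `"ratio"` is the plain fold-change rule: up when
#' ratio >= `fc_up`, down when ratio <= `fc_down`. All metabolite cutoffs
#' are inclusive.
#'
#' @inheritParams metabolite_fold_change
#' @param thresholds a [threshold_config()] (mode `"metabolite"`).
#' @param criterion `"vip"` or `"ratio"`.
#' @param vip a tibble from [vip_scores()] (required for `criterion =
#'   "vip"`); matched to the table by `variable` = `metabolite_id`.
#' @return a tibble with `metabolite_id`, `name`, `lipid_class`, `ratio`,
#'   `log2fc`, `vip` (NA in ratio mode) and `direction`.
#' @export
call_differential_metabolites <- function(table, contrast, sheet,
                                          thresholds,
                                          criterion = c("vip", "ratio"),
                                          vip = NULL) {
  criterion <- match.arg(criterion)
  fc <- metabolite_fold_change(table, contrast, sheet)
  if (!"name" %in% names(fc)) fc$name <- fc$metabolite_id
  fc$lipid_class <- classify_lipid(
    fc$name,
    if ("lipid_class" %in% names(fc)) fc$lipid_class else NULL
  )
  if (criterion == "vip") {
    if (is.null(vip)) config_error("criterion 'vip' needs VIP scores")
    fc$vip <- vip$vip[match(fc$metabolite_id, vip$variable)]
    fc |>
      mutate(direction = dplyr::case_when(
        is.na(.data$vip) ~ "ns",
        .data$vip >= thresholds$vip_min &
          .data$log2fc >= thresholds$abs_log2fc_min ~ "up",
        .data$vip >= thresholds$vip_min &
          .data$log2fc <= -thresholds$abs_log2fc_min ~ "down",
        TRUE ~ "ns"
      ))
  } else {
    fc |>
      mutate(
        vip = NA_real_,
        direction = dplyr::case_when(
          .data$ratio >= thresholds$fc_up ~ "up",
          .data$ratio <= thresholds$fc_down ~ "down",
          TRUE ~ "ns"
        )
      )
  }
}

#' Summarize differential calls by lipid class or direction
#'
#' Counts and percentages are computed over the differential subset
#' (direction `up` or `down`). With `by = "class"` each class gets its
#' total, up and down counts, its share of all differential metabolites,
#' and the up/down shares within the class. With `by = "direction"` the
#' up/down counts and their shares of all differential calls are returned.
#' Percentages are rounded half-up to `digits` decimals. `composites` adds
#' rows for named groupings of classes (e.g. phospholipid = PE, PC, PI),
#' computed as views over the same calls.
#'
#' @param calls a calls tibble with `direction` and (for `by = "class"`) a
#'   `lipid_class` column.
#' @param by `"class"` or `"direction"`.
#' @param digits decimals for reported percentages.
#' @param composites named list of class vectors to add as composite rows.
#' @return a summary tibble; empty input gives an empty tibble.
#' @export
class_summary <- function(calls, by = c("class", "direction"), digits = 2,
                          composites = NULL) {
  by <- match.arg(by)
  diff <- filter(calls, .data$direction %in% c("up", "down"))
  n_diff <- nrow(diff)
  if (by == "direction") {
    if (n_diff == 0) {
      return(tibble(
        direction = character(), n = integer(),
        pct_of_all_differential = double()
      ))
    }
    return(
      diff |>
        group_by(.data$direction) |>
        summarise(n = n(), .groups = "drop") |>
        mutate(pct_of_all_differential = pct(.data$n, n_diff, digits))
    )
  }
  if (n_diff == 0) {
    return(tibble(
      class = character(), n_total = integer(), n_up = integer(),
      n_down = integer(), pct_of_all_differential = double(),
      pct_up_within_class = double(), pct_down_within_class = double()
    ))
  }
  one <- function(d, label) {
    tibble(
      class = label,
      n_total = nrow(d),
      n_up = sum(d$direction == "up"),
      n_down = sum(d$direction == "down")
    )
  }
  out <- diff |>
    dplyr::group_split(.data$lipid_class) |>
    purrr::map(~ one(.x, .x$lipid_class[1])) |>
    bind_rows()
  if (!is.null(composites)) {
    comp <- purrr::imap(
      composites,
      function(cls, label) one(filter(diff, .data$lipid_class %in% cls), label)
    )
    out <- bind_rows(out, bind_rows(comp))
  }
  out |>
    mutate(
      pct_of_all_differential = pct(.data$n_total, n_diff, digits),
      pct_up_within_class = ifelse(
        .data$n_total > 0, pct(.data$n_up, .data$n_total, digits), NA_real_
      ),
      pct_down_within_class = ifelse(
        .data$n_total > 0, pct(.data$n_down, .data$n_total, digits), NA_real_
      )
    )
}

#' Composite lipid groupings used for reporting
#'
#' Phospholipid = PE, PC, PI; lysophospholipid = LPE, LPC, LPA.
#'
#' @return a named list of class vectors.
#' @export
lipid_composites <- function() {
  list(
    phospholipid = c("PE", "PC", "PI"),
    lysophospholipid = c("LPE", "LPC", "LPA")
  )
}

#' Three-group rescue analysis
#'
#' Step 1 calls metabolites differential between stress and control with
#' the plain ratio rule (ratio >= `fc_up` or <= `fc_down`). Step 2 asks
#' whether the rescue arm reverses the change relative to stress: a
#' metabolite that went down is recovered when rescue/stress >=
#' `rescue_up`; one that went up is recovered when rescue/stress <=
#' `rescue_down`. Metabolites not differential in step 1 are never
#' recovered.
#'
#' @param table a metabolite tibble covering all three groups.
#' @param sheet the sample sheet.
#' @param groups `c(control, stress, rescue)` labels, in that order.
#' @param thresholds a [threshold_config()].
#' @return a tibble with `metabolite_id`, `name`, `lipid_class`,
#'   `dir_cs_vs_ctrl`, `ratio_stress_vs_ctrl`, `ratio_rescue_vs_cs`,
#'   `recovered`.
#' @export
recovery_analysis <- function(table, sheet, groups, thresholds) {
  if (length(groups) != 3) {
    config_error("groups must be c(control, stress, rescue)")
  }
  step1 <- call_differential_metabolites(
    table, c(groups[2], groups[1]), sheet, thresholds, criterion = "ratio"
  )
  step2 <- metabolite_fold_change(table, c(groups[3], groups[2]), sheet)
  out <- step1 |>
    select(any_of(c("metabolite_id", "name", "lipid_class")),
           ratio_stress_vs_ctrl = "ratio",
           dir_cs_vs_ctrl = "direction") |>
    left_join(
      select(step2, "metabolite_id", ratio_rescue_vs_cs = "ratio"),
      by = "metabolite_id"
    )
  out |>
    mutate(recovered = dplyr::case_when(
      .data$dir_cs_vs_ctrl == "down" &
        .data$ratio_rescue_vs_cs >= thresholds$rescue_up ~ TRUE,
      .data$dir_cs_vs_ctrl == "up" &
        .data$ratio_rescue_vs_cs <= thresholds$rescue_down ~ TRUE,
      TRUE ~ FALSE
    ))
}

#' Hypergeometric enrichment of a selection against annotated categories
#'
#' For each category, the one-sided hypergeometric tail probability of
#' seeing at least the observed overlap between the selected set and the
#' category members within the universe, with Benjamini-Hochberg adjustment
#' across categories. A generic annotation-enrichment utility for
#' user-supplied category maps.
#'
#' @param selected character vector of selected ids (subset of `universe`).
#' @param universe character vector of all tested ids.
#' @param annotation tibble with columns `id` and `category` (one row per
#'   membership).
#' @return a tibble with `category`, `n_category`, `n_selected_in_category`,
#'   `p_value`, `p_adjust`, ordered by p-value.
#' @export
enrichment_test <- function(selected, universe, annotation) {
  if (!all(selected %in% universe)) {
    config_error("selected must be a subset of universe")
  }
  ann <- filter(annotation, .data$id %in% universe)
  dropped <- setdiff(unique(annotation$category), unique(ann$category))
  if (length(dropped) > 0) {
    inform(paste0(
      "skipping categor(ies) with no members in universe: ",
      paste(dropped, collapse = ", ")
    ))
  }
  n_universe <- length(unique(universe))
  n_sel <- length(unique(selected))
  out <- ann |>
    group_by(.data$category) |>
    summarise(
      n_category = dplyr::n_distinct(.data$id),
      n_selected_in_category = dplyr::n_distinct(
        intersect(.data$id, selected)
      ),
      .groups = "drop"
    ) |>
    mutate(
      p_value = phyper(
        .data$n_selected_in_category - 1, .data$n_category,
        n_universe - .data$n_category, n_sel, lower.tail = FALSE
      ),
      p_adjust = p.adjust(.data$p_value, method = "BH")
    ) |>
    arrange(.data$p_value)
  out
}

#' Bar plot of a class summary
#'
#' Up/down counts per lipid class.
#'
#' @param summary output of [class_summary()] with `by = "class"`.
#' @return a ggplot object.
#' @export
plot_class_summary <- function(summary) {
  summary |>
    select("class", "n_up", "n_down") |>
    tidyr::pivot_longer(c("n_up", "n_down"),
                        names_to = "direction", values_to = "n") |>
    mutate(direction = sub("^n_", "", .data$direction)) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$class, y = .data$n, fill = .data$direction
    )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "differential metabolites") +
    ggplot2::theme_minimal()
}
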
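#' Simulate a PTM quantification experiment with known ground truth
#'
#' Generates a site-level modified-peptide intensity table, the matching
#' protein-level table and sample sheet, and the list of truly differential
#' sites. The generative model mirrors what the downstream quantification
#' chain assumes: each protein has a log-normal baseline abundance; each site
#' carries a per-site occupancy; a site's intensity in a sample is
#'
#'   baseline x protein group effect x occupancy x site group effect x noise
#'
#' with independent multiplicative log-normal noise per cell, after which
#' cells are masked missing at `missing_rate`. Group effects are applied to
#' the last group in `groups` (the stress arm). With
#' `coupled_protein_effect = TRUE` the host protein of every differential
#' site is scaled by the same fold, emulating a modification change that
#' drags whole-protein abundance with it; protein normalization should then
#' cancel the protein-driven part. `tmt_compression` shrinks the realized
#' site fold change to `fold^(1 - compression)`, emulating isobaric reporter
#' ratio compression.
#'
#' @param n_proteins number of proteins.
#' @param sites_per_protein modified sites per protein.
#' @param n_replicates_per_group replicates per group (>= 2).
#' @param groups group labels; the last receives the injected effects.
#' @param baseline_log_mean,baseline_log_sd log-normal protein baseline
#'   parameters (natural log).
#' @param occupancy_mean mean site occupancy in (0, 1).
#' @param noise_log_sd sd of the per-cell multiplicative noise (natural log).
#' @param missing_rate fraction of site cells masked missing, in [0, 1).
#' @param n_true_up,n_true_down number of sites with injected up/down effects.
#' @param effect_fold injected fold change (> 1); down sites use its inverse.
#' @param coupled_protein_effect scale host proteins of differential sites by
#'   the same fold (at most one differential site per protein then).
#' @param tmt_compression fold-change compression in [0, 1]; 0 means none.
#' @param modification modification tag written on every site.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list of class `ptm_simulation` with elements `sites`,
#'   `proteins`, `sheet` and `truth` (tibble of differential sites with a
#'   `direction` column).
#' @export
simulate_ptm_experiment <- function(n_proteins = 200,
                                    sites_per_protein = 2,
                                    n_replicates_per_group = 3,
                                    groups = c("control", "CS"),
                                    baseline_log_mean = log(1e7),
                                    baseline_log_sd = 1.0,
                                    occupancy_mean = 0.3,
                                    noise_log_sd = 0.15,
                                    missing_rate = 0.0,
                                    n_true_up = 20,
                                    n_true_down = 20,
                                    effect_fold = 2.0,
                                    coupled_protein_effect = FALSE,
                                    tmt_compression = 0.0,
                                    modification = "crotonyl",
                                    seed = 20221124) {
  if (n_proteins < 1 || sites_per_protein < 1) {
    config_error("n_proteins and sites_per_protein must be positive")
  }
  if (n_replicates_per_group < 2) {
    config_error("n_replicates_per_group must be >= 2")
  }
  if (length(groups) < 2) config_error("need at least two groups")
  if (occupancy_mean <= 0 || occupancy_mean >= 1) {
    config_error("occupancy_mean must be in (0, 1)")
  }
  if (noise_log_sd < 0) config_error("noise_log_sd must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    config_error("missing_rate must be in [0, 1)")
  }
  n_sites <- n_proteins * sites_per_protein
  if (n_true_up + n_true_down > n_sites) {
    config_error("n_true_up + n_true_down exceeds the number of sites")
  }
  if (coupled_protein_effect && n_true_up + n_true_down > n_proteins) {
    config_error(
      "coupled_protein_effect requires n_true_up + n_true_down <= n_proteins"
    )
  }
  if (effect_fold <= 1) config_error("effect_fold must be > 1")
  if (tmt_compression < 0 || tmt_compression > 1) {
    config_error("tmt_compression must be in [0, 1]")
  }

  withr::with_seed(seed, {
    stress <- groups[length(groups)]
    sheet <- tibble(
      sample_id = as.vector(vapply(
        groups,
        function(g) paste0(g, "_", seq_len(n_replicates_per_group)),
        character(n_replicates_per_group)
      )),
      group = rep(groups, each = n_replicates_per_group),
      replicate_index = rep(seq_len(n_replicates_per_group), length(groups))
    )

    protein_ids <- sprintf("P%04d", seq_len(n_proteins))
    baseline <- exp(rnorm(n_proteins, baseline_log_mean, baseline_log_sd))

    sites <- tibble(
      protein_id = rep(protein_ids, each = sites_per_protein),
      residue = "K",
      position = as.integer(
        rep(seq_len(sites_per_protein), n_proteins) * 50L +
          sample.int(49L, n_sites, replace = TRUE)
      ),
      modification = modification
    )
    site_protein <- rep(seq_len(n_proteins), each = sites_per_protein)

    # injected effects; when coupled, one differential site per protein so a
    # protein's fold is unambiguous
    if (coupled_protein_effect) {
      host <- sample.int(n_proteins, n_true_up + n_true_down)
      diff_idx <- (host - 1L) * sites_per_protein +
        sample.int(sites_per_protein, length(host), replace = TRUE)
    } else {
      diff_idx <- sample.int(n_sites, n_true_up + n_true_down)
    }
    up_idx <- diff_idx[seq_len(n_true_up)]
    down_idx <- setdiff(diff_idx, up_idx)

    realized_up <- effect_fold^(1 - tmt_compression)
    realized_down <- (1 / effect_fold)^(1 - tmt_compression)
    site_fold <- rep(1, n_sites)
    site_fold[up_idx] <- realized_up
    site_fold[down_idx] <- realized_down

    protein_fold <- rep(1, n_proteins)
    if (coupled_protein_effect) {
      protein_fold[site_protein[up_idx]] <- realized_up
      protein_fold[site_protein[down_idx]] <- realized_down
    }

    occ_shape <- 20
    occupancy <- stats::rbeta(
      n_sites, occupancy_mean * occ_shape, (1 - occupancy_mean) * occ_shape
    )

    is_stress <- sheet$group == stress
    n_samples <- nrow(sheet)

    proteins <- tibble(protein_id = protein_ids)
    for (i in seq_len(n_samples)) {
      eff <- if (is_stress[i]) protein_fold else rep(1, n_proteins)
      proteins[[sheet$sample_id[i]]] <-
        baseline * eff * exp(rnorm(n_proteins, 0, noise_log_sd))
    }

    for (i in seq_len(n_samples)) {
      p_eff <- if (is_stress[i]) protein_fold[site_protein] else 1
      s_eff <- if (is_stress[i]) site_fold else 1
      sites[[sheet$sample_id[i]]] <-
        baseline[site_protein] * p_eff * occupancy * s_eff *
        exp(rnorm(n_sites, 0, noise_log_sd))
    }

    if (missing_rate > 0) {
      sample_ids <- sheet$sample_id
      mask <- matrix(
        runif(n_sites * n_samples) < missing_rate,
        nrow = n_sites
      )
      for (i in seq_len(n_samples)) {
        col <- sites[[sample_ids[i]]]
        col[mask[, i]] <- NA_real_
        sites[[sample_ids[i]]] <- col
      }
    }

    truth <- bind_rows(
      sites[up_idx, SITE_KEY_COLS] |> mutate(direction = "up"),
      sites[down_idx, SITE_KEY_COLS] |> mutate(direction = "down")
    )

    structure(
      list(sites = sites, proteins = proteins, sheet = sheet, truth = truth),
      class = "ptm_simulation"
    )
  })
}

#' Simulate a metabolomics experiment with class-structured effects
#'
#' Generates a metabolite peak-area table across a two-group
#' (control/stress) or three-group (control/stress/rescue) design. Each
#' metabolite has a log-normal baseline area; metabolites of classes named in
#' `group_effects` are multiplied by the class effect in the stress group.
#' In the rescue group a fraction `rescue_fraction` of the affected
#' metabolites is returned to the control baseline (fully rescued); the rest
#' remain at the stress level. Independent multiplicative log-normal noise is
#' applied per cell.
#'
#' @param class_spec named integer vector: metabolites per lipid class; use
#'   class `"other"` for non-lipid compounds.
#' @param n_per_group samples per group (>= 3).
#' @param groups two or three group labels (control, stress and, if present,
#'   rescue), in that order.
#' @param group_effects named numeric vector of multiplicative stress-group
#'   effects per class; classes not named get effect 1.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline parameters.
#' @param noise_log_sd sd of per-cell multiplicative noise (natural log).
#' @param rescue_fraction fraction of affected metabolites reversed in the
#'   rescue group, in [0, 1]; ignored in a two-group design.
#' @param seed integer seed.
#' @return a list of class `metab_simulation` with elements `table`, `sheet`
#'   and `truth` (differential metabolites with `direction` and `recovered`).
#' @export
simulate_metabolite_experiment <- function(
    class_spec = c(PC = 30, PE = 25, PI = 10, PA = 8, LPC = 10, LPE = 8,
                   LPA = 5, TG = 40, SM = 12, other = 52),
    n_per_group = 6,
    groups = c("control", "CS", "CS_THP"),
    group_effects = c(PC = 0.4, PE = 0.4, PI = 0.5, PA = 0.5,
                      LPC = 2.5, LPE = 2.5, LPA = 2.0),
    baseline_log_mean = log(1e6),
    baseline_log_sd = 1.0,
    noise_log_sd = 0.2,
    rescue_fraction = 0.5,
    seed = 20221124) {
  if (any(class_spec < 1)) config_error("class_spec counts must be positive")
  if (n_per_group < 3) config_error("n_per_group must be >= 3")
  if (!length(groups) %in% c(2, 3)) {
    config_error("groups must name two or three groups")
  }
  if (any(group_effects <= 0)) config_error("group effects must be positive")
  if (noise_log_sd < 0) config_error("noise_log_sd must be >= 0")
  if (rescue_fraction < 0 || rescue_fraction > 1) {
    config_error("rescue_fraction must be in [0, 1]")
  }

  withr::with_seed(seed, {
    sheet <- tibble(
      sample_id = as.vector(vapply(
        groups, function(g) paste0(g, "_", seq_len(n_per_group)),
        character(n_per_group)
      )),
      group = rep(groups, each = n_per_group),
      replicate_index = rep(seq_len(n_per_group), length(groups))
    )

    classes <- rep(names(class_spec), class_spec)
    n_metab <- length(classes)
    ids <- sprintf("M%04d", seq_len(n_metab))
    name <- character(n_metab)
    for (cl in unique(classes)) {
      k <- which(classes == cl)
      name[k] <- if (cl == "other") {
        sprintf("cmpd_%03d", k)
      } else {
        sprintf("%s(%d:0/%d:1)", cl,
                12 + (seq_along(k) %% 8) * 2, 16 + seq_along(k) %% 5)
      }
    }

    effect <- unname(ifelse(
      classes %in% names(group_effects), group_effects[classes], 1
    ))
    affected <- which(effect != 1)
    rescued <- integer(0)
    if (length(groups) == 3 && length(affected) > 0) {
      n_resc <- round(rescue_fraction * length(affected))
      rescued <- sort(sample(affected, n_resc))
    }

    baseline <- exp(rnorm(n_metab, baseline_log_mean, baseline_log_sd))
    tab <- tibble(
      metabolite_id = ids, name = name,
      lipid_class = ifelse(classes == "other", NA_character_, classes)
    )
    for (i in seq_len(nrow(sheet))) {
      g <- sheet$group[i]
      eff <- rep(1, n_metab)
      if (g == groups[2]) eff <- effect
      if (length(groups) == 3 && g == groups[3]) {
        eff <- effect
        eff[rescued] <- 1
      }
      tab[[sheet$sample_id[i]]] <-
        baseline * eff * exp(rnorm(n_metab, 0, noise_log_sd))
    }

    truth <- tibble(
      metabolite_id = ids[affected],
      direction = ifelse(effect[affected] > 1, "up", "down"),
      recovered = affected %in% rescued
    )

    structure(
      list(table = tab, sheet = sheet, truth = truth),
      class = "metab_simulation"
    )
  })
}
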
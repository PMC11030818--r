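# independent brute-force evaluations of the three formulas, written
# deliberately row-by-row with base loops, against which the vectorized
# implementation is checked

brute_centralize <- function(tab) {
  samples <- sample_cols(tab)
  out <- tab
  for (i in seq_len(nrow(tab))) {
    vals <- as.numeric(tab[i, samples])
    mu <- mean(vals[!is.na(vals)])
    for (s in samples) out[[s]][i] <- tab[[s]][i] / mu
  }
  out
}

brute_fc <- function(relq, contrast, sheet) {
  a <- sheet$sample_id[sheet$group == contrast[1]]
  b <- sheet$sample_id[sheet$group == contrast[2]]
  vapply(seq_len(nrow(relq)), function(i) {
    va <- as.numeric(relq[i, a])
    vb <- as.numeric(relq[i, b])
    if (all(is.na(va)) || all(is.na(vb))) return(NA_real_)
    mean(va, na.rm = TRUE) / mean(vb, na.rm = TRUE)
  }, numeric(1))
}

brute_cv <- function(relq, contrast, sheet) {
  sa <- sheet[sheet$group == contrast[1], ]
  sb <- sheet[sheet$group == contrast[2], ]
  reps <- sort(intersect(sa$replicate_index, sb$replicate_index))
  vapply(seq_len(nrow(relq)), function(i) {
    ratios <- c()
    for (r in reps) {
      va <- relq[[sa$sample_id[sa$replicate_index == r]]][i]
      vb <- relq[[sb$sample_id[sb$replicate_index == r]]][i]
      if (!is.na(va) && !is.na(vb) && vb != 0) ratios <- c(ratios, va / vb)
    }
    if (length(ratios) < 2) return(NA_real_)
    sd(ratios) / mean(ratios)
  }, numeric(1))
}

test_that("centralization matches hand-computable rows and the brute oracle", {
  tab <- make_site_table(rbind(c(10, 10), c(2, 4)))
  rel <- centralize(tab)
  expect_equal(as.numeric(rel[1, c("S1", "S2")]), c(1, 1))
  expect_equal(as.numeric(rel[2, c("S1", "S2")]), c(2 / 3, 4 / 3))

  set.seed(21)
  sheet <- make_sheet(c("g1", "g2"), 2)
  tab <- random_site_table(6, sheet, missing_rate = 0.25)
  rel <- centralize(tab)
  oracle <- brute_centralize(tab)
  expect_equal(as.matrix(rel[sheet$sample_id]),
               as.matrix(oracle[sheet$sample_id]), tolerance = 1e-12)
  # every row of relative values averages to exactly 1
  m <- as.matrix(rel[sheet$sample_id])
  expect_equal(rowMeans(m, na.rm = TRUE), rep(1, nrow(m)), tolerance = 1e-9)
})

test_that("centralization is idempotent and drops all-missing rows", {
  set.seed(3)
  sheet <- make_sheet(c("g1", "g2"), 3)
  tab <- random_site_table(8, sheet, missing_rate = 0.3)
  once <- centralize(tab)
  twice <- centralize(once)
  expect_equal(as.matrix(twice[sheet$sample_id]),
               as.matrix(once[sheet$sample_id]), tolerance = 1e-12)

  tab2 <- tab
  tab2[3, sheet$sample_id] <- NA_real_
  expect_message(rel <- centralize(tab2), "dropping 1")
  expect_equal(nrow(rel), 7)
})

test_that("fold change is the ratio of group means and inverts with the contrast", {
  sheet <- make_sheet(c("A", "B"), 2)
  # mean_A = 0.2, mean_B = 2.0 by construction -> fc 0.1
  rel <- make_site_table(matrix(c(0.1, 0.3, 1.5, 2.5), nrow = 1,
                                dimnames = list(NULL, sheet$sample_id)))
  fc <- fold_change(rel, c("A", "B"), sheet)
  expect_equal(fc$fc, 0.1)

  # identical groups give fc 1
  rel2 <- make_site_table(matrix(c(0.5, 1.5, 0.5, 1.5), nrow = 1,
                                 dimnames = list(NULL, sheet$sample_id)))
  expect_equal(fold_change(rel2, c("A", "B"), sheet)$fc, 1)

  # fc(A,B) * fc(B,A) = 1 on random data
  set.seed(4)
  tab <- random_site_table(10, sheet, missing_rate = 0.2)
  rel <- centralize(tab)
  ab <- fold_change(rel, c("A", "B"), sheet)$fc
  ba <- fold_change(rel, c("B", "A"), sheet)$fc
  ok <- !is.na(ab) & !is.na(ba)
  expect_equal(ab[ok] * ba[ok], rep(1, sum(ok)), tolerance = 1e-12)
})

test_that("fold change is invariant under global per-row rescaling", {
  set.seed(5)
  sheet <- make_sheet(c("A", "B"), 3)
  tab <- random_site_table(6, sheet)
  fc1 <- fold_change(centralize(tab), c("A", "B"), sheet)$fc
  tab2 <- tab
  scale <- runif(6, 0.1, 10)
  for (s in sheet$sample_id) tab2[[s]] <- tab2[[s]] * scale
  fc2 <- fold_change(centralize(tab2), c("A", "B"), sheet)$fc
  expect_equal(fc1, fc2, tolerance = 1e-12)
})

test_that("CV uses the sample SD of replicate-paired ratios", {
  sheet <- make_sheet(c("A", "B"), 2)
  # paired ratios (2, 2): CV = 0
  rel <- make_site_table(matrix(c(2, 4, 1, 2), nrow = 1,
                                dimnames = list(NULL, sheet$sample_id)))
  expect_equal(cv_statistic(rel, c("A", "B"), sheet)$cv, 0)

  # paired ratios (1.0, 1.2): CV = sd/mean = (0.2/sqrt(2))/1.1
  rel2 <- make_site_table(matrix(c(1, 1.2, 1, 1), nrow = 1,
                                 dimnames = list(NULL, sheet$sample_id)))
  cv <- cv_statistic(rel2, c("A", "B"), sheet)$cv
  expect_equal(cv, sd(c(1, 1.2)) / 1.1, tolerance = 1e-12)
  expect_equal(cv, 0.1285649, tolerance = 1e-6)

  # a single usable pair leaves the CV undefined and the call undetermined
  rel3 <- make_site_table(matrix(c(1, NA, 1, 1), nrow = 1,
                                 dimnames = list(NULL, sheet$sample_id)))
  cvt <- cv_statistic(rel3, c("A", "B"), sheet)
  expect_true(is.na(cvt$cv))
  expect_equal(cvt$n_ratio_pairs, 1L)
  calls <- call_differential_sites(rel3, c("A", "B"), sheet,
                                   threshold_config("label_free"))
  expect_equal(calls$direction, "undetermined")
})

test_that("centralize/fold_change/cv_statistic match the brute oracle on random tables", {
  set.seed(42)
  for (rep in 1:25) {
    n_rep <- sample(2:4, 1)
    sheet <- make_sheet(c("A", "B"), n_rep)
    tab <- random_site_table(sample(3:8, 1), sheet,
                             missing_rate = runif(1, 0, 0.3))
    rel <- centralize(tab)
    expect_equal(fold_change(rel, c("A", "B"), sheet)$fc,
                 brute_fc(rel, c("A", "B"), sheet), tolerance = 1e-10)
    expect_equal(cv_statistic(rel, c("A", "B"), sheet)$cv,
                 brute_cv(rel, c("A", "B"), sheet), tolerance = 1e-10)
  }
})

test_that("protein normalization cancels protein-driven signal", {
  sheet <- make_sheet(c("A", "B"), 1)
  # site R = (0.5, 1.5) against protein raw (0.5, 1.5): both centralize to
  # the same profile, so the normalized site is flat at 1
  site <- make_site_table(matrix(c(0.5, 1.5), nrow = 1,
                                 dimnames = list(NULL, sheet$sample_id)),
                          protein_id = "P001")
  rel <- centralize(site)
  prot <- tibble::tibble(protein_id = "P001", A_1 = 0.5, B_1 = 1.5)
  norm <- protein_normalize(rel, prot)
  expect_equal(as.numeric(norm[1, sheet$sample_id]), c(1, 1))
  expect_true(norm$protein_normalized)

  # absent protein: values unchanged, row flagged not normalized
  prot2 <- tibble::tibble(protein_id = "OTHER", A_1 = 1, B_1 = 1)
  norm2 <- protein_normalize(rel, prot2)
  expect_equal(as.numeric(norm2[1, sheet$sample_id]),
               as.numeric(rel[1, sheet$sample_id]))
  expect_false(norm2$protein_normalized)

  # coupled simulation: protein-driven sites come back to fold 1
  sim <- simulate_ptm_experiment(
    n_proteins = 30, sites_per_protein = 2, noise_log_sd = 0,
    missing_rate = 0, n_true_up = 4, n_true_down = 4,
    effect_fold = 2, coupled_protein_effect = TRUE, seed = 6
  )
  rel <- centralize(sim$sites)
  raw_fc <- fold_change(rel, c("CS", "control"), sim$sheet)
  norm <- protein_normalize(rel, sim$proteins)
  nrm_fc <- fold_change(norm, c("CS", "control"), sim$sheet)
  diff_prot <- unique(sim$truth$protein_id)
  # sibling sites on differential proteins move with the protein before
  # normalization and sit at 1 after it
  sibling <- raw_fc$protein_id %in% diff_prot &
    !(site_key(raw_fc) %in% site_key(sim$truth))
  expect_true(any(sibling))
  expect_false(any(abs(raw_fc$fc[sibling] - 1) < 1e-9))
  expect_equal(nrm_fc$fc[sibling], rep(1, sum(sibling)), tolerance = 1e-9)
  # the truly differential sites keep their site-level fold after
  # normalization
  truth_idx <- match(site_key(sim$truth), site_key(nrm_fc))
  expected <- ifelse(sim$truth$direction == "up", 2, 0.5)
  expect_equal(nrm_fc$fc[truth_idx], expected, tolerance = 1e-9)
})

test_that("differential calling applies strict thresholds per regime", {
  sheet <- make_sheet(c("A", "B"), 2)
  mk_rel <- function(fc) {
    # two exact ratios fc with tiny spread so cv ~ 0
    make_site_table(matrix(c(fc, fc, 1, 1), nrow = 1,
                           dimnames = list(NULL, sheet$sample_id)))
  }
  lf <- threshold_config("label_free")
  tmt <- threshold_config("tmt")

  expect_equal(call_differential_sites(mk_rel(0.1), c("A", "B"), sheet,
                                       lf)$direction, "down")
  # fc exactly on the cutoff is not significant (strict inequality)
  expect_equal(call_differential_sites(mk_rel(1.3), c("A", "B"), sheet,
                                       lf)$direction, "ns")
  # the same fc can be ns under label_free and up under tmt
  expect_equal(call_differential_sites(mk_rel(1.25), c("A", "B"), sheet,
                                       lf)$direction, "ns")
  expect_equal(call_differential_sites(mk_rel(1.25), c("A", "B"), sheet,
                                       tmt)$direction, "up")
  # metabolite mode is rejected for site calling
  expect_error(
    call_differential_sites(mk_rel(2), c("A", "B"), sheet,
                            threshold_config("metabolite")),
    class = "ptmlipidr_config_error"
  )
})

test_that("noiseless simulations are recovered exactly and FPR is controlled", {
  sim <- simulate_ptm_experiment(
    n_proteins = 50, noise_log_sd = 0, missing_rate = 0,
    n_true_up = 6, n_true_down = 6, effect_fold = 2, seed = 9
  )
  calls <- call_differential_sites(
    centralize(sim$sites), c("CS", "control"), sim$sheet,
    threshold_config("label_free")
  )
  called <- calls[calls$direction %in% c("up", "down"), ]
  expect_setequal(
    paste(site_key(called), called$direction),
    paste(site_key(sim$truth), sim$truth$direction)
  )
})

test_that("site calls aggregate to proteins with >=1-site-per-direction rule", {
  calls <- tibble::tibble(
    protein_id = c("P1", "P1", "P2", "P2", "P3"),
    residue = "K", position = 1:5, modification = "m",
    fc = 1, cv = 0, n_ratio_pairs = 2L,
    direction = c("down", "down", "up", "down", "ns")
  )
  agg <- aggregate_sites_to_proteins(calls)
  p1 <- agg[agg$protein_id == "P1", ]
  expect_true(p1$protein_direction_down && !p1$protein_direction_up)
  p2 <- agg[agg$protein_id == "P2", ]
  expect_true(p2$protein_direction_down && p2$protein_direction_up)

  # property: protein counts per direction never exceed site counts
  set.seed(10)
  for (i in 1:20) {
    rc <- tibble::tibble(
      protein_id = sample(paste0("P", 1:5), 12, replace = TRUE),
      residue = "K", position = 1:12, modification = "m",
      fc = 1, cv = 0, n_ratio_pairs = 2L,
      direction = sample(c("up", "down", "ns"), 12, replace = TRUE)
    )
    a <- aggregate_sites_to_proteins(rc)
    expect_lte(sum(a$protein_direction_up), sum(rc$direction == "up"))
    expect_lte(sum(a$protein_direction_down), sum(rc$direction == "down"))
  }
})
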
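#' Preprocess a metabolite table for OPLS-DA
#'
#' Selects the samples of a two-group contrast, imputes missing peak areas
#' with half the metabolite's minimum observed area (a detection-floor
#' surrogate), log2-transforms, and mean-centers each metabolite column.
#' No unit-variance scaling is applied. The class vector encodes the
#' numerator group as +1 and the denominator group as -1.
#'
#' @param table a metabolite tibble (see [read_metabolite_table()]).
#' @param sheet the sample sheet.
#' @param contrast `c(numerator_group, denominator_group)`.
#' @return a list with `X` (samples x metabolites, log2, centered), `y`
#'   (+1/-1), `sample_id`, `metabolite_id`, `groups`.
#' @export
preprocess_metabolites <- function(table, sheet, contrast) {
  g <- contrast_groups(contrast)
  a <- intersect(sample_cols(table), group_samples(sheet, g[1]))
  b <- intersect(sample_cols(table), group_samples(sheet, g[2]))
  if (length(a) < 2 || length(b) < 2) {
    config_error("each group needs at least 2 samples for OPLS-DA")
  }
  samples <- c(a, b)
  m <- intensity_matrix(table, samples)
  rownames(m) <- table$metabolite_id

  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing)) {
    inform(sprintf(
      "dropping %d metabolite(s) with no observed area", sum(all_missing)
    ))
    m <- m[!all_missing, , drop = FALSE]
  }
  # floor imputation: half the minimum observed area of the metabolite
  if (anyNA(m)) {
    floor_val <- apply(m, 1, min, na.rm = TRUE) / 2
    miss <- which(is.na(m), arr.ind = TRUE)
    m[miss] <- floor_val[miss[, 1]]
  }
  if (any(m <= 0)) {
    config_error("peak areas must be positive for the log2 transform")
  }

  X <- t(log2(m))
  X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  y <- c(rep(1, length(a)), rep(-1, length(b)))
  list(
    X = X, y = y, sample_id = samples,
    metabolite_id = rownames(m), groups = g
  )
}

norm2 <- function(v) sqrt(sum(v^2))

#' Fit an OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis for a two-class
#' response. The algorithm iteratively extracts `k_ortho` components of X
#' variation orthogonal to (uncorrelated with) the class vector, deflates
#' them from X, then fits a single predictive PLS component on the deflated
#' matrix. With `k_ortho = 0` the model reduces to single-component PLS with
#' weight vector proportional to X'y. The fit is deterministic; there is no
#' random initialization.
#'
#' @param X numeric matrix, samples x variables (will be column-centered if
#'   it is not already).
#' @param y two-class response; any two distinct values (internally centered).
#' @param k_ortho number of orthogonal components to extract (>= 0).
#' @return an object of class `opls_model` with predictive scores `t`,
#'   weights `w` (unit norm), loadings `p`, regression coefficient `c_coef`,
#'   orthogonal component matrices `t_ortho`/`w_ortho`/`p_ortho`, and fit
#'   statistics `R2X`, `R2Y`.
#' @export
fit_opls_da <- function(X, y, k_ortho = 1) {
  X <- as.matrix(X)
  if (length(unique(y)) != 2) config_error("y must have exactly two classes")
  if (nrow(X) != length(y)) config_error("nrow(X) must equal length(y)")
  if (k_ortho < 0) config_error("k_ortho must be >= 0")

  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  if (all(abs(Xc) < .Machine$double.eps * 100)) {
    config_error("X has zero variance")
  }
  y_num <- as.numeric(y)
  y_mean <- mean(y_num)
  yc <- y_num - y_mean
  ssx_total <- sum(Xc^2)
  ssy_total <- sum(yc^2)

  Xd <- Xc
  w_ortho <- p_ortho <- t_ortho <- NULL
  ssx_ortho <- 0
  for (a in seq_len(k_ortho)) {
    w <- drop(crossprod(Xd, yc))
    nw <- norm2(w)
    if (nw < 1e-12) break
    w <- w / nw
    t_pred <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
    wo <- p - sum(w * p) * w
    nwo <- norm2(wo)
    if (nwo < 1e-10) break  # no y-orthogonal variation left
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    w_ortho <- cbind(w_ortho, wo)
    p_ortho <- cbind(p_ortho, po)
    t_ortho <- cbind(t_ortho, to)
    ssx_ortho <- ssx_ortho + sum(to^2) * sum(po^2)
  }

  w <- drop(crossprod(Xd, yc))
  nw <- norm2(w)
  if (nw < 1e-12) config_error("X carries no covariance with y")
  w <- w / nw
  t_pred <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
  c_coef <- sum(yc * t_pred) / sum(t_pred^2)

  r2y <- 1 - sum((yc - c_coef * t_pred)^2) / ssy_total
  r2x <- (sum(t_pred^2) * sum(p^2) + ssx_ortho) / ssx_total

  structure(
    list(
      t = t_pred, w = w, p = p, c_coef = c_coef, y = y_num,
      t_ortho = t_ortho, w_ortho = w_ortho, p_ortho = p_ortho,
      k_ortho = if (is.null(t_ortho)) 0L else ncol(t_ortho),
      R2X = r2x, R2Y = r2y,
      x_center = x_center, y_mean = y_mean,
      variables = colnames(X) %||% paste0("V", seq_len(ncol(X)))
    ),
    class = "opls_model"
  )
}

#' Predict scores and response for new samples
#'
#' Centers new rows with the training column means, strips the fitted
#' orthogonal components, and projects onto the predictive weight vector.
#'
#' @param object an `opls_model`.
#' @param newdata matrix of new samples (same variables as training).
#' @param ... unused.
#' @return a list with `t` (predictive scores) and `y_hat`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- sweep(as.matrix(newdata), 2, object$x_center)
  if (object$k_ortho > 0) {
    for (a in seq_len(object$k_ortho)) {
      to <- drop(Xn %*% object$w_ortho[, a])
      Xn <- Xn - tcrossprod(to, object$p_ortho[, a])
    }
  }
  t_new <- drop(Xn %*% object$w)
  list(t = t_new, y_hat = object$y_mean + object$c_coef * t_new)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> 1 predictive + %d orthogonal component(s); R2X = %.3f, R2Y = %.3f\n",
    x$k_ortho, x$R2X, x$R2Y
  ))
  invisible(x)
}

#' VIP scores of a fitted OPLS-DA model
#'
#' Variable importance in projection, computed from the predictive component
#' only (orthogonal components are y-uncorrelated by construction). With a
#' single predictive component and a unit-norm weight vector the score
#' reduces to `sqrt(p) * |w_j|` where p is the number of variables, so the
#' squared scores always average to exactly 1.
#'
#' @param model an `opls_model`.
#' @return a tibble with `variable` and `vip`.
#' @export
vip_scores <- function(model) {
  p_vars <- length(model$w)
  tibble(
    variable = model$variables,
    vip = sqrt(p_vars) * abs(unname(model$w))
  )
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Q2 = 1 - PRESS/TSS over class-stratified folds: each fold is held out,
#' the model is refit on the remainder, and held-out responses are
#' predicted. Fold assignment is deterministic given `seed`. The fold count
#' is capped at the smaller class size so every training set keeps both
#' classes.
#'
#' @inheritParams fit_opls_da
#' @param n_folds requested number of folds (default 7).
#' @param seed integer seed controlling fold assignment.
#' @return Q2 (a scalar, at most 1; negative when held-out prediction is
#'   worse than the class mean).
#' @export
q2_cross_validation <- function(X, y, k_ortho = 1, n_folds = 7,
                                seed = 20221124) {
  X <- as.matrix(X)
  y_num <- as.numeric(y)
  classes <- unique(y_num)
  if (length(classes) != 2) config_error("y must have exactly two classes")
  min_class <- min(table(y_num))
  if (min_class < 2) config_error("each class needs >= 2 samples")
  n_folds <- max(2L, min(n_folds, min_class))

  fold <- integer(length(y_num))
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(y_num == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })

  yc_all <- y_num - mean(y_num)
  tss <- sum(yc_all^2)
  press <- 0
  for (f in seq_len(n_folds)) {
    test <- fold == f
    # a degenerate training fold (no X-y covariance) predicts the class mean
    y_hat <- tryCatch({
      fit <- fit_opls_da(X[!test, , drop = FALSE], y_num[!test], k_ortho)
      predict(fit, X[test, , drop = FALSE])$y_hat
    }, ptmlipidr_config_error = function(e) rep(mean(y_num[!test]), sum(test)))
    press <- press + sum((y_num[test] - y_hat)^2)
  }
  1 - press / tss
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model `n_perm` times with the class labels permuted uniformly
#' at random and records R2Y and Q2 for every permutation. The p-value uses
#' the add-one rule p = (1 + #\{permuted >= observed\}) / (1 + n_perm), so the
#' smallest attainable p with 200 permutations is 1/201.
#'
#' @inheritParams q2_cross_validation
#' @param n_perm number of permutations (default 200).
#' @return an object of class `opls_permutation` with observed and permuted
#'   R2Y/Q2 and the two p-values.
#' @export
permutation_test <- function(X, y, k_ortho = 1, n_perm = 200,
                             seed = 20221124, n_folds = 7) {
  if (n_perm < 1) config_error("n_perm must be >= 1")
  X <- as.matrix(X)
  y_num <- as.numeric(y)

  obs_fit <- fit_opls_da(X, y_num, k_ortho)
  obs_q2 <- q2_cross_validation(X, y_num, k_ortho, n_folds, seed = seed)

  perm_q2 <- perm_r2y <- numeric(n_perm)
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      yp <- sample(y_num)
      # a permutation with no X-y covariance explains nothing
      perm_r2y[i] <- tryCatch(
        fit_opls_da(X, yp, k_ortho)$R2Y,
        ptmlipidr_config_error = function(e) 0
      )
      perm_q2[i] <- q2_cross_validation(
        X, yp, k_ortho, n_folds, seed = seed + i
      )
    }
  })

  structure(
    list(
      observed_q2 = obs_q2, observed_r2y = obs_fit$R2Y,
      permuted_q2 = perm_q2, permuted_r2y = perm_r2y,
      p_value_q2 = (1 + sum(perm_q2 >= obs_q2)) / (1 + n_perm),
      p_value_r2y = (1 + sum(perm_r2y >= obs_fit$R2Y)) / (1 + n_perm),
      n_perm = n_perm
    ),
    class = "opls_permutation"
  )
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf(
    "<opls_permutation> %d permutations\n  R2Y = %.3f (p = %.4g)\n  Q2  = %.3f (p = %.4g)\n",
    x$n_perm, x$observed_r2y, x$p_value_r2y, x$observed_q2, x$p_value_q2
  ))
  invisible(x)
}

#' Fit OPLS-DA directly from a metabolite table
#'
#' Convenience wrapper: [preprocess_metabolites()] then [fit_opls_da()],
#' carrying metabolite ids into the fitted model so [vip_scores()] and
#' [tidy()] report them.
#'
#' @inheritParams preprocess_metabolites
#' @inheritParams fit_opls_da
#' @return an `opls_model`.
#' @export
opls_da <- function(table, sheet, contrast, k_ortho = 1) {
  prep <- preprocess_metabolites(table, sheet, contrast)
  fit <- fit_opls_da(prep$X, prep$y, k_ortho)
  fit$variables <- prep$metabolite_id
  fit$sample_id <- prep$sample_id
  fit$groups <- prep$groups
  fit
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-variable summary of an OPLS-DA fit
#'
#' @param x an `opls_model`.
#' @param ... unused.
#' @return tibble with `variable`, predictive `weight`, `loading`, `vip`.
#' @exportS3Method generics::tidy
tidy.opls_model <- function(x, ...) {
  tibble(
    variable = x$variables,
    weight = unname(x$w),
    loading = unname(x$p),
    vip = sqrt(length(x$w)) * abs(unname(x$w))
  )
}

#' One-row fit summary of an OPLS-DA model
#'
#' @param x an `opls_model`.
#' @param ... unused.
#' @return tibble with `R2X`, `R2Y`, `k_ortho`.
#' @exportS3Method generics::glance
glance.opls_model <- function(x, ...) {
  tibble(R2X = x$R2X, R2Y = x$R2Y, k_ortho = x$k_ortho)
}

#' Score plot of an OPLS-DA model
#'
#' Predictive score against the first orthogonal score (or sample index when
#' no orthogonal component was fitted).
#'
#' @param object an `opls_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.opls_model <- function(object, ...) {
  df <- tibble(
    t_pred = object$t,
    t_ortho = if (object$k_ortho > 0) {
      object$t_ortho[, 1]
    } else {
      seq_along(object$t)
    },
    group = if (!is.null(object$groups)) {
      ifelse(object$y > object$y_mean, object$groups[1], object$groups[2])
    } else {
      factor(object$y)
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$t_pred, y = .data$t_ortho, colour = .data$group
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "predictive score t[1]",
      y = if (object$k_ortho > 0) "orthogonal score to[1]" else "sample index"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
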
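#' Orthogonal PLS discriminant analysis (OPLS-DA)
#'
#' Two-class OPLS-DA by the NIPALS orthogonal-deflation scheme: the class
#' vector is encoded 0/1 and centred, Y-orthogonal components are
#' estimated and stripped from X one at a time, and a single predictive
#' component is fitted to the deflated matrix. Reported statistics are
#' R2X (fraction of X sum of squares captured by all components), R2Y
#' (`1 - RSS/TSS` on the centred class vector) and the cross-validated
#' Q2 (`1 - PRESS/TSS`, stratified folds).
#'
#' With `n_orth = "auto"` orthogonal components are added while the
#' cross-validated Q2 improves by more than 0.01, the usual stopping rule
#' for this model family.
#'
#' @param x A `scaled_matrix` from [pareto_scale()] (QC samples already
#'   excluded), or a centred numeric matrix (samples x features).
#' @param y Class labels, exactly two distinct values, each with at least
#'   two samples; aligned with the rows of `x`.
#' @param n_orth Number of Y-orthogonal components, or `"auto"`.
#' @param cv_folds Cross-validation folds (default 7, capped at n).
#' @param seed Seed for the fold shuffle.
#' @return An `opls_model` with elements `w` (predictive weights, unit
#'   norm), `t_pred`, `p_pred`, `c` (Y loading), `t_orth`, `p_orth`,
#'   `w_orth`, `r2x`, `r2y`, `q2`, `n_orth`, the class encoding and
#'   feature ids.
#' @export
fit_oplsda <- function(x, y, n_orth = "auto", cv_folds = 7, seed = 1) {
  sm <- as_scaled(x)
  X <- sm$values
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    abort(sprintf("OPLS-DA needs exactly two classes, got %d",
                  length(classes)))
  }
  if (any(table(y) < 2)) abort("each class needs at least 2 samples")
  if (length(y) != nrow(X)) abort("y length must match the sample count")
  y01 <- as.numeric(y == classes[2])
  yc <- y01 - mean(y01)
  kmax <- min(nrow(X) - 2, ncol(X) - 1)
  if (identical(n_orth, "auto")) {
    q2 <- opls_cv_q2(X, y01, 0, cv_folds, seed)
    k <- 0
    while (k < kmax) {
      q2_next <- opls_cv_q2(X, y01, k + 1, cv_folds, seed)
      if (q2_next > q2 + 0.01) { k <- k + 1; q2 <- q2_next } else break
    }
    n_orth <- k
  } else {
    if (n_orth > kmax) {
      abort(sprintf("n_orth = %d exceeds what %d samples x %d features allow",
                    n_orth, nrow(X), ncol(X)))
    }
    q2 <- opls_cv_q2(X, y01, n_orth, cv_folds, seed)
  }
  core <- opls_core(X, yc, n_orth)
  rss <- sum((yc - core$fitted)^2)
  tss <- sum(yc^2)
  r2y <- 1 - rss / tss
  ss_pred <- sum((core$t_pred %*% t(core$p_pred))^2)
  ss_orth <- if (n_orth > 0)
    sum((core$t_orth %*% t(core$p_orth))^2) else 0
  structure(list(w = drop(core$w), t_pred = drop(core$t_pred),
                 p_pred = drop(core$p_pred), c = core$c,
                 t_orth = core$t_orth, p_orth = core$p_orth,
                 w_orth = core$w_orth,
                 r2x = (ss_pred + ss_orth) / sum(X^2),
                 r2y = r2y, q2 = q2, n_orth = n_orth,
                 classes = classes, y01 = y01,
                 feature_id = sm$feature_id, samples = sm$samples),
            class = "opls_model")
}

## Trygg-Wold O-PLS for a single centred response. X must be centred.
opls_core <- function(X, yc, n_orth) {
  p <- ncol(X)
  W_o <- matrix(0, p, 0); P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- X
  w <- drop(crossprod(Xd, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) abort("X carries no covariance with the class vector")
  w <- w / nw
  for (a in seq_len(n_orth)) {
    t <- drop(Xd %*% w)
    pl <- drop(crossprod(Xd, t)) / sum(t^2)
    w_o <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-12) break  # no Y-orthogonal variation left
    w_o <- w_o / nwo
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    # weights re-estimated on the deflated matrix
    w <- drop(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
  }
  t <- drop(Xd %*% w)
  pl <- drop(crossprod(Xd, t)) / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  list(w = w, t_pred = cbind(t), p_pred = cbind(pl), c = cc,
       w_orth = W_o, p_orth = P_o, t_orth = T_o,
       fitted = cc * t)
}

## Project new (centred) rows through a fitted core: strip orthogonal
## components, then score on the predictive weights.
opls_predict_score <- function(core, Xnew) {
  if (ncol(core$w_orth) > 0) {
    for (a in seq_len(ncol(core$w_orth))) {
      t_o <- drop(Xnew %*% core$w_orth[, a])
      Xnew <- Xnew - tcrossprod(t_o, core$p_orth[, a])
    }
  }
  drop(Xnew %*% core$w)
}

## Deterministic stratified fold assignment: seeded shuffle within each
## stratum, then round-robin.
make_folds <- function(strata, k, seed) {
  folds <- integer(length(strata))
  set.seed(seed)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

opls_cv_q2 <- function(X, y01, n_orth, cv_folds, seed) {
  n <- nrow(X)
  k <- min(cv_folds, n)
  folds <- make_folds(y01, k, seed)
  press <- 0
  for (f in sort(unique(folds))) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y01[!test]
    if (length(unique(ytr)) < 2) next
    mtr <- mean(ytr)
    core <- opls_core(sweep(Xtr, 2, colMeans(Xtr), "-"), ytr - mtr,
                      min(n_orth, nrow(Xtr) - 2))
    Xte <- sweep(X[test, , drop = FALSE], 2, colMeans(Xtr), "-")
    t_new <- opls_predict_score(core, Xte)
    press <- press + sum((y01[test] - (core$c * t_new + mtr))^2)
  }
  1 - press / sum((y01 - mean(y01))^2)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "# OPLS-DA (%s vs %s): 1 predictive + %d orthogonal component(s)\n",
    x$classes[1], x$classes[2], x$n_orth))
  cat(sprintf("# R2X = %.4f  R2Y = %.4f  Q2 = %.4f\n", x$r2x, x$r2y, x$q2))
  invisible(x)
}

#' @rdname fit_oplsda
#' @param x,object An `opls_model`.
#' @param ... Unused.
#' @export
tidy.opls_model <- function(x, ...) {
  tibble::tibble(feature_id = x$feature_id, weight = x$w,
                 loading = drop(x$p_pred), vip = vip_scores(x)$vip)
}

#' @rdname fit_oplsda
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(r2x = x$r2x, r2y = x$r2y, q2 = x$q2, n_orth = x$n_orth,
                 n_samples = length(x$y01), n_features = length(x$w))
}

#' @rdname fit_oplsda
#' @export
autoplot.opls_model <- function(object, ...) {
  df <- tibble::tibble(
    t_pred = object$t_pred,
    t_orth = if (object$n_orth > 0) object$t_orth[, 1]
             else seq_along(object$t_pred),
    class = object$classes[object$y01 + 1])
  ggplot2::ggplot(df, ggplot2::aes(.data$t_pred, .data$t_orth,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "predictive score t[1]",
                  y = if (object$n_orth > 0) "orthogonal score t[o1]"
                      else "sample index")
}

#' Variable importance in projection (VIP)
#'
#' Per-feature influence in a fitted OPLS-DA model, computed on the
#' predictive component (orthogonal components explain no Y by
#' construction, so they receive zero weight in the explained-Y sum).
#' With a single predictive component this reduces to
#' `VIP_j = sqrt(p) * |w_j|`, and the mean of `VIP^2` over features is
#' exactly 1.
#'
#' @param m An `opls_model`.
#' @return Tibble with `feature_id` and `vip` (>= 0).
#' @export
vip_scores <- function(m) {
  p <- length(m$w)
  tibble::tibble(feature_id = m$feature_id, vip = sqrt(p) * abs(m$w))
}

#' S-plot covariance and correlation table
#'
#' For each (scaled) feature, its covariance and correlation with the
#' predictive score vector. Features at the extremes of both axes drive
#' the class separation. Zero-variance features get `p_corr = 0` and are
#' flagged.
#'
#' @param m An `opls_model`.
#' @param x The `scaled_matrix` (or centred matrix) the model was fitted
#'   on.
#' @return Tibble with `feature_id`, `p_cov`, `p_corr`,
#'   `zero_variance`.
#' @export
s_plot <- function(m, x) {
  sm <- as_scaled(x)
  X <- sm$values
  t <- m$t_pred
  p_cov <- drop(crossprod(X, t - mean(t))) / (nrow(X) - 1)
  sds <- apply(X, 2, sd)
  zero <- sds == 0
  p_corr <- ifelse(zero, 0, p_cov / (sds * sd(t)))
  tibble::tibble(feature_id = sm$feature_id, p_cov = p_cov,
                 p_corr = p_corr, zero_variance = zero)
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model `n_perm` times with the class labels randomly
#' permuted (X fixed), recording R2Y and Q2 each time. The permutation
#' p-value for Q2 is `(#{permuted Q2 >= observed Q2} + 1) / (n_perm + 1)`.
#' A valid model has an observed Q2 well above the permuted distribution.
#'
#' @inheritParams fit_oplsda
#' @param n_perm Number of label permutations (default 200).
#' @return An `opls_permutation`: `observed_r2y`, `observed_q2`,
#'   `permuted_r2y`, `permuted_q2` (length `n_perm`), `p_q2`, `n_perm`.
#' @export
permutation_test <- function(x, y, n_orth = "auto", cv_folds = 7,
                             n_perm = 200, seed = 1) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  obs <- fit_oplsda(x, y, n_orth = n_orth, cv_folds = cv_folds, seed = seed)
  sm <- as_scaled(x)
  y <- as.character(y)
  # draw all label permutations up front: the fitting path seeds the
  # fold shuffle internally and must not disturb the permutation stream
  set.seed(seed)
  perms <- lapply(seq_len(n_perm), function(i) sample.int(length(y)))
  perm_r2y <- perm_q2 <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    yp <- y[perms[[i]]]
    fit <- tryCatch(
      fit_oplsda(sm, yp, n_orth = obs$n_orth, cv_folds = cv_folds,
                 seed = seed),
      error = function(e) NULL)
    if (is.null(fit)) { perm_r2y[i] <- NA; perm_q2[i] <- -Inf; next }
    perm_r2y[i] <- fit$r2y
    perm_q2[i] <- fit$q2
  }
  structure(list(observed_r2y = obs$r2y, observed_q2 = obs$q2,
                 permuted_r2y = perm_r2y, permuted_q2 = perm_q2,
                 p_q2 = (sum(perm_q2 >= obs$q2) + 1) / (n_perm + 1),
                 n_perm = n_perm),
            class = "opls_permutation")
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf("# Permutation validation (n = %d)\n", x$n_perm))
  cat(sprintf("# observed R2Y = %.4f  Q2 = %.4f; permuted Q2 max = %.4f\n",
              x$observed_r2y, x$observed_q2, max(x$permuted_q2)))
  cat(sprintf("# p(Q2) = %.4g\n", x$p_q2))
  invisible(x)
}

#' @rdname permutation_test
#' @param x,object An `opls_permutation`.
#' @param ... Unused.
#' @export
tidy.opls_permutation <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm),
                 r2y = x$permuted_r2y, q2 = x$permuted_q2)
}

#' @rdname permutation_test
#' @export
autoplot.opls_permutation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$q2)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_q2,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "permuted Q2",
                  title = sprintf("observed Q2 = %.3f, p = %.3g",
                                  object$observed_q2, object$p_q2))
}
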
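#' Principal component analysis of a scaled feature matrix
#'
#' PCA by singular value decomposition of the (already centred) sample x
#' feature matrix. In `"auto"` mode the number of components is chosen by
#' cross-validation: samples are split into folds, each fold is
#' reconstructed from loadings fitted without it, and components are kept
#' while the cumulative cross-validated Q2 keeps improving.
#'
#' @param x A `scaled_matrix` from [pareto_scale()], or a numeric matrix
#'   (samples x features) which is then centred.
#' @param n_components Number of components, or `"auto"` (default).
#' @param cv_folds Folds for the auto rule. Default 7 (capped at the
#'   number of samples).
#' @param seed Seed for the fold shuffle in auto mode.
#' @return A `pca_model`: scores (samples x k), loadings (features x k),
#'   `r2x_per_component`, `r2x_cum`, singular values, and the sample
#'   metadata when available.
#' @export
fit_pca <- function(x, n_components = "auto", cv_folds = 7, seed = 1) {
  sm <- as_scaled(x)
  X <- sm$values
  n <- nrow(X); p <- ncol(X)
  if (n < 2) abort("PCA needs at least 2 samples")
  kmax <- min(n - 1, p)
  if (!identical(n_components, "auto")) {
    if (n_components > kmax) {
      abort(sprintf("n_components = %d exceeds min(samples - 1, features) = %d",
                    n_components, kmax))
    }
    k <- n_components
  } else {
    k <- pca_auto_k(X, kmax, cv_folds, seed)
  }
  dec <- svd(X, nu = k, nv = k)
  total_ss <- sum(X^2)
  r2x <- dec$d[seq_len(k)]^2 / total_ss
  scores <- dec$u %*% diag(dec$d[seq_len(k)], k, k)
  loadings <- dec$v
  rownames(loadings) <- sm$feature_id
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 r2x_per_component = r2x, r2x_cum = sum(r2x),
                 singular_values = dec$d[seq_len(k)],
                 n_components = k, samples = sm$samples),
            class = "pca_model")
}

as_scaled <- function(x) {
  if (inherits(x, "scaled_matrix")) return(x)
  if (is.list(x) && !is.null(x$values)) return(x)  # already prepared
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x), "-")
  list(values = xc, samples = NULL,
       feature_id = colnames(x) %||% paste0("V", seq_len(ncol(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Cross-validated component count. Loadings are fitted without the
## held-out rows; each held-out entry x_ij is then predicted from the
## other variables of its own row, so the entry never takes part in its
## own prediction: with V_k the training loadings and h_j the leverage
## ||row_j(V_k)||^2, the leave-one-variable-out projection gives
## xhat_ij = (recon_ij - x_ij h_j) / (1 - h_j). Components are kept
## while the cross-validated Q2 improves.
pca_auto_k <- function(X, kmax, cv_folds, seed) {
  n <- nrow(X)
  folds <- make_folds(rep(1, n), min(cv_folds, n), seed)
  press <- numeric(kmax)
  for (f in unique(folds)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    km <- min(kmax, nrow(Xtr) - 1, ncol(Xtr))
    V <- svd(Xtr, nu = 0, nv = km)$v
    for (k in seq_len(kmax)) {
      kk <- min(k, km)
      Vk <- V[, seq_len(kk), drop = FALSE]
      h <- pmin(rowSums(Vk^2), 1 - 1e-9)
      recon <- Xte %*% Vk %*% t(Vk)
      xhat <- sweep(recon - sweep(Xte, 2, h, "*"), 2, 1 - h, "/")
      press[k] <- press[k] + sum((Xte - xhat)^2)
    }
  }
  q2 <- 1 - press / sum(X^2)
  k <- 1
  while (k < kmax && q2[k + 1] > q2[k] + 0.01) k <- k + 1
  k
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("# PCA: %d components, cumulative R2X = %.3f\n",
              x$n_components, x$r2x_cum))
  cat("# per-component R2X: ",
      paste(sprintf("%.3f", x$r2x_per_component), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_pca
#' @param object,x A `pca_model`.
#' @param matrix Which quantity to tidy: `"scores"`, `"loadings"` or
#'   `"r2x"`.
#' @param ... Unused.
#' @export
tidy.pca_model <- function(x, matrix = c("scores", "loadings", "r2x"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "r2x") {
    return(tibble::tibble(component = seq_along(x$r2x_per_component),
                          r2x = x$r2x_per_component,
                          r2x_cum = cumsum(x$r2x_per_component)))
  }
  m <- x[[matrix]]
  id_col <- if (matrix == "scores") "sample_id" else "feature_id"
  ids <- rownames(m) %||%
    (if (matrix == "scores" && !is.null(x$samples)) x$samples$sample_id
     else as.character(seq_len(nrow(m))))
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := ids),
                          tibble::as_tibble(m))
  if (matrix == "scores" && !is.null(x$samples)) {
    out$group <- x$samples$group
  }
  out
}

#' @rdname fit_pca
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, r2x_cum = x$r2x_cum)
}

#' @rdname fit_pca
#' @export
autoplot.pca_model <- function(object, ...) {
  df <- tibble::tibble(PC1 = object$scores[, 1],
                       PC2 = if (object$n_components >= 2)
                         object$scores[, 2] else 0)
  if (!is.null(object$samples)) df$group <- object$samples$group
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$r2x_per_component[1]),
      y = if (object$n_components >= 2)
        sprintf("PC2 (%.1f%%)", 100 * object$r2x_per_component[2]) else "")
  if (!is.null(object$samples)) {
    gg + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    gg + ggplot2::geom_point(size = 2)
  }
}
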
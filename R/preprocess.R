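#' Impute missing intensities
#'
#' Aligned LC-MS tables routinely contain missing peaks. Three rules are
#' supported: `half_min` replaces missing values of a feature with half
#' the feature's observed minimum (the usual limit-of-detection
#' convention), `zero` sets them to 0, and `drop_feature` removes any
#' feature with a missing value.
#'
#' @param ft A [feature_table()].
#' @param rule One of `"half_min"`, `"zero"`, `"drop_feature"`.
#' @return A [feature_table()] with no missing intensities. Features
#'   dropped (by `drop_feature`, or by `half_min` when a feature is
#'   entirely missing) are recorded in attribute `dropped_features`.
#' @export
impute_missing <- function(ft, rule = c("half_min", "zero", "drop_feature")) {
  rule <- match.arg(rule)
  m <- intensity_matrix(ft)
  dropped <- character()
  if (rule == "zero") {
    m[is.na(m)] <- 0
  } else if (rule == "drop_feature") {
    keep <- !apply(is.na(m), 1, any)
    dropped <- rownames(m)[!keep]
    ft <- ft[keep, , drop = FALSE]
    m <- m[keep, , drop = FALSE]
  } else {
    all_na <- apply(is.na(m), 1, all)
    if (any(all_na)) {
      dropped <- rownames(m)[all_na]
      warn(paste0("features entirely missing dropped under half_min: ",
                  paste(dropped, collapse = ", ")))
      ft <- ft[!all_na, , drop = FALSE]
      m <- m[!all_na, , drop = FALSE]
    }
    for (i in seq_len(nrow(m))) {
      na <- is.na(m[i, ])
      if (any(na)) m[i, na] <- min(m[i, !na]) / 2
    }
  }
  out <- set_intensities(new_feature_table(ft, sample_info(ft)), m)
  attr(out, "dropped_features") <- dropped
  out
}

#' Filter features by QC relative standard deviation
#'
#' Pooled QC injections monitor system consistency; features whose
#' relative standard deviation (RSD = SD / mean, as a percentage) across
#' the QC samples exceeds `max_rsd_pct` are considered unstable and
#' removed. With fewer than two QC samples the table is returned
#' unchanged with a warning. The filter is idempotent.
#'
#' @param ft A [feature_table()].
#' @param max_rsd_pct Maximum tolerated QC RSD, percent. Default 30.
#' @return A filtered [feature_table()]; removed feature ids are recorded
#'   in attribute `qc_removed`.
#' @export
qc_rsd_filter <- function(ft, max_rsd_pct = 30) {
  s <- sample_info(ft)
  if (sum(s$is_qc) < 2) {
    warn("fewer than 2 QC samples: QC RSD filter skipped")
    attr(ft, "qc_removed") <- character()
    return(ft)
  }
  m <- intensity_matrix(ft)[, s$sample_id[s$is_qc], drop = FALSE]
  rsd <- 100 * apply(m, 1, sd) / rowMeans(m)
  rsd[is.nan(rsd)] <- 0  # all-zero QC feature: no evidence of instability
  keep <- rsd <= max_rsd_pct
  out <- new_feature_table(ft[keep, , drop = FALSE], s)
  attr(out, "qc_removed") <- ft$feature_id[!keep]
  out
}

#' Scale a feature table for multivariate modelling
#'
#' Pareto scaling mean-centres each feature and divides by the square
#' root of its sample standard deviation (`n - 1` denominator) — the
#' compromise between plain centring and unit-variance scaling that is
#' standard for LC-MS intensity data, damping the dominance of abundant
#' ions without inflating noise. Unit-variance and centre-only variants
#' are available. QC samples are excluded. Constant features are mapped
#' to all-zeros and flagged rather than producing division by zero.
#'
#' @param ft A [feature_table()].
#' @param method `"pareto"` (default), `"unit_variance"` or
#'   `"center_only"`.
#' @return A `scaled_matrix`: list with `values` (samples x features
#'   matrix), `feature_means`, `feature_sds`, `scaling`, logical
#'   `zero_variance`, and the non-QC `samples` tibble.
#' @export
pareto_scale <- function(ft, method = c("pareto", "unit_variance",
                                        "center_only")) {
  method <- match.arg(method)
  s <- sample_info(ft)
  s <- s[!s$is_qc, , drop = FALSE]
  if (nrow(s) < 2) abort("scaling needs at least 2 non-QC samples")
  x <- t(intensity_matrix(ft, qc = FALSE))  # samples x features
  if (anyNA(x)) abort("impute missing values before scaling")
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  zero_var <- sds == 0
  div <- switch(method,
                pareto = sqrt(sds),
                unit_variance = sds,
                center_only = rep(1, length(sds)))
  div[zero_var & method != "center_only"] <- 1
  values <- sweep(sweep(x, 2, mu, "-"), 2, div, "/")
  values[, zero_var] <- 0
  structure(list(values = values, feature_means = mu, feature_sds = sds,
                 scaling = method, zero_variance = zero_var, samples = s,
                 feature_id = ft$feature_id),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("# A scaled_matrix (%s): %d samples x %d features, %d constant\n",
              x$scaling, nrow(x$values), ncol(x$values),
              sum(x$zero_variance)))
  invisible(x)
}
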
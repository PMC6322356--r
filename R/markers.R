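#' Screen differential features by VIP and t-test
#'
#' A feature is a potential marker when its VIP from the control-vs-model
#' OPLS-DA exceeds `vip_min` (strict) and its two-sided Welch t-test
#' p-value on the raw intensities is below `alpha` (strict). Fold change
#' is the ratio of the raw model-group mean to the control-group mean;
#' trend is `up` when the fold change exceeds 1, `down` otherwise (a tie
#' at exactly 1 is labelled `down`). A Benjamini-Hochberg adjusted column
#' is reported for transparency but plays no part in selection.
#'
#' @param ft A [feature_table()] containing `control` and `model`
#'   samples.
#' @param vips Tibble with `feature_id` and `vip`, e.g. from
#'   [vip_scores()].
#' @param vip_min VIP threshold (strict `>`). Default 1.5.
#' @param alpha p-value threshold (strict `<`). Default 0.05.
#' @param control,model Group labels. Defaults `"control"` / `"model"`.
#' @return Tibble of selected markers, one row per feature, sorted by
#'   `vip` descending: `feature_id`, `mz`, `rt`, `vip`, `p_value`,
#'   `p_adj`, `fold_change`, `trend`. The full unselected table is
#'   attached as attribute `all_features`.
#' @export
screen_markers <- function(ft, vips, vip_min = 1.5, alpha = 0.05,
                           control = "control", model = "model") {
  s <- sample_info(ft)
  m <- intensity_matrix(ft)
  ctrl_ids <- s$sample_id[s$group == control & !s$is_qc]
  model_ids <- s$sample_id[s$group == model & !s$is_qc]
  if (length(ctrl_ids) < 2 || length(model_ids) < 2) {
    abort("both control and model groups need at least 2 samples")
  }
  pvals <- vapply(seq_len(nrow(m)), function(i) {
    welch_p(m[i, model_ids], m[i, ctrl_ids])
  }, numeric(1))
  mc <- unname(rowMeans(m[, ctrl_ids, drop = FALSE]))
  mm <- unname(rowMeans(m[, model_ids, drop = FALSE]))
  fc <- mm / mc
  full <- tibble::tibble(feature_id = ft$feature_id, mz = ft$mz, rt = ft$rt,
                         p_value = pvals,
                         p_adj = p.adjust(pvals, "BH"),
                         fold_change = fc,
                         trend = ifelse(fc > 1, "up", "down")) |>
    dplyr::left_join(vips[c("feature_id", "vip")], by = "feature_id")
  out <- full |>
    dplyr::filter(.data$vip > vip_min, .data$p_value < alpha) |>
    dplyr::arrange(dplyr::desc(.data$vip)) |>
    dplyr::select("feature_id", "mz", "rt", "vip", "p_value", "p_adj",
                  "fold_change", "trend")
  attr(out, "all_features") <- full
  out
}

## Welch t-test p-value, robust to zero-variance pairs.
welch_p <- function(a, b) {
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  tryCatch(t.test(a, b)$p.value, error = function(e) 1)
}

#' Fold change and trend of a single feature
#'
#' @param ft A [feature_table()].
#' @param feature_id Feature to assess.
#' @param control,model Group labels.
#' @return Tibble with `feature_id`, `fold_change` (mean model / mean
#'   control on raw intensities) and `trend` (`"up"` iff fold change
#'   > 1).
#' @export
fold_change_trend <- function(ft, feature_id, control = "control",
                              model = "model") {
  s <- sample_info(ft)
  m <- intensity_matrix(ft)
  if (!feature_id %in% rownames(m)) {
    abort(paste0("unknown feature: ", feature_id))
  }
  ctrl <- m[feature_id, s$sample_id[s$group == control & !s$is_qc]]
  mod <- m[feature_id, s$sample_id[s$group == model & !s$is_qc]]
  if (!length(ctrl) || !length(mod)) abort("empty group")
  if (mean(ctrl) == 0) abort("control mean is zero; fold change undefined")
  fc <- mean(mod) / mean(ctrl)
  tibble::tibble(feature_id = feature_id, fold_change = fc,
                 trend = ifelse(fc > 1, "up", "down"))
}

#' Treated-group recovery of screened markers
#'
#' For each marker and each treated group, a two-sided Welch t-test of
#' treated vs model raw intensities, flagged `ns` (p >= 0.05), `p05`
#' (0.01 <= p < 0.05) or `p01` (p < 0.01). A significant difference from
#' the model group in the direction of control indicates the treatment
#' pulls the disturbed metabolite back.
#'
#' @param ft A [feature_table()].
#' @param markers Tibble with a `feature_id` column (e.g. from
#'   [screen_markers()]).
#' @param treated Character vector of treated group labels.
#' @param model Model group label.
#' @return Long tibble: `feature_id`, `group`, `p_value`, `flag`.
#' @export
recovery_assessment <- function(ft, markers,
                                treated = c("kansui", "vkansui"),
                                model = "model") {
  s <- sample_info(ft)
  m <- intensity_matrix(ft)
  model_ids <- s$sample_id[s$group == model & !s$is_qc]
  purrr::map_dfr(treated, function(g) {
    g_ids <- s$sample_id[s$group == g & !s$is_qc]
    purrr::map_dfr(markers$feature_id, function(f) {
      p <- welch_p(m[f, g_ids], m[f, model_ids])
      tibble::tibble(feature_id = f, group = g, p_value = p,
                     flag = dplyr::case_when(p < 0.01 ~ "p01",
                                             p < 0.05 ~ "p05",
                                             TRUE ~ "ns"))
    })
  })
}

#' Marker heatmap matrix with clustered orders
#'
#' Z-scores each marker across all non-QC samples and clusters both axes
#' by average-linkage hierarchical clustering on Euclidean distance,
#' giving the matrix behind the usual marker heatmap. Leaf orders are
#' deterministic. Zero-variance markers are set to all-zero rows and
#' flagged.
#'
#' @param ft A [feature_table()].
#' @param markers Tibble with `feature_id` (>= 2 rows).
#' @return A `marker_heatmap`: list with `z` (markers x samples),
#'   `row_order`, `col_order` (leaf orders), `zero_variance` and the
#'   sample metadata.
#' @export
heatmap_matrix <- function(ft, markers) {
  if (nrow(markers) < 2) abort("need at least 2 markers to cluster")
  s <- sample_info(ft)
  s <- s[!s$is_qc, , drop = FALSE]
  m <- intensity_matrix(ft, qc = FALSE)[markers$feature_id, , drop = FALSE]
  sds <- apply(m, 1, sd)
  zero <- sds == 0
  z <- (m - rowMeans(m)) / ifelse(zero, 1, sds)
  z[zero, ] <- 0
  row_hc <- hclust(dist(z), method = "average")
  col_hc <- hclust(dist(t(z)), method = "average")
  structure(list(z = z, row_order = row_hc$order, col_order = col_hc$order,
                 row_hclust = row_hc, col_hclust = col_hc,
                 zero_variance = zero, samples = s),
            class = "marker_heatmap")
}

#' @export
print.marker_heatmap <- function(x, ...) {
  cat(sprintf("# marker heatmap: %d markers x %d samples (%d zero-variance)\n",
              nrow(x$z), ncol(x$z), sum(x$zero_variance)))
  invisible(x)
}

#' @rdname heatmap_matrix
#' @param x,object A `marker_heatmap`.
#' @param ... Unused.
#' @export
tidy.marker_heatmap <- function(x, ...) {
  tibble::as_tibble(x$z, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "z") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' @rdname heatmap_matrix
#' @export
autoplot.marker_heatmap <- function(object, ...) {
  df <- tidy(object)
  df$feature_id <- factor(df$feature_id,
                          levels = rownames(object$z)[object$row_order])
  df$sample_id <- factor(df$sample_id,
                         levels = colnames(object$z)[object$col_order])
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$feature_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
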
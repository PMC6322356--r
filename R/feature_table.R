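#' Construct an aligned LC-MS feature table
#'
#' A `feature_table` is a wide tibble with one row per aligned feature
#' (columns `feature_id`, `mz`, `rt`, then one numeric column per sample)
#' carrying the sample metadata (`sample_id`, `group`, `is_qc`) as an
#' attribute. It is the container every preprocessing step takes first and
#' returns, so steps chain with the pipe.
#'
#' @param features Tibble with columns `feature_id` (unique, character),
#'   `mz` (Thomson, > 0) and `rt` (minutes, >= 0).
#' @param intensities Numeric matrix, features x samples, non-negative or
#'   `NA`; row order matches `features`, column names are sample ids.
#' @param samples Tibble with columns `sample_id` (unique), `group`
#'   (character label, e.g. `"control"`, `"model"`, `"kansui"`,
#'   `"vkansui"`) and logical `is_qc`.
#'
#' @return A `feature_table` tibble.
#' @export
#' @examples
#' ft <- feature_table(
#'   tibble::tibble(feature_id = c("F1", "F2"), mz = c(100.1, 200.2), rt = c(1, 2)),
#'   matrix(1:6, 2, 3, dimnames = list(NULL, c("a", "b", "c"))),
#'   tibble::tibble(sample_id = c("a", "b", "c"),
#'                  group = c("control", "control", "model"),
#'                  is_qc = FALSE)
#' )
feature_table <- function(features, intensities, samples) {
  features <- tibble::as_tibble(features)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("feature_id", "mz", "rt") %in% names(features)),
            all(c("sample_id", "group", "is_qc") %in% names(samples)))
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features) ||
      ncol(intensities) != nrow(samples)) {
    abort(sprintf(
      "intensity matrix is %d x %d but there are %d features and %d samples",
      nrow(intensities), ncol(intensities), nrow(features), nrow(samples)),
      class = "vkmet_format_error")
  }
  if (anyDuplicated(features$feature_id)) {
    dup <- unique(features$feature_id[duplicated(features$feature_id)])
    abort(paste0("duplicate feature ids: ", paste(dup, collapse = ", ")),
          class = "vkmet_format_error")
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    abort(paste0("duplicate sample ids: ", paste(dup, collapse = ", ")),
          class = "vkmet_format_error")
  }
  if (!is.numeric(intensities)) {
    abort("intensities must be numeric", class = "vkmet_format_error")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative", class = "vkmet_format_error")
  }
  if (any(features$mz <= 0) || any(features$rt < 0)) {
    abort("mz must be positive and rt non-negative",
          class = "vkmet_format_error")
  }
  colnames(intensities) <- samples$sample_id
  out <- dplyr::bind_cols(features[c("feature_id", "mz", "rt")],
                          tibble::as_tibble(intensities))
  new_feature_table(out, samples)
}

new_feature_table <- function(tbl, samples) {
  structure(tbl,
            samples = tibble::as_tibble(samples),
            class = c("feature_table", class(tibble::tibble())))
}

#' @export
print.feature_table <- function(x, ...) {
  s <- sample_info(x)
  cat(sprintf("# A feature_table: %d features x %d samples (%d QC)\n",
              nrow(x), nrow(s), sum(s$is_qc)))
  grp <- table(s$group[!s$is_qc])
  cat("# groups: ", paste(names(grp), grp, sep = "=", collapse = ", "), "\n",
      sep = "")
  NextMethod()
}

#' Sample metadata of a feature table
#'
#' @param ft A [feature_table()].
#' @return Tibble with `sample_id`, `group`, `is_qc`.
#' @export
sample_info <- function(ft) {
  s <- attr(ft, "samples")
  if (is.null(s)) abort("not a feature_table (missing sample metadata)")
  s
}

#' Intensity matrix of a feature table
#'
#' @param ft A [feature_table()].
#' @param qc Include QC samples? Default `TRUE`.
#' @return Numeric matrix, features x samples, with feature ids as row
#'   names and sample ids as column names.
#' @export
intensity_matrix <- function(ft, qc = TRUE) {
  s <- sample_info(ft)
  ids <- if (qc) s$sample_id else s$sample_id[!s$is_qc]
  m <- as.matrix(as.data.frame(ft)[, ids, drop = FALSE])
  rownames(m) <- ft$feature_id
  m
}

#' Subset a feature table to selected sample groups
#'
#' @param ft A [feature_table()].
#' @param groups Group labels to keep, or `NULL` for all.
#' @param keep_qc Keep QC samples? Default `FALSE`.
#' @return A [feature_table()] with only the requested samples.
#' @export
subset_samples <- function(ft, groups = NULL, keep_qc = FALSE) {
  s <- sample_info(ft)
  keep <- if (is.null(groups)) rep(TRUE, nrow(s)) else s$group %in% groups
  if (!keep_qc) keep <- keep & !s$is_qc else keep <- keep | s$is_qc
  feature_table(ft[c("feature_id", "mz", "rt")],
                intensity_matrix(ft)[, s$sample_id[keep], drop = FALSE],
                s[keep, , drop = FALSE])
}

## Rebuild a feature_table after row subsetting / intensity replacement.
set_intensities <- function(ft, m) {
  s <- sample_info(ft)
  feature_table(ft[c("feature_id", "mz", "rt")], m, s)
}

#' Read an aligned feature table and its sample metadata
#'
#' The table is a CSV with header `feature_id,mz,rt,<sample_id...>`;
#' metadata is a TSV with columns `sample_id`, `group`, `is_qc`. Missing
#' intensities are encoded as empty fields. The two files must describe
#' exactly the same samples.
#'
#' @param path Path to the feature CSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, metadata_path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(
                            sample_id = readr::col_character(),
                            group = readr::col_character(),
                            is_qc = readr::col_logical()))
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(raw))) {
    abort(paste0("feature CSV must start with columns ",
                 paste(need, collapse = ", ")),
          class = "vkmet_format_error")
  }
  sample_cols <- setdiff(names(raw), need)
  missing_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_meta)) {
    abort(paste0("samples absent from metadata: ",
                 paste(missing_meta, collapse = ", ")),
          class = "vkmet_format_error")
  }
  missing_tbl <- setdiff(meta$sample_id, sample_cols)
  if (length(missing_tbl)) {
    abort(paste0("metadata samples absent from table: ",
                 paste(missing_tbl, collapse = ", ")),
          class = "vkmet_format_error")
  }
  bad <- sample_cols[!vapply(raw[sample_cols], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("non-numeric intensity column(s): ",
                 paste(bad, collapse = ", ")),
          class = "vkmet_format_error")
  }
  m <- as.matrix(raw[, meta$sample_id, drop = FALSE])
  feature_table(raw[need], m, meta)
}

#' Write a feature table and its sample metadata
#'
#' Inverse of [read_feature_table()]; a write -> read round trip
#' reproduces the table to full double precision.
#'
#' @param ft A [feature_table()].
#' @param path,metadata_path Output CSV / TSV paths.
#' @return `ft`, invisibly.
#' @export
write_feature_table <- function(ft, path, metadata_path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(ft)), path)
  readr::write_tsv(sample_info(ft), metadata_path)
  invisible(ft)
}
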
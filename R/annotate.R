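## Monoisotopic atomic masses (Da) for the elements found in common
## endogenous metabolites. Charge carrier is the proton, so electron
## mass needs no separate bookkeeping.
MONO_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, P = 30.97376151, S = 31.97207069)
PROTON_MASS <- 1.00727646
FORMIC_ACID_MASS <- 46.0054793  # CH2O2, monoisotopic

## Built-in ESI adducts: m/z = mass + shift, tagged by polarity.
ADDUCTS <- tibble::tibble(
  adduct = c("M+H", "M-H", "M+FA-H"),
  shift = c(PROTON_MASS, -PROTON_MASS, FORMIC_ACID_MASS - PROTON_MASS),
  mode = c("pos", "neg", "neg"))

#' Parse an elemental formula
#'
#' Accepts Hill-style formulas over C, H, N, O, P, S (e.g. `"C24H40O5"`,
#' `"H2O"`). Counts default to 1 when omitted.
#'
#' @param formula Formula string.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  formula <- gsub("\\s", "", formula)
  counts <- setNames(integer(length(MONO_MASS)), names(MONO_MASS))
  if (!nzchar(formula)) return(counts)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    abort(paste0("cannot parse formula: ", formula),
          class = "vkmet_parse_error")
  }
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[^0-9]", "", tok)
    if (!el %in% names(MONO_MASS)) {
      abort(paste0("unknown element '", el, "' in formula ", formula),
            class = "vkmet_parse_error")
    }
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of monoisotopic atomic masses (C 12 exactly, H 1.0078250319,
#' N 14.0030740052, O 15.9949146221, P 30.97376151, S 31.97207069).
#'
#' @param formula Formula string, or vector of them.
#' @return Mass in Da (vectorised). An empty formula gives 0 with a
#'   warning.
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    if (sum(counts) == 0) warn(paste0("empty formula: '", f, "' -> 0 Da"))
    sum(counts * MONO_MASS)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Theoretical adduct m/z
#'
#' `[M+H]+` adds, `[M-H]-` subtracts, a proton (1.00727646 Da);
#' `[M+FA-H]-` adds formic acid (46.0054793 Da) and removes a proton.
#'
#' @param mass Neutral monoisotopic mass, Da.
#' @param adduct One of `"M+H"`, `"M-H"`, `"M+FA-H"`.
#' @return m/z in Th (vectorised over `mass`).
#' @export
adduct_mz <- function(mass, adduct) {
  i <- match(adduct, ADDUCTS$adduct)
  if (anyNA(i)) {
    abort(paste0("unknown adduct: ",
                 paste(unique(adduct[is.na(i)]), collapse = ", ")))
  }
  mass + ADDUCTS$shift[i]
}

#' Signed mass error in parts per million
#'
#' @param observed,theoretical m/z values in Th; `theoretical` must be
#'   positive.
#' @return `(observed - theoretical) / theoretical * 1e6` (vectorised).
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) abort("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Read a compound library
#'
#' TSV with columns `id`, `name`, `formula`, `adducts`
#' (semicolon-separated subset of `M+H`, `M-H`, `M+FA-H`), `kegg_id` and
#' optional `pathways` (semicolon-separated names).
#'
#' @param path Library TSV path.
#' @return Tibble, one row per compound, `adducts`/`pathways` as
#'   list-columns.
#' @export
read_compound_library <- function(path) {
  lib <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("id", "name", "formula", "adducts", "kegg_id")
                %in% names(lib)))
  lib$adducts <- strsplit(lib$adducts, ";", fixed = TRUE)
  if ("pathways" %in% names(lib)) {
    lib$pathways <- strsplit(lib$pathways, ";", fixed = TRUE)
  }
  tibble::as_tibble(lib)
}

#' The bundled 16-metabolite library
#'
#' Compound library built from the published serum/urine marker table:
#' name, formula, observed adduct, KEGG id and pathway annotations for
#' the 16 identified metabolites.
#'
#' @return A compound-library tibble as from [read_compound_library()].
#' @export
table1_library <- function() {
  t1 <- load_fixture("table1")
  tibble::tibble(id = t1$id, name = t1$name, formula = t1$formula,
                 adducts = as.list(t1$adduct), kegg_id = t1$kegg_id,
                 pathways = strsplit(t1$pathways, ";", fixed = TRUE))
}

#' Annotate features against a compound library by exact mass
#'
#' For every feature, computes the theoretical m/z of each library
#' compound under each of its adducts consistent with the feature's
#' polarity (`pos` -> `M+H`; `neg` -> `M-H`, `M+FA-H`), and keeps pairs
#' whose absolute ppm error is at most `tol_ppm` (features exactly at
#' the tolerance are kept; beyond it, excluded). Isomeric library
#' entries hitting the same feature are returned as co-equal candidate
#' rows. Features with no hit appear once with `NA` annotation columns.
#'
#' @param features Tibble with `feature_id`, `mz` and `mode`
#'   (`"pos"`/`"neg"`).
#' @param library Compound library tibble (see
#'   [read_compound_library()]).
#' @param tol_ppm Mass tolerance, ppm. Default 10.
#' @return Tibble sorted by `|ppm|` within feature: `feature_id`, `mz`,
#'   `mode`, `compound_id`, `name`, `adduct`, `kegg_id`,
#'   `theoretical_mz`, `ppm`.
#' @export
match_library <- function(features, library, tol_ppm = 10) {
  stopifnot(all(c("feature_id", "mz", "mode") %in% names(features)))
  cand <- library |>
    dplyr::mutate(mass = monoisotopic_mass(.data$formula)) |>
    tidyr::unnest_longer("adducts", values_to = "adduct") |>
    dplyr::inner_join(ADDUCTS, by = "adduct") |>
    dplyr::mutate(theoretical_mz = .data$mass + .data$shift)
  hits <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    ok <- cand[cand$mode == f$mode, , drop = FALSE]
    ppm <- ppm_error(f$mz, ok$theoretical_mz)
    keep <- abs(ppm) <= tol_ppm
    if (!any(keep)) {
      return(tibble::tibble(feature_id = f$feature_id, mz = f$mz,
                            mode = f$mode, compound_id = NA_character_,
                            name = NA_character_, adduct = NA_character_,
                            kegg_id = NA_character_,
                            theoretical_mz = NA_real_, ppm = NA_real_))
    }
    tibble::tibble(feature_id = f$feature_id, mz = f$mz, mode = f$mode,
                   compound_id = as.character(ok$id[keep]),
                   name = ok$name[keep], adduct = ok$adduct[keep],
                   kegg_id = ok$kegg_id[keep],
                   theoretical_mz = ok$theoretical_mz[keep],
                   ppm = ppm[keep]) |>
      dplyr::arrange(abs(.data$ppm))
  })
  hits
}
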
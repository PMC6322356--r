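#' Simulate a four-group LC-MS feature study
#'
#' Generates an aligned feature table emulating the rat serum/urine
#' study design: four groups (`control`, `model`, `kansui`, `vkansui`)
#' of `n_per_group` animals, log-normal intensities (per-feature
#' log-mean shared across groups), a set of planted marker features
#' whose log-mean is shifted by `+/- log_fold_change` in the model
#' group, and treated groups whose marker means sit a fraction
#' `recovery` of the way back from the model mean towards control. All
#' randomness flows from the single `seed`.
#'
#' @param n_per_group Animals per group. Default 6.
#' @param n_features Aligned features. Default 300.
#' @param n_markers Planted differential features (`<= n_features`).
#'   Default 20.
#' @param log_fold_change Natural-log shift of marker means, model vs
#'   control. Default 1.1.
#' @param recovery Fraction of the model shift reversed in the treated
#'   groups, in \[0, 1\]; both treated groups share it. Default 0.8.
#' @param noise_sd Log-scale SD of intensities. Default 0.4.
#' @param baseline_log_mean,baseline_log_sd Mean and SD of the
#'   per-feature baseline log-intensity. The default spread (0.3) keeps
#'   features on comparable scales so that a planted log effect
#'   translates into a comparable VIP for every marker under Pareto
#'   scaling — the generator favours testability of the screening rule
#'   over the decades-wide abundance range of real LC-MS data.
#' @param n_qc Pooled QC injections added (group `"QC"`, `is_qc` =
#'   `TRUE`). A pooled QC mixes all study samples, so its log-mean is
#'   the average of the group means and its variation is technical
#'   only (`qc_noise_sd`). Default 3.
#' @param qc_noise_sd Log-scale technical SD of QC injections. Default
#'   `noise_sd / 4` (about 10% RSD at the default `noise_sd`).
#' @param missing_rate Fraction of intensities set missing at random.
#'   Default 0.
#' @param seed Integer seed.
#' @return A `synthetic_study`: list with `table` (a
#'   [feature_table()]), `truth` (tibble `feature_id`, `direction` of
#'   the planted markers) and the parameters.
#' @export
simulate_feature_study <- function(n_per_group = 6, n_features = 300,
                                   n_markers = 20, log_fold_change = 1.1,
                                   recovery = 0.8, noise_sd = 0.4,
                                   n_qc = 3, qc_noise_sd = noise_sd / 4,
                                   baseline_log_mean = 8,
                                   baseline_log_sd = 0.3,
                                   missing_rate = 0, seed = 1) {
  if (n_markers > n_features) abort("n_markers must not exceed n_features")
  if (recovery < 0 || recovery > 1) abort("recovery must lie in [0, 1]")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (n_per_group < 2) abort("n_per_group must be at least 2")
  set.seed(seed)
  groups <- c("control", "model", "kansui", "vkansui")
  samples <- tibble::tibble(
    sample_id = c(paste0(rep(groups, each = n_per_group), "_",
                         rep(seq_len(n_per_group), 4)),
                  if (n_qc > 0) paste0("QC_", seq_len(n_qc))),
    group = c(rep(groups, each = n_per_group), rep("QC", n_qc)),
    is_qc = c(rep(FALSE, 4 * n_per_group), rep(TRUE, n_qc)))
  features <- tibble::tibble(
    feature_id = sprintf("F%04d", seq_len(n_features)),
    mz = sort(runif(n_features, 100, 1000)),
    rt = runif(n_features, 0.5, 15))
  base_mu <- rnorm(n_features, baseline_log_mean, baseline_log_sd)
  marker_idx <- sort(sample.int(n_features, n_markers))
  direction <- sample(c(-1, 1), n_markers, replace = TRUE)
  # per-feature, per-group log-means
  mu <- matrix(base_mu, n_features, length(groups) + (n_qc > 0),
               dimnames = list(NULL, c(groups, if (n_qc > 0) "QC")))
  shift <- direction * log_fold_change
  mu[marker_idx, "model"] <- base_mu[marker_idx] + shift
  treated_shift <- shift * (1 - recovery)
  mu[marker_idx, "kansui"] <- base_mu[marker_idx] + treated_shift
  mu[marker_idx, "vkansui"] <- base_mu[marker_idx] + treated_shift
  if (n_qc > 0) mu[, "QC"] <- rowMeans(mu[, groups, drop = FALSE])
  m <- matrix(0, n_features, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    g <- samples$group[j]
    m[, j] <- exp(rnorm(n_features, mu[, g],
                        if (g == "QC") qc_noise_sd else noise_sd))
  }
  if (missing_rate > 0) {
    m[runif(length(m)) < missing_rate] <- NA
  }
  structure(list(
    table = feature_table(features, m, samples),
    truth = tibble::tibble(feature_id = features$feature_id[marker_idx],
                           direction = direction),
    params = list(n_per_group = n_per_group, n_features = n_features,
                  n_markers = n_markers,
                  log_fold_change = log_fold_change, recovery = recovery,
                  noise_sd = noise_sd, n_qc = n_qc,
                  qc_noise_sd = qc_noise_sd,
                  missing_rate = missing_rate, seed = seed)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "# synthetic study: %d features x 4 x %d samples (+%d QC), %d planted markers\n",
    p$n_features, p$n_per_group, p$n_qc, p$n_markers))
  cat(sprintf("# log-FC %.2f, recovery %.2f, noise SD %.2f, seed %d\n",
              p$log_fold_change, p$recovery, p$noise_sd, p$seed))
  invisible(x)
}

#' Simulate a protein interactome with a planted bridge target
#'
#' Builds two dense protein communities joined through a single bridge
#' node — a cut vertex carrying all inter-community shortest paths, so
#' it has maximal betweenness and low average path length by
#' construction. Seed proteins for the compound-target side are drawn
#' from one community and metabolite-gene seeds from the other, giving
#' the target-ranking stage a known right answer.
#'
#' @param n_proteins Total nodes including the bridge (>= 10).
#' @param mean_degree Average within-community degree. Default 4.
#' @param n_seeds Seed proteins drawn per side. Default 3.
#' @param seed Integer seed.
#' @return A `synthetic_interactome`: list with `edges` (tibble
#'   `from`, `to`), `planted_bridge`, `seed_compound_targets`,
#'   `seed_metabolite_genes`.
#' @export
simulate_interactome <- function(n_proteins = 40, mean_degree = 4,
                                 n_seeds = 3, seed = 1) {
  if (n_proteins < 10) abort("n_proteins must be at least 10")
  set.seed(seed)
  bridge <- "BRG1"
  n_side <- (n_proteins - 1) %/% 2
  a <- sprintf("PA%02d", seq_len(n_side))
  b <- sprintf("PB%02d", seq_len(n_proteins - 1 - n_side))
  community <- function(nodes) {
    n <- length(nodes)
    # random spanning tree for connectivity, then extra random edges
    el <- tibble::tibble(
      from = nodes[vapply(2:n, function(i) sample.int(i - 1, 1), 1L)],
      to = nodes[2:n])
    p_extra <- max(0, mean_degree / (n - 1) - 2 / n)
    pairs <- utils::combn(nodes, 2)
    extra <- runif(ncol(pairs)) < p_extra
    dplyr::distinct(dplyr::bind_rows(
      el, tibble::tibble(from = pairs[1, extra], to = pairs[2, extra])))
  }
  anchors_a <- sample(a, 2)
  anchors_b <- sample(b, 2)
  edges <- dplyr::bind_rows(
    community(a), community(b),
    tibble::tibble(from = bridge, to = c(anchors_a, anchors_b)))
  structure(list(edges = edges, planted_bridge = bridge,
                 seed_compound_targets = sample(a, n_seeds),
                 seed_metabolite_genes = sample(b, n_seeds),
                 params = list(n_proteins = n_proteins,
                               mean_degree = mean_degree,
                               n_seeds = n_seeds, seed = seed)),
            class = "synthetic_interactome")
}

#' @export
print.synthetic_interactome <- function(x, ...) {
  cat(sprintf(
    "# synthetic interactome: %d nodes, %d edges, bridge = %s\n",
    length(unique(c(x$edges$from, x$edges$to))), nrow(x$edges),
    x$planted_bridge))
  invisible(x)
}

#' Load a bundled published table
#'
#' The three printed tables ship with the package as plain TSV:
#' `"table1"` — the 16 identified serum (S1-S8) and urine (U1-U8)
#' metabolites with retention time, observed m/z, VIP, adduct, formula,
#' KEGG id, trend and pathway annotations; `"table2"` — the 31
#' compounds of vinegar-processed kansui with oral bioavailability and
#' drug-likeness; `"table3"` — the 12 intersection targets with average
#' shortest path length, betweenness centrality and the printed R
#' score.
#'
#' @param name `"table1"`, `"table2"` or `"table3"`.
#' @return A tibble.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  file <- c(table1 = "table1_metabolites.tsv",
            table2 = "table2_compounds.tsv",
            table3 = "table3_targets.tsv")[[name]]
  path <- system.file("extdata", file, package = "vkmet", mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (name == "table3") tbl <- dplyr::rename(tbl, node_id = "gene")
  tbl
}
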
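#' Default pipeline configuration
#'
#' Thresholds mirror the workflow's standard settings: VIP > 1.5 with
#' p < 0.05 for marker screening, 10 ppm annotation tolerance,
#' OB >= 30% and DL >= 0.18 for the ADME filter, 200 label
#' permutations, 7 cross-validation folds, top 6 crucial targets.
#'
#' @param seed Top-level seed; per-stage seeds are derived from it.
#' @param output_dir Where artifacts and the manifest are written.
#' @return A named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1, output_dir = tempfile("vkmet_run_")) {
  list(
    simulate = list(),          # simulate_feature_study() arguments
    feature_csv = NULL,         # or: paths to a real table
    metadata_tsv = NULL,
    impute_rule = "half_min",
    qc_max_rsd = 30,
    scaling = "pareto",
    vip_min = 1.5, alpha = 0.05,
    tol_ppm = 10,
    ob_min = 30, dl_min = 0.18,
    adme_whitelist = character(),
    n_perm = 200, cv_folds = 7,
    top_k = 6,
    seed = seed, output_dir = output_dir)
}

#' Run the full metabolomics + network-pharmacology pipeline
#'
#' Executes the seven stages in order — preprocess, chemometrics
#' (PCA + OPLS-DA with permutation validation), marker screening,
#' annotation, pathway analysis, network assembly, target ranking —
#' writing each stage's artifact as TSV/JSON under
#' `config$output_dir` together with a manifest (inputs, parameters,
#' seed, md5 checksums). Re-running with an identical config reproduces
#' identical numeric outputs.
#'
#' With no input paths the feature table is simulated via
#' [simulate_feature_study()] and the interactome via
#' [simulate_interactome()]; the compound library defaults to the
#' bundled 16-metabolite table and the ADME table to the bundled
#' 31-compound table, so the default config exercises every stage.
#'
#' @param config A list as from [default_config()], or a path to a YAML
#'   file holding one.
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(cfg$feature_csv) &&
      (!file.exists(cfg$feature_csv) || !file.exists(cfg$metadata_tsv))) {
    abort("configured feature/metadata paths do not exist")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  save_tsv <- function(x, name) {
    p <- file.path(cfg$output_dir, paste0(name, ".tsv"))
    readr::write_tsv(x, p)
    artifacts[[name]] <<- p
    x
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  ## 1 preprocess ------------------------------------------------------
  truth <- NULL
  ft <- stage("preprocess", {
    raw <- if (is.null(cfg$feature_csv)) {
      sim <- do.call(simulate_feature_study,
                     utils::modifyList(list(seed = cfg$seed),
                                       as.list(cfg$simulate)))
      truth <- sim$truth
      sim$table
    } else {
      read_feature_table(cfg$feature_csv, cfg$metadata_tsv)
    }
    raw |>
      impute_missing(cfg$impute_rule) |>
      qc_rsd_filter(cfg$qc_max_rsd)
  })
  save_tsv(tibble::as_tibble(as.data.frame(ft)), "preprocessed_features")

  ## 2 chemometrics ----------------------------------------------------
  chem <- stage("chemometrics", {
    sc_all <- pareto_scale(ft, cfg$scaling)
    ft_cm <- subset_samples(ft, c("control", "model"))
    sc_cm <- pareto_scale(ft_cm, cfg$scaling)
    y <- sample_info(ft_cm)$group
    pca <- fit_pca(sc_all, seed = cfg$seed + 11L)
    opls <- fit_oplsda(sc_cm, y, cv_folds = cfg$cv_folds,
                       seed = cfg$seed + 13L)
    perm <- permutation_test(sc_cm, y, n_orth = opls$n_orth,
                             cv_folds = cfg$cv_folds,
                             n_perm = cfg$n_perm, seed = cfg$seed + 17L)
    list(pca = pca, opls = opls, perm = perm, scaled_cm = sc_cm)
  })
  model_summary <- list(
    pca = as.list(glance(chem$pca)),
    oplsda = as.list(glance(chem$opls)),
    permutation = list(n_perm = chem$perm$n_perm,
                       observed_q2 = chem$perm$observed_q2,
                       p_q2 = chem$perm$p_q2))
  jsonlite::write_json(model_summary,
                       file.path(cfg$output_dir, "model_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  artifacts$model_summary <- file.path(cfg$output_dir, "model_summary.json")
  save_tsv(s_plot(chem$opls, chem$scaled_cm), "s_plot")

  ## 3 screen ----------------------------------------------------------
  markers <- stage("screen", {
    screen_markers(ft, vip_scores(chem$opls),
                   vip_min = cfg$vip_min, alpha = cfg$alpha)
  })
  save_tsv(markers, "markers")

  ## 4 annotate --------------------------------------------------------
  ann <- stage("annotate", {
    lib <- if (is.null(cfg$library_tsv)) table1_library()
           else read_compound_library(cfg$library_tsv)
    feats <- markers |>
      dplyr::transmute(.data$feature_id, .data$mz,
                       mode = ifelse(.data$mz %% 2 < 1, "neg", "pos"))
    if (is.null(cfg$feature_csv)) {
      # simulated m/z are arbitrary: annotate the library's own ions as
      # a self-consistency pass instead
      feats <- tibble::tibble(
        feature_id = lib$id,
        mz = adduct_mz(monoisotopic_mass(lib$formula),
                       vapply(lib$adducts, `[`, "", 1)),
        mode = ADDUCTS$mode[match(vapply(lib$adducts, `[`, "", 1),
                                  ADDUCTS$adduct)])
    }
    match_library(feats, lib, tol_ppm = cfg$tol_ppm)
  })
  save_tsv(ann, "annotations")

  ## 5 pathways --------------------------------------------------------
  pw <- stage("pathways", {
    db <- if (!is.null(cfg$pathway_gmt)) read_gmt(cfg$pathway_gmt)
          else table1_pathway_db()
    edges <- if (!is.null(cfg$pathway_edges))
      read_pathway_edges(cfg$pathway_edges)
    universe <- max(length(unique(ann$kegg_id[!is.na(ann$kegg_id)])),
                    cfg$pathway_universe %||% 16)
    pathway_summary(ann, db, universe_size = universe, edges = edges)
  })
  save_tsv(pw, "pathways")

  ## 6 network ---------------------------------------------------------
  net <- stage("network", {
    adme <- if (is.null(cfg$adme_tsv)) load_fixture("table2")
            else readr::read_tsv(cfg$adme_tsv, show_col_types = FALSE)
    active <- adme_filter(adme, cfg$ob_min, cfg$dl_min,
                          cfg$adme_whitelist)
    if (!is.null(cfg$ct_tsv)) {
      ct_tab <- readr::read_tsv(cfg$ct_tsv, show_col_types = FALSE)
      ppi_tab <- read_edge_tsv(cfg$ppi_tsv)
      gm_tab <- readr::read_tsv(cfg$gm_tsv, show_col_types = FALSE)
      inter <- NULL
    } else {
      inter <- simulate_interactome(seed = cfg$seed + 23L)
      ct_tab <- tidyr::expand_grid(compound_id = active$compound_id,
                                   target = inter$seed_compound_targets)
      ppi_tab <- inter$edges
      kegg <- unique(ann$kegg_id[!is.na(ann$kegg_id)])
      gm_tab <- tidyr::expand_grid(kegg_id = kegg,
                                   gene = inter$seed_metabolite_genes)
    }
    ct <- compound_target_network(active$compound_id, ct_tab)
    gm <- gene_metabolite_network(unique(gm_tab$kegg_id), gm_tab)
    ppi <- expand_ppi(unique(gm_tab$gene), ppi_tab)
    merged <- merge_tripartite(ct, ppi, gm,
                               disease_genes = cfg$disease_genes %||%
                                 character())
    list(active = active, merged = merged, inter = inter)
  })
  save_tsv(net$active, "active_compounds")
  write_sif(net$merged$network,
            file.path(cfg$output_dir, "merged_network.sif"))
  write_graphml(net$merged$network,
                file.path(cfg$output_dir, "merged_network.graphml"))
  artifacts$merged_network <- file.path(cfg$output_dir,
                                        "merged_network.sif")

  ## 7 rank ------------------------------------------------------------
  ranked <- stage("rank", {
    cent <- node_centralities(net$merged$network)
    cand <- cent[cent$betweenness > 0 &
                   cent$layer %in% c("target", "pathway_gene",
                                     "adjacent_protein", NA), ]
    rank_targets(r_score(cand), top_k = cfg$top_k)
  })
  save_tsv(ranked, "ranked_targets")

  manifest <- list(
    package_version = as.character(utils::packageVersion("vkmet")),
    config = cfg[setdiff(names(cfg), "output_dir")],
    stages = names(artifacts),
    artifacts = lapply(artifacts, basename),
    checksums = as.list(tools::md5sum(unlist(artifacts))),
    n_markers = nrow(markers),
    crucial_targets = ranked$node_id[ranked$crucial])
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

## Mini pathway database built from the bundled metabolite table's
## pathway annotations (KEGG-id membership only; no edges).
table1_pathway_db <- function() {
  lib <- table1_library()
  tibble::tibble(kegg_id = lib$kegg_id, pathway = lib$pathways) |>
    tidyr::unnest_longer("pathway") |>
    dplyr::distinct() |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(members = list(unique(.data$kegg_id)),
                     .groups = "drop") |>
    dplyr::transmute(pathway_id = gsub("[^A-Za-z0-9]+", "_",
                                       .data$pathway),
                     name = .data$pathway, members = .data$members)
}
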
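#' ADME filter for herbal compounds
#'
#' Selects active compounds as those meeting both the oral
#' bioavailability and drug-likeness thresholds (`ob >= ob_min` and
#' `dl >= dl_min`), plus any compounds on a literature whitelist —
#' constituents known to be active despite weak ADME scores. The two
#' routes are reported separately so overlaps are visible.
#'
#' @param compounds Tibble with `compound_id`, `name`, `ob` (percent
#'   oral bioavailability) and `dl` (drug-likeness), e.g.
#'   `load_fixture("table2")`.
#' @param ob_min,dl_min Thresholds. Defaults 30 and 0.18.
#' @param whitelist Character vector of `compound_id`s to force-include;
#'   ids absent from `compounds` are an error.
#' @return Tibble of selected compounds: `compound_id`, `name`, `ob`,
#'   `dl`, `pass_rule`, `whitelisted`, deduplicated, in table order.
#' @export
adme_filter <- function(compounds, ob_min = 30, dl_min = 0.18,
                        whitelist = character()) {
  stopifnot(ob_min >= 0, dl_min >= 0)
  missing_wl <- setdiff(whitelist, compounds$compound_id)
  if (length(missing_wl)) {
    abort(paste0("whitelist ids absent from the compound table: ",
                 paste(missing_wl, collapse = ", ")))
  }
  compounds |>
    dplyr::mutate(pass_rule = .data$ob >= ob_min & .data$dl >= dl_min,
                  whitelisted = .data$compound_id %in% whitelist) |>
    dplyr::filter(.data$pass_rule | .data$whitelisted) |>
    dplyr::select("compound_id", "name", "ob", "dl", "pass_rule",
                  "whitelisted")
}

## ---- layered networks -----------------------------------------------

LAYERS <- c("compound", "target", "adjacent_protein", "pathway_gene",
            "metabolite")
## Protein-side layers can legitimately overlap between input networks
## (an intersection protein is both a compound target and a PPI node);
## the most specific tag wins. Cross-kind overlaps are errors.
LAYER_PRECEDENCE <- c(target = 1, pathway_gene = 2, adjacent_protein = 3)

new_layered_network <- function(nodes, edges) {
  # nodes: tibble(node_id, layer); edges: tibble(from, to)
  stopifnot(all(nodes$layer %in% LAYERS))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(nodes$node_id, layer = nodes$layer)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(as.matrix(edges[, c("from", "to")])))
  }
  g <- igraph::simplify(g)
  class(g) <- c("layered_network", class(g))
  g
}

#' Node table of a layered network
#'
#' @param g A layered network (igraph with a `layer` vertex attribute).
#' @return Tibble with `node_id`, `layer`, `degree`.
#' @export
network_nodes <- function(g) {
  tibble::tibble(node_id = igraph::V(g)$name,
                 layer = igraph::V(g)$layer,
                 degree = unname(igraph::degree(g)))
}

#' Edge table of a layered network
#'
#' @param g A layered network.
#' @return Tibble with `from`, `to`.
#' @export
network_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  tibble::tibble(from = el[, 1], to = el[, 2])
}

#' @export
print.layered_network <- function(x, ...) {
  tab <- table(igraph::V(x)$layer)
  cat(sprintf("# layered network: %d nodes, %d edges\n",
              igraph::vcount(x), igraph::ecount(x)))
  cat("# layers: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Gene-metabolite association network
#'
#' Bipartite graph linking screened metabolites (KEGG ids) to the genes
#' of the enzymes handling them. Metabolites with no association are
#' kept as isolated nodes so they remain visible in the merged network.
#'
#' @param metabolites Character vector of metabolite KEGG ids.
#' @param associations Tibble with columns `kegg_id`, `gene`.
#' @return A layered network (`metabolite` / `pathway_gene` layers).
#' @export
gene_metabolite_network <- function(metabolites, associations) {
  metabolites <- unique(metabolites)
  assoc <- associations |>
    dplyr::filter(.data$kegg_id %in% metabolites) |>
    dplyr::mutate(gene = toupper(.data$gene)) |>
    dplyr::distinct(.data$kegg_id, .data$gene)
  nodes <- dplyr::bind_rows(
    tibble::tibble(node_id = metabolites, layer = "metabolite"),
    tibble::tibble(node_id = unique(assoc$gene), layer = "pathway_gene"))
  new_layered_network(nodes,
                      tibble::tibble(from = assoc$kegg_id, to = assoc$gene))
}

#' Expand seed proteins by one hop in an interactome
#'
#' Induced subgraph on the seeds and their direct interactors; the added
#' neighbours are tagged `adjacent_protein`. Seeds missing from the
#' interactome are kept isolated with a warning.
#'
#' @param seeds Character vector of seed gene symbols.
#' @param interactome Tibble of undirected edges, columns `from`, `to`.
#' @return A layered network (`pathway_gene` seeds +
#'   `adjacent_protein` neighbours).
#' @export
expand_ppi <- function(seeds, interactome) {
  seeds <- toupper(unique(seeds))
  inter <- interactome |>
    dplyr::mutate(from = toupper(.data$from), to = toupper(.data$to)) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::distinct()
  known <- unique(c(inter$from, inter$to))
  lost <- setdiff(seeds, known)
  if (length(lost)) {
    warn(paste0("seeds absent from the interactome kept isolated: ",
                paste(lost, collapse = ", ")))
  }
  touch <- inter$from %in% seeds | inter$to %in% seeds
  sub <- inter[touch, , drop = FALSE]
  nbrs <- setdiff(unique(c(sub$from, sub$to)), seeds)
  nodes <- dplyr::bind_rows(
    tibble::tibble(node_id = seeds, layer = "pathway_gene"),
    tibble::tibble(node_id = nbrs, layer = "adjacent_protein"))
  new_layered_network(nodes, sub)
}

#' Compound-target bipartite network
#'
#' Restricts a compound-target table to the selected compound set and
#' builds the bipartite graph; the target union over all selected
#' compounds is available via [network_nodes()].
#'
#' @param compounds Character vector of selected compound ids.
#' @param targets Tibble with columns `compound_id`, `target`.
#' @return A layered network (`compound` / `target` layers).
#' @export
compound_target_network <- function(compounds, targets) {
  compounds <- unique(compounds)
  tt <- targets |>
    dplyr::filter(.data$compound_id %in% compounds) |>
    dplyr::mutate(target = toupper(.data$target)) |>
    dplyr::distinct(.data$compound_id, .data$target)
  nodes <- dplyr::bind_rows(
    tibble::tibble(node_id = compounds, layer = "compound"),
    tibble::tibble(node_id = unique(tt$target), layer = "target"))
  new_layered_network(nodes,
                      tibble::tibble(from = tt$compound_id, to = tt$target))
}

#' Merge the compound-target, PPI and gene-metabolite layers
#'
#' Takes the union of nodes and edges of the three networks. Protein
#' nodes appearing in several layers keep the most specific tag
#' (`target` over `pathway_gene` over `adjacent_protein`); an id tagged
#' both as a protein-side node and as a compound or metabolite is an
#' error. The intersection set — compound targets that also occur in
#' the PPI or gene-metabolite layers — is reported alongside; these are
#' the candidate disease targets. `disease_genes` marks which of them
#' are known disease genes.
#'
#' @param ct,ppi,gm Layered networks from [compound_target_network()],
#'   [expand_ppi()] and [gene_metabolite_network()].
#' @param disease_genes Optional character vector of disease gene
#'   symbols.
#' @return List with `network` (merged layered network), `intersection`
#'   (character vector) and `intersection_disease` (subset in
#'   `disease_genes`).
#' @export
merge_tripartite <- function(ct, ppi, gm, disease_genes = character()) {
  nets <- list(ct = ct, ppi = ppi, gm = gm)
  nodes <- purrr::map_dfr(nets, network_nodes)[c("node_id", "layer")]
  kind <- function(l) ifelse(l %in% names(LAYER_PRECEDENCE), "protein", l)
  kinds <- nodes |>
    dplyr::distinct(.data$node_id, kind = kind(.data$layer))
  clash <- kinds$node_id[duplicated(kinds$node_id)]
  if (length(clash)) {
    abort(paste0("conflicting layer kinds for node(s): ",
                 paste(unique(clash), collapse = ", ")))
  }
  merged_nodes <- nodes |>
    dplyr::mutate(prec = dplyr::coalesce(LAYER_PRECEDENCE[.data$layer], 0)) |>
    dplyr::group_by(.data$node_id) |>
    dplyr::slice_min(.data$prec, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("node_id", "layer")
  edges <- purrr::map_dfr(nets, network_edges) |> dplyr::distinct()
  targets <- network_nodes(ct) |>
    dplyr::filter(.data$layer == "target") |> dplyr::pull("node_id")
  prot <- dplyr::bind_rows(network_nodes(ppi), network_nodes(gm)) |>
    dplyr::filter(.data$layer != "metabolite") |> dplyr::pull("node_id")
  intersection <- sort(intersect(targets, unique(prot)))
  list(network = new_layered_network(merged_nodes, edges),
       intersection = intersection,
       intersection_disease = sort(intersect(intersection,
                                             toupper(disease_genes))))
}

#' Node centralities: average shortest path length and betweenness
#'
#' Unweighted, undirected shortest paths. For each node, `aspl` is the
#' mean hop distance to the other nodes of its connected component;
#' betweenness is normalized by `(n - 1)(n - 2) / 2` within the
#' component, giving values in \[0, 1\]. Isolated nodes have no defined
#' path length and are dropped with a warning.
#'
#' @param g A layered network or any undirected igraph with named
#'   vertices.
#' @return Tibble with `node_id`, `layer` (if present), `aspl`,
#'   `betweenness`, `component`, `component_size`.
#' @export
node_centralities <- function(g) {
  if (igraph::vcount(g) < 3) abort("centralities need at least 3 nodes")
  comp <- igraph::components(g)
  iso <- igraph::V(g)$name[comp$csize[comp$membership] == 1]
  if (length(iso)) {
    warn(paste0("isolated node(s) dropped (no defined path length): ",
                paste(iso, collapse = ", ")))
  }
  res <- purrr::map_dfr(which(comp$csize > 1), function(ci) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == ci))
    n <- igraph::vcount(sub)
    d <- igraph::distances(sub)
    btw <- igraph::betweenness(sub, directed = FALSE, normalized = FALSE)
    denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
    tibble::tibble(
      node_id = igraph::V(sub)$name,
      layer = if (!is.null(igraph::V(sub)$layer)) igraph::V(sub)$layer
              else NA_character_,
      aspl = unname(rowSums(d)) / (n - 1),
      betweenness = unname(btw) / denom,
      component = ci, component_size = n)
  })
  res[order(match(res$node_id, igraph::V(g)$name)), ]
}

#' R score: combined centrality rank statistic
#'
#' Combines the min-max-normalized average shortest path length with the
#' min-max-normalized reciprocal of betweenness centrality, each
#' weighted 50%:
#' \deqn{R = 0.5 \frac{A_i - A_{min}}{A_{max} - A_{min}} +
#'       0.5 \frac{1/B_j - \min(1/B)}{\max(1/B) - \min(1/B)}}
#' Lower R means a more central, hence more important, target: the node
#' holding both the minimal path length and the maximal betweenness
#' scores exactly 0. Candidates with zero betweenness have an undefined
#' reciprocal and are excluded with a warning. If all path lengths (or
#' all betweenness values) coincide, that term is 0 for every candidate.
#'
#' @param rows Tibble of candidates with `node_id`, `aspl`,
#'   `betweenness` (e.g. from [node_centralities()], or
#'   `load_fixture("table3")`).
#' @return Tibble `node_id`, `aspl`, `betweenness`, `r`, in input order.
#' @export
r_score <- function(rows) {
  stopifnot(all(c("node_id", "aspl", "betweenness") %in% names(rows)))
  drop0 <- rows$betweenness == 0
  if (any(drop0)) {
    warn(paste0("candidates with zero betweenness excluded: ",
                paste(rows$node_id[drop0], collapse = ", ")))
    rows <- rows[!drop0, , drop = FALSE]
  }
  if (nrow(rows) < 2) abort("R score needs at least 2 candidates")
  a <- rows$aspl
  rb <- 1 / rows$betweenness
  term <- function(v) {
    if (max(v) == min(v)) rep(0, length(v))
    else (v - min(v)) / (max(v) - min(v))
  }
  tibble::tibble(node_id = rows$node_id, aspl = a,
                 betweenness = rows$betweenness,
                 r = 0.5 * term(a) + 0.5 * term(rb))
}

#' Rank candidate targets by R score
#'
#' Ascending R (lower = more important), ties broken by node id.
#'
#' @param scores Tibble from [r_score()].
#' @param top_k How many leading targets to flag as crucial. Default 6.
#' @return `scores` sorted with columns `rank` and logical `crucial`
#'   added.
#' @export
rank_targets <- function(scores, top_k = 6) {
  if (top_k > nrow(scores)) {
    warn(sprintf("top_k = %d exceeds the %d candidates; returning all",
                 top_k, nrow(scores)))
    top_k <- nrow(scores)
  }
  scores |>
    dplyr::arrange(.data$r, .data$node_id) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  crucial = dplyr::row_number() <= top_k)
}

## ---- network IO ------------------------------------------------------

#' Read / write simple interaction format (SIF) and edge TSV
#'
#' SIF lines are `source interaction target` (whitespace separated);
#' edge TSVs have columns `from`, `to`.
#'
#' @param path File path.
#' @return For readers, a tibble of edges (`from`, `to`).
#' @export
read_sif <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- lengths(parts) < 3
  if (any(bad)) abort("SIF lines need source, interaction and target")
  tibble::tibble(from = vapply(parts, `[`, "", 1),
                 to = vapply(parts, `[`, "", 3))
}

#' @rdname read_sif
#' @param g A layered network.
#' @param interaction Interaction label written in the middle column.
#' @export
write_sif <- function(g, path, interaction = "pp") {
  e <- network_edges(g)
  readr::write_lines(paste(e$from, interaction, e$to), path)
  invisible(g)
}

#' @rdname read_sif
#' @export
read_edge_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "cc", col_names = c("from", "to"),
                  skip = if (grepl("^from\t", readr::read_lines(path, n_max = 1))) 1 else 0)
}

#' @rdname read_sif
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
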
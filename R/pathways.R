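#' Read pathway membership from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `id<TAB>name<TAB>member...`.
#'
#' @param path GMT file path.
#' @return Tibble with `pathway_id`, `name` and `members` (list-column
#'   of compound ids).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    pathway_id = vapply(parts, `[`, "", 1),
    name = vapply(parts, `[`, "", 2),
    members = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' Read per-pathway edge lists
#'
#' TSV with columns `pathway_id`, `source`, `target` describing the
#' within-pathway reaction graph used by the topology impact statistic.
#'
#' @param path Edge TSV path.
#' @return Tibble with those three character columns.
#' @export
read_pathway_edges <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "ccc")
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least `n_hits` of the
#' `n_selected` screened metabolites inside a pathway of
#' `pathway_size` members, drawing without replacement from a universe
#' of `universe_size` annotated compounds.
#'
#' @param n_hits Selected metabolites inside the pathway.
#' @param pathway_size Pathway member count.
#' @param universe_size Annotated universe size.
#' @param n_selected Total selected metabolites.
#' @return `P(X >= n_hits)` under the hypergeometric null.
#' @export
ora_pvalue <- function(n_hits, pathway_size, universe_size, n_selected) {
  if (n_hits > min(pathway_size, n_selected) ||
      pathway_size > universe_size || n_selected > universe_size ||
      any(c(n_hits, pathway_size, universe_size, n_selected) < 0)) {
    abort("inconsistent counts for over-representation test")
  }
  phyper(n_hits - 1, pathway_size, universe_size - pathway_size,
         n_selected, lower.tail = FALSE)
}

#' Topology impact of matched metabolites in a pathway
#'
#' Builds the pathway's compound graph and sums the relative betweenness
#' centrality of the matched members over the total centrality mass of
#' the pathway, giving a value in \[0, 1\]: 1 when the matched nodes
#' carry all shortest-path traffic, 0 when they are peripheral. When
#' every node has zero betweenness (edgeless or fully symmetric graphs)
#' the centrality mass falls back to uniform `1/|members|` per node so
#' the statistic stays defined.
#'
#' @param members Character vector of pathway member compound ids.
#' @param edges Two-column data frame (`source`, `target`) of
#'   within-pathway edges, or `NULL` for an edgeless pathway.
#' @param matched Character vector of matched member ids (subset of
#'   `members`).
#' @return Impact value in \[0, 1\].
#' @export
pathway_impact <- function(members, edges = NULL, matched) {
  members <- unique(members)
  if (!length(members)) abort("empty pathway")
  if (!all(matched %in% members)) {
    abort("matched compounds must be pathway members")
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(members)
  if (!is.null(edges) && nrow(edges) > 0) {
    el <- as.matrix(edges[, 1:2])
    if (!all(el %in% members)) abort("edge endpoints must be members")
    g <- igraph::add_edges(g, t(el))
    g <- igraph::simplify(g)
  }
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (sum(btw) == 0) {
    btw <- rep(1 / length(members), length(members))
    names(btw) <- members
  }
  sum(btw[matched]) / sum(btw)
}

#' Pathway-level summary of annotated markers
#'
#' Combines over-representation (hypergeometric upper tail on KEGG-id
#' hits) with the topology impact statistic for every pathway with at
#' least one hit. No multiple-testing correction is applied to the
#' ranking; a Benjamini-Hochberg column is included for transparency.
#'
#' @param matches Annotation tibble from [match_library()] (rows with
#'   `NA` `kegg_id` are ignored), or any tibble with a `kegg_id` column.
#' @param pathway_db Tibble from [read_gmt()] (`pathway_id`, `name`,
#'   `members` holding KEGG ids).
#' @param universe_size Number of annotated compounds in the screening
#'   universe.
#' @param edges Optional per-pathway edge tibble from
#'   [read_pathway_edges()].
#' @return Tibble sorted by `p_value` then impact descending:
#'   `pathway_id`, `name`, `n_hits`, `pathway_size`, `p_value`, `p_adj`,
#'   `impact`.
#' @export
pathway_summary <- function(matches, pathway_db, universe_size,
                            edges = NULL) {
  if (!nrow(pathway_db)) abort("empty pathway database")
  hits <- unique(matches$kegg_id[!is.na(matches$kegg_id)])
  res <- purrr::map_dfr(seq_len(nrow(pathway_db)), function(i) {
    p <- pathway_db[i, ]
    members <- p$members[[1]]
    matched <- intersect(hits, members)
    if (!length(matched)) return(NULL)
    e <- if (!is.null(edges)) {
      ei <- edges[edges$pathway_id == p$pathway_id, c("source", "target")]
      if (nrow(ei)) ei else NULL
    }
    tibble::tibble(
      pathway_id = p$pathway_id, name = p$name,
      n_hits = length(matched), pathway_size = length(members),
      p_value = ora_pvalue(length(matched), length(members),
                           universe_size, length(hits)),
      impact = pathway_impact(members, e, matched))
  })
  if (is.null(res) || !nrow(res)) {
    return(tibble::tibble(pathway_id = character(), name = character(),
                          n_hits = integer(), pathway_size = integer(),
                          p_value = numeric(), p_adj = numeric(),
                          impact = numeric()))
  }
  res |>
    dplyr::mutate(p_adj = p.adjust(.data$p_value, "BH"),
                  .after = "p_value") |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$impact))
}

#' @rdname pathway_summary
#' @param object A pathway summary tibble.
#' @param ... Unused.
#' @export
plot_pathway_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$impact, -log10(.data$p_value),
                               size = .data$n_hits)) +
    ggplot2::geom_point(colour = "firebrick", alpha = 0.8) +
    ggplot2::labs(x = "pathway impact", y = expression(-log[10]~p))
}
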
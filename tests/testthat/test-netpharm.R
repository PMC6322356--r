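test_that("ADME filter reproduces the published active-compound sets", {
  t2 <- load_fixture("table2")
  rule <- adme_filter(t2)
  expect_identical(nrow(rule), 8L)
  expect_setequal(rule$compound_id,
                  c("GE10", "GE11", "GE13", "GE16", "GE20", "GE21",
                    "GE22", "GE26"))
  wl <- c("GE05", "GE06", "GE07", "GE08", "GE12", "GE14", "GE15",
          "GE17", "GE18", "GE24", "GE25", "GE26", "GE27")
  both <- adme_filter(t2, whitelist = wl)
  # GE26 passes the rule and is whitelisted: union is 20 unique ids
  expect_identical(nrow(both), 20L)
  expect_identical(sum(both$pass_rule & both$whitelisted), 1L)
  expect_identical(both$compound_id[both$pass_rule & both$whitelisted],
                   "GE26")
  expect_identical(nrow(adme_filter(t2, ob_min = 0, dl_min = 0)), 31L)
  expect_error(adme_filter(t2, whitelist = "GE99"), "GE99")
})

test_that("gene-metabolite networks are simple bipartite graphs", {
  assoc <- tibble::tibble(kegg_id = c("C1", "C2", "C1"),
                          gene = c("g1", "g1", "g1"))  # duplicate row
  g <- gene_metabolite_network(c("C1", "C2", "C3"), assoc)
  nodes <- network_nodes(g)
  expect_identical(nrow(nodes), 4L)                  # 3 metab + 1 gene
  expect_identical(igraph::ecount(g), 2)
  expect_identical(nodes$degree[nodes$node_id == "C3"], 0)
  expect_identical(nodes$layer[nodes$node_id == "G1"], "pathway_gene")
  # empty associations: all isolated
  g0 <- gene_metabolite_network(c("C1", "C2"),
                                tibble::tibble(kegg_id = character(),
                                               gene = character()))
  expect_identical(igraph::ecount(g0), 0)
})

test_that("PPI expansion matches a brute-force adjacency scan", {
  star <- tibble::tibble(from = "HUB", to = paste0("L", 1:5))
  g <- expand_ppi("L1", star)
  expect_setequal(network_nodes(g)$node_id, c("L1", "HUB"))
  expect_identical(network_edges(g) |> nrow(), 1L)
  # all nodes as seeds returns the full interactome
  gall <- expand_ppi(c("HUB", paste0("L", 1:5)), star)
  expect_identical(igraph::ecount(gall), igraph::ecount(
    igraph::graph_from_data_frame(star, directed = FALSE)))
  # absent seed kept isolated with warning
  expect_warning(gm <- expand_ppi(c("L1", "GHOST"), star), "GHOST")
  expect_true("GHOST" %in% network_nodes(gm)$node_id)

  si <- simulate_interactome(n_proteins = 30, seed = 13)
  seeds <- si$seed_metabolite_genes
  ge <- expand_ppi(seeds, si$edges)
  nbr_oracle <- unique(c(
    si$edges$to[si$edges$from %in% seeds],
    si$edges$from[si$edges$to %in% seeds]))
  nbr_oracle <- setdiff(toupper(nbr_oracle), toupper(seeds))
  got <- network_nodes(ge)
  expect_setequal(got$node_id[got$layer == "adjacent_protein"], nbr_oracle)
})

test_that("compound-target networks union their target sets", {
  tt <- tibble::tibble(compound_id = c("GE1", "GE1", "GE2", "GE2"),
                       target = c("A", "B", "B", "C"))
  g <- compound_target_network(c("GE1", "GE2"), tt)
  nodes <- network_nodes(g)
  expect_setequal(nodes$node_id[nodes$layer == "target"],
                  c("A", "B", "C"))
  g0 <- compound_target_network(character(), tt)
  expect_identical(igraph::vcount(g0), 0)
})

test_that("the tripartite merge preserves edges and finds intersections", {
  ct <- compound_target_network(
    "GE1", tibble::tibble(compound_id = "GE1", target = c("A", "B", "C")))
  ppi <- expand_ppi("B", tibble::tibble(from = c("B", "C"),
                                        to = c("C", "D")))
  gm <- gene_metabolite_network(
    "C05122", tibble::tibble(kegg_id = "C05122", gene = "D"))
  merged <- merge_tripartite(ct, ppi, gm, disease_genes = c("B", "X"))
  expect_setequal(merged$intersection, c("B", "C"))
  expect_identical(merged$intersection_disease, "B")
  # no edge from any layer is lost
  all_in <- dplyr::bind_rows(network_edges(ct), network_edges(ppi),
                             network_edges(gm))
  out <- network_edges(merged$network)
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_true(all(key(all_in) %in% key(out)))
  # target tag wins for intersection proteins
  nodes <- network_nodes(merged$network)
  expect_identical(nodes$layer[nodes$node_id == "B"], "target")
  # compound/protein id clash is an error
  bad_gm <- gene_metabolite_network(
    "GE1", tibble::tibble(kegg_id = "GE1", gene = "D"))
  expect_error(merge_tripartite(ct, ppi, bad_gm), "GE1")
})

test_that("centralities agree with the brute-force oracle", {
  # path graph: middle node carries everything
  pg <- igraph::graph_from_data_frame(
    tibble::tibble(from = c("A", "B"), to = c("B", "C")), directed = FALSE)
  cent <- node_centralities(pg)
  expect_equal(cent$aspl[cent$node_id == "B"], 1)
  expect_equal(cent$aspl[cent$node_id == "A"], 1.5)
  expect_equal(cent$betweenness[cent$node_id == "B"], 1)
  expect_equal(cent$betweenness[cent$node_id == "A"], 0)
  # complete graph: aspl 1, betweenness 0
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("K", 1:4)
  ck <- node_centralities(k4)
  expect_equal(ck$aspl, rep(1, 4))
  expect_equal(ck$betweenness, rep(0, 4))
  # 50 random graphs up to 12 nodes
  withr::local_seed(17)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    edges <- random_graph_edges(n)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    got <- node_centralities(g)
    want <- oracle_centralities(edges)
    got <- got[match(want$node_id, got$node_id), ]
    expect_equal(got$aspl, want$aspl, tolerance = 1e-12)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
  }
})

test_that("R scores reproduce the published target table", {
  t3 <- load_fixture("table3")
  rs <- r_score(t3)
  # the node holding min ASPL and max betweenness scores exactly 0
  expect_equal(rs$r[rs$node_id == "HSP90AA1"], 0)
  expect_identical(rs$node_id[which.min(rs$r)], "HSP90AA1")
  # sorted recomputed scores match the printed column within 0.005
  expect_equal(sort(rs$r), sort(t3$r_printed), tolerance = 0.005,
               ignore_attr = TRUE)
  expect_lt(max(abs(sort(rs$r) - sort(t3$r_printed))), 0.005)
  rk <- rank_targets(rs, top_k = 6)
  expect_identical(rk$node_id[1], "HSP90AA1")
  expect_identical(sum(rk$crucial), 6L)
})

test_that("R score corners and invariances hold", {
  rows <- tibble::tibble(node_id = c("min", "mid", "max"),
                         aspl = c(1, 2, 3),
                         betweenness = c(0.5, 0.1, 0.01))
  rs <- r_score(rows)
  expect_equal(rs$r[1], 0)    # min A, max B
  expect_equal(rs$r[3], 1)    # max A, min B
  expect_true(all(rs$r >= 0 & rs$r <= 1))
  # affine rescale of A and scalar rescale of B leave R unchanged
  rs2 <- r_score(dplyr::mutate(rows, aspl = 3 * .data$aspl + 2,
                               betweenness = 0.1 * .data$betweenness))
  expect_equal(rs2$r, rs$r, tolerance = 1e-12)
  # zero betweenness excluded with warning
  rows0 <- dplyr::bind_rows(rows,
                            tibble::tibble(node_id = "dead", aspl = 2,
                                           betweenness = 0))
  expect_warning(rs0 <- r_score(rows0), "dead")
  expect_false("dead" %in% rs0$node_id)
  # all-equal A: first term vanishes for everyone
  rse <- r_score(tibble::tibble(node_id = c("a", "b"), aspl = c(2, 2),
                                betweenness = c(0.2, 0.1)))
  expect_equal(rse$r, c(0, 0.5))
  # ties broken lexicographically, deterministically
  tie <- rank_targets(tibble::tibble(node_id = c("B", "A"),
                                     aspl = c(1, 1),
                                     betweenness = c(0.2, 0.2),
                                     r = c(0, 0)), top_k = 1)
  expect_identical(tie$node_id, c("A", "B"))
  expect_warning(rank_targets(rs, top_k = 10), "candidates")
})

test_that("planted bridges rank at the top across interactomes", {
  ranks <- vapply(1:20, function(s) {
    si <- simulate_interactome(seed = s)
    g <- igraph::graph_from_data_frame(si$edges, directed = FALSE)
    cent <- suppressWarnings(node_centralities(g))
    rk <- rank_targets(suppressWarnings(r_score(cent)), top_k = 3)
    which(rk$node_id == si$planted_bridge)
  }, numeric(1))
  expect_gte(mean(ranks <= 3), 0.8)
})

test_that("network files round-trip through SIF and edge TSV", {
  dir <- withr::local_tempdir()
  ct <- compound_target_network(
    "GE1", tibble::tibble(compound_id = "GE1", target = c("A", "B")))
  sif <- file.path(dir, "net.sif")
  write_sif(ct, sif)
  back <- read_sif(sif)
  expect_setequal(paste(back$from, back$to),
                  paste(network_edges(ct)$from, network_edges(ct)$to))
  gml <- file.path(dir, "net.graphml")
  write_graphml(ct, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::vcount(g2), igraph::vcount(ct))
})
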
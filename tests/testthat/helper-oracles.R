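# Independent oracles used to cross-check the package implementations.

# Single-component PLS1 (NIPALS), written directly from the algorithm
# definition: X and y are centred.
pls1_oracle <- function(X, y) {
  w <- drop(crossprod(X, y))
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  p <- drop(crossprod(X, t)) / sum(t^2)
  c <- sum(y * t) / sum(t^2)
  list(w = w, scores = t, loading = p, c = c, fitted = c * t)
}

# Brute-force node centralities from first principles: BFS distances,
# shortest-path counts by the layered DP, and betweenness via the
# pair-sum identity sigma_sv * sigma_vt / sigma_st.
oracle_centralities <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  adj <- lapply(nodes, function(v) {
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  names(adj) <- nodes
  bfs <- function(s) {
    d <- setNames(rep(Inf, n), nodes)
    sig <- setNames(rep(0, n), nodes)
    d[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (is.infinite(d[u])) { d[u] <- d[v] + 1; nxt <- c(nxt, u) }
          if (d[u] == d[v] + 1) sig[u] <- sig[u] + sig[v]
        }
      }
      frontier <- unique(nxt)
    }
    list(d = d, sig = sig)
  }
  B <- lapply(nodes, bfs)
  names(B) <- nodes
  dmat <- do.call(rbind, lapply(B, function(b) b$d))
  btw <- setNames(rep(0, n), nodes)
  for (v in nodes) {
    for (s in nodes) {
      for (t in nodes) {
        if (s >= t || s == v || t == v) next
        if (is.infinite(dmat[s, t])) next
        if (dmat[s, v] + dmat[v, t] == dmat[s, t]) {
          btw[v] <- btw[v] +
            B[[s]]$sig[v] * B[[v]]$sig[t] / B[[s]]$sig[t]
        }
      }
    }
  }
  comp_of <- setNames(rep(NA_integer_, n), nodes)
  ci <- 0
  for (v in nodes) {
    if (is.na(comp_of[v])) {
      ci <- ci + 1
      comp_of[names(which(is.finite(dmat[v, ])))] <- ci
    }
  }
  do.call(rbind, lapply(nodes, function(v) {
    members <- nodes[comp_of == comp_of[v]]
    nc <- length(members)
    if (nc < 2) return(NULL)
    denom <- if (nc > 2) (nc - 1) * (nc - 2) / 2 else 1
    data.frame(node_id = v,
               aspl = mean(dmat[v, setdiff(members, v)]),
               betweenness = btw[v] / denom,
               stringsAsFactors = FALSE)
  }))
}

# Hypergeometric upper tail by explicit term enumeration.
ora_oracle <- function(hits, pathway, universe, selected) {
  ks <- hits:min(pathway, selected)
  sum(choose(pathway, ks) * choose(universe - pathway, selected - ks)) /
    choose(universe, selected)
}

# Quick feature-table builder for toys: mat is features x samples.
make_ft <- function(mat, groups, is_qc = rep(FALSE, length(groups)),
                    mz = NULL, rt = NULL) {
  nf <- nrow(mat)
  feats <- tibble::tibble(
    feature_id = rownames(mat) %||% paste0("F", seq_len(nf)),
    mz = mz %||% seq(100, 100 + nf - 1),
    rt = rt %||% seq_len(nf))
  samp <- tibble::tibble(
    sample_id = colnames(mat) %||% paste0("s", seq_len(ncol(mat))),
    group = groups, is_qc = is_qc)
  feature_table(feats, mat, samp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Erdos-Renyi random graph edge list for oracle tests; a short chain is
# always included so the graph has at least 3 non-isolated nodes.
random_graph_edges <- function(n, p = 0.35) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  pick <- stats::runif(ncol(pairs)) < p
  base <- tibble::tibble(from = nodes[1:2], to = nodes[2:3])
  dplyr::distinct(dplyr::bind_rows(
    base, tibble::tibble(from = pairs[1, pick], to = pairs[2, pick])))
}

# Two-class toy scaled matrix with a planted separation.
toy_two_class <- function(n_per = 6, p = 10, delta = 3, sd = 1, seed = 1) {
  withr::local_seed(seed)
  X <- matrix(stats::rnorm(2 * n_per * p, sd = sd), 2 * n_per, p)
  X[(n_per + 1):(2 * n_per), 1] <- X[(n_per + 1):(2 * n_per), 1] + delta
  y <- rep(c("a", "b"), each = n_per)
  list(X = sweep(X, 2, colMeans(X)), y = y)
}
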
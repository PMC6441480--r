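# Independent oracles and graph fixtures used across test files.

# Random connected G(n, p) graph with named vertices.
random_connected_graph <- function(n, p = 0.15, seed = 1L) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# Brute-force centralities by explicit geodesic enumeration: for every node
# pair, depth-first enumerate all shortest paths (guided only by the
# distance matrix) and count how many pass through each interior node.
# Deliberately naive and independent of the Brandes accumulation scheme.
oracle_centralities <- function(g) {
  n <- igraph::vcount(g)
  D <- igraph::distances(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  betw <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
    paths <- list()
    enumerate <- function(v, acc) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- acc
        return(invisible(NULL))
      }
      for (w in adj[[v]])
        if (D[w, t] == D[v, t] - 1) enumerate(w, c(acc, w))
    }
    enumerate(s, integer())
    interior <- unlist(lapply(paths, function(p) p[-length(p)]))
    if (length(interior))
      betw <- betw + tabulate(interior, n) / length(paths)
  }
  if (n > 2L) betw <- betw / ((n - 1) * (n - 2) / 2)
  data.frame(node = igraph::V(g)$name,
             degree = as.integer(igraph::degree(g)),
             betweenness = betw,
             closeness = unname((n - 1) / rowSums(D)))
}

# Exhaustive hypergeometric tail: enumerate every size-n draw from a
# universe of U genes of which the first K are marked.
oracle_hypergeom <- function(k, K, n, U) {
  draws <- utils::combn(U, n)
  mean(colSums(draws <= K) >= k)
}

# 300-node preferential-attachment graph with one explicitly planted
# high-degree, high-betweenness node wired to a quarter of the network.
planted_hub_graph <- function(seed = 11L) {
  g <- generate_scale_free_network(299L, 2L, seed = seed)
  set.seed(seed + 1L)
  targets <- sample(igraph::V(g)$name, 75L)
  g <- igraph::add_vertices(g, 1L, name = "PLANTED")
  igraph::add_edges(g, rbind("PLANTED", targets))
}
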
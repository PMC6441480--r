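#' Build a simple undirected interaction graph
#'
#' Constructs the protein-protein interaction graph from an edge list:
#' self-loops are dropped and duplicate edges (in either orientation)
#' collapsed, so the result is a simple undirected graph. Nodes listed in
#' `nodes` but absent from any edge become isolated vertices.
#'
#' @param edges Two-column character matrix or data frame of endpoint pairs.
#' @param nodes Optional character vector of node ids to include even when
#'   isolated.
#' @return An igraph undirected simple graph with named vertices.
#' @export
build_graph <- function(edges, nodes = character()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), 0L, 2L)
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop("`edges` must have two columns (source, target)", call. = FALSE)
  mode(edges) <- "character"
  bad <- which(is.na(edges) | !nzchar(trimws(edges)), arr.ind = TRUE)
  if (nrow(bad))
    stop("malformed edge record at row ", bad[1L, 1L], call. = FALSE)
  ids <- sort(unique(c(as.character(edges), as.character(nodes))))
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Extract the main connected component
#'
#' Returns the induced subgraph on the largest connected node set. If two
#' components tie for size, the one containing the lexicographically
#' smallest node id wins, so the choice is reproducible.
#'
#' @param g An igraph graph with named vertices.
#' @return The main component as an igraph graph.
#' @export
main_component <- function(g) {
  if (igraph::vcount(g) == 0L)
    stop("empty graph has no components", call. = FALSE)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    best <- best[which.min(rank(firsts, ties.method = "first"))]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

# Adjacency list as integer indices, from a named igraph graph.
adjacency_index <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

#' Degree, betweenness and closeness centralities
#'
#' Computes the three centralities used for hub and central-node selection
#' on a connected simple graph, with unweighted shortest paths:
#' \describe{
#'   \item{degree}{number of incident edges;}
#'   \item{betweenness}{Brandes' shortest-path betweenness — the fraction of
#'     geodesics between other node pairs passing through the node —
#'     normalized by `(N-1)(N-2)/2` so values lie in `[0, 1]`;}
#'   \item{closeness}{`(N-1) / sum of distances` to all other nodes, the
#'     reciprocal of the average shortest-path length.}
#' }
#' Both conventions match Cytoscape's NetworkAnalyzer on connected
#' undirected networks.
#'
#' @param g A connected igraph graph with named vertices (run on
#'   [main_component()] output; disconnected input is an error because
#'   closeness is undefined across components).
#' @return Data frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, sorted by degree descending (ties by node id).
#' @export
compute_centralities <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L)
    stop("empty graph", call. = FALSE)
  if (!igraph::is_connected(g))
    stop("graph must be connected; extract the main component first",
         call. = FALSE)
  adj <- adjacency_index(g)
  names_ <- igraph::V(g)$name
  betw <- numeric(n)
  dist_sum <- numeric(n)

  for (s in seq_len(n)) {
    # Brandes (2001): BFS from s accumulating geodesic counts sigma and
    # predecessor lists, then back-propagate pair dependencies.
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(n); head <- 1L; tail_ <- 1L
    order_visited[1L] <- s
    while (head <= tail_) {
      v <- order_visited[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail_ <- tail_ + 1L
          order_visited[tail_] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in seq.int(tail_, 1L)) {
      w <- order_visited[i]
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) betw[w] <- betw[w] + delta[w]
    }
    dist_sum <- dist_sum + dist
  }

  # Each undirected pair was counted from both endpoints; halve, then
  # normalize by the number of ordered pairs excluding the node itself.
  betw <- betw / 2
  if (n > 2L) betw <- betw / ((n - 1) * (n - 2) / 2)
  clo <- if (n == 1L) rep(1, n) else (n - 1) / dist_sum
  out <- data.frame(node = names_, degree = lengths(adj),
                    betweenness = betw, closeness = clo, row.names = NULL)
  out <- out[order(-out$degree, out$node, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree distribution of a graph
#'
#' Counts nodes per observed degree, for degrees at least 1 (degree-0 nodes
#' cannot enter a log-log power-law fit).
#'
#' @param g An igraph graph.
#' @return Data frame with columns `k` (degree, ascending) and `count`
#'   (number of nodes of that degree).
#' @export
degree_distribution_table <- function(g) {
  if (igraph::vcount(g) == 0L)
    stop("empty graph", call. = FALSE)
  deg <- igraph::degree(g)
  deg <- deg[deg >= 1]
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab),
             row.names = NULL)
}

#' Fit a power law to a degree distribution
#'
#' Fits `count = a * k^b` by ordinary least squares of `log(count)` on
#' `log(k)` — the standard log-log regression diagnostic for scale-free
#' topology. The correlation is the Pearson correlation of the logged pairs
#' and R-squared its square, i.e. R-squared is computed on logarithmized
#' values. A clearly negative exponent `b` is the scale-free signature.
#'
#' @param dist Data frame with columns `k` and `count`, as produced by
#'   [degree_distribution_table()]; rows with `k < 1` or `count < 1` are
#'   excluded (their logarithm is undefined).
#' @return An object of class `power_law_fit`: list with `a`, `b`,
#'   `correlation`, `r_squared`, `n_points`.
#' @export
fit_power_law <- function(dist) {
  stopifnot(is.data.frame(dist), all(c("k", "count") %in% names(dist)))
  use <- dist$k >= 1 & dist$count >= 1
  k <- dist$k[use]
  count <- dist$count[use]
  if (length(k) < 2L)
    stop("need at least two usable (k >= 1, count >= 1) points", call. = FALSE)
  lx <- log(k)
  ly <- log(count)
  fit <- stats::lm(ly ~ lx)
  r <- stats::cor(lx, ly)
  structure(list(a = unname(exp(stats::coef(fit)[1L])),
                 b = unname(stats::coef(fit)[2L]),
                 correlation = r,
                 r_squared = r^2,
                 n_points = length(k)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit: count = %.3f * k^%.3f  (r = %.3f, R^2 = %.3f, %d points)\n",
    x$a, x$b, x$correlation, x$r_squared, x$n_points))
  invisible(x)
}

#' Write a centrality table as TSV
#'
#' Columns `node`, `degree`, `betweenness`, `closeness`, sorted by degree
#' descending — the layout of a hub-candidate table.
#'
#' @param table Data frame from [compute_centralities()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centralities <- function(table, path) {
  utils::write.table(table[order(-table$degree, table$node), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
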
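#' Annotation table of gene sets
#'
#' Gene-set annotations (term id, term name, member genes) together with the
#' annotation universe — the gene background against which enrichment is
#' tested.
#'
#' @param sets Named list of character vectors; names are term ids, values
#'   the member genes of each term.
#' @param names Named character vector of human-readable term names (same
#'   names as `sets`). Defaults to the term ids.
#' @param universe Character vector of all annotated gene ids. Defaults to
#'   the union of the term gene sets.
#' @return An object of class `annotation_table` with elements `sets`,
#'   `names` and `universe`.
#' @export
annotation_table <- function(sets, names = NULL, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(base::names(sets)))
    stop("`sets` must be a named list (term ids)", call. = FALSE)
  if (anyDuplicated(base::names(sets)))
    stop("duplicate term ids", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("every term must annotate at least one gene", call. = FALSE)
  sets <- lapply(sets, as.character)
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  outside <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(outside))
    stop("term genes outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  if (is.null(names))
    names <- stats::setNames(base::names(sets), base::names(sets))
  structure(list(sets = sets,
                 names = names[base::names(sets)],
                 universe = as.character(universe)),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("annotation_table: %d terms over %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

# Runs `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards, so generators are pure functions of their
# arguments.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a two-group log2 expression matrix with planted fold changes
#'
#' Draws gene baselines from N(8, 2) on the log2 scale, adds independent
#' N(0, sigma) noise per entry, and plants a log2 effect of `log2_effect` in
#' the second group for `n_deg` randomly chosen genes. With `sigma = 0` every
#' planted gene's fold change is exactly `2^log2_effect`. The defaults mirror
#' a small two-arm microarray comparison: three samples per group.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (at least 2, so a t-test is defined).
#' @param n_deg Number of genes given a planted effect (at most `n_genes`).
#' @param log2_effect Log2 fold change added to group B for planted genes.
#' @param sigma Per-entry noise standard deviation on the log2 scale.
#' @param seed Integer seed; identical arguments give identical output.
#' @return List with `matrix` (an [expr_matrix], groups `A`/`B`) and `truth`
#'   (list: `planted_genes`, `log2_effect`, `sigma`, `seed`).
#' @export
generate_expression <- function(n_genes, n_per_group = 3L, n_deg = 0L,
                                log2_effect = 2, sigma = 0.5, seed = 1L) {
  if (n_deg > n_genes)
    stop("n_deg must not exceed n_genes", call. = FALSE)
  if (n_per_group < 2L)
    stop("need at least two samples per group", call. = FALSE)
  if (sigma < 0)
    stop("sigma must be non-negative", call. = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- c(sprintf("A%d", seq_len(n_per_group)),
               sprintf("B%d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("A", "B"), each = n_per_group), samples)
  with_seed(seed, {
    baseline <- stats::rnorm(n_genes, mean = 8, sd = 2)
    values <- matrix(baseline, n_genes, 2L * n_per_group,
                     dimnames = list(genes, samples))
    values <- values + matrix(stats::rnorm(length(values), 0, sigma),
                              nrow = n_genes)
    planted <- if (n_deg > 0L) sort(sample(genes, n_deg)) else character()
    if (length(planted))
      values[planted, groups == "B"] <-
        values[planted, groups == "B"] + log2_effect
    list(matrix = expr_matrix(values, groups),
         truth = list(planted_genes = planted, log2_effect = log2_effect,
                      sigma = sigma, seed = seed))
  })
}

#' Generate a scale-free network by preferential attachment
#'
#' Barabasi-Albert style growth: start from a clique of `m_edges_per_node`
#' nodes (which guarantees connectivity), then attach each new node to `m`
#' distinct existing nodes chosen with probability proportional to current
#' degree. The resulting degree distribution follows a power law with
#' negative exponent, the diagnostic under which hub-based analyses are
#' justified.
#'
#' @param n_nodes Number of nodes.
#' @param m_edges_per_node Edges added per new node; must be < `n_nodes`.
#' @param seed Integer seed.
#' @return A connected simple undirected igraph graph with `n_nodes` named
#'   vertices (`n0001`, ...).
#' @export
generate_scale_free_network <- function(n_nodes, m_edges_per_node = 2L,
                                        seed = 1L) {
  m <- as.integer(m_edges_per_node)
  if (m < 1L || m >= n_nodes)
    stop("need 1 <= m_edges_per_node < n_nodes", call. = FALSE)
  ids <- sprintf("n%04d", seq_len(n_nodes))
  with_seed(seed, {
    deg <- integer(n_nodes)
    from <- integer(0)
    to <- integer(0)
    if (m > 1L) {
      seedpairs <- utils::combn(m, 2L)
      from <- seedpairs[1L, ]
      to <- seedpairs[2L, ]
      deg[seq_len(m)] <- m - 1L
    }
    for (v in seq.int(m + 1L, n_nodes)) {
      existing <- seq_len(v - 1L)
      w <- deg[existing]
      if (sum(w) == 0) w <- rep(1, length(existing))
      targets <- if (length(existing) == m) existing
                 else sample(existing, m, prob = w)
      from <- c(from, rep.int(v, m))
      to <- c(to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
    g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::V(g)$name <- ids
    g
  })
}

#' Generate random term annotations over a gene universe
#'
#' Each term draws its genes uniformly without replacement from `genes`,
#' with term sizes uniform on `[min_size, max_size]` — a null annotation
#' model with no relation between terms and any expression signal.
#'
#' @param genes Character vector of gene ids (the universe).
#' @param n_terms Number of terms.
#' @param min_size,max_size Term size bounds; `max_size` at most
#'   `length(genes)`.
#' @param seed Integer seed.
#' @return An [annotation_table] with terms `T001`, ... and universe `genes`.
#' @export
generate_annotations <- function(genes, n_terms, min_size = 5L,
                                 max_size = 50L, seed = 1L) {
  genes <- as.character(genes)
  if (!length(genes))
    stop("empty gene universe", call. = FALSE)
  if (!(min_size <= max_size && max_size <= length(genes)))
    stop("need min_size <= max_size <= number of genes", call. = FALSE)
  ids <- sprintf("T%03d", seq_len(n_terms))
  with_seed(seed, {
    sizes <- if (n_terms) min_size - 1L +
      sample.int(max_size - min_size + 1L, n_terms, replace = TRUE)
    else integer()
    sets <- lapply(sizes, function(s) sample(genes, s))
    annotation_table(stats::setNames(sets, ids),
                     stats::setNames(ids, ids), universe = sort(genes))
  })
}

#' Packaged enrichment table of the six-gene critical set
#'
#' The 34 enriched biological terms reported for the colon-cancer grade
#' II/III critical genes, shipped as a plain-text fixture: term name, source
#' database, percent genes per term (%G/T), genes per term (G/T) and the
#' associated genes found, transcribed verbatim — including the misprinted
#' gene symbol "APK3" in the first row, which is additionally exposed
#' normalized to MAPK3 so that membership counts come out right.
#'
#' @return List with `rows` (data frame: `row`, `source`, `term_name`,
#'   `percent_gt`, `gt`, and list-columns `genes_raw` / `genes` with the
#'   verbatim and symbol-normalized gene sets) and `query` (the six critical
#'   genes the table was computed for).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "critical_set_enrichment.tsv",
                      package = "critnet", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  genes_raw <- strsplit(df$genes, ",", fixed = TRUE)
  genes <- lapply(genes_raw, function(g) unique(ifelse(g == "APK3", "MAPK3", g)))
  rows <- data.frame(row = df$row, source = df$source,
                     term_name = df$term_name, percent_gt = df$percent_gt,
                     gt = df$gt, row.names = NULL)
  rows$genes_raw <- genes_raw
  rows$genes <- genes
  list(rows = rows,
       query = c("MAPK3", "AKT1", "SRC", "TP53", "GAPDH", "ALB"))
}

#' Write a complete synthetic study bundle
#'
#' Generates and writes every input the pipeline consumes, wired together
#' the way the study design assumes: a two-group log2 expression matrix
#' with planted fold changes; a preferential-attachment interaction network
#' whose nodes are the fold-change-passing top genes of that matrix plus a
#' set of added relevant genes; random term annotations over the network
#' genes; and a characterized-gene list covering a fraction of all genes.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes,n_per_group,n_deg,log2_effect,sigma,seed Passed to
#'   [generate_expression()].
#' @param top_n,fc_low,fc_high Thresholds used to pick the network's
#'   differential genes (defaults 250, 0.5, 2).
#' @param n_added Added interaction partners that are not differential
#'   genes (default 100).
#' @param m_edges_per_node Preferential-attachment density (default 3).
#' @param n_terms Random annotation terms (default 50).
#' @param characterized_fraction Fraction of genes marked characterized
#'   (default 0.95).
#' @return List with the file `paths` (expression, groups, edges,
#'   annotations, characterized), the simulation `truth`, and the network
#'   node ids.
#' @export
generate_study_bundle <- function(dir, n_genes = 1000L, n_per_group = 3L,
                                  n_deg = 50L, log2_effect = 3, sigma = 0.5,
                                  seed = 1L, top_n = 250L, fc_low = 0.5,
                                  fc_high = 2.0, n_added = 100L,
                                  m_edges_per_node = 3L, n_terms = 50L,
                                  characterized_fraction = 0.95) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                groups = file.path(dir, "groups.tsv"),
                edges = file.path(dir, "network.tsv"),
                annotations = file.path(dir, "annotations.gmt"),
                characterized = file.path(dir, "characterized.txt"))
  sim <- generate_expression(n_genes, n_per_group, n_deg, log2_effect,
                             sigma, seed)
  write_expression(sim$matrix, paths$expression, paths$groups)
  degs <- filter_degs(rank_genes(median_center(sim$matrix)),
                      top_n, fc_low, fc_high)
  nodes <- c(degs$gene, sprintf("added%03d", seq_len(n_added)))
  g <- generate_scale_free_network(length(nodes), m_edges_per_node,
                                   seed = seed + 1L)
  igraph::V(g)$name <- with_seed(seed + 2L, sample(nodes))
  write_network(g, paths$edges)
  ann <- generate_annotations(nodes, n_terms, min_size = 5L,
                              max_size = min(50L, length(nodes)),
                              seed = seed + 3L)
  write_gmt(ann, paths$annotations)
  characterized <- with_seed(seed + 4L, sample(
    rownames(sim$matrix$values),
    round(characterized_fraction * n_genes)))
  writeLines(sort(characterized), paths$characterized)
  list(paths = paths, truth = sim$truth, network_nodes = nodes)
}
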
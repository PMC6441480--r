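#' Right-tailed hypergeometric p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `U` genes of which `K`
#' carry the annotation — the standard over-representation test for gene
#' sets. Computed via the stable tail routine of [stats::phyper()].
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param U Universe size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(U, K, n)`.
#' @export
hypergeom_pvalue <- function(k, K, n, U) {
  if (K > U || n > U || k > min(K, n) || k < 0 || min(K, n, U) < 0)
    stop("impossible hypergeometric configuration", call. = FALSE)
  stats::phyper(k - 1, K, U - K, n, lower.tail = FALSE)
}

# Half-up rounding to `digits` decimals (round() rounds half to even, which
# would print 7.315 as 7.31 rather than the conventional 7.32).
round_half_up <- function(x, digits = 2L) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

#' Percent genes per term
#'
#' The %G/T statistic of an enrichment row: the percentage of a term's
#' annotated genes found in the query, `100 * k / K`, rounded half-up to
#' two decimals as conventionally printed.
#'
#' @param k Overlap count (1 <= k <= K).
#' @param K Term size.
#' @return `round(100 * k / K, 2)` with half-up rounding.
#' @export
percent_genes_per_term <- function(k, K) {
  if (any(K < 1)) stop("term size K must be positive", call. = FALSE)
  if (any(k < 1 | k > K)) stop("need 1 <= k <= K", call. = FALSE)
  round_half_up(100 * k / K, 2L)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests every annotation term overlapping the query for over-representation
#' against the annotation universe, adjusts p-values by Holm's step-down
#' procedure across all tested terms, and returns the significant rows.
#' Query genes outside the universe are dropped with a warning (they carry
#' no annotation information).
#'
#' @param query Character vector of query gene ids.
#' @param annotations An [annotation_table].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param all Return all tested rows instead of only the significant ones.
#' @return Data frame sorted by `p_value` ascending with columns `term_id`,
#'   `term_name`, `term_size` (K), `overlap` (k), `percent_gt`, `p_value`,
#'   `adjusted_p` and list-column `overlap_genes`; one row per term with
#'   overlap at least 1.
#' @export
enrich <- function(query, annotations, alpha = 0.05, all = FALSE) {
  stopifnot(inherits(annotations, "annotation_table"))
  query <- unique(as.character(query))
  if (!length(query))
    stop("empty query", call. = FALSE)
  outside <- setdiff(query, annotations$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the annotation ",
            "universe dropped: ", paste(outside, collapse = ", "),
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (!length(query))
    stop("no query genes left inside the annotation universe", call. = FALSE)
  U <- length(annotations$universe)
  n <- length(query)
  overlap <- lapply(annotations$sets, intersect, query)
  keep <- lengths(overlap) >= 1L
  if (!any(keep)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      term_size = integer(), overlap = integer(),
                      percent_gt = numeric(), p_value = numeric(),
                      adjusted_p = numeric())
    out$overlap_genes <- list()
    return(out)
  }
  ids <- names(annotations$sets)[keep]
  K <- lengths(annotations$sets)[keep]
  k <- lengths(overlap)[keep]
  p <- mapply(hypergeom_pvalue, k = k, K = K,
              MoreArgs = list(n = n, U = U))
  out <- data.frame(term_id = ids,
                    term_name = unname(annotations$names[ids]),
                    term_size = unname(K), overlap = unname(k),
                    percent_gt = percent_genes_per_term(unname(k), unname(K)),
                    p_value = unname(p),
                    adjusted_p = unname(stats::p.adjust(p, method = "holm")),
                    row.names = NULL)
  out$overlap_genes <- unname(overlap[keep])
  if (!all) out <- out[out$adjusted_p < alpha, , drop = FALSE]
  out <- out[order(out$p_value, out$term_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene term-membership counts
#'
#' Counts, for each gene, how many enrichment rows list it among the
#' associated genes — a summary of how broadly each critical gene is
#' implicated across terms.
#'
#' @param rows Data frame with a `genes` list-column (e.g.
#'   `table2_fixture()$rows` or the output of [enrich()] via its
#'   `overlap_genes` column renamed).
#' @param genes Character vector of genes to count.
#' @return Named integer vector of row counts per gene.
#' @export
membership_counts <- function(rows, genes) {
  sets <- if ("genes" %in% names(rows)) rows$genes else rows$overlap_genes
  counts <- vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
  stats::setNames(as.integer(counts), genes)
}

#' Cohen's kappa between two terms' gene memberships
#'
#' Chance-corrected agreement of the two binary membership vectors over the
#' universe: `kappa = (p_o - p_e) / (1 - p_e)` where `p_o` is the observed
#' agreement and `p_e` the agreement expected from the marginal membership
#' rates. Used to decide whether two enriched terms describe the same gene
#' group. When both vectors are constant and equal (`p_e = 1`) the score is
#' defined as 1.
#'
#' @param term_a,term_b Character vectors of member genes (subsets of
#'   `universe`).
#' @param universe Character vector of at least 2 genes.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_score <- function(term_a, term_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) < 2L)
    stop("universe must contain at least two genes", call. = FALSE)
  if (length(setdiff(term_a, universe)) || length(setdiff(term_b, universe)))
    stop("terms must be subsets of the universe", call. = FALSE)
  a <- universe %in% term_a
  b <- universe %in% term_b
  N <- length(universe)
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Cluster enriched terms by kappa agreement
#'
#' Builds a term graph with an edge wherever the pairwise kappa of the two
#' terms' gene sets reaches `threshold`, and takes connected components as
#' clusters. Cluster ids are assigned in order of each cluster's best
#' (smallest) p-value, so cluster 1 contains the most significant term.
#'
#' @param rows Enrichment rows carrying gene sets: a `genes` or
#'   `overlap_genes` list-column, a term identifier column (`term_id`,
#'   `term_name` or `row`) and optionally `p_value` (row order is used
#'   otherwise).
#' @param threshold Kappa threshold in `(0, 1]` (default 0.4).
#' @param universe Gene universe for the membership vectors; defaults to
#'   the union of the rows' gene sets.
#' @return Named integer vector mapping term identifier to cluster id.
#' @export
cluster_terms <- function(rows, threshold = 0.4, universe = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  sets <- if ("genes" %in% names(rows)) rows$genes else rows$overlap_genes
  idcol <- intersect(c("term_id", "term_name", "row"), names(rows))[1L]
  ids <- as.character(rows[[idcol]])
  m <- length(sets)
  if (m == 0L) return(stats::setNames(integer(), character()))
  if (is.null(universe))
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  p <- if ("p_value" %in% names(rows)) rows$p_value else seq_len(m)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1L) {
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      if (kappa_score(sets[[i]], sets[[j]], universe) >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(m), find, integer(1))
  best_p <- vapply(split(seq_len(m), root), function(ix) min(p[ix]), numeric(1))
  cluster_of_root <- stats::setNames(rank(best_p, ties.method = "first"),
                                     names(best_p))
  stats::setNames(as.integer(cluster_of_root[as.character(root)]), ids)
}

#' Write enrichment rows as TSV
#'
#' Mirrors the published layout: term, %G/T, G/T and the associated genes,
#' plus the raw and adjusted p-values; optionally a second TSV of cluster
#' assignments.
#'
#' @param rows [enrich()] output.
#' @param path Output TSV path.
#' @param clusters Optional [cluster_terms()] result.
#' @param clusters_path Output path for the cluster TSV.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path, clusters = NULL,
                             clusters_path = NULL) {
  sets <- if ("overlap_genes" %in% names(rows)) rows$overlap_genes
          else rows$genes
  flat <- data.frame(term_id = rows$term_id, term_name = rows$term_name,
                     percent_gt = rows$percent_gt, gt = rows$overlap,
                     term_size = rows$term_size,
                     p_value = rows$p_value, adjusted_p = rows$adjusted_p,
                     genes = vapply(sets, paste, character(1), collapse = ","))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(clusters)) {
    stopifnot(!is.null(clusters_path))
    utils::write.table(
      data.frame(term = names(clusters), cluster = as.integer(clusters)),
      clusters_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
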
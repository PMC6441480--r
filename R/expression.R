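#' Two-group expression matrix
#'
#' Container for a log2-scale expression matrix (genes in rows, samples in
#' columns) with a two-group sample design. This is the unit every
#' differential-expression step of the pipeline operates on.
#'
#' @param values Numeric matrix of log2 intensities with gene ids as row names
#'   and sample ids as column names.
#' @param groups Character or factor vector assigning each sample to one of
#'   exactly two groups. Either named by sample id or given in column order.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (a named factor with two levels; the first
#'   level is the reference group for fold changes).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' @export
expr_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("`groups` length must match the number of samples", call. = FALSE)
    names(groups) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  groups <- factor(as.character(groups[colnames(values)]))
  if (nlevels(groups) != 2L)
    stop("exactly two sample groups are required, got ", nlevels(groups),
         call. = FALSE)
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (groups: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", levels(x$groups),
                            tabulate(x$groups)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

group_columns <- function(x) split(seq_len(ncol(x$values)), x$groups)

#' Median-center each sample
#'
#' Subtracts the per-sample median so every column has median zero, the
#' normalization under which array profiles become comparable in a box plot.
#' Idempotent; gene and sample order are preserved.
#'
#' @param matrix An [expr_matrix].
#' @return An [expr_matrix] with column medians 0 (to numerical tolerance).
#' @export
median_center <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (nrow(matrix$values) == 0L || ncol(matrix$values) == 0L)
    stop("empty expression matrix", call. = FALSE)
  centered <- sweep(matrix$values, 2L,
                    apply(matrix$values, 2L, stats::median), "-")
  expr_matrix(centered, matrix$groups)
}

#' Per-sample five-number summaries
#'
#' The statistics behind a box-plot diagnostic of sample comparability:
#' minimum, lower hinge, median, upper hinge and maximum of each sample
#' column (Tukey hinges, as drawn by [graphics::boxplot()]).
#'
#' @param matrix An [expr_matrix].
#' @return Data frame with columns `sample`, `min`, `q1`, `median`, `q3`,
#'   `max`, one row per sample, in column order.
#' @export
boxplot_stats <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (nrow(matrix$values) == 0L)
    stop("empty expression matrix", call. = FALSE)
  fn <- t(apply(matrix$values, 2L, stats::fivenum))
  data.frame(sample = colnames(matrix$values),
             min = fn[, 1L], q1 = fn[, 2L], median = fn[, 3L],
             q3 = fn[, 4L], max = fn[, 5L], row.names = NULL)
}

#' Linear-scale fold change per gene
#'
#' Fold change of the second group relative to the first, computed as
#' `2^(mean_B - mean_A)` of the log2 values, i.e. the ratio of the group
#' geometric means on the raw scale.
#'
#' @param matrix An [expr_matrix].
#' @return Named numeric vector of strictly positive fold changes, one per
#'   gene.
#' @export
fold_change <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  cols <- group_columns(matrix)
  if (any(lengths(cols) < 1L))
    stop("both groups need at least one sample", call. = FALSE)
  mean_a <- rowMeans(matrix$values[, cols[[1L]], drop = FALSE])
  mean_b <- rowMeans(matrix$values[, cols[[2L]], drop = FALSE])
  2 ^ (mean_b - mean_a)
}

# Welch two-sample p-value for one gene; both groups constant is handled by
# convention (p = 1 if the means agree, p = 0 if they differ) because the
# t statistic is undefined there.
welch_p <- function(a, b) {
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Rank genes by differential-expression significance
#'
#' Runs Welch's unequal-variance t-test between the two groups on the log2
#' values of every gene and ranks genes by p-value (ascending). Ties are
#' broken by absolute log2 fold change (descending), then by gene id.
#'
#' @param matrix An [expr_matrix] with at least two samples per group.
#' @return Data frame with columns `gene`, `fold_change` (linear scale),
#'   `p_value` and `rank` (1 = most significant), sorted by rank.
#' @export
rank_genes <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  cols <- group_columns(matrix)
  if (any(lengths(cols) < 2L))
    stop("each group needs at least two samples for the t-test", call. = FALSE)
  v <- matrix$values
  p <- vapply(seq_len(nrow(v)), function(i)
    welch_p(v[i, cols[[1L]]], v[i, cols[[2L]]]), numeric(1))
  fc <- fold_change(matrix)
  ord <- order(p, -abs(log2(fc)), rownames(v), method = "radix")
  data.frame(gene = rownames(v)[ord],
             fold_change = unname(fc[ord]),
             p_value = p[ord],
             rank = seq_along(ord),
             row.names = NULL)
}

#' Filter ranked genes to fold-change-passing top hits
#'
#' Takes the `top_n` most significant records and keeps those whose linear
#' fold change lies outside `(fc_low, fc_high)` — strictly below `fc_low` or
#' strictly above `fc_high`. Defaults follow the usual two-fold rule on
#' top-250 rankings.
#'
#' @param records Data frame as returned by [rank_genes()].
#' @param top_n Number of top-ranked records considered (default 250).
#' @param fc_low,fc_high Fold-change thresholds (defaults 0.5 and 2).
#' @return The surviving records, original order preserved. May be empty.
#' @export
filter_degs <- function(records, top_n = 250L, fc_low = 0.5, fc_high = 2.0) {
  stopifnot(is.data.frame(records), top_n >= 1L, fc_low > 0, fc_high >= fc_low)
  kept <- records[records$rank <= top_n, , drop = FALSE]
  kept[kept$fold_change < fc_low | kept$fold_change > fc_high, , drop = FALSE]
}

#' Drop genes without annotation
#'
#' Keeps only records whose gene id is in the characterized set, mirroring
#' the removal of unannotated probes before network construction.
#'
#' @param records Data frame with a `gene` column.
#' @param characterized Character vector of characterized gene ids.
#' @return The records whose gene is characterized, order preserved.
#' @export
drop_uncharacterized <- function(records, characterized) {
  stopifnot(is.data.frame(records))
  records[records$gene %in% characterized, , drop = FALSE]
}
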
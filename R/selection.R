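#' Selection thresholds for hub, central and critical nodes
#'
#' @param sd_multiplier Non-negative multiplier on the degree standard
#'   deviation; the hub cutoff is `mean(degree) + sd_multiplier * sd(degree)`
#'   (default 2).
#' @param central_fraction Fraction of nodes taken as central per centrality
#'   metric, in `(0, 1]` (default 0.05, i.e. the top 5%).
#' @param central_mode How the betweenness-top and closeness-top sets are
#'   combined into the central set: `"intersection"` (stricter, default) or
#'   `"union"`.
#' @return A `selection_config` list.
#' @export
selection_config <- function(sd_multiplier = 2, central_fraction = 0.05,
                             central_mode = c("intersection", "union")) {
  central_mode <- match.arg(central_mode)
  stopifnot(sd_multiplier >= 0,
            central_fraction > 0, central_fraction <= 1)
  structure(list(sd_multiplier = sd_multiplier,
                 central_fraction = central_fraction,
                 central_mode = central_mode),
            class = "selection_config")
}

#' Select hub nodes by the mean + k*SD degree cutoff
#'
#' A node is a hub when its degree is at least the mean degree plus
#' `sd_multiplier` sample standard deviations (denominator N-1). The
#' comparison is inclusive, so when every degree is equal (SD = 0) the
#' cutoff collapses to the mean and all nodes qualify.
#'
#' @param table Centrality table from [compute_centralities()] (needs
#'   `node` and `degree` columns; at least 2 rows, else the SD is
#'   undefined).
#' @param config A [selection_config()].
#' @return Character vector of hub node ids, sorted.
#' @export
select_hubs <- function(table, config = selection_config()) {
  stopifnot(is.data.frame(table), all(c("node", "degree") %in% names(table)))
  if (nrow(table) < 2L)
    stop("need at least two nodes to form a degree SD", call. = FALSE)
  cutoff <- mean(table$degree) + config$sd_multiplier * stats::sd(table$degree)
  sort(table$node[table$degree >= cutoff])
}

#' Select the top fraction of nodes by a centrality metric
#'
#' Returns exactly `ceiling(central_fraction * N)` nodes ranked by the
#' metric descending; ties are broken by degree descending, then node id,
#' so the selection is deterministic.
#'
#' @param table Centrality table from [compute_centralities()].
#' @param metric `"betweenness"` or `"closeness"`.
#' @param config A [selection_config()].
#' @return Character vector of selected node ids, sorted.
#' @export
select_top_fraction <- function(table, metric = c("betweenness", "closeness"),
                                config = selection_config()) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  n_take <- ceiling(config$central_fraction * nrow(table))
  ord <- order(-table[[metric]], -table$degree, table$node, method = "radix")
  sort(table$node[ord[seq_len(n_take)]])
}

#' Critical nodes: hubs that are also central
#'
#' @param hubs,central_bc,central_cc Character vectors of node ids from
#'   [select_hubs()] and [select_top_fraction()].
#' @return Sorted character vector: the intersection of all three sets.
#' @export
critical_nodes <- function(hubs, central_bc, central_cc) {
  sort(intersect(hubs, intersect(central_bc, central_cc)))
}

#' Full hub / central / critical selection
#'
#' Applies the three selection rules to a centrality table: hubs by the
#' mean + k*SD degree cutoff, central nodes as the top fraction by
#' betweenness and by closeness (combined by intersection or union per the
#' config), and critical nodes as the hubs that are also central — the
#' candidate biomarker set.
#'
#' @param table Centrality table from [compute_centralities()].
#' @param config A [selection_config()].
#' @return An object of class `selection_result`: list with sorted node-id
#'   vectors `hubs`, `central_bc`, `central_cc`, `central`, `critical`.
#' @export
select_nodes <- function(table, config = selection_config()) {
  hubs <- select_hubs(table, config)
  bc <- select_top_fraction(table, "betweenness", config)
  cc <- select_top_fraction(table, "closeness", config)
  central <- if (config$central_mode == "union") sort(union(bc, cc))
             else sort(intersect(bc, cc))
  structure(list(hubs = hubs, central_bc = bc, central_cc = cc,
                 central = central,
                 critical = sort(intersect(hubs, central))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d hubs, %d central (BC %d, CC %d), %d critical\n",
              length(x$hubs), length(x$central), length(x$central_bc),
              length(x$central_cc), length(x$critical)))
  if (length(x$critical))
    cat("critical:", paste(x$critical, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection result
#'
#' Writes the named node sets as JSON and, when a centrality table is
#' supplied, the critical set as a ranked TSV (rank, node, degree,
#' betweenness, closeness) ordered by degree descending.
#'
#' @param result A [select_nodes()] result.
#' @param json_path Output JSON path.
#' @param table Optional centrality table for the critical-set TSV.
#' @param tsv_path Output TSV path (required when `table` is given).
#' @return `json_path`, invisibly.
#' @export
write_selection <- function(result, json_path, table = NULL,
                            tsv_path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(unclass(result), json_path, pretty = TRUE)
  if (!is.null(table)) {
    stopifnot(!is.null(tsv_path))
    crit <- table[table$node %in% result$critical, , drop = FALSE]
    crit <- crit[order(-crit$degree, crit$node), , drop = FALSE]
    crit <- cbind(rank = seq_len(nrow(crit)), crit)
    utils::write.table(crit, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
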
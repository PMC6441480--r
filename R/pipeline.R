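#' Pipeline configuration
#'
#' One declarative object holding every input path and threshold of the
#' end-to-end analysis. Paths may be `NULL` where a stage is optional:
#' without `annotations` the enrichment stage is skipped, without
#' `characterized` no annotation filter is applied, without `actions` no
#' action-map summary is produced.
#'
#' @param expression,groups Expression TSV and sample-group TSV
#'   (see [read_expression()]).
#' @param edges Interaction edge list (TSV or SIF, see [read_network()]).
#' @param annotations Optional GMT path.
#' @param characterized Optional path to a one-gene-per-line list of
#'   characterized genes.
#' @param actions Optional action-edge TSV (see [read_action_edges()]).
#' @param output_dir Directory for all written artifacts (created if
#'   needed).
#' @param top_n,fc_low,fc_high Differential-expression thresholds
#'   (defaults 250, 0.5, 2).
#' @param sd_multiplier,central_fraction,central_mode Node-selection
#'   thresholds (defaults 2, 0.05, `"intersection"`;
#'   see [selection_config()]).
#' @param alpha Enrichment significance level (default 0.05).
#' @param kappa_threshold Term-clustering kappa threshold (default 0.4).
#' @param seed Integer seed recorded in the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, groups, edges,
                            annotations = NULL, characterized = NULL,
                            actions = NULL, output_dir = tempfile("critnet_"),
                            top_n = 250L, fc_low = 0.5, fc_high = 2.0,
                            sd_multiplier = 2, central_fraction = 0.05,
                            central_mode = "intersection",
                            alpha = 0.05, kappa_threshold = 0.4, seed = 1L) {
  stopifnot(top_n >= 1L, fc_low > 0, fc_high >= fc_low,
            sd_multiplier >= 0, central_fraction > 0, central_fraction <= 1,
            alpha > 0, alpha <= 1, kappa_threshold > 0, kappa_threshold <= 1)
  structure(list(expression = expression, groups = groups, edges = edges,
                 annotations = annotations, characterized = characterized,
                 actions = actions, output_dir = output_dir,
                 top_n = as.integer(top_n), fc_low = fc_low,
                 fc_high = fc_high, sd_multiplier = sd_multiplier,
                 central_fraction = central_fraction,
                 central_mode = match.arg(central_mode,
                                          c("intersection", "union")),
                 alpha = alpha, kappa_threshold = kappa_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(verbose, ...) if (verbose) message("[critnet] ", ...)

#' Run the full critical-node analysis
#'
#' Executes the pipeline stage by stage: median-center the expression
#' matrix, rank genes by Welch's t-test, filter by rank and fold change,
#' optionally drop uncharacterized genes, build the interaction graph,
#' extract its main component, compute degree/betweenness/closeness, fit
#' the degree-distribution power law, select hub, central and critical
#' nodes, and (when annotations are supplied) run hypergeometric enrichment
#' of the critical set with kappa term clustering. Every intermediate table
#' is written under `config$output_dir`, together with a JSON report. The
#' run is deterministic: identical config and inputs give an identical
#' report.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage cardinalities via [message()] (default
#'   TRUE).
#' @return The report, invisibly: a list with `config` (thresholds and
#'   seed), `degs` (counts per attrition step and the retained gene ids),
#'   `network` (node/edge/component counts), `fit` (power-law parameters),
#'   `selection` (all selected sets), `enrichment` (significant rows) and
#'   `actions` (per-node action counts), also written to `report.json`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output_dir, name)

  mat <- read_expression(config$expression, config$groups)
  stage_log(verbose, "expression: ", nrow(mat$values), " genes x ",
            ncol(mat$values), " samples")
  mat <- median_center(mat)
  utils::write.table(boxplot_stats(mat), out("boxplot_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ranked <- rank_genes(mat)
  degs <- filter_degs(ranked, config$top_n, config$fc_low, config$fc_high)
  stage_log(verbose, "DEG filter: ", min(config$top_n, nrow(ranked)),
            " top-ranked -> ", nrow(degs), " passing fold change")
  n_before_char <- nrow(degs)
  if (!is.null(config$characterized)) {
    characterized <- readLines(config$characterized)
    degs <- drop_uncharacterized(degs, characterized)
    stage_log(verbose, "characterized: ", n_before_char, " -> ", nrow(degs))
  }
  utils::write.table(degs, out("degs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  g <- read_network(config$edges)
  comp <- main_component(g)
  stage_log(verbose, "network: ", igraph::vcount(g), " nodes, ",
            igraph::ecount(g), " edges; main component ",
            igraph::vcount(comp), " nodes, ", igraph::ecount(comp), " edges")

  cent <- compute_centralities(comp)
  write_centralities(cent, out("centralities.tsv"))
  dist <- degree_distribution_table(comp)
  utils::write.table(dist, out("degree_distribution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fit <- fit_power_law(dist)
  stage_log(verbose, sprintf("power law: a=%.3f b=%.3f R^2=%.3f",
                             fit$a, fit$b, fit$r_squared))

  sel <- select_nodes(cent, selection_config(config$sd_multiplier,
                                             config$central_fraction,
                                             config$central_mode))
  write_selection(sel, out("selection.json"), cent, out("critical_nodes.tsv"))
  stage_log(verbose, length(sel$hubs), " hubs, ", length(sel$central),
            " central -> ", length(sel$critical), " critical")
  if (!length(sel$critical))
    warning("critical set is empty", call. = FALSE)

  enr <- NULL
  clusters <- NULL
  if (!is.null(config$annotations) && length(sel$critical)) {
    ann <- read_gmt(config$annotations)
    usable <- intersect(sel$critical, ann$universe)
    if (length(usable)) {
      enr <- enrich(sel$critical, ann, alpha = config$alpha)
      clusters <- if (nrow(enr)) cluster_terms(enr, config$kappa_threshold)
                  else stats::setNames(integer(), character())
      write_enrichment(enr, out("enrichment.tsv"), clusters,
                       out("term_clusters.tsv"))
      stage_log(verbose, "enrichment: ", nrow(enr),
                " significant terms in ",
                length(unique(clusters)), " cluster(s)")
    } else {
      stage_log(verbose, "enrichment skipped: no critical gene is annotated")
    }
  }

  actions <- NULL
  if (!is.null(config$actions)) {
    edges <- read_action_edges(config$actions)
    actions <- summarize_actions(edges)
    utils::write.table(actions, out("action_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  report <- list(
    config = unclass(config)[c("top_n", "fc_low", "fc_high", "sd_multiplier",
                               "central_fraction", "central_mode", "alpha",
                               "kappa_threshold", "seed")],
    degs = list(n_ranked = nrow(ranked),
                n_top = min(config$top_n, nrow(ranked)),
                n_pass_fc = n_before_char,
                n_characterized = nrow(degs),
                genes = degs$gene),
    network = list(n_nodes = igraph::vcount(g),
                   n_edges = igraph::ecount(g),
                   n_isolated = sum(igraph::degree(g) == 0),
                   component_nodes = igraph::vcount(comp),
                   component_edges = igraph::ecount(comp)),
    fit = unclass(fit),
    selection = unclass(sel),
    enrichment = if (!is.null(enr)) list(
      n_significant = nrow(enr),
      terms = enr$term_id,
      n_clusters = length(unique(clusters))),
    actions = actions)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(report)
}

#' Read typed action edges
#'
#' Reads a TSV of curated regulatory actions among genes: columns `source`,
#' `target`, `action` (one of `activation`, `inhibition`, `binding`,
#' `expression`) and `directed` (logical). Binding edges must be
#' undirected. These edges are user-supplied curation, never inferred by
#' the pipeline.
#'
#' @param path Input TSV path (header required; an empty file yields an
#'   empty edge table).
#' @return Data frame of validated action edges.
#' @export
read_action_edges <- function(path) {
  empty <- data.frame(source = character(), target = character(),
                      action = character(), directed = logical())
  lines <- readLines(path)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(empty)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "action", "directed") %in% names(df)))
    stop("action TSV needs columns source, target, action, directed",
         call. = FALSE)
  if (!nrow(df)) return(empty)
  vocab <- c("activation", "inhibition", "binding", "expression")
  bad <- which(!df$action %in% vocab)
  if (length(bad))
    stop("unknown action '", df$action[bad[1L]], "' at line ", bad[1L] + 1L,
         call. = FALSE)
  df$directed <- as.logical(df$directed)
  if (anyNA(df$directed))
    stop("column `directed` must be logical (true/false)", call. = FALSE)
  undirected_binding <- df$action == "binding" & df$directed
  if (any(undirected_binding))
    stop("binding edges must be undirected (line ",
         which(undirected_binding)[1L] + 1L, ")", call. = FALSE)
  df
}

#' Summarize action edges per node
#'
#' Tabulates incoming and outgoing action counts per node and action type.
#' Directed edges contribute one outgoing count at the source and one
#' incoming at the target; undirected edges contribute one undirected
#' count at each endpoint, so the outgoing total equals the number of
#' directed edges.
#'
#' @param edges Data frame from [read_action_edges()].
#' @return Data frame with columns `node`, `action`, `direction`
#'   (`in`/`out`/`undirected`) and `count`, sorted by node.
#' @export
summarize_actions <- function(edges) {
  empty <- data.frame(node = character(), action = character(),
                      direction = character(), count = integer())
  if (!nrow(edges)) return(empty)
  dir_e <- edges[edges$directed, , drop = FALSE]
  und_e <- edges[!edges$directed, , drop = FALSE]
  recs <- rbind(
    if (nrow(dir_e)) data.frame(node = dir_e$source, action = dir_e$action,
                                direction = "out"),
    if (nrow(dir_e)) data.frame(node = dir_e$target, action = dir_e$action,
                                direction = "in"),
    if (nrow(und_e)) data.frame(node = c(und_e$source, und_e$target),
                                action = rep(und_e$action, 2L),
                                direction = "undirected"))
  agg <- stats::aggregate(list(count = rep(1L, nrow(recs))),
                          recs[c("node", "action", "direction")], sum)
  agg <- agg[order(agg$node, agg$action, agg$direction), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
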
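#' Read and write pipeline file formats
#'
#' All artifacts are plain text: expression matrices and group labels as TSV,
#' networks as two-column edge-list TSV or SIF, gene sets as GMT.
#'
#' @name critnet-io
NULL

#' Write an expression matrix and its group labels
#'
#' @param matrix An [expr_matrix].
#' @param path Output TSV path: first column `gene`, then one column per
#'   sample of log2 intensities.
#' @param groups_path Output TSV path for the two-column (sample, group)
#'   table. Omit to skip.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path, groups_path = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  df <- data.frame(gene = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    gdf <- data.frame(sample = names(matrix$groups),
                      group = as.character(matrix$groups))
    utils::write.table(gdf, groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an expression matrix and its group labels
#'
#' @param path Expression TSV as written by [write_expression()].
#' @param groups_path Two-column (sample, group) TSV.
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, groups_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression TSV needs a gene column and at least one sample",
         call. = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- as.character(df[[1L]])
  gdf <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  groups <- stats::setNames(as.character(gdf[[2L]]), as.character(gdf[[1L]]))
  expr_matrix(values, groups)
}

#' Write a graph as an edge list
#'
#' @param g An igraph graph with named vertices.
#' @param path Output path.
#' @param format `"tsv"` for a two-column edge list or `"sif"` for a
#'   Cytoscape simple-interaction file (`nodeA<TAB>pp<TAB>nodeB`); isolated
#'   nodes are written as single-column rows in either format.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  el <- igraph::as_edgelist(g)
  iso <- setdiff(igraph::V(g)$name, unique(as.character(el)))
  lines <- if (format == "sif") {
    c(if (nrow(el)) paste(el[, 1L], "pp", el[, 2L], sep = "\t"), iso)
  } else {
    c("source\ttarget",
      if (nrow(el)) paste(el[, 1L], el[, 2L], sep = "\t"), iso)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a network edge list
#'
#' Accepts a two-column TSV (with or without a `source`/`target` header) or a
#' SIF file whose middle column is the interaction type. Rows with a single
#' field declare isolated nodes. Malformed rows are reported by line number.
#'
#' @param path Input path.
#' @return An igraph graph built with [build_graph()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(tolower(lines[1L]), "source\ttarget"))
    lines <- lines[-1L]
  if (!length(lines))
    return(build_graph(matrix(character(), 0L, 2L)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n == 0L | n > 3L)
  if (length(bad))
    stop("malformed edge record at line ", bad[1L], ": ", lines[bad[1L]],
         call. = FALSE)
  iso <- vapply(fields[n == 1L], `[`, character(1), 1L)
  edges <- fields[n >= 2L]
  el <- if (length(edges)) {
    t(vapply(edges, function(f) c(f[1L], f[length(f)]), character(2)))
  } else {
    matrix(character(), 0L, 2L)
  }
  build_graph(el, nodes = iso)
}

#' Write an annotation table as GMT
#'
#' One line per term: term id, description, then the member genes, all
#' tab-separated.
#'
#' @param annotations An [annotation_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_table"))
  lines <- vapply(names(annotations$sets), function(id) {
    paste(c(id, annotations$names[[id]], annotations$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path: term id, description, member genes, tab-separated.
#' @return An [annotation_table] whose universe is the union of all member
#'   genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT record at line ", bad[1L], " (need id, description, ",
         "and at least one gene)", call. = FALSE)
  ids <- vapply(fields, `[`, character(1), 1L)
  descs <- vapply(fields, `[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  annotation_table(stats::setNames(sets, ids), stats::setNames(descs, ids))
}
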
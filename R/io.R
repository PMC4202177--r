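#' Read a directed edge list from tab-delimited text
#'
#' Columns \code{from}, \code{to} and optionally \code{required}; a header
#' row is expected. Extra columns are ignored.
#'
#' @param path file path.
#' @param nodes optional full node set (isolated nodes are not
#'   representable in an edge list); defaults to the endpoint union.
#' @return a [PathwayGraph-class]
#' @export
readEdgeList <- function(path, nodes = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(tab)))
    stop("edge list needs 'from' and 'to' columns: ", path)
  if (!"required" %in% names(tab)) tab$required <- FALSE
  if (is.null(nodes)) nodes <- unique(c(tab$from, tab$to))
  PathwayGraph(nodes, tab[, c("from", "to", "required"), drop = FALSE])
}

#' Write a pathway graph as a tab-delimited edge list
#'
#' @param graph a [PathwayGraph-class].
#' @param path output file (columns \code{from}, \code{to},
#'   \code{required}).
#' @export
writeEdgeList <- function(graph, path) {
  write.table(graph@edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export a pathway graph to GraphML
#'
#' Convenience export for network viewers; edge attribute \code{required}
#' is preserved.
#'
#' @param graph a [PathwayGraph-class].
#' @param path output file.
#' @export
writeGraphML <- function(graph, path) {
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(graph@nodes)
  e <- graph@edges
  if (nrow(e)) {
    g <- igraph::add_edges(g, rbind(e$from, e$to))
    igraph::E(g)$required <- e$required
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
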
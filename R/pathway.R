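#' Project genes onto a reference pathway map
#'
#' Marks up the reference map's enzyme entries that contain any KO number
#' assigned to the organism's genes, yielding the initial ("seed") pathway:
#' nodes are the genes whose KO set intersects some enzyme entry, edges the
#' gene-level expansion of the map's relations with both endpoints mapped.
#' All resulting edges are flagged required — they are held fixed during
#' structure search.
#'
#' Metabolic maps are frequently cyclic while Bayesian networks must be
#' acyclic; when the expanded seed contains a directed cycle, one edge per
#' detected cycle (the lexicographically first by endpoint ids) is dropped
#' from the seed until it is a DAG. Dropped edges remain available through
#' the knowledgebase whitelist, so the search can restore one orientation.
#'
#' @param reference a [PathwayMap-class].
#' @param komap a [GeneKOMap-class].
#' @return a [PathwayGraph-class] (possibly empty when nothing maps)
#' @export
initialMap <- function(reference, komap) {
  enz <- reference@entries[reference@entries$node_kind == "enzyme", ,
                           drop = FALSE]
  map_kos <- unique(unlist(enz$ko_ids, use.names = FALSE))
  genes <- names(komap@map)[vapply(komap@map,
                                   function(k) any(k %in% map_kos), NA)]
  if (!length(genes)) return(PathwayGraph(character(0)))
  kb1 <- suppressWarnings(buildKnowledgebase(list(reference)))
  e <- allowedGeneEdges(kb1, komap, genes)
  g <- PathwayGraph(genes, if (nrow(e)) cbind(e, required = TRUE) else NULL)
  .breakCycles(g)
}

# Demote edges until the graph is a DAG: repeatedly locate a cycle and drop
# its lexicographically first edge. Deterministic.
.breakCycles <- function(graph) {
  repeat {
    A <- .adjMatrix(graph)
    if (.isAcyclicAdj(A)) return(graph)
    cyc <- .findCycle(A)
    ce <- data.frame(from = cyc[-length(cyc)], to = cyc[-1L],
                     stringsAsFactors = FALSE)
    ce <- ce[order(ce$from, ce$to), , drop = FALSE]
    drop_key <- .edgeKey(ce$from[1L], ce$to[1L])
    keep <- .edgeKey(graph@edges$from, graph@edges$to) != drop_key
    message("seed pathway cycle broken by dropping edge ",
            sub("\t", " -> ", drop_key))
    graph <- PathwayGraph(graph@nodes, graph@edges[keep, , drop = FALSE])
  }
}

#' Assemble the knowledge constraints for a candidate gene set
#'
#' Builds the two constraint subsets that restrain structure search: the
#' required edges of the initial mapped pathway (always present in every
#' candidate graph) and the allowed edges derived from the knowledgebase
#' over the full candidate gene pool (the only edges a move may introduce;
#' everything else is excluded). Required edges are always allowed, even
#' when the knowledgebase does not list them.
#'
#' @param initial the seed [PathwayGraph-class]; its nodes must be a subset
#'   of \code{candidates}.
#' @param kb a [RelationKnowledgebase-class].
#' @param komap a [GeneKOMap-class].
#' @param candidates character vector of candidate gene ids (seed genes
#'   plus sampled genes).
#' @return a [ConstraintSet-class]
#' @export
buildConstraints <- function(initial, kb, komap, candidates) {
  candidates <- unique(as.character(candidates))
  extra <- setdiff(initial@nodes, candidates)
  if (length(extra))
    stop("initial pathway nodes missing from candidates: ",
         paste(extra, collapse = ", "))
  ConstraintSet(required = requiredEdges(initial),
                allowed = allowedGeneEdges(kb, komap, candidates))
}

#' Attach chemical compounds to a predicted relation network
#'
#' For each predicted edge, collects the compounds of every knowledgebase
#' record supporting any KO pair formed by the endpoint genes' KO sets.
#' Edges supported only by compound-free records get an empty set.
#'
#' @param graph a predicted [PathwayGraph-class].
#' @param kb a [RelationKnowledgebase-class].
#' @param komap a [GeneKOMap-class] covering the graph's nodes.
#' @return a [MetabolicNetwork-class]
#' @export
attachCompounds <- function(graph, kb, komap) {
  e <- graph@edges
  cpds <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    ku <- komap@map[[e$from[i]]]
    kd <- komap@map[[e$to[i]]]
    if (is.null(ku) || is.null(kd)) {
      cpds[[i]] <- character(0)
      next
    }
    keys <- .edgeKey(rep(ku, each = length(kd)), rep(kd, length(ku)))
    ridx <- unique(unlist(kb@pairIndex[intersect(keys,
                                                 names(kb@pairIndex))],
                          use.names = FALSE))
    cpds[[i]] <- sort(unique(unlist(kb@records$compounds[ridx],
                                    use.names = FALSE)))
  }
  new("MetabolicNetwork", graph = graph, edgeCompounds = cpds)
}

#' Write a metabolic network as an edge list with compounds
#'
#' @param net a [MetabolicNetwork-class].
#' @param path output TSV (columns \code{from}, \code{to},
#'   \code{required}, \code{compounds} comma-joined).
#' @export
writeMetabolicNetwork <- function(net, path) {
  e <- net@graph@edges
  out <- data.frame(from = e$from, to = e$to, required = e$required,
                    compounds = vapply(net@edgeCompounds, paste, "",
                                       collapse = ","),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
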
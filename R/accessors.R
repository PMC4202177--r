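#' @rdname PathwayMap-class
setMethod("mapId", "PathwayMap", function(x) x@mapId)

#' @rdname PathwayMap-class
setMethod("entries", "PathwayMap", function(x) x@entries)

#' @rdname PathwayMap-class
setMethod("records", "PathwayMap", function(x) x@records)

#' @rdname RelationKnowledgebase-class
setMethod("records", "RelationKnowledgebase", function(x) x@records)

#' @rdname RelationKnowledgebase-class
setMethod("koPairs", "RelationKnowledgebase", function(x) {
  if (length(x@pairIndex) == 0L) return(.emptyEdges())
  parts <- strsplit(names(x@pairIndex), "\t", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1L),
             to = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
})

#' @rdname GeneKOMap-class
setMethod("mappedGenes", "GeneKOMap", function(x) names(x@map))

#' @rdname GeneKOMap-class
setMethod("kosOf", "GeneKOMap", function(x, gene) {
  missing_genes <- setdiff(gene, names(x@map))
  if (length(missing_genes))
    stop("gene(s) not in KO map: ", paste(missing_genes, collapse = ", "))
  if (length(gene) == 1L) x@map[[gene]] else x@map[gene]
})

#' @rdname GeneKOMap-class
setMethod("genesOfKO", "GeneKOMap", function(x, ko) {
  names(x@map)[vapply(x@map, function(k) ko %in% k, NA)]
})

#' @rdname PathwayGraph-class
setMethod("nodes", "PathwayGraph", function(x) x@nodes)

#' @rdname PathwayGraph-class
setMethod("edges", "PathwayGraph", function(x) x@edges)

#' @rdname PathwayGraph-class
setMethod("requiredEdges", "PathwayGraph", function(x) {
  e <- x@edges[x@edges$required, c("from", "to"), drop = FALSE]
  rownames(e) <- NULL
  e
})

#' @rdname ConstraintSet-class
setMethod("requiredEdges", "ConstraintSet", function(x) x@required)

#' @rdname ConstraintSet-class
setMethod("allowedEdges", "ConstraintSet", function(x) x@allowed)

#' @rdname ExpressionData-class
setMethod("exprsValues", "ExpressionData", function(x) {
  SummarizedExperiment::assay(x, "exprs")
})

#' @rdname ClusterModel-class
setMethod("nClusters", "ClusterModel", function(x) x@k)

#' @rdname ClusterModel-class
setMethod("clusterMeans", "ClusterModel", function(x) x@means)

#' @rdname ClusterModel-class
setMethod("clusterAssignments", "ClusterModel", function(x) x@assignments)

#' @rdname ClusterModel-class
setMethod("mixingWeights", "ClusterModel", function(x) x@weights)

#' @rdname MetabolicNetwork-class
setMethod("edgeCompounds", "MetabolicNetwork", function(x) x@edgeCompounds)

#' @rdname MetabolicNetwork-class
setMethod("nodes", "MetabolicNetwork", function(x) x@graph@nodes)

#' @rdname MetabolicNetwork-class
setMethod("edges", "MetabolicNetwork", function(x) x@graph@edges)

setMethod("show", "PathwayMap", function(object) {
  cat("PathwayMap", object@mapId, "\n",
      " entries: ", nrow(object@entries),
      " (", sum(object@entries$node_kind == "enzyme"), " enzyme)\n",
      " records: ", nrow(object@records),
      if (object@nSkipped) paste0("  [", object@nSkipped, " skipped]"),
      "\n", sep = "")
})

setMethod("show", "RelationKnowledgebase", function(object) {
  cat("RelationKnowledgebase with", nrow(object@records), "records over",
      length(object@pairIndex), "ordered KO pairs\n")
})

setMethod("show", "GeneKOMap", function(object) {
  cat("GeneKOMap:", length(object@map), "genes,",
      length(unique(unlist(object@map, use.names = FALSE))), "KO groups\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: k =", object@k, "components over",
      ncol(object@means), "conditions;",
      length(object@assignments), "genes assigned\n")
})

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges (",
      sum(object@edges$required), "required )\n")
})

setMethod("show", "ConstraintSet", function(object) {
  cat("ConstraintSet:", nrow(object@required), "required /",
      nrow(object@allowed), "allowed edges\n")
})

setMethod("show", "MetabolicNetwork", function(object) {
  n_cpd <- length(unique(unlist(object@edgeCompounds, use.names = FALSE)))
  cat("MetabolicNetwork:", length(object@graph@nodes), "genes,",
      nrow(object@graph@edges), "edges,", n_cpd, "distinct compounds\n")
})

setMethod("show", "ScoreReport", function(object) {
  cat(sprintf(
    "ScoreReport: total %.4f = loglik %.4f - (log(%d)/2) * %d\n",
    object@total, object@loglik, object@M, object@dim))
})
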
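# Accessor generics. Slot access from user code goes through these.

#' @rdname PathwayMap-class
#' @param x object
#' @export
setGeneric("mapId", function(x) standardGeneric("mapId"))

#' @rdname PathwayMap-class
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))

#' @rdname PathwayMap-class
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname RelationKnowledgebase-class
#' @param x object
#' @export
setGeneric("koPairs", function(x) standardGeneric("koPairs"))

#' @rdname GeneKOMap-class
#' @param x object
#' @export
setGeneric("mappedGenes", function(x) standardGeneric("mappedGenes"))

#' @rdname GeneKOMap-class
#' @param gene gene identifier(s)
#' @export
setGeneric("kosOf", function(x, gene) standardGeneric("kosOf"))

#' @rdname GeneKOMap-class
#' @param ko KO identifier
#' @export
setGeneric("genesOfKO", function(x, ko) standardGeneric("genesOfKO"))

#' @rdname PathwayGraph-class
#' @param x object
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("requiredEdges", function(x) standardGeneric("requiredEdges"))

#' @rdname ConstraintSet-class
#' @param x object
#' @export
setGeneric("allowedEdges", function(x) standardGeneric("allowedEdges"))

#' @rdname ExpressionData-class
#' @param x object
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))

#' @rdname ClusterModel-class
#' @param x object
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ClusterModel-class
#' @export
setGeneric("clusterMeans", function(x) standardGeneric("clusterMeans"))

#' @rdname ClusterModel-class
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))

#' @rdname ClusterModel-class
#' @export
setGeneric("mixingWeights", function(x) standardGeneric("mixingWeights"))

#' @rdname MetabolicNetwork-class
#' @param x object
#' @export
setGeneric("edgeCompounds", function(x) standardGeneric("edgeCompounds"))
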
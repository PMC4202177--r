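#' @import methods
#' @importFrom stats dnorm quantile rnorm runif sd var setNames
#' @importFrom utils head read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames
#' @importFrom S4Vectors metadata metadata<-
NULL

.KO_PATTERN <- "^K[0-9]{5}$"

.emptyEdges <- function() {
  data.frame(from = character(0), to = character(0),
             stringsAsFactors = FALSE)
}

.emptyEdgesReq <- function() {
  data.frame(from = character(0), to = character(0), required = logical(0),
             stringsAsFactors = FALSE)
}

.edgeKey <- function(from, to) paste(from, to, sep = "\t")

#' Gene-to-KO orthology assignment map
#'
#' Stores the assignment of an organism's genes to KEGG Orthology (KO)
#' groups, as produced by an automatic annotation server. Each gene maps to
#' one or more KO identifiers; the reverse index (KO to genes) is derived on
#' demand by [genesOfKO()].
#'
#' @slot map named list; one character vector of KO identifiers
#'   (\code{"K"} followed by five digits) per gene.
#' @seealso [readGeneKOMap()], [allowedGeneEdges()]
#' @export
setClass("GeneKOMap", slots = c(map = "list"))

setValidity("GeneKOMap", function(object) {
  m <- object@map
  if (length(m) == 0L) return(TRUE)
  if (is.null(names(m)) || anyNA(names(m)) || any(names(m) == ""))
    return("all genes must be named")
  if (anyDuplicated(names(m)))
    return("duplicate gene identifiers")
  kos <- unlist(m, use.names = FALSE)
  if (any(lengths(m) == 0L))
    return("every gene must map to at least one KO")
  bad <- kos[!grepl(.KO_PATTERN, kos)]
  if (length(bad))
    return(paste0("malformed KO identifiers: ",
                  paste(unique(bad), collapse = ", ")))
  TRUE
})

#' A parsed KGML reference pathway map
#'
#' @slot mapId pathway map identifier (e.g. \code{"map00020"}).
#' @slot entries data.frame with columns \code{entry_id}, \code{node_kind}
#'   (\code{"enzyme"}, \code{"compound"}, \code{"map"} or \code{"other"}),
#'   \code{ko_ids} (list column of KO identifiers) and \code{compound_id}.
#' @slot records data.frame of relation/reaction records with list columns
#'   \code{upstream}, \code{downstream}, \code{compounds} and character
#'   columns \code{record_type}, \code{source_map}.
#' @slot nSkipped number of relation/reaction elements skipped because they
#'   referenced entry ids absent from the map.
#' @export
setClass("PathwayMap",
         slots = c(mapId = "character", entries = "data.frame",
                   records = "data.frame", nSkipped = "integer"))

setValidity("PathwayMap", function(object) {
  e <- object@entries
  r <- object@records
  need_e <- c("entry_id", "node_kind", "ko_ids", "compound_id")
  need_r <- c("upstream", "downstream", "record_type", "compounds",
              "source_map")
  if (!all(need_e %in% names(e))) return("entries missing columns")
  if (!all(need_r %in% names(r))) return("records missing columns")
  if (nrow(r)) {
    if (any(lengths(r$upstream) == 0L) || any(lengths(r$downstream) == 0L))
      return("records must have non-empty upstream and downstream KO sets")
  }
  enz <- e$node_kind == "enzyme"
  if (any(enz) && any(lengths(e$ko_ids[enz]) == 0L))
    return("enzyme entries must carry at least one KO id")
  TRUE
})

#' KO-level relation/reaction knowledgebase
#'
#' Aggregates the relation and reaction records of one or more reference
#' pathway maps and indexes them by ordered KO pair. The index is the
#' whitelist from which candidate gene-gene edges are drawn during
#' constrained structure learning.
#'
#' @slot records data.frame of all retained [PathwayMap-class] records
#'   (duplicates across maps kept for provenance).
#' @slot pairIndex named list; names are ordered KO pairs
#'   (\code{"Kxxxxx\tKyyyyy"}), values integer indices of the supporting
#'   rows of \code{records}.
#' @seealso [buildKnowledgebase()], [allowedGeneEdges()]
#' @export
setClass("RelationKnowledgebase",
         slots = c(records = "data.frame", pairIndex = "list"))

setValidity("RelationKnowledgebase", function(object) {
  if (length(object@pairIndex)) {
    if (any(lengths(object@pairIndex) == 0L))
      return("every indexed KO pair must be backed by >= 1 record")
    idx <- unlist(object@pairIndex, use.names = FALSE)
    if (nrow(object@records) == 0L || max(idx) > nrow(object@records))
      return("pair index references records that do not exist")
  }
  TRUE
})

#' Gene expression data container
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding a genes x
#' conditions matrix in assay \code{"exprs"}. Missing measurements are
#' \code{NA}; [filterMissing()] and [imputeExpression()] operate on them.
#' The number of conditions is the data size M of the network score.
#'
#' @export
setClass("ExpressionData", contains = "SummarizedExperiment")

setValidity("ExpressionData", function(object) {
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("gene ids (rownames) must be present and unique")
  if (ncol(object) < 2L)
    return("at least 2 conditions are required")
  TRUE
})

#' Fitted Gaussian-mixture clustering of genes
#'
#' Result of [emFit()]: a diagonal-covariance Gaussian mixture over gene
#' expression profiles, with hard assignments by maximum responsibility.
#'
#' @slot k number of mixture components.
#' @slot means k x conditions matrix of component means.
#' @slot variances k x conditions matrix of per-dimension variances
#'   (floored at 1e-6).
#' @slot weights mixing proportions, summing to 1.
#' @slot assignments named integer vector, gene -> component index (1-based).
#' @slot logLik per-iteration training log-likelihood trace (non-decreasing).
#' @slot cvTable cross-validation table filled by [selectNumClusters()]
#'   (columns \code{k}, \code{heldout_loglik}); empty otherwise.
#' @export
setClass("ClusterModel",
         slots = c(k = "integer", means = "matrix", variances = "matrix",
                   weights = "numeric", assignments = "integer",
                   logLik = "numeric", cvTable = "data.frame"))

setValidity("ClusterModel", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (nrow(object@means) != object@k || nrow(object@variances) != object@k)
    return("means/variances must have one row per component")
  if (length(object@weights) != object@k)
    return("one mixing weight per component")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("mixing weights must sum to 1")
  if (any(object@variances <= 0))
    return("variances must be positive")
  if (length(object@assignments) &&
      (is.null(names(object@assignments)) ||
       any(object@assignments < 1L | object@assignments > object@k)))
    return("assignments must be named component indices in 1..k")
  TRUE
})

#' Plan for cluster-guided gene sampling
#'
#' @slot pivot index of the pivotal cluster (must carry the maximal weight).
#' @slot weights per-cluster selection probabilities, summing to 1.
#' @slot nToSample number of genes to draw.
#' @slot seed RNG seed making the draw reproducible.
#' @seealso [pivotalCluster()], [clusterWeights()], [sampleGenes()]
#' @export
setClass("SamplingPlan",
         slots = c(pivot = "integer", weights = "numeric",
                   nToSample = "integer", seed = "integer"))

setValidity("SamplingPlan", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("cluster weights must sum to 1")
  if (object@pivot < 1L || object@pivot > length(object@weights))
    return("pivot out of range")
  if (object@weights[object@pivot] < max(object@weights) - 1e-12)
    return("pivot must carry the maximal weight")
  if (object@nToSample < 1L) return("nToSample must be >= 1")
  TRUE
})

#' Directed gene-level pathway graph
#'
#' The graph G of the network score: nodes are genes, directed edges are
#' relations/reactions. Edges flagged \code{required} originate from the
#' initial reference-map projection and are held fixed during search.
#'
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{required}.
#' @export
setClass("PathwayGraph",
         slots = c(nodes = "character", edges = "data.frame"))

setValidity("PathwayGraph", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "required") %in% names(e)))
    return("edges need columns from, to, required")
  if (anyDuplicated(object@nodes)) return("duplicate node ids")
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% object@nodes))
      return("edge endpoints must be graph nodes")
    if (any(e$from == e$to)) return("self-edges are not allowed")
    if (anyDuplicated(.edgeKey(e$from, e$to)))
      return("duplicate edges")
  }
  TRUE
})

#' Knowledge constraints for structure search
#'
#' Two edge sets restraining the search space: \code{required} edges (from
#' the initial mapped pathway) must appear in every candidate graph;
#' \code{allowed} edges (from the relation knowledgebase, a superset of
#' required) are the only edges a local move may introduce. Everything else
#' is excluded.
#'
#' @slot required data.frame(from, to).
#' @slot allowed data.frame(from, to); always contains \code{required}.
#' @export
setClass("ConstraintSet",
         slots = c(required = "data.frame", allowed = "data.frame"))

setValidity("ConstraintSet", function(object) {
  r <- object@required; a <- object@allowed
  if (nrow(r) && any(r$from == r$to)) return("self-pairs in required")
  if (nrow(a) && any(a$from == a$to)) return("self-pairs in allowed")
  if (nrow(r) && !all(.edgeKey(r$from, r$to) %in% .edgeKey(a$from, a$to)))
    return("required edges must be a subset of allowed edges")
  if (anyDuplicated(.edgeKey(a$from, a$to)))
    return("duplicate allowed pairs")
  TRUE
})

#' Predicted metabolic network with attached compounds
#'
#' A relation network decorated with the chemical compounds that the
#' knowledgebase associates with each predicted edge.
#'
#' @slot graph the underlying [PathwayGraph-class].
#' @slot edgeCompounds list parallel to the graph's edge rows; each element
#'   a character vector of compound ids (possibly empty).
#' @export
setClass("MetabolicNetwork",
         slots = c(graph = "PathwayGraph", edgeCompounds = "list"))

setValidity("MetabolicNetwork", function(object) {
  if (length(object@edgeCompounds) != nrow(object@graph@edges))
    return("one compound set per graph edge is required")
  TRUE
})

#' BIC score report for a pathway graph
#'
#' Decomposed network score: \code{total = loglik - (log(M)/2) * dim}, with
#' per-node family contributions whose sum equals the total.
#'
#' @slot total total score.
#' @slot perNode named numeric vector of family score contributions.
#' @slot dim number of independent parameters of the linear-Gaussian model
#'   (per node: one coefficient per parent + intercept + variance).
#' @slot loglik maximized log-likelihood (natural log).
#' @slot M data size (number of conditions).
#' @export
setClass("ScoreReport",
         slots = c(total = "numeric", perNode = "numeric", dim = "integer",
                   loglik = "numeric", M = "integer"))

setValidity("ScoreReport", function(object) {
  if (abs(object@total - (object@loglik - log(object@M) / 2 * object@dim)) >
      1e-9 * max(1, abs(object@total)))
    return("total must equal loglik - (log(M)/2) * dim")
  if (abs(sum(object@perNode) - object@total) >
      1e-9 * max(1, abs(object@total)))
    return("per-node contributions must sum to the total")
  TRUE
})
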
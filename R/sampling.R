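#' Construct a sampling plan
#'
#' @param pivot pivotal cluster index.
#' @param weights per-cluster selection probabilities (will be normalised).
#' @param nToSample number of genes to draw.
#' @param seed RNG seed for the draw.
#' @return a [SamplingPlan-class]
#' @export
SamplingPlan <- function(pivot, weights, nToSample, seed = 1L) {
  new("SamplingPlan", pivot = as.integer(pivot),
      weights = weights / sum(weights),
      nToSample = as.integer(nToSample), seed = as.integer(seed))
}

#' Pivotal cluster of a seed pathway
#'
#' The cluster holding the most genes of the initially mapped pathway is
#' the pivot; gene sampling favours it. Ties break toward the lower
#' cluster index.
#'
#' @param model a [ClusterModel-class].
#' @param seedGenes non-empty character vector of gene ids, all assigned in
#'   \code{model}.
#' @return pivotal cluster index (integer)
#' @export
pivotalCluster <- function(model, seedGenes) {
  seedGenes <- unique(as.character(seedGenes))
  if (!length(seedGenes)) stop("seedGenes must be non-empty")
  missing_genes <- setdiff(seedGenes, names(model@assignments))
  if (length(missing_genes))
    stop("seed gene(s) not assigned in the cluster model: ",
         paste(missing_genes, collapse = ", "))
  counts <- tabulate(model@assignments[seedGenes], nbins = model@k)
  which.max(counts)  # first max = lowest index on ties
}

#' Per-cluster sampling weights around a pivot
#'
#' Weight of cluster c is proportional to \code{1 / (1 + d(c, pivot))}
#' with d the Euclidean distance between cluster means, normalised to sum
#' to 1. The pivot always carries the maximal weight (shared only by
#' clusters with an identical mean).
#'
#' @param model a [ClusterModel-class].
#' @param pivot pivotal cluster index.
#' @return numeric vector of probabilities, one per cluster
#' @export
clusterWeights <- function(model, pivot) {
  pivot <- as.integer(pivot)
  if (pivot < 1L || pivot > model@k)
    stop("pivot out of range 1..", model@k)
  d <- vapply(seq_len(model@k),
              function(c_) clusterDistance(model, c_, pivot), 0)
  w <- 1 / (1 + d)
  w / sum(w)
}

#' Number of genes to sample for a pathway
#'
#' The rounded mean number of enzyme (KO-bearing) entries over the
#' reference maps, rounded half up, with a floor of 1.
#'
#' @param referenceMaps non-empty list of [PathwayMap-class] objects.
#' @return positive integer
#' @export
targetSampleSize <- function(referenceMaps) {
  if (is(referenceMaps, "PathwayMap")) referenceMaps <- list(referenceMaps)
  if (!length(referenceMaps)) stop("at least one reference map is required")
  counts <- vapply(referenceMaps,
                   function(m) sum(m@entries$node_kind == "enzyme"), 0L)
  max(1L, as.integer(.roundHalfUp(mean(counts))))
}

#' Sample candidate genes guided by cluster weights
#'
#' Draws \code{plan@nToSample} distinct genes without replacement:
#' repeatedly pick a cluster according to the plan weights (renormalised
#' over clusters that still hold unused genes), then a uniformly random
#' unused gene from it. The draw is deterministic given \code{plan@seed}
#' and never returns genes from \code{exclude}.
#'
#' @param model a [ClusterModel-class].
#' @param plan a [SamplingPlan-class].
#' @param exclude gene ids barred from sampling (e.g. the seed pathway's
#'   genes, already in the candidate pool).
#' @return character vector of sampled gene ids
#' @export
sampleGenes <- function(model, plan, exclude = character(0)) {
  stopifnot(is(plan, "SamplingPlan"))
  if (length(plan@weights) != model@k)
    stop("plan has ", length(plan@weights), " weights for ", model@k,
         " clusters")
  pools <- lapply(seq_len(model@k), function(c_) {
    setdiff(names(model@assignments)[model@assignments == c_], exclude)
  })
  avail <- sum(lengths(pools))
  if (avail < plan@nToSample)
    stop("only ", avail, " genes available outside the exclusion set; ",
         plan@nToSample, " requested")
  .withSeed(plan@seed, {
    out <- character(0)
    for (i in seq_len(plan@nToSample)) {
      active <- which(lengths(pools) > 0L)
      w <- plan@weights[active]
      c_ <- if (length(active) == 1L) active else
        active[sample.int(length(active), 1L, prob = w / sum(w))]
      pool <- pools[[c_]]
      g <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
      out <- c(out, g)
      pools[[c_]] <- setdiff(pool, g)
    }
    out
  })
}
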
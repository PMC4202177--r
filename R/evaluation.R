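#' Edge-level recall and precision of a predicted network
#'
#' Recall is the fraction of target-pathway edges recovered by the
#' prediction; precision the fraction of predicted edges present in the
#' target. In \code{directed} mode an edge matches only with its
#' orientation; in \code{undirected} mode either orientation matches.
#' When \code{requiredEdges} is supplied, precision is additionally
#' reported with those (seeded) edges excluded from the prediction, since
#' they are inherited from the mapping rather than inferred.
#'
#' @param predicted,target data.frame(from, to) edge sets (or
#'   [PathwayGraph-class] objects) without self-edges.
#' @param directionMode \code{"directed"} (default) or \code{"undirected"}.
#' @param requiredEdges optional data.frame(from, to) of seeded edges.
#' @return list with \code{recall}, \code{precision},
#'   \code{true_positives}, \code{n_target}, \code{n_predicted},
#'   \code{direction_mode}, and, when \code{requiredEdges} is given,
#'   \code{precision_excluding_required}.
#' @export
evaluateEdges <- function(predicted, target,
                          directionMode = c("directed", "undirected"),
                          requiredEdges = NULL) {
  directionMode <- match.arg(directionMode)
  as_edges <- function(x) {
    if (is(x, "PathwayGraph")) x <- x@edges
    if (!nrow(x)) return(.emptyEdges())
    x <- data.frame(from = as.character(x$from), to = as.character(x$to),
                    stringsAsFactors = FALSE)
    if (any(x$from == x$to)) stop("self-edges are not allowed")
    x[!duplicated(.edgeKey(x$from, x$to)), , drop = FALSE]
  }
  p <- as_edges(predicted); t_ <- as_edges(target)
  tkeys <- .edgeKey(t_$from, t_$to)
  match_fun <- function(e) {
    if (directionMode == "directed") .edgeKey(e$from, e$to) %in% tkeys
    else .edgeKey(e$from, e$to) %in% tkeys |
      .edgeKey(e$to, e$from) %in% tkeys
  }
  hit <- if (nrow(p)) match_fun(p) else logical(0)
  tp <- sum(hit)
  # recall counts target edges recovered (undirected: either orientation)
  pkeys <- .edgeKey(p$from, p$to)
  t_hit <- if (directionMode == "directed") tkeys %in% pkeys
  else tkeys %in% pkeys | .edgeKey(t_$to, t_$from) %in% pkeys
  res <- list(recall = if (nrow(t_)) sum(t_hit) / nrow(t_) else 0,
              precision = if (nrow(p)) tp / nrow(p) else 0,
              true_positives = tp, n_target = nrow(t_),
              n_predicted = nrow(p), direction_mode = directionMode)
  if (!is.null(requiredEdges)) {
    r <- as_edges(requiredEdges)
    novel <- !(pkeys %in% .edgeKey(r$from, r$to))
    res$precision_excluding_required <-
      if (any(novel)) sum(hit[novel]) / sum(novel) else 0
  }
  res
}

#' Summarize repeated evaluation runs
#'
#' Five-number summary (minimum, lower quartile, median, upper quartile,
#' maximum) of recall and precision over repeated stochastic runs.
#' Quartiles use linear interpolation between closest ranks
#' (\code{stats::quantile} type 7).
#'
#' @param results non-empty list of [evaluateEdges()] results.
#' @return data.frame with one row per metric and columns \code{metric},
#'   \code{min}, \code{q25}, \code{median}, \code{q75}, \code{max};
#'   attribute \code{"n_runs"} carries the run count.
#' @export
summarizeRuns <- function(results) {
  if (!length(results)) stop("at least one run result is required")
  metrics <- c("recall", "precision")
  rows <- lapply(metrics, function(m) {
    v <- vapply(results, function(r) r[[m]], 0)
    q <- quantile(v, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    data.frame(metric = m, min = q[1L], q25 = q[2L], median = q[3L],
               q75 = q[4L], max = q[5L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_runs") <- length(results)
  out
}

#' Compare two methods' run summaries across test instances
#'
#' For each instance (e.g. each target pathway), compares the median of a
#' metric between two methods; a strictly larger median for method A
#' counts as a win, equality as a tie.
#'
#' @param summariesA,summariesB named lists of [summarizeRuns()] outputs,
#'   one per instance; the instance names must coincide.
#' @param metric \code{"recall"} or \code{"precision"}.
#' @return list with \code{wins}, \code{ties}, \code{losses} (fractions of
#'   instances) and \code{n_instances}.
#' @export
compareMethods <- function(summariesA, summariesB,
                           metric = c("recall", "precision")) {
  metric <- match.arg(metric)
  if (is.null(names(summariesA)) || is.null(names(summariesB)) ||
      !setequal(names(summariesA), names(summariesB)))
    stop("instance sets of the two methods do not match")
  ids <- names(summariesA)
  med <- function(s) s$median[s$metric == metric]
  a <- vapply(summariesA[ids], med, 0)
  b <- vapply(summariesB[ids], med, 0)
  list(wins = mean(a > b), ties = mean(a == b), losses = mean(a < b),
       n_instances = length(ids))
}

#' Write per-run evaluation results to tab-delimited text
#'
#' @param results list of [evaluateEdges()] results.
#' @param path output file.
#' @export
writeEvalResults <- function(results, path) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(run = i, recall = r$recall, precision = r$precision,
               true_positives = r$true_positives, n_target = r$n_target,
               n_predicted = r$n_predicted,
               direction_mode = r$direction_mode,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
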
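# Constrained greedy hill climbing over DAG structures, plus an exhaustive
# enumeration oracle for tiny instances. Moves are the three local edge
# operations (add, remove, reverse); the knowledge constraints pin required
# edges and whitelist which edges may ever exist.

# family-score cache over (node, sorted parent set); data fixed per search
.makeFamCache <- function(data, nodes) {
  V <- exprsValues(data)
  miss <- setdiff(nodes, rownames(V))
  if (length(miss))
    stop("graph node(s) without expression data: ",
         paste(miss, collapse = ", "))
  V <- V[nodes, , drop = FALSE]
  M <- ncol(V)
  cache <- new.env(parent = emptyenv())
  function(v, parents) {
    parents <- sort(parents)
    key <- paste(v, paste(parents, collapse = ","), sep = "|")
    if (!is.null(got <- cache[[key]])) return(got)
    y <- V[v, ]
    X <- if (length(parents)) t(V[parents, , drop = FALSE]) else
      matrix(0, M, 0L)
    fit <- .olsFamily(y, X)
    res <- c(score = fit$loglik - log(M) / 2 * (length(parents) + 2),
             loglik = fit$loglik)
    cache[[key]] <- res
    res
  }
}

# logical constraint matrices over an explicit node order
.constraintMatrices <- function(constraints, nds) {
  mk <- function(df) {
    A <- matrix(FALSE, length(nds), length(nds), dimnames = list(nds, nds))
    df <- df[df$from %in% nds & df$to %in% nds, , drop = FALSE]
    if (nrow(df)) A[cbind(df$from, df$to)] <- TRUE
    A
  }
  list(required = mk(constraints@required), allowed = mk(constraints@allowed))
}

.checkConsistent <- function(A, req, alw) {
  if (any(req & !A)) stop("graph is missing required edge(s)")
  if (any(A & !alw)) stop("graph contains edge(s) outside the allowed set")
  if (!.isAcyclicAdj(A)) stop("graph is cyclic")
  invisible(TRUE)
}

# enumerate legal moves on adjacency A under constraint matrices.
# Returns data.frame(kind, from, to) in deterministic tie-break order:
# add < remove < reverse, then lexicographic (from, to).
.legalMovesAdj <- function(A, req, alw) {
  nds <- rownames(A)
  R <- .reachability(A)
  out <- list()
  cand <- which(alw & !A, arr.ind = TRUE)
  if (nrow(cand)) {
    ok <- !R[cbind(cand[, 2L], cand[, 1L])]   # adding u->v: no path v->u
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand))
      out$add <- data.frame(kind = "add", from = nds[cand[, 1L]],
                            to = nds[cand[, 2L]], stringsAsFactors = FALSE)
  }
  cand <- which(A & !req, arr.ind = TRUE)
  if (nrow(cand))
    out$remove <- data.frame(kind = "remove", from = nds[cand[, 1L]],
                             to = nds[cand[, 2L]], stringsAsFactors = FALSE)
  cand <- which(A & !req & t(alw), arr.ind = TRUE)   # reversal allowed
  if (nrow(cand)) {
    ok <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      u <- cand[i, 1L]; v <- cand[i, 2L]
      A2 <- A; A2[u, v] <- FALSE
      # reversing u->v adds v->u; illegal iff an alternative path u->v stays
      ok[i] <- !.reaches(A2, u, v)
    }
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand))
      out$reverse <- data.frame(kind = "reverse", from = nds[cand[, 1L]],
                                to = nds[cand[, 2L]],
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(list(data.frame(kind = character(0),
                                          from = character(0),
                                          to = character(0),
                                          stringsAsFactors = FALSE)), out))
  kind_rank <- match(res$kind, c("add", "remove", "reverse"))
  res <- res[order(kind_rank, res$from, res$to), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# BFS: does u reach v in adjacency A?
.reaches <- function(A, u, v) {
  seen <- logical(nrow(A))
  frontier <- u
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    if (v %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Legal local moves on a constrained graph
#'
#' Enumerates every add/remove/reverse operation that (a) never removes or
#' reverses a required edge, (b) adds only whitelisted edges, (c) reverses
#' an edge only when the reversed orientation is itself whitelisted, and
#' (d) keeps the graph acyclic.
#'
#' @param graph a [PathwayGraph-class] consistent with the constraints.
#' @param constraints a [ConstraintSet-class].
#' @return data.frame with columns \code{kind} (\code{"add"},
#'   \code{"remove"}, \code{"reverse"}), \code{from}, \code{to}, in the
#'   deterministic tie-break order used by [greedySearch()].
#' @export
legalMoves <- function(graph, constraints) {
  nds <- sort(graph@nodes)
  A <- .adjMatrix(graph, nds)
  cm <- .constraintMatrices(constraints, nds)
  .checkConsistent(A, cm$required, cm$allowed)
  .legalMovesAdj(A, cm$required, cm$allowed)
}

#' Greedy hill-climbing structure search under knowledge constraints
#'
#' Starting from the initial graph, each iteration enumerates all legal
#' local operations (see [legalMoves()]), scores each by its change to the
#' decomposed network score (only the affected node families are refitted),
#' and applies the highest-scoring move. The search stops when no move
#' improves the score by more than \code{tol}, or after \code{maxIters}
#' accepted moves. Ties between equal-best moves break deterministically
#' (add < remove < reverse, then lexicographically by edge), so runs are
#' reproducible.
#'
#' @param initial a [PathwayGraph-class] satisfying the constraints
#'   (required edges present, all edges allowed, acyclic).
#' @param data an [ExpressionData-class] covering the graph's nodes.
#' @param constraints a [ConstraintSet-class].
#' @param maxIters cap on accepted moves.
#' @param tol minimum score improvement to accept a move.
#' @param validate when \code{TRUE}, re-assert constraint satisfaction and
#'   acyclicity after every accepted move (used by the test suite).
#' @return list with elements \code{graph} (the final
#'   [PathwayGraph-class]), \code{score} (a [ScoreReport-class]) and
#'   \code{trace} (data.frame of accepted moves with the score after each;
#'   row 0 is the initial score).
#' @export
greedySearch <- function(initial, data, constraints, maxIters = 500L,
                         tol = 1e-9, validate = FALSE) {
  nds <- sort(initial@nodes)
  A <- .adjMatrix(initial, nds)
  cm <- .constraintMatrices(constraints, nds)
  .checkConsistent(A, cm$required, cm$allowed)
  fam <- .makeFamCache(data, nds)

  parents_of <- function(A, v) nds[A[, v]]
  node_scores <- vapply(nds, function(v) fam(v, parents_of(A, v))["score"],
                        0)
  names(node_scores) <- nds
  total <- sum(node_scores)
  trace <- data.frame(iter = 0L, kind = "init", from = NA_character_,
                      to = NA_character_, score = total,
                      stringsAsFactors = FALSE)

  for (it in seq_len(maxIters)) {
    moves <- .legalMovesAdj(A, cm$required, cm$allowed)
    if (!nrow(moves)) break
    delta <- numeric(nrow(moves))
    for (i in seq_len(nrow(moves))) {
      u <- moves$from[i]; v <- moves$to[i]
      delta[i] <- switch(
        moves$kind[i],
        add = fam(v, c(parents_of(A, v), u))["score"] - node_scores[v],
        remove = fam(v, setdiff(parents_of(A, v), u))["score"] -
          node_scores[v],
        reverse = (fam(v, setdiff(parents_of(A, v), u))["score"] -
                     node_scores[v]) +
          (fam(u, c(parents_of(A, u), v))["score"] - node_scores[u]))
    }
    best <- which.max(delta)   # moves are pre-sorted in tie-break order
    if (delta[best] <= tol) break
    u <- moves$from[best]; v <- moves$to[best]
    kind <- moves$kind[best]
    if (kind == "add") {
      A[u, v] <- TRUE
    } else if (kind == "remove") {
      A[u, v] <- FALSE
    } else {
      A[u, v] <- FALSE; A[v, u] <- TRUE
    }
    node_scores[v] <- fam(v, parents_of(A, v))["score"]
    if (kind == "reverse")
      node_scores[u] <- fam(u, parents_of(A, u))["score"]
    total <- total + delta[best]
    trace <- rbind(trace, data.frame(iter = it, kind = kind, from = u,
                                     to = v, score = total,
                                     stringsAsFactors = FALSE))
    if (validate) .checkConsistent(A, cm$required, cm$allowed)
  }

  idx <- which(A, arr.ind = TRUE)
  e <- data.frame(from = nds[idx[, 1L]], to = nds[idx[, 2L]],
                  stringsAsFactors = FALSE)
  e$required <- cm$required[idx]
  graph <- PathwayGraph(initial@nodes, e)
  list(graph = graph, score = bicScore(graph, data), trace = trace)
}

#' Exhaustive structure search over tiny gene sets
#'
#' Enumerates every DAG over at most five genes whose edge set contains
#' the required edges and stays within the allowed set, and returns the
#' highest-scoring one. Ties break toward fewer edges, then the
#' lexicographically smallest edge list. Serves as the independent optimum
#' against which the greedy search is checked.
#'
#' @param genes character vector of at most 5 gene ids.
#' @param data an [ExpressionData-class].
#' @param constraints a [ConstraintSet-class]; \code{NULL} means
#'   unconstrained (all ordered pairs allowed, none required).
#' @return list with \code{graph}, \code{score} (a [ScoreReport-class])
#'   and \code{nDags}, the number of admissible DAGs enumerated.
#' @export
exhaustiveSearch <- function(genes, data, constraints = NULL) {
  genes <- sort(unique(as.character(genes)))
  n <- length(genes)
  if (n > 5L)
    stop("exhaustive enumeration is limited to 5 genes (got ", n, ")")
  if (is.null(constraints)) {
    grid <- expand.grid(from = genes, to = genes, stringsAsFactors = FALSE)
    constraints <- ConstraintSet(allowed = grid[grid$from != grid$to, ])
  }
  cm <- .constraintMatrices(constraints, genes)
  fam <- .makeFamCache(data, genes)
  opt <- which(cm$allowed & !cm$required, arr.ind = TRUE)
  m <- nrow(opt)
  req_idx <- which(cm$required, arr.ind = TRUE)

  best_score <- -Inf; best_A <- NULL; best_keys <- NULL; n_dags <- 0L
  base <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  if (nrow(req_idx)) base[req_idx] <- TRUE

  for (mask in 0:(2^m - 1)) {
    A <- base
    if (m) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
      if (length(sel)) A[opt[sel, , drop = FALSE]] <- TRUE
    }
    if (!.isAcyclicAdj(A)) next
    n_dags <- n_dags + 1L
    total <- 0
    for (v in genes) total <- total + fam(v, genes[A[, v]])["score"]
    keys <- sort(.edgeKey(genes[which(A, arr.ind = TRUE)[, 1L]],
                          genes[which(A, arr.ind = TRUE)[, 2L]]))
    better <- total > best_score + 1e-12 ||
      (abs(total - best_score) <= 1e-12 && !is.null(best_keys) &&
         (length(keys) < length(best_keys) ||
            (length(keys) == length(best_keys) && length(keys) &&
               paste(keys, collapse = ";") <
                 paste(best_keys, collapse = ";"))))
    if (is.null(best_A) || better) {
      best_score <- total; best_A <- A; best_keys <- keys
    }
  }
  idx <- which(best_A, arr.ind = TRUE)
  e <- data.frame(from = genes[idx[, 1L]], to = genes[idx[, 2L]],
                  stringsAsFactors = FALSE)
  e$required <- cm$required[idx]
  graph <- PathwayGraph(genes, e)
  list(graph = graph, score = bicScore(graph, data), nDags = n_dags)
}
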
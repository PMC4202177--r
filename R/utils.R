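# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and stream offsets, staying < 2^31.
.childSeed <- function(seed, ...) {
  offs <- c(...)
  s <- (as.double(seed) + sum(offs * seq_along(offs) * 10007)) %% 2147483629
  as.integer(s)
}

# round-half-up, used wherever a count is derived from a mean or fraction
.roundHalfUp <- function(x) floor(x + 0.5)

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# rowwise logsumexp over a matrix
.rowLogSumExp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

.makeEdgeDF <- function(from, to, required = FALSE) {
  data.frame(from = as.character(from), to = as.character(to),
             required = rep_len(as.logical(required), length(from)),
             stringsAsFactors = FALSE)
}

#' Construct a pathway graph
#'
#' @param nodes character vector of gene ids.
#' @param edges data.frame with columns \code{from}, \code{to} and optional
#'   \code{required} (default \code{FALSE}); \code{NULL} for an edgeless
#'   graph.
#' @return a [PathwayGraph-class]
#' @examples
#' g <- PathwayGraph(c("g1", "g2"), data.frame(from = "g1", to = "g2"))
#' edges(g)
#' @export
PathwayGraph <- function(nodes, edges = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    e <- .emptyEdgesReq()
  } else {
    if (!"required" %in% names(edges)) edges$required <- FALSE
    e <- data.frame(from = as.character(edges$from),
                    to = as.character(edges$to),
                    required = as.logical(edges$required),
                    stringsAsFactors = FALSE)
    rownames(e) <- NULL
  }
  new("PathwayGraph", nodes = as.character(nodes), edges = e)
}

#' Construct a constraint set
#'
#' The allowed set is automatically unioned with the required set so that
#' the invariant required ⊆ allowed always holds.
#'
#' @param required data.frame(from, to) of edges fixed during search.
#' @param allowed data.frame(from, to) of edges search may introduce.
#' @return a [ConstraintSet-class]
#' @export
ConstraintSet <- function(required = NULL, allowed = NULL) {
  norm <- function(d) {
    if (is.null(d) || nrow(d) == 0L) return(.emptyEdges())
    out <- data.frame(from = as.character(d$from), to = as.character(d$to),
                      stringsAsFactors = FALSE)
    out <- out[!duplicated(.edgeKey(out$from, out$to)), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  req <- norm(required)
  alw <- norm(rbind(norm(allowed), req))
  new("ConstraintSet", required = req, allowed = alw)
}

#' Construct a gene-to-KO map from a named list
#'
#' @param map named list, gene id -> character vector of KO ids.
#' @return a [GeneKOMap-class]
#' @export
GeneKOMap <- function(map = list()) {
  map <- lapply(map, function(k) sort(unique(as.character(k))))
  new("GeneKOMap", map = map)
}

#' Construct an expression data container
#'
#' @param values numeric genes x conditions matrix with rownames (gene ids)
#'   and colnames (condition ids); \code{NA} marks missing measurements.
#' @return an [ExpressionData-class]
#' @export
ExpressionData <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("gene ids must be supplied as rownames")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("cond", seq_len(ncol(values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("ExpressionData", se)
}

# adjacency (logical) matrix of a PathwayGraph over an explicit node order
.adjMatrix <- function(graph, node_order = NULL) {
  nds <- if (is.null(node_order)) graph@nodes else node_order
  A <- matrix(FALSE, length(nds), length(nds), dimnames = list(nds, nds))
  e <- graph@edges
  if (nrow(e)) A[cbind(e$from, e$to)] <- TRUE
  A
}

# Warshall transitive closure; A logical adjacency. Returns reachability
# (paths of length >= 1).
.reachability <- function(A) {
  n <- nrow(A)
  R <- A
  for (k in seq_len(n)) {
    rk <- R[, k]
    if (any(rk)) R[rk, ] <- R[rk, , drop = FALSE] | rep(R[k, ], each = sum(rk))
  }
  R
}

.isAcyclicAdj <- function(A) !any(diag(.reachability(A)))

# Is the graph (given as adjacency) acyclic? For PathwayGraph objects.
.isAcyclic <- function(graph) {
  if (nrow(graph@edges) == 0L) return(TRUE)
  .isAcyclicAdj(.adjMatrix(graph))
}

# topological order of an acyclic adjacency matrix (Kahn); stops on a cycle,
# reporting one.
.topoOrder <- function(A) {
  nds <- rownames(A)
  indeg <- colSums(A)
  order <- character(0)
  active <- rep(TRUE, length(nds))
  names(active) <- nds
  repeat {
    ready <- nds[active & indeg == 0]
    if (!length(ready)) break
    v <- ready[1L]
    order <- c(order, v)
    active[v] <- FALSE
    indeg <- indeg - A[v, ]
    A[v, ] <- FALSE
  }
  if (any(active)) {
    cyc <- .findCycle(A[active, active, drop = FALSE])
    stop("graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  order
}

# find one directed cycle in a (sub)adjacency matrix known to contain one
.findCycle <- function(A) {
  nds <- rownames(A)
  color <- setNames(rep(0L, length(nds)), nds)  # 0 white 1 grey 2 black
  stack <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in nds[A[v, ]]) {
      if (!is.null(found)) return()
      if (color[w] == 1L) {
        i <- match(w, stack)
        found <<- c(stack[i:length(stack)], w)
        return()
      }
      if (color[w] == 0L) visit(w)
    }
    color[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in nds) {
    if (color[v] == 0L) visit(v)
    if (!is.null(found)) break
  }
  found
}
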
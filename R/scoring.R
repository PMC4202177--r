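# BIC scoring of linear-Gaussian networks. Each gene's expression is
# modelled as Gaussian around a linear function of its parents' expression;
# the network score is the maximized log-likelihood minus (log M / 2) times
# the number of independent parameters, decomposed over node families.

.NODE_VAR_FLOOR <- 1e-6

# OLS fit of y on columns of X (with intercept); ML residual variance.
.olsFamily <- function(y, X) {
  M <- length(y)
  D <- cbind(`(intercept)` = 1, X)
  qr_ <- qr(D)
  if (qr_$rank < ncol(D)) {
    # collinear parents: minimum-norm solution via pseudo-inverse
    beta <- MASS::ginv(crossprod(D)) %*% crossprod(D, y)
    message("rank-deficient design for a node family; pseudo-inverse used")
  } else {
    beta <- qr.coef(qr_, y)
  }
  beta <- as.numeric(beta)
  resid <- y - as.numeric(D %*% beta)
  rss <- sum(resid^2)
  sigma2 <- max(rss / M, .NODE_VAR_FLOOR)
  loglik <- -M / 2 * log(2 * pi * sigma2) - rss / (2 * sigma2)
  list(beta = beta, rss = rss, sigma2 = sigma2, loglik = loglik, M = M)
}

#' Fit the linear-Gaussian model of one node family
#'
#' Ordinary least squares of the node's expression on its parents'
#' expression (with intercept); the variance is the maximum-likelihood
#' residual variance (residual sum of squares over M), floored at 1e-6.
#' With no parents this reduces to the sample mean and population variance.
#' Collinear parent sets are handled through the pseudo-inverse.
#'
#' @param node gene id.
#' @param parents character vector of parent gene ids (possibly empty).
#' @param data an [ExpressionData-class] containing all the genes.
#' @return a \code{GaussianNodeModel}: a list with elements \code{node},
#'   \code{parents}, \code{intercept}, \code{coefficients} (one per
#'   parent), \code{variance}, \code{loglik} and \code{M}.
#' @export
fitNode <- function(node, parents, data) {
  V <- exprsValues(data)
  miss <- setdiff(c(node, parents), rownames(V))
  if (length(miss))
    stop("gene(s) not in expression data: ", paste(miss, collapse = ", "))
  y <- V[node, ]
  X <- if (length(parents)) t(V[parents, , drop = FALSE]) else
    matrix(0, length(y), 0L)
  fit <- .olsFamily(y, X)
  structure(list(node = node, parents = as.character(parents),
                 intercept = fit$beta[1L],
                 coefficients = setNames(fit$beta[-1L],
                                         as.character(parents)),
                 variance = fit$sigma2, loglik = fit$loglik, M = fit$M),
            class = "GaussianNodeModel")
}

#' @export
print.GaussianNodeModel <- function(x, ...) {
  cat("GaussianNodeModel for", x$node, "| parents:",
      if (length(x$parents)) paste(x$parents, collapse = ", ") else "none",
      sprintf("| variance %.4g\n", x$variance))
  invisible(x)
}

#' Family score of one node under the network score
#'
#' The node's maximized Gaussian log-likelihood (natural log) minus the
#' penalty \code{(log M / 2) * (|parents| + 2)}: one regression coefficient
#' per parent, plus intercept and variance.
#'
#' @inheritParams fitNode
#' @return numeric score; the log-likelihood part is attached as attribute
#'   \code{"loglik"}.
#' @export
familyScore <- function(node, parents, data) {
  fit <- fitNode(node, parents, data)
  score <- fit$loglik - log(fit$M) / 2 * (length(parents) + 2)
  attr(score, "loglik") <- fit$loglik
  score
}

#' BIC score of a pathway graph
#'
#' Total network score \code{loglik - (log M / 2) * dim}, decomposed into
#' per-node family contributions; \code{dim} counts, per node, one
#' coefficient per parent plus intercept and variance. The graph must be
#' acyclic.
#'
#' @param graph an acyclic [PathwayGraph-class] whose nodes are all in
#'   \code{data}.
#' @param data an [ExpressionData-class].
#' @return a [ScoreReport-class]
#' @export
bicScore <- function(graph, data) {
  .topoOrder(.adjMatrix(graph))  # errors with a named cycle if cyclic
  nds <- sort(graph@nodes)
  e <- graph@edges
  per <- numeric(length(nds)); ll <- 0; dim_ <- 0L
  for (i in seq_along(nds)) {
    v <- nds[i]
    pa <- sort(e$from[e$to == v])
    s <- familyScore(v, pa, data)
    per[i] <- as.numeric(s)
    ll <- ll + attr(s, "loglik")
    dim_ <- dim_ + length(pa) + 2L
  }
  new("ScoreReport", total = sum(per), perNode = setNames(per, nds),
      dim = dim_, loglik = ll, M = ncol(data))
}

#' Write a score report as JSON
#'
#' @param report a [ScoreReport-class].
#' @param path output file.
#' @export
writeScoreReport <- function(report, path) {
  jsonlite::write_json(
    list(total = report@total, loglik = report@loglik, dim = report@dim,
         M = report@M, per_node = as.list(report@perNode)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
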
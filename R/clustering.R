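# Diagonal-covariance Gaussian-mixture EM over gene expression profiles.
# Genes are the observations, conditions the dimensions. The component
# count is chosen by cross-validated held-out log-likelihood, mirroring
# EM-clustering tools that pick k by cross-validation.

.VAR_FLOOR <- 1e-6

# per-component log density of each row of Y under N(mu, diag(s2))
.gmmLogDens <- function(Y, means, vars) {
  n <- nrow(Y); k <- nrow(means)
  L <- matrix(0, n, k)
  for (j in seq_len(k)) {
    mu <- means[j, ]; s2 <- vars[j, ]
    L[, j] <- -0.5 * sum(log(2 * pi * s2)) -
      0.5 * colSums((t(Y) - mu)^2 / s2)
  }
  L
}

#' Fit a Gaussian mixture to gene expression profiles by EM
#'
#' Fits a k-component mixture of diagonal-covariance Gaussians over the
#' gene rows of \code{x}. Initialisation takes k distinct genes (seeded
#' draw) as starting means with pooled per-condition variances and uniform
#' weights; EM iterates until the relative log-likelihood improvement drops
#' below 1e-6 or 500 iterations. Variances are floored at 1e-6 so
#' degenerate (duplicated) data cannot collapse a component. The training
#' log-likelihood trace is stored and is non-decreasing.
#'
#' @param x an [ExpressionData-class] with no missing values.
#' @param k number of components, \code{1 <= k <=} number of genes.
#' @param seed integer seed; the fit is deterministic given \code{seed}.
#' @param maxIter iteration cap.
#' @return a [ClusterModel-class]
#' @export
emFit <- function(x, k, seed = 1L, maxIter = 500L) {
  Y <- exprsValues(x)
  if (anyNA(Y)) stop("expression data contain missing values; impute first")
  n <- nrow(Y); d <- ncol(Y); k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of genes (", n, ")")

  pooled <- pmax(apply(Y, 2L, var) * (n - 1) / max(1, n), .VAR_FLOOR)
  # seeded k-means initialisation; random distinct rows if k-means cannot
  # run (fewer distinct profiles than components)
  means <- .withSeed(seed, tryCatch(
    stats::kmeans(Y, k, nstart = 5L, iter.max = 50L)$centers,
    error = function(e) Y[sample.int(n, k), , drop = FALSE]))
  vars <- matrix(pooled, k, d, byrow = TRUE)
  w <- rep(1 / k, k)

  ll_trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(maxIter)) {
    L <- .gmmLogDens(Y, means, vars)
    Lw <- sweep(L, 2L, log(w), "+")
    norm <- .rowLogSumExp(Lw)
    ll <- sum(norm)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(Lw - norm)
    if (is.finite(prev) && (ll - prev) <= 1e-6 * abs(prev)) break
    prev <- ll
    Nj <- pmax(colSums(resp), 1e-10)
    w <- Nj / sum(Nj)
    means <- (t(resp) %*% Y) / Nj
    for (j in seq_len(k)) {
      dev2 <- (t(Y) - means[j, ])^2
      vars[j, ] <- pmax(colSums(t(dev2) * resp[, j]) / Nj[j], .VAR_FLOOR)
    }
  }
  assign_idx <- max.col(resp, ties.method = "first")
  rownames(means) <- rownames(vars) <- NULL
  colnames(means) <- colnames(vars) <- colnames(Y)
  new("ClusterModel", k = k, means = means, variances = vars,
      weights = w / sum(w),
      assignments = setNames(as.integer(assign_idx), rownames(Y)),
      logLik = ll_trace,
      cvTable = data.frame(k = integer(0), heldout_loglik = numeric(0)))
}

# held-out log-likelihood of rows of Y under a fitted model
.gmmHeldout <- function(model, Y) {
  Lw <- sweep(.gmmLogDens(Y, model@means, model@variances), 2L,
              log(model@weights), "+")
  sum(.rowLogSumExp(Lw))
}

#' Choose the number of mixture components by cross-validation
#'
#' Splits genes into folds (seeded permutation), fits the mixture on the
#' training genes for each candidate k, scores the held-out genes' mixture
#' log-likelihood, and returns the k maximising the mean held-out
#' log-likelihood across folds. Ties break toward the smaller k.
#'
#' @param x an [ExpressionData-class] with no missing values.
#' @param kMin,kMax candidate range, \code{1 <= kMin <= kMax <=} genes.
#' @param folds number of cross-validation folds (>= 2); 10 by default.
#' @param seed integer seed driving the fold split and every EM fit.
#' @return the selected number of clusters (integer); the cross-validation
#'   table is attached as attribute \code{"cvTable"}.
#' @export
selectNumClusters <- function(x, kMin = 1L, kMax = 10L, folds = 10L,
                              seed = 1L) {
  Y <- exprsValues(x)
  n <- nrow(Y)
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  stopifnot(kMin >= 1L, kMin <= kMax, kMax <= n, folds >= 2L)
  if (kMin == kMax) return(kMin)
  fold_id <- .withSeed(.childSeed(seed, 1L),
                       sample(rep_len(seq_len(folds), n)))
  ks <- kMin:kMax
  mean_ll <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    fold_ll <- numeric(folds)
    for (f in seq_len(folds)) {
      train <- which(fold_id != f)
      test <- which(fold_id == f)
      if (length(train) < k || !length(test)) {
        fold_ll[f] <- NA_real_
        next
      }
      m <- emFit(x[train, ], k, seed = .childSeed(seed, k, f))
      fold_ll[f] <- .gmmHeldout(m, Y[test, , drop = FALSE])
    }
    mean_ll[i] <- mean(fold_ll, na.rm = TRUE)
  }
  best <- ks[which.max(mean_ll)]   # first max = smallest k on ties
  attr(best, "cvTable") <- data.frame(k = ks, heldout_loglik = mean_ll)
  best
}

#' Euclidean distance between cluster means
#'
#' Used by the sampling stage: selection probability of a non-pivotal
#' cluster decreases with its distance from the pivot.
#'
#' @param model a [ClusterModel-class].
#' @param a,b component indices (1-based).
#' @return non-negative distance; symmetric; 0 for \code{a == b}.
#' @export
clusterDistance <- function(model, a, b) {
  k <- model@k
  if (a < 1L || a > k || b < 1L || b > k)
    stop("cluster index out of range 1..", k)
  sqrt(sum((model@means[a, ] - model@means[b, ])^2))
}
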
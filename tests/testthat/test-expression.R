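test_that("filterMissing applies a strict threshold and is idempotent", {
  V <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  V["g1", 1:3] <- NA   # 30% missing -> removed
  V["g2", 1:2] <- NA   # exactly 20% -> kept
  x <- exprsFixture <- ExpressionData(V)
  f <- filterMissing(x, 0.2)
  expect_identical(rownames(f), c("g2", "g3", "g4"))
  expect_identical(rownames(filterMissing(f, 0.2)), rownames(f))

  # fully observed matrix unchanged
  x2 <- ExpressionData(V[c("g3", "g4"), ])
  expect_identical(exprsValues(filterMissing(x2, 0.2)), V[c("g3", "g4"), ])

  V3 <- V; V3[] <- NA; V3[1, 1] <- 0
  expect_error(filterMissing(ExpressionData(V3), 0.2), "all genes")
})

test_that("row-mean imputation fills gaps with the gene's observed mean", {
  V <- rbind(g1 = c(1, NA, 3), g2 = c(0, 1, 2))
  colnames(V) <- paste0("c", 1:3)
  out <- exprsValues(imputeExpression(ExpressionData(V), "row_mean"))
  expect_identical(out["g1", 2], 2)
  expect_identical(out["g2", ], V["g2", ])  # observed untouched

  # fully observed input is returned bit-identical
  x <- randomExpr(paste0("g", 1:5), 6, seed = 1)
  expect_identical(exprsValues(imputeExpression(x, "row_mean")),
                   exprsValues(x))

  V4 <- rbind(g1 = c(NA, NA, NA), g2 = c(1, 2, 3))
  colnames(V4) <- paste0("c", 1:3)
  expect_error(imputeExpression(ExpressionData(V4)), "g1")
})

test_that("knn imputation matches a brute-force nearest-neighbour oracle", {
  set.seed(42)
  V <- matrix(rnorm(25), 5, 5,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:5)))
  V[1, 3] <- NA
  out <- exprsValues(imputeExpression(ExpressionData(V), "knn", k = 2L))
  # oracle: mean squared difference over shared observed conditions,
  # computed independently over all pairs
  d2 <- sapply(2:5, function(j) mean((V[j, -3] - V[1, -3])^2))
  nn <- (2:5)[order(d2)][1:2]
  expect_equal(out[1, 3], mean(V[nn, 3]), tolerance = 1e-12)
  expect_identical(out[-1, ], V[-1, ])
})

test_that("emFit recovers closed forms and separated components", {
  x <- randomExpr(paste0("g", 1:20), 4, seed = 3)
  m1 <- emFit(x, 1, seed = 1)
  expect_equal(unname(m1@means[1, ]), unname(colMeans(exprsValues(x))),
               tolerance = 1e-8)
  expect_identical(m1@weights, 1)

  # three well-separated components: assignments match generating labels
  set.seed(11)
  Y <- rbind(matrix(rnorm(20 * 3, 0), 20), matrix(rnorm(20 * 3, 8), 20),
             matrix(rnorm(20 * 3, -8), 20))
  rownames(Y) <- paste0("g", 1:60)
  m3 <- emFit(ExpressionData(Y), 3, seed = 5)
  labels <- rep(1:3, each = 20)
  tab <- table(clusterAssignments(m3), labels)
  expect_identical(sum(apply(tab, 2, max)), 60L)  # perfect up to permutation

  # determinism
  m3b <- emFit(ExpressionData(Y), 3, seed = 5)
  expect_identical(m3@means, m3b@means)
  expect_identical(m3@assignments, m3b@assignments)

  expect_error(emFit(x, 21, seed = 1), "exceeds")
})

test_that("EM training log-likelihood is monotone non-decreasing", {
  for (s in 1:4) {
    x <- randomExpr(paste0("g", 1:40), 5, seed = s)
    m <- emFit(x, 3, seed = s)
    expect_true(all(diff(m@logLik) >= -1e-6 * abs(m@logLik[1])))
  }
})

test_that("selectNumClusters picks the generating k and handles degenerate
          input", {
  set.seed(2)
  Y <- rbind(matrix(rnorm(30 * 4, 0), 30), matrix(rnorm(30 * 4, 7), 30),
             matrix(rnorm(30 * 4, -7), 30))
  rownames(Y) <- paste0("g", 1:90)
  k <- selectNumClusters(ExpressionData(Y), 1, 6, folds = 10, seed = 2)
  expect_identical(as.integer(k), 3L)
  cv <- attr(k, "cvTable")
  expect_identical(cv$k, 1:6)

  # degenerate range returns without alternative fits
  expect_identical(selectNumClusters(ExpressionData(Y), 4, 4, seed = 1), 4L)

  # duplicated rows: variance floor keeps EM finite
  Yd <- matrix(1, 12, 3, dimnames = list(paste0("g", 1:12), NULL))
  m <- emFit(ExpressionData(Yd), 2, seed = 1)
  expect_true(all(is.finite(m@logLik)))
  expect_true(all(m@variances >= 1e-6))
})

test_that("emFit agrees with an independent mixture implementation on
          separated data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(9)
  Y <- rbind(matrix(rnorm(25 * 3, 0), 25), matrix(rnorm(25 * 3, 9), 25))
  rownames(Y) <- paste0("g", 1:50)
  m <- emFit(ExpressionData(Y), 2, seed = 1)
  ref <- mclust::Mclust(Y, G = 2, modelNames = "VVI", verbose = FALSE)
  # identical partitions up to label permutation
  tab <- table(clusterAssignments(m), ref$classification)
  expect_identical(sum(apply(tab, 2, max)), 50L)
})

test_that("clusterDistance is the Euclidean distance between means", {
  m <- toyClusterModel(rbind(c(0, 0), c(3, 4), c(1, 1)),
                       setNames(c(1L, 2L, 3L), paste0("g", 1:3)))
  expect_identical(clusterDistance(m, 1, 1), 0)
  expect_identical(clusterDistance(m, 1, 2), 5)
  expect_identical(clusterDistance(m, 2, 3), clusterDistance(m, 3, 2))
  expect_error(clusterDistance(m, 1, 4), "out of range")
})

test_that("expression TSV reader round-trips values and missingness", {
  f <- withr::local_tempfile(lines = c(
    "gene_id\tc1\tc2\tc3", "g1\t1.5\t\t3", "g2\tNA\t2\t4"))
  x <- readExpressionMatrix(f)
  V <- exprsValues(x)
  expect_identical(dim(V), c(2L, 3L))
  expect_true(is.na(V["g1", "c2"]) && is.na(V["g2", "c1"]))
  expect_identical(V["g1", "c3"], 3)
})
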
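test_that("fitNode matches closed forms and the normal equations", {
  x <- randomExpr(c("a", "b", "c"), 60, seed = 2)
  V <- exprsValues(x)

  # no parents: sample mean, population (ML) variance
  f0 <- fitNode("a", character(0), x)
  expect_equal(f0$intercept, mean(V["a", ]), tolerance = 1e-12)
  expect_equal(f0$variance, mean((V["a", ] - mean(V["a", ]))^2),
               tolerance = 1e-12)

  # exact linear child: coefficient 2, intercept 1, variance at the floor
  V2 <- rbind(p = V["a", ], q = 2 * V["a", ] + 1)
  f1 <- fitNode("q", "p", ExpressionData(V2))
  expect_equal(unname(f1$coefficients), 2, tolerance = 1e-8)
  expect_equal(f1$intercept, 1, tolerance = 1e-8)
  expect_identical(f1$variance, 1e-6)

  # two parents: solve the normal equations independently
  f2 <- fitNode("c", c("a", "b"), x)
  D <- cbind(1, V["a", ], V["b", ])
  beta <- solve(t(D) %*% D, t(D) %*% V["c", ])
  expect_equal(c(f2$intercept, unname(f2$coefficients)), as.numeric(beta),
               tolerance = 1e-8)

  expect_error(fitNode("zz", "a", x), "zz")
})

test_that("familyScore equals direct density summation minus the penalty", {
  x <- randomExpr("a", 100, seed = 5)
  v <- exprsValues(x)["a", ]
  s <- familyScore("a", character(0), x)
  s2_ml <- mean((v - mean(v))^2)
  direct <- sum(dnorm(v, mean(v), sqrt(s2_ml), log = TRUE)) -
    log(100) / 2 * 2
  expect_equal(as.numeric(s), direct, tolerance = 1e-9)

  # adding a parent changes the penalty by exactly -(log M)/2
  x2 <- randomExpr(c("a", "b"), 100, seed = 6)
  s0 <- familyScore("a", character(0), x2)
  s1 <- familyScore("a", "b", x2)
  pen_change <- (as.numeric(s1) - attr(s1, "loglik")) -
    (as.numeric(s0) - attr(s0, "loglik"))
  expect_equal(pen_change, -log(100) / 2, tolerance = 1e-12)
  expect_true(attr(s1, "loglik") >= attr(s0, "loglik") - 1e-9)

  # duplicated (collinear) parent stays finite
  V <- exprsValues(x2)
  V3 <- rbind(V, b2 = V["b", ])
  expect_message(s3 <- familyScore("a", c("b", "b2"), ExpressionData(V3)),
                 "rank-deficient")
  expect_true(is.finite(s3))
})

test_that("bicScore decomposes over families and is order-invariant", {
  genes <- c("a", "b", "c", "d")
  x <- randomExpr(genes, 50, seed = 8)
  g <- PathwayGraph(genes, data.frame(from = c("a", "b", "a"),
                                      to = c("b", "c", "c")))
  rep_ <- bicScore(g, x)
  expect_equal(rep_@total, sum(rep_@perNode), tolerance = 1e-9)
  expect_identical(rep_@dim, 3L + 4L + 2L + 2L)  # b:1pa, c:2pa, a/d:0pa
  expect_equal(rep_@total, rep_@loglik - log(50) / 2 * rep_@dim,
               tolerance = 1e-9)

  # empty graph: sum of marginal families, dim = 2n
  g0 <- PathwayGraph(genes)
  r0 <- bicScore(g0, x)
  expect_identical(r0@dim, 8L)
  expect_equal(r0@total,
               sum(sapply(genes, function(v)
                 as.numeric(familyScore(v, character(0), x)))),
               tolerance = 1e-9)

  # node-order invariance
  g_perm <- PathwayGraph(rev(genes), edges(g)[c(3, 1, 2), ])
  expect_equal(bicScore(g_perm, x)@total, rep_@total, tolerance = 1e-9)

  g_cyc <- PathwayGraph(genes, data.frame(from = c("a", "b"),
                                          to = c("b", "a")))
  expect_error(bicScore(g_cyc, x), "cycle")
})

test_that("single-move neighbours differ only in the affected families", {
  genes <- paste0("g", 1:5)
  x <- randomExpr(genes, 40, seed = 10)
  g <- PathwayGraph(genes, data.frame(from = c("g1", "g2"),
                                      to = c("g2", "g3")))
  base <- bicScore(g, x)
  # add g4 -> g5: only g5's family changes
  g_add <- PathwayGraph(genes, rbind(edges(g),
                                     data.frame(from = "g4", to = "g5",
                                                required = FALSE)))
  r_add <- bicScore(g_add, x)
  delta_full <- r_add@total - base@total
  delta_fam <- as.numeric(familyScore("g5", "g4", x)) -
    as.numeric(familyScore("g5", character(0), x))
  expect_equal(delta_full, delta_fam, tolerance = 1e-9)
  unchanged <- setdiff(genes, "g5")
  expect_equal(r_add@perNode[unchanged], base@perNode[unchanged],
               tolerance = 1e-12)
})

test_that("legalMoves enumerates exactly the constraint-respecting moves", {
  genes <- c("A", "B", "C")
  # fully pinned 2-node graph: no moves
  g2 <- PathwayGraph(c("A", "B"),
                     data.frame(from = "A", to = "B", required = TRUE))
  cs2 <- ConstraintSet(required = data.frame(from = "A", to = "B"),
                       allowed = data.frame(from = "A", to = "B"))
  expect_identical(nrow(legalMoves(g2, cs2)), 0L)

  # empty 3-node graph, all pairs allowed: 6 adds
  cs <- allPairsConstraints(genes)
  mv0 <- legalMoves(PathwayGraph(genes), cs)
  expect_identical(nrow(mv0), 6L)
  expect_true(all(mv0$kind == "add"))

  # chain A->B->C: adds {A->C}, removes {A->B,B->C}, reversals {A->B,B->C}
  chain <- PathwayGraph(genes, data.frame(from = c("A", "B"),
                                          to = c("B", "C")))
  mv <- legalMoves(chain, cs)
  expect_identical(nrow(mv), 5L)
  got <- paste(mv$kind, mv$from, mv$to)
  expect_setequal(got, c("add A C", "remove A B", "remove B C",
                         "reverse A B", "reverse B C"))

  # graph violating its constraints is rejected
  bad <- PathwayGraph(genes, data.frame(from = "A", to = "B"))
  cs_bad <- ConstraintSet(allowed = data.frame(from = "B", to = "C"))
  expect_error(legalMoves(bad, cs_bad), "outside the allowed")
})

test_that("reversals require the reversed direction to be whitelisted", {
  genes <- c("A", "B")
  g <- PathwayGraph(genes, data.frame(from = "A", to = "B"))
  cs_one_way <- ConstraintSet(allowed = data.frame(from = "A", to = "B"))
  mv <- legalMoves(g, cs_one_way)
  expect_false("reverse" %in% mv$kind)
  cs_both <- ConstraintSet(allowed = data.frame(from = c("A", "B"),
                                                to = c("B", "A")))
  expect_true("reverse" %in% legalMoves(g, cs_both)$kind)
})

test_that("greedySearch is a fixed point without improving moves and
          traces strictly increasing scores", {
  genes <- c("A", "B")
  g <- PathwayGraph(genes, data.frame(from = "A", to = "B", required = TRUE))
  cs <- ConstraintSet(required = data.frame(from = "A", to = "B"),
                      allowed = data.frame(from = "A", to = "B"))
  x <- randomExpr(genes, 30, seed = 4)
  fit <- greedySearch(g, x, cs)
  expect_identical(edges(fit$graph), edges(g))
  expect_identical(nrow(fit$trace), 1L)

  truth <- generateTruthDag(6, 0.4, seed = 3)
  d <- simulateExpression(truth, 300, seed = 4)
  fit2 <- greedySearch(PathwayGraph(nodes(truth)), d,
                       allPairsConstraints(nodes(truth)), validate = TRUE)
  expect_true(all(diff(fit2$trace$score) > 0))
  expect_equal(fit2$trace$score[nrow(fit2$trace)], fit2$score@total,
               tolerance = 1e-9)
})

test_that("search output always satisfies the constraints", {
  for (s in 1:5) {
    b <- generateBenchmarkBundle(nNodes = 7, M = 300, seed = s)
    ref <- parseKGML(b$kgmlDocs$reference)
    kb <- buildKnowledgebase(lapply(b$kgmlDocs, parseKGML))
    init <- initialMap(ref, b$komap)
    init_full <- PathwayGraph(nodes(b$truth), edges(init))
    cs <- buildConstraints(init_full, kb, b$komap, nodes(b$truth))
    fit <- greedySearch(init_full, b$data, cs, validate = TRUE)
    e <- edges(fit$graph)
    req <- requiredEdges(cs)
    expect_true(all(edgeKeySet(req) %in% edgeKeySet(e)))
    expect_true(all(edgeKeySet(e) %in% edgeKeySet(allowedEdges(cs))))
    expect_true(bnpath:::.isAcyclic(fit$graph))
  }
})

test_that("exhaustiveSearch enumerates DAG space and honours constraints", {
  genes2 <- c("A", "B")
  x2 <- randomExpr(genes2, 40, seed = 12)
  ex2 <- exhaustiveSearch(genes2, x2)
  expect_identical(ex2$nDags, 3L)  # empty, A->B, B->A

  genes3 <- c("A", "B", "C")
  x3 <- randomExpr(genes3, 40, seed = 13)
  ex3 <- exhaustiveSearch(genes3, x3)
  expect_identical(ex3$nDags, 25L)

  # a required edge appears in every enumerated DAG, hence in the optimum
  cs <- ConstraintSet(required = data.frame(from = "A", to = "B"),
                      allowed = expand.grid(from = genes3, to = genes3,
                                            stringsAsFactors = FALSE) |>
                        (\(g) g[g$from != g$to, ])())
  ex_req <- exhaustiveSearch(genes3, x3, cs)
  expect_true("A->B" %in% edgeKeySet(edges(ex_req$graph)))
  expect_identical(ex_req$nDags, 8L)  # of the 25 DAGs, 8 contain A->B

  expect_error(exhaustiveSearch(paste0("g", 1:6), x3), "5 genes")
})

test_that("greedy search attains the exhaustive optimum on small instances", {
  hits <- 0L
  for (s in 1:10) {
    x <- randomExpr(paste0("g", 1:4), 500, seed = s)
    fit <- greedySearch(PathwayGraph(rownames(exprsValues(x))), x,
                        allPairsConstraints(rownames(exprsValues(x))))
    ex <- exhaustiveSearch(rownames(exprsValues(x)), x)
    if (abs(fit$score@total - ex$score@total) <=
        1e-9 * max(1, abs(ex$score@total))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("constrained learning beats unconstrained on decoy-laced truth", {
  wins <- 0L
  for (s in 1:8) {
    b <- generateBenchmarkBundle(nNodes = 8, M = 1000, decoyFraction = 0.5,
                                 dropFraction = 0, seed = s)
    ref <- parseKGML(b$kgmlDocs$reference)
    kb <- buildKnowledgebase(lapply(b$kgmlDocs, parseKGML))
    init <- initialMap(ref, b$komap)
    init_full <- PathwayGraph(nodes(b$truth), edges(init))
    cs <- buildConstraints(init_full, kb, b$komap, nodes(b$truth))
    fit_c <- greedySearch(init_full, b$data, cs)
    fit_u <- greedySearch(PathwayGraph(nodes(b$truth)), b$data,
                          allPairsConstraints(nodes(b$truth)))
    ev_c <- evaluateEdges(fit_c$graph, b$truth)
    ev_u <- evaluateEdges(fit_u$graph, b$truth)
    if (ev_c$precision > ev_u$precision) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})
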
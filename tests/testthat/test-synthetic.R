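test_that("generateTruthDag draws seeded acyclic graphs at the asked
          density", {
  g <- generateTruthDag(8, 0.5, seed = 2)
  g2 <- generateTruthDag(8, 0.5, seed = 2)
  expect_identical(edges(g), edges(g2))
  expect_true(bnpath:::.isAcyclic(g))

  # density -> 1: the full DAG over the drawn order
  g_full <- generateTruthDag(3, 1 - 1e-12, seed = 1)
  expect_identical(nrow(edges(g_full)), 3L)

  expect_error(generateTruthDag(4, 0), "strictly inside")
  expect_error(generateTruthDag(4, 1.2), "strictly inside")
  expect_error(generateTruthDag(1, 0.5), ">= 2")

  # binomial expectation over many draws
  n_pairs <- choose(6, 2)
  counts <- vapply(1:1000,
                   function(s) nrow(edges(generateTruthDag(6, 0.3, s))), 0L)
  se <- sqrt(n_pairs * 0.3 * 0.7 / 1000)
  expect_lt(abs(mean(counts) - 0.3 * n_pairs), 3 * se)
})

test_that("simulateExpression follows the linear-Gaussian model", {
  # single node: iid draws around 0
  g1 <- PathwayGraph(c("a", "b"))
  M <- 400
  d <- simulateExpression(g1, M, noiseSd = 1, seed = 9)
  expect_lt(abs(mean(exprsValues(d)["a", ])), 4 / sqrt(M))

  # deterministic chain with coefficient 1 and tiny noise
  chain <- PathwayGraph(c("a", "b"),
                        data.frame(from = "a", to = "b"))
  d2 <- simulateExpression(chain, 50, coefRange = c(1, 1),
                           noiseSd = 1e-6, seed = 3, randomSign = FALSE)
  V <- exprsValues(d2)
  expect_equal(V["b", ], V["a", ], tolerance = 1e-4)

  d3 <- simulateExpression(chain, 50, seed = 3)
  expect_identical(exprsValues(simulateExpression(chain, 50, seed = 3)),
                   exprsValues(d3))
})

test_that("corruptKnowledgebase drops and decoys by exact counts", {
  truth <- generateTruthDag(8, 0.5, seed = 5)
  e <- edges(truth)

  same <- corruptKnowledgebase(truth, 0, 0, seed = 1)
  expect_setequal(edgeKeySet(same), edgeKeySet(e))

  none <- corruptKnowledgebase(truth, 0, 1, seed = 1)
  expect_identical(nrow(none), 0L)

  ten <- generateTruthDag(10, 0.999999, seed = 2)  # dense: many edges
  e10 <- edges(ten)[1:10, ]
  ten10 <- PathwayGraph(nodes(ten), e10)
  dropped <- corruptKnowledgebase(ten10, 0, 0.2, seed = 4)
  expect_identical(nrow(dropped), 8L)
  expect_true(all(edgeKeySet(dropped) %in% edgeKeySet(e10)))

  dec <- corruptKnowledgebase(ten10, 0.5, 0, seed = 4)
  expect_identical(nrow(dec), 15L)
  expect_true(all(edgeKeySet(e10) %in% edgeKeySet(dec)))
  # decoys never duplicate true edges
  expect_identical(anyDuplicated(edgeKeySet(dec)), 0L)

  two <- PathwayGraph(c("a", "b"), data.frame(from = "a", to = "b"))
  expect_error(corruptKnowledgebase(two, 1, 0, seed = 1), NA)
  expect_error(
    corruptKnowledgebase(PathwayGraph(c("a", "b"),
                                      data.frame(from = c("a", "b"),
                                                 to = c("b", "a"))), 1, 0, 1),
    "decoys")
})

test_that("KGML fixtures round-trip through the parser and knowledgebase", {
  for (s in 1:6) {
    truth <- generateTruthDag(6, 0.4, seed = s)
    km <- makeSyntheticKOMap(nodes(truth), kosPerGene = 1L + s %% 2)
    doc <- emitKGMLFixture(truth, km, mapId = sprintf("map%05d", s))
    pm <- parseKGML(doc)
    # identical entry/record structure on re-emission
    kb <- buildKnowledgebase(list(pm))
    back <- allowedGeneEdges(kb, km, nodes(truth))
    expect_setequal(edgeKeySet(back), edgeKeySet(edges(truth)))
  }

  # 2-node case with entries only
  g0 <- PathwayGraph(c("a", "b"))
  km0 <- makeSyntheticKOMap(c("a", "b"))
  pm0 <- parseKGML(emitKGMLFixture(g0, km0))
  expect_identical(nrow(records(pm0)), 0L)
  expect_identical(nrow(entries(pm0)), 2L)

  # compound annotations survive the round trip
  g1 <- PathwayGraph(c("a", "b"), data.frame(from = "a", to = "b"))
  doc1 <- emitKGMLFixture(g1, km0, edgeCompounds = c("a|b" = "C00099"))
  pm1 <- parseKGML(doc1)
  expect_identical(records(pm1)$compounds[[1]], "C00099")

  expect_error(emitKGMLFixture(g1, GeneKOMap(list(a = "K00001"))), "b")
})

test_that("benchmark bundles are seed-reproducible end to end", {
  b1 <- generateBenchmarkBundle(nNodes = 7, M = 100, seed = 11)
  b2 <- generateBenchmarkBundle(nNodes = 7, M = 100, seed = 11)
  expect_identical(edges(b1$truth), edges(b2$truth))
  expect_identical(exprsValues(b1$data), exprsValues(b2$data))
  expect_identical(b1$kgmlDocs, b2$kgmlDocs)
  expect_identical(b1$allowed, b2$allowed)

  b3 <- generateBenchmarkBundle(nNodes = 7, M = 100, seed = 12)
  expect_false(identical(exprsValues(b1$data), exprsValues(b3$data)))

  # decoys in the whitelist never duplicate true edges
  expect_identical(anyDuplicated(edgeKeySet(b1$allowed)), 0L)
})

test_that("full pipeline on a clean bundle never loses the seed recall", {
  b <- generateBenchmarkBundle(nNodes = 10, M = 800, decoyFraction = 0.5,
                               dropFraction = 0, seed = 21)
  ref <- parseKGML(b$kgmlDocs$reference)
  kb <- buildKnowledgebase(lapply(b$kgmlDocs, parseKGML))
  init <- initialMap(ref, b$komap)
  init_full <- PathwayGraph(nodes(b$truth), edges(init))
  cs <- buildConstraints(init_full, kb, b$komap, nodes(b$truth))
  fit <- greedySearch(init_full, b$data, cs, validate = TRUE)
  rec_init <- evaluateEdges(init, b$truth)$recall
  rec_fit <- evaluateEdges(fit$graph, b$truth)$recall
  expect_gte(rec_fit, rec_init)
})
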
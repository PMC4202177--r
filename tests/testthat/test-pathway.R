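test_that("initialMap marks up genes and expands reference relations", {
  pm <- parseKGML(kgmlThreeEntries())
  km <- GeneKOMap(list(g1 = "K00001", g2 = "K00002"))
  g <- initialMap(pm, km)
  expect_setequal(nodes(g), c("g1", "g2"))
  expect_identical(edgeKeySet(edges(g)), "g1->g2")
  expect_true(all(edges(g)$required))

  # no KO overlap -> empty graph
  km0 <- GeneKOMap(list(x = "K99999"))
  expect_length(nodes(initialMap(pm, km0)), 0L)

  # multi-KO entry {K00003,K00004}: genes on either KO map in
  km2 <- GeneKOMap(list(g2 = "K00002", g3 = "K00003", g4 = "K00004"))
  g2 <- initialMap(pm, km2)
  expect_setequal(edgeKeySet(edges(g2)), c("g2->g3", "g2->g4"))
})

test_that("initialMap edges are a subset of the map's own allowed edges", {
  for (s in 1:5) {
    truth <- generateTruthDag(6, 0.5, seed = s)
    km <- makeSyntheticKOMap(nodes(truth))
    pm <- parseKGML(emitKGMLFixture(truth, km))
    g <- initialMap(pm, km)
    allowed <- allowedGeneEdges(buildKnowledgebase(list(pm)), km, nodes(g))
    expect_true(all(edgeKeySet(edges(g)) %in% edgeKeySet(allowed)))
  }
})

test_that("cyclic reference expansions are demoted to a DAG deterministically", {
  kgml_cycle <- paste0(
    '<pathway name="path:map00077">',
    '<entry id="1" name="ko:K00001" type="ortholog"/>',
    '<entry id="2" name="ko:K00002" type="ortholog"/>',
    '<entry id="3" name="ko:K00003" type="ortholog"/>',
    '<relation entry1="1" entry2="2" type="ECrel"/>',
    '<relation entry1="2" entry2="3" type="ECrel"/>',
    '<relation entry1="3" entry2="1" type="ECrel"/>',
    '</pathway>')
  km <- GeneKOMap(list(a = "K00001", b = "K00002", c = "K00003"))
  expect_message(g <- initialMap(parseKGML(kgml_cycle), km), "cycle")
  expect_identical(nrow(edges(g)), 2L)
  # lexicographically first edge of the cycle (a->b) is the one dropped
  expect_setequal(edgeKeySet(edges(g)), c("b->c", "c->a"))
  expect_message(g2 <- initialMap(parseKGML(kgml_cycle), km))
  expect_identical(edges(g), edges(g2))
})

test_that("buildConstraints unions knowledgebase edges with required ones", {
  pm <- parseKGML(kgmlThreeEntries())
  kb <- buildKnowledgebase(list(pm))
  km <- GeneKOMap(list(g1 = "K00001", g2 = "K00002", g3 = "K00003"))

  # empty kb: allowed = required
  kb0 <- buildKnowledgebase(list(parseKGML(kgmlNoRelations())))
  init <- PathwayGraph(c("g1", "g2"),
                       data.frame(from = "g1", to = "g2", required = TRUE))
  cs0 <- buildConstraints(init, kb0, km, c("g1", "g2", "g3"))
  expect_identical(edgeKeySet(allowedEdges(cs0)), "g1->g2")
  expect_identical(edgeKeySet(requiredEdges(cs0)), "g1->g2")

  # kb pair over candidates, empty initial
  cs1 <- buildConstraints(PathwayGraph(character(0)), kb, km,
                          c("g1", "g2", "g3"))
  expect_identical(nrow(requiredEdges(cs1)), 0L)
  expect_setequal(edgeKeySet(allowedEdges(cs1)), c("g1->g2", "g2->g3"))

  # required edge missing from the kb stays allowed
  init2 <- PathwayGraph(c("g3", "g1"),
                        data.frame(from = "g3", to = "g1", required = TRUE))
  cs2 <- buildConstraints(init2, kb, km, c("g1", "g2", "g3"))
  expect_true("g3->g1" %in% edgeKeySet(allowedEdges(cs2)))
  expect_false(any(allowedEdges(cs2)$from == allowedEdges(cs2)$to))

  expect_error(buildConstraints(init2, kb, km, "g1"), "missing from")
})

test_that("attachCompounds unions the compounds of supporting records", {
  pm <- parseKGML(kgmlThreeEntries())
  kb <- buildKnowledgebase(list(pm))
  km <- GeneKOMap(list(g1 = "K00001", g2 = "K00002", g3 = "K00003"))
  g <- PathwayGraph(c("g1", "g2", "g3"),
                    data.frame(from = c("g1", "g2"), to = c("g2", "g3")))
  net <- attachCompounds(g, kb, km)
  expect_identical(edgeCompounds(net)[[1]], "C00022")  # ECrel compound
  expect_identical(edgeCompounds(net)[[2]], character(0))  # PPrel, none

  # two records with different compounds on the same KO pair -> union
  kgml_b <- paste0(
    '<pathway name="path:map00012">',
    '<entry id="1" name="ko:K00001" type="ortholog"/>',
    '<entry id="2" name="ko:K00002" type="ortholog"/>',
    '<entry id="9" name="cpd:C00031" type="compound"/>',
    '<relation entry1="1" entry2="2" type="ECrel">',
    '<subtype name="compound" value="9"/></relation>',
    '</pathway>')
  kb2 <- buildKnowledgebase(list(pm, parseKGML(kgml_b)))
  net2 <- attachCompounds(g, kb2, km)
  expect_setequal(net2@edgeCompounds[[1]], c("C00022", "C00031"))
})

test_that("graph edge-list IO round-trips including required flags", {
  g <- PathwayGraph(c("a", "b", "c"),
                    data.frame(from = c("a", "b"), to = c("b", "c"),
                               required = c(TRUE, FALSE)))
  f <- withr::local_tempfile()
  writeEdgeList(g, f)
  g2 <- readEdgeList(f, nodes = nodes(g))
  expect_identical(edges(g2), edges(g))

  f2 <- withr::local_tempfile()
  writeGraphML(g, f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
})
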
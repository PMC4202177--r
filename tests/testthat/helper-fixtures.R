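# Fixtures built in code; no data files.

# Minimal KGML document with 3 enzyme entries and 2 relations
# (e1 -> e2 ECrel with compound C00022; e2 -> e3 PPrel); entry 3 carries
# two KO numbers.
kgmlThreeEntries <- function() {
  paste0(
    '<?xml version="1.0"?>',
    '<pathway name="path:map00010" org="map" title="fixture">',
    '<entry id="1" name="ko:K00001" type="ortholog"/>',
    '<entry id="2" name="ko:K00002" type="ortholog"/>',
    '<entry id="3" name="ko:K00003 ko:K00004" type="ortholog"/>',
    '<entry id="4" name="cpd:C00022" type="compound"/>',
    '<relation entry1="1" entry2="2" type="ECrel">',
    '<subtype name="compound" value="4"/>',
    '</relation>',
    '<relation entry1="2" entry2="3" type="PPrel"/>',
    '</pathway>')
}

kgmlNoRelations <- function() {
  paste0('<pathway name="path:map00020">',
         '<entry id="1" name="ko:K00001" type="ortholog"/>',
         '<entry id="2" name="ko:K00002" type="ortholog"/>',
         '</pathway>')
}

kgmlDanglingRelation <- function() {
  paste0('<pathway name="path:map00030">',
         '<entry id="1" name="ko:K00001" type="ortholog"/>',
         '<relation entry1="1" entry2="99" type="ECrel"/>',
         '</pathway>')
}

# Expression fixture with controllable values
exprFixture <- function(values) {
  ExpressionData(values)
}

# A hand-built, valid ClusterModel (diagonal unit variances)
toyClusterModel <- function(means, assignments, weights = NULL) {
  means <- as.matrix(means)
  k <- nrow(means)
  if (is.null(weights)) weights <- rep(1 / k, k)
  new("ClusterModel", k = as.integer(k), means = means,
      variances = matrix(1, k, ncol(means)),
      weights = weights,
      assignments = as.integer(assignments) |>
        stats::setNames(names(assignments)),
      logLik = numeric(0),
      cvTable = data.frame(k = integer(0), heldout_loglik = numeric(0)))
}

# draw a small random expression matrix (iid standard normal)
randomExpr <- function(genes, M, seed) {
  set.seed(seed)
  Y <- matrix(rnorm(length(genes) * M), length(genes), M,
              dimnames = list(genes, paste0("c", seq_len(M))))
  ExpressionData(Y)
}

allPairsConstraints <- function(genes) {
  grid <- expand.grid(from = genes, to = genes, stringsAsFactors = FALSE)
  ConstraintSet(allowed = grid[grid$from != grid$to, ])
}

edgeKeySet <- function(df) sort(paste(df$from, df$to, sep = "->"))
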
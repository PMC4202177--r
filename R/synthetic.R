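# Self-contained benchmark generator: ground-truth DAGs, linear-Gaussian
# expression data sampled from them, corrupted knowledgebases, KGML
# fixtures and gene-to-KO tables. Everything is seeded and reproducible.

#' Generate a random ground-truth DAG
#'
#' Draws a random topological order of the nodes and includes each forward
#' edge independently with the given density; the result is acyclic by
#' construction. Node ids are \code{g1..gn}.
#'
#' @param nNodes number of genes (>= 2).
#' @param edgeDensity edge inclusion probability, in (0, 1).
#' @param seed integer RNG seed.
#' @return a [PathwayGraph-class] with no required edges
#' @export
generateTruthDag <- function(nNodes, edgeDensity = 0.3, seed = 1L) {
  nNodes <- as.integer(nNodes)
  if (nNodes < 2L) stop("nNodes must be >= 2")
  if (edgeDensity <= 0 || edgeDensity >= 1)
    stop("edgeDensity must lie strictly inside (0, 1)")
  nds <- paste0("g", seq_len(nNodes))
  .withSeed(seed, {
    ord <- sample(nds)
    from <- character(0); to <- character(0)
    for (i in seq_len(nNodes - 1L))
      for (j in (i + 1L):nNodes)
        if (runif(1) < edgeDensity) {
          from <- c(from, ord[i]); to <- c(to, ord[j])
        }
    PathwayGraph(nds, if (length(from))
      data.frame(from = from, to = to, stringsAsFactors = FALSE) else NULL)
  })
}

#' Simulate expression data from a ground-truth network
#'
#' Ancestral sampling in topological order under the linear-Gaussian model:
#' root genes are N(0, noiseSd^2); every other gene is the coefficient-
#' weighted sum of its parents plus N(0, noiseSd^2) noise, independently
#' for each of M conditions. Edge coefficients have magnitude drawn
#' uniformly from \code{[coefRange[1], coefRange[2]]}, with a random sign
#' when \code{randomSign} is \code{TRUE}.
#'
#' @param truth an acyclic [PathwayGraph-class].
#' @param M number of conditions (>= 2).
#' @param coefRange magnitude interval for edge coefficients; a single
#'   number is treated as a zero-width interval.
#' @param noiseSd standard deviation of the Gaussian noise.
#' @param seed integer RNG seed.
#' @param randomSign flip each coefficient's sign with probability 1/2.
#' @return an [ExpressionData-class]; the drawn coefficients are attached
#'   to the assay container as metadata column-free attribute
#'   \code{"coefficients"} (data.frame from, to, coef).
#' @export
simulateExpression <- function(truth, M, coefRange = c(0.8, 0.8),
                               noiseSd = 1, seed = 1L, randomSign = TRUE) {
  if (M < 2L) stop("M must be >= 2")
  if (!.isAcyclic(truth)) stop("truth graph must be acyclic")
  if (length(coefRange) == 1L) coefRange <- rep(coefRange, 2L)
  nds <- truth@nodes
  A <- .adjMatrix(truth)
  ord <- .topoOrder(A)
  ord <- c(ord, setdiff(nds, ord))
  e <- truth@edges
  .withSeed(seed, {
    mag <- runif(nrow(e), coefRange[1L], coefRange[2L])
    sgn <- if (randomSign) sample(c(-1, 1), nrow(e), replace = TRUE)
    else rep(1, nrow(e))
    coef <- mag * sgn
    V <- matrix(0, length(nds), M,
                dimnames = list(nds, paste0("cond", seq_len(M))))
    for (v in ord) {
      pa <- which(e$to == v)
      mu <- rep(0, M)
      for (i in pa) mu <- mu + coef[i] * V[e$from[i], ]
      V[v, ] <- mu + rnorm(M, 0, noiseSd)
    }
    out <- ExpressionData(V)
    S4Vectors::metadata(out)$coefficients <-
      data.frame(from = e$from, to = e$to, coef = coef,
                 stringsAsFactors = FALSE)
    out
  })
}

#' Corrupt a ground-truth edge set into a noisy knowledgebase whitelist
#'
#' Models an imperfect relation knowledgebase: a random
#' \code{round(dropFraction * |E|)} of the true edges are removed and
#' \code{round(decoyFraction * |E|)} decoy edges (random ordered non-true,
#' non-self pairs) are added.
#'
#' @param truth a [PathwayGraph-class].
#' @param decoyFraction,dropFraction fractions in \[0, 1\] relative to the
#'   number of true edges.
#' @param seed integer RNG seed.
#' @return data.frame(from, to) of allowed edges
#' @export
corruptKnowledgebase <- function(truth, decoyFraction = 0.5,
                                 dropFraction = 0, seed = 1L) {
  stopifnot(decoyFraction >= 0, decoyFraction <= 1,
            dropFraction >= 0, dropFraction <= 1)
  e <- truth@edges[, c("from", "to"), drop = FALSE]
  n_e <- nrow(e)
  n_drop <- .roundHalfUp(dropFraction * n_e)
  n_decoy <- .roundHalfUp(decoyFraction * n_e)
  nds <- truth@nodes
  grid <- expand.grid(from = nds, to = nds, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  true_keys <- .edgeKey(e$from, e$to)
  non_true <- grid[!(.edgeKey(grid$from, grid$to) %in% true_keys), ,
                   drop = FALSE]
  if (n_decoy > nrow(non_true))
    stop("requested ", n_decoy, " decoys but only ", nrow(non_true),
         " non-true ordered pairs exist")
  .withSeed(seed, {
    keep <- if (n_drop > 0L) e[-sample.int(n_e, n_drop), , drop = FALSE]
    else e
    decoys <- if (n_decoy > 0L)
      non_true[sample.int(nrow(non_true), n_decoy), , drop = FALSE]
    else .emptyEdges()
    out <- rbind(keep, decoys)
    rownames(out) <- NULL
    out
  })
}

#' Emit a KGML fixture for a ground-truth network
#'
#' Writes the network as a well-formed KGML document: one ortholog entry
#' per distinct KO set among the truth's nodes, one ECrel relation per
#' truth edge (at entry level), and optional compound entries referenced by
#' relation subtypes. [parseKGML()] of the output, expanded back to gene
#' level through the same KO map, reproduces the edge set exactly.
#'
#' @param truth a [PathwayGraph-class].
#' @param komap a [GeneKOMap-class] covering every truth node.
#' @param mapId pathway map identifier.
#' @param edgeCompounds optional named character vector mapping
#'   \code{"from|to"} gene-edge labels to compound ids to attach.
#' @return single string of KGML text
#' @export
emitKGMLFixture <- function(truth, komap, mapId = "map99999",
                            edgeCompounds = NULL) {
  miss <- setdiff(truth@nodes, names(komap@map))
  if (length(miss))
    stop("truth node(s) missing from the KO map: ",
         paste(miss, collapse = ", "))
  ko_sets <- vapply(truth@nodes,
                    function(g) paste(sort(komap@map[[g]]), collapse = " "),
                    "")
  groups <- unique(ko_sets)
  entry_of_gene <- match(ko_sets, groups)
  xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(sprintf('<?xml version="1.0"?>'),
             sprintf('<pathway name="path:%s" org="map" number="%s" title="synthetic fixture">',
                     xml_escape(mapId), xml_escape(mapId)))
  for (i in seq_along(groups)) {
    kos <- strsplit(groups[i], " ", fixed = TRUE)[[1L]]
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="%s" type="ortholog"/>',
      i, paste0("ko:", kos, collapse = " ")))
  }
  cpd_entries <- character(0)
  cpd_ids <- unique(unname(edgeCompounds))
  cpd_entry_id <- setNames(length(groups) + seq_along(cpd_ids), cpd_ids)
  for (cpd in cpd_ids)
    cpd_entries <- c(cpd_entries, sprintf(
      '  <entry id="%d" name="cpd:%s" type="compound"/>',
      cpd_entry_id[[cpd]], xml_escape(cpd)))
  lines <- c(lines, cpd_entries)
  e <- truth@edges
  rel_seen <- character(0)
  for (i in seq_len(nrow(e))) {
    e1 <- entry_of_gene[match(e$from[i], truth@nodes)]
    e2 <- entry_of_gene[match(e$to[i], truth@nodes)]
    rel_key <- paste(e1, e2)
    if (rel_key %in% rel_seen) next
    rel_seen <- c(rel_seen, rel_key)
    cpd <- if (!is.null(edgeCompounds))
      edgeCompounds[[paste(e$from[i], e$to[i], sep = "|")]] else NULL
    if (!is.null(cpd)) {
      lines <- c(lines, sprintf(
        '  <relation entry1="%d" entry2="%d" type="ECrel">', e1, e2),
        sprintf('    <subtype name="compound" value="%d"/>',
                cpd_entry_id[[cpd]]),
        '  </relation>')
    } else {
      lines <- c(lines, sprintf(
        '  <relation entry1="%d" entry2="%d" type="ECrel"/>', e1, e2))
    }
  }
  lines <- c(lines, "</pathway>")
  paste(lines, collapse = "\n")
}

#' Generate a one-KO-per-gene (or multi-KO) gene-to-KO map
#'
#' @param genes character vector of gene ids.
#' @param kosPerGene KO identifiers per gene (default 1; 2 exercises the
#'   multi-KO cartesian expansion paths).
#' @return a [GeneKOMap-class]
#' @export
makeSyntheticKOMap <- function(genes, kosPerGene = 1L) {
  n <- length(genes)
  m <- lapply(seq_len(n), function(i) {
    sprintf("K%05d", (i - 1L) * kosPerGene + seq_len(kosPerGene))
  })
  names(m) <- genes
  GeneKOMap(m)
}

#' Generate a complete synthetic benchmark bundle
#'
#' Produces, from one seed, everything a full pipeline run needs: a
#' ground-truth DAG, expression data sampled from its linear-Gaussian
#' model, a gene-to-KO map, a reference KGML map holding a subset of the
#' truth (the seed pathway for initial mapping), a knowledgebase KGML map
#' holding the corrupted whitelist (truth minus dropped edges plus
#' decoys), and the target edge list.
#'
#' @param nNodes,edgeDensity,M,coefRange,noiseSd see
#'   [generateTruthDag()] and [simulateExpression()].
#' @param decoyFraction,dropFraction knowledgebase corruption, see
#'   [corruptKnowledgebase()].
#' @param referenceFraction fraction of true edges exposed in the
#'   reference (seed) map.
#' @param kosPerGene KO identifiers per gene.
#' @param seed integer RNG seed; the bundle is bit-reproducible given it.
#' @return list with elements \code{truth} ([PathwayGraph-class]),
#'   \code{data} ([ExpressionData-class]), \code{komap}
#'   ([GeneKOMap-class]), \code{komapTable} (two-column text),
#'   \code{kgmlDocs} (list of KGML strings: \code{reference},
#'   \code{knowledge}), \code{allowed} (corrupted whitelist, data.frame),
#'   \code{kbNoise}, and \code{seed}.
#' @export
generateBenchmarkBundle <- function(nNodes = 10L, edgeDensity = 0.3,
                                    M = 800L, coefRange = c(0.8, 0.8),
                                    noiseSd = 1, decoyFraction = 0.5,
                                    dropFraction = 0,
                                    referenceFraction = 0.5,
                                    kosPerGene = 1L, seed = 1L) {
  truth <- generateTruthDag(nNodes, edgeDensity, seed = .childSeed(seed, 1))
  # guarantee at least one edge so downstream stages are exercised
  if (nrow(truth@edges) == 0L) {
    nds <- truth@nodes
    truth <- PathwayGraph(nds, data.frame(from = nds[1L], to = nds[2L],
                                          stringsAsFactors = FALSE))
  }
  data <- simulateExpression(truth, M, coefRange, noiseSd,
                             seed = .childSeed(seed, 2))
  komap <- makeSyntheticKOMap(truth@nodes, kosPerGene)
  allowed <- corruptKnowledgebase(truth, decoyFraction, dropFraction,
                                  seed = .childSeed(seed, 3))
  n_ref <- max(1L, .roundHalfUp(referenceFraction * nrow(truth@edges)))
  ref_idx <- .withSeed(.childSeed(seed, 4),
                       sort(sample.int(nrow(truth@edges), n_ref)))
  ref_edges <- truth@edges[ref_idx, , drop = FALSE]
  ref_nodes <- unique(c(ref_edges$from, ref_edges$to))
  ref_graph <- PathwayGraph(ref_nodes, ref_edges)
  kgml_ref <- emitKGMLFixture(ref_graph, komap, mapId = "map90001")
  kb_graph <- PathwayGraph(truth@nodes, allowed)
  kgml_kb <- emitKGMLFixture(kb_graph, komap, mapId = "map90002")
  komap_table <- paste(vapply(names(komap@map), function(g)
    paste(paste(g, komap@map[[g]], sep = "\t"), collapse = "\n"), ""),
    collapse = "\n")
  list(truth = truth, data = data, komap = komap,
       komapTable = komap_table,
       kgmlDocs = list(reference = kgml_ref, knowledge = kgml_kb),
       allowed = allowed,
       kbNoise = c(decoy_edge_fraction = decoyFraction,
                   dropped_edge_fraction = dropFraction),
       seed = as.integer(seed))
}

#' Write a benchmark bundle to a directory
#'
#' Emits \code{truth.tsv}, \code{expr.tsv}, \code{map.kgml} (reference),
#' \code{knowledge.kgml}, \code{gene2ko.tsv} and \code{bundle.json}
#' (parameters and seed).
#'
#' @param bundle result of [generateBenchmarkBundle()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeEdgeList(bundle$truth, file.path(dir, "truth.tsv"))
  V <- exprsValues(bundle$data)
  write.table(data.frame(gene_id = rownames(V), V, check.names = FALSE),
              file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(bundle$kgmlDocs$reference, file.path(dir, "map.kgml"))
  writeLines(bundle$kgmlDocs$knowledge, file.path(dir, "knowledge.kgml"))
  writeLines(bundle$komapTable, file.path(dir, "gene2ko.tsv"))
  jsonlite::write_json(
    list(seed = bundle$seed, kb_noise = as.list(bundle$kbNoise),
         n_nodes = length(bundle$truth@nodes),
         n_true_edges = nrow(bundle$truth@edges),
         M = ncol(bundle$data)),
    file.path(dir, "bundle.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
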
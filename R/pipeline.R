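# Staged pipeline driver: build-kb -> cluster -> map -> sample -> learn ->
# attach -> evaluate. Each stage writes its interface files plus a cached
# state snapshot; a checksum over its inputs makes re-running a completed
# stage with unchanged inputs a no-op.

.PIPELINE_STAGES <- c("build_kb", "cluster", "map", "sample", "learn",
                      "attach", "evaluate")

.configDefaults <- list(
  missingThreshold = 0.2, imputeMethod = "row_mean", imputeK = 10L,
  clusterK = NULL, kMin = 1L, kMax = 10L, cvFolds = 10L,
  nSample = NULL, maxIters = 500L, directionMode = "directed",
  excludeMaps = character(0), seed = 1L)

#' Validate and normalise a pipeline configuration
#'
#' A configuration is a named list (or path to a JSON file holding one)
#' with input paths \code{expression}, \code{gene2ko}, \code{kgml} (one or
#' more KGML files), optional \code{reference} (defaults to the first KGML
#' file) and \code{target} (edge-list TSV enabling the evaluation stage),
#' the output directory \code{outDir}, and tuning fields with defaults:
#' \code{missingThreshold} (0.2), \code{imputeMethod} ("row_mean"),
#' \code{imputeK} (10), \code{clusterK} (fixed component count; otherwise
#' \code{kMin}/\code{kMax}/\code{cvFolds} drive cross-validated selection),
#' \code{nSample} (defaults to the mean reference pathway size),
#' \code{maxIters} (500), \code{directionMode} ("directed"),
#' \code{excludeMaps}, and \code{seed}.
#'
#' @param config named list or JSON file path.
#' @return the normalised configuration list
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  for (nm in names(.configDefaults))
    if (is.null(config[[nm]])) config[[nm]] <- .configDefaults[[nm]]
  for (nm in c("expression", "gene2ko", "kgml", "outDir"))
    if (is.null(config[[nm]])) stop("config field missing: ", nm)
  if (is.null(config$reference)) config$reference <- config$kgml[[1L]]
  for (nm in c("expression", "gene2ko", "reference", "target")) {
    p <- config[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("config input path does not exist: ", nm, " = ", p)
  }
  missing_kgml <- config$kgml[!file.exists(unlist(config$kgml))]
  if (length(missing_kgml))
    stop("KGML file(s) not found: ", paste(missing_kgml, collapse = ", "))
  config$seed <- as.integer(config$seed)
  config
}

.stageChecksum <- function(config, stage, input_files) {
  params <- config[setdiff(names(config), "outDir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(params[order(names(params))], tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  sums <- c(unname(tools::md5sum(c(tmp, input_files))), stage)
  paste(sums, collapse = "|")
}

.stageDone <- function(outDir, stage) {
  file.path(outDir, sprintf(".stage_%s.json", stage))
}

.stageState <- function(outDir, stage) {
  file.path(outDir, sprintf(".state_%s.rds", stage))
}

.stageUpToDate <- function(outDir, stage, checksum) {
  f <- .stageDone(outDir, stage)
  if (!file.exists(f) || !file.exists(.stageState(outDir, stage)))
    return(FALSE)
  rec <- jsonlite::read_json(f)
  identical(rec$checksum, checksum)
}

.markStage <- function(outDir, stage, checksum, state) {
  saveRDS(state, .stageState(outDir, stage))
  jsonlite::write_json(list(stage = stage, checksum = checksum,
                            finished = format(Sys.time())),
                       .stageDone(outDir, stage), auto_unbox = TRUE)
}

#' Run the pathway-reconstruction pipeline
#'
#' Executes the staged workflow: parse the KGML maps into a relation
#' knowledgebase; preprocess and cluster the expression data; project
#' genes onto the reference map into a seed pathway; sample additional
#' candidate genes guided by the pivotal cluster; learn the constrained
#' network by greedy search; attach compounds; and, when a target edge
#' list is configured, evaluate the prediction. Each stage writes its
#' interface files under \code{outDir}; \code{manifest.json} records
#' per-stage status, wall time, parameters and the seed.
#'
#' @param config configuration list or JSON path, see [validateConfig()].
#' @param stages subset of stages to run (in pipeline order); earlier
#'   stages a requested stage depends on are loaded from their cached
#'   state or recomputed.
#' @param resume when \code{TRUE} (default), a stage whose inputs are
#'   unchanged since its last completed run is skipped.
#' @return invisibly, a list with the final state (knowledgebase, cluster
#'   model, graphs, score, evaluation) and the manifest
#' @export
runPipeline <- function(config, stages = .PIPELINE_STAGES, resume = TRUE) {
  config <- validateConfig(config)
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  manifest <- list()

  run_stage <- function(stage, inputs, fun) {
    t0 <- Sys.time()
    checksum <- .stageChecksum(config, stage, inputs)
    if (resume && .stageUpToDate(outDir, stage, checksum)) {
      st <- readRDS(.stageState(outDir, stage))
      manifest[[stage]] <<- list(status = "skipped (up to date)",
                                 seconds = 0)
      return(st)
    }
    st <- tryCatch(fun(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    .markStage(outDir, stage, checksum, st)
    manifest[[stage]] <<- list(
      status = "completed",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    st
  }

  need <- function(stage) {
    # a later requested stage pulls its prerequisites from cached state
    st_file <- .stageState(outDir, stage)
    if (!is.null(state[[stage]])) return(state[[stage]])
    if (file.exists(st_file)) return(readRDS(st_file))
    stop("stage '", stage, "' has not been run yet")
  }

  if ("build_kb" %in% stages) {
    state$build_kb <- run_stage("build_kb", unlist(config$kgml), function() {
      maps <- lapply(unlist(config$kgml), parseKGML)
      kb <- buildKnowledgebase(maps, excludeMaps = config$excludeMaps)
      writeKnowledgebase(kb, file.path(outDir, "knowledgebase.tsv"))
      writePairIndex(kb, file.path(outDir, "ko_pairs.tsv"))
      list(kb = kb, maps = maps)
    })
  }

  if ("cluster" %in% stages) {
    state$cluster <- run_stage("cluster", config$expression, function() {
      x <- readExpressionMatrix(config$expression)
      x <- filterMissing(x, config$missingThreshold)
      x <- imputeExpression(x, config$imputeMethod, config$imputeK)
      k <- if (!is.null(config$clusterK)) as.integer(config$clusterK)
      else selectNumClusters(x, config$kMin, config$kMax, config$cvFolds,
                             seed = .childSeed(config$seed, 11))
      model <- emFit(x, k, seed = .childSeed(config$seed, 12))
      writeClusterAssignments(model, file.path(outDir, "clusters.tsv"))
      jsonlite::write_json(
        list(k = model@k, mixing_weights = model@weights,
             mean_norms = sqrt(rowSums(model@means^2)),
             imputation = config$imputeMethod,
             seed = config$seed),
        file.path(outDir, "cluster_model.json"), auto_unbox = TRUE,
        digits = NA)
      list(data = x, model = model)
    })
  }

  if ("map" %in% stages) {
    state$map <- run_stage("map", c(config$reference, config$gene2ko,
                                    config$expression), function() {
      komap <- readGeneKOMap(config$gene2ko)
      ref <- parseKGML(config$reference)
      seed_graph <- initialMap(ref, komap)
      expr_genes <- rownames(need("cluster")$data)
      dropped <- setdiff(seed_graph@nodes, expr_genes)
      if (length(dropped)) {
        message("dropping ", length(dropped),
                " mapped gene(s) without expression data: ",
                paste(dropped, collapse = ", "))
        keep_nodes <- intersect(seed_graph@nodes, expr_genes)
        e <- seed_graph@edges
        e <- e[e$from %in% keep_nodes & e$to %in% keep_nodes, ,
               drop = FALSE]
        seed_graph <- PathwayGraph(keep_nodes, e)
      }
      writeEdgeList(seed_graph, file.path(outDir, "initial.tsv"))
      list(komap = komap, reference = ref, seed_graph = seed_graph)
    })
  }

  if ("sample" %in% stages) {
    state$sample <- run_stage("sample", c(.stageState(outDir, "cluster"),
                                          .stageState(outDir, "map")),
                              function() {
      model <- need("cluster")$model
      mp <- need("map")
      seed_genes <- intersect(mp$seed_graph@nodes,
                              names(model@assignments))
      if (length(seed_genes)) {
        pivot <- pivotalCluster(model, seed_genes)
        w <- clusterWeights(model, pivot)
      } else {
        pivot <- 1L
        w <- rep(1 / model@k, model@k)
      }
      n <- if (!is.null(config$nSample)) as.integer(config$nSample)
      else targetSampleSize(need("build_kb")$maps)
      n <- min(n, length(setdiff(names(model@assignments),
                                 mp$seed_graph@nodes)))
      plan <- SamplingPlan(pivot, w, max(1L, n),
                           seed = .childSeed(config$seed, 13))
      sampled <- sampleGenes(model, plan,
                             exclude = mp$seed_graph@nodes)
      writeLines(sampled, file.path(outDir, "sampled_genes.txt"))
      jsonlite::write_json(
        list(pivot = plan@pivot, weights = plan@weights,
             n_to_sample = plan@nToSample, seed = plan@seed,
             weight_form = "1/(1+d)"),
        file.path(outDir, "sampled_genes.json"), auto_unbox = TRUE,
        digits = NA)
      list(plan = plan, sampled = sampled)
    })
  }

  if ("learn" %in% stages) {
    learn_deps <- .stageState(outDir, c("build_kb", "cluster", "map",
                                        "sample"))
    state$learn <- run_stage("learn", learn_deps, function() {
      kb <- need("build_kb")$kb
      cl <- need("cluster")
      mp <- need("map")
      sm <- need("sample")
      candidates <- union(mp$seed_graph@nodes, sm$sampled)
      candidates <- intersect(candidates, names(mp$komap@map))
      candidates <- intersect(candidates, rownames(cl$data))
      seed_graph <- mp$seed_graph
      init <- PathwayGraph(candidates, seed_graph@edges)
      constraints <- buildConstraints(init, kb, mp$komap, candidates)
      fit <- greedySearch(init, cl$data, constraints,
                          maxIters = config$maxIters)
      writeEdgeList(fit$graph, file.path(outDir, "learned.tsv"))
      writeScoreReport(fit$score, file.path(outDir, "score.json"))
      write.table(fit$trace, file.path(outDir, "trace.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(graph = fit$graph, score = fit$score, trace = fit$trace,
           constraints = constraints)
    })
  }

  if ("attach" %in% stages) {
    state$attach <- run_stage("attach",
                              .stageState(outDir, c("learn", "build_kb",
                                                    "map")), function() {
      net <- attachCompounds(need("learn")$graph, need("build_kb")$kb,
                             need("map")$komap)
      writeMetabolicNetwork(net, file.path(outDir, "network.tsv"))
      list(network = net)
    })
  }

  if ("evaluate" %in% stages && !is.null(config$target)) {
    state$evaluate <- run_stage("evaluate",
                                c(config$target,
                                  .stageState(outDir, "learn")),
                                function() {
      target <- readEdgeList(config$target)
      learned <- need("learn")$graph
      res <- evaluateEdges(learned, target,
                           directionMode = config$directionMode,
                           requiredEdges = requiredEdges(learned))
      jsonlite::write_json(res, file.path(outDir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
      list(result = res)
    })
  }

  manifest_out <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config), "outDir")],
    stages = manifest)
  jsonlite::write_json(manifest_out, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(state, list(manifest = manifest_out)))
}
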
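# end-to-end pipeline: build interolog network -> cluster -> back-project ->
# evaluate; plus the two comparison arms (direct clustering of each PPI
# network, and clustering of the conserved subnetworks)

#' Predict conserved complexes from an interolog network (full pipeline)
#'
#' Chains the stages: (optionally) re-weight edges with [adjustCDWeights()],
#' build the interolog network, cluster it, back-project every cluster to
#' its two per-species protein sets, and evaluate the projected pairs
#' against the curated catalogs and the gold conserved benchmark in
#' `"paired"` mode.
#'
#' @param ppiA,ppiB [PPINetwork-class] objects.
#' @param map an [OrthologMap-class] spanning the two species.
#' @param catalogA,catalogB curated [ComplexCatalog-class] objects.
#' @param gold a [ConservedBenchmark-class].
#' @param engine clustering engine, `"cmc"` (default) or `"mcl"`.
#' @param minSize minimum cluster size (default 4).
#' @param t match threshold (default 0.5).
#' @param weightIterations rounds of [adjustCDWeights()] applied to both
#'   input networks before construction (0 = off, the default).
#' @param includeSharedProteinEdges,dropSharedProteinEdges control
#'   shared-protein edges at construction and at clustering time.
#' @param checkSpecies passed to [buildInterologNetwork()].
#' @param ... further engine parameters for [clusterGraph()].
#' @return list with elements `interolog` ([InterologNetwork-class]),
#'   `clusters` ([ClusterSet-class]), `predictions` (list of projected
#'   pairs) and `report` ([EvaluationReport-class]).
#' @export
cocinPipeline <- function(ppiA, ppiB, map, catalogA, catalogB, gold,
                          engine = "cmc", minSize = 4L, t = 0.5,
                          weightIterations = 0L,
                          includeSharedProteinEdges = TRUE,
                          dropSharedProteinEdges = FALSE,
                          checkSpecies = TRUE, ...) {
  if (weightIterations > 0L) {
    ppiA <- adjustCDWeights(ppiA, weightIterations)
    ppiB <- adjustCDWeights(ppiB, weightIterations)
  }
  inet <- buildInterologNetwork(ppiA, ppiB, map,
                                includeSharedProteinEdges = includeSharedProteinEdges,
                                checkSpecies = checkSpecies)
  g <- interologGraph(inet, dropSharedProteinEdges = dropSharedProteinEdges)
  cs <- clusterGraph(g, engine = engine, minSize = minSize, ...)
  predictions <- lapply(clusters(cs), function(cl)
    list(a = projectCluster(cl, "a"), b = projectCluster(cl, "b")))
  predictions <- predictions[!duplicated(vapply(predictions, function(p)
    paste(paste(p$a, collapse = " "), paste(p$b, collapse = " "), sep = "\t"),
    character(1)))]
  report <- evaluateComplexes(predictions, catalogA, catalogB, gold,
                              t = t, mode = "paired")
  list(interolog = inet, clusters = cs, predictions = predictions,
       report = report)
}

#' Direct-clustering baseline
#'
#' Clusters each species' PPI network separately with the same engine and
#' parameters, treats every cluster as a single-species prediction, and
#' evaluates in `"per_side"` mode: a gold conserved pair is detected when
#' its species-A complex is matched by some species-A cluster and its
#' species-B complex by some species-B cluster.
#'
#' @inheritParams cocinPipeline
#' @param ... engine parameters for [clusterGraph()].
#' @return list with `clustersA`, `clustersB`, `predictions`, `report`.
#' @export
directClusteringBaseline <- function(ppiA, ppiB, catalogA, catalogB, gold,
                                     engine = "cmc", minSize = 4L, t = 0.5,
                                     weightIterations = 0L, ...) {
  if (weightIterations > 0L) {
    ppiA <- adjustCDWeights(ppiA, weightIterations)
    ppiB <- adjustCDWeights(ppiB, weightIterations)
  }
  csA <- clusterGraph(ppiA, engine = engine, minSize = minSize, ...)
  csB <- clusterGraph(ppiB, engine = engine, minSize = minSize, ...)
  predictions <- c(
    lapply(clusters(csA), function(cl) list(a = cl, b = character(0))),
    lapply(clusters(csB), function(cl) list(a = character(0), b = cl)))
  report <- evaluateComplexes(predictions, catalogA, catalogB, gold,
                              t = t, mode = "per_side")
  list(clustersA = csA, clustersB = csB, predictions = predictions,
       report = report)
}

#' Conserved-subnetwork baseline
#'
#' Restricts each species' network to its conserved subnetwork (the
#' interactions whose orthologous counterparts exist in the other species),
#' clusters each conserved subnetwork with the same engine and parameters,
#' and evaluates in `"per_side"` mode as in
#' [directClusteringBaseline()].
#'
#' @inheritParams cocinPipeline
#' @param ... engine parameters for [clusterGraph()].
#' @return list with `clustersA`, `clustersB`, `predictions`, `report`.
#' @export
conservedSubnetworkBaseline <- function(ppiA, ppiB, map, catalogA, catalogB,
                                        gold, engine = "cmc", minSize = 4L,
                                        t = 0.5, weightIterations = 0L, ...) {
  if (weightIterations > 0L) {
    ppiA <- adjustCDWeights(ppiA, weightIterations)
    ppiB <- adjustCDWeights(ppiB, weightIterations)
  }
  csubA <- conservedSubnetwork(ppiA, ppiB, map, side = "a")
  csubB <- conservedSubnetwork(ppiB, ppiA, map, side = "b")
  csA <- clusterGraph(csubA, engine = engine, minSize = minSize, ...)
  csB <- clusterGraph(csubB, engine = engine, minSize = minSize, ...)
  predictions <- c(
    lapply(clusters(csA), function(cl) list(a = cl, b = character(0))),
    lapply(clusters(csB), function(cl) list(a = character(0), b = cl)))
  report <- evaluateComplexes(predictions, catalogA, catalogB, gold,
                              t = t, mode = "per_side")
  list(clustersA = csA, clustersB = csB, predictions = predictions,
       report = report)
}

#' Run the full pipeline and both baselines on one dataset
#'
#' Runs the interolog-network pipeline, the direct-clustering baseline and
#' the conserved-subnetwork baseline with the same engine and parameters,
#' and returns a comparison table with one row per arm (columns: number of
#' predicted complexes, matched predictions, precision, gold conserved
#' pairs, detected conserved pairs, conserved-complex recall).
#'
#' @inheritParams cocinPipeline
#' @param arms subset of `c("cocin", "direct", "conserved_subnetwork")`.
#' @param ... engine parameters for [clusterGraph()].
#' @return list with `table` (data.frame) and `runs` (named list of the
#'   per-arm result lists).
#' @export
runBaselines <- function(ppiA, ppiB, map, catalogA, catalogB, gold,
                         engine = "cmc", minSize = 4L, t = 0.5,
                         weightIterations = 0L,
                         arms = c("cocin", "direct", "conserved_subnetwork"),
                         ...) {
  arms <- match.arg(arms, several.ok = TRUE)
  runs <- list()
  rows <- list()
  if ("cocin" %in% arms) {
    runs$cocin <- cocinPipeline(ppiA, ppiB, map, catalogA, catalogB, gold,
                                engine = engine, minSize = minSize, t = t,
                                weightIterations = weightIterations, ...)
    rows$cocin <- reportRow(runs$cocin$report, "cocin")
  }
  if ("direct" %in% arms) {
    runs$direct <- directClusteringBaseline(ppiA, ppiB, catalogA, catalogB,
                                            gold, engine = engine,
                                            minSize = minSize, t = t,
                                            weightIterations = weightIterations,
                                            ...)
    rows$direct <- reportRow(runs$direct$report, "direct")
  }
  if ("conserved_subnetwork" %in% arms) {
    runs$conserved_subnetwork <-
      conservedSubnetworkBaseline(ppiA, ppiB, map, catalogA, catalogB, gold,
                                  engine = engine, minSize = minSize, t = t,
                                  weightIterations = weightIterations, ...)
    rows$conserved_subnetwork <-
      reportRow(runs$conserved_subnetwork$report, "conserved_subnetwork")
  }
  tab <- do.call(rbind, unname(rows))
  rownames(tab) <- NULL
  list(table = tab, runs = runs)
}

#' Run the scenario-driven pipeline from a configuration
#'
#' Convenience wrapper for synthetic studies: generates (or accepts) a
#' scenario, runs the requested arms, and optionally writes all artifacts
#' (networks, map, catalogs, clusters, report JSON/TSV and the resolved
#' configuration) to an output directory.
#'
#' @param config named list as produced by [defaultRunConfig()] /
#'   [readRunConfig()].
#' @param scenario optional pre-built [Scenario-class]; when `NULL` one is
#'   generated from the config's scenario parameters.
#' @return list with `scenario`, `table`, `runs`.
#' @export
runPipeline <- function(config = defaultRunConfig(), scenario = NULL) {
  config <- utils::modifyList(defaultRunConfig(), config)
  if (is.null(scenario)) {
    sp <- do.call(scenarioParams, config$scenario)
    scenario <- generateScenario(sp)
  }
  res <- runBaselines(scenario@ppiA, scenario@ppiB, scenario@map,
                      scenario@catalogA, scenario@catalogB,
                      scenario@benchmark,
                      engine = config$engine, minSize = config$min_size,
                      t = config$t,
                      weightIterations = config$weight_iterations,
                      arms = config$arms)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_run_outputs(config$out_dir, scenario, res, config)
  }
  c(list(scenario = scenario), res)
}

.write_run_outputs <- function(dir, scenario, res, config) {
  writePPIEdgelist(scenario@ppiA, file.path(dir, "ppi_a.tsv"))
  writePPIEdgelist(scenario@ppiB, file.path(dir, "ppi_b.tsv"))
  writeOrthologGroups(scenario@map, file.path(dir, "orthologs.txt"))
  writeClusters(scenario@catalogA, file.path(dir, "complexes_a.tsv"))
  writeClusters(scenario@catalogB, file.path(dir, "complexes_b.tsv"))
  utils::write.table(benchmarkPairs(scenario@benchmark),
                     file.path(dir, "gold_benchmark.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$table, file.path(dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$runs$cocin))
    writeInterologNetwork(res$runs$cocin$interolog,
                          file.path(dir, "interolog_network.tsv"))
  summary <- lapply(seq_len(nrow(res$table)), function(i) as.list(res$table[i, ]))
  names(summary) <- res$table$method
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeRunConfig(config, file.path(dir, "config_resolved.yaml"))
  invisible(dir)
}

#' Default run configuration
#'
#' A named list holding every knob of [runPipeline()]: the scenario
#' parameters (see [scenarioParams()]), engine and parameters, evaluation
#' threshold, arms to run, and an optional output directory. Serializable
#' to YAML via [writeRunConfig()]/[readRunConfig()].
#'
#' @return named list.
#' @export
defaultRunConfig <- function() {
  list(scenario = list(nConserved = 20L, sizeRange = c(4L, 8L),
                       pIntra = 0.9, pConserve = 0.9, paralogRate = 0.2,
                       nBackgroundA = 100L, nBackgroundB = 100L,
                       backgroundOrthologRate = 0.3,
                       noiseMultiplier = 2, edgeLossRate = 0.1, seed = 1L),
       engine = "cmc",
       min_size = 4L,
       t = 0.5,
       weight_iterations = 0L,
       arms = c("cocin", "direct", "conserved_subnetwork"),
       out_dir = NULL)
}

#' Read / write a run configuration (YAML)
#'
#' @param path file path.
#' @return `readRunConfig()`: the config list merged over the defaults.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultRunConfig(), cfg)
  cfg$scenario <- lapply(cfg$scenario, function(x)
    if (is.numeric(x) && all(x == round(x))) as.integer(x) else x)
  cfg
}

#' @rdname readRunConfig
#' @param config named list.
#' @return `writeRunConfig()`: invisibly, `path`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
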
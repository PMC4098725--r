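# accessor generics and show methods

#' Species label(s) of an object
#' @param x a package object carrying species labels.
#' @return a character vector of one (single-species objects) or two labels.
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' Protein identifiers of a network
#' @param x a [PPINetwork-class] or [InterologNetwork-class].
#' @return character vector of node identifiers.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' Edge table of a network
#' @param x a [PPINetwork-class] or [InterologNetwork-class].
#' @return the canonical edge `data.frame`.
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' Number of nodes / edges
#' @param x a network object.
#' @return integer count.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Ortholog groups of a map
#' @param x an [OrthologMap-class].
#' @return the named list of groups (`list(a = <chr>, b = <chr>)` each).
#' @export
setGeneric("orthologGroups", function(x) standardGeneric("orthologGroups"))

#' Complex membership list of a catalog
#' @param x a [ComplexCatalog-class].
#' @return named list of member vectors.
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))

#' Clusters of a ClusterSet
#' @param x a [ClusterSet-class].
#' @return list of character node sets.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' Cluster scores (weighted densities)
#' @param x a [ClusterSet-class].
#' @return numeric vector parallel to [clusters()].
#' @export
setGeneric("clusterScores", function(x) standardGeneric("clusterScores"))

#' Benchmark pair table
#' @param x a [ConservedBenchmark-class].
#' @return data.frame with columns `complex_a`, `complex_b`, `msj`.
#' @export
setGeneric("benchmarkPairs", function(x) standardGeneric("benchmarkPairs"))

#' @describeIn speciesLabels species of a PPI network
#' @export
setMethod("speciesLabels", "PPINetwork", function(x) x@species)
#' @describeIn speciesLabels the two species of an ortholog map
#' @export
setMethod("speciesLabels", "OrthologMap", function(x) c(x@speciesA, x@speciesB))
#' @describeIn speciesLabels species of a complex catalog
#' @export
setMethod("speciesLabels", "ComplexCatalog", function(x) x@species)
#' @describeIn speciesLabels the two source species of an interolog network
#' @export
setMethod("speciesLabels", "InterologNetwork", function(x) c(x@speciesA, x@speciesB))

#' @describeIn proteins node set of a PPI network
#' @export
setMethod("proteins", "PPINetwork", function(x) x@nodes)
#' @describeIn proteins node-id set (`"p|q"`) of an interolog network
#' @export
setMethod("proteins", "InterologNetwork", function(x) x@nodes$id)

#' @describeIn interactions edge table of a PPI network
#' @export
setMethod("interactions", "PPINetwork", function(x) x@edges)
#' @describeIn interactions edge table of an interolog network
#' @export
setMethod("interactions", "InterologNetwork", function(x) x@edges)

#' @describeIn numNodes nodes in a PPI network
#' @export
setMethod("numNodes", "PPINetwork", function(x) length(x@nodes))
#' @describeIn numNodes nodes in an interolog network
#' @export
setMethod("numNodes", "InterologNetwork", function(x) nrow(x@nodes))
#' @describeIn numNodes edges in a PPI network
#' @export
setMethod("numEdges", "PPINetwork", function(x) nrow(x@edges))
#' @describeIn numNodes edges in an interolog network
#' @export
setMethod("numEdges", "InterologNetwork", function(x) nrow(x@edges))

#' @describeIn orthologGroups groups of an ortholog map
#' @export
setMethod("orthologGroups", "OrthologMap", function(x) x@groups)

#' @describeIn complexes membership list of a catalog
#' @export
setMethod("complexes", "ComplexCatalog", function(x) x@complexes)

#' @describeIn clusters clusters of a ClusterSet
#' @export
setMethod("clusters", "ClusterSet", function(x) x@clusters)
#' @describeIn clusterScores scores of a ClusterSet
#' @export
setMethod("clusterScores", "ClusterSet", function(x) x@scores)

#' @describeIn benchmarkPairs pair table of a benchmark
#' @export
setMethod("benchmarkPairs", "ConservedBenchmark", function(x) x@pairs)

setMethod("show", "PPINetwork", function(object) {
  cat(sprintf("PPINetwork of '%s': %d proteins, %d interactions\n",
              object@species, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "OrthologMap", function(object) {
  g <- object@groups
  na <- lengths(lapply(g, `[[`, "a"))
  nb <- lengths(lapply(g, `[[`, "b"))
  cross <- sum(na > 0L & nb > 0L)
  cat(sprintf("OrthologMap '%s' <-> '%s': %d groups (%d cross-species, %d paralog-only)\n",
              object@speciesA, object@speciesB, length(g), cross, length(g) - cross))
})

setMethod("show", "ComplexCatalog", function(object) {
  cat(sprintf("ComplexCatalog of '%s': %d complexes (sizes %s)\n",
              object@species, length(object@complexes),
              if (length(object@complexes))
                paste(range(lengths(object@complexes)), collapse = "-")
              else "none"))
})

setMethod("show", "InterologNetwork", function(object) {
  prov <- table(factor(object@edges$provenance,
                       levels = c("conserved_interaction", "shared_protein")))
  cat(sprintf(paste0("InterologNetwork '%s' x '%s': %d homolog-pair nodes, ",
                     "%d interolog edges, %d shared-protein edges\n"),
              object@speciesA, object@speciesB, nrow(object@nodes),
              prov[["conserved_interaction"]], prov[["shared_protein"]]))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet (%s) on '%s': %d clusters (sizes %s)\n",
              object@engine, object@graphLabel, length(object@clusters),
              if (length(object@clusters))
                paste(range(lengths(object@clusters)), collapse = "-")
              else "none"))
})

setMethod("show", "ConservedBenchmark", function(object) {
  cat(sprintf("ConservedBenchmark: %d conserved pairs (MSJ >= %.2f, size >= %d)\n",
              nrow(object@pairs), object@msjThreshold, object@minSize))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(paste0("EvaluationReport (mode=%s, t=%.2f):\n",
                     "  predictions: %d (%d matched) -> precision %.3f\n",
                     "  gold conserved pairs: %d (%d detected) -> recall %s\n"),
              object@mode, object@t, object@nPredictions, object@nMatched,
              object@precision, object@nGold, object@nDetected,
              ifelse(is.na(object@recallConserved), "NA",
                     sprintf("%.3f", object@recallConserved))))
})

setMethod("show", "GroupProfile", function(object) {
  cat(sprintf("GroupProfile of '%s': %d groups (total multiplicity %d), %d ungrouped\n",
              object@complexId, length(object@multiplicities),
              sum(object@multiplicities), length(object@ungrouped)))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario: %d planted conserved complexes, seed %d\n",
              object@params@nConserved, object@params@seed))
  show(object@ppiA); show(object@ppiB); show(object@map); show(object@benchmark)
})

setMethod("show", "ScenarioParams", function(object) {
  cat(sprintf(paste0("ScenarioParams: %d complexes (sizes %d-%d), pIntra=%.2f, ",
                     "pConserve=%.2f, paralogRate=%.2f, noise x%.1f, ",
                     "edgeLoss=%.2f, seed=%d\n"),
              object@nConserved, object@sizeMin, object@sizeMax, object@pIntra,
              object@pConserve, object@paralogRate, object@noiseMultiplier,
              object@edgeLossRate, object@seed))
})
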
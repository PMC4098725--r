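#' @import methods
#' @importFrom stats setNames
NULL

#' PPINetwork: an undirected protein-protein interaction network
#'
#' A simple undirected graph over the proteins of one species. Edges carry a
#' reliability weight in `(0, 1]` (unweighted input is given weight 1).
#' Self-loops are forbidden and `(a, b)` and `(b, a)` denote the same edge;
#' the edge table is stored in canonical form (endpoints sorted within each
#' row, rows sorted lexicographically).
#'
#' @slot species species label (single string).
#' @slot nodes character vector of protein identifiers (opaque strings,
#'   compared case-sensitively).
#' @slot edges data.frame with columns `a`, `b`, `weight`.
#'
#' @seealso [ppiNetwork()], [readPPIEdgelist()]
#' @exportClass PPINetwork
setClass("PPINetwork",
  representation(species = "character", nodes = "character",
                 edges = "data.frame"))

setValidity("PPINetwork", function(object) {
  e <- object@edges
  msg <- character(0)
  if (length(object@species) != 1L || is.na(object@species))
    msg <- c(msg, "species must be a single string")
  if (!all(c("a", "b", "weight") %in% names(e)))
    msg <- c(msg, "edges must have columns a, b, weight")
  else {
    if (any(e$a == e$b)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$a > e$b)) msg <- c(msg, "edges must be canonically ordered (a <= b)")
    if (anyDuplicated(paste(e$a, e$b, sep = "\r")))
      msg <- c(msg, "duplicate edges are not allowed")
    if (!all(e$a %in% object@nodes & e$b %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a node")
    if (any(!is.finite(e$weight)) || any(e$weight <= 0) || any(e$weight > 1))
      msg <- c(msg, "edge weights must lie in (0, 1]")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "nodes must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PPINetwork
#'
#' Builds a [PPINetwork-class] from an edge table, canonicalizing as needed:
#' self-loops are dropped, reversed duplicates collapsed (keeping the maximum
#' weight), and rows sorted deterministically.
#'
#' @param species species label.
#' @param edges data.frame with columns `a`, `b` and optionally `weight`
#'   (default 1 per edge).
#' @param nodes optional extra isolated nodes to include beyond edge
#'   endpoints.
#' @return a `PPINetwork`.
#' @examples
#' g <- ppiNetwork("yeast", data.frame(a = c("p1", "p2"), b = c("p2", "p3")))
#' numEdges(g)
#' @export
ppiNetwork <- function(species, edges = NULL, nodes = character(0)) {
  if (is.null(edges) || nrow(edges) == 0L) {
    e <- .empty_edges()
  } else {
    w <- if ("weight" %in% names(edges)) edges$weight else NULL
    e <- .canonical_edges(edges$a, edges$b, w)
  }
  nodes <- sort(unique(c(as.character(nodes), e$a, e$b)), method = "radix")
  new("PPINetwork", species = as.character(species), nodes = nodes, edges = e)
}

#' OrthologMap: ortholog groups spanning two species
#'
#' A collection of ortholog groups, each holding the member proteins of the
#' group on each of the two species' sides. Groups may be 1-to-1, 1-to-many,
#' many-to-many, or single-species (paralog groups, which contribute no
#' cross-species pairs). A protein may belong to several groups; the
#' many-to-many correspondence theta is the union over groups of the
#' cross-species member products.
#'
#' @slot speciesA,speciesB species labels for the two sides.
#' @slot groups named list; each element is `list(a = <chr>, b = <chr>)`
#'   giving the side-A and side-B members of that group.
#'
#' @seealso [orthologMap()], [thetaPairs()], [readOrthologGroups()]
#' @exportClass OrthologMap
setClass("OrthologMap",
  representation(speciesA = "character", speciesB = "character",
                 groups = "list"))

setValidity("OrthologMap", function(object) {
  msg <- character(0)
  if (length(object@speciesA) != 1L || length(object@speciesB) != 1L)
    msg <- c(msg, "species labels must be single strings")
  g <- object@groups
  if (length(g)) {
    if (is.null(names(g)) || anyDuplicated(names(g)) || any(names(g) == ""))
      msg <- c(msg, "groups must have unique non-empty names")
    ok <- vapply(g, function(x) {
      is.list(x) && all(c("a", "b") %in% names(x)) &&
        is.character(x$a) && is.character(x$b) &&
        !anyDuplicated(x$a) && !anyDuplicated(x$b)
    }, logical(1))
    if (!all(ok)) msg <- c(msg, "each group must be list(a=<chr>, b=<chr>) with unique members")
    if (any(vapply(g, function(x) length(x$a) + length(x$b), integer(1)) == 0L))
      msg <- c(msg, "groups must have at least one member")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OrthologMap
#'
#' @param speciesA,speciesB species labels.
#' @param groups named list of `list(a = <chr>, b = <chr>)` member sets.
#' @return an `OrthologMap`.
#' @examples
#' m <- orthologMap("y", "h", list(G1 = list(a = "p1", b = c("q1", "q2"))))
#' thetaPairs(m)
#' @export
orthologMap <- function(speciesA, speciesB, groups = list()) {
  groups <- lapply(groups, function(x) {
    list(a = sort(unique(as.character(x$a)), method = "radix"),
         b = sort(unique(as.character(x$b)), method = "radix"))
  })
  if (length(groups))
    groups <- groups[order(names(groups), method = "radix")]
  new("OrthologMap", speciesA = as.character(speciesA),
      speciesB = as.character(speciesB), groups = groups)
}

#' GroupProfile: ortholog-group multiplicities of one complex
#'
#' The profile of a complex against an [OrthologMap-class]: for each ortholog
#' group, the number of complex members assigned to it (its multiplicity,
#' i.e. the number of paralogs of the group present in the complex; a protein
#' belonging to k groups contributes to all k), plus the multiset of members
#' belonging to no group.
#'
#' @slot complexId identifier of the profiled complex.
#' @slot multiplicities named integer vector, group id -> multiplicity (> 0).
#' @slot ungrouped character multiset of unassigned members.
#'
#' @seealso [groupProfile()], [msj()], [groupJaccard()]
#' @exportClass GroupProfile
setClass("GroupProfile",
  representation(complexId = "character", multiplicities = "integer",
                 ungrouped = "character"))

setValidity("GroupProfile", function(object) {
  m <- object@multiplicities
  msg <- character(0)
  if (length(m) && (is.null(names(m)) || anyDuplicated(names(m))))
    msg <- c(msg, "multiplicities must be uniquely named")
  if (any(m <= 0L)) msg <- c(msg, "multiplicities must be positive")
  if (length(msg)) msg else TRUE
})

#' ComplexCatalog: named protein complexes of one species
#'
#' A catalog of protein complexes (curated benchmark complexes or predicted
#' clusters) for one species. Members are multisets: a member may appear with
#' multiplicity greater than one (paralog duplication within a complex),
#' though file readers collapse repeated rows to multiplicity 1 unless an
#' explicit count column is present.
#'
#' @slot species species label.
#' @slot complexes named list of character vectors (member multisets).
#'
#' @seealso [complexCatalog()], [readComplexCatalog()]
#' @exportClass ComplexCatalog
setClass("ComplexCatalog",
  representation(species = "character", complexes = "list"))

setValidity("ComplexCatalog", function(object) {
  msg <- character(0)
  cx <- object@complexes
  if (length(cx)) {
    if (is.null(names(cx)) || anyDuplicated(names(cx)) || any(names(cx) == ""))
      msg <- c(msg, "complex ids must be unique and non-empty")
    if (!all(vapply(cx, is.character, logical(1))))
      msg <- c(msg, "complex members must be character vectors")
    if (any(lengths(cx) == 0L))
      msg <- c(msg, "every complex must have at least one member")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ComplexCatalog
#'
#' @param species species label.
#' @param complexes named list of character member vectors (multisets).
#' @return a `ComplexCatalog`.
#' @examples
#' complexCatalog("yeast", list(c1 = c("A", "B"), c2 = "A"))
#' @export
complexCatalog <- function(species, complexes = list()) {
  complexes <- lapply(complexes, function(x) sort(as.character(x), method = "radix"))
  if (length(complexes))
    complexes <- complexes[order(names(complexes), method = "radix")]
  new("ComplexCatalog", species = as.character(species), complexes = complexes)
}

#' InterologNetwork: graph of conserved cross-species interactions
#'
#' Nodes are homologous protein pairs `(p, q)` -- `p` from species A, `q`
#' from species B, `(p, q)` related by the ortholog map. Edges tagged
#' `conserved_interaction` join node pairs whose species-A proteins interact
#' in network A and whose species-B proteins interact in network B
#' (interologs); edges tagged `shared_protein` join nodes sharing exactly
#' one coordinate (arising from many-to-many orthology). Node ids are
#' `"p|q"`, so protein identifiers must not contain `"|"`.
#'
#' @slot speciesA,speciesB source network labels.
#' @slot nodes data.frame with columns `p`, `q`, `id`.
#' @slot edges data.frame with columns `from`, `to` (node ids), `weight`,
#'   `provenance`.
#'
#' @seealso [buildInterologNetwork()], [projectCluster()]
#' @exportClass InterologNetwork
setClass("InterologNetwork",
  representation(speciesA = "character", speciesB = "character",
                 nodes = "data.frame", edges = "data.frame"))

setValidity("InterologNetwork", function(object) {
  msg <- character(0)
  n <- object@nodes; e <- object@edges
  if (!all(c("p", "q", "id") %in% names(n)))
    msg <- c(msg, "nodes must have columns p, q, id")
  else {
    if (any(grepl("|", c(n$p, n$q), fixed = TRUE)))
      msg <- c(msg, "protein identifiers must not contain '|'")
    if (anyDuplicated(n$id)) msg <- c(msg, "node ids must be unique")
  }
  if (!all(c("from", "to", "weight", "provenance") %in% names(e)))
    msg <- c(msg, "edges must have columns from, to, weight, provenance")
  else {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (!all(e$provenance %in% c("conserved_interaction", "shared_protein")))
      msg <- c(msg, "unknown edge provenance tag")
    if (!all(c(e$from, e$to) %in% n$id))
      msg <- c(msg, "every edge endpoint must be a node")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterSet: clusters detected in a graph
#'
#' The result of a clustering engine: a list of node sets with their weighted
#' interaction densities, plus the engine name and parameters used. Clusters
#' may overlap (maximal-clique merging allows protein sharing); Markov
#' clustering yields a partition.
#'
#' @slot clusters list of character vectors (sorted node sets).
#' @slot scores numeric weighted densities, parallel to `clusters`.
#' @slot engine engine name (`"cmc"` or `"mcl"`).
#' @slot graphLabel label of the clustered graph.
#' @slot params named list of engine parameters (includes `min_size`).
#'
#' @seealso [cmcCluster()], [mclCluster()], [clusterGraph()]
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(clusters = "list", scores = "numeric", engine = "character",
                 graphLabel = "character", params = "list"))

setValidity("ClusterSet", function(object) {
  msg <- character(0)
  if (length(object@clusters) != length(object@scores))
    msg <- c(msg, "clusters and scores must have equal length")
  if (any(vapply(object@scores, function(s) !is.finite(s) || s < 0, logical(1))))
    msg <- c(msg, "scores must be finite and non-negative")
  ms <- object@params$min_size
  if (!is.null(ms) && length(object@clusters) &&
      any(lengths(object@clusters) < ms))
    msg <- c(msg, "every cluster must have size >= min_size")
  if (length(msg)) msg else TRUE
})

#' ConservedBenchmark: gold-standard conserved complex pairs
#'
#' Pairs of complexes, one per species, whose Multi-set Jaccard conservation
#' score reaches the selection threshold, together with the thresholds used.
#'
#' @slot pairs data.frame with columns `complex_a`, `complex_b`, `msj`.
#' @slot msjThreshold minimum Multi-set Jaccard score for inclusion.
#' @slot minSize minimum complex size (both sides) for inclusion.
#'
#' @seealso [buildConservedBenchmark()], [evaluateComplexes()]
#' @exportClass ConservedBenchmark
setClass("ConservedBenchmark",
  representation(pairs = "data.frame", msjThreshold = "numeric",
                 minSize = "integer"))

setValidity("ConservedBenchmark", function(object) {
  msg <- character(0)
  p <- object@pairs
  if (!all(c("complex_a", "complex_b", "msj") %in% names(p)))
    msg <- c(msg, "pairs must have columns complex_a, complex_b, msj")
  else {
    if (any(p$msj < object@msjThreshold - 1e-12))
      msg <- c(msg, "every pair must score at least msjThreshold")
    if (any(p$msj < 0 | p$msj > 1)) msg <- c(msg, "msj scores must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: prediction-vs-benchmark evaluation summary
#'
#' Produced by [evaluateComplexes()]. A predicted complex pair is a *matched
#' prediction* when each of its non-empty sides has Jaccard overlap at least
#' `t` with some curated complex of its species; a gold conserved pair is
#' *detected* when its two benchmark complexes are both matched (by the same
#' prediction in `"paired"` mode, or by any predictions in `"per_side"`
#' mode). Precision is the fraction of predictions matched; recall is the
#' fraction of gold conserved pairs detected.
#'
#' @slot matched data.frame of individual matches (`prediction`, `side`,
#'   `benchmark`, `jaccard`).
#' @slot detectedPairs data.frame of detected gold pairs.
#' @slot derivedBenchmarks character vector of benchmark complexes matched by
#'   at least one prediction (species-tagged `"a:<id>"` / `"b:<id>"`).
#' @slot nPredictions,nMatched,nGold,nDetected integer counts.
#' @slot precision,recallConserved the two headline fractions (`recall` is
#'   `NA` when the gold set is empty).
#' @slot t match threshold used.
#' @slot mode `"paired"` or `"per_side"`.
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(matched = "data.frame", detectedPairs = "data.frame",
                 derivedBenchmarks = "character",
                 nPredictions = "integer", nMatched = "integer",
                 nGold = "integer", nDetected = "integer",
                 precision = "numeric", recallConserved = "numeric",
                 t = "numeric", mode = "character"))

#' ScenarioParams: parameters of a synthetic two-species scenario
#'
#' Controls the planted-conserved-complex generator. Each planted complex is
#' a set of ortholog groups realized as proteins on both sides; paralog
#' expansions create 1-to-many and many-to-many groups; within-complex edges
#' are sampled per species with cross-species co-occurrence, then degraded by
#' false negatives; species-specific noise edges model false positives.
#'
#' @slot nConserved number of planted conserved complexes.
#' @slot sizeMin,sizeMax complex size range (number of ortholog groups).
#' @slot pIntra within-complex edge probability per species.
#' @slot pConserve probability that a planted within-complex edge present in
#'   species A is also present in species B.
#' @slot paralogRate probability that a group gains an extra member on one
#'   (random) side.
#' @slot nBackgroundA,nBackgroundB species-specific background proteins.
#' @slot backgroundOrthologRate probability that a background protein pair is
#'   linked by a 1-to-1 ortholog group.
#' @slot noiseMultiplier noise (false-positive) edges per species, as a
#'   multiple of that species' planted edge count.
#' @slot edgeLossRate probability a planted edge is lost (false negatives),
#'   independently per species.
#' @slot seed integer seed making the scenario reproducible.
#'
#' @seealso [scenarioParams()], [generateScenario()]
#' @exportClass ScenarioParams
setClass("ScenarioParams",
  representation(nConserved = "integer", sizeMin = "integer", sizeMax = "integer",
                 pIntra = "numeric", pConserve = "numeric",
                 paralogRate = "numeric",
                 nBackgroundA = "integer", nBackgroundB = "integer",
                 backgroundOrthologRate = "numeric",
                 noiseMultiplier = "numeric", edgeLossRate = "numeric",
                 seed = "integer"))

setValidity("ScenarioParams", function(object) {
  msg <- character(0)
  probs <- c(object@pIntra, object@pConserve, object@paralogRate,
             object@backgroundOrthologRate, object@edgeLossRate)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@nConserved < 1L) msg <- c(msg, "nConserved must be positive")
  if (object@sizeMin < 2L || object@sizeMax < object@sizeMin)
    msg <- c(msg, "size range must satisfy 2 <= sizeMin <= sizeMax")
  if (object@noiseMultiplier < 0) msg <- c(msg, "noiseMultiplier must be >= 0")
  if (object@nBackgroundA < 0L || object@nBackgroundB < 0L)
    msg <- c(msg, "background counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Scenario: a generated synthetic two-species dataset
#'
#' The six artifacts produced by [generateScenario()]: the two PPI networks,
#' the ortholog map, the two complex catalogs, and the benchmark of planted
#' conserved pairs (with their true Multi-set Jaccard scores), plus the
#' parameters used.
#'
#' @slot ppiA,ppiB [PPINetwork-class] objects.
#' @slot map an [OrthologMap-class].
#' @slot catalogA,catalogB [ComplexCatalog-class] objects of the planted
#'   complexes.
#' @slot benchmark a [ConservedBenchmark-class] listing the planted pairs.
#' @slot params the [ScenarioParams-class] used.
#'
#' @exportClass Scenario
setClass("Scenario",
  representation(ppiA = "PPINetwork", ppiB = "PPINetwork",
                 map = "OrthologMap",
                 catalogA = "ComplexCatalog", catalogB = "ComplexCatalog",
                 benchmark = "ConservedBenchmark", params = "ScenarioParams"))
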
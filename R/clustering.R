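# cluster detection engines: CMC-style maximal-clique merging and Markov
# clustering, plus the iterative Czekanowski-Dice edge-reliability weighting
# used as optional preprocessing

#' @importFrom igraph graph_from_data_frame max_cliques components V
NULL

.as_igraph <- function(g) {
  stopifnot(is(g, "PPINetwork"))
  igraph::graph_from_data_frame(
    g@edges[, c("a", "b", "weight")], directed = FALSE,
    vertices = data.frame(name = g@nodes, stringsAsFactors = FALSE))
}

# weight lookup environment keyed by canonical edge key
.weight_env <- function(g) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  e <- g@edges
  for (i in seq_len(nrow(e)))
    env[[paste(e$a[i], e$b[i], sep = "\r")]] <- e$weight[i]
  env
}

.pair_weight <- function(env, u, v) {
  key <- if (u < v) paste(u, v, sep = "\r") else paste(v, u, sep = "\r")
  w <- env[[key]]
  if (is.null(w)) 0 else w
}

# sum of pairwise weights inside a node set
.internal_weight <- function(env, members) {
  n <- length(members)
  if (n < 2L) return(0)
  tot <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + .pair_weight(env, members[i], members[j])
  tot
}

#' Iterative Czekanowski-Dice edge-reliability weights (AdjustCD)
#'
#' Re-weights each interaction by the similarity of its endpoints' closed
#' neighbourhoods, iterated so that the k-th round uses the (k-1)-th weights.
#' With closed neighbourhoods `N(u)` (including `u` itself, with
#' `w(u, u) = 1`) and weighted degrees `d(u) = sum_{x in N(u)} w(u, x)`,
#' round k assigns
#' \deqn{w_k(u,v) = \frac{\sum_{x \in N(u) \cap N(v)} (w_{k-1}(u,x) + w_{k-1}(x,v))}
#'   {\max(d(u), \bar d) + \max(d(v), \bar d)}}
#' where `\bar d` is the average weighted degree over all nodes -- a penalty
#' floor that damps weights between sparsely connected proteins. Round 1
#' reduces to the plain Czekanowski-Dice neighbourhood overlap
#' `2 |N(u) \cap N(v)| / (max(|N(u)|, \bar d) + max(|N(v)|, \bar d))`.
#' Weights stay in `[0, 1]` and are strictly positive on existing edges.
#'
#' @param g a [PPINetwork-class] (existing weights are ignored; the graph
#'   structure drives the computation).
#' @param iterations number of rounds (>= 1, default 2).
#' @return a [PPINetwork-class] with the same edges, re-weighted.
#' @export
adjustCDWeights <- function(g, iterations = 2L) {
  stopifnot(is(g, "PPINetwork"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    .stopf("iterations must be a positive integer")
  nodes <- g@nodes
  n <- length(nodes)
  if (n == 0L || numEdges(g) == 0L) return(g)
  id <- setNames(seq_len(n), nodes)
  e <- g@edges
  ia <- id[e$a]; ib <- id[e$b]
  # closed-neighbourhood adjacency with unit self weights
  A <- Matrix::sparseMatrix(i = c(ia, ib, seq_len(n)),
                            j = c(ib, ia, seq_len(n)),
                            x = 1, dims = c(n, n))
  nbr <- A != 0                                 # fixed structure, all rounds
  for (k in seq_len(iterations)) {
    deg <- Matrix::colSums(A)
    davg <- mean(deg)
    # common[u,v] = sum over shared closed neighbours x of (w(u,x) + w(x,v))
    common <- A %*% nbr * 1 + nbr %*% A * 1
    denom_u <- pmax(deg[ia], davg) + pmax(deg[ib], davg)
    wnew <- as.numeric(common[cbind(ia, ib)]) / denom_u
    A <- Matrix::sparseMatrix(i = c(ia, ib, seq_len(n)),
                              j = c(ib, ia, seq_len(n)),
                              x = c(wnew, wnew, rep(1, n)), dims = c(n, n))
  }
  wnew <- pmin(pmax(wnew, .Machine$double.eps), 1)
  ppiNetwork(g@species, data.frame(a = e$a, b = e$b, weight = wnew,
                                   stringsAsFactors = FALSE),
             nodes = nodes)
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of the graph with at least `minSize` nodes, each
#' returned as a sorted character vector, with the list itself sorted
#' lexicographically for deterministic output.
#'
#' @param g a [PPINetwork-class].
#' @param minSize minimum clique size (default 1).
#' @return list of character vectors.
#' @export
maximalCliques <- function(g, minSize = 1L) {
  stopifnot(is(g, "PPINetwork"))
  if (numNodes(g) == 0L) return(list())
  ig <- .as_igraph(g)
  cl <- igraph::max_cliques(ig, min = max(1L, as.integer(minSize)))
  cl <- lapply(cl, function(x) sort(igraph::V(ig)$name[x], method = "radix"))
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order(keys, method = "radix")]
}

#' Cluster a graph by merging overlapping maximal cliques (CMC)
#'
#' Enumerates all maximal cliques, ranks them in descending order of
#' weighted interaction density (sum of internal edge weights over the
#' number of node pairs), then walks the ranking: for each surviving clique,
#' every lower-ranked clique `B` whose overlap ratio `|A n B| / |B|` reaches
#' `overlapThreshold` is either merged into `A` -- when the inter-connectivity
#' between `B \\ A` and `A` (mean edge weight over all crossing pairs)
#' exceeds `mergeThreshold` -- or discarded. Reported clusters are the
#' survivors of size at least `minSize`, re-scored by weighted density.
#' Ties in the ranking are broken lexicographically, so the output is
#' deterministic. Clusters may overlap.
#'
#' @param g a weighted [PPINetwork-class] (weights in `(0, 1]`).
#' @param minSize minimum reported cluster size (default 4: complexes with
#'   more than 3 subunits are the usual evaluation target).
#' @param overlapThreshold minimum overlap ratio for considering a merge
#'   (default 0.5).
#' @param mergeThreshold minimum inter-connectivity for accepting a merge
#'   (default 0.25).
#' @return a [ClusterSet-class].
#' @export
cmcCluster <- function(g, minSize = 4L, overlapThreshold = 0.5,
                       mergeThreshold = 0.25) {
  stopifnot(is(g, "PPINetwork"))
  if (overlapThreshold <= 0 || overlapThreshold > 1)
    .stopf("overlapThreshold must lie in (0, 1]")
  if (mergeThreshold <= 0 || mergeThreshold > 1)
    .stopf("mergeThreshold must lie in (0, 1]")
  minSize <- as.integer(minSize)
  params <- list(min_size = minSize, overlap_threshold = overlapThreshold,
                 merge_threshold = mergeThreshold)
  cl <- maximalCliques(g, minSize = 2L)
  if (!length(cl))
    return(new("ClusterSet", clusters = list(), scores = numeric(0),
               engine = "cmc", graphLabel = g@species, params = params))
  env <- .weight_env(g)
  dens <- vapply(cl, function(m)
    .internal_weight(env, m) / choose(length(m), 2L), numeric(1))
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  ord <- order(-dens, keys, method = "radix")
  cl <- cl[ord]
  status <- rep("live", length(cl))            # live | merged | discarded
  for (i in seq_along(cl)) {
    if (status[i] != "live") next
    j <- i + 1L
    while (j <= length(cl)) {
      if (status[j] == "live") {
        B <- cl[[j]]
        ov <- length(intersect(cl[[i]], B)) / length(B)
        if (ov >= overlapThreshold) {
          extra <- setdiff(B, cl[[i]])
          if (length(extra) == 0L) {
            status[j] <- "merged"              # B already contained in A
          } else {
            cross <- 0
            for (u in extra) for (v in cl[[i]])
              cross <- cross + .pair_weight(env, u, v)
            inter <- cross / (length(extra) * length(cl[[i]]))
            if (inter > mergeThreshold) {
              cl[[i]] <- sort(c(cl[[i]], extra), method = "radix")
              status[j] <- "merged"
            } else {
              status[j] <- "discarded"
            }
          }
        }
      }
      j <- j + 1L
    }
  }
  out <- cl[status == "live"]
  out <- out[lengths(out) >= minSize]
  if (length(out)) {
    keys <- vapply(out, paste, character(1), collapse = "\r")
    out <- out[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
    out <- out[order(keys, method = "radix")]
  }
  scores <- vapply(out, function(m)
    .internal_weight(env, m) / choose(length(m), 2L), numeric(1))
  new("ClusterSet", clusters = out, scores = scores, engine = "cmc",
      graphLabel = g@species, params = params)
}

#' Markov clustering (MCL)
#'
#' Simulates flow on the graph: the column-stochastic transition matrix
#' (with self-loops) is alternately expanded (matrix power, spreading flow
#' along paths) and inflated (entrywise power followed by column
#' renormalization, sharpening strong currents), with small entries pruned,
#' until the matrix change falls below `tolerance`. Clusters are read off as
#' the connected components of the non-zero pattern of the limit matrix, so
#' every node lies in exactly one cluster; clusters smaller than `minSize`
#' are dropped from the reported set.
#'
#' @param g a weighted [PPINetwork-class].
#' @param inflation inflation exponent (> 1; default 2).
#' @param expansion expansion power (integer >= 2; default 2).
#' @param selfLoopWeight weight of the added self-loops (default 1).
#' @param pruneThreshold entries below this are zeroed each round
#'   (default 1e-5).
#' @param maxIterations iteration cap (default 200); non-convergence yields
#'   a warning and the current state is used.
#' @param tolerance convergence threshold on the max entry change
#'   (default 1e-6).
#' @param minSize minimum reported cluster size (default 4).
#' @return a [ClusterSet-class]; `params$max_colsum_dev` records the largest
#'   deviation of any column sum from 1 observed after any normalization.
#' @export
mclCluster <- function(g, inflation = 2, expansion = 2L, selfLoopWeight = 1,
                       pruneThreshold = 1e-5, maxIterations = 200L,
                       tolerance = 1e-6, minSize = 4L) {
  stopifnot(is(g, "PPINetwork"))
  if (inflation <= 1) .stopf("inflation must be > 1")
  expansion <- as.integer(expansion)
  if (expansion < 2L) .stopf("expansion must be an integer >= 2")
  nodes <- g@nodes
  n <- length(nodes)
  params <- list(min_size = as.integer(minSize), inflation = inflation,
                 expansion = expansion, self_loop_weight = selfLoopWeight,
                 prune_threshold = pruneThreshold,
                 max_iterations = as.integer(maxIterations),
                 tolerance = tolerance)
  if (n == 0L)
    return(new("ClusterSet", clusters = list(), scores = numeric(0),
               engine = "mcl", graphLabel = g@species, params = params))
  id <- setNames(seq_len(n), nodes)
  e <- g@edges
  M <- Matrix::sparseMatrix(i = c(id[e$a], id[e$b], seq_len(n)),
                            j = c(id[e$b], id[e$a], seq_len(n)),
                            x = c(e$weight, e$weight, rep(selfLoopWeight, n)),
                            dims = c(n, n))
  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize(M)
  max_dev <- max(abs(Matrix::colSums(M) - 1))
  converged <- FALSE
  for (it in seq_len(maxIterations)) {
    M2 <- M
    for (k in seq_len(expansion - 1L)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M2@x[M2@x < pruneThreshold] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- normalize(M2)
    max_dev <- max(max_dev, max(abs(Matrix::colSums(M2) - 1)))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge within %d iterations", maxIterations))
  params$max_colsum_dev <- max_dev
  params$iterations_run <- it
  # attractor-based components of the limit matrix's non-zero pattern
  S <- (M + Matrix::t(M)) != 0
  ig <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(ig)$membership
  cl <- split(nodes, comp)
  cl <- lapply(unname(cl), function(m) sort(m, method = "radix"))
  cl <- cl[lengths(cl) >= as.integer(minSize)]
  if (length(cl)) {
    keys <- vapply(cl, paste, character(1), collapse = "\r")
    cl <- cl[order(keys, method = "radix")]
  }
  env <- .weight_env(g)
  scores <- vapply(cl, function(m)
    if (length(m) < 2L) 0 else .internal_weight(env, m) / choose(length(m), 2L),
    numeric(1))
  new("ClusterSet", clusters = cl, scores = scores, engine = "mcl",
      graphLabel = g@species, params = params)
}

#' Cluster a graph with a chosen engine
#'
#' Dispatch wrapper over [cmcCluster()] and [mclCluster()]; engine
#' parameters are passed through `...` and recorded in the result.
#'
#' @param g a weighted [PPINetwork-class].
#' @param engine `"cmc"` or `"mcl"`.
#' @param ... engine parameters.
#' @return a [ClusterSet-class].
#' @export
clusterGraph <- function(g, engine = c("cmc", "mcl"), ...) {
  engine <- tryCatch(match.arg(engine),
                     error = function(e) .stopf("unknown clustering engine"))
  switch(engine, cmc = cmcCluster(g, ...), mcl = mclCluster(g, ...))
}
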
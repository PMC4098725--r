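# interolog network construction, conserved subnetworks, cluster projection

# internal constructor enforcing deterministic ordering
.interologNetwork <- function(speciesA, speciesB, nodes, edges) {
  if (nrow(nodes)) {
    nodes <- nodes[order(nodes$p, nodes$q, method = "radix"), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    if (any(swap)) {
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
    }
    edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("InterologNetwork", speciesA = speciesA, speciesB = speciesB,
      nodes = nodes, edges = edges)
}

#' Build the interolog network from two PPI networks and an ortholog map
#'
#' Nodes are homologous protein pairs: every theta pair `(p, q)` with `p` a
#' node of `g1` and `q` a node of `g2`. An edge tagged
#' `conserved_interaction` joins nodes `(p, q)` and `(r, s)` exactly when
#' `p--r` is an interaction of `g1` and `q--s` an interaction of `g2` -- a
#' conserved interaction (interolog). When a protein is orthologous to
#' several proteins of the other species it yields several nodes; with
#' `includeSharedProteinEdges = TRUE` (default) every pair of nodes sharing a
#' protein (on either side) is additionally joined by a `shared_protein`
#' edge, integrating the many-to-many ortholog relationships into the
#' network. Interolog edge weights are the product of the two source-edge
#' weights; shared-protein edges get weight 1.
#'
#' @param g1,g2 [PPINetwork-class] objects for species A and B.
#' @param map an [OrthologMap-class] spanning the two species.
#' @param includeSharedProteinEdges add `shared_protein` edges (default TRUE).
#' @param pruneIsolated drop degree-0 nodes from the result (default TRUE).
#' @param checkSpecies require the map's species labels to equal the
#'   networks' labels (default TRUE).
#' @return an [InterologNetwork-class]; output is deterministic and
#'   independent of input ordering.
#' @examples
#' g1 <- ppiNetwork("y", data.frame(a = "p1", b = "p2"))
#' g2 <- ppiNetwork("h", data.frame(a = "q1", b = "q2"))
#' m <- orthologMap("y", "h", list(G1 = list(a = "p1", b = "q1"),
#'                                 G2 = list(a = "p2", b = "q2")))
#' buildInterologNetwork(g1, g2, m)
#' @export
buildInterologNetwork <- function(g1, g2, map,
                                  includeSharedProteinEdges = TRUE,
                                  pruneIsolated = TRUE,
                                  checkSpecies = TRUE) {
  stopifnot(is(g1, "PPINetwork"), is(g2, "PPINetwork"), is(map, "OrthologMap"))
  if (numNodes(g1) == 0L || numNodes(g2) == 0L)
    .stopf("both input networks must be non-empty")
  if (checkSpecies &&
      !identical(speciesLabels(map), c(speciesLabels(g1), speciesLabels(g2))))
    .stopf("species labels of the map (%s, %s) do not match the networks (%s, %s)",
           map@speciesA, map@speciesB, g1@species, g2@species)
  th <- thetaPairs(map, restrictA = g1@nodes, restrictB = g2@nodes)
  nodes <- data.frame(p = th$a, q = th$b,
                      id = paste(th$a, th$b, sep = "|"),
                      stringsAsFactors = FALSE)
  if (any(grepl("|", c(th$a, th$b), fixed = TRUE)))
    .stopf("protein identifiers must not contain '|'")

  # index: protein -> row indices of nodes having it as the given coordinate
  idx_p <- split(seq_len(nrow(nodes)), nodes$p)
  idx_q <- split(seq_len(nrow(nodes)), nodes$q)

  e2key <- new.env(parent = emptyenv(), hash = TRUE)
  e2 <- g2@edges
  for (i in seq_len(nrow(e2))) e2key[[paste(e2$a[i], e2$b[i], sep = "\r")]] <- e2$weight[i]

  from <- to <- character(0); w <- numeric(0)
  e1 <- g1@edges
  for (i in seq_len(nrow(e1))) {
    us <- idx_p[[e1$a[i]]]
    vs <- idx_p[[e1$b[i]]]
    if (is.null(us) || is.null(vs)) next
    for (u in us) {
      qu <- nodes$q[u]
      for (v in vs) {
        qv <- nodes$q[v]
        if (qu == qv) next                       # q--q is not an interaction
        key <- if (qu < qv) paste(qu, qv, sep = "\r") else paste(qv, qu, sep = "\r")
        w2 <- e2key[[key]]
        if (is.null(w2)) next
        from <- c(from, nodes$id[u]); to <- c(to, nodes$id[v])
        w <- c(w, max(e1$weight[i] * w2, .Machine$double.eps))
      }
    }
  }
  edges <- data.frame(from = from, to = to, weight = w,
                      provenance = rep("conserved_interaction", length(from)),
                      stringsAsFactors = FALSE)

  if (includeSharedProteinEdges) {
    shared <- .shared_protein_edges(nodes, idx_p, idx_q)
    edges <- rbind(edges, shared)
  }

  net <- .interologNetwork(g1@species, g2@species, nodes, edges)
  if (pruneIsolated) {
    used <- net@nodes$id %in% c(net@edges$from, net@edges$to)
    net <- .interologNetwork(g1@species, g2@species,
                             net@nodes[used, , drop = FALSE], net@edges)
  }
  net
}

.shared_protein_edges <- function(nodes, idx_p, idx_q) {
  from <- to <- character(0)
  for (idx in list(idx_p, idx_q)) {
    for (rows in idx) {
      if (length(rows) < 2L) next
      prs <- utils::combn(rows, 2L)
      from <- c(from, nodes$id[prs[1L, ]])
      to <- c(to, nodes$id[prs[2L, ]])
    }
  }
  data.frame(from = from, to = to, weight = rep(1, length(from)),
             provenance = rep("shared_protein", length(from)),
             stringsAsFactors = FALSE)
}

#' Conserved subnetwork of one species
#'
#' Restricts a species' PPI network to the interactions conserved in the
#' other species: an edge `p--r` of the target network is kept exactly when
#' there exist orthologs `q` of `p` and `s` of `r` (distinct) that interact
#' in the other network. The node set of the result is the set of endpoints
#' of retained edges.
#'
#' @param gTarget the [PPINetwork-class] to restrict.
#' @param gOther the [PPINetwork-class] providing conservation evidence.
#' @param map an [OrthologMap-class]; `side` says which side of the map the
#'   target species is on.
#' @param side `"a"` (default) if `gTarget` is the map's species A, else
#'   `"b"`.
#' @return a [PPINetwork-class] with the conserved edges only.
#' @export
conservedSubnetwork <- function(gTarget, gOther, map, side = c("a", "b")) {
  side <- match.arg(side)
  stopifnot(is(gTarget, "PPINetwork"), is(gOther, "PPINetwork"),
            is(map, "OrthologMap"))
  th <- if (side == "a")
    thetaPairs(map, restrictA = gTarget@nodes, restrictB = gOther@nodes)
  else {
    t0 <- thetaPairs(map, restrictA = gOther@nodes, restrictB = gTarget@nodes)
    data.frame(a = t0$b, b = t0$a, stringsAsFactors = FALSE)  # target-first
  }
  orth <- split(th$b, th$a)                     # target protein -> orthologs
  okey <- new.env(parent = emptyenv(), hash = TRUE)
  eo <- gOther@edges
  for (i in seq_len(nrow(eo))) okey[[paste(eo$a[i], eo$b[i], sep = "\r")]] <- TRUE
  e <- gTarget@edges
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    qs <- orth[[e$a[i]]]
    ss <- orth[[e$b[i]]]
    if (is.null(qs) || is.null(ss)) next
    found <- FALSE
    for (q in qs) {
      for (s in ss) {
        if (q == s) next
        key <- if (q < s) paste(q, s, sep = "\r") else paste(s, q, sep = "\r")
        if (!is.null(okey[[key]])) { found <- TRUE; break }
      }
      if (found) break
    }
    keep[i] <- found
  }
  ppiNetwork(gTarget@species, e[keep, , drop = FALSE])
}

#' Project an interolog cluster onto one species
#'
#' Maps a cluster of interolog-network nodes back to a protein set of one
#' species by taking the chosen coordinate of each homolog-pair node.
#' Because several nodes can share a coordinate (many-to-many orthology),
#' the projection can be smaller than the cluster.
#'
#' @param cluster character vector of interolog node ids (`"p|q"`).
#' @param side `"a"` (first coordinate) or `"b"` (second).
#' @return sorted character vector of distinct proteins.
#' @examples
#' projectCluster(c("p1|q1", "p2|q1"), "a")
#' projectCluster(c("p1|q1", "p2|q1"), "b")
#' @export
projectCluster <- function(cluster, side = c("a", "b")) {
  side <- match.arg(side)
  cluster <- as.character(cluster)
  if (!length(cluster)) .stopf("cannot project an empty cluster")
  coords <- strsplit(cluster, "|", fixed = TRUE)
  if (any(lengths(coords) != 2L))
    .stopf("malformed interolog node id (expected 'p|q')")
  i <- if (side == "a") 1L else 2L
  sort(unique(vapply(coords, `[[`, character(1), i)), method = "radix")
}

#' View an interolog network as a plain weighted PPI-style graph
#'
#' Clustering engines operate on ordinary weighted graphs; this coercion
#' forgets the pair structure (node ids `"p|q"` become opaque identifiers).
#'
#' @param x an [InterologNetwork-class].
#' @param dropSharedProteinEdges exclude `shared_protein` edges (default
#'   FALSE: provenance is ignored and all edges are kept).
#' @return a [PPINetwork-class] labelled
#'   `"<speciesA>|<speciesB> interolog"`.
#' @export
interologGraph <- function(x, dropSharedProteinEdges = FALSE) {
  stopifnot(is(x, "InterologNetwork"))
  e <- x@edges
  if (dropSharedProteinEdges)
    e <- e[e$provenance == "conserved_interaction", , drop = FALSE]
  ppiNetwork(paste0(x@speciesA, "|", x@speciesB, " interolog"),
             data.frame(a = e$from, b = e$to, weight = e$weight,
                        stringsAsFactors = FALSE),
             nodes = x@nodes$id)
}
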
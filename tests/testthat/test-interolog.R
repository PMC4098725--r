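# interolog network construction, conserved subnetworks, projection

minimal_pair <- function() {
  list(g1 = ppiNetwork("y", data.frame(a = "p1", b = "p2")),
       g2 = ppiNetwork("h", data.frame(a = "q1", b = "q2")))
}

test_that("the minimal interolog: one conserved edge from matched 1-1 orthologs", {
  gs <- minimal_pair()
  m <- orthologMap("y", "h", list(G1 = list(a = "p1", b = "q1"),
                                  G2 = list(a = "p2", b = "q2")))
  inet <- buildInterologNetwork(gs$g1, gs$g2, m)
  expect_equal(inet@nodes$id, c("p1|q1", "p2|q2"))
  expect_equal(nrow(inet@edges), 1L)
  expect_equal(inet@edges$provenance, "conserved_interaction")
})

test_that("two nodes sharing an ortholog give a shared_protein edge, not an interolog", {
  gs <- minimal_pair()
  m <- orthologMap("y", "h", list(G1 = list(a = c("p1", "p2"), b = "q1")))
  inet <- buildInterologNetwork(gs$g1, gs$g2, m, pruneIsolated = FALSE)
  expect_equal(inet@nodes$id, c("p1|q1", "p2|q1"))
  expect_equal(inet@edges$provenance, "shared_protein")
  # with the flag off there is no edge at all
  inet2 <- buildInterologNetwork(gs$g1, gs$g2, m,
                                 includeSharedProteinEdges = FALSE,
                                 pruneIsolated = FALSE)
  expect_equal(nrow(inet2@edges), 0L)
  # and pruning then removes the isolated nodes
  inet3 <- buildInterologNetwork(gs$g1, gs$g2, m,
                                 includeSharedProteinEdges = FALSE)
  expect_equal(nrow(inet3@nodes), 0L)
})

test_that("empty theta yields an empty network; label mismatches error", {
  gs <- minimal_pair()
  m0 <- orthologMap("y", "h", list())
  inet <- buildInterologNetwork(gs$g1, gs$g2, m0)
  expect_equal(nrow(inet@nodes), 0L)
  expect_equal(nrow(inet@edges), 0L)
  m_bad <- orthologMap("y", "mouse", list(G1 = list(a = "p1", b = "q1")))
  expect_error(buildInterologNetwork(gs$g1, gs$g2, m_bad), "species labels")
})

test_that("construction equals the literal definition on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    g1 <- random_ppi(sample(5:15, 1), 0.25, "y", "p")
    g2 <- random_ppi(sample(5:15, 1), 0.25, "h", "q")
    m <- random_map(g1, g2, n_groups = sample(2:10, 1))
    oracle <- interolog_oracle(g1, g2, m)
    inet <- buildInterologNetwork(g1, g2, m, pruneIsolated = FALSE)
    expect_equal(inet@nodes$id, oracle$nodes)
    got <- paste(inet@edges$from, inet@edges$to, sep = "\t")
    expect_equal(sort(got), oracle$edges)
    expect_equal(inet@edges$provenance[order(got)], oracle$prov)
    # pruning keeps exactly the nodes used by edges
    pruned <- buildInterologNetwork(g1, g2, m, pruneIsolated = TRUE)
    expect_equal(pruned@nodes$id, oracle$pruned_nodes)
  }
})

test_that("construction is monotone and symmetric", {
  set.seed(55)
  for (rep in 1:5) {
    g1 <- random_ppi(8, 0.3, "y", "p")
    g2 <- random_ppi(8, 0.3, "h", "q")
    m <- random_map(g1, g2, 5)
    inet <- buildInterologNetwork(g1, g2, m, pruneIsolated = FALSE)
    # add one edge to g1: no interolog edge disappears
    non_edges <- t(combn(proteins(g1), 2L))
    keys <- apply(non_edges, 1, function(x)
      any(interactions(g1)$a == min(x) & interactions(g1)$b == max(x)))
    if (any(!keys)) {
      add <- non_edges[which(!keys)[1L], ]
      g1p <- ppiNetwork("y", rbind(interactions(g1),
                                   data.frame(a = add[1L], b = add[2L],
                                              weight = 1)),
                        nodes = proteins(g1))
      inet2 <- buildInterologNetwork(g1p, g2, m, pruneIsolated = FALSE)
      old_edges <- paste(inet@edges$from, inet@edges$to)
      expect_true(all(old_edges %in% paste(inet2@edges$from, inet2@edges$to)))
    }
    # swap species and transpose theta: same network with coordinates swapped
    mt <- orthologMap("h", "y", lapply(orthologGroups(m), function(g)
      list(a = g$b, b = g$a)))
    inet_t <- buildInterologNetwork(g2, g1, mt, pruneIsolated = FALSE)
    swap_id <- function(id) {
      xy <- strsplit(id, "|", fixed = TRUE)
      vapply(xy, function(v) paste(v[2L], v[1L], sep = "|"), character(1))
    }
    expect_equal(sort(swap_id(inet@nodes$id)), sort(inet_t@nodes$id))
    et <- apply(cbind(swap_id(inet@edges$from), swap_id(inet@edges$to)), 1,
                function(x) paste(sort(x), collapse = "\t"))
    et2 <- paste(inet_t@edges$from, inet_t@edges$to, sep = "\t")
    expect_equal(sort(et), sort(et2))
  }
})

test_that("interolog edge weights are products of the source edge weights", {
  g1 <- ppiNetwork("y", data.frame(a = "p1", b = "p2", weight = 0.5))
  g2 <- ppiNetwork("h", data.frame(a = "q1", b = "q2", weight = 0.4))
  m <- orthologMap("y", "h", list(G1 = list(a = "p1", b = "q1"),
                                  G2 = list(a = "p2", b = "q2")))
  inet <- buildInterologNetwork(g1, g2, m)
  expect_equal(inet@edges$weight, 0.2)
})

test_that("conserved subnetwork keeps exactly the conserved edges", {
  gs <- minimal_pair()
  m <- orthologMap("y", "h", list(G1 = list(a = "p1", b = "q1"),
                                  G2 = list(a = "p2", b = "q2")))
  cs <- conservedSubnetwork(gs$g1, gs$g2, m)
  expect_equal(interactions(cs)[, c("a", "b")],
               data.frame(a = "p1", b = "p2", stringsAsFactors = FALSE))
  # no edges in the other network -> empty conserved subnetwork
  g2_empty <- ppiNetwork("h", nodes = c("q1", "q2"))
  cs0 <- conservedSubnetwork(gs$g1, g2_empty, m)
  expect_equal(numEdges(cs0), 0L)
  expect_equal(numNodes(cs0), 0L)
})

test_that("conserved subnetwork equals the side-a projection of interolog edges", {
  set.seed(77)
  for (rep in 1:10) {
    g1 <- random_ppi(10, 0.3, "y", "p")
    g2 <- random_ppi(10, 0.3, "h", "q")
    m <- random_map(g1, g2, 6)
    cs <- conservedSubnetwork(g1, g2, m, side = "a")
    inet <- buildInterologNetwork(g1, g2, m, includeSharedProteinEdges = FALSE)
    e <- inet@edges
    project_edges <- function(coord) {
      if (!nrow(e)) return(character(0))
      x <- vapply(strsplit(e$from, "|", fixed = TRUE), `[[`, character(1), coord)
      y <- vapply(strsplit(e$to, "|", fixed = TRUE), `[[`, character(1), coord)
      sort(unique(paste(pmin(x, y), pmax(x, y))))
    }
    got <- interactions(cs)
    expect_equal(paste(got$a, got$b), project_edges(1L))
    # symmetric check for side b
    cs_b <- conservedSubnetwork(g2, g1, m, side = "b")
    got_b <- interactions(cs_b)
    expect_equal(paste(got_b$a, got_b$b), project_edges(2L))
  }
})

test_that("projection extracts coordinates and dedups", {
  expect_equal(projectCluster(c("p1|q1", "p2|q1"), "a"), c("p1", "p2"))
  expect_equal(projectCluster(c("p1|q1", "p2|q1"), "b"), "q1")
  expect_equal(projectCluster("p|q", "a"), "p")
  expect_error(projectCluster(character(0)), "empty cluster")
  # duplicated b coordinates shrink the projection
  cl <- c("x1|y1", "x2|y1", "x3|y2", "x4|y2", "x5|y3")
  expect_lt(length(projectCluster(cl, "b")), length(cl))
})
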
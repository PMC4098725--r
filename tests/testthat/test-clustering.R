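# clustering engines and edge re-weighting

k_graph <- function(n, prefix = "v", species = "k") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  prs <- t(combn(nodes, 2L))
  ppiNetwork(species, data.frame(a = prs[, 1L], b = prs[, 2L], weight = 1,
                                 stringsAsFactors = FALSE))
}

union_ppi <- function(species, ...) {
  parts <- list(...)
  ppiNetwork(species, do.call(rbind, lapply(parts, interactions)),
             nodes = unlist(lapply(parts, proteins)))
}

test_that("AdjustCD gives weight 1 to isolated mutually-exclusive partners and equal weights on K3", {
  # two nodes connected only to each other: identical closed neighbourhoods
  # of size 2 = the average degree -> weight exactly 1 at iteration 1
  g <- ppiNetwork("s", data.frame(a = "u", b = "v"))
  expect_equal(interactions(adjustCDWeights(g, 1))$weight, 1)
  # K3 symmetry: all three edges equal
  w3 <- interactions(adjustCDWeights(k_graph(3), 2))$weight
  expect_equal(length(unique(round(w3, 12))), 1L)
  expect_error(adjustCDWeights(g, 0), "positive integer")
})

test_that("AdjustCD penalizes a detached pair as the rest of the graph grows", {
  base <- data.frame(a = "u", b = "v", weight = 1)
  w_small <- interactions(adjustCDWeights(
    union_ppi("s", ppiNetwork("s", base), k_graph(4, "x")), 1))
  w_big <- interactions(adjustCDWeights(
    union_ppi("s", ppiNetwork("s", base), k_graph(8, "x")), 1))
  wu_small <- w_small$weight[w_small$a == "u"]
  wu_big <- w_big$weight[w_big$a == "u"]
  expect_lt(wu_big, wu_small)  # average-degree floor grows with the graph
  expect_lt(wu_small, 1)
})

test_that("AdjustCD weights stay in (0, 1] over random graphs, for several iteration depths", {
  set.seed(19)
  for (rep in 1:8) {
    g <- random_ppi(12, 0.35, "s")
    if (numEdges(g) == 0L) next
    for (it in c(1L, 2L, 4L)) {
      w <- interactions(adjustCDWeights(g, it))$weight
      expect_true(all(w > 0 & w <= 1))
    }
  }
})

test_that("maximal cliques match the exhaustive subset oracle", {
  expect_equal(maximalCliques(k_graph(4)), list(sprintf("v%02d", 1:4)))
  # two K4s sharing one vertex: two cliques
  g <- union_ppi("k", k_graph(4, "a"), k_graph(4, "b"))
  shared <- ppiNetwork("k", rbind(interactions(g),
    data.frame(a = "a01", b = "b01", weight = 1)))
  # still two 4-cliques plus the bridge edge clique
  cl <- maximalCliques(shared, minSize = 3L)
  expect_equal(length(cl), 2L)
  set.seed(23)
  for (rep in 1:10) {
    g <- random_ppi(sample(6:12, 1), 0.5, "s")
    expect_equal(maximalCliques(g, minSize = 2L), clique_oracle(g, 2L))
  }
})

test_that("CMC recovers, merges and separates cliques as specified", {
  # lone K5 -> one cluster, density 1
  cs <- cmcCluster(k_graph(5), minSize = 4L)
  expect_equal(clusters(cs), list(sprintf("v%02d", 1:5)))
  expect_equal(clusterScores(cs), 1)
  # two K4s sharing 3 nodes merge into one cluster of 5
  n1 <- c("a", "b", "c", "d"); n2 <- c("b", "c", "d", "e")
  prs <- unique(rbind(t(combn(n1, 2)), t(combn(n2, 2))))
  g <- ppiNetwork("s", data.frame(a = prs[, 1], b = prs[, 2], weight = 1))
  cs <- cmcCluster(g, minSize = 4L, overlapThreshold = 0.5)
  expect_equal(clusters(cs), list(c("a", "b", "c", "d", "e")))
  # two disjoint K4s stay apart
  g2 <- union_ppi("s", k_graph(4, "x"), k_graph(4, "y"))
  expect_equal(length(clusters(cmcCluster(g2, minSize = 4L))), 2L)
  expect_error(cmcCluster(g2, overlapThreshold = 1.2), "overlapThreshold")
})

test_that("every CMC cluster contains a seed maximal clique and respects min size", {
  set.seed(41)
  for (rep in 1:6) {
    g <- random_ppi(15, 0.4, "s", weighted = TRUE)
    cs <- cmcCluster(g, minSize = 3L)
    seeds <- maximalCliques(g, minSize = 2L)
    for (cl in clusters(cs)) {
      expect_gte(length(cl), 3L)
      expect_true(any(vapply(seeds, function(s) all(s %in% cl), logical(1))))
    }
  }
})

test_that("MCL separates disconnected and bridged dense regions", {
  two_k5 <- union_ppi("s", k_graph(5, "x"), k_graph(5, "y"))
  cs <- mclCluster(two_k5, minSize = 4L)
  expect_equal(clusters(cs),
               list(sprintf("x%02d", 1:5), sprintf("y%02d", 1:5)))
  expect_lte(cs@params$max_colsum_dev, 1e-9)
  # single K4
  expect_equal(clusters(mclCluster(k_graph(4), minSize = 4L)),
               list(sprintf("v%02d", 1:4)))
  # two K6s joined by one bridge edge split at the bridge
  g <- union_ppi("s", k_graph(6, "x"), k_graph(6, "y"))
  g <- ppiNetwork("s", rbind(interactions(g),
                             data.frame(a = "x01", b = "y01", weight = 1)))
  cs2 <- mclCluster(g, inflation = 2, minSize = 4L)
  expect_equal(clusters(cs2),
               list(sprintf("x%02d", 1:6), sprintf("y%02d", 1:6)))
  expect_error(mclCluster(g, inflation = 1), "inflation")
})

test_that("MCL output partitions the node set and is invariant under relabeling", {
  set.seed(59)
  for (rep in 1:5) {
    g <- random_ppi(14, 0.3, "s")
    cs <- mclCluster(g, minSize = 1L)
    all_members <- unlist(clusters(cs))
    expect_equal(sort(all_members), proteins(g))   # partition, no overlap
    expect_lte(cs@params$max_colsum_dev, 1e-9)
    # relabel nodes with a random permutation of fresh names
    perm <- setNames(sprintf("w%02d", sample(numNodes(g))), proteins(g))
    e <- interactions(g)
    g2 <- ppiNetwork("s", data.frame(a = perm[e$a], b = perm[e$b],
                                     weight = e$weight),
                     nodes = unname(perm))
    cs2 <- mclCluster(g2, minSize = 1L)
    canon <- function(cl, f = identity) {
      sort(vapply(cl, function(x) paste(sort(f(x)), collapse = " "),
                  character(1)))
    }
    expect_equal(canon(clusters(cs2)), canon(clusters(cs), function(x) unname(perm[x])))
  }
})

test_that("clusterGraph dispatches and records parameters", {
  g <- k_graph(5)
  cs <- clusterGraph(g, "cmc", minSize = 4L)
  expect_equal(cs@engine, "cmc")
  expect_equal(cs@params$min_size, 4L)
  cs2 <- clusterGraph(union_ppi("s", k_graph(5, "x"), k_graph(5, "y")), "mcl")
  expect_equal(length(clusters(cs2)), 2L)
  expect_error(clusterGraph(g, "haco"), "unknown clustering engine")
})

test_that("both engines recover planted complexes at zero noise", {
  sc <- generateScenario(tiny_clean_params(seed = 3L))
  inet <- buildInterologNetwork(sc@ppiA, sc@ppiB, sc@map)
  g <- interologGraph(inet)
  truth <- lapply(names(complexes(sc@catalogA)), function(id) {
    a <- complexes(sc@catalogA)[[id]]
    b <- complexes(sc@catalogB)[[sub("_a_", "_b_", id)]]
    sort(paste(a, b, sep = "|"))
  })
  for (engine in c("cmc", "mcl")) {
    cs <- clusterGraph(g, engine, minSize = 4L)
    canon <- vapply(clusters(cs), paste, character(1), collapse = " ")
    for (tr in truth)
      expect_true(paste(tr, collapse = " ") %in% canon)
  }
})
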
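# fixtures and independent brute-force oracles used across test files

# random simple undirected graph as a PPINetwork
random_ppi <- function(n, p, species = "s", prefix = "n", weighted = FALSE) {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  prs <- t(combn(nodes, 2L))
  keep <- runif(nrow(prs)) < p
  w <- if (weighted) runif(sum(keep), 0.1, 1) else rep(1, sum(keep))
  ppiNetwork(species, data.frame(a = prs[keep, 1L], b = prs[keep, 2L],
                                 weight = w, stringsAsFactors = FALSE),
             nodes = nodes)
}

# random many-to-many ortholog map between the node sets of two networks
random_map <- function(g1, g2, n_groups = 8L, max_side = 3L) {
  groups <- list()
  for (k in seq_len(n_groups)) {
    a <- sample(proteins(g1), sample.int(max_side, 1L))
    b <- sample(proteins(g2), sample.int(max_side, 1L))
    groups[[sprintf("G%02d", k)]] <- list(a = a, b = b)
  }
  orthologMap(speciesLabels(g1), speciesLabels(g2), groups)
}

has_edge <- function(g, x, y) {
  e <- interactions(g)
  any((e$a == x & e$b == y) | (e$a == y & e$b == x))
}

# literal unrolling of the interolog-network definition: loop over all
# theta pairs and all pairs of theta pairs
interolog_oracle <- function(g1, g2, map, shared = TRUE) {
  th <- thetaPairs(map)
  th <- th[th$a %in% proteins(g1) & th$b %in% proteins(g2), , drop = FALSE]
  ids <- character(0)
  if (nrow(th)) ids <- paste(th$a, th$b, sep = "|")
  edges <- character(0)
  prov <- character(0)
  if (nrow(th) >= 2L) {
    for (i in 1:(nrow(th) - 1L)) {
      for (j in (i + 1L):nrow(th)) {
        p <- th$a[i]; q <- th$b[i]; r <- th$a[j]; s <- th$b[j]
        conserved <- p != r && q != s && has_edge(g1, p, r) && has_edge(g2, q, s)
        share <- xor(p == r, q == s)
        if (conserved || (shared && share)) {
          key <- sort(c(ids[i], ids[j]))
          edges <- c(edges, paste(key[1L], key[2L], sep = "\t"))
          prov <- c(prov, if (conserved) "conserved_interaction" else "shared_protein")
        }
      }
    }
  }
  used <- unique(unlist(strsplit(edges, "\t", fixed = TRUE)))
  list(nodes = sort(ids), edges = sort(edges),
       prov = prov[order(edges)],
       pruned_nodes = sort(used))
}

# exhaustive maximal-clique oracle over all vertex subsets (n <= 12)
clique_oracle <- function(g, min_size = 1L) {
  nodes <- proteins(g)
  n <- length(nodes)
  e <- interactions(g)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(e))) {
    adj[e$a[i], e$b[i]] <- TRUE
    adj[e$b[i], e$a[i]] <- TRUE
  }
  is_clique <- function(members) {
    if (length(members) < 2L) return(TRUE)
    all(adj[members, members][upper.tri(diag(length(members)))])
  }
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1L)) != 0L]
    if (length(members) < min_size || !is_clique(members)) next
    others <- setdiff(nodes, members)
    maximal <- !any(vapply(others, function(v) all(adj[v, members]), logical(1)))
    if (maximal) out[[length(out) + 1L]] <- sort(members)
  }
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out[order(keys)]
}

# random group profile for MSJ property tests
random_profile <- function(pool = sprintf("G%02d", 1:12), max_mult = 4L,
                           max_ungrouped = 2L) {
  gs <- sample(pool, sample.int(6L, 1L))
  mult <- setNames(sample.int(max_mult, length(gs), replace = TRUE), gs)
  n_u <- sample.int(max_ungrouped + 1L, 1L) - 1L
  new("GroupProfile", complexId = "r",
      multiplicities = mult[order(names(mult))],
      ungrouped = if (n_u) sprintf("u%02d", seq_len(n_u)) else character(0))
}

# direct MSJ computation from two multiplicity vectors (independent of msj())
msj_reference <- function(m1, m2, n_u1 = 0L, n_u2 = 0L) {
  gs <- union(names(m1), names(m2))
  i1 <- vapply(gs, function(g) if (g %in% names(m1)) m1[[g]] else 0L, numeric(1))
  i2 <- vapply(gs, function(g) if (g %in% names(m2)) m2[[g]] else 0L, numeric(1))
  sum(pmin(i1, i2)) / (sum(pmax(i1, i2)) + n_u1 + n_u2)
}

# small deterministic scenario used by several files
tiny_clean_params <- function(seed = 1L, n = 4L) {
  scenarioParams(nConserved = n, sizeRange = c(4L, 6L), pIntra = 1,
                 pConserve = 1, paralogRate = 0, nBackgroundA = 10L,
                 nBackgroundB = 10L, backgroundOrthologRate = 0.5,
                 noiseMultiplier = 0, edgeLossRate = 0, seed = seed)
}
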
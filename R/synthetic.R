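# synthetic two-species scenarios with planted conserved complexes:
# paired PPI networks, a many-to-many ortholog map with paralog expansions,
# complex catalogs, and the benchmark of planted conserved pairs

#' Construct scenario parameters
#'
#' Defaults describe a moderately noisy regime: 20 planted conserved
#' complexes of 4-8 ortholog groups, within-complex edge probability 0.9
#' per species with 0.9 cross-species co-occurrence, a 0.2 paralog-expansion
#' rate creating 1-to-many and many-to-many groups, 100 species-specific
#' background proteins per species, random false-positive edges at twice the
#' planted edge count, and a 0.1 false-negative rate.
#'
#' @param nConserved number of planted conserved complexes (default 20).
#' @param sizeRange integer range of complex sizes in ortholog groups
#'   (default `c(4, 8)`).
#' @param pIntra within-complex edge probability per species (default 0.9).
#' @param pConserve probability a planted within-complex edge co-occurs in
#'   the other species (default 0.9).
#' @param paralogRate probability a group gains an extra member on a random
#'   side (default 0.2).
#' @param nBackgroundA,nBackgroundB species-specific background proteins
#'   (default 100 each).
#' @param backgroundOrthologRate probability a background protein pair is
#'   linked 1-to-1 by an ortholog group (default 0.3), so the interolog
#'   network is not trivially identical to the planted complexes.
#' @param noiseMultiplier false-positive edges per species as a multiple of
#'   planted edges (default 2).
#' @param edgeLossRate false-negative rate, independent per species
#'   (default 0.1).
#' @param seed integer seed (default 1).
#' @return a [ScenarioParams-class].
#' @export
scenarioParams <- function(nConserved = 20L, sizeRange = c(4L, 8L),
                           pIntra = 0.9, pConserve = 0.9, paralogRate = 0.2,
                           nBackgroundA = 100L, nBackgroundB = 100L,
                           backgroundOrthologRate = 0.3,
                           noiseMultiplier = 2, edgeLossRate = 0.1,
                           seed = 1L) {
  new("ScenarioParams",
      nConserved = as.integer(nConserved),
      sizeMin = as.integer(sizeRange[1L]), sizeMax = as.integer(sizeRange[2L]),
      pIntra = pIntra, pConserve = pConserve, paralogRate = paralogRate,
      nBackgroundA = as.integer(nBackgroundA),
      nBackgroundB = as.integer(nBackgroundB),
      backgroundOrthologRate = backgroundOrthologRate,
      noiseMultiplier = noiseMultiplier, edgeLossRate = edgeLossRate,
      seed = as.integer(seed))
}

#' Generate a synthetic two-species scenario
#'
#' Each planted complex is a set of ortholog groups realized as proteins on
#' both species' sides; with probability `paralogRate` a group gains an
#' extra paralog on a random side, creating 1-to-many and many-to-many
#' groups. Within a complex, each pair of groups interacts in species A with
#' probability `pIntra`; an interacting pair co-occurs in species B with
#' probability `pConserve` (otherwise species B redraws independently), and
#' group-level interactions are realized as edges between all member pairs.
#' Paralogs of one group are connected within their species with
#' probability `pIntra`. Planted edges are then lost independently per
#' species at `edgeLossRate` (false negatives), and species-specific noise
#' edges (false positives, non-conserved by construction) are added
#' uniformly over non-planted pairs at `noiseMultiplier` times the planted
#' edge count. Background proteins receive 1-to-1 ortholog groups at
#' `backgroundOrthologRate`.
#'
#' The returned benchmark lists exactly the planted complex pairs with
#' their true Multi-set Jaccard scores, computed directly from the group
#' construction (groups are shared; only paralog multiplicities differ).
#' The result is fully deterministic given `params@seed`, and the caller's
#' RNG state is left untouched.
#'
#' @param params a [ScenarioParams-class].
#' @return a [Scenario-class].
#' @examples
#' sc <- generateScenario(scenarioParams(nConserved = 3, seed = 7))
#' sc
#' @export
generateScenario <- function(params) {
  stopifnot(is(params, "ScenarioParams"))
  validObject(params)
  .with_seed(params@seed, .generate_scenario_impl(params))
}

.generate_scenario_impl <- function(params) {
  n_cx <- params@nConserved
  groups <- list()
  cxa <- list(); cxb <- list()
  cx_groups <- vector("list", n_cx)   # group ids per complex
  true_msj <- numeric(n_cx)
  pa_count <- 0L; pb_count <- 0L      # protein counters per species

  new_a <- function() { pa_count <<- pa_count + 1L; sprintf("ya%04d", pa_count) }
  new_b <- function() { pb_count <<- pb_count + 1L; sprintf("hb%04d", pb_count) }

  sizes <- sample(seq(params@sizeMin, params@sizeMax), n_cx, replace = TRUE)
  for (i in seq_len(n_cx)) {
    k <- sizes[i]
    gids <- sprintf("cx%02d_g%02d", i, seq_len(k))
    cx_groups[[i]] <- gids
    members_a <- list(); members_b <- list()
    for (j in seq_len(k)) {
      a <- new_a(); b <- new_b()
      if (stats::runif(1) < params@paralogRate) {
        if (stats::runif(1) < 0.5) a <- c(a, new_a()) else b <- c(b, new_b())
      }
      groups[[gids[j]]] <- list(a = a, b = b)
      members_a[[j]] <- a; members_b[[j]] <- b
    }
    cxa[[sprintf("cpx_a_%02d", i)]] <- unlist(members_a)
    cxb[[sprintf("cpx_b_%02d", i)]] <- unlist(members_b)
    # true MSJ from the group bookkeeping: shared group set, multiplicities
    # are the per-side member counts (no ungrouped members by construction)
    na <- lengths(members_a); nb <- lengths(members_b)
    true_msj[i] <- sum(pmin(na, nb)) / sum(pmax(na, nb))
  }

  # planted within-complex edges, sampled at the group-pair level so that
  # cross-species co-occurrence is controlled by pConserve
  edges_a <- list(); edges_b <- list()
  add_pairs <- function(m1, m2) {
    # all unordered pairs between two member vectors (possibly the same)
    if (identical(m1, m2)) {
      if (length(m1) < 2L) return(NULL)
      prs <- utils::combn(m1, 2L)
      data.frame(a = prs[1L, ], b = prs[2L, ], stringsAsFactors = FALSE)
    } else {
      expand.grid(a = m1, b = m2, KEEP.OUT.ATTRS = FALSE,
                  stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_cx)) {
    gids <- cx_groups[[i]]
    k <- length(gids)
    for (j1 in seq_len(k)) {
      # paralog pairs inside one group, independent per species
      g1 <- groups[[gids[j1]]]
      if (length(g1$a) > 1L && stats::runif(1) < params@pIntra)
        edges_a[[length(edges_a) + 1L]] <- add_pairs(g1$a, g1$a)
      if (length(g1$b) > 1L && stats::runif(1) < params@pIntra)
        edges_b[[length(edges_b) + 1L]] <- add_pairs(g1$b, g1$b)
      if (j1 == k) next
      for (j2 in (j1 + 1L):k) {
        g2 <- groups[[gids[j2]]]
        in_a <- stats::runif(1) < params@pIntra
        in_b <- if (in_a) {
          stats::runif(1) < params@pConserve || stats::runif(1) < params@pIntra
        } else {
          stats::runif(1) < params@pIntra
        }
        if (in_a) edges_a[[length(edges_a) + 1L]] <- add_pairs(g1$a, g2$a)
        if (in_b) edges_b[[length(edges_b) + 1L]] <- add_pairs(g1$b, g2$b)
      }
    }
  }
  planted_a <- if (length(edges_a)) do.call(rbind, edges_a) else
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  planted_b <- if (length(edges_b)) do.call(rbind, edges_b) else
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)

  # background proteins; some get 1-to-1 ortholog groups
  bg_a <- if (params@nBackgroundA > 0L)
    sprintf("ybg%04d", seq_len(params@nBackgroundA)) else character(0)
  bg_b <- if (params@nBackgroundB > 0L)
    sprintf("hbg%04d", seq_len(params@nBackgroundB)) else character(0)
  n_bg_pair <- min(length(bg_a), length(bg_b))
  if (n_bg_pair > 0L) {
    linked <- stats::runif(n_bg_pair) < params@backgroundOrthologRate
    for (j in which(linked))
      groups[[sprintf("bg_g%04d", j)]] <- list(a = bg_a[j], b = bg_b[j])
  }

  all_a <- c(sprintf("ya%04d", seq_len(pa_count)), bg_a)
  all_b <- c(sprintf("hb%04d", seq_len(pb_count)), bg_b)

  # false negatives: drop planted edges independently per species
  keep_a <- stats::runif(nrow(planted_a)) >= params@edgeLossRate
  keep_b <- stats::runif(nrow(planted_b)) >= params@edgeLossRate
  kept_a <- planted_a[keep_a, , drop = FALSE]
  kept_b <- planted_b[keep_b, , drop = FALSE]

  # false positives: uniform over non-planted pairs (planted = pre-loss)
  noise_a <- .sample_noise_edges(all_a, planted_a,
                                 round(params@noiseMultiplier * nrow(planted_a)))
  noise_b <- .sample_noise_edges(all_b, planted_b,
                                 round(params@noiseMultiplier * nrow(planted_b)))

  ga <- ppiNetwork("speciesA", rbind(kept_a, noise_a), nodes = all_a)
  gb <- ppiNetwork("speciesB", rbind(kept_b, noise_b), nodes = all_b)
  map <- orthologMap("speciesA", "speciesB", groups)
  catalog_a <- complexCatalog("speciesA", cxa)
  catalog_b <- complexCatalog("speciesB", cxb)
  pairs <- data.frame(complex_a = sprintf("cpx_a_%02d", seq_len(n_cx)),
                      complex_b = sprintf("cpx_b_%02d", seq_len(n_cx)),
                      msj = true_msj, stringsAsFactors = FALSE)
  bench <- new("ConservedBenchmark", pairs = pairs, msjThreshold = 0,
               minSize = params@sizeMin)
  new("Scenario", ppiA = ga, ppiB = gb, map = map,
      catalogA = catalog_a, catalogB = catalog_b,
      benchmark = bench, params = params)
}

# sample n distinct unordered pairs over `nodes`, excluding `exclude` pairs,
# by drawing linearized pair indices
.sample_noise_edges <- function(nodes, exclude, n) {
  n <- as.integer(n)
  empty <- data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE)
  if (n <= 0L || length(nodes) < 2L) return(empty)
  npair <- choose(length(nodes), 2L)
  excl_keys <- if (nrow(exclude)) unique(.edge_key(exclude$a, exclude$b))
  else character(0)
  if (n > npair - length(excl_keys)) .stopf("not enough free pairs for noise edges")
  chosen <- character(0)
  out_a <- character(0); out_b <- character(0)
  # rejection sampling; the pair space is much larger than n in practice
  while (length(out_a) < n) {
    need <- n - length(out_a)
    i <- sample.int(length(nodes), 2L * need, replace = TRUE)
    j <- sample.int(length(nodes), 2L * need, replace = TRUE)
    ok <- i != j
    a <- pmin(nodes[i[ok]], nodes[j[ok]])
    b <- pmax(nodes[i[ok]], nodes[j[ok]])
    key <- paste(a, b, sep = "\r")
    fresh <- !(key %in% excl_keys) & !(key %in% chosen) & !duplicated(key)
    take <- which(fresh)[seq_len(min(need, sum(fresh)))]
    out_a <- c(out_a, a[take]); out_b <- c(out_b, b[take])
    chosen <- c(chosen, key[take])
  }
  data.frame(a = out_a, b = out_b, stringsAsFactors = FALSE)
}

#' Break conserved within-complex edge pairs (stress test)
#'
#' Locates the conserved within-complex edge pairs of a scenario -- edges
#' `(p, r)` of species A inside a planted complex whose orthologous
#' counterpart `(q, s)` exists in species B -- and breaks a given fraction
#' of them by removing the edge from exactly one (randomly chosen) species.
#' This degrades interolog density while keeping single-species density,
#' emulating evolutionary dispersion and re-distribution of complex
#' members. Exactly `floor(rewireFraction * n)` of the `n` conserved pairs
#' are broken.
#'
#' @param scenario a [Scenario-class] from [generateScenario()].
#' @param rewireFraction fraction in `[0, 1]` of conserved pairs to break.
#' @param seed integer seed for the selection.
#' @return list with elements `ppiA` and `ppiB`, the modified networks.
#' @export
degradeConservation <- function(scenario, rewireFraction, seed = 1L) {
  stopifnot(is(scenario, "Scenario"))
  if (rewireFraction < 0 || rewireFraction > 1)
    .stopf("rewireFraction must lie in [0, 1]")
  pairs <- .conserved_complex_edge_pairs(scenario)
  n_break <- floor(rewireFraction * nrow(pairs))
  if (n_break == 0L) return(list(ppiA = scenario@ppiA, ppiB = scenario@ppiB))
  .with_seed(seed, {
    sel <- sample.int(nrow(pairs), n_break)
    drop_a <- character(0); drop_b <- character(0)
    for (k in sel) {
      ka <- pairs$key_a[k]; kb <- pairs$key_b[k]
      if (ka %in% drop_a || kb %in% drop_b) next   # already broken
      if (stats::runif(1) < 0.5) drop_a <- c(drop_a, ka)
      else drop_b <- c(drop_b, kb)
    }
    ea <- scenario@ppiA@edges
    eb <- scenario@ppiB@edges
    ea <- ea[!(paste(ea$a, ea$b, sep = "\r") %in% drop_a), , drop = FALSE]
    eb <- eb[!(paste(eb$a, eb$b, sep = "\r") %in% drop_b), , drop = FALSE]
    list(ppiA = ppiNetwork(scenario@ppiA@species, ea, nodes = scenario@ppiA@nodes),
         ppiB = ppiNetwork(scenario@ppiB@species, eb, nodes = scenario@ppiB@nodes))
  })
}

# matched (edge_a, edge_b) pairs: species-A within-complex edges with an
# orthologous counterpart edge present in species B
.conserved_complex_edge_pairs <- function(scenario) {
  th <- thetaPairs(scenario@map)
  orth <- split(th$b, th$a)
  ea <- scenario@ppiA@edges
  eb_keys <- paste(scenario@ppiB@edges$a, scenario@ppiB@edges$b, sep = "\r")
  members_a <- unique(unlist(scenario@catalogA@complexes))
  in_cx <- ea$a %in% members_a & ea$b %in% members_a
  rows <- list()
  for (i in which(in_cx)) {
    qs <- orth[[ea$a[i]]]; ss <- orth[[ea$b[i]]]
    if (is.null(qs) || is.null(ss)) next
    for (q in qs) for (s in ss) {
      if (q == s) next
      kb <- if (q < s) paste(q, s, sep = "\r") else paste(s, q, sep = "\r")
      if (kb %in% eb_keys)
        rows[[length(rows) + 1L]] <- data.frame(
          key_a = paste(ea$a[i], ea$b[i], sep = "\r"), key_b = kb,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out[!duplicated(paste(out$key_a, out$key_b)), , drop = FALSE]
  } else {
    data.frame(key_a = character(0), key_b = character(0),
               stringsAsFactors = FALSE)
  }
}
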
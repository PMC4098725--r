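# conservation scoring (plain and Multi-set Jaccard), gold-standard
# benchmark construction, and precision/recall evaluation of predictions

#' Jaccard overlap between two protein sets
#'
#' `|c n b| / |c u b|` over the distinct members. A predicted complex is
#' considered a correct prediction for a curated complex when this score
#' reaches the match threshold `t` (0.50 by convention).
#'
#' @param c,b character vectors (at least one non-empty).
#' @return a number in `[0, 1]`.
#' @examples
#' jaccardMatch(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
#' @export
jaccardMatch <- function(c, b) {
  c <- unique(as.character(c)); b <- unique(as.character(b))
  if (!length(c) && !length(b)) .stopf("both sets are empty")
  length(intersect(c, b)) / length(union(c, b))
}

# private-group identifiers for ungrouped members; the side prefix keeps
# them disjoint between the two profiles (a shared ungrouped protein name
# never counts as shared: the members come from different species)
.private_ids <- function(profile, tag) {
  u <- profile@ungrouped
  if (!length(u)) character(0) else paste0("..", tag, ".", u, ".", seq_along(u))
}

#' Plain ortholog-group Jaccard between two complexes
#'
#' Jaccard overlap of the two complexes' ortholog-group sets (multiplicity
#' ignored). Members assigned to no group count as unique species-private
#' groups: they enlarge the union without ever being shared, so complexes
#' full of unmapped proteins cannot score as conserved.
#'
#' @param profile1,profile2 [GroupProfile-class] objects built against the
#'   same [OrthologMap-class], for the two species respectively.
#' @param ignoreUngrouped drop ungrouped members instead (default FALSE).
#' @return a number in `[0, 1]`.
#' @export
groupJaccard <- function(profile1, profile2, ignoreUngrouped = FALSE) {
  stopifnot(is(profile1, "GroupProfile"), is(profile2, "GroupProfile"))
  g1 <- names(profile1@multiplicities)
  g2 <- names(profile2@multiplicities)
  if (!ignoreUngrouped) {
    g1 <- c(g1, .private_ids(profile1, "u1"))
    g2 <- c(g2, .private_ids(profile2, "u2"))
  }
  if (!length(g1) && !length(g2)) .stopf("both profiles are empty")
  length(intersect(g1, g2)) / length(union(g1, g2))
}

#' Multi-set Jaccard conservation score between two complexes
#'
#' Conservation score accounting for paralog multiplicity: with `I_1(g)` and
#' `I_2(g)` the multiplicities of ortholog group `g` in the two complexes
#' (0 when absent),
#' \deqn{MSJ = \frac{\sum_g \min(I_1(g), I_2(g))}{\sum_g \max(I_1(g), I_2(g))}}
#' summing over the union of the two group collections. Gene duplication
#' puts several paralogs of one group inside a complex; counting
#' multiplicities makes the estimate more conservative than the plain group
#' Jaccard. Ungrouped members enter as species-private groups with
#' multiplicity equal to their count, contributing to the denominator only.
#'
#' @inheritParams groupJaccard
#' @return a number in `[0, 1]`.
#' @examples
#' m <- orthologMap("y", "h", list())
#' p1 <- new("GroupProfile", complexId = "c1",
#'           multiplicities = c(G1 = 2L, G2 = 1L), ungrouped = character(0))
#' p2 <- new("GroupProfile", complexId = "c2",
#'           multiplicities = c(G1 = 1L, G3 = 1L), ungrouped = character(0))
#' msj(p1, p2)  # 0.25
#' @export
msj <- function(profile1, profile2, ignoreUngrouped = FALSE) {
  stopifnot(is(profile1, "GroupProfile"), is(profile2, "GroupProfile"))
  m1 <- profile1@multiplicities
  m2 <- profile2@multiplicities
  n_u1 <- length(profile1@ungrouped)
  n_u2 <- length(profile2@ungrouped)
  if (ignoreUngrouped) { n_u1 <- 0L; n_u2 <- 0L }
  if (!length(m1) && !length(m2) && n_u1 + n_u2 == 0L)
    .stopf("both profiles are empty")
  gs <- union(names(m1), names(m2))
  i1 <- ifelse(gs %in% names(m1), m1[gs], 0L)
  i2 <- ifelse(gs %in% names(m2), m2[gs], 0L)
  minsum <- sum(pmin(i1, i2))
  maxsum <- sum(pmax(i1, i2)) + n_u1 + n_u2
  if (maxsum == 0) return(0)
  minsum / maxsum
}

#' Build the gold standard of conserved complex pairs
#'
#' Scores every cross-catalog complex pair with the Multi-set Jaccard and
#' keeps the pairs with `MSJ >= msjThreshold` where both complexes have at
#' least `minSize` members -- the benchmark of conserved complexes used to
#' compute conserved-complex recall.
#'
#' @param catalogA,catalogB [ComplexCatalog-class] objects of the map's two
#'   species.
#' @param map an [OrthologMap-class].
#' @param msjThreshold minimum MSJ score (default 0.5).
#' @param minSize minimum complex size on both sides (default 4, i.e.
#'   complexes with more than 3 subunits).
#' @param ignoreUngrouped passed to [msj()].
#' @return a [ConservedBenchmark-class] with deterministic pair ordering.
#' @export
buildConservedBenchmark <- function(catalogA, catalogB, map,
                                    msjThreshold = 0.5, minSize = 4L,
                                    ignoreUngrouped = FALSE) {
  stopifnot(is(catalogA, "ComplexCatalog"), is(catalogB, "ComplexCatalog"),
            is(map, "OrthologMap"))
  minSize <- as.integer(minSize)
  cxa <- catalogA@complexes[lengths(catalogA@complexes) >= minSize]
  cxb <- catalogB@complexes[lengths(catalogB@complexes) >= minSize]
  profA <- lapply(names(cxa), function(id) groupProfile(cxa[[id]], "a", map, id))
  profB <- lapply(names(cxb), function(id) groupProfile(cxb[[id]], "b", map, id))
  rows <- list()
  for (i in seq_along(profA)) {
    for (j in seq_along(profB)) {
      s <- tryCatch(msj(profA[[i]], profB[[j]], ignoreUngrouped),
                    error = function(e) 0)
      if (s >= msjThreshold)
        rows[[length(rows) + 1L]] <- data.frame(
          complex_a = names(cxa)[i], complex_b = names(cxb)[j], msj = s,
          stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
  else data.frame(complex_a = character(0), complex_b = character(0),
                  msj = numeric(0), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$complex_a, pairs$complex_b, method = "radix"), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  new("ConservedBenchmark", pairs = pairs, msjThreshold = msjThreshold,
      minSize = minSize)
}

#' Evaluate predicted complex pairs against catalogs and a gold standard
#'
#' Each prediction is a pair of protein sets, one per species (either side
#' may be empty, e.g. for single-species direct-clustering baselines). A
#' prediction is a *matched prediction* when every non-empty side has
#' Jaccard overlap `>= t` with some complex of its species' catalog; the
#' catalog complexes so matched are the *derived benchmark complexes*. A
#' gold conserved pair `(B_a, B_b)` is *detected* when `B_a` and `B_b` are
#' matched on their respective sides -- by one and the same prediction in
#' `"paired"` mode (the default for interolog-derived predictions, which
#' carry both projections), or by any predictions in `"per_side"` mode
#' (for baselines evaluated per species independently). Precision is the
#' fraction of predictions matched; conserved-complex recall is the
#' fraction of gold pairs detected (denominator: the gold conserved set).
#'
#' @param predictions list of `list(a = <chr>, b = <chr>)` protein-set
#'   pairs.
#' @param catalogA,catalogB curated [ComplexCatalog-class] objects.
#' @param gold a [ConservedBenchmark-class].
#' @param t match threshold in `(0, 1]` (default 0.5).
#' @param mode `"paired"` or `"per_side"` (see above).
#' @return an [EvaluationReport-class]. With no predictions, precision is 0
#'   by convention; with an empty gold set, recall is `NA` with a warning.
#' @export
evaluateComplexes <- function(predictions, catalogA, catalogB, gold,
                              t = 0.5, mode = c("paired", "per_side")) {
  mode <- match.arg(mode)
  stopifnot(is(catalogA, "ComplexCatalog"), is(catalogB, "ComplexCatalog"),
            is(gold, "ConservedBenchmark"))
  if (t <= 0 || t > 1) .stopf("match threshold t must lie in (0, 1]")
  n_pred <- length(predictions)
  cxa <- catalogA@complexes
  cxb <- catalogB@complexes
  matched_rows <- list()
  # per prediction: matched catalog ids on each side
  matches_a <- vector("list", n_pred)
  matches_b <- vector("list", n_pred)
  is_matched <- logical(n_pred)
  for (i in seq_len(n_pred)) {
    pred <- predictions[[i]]
    pa <- unique(as.character(pred$a))
    pb <- unique(as.character(pred$b))
    if (!length(pa) && !length(pb))
      .stopf("prediction %d has both sides empty", i)
    ok_a <- TRUE; ok_b <- TRUE
    if (length(pa)) {
      js <- vapply(cxa, function(m) jaccardMatch(pa, m), numeric(1))
      hit <- which(js >= t)
      matches_a[[i]] <- names(cxa)[hit]
      ok_a <- length(hit) > 0L
      for (h in hit)
        matched_rows[[length(matched_rows) + 1L]] <- data.frame(
          prediction = i, side = "a", benchmark = names(cxa)[h],
          jaccard = js[[h]], stringsAsFactors = FALSE)
    }
    if (length(pb)) {
      js <- vapply(cxb, function(m) jaccardMatch(pb, m), numeric(1))
      hit <- which(js >= t)
      matches_b[[i]] <- names(cxb)[hit]
      ok_b <- length(hit) > 0L
      for (h in hit)
        matched_rows[[length(matched_rows) + 1L]] <- data.frame(
          prediction = i, side = "b", benchmark = names(cxb)[h],
          jaccard = js[[h]], stringsAsFactors = FALSE)
    }
    is_matched[i] <- ok_a && ok_b
  }
  matched <- if (length(matched_rows)) do.call(rbind, matched_rows)
  else data.frame(prediction = integer(0), side = character(0),
                  benchmark = character(0), jaccard = numeric(0),
                  stringsAsFactors = FALSE)
  derived <- if (nrow(matched))
    sort(unique(paste0(matched$side, ":", matched$benchmark)), method = "radix")
  else character(0)

  gp <- gold@pairs
  n_gold <- nrow(gp)
  detected <- logical(n_gold)
  if (n_gold) {
    if (mode == "paired") {
      for (k in seq_len(n_gold)) {
        detected[k] <- any(vapply(seq_len(n_pred), function(i) {
          is_matched[i] &&
            gp$complex_a[k] %in% matches_a[[i]] &&
            gp$complex_b[k] %in% matches_b[[i]]
        }, logical(1)))
      }
    } else {
      all_a <- unique(unlist(matches_a))
      all_b <- unique(unlist(matches_b))
      detected <- gp$complex_a %in% all_a & gp$complex_b %in% all_b
    }
  }
  precision <- if (n_pred == 0L) 0 else sum(is_matched) / n_pred
  if (n_pred == 0L)
    message("evaluateComplexes: no predictions; precision set to 0")
  recall <- if (n_gold == 0L) {
    warning("empty gold benchmark: conserved-complex recall is NA")
    NA_real_
  } else sum(detected) / n_gold
  new("EvaluationReport",
      matched = matched,
      detectedPairs = gp[detected, , drop = FALSE],
      derivedBenchmarks = derived,
      nPredictions = as.integer(n_pred), nMatched = as.integer(sum(is_matched)),
      nGold = as.integer(n_gold), nDetected = as.integer(sum(detected)),
      precision = precision, recallConserved = recall,
      t = t, mode = mode)
}

#' Summarise an evaluation report as a one-row data.frame
#'
#' Columns mirror the usual comparison-table layout: number of predicted
#' complexes, matched predictions, precision, gold conserved pairs, detected
#' conserved pairs, conserved-complex recall.
#'
#' @param report an [EvaluationReport-class].
#' @param method label for the first column.
#' @return a one-row data.frame.
#' @export
reportRow <- function(report, method = "cocin") {
  stopifnot(is(report, "EvaluationReport"))
  data.frame(method = method,
             n_predicted = report@nPredictions,
             n_matched = report@nMatched,
             precision = report@precision,
             n_gold = report@nGold,
             n_detected = report@nDetected,
             recall = report@recallConserved,
             stringsAsFactors = FALSE)
}
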
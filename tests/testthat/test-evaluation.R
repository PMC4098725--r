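# conservation scores, benchmark construction, precision/recall

profile_of <- function(mult, ungrouped = character(0), id = "c") {
  new("GroupProfile", complexId = id,
      multiplicities = setNames(as.integer(mult), names(mult)),
      ungrouped = ungrouped)
}

test_that("jaccardMatch computes |intersection| / |union| on sets", {
  expect_equal(jaccardMatch(c("A", "B", "C"), c("A", "B", "C")), 1)
  expect_equal(jaccardMatch(c("A", "B", "C"), c("D", "E")), 0)
  expect_equal(jaccardMatch(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_true(jaccardMatch(c("A", "B", "C"), c("B", "C", "D")) >= 0.5)
  expect_error(jaccardMatch(character(0), character(0)), "empty")
  # symmetry and the equality criterion
  set.seed(3)
  for (rep in 1:20) {
    x <- sample(LETTERS, sample(1:8, 1))
    y <- sample(LETTERS, sample(1:8, 1))
    expect_equal(jaccardMatch(x, y), jaccardMatch(y, x))
    expect_equal(jaccardMatch(x, y) == 1, setequal(x, y))
  }
})

test_that("group Jaccard ignores multiplicity and counts ungrouped as private", {
  expect_equal(groupJaccard(profile_of(c(G1 = 2, G2 = 1)),
                            profile_of(c(G1 = 5, G2 = 9))), 1)
  expect_equal(groupJaccard(profile_of(c(G1 = 1, G2 = 1)),
                            profile_of(c(G1 = 1, G3 = 1))), 1 / 3)
  # one ungrouped protein on side 1 halves a perfect single-group overlap
  expect_equal(groupJaccard(profile_of(c(G1 = 1), ungrouped = "x"),
                            profile_of(c(G1 = 1))), 1 / 2)
  expect_equal(groupJaccard(profile_of(c(G1 = 1), ungrouped = "x"),
                            profile_of(c(G1 = 1)), ignoreUngrouped = TRUE), 1)
  # the same ungrouped name on both sides is NOT shared (different species)
  expect_equal(groupJaccard(profile_of(c(G1 = 1), ungrouped = "x"),
                            profile_of(c(G1 = 1), ungrouped = "x")), 1 / 3)
  expect_error(groupJaccard(profile_of(integer(0)), profile_of(integer(0))),
               "empty")
})

test_that("MSJ evaluates the min/max multiplicity ratio", {
  expect_equal(msj(profile_of(c(G1 = 2, G2 = 1)),
                   profile_of(c(G1 = 1, G3 = 1))), 0.25)
  expect_equal(msj(profile_of(c(G1 = 3, G2 = 2)),
                   profile_of(c(G1 = 3, G2 = 2))), 1)
  expect_equal(msj(profile_of(c(G1 = 2)), profile_of(c(G2 = 2))), 0)
  # ungrouped members inflate the denominator only
  expect_equal(msj(profile_of(c(G1 = 2), ungrouped = c("x", "y")),
                   profile_of(c(G1 = 2))), 2 / 4)
  expect_equal(msj(profile_of(c(G1 = 2), ungrouped = c("x", "y")),
                   profile_of(c(G1 = 2)), ignoreUngrouped = TRUE), 1)
})

test_that("MSJ properties: symmetry, bounds, identity, monotonicity", {
  set.seed(29)
  for (rep in 1:200) {
    p1 <- random_profile(); p2 <- random_profile()
    s <- msj(p1, p2)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, msj(p2, p1))
    ref <- msj_reference(p1@multiplicities, p2@multiplicities,
                         length(p1@ungrouped), length(p2@ungrouped))
    expect_equal(s, ref)
    # MSJ = 1 iff identical multiset profiles (with no ungrouped members)
    expect_equal(s == 1,
                 identical(p1@multiplicities, p2@multiplicities) &&
                   !length(p1@ungrouped) && !length(p2@ungrouped))
    # raising a min-side multiplicity toward the other side never decreases
    m1 <- p1@multiplicities
    shared <- intersect(names(m1), names(p2@multiplicities))
    low <- shared[m1[shared] < p2@multiplicities[shared]]
    if (length(low)) {
      m1[low[1L]] <- m1[low[1L]] + 1L
      expect_gte(msj(profile_of(m1, p1@ungrouped), p2), s)
    }
  }
})

test_that("profiles computed through an ortholog map feed MSJ correctly", {
  m <- orthologMap("y", "h", list(G1 = list(a = c("p1", "p2"), b = "q1"),
                                  G2 = list(a = "p3", b = c("q2", "q3"))))
  p_a <- groupProfile(c("p1", "p2", "p3"), "a", m, "ca")
  p_b <- groupProfile(c("q1", "q2", "q3"), "b", m, "cb")
  # side a: {G1:2, G2:1}; side b: {G1:1, G2:2} -> 2/4
  expect_equal(msj(p_a, p_b), 0.5)
  expect_equal(groupJaccard(p_a, p_b), 1)
})

test_that("benchmark construction filters by MSJ threshold and complex size", {
  groups <- setNames(lapply(1:7, function(i)
    list(a = sprintf("p%d", i), b = sprintf("q%d", i))), sprintf("G%d", 1:7))
  m <- orthologMap("y", "h", groups)
  ca <- complexCatalog("y", list(
    c_perfect = sprintf("p%d", 1:4),
    c_extra = sprintf("p%d", 1:4),
    c_weak = sprintf("p%d", 1:7),
    c_small = sprintf("p%d", 1:3)))
  cb <- complexCatalog("h", list(
    d_perfect = sprintf("q%d", 1:4),
    d_weak = c("q1", "x1", "x2", "x3", "x4", "x5", "x6")))
  gold <- buildConservedBenchmark(ca, cb, m, msjThreshold = 0.5, minSize = 4)
  p <- benchmarkPairs(gold)
  # perfect 4-group 1-1 pair scores 1; c_small is size-filtered out
  expect_true(any(p$complex_a == "c_perfect" & p$complex_b == "d_perfect" &
                  p$msj == 1))
  expect_false(any(p$complex_a == "c_small"))
  # sharing 1 of 7 groups scores 1/7 < 0.5 -> excluded
  expect_false(any(p$complex_a == "c_weak" & p$complex_b == "d_weak"))
  # two extra unmapped proteins: 4/6 >= 0.5 -> kept
  ca2 <- complexCatalog("y", list(cx = c(sprintf("p%d", 1:4), "z1", "z2")))
  gold2 <- buildConservedBenchmark(ca2, cb, m)
  expect_equal(benchmarkPairs(gold2)$msj, 4 / 6)
  # threshold 0 keeps all size-filtered pairs; threshold > 1 keeps none
  expect_equal(nrow(benchmarkPairs(
    buildConservedBenchmark(ca, cb, m, msjThreshold = 0))), 6L)
  expect_equal(nrow(benchmarkPairs(
    buildConservedBenchmark(ca, cb, m, msjThreshold = 1.01))), 0L)
})

make_gold <- function(pairs_df) {
  new("ConservedBenchmark", pairs = pairs_df, msjThreshold = 0, minSize = 4L)
}

test_that("evaluation computes precision and conserved-complex recall", {
  ca <- complexCatalog("y", list(A1 = c("p1", "p2", "p3", "p4"),
                                 A2 = c("p5", "p6", "p7", "p8")))
  cb <- complexCatalog("h", list(B1 = c("q1", "q2", "q3", "q4"),
                                 B2 = c("q5", "q6", "q7", "q8")))
  gold <- make_gold(data.frame(complex_a = c("A1", "A2"),
                               complex_b = c("B1", "B2"), msj = 1,
                               stringsAsFactors = FALSE))
  # predictions identical to the gold complexes: perfect scores
  preds <- list(list(a = complexes(ca)$A1, b = complexes(cb)$B1),
                list(a = complexes(ca)$A2, b = complexes(cb)$B2))
  rep1 <- evaluateComplexes(preds, ca, cb, gold)
  expect_equal(rep1@precision, 1)
  expect_equal(rep1@recallConserved, 1)
  # no predictions: zeros by convention
  rep0 <- suppressMessages(evaluateComplexes(list(), ca, cb, gold))
  expect_equal(rep0@precision, 0)
  expect_equal(rep0@recallConserved, 0)
  # one J=0.5 match on both sides, one prediction matching nothing
  preds2 <- list(list(a = c("p1", "p2", "x1", "x2"),    # J = 2/6... not a match
                      b = c("q1", "q2", "q3", "q4")),
                 list(a = c("z1", "z2"), b = c("w1", "w2")))
  # make side a a J = 0.5 match: 3 shared of 4+3-3
  preds2[[1]]$a <- c("p1", "p2", "p3", "x1")            # J = 3/5... still < .5
  preds2[[1]]$a <- c("p1", "p2", "p3", "p4", "x1", "x2", "x3", "x4")  # J = 4/8
  rep2 <- evaluateComplexes(preds2, ca, cb, gold)
  expect_equal(rep2@precision, 0.5)
  expect_equal(rep2@recallConserved, 0.5)
  expect_equal(rep2@nDetected, 1L)
  # empty gold set: recall NA with warning
  expect_warning(
    rep3 <- evaluateComplexes(preds, ca, cb, make_gold(
      data.frame(complex_a = character(0), complex_b = character(0),
                 msj = numeric(0), stringsAsFactors = FALSE))),
    "empty gold")
  expect_true(is.na(rep3@recallConserved))
  expect_error(evaluateComplexes(preds, ca, cb, gold, t = 0), "threshold")
})

test_that("paired mode needs one prediction to match both sides; per_side does not", {
  ca <- complexCatalog("y", list(A1 = c("p1", "p2", "p3", "p4")))
  cb <- complexCatalog("h", list(B1 = c("q1", "q2", "q3", "q4")))
  gold <- make_gold(data.frame(complex_a = "A1", complex_b = "B1", msj = 1,
                               stringsAsFactors = FALSE))
  one_sided <- list(list(a = complexes(ca)$A1, b = character(0)),
                    list(a = character(0), b = complexes(cb)$B1))
  expect_equal(evaluateComplexes(one_sided, ca, cb, gold,
                                 mode = "per_side")@recallConserved, 1)
  expect_equal(evaluateComplexes(one_sided, ca, cb, gold,
                                 mode = "paired")@recallConserved, 0)
  expect_equal(evaluateComplexes(one_sided, ca, cb, gold,
                                 mode = "per_side")@precision, 1)
})

test_that("raising the match threshold never increases precision or recall", {
  set.seed(83)
  for (rep in 1:10) {
    ca <- complexCatalog("y", setNames(
      lapply(1:5, function(i) sample(sprintf("p%02d", 1:25), sample(4:8, 1))),
      sprintf("A%d", 1:5)))
    cb <- complexCatalog("h", setNames(
      lapply(1:5, function(i) sample(sprintf("q%02d", 1:25), sample(4:8, 1))),
      sprintf("B%d", 1:5)))
    gold <- make_gold(data.frame(complex_a = sprintf("A%d", 1:5),
                                 complex_b = sprintf("B%d", 1:5), msj = 1,
                                 stringsAsFactors = FALSE))
    preds <- lapply(1:6, function(i)
      list(a = sample(sprintf("p%02d", 1:25), sample(3:8, 1)),
           b = sample(sprintf("q%02d", 1:25), sample(3:8, 1))))
    ts <- c(0.2, 0.4, 0.6, 0.8)
    reps <- lapply(ts, function(t)
      evaluateComplexes(preds, ca, cb, gold, t = t))
    prec <- vapply(reps, function(r) r@precision, numeric(1))
    rec <- vapply(reps, function(r) r@recallConserved, numeric(1))
    expect_true(all(diff(prec) <= 1e-12))
    expect_true(all(diff(rec) <= 1e-12))
  }
})
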
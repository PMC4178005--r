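## Profiles with hand-controlled class counts for fraction arithmetic.
fractionProfile <- function(gene, interphase, total, seed = 1) {
  classes <- cellClasses()
  rest <- total - interphase
  cc <- matrix(
    c(interphase, rest, 0L, 0L), 1L,
    dimnames = list("1", classes)
  )
  set.seed(seed)
  f <- matrix(rnorm(total * 2), total, 2, dimnames = list(NULL, c("f1", "intensity")))
  new("KnockdownProfile",
    gene = gene, features = f, timePoint = rep(1L, total),
    classLabel = rep(classes[1:2], c(interphase, rest)),
    classCounts = cc,
    intensityMedian = median(f[, "intensity"]), intensitySd = sd(f[, "intensity"])
  )
}

test_that("fraction features are absolute per-feature differences", {
  a <- fractionProfile("a", 50L, 100L, seed = 1)
  b <- fractionProfile("b", 30L, 100L, seed = 2)
  d <- fractionFeatures(a, b)
  expect_equal(unname(d["frac.interphase"]), 0.2)
  expect_equal(unname(d["n.cells"]), 0)
  ## identity and symmetry
  expect_true(all(fractionFeatures(a, a) == 0))
  expect_identical(fractionFeatures(a, b), fractionFeatures(b, a))
})

test_that("maxima profiles score the peak knockdown-control difference", {
  classes <- cellClasses()
  tps <- 1:50
  ctrl <- matrix(5L, length(tps), length(classes),
    dimnames = list(tps, classes)
  )
  ## identical series: all scores 0 at the first time point
  mp0 <- computeMaximaProfile(ctrl, ctrl)
  expect_true(all(maximaScores(mp0) == 0))
  expect_true(all(peakTimes(mp0) == 1))

  ## a +40 spike in mitosis at t = 30
  kd <- ctrl
  kd["30", "mitosis"] <- 45L
  mp <- computeMaximaProfile(kd, ctrl)
  expect_equal(unname(maximaScores(mp)["mitotic_delay"]), 40)
  expect_equal(unname(peakTimes(mp)["mitotic_delay"]), 30)

  ## equal maxima at t = 10 and t = 20: the earlier one wins
  kd2 <- ctrl
  kd2[c("10", "20"), "apoptosis"] <- 9L
  mp2 <- computeMaximaProfile(kd2, ctrl)
  expect_equal(unname(peakTimes(mp2)["cell_death"]), 10)

  expect_error(
    computeMaximaProfile(ctrl[1:10, ], ctrl),
    "share the time axis"
  )
})

test_that("LDA performance is near chance for one distribution, high for separated ones", {
  null1 <- gaussianCells(rep(0, 6), cellsPerTp = 10, tps = 1:20, seed = 51)
  null2 <- gaussianCells(rep(0, 6), cellsPerTp = 10, tps = 1:20, seed = 52)
  accNull <- accuracy(ldaPerformance(null1, null2, seed = 1))
  expect_lt(abs(accNull - 0.5), 0.1)

  far <- gaussianCells(c(10, rep(0, 5)), cellsPerTp = 10, tps = 1:20, seed = 53)
  expect_gte(accuracy(ldaPerformance(null1, far, seed = 1)), 0.95)
})

test_that("LDA performance is symmetric in its inputs and in the class labels", {
  a <- gaussianCells(rep(0, 4), cellsPerTp = 8, tps = 1:15, seed = 61)
  b <- gaussianCells(c(1.5, 0, 0, 0), cellsPerTp = 8, tps = 1:15, seed = 62)
  r1 <- ldaPerformance(a, b, seed = 5)
  r2 <- ldaPerformance(b, a, seed = 5)
  ## swapping inputs swaps the confusion roles but not the accuracy
  expect_equal(accuracy(r1), accuracy(r2))
  expect_equal(r1@tp, r2@tn)
  expect_equal(r1@fp, r2@fn)
  ## accuracy identity
  expect_equal(
    accuracy(r1),
    (r1@tp + r1@tn) / (r1@tp + r1@tn + r1@fp + r1@fn)
  )
  ## too few cells is an explicit error
  tiny <- gaussianCells(rep(0, 3), cellsPerTp = 2, tps = 1:3, seed = 63)
  expect_error(ldaPerformance(tiny, tiny, seed = 1), "fewer than 5 cells")
})

test_that("time filtering keeps only the trailing window", {
  ## signal exists only in early time points; restricting to the last
  ## 10 of 30 time points must hide it
  early <- gaussianCells(rep(0, 3), cellsPerTp = 8, tps = 1:30, seed = 71)
  late <- gaussianCells(rep(0, 3), cellsPerTp = 8, tps = 1:30, seed = 72)
  late[late$time_point <= 20, -1] <- late[late$time_point <= 20, -1] + 8
  accWindow <- accuracy(ldaPerformance(early, late, lastNTimepoints = 10, seed = 2))
  expect_lt(abs(accWindow - 0.5), 0.12)
  accAll <- accuracy(ldaPerformance(early, late, lastNTimepoints = 30, seed = 2))
  expect_gt(accAll, 0.7)
})

test_that("discriminative feature selection ranks the informative feature first", {
  ## gene centroids differ only in feature 1
  set.seed(81)
  profs <- lapply(sprintf("g%02d", 1:12), function(g) {
    centroid <- c(rnorm(1, sd = 4), rep(0, 5))
    makeProfile(g, as.matrix(gaussianCells(centroid,
      cellsPerTp = 6,
      tps = 1:10, seed = sum(utf8ToInt(g))
    )[, -1]), rep(1:10, each = 6))
  })
  names(profs) <- sprintf("g%02d", 1:12)
  sel <- selectDiscriminativeFeatures(profs, nPairs = 40, k = 3, seed = 1)
  expect_equal(sel[1], "f01")
  ## whole-registry request returns the registry, ordered
  all6 <- selectDiscriminativeFeatures(profs, nPairs = 10, k = 6, seed = 1)
  expect_setequal(all6, sprintf("f%02d", 1:6))
  expect_error(
    selectDiscriminativeFeatures(profs, nPairs = 10, k = 7),
    "registry size"
  )
  ## stability: two seeds agree on the ranking of a clear signal
  selB <- selectDiscriminativeFeatures(profs, nPairs = 40, k = 3, seed = 99)
  expect_equal(selB[1], "f01")
})

test_that("the inhibiting-vs-activating LDA gap grows with the effect size", {
  gap <- vapply(c(0, 2, 4, 6), function(delta) {
    fx <- makeScreen(delta, seed = 33, nGenes = 16, nAct = 4, nInh = 4)
    e <- edgeTable(fx$network)
    acc <- vapply(seq_len(nrow(e)), function(i) {
      accuracy(ldaPerformance(
        profiles(fx$screen)[[e$geneA[i]]],
        profiles(fx$screen)[[e$geneB[i]]],
        seed = 13
      ))
    }, numeric(1))
    mean(acc[e$effect == "inhibiting"]) - mean(acc[e$effect == "activating"])
  }, numeric(1))
  ## nondecreasing up to Monte-Carlo noise, and clearly ordered overall
  expect_true(all(diff(gap) > -0.05))
  expect_lt(abs(gap[1]), 0.1)
  expect_gt(gap[4], 0.3)
})

test_that("proximity features are reference-wise absolute differences", {
  fx <- fixture("screen_prox", makeScreen(4, seed = 31, nGenes = 10, nAct = 2, nInh = 2))
  scr <- fx$screen
  genes <- geneNames(scr)
  cfg <- pairConfig(nRef = 2, seed = 3)
  ## identity: a pair of one gene with itself gives all zeros
  pz <- proximityFeatures(genes[1], genes[1], genes[3:4], scr, cfg)
  expect_true(all(pz == 0))
  ## symmetry under pair swap
  p1 <- proximityFeatures(genes[1], genes[2], genes[3:4], scr, cfg)
  p2 <- proximityFeatures(genes[2], genes[1], genes[3:4], scr, cfg)
  expect_equal(p1, p2)
  expect_length(p1, 4L)
  ## reference overlapping the pair is an error
  expect_error(
    proximityFeatures(genes[1], genes[2], genes[2], scr, cfg),
    "disjoint"
  )
})

test_that("maxima-distance proximity entries reduce to |d(A,r) - d(B,r)|", {
  mk <- function(g, score) {
    new("MaximaProfile",
      gene = g,
      scores = setNames(c(score, rep(0, 6)), names(defaultPhenotypeMap())),
      peakTimes = setNames(rep(1, 7), names(defaultPhenotypeMap()))
    )
  }
  ## d(A, r) = 3, d(B, r) = 7 -> proximity entry 4
  expect_equal(maximaDistance(mk("a", 3), mk("r", 0)), 3)
  expect_equal(maximaDistance(mk("b", 7), mk("r", 0)), 7)
  expect_equal(
    abs(maximaDistance(mk("a", 3), mk("r", 0)) -
      maximaDistance(mk("b", 7), mk("r", 0))),
    4
  )
})

test_that("pair descriptors are symmetric, complete and null-calibrated", {
  fx <- fixture("screen_prox", makeScreen(4, seed = 31, nGenes = 10, nAct = 2, nInh = 2))
  scr <- fx$screen
  genes <- geneNames(scr)
  refs <- genes[5:6]
  cfg <- pairConfig(nRef = 2, seed = 11)
  d1 <- assemblePairDescriptor(genes[1], genes[2], scr, refs, cfg)
  d2 <- assemblePairDescriptor(genes[2], genes[1], scr, refs, cfg)
  expect_identical(d1, d2)
  ## length: 7 fraction + 14 maxima + 1 lda + 2 per reference
  expect_length(d1, 7L + 14L + 1L + 2L * 2L)
  expect_true(all(is.finite(d1)))
  ## a gene against itself: all differences zero, LDA near chance
  dSelf <- assemblePairDescriptor(genes[7], genes[7], scr, refs, cfg)
  diffs <- dSelf[setdiff(names(dSelf), "lda.accuracy")]
  expect_true(all(diffs == 0))
  expect_lt(abs(dSelf[["lda.accuracy"]] - 0.5), 0.15)
  ## unknown gene names the pair in the error
  expect_error(
    assemblePairDescriptor("nope", genes[1], scr, refs, cfg),
    "nope"
  )
})
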
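smallConfig <- function(seed = 1, ...) {
  trainingConfig(
    nRepeats = 1, nFolds = 4, svmsPerFold = 2, stratumSize = 20,
    innerFolds = 3, gridExp = c(-5L, 0L, 5L), seed = seed, ...
  )
}

test_that("ensemble bookkeeping: size, stratification, determinism", {
  fx <- fixture("desc_sep", makeDescriptors(nPerClass = 40, sep = 6, seed = 2))
  cfg <- smallConfig(seed = 3)
  fit <- fixture("fit_sep", stratifiedCvTrain(fx$pairs, fx$descriptors, cfg))
  expect_equal(ensembleSize(fit$ensemble), 1L * 4L * 2L)
  ## every member trained on exactly stratumSize pairs of each class
  actKeys <- pairKeys(fx$pairs[fx$pairs$effect == "activating", ])
  for (m in fit$ensemble@models) {
    expect_length(m$trainKeys, 2L * 20L)
    expect_equal(sum(m$trainKeys %in% actKeys), 20L)
  }
  ## votes are complete and bounded
  v <- voteTable(fit$votes)
  expect_equal(nrow(v), nrow(fx$pairs))
  expect_true(all(v$votesTotal == 1L * 2L))
  ## fixed seed reruns reproduce the votes exactly
  fit2 <- stratifiedCvTrain(fx$pairs, fx$descriptors, cfg)
  expect_identical(voteTable(fit2$votes), v)
})

test_that("separable descriptors yield extreme held-out votes", {
  fx <- fixture("desc_sep", makeDescriptors(nPerClass = 40, sep = 6, seed = 2))
  fit <- fixture(
    "fit_sep",
    stratifiedCvTrain(fx$pairs, fx$descriptors, smallConfig(seed = 3))
  )
  v <- voteTable(fit$votes)
  expect_gt(median(v$voteFraction[v$label == "activating"]), 0.9)
  expect_lt(median(v$voteFraction[v$label == "inhibiting"]), 0.1)
  expect_gte(auc(rocAuc(fit$votes)), 0.95)
})

test_that("shuffled labels drive cross-validated AUC to chance", {
  fx <- makeDescriptors(nPerClass = 40, sep = 6, seed = 4)
  pairsNull <- fx$pairs
  set.seed(17)
  pairsNull$effect <- sample(pairsNull$effect)
  fit <- stratifiedCvTrain(pairsNull, fx$descriptors, smallConfig(seed = 5))
  expect_lt(abs(auc(rocAuc(fit$votes)) - 0.5), 0.12)
})

test_that("training rejects degenerate inputs", {
  fx <- makeDescriptors(nPerClass = 30, sep = 2, seed = 6)
  oneClass <- fx$pairs
  oneClass$effect <- "activating"
  expect_error(stratifiedCvTrain(oneClass, fx$descriptors, smallConfig()), "both classes")
  ## too few pairs per class for the stratum size
  expect_error(
    stratifiedCvTrain(fx$pairs[c(1:10, 31:40), ], fx$descriptors, smallConfig()),
    "not available"
  )
  expect_error(
    stratifiedCvTrain(fx$pairs, fx$descriptors[1:5, ], smallConfig()),
    "missing"
  )
})

test_that("ROC sweep matches an independent AUC implementation", {
  set.seed(23)
  n <- 80
  v <- data.frame(
    geneA = sprintf("a%02d", 1:n), geneB = sprintf("b%02d", 1:n),
    votesActivation = sample(0:10, n, replace = TRUE), votesTotal = 10
  )
  v$voteFraction <- v$votesActivation / v$votesTotal
  v$label <- ifelse(runif(n) < plogis(3 * (v$voteFraction - 0.5)),
    "activating", "inhibiting"
  )
  if (length(unique(v$label)) < 2) v$label[1:2] <- c("activating", "inhibiting")
  rep <- rocAuc(v)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = v$label, predictor = v$voteFraction,
    levels = c("inhibiting", "activating"), direction = "<"
  )))
  expect_equal(auc(rep), as.numeric(ref), tolerance = 1e-9)
})

test_that("ROC extremes and activation/inhibition symmetry", {
  v <- data.frame(
    geneA = letters[1:6], geneB = LETTERS[1:6],
    votesActivation = c(10L, 10L, 10L, 0L, 0L, 0L), votesTotal = 10L,
    voteFraction = c(1, 1, 1, 0, 0, 0),
    label = rep(c("activating", "inhibiting"), each = 3)
  )
  expect_equal(auc(rocAuc(v)), 1.0)
  ## votes carrying no information stay near 0.5 (permutation oracle)
  set.seed(41)
  vr <- v
  vr$votesActivation <- sample(0:10, 6, replace = TRUE)
  vr$voteFraction <- vr$votesActivation / 10
  aucs <- replicate(200, {
    vp <- vr
    vp$label <- sample(vp$label)
    auc(rocAuc(vp))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  ## AUC for activation equals AUC for inhibition on reversed votes
  expect_equal(
    auc(rocAuc(v, positiveClass = "activating")),
    auc(rocAuc(v, positiveClass = "inhibiting"))
  )
  vOne <- v
  vOne$label <- "activating"
  expect_error(rocAuc(vOne), "both classes")
})

test_that("calibration finds the precision-constrained cutoffs", {
  ## perfectly separating votes: at a strict target the activation
  ## cutoff is the smallest vote fraction observed on a positive pair,
  ## the inhibition cutoff the largest observed on a negative pair
  v <- data.frame(
    geneA = letters[1:8], geneB = LETTERS[1:8],
    votesActivation = c(9L, 8L, 5L, 4L, 3L, 2L, 1L, 0L), votesTotal = 10L,
    voteFraction = c(9, 8, 5, 4, 3, 2, 1, 0) / 10,
    label = rep(c("activating", "inhibiting"), c(2, 6))
  )
  cal <- calibrateThresholds(v, targetPrecision = 0.9)
  expect_equal(actCutoff(cal), 0.8)
  expect_equal(inhCutoff(cal), 0.5)
  ## degenerate target: cutoffs at the extreme observed fractions
  cal0 <- calibrateThresholds(v, targetPrecision = 0)
  expect_equal(actCutoff(cal0), 0)
  expect_equal(inhCutoff(cal0), 0.9)
  ## unreachable target is flagged, not invented
  vBad <- v
  vBad$label <- rev(v$label)
  calBad <- calibrateThresholds(vBad, targetPrecision = 0.99)
  expect_true(is.na(actCutoff(calBad)))
  expect_false(any(calBad@table$reachesTargetAct))
})

test_that("undefined pairs get calls from calibrated cutoffs", {
  fx <- fixture("desc_sep", makeDescriptors(nPerClass = 40, sep = 6, seed = 2))
  fit <- fixture(
    "fit_sep",
    stratifiedCvTrain(fx$pairs, fx$descriptors, smallConfig(seed = 3))
  )
  cal <- calibrateThresholds(fit$votes, targetPrecision = 0.8)
  ## score fresh pairs drawn from the two descriptor populations
  new <- makeDescriptors(nPerClass = 15, sep = 6, seed = 77)
  pred <- predictUndefined(fit$ensemble, new$pairs, new$descriptors, cal)
  pv <- voteTable(pred)
  expect_equal(nrow(pv), 30L)
  expect_true(all(pv$call %in% c("activating", "inhibiting", "none")))
  ## strong-majority calls match the planted classes
  confident <- pv$call != "none"
  expect_gt(mean(confident), 0.5)
  expect_gte(
    mean(pv$call[confident] == new$pairs$effect[confident]), 0.9
  )
  ## a pair without a descriptor row is skipped with a message
  extra <- rbind(new$pairs, data.frame(
    geneA = "zz1", geneB = "zz2",
    effect = "undefined"
  ))
  expect_message(
    predictUndefined(fit$ensemble, extra, new$descriptors, cal),
    "skipping 1 pair"
  )
})

test_that("cutoff application and multi-pathway vote averaging arithmetic", {
  cal <- new("ConfidenceCalibration",
    table = data.frame(), actCutoff = 0.92, inhCutoff = 0.088,
    targetPrecision = 0.8
  )
  expect_equal(
    ppisign:::applyCutoffs(c(1, 0.95, 0.5, 0.05, 0.92, 0.088), cal),
    c("activating", "activating", "none", "inhibiting", "activating", "inhibiting")
  )
  ## two pathway models voting 900 and 940 of 1000 average to 920
  expect_equal(ppisign:::averageVoteFractions(c(0.90, 0.94)), 0.92)
})

test_that("sign-score baseline reproduces hand-computed correlation counts", {
  ## z-scores: two values of 20 among six zeros give z = 1.62 for the
  ## extremes; a +20/-20 pair gives z = +/-1.87 -- both past +/-1.5
  feat <- rbind(
    gA = c(20, 20, 0, 0), gB = c(20, 20, 0, 0),
    gC = c(0, 0, 20, 20), gD = c(0, 0, -20, -20),
    gE = c(0, 0, 0, 0), gF = c(0, 0, 0, 0),
    gG = c(0, 0, 0, 0), gH = c(0, 0, 0, 0)
  )
  colnames(feat) <- c("f1", "f2", "f3", "f4")
  pairs <- data.frame(
    geneA = c("gA", "gC", "gE"),
    geneB = c("gB", "gD", "gF"),
    stringsAsFactors = FALSE
  )
  gold <- c("activating", "inhibiting", "activating")
  res <- signScoreBaseline(feat, pairs, gold, zCutoff = 1.5, minMatching = 2)
  sc <- res$scores
  ## gA-gB: both +1 on f1 and f2 -> 2 positive correlations, activating
  expect_equal(sc$nPos[1], 2L)
  expect_equal(sc$prediction[1], "activating")
  ## gC-gD: opposite signs on f1 and f2 -> 2 negative, inhibiting
  expect_equal(sc$nNeg[2], 2L)
  expect_equal(sc$prediction[2], "inhibiting")
  ## gE-gF: no matched features -> dropped by the filter
  expect_false(sc$kept[3])
  expect_equal(res$nSelected, 2L)
  ## precision: 1 correct activating call of 1; recall 1 of 2 activating
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 0.5)

  ## the pair-level LDA feature enters as a correlation call
  lda <- setNames(c(0.95, 0.5, 0.5), pairKeys(pairs))
  res2 <- signScoreBaseline(feat, pairs, gold,
    pairLda = lda, zCutoff = 1.1,
    minMatching = 2
  )
  expect_equal(res2$scores$nNeg[1], 1L) # high accuracy reads as dissimilar

  ## a zero-variance feature is skipped with a message
  featZ <- cbind(feat, fz = 1)
  expect_message(
    signScoreBaseline(featZ, pairs, gold, minMatching = 2),
    "zero-variance"
  )
  ## below the matching filter nothing is evaluated
  res3 <- signScoreBaseline(feat, pairs[3, ], gold[3], minMatching = 2)
  expect_equal(res3$nSelected, 0L)
})
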
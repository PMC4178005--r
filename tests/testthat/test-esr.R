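test_that("effect concordance classifies call pairs", {
  calls <- c(ppisign:::pairKey("i", "k"), ppisign:::pairKey("j", "k"))
  mk <- function(ci, cj) {
    setNames(c(ci, cj), c(ppisign:::pairKey("i", "k"), ppisign:::pairKey("j", "k")))
  }
  expect_equal(effectConcordance("i", "j", "k", mk("activating", "activating")), "similar")
  expect_equal(effectConcordance("i", "j", "k", mk("inhibiting", "inhibiting")), "similar")
  expect_equal(effectConcordance("i", "j", "k", mk("activating", "inhibiting")), "dissimilar")
  expect_equal(effectConcordance("i", "j", "k", mk("activating", "none")), "neither")
  ## a missing call reads as none
  expect_equal(effectConcordance("i", "j", "k", mk("activating", "activating")[1]), "neither")
  expect_error(effectConcordance("i", "j", "i", mk("activating", "activating")), "differ")
})

test_that("ESR closed forms and monotonicity in the concordance difference", {
  thirds <- sprintf("t%02d", 1:12)
  universe <- c("i", "j", thirds)
  ## build calls giving nS similar and nD dissimilar thirds
  mkCalls <- function(nS, nD) {
    calls <- character(0)
    for (idx in seq_along(thirds)) {
      k <- thirds[idx]
      if (idx <= nS) {
        calls[ppisign:::pairKey("i", k)] <- "activating"
        calls[ppisign:::pairKey("j", k)] <- "activating"
      } else if (idx <= nS + nD) {
        calls[ppisign:::pairKey("i", k)] <- "activating"
        calls[ppisign:::pairKey("j", k)] <- "inhibiting"
      } else {
        calls[ppisign:::pairKey("i", k)] <- "none"
        calls[ppisign:::pairKey("j", k)] <- "none"
      }
    }
    calls
  }
  ## X = 0 -> ESR = 0 (balanced concordance)
  expect_equal(computeEsr("i", "j", universe, mkCalls(4, 4)), 0)
  ## X = 1 -> tanh(5); X = -1 -> -tanh(5) (odd symmetry)
  expect_equal(computeEsr("i", "j", universe, mkCalls(12, 0)), tanh(5))
  expect_equal(computeEsr("i", "j", universe, mkCalls(0, 12)), -tanh(5))
  expect_equal(tanh(5), 0.999909, tolerance = 1e-6)
  ## strictly increasing in X over the nS grid
  esrs <- vapply(0:12, function(nS) {
    computeEsr("i", "j", universe, mkCalls(nS, 12 - nS))
  }, numeric(1))
  expect_true(all(diff(esrs) > 0))
  ## confident-only denominator rescales X
  expect_equal(
    computeEsr("i", "j", universe, mkCalls(4, 0), denominator = "confident"),
    tanh(5)
  )
  expect_equal(
    computeEsr("i", "j", universe, mkCalls(4, 0), denominator = "all"),
    tanh(5 * 4 / 12)
  )
  expect_error(computeEsr("i", "j", c("i", "j"), mkCalls(1, 0)), "third")
})

test_that("ESR matrices are symmetric, bounded and uniform for identical callers", {
  genes <- sprintf("g%d", 1:5)
  thirds <- sprintf("t%d", 1:8)
  calls <- character(0)
  for (g in genes) {
    for (k in thirds[1:6]) calls[ppisign:::pairKey(g, k)] <- "activating"
    for (k in thirds[7:8]) calls[ppisign:::pairKey(g, k)] <- "none"
  }
  m <- esrMatrix(c(genes, thirds), calls)
  v <- esrValues(m)
  expect_identical(v, t(v))
  expect_true(all(is.na(diag(v))))
  off <- v[row(v) != col(v)]
  expect_true(all(off >= -1 & off <= 1))
  ## genes with identical call vectors all share one ESR value
  within <- v[genes, genes]
  within <- within[row(within) != col(within)]
  expect_equal(unique(round(within, 12)), round(tanh(5 * 6 / 11), 12))
  expect_error(esrMatrix(genes[1:2], calls), "3 genes")
})

test_that("planted concordance blocks are recovered; randomized calls are not", {
  blockA <- sprintf("a%d", 1:5)
  blockB <- sprintf("b%d", 1:5)
  thirds <- sprintf("t%02d", 1:12)
  calls <- plantedBlockCalls(blockA, blockB, thirds)
  universe <- c(blockA, blockB, thirds)
  m <- esrMatrix(c(blockA, blockB), calls, universe = universe)
  cl <- clusterEsr(m)
  cut <- cutEsrClusters(cl, 2)
  planted <- rep(1:2, each = 5)
  expect_equal(adjustedRand(cut, planted), 1)
  ## distances live in [0, 1]
  expect_true(all(cl$distance >= 0 & cl$distance <= 1))

  ## randomizing the calls destroys the block structure
  set.seed(55)
  ari <- replicate(20, {
    rnd <- setNames(sample(calls), names(calls))
    cutR <- cutEsrClusters(
      clusterEsr(esrMatrix(c(blockA, blockB), rnd, universe = universe)), 2
    )
    adjustedRand(cutR, planted)
  })
  expect_lt(abs(mean(ari)), 0.25)

  ## incomplete matrices are refused with the missing pairs listed
  bad <- esrValues(m)
  bad["a1", "b2"] <- bad["b2", "a1"] <- NA
  expect_error(clusterEsr(new("ESRMatrix", values = bad)), "a1-b2")
})

test_that("subset ESR comparison: power on separated blocks, calibrated nulls", {
  blockA <- sprintf("a%d", 1:5)
  blockB <- sprintf("b%d", 1:5)
  thirds <- sprintf("t%02d", 1:12)
  m <- esrMatrix(
    c(blockA, blockB),
    plantedBlockCalls(blockA, blockB, thirds),
    universe = c(blockA, blockB, thirds)
  )
  ## within-A ESRs are ~1, within-B ~1 but between-pairs ~ -1
  cmp <- compareEsrSubsets(m, blockA, blockB, mode = "within-between")
  expect_lt(cmp$p.value, 0.01)
  ## exact rank-sum oracle for complete separation of 10 vs 25:
  ## p = 1 / choose(35, 10) under full enumeration, far below 0.01
  expect_lt(1 / choose(35, 10), 0.01)
  expect_error(compareEsrSubsets(m, blockA, c(blockA[1], blockB)), "disjoint")
  expect_error(compareEsrSubsets(m, blockA, blockB[1]), "at least 2")

  ## type-I calibration: iid scores reject at ~ the nominal rate
  set.seed(71)
  pvals <- replicate(500, {
    v <- matrix(NA_real_, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
    sc <- runif(28, -1, 1)
    v[upper.tri(v)] <- sc
    v <- pmax(v, t(v), na.rm = TRUE)
    diag(v) <- NA
    mm <- new("ESRMatrix", values = v)
    compareEsrSubsets(mm, letters[1:4], letters[5:8])$p.value
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
})
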
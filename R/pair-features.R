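## Pairwise phenotype descriptors.
##
## Four feature families describe a gene pair: absolute differences of
## morphological-class fractions and global summaries (fraction
## features), absolute differences of phenotype-maxima scores and peak
## times against the negative control (maxima features), the held-out
## accuracy of a linear discriminant separating the two knockdowns
## (LDA-performance feature), and differences of each member's
## similarity to a common reference gene set (proximity features).

#' Pair feature configuration
#'
#' @param trainFrac Fraction of time points used to train each pairwise
#'   discriminant (the remainder is the held-out test portion).
#' @param lastNTimepoints Only the last n time points of the course are
#'   used, where the knockdown phenotype is expressed.
#' @param nRef Number of reference genes for the proximity features.
#' @param features Optional character vector restricting the cell
#'   features used by the discriminants (e.g. the output of
#'   \code{\link{selectDiscriminativeFeatures}}); NULL uses all.
#' @param seed Integer seed for the train/test splits.
#' @return A list of class `pairConfig`.
#' @export
pairConfig <- function(trainFrac = 0.6, lastNTimepoints = 40L, nRef = 10L,
                       features = NULL, seed = 1L) {
  stopifnot(trainFrac > 0, trainFrac < 1, lastNTimepoints >= 1)
  structure(
    list(
      trainFrac = trainFrac, lastNTimepoints = as.integer(lastNTimepoints),
      nRef = as.integer(nRef), features = features, seed = as.integer(seed)
    ),
    class = "pairConfig"
  )
}

## Coerce a KnockdownProfile or data.frame into (features, timePoint).
cellsInput <- function(x, features = NULL) {
  if (is(x, "KnockdownProfile")) {
    f <- x@features
    tp <- x@timePoint
  } else if (is.data.frame(x)) {
    tpCol <- intersect(c("time_point", "timePoint"), names(x))
    if (length(tpCol) == 0L) stop("cell table needs a time_point column")
    tp <- as.integer(x[[tpCol[1L]]])
    keep <- setdiff(
      names(x)[vapply(x, is.numeric, logical(1))],
      c(tpCol, "class_label")
    )
    f <- as.matrix(x[, keep, drop = FALSE])
  } else {
    stop("cells must be a KnockdownProfile or a data.frame")
  }
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(f))
    if (length(miss)) {
      stop("cell features missing: ", paste(miss, collapse = ", "))
    }
    f <- f[, features, drop = FALSE]
  }
  list(features = f, timePoint = tp)
}

#' Fraction features of a gene pair
#'
#' Per gene: the fraction of cells in each morphological class, the
#' overall cell count and the intensity median and SD. The pair feature
#' is the absolute difference per entry, so it is symmetric in the two
#' genes by construction.
#'
#' @param a,b \linkS4class{KnockdownProfile} objects.
#' @return Named numeric vector of absolute differences.
#' @export
fractionFeatures <- function(a, b) {
  per <- function(p) {
    n <- nCells(p)
    if (n == 0L) stop("profile for ", p@gene, " has zero cells")
    cls <- colSums(p@classCounts) / n
    c(
      stats::setNames(cls, paste0("frac.", colnames(p@classCounts))),
      n.cells = n,
      intensity.median = p@intensityMedian,
      intensity.sd = p@intensitySd
    )
  }
  va <- per(a)
  vb <- per(b)
  if (!identical(names(va), names(vb))) {
    stop("profiles have differing class registries")
  }
  abs(va - vb)
}

#' Default mapping of imaging phenotypes to morphological classes
#'
#' The seven canonical mitotic-screen phenotypes are sourced from the
#' four-class counts many-to-one; screens that emit the seven
#' phenotype classes directly can use an identity map instead.
#'
#' @return Named character vector, phenotype -> class.
#' @export
defaultPhenotypeMap <- function() {
  c(
    mitotic_delay = "mitosis",
    binuclear = "shape",
    polylobed = "shape",
    grape = "apoptosis",
    large = "shape",
    dynamic_change = "mitosis",
    cell_death = "apoptosis"
  )
}

#' Phenotype maxima profile of a knockdown
#'
#' For each phenotype, the score is the maximal difference of cell
#' counts between the knockdown and the negative control over the time
#' course, and the peak time is the time point where that maximum is
#' attained (the earliest one on ties).
#'
#' @param kdCounts,controlCounts Count matrices (time points x classes)
#'   on a shared time axis.
#' @param phenotypeMap Named character vector phenotype -> class column;
#'   defaults to \code{\link{defaultPhenotypeMap}}.
#' @param gene Gene identifier recorded in the result.
#' @return A \linkS4class{MaximaProfile}.
#' @export
computeMaximaProfile <- function(kdCounts, controlCounts,
                                 phenotypeMap = defaultPhenotypeMap(),
                                 gene = "") {
  if (!identical(dim(kdCounts), dim(controlCounts)) ||
      !identical(rownames(kdCounts), rownames(controlCounts)) ||
      !identical(colnames(kdCounts), colnames(controlCounts))) {
    stop("knockdown and control count series must share the time axis")
  }
  miss <- setdiff(unname(phenotypeMap), colnames(kdCounts))
  if (length(miss)) {
    stop("phenotype map names unknown classes: ", paste(miss, collapse = ", "))
  }
  times <- as.numeric(rownames(kdCounts))
  if (any(is.na(times))) times <- seq_len(nrow(kdCounts))
  scores <- numeric(length(phenotypeMap))
  peaks <- numeric(length(phenotypeMap))
  for (i in seq_along(phenotypeMap)) {
    d <- kdCounts[, phenotypeMap[[i]]] - controlCounts[, phenotypeMap[[i]]]
    scores[i] <- max(d)
    peaks[i] <- times[which.max(d)] # which.max takes the earliest tie
  }
  names(scores) <- names(peaks) <- names(phenotypeMap)
  new("MaximaProfile", gene = gene, scores = scores, peakTimes = peaks)
}

## 14-entry vector (7 scores + 7 peak times) of a MaximaProfile.
maximaVector <- function(mp) {
  c(
    stats::setNames(mp@scores, paste0("max.", names(mp@scores))),
    stats::setNames(mp@peakTimes, paste0("peak.", names(mp@peakTimes)))
  )
}

#' Euclidean distance between two maxima profiles
#'
#' Computed over the 14 maxima values (7 scores and 7 peak times).
#'
#' @param a,b \linkS4class{MaximaProfile} objects.
#' @return Nonnegative numeric distance.
#' @export
maximaDistance <- function(a, b) {
  sqrt(sum((maximaVector(a) - maximaVector(b))^2))
}

#' LDA-performance similarity feature for two knockdowns
#'
#' Trains a linear discriminant to tell cells of the two knockdowns
#' apart and reports its held-out confusion counts. High accuracy means
#' well separable, hence dissimilar, phenotypes (candidate inhibition);
#' accuracy near 0.5 means indistinguishable phenotypes (candidate
#' activation). Cells are restricted to the last `lastNTimepoints` time
#' points; whole time points are then assigned to the train or test
#' portion (60/40 by default), the same split for both genes, so no
#' near-duplicate cells of one frame leak across the split and the
#' result is invariant to swapping the two inputs.
#'
#' @param a,b \linkS4class{KnockdownProfile} objects or data.frames
#'   with a `time_point` column and numeric feature columns.
#' @param trainFrac Fraction of time points in the training portion.
#' @param lastNTimepoints Number of trailing time points retained.
#' @param features Optional cell-feature subset to use.
#' @param seed Integer seed for the time-point split.
#' @return An \linkS4class{LDAResult}; see \code{\link{accuracy}}.
#' @examples
#' ## two identical populations are not separable
#' x <- data.frame(time_point = rep(1:10, each = 20), f = rnorm(200))
#' accuracy(ldaPerformance(x, x, seed = 1))
#' @export
ldaPerformance <- function(a, b, trainFrac = 0.6, lastNTimepoints = 40L,
                           features = NULL, seed = 1L) {
  ca <- cellsInput(a, features)
  cb <- cellsInput(b, features)
  if (!identical(colnames(ca$features), colnames(cb$features))) {
    stop("the two cell tables must share the feature registry")
  }
  tps <- sort(unique(c(ca$timePoint, cb$timePoint)))
  tps <- utils::tail(tps, lastNTimepoints)
  keepA <- ca$timePoint %in% tps
  keepB <- cb$timePoint %in% tps
  nTrain <- max(1L, min(length(tps) - 1L, round(trainFrac * length(tps))))
  trainTps <- withSeed(seed, sample(tps, nTrain))
  aTrain <- keepA & ca$timePoint %in% trainTps
  bTrain <- keepB & cb$timePoint %in% trainTps
  aTest <- keepA & !ca$timePoint %in% trainTps
  bTest <- keepB & !cb$timePoint %in% trainTps
  if (min(sum(aTrain), sum(bTrain), sum(aTest), sum(bTest)) < 5L) {
    stop("fewer than 5 cells per gene in a train/test split")
  }
  x <- rbind(
    ca$features[aTrain, , drop = FALSE],
    cb$features[bTrain, , drop = FALSE]
  )
  y <- factor(
    rep(c("A", "B"), c(sum(aTrain), sum(bTrain))),
    levels = c("A", "B")
  )
  fit <- fitShrinkageLda(x, y)
  predA <- predictShrinkageLda(fit, ca$features[aTest, , drop = FALSE])
  predB <- predictShrinkageLda(fit, cb$features[bTest, , drop = FALSE])
  new("LDAResult",
    tp = sum(predA == "A"), fn = sum(predA == "B"),
    tn = sum(predB == "B"), fp = sum(predB == "A")
  )
}

#' Select the most discriminative cell features
#'
#' Fits pairwise linear discriminants on randomly drawn gene pairs,
#' ranks the features of each fit by the magnitude of their
#' discriminant coefficients, sums the ranks across pairs and returns
#' the k features with the best (smallest) rank sums.
#'
#' @param screen A \linkS4class{SyntheticScreen} (or any named list of
#'   \linkS4class{KnockdownProfile}).
#' @param nPairs Number of random gene pairs to fit.
#' @param k Number of features to retain (default 50).
#' @param lastNTimepoints Trailing time points used by each fit.
#' @param seed Integer seed.
#' @return Ordered character vector of k feature names.
#' @export
selectDiscriminativeFeatures <- function(screen, nPairs, k = 50L,
                                         lastNTimepoints = 40L, seed = 1L) {
  profs <- if (is(screen, "SyntheticScreen")) profiles(screen) else screen
  genes <- names(profs)
  if (nPairs < 1L) stop("nPairs must be >= 1")
  registry <- colnames(profs[[1L]]@features)
  if (k > length(registry)) {
    stop("k exceeds the feature registry size (", length(registry), ")")
  }
  rankSum <- stats::setNames(numeric(length(registry)), registry)
  withSeed(subSeed(seed, "featsel"), {
    for (i in seq_len(nPairs)) {
      pr <- sample(genes, 2L)
      ca <- cellsInput(profs[[pr[1L]]])
      cb <- cellsInput(profs[[pr[2L]]])
      tps <- utils::tail(sort(unique(c(ca$timePoint, cb$timePoint))),
        lastNTimepoints
      )
      x <- rbind(
        ca$features[ca$timePoint %in% tps, , drop = FALSE],
        cb$features[cb$timePoint %in% tps, , drop = FALSE]
      )
      y <- rep(c("A", "B"), c(
        sum(ca$timePoint %in% tps),
        sum(cb$timePoint %in% tps)
      ))
      ## scale coefficients by feature SD so ranks compare loadings,
      ## not units
      w <- fitShrinkageLda(x, y)$w * apply(x, 2L, stats::sd)
      rankSum <- rankSum + rank(-abs(w), ties.method = "first")
    }
  })
  names(sort(rankSum))[seq_len(k)]
}

#' Pick reference genes for the proximity features
#'
#' A seeded random sample of genes outside the evaluated pairs. The
#' reference list is configurable: any explicit character vector of
#' genes disjoint from the evaluated pairs can be used instead.
#'
#' @param screen A \linkS4class{SyntheticScreen}.
#' @param pairs data.frame with geneA/geneB columns of evaluated pairs.
#' @param nRef Number of reference genes.
#' @param seed Integer seed.
#' @return Character vector of reference gene names.
#' @export
selectReferenceGenes <- function(screen, pairs, nRef = 10L, seed = 1L) {
  pool <- setdiff(geneNames(screen), unique(c(pairs$geneA, pairs$geneB)))
  if (length(pool) < nRef) {
    stop(
      "only ", length(pool),
      " genes outside the evaluated pairs; asked for ", nRef
    )
  }
  withSeed(subSeed(seed, "refs"), sort(sample(pool, nRef)))
}

## Cache-aware helpers used by proximity/descriptor assembly ---------------

cachedLda <- function(g1, g2, profs, config, cache) {
  key <- pairKey(g1, g2)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  res <- accuracy(ldaPerformance(
    profs[[g1]], profs[[g2]],
    trainFrac = config$trainFrac,
    lastNTimepoints = config$lastNTimepoints,
    features = config$features,
    seed = subSeed(config$seed, paste0("lda:", key))
  ))
  if (!is.null(cache)) cache[[key]] <- res
  res
}

cachedMaxima <- function(g, screen, cache) {
  key <- paste0("maxima:", g)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  res <- computeMaximaProfile(
    classCounts(profiles(screen)[[g]]),
    classCounts(controlProfile(screen)),
    gene = g
  )
  if (!is.null(cache)) cache[[key]] <- res
  res
}

#' Proximity features of a gene pair
#'
#' For each reference gene r, the absolute difference of the two pair
#' members' similarities to r, measured once by the LDA-performance
#' feature and once by the Euclidean distance between maxima profiles.
#'
#' @param geneA,geneB The gene pair.
#' @param references Reference genes, disjoint from the pair.
#' @param screen A \linkS4class{SyntheticScreen}.
#' @param config A \code{\link{pairConfig}}.
#' @param maxima Optional named list of precomputed
#'   \linkS4class{MaximaProfile} objects.
#' @param cache Optional environment memoizing per-pair LDA fits and
#'   per-gene maxima across calls.
#' @return Named numeric vector, two entries per reference.
#' @export
proximityFeatures <- function(geneA, geneB, references, screen,
                              config = pairConfig(), maxima = NULL,
                              cache = NULL) {
  if (length(references) == 0L) stop("references must be nonempty")
  if (any(references %in% c(geneA, geneB))) {
    stop("reference genes must be disjoint from the pair")
  }
  profs <- profiles(screen)
  getMax <- function(g) {
    if (!is.null(maxima) && !is.null(maxima[[g]])) {
      maxima[[g]]
    } else {
      cachedMaxima(g, screen, cache)
    }
  }
  mA <- getMax(geneA)
  mB <- getMax(geneB)
  out <- numeric(0)
  for (r in references) {
    ldaA <- cachedLda(geneA, r, profs, config, cache)
    ldaB <- cachedLda(geneB, r, profs, config, cache)
    mR <- getMax(r)
    out <- c(
      out,
      stats::setNames(abs(ldaA - ldaB), paste0("prox.lda.", r)),
      stats::setNames(
        abs(maximaDistance(mA, mR) - maximaDistance(mB, mR)),
        paste0("prox.maxdist.", r)
      )
    )
  }
  out
}

#' Assemble the full descriptor of a gene pair
#'
#' Concatenates, in fixed registry order, the fraction features, the
#' maxima features (absolute differences of the two genes' maxima
#' profiles), the LDA-performance feature of the pair and the
#' proximity features. The pair is canonicalized (sorted gene names)
#' first, so the descriptor is symmetric under gene swap.
#'
#' @inheritParams proximityFeatures
#' @return Named numeric vector.
#' @export
assemblePairDescriptor <- function(geneA, geneB, screen, references,
                                   config = pairConfig(), cache = NULL) {
  g <- sort(c(geneA, geneB))
  profs <- profiles(screen)
  miss <- setdiff(c(g, references), names(profs))
  if (length(miss)) {
    stop(
      "pair ", pairKey(geneA, geneB), ": no profile for ",
      paste(miss, collapse = ", ")
    )
  }
  frac <- fractionFeatures(profs[[g[1L]]], profs[[g[2L]]])
  mA <- cachedMaxima(g[1L], screen, cache)
  mB <- cachedMaxima(g[2L], screen, cache)
  maxd <- abs(maximaVector(mA) - maximaVector(mB))
  ldaAcc <- cachedLda(g[1L], g[2L], profs, config, cache)
  prox <- proximityFeatures(
    g[1L], g[2L], references, screen,
    config = config, cache = cache
  )
  c(frac, maxd, lda.accuracy = ldaAcc, prox)
}

#' Descriptor table for a set of gene pairs
#'
#' @param pairs data.frame with columns geneA, geneB (extra columns,
#'   e.g. effect labels, are preserved as attributes of the rownames).
#' @param screen A \linkS4class{SyntheticScreen}.
#' @param references Reference genes for the proximity features.
#' @param config A \code{\link{pairConfig}}.
#' @return Numeric matrix, one row per pair (rownames are pair keys),
#'   one column per descriptor feature.
#' @export
pairDescriptorTable <- function(pairs, screen, references,
                                config = pairConfig()) {
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    assemblePairDescriptor(
      pairs$geneA[i], pairs$geneB[i], screen, references,
      config = config, cache = cache
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- pairKey(pairs$geneA, pairs$geneB)
  out
}
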
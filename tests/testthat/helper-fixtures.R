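## Shared fixtures, memoized so expensive screens are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

## A small screen with labeled edges at a given effect size.
makeScreen <- function(effectSize, seed = 42, nGenes = 16, nAct = 4,
                       nInh = 4, cells = 4, tps = 60, latentDim = 6) {
  net <- generateNetwork(nGenes, nAct = nAct, nInh = nInh, seed = seed)
  mod <- phenotypeModel(net,
    latentDim = latentDim, effectSize = effectSize,
    seed = seed
  )
  list(
    network = net,
    screen = sampleScreen(net, mod,
      cellsPerTimepoint = cells,
      timePoints = tps, seed = seed
    )
  )
}

## Build a KnockdownProfile directly from a feature matrix.
makeProfile <- function(gene, features, timePoint,
                        classes = cellClasses()) {
  n <- nrow(features)
  lab <- rep(classes, length.out = n)
  tps <- sort(unique(timePoint))
  cc <- matrix(0L, length(tps), length(classes),
    dimnames = list(tps, classes)
  )
  for (i in seq_len(n)) {
    cc[as.character(timePoint[i]), lab[i]] <-
      cc[as.character(timePoint[i]), lab[i]] + 1L
  }
  intens <- if ("intensity" %in% colnames(features)) {
    features[, "intensity"]
  } else {
    features[, 1L]
  }
  new("KnockdownProfile",
    gene = gene, features = features, timePoint = as.integer(timePoint),
    classLabel = lab, classCounts = cc,
    intensityMedian = stats::median(intens),
    intensitySd = stats::sd(intens)
  )
}

## Gaussian cell population around a centroid, over a time axis.
gaussianCells <- function(centroid, cellsPerTp = 10, tps = 1:20, sd = 1,
                          seed = 1) {
  d <- length(centroid)
  n <- cellsPerTp * length(tps)
  set.seed(seed)
  f <- matrix(rnorm(n * d, sd = sd), n, d)
  f <- sweep(f, 2L, centroid, "+")
  colnames(f) <- sprintf("f%02d", seq_len(d))
  data.frame(time_point = rep(tps, each = cellsPerTp), f)
}

## Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(0)
  (sumij - expected) / (maxidx - expected)
}

## Phantom image with bright discs on a flat background.
discImage <- function(dim = c(96, 96), centers, radius = 8,
                      bg = 100, fg = 1000) {
  px <- matrix(bg, dim[1], dim[2])
  for (ctr in centers) {
    for (i in seq_len(dim[1])) {
      for (j in seq_len(dim[2])) {
        if ((i - ctr[1])^2 + (j - ctr[2])^2 <= radius^2) px[i, j] <- fg
      }
    }
  }
  px
}

## Synthetic effect-classifier descriptors: two Gaussian classes whose
## separation is controlled directly (no screen needed).
makeDescriptors <- function(nPerClass = 60, nFeat = 10, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(nPerClass * nFeat), nPerClass),
    matrix(rnorm(nPerClass * nFeat, mean = sep / sqrt(nFeat)), nPerClass)
  )
  colnames(x) <- sprintf("d%02d", seq_len(nFeat))
  genes <- sprintf("p%03d", seq_len(2 * nPerClass * 2))
  pairs <- data.frame(
    geneA = genes[seq_len(2 * nPerClass) * 2 - 1],
    geneB = genes[seq_len(2 * nPerClass) * 2],
    effect = rep(c("activating", "inhibiting"), each = nPerClass),
    stringsAsFactors = FALSE
  )
  rownames(x) <- pairKeys(pairs)
  list(pairs = pairs, descriptors = x)
}

pairKeys <- function(pairs) {
  ifelse(pairs$geneA < pairs$geneB,
    paste(pairs$geneA, pairs$geneB, sep = "||"),
    paste(pairs$geneB, pairs$geneA, sep = "||")
  )
}

## Calls where two gene blocks behave concordantly within and
## discordantly across blocks, toward a set of third genes.
plantedBlockCalls <- function(blockA, blockB, thirds) {
  calls <- character(0)
  for (g in blockA) {
    calls[ppisign:::pairKey(g, thirds)] <- "activating"
  }
  for (g in blockB) {
    calls[ppisign:::pairKey(g, thirds)] <- "inhibiting"
  }
  calls
}
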
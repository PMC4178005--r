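## Synthetic knockdown screens.
##
## The generator realizes the method's core premise: knocking down two
## proteins that activate one another produces near-identical cell
## populations, while an inhibiting relationship produces systematically
## displaced populations. One knob (effectSize, in units of the
## within-gene noise SD) controls how far inhibiting partners are pushed
## apart in latent phenotype space.

#' Generate a random signed interaction network
#'
#' Samples unordered gene pairs without replacement and labels the
#' requested numbers of them activating, inhibiting and undefined.
#'
#' @param nGenes Number of genes (identifiers g001, g002, ...).
#' @param nAct,nInh,nUndef Edge counts per effect label.
#' @param seed Integer seed; identical seeds reproduce the network exactly.
#' @return A \linkS4class{LatentNetwork}.
#' @examples
#' net <- generateNetwork(10, nAct = 5, nInh = 5, seed = 1)
#' table(edgeTable(net)$effect)
#' @export
generateNetwork <- function(nGenes, nAct, nInh, nUndef = 0L, seed = 1L) {
  nGenes <- as.integer(nGenes)
  nEdges <- nAct + nInh + nUndef
  nPairs <- nGenes * (nGenes - 1) / 2
  if (nEdges > nPairs) {
    stop(
      "requested ", nEdges, " edges but only ", nPairs,
      " unordered pairs exist for ", nGenes, " genes"
    )
  }
  genes <- sprintf("g%03d", seq_len(nGenes))
  idx <- withSeed(seed, sample.int(nPairs, nEdges))
  ## unrank pair index k (1-based, column-major over i < j)
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  edges <- data.frame(
    geneA = genes[i], geneB = genes[j],
    effect = rep(
      c("activating", "inhibiting", "undefined"),
      times = c(nAct, nInh, nUndef)
    ),
    stringsAsFactors = FALSE
  )
  tags <- stats::setNames(rep(list(character()), nGenes), genes)
  new("LatentNetwork", genes = genes, edges = edges, pathwayTags = tags)
}

#' Default morphological classes of the cell classifier
#'
#' @return Character vector of the four class names.
#' @export
cellClasses <- function() c("interphase", "apoptosis", "mitosis", "shape")

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Build a generative phenotype model for a network
#'
#' Every gene receives a Gaussian latent centroid. Genes connected by
#' activating edges share one centroid (they form activation
#' components); an inhibiting edge places the two components
#' `effectSize * noiseSd` apart along a random unit vector,
#' propagated breadth-first so that chains of constraints stay
#' consistent. Constraint cycles that cannot all be satisfied keep the
#' breadth-first placement (their residual distances are of the right
#' order).
#' Each gene's end-of-course class mixture is a softmax perturbation of
#' the control mixture driven by its centroid, tying class-count
#' dynamics to the latent phenotype.
#'
#' @param network A \linkS4class{LatentNetwork}.
#' @param latentDim Latent feature dimension.
#' @param effectSize Centroid separation for inhibiting pairs, in units
#'   of `noiseSd`. Zero makes activating and inhibiting pairs
#'   statistically indistinguishable.
#' @param noiseSd Within-gene standard deviation of cell features.
#' @param seed Integer seed.
#' @return A \linkS4class{PhenotypeModel}.
#' @export
phenotypeModel <- function(network, latentDim = 10L, effectSize = 6,
                           noiseSd = 1, seed = 1L) {
  genes <- geneNames(network)
  classes <- cellClasses()
  d <- as.integer(latentDim)
  withSeed(subSeed(seed, "model"), {
    e <- edgeTable(network)
    ## activation components: union-find over activating edges
    comp <- stats::setNames(seq_along(genes), genes)
    find <- function(i) {
      while (comp[i] != i) i <- comp[i]
      i
    }
    for (r in which(e$effect == "activating")) {
      comp[find(match(e$geneA[r], genes))] <-
        find(match(e$geneB[r], genes))
    }
    compOf <- vapply(seq_along(genes), find, numeric(1))
    ## place components: random base centroids, then breadth-first
    ## displacement along inhibiting edges
    base <- matrix(
      stats::rnorm(length(genes) * d, sd = 2 * noiseSd),
      nrow = length(genes)
    )
    compCentroid <- base # row i used when component root is i
    inhA <- compOf[match(e$geneA[e$effect == "inhibiting"], genes)]
    inhB <- compOf[match(e$geneB[e$effect == "inhibiting"], genes)]
    placed <- logical(length(genes))
    queue <- unique(c(inhA, inhB))
    for (root in queue) {
      if (placed[root]) next
      placed[root] <- TRUE
      frontier <- root
      while (length(frontier)) {
        nxt <- integer(0)
        for (cc in frontier) {
          nb <- unique(c(inhB[inhA == cc], inhA[inhB == cc]))
          for (q in nb[!placed[nb]]) {
            u <- stats::rnorm(d)
            u <- u / sqrt(sum(u^2))
            compCentroid[q, ] <- compCentroid[cc, ] +
              effectSize * noiseSd * u
            placed[q] <- TRUE
            nxt <- c(nxt, q)
          }
        }
        frontier <- nxt
      }
    }
    centroids <- compCentroid[compOf, , drop = FALSE]
    dimnames(centroids) <- list(genes, sprintf("lf%02d", seq_len(d)))
    ## class mixtures: common start, centroid-tied end
    startMix <- matrix(
      rep(c(0.85, 0.03, 0.09, 0.03), each = length(genes)),
      nrow = length(genes), dimnames = list(genes, classes)
    )
    controlEnd <- c(0.70, 0.08, 0.12, 0.10)
    w <- matrix(
      stats::rnorm(length(classes) * min(4L, d), sd = 0.15),
      nrow = length(classes)
    )
    endMix <- t(vapply(genes, function(g) {
      softmax(log(controlEnd) + drop(w %*% centroids[g, seq_len(min(4L, d))]))
    }, numeric(length(classes))))
    dimnames(endMix) <- list(genes, classes)
  })
  new("PhenotypeModel",
    latentDim = d, centroids = centroids, effectSize = effectSize,
    noiseSd = noiseSd, classes = classes,
    classMixStart = startMix, classMixEnd = endMix
  )
}

## Simulate one knockdown condition: cells at every time point plus the
## multinomial class-count series interpolating startMix -> endMix.
simulateProfile <- function(gene, centroid, startMix, endMix, classes,
                            noiseSd, cellsPerTimepoint, timePoints, seed) {
  d <- length(centroid)
  withSeed(seed, {
    counts <- matrix(0L, nrow = timePoints, ncol = length(classes),
      dimnames = list(seq_len(timePoints), classes)
    )
    nTot <- cellsPerTimepoint * timePoints
    feat <- matrix(stats::rnorm(nTot * d, sd = noiseSd),
      nrow = nTot, byrow = TRUE
    )
    feat <- sweep(feat, 2L, -centroid)
    colnames(feat) <- names(centroid)
    tp <- rep(seq_len(timePoints), each = cellsPerTimepoint)
    lab <- character(nTot)
    for (t in seq_len(timePoints)) {
      frac <- if (timePoints == 1L) 1 else (t - 1) / (timePoints - 1)
      mix <- startMix + frac * (endMix - startMix)
      cnt <- drop(stats::rmultinom(1L, cellsPerTimepoint, mix))
      counts[t, ] <- cnt
      lab[tp == t] <- rep(classes, times = cnt)
    }
    ## reported intensity tracks the first latent coordinate
    intensity <- 500 + 40 * feat[, 1L] + stats::rnorm(nTot, sd = 20)
    feat <- cbind(feat, intensity = intensity)
  })
  new("KnockdownProfile",
    gene = gene, features = feat, timePoint = tp, classLabel = lab,
    classCounts = counts,
    intensityMedian = stats::median(intensity), intensitySd = stats::sd(intensity)
  )
}

#' Sample a synthetic knockdown screen
#'
#' Draws per-cell feature vectors (gene centroid plus independent
#' Gaussian noise) and multinomial class-count time series for every
#' gene of the network, plus a negative-control condition at the origin
#' of latent space.
#'
#' @param network A \linkS4class{LatentNetwork}.
#' @param model A \linkS4class{PhenotypeModel} built for that network.
#' @param cellsPerTimepoint Cells simulated at each time point (>= 2).
#' @param timePoints Length of the imaging time course (default 96, the
#'   screen layout of a 48 h live-imaging assay at 30 min intervals).
#' @param seed Integer seed; per-gene sub-seeds are derived from it.
#' @return A \linkS4class{SyntheticScreen}.
#' @examples
#' net <- generateNetwork(6, 2, 2, seed = 1)
#' mod <- phenotypeModel(net, effectSize = 6, seed = 1)
#' scr <- sampleScreen(net, mod, cellsPerTimepoint = 3, timePoints = 12)
#' scr
#' @export
sampleScreen <- function(network, model, cellsPerTimepoint = 10L,
                         timePoints = 96L, seed = 1L) {
  if (cellsPerTimepoint < 2L) stop("cellsPerTimepoint must be >= 2")
  genes <- geneNames(network)
  timePoints <- as.integer(timePoints)
  profs <- lapply(genes, function(g) {
    simulateProfile(
      gene = g,
      centroid = model@centroids[g, ],
      startMix = model@classMixStart[g, ],
      endMix = model@classMixEnd[g, ],
      classes = model@classes,
      noiseSd = model@noiseSd,
      cellsPerTimepoint = as.integer(cellsPerTimepoint),
      timePoints = timePoints,
      seed = subSeed(seed, paste0("gene:", g))
    )
  })
  names(profs) <- genes
  ctrlEnd <- softmax(log(c(0.70, 0.08, 0.12, 0.10)))
  names(ctrlEnd) <- model@classes
  ctrl <- simulateProfile(
    gene = "negative_control",
    centroid = stats::setNames(
      numeric(model@latentDim),
      colnames(model@centroids)
    ),
    startMix = stats::setNames(c(0.85, 0.03, 0.09, 0.03), model@classes),
    endMix = ctrlEnd,
    classes = model@classes,
    noiseSd = model@noiseSd,
    cellsPerTimepoint = as.integer(cellsPerTimepoint),
    timePoints = timePoints,
    seed = subSeed(seed, "gene:negative_control")
  )
  new("SyntheticScreen",
    profiles = profs, negativeControl = ctrl,
    timePoints = timePoints, seed = as.integer(seed)
  )
}

#' Generate synthetic domain-class annotations
#'
#' Every gene receives at least one functional class; genes may belong
#' to several classes, mirroring multi-domain proteins.
#'
#' @param network A \linkS4class{LatentNetwork}.
#' @param classes Nonempty character vector of class names.
#' @param seed Integer seed.
#' @return Named list mapping each gene to a character vector of classes.
#' @export
generateDomainAnnotations <- function(network, classes, seed = 1L) {
  if (length(classes) == 0L) stop("classes must be nonempty")
  genes <- geneNames(network)
  withSeed(subSeed(seed, "domains"), {
    ann <- lapply(genes, function(g) {
      k <- 1L + stats::rbinom(1L, length(classes) - 1L, 0.25)
      sort(sample(classes, k))
    })
  })
  stats::setNames(ann, genes)
}
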
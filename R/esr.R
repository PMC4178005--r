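## Effect Similarity Rate (ESR).
##
## Two genes are effect-similar when they receive concordant
## activation/inhibition predictions toward the same third genes. With
## X the difference between the fractions of similar and dissimilar
## third-gene comparisons, ESR = tanh(5 X), a score in [-1, 1] that is
## odd in X and saturates as the concordance becomes unanimous.

#' Extract per-pair effect calls as a lookup table
#'
#' @param votes A \linkS4class{VoteSet} with a `call` column, or a
#'   data.frame with geneA, geneB, call.
#' @return Named character vector of calls, keyed by canonical pair key.
#' @export
effectCalls <- function(votes) {
  v <- if (is(votes, "VoteSet")) voteTable(votes) else votes
  if (!"call" %in% names(v)) stop("votes carry no call column")
  stats::setNames(v$call, pairKey(v$geneA, v$geneB))
}

lookupCall <- function(calls, a, b) {
  x <- calls[pairKey(a, b)]
  ifelse(is.na(x), "none", x)
}

#' Concordance of two genes' effects on a third gene
#'
#' @param i,j The gene pair.
#' @param k A third gene, not in the pair.
#' @param calls Named call vector from \code{\link{effectCalls}}.
#' @return "similar" (both activating or both inhibiting), "dissimilar"
#'   (one of each), or "neither" (any call is none or missing).
#' @export
effectConcordance <- function(i, j, k, calls) {
  if (k %in% c(i, j)) stop("third gene must differ from the pair")
  ci <- lookupCall(calls, i, k)
  cj <- lookupCall(calls, j, k)
  if (ci == "none" || cj == "none") {
    "neither"
  } else if (ci == cj) {
    "similar"
  } else {
    "dissimilar"
  }
}

#' Effect Similarity Rate of a gene pair
#'
#' X = (nSimilar - nDissimilar) / nThird, over all third genes of the
#' universe; ESR = tanh(5 X). With `denominator = "confident"` only
#' third genes with confident calls from both pair members count in
#' the denominator (NA when there are none).
#'
#' @param i,j The gene pair.
#' @param universe Character vector of all investigated genes.
#' @param calls Named call vector from \code{\link{effectCalls}}.
#' @param denominator "all" (default) or "confident".
#' @return Numeric ESR in [-1, 1].
#' @export
computeEsr <- function(i, j, universe, calls,
                       denominator = c("all", "confident")) {
  denominator <- match.arg(denominator)
  third <- setdiff(universe, c(i, j))
  if (length(third) == 0L) stop("universe holds no third genes")
  conc <- vapply(
    third, function(k) effectConcordance(i, j, k, calls),
    character(1)
  )
  nS <- sum(conc == "similar")
  nD <- sum(conc == "dissimilar")
  den <- if (denominator == "all") length(third) else nS + nD
  if (den == 0L) return(NA_real_)
  tanh(5 * (nS - nD) / den)
}

#' ESR matrix over a gene set
#'
#' @param genes Character vector of genes to tabulate (>= 3 when they
#'   are also the universe).
#' @param calls Named call vector from \code{\link{effectCalls}}.
#' @param universe Genes the concordance is evaluated against;
#'   defaults to `genes` itself, but may be a superset (e.g. the whole
#'   pathway set when only a subnetwork is tabulated).
#' @param denominator Passed to \code{\link{computeEsr}}.
#' @return An \linkS4class{ESRMatrix} (diagonal unset).
#' @export
esrMatrix <- function(genes, calls, universe = genes, denominator = "all") {
  if (length(universe) < 3L) stop("need at least 3 genes in the universe")
  if (length(genes) < 2L) stop("need at least 2 genes to tabulate")
  n <- length(genes)
  m <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      m[a, b] <- m[b, a] <- computeEsr(
        genes[a], genes[b], universe, calls,
        denominator = denominator
      )
    }
  }
  new("ESRMatrix", values = m)
}

#' Hierarchical clustering of genes by ESR
#'
#' ESR is mapped to a distance d = (1 - ESR) / 2 in [0, 1] and genes
#' are clustered agglomeratively. The leaf order is the deterministic
#' merge order of \code{\link[stats]{hclust}}.
#'
#' @param esr An \linkS4class{ESRMatrix}, complete off the diagonal.
#' @param linkage Agglomeration method (default "average").
#' @return List with `hclust` (the tree), `order` (genes in leaf
#'   order) and `distance` (the dist object used).
#' @export
clusterEsr <- function(esr, linkage = "average") {
  v <- esrValues(esr)
  off <- is.na(v) & row(v) != col(v)
  if (any(off)) {
    idx <- which(off & upper.tri(v), arr.ind = TRUE)
    stop(
      "ESR matrix incomplete; missing pairs: ",
      paste(
        utils::head(paste(rownames(v)[idx[, 1]], colnames(v)[idx[, 2]],
          sep = "-"
        ), 10L),
        collapse = ", "
      )
    )
  }
  d <- (1 - v) / 2
  diag(d) <- 0
  dd <- stats::as.dist(d)
  hc <- stats::hclust(dd, method = linkage)
  list(hclust = hc, order = rownames(v)[hc$order], distance = dd)
}

#' Cut an ESR clustering into k groups
#'
#' @param clustering Result of \code{\link{clusterEsr}}.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cutEsrClusters <- function(clustering, k) {
  stats::cutree(clustering$hclust, k = k)
}

#' Compare ESR distributions between gene subsets
#'
#' One-sided Wilcoxon rank-sum test that the ESR scores of pairs
#' within subset A exceed either the scores of pairs within subset B
#' ("within-within") or the scores of pairs spanning the two subsets
#' ("within-between").
#'
#' @param esr An \linkS4class{ESRMatrix}.
#' @param subsetA,subsetB Disjoint gene sets with >= 2 genes each.
#' @param mode "within-within" or "within-between".
#' @return List with `statistic`, `p.value`, and the two score vectors.
#' @export
compareEsrSubsets <- function(esr, subsetA, subsetB,
                              mode = c("within-within", "within-between")) {
  mode <- match.arg(mode)
  if (length(intersect(subsetA, subsetB)) > 0L) {
    stop("subsets must be disjoint")
  }
  if (length(subsetA) < 2L || length(subsetB) < 2L) {
    stop("each subset needs at least 2 genes")
  }
  v <- esrValues(esr)
  withinPairs <- function(g) {
    m <- v[g, g, drop = FALSE]
    m[upper.tri(m)]
  }
  x <- withinPairs(subsetA)
  y <- if (mode == "within-within") {
    withinPairs(subsetB)
  } else {
    as.vector(v[subsetA, subsetB, drop = FALSE])
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)
  )
  list(
    statistic = unname(wt$statistic), p.value = wt$p.value,
    scoresA = x, scoresOther = y
  )
}
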
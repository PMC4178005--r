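## Functional validation by domain-class pair enrichment.
##
## Proteins carry functional classes derived from their Pfam domains
## (effector, receptor, kinase, phosphatase, signalling, ...). For
## every unordered class pair, the fraction of predicted activating
## interactions containing the pair is compared with the fraction of
## predicted inhibiting interactions; the ratio of the two fractions is
## the enrichment, and a Pearson chi-square on the 2x2 table gives the
## significance.

#' Count predictions containing a class pair
#'
#' A prediction counts for (classA, classB) when one endpoint carries
#' classA and the other classB (unordered; a gene annotated with both
#' classes can satisfy either side, and a homodimeric class pair
#' requires both endpoints to carry the class). Each prediction counts
#' at most once per class pair; genes without annotation contribute no
#' class pairs.
#'
#' @param predictions data.frame with columns geneA, geneB, call
#'   (activating / inhibiting / none), e.g. from
#'   \code{\link{voteTable}}.
#' @param annotations Named list mapping genes to character vectors of
#'   classes.
#' @param classA,classB Class names to count.
#' @param vocabulary Declared class vocabulary; defaults to all classes
#'   present in the annotations.
#' @return Integer vector c(nAct, nInh).
#' @export
countClassPairs <- function(predictions, annotations, classA, classB,
                            vocabulary = NULL) {
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(annotations)))
  }
  bad <- setdiff(c(classA, classB), vocabulary)
  if (length(bad)) {
    stop("unknown class name(s): ", paste(bad, collapse = ", "))
  }
  hasPair <- function(a, b) {
    ca <- annotations[[a]]
    cb <- annotations[[b]]
    if (is.null(ca) || is.null(cb)) return(FALSE)
    (classA %in% ca && classB %in% cb) || (classA %in% cb && classB %in% ca)
  }
  hit <- mapply(hasPair, predictions$geneA, predictions$geneB)
  c(
    nAct = sum(hit & predictions$call == "activating"),
    nInh = sum(hit & predictions$call == "inhibiting")
  )
}

#' Enrichment ratio of a class pair
#'
#' The fraction of activating predictions containing the class pair
#' over the fraction of inhibiting predictions containing it:
#' (nAct / NAct) / (nInh / NInh).
#'
#' @param nAct,nInh Predictions containing the pair, per call.
#' @param NAct,NInh Total activating / inhibiting predictions.
#' @return Numeric ratio; Inf when nInh is 0 (excluded downstream by
#'   the no-zero filter).
#' @examples
#' enrichmentRatio(70, 1549, 2, 407) # 9.2 after one-decimal rounding
#' @export
enrichmentRatio <- function(nAct, NAct, nInh, NInh) {
  if (NAct <= 0 || NInh <= 0) stop("totals must be positive")
  if (nAct < 0 || nInh < 0) stop("counts must be nonnegative")
  if (nInh == 0) return(Inf)
  (nAct / NAct) / (nInh / NInh)
}

#' Chi-square p-value for a class-pair count difference
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2
#' table [[nAct, NAct - nAct], [nInh, NInh - nInh]]; two-sided.
#'
#' @inheritParams enrichmentRatio
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return Two-sided p-value; NA when any expected cell is zero.
#' @export
chiSquarePvalue <- function(nAct, NAct, nInh, NInh, correct = FALSE) {
  tab <- rbind(c(nAct, NAct - nAct), c(nInh, NInh - nInh))
  if (any(tab < 0)) stop("counts may not exceed totals")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) return(NA_real_)
  suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
}

#' Enrichment table over all class pairs
#'
#' Evaluates every unordered class pair of the vocabulary, sorted by
#' enrichment (descending). The filter flag applies the reporting
#' rule: p <= 0.1 and at least one counted prediction on each side (no
#' zeroes).
#'
#' @inheritParams countClassPairs
#' @param vocabulary Class vocabulary; defaults to the classes present.
#' @param pCutoff Filter p-value cutoff (default 0.1).
#' @return data.frame with columns classA, classB, nAct, nInh,
#'   enrichment, pValue, passesFilter.
#' @export
enrichmentTable <- function(predictions, annotations, vocabulary = NULL,
                            pCutoff = 0.1) {
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(annotations)))
  }
  NAct <- sum(predictions$call == "activating")
  NInh <- sum(predictions$call == "inhibiting")
  if (NAct == 0 || NInh == 0) {
    stop("need at least one activating and one inhibiting prediction")
  }
  cp <- expand.grid(
    a = seq_along(vocabulary), b = seq_along(vocabulary)
  )
  cp <- cp[cp$a <= cp$b, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cp)), function(i) {
    ca <- vocabulary[cp$a[i]]
    cb <- vocabulary[cp$b[i]]
    cnt <- countClassPairs(predictions, annotations, ca, cb, vocabulary)
    enr <- enrichmentRatio(cnt[["nAct"]], NAct, cnt[["nInh"]], NInh)
    p <- chiSquarePvalue(cnt[["nAct"]], NAct, cnt[["nInh"]], NInh)
    data.frame(
      classA = ca, classB = cb,
      nAct = cnt[["nAct"]], nInh = cnt[["nInh"]],
      enrichment = enr, pValue = p,
      passesFilter = !is.na(p) && p <= pCutoff &&
        cnt[["nAct"]] >= 1L && cnt[["nInh"]] >= 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(-out$enrichment, out$classA, out$classB), , drop = FALSE]
}
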
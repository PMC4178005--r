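#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers, so user code
#' never touches slots directly.
#'
#' @param object An object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("pathwayTags", function(object) standardGeneric("pathwayTags"))

#' @rdname accessors
#' @export
setGeneric("profiles", function(object) standardGeneric("profiles"))

#' @rdname accessors
#' @export
setGeneric("controlProfile", function(object) standardGeneric("controlProfile"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("cellFeatures", function(object) standardGeneric("cellFeatures"))

#' @rdname accessors
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("maximaScores", function(object) standardGeneric("maximaScores"))

#' @rdname accessors
#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))

#' @rdname accessors
#' @export
setGeneric("voteTable", function(object) standardGeneric("voteTable"))

#' @rdname accessors
#' @export
setGeneric("ensembleSize", function(object) standardGeneric("ensembleSize"))

#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' @rdname accessors
#' @export
setGeneric("actCutoff", function(object) standardGeneric("actCutoff"))

#' @rdname accessors
#' @export
setGeneric("inhCutoff", function(object) standardGeneric("inhCutoff"))

#' @rdname accessors
#' @export
setGeneric("esrValues", function(object) standardGeneric("esrValues"))

## ---------------------------------------------------------------------------
## Methods
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("geneNames", "LatentNetwork", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "LatentNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("pathwayTags", "LatentNetwork", function(object) object@pathwayTags)

#' @rdname accessors
#' @export
setMethod("geneNames", "SyntheticScreen", function(object) {
  names(object@profiles)
})

#' @rdname accessors
#' @export
setMethod("profiles", "SyntheticScreen", function(object) object@profiles)

#' @rdname accessors
#' @export
setMethod(
  "controlProfile", "SyntheticScreen",
  function(object) object@negativeControl
)

#' @rdname accessors
#' @export
setMethod("nCells", "KnockdownProfile", function(object) {
  nrow(object@features)
})

#' @rdname accessors
#' @export
setMethod("cellFeatures", "KnockdownProfile", function(object) object@features)

#' @rdname accessors
#' @export
setMethod("classCounts", "KnockdownProfile", function(object) {
  object@classCounts
})

#' @rdname accessors
#' @export
setMethod("accuracy", "LDAResult", function(object) {
  (object@tp + object@tn) /
    (object@tp + object@tn + object@fp + object@fn)
})

#' @rdname accessors
#' @export
setMethod("maximaScores", "MaximaProfile", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("peakTimes", "MaximaProfile", function(object) object@peakTimes)

#' @rdname accessors
#' @export
setMethod("voteTable", "VoteSet", function(object) object@votes)

#' @rdname accessors
#' @export
setMethod("ensembleSize", "PPIEnsemble", function(object) {
  length(object@models)
})

#' @rdname accessors
#' @export
setMethod("auc", "PerformanceReport", function(object) object@auc)

#' @rdname accessors
#' @export
setMethod("actCutoff", "ConfidenceCalibration", function(object) {
  object@actCutoff
})

#' @rdname accessors
#' @export
setMethod("inhCutoff", "ConfidenceCalibration", function(object) {
  object@inhCutoff
})

#' @rdname accessors
#' @export
setMethod("esrValues", "ESRMatrix", function(object) object@values)

#' @export
#' @rdname accessors
setMethod("dim", "ESRMatrix", function(x) dim(x@values))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "LatentNetwork", function(object) {
  eff <- table(factor(object@edges$effect, levels = effectLevels()))
  cat(
    "LatentNetwork with", length(object@genes), "genes and",
    nrow(object@edges), "edges\n"
  )
  cat(
    "  activating:", eff[["activating"]],
    " inhibiting:", eff[["inhibiting"]],
    " undefined:", eff[["undefined"]], "\n"
  )
})

setMethod("show", "SyntheticScreen", function(object) {
  cat(
    "SyntheticScreen:", length(object@profiles), "knockdowns over",
    object@timePoints, "time points\n"
  )
  p <- object@profiles[[1]]
  cat(
    "  ", ncol(p@features), "cell features;",
    format(sum(vapply(object@profiles, nCells, integer(1))), big.mark = ","),
    "cells in total (seed", paste0(object@seed, ")\n")
  )
})

setMethod("show", "KnockdownProfile", function(object) {
  cat(
    "KnockdownProfile", object@gene, "-", nrow(object@features), "cells,",
    ncol(object@features), "features,",
    nrow(object@classCounts), "time points\n"
  )
})

setMethod("show", "LDAResult", function(object) {
  cat(
    "LDAResult: accuracy", sprintf("%.3f", accuracy(object)),
    sprintf(
      "(tp %d, tn %d, fp %d, fn %d)\n",
      object@tp, object@tn, object@fp, object@fn
    )
  )
})

setMethod("show", "MaximaProfile", function(object) {
  cat("MaximaProfile for", object@gene, "\n")
  print(rbind(score = object@scores, peakTime = object@peakTimes))
})

setMethod("show", "TrainingConfig", function(object) {
  cat(
    "TrainingConfig:", object@nRepeats, "repeats x", object@nFolds,
    "folds x", object@svmsPerFold, "SVMs =",
    object@nRepeats * object@nFolds * object@svmsPerFold,
    "ensemble members\n"
  )
  cat(
    "  stratum", object@stratumSize, "per class; inner",
    object@innerFolds, "folds; C, gamma = 2^n, n in {",
    paste(range(object@gridExp), collapse = " .. "), "}\n"
  )
})

setMethod("show", "PPIEnsemble", function(object) {
  cat(
    "PPIEnsemble of", length(object@models), "SVMs over",
    length(object@featureNames), "descriptor features",
    if (nzchar(object@pathway)) paste0("(pathway ", object@pathway, ")"),
    "\n"
  )
})

setMethod("show", "VoteSet", function(object) {
  v <- object@votes
  cat("VoteSet:", nrow(v), "gene pairs,", v$votesTotal[1], "votes each\n")
  if ("call" %in% names(v)) {
    print(table(factor(v$call, levels = c("activating", "inhibiting", "none"))))
  }
})

setMethod("show", "PerformanceReport", function(object) {
  cat(
    "PerformanceReport (positive:", object@positiveClass,
    ") AUC =", sprintf("%.3f", object@auc), "\n"
  )
})

setMethod("show", "ConfidenceCalibration", function(object) {
  cat(
    "ConfidenceCalibration at target precision",
    object@targetPrecision, "\n",
    " activation cutoff (vote fraction):", object@actCutoff, "\n",
    " inhibition cutoff (vote fraction):", object@inhCutoff, "\n"
  )
})

setMethod("show", "ESRMatrix", function(object) {
  cat(
    "ESRMatrix over", nrow(object@values), "genes; range",
    paste(sprintf("%.3f", range(object@values, na.rm = TRUE)),
      collapse = " .. "
    ), "\n"
  )
})

setMethod("show", "CellClassifierModel", function(object) {
  cat(
    "CellClassifierModel over", length(object@featureNames),
    "features; classes:", paste(object@classes, collapse = ", "), "\n"
  )
})
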
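#' @import methods
NULL

## ---------------------------------------------------------------------------
## Network and generative model
## ---------------------------------------------------------------------------

#' LatentNetwork: a gene set with signed interaction edges
#'
#' Holds gene identifiers, an edge table with effect labels
#' (activating / inhibiting / undefined) and optional pathway-set tags
#' per gene. Used both for synthetic benchmarks and for user-supplied
#' reference interaction sets.
#'
#' @slot genes Character vector of gene identifiers.
#' @slot edges data.frame with columns `geneA`, `geneB`, `effect`.
#' @slot pathwayTags Named list mapping genes to character vectors of
#'   pathway-set labels (possibly empty).
#' @exportClass LatentNetwork
setClass("LatentNetwork",
  representation(
    genes = "character",
    edges = "data.frame",
    pathwayTags = "list"
  )
)

setValidity("LatentNetwork", function(object) {
  e <- object@edges
  msgs <- character()
  need <- c("geneA", "geneB", "effect")
  if (!all(need %in% names(e))) {
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  }
  if (any(e$geneA == e$geneB)) msgs <- c(msgs, "self-edges are not allowed")
  keys <- pairKey(e$geneA, e$geneB)
  if (anyDuplicated(keys)) {
    msgs <- c(msgs, "each unordered pair may appear at most once")
  }
  if (!all(e$effect %in% effectLevels())) {
    msgs <- c(msgs, paste(
      "effect labels must be one of:",
      paste(effectLevels(), collapse = ", ")
    ))
  }
  if (!all(c(e$geneA, e$geneB) %in% object@genes)) {
    msgs <- c(msgs, "edge endpoints must be listed in genes")
  }
  if (length(msgs)) msgs else TRUE
})

#' PhenotypeModel: generative model for knockdown phenotypes
#'
#' A latent Gaussian phenotype per gene. Activating partners share a
#' centroid; inhibiting partners are separated by
#' `effectSize * noiseSd` in latent space. Each gene's morphological
#' class mixture interpolates linearly from a common start simplex to a
#' gene-specific end simplex tied to its centroid.
#'
#' @slot latentDim Integer, dimension of the latent phenotype space.
#' @slot centroids Numeric matrix, genes x latentDim (plus the
#'   negative control row `".control"`).
#' @slot effectSize Nonnegative centroid separation for inhibiting
#'   pairs, in units of `noiseSd`.
#' @slot noiseSd Positive within-gene standard deviation.
#' @slot classes Character vector of morphological class names.
#' @slot classMixStart Numeric matrix genes x classes, rows on the simplex.
#' @slot classMixEnd Numeric matrix genes x classes, rows on the simplex.
#' @exportClass PhenotypeModel
setClass("PhenotypeModel",
  representation(
    latentDim = "integer",
    centroids = "matrix",
    effectSize = "numeric",
    noiseSd = "numeric",
    classes = "character",
    classMixStart = "matrix",
    classMixEnd = "matrix"
  )
)

setValidity("PhenotypeModel", function(object) {
  msgs <- character()
  if (object@noiseSd <= 0) msgs <- c(msgs, "noiseSd must be positive")
  if (object@effectSize < 0) msgs <- c(msgs, "effectSize must be nonnegative")
  for (m in list(object@classMixStart, object@classMixEnd)) {
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
      msgs <- c(msgs, "class mixtures must be rows on the simplex")
    }
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Screen containers
## ---------------------------------------------------------------------------

#' KnockdownProfile: per-gene summary of a knockdown condition
#'
#' @slot gene Gene identifier (the negative control uses its own name).
#' @slot features Numeric matrix, one row per cell, named feature columns.
#' @slot timePoint Integer vector, the time point of each cell.
#' @slot classLabel Character vector, morphological class of each cell.
#' @slot classCounts Integer matrix time points x classes.
#' @slot intensityMedian,intensitySd Numeric intensity summaries.
#' @exportClass KnockdownProfile
setClass("KnockdownProfile",
  representation(
    gene = "character",
    features = "matrix",
    timePoint = "integer",
    classLabel = "character",
    classCounts = "matrix",
    intensityMedian = "numeric",
    intensitySd = "numeric"
  )
)

setValidity("KnockdownProfile", function(object) {
  msgs <- character()
  n <- nrow(object@features)
  if (length(object@timePoint) != n || length(object@classLabel) != n) {
    msgs <- c(msgs, "timePoint and classLabel must match the cell rows")
  }
  if (sum(object@classCounts) != n) {
    msgs <- c(msgs, "classCounts must sum to the number of cells")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticScreen: a full knockdown screen
#'
#' @slot profiles Named list of \linkS4class{KnockdownProfile}, one per gene.
#' @slot negativeControl \linkS4class{KnockdownProfile} of the negative
#'   control condition.
#' @slot timePoints Integer, number of time points on the shared axis.
#' @slot seed Integer seed the screen was generated from.
#' @exportClass SyntheticScreen
setClass("SyntheticScreen",
  representation(
    profiles = "list",
    negativeControl = "KnockdownProfile",
    timePoints = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticScreen", function(object) {
  msgs <- character()
  if (is.null(names(object@profiles)) || anyDuplicated(names(object@profiles))) {
    msgs <- c(msgs, "profiles must be uniquely named by gene")
  }
  fn <- lapply(object@profiles, function(p) colnames(p@features))
  if (length(fn) > 1L && !all(vapply(fn, identical, logical(1), fn[[1]]))) {
    msgs <- c(msgs, "all profiles must share the same feature names")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Image processing
## ---------------------------------------------------------------------------

#' NucleusImage: one grey-level screen image
#'
#' @slot pixels Numeric matrix of nonnegative grey values (16-bit
#'   semantics, i.e. values in [0, 65535]).
#' @slot timePoint Integer time point.
#' @slot gene Knocked-down gene.
#' @exportClass NucleusImage
setClass("NucleusImage",
  representation(pixels = "matrix", timePoint = "integer", gene = "character")
)

setValidity("NucleusImage", function(object) {
  if (any(object@pixels < 0)) return("pixel values must be nonnegative")
  if (any(dim(object@pixels) < 1L)) return("image dimensions must be positive")
  TRUE
})

#' SegmentationMask: labeled nucleus segmentation
#'
#' @slot labels Integer matrix; 0 is background, objects are 1..nObjects.
#' @slot nObjects Integer object count.
#' @slot threshold The grey-level threshold used (original image scale).
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(labels = "matrix", nObjects = "integer", threshold = "numeric")
)

setValidity("SegmentationMask", function(object) {
  lab <- object@labels
  n <- object@nObjects
  if (n > 0 && !all(seq_len(n) %in% lab)) {
    return("labels 1..nObjects must each be nonempty")
  }
  if (any(lab < 0) || any(lab > n)) return("labels out of range")
  TRUE
})

#' CellClassifierModel: the four-class cell morphology classifier
#'
#' A one-vs-one multi-class support vector machine over standardized
#' cell features; the standardization parameters are stored with the
#' model.
#'
#' @slot fit The underlying \code{\link[e1071]{svm}} model.
#' @slot center,scale Numeric vectors of standardization parameters.
#' @slot featureNames Feature registry the model was trained on.
#' @slot classes The class labels the model can predict.
#' @slot formatVersion Integer serialization format version.
#' @exportClass CellClassifierModel
setClass("CellClassifierModel",
  representation(
    fit = "ANY",
    center = "numeric",
    scale = "numeric",
    featureNames = "character",
    classes = "character",
    formatVersion = "integer"
  )
)

## ---------------------------------------------------------------------------
## Pair features
## ---------------------------------------------------------------------------

#' LDAResult: confusion counts of a pairwise linear discriminant
#'
#' @slot tp,tn,fp,fn Integer confusion counts on the held-out split.
#' @exportClass LDAResult
setClass("LDAResult",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer")
)

setValidity("LDAResult", function(object) {
  tot <- object@tp + object@tn + object@fp + object@fn
  if (any(c(object@tp, object@tn, object@fp, object@fn) < 0)) {
    return("confusion counts must be nonnegative")
  }
  if (tot <= 0) return("confusion counts must sum to a positive total")
  TRUE
})

#' MaximaProfile: per-gene phenotype maxima scores
#'
#' For each named phenotype, the maximal knockdown-minus-control cell
#' count difference over the time course and the time point where it
#' is attained (earliest on ties).
#'
#' @slot gene Gene identifier.
#' @slot scores Named numeric vector of maximal count differences.
#' @slot peakTimes Named numeric vector of the corresponding time points.
#' @exportClass MaximaProfile
setClass("MaximaProfile",
  representation(gene = "character", scores = "numeric", peakTimes = "numeric")
)

setValidity("MaximaProfile", function(object) {
  if (!identical(names(object@scores), names(object@peakTimes))) {
    return("scores and peakTimes must share phenotype names")
  }
  if (any(!is.finite(object@scores))) return("scores must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## Effect classifier
## ---------------------------------------------------------------------------

#' TrainingConfig: configuration of the voting ensemble
#'
#' The reference configuration is 10 cross-validation repeats x 10
#' folds x 10 SVMs per fold (a 1000-member ensemble), balanced
#' training strata of 80-400 pairs per class, and an inner 5-fold grid
#' search over C = 2^n, gamma = 2^n for n in -5..5. All sizes scale
#' down for smaller studies.
#'
#' @slot nRepeats,nFolds,svmsPerFold,stratumSize,innerFolds Integers.
#' @slot gridExp Integer exponents n defining the C and gamma grids 2^n.
#' @slot seed Integer master seed.
#' @slot perPathway Logical; train one ensemble per pathway set.
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(
    nRepeats = "integer",
    nFolds = "integer",
    svmsPerFold = "integer",
    stratumSize = "integer",
    innerFolds = "integer",
    gridExp = "integer",
    seed = "integer",
    perPathway = "logical"
  )
)

setValidity("TrainingConfig", function(object) {
  msgs <- character()
  if (object@nRepeats < 1 || object@nFolds < 2 || object@svmsPerFold < 1) {
    msgs <- c(msgs, "need nRepeats >= 1, nFolds >= 2, svmsPerFold >= 1")
  }
  if (object@stratumSize < 1) msgs <- c(msgs, "stratumSize must be >= 1")
  if (object@innerFolds < 2) msgs <- c(msgs, "innerFolds must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' PPIEnsemble: a trained voting ensemble
#'
#' @slot models List of trained members; each carries its SVM, its
#'   standardization parameters and the pairs it was trained on.
#' @slot config The \linkS4class{TrainingConfig} used.
#' @slot featureNames Descriptor columns the ensemble expects.
#' @slot pathway Pathway-set label ("" for the all-pathway ensemble).
#' @exportClass PPIEnsemble
setClass("PPIEnsemble",
  representation(
    models = "list",
    config = "TrainingConfig",
    featureNames = "character",
    pathway = "character"
  )
)

#' VoteSet: ensemble votes per gene pair
#'
#' @slot votes data.frame with columns `geneA`, `geneB`,
#'   `votesActivation`, `votesTotal`, `voteFraction`, and optionally
#'   `label` (known effect), `call` and `confidence`.
#' @exportClass VoteSet
setClass("VoteSet", representation(votes = "data.frame"))

setValidity("VoteSet", function(object) {
  v <- object@votes
  need <- c("geneA", "geneB", "votesActivation", "votesTotal", "voteFraction")
  if (!all(need %in% names(v))) {
    return(paste("votes must have columns", paste(need, collapse = ", ")))
  }
  if (any(v$votesActivation < 0 | v$votesActivation > v$votesTotal)) {
    return("votesActivation must lie in [0, votesTotal]")
  }
  if (any(abs(v$voteFraction - v$votesActivation / v$votesTotal) > 1e-8)) {
    return("voteFraction must equal votesActivation / votesTotal")
  }
  TRUE
})

#' PerformanceReport: ROC curve and threshold table for ensemble votes
#'
#' @slot rocPoints data.frame with columns `threshold`, `fpr`, `tpr`.
#' @slot auc Numeric area under the ROC curve (trapezoidal).
#' @slot thresholds data.frame of per-threshold precision, accuracy,
#'   sensitivity and specificity.
#' @slot positiveClass "activating" or "inhibiting".
#' @exportClass PerformanceReport
setClass("PerformanceReport",
  representation(
    rocPoints = "data.frame",
    auc = "numeric",
    thresholds = "data.frame",
    positiveClass = "character"
  )
)

#' ConfidenceCalibration: vote cutoffs for a target precision
#'
#' Cutoffs are stored as fractions of the total votes so that scaled
#' ensembles remain comparable to the 1000-SVM reference convention
#' (e.g. 920/1000 and 88/1000).
#'
#' @slot table data.frame of per-threshold precision, sensitivity,
#'   specificity and accuracy for both call directions.
#' @slot actCutoff Smallest vote fraction calling activation at the
#'   target precision (NA when unreachable).
#' @slot inhCutoff Largest vote fraction calling inhibition at the
#'   target precision (NA when unreachable).
#' @slot targetPrecision The requested precision.
#' @exportClass ConfidenceCalibration
setClass("ConfidenceCalibration",
  representation(
    table = "data.frame",
    actCutoff = "numeric",
    inhCutoff = "numeric",
    targetPrecision = "numeric"
  )
)

## ---------------------------------------------------------------------------
## ESR
## ---------------------------------------------------------------------------

#' ESRMatrix: symmetric Effect Similarity Rate matrix
#'
#' @slot values Symmetric numeric matrix with entries in [-1, 1] and an
#'   unset (NA) diagonal; dimnames are the gene identifiers.
#' @exportClass ESRMatrix
setClass("ESRMatrix", representation(values = "matrix"))

setValidity("ESRMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v) || is.null(rownames(v)) ||
      !identical(rownames(v), colnames(v))) {
    return("values must be square with matching gene dimnames")
  }
  off <- v[row(v) != col(v)]
  if (any(!is.na(off) & (off < -1 | off > 1))) {
    msgs <- c(msgs, "ESR entries must lie in [-1, 1]")
  }
  if (!isTRUE(all.equal(v, t(v)))) msgs <- c(msgs, "matrix must be symmetric")
  if (length(msgs)) msgs else TRUE
})
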
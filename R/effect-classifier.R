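## Stratified SVM voting ensemble for activating vs. inhibiting PPIs.
##
## Training follows the repeated stratified cross-validation scheme:
## per repeat the labeled pairs are split (per class) into folds; for
## each fold's training complement, several SVMs are each fitted on a
## balanced random stratum of activating and inhibiting pairs, with an
## inner-fold grid search over the RBF cost and kernel width. Each
## held-out pair collects one activation vote per SVM of its own fold
## across all repeats, so no classifier ever votes on a pair it saw in
## training. Vote thresholds are expressed as fractions of the total
## votes, keeping scaled ensembles comparable to the 1000-SVM
## reference convention (cutoffs 920/1000 and 88/1000 at 80%
## precision).

#' Construct a training configuration
#'
#' Defaults are a scaled-down ensemble suitable for desk-size studies;
#' the reference configuration of the full-scale method is
#' `trainingConfig(10, 10, 10, stratumSize = 80)` (1000 SVMs, strata of
#' 80-400 pairs per class).
#'
#' @param nRepeats Cross-validation repeats.
#' @param nFolds Folds per repeat.
#' @param svmsPerFold Balanced SVMs trained per fold.
#' @param stratumSize Pairs per class in each balanced training sample.
#' @param innerFolds Folds of the inner grid-search cross-validation.
#' @param gridExp Integer exponents: C and gamma are searched over 2^n.
#' @param seed Master seed; all randomness derives from it.
#' @param perPathway Train one ensemble per pathway set.
#' @return A \linkS4class{TrainingConfig}.
#' @export
trainingConfig <- function(nRepeats = 2L, nFolds = 5L, svmsPerFold = 5L,
                           stratumSize = 40L, innerFolds = 5L,
                           gridExp = -5:5, seed = 1L, perPathway = FALSE) {
  new("TrainingConfig",
    nRepeats = as.integer(nRepeats), nFolds = as.integer(nFolds),
    svmsPerFold = as.integer(svmsPerFold),
    stratumSize = as.integer(stratumSize),
    innerFolds = as.integer(innerFolds), gridExp = as.integer(gridExp),
    seed = as.integer(seed), perPathway = isTRUE(perPathway)
  )
}

## Grid search over (C, gamma) = (2^i, 2^j) minimizing inner-CV
## misclassification. Ties break to the smallest C, then the smallest
## gamma (the smoother model), deterministically.
svmGridSearch <- function(x, y, gridExp, innerFolds, seed) {
  n <- nrow(x)
  folds <- withSeed(seed, sample(rep_len(seq_len(innerFolds), n)))
  grid <- expand.grid(gexp = gridExp, cexp = gridExp) # C varies slowest
  grid <- grid[order(grid$cexp, grid$gexp), ]
  best <- NULL
  bestErr <- Inf
  for (r in seq_len(nrow(grid))) {
    cc <- 2^grid$cexp[r]
    gg <- 2^grid$gexp[r]
    err <- 0
    for (f in seq_len(innerFolds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr],
        kernel = "radial", cost = cc, gamma = gg, scale = FALSE
      )
      err <- err + sum(predict(m, x[!tr, , drop = FALSE]) != y[!tr])
    }
    if (err < bestErr) { # strict: first (smallest C, gamma) wins ties
      bestErr <- err
      best <- c(cost = cc, gamma = gg)
    }
  }
  best
}

## Standardize by training-sample column means/SDs (zero SD -> scale 1).
fitScaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

applyScaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

## Train one balanced ensemble member on a stratum of the training
## complement. Returns the fitted svm plus its scaler and metadata.
trainMember <- function(descriptors, actKeys, inhKeys, config, seed) {
  stratum <- config@stratumSize
  if (length(actKeys) < stratum || length(inhKeys) < stratum) {
    stop(
      "training fold has ", length(actKeys), " activating and ",
      length(inhKeys), " inhibiting pairs; stratumSize ", stratum,
      " is not available"
    )
  }
  sel <- withSeed(seed, c(sample(actKeys, stratum), sample(inhKeys, stratum)))
  x <- descriptors[sel, , drop = FALSE]
  y <- factor(
    rep(c("activating", "inhibiting"), each = stratum),
    levels = c("activating", "inhibiting")
  )
  scaler <- fitScaler(x)
  xs <- applyScaler(x, scaler)
  par <- svmGridSearch(
    xs, y, config@gridExp, config@innerFolds,
    seed = subSeed(seed, "grid")
  )
  fit <- e1071::svm(xs, y,
    kernel = "radial", cost = par[["cost"]], gamma = par[["gamma"]],
    scale = FALSE
  )
  list(
    fit = fit, scaler = scaler, cost = par[["cost"]],
    gamma = par[["gamma"]], trainKeys = sel
  )
}

memberVotes <- function(member, descriptors) {
  xs <- applyScaler(descriptors, member$scaler)
  predict(member$fit, xs) == "activating"
}

#' Train the voting ensemble by stratified cross-validation
#'
#' @param pairs data.frame with columns `geneA`, `geneB`, `effect`
#'   (activating / inhibiting); additional columns are ignored.
#' @param descriptors Numeric matrix of pair descriptors with rownames
#'   equal to the pair keys (see \code{\link{pairDescriptorTable}}).
#' @param config A \linkS4class{TrainingConfig}.
#' @return List with elements `ensemble` (a \linkS4class{PPIEnsemble}
#'   of all nRepeats x nFolds x svmsPerFold members) and `votes` (a
#'   \linkS4class{VoteSet} of cross-validated held-out votes, with the
#'   known labels attached).
#' @export
stratifiedCvTrain <- function(pairs, descriptors, config = trainingConfig()) {
  keys <- pairKey(pairs$geneA, pairs$geneB)
  if (anyDuplicated(keys)) stop("duplicate gene pairs in training data")
  lab <- pairs$effect
  if (!all(lab %in% c("activating", "inhibiting"))) {
    stop("training pairs must be labeled activating or inhibiting")
  }
  if (length(unique(lab)) < 2L) stop("both classes must be present")
  miss <- setdiff(keys, rownames(descriptors))
  if (length(miss)) {
    stop("descriptors missing for pairs: ", paste(miss, collapse = ", "))
  }
  descriptors <- descriptors[keys, , drop = FALSE]
  actKeys <- keys[lab == "activating"]
  inhKeys <- keys[lab == "inhibiting"]
  R <- config@nRepeats
  nF <- config@nFolds
  S <- config@svmsPerFold
  votesAct <- stats::setNames(integer(length(keys)), keys)
  members <- vector("list", R * nF * S)
  for (r in seq_len(R)) {
    ## per-class fold assignment keeps every training complement
    ## balanced enough for the stratum
    foldOf <- withSeed(subSeed(config@seed, paste0("folds:", r)), {
      f <- integer(length(keys))
      names(f) <- keys
      f[actKeys] <- sample(rep_len(seq_len(nF), length(actKeys)))
      f[inhKeys] <- sample(rep_len(seq_len(nF), length(inhKeys)))
      f
    })
    for (f in seq_len(nF)) {
      holdKeys <- keys[foldOf == f]
      trainAct <- actKeys[foldOf[actKeys] != f]
      trainInh <- inhKeys[foldOf[inhKeys] != f]
      for (s in seq_len(S)) {
        m <- trainMember(
          descriptors, trainAct, trainInh, config,
          seed = subSeed(config@seed, sprintf("member:%d:%d:%d", r, f, s))
        )
        members[[((r - 1) * nF + (f - 1)) * S + s]] <- m
        if (length(holdKeys)) {
          v <- memberVotes(m, descriptors[holdKeys, , drop = FALSE])
          votesAct[holdKeys] <- votesAct[holdKeys] + v
        }
      }
    }
  }
  total <- R * S # votes a pair receives: its fold's S SVMs per repeat
  votes <- data.frame(
    geneA = pairs$geneA, geneB = pairs$geneB,
    votesActivation = as.integer(votesAct[keys]),
    votesTotal = total,
    voteFraction = as.numeric(votesAct[keys]) / total,
    label = lab,
    stringsAsFactors = FALSE
  )
  ensemble <- new("PPIEnsemble",
    models = members, config = config,
    featureNames = colnames(descriptors), pathway = ""
  )
  list(ensemble = ensemble, votes = new("VoteSet", votes = votes))
}

#' ROC curve and AUC of cross-validated votes
#'
#' Sweeps the decision threshold over all observed vote fractions and
#' reports the trapezoidal area under the ROC curve. For
#' `positiveClass = "inhibiting"` the vote scale is reversed, so both
#' prediction directions can be evaluated.
#'
#' @param votes A \linkS4class{VoteSet} with a `label` column, or its
#'   underlying data.frame.
#' @param labels Optional character vector of known effects overriding
#'   the `label` column.
#' @param positiveClass "activating" (default) or "inhibiting".
#' @return A \linkS4class{PerformanceReport}.
#' @export
rocAuc <- function(votes, labels = NULL, positiveClass = "activating") {
  v <- if (is(votes, "VoteSet")) voteTable(votes) else votes
  if (is.null(labels)) labels <- v$label
  if (is.null(labels)) stop("labels are required")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in labels")
  }
  positiveClass <- match.arg(positiveClass, c("activating", "inhibiting"))
  score <- if (positiveClass == "activating") {
    v$voteFraction
  } else {
    1 - v$voteFraction
  }
  pos <- labels == positiveClass
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pred <- score >= t
    c(
      fpr = sum(pred & !pos) / sum(!pos),
      tpr = sum(pred & pos) / sum(pos),
      precision = if (any(pred)) sum(pred & pos) / sum(pred) else NA_real_,
      accuracy = mean(pred == pos),
      sensitivity = sum(pred & pos) / sum(pos),
      specificity = sum(!pred & !pos) / sum(!pos)
    )
  }, numeric(6)))
  roc <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, pts[, "fpr"]),
    tpr = c(0, pts[, "tpr"])
  )
  if (utils::tail(roc$fpr, 1) < 1 || utils::tail(roc$tpr, 1) < 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  o <- order(roc$fpr, roc$tpr)
  aucVal <- sum(diff(roc$fpr[o]) *
    (utils::head(roc$tpr[o], -1) + utils::tail(roc$tpr[o], -1)) / 2)
  new("PerformanceReport",
    rocPoints = roc,
    auc = aucVal,
    thresholds = data.frame(threshold = thr, pts),
    positiveClass = positiveClass
  )
}

#' Calibrate vote cutoffs to a target precision
#'
#' From held-out cross-validation votes only: the activation cutoff is
#' the smallest vote fraction whose >=-threshold precision for
#' activation reaches the target; the inhibition cutoff is the largest
#' vote fraction whose <=-threshold precision for inhibition reaches
#' it. When a direction cannot reach the target its cutoff is NA and
#' the table flags it.
#'
#' @param votes A \linkS4class{VoteSet} with labels (cross-validated,
#'   never training predictions).
#' @param labels Optional label override.
#' @param targetPrecision Target precision (default 0.8, the
#'   80%-confidence convention).
#' @return A \linkS4class{ConfidenceCalibration}.
#' @export
calibrateThresholds <- function(votes, labels = NULL, targetPrecision = 0.8) {
  v <- if (is(votes, "VoteSet")) voteTable(votes) else votes
  if (is.null(labels)) labels <- v$label
  if (is.null(labels)) stop("labels are required")
  fr <- v$voteFraction
  act <- labels == "activating"
  thr <- sort(unique(fr))
  tab <- data.frame(
    threshold = thr,
    precisionAct = vapply(thr, function(t) mean(act[fr >= t]), numeric(1)),
    sensitivityAct = vapply(
      thr, function(t) sum(act & fr >= t) / sum(act),
      numeric(1)
    ),
    specificityAct = vapply(
      thr, function(t) sum(!act & fr < t) / sum(!act),
      numeric(1)
    ),
    precisionInh = vapply(thr, function(t) mean(!act[fr <= t]), numeric(1)),
    sensitivityInh = vapply(
      thr, function(t) sum(!act & fr <= t) / sum(!act),
      numeric(1)
    ),
    specificityInh = vapply(
      thr, function(t) sum(act & fr > t) / sum(act),
      numeric(1)
    ),
    accuracyAct = vapply(
      thr, function(t) mean((fr >= t) == act),
      numeric(1)
    )
  )
  okAct <- thr[!is.na(tab$precisionAct) & tab$precisionAct >= targetPrecision]
  okInh <- thr[!is.na(tab$precisionInh) & tab$precisionInh >= targetPrecision]
  tab$reachesTargetAct <- tab$threshold %in% okAct
  tab$reachesTargetInh <- tab$threshold %in% okInh
  new("ConfidenceCalibration",
    table = tab,
    actCutoff = if (length(okAct)) min(okAct) else NA_real_,
    inhCutoff = if (length(okInh)) max(okInh) else NA_real_,
    targetPrecision = targetPrecision
  )
}

## Turn vote fractions into calls using calibrated cutoffs.
applyCutoffs <- function(fraction, calibration) {
  call <- rep("none", length(fraction))
  a <- actCutoff(calibration)
  i <- inhCutoff(calibration)
  if (!is.na(a)) call[fraction >= a] <- "activating"
  if (!is.na(i)) call[call == "none" & fraction <= i] <- "inhibiting"
  call
}

## Average vote fractions of one pair across several applicable
## ensembles (pairs belonging to more than one pathway set).
averageVoteFractions <- function(fractions) {
  mean(fractions)
}

#' Predict the effect of undefined interactions
#'
#' Every ensemble member votes on every pair; calls are made with the
#' calibrated cutoffs. With a named list of per-pathway ensembles, a
#' pair belonging to several pathway sets has its vote fractions
#' averaged across the applicable models. Pairs without a descriptor
#' row are skipped with a message.
#'
#' @param ensemble A \linkS4class{PPIEnsemble}, or a named list of them
#'   for per-pathway prediction.
#' @param pairs data.frame with columns geneA, geneB (and, for
#'   per-pathway prediction, a `pathways` list-column of set labels).
#' @param descriptors Descriptor matrix with pair-key rownames.
#' @param calibration A \linkS4class{ConfidenceCalibration}.
#' @return A \linkS4class{VoteSet} with `call` and `confidence` columns
#'   (confidence is the calibrated precision at the pair's vote
#'   fraction, when available).
#' @export
predictUndefined <- function(ensemble, pairs, descriptors, calibration) {
  keys <- pairKey(pairs$geneA, pairs$geneB)
  have <- keys %in% rownames(descriptors)
  if (any(!have)) {
    message(
      "skipping ", sum(!have), " pair(s) without descriptors: ",
      paste(utils::head(keys[!have], 5L), collapse = ", ")
    )
    pairs <- pairs[have, , drop = FALSE]
    keys <- keys[have]
  }
  ensembles <- if (is(ensemble, "PPIEnsemble")) list(ensemble) else ensemble
  fracPerEns <- vapply(ensembles, function(ens) {
    x <- descriptors[keys, ens@featureNames, drop = FALSE]
    votes <- rowSums(vapply(
      ens@models, function(m) memberVotes(m, x),
      logical(length(keys))
    ))
    votes / length(ens@models)
  }, numeric(length(keys)))
  fracPerEns <- matrix(fracPerEns, nrow = length(keys))
  if (length(ensembles) > 1L && !is.null(names(ensembles)) &&
      "pathways" %in% names(pairs)) {
    frac <- vapply(seq_along(keys), function(i) {
      appl <- which(names(ensembles) %in% pairs$pathways[[i]])
      if (length(appl) == 0L) appl <- seq_along(ensembles)
      averageVoteFractions(fracPerEns[i, appl])
    }, numeric(1))
  } else {
    frac <- rowMeans(fracPerEns)
  }
  total <- length(ensembles[[1L]]@models)
  call <- applyCutoffs(frac, calibration)
  ## confidence: calibrated >= / <= -threshold precision at the pair's
  ## vote fraction
  tab <- calibration@table
  conf <- rep(NA_real_, length(frac))
  for (i in seq_along(frac)) {
    if (call[i] == "activating") {
      rows <- tab$threshold <= frac[i]
      if (any(rows)) conf[i] <- tab$precisionAct[max(which(rows))]
    } else if (call[i] == "inhibiting") {
      rows <- tab$threshold >= frac[i]
      if (any(rows)) conf[i] <- tab$precisionInh[min(which(rows))]
    }
  }
  new("VoteSet", votes = data.frame(
    geneA = pairs$geneA, geneB = pairs$geneB,
    votesActivation = as.integer(round(frac * total)),
    votesTotal = total,
    voteFraction = round(frac * total) / total,
    call = call,
    confidence = conf,
    stringsAsFactors = FALSE
  ))
}

#' Sign-score baseline for effect prediction
#'
#' The z-score regulator-calling procedure used for method comparison:
#' per-gene features are z-transformed per column; a gene is a positive
#' (+1) or negative (-1) regulator of a feature when its z-score passes
#' +/- `zCutoff`. For an interacting pair, each feature with both genes
#' called contributes a positive correlation (same sign) or a negative
#' one (opposite signs). Pair-level discriminant accuracies are
#' z-transformed directly into correlation calls (high accuracy =
#' dissimilar = negative correlation). The sign score
#' (nPos - nNeg) / (nPos + nNeg) predicts activation when positive and
#' inhibition when negative; pairs with fewer than `minMatching`
#' matched features are dropped from evaluation.
#'
#' @param geneFeatures Numeric matrix, genes x features.
#' @param pairs data.frame with columns geneA, geneB.
#' @param gold Character vector of known effects for `pairs`
#'   (activating / inhibiting), used for precision and recall.
#' @param pairLda Optional named numeric vector (pair keys) of
#'   LDA-performance accuracies.
#' @param zCutoff Regulator z-score cutoff (default 1.5).
#' @param minMatching Minimum matched features per pair (default 2).
#' @return List with `scores` (per-pair data.frame: nPos, nNeg,
#'   signScore, prediction, kept), `precision`, `recall` and
#'   `nSelected`. Precision takes activation as the positive class;
#'   recall is over all supplied activating pairs.
#' @export
signScoreBaseline <- function(geneFeatures, pairs, gold, pairLda = NULL,
                              zCutoff = 1.5, minMatching = 2L) {
  sds <- apply(geneFeatures, 2L, stats::sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    message(
      "skipping zero-variance feature(s): ",
      paste(colnames(geneFeatures)[drop], collapse = ", ")
    )
    geneFeatures <- geneFeatures[, !drop, drop = FALSE]
  }
  z <- scale(geneFeatures)
  reg <- matrix(0L, nrow(z), ncol(z), dimnames = dimnames(z))
  reg[z >= zCutoff] <- 1L
  reg[z <= -zCutoff] <- -1L
  ldaCall <- NULL
  if (!is.null(pairLda)) {
    zl <- (pairLda - mean(pairLda)) / stats::sd(pairLda)
    ## dissimilar phenotypes (high accuracy) read as negative correlation
    ldaCall <- ifelse(zl >= zCutoff, -1L, ifelse(zl <= -zCutoff, 1L, 0L))
    names(ldaCall) <- names(pairLda)
  }
  keys <- pairKey(pairs$geneA, pairs$geneB)
  nPos <- nNeg <- integer(length(keys))
  for (i in seq_along(keys)) {
    ra <- reg[pairs$geneA[i], ]
    rb <- reg[pairs$geneB[i], ]
    both <- ra != 0L & rb != 0L
    nPos[i] <- sum(both & ra == rb)
    nNeg[i] <- sum(both & ra != rb)
    if (!is.null(ldaCall) && !is.na(ldaCall[keys[i]]) &&
        ldaCall[keys[i]] != 0L) {
      if (ldaCall[keys[i]] > 0L) nPos[i] <- nPos[i] + 1L
      if (ldaCall[keys[i]] < 0L) nNeg[i] <- nNeg[i] + 1L
    }
  }
  matched <- nPos + nNeg
  score <- ifelse(matched > 0L, (nPos - nNeg) / matched, NA_real_)
  kept <- matched >= minMatching
  prediction <- rep(NA_character_, length(keys))
  prediction[kept & score > 0] <- "activating"
  prediction[kept & score < 0] <- "inhibiting"
  eval <- kept & !is.na(prediction)
  tp <- sum(eval & prediction == "activating" & gold == "activating")
  fp <- sum(eval & prediction == "activating" & gold != "activating")
  list(
    scores = data.frame(
      geneA = pairs$geneA, geneB = pairs$geneB,
      nPos = nPos, nNeg = nNeg, signScore = score,
      prediction = prediction, kept = kept,
      stringsAsFactors = FALSE
    ),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (sum(gold == "activating") > 0) {
      tp / sum(gold == "activating")
    } else {
      NA_real_
    },
    nSelected = sum(eval)
  )
}
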
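## Image front end: nucleus segmentation, per-cell features, four-class
## morphology classification.
##
## Nuclei are segmented by Otsu thresholding; touching nuclei are not
## split, since clusters of cells form their own morphological class
## ("shape"). Each object is described by a fixed feature registry
## spanning intensity, shape, Haralick texture (64 grey levels,
## distance-1 co-occurrence averaged over 4 directions), a Zernike
## moment subset and edge-related features.

#' Construct a NucleusImage
#'
#' @param pixels Numeric matrix of grey values (16-bit semantics).
#' @param gene Knocked-down gene identifier.
#' @param timePoint Integer time point of the frame.
#' @return A \linkS4class{NucleusImage}.
#' @export
nucleusImage <- function(pixels, gene = "", timePoint = 1L) {
  new("NucleusImage",
    pixels = pixels, gene = gene,
    timePoint = as.integer(timePoint)
  )
}

#' Read a 16-bit grey TIFF or PNG screen image
#'
#' @param file Path to the image.
#' @param gene,timePoint Metadata attached to the image.
#' @return A \linkS4class{NucleusImage} with pixel values on the
#'   16-bit scale.
#' @export
readNucleusImage <- function(file, gene = "", timePoint = 1L) {
  img <- EBImage::readImage(file)
  px <- EBImage::imageData(img)
  if (length(dim(px)) > 2L) px <- px[, , 1L]
  nucleusImage(px * 65535, gene = gene, timePoint = timePoint)
}

#' Segment nuclei by Otsu thresholding
#'
#' Chooses the grey-level threshold maximizing the between-class
#' variance of the image histogram, labels connected foreground
#' components, removes components smaller than `minObjectArea` and
#' relabels the rest in scan order of their first pixel.
#'
#' @param image A \linkS4class{NucleusImage} or a numeric matrix.
#' @param minObjectArea Minimum object area in pixels.
#' @return A \linkS4class{SegmentationMask}; the chosen threshold (on
#'   the original grey scale) is available in its `threshold` slot.
#' @examples
#' px <- matrix(100, 64, 64)
#' px[10:20, 10:20] <- 1000
#' mask <- segmentOtsu(nucleusImage(px))
#' mask@nObjects
#' @export
segmentOtsu <- function(image, minObjectArea = 0L) {
  px <- if (is(image, "NucleusImage")) image@pixels else image
  rng <- range(px)
  if (diff(rng) == 0) stop("degenerate histogram: image is constant")
  img01 <- (px - rng[1L]) / diff(rng)
  th01 <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1), levels = 4096L)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(img01 > th01)))
  n <- max(lab)
  if (n > 0L) {
    areas <- tabulate(lab, nbins = n)
    keep <- which(areas >= minObjectArea)
    ## relabel survivors by first-pixel scan order
    first <- vapply(keep, function(l) which(lab == l)[1L], integer(1))
    keep <- keep[order(first)]
    relab <- integer(n + 1L) # index by label + 1; background stays 0
    relab[keep + 1L] <- seq_along(keep)
    lab[] <- relab[lab + 1L]
    n <- length(keep)
  }
  new("SegmentationMask",
    labels = matrix(as.integer(lab), nrow(px)),
    nObjects = as.integer(n),
    threshold = rng[1L] + th01 * diff(rng)
  )
}

## Zernike moment magnitudes of one object, computed on its
## mass-normalized intensity over the enclosing disk centered at the
## intensity centroid (hence translation invariant). Orders (n, m)
## with n <= 4.
zernikeRadial <- function(n, m, rho) {
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
        factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
  }
  out
}

zernikeMoments <- function(rows, cols, vals,
                           orders = list(
                             c(2, 0), c(2, 2), c(3, 1),
                             c(3, 3), c(4, 0), c(4, 2)
                           )) {
  w <- vals / sum(vals)
  cy <- sum(rows * w)
  cx <- sum(cols * w)
  dy <- rows - cy
  dx <- cols - cx
  r <- sqrt(dx^2 + dy^2)
  rad <- max(r, 1)
  rho <- r / rad
  theta <- atan2(dy, dx)
  out <- vapply(orders, function(nm) {
    n <- nm[1L]
    m <- nm[2L]
    v <- sum(w * zernikeRadial(n, m, rho) * exp(complex(imaginary = -m * theta)))
    (n + 1) / pi * Mod(v)
  }, numeric(1))
  names(out) <- vapply(orders, function(nm) {
    sprintf("z.%d%d", nm[1L], nm[2L])
  }, character(1))
  out
}

#' The fixed cell feature registry
#'
#' Feature names, in extraction order, shared by every run: intensity
#' summaries, shape descriptors, eccentricity and major axis, 13
#' Haralick texture features (64 grey levels, distance 1, averaged
#' over 4 directions), 6 Zernike moment magnitudes and edge features.
#'
#' @return Character vector of feature names.
#' @export
cellFeatureRegistry <- function() {
  c(
    "intensity.mean", "intensity.median", "intensity.sd",
    "s.area", "s.perimeter", "s.radius.mean", "s.radius.sd",
    "s.radius.min", "s.radius.max",
    "m.majoraxis", "m.eccentricity",
    paste0("h.", c(
      "asm", "con", "cor", "var", "idm", "sav", "sva",
      "sen", "ent", "dva", "den", "f12", "f13"
    ), ".s1"),
    "z.20", "z.22", "z.31", "z.33", "z.40", "z.42",
    "edge.mean", "edge.frac"
  )
}

#' Extract per-cell features from a segmented image
#'
#' @param image A \linkS4class{NucleusImage}.
#' @param mask A matching \linkS4class{SegmentationMask}.
#' @return data.frame with columns gene, time_point, class_label
#'   (unset) and one column per registry feature; one row per object
#'   (empty for an empty mask).
#' @export
extractCellFeatures <- function(image, mask) {
  px <- image@pixels
  lab <- mask@labels
  if (!identical(dim(px), dim(lab))) {
    stop("mask shape does not match the image")
  }
  reg <- cellFeatureRegistry()
  empty <- as.data.frame(
    stats::setNames(
      c(
        list(character(0), integer(0), character(0)),
        rep(list(numeric(0)), length(reg))
      ),
      c("gene", "time_point", "class_label", reg)
    )
  )
  n <- mask@nObjects
  if (n == 0L) return(empty)
  rng <- range(px)
  img01 <- if (diff(rng) > 0) (px - rng[1L]) / diff(rng) else px * 0
  labImg <- EBImage::Image(lab)
  refImg <- EBImage::Image(img01)
  shp <- EBImage::computeFeatures.shape(labImg)
  mom <- EBImage::computeFeatures.moment(labImg, refImg)
  har <- EBImage::computeFeatures.haralick(labImg, refImg,
    haralick.nbins = 64L, haralick.scales = 1L
  )
  ## boundary: object pixels with a 4-neighbour outside the object
  nr <- nrow(lab)
  nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  isEdge <- ctr > 0L & (
    pad[1:nr, 2:(nc + 1L)] != ctr | pad[3:(nr + 2L), 2:(nc + 1L)] != ctr |
      pad[2:(nr + 1L), 1:nc] != ctr | pad[2:(nr + 1L), 3:(nc + 2L)] != ctr
  )
  rows <- lapply(seq_len(n), function(l) {
    sel <- lab == l
    vals <- px[sel]
    pos <- which(sel, arr.ind = TRUE)
    zr <- zernikeMoments(pos[, 1L], pos[, 2L], img01[sel] + 1e-12)
    edgeSel <- sel & isEdge
    c(
      intensity.mean = mean(vals),
      intensity.median = stats::median(vals),
      intensity.sd = if (length(vals) > 1L) stats::sd(vals) else 0,
      shp[l, c(
        "s.area", "s.perimeter", "s.radius.mean", "s.radius.sd",
        "s.radius.min", "s.radius.max"
      )],
      mom[l, c("m.majoraxis", "m.eccentricity")],
      har[l, ],
      zr,
      edge.mean = mean(px[edgeSel]),
      edge.frac = sum(edgeSel) / sum(sel)
    )
  })
  feat <- do.call(rbind, rows)
  colnames(feat) <- reg
  out <- data.frame(
    gene = rep(image@gene, n),
    time_point = rep(image@timePoint, n),
    class_label = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(feat))
}

cellFeatureMatrix <- function(cells, featureNames) {
  miss <- setdiff(featureNames, names(cells))
  if (length(miss)) {
    stop("cell features missing: ", paste(miss, collapse = ", "))
  }
  as.matrix(cells[, featureNames, drop = FALSE])
}

#' Train the four-class cell morphology classifier
#'
#' A one-vs-one multi-class SVM (RBF kernel) over standardized
#' features, with the cost and kernel width chosen by an inner
#' cross-validated grid search over C = 2^n, gamma = 2^n.
#'
#' @param cells data.frame of labeled cells: a `class_label` column
#'   plus numeric feature columns (e.g. from
#'   \code{\link{extractCellFeatures}}).
#' @param featureNames Features to train on; defaults to all numeric
#'   columns except bookkeeping ones.
#' @param gridExp Grid-search exponents.
#' @param innerFolds Inner cross-validation folds.
#' @param seed Integer seed.
#' @return A \linkS4class{CellClassifierModel}.
#' @export
trainCellClassifier <- function(cells, featureNames = NULL, gridExp = -5:5,
                                innerFolds = 5L, seed = 1L) {
  if (is.null(featureNames)) {
    featureNames <- setdiff(
      names(cells)[vapply(cells, is.numeric, logical(1))],
      c("time_point", "timePoint")
    )
  }
  y <- factor(cells$class_label)
  if (nlevels(y) < 2L) stop("need at least 2 classes to train")
  if (any(table(y) < 10L)) stop("need at least 10 cells per class")
  x <- cellFeatureMatrix(cells, featureNames)
  scaler <- fitScaler(x)
  xs <- applyScaler(x, scaler)
  par <- svmGridSearch(xs, y, gridExp, innerFolds,
    seed = subSeed(seed, "cellgrid")
  )
  fit <- e1071::svm(xs, y,
    kernel = "radial", cost = par[["cost"]],
    gamma = par[["gamma"]], scale = FALSE
  )
  new("CellClassifierModel",
    fit = fit, center = scaler$center, scale = scaler$scale,
    featureNames = featureNames, classes = levels(y), formatVersion = 1L
  )
}

#' Classify cells into the morphological classes
#'
#' @param model A \linkS4class{CellClassifierModel}.
#' @param cells data.frame of cells with the model's feature registry.
#' @return `cells` with `class_label` filled in; input order preserved.
#' @export
classifyCells <- function(model, cells) {
  if (nrow(cells) == 0L) return(cells)
  x <- cellFeatureMatrix(cells, model@featureNames)
  xs <- applyScaler(x, list(center = model@center, scale = model@scale))
  cells$class_label <- as.character(predict(model@fit, xs))
  cells
}

#' Serialize / restore a cell classifier
#'
#' The file carries a format-version field so future layouts can be
#' migrated.
#'
#' @param model A \linkS4class{CellClassifierModel}.
#' @param file Path to write to / read from.
#' @return `loadCellClassifier` returns the model.
#' @export
saveCellClassifier <- function(model, file) {
  saveRDS(list(
    formatVersion = model@formatVersion,
    fit = model@fit, center = model@center, scale = model@scale,
    featureNames = model@featureNames, classes = model@classes
  ), file)
  invisible(file)
}

#' @rdname saveCellClassifier
#' @export
loadCellClassifier <- function(file) {
  obj <- readRDS(file)
  if (is.null(obj$formatVersion) || obj$formatVersion != 1L) {
    stop("unsupported classifier file format")
  }
  new("CellClassifierModel",
    fit = obj$fit, center = obj$center, scale = obj$scale,
    featureNames = obj$featureNames, classes = obj$classes,
    formatVersion = obj$formatVersion
  )
}
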
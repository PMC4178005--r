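## Plain-text interchange formats. All tables are tab-separated with a
## header; screens round-trip through a per-cell table and a long-form
## class-count table.

writeTsv <- function(x, file) {
  utils::write.table(x, file,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(file)
}

readTsv <- function(file) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a network as 3-column TSV
#'
#' Columns: geneA, geneB, effect. `readNetwork` accepts an optional
#' full gene list; by default the genes are those on the edges.
#'
#' @param network A \linkS4class{LatentNetwork}.
#' @param file Path of the TSV file.
#' @param genes Optional gene universe for `readNetwork`.
#' @return `readNetwork` returns a \linkS4class{LatentNetwork}.
#' @export
writeNetwork <- function(network, file) {
  writeTsv(edgeTable(network), file)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(file, genes = NULL) {
  e <- readTsv(file)
  checkEffects(e$effect)
  if (is.null(genes)) genes <- sort(unique(c(e$geneA, e$geneB)))
  new("LatentNetwork",
    genes = genes, edges = e,
    pathwayTags = stats::setNames(rep(list(character()), length(genes)), genes)
  )
}

profileCellTable <- function(p) {
  data.frame(
    gene = p@gene,
    time_point = p@timePoint,
    class_label = p@classLabel,
    p@features,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}

profileCountTable <- function(p) {
  cc <- p@classCounts
  data.frame(
    gene = p@gene,
    time_point = rep(as.integer(rownames(cc)), ncol(cc)),
    class = rep(colnames(cc), each = nrow(cc)),
    count = as.vector(cc),
    stringsAsFactors = FALSE
  )
}

#' Write a screen to a directory of TSV files
#'
#' Produces `cells.tsv` (one row per cell: gene, time_point,
#' class_label, feature columns) and `class_counts.tsv` (long form:
#' gene, time_point, class, count). The negative control is stored
#' under the gene name `negative_control`.
#'
#' @param screen A \linkS4class{SyntheticScreen}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeScreen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all <- c(profiles(screen), list(controlProfile(screen)))
  writeTsv(
    do.call(rbind, lapply(all, profileCellTable)),
    file.path(dir, "cells.tsv")
  )
  writeTsv(
    do.call(rbind, lapply(all, profileCountTable)),
    file.path(dir, "class_counts.tsv")
  )
  invisible(dir)
}

#' Read a screen from its TSV directory
#'
#' @param dir Directory written by \code{\link{writeScreen}}.
#' @return A \linkS4class{SyntheticScreen}.
#' @export
readScreen <- function(dir) {
  cells <- readTsv(file.path(dir, "cells.tsv"))
  counts <- readTsv(file.path(dir, "class_counts.tsv"))
  featureCols <- setdiff(names(cells), c("gene", "time_point", "class_label"))
  classes <- unique(counts$class) # keep the written column order
  timePoints <- sort(unique(counts$time_point))
  mkProfile <- function(g) {
    cg <- cells[cells$gene == g, , drop = FALSE]
    kg <- counts[counts$gene == g, , drop = FALSE]
    cc <- matrix(0L, length(timePoints), length(classes),
      dimnames = list(timePoints, classes)
    )
    cc[cbind(match(kg$time_point, timePoints), match(kg$class, classes))] <-
      kg$count
    intens <- if ("intensity" %in% featureCols) cg$intensity else unlist(cg[featureCols])
    new("KnockdownProfile",
      gene = g,
      features = as.matrix(cg[, featureCols, drop = FALSE]),
      timePoint = as.integer(cg$time_point),
      classLabel = as.character(cg$class_label),
      classCounts = cc,
      intensityMedian = stats::median(intens),
      intensitySd = stats::sd(intens)
    )
  }
  genes <- setdiff(unique(cells$gene), "negative_control")
  profs <- stats::setNames(lapply(genes, mkProfile), genes)
  new("SyntheticScreen",
    profiles = profs,
    negativeControl = mkProfile("negative_control"),
    timePoints = length(timePoints),
    seed = NA_integer_
  )
}

#' Write / read a pair descriptor table
#'
#' TSV with a `pair` key column followed by one named column per
#' descriptor feature.
#'
#' @param descriptors Matrix from \code{\link{pairDescriptorTable}}.
#' @param file TSV path.
#' @return `readPairDescriptors` returns the matrix.
#' @export
writePairDescriptors <- function(descriptors, file) {
  writeTsv(
    data.frame(
      pair = rownames(descriptors), descriptors,
      check.names = FALSE
    ),
    file
  )
}

#' @rdname writePairDescriptors
#' @export
readPairDescriptors <- function(file) {
  d <- readTsv(file)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d$pair
  m
}

#' Write / read ensemble votes
#'
#' @param votes A \linkS4class{VoteSet}.
#' @param file TSV path.
#' @return `readVotes` returns a \linkS4class{VoteSet}.
#' @export
writeVotes <- function(votes, file) {
  writeTsv(voteTable(votes), file)
}

#' @rdname writeVotes
#' @export
readVotes <- function(file) {
  new("VoteSet", votes = readTsv(file))
}

#' Write a calibration threshold table
#'
#' @param calibration A \linkS4class{ConfidenceCalibration}.
#' @param file TSV path.
#' @export
writeCalibration <- function(calibration, file) {
  writeTsv(calibration@table, file)
}

#' Write an ESR matrix as TSV
#'
#' @param esr An \linkS4class{ESRMatrix}.
#' @param file TSV path.
#' @export
writeEsrMatrix <- function(esr, file) {
  v <- esrValues(esr)
  writeTsv(data.frame(gene = rownames(v), v, check.names = FALSE), file)
}

#' Write an ESR dendrogram in newick format
#'
#' @param clustering Result of \code{\link{clusterEsr}}.
#' @param file Newick path.
#' @export
writeEsrDendrogram <- function(clustering, file) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file)
  invisible(file)
}

#' Write an enrichment table as TSV
#'
#' @param table data.frame from \code{\link{enrichmentTable}}.
#' @param file TSV path.
#' @export
writeEnrichmentTable <- function(table, file) {
  writeTsv(table, file)
}

#' Read gene-to-class annotations from TSV
#'
#' Two columns: gene, class; one row per membership (genes may appear
#' on several rows).
#'
#' @param file TSV path.
#' @return Named list mapping genes to class vectors.
#' @export
readAnnotations <- function(file) {
  a <- readTsv(file)
  split(as.character(a$class), a$gene)
}

#' Write gene-to-class annotations as TSV
#'
#' @param annotations Named list of class vectors.
#' @param file TSV path.
#' @export
writeAnnotations <- function(annotations, file) {
  writeTsv(
    data.frame(
      gene = rep(names(annotations), lengths(annotations)),
      class = unlist(annotations, use.names = FALSE),
      stringsAsFactors = FALSE
    ),
    file
  )
}
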
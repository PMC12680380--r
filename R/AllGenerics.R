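#' Extract the score matrix
#'
#' @param x a [ScoreMatrix-class].
#' @param ... unused.
#' @return character matrix of mapping scores (markers x individuals).
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "ScoreMatrix", function(x, ...)
  SummarizedExperiment::assay(x, "scores"))

#' Marker metadata of a ScoreMatrix
#'
#' @param x a [ScoreMatrix-class].
#' @return data.frame with marker_id, scaffold, bp, tag_id, reversed.
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname markerInfo
#' @export
setMethod("markerInfo", "ScoreMatrix", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' Sample ids by role
#'
#' @param x a [ScoreMatrix-class].
#' @param role one or more of `"parent1"`, `"parent2"`, `"f1"`, `"progeny"`.
#' @return character vector of column names with that role.
#' @export
setGeneric("samplesByRole", function(x, role) standardGeneric("samplesByRole"))

#' @rdname samplesByRole
#' @export
setMethod("samplesByRole", "ScoreMatrix", function(x, role) {
  cd <- SummarizedExperiment::colData(x)
  colnames(x)[cd$role %in% role]
})

#' Progeny ids of a ScoreMatrix
#'
#' @param x a [ScoreMatrix-class].
#' @return character vector of progeny column names.
#' @export
progenyIds <- function(x) samplesByRole(x, "progeny")

#' Progeny score submatrix
#'
#' @param x a [ScoreMatrix-class].
#' @return character matrix restricted to progeny columns.
#' @export
progenyScores <- function(x) scores(x)[, progenyIds(x), drop = FALSE]

#' Chromosome table of a GenomeSpec
#'
#' @param x a [GenomeSpec-class].
#' @return data.frame with chrom, length_cM, length_bp.
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname chromosomes
#' @export
setMethod("chromosomes", "GenomeSpec", function(x) x@chromosomes)

#' Marker table of a GenomeSpec
#'
#' @param x a [GenomeSpec-class].
#' @return data.frame with marker_id, chrom, cM, bp.
#' @export
setGeneric("markerPositions", function(x) standardGeneric("markerPositions"))

#' @rdname markerPositions
#' @export
setMethod("markerPositions", "GenomeSpec", function(x) x@markers)

#' Linkage groups of a map
#'
#' @param x a [LinkageMap-class].
#' @return named list of [LinkageGroup-class] objects.
#' @export
setGeneric("linkageGroups", function(x) standardGeneric("linkageGroups"))

#' @rdname linkageGroups
#' @export
setMethod("linkageGroups", "LinkageMap", function(x) x@groups)

#' Map table of a linkage group or map
#'
#' @param x a [LinkageGroup-class] or [LinkageMap-class].
#' @return data.frame with one row per marker in map order (for a map, with
#'   an `lg` column prepended).
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname mapTable
#' @export
setMethod("mapTable", "LinkageGroup", function(x) x@table)

#' @rdname mapTable
#' @export
setMethod("mapTable", "LinkageMap", function(x) {
  do.call(rbind, lapply(x@groups, function(g)
    cbind(lg = g@name, g@table, row.names = NULL)))
})

#' LOD curve of a scan
#'
#' @param x a [ScanResult-class].
#' @return data.frame with chrom, cM, marker, lod.
#' @export
setGeneric("lodCurve", function(x) standardGeneric("lodCurve"))

#' @rdname lodCurve
#' @export
setMethod("lodCurve", "ScanResult", function(x) x@lod)

#' Peak of a scan
#'
#' @param x a [ScanResult-class].
#' @return list with chrom, cM, marker, lod.
#' @export
setGeneric("scanPeak", function(x) standardGeneric("scanPeak"))

#' @rdname scanPeak
#' @export
setMethod("scanPeak", "ScanResult", function(x) x@peak)

#' Unphased genotype at site 632
#'
#' @param d a [GeneDiplotype-class].
#' @return `"GG"`, `"GT"` or `"TT"`.
#' @export
setGeneric("g632", function(d) standardGeneric("g632"))

#' @rdname g632
#' @export
setMethod("g632", "GeneDiplotype", function(d) {
  a <- sort(factor(c(d@h1@a632, d@h2@a632), levels = c("G", "T")))
  paste(as.character(a), collapse = "")
})

#' Unphased genotype at site 917
#'
#' @param d a [GeneDiplotype-class].
#' @return `"GG"`, `"GA"` or `"AA"`.
#' @export
setGeneric("g917", function(d) standardGeneric("g917"))

#' @rdname g917
#' @export
setMethod("g917", "GeneDiplotype", function(d) {
  a <- sort(factor(c(d@h1@a917, d@h2@a917), levels = c("G", "A")))
  paste(as.character(a), collapse = "")
})

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec: %d chromosomes, %d markers, %.1f cM / %.1f Mb\n",
              nrow(object@chromosomes), nrow(object@markers),
              sum(object@chromosomes$length_cM),
              sum(object@chromosomes$length_bp) / 1e6))
})

setMethod("show", "ScoreMatrix", function(object) {
  role <- SummarizedExperiment::colData(object)$role
  cat(sprintf(
    "ScoreMatrix: %d markers x %d individuals (%d progeny)\n",
    nrow(object), ncol(object), sum(role == "progeny")))
  sc <- scores(object)
  tb <- table(factor(sc, levels = SCORE_CODES))
  cat("  codes:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %s design, %d individuals, %d markers, %d distortion loci\n",
              object@design, length(object@gametes), nrow(object@hap1),
              length(object@distortions)))
})

setMethod("show", "LinkageGroup", function(object) {
  cat(sprintf("LinkageGroup %s: %d markers, %.1f cM\n", object@name,
              nrow(object@table),
              if (all(is.na(object@table$cM))) NA_real_
              else max(object@table$cM)))
})

setMethod("show", "LinkageMap", function(object) {
  n <- vapply(object@groups, function(g) nrow(g@table), 0L)
  len <- vapply(object@groups, function(g)
    if (all(is.na(g@table$cM))) NA_real_ else max(g@table$cM), 0)
  cat(sprintf("LinkageMap: %d groups, %d markers, %.1f cM total (%d ungrouped)\n",
              length(object@groups), sum(n), sum(len, na.rm = TRUE),
              length(object@ungrouped)))
})

setMethod("show", "GenoProbGrid", function(object) {
  cat(sprintf("GenoProbGrid: %d positions x %d individuals, step %.2f cM, eps %g\n",
              dim(object@probs)[1], dim(object@probs)[2],
              object@step, object@eps))
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult: %d positions, peak LOD %.2f at %s %.1f cM",
              nrow(object@lod), object@peak$lod, object@peak$chrom,
              object@peak$cM))
  if (length(object@pve) && !is.na(object@pve))
    cat(sprintf(", PVE %.1f%%", 100 * object@pve))
  if (!is.na(object@threshold))
    cat(sprintf(", threshold %.2f", object@threshold))
  cat("\n")
})

setMethod("show", "GeneDiplotype", function(object) {
  cat(sprintf("GeneDiplotype: [%s-%s] / [%s-%s] (g632 %s, g917 %s)\n",
              object@h1@a632, object@h1@a917, object@h2@a632, object@h2@a917,
              g632(object), g917(object)))
})
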
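#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats optimize pchisq quantile rnbinom rpois runif
#'   cor.test lm.fit cmdscale qr.resid
#' @importFrom utils head tail read.delim
NULL

SCORE_CODES <- c("A", "H", "B", "C", "D", "U")

## genotype compatibility of each score code with the F2 states {AA, AB, BB}
CODE_STATES <- matrix(
  c(1, 0, 0,   # A
    0, 1, 0,   # H
    0, 0, 1,   # B
    0, 1, 1,   # C = "B or H"
    1, 1, 0,   # D = "A or H"
    1, 1, 1),  # U
  nrow = 6, byrow = TRUE,
  dimnames = list(SCORE_CODES, c("AA", "AB", "BB"))
)

#' GenomeSpec: chromosome and marker layout for cross simulation
#'
#' Describes a genome as a set of chromosomes with genetic (cM) and physical
#' (bp) lengths, and a set of marker positions on them. Used as the template
#' for [simulateCross()].
#'
#' @slot chromosomes data.frame with columns `chrom`, `length_cM`,
#'   `length_bp`.
#' @slot markers data.frame with columns `marker_id`, `chrom`, `cM`, `bp`;
#'   cM positions lie in `[0, length_cM]` and are strictly increasing within
#'   each chromosome, bp positions are strictly increasing in the same rank
#'   order.
#' @seealso [genomeSpec()], [defaultGenome()]
#' @export
setClass("GenomeSpec",
  representation(chromosomes = "data.frame", markers = "data.frame"))

setValidity("GenomeSpec", function(object) {
  ch <- object@chromosomes
  mk <- object@markers
  if (!all(c("chrom", "length_cM", "length_bp") %in% names(ch)))
    return("chromosomes needs columns chrom, length_cM, length_bp")
  if (nrow(ch) == 0L) return("empty genome: no chromosomes")
  if (anyDuplicated(ch$chrom)) return("duplicated chromosome names")
  if (any(ch$length_cM < 0)) return("negative chromosome cM length")
  if (any(ch$length_bp <= 0)) return("chromosome bp length must be positive")
  if (!all(c("marker_id", "chrom", "cM", "bp") %in% names(mk)))
    return("markers needs columns marker_id, chrom, cM, bp")
  if (anyDuplicated(mk$marker_id)) return("duplicated marker ids")
  if (!all(mk$chrom %in% ch$chrom)) return("marker on unknown chromosome")
  for (cc in unique(mk$chrom)) {
    pos <- mk$cM[mk$chrom == cc]
    bp <- mk$bp[mk$chrom == cc]
    len <- ch$length_cM[match(cc, ch$chrom)]
    if (any(pos < 0 | pos > len))
      return(sprintf("marker cM outside [0, %g] on %s", len, cc))
    if (is.unsorted(pos, strictly = TRUE))
      return(sprintf("marker cM positions not strictly sorted on %s", cc))
    if (is.unsorted(bp, strictly = TRUE))
      return(sprintf("marker bp positions not strictly sorted on %s", cc))
  }
  TRUE
})

#' ScoreMatrix: marker-by-individual mapping scores
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' `scores` assay, a character matrix of mapping scores over
#' markers (rows) and individuals (columns). Codes are `A` (homozygous for
#' the parent-1 / reference allele), `B` (homozygous parent-2 / alternate),
#' `H` (heterozygous), `C` ("B or H"), `D` ("A or H") and `U` (missing).
#' Row metadata carries `marker_id`, `scaffold`, `bp` (1-based), `tag_id`
#' and `reversed` (phase-duplicated "r" copies); column metadata carries the
#' sample `role` (`parent1`, `parent2`, `f1` or `progeny`).
#'
#' @seealso [ScoreMatrix()], [scores()], [markerInfo()]
#' @export
setClass("ScoreMatrix", contains = "SummarizedExperiment")

setValidity("ScoreMatrix", function(object) {
  if (!"scores" %in% SummarizedExperiment::assayNames(object))
    return("missing 'scores' assay")
  sc <- SummarizedExperiment::assay(object, "scores")
  if (!is.character(sc)) return("scores assay must be a character matrix")
  bad <- !(sc %in% SCORE_CODES)
  if (any(bad))
    return(sprintf("invalid score codes: %s",
                   paste(unique(sc[bad]), collapse = ", ")))
  need <- c("marker_id", "scaffold", "bp", "tag_id", "reversed")
  if (!all(need %in% names(SummarizedExperiment::rowData(object))))
    return("rowData needs marker_id, scaffold, bp, tag_id, reversed")
  if (!"role" %in% names(SummarizedExperiment::colData(object)))
    return("colData needs a 'role' column")
  role <- SummarizedExperiment::colData(object)$role
  if (!all(role %in% c("parent1", "parent2", "f1", "progeny")))
    return("role must be parent1/parent2/f1/progeny")
  rd <- SummarizedExperiment::rowData(object)
  if (!identical(grepl("r$", rd$marker_id), as.logical(rd$reversed)))
    return("reversed flag must match the marker_id 'r' suffix")
  TRUE
})

#' SimTruth: ground truth of a simulated cross
#'
#' Ground-truth record of a simulated F2 (selfed F1) or F1 family:
#' per-individual gametes (founder-homolog mosaic per chromosome, i.e.
#' starting homolog plus crossover breakpoints), realized marker haplotypes,
#' and the distortion loci applied. For the `"f2"` design founder homolog 1
#' is the parent-1 genome and homolog 2 the parent-2 genome of the selfed F1,
#' so the marker genotype is the homolog-2 dosage (0 = A, 1 = H, 2 = B).
#'
#' @slot genome the [GenomeSpec-class] simulated from.
#' @slot design `"f2"` or `"f1"`.
#' @slot gametes per-individual list of two gametes; each gamete is a
#'   per-chromosome list with elements `start` (founder homolog index) and
#'   `breaks` (crossover positions, cM).
#' @slot hap1,hap2 integer matrices (markers x individuals) of founder
#'   homolog indices carried by the maternal / paternal gamete.
#' @slot distortions list of distortion specifications (see
#'   [distortionSpec()]).
#' @slot seed integer seed the simulation was run with.
#' @export
setClass("SimTruth",
  representation(genome = "GenomeSpec", design = "character",
                 gametes = "list", hap1 = "matrix", hap2 = "matrix",
                 distortions = "list", seed = "integer"))

setValidity("SimTruth", function(object) {
  if (!object@design %in% c("f2", "f1")) return("design must be 'f2' or 'f1'")
  ch <- object@genome@chromosomes
  for (g in object@gametes) {
    for (side in g) {
      for (i in seq_along(side)) {
        br <- side[[i]]$breaks
        if (length(br) &&
            (any(br < 0) || any(br > ch$length_cM[i])))
          return("crossover position outside chromosome bounds")
        if (!side[[i]]$start %in% c(1L, 2L))
          return("founder homolog index must be 1 or 2")
      }
    }
  }
  TRUE
})

#' LinkageGroup: one ordered linkage group
#'
#' An ordered set of markers with adjacent recombination-fraction estimates,
#' cumulative Kosambi cM positions and double-recombination counts.
#'
#' @slot name group name.
#' @slot table data.frame with one row per marker in map order: `marker_id`,
#'   `scaffold`, `bp`, `reversed`, `cM` (cumulative, first marker at 0 once
#'   distances are computed), `dbl_rec` (double-recombination events).
#' @slot rfAdj adjacent recombination fractions, length `nrow(table) - 1`.
#' @export
setClass("LinkageGroup",
  representation(name = "character", table = "data.frame", rfAdj = "numeric"))

setValidity("LinkageGroup", function(object) {
  tb <- object@table
  if (!all(c("marker_id", "scaffold", "bp", "cM") %in% names(tb)))
    return("table needs marker_id, scaffold, bp, cM")
  if (nrow(tb) > 1 && length(object@rfAdj) != nrow(tb) - 1L)
    return("rfAdj must have one entry per adjacent marker pair")
  if (!all(is.na(tb$cM))) {
    if (is.unsorted(tb$cM)) return("cM positions must be non-decreasing")
    if (tb$cM[1] != 0) return("first marker must sit at 0 cM")
  }
  TRUE
})

#' LinkageMap: a set of linkage groups
#'
#' @slot groups list of [LinkageGroup-class] objects.
#' @slot ungrouped marker ids that could not be placed.
#' @slot phaseReport data.frame reporting, for each phase-duplicated marker
#'   pair, which copy was retained.
#' @export
setClass("LinkageMap",
  representation(groups = "list", ungrouped = "character",
                 phaseReport = "data.frame"))

setValidity("LinkageMap", function(object) {
  ids <- unlist(lapply(object@groups, function(g) g@table$marker_id))
  if (anyDuplicated(ids)) return("a marker appears in two linkage groups")
  base <- sub("r$", "", ids)
  if (anyDuplicated(base))
    return("a marker co-occurs with its reversed twin on the map")
  TRUE
})

#' GenoProbGrid: conditional QTL genotype probabilities
#'
#' Probabilities of the F2 states {AA, AB, BB} for every individual at every
#' scan position (markers plus a pseudomarker grid), computed by a hidden
#' Markov model.
#'
#' @slot positions data.frame with `chrom`, `cM` and `marker` (NA at
#'   pseudomarkers).
#' @slot probs numeric array `[position, individual, state]`; each
#'   individual/position slice is a probability vector.
#' @slot eps assumed genotyping error rate.
#' @slot step grid step in cM.
#' @export
setClass("GenoProbGrid",
  representation(positions = "data.frame", probs = "array",
                 eps = "numeric", step = "numeric"))

setValidity("GenoProbGrid", function(object) {
  p <- object@probs
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("probs must be a positions x individuals x 3 array")
  if (dim(p)[1] != nrow(object@positions))
    return("probs rows must match positions")
  if (any(p < -1e-9)) return("negative probabilities")
  s <- apply(p, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-6)) return("state probabilities must sum to 1")
  TRUE
})

#' ScanResult: a genome scan with peak, threshold and interval
#'
#' @slot lod data.frame with `chrom`, `cM`, `marker`, `lod`.
#' @slot peak list with `chrom`, `cM`, `marker`, `lod` at the maximum.
#' @slot pve proportion of phenotypic variance explained at the peak.
#' @slot threshold genome-wide LOD threshold (NA until permutations are run).
#' @slot interval list with `left`/`right` positions and flanking markers.
#' @slot covariates names of covariates included in the model.
#' @export
setClass("ScanResult",
  representation(lod = "data.frame", peak = "list", pve = "numeric",
                 threshold = "numeric", interval = "list",
                 covariates = "character"))

setValidity("ScanResult", function(object) {
  if (!all(c("chrom", "cM", "lod") %in% names(object@lod)))
    return("lod table needs chrom, cM, lod")
  if (length(object@pve) && !is.na(object@pve) &&
      (object@pve < 0 || object@pve > 1))
    return("pve must lie in [0, 1]")
  if (length(object@peak) &&
      abs(object@peak$lod - max(object@lod$lod)) > 1e-8)
    return("peak LOD must equal the curve maximum")
  TRUE
})

#' GeneHaplotype: one haplotype over the two causal gene sites
#'
#' Alleles at the two intragenic SNPs of the anthocyanin-regulator model:
#' site 632 (exon 3; wild type G, variant T) and site 917 (last base of
#' exon 7; wild type G, variant A).
#'
#' @slot a632 `"G"` or `"T"`.
#' @slot a917 `"G"` or `"A"`.
#' @export
setClass("GeneHaplotype", representation(a632 = "character", a917 = "character"))

setValidity("GeneHaplotype", function(object) {
  if (!object@a632 %in% c("G", "T")) return("a632 must be G or T")
  if (!object@a917 %in% c("G", "A")) return("a917 must be G or A")
  TRUE
})

#' GeneDiplotype: an unordered pair of gene haplotypes
#'
#' @slot h1,h2 [GeneHaplotype-class] objects.
#' @seealso [g632()], [g917()], [phenotypeFromDiplotype()]
#' @export
setClass("GeneDiplotype",
  representation(h1 = "GeneHaplotype", h2 = "GeneHaplotype"))

#' CapsAssay: an in-silico CAPS genotyping assay
#'
#' A CAPS (cleaved amplified polymorphic sequence) assay: an amplicon, a SNP
#' offset within it, the allele bases, and a restriction enzyme recognition
#' pattern (IUPAC) with its cut offset.
#'
#' @slot amplicon amplicon sequence (character, IUPAC DNA).
#' @slot snpOffset 0-based offset of the SNP within the amplicon.
#' @slot alleles character vector of allele bases, e.g. `c("G", "A")`.
#' @slot pattern enzyme recognition pattern (IUPAC), length >= 4.
#' @slot cutOffset number of pattern bases 5' of the cut on the matched
#'   strand (e.g. 1 for DdeI, C^TNAG).
#' @export
setClass("CapsAssay",
  representation(amplicon = "character", snpOffset = "integer",
                 alleles = "character", pattern = "character",
                 cutOffset = "integer"))

setValidity("CapsAssay", function(object) {
  if (nchar(object@pattern) < 4L) return("pattern length must be >= 4")
  if (object@snpOffset < 0L || object@snpOffset >= nchar(object@amplicon))
    return("snpOffset outside the amplicon")
  if (object@cutOffset < 0L || object@cutOffset > nchar(object@pattern))
    return("cutOffset outside the pattern")
  TRUE
})
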
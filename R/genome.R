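#' Construct a GenomeSpec
#'
#' Builds a [GenomeSpec-class] from a chromosome table and either an explicit
#' marker table or a regular marker spacing.
#'
#' @param chromosomes data.frame with columns `chrom`, `length_cM`,
#'   `length_bp`.
#' @param markers optional data.frame with `marker_id`, `chrom`, `cM`, `bp`.
#'   If `NULL`, markers are laid down every `spacing_cM` centimorgans from 0
#'   to the chromosome end, with bp positions interpolated proportionally.
#' @param spacing_cM marker spacing in cM used when `markers` is `NULL`.
#' @return a [GenomeSpec-class].
#' @examples
#' g <- genomeSpec(data.frame(chrom = "1", length_cM = 100, length_bp = 1e7),
#'                 spacing_cM = 10)
#' nrow(markerPositions(g))
#' @export
genomeSpec <- function(chromosomes, markers = NULL, spacing_cM = 1) {
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (is.null(markers)) {
    stopifnot(spacing_cM > 0)
    markers <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
      len <- chromosomes$length_cM[i]
      pos <- if (len > 0) seq(0, len, by = spacing_cM) else 0
      bp <- round(1 + pos / max(len, spacing_cM) *
                    (chromosomes$length_bp[i] - 1))
      bp <- bp + seq_along(bp) - 1L  # enforce strictly increasing bp
      data.frame(
        marker_id = sprintf("c%s_m%03d", chromosomes$chrom[i],
                            seq_along(pos)),
        chrom = chromosomes$chrom[i], cM = pos, bp = bp,
        stringsAsFactors = FALSE)
    }))
  }
  markers$chrom <- as.character(markers$chrom)
  new("GenomeSpec", chromosomes = chromosomes,
      markers = markers[order(match(markers$chrom, chromosomes$chrom),
                              markers$cM), , drop = FALSE])
}

#' Published zoysiagrass F2 map summary (packaged fixture)
#'
#' Per-chromosome statistics of a published high-density interspecific
#' zoysiagrass (Z. japonica x Z. matrella) F2 linkage map: assembly length,
#' marker count, genetic length, and first/last mapped marker positions.
#' Used as the default genome template for simulations and as a regression
#' fixture for the map-report arithmetic.
#'
#' @return data.frame with columns `chrom`, `length_bp`, `n_markers`,
#'   `length_cM`, `first_bp`, `last_bp` (20 rows).
#' @export
referenceMapSummary <- function() {
  f <- system.file("extdata", "zoysia_f2_map_stats.tsv", package = "zoymap",
                   mustWork = TRUE)
  df <- read.delim(f, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df
}

#' Default 20-chromosome genome template
#'
#' A [GenomeSpec-class] with the 20 chromosomes of the reference zoysiagrass
#' F2 map ([referenceMapSummary()]): genetic lengths 53.5-126.4 cM, physical
#' lengths 7.7-21.1 Mb, and markers every `spacing_cM` centimorgans.
#'
#' @param spacing_cM marker spacing in cM (default 1, i.e. dense markers).
#' @return a [GenomeSpec-class].
#' @export
defaultGenome <- function(spacing_cM = 1) {
  ref <- referenceMapSummary()
  genomeSpec(data.frame(chrom = ref$chrom, length_cM = ref$length_cM,
                        length_bp = ref$length_bp, stringsAsFactors = FALSE),
             spacing_cM = spacing_cM)
}
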
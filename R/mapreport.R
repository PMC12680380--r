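#' Map summary statistics
#'
#' Computes per-group map statistics in the style of a published map table:
#' marker count, genetic length, first/last marker bp, covered span
#' (last minus first), percent physical coverage, and a census of adjacent
#' intervals at or above a gap threshold; plus totals and (arithmetic mean)
#' averages over groups.
#'
#' @param map a [LinkageMap-class] whose markers carry bp metadata.
#' @param chrom_lengths named numeric vector of physical chromosome
#'   lengths (bp), named by linkage-group name.
#' @param gap_cM gap census threshold in cM (default 5).
#' @return list with `per_lg` (data.frame), `totals` (list) and
#'   `gap_cM`.
#' @export
summarizeMap <- function(map, chrom_lengths, gap_cM = 5) {
  per <- lapply(map@groups, function(g) {
    tb <- g@table
    first <- min(tb$bp); last <- max(tb$bp)
    covered <- if (nrow(tb) > 1) last - first else 0
    len_bp <- unname(chrom_lengths[g@name])
    data.frame(lg = g@name, length_bp = len_bp, n_markers = nrow(tb),
               length_cM = max(tb$cM), first_bp = first, last_bp = last,
               covered_bp = covered,
               pct_coverage = if (!is.na(len_bp)) 100 * covered / len_bp
               else NA_real_,
               n_gaps = sum(diff(tb$cM) >= gap_cM),
               stringsAsFactors = FALSE)
  })
  per_lg <- do.call(rbind, per)
  rownames(per_lg) <- NULL
  list(per_lg = per_lg, totals = .mapTotals(per_lg), gap_cM = gap_cM)
}

.mapTotals <- function(per) {
  n_lg <- nrow(per)
  list(n_lg = n_lg,
       total_length_bp = sum(per$length_bp),
       total_markers = sum(per$n_markers),
       total_cM = sum(per$length_cM),
       total_covered_bp = sum(per$covered_bp),
       avg_markers = mean(per$n_markers),
       avg_cM = mean(per$length_cM),
       avg_coverage_pct = mean(per$pct_coverage),
       overall_coverage_pct = 100 * sum(per$covered_bp) /
         sum(per$length_bp),
       mean_spacing_cM = sum(per$length_cM) /
         (sum(per$n_markers) - n_lg))
}

#' Map statistics from a published-style summary table
#'
#' Recomputes the derived columns (covered span, percent coverage) and the
#' totals/averages from the printed columns of a map summary table such as
#' [referenceMapSummary()]: chromosome, assembly length, marker count,
#' genetic length, first/last marker positions. The mean inter-marker
#' spacing is total cM divided by the number of adjacent intervals
#' (markers minus groups).
#'
#' @param tab data.frame with `length_bp`, `n_markers`, `length_cM`,
#'   `first_bp`, `last_bp`.
#' @return list with `per_lg` (input plus `covered_bp`, `pct_coverage`)
#'   and `totals` (as in [summarizeMap()]).
#' @examples
#' s <- summarizeMapTable(referenceMapSummary())
#' s$per_lg$covered_bp[1]      # 18950007
#' s$totals$total_covered_bp   # 270775636
#' @export
summarizeMapTable <- function(tab) {
  per <- tab
  per$covered_bp <- per$last_bp - per$first_bp
  per$pct_coverage <- 100 * per$covered_bp / per$length_bp
  list(per_lg = per, totals = .mapTotals(per))
}

#' Genetic vs physical length correlation
#'
#' Pearson correlation of genetic group length against physical chromosome
#' length, with a two-sided t-test p-value. Because the published statistic
#' could have used either the assembly length or the mapped (covered)
#' span, both variants are reported.
#'
#' @param per_lg data.frame with `length_cM`, `length_bp` and optionally
#'   `covered_bp` (e.g. `summarizeMap()$per_lg`).
#' @return data.frame with one row per variant: `variant`, `r`, `r2`, `p`.
#' @export
lengthCorrelation <- function(per_lg) {
  if (nrow(per_lg) < 3) stop("need at least 3 linkage groups")
  one <- function(xx, label) {
    ct <- cor.test(per_lg$length_cM, xx)
    data.frame(variant = label, r = unname(ct$estimate),
               r2 = unname(ct$estimate)^2, p = ct$p.value,
               stringsAsFactors = FALSE)
  }
  out <- one(per_lg$length_bp, "chromosome_bp")
  if (!is.null(per_lg$covered_bp))
    out <- rbind(out, one(per_lg$covered_bp, "covered_bp"))
  rownames(out) <- NULL
  out
}

#' Segregation-distortion scan along the map
#'
#' Per-marker genotype-class frequencies and 1:2:1 chi-squared p-values
#' over the definite codes, with the favoured parent labelled wherever the
#' classes are unbalanced. When a map is supplied, contiguous runs of
#' distorted markers (p below the threshold) are flagged as distorted
#' regions with their majority favoured allele.
#'
#' @param x a [ScoreMatrix-class].
#' @param map optional [LinkageMap-class] for region flagging.
#' @param p_threshold distortion p-value threshold (default 1e-10, the
#'   mapping filter's).
#' @return list with `profile` (per-marker data.frame: counts,
#'   frequencies over definite codes, `p_value`, `favoured`) and
#'   `regions` (data.frame `lg`, `start_cM`, `end_cM`, `n_markers`,
#'   `favoured`; empty without a map).
#' @export
distortionScan <- function(x, map = NULL, p_threshold = 1e-10) {
  seg <- markerSegregation(x)
  tot <- seg$nA + seg$nH + seg$nB
  profile <- data.frame(seg,
                        fA = seg$nA / tot, fH = seg$nH / tot,
                        fB = seg$nB / tot,
                        favoured = ifelse(seg$nA > seg$nB, "P1",
                                          ifelse(seg$nB > seg$nA, "P2",
                                                 "none")),
                        stringsAsFactors = FALSE)
  regions <- data.frame(lg = character(0), start_cM = numeric(0),
                        end_cM = numeric(0), n_markers = integer(0),
                        favoured = character(0))
  if (!is.null(map)) {
    for (g in map@groups) {
      tb <- g@table
      p <- profile$p_value[match(tb$marker_id, profile$marker_id)]
      hot <- !is.na(p) & p < p_threshold
      if (!any(hot)) next
      runs <- rle(hot)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      for (k in which(runs$values)) {
        ii <- starts[k]:ends[k]
        fav <- profile$favoured[match(tb$marker_id[ii],
                                      profile$marker_id)]
        regions <- rbind(regions, data.frame(
          lg = g@name, start_cM = tb$cM[ii[1]],
          end_cM = tb$cM[ii[length(ii)]], n_markers = length(ii),
          favoured = names(sort(table(fav), decreasing = TRUE))[1],
          stringsAsFactors = FALSE))
      }
    }
  }
  list(profile = profile, regions = regions)
}
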
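.FLIP <- c(A = "B", B = "A", C = "D", D = "C", H = "H", U = "U")

#' Construct a ScoreMatrix
#'
#' @param scores character matrix of codes in `{A,B,H,C,D,U}`
#'   (markers x individuals, with column names).
#' @param markerInfo data.frame with `marker_id`, `scaffold`, `bp`,
#'   `tag_id`, `reversed` (one row per marker).
#' @param role character vector of sample roles (`parent1`, `parent2`,
#'   `f1`, `progeny`), one per column.
#' @return a [ScoreMatrix-class].
#' @export
ScoreMatrix <- function(scores, markerInfo, role) {
  rownames(scores) <- markerInfo$marker_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scores = scores),
    rowData = S4Vectors::DataFrame(markerInfo, row.names = markerInfo$marker_id),
    colData = S4Vectors::DataFrame(role = role, row.names = colnames(scores)))
  new("ScoreMatrix", se)
}

#' VariantCallSet: per-sample biallelic variant calls
#'
#' Raw variant calls from one caller (or a merged pair): site information,
#' per-sample genotype strings (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`), and
#' per-sample read depths.
#'
#' @slot info data.frame with `scaffold`, `pos` (1-based), `ref`, `alt`,
#'   `caller`, and optional `qd`, `maf`, `origin` columns.
#' @slot geno character matrix (sites x samples) of genotype strings.
#' @slot depth numeric matrix (sites x samples) of read depths.
#' @slot meta list of bookkeeping (e.g. merge tallies).
#' @export
setClass("VariantCallSet",
  representation(info = "data.frame", geno = "matrix", depth = "matrix",
                 meta = "list"))

setValidity("VariantCallSet", function(object) {
  if (!all(c("scaffold", "pos", "ref", "alt", "caller") %in%
           names(object@info)))
    return("info needs scaffold, pos, ref, alt, caller")
  if (nrow(object@info) != nrow(object@geno))
    return("geno rows must match info rows")
  key <- paste(object@info$scaffold, object@info$pos, object@info$caller)
  if (anyDuplicated(key)) return("duplicate positions within a caller set")
  TRUE
})

#' @describeIn VariantCallSet-class constructor.
#' @param info,geno,depth,meta see slots.
#' @export
variantCallSet <- function(info, geno, depth, meta = list()) {
  new("VariantCallSet", info = info, geno = as.matrix(geno),
      depth = as.matrix(depth), meta = meta)
}

setMethod("show", "VariantCallSet", function(object) {
  cat(sprintf("VariantCallSet: %d sites x %d samples (caller: %s)\n",
              nrow(object@info), ncol(object@geno),
              paste(unique(object@info$caller), collapse = "/")))
})

#' Read a VCF into a VariantCallSet
#'
#' Thin wrapper around \pkg{vcfR} extracting genotypes, depths and the QD
#' annotation.
#'
#' @param file path to a VCF file.
#' @param caller label for the calling pipeline (e.g. `"HC"` or `"UG"`).
#' @return a [VariantCallSet-class].
#' @export
readCallsVCF <- function(file, caller = "HC") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readCallsVCF() needs the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  gt[is.na(gt)] <- "./."
  gt <- gsub("\\|", "/", gt)
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  fix <- vcfR::getFIX(v)
  info <- data.frame(scaffold = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     caller = caller, qd = qd, stringsAsFactors = FALSE)
  ## minor-allele frequency from the called genotypes
  alt_dose <- (gt == "0/1" | gt == "1/0") + 2 * (gt == "1/1")
  called <- gt %in% c("0/0", "0/1", "1/0", "1/1")
  dim(called) <- dim(gt)
  af <- rowSums(alt_dose * called) / (2 * pmax(rowSums(called), 1))
  info$maf <- pmin(af, 1 - af)
  variantCallSet(info, gt, dp)
}

#' Encode variant calls as mapping scores
#'
#' Applies the site-level filters (biallelic, minor-allele frequency > 5%,
#' quality-by-depth > 10) and converts genotypes to mapping scores:
#' reference homozygote to `A`, alternate homozygote to `B`, heterozygote to
#' `H`; any call with per-sample read depth below `min_depth` becomes `U`.
#'
#' @param calls a [VariantCallSet-class].
#' @param min_depth per-sample depth floor for a definite call (default 8;
#'   the boundary is inclusive).
#' @param maf_min,qd_min site-level thresholds; sites with missing
#'   annotations pass.
#' @param role sample roles (as in [ScoreMatrix()]); default: samples named
#'   `P1`/`P2`/`F1` take those roles, all others are progeny.
#' @return a [ScoreMatrix-class]; rejected multiallelic records are reported
#'   in `attr(, "rejected")`.
#' @export
encodeCalls <- function(calls, min_depth = 8, maf_min = 0.05, qd_min = 10,
                        role = NULL) {
  stopifnot(is(calls, "VariantCallSet"))
  info <- calls@info
  multi <- grepl(",", info$alt)
  rejected <- info[multi, c("scaffold", "pos", "alt")]
  keep <- !multi
  if (!is.null(info$maf)) keep <- keep & (is.na(info$maf) | info$maf > maf_min)
  if (!is.null(info$qd)) keep <- keep & (is.na(info$qd) | info$qd > qd_min)

  gt <- calls@geno[keep, , drop = FALSE]
  dp <- calls@depth[keep, , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  sc <- matrix("U", nrow(gt), ncol(gt), dimnames = dimnames(gt))
  sc[gt == "0/0"] <- "A"
  sc[gt == "1/1"] <- "B"
  sc[gt == "0/1" | gt == "1/0"] <- "H"
  sc[is.na(dp) | dp < min_depth] <- "U"

  if (is.null(role)) {
    role <- rep("progeny", ncol(sc))
    role[colnames(sc) == "P1"] <- "parent1"
    role[colnames(sc) == "P2"] <- "parent2"
    role[colnames(sc) == "F1"] <- "f1"
  }
  mid <- sprintf("%s_%d", info$scaffold, info$pos)
  out <- ScoreMatrix(sc, data.frame(
    marker_id = mid, scaffold = info$scaffold, bp = info$pos,
    tag_id = mid, reversed = FALSE, stringsAsFactors = FALSE), role)
  attr(out, "rejected") <- rejected
  out
}

#' Merge two caller-specific call sets
#'
#' Union by (scaffold, position). Sites found by both callers are emitted
#' once with origin `"common"`; per-sample genotype conflicts at common
#' sites are resolved by the configured precedence (optionally set to
#' missing), and allele mismatches are flagged. Origin tallies and conflict
#' counts are stored in the `meta` slot.
#'
#' @param set_hc,set_ug [VariantCallSet-class] objects with the same
#'   samples.
#' @param precedence which caller wins per-sample conflicts (`"HC"` or
#'   `"UG"`).
#' @param conflict_to_missing set conflicting definite genotypes to `./.`
#'   instead of using precedence.
#' @return a merged [VariantCallSet-class] with an `origin` column
#'   (`HC-only`, `UG-only`, `common`).
#' @export
mergeCallers <- function(set_hc, set_ug, precedence = c("HC", "UG"),
                         conflict_to_missing = FALSE) {
  precedence <- match.arg(precedence)
  stopifnot(identical(colnames(set_hc@geno), colnames(set_ug@geno)))
  key_hc <- paste(set_hc@info$scaffold, set_hc@info$pos)
  key_ug <- paste(set_ug@info$scaffold, set_ug@info$pos)
  common <- intersect(key_hc, key_ug)
  i_hc <- match(common, key_hc)
  i_ug <- match(common, key_ug)

  allele_mismatch <- sum(set_hc@info$ref[i_hc] != set_ug@info$ref[i_ug] |
                           set_hc@info$alt[i_hc] != set_ug@info$alt[i_ug])
  win <- if (precedence == "HC") list(set_hc, i_hc, set_ug, i_ug)
         else list(set_ug, i_ug, set_hc, i_hc)
  g_win <- win[[1]]@geno[win[[2]], , drop = FALSE]
  g_lose <- win[[3]]@geno[win[[4]], , drop = FALSE]
  conflict <- g_win != "./." & g_lose != "./." & g_win != g_lose
  n_conflict <- sum(conflict)
  g_merged <- g_win
  g_merged[g_win == "./."] <- g_lose[g_win == "./."]
  if (conflict_to_missing) g_merged[conflict] <- "./."
  d_merged <- pmax(win[[1]]@depth[win[[2]], , drop = FALSE],
                   win[[3]]@depth[win[[4]], , drop = FALSE], na.rm = TRUE)

  only_hc <- which(!key_hc %in% common)
  only_ug <- which(!key_ug %in% common)
  tag <- function(df, lab) { df$origin <- rep(lab, nrow(df)); df }
  info <- rbind(
    tag(set_hc@info[only_hc, , drop = FALSE], "HC-only"),
    tag(set_ug@info[only_ug, , drop = FALSE], "UG-only"),
    tag(win[[1]]@info[win[[2]], , drop = FALSE], "common"))
  info$caller <- ifelse(info$origin == "common", "merged", info$caller)
  geno <- rbind(set_hc@geno[only_hc, , drop = FALSE],
                set_ug@geno[only_ug, , drop = FALSE], g_merged)
  depth <- rbind(set_hc@depth[only_hc, , drop = FALSE],
                 set_ug@depth[only_ug, , drop = FALSE], d_merged)
  ord <- order(info$scaffold, info$pos)
  variantCallSet(info[ord, , drop = FALSE], geno[ord, , drop = FALSE],
                 depth[ord, , drop = FALSE],
                 meta = list(n_hc_only = length(only_hc),
                             n_ug_only = length(only_ug),
                             n_common = length(common),
                             n_sample_conflicts = n_conflict,
                             n_allele_mismatch = allele_mismatch))
}

## consensus of several codes for one individual: intersect compatible
## genotype sets; empty or unrepresentable intersections give U
.consensusCodes <- function(codeMat) {
  idx <- matrix(match(codeMat, SCORE_CODES), nrow(codeMat), ncol(codeMat))
  out <- character(ncol(codeMat))
  pat <- c("100" = "A", "010" = "H", "001" = "B",
           "011" = "C", "110" = "D", "111" = "U")
  for (j in seq_len(ncol(codeMat))) {
    s <- CODE_STATES[idx[1, j], ]
    for (i in seq_len(nrow(codeMat))[-1]) s <- s & CODE_STATES[idx[i, j], ]
    key <- paste(as.integer(s), collapse = "")
    out[j] <- if (key %in% names(pat)) pat[[key]] else "U"
  }
  out
}

#' Consolidate SNPs within a GBS tag
#'
#' Collapses SNPs falling in the same tag (a `tag_window_bp` window on a
#' scaffold) to one consensus row per tag. Per individual, codes are
#' combined by intersecting their compatible genotype sets: agreement keeps
#' the code, a definite code absorbs a compatible partial code (`A` with
#' `D`, `B` or `H` with `C`), and a contradiction gives `U`.
#'
#' @param x a [ScoreMatrix-class] sorted by (scaffold, position).
#' @param tag_window_bp tag width in bp (default 1000).
#' @return a [ScoreMatrix-class] with one row per tag.
#' @export
consolidateTags <- function(x, tag_window_bp = 1000) {
  mi <- markerInfo(x)
  sc <- scores(x)
  tag <- paste0(mi$scaffold, ":", (mi$bp - 1) %/% tag_window_bp)
  ord <- order(mi$scaffold, mi$bp)
  sc <- sc[ord, , drop = FALSE]; mi <- mi[ord, , drop = FALSE]
  tag <- tag[ord]
  groups <- split(seq_len(nrow(mi)), factor(tag, levels = unique(tag)))
  rows <- lapply(groups, function(ii) {
    if (length(ii) == 1L) sc[ii, ] else .consensusCodes(sc[ii, , drop = FALSE])
  })
  newsc <- do.call(rbind, rows)
  colnames(newsc) <- colnames(sc)
  first <- vapply(groups, `[`, 0L, 1L)
  info <- data.frame(
    marker_id = sprintf("tag_%s", gsub(":", "_", names(groups))),
    scaffold = mi$scaffold[first], bp = mi$bp[first],
    tag_id = names(groups), reversed = FALSE, stringsAsFactors = FALSE)
  ScoreMatrix(newsc, info, SummarizedExperiment::colData(x)$role)
}

#' Per-marker segregation counts and 1:2:1 test
#'
#' Counts the score classes over progeny for every marker and tests the
#' definite classes (`A`, `H`, `B`; partial codes excluded) against the
#' Mendelian 1:2:1 F2 expectation.
#'
#' @param x a [ScoreMatrix-class].
#' @return data.frame with per-marker counts `nA`, `nH`, `nB`, `nC`, `nD`,
#'   `nU`, the chi-squared statistic, and `p_value`.
#' @export
markerSegregation <- function(x) {
  sc <- progenyScores(x)
  cnt <- sapply(c("A", "H", "B", "C", "D", "U"), function(cc)
    rowSums(sc == cc))
  if (nrow(sc) == 1L) cnt <- matrix(cnt, nrow = 1,
                                    dimnames = list(rownames(sc), names(cnt)))
  colnames(cnt) <- paste0("n", colnames(cnt))
  tot <- cnt[, "nA"] + cnt[, "nH"] + cnt[, "nB"]
  e <- cbind(tot / 4, tot / 2, tot / 4)
  o <- cnt[, c("nA", "nH", "nB"), drop = FALSE]
  stat <- rowSums((o - e)^2 / pmax(e, .Machine$double.eps))
  p <- ifelse(tot > 0, pchisq(stat, df = 2, lower.tail = FALSE), NA_real_)
  data.frame(marker_id = rownames(sc), cnt, statistic = stat, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chi-squared segregation test
#'
#' Pearson goodness-of-fit of observed class counts against an expected
#' ratio (e.g. 1:3 for a recessive phenotype class, 1:2:1 for codominant
#' marker classes), with `df = classes - 1` and an exact chi-squared CDF
#' p-value.
#'
#' @param counts non-negative observed counts.
#' @param ratio expected ratio, same length (e.g. `c(1, 3)`).
#' @return list with `counts`, `expected`, `statistic`, `df`, `p_value`,
#'   `ratio`.
#' @examples
#' segregationTest(c(136, 371), c(1, 3))$p_value  # 0.343
#' @export
segregationTest <- function(counts, ratio) {
  if (any(counts < 0) || any(ratio <= 0))
    stop("counts must be non-negative and ratio positive")
  if (length(counts) != length(ratio))
    stop("counts and ratio must have the same length")
  tot <- sum(counts)
  if (tot == 0) stop("zero total count")
  e <- tot * ratio / sum(ratio)
  stat <- sum((counts - e)^2 / e)
  df <- length(counts) - 1L
  list(counts = counts, expected = e, statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE), ratio = ratio)
}

#' Reorient markers to the cross convention
#'
#' Markers called against the parent-1-side reference should show parent 1
#' as `A` and parent 2 as `B`. Rows where the parent-1 column is `B` or the
#' parent-2 column is `A`, and whose progeny fit 1:2:1 (chi-squared p-value
#' at or above `min_p`), have `A` and `B` (and `C`/`D`) swapped in parents
#' and progeny alike. Markers with `H` or missing parents are untouched
#' (handled by [duplicatePhaseUnknown()]).
#'
#' @param x a [ScoreMatrix-class] with parent columns.
#' @param min_p markers below this 1:2:1 p-value are not reoriented.
#' @return a [ScoreMatrix-class].
#' @export
reorientToCross <- function(x, min_p = 1e-10) {
  p1 <- samplesByRole(x, "parent1"); p2 <- samplesByRole(x, "parent2")
  if (!length(p1) || !length(p2)) stop("parent columns are required")
  sc <- scores(x)
  seg <- markerSegregation(x)
  swap <- (sc[, p1[1]] == "B" | sc[, p2[1]] == "A") &
    !is.na(seg$p_value) & seg$p_value >= min_p
  sc[swap, ] <- matrix(.FLIP[sc[swap, , drop = FALSE]], sum(swap))
  out <- x
  SummarizedExperiment::assay(out, "scores") <- sc
  out
}

#' Duplicate phase-unknown markers
#'
#' Linkage phase is unknown for markers whose parents are heterozygous,
#' ambiguous or missing (`H`, `C`, `D` or `U`). Each such marker is
#' duplicated; in the copy `A` and `B` are swapped, `C` and `D` are swapped,
#' and the marker id gets the suffix `"r"`.
#'
#' @param x a reoriented [ScoreMatrix-class].
#' @return a [ScoreMatrix-class] with the duplicated rows appended after
#'   their originals.
#' @export
duplicatePhaseUnknown <- function(x) {
  p1 <- samplesByRole(x, "parent1"); p2 <- samplesByRole(x, "parent2")
  if (!length(p1) || !length(p2)) stop("parent columns are required")
  sc <- scores(x)
  mi <- markerInfo(x)
  amb <- c("H", "C", "D", "U")
  dup <- sc[, p1[1]] %in% amb | sc[, p2[1]] %in% amb
  if (!any(dup)) return(x)
  flip <- matrix(.FLIP[sc[dup, , drop = FALSE]], sum(dup),
                 dimnames = list(NULL, colnames(sc)))
  mi_r <- mi[dup, , drop = FALSE]
  mi_r$marker_id <- paste0(mi_r$marker_id, "r")
  mi_r$reversed <- TRUE
  ## interleave each duplicate right after its original
  ord <- order(c(seq_len(nrow(sc)), which(dup) + 0.5))
  ScoreMatrix(rbind(sc, flip)[ord, , drop = FALSE],
              rbind(mi, mi_r)[ord, , drop = FALSE],
              SummarizedExperiment::colData(x)$role)
}

#' Collapse cosegregating markers
#'
#' Markers whose progeny score vectors are exactly identical (string match,
#' including `U`) are binned, and only one representative per bin — the one
#' with the lowest (scaffold, position) — is retained. The bin map allows
#' re-expanding collapsed markers onto the final map.
#'
#' @param x a [ScoreMatrix-class].
#' @return list with `scores` (the collapsed [ScoreMatrix-class]) and
#'   `bins` (data.frame `representative`, `member`).
#' @export
collapseCosegregating <- function(x) {
  sc <- progenyScores(x)
  mi <- markerInfo(x)
  key <- apply(sc, 1, paste, collapse = "")
  ord <- order(mi$scaffold, mi$bp, mi$marker_id)
  rep_of <- ord[!duplicated(key[ord])]
  names(rep_of) <- key[rep_of]
  bins <- data.frame(representative = mi$marker_id[rep_of[key]],
                     member = mi$marker_id, stringsAsFactors = FALSE)
  keep <- sort(rep_of)
  list(scores = x[keep, ], bins = bins)
}

#' Filter a score matrix on missingness and segregation
#'
#' Progeny with more than `max_missing` missing scores are dropped first
#' (so one bad sample cannot eliminate markers), then markers with more
#' than `max_missing` missing data over the retained progeny, then markers
#' whose 1:2:1 chi-squared p-value falls below `min_p`. Removal lists are
#' returned so distortion-filtered markers can be rescued later
#' ([rescueDistortedRegions()]).
#'
#' @param x a [ScoreMatrix-class].
#' @param max_missing maximum tolerated missing fraction (default 0.20).
#' @param min_p segregation p-value floor (default 1e-10).
#' @return list with `scores`, `removed_progeny`,
#'   `removed_markers_missing`, and `removed_markers_distorted` (data.frame
#'   with marker metadata, counts and p-values).
#' @export
filterScoreMatrix <- function(x, max_missing = 0.20, min_p = 1e-10) {
  prog <- progenyIds(x)
  sc <- scores(x)[, prog, drop = FALSE]
  miss_prog <- colMeans(sc == "U")
  bad_prog <- prog[miss_prog > max_missing]
  keep_cols <- setdiff(colnames(x), bad_prog)
  if (!any(SummarizedExperiment::colData(x)$role[
    colnames(x) %in% keep_cols] == "progeny"))
    stop("all progeny removed by the missing-data filter")
  x2 <- x[, keep_cols]

  sc2 <- progenyScores(x2)
  miss_mark <- rowMeans(sc2 == "U")
  bad_miss <- markerInfo(x2)$marker_id[miss_mark > max_missing]
  x3 <- x2[!markerInfo(x2)$marker_id %in% bad_miss, ]

  seg <- markerSegregation(x3)
  dist <- !is.na(seg$p_value) & seg$p_value < min_p
  removed_dist <- cbind(markerInfo(x3)[dist, , drop = FALSE],
                        seg[dist, c("nA", "nH", "nB", "p_value"),
                            drop = FALSE])
  rownames(removed_dist) <- NULL
  list(scores = x3[!dist, ], removed_progeny = bad_prog,
       removed_markers_missing = bad_miss,
       removed_markers_distorted = removed_dist)
}
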
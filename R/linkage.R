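#' Map functions
#'
#' Kosambi and Haldane map functions and their inverses. Reported map
#' distances use Kosambi, `d = 25 ln((1 + 2r) / (1 - 2r))` cM, with inverse
#' `r = tanh(2d / 100) / 2`; the QTL scan's hidden Markov model uses Haldane
#' transitions, `r = (1 - exp(-2d / 100)) / 2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5]`.
#' @param d map distance(s) in cM.
#' @param max_cM distance cap applied (with a warning) when `r` reaches 0.5.
#' @return distances in cM, or recombination fractions.
#' @examples
#' kosambiMap(0.1)            # 10.14 cM
#' kosambiInverse(kosambiMap(0.3))
#' @export
kosambiMap <- function(r, max_cM = 50) {
  r <- pmin(pmax(r, 0), 0.5)
  d <- 25 * log((1 + 2 * r) / (1 - 2 * r))
  if (any(is.infinite(d) | d > max_cM)) {
    warning("recombination fraction at 0.5; distance capped at ", max_cM,
            " cM")
    d <- pmin(d, max_cM)
  }
  d
}

#' @rdname kosambiMap
#' @export
kosambiInverse <- function(d) tanh(2 * d / 100) / 2

#' @rdname kosambiMap
#' @export
haldaneMap <- function(r) -50 * log(1 - 2 * pmin(r, 0.5 - 1e-12))

#' @rdname kosambiMap
#' @export
haldaneInverse <- function(d) (1 - exp(-2 * d / 100)) / 2

## F2 joint genotype probabilities at two loci, independent gametes:
## parental gamete (1-r)/2, recombinant r/2
.f2Joint <- function(r) {
  matrix(c((1 - r)^2 / 4, r * (1 - r) / 2, r^2 / 4,
           r * (1 - r) / 2, ((1 - r)^2 + r^2) / 2, r * (1 - r) / 2,
           r^2 / 4, r * (1 - r) / 2, (1 - r)^2 / 4),
         3, 3, byrow = TRUE,
         dimnames = list(c("AA", "AB", "BB"), c("AA", "AB", "BB")))
}

## 6x6 code-pair probabilities: partial codes sum over compatible genotypes
.codePairProb <- function(r)
  CODE_STATES %*% .f2Joint(r) %*% t(CODE_STATES)

.pairCounts <- function(v1, v2) {
  table(factor(v1, levels = SCORE_CODES), factor(v2, levels = SCORE_CODES))
}

#' Two-point recombination fraction estimate
#'
#' Maximum-likelihood estimate of the recombination fraction between two
#' markers under the F2 intercross joint-genotype model (independent
#' gametes). Partial codes `C`/`D` contribute the summed probability of
#' their compatible genotypes; individuals missing (`U`) at either marker
#' are skipped. The likelihood is maximized by bounded 1-D search and the
#' linkage LOD is computed against `r = 0.5`.
#'
#' @param v1,v2 score vectors of equal length (codes `A,B,H,C,D,U`).
#' @return list with `r_hat` (in `[0, 0.5]`), `lod` (>= 0 at the MLE) and
#'   `n_informative`; `r_hat` is `NA` with fewer than two jointly
#'   informative individuals.
#' @export
estimateRF <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  inf <- v1 != "U" & v2 != "U"
  n_inf <- sum(inf)
  if (n_inf < 2)
    return(list(r_hat = NA_real_, lod = NA_real_, n_informative = n_inf))
  N <- .pairCounts(v1[inf], v2[inf])
  pos <- N > 0
  ll <- function(r) {
    P <- .codePairProb(r)
    if (any(pos & P <= 0)) return(-Inf)
    sum(N[pos] * log(P[pos]))
  }
  opt <- optimize(ll, c(1e-9, 0.5 - 1e-9), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 0.5)
  vals <- vapply(cand, ll, 0)
  best <- which.max(vals)
  r_hat <- min(max(cand[best], 0), 0.5)
  lod <- max((vals[best] - ll(0.5)) / log(10), 0)
  list(r_hat = r_hat, lod = lod, n_informative = n_inf)
}

#' All-pairs recombination fractions and LODs
#'
#' Grid-based two-point estimation for every marker pair of a score matrix:
#' the code-pair count table of each pair is scored against the F2
#' joint-genotype likelihood on a grid of recombination fractions, giving
#' the grid MLE and the LOD against `r = 0.5`. Used for linkage grouping
#' and ordering, where thousands of pairs are needed; [estimateRF()] gives
#' the exact MLE for a single pair.
#'
#' @param x a [ScoreMatrix-class] (progeny columns are used).
#' @param markers marker ids to include (default all).
#' @param grid_step grid resolution for `r` (default 0.005).
#' @return list with matrices `r_hat`, `lod`, `n_informative` (marker x
#'   marker; `NA` where fewer than 2 jointly informative individuals).
#' @export
pairwiseRF <- function(x, markers = NULL, grid_step = 0.005) {
  sc <- progenyScores(x)
  if (!is.null(markers)) sc <- sc[markers, , drop = FALSE]
  m <- nrow(sc)
  ids <- rownames(sc)
  idx <- matrix(match(sc, SCORE_CODES), m)
  ind <- lapply(1:6, function(k) (idx == k) * 1)
  notU <- 1 - ind[[6]]
  n_inf <- tcrossprod(notU)

  counts <- vector("list", 25L)  # U pairs skipped
  k <- 0L
  for (c1 in 1:5) for (c2 in 1:5) {
    k <- k + 1L
    counts[[k]] <- tcrossprod(ind[[c1]], ind[[c2]])
  }
  grid <- unique(c(seq(0, 0.5, by = grid_step), 0.5))
  best <- matrix(-Inf, m, m)
  bestr <- matrix(NA_real_, m, m)
  ll05 <- NULL
  for (g in grid) {
    P <- .codePairProb(g)
    lp <- log(P)
    lp[!is.finite(lp)] <- -1e10
    LL <- matrix(0, m, m)
    k <- 0L
    for (c1 in 1:5) for (c2 in 1:5) {
      k <- k + 1L
      if (lp[c1, c2] != 0) LL <- LL + counts[[k]] * lp[c1, c2]
    }
    upd <- LL > best
    best[upd] <- LL[upd]
    bestr[upd] <- g
    if (g == 0.5) ll05 <- LL
  }
  lod <- (best - ll05) / log(10)
  lod[n_inf < 2] <- NA
  bestr[n_inf < 2] <- NA
  diag(lod) <- 0; diag(bestr) <- 0
  dimnames(lod) <- dimnames(bestr) <- dimnames(n_inf) <- list(ids, ids)
  list(r_hat = bestr, lod = lod, n_informative = n_inf)
}

#' Assign markers to linkage groups
#'
#' Groups are the connected components of the marker graph with an edge
#' wherever the two-point LOD reaches `min_lod`. Markers whose nearest
#' linked neighbour is farther than `no_map_cM` (Kosambi-transformed
#' r-hat), and markers with no informative linkage at all (singletons), are
#' set aside as unplaceable.
#'
#' @param x a [ScoreMatrix-class].
#' @param min_lod LOD threshold for a linkage edge (default 12).
#' @param no_map_cM placement gate in cM (default 15).
#' @param rf optional precomputed [pairwiseRF()] result.
#' @return list with `groups` (named list of marker-id vectors),
#'   `ungrouped` and the `rf` object.
#' @export
groupMarkers <- function(x, min_lod = 12, no_map_cM = 15, rf = NULL) {
  if (is.null(rf)) rf <- pairwiseRF(x)
  lod <- rf$lod
  adj <- !is.na(lod) & lod >= min_lod
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(gr)$membership
  ids <- rownames(lod)

  ungrouped <- character(0)
  groups <- list()
  for (g in sort(unique(memb))) {
    members <- ids[memb == g]
    if (length(members) < 2) { ungrouped <- c(ungrouped, members); next }
    ## placement gate: nearest linked neighbour within no_map_cM
    sub_lod <- lod[members, members, drop = FALSE]
    sub_r <- rf$r_hat[members, members, drop = FALSE]
    dd <- suppressWarnings(kosambiMap(sub_r, max_cM = 1e6))
    dd[is.na(sub_lod) | sub_lod < min_lod] <- Inf
    diag(dd) <- Inf
    nearest <- apply(dd, 1, min)
    far <- members[nearest > no_map_cM]
    members <- setdiff(members, far)
    ungrouped <- c(ungrouped, far)
    if (length(members) < 2) ungrouped <- c(ungrouped, members)
    else groups[[length(groups) + 1L]] <- members
  }
  names(groups) <- sprintf("LG%02d", seq_along(groups))
  list(groups = groups, ungrouped = ungrouped, rf = rf)
}

#' Remove mirror-image linkage groups
#'
#' Phase duplication creates pairs of linkage groups whose marker sets
#' correspond one-to-one under the `"r"` twin pairing. Each such pair is
#' collapsed to one group — the copy with more non-reversed markers (ties
#' broken lexicographically) — and the retained phase of every duplicated
#' marker is reported. A marker co-occurring with its own twin inside one
#' group is kept and reported as a conflict for the ordering stage.
#'
#' @param groups named list of marker-id vectors (from [groupMarkers()]).
#' @return list with `groups`, `phase_report` (data.frame `base`, `kept`)
#'   and `conflicts`.
#' @export
dedupeMirrorGroups <- function(groups) {
  base <- lapply(groups, function(g) sub("r$", "", g))
  conflicts <- unlist(lapply(seq_along(groups), function(i) {
    b <- base[[i]]
    b[duplicated(b)]
  }))
  key <- vapply(base, function(b) paste(sort(b), collapse = "\r"), "")
  drop <- logical(length(groups))
  report <- list()
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k & !drop)
    while (length(idx) >= 2) {
      i <- idx[1]
      mate <- NULL
      for (j in idx[-1]) {
        gi <- groups[[i]]; gj <- groups[[j]]
        bi <- sub("r$", "", gi)
        ## mirror iff every marker appears in the opposite phase in j
        if (all(ifelse(grepl("r$", gi), bi, paste0(bi, "r")) %in% gj)) {
          mate <- j; break
        }
      }
      if (is.null(mate)) break
      nrev_i <- sum(!grepl("r$", groups[[i]]))
      nrev_j <- sum(!grepl("r$", groups[[mate]]))
      keep <- if (nrev_i > nrev_j) i
      else if (nrev_j > nrev_i) mate
      else c(i, mate)[order(vapply(list(groups[[i]], groups[[mate]]),
                                   function(g) min(sort(g)), ""))[1]]
      lose <- setdiff(c(i, mate), keep)
      drop[lose] <- TRUE
      report[[length(report) + 1L]] <- data.frame(
        base = sub("r$", "", groups[[keep]]), kept = groups[[keep]],
        stringsAsFactors = FALSE)
      idx <- setdiff(idx, c(keep, lose))
    }
  }
  phase_report <- if (length(report)) do.call(rbind, report)
  else data.frame(base = character(0), kept = character(0))
  list(groups = groups[!drop], phase_report = phase_report,
       conflicts = unique(conflicts))
}

.sarf <- function(ord, rhat)
  sum(rhat[cbind(ord[-length(ord)], ord[-1])])

.twoOpt <- function(ord, rhat) {
  m <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        delta <- 0
        if (i > 1)
          delta <- delta + rhat[ord[i - 1], ord[j]] - rhat[ord[i - 1], ord[i]]
        if (j < m)
          delta <- delta + rhat[ord[i], ord[j + 1]] - rhat[ord[j], ord[j + 1]]
        if (delta < -1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Order the markers of a linkage group
#'
#' A framework order is obtained by seriation — the first principal
#' coordinate of the Kosambi-transformed distance matrix — and polished by
#' 2-opt segment reversals minimizing SARF (the sum of adjacent
#' recombination fractions), with seeded random restarts. Runs of markers
#' not separated by any recombination event are ordered by physical
#' (scaffold, bp) position, and the group is oriented so the first marker
#' has the smaller bp position on the majority scaffold. Adjacent
#' recombination fractions of the final order are re-estimated exactly.
#'
#' @param x a [ScoreMatrix-class].
#' @param markers marker ids of the group (>= 2).
#' @param rf optional [pairwiseRF()] result covering the markers.
#' @param n_restarts random restarts for the 2-opt polish (default 5).
#' @param seed seed for the restarts.
#' @param name group name.
#' @return a [LinkageGroup-class] (cM positions unset; see
#'   [mapDistances()]).
#' @export
orderMarkers <- function(x, markers, rf = NULL, n_restarts = 5, seed = 1L,
                         name = "LG") {
  if (length(markers) < 2) stop("a linkage group needs at least 2 markers")
  if (is.null(rf)) rf <- pairwiseRF(x, markers)
  rhat <- rf$r_hat[markers, markers]
  if (any(!is.finite(rhat))) {
    warning("uninformative marker pairs in group '", name,
            "'; treated as unlinked")
    rhat[!is.finite(rhat)] <- 0.499
  }
  m <- length(markers)
  D <- suppressWarnings(kosambiMap(rhat, max_cM = 1e3))

  starts <- list()
  pc <- tryCatch(cmdscale(as.dist(D), k = 1), error = function(e) NULL)
  starts[[1]] <- if (!is.null(pc)) order(pc[, 1]) else seq_len(m)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (i in seq_len(max(n_restarts - 1, 0)))
    starts[[i + 1]] <- sample(m)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  rn <- matrix(0, m, m, dimnames = list(markers, markers))
  rn[] <- rhat
  orders <- lapply(starts, function(s) .twoOpt(markers[s], rn))
  sarfs <- vapply(orders, .sarf, 0, rhat = rn)
  ord <- orders[[which.min(sarfs)]]

  mi <- markerInfo(x)
  mi <- mi[match(ord, mi$marker_id), , drop = FALSE]
  ## physical tie-break inside zero-recombination runs
  adj <- rn[cbind(ord[-m], ord[-1])]
  run <- cumsum(c(1, adj > 0))
  for (rr in unique(run[duplicated(run)])) {
    ii <- which(run == rr)
    mi[ii, ] <- mi[ii[order(mi$scaffold[ii], mi$bp[ii])], , drop = FALSE]
  }
  ord <- mi$marker_id
  ## orientation: first marker at the smaller bp on the majority scaffold
  sc_major <- names(sort(table(mi$scaffold), decreasing = TRUE))[1]
  on_major <- which(mi$scaffold == sc_major)
  if (length(on_major) >= 2 &&
      mi$bp[on_major[1]] > mi$bp[on_major[length(on_major)]]) {
    ord <- rev(ord)
    mi <- mi[rev(seq_len(nrow(mi))), , drop = FALSE]
  }

  sc <- progenyScores(x)
  rf_adj <- vapply(seq_len(m - 1), function(i)
    estimateRF(sc[ord[i], ], sc[ord[i + 1], ])$r_hat, 0)
  new("LinkageGroup", name = name,
      table = data.frame(marker_id = ord, scaffold = mi$scaffold,
                         bp = mi$bp,
                         reversed = grepl("r$", ord),
                         cM = NA_real_, dbl_rec = NA_integer_,
                         row.names = NULL, stringsAsFactors = FALSE),
      rfAdj = rf_adj)
}

#' Count and filter double recombinants
#'
#' For each internal marker of an ordered group, counts the progeny whose
#' scores at the two flanking markers are equal, definite, and definitely
#' different from the marker's own score (an X-Y-X pattern implying two
#' crossovers, usually a genotyping error). `filterDoubleRecombinants()`
#' removes markers with more than `max_events` such events and recomputes
#' adjacent distances.
#'
#' @param lg a [LinkageGroup-class].
#' @param x the [ScoreMatrix-class] the group was built from.
#' @return `countDoubleRecombinants()`: named integer vector of per-marker
#'   event counts.
#' @export
countDoubleRecombinants <- function(lg, x) {
  ord <- lg@table$marker_id
  sc <- progenyScores(x)[ord, , drop = FALSE]
  def <- matrix(sc %in% c("A", "H", "B"), nrow(sc))
  m <- length(ord)
  counts <- integer(m)
  if (m >= 3) for (i in 2:(m - 1)) {
    ok <- def[i - 1, ] & def[i, ] & def[i + 1, ]
    counts[i] <- sum(ok & sc[i - 1, ] == sc[i + 1, ] &
                       sc[i, ] != sc[i - 1, ])
  }
  names(counts) <- ord
  counts
}

#' @rdname countDoubleRecombinants
#' @param max_events maximum tolerated double-recombination events
#'   (default 10).
#' @return `filterDoubleRecombinants()`: the filtered [LinkageGroup-class]
#'   with `dbl_rec` filled in and distances recomputed.
#' @export
filterDoubleRecombinants <- function(lg, x, max_events = 10) {
  counts <- countDoubleRecombinants(lg, x)
  lg@table$dbl_rec <- as.integer(counts)
  keep <- counts <= max_events
  if (all(keep)) return(lg)
  ord <- lg@table$marker_id[keep]
  sc <- progenyScores(x)
  rf_adj <- if (length(ord) > 1)
    vapply(seq_len(length(ord) - 1), function(i)
      estimateRF(sc[ord[i], ], sc[ord[i + 1], ])$r_hat, 0)
  else numeric(0)
  lg@table <- lg@table[keep, , drop = FALSE]
  rownames(lg@table) <- NULL
  lg@rfAdj <- rf_adj
  if (!all(is.na(lg@table$cM))) lg <- mapDistances(lg)
  lg
}

#' Mask apparent genotyping errors before distance estimation
#'
#' A single marker disagreeing with two identical definite flanking markers
#' in one individual (an X-Y-X pattern) implies two crossovers within a few
#' cM and is almost always a miscoded genotype. Left in place, such errors
#' inflate every adjacent recombination-fraction estimate and hence the map
#' length. This step sets the middle genotype of every definite X-Y-X
#' triple to missing, mirroring the genotyping-error detection the
#' classical mappers run before computing final distances.
#'
#' @param lg an ordered [LinkageGroup-class].
#' @param x the [ScoreMatrix-class] the group was built from.
#' @return `x` with the flagged cells set to `U`.
#' @export
maskDoubleRecombinants <- function(lg, x) {
  ord <- lg@table$marker_id
  sc <- scores(x)
  prog <- progenyIds(x)
  sub <- sc[ord, prog, drop = FALSE]
  def <- matrix(sub %in% c("A", "H", "B"), nrow(sub))
  m <- length(ord)
  if (m >= 3) for (i in 2:(m - 1)) {
    bad <- def[i - 1, ] & def[i, ] & def[i + 1, ] &
      sub[i - 1, ] == sub[i + 1, ] & sub[i, ] != sub[i - 1, ]
    sc[ord[i], prog[bad]] <- "U"
  }
  out <- x
  SummarizedExperiment::assay(out, "scores") <- sc
  out
}

#' Compute Kosambi map positions
#'
#' Converts the adjacent recombination fractions of an ordered group to
#' Kosambi centimorgans and accumulates positions from 0.
#'
#' @param lg a [LinkageGroup-class] with adjacent r estimates.
#' @param max_cM cap for unlinked adjacencies (`r = 0.5`), applied with a
#'   warning.
#' @return the [LinkageGroup-class] with `cM` filled in.
#' @export
mapDistances <- function(lg, max_cM = 50) {
  d <- kosambiMap(lg@rfAdj, max_cM = max_cM)
  lg@table$cM <- cumsum(c(0, d))
  lg
}

#' Rescue distortion-filtered markers into their physical linkage groups
#'
#' Markers removed by the segregation-distortion filter whose scaffolds
#' physically belong to a target linkage group are re-admitted, and those
#' groups are re-ordered without the chi-squared filter. Removed markers
#' whose scaffold occurs on no group are skipped with a warning.
#'
#' @param map a [LinkageMap-class].
#' @param removed data.frame of removed markers (from
#'   [filterScoreMatrix()]`$removed_markers_distorted`), needing
#'   `marker_id` and `scaffold`.
#' @param x a [ScoreMatrix-class] still containing the removed markers.
#' @param max_events double-recombination filter re-applied after
#'   re-ordering.
#' @param seed seed for the ordering restarts.
#' @return the updated [LinkageMap-class].
#' @export
rescueDistortedRegions <- function(map, removed, x, max_events = 10,
                                   seed = 1L) {
  if (!nrow(removed)) return(map)
  lg_scaffolds <- lapply(map@groups, function(g) unique(g@table$scaffold))
  target <- vapply(removed$scaffold, function(s) {
    hit <- which(vapply(lg_scaffolds, function(ss) s %in% ss, TRUE))
    if (length(hit)) hit[1] else NA_integer_
  }, 0L)
  if (any(is.na(target)))
    warning(sum(is.na(target)),
            " removed marker(s) without a physical group assignment; skipped")
  for (gi in unique(target[!is.na(target)])) {
    add <- removed$marker_id[!is.na(target) & target == gi]
    add <- intersect(add, markerInfo(x)$marker_id)
    if (!length(add)) next
    members <- union(map@groups[[gi]]@table$marker_id, add)
    lg <- orderMarkers(x, members, name = map@groups[[gi]]@name, seed = seed)
    lg <- mapDistances(lg)
    lg <- filterDoubleRecombinants(lg, x, max_events = max_events)
    map@groups[[gi]] <- mapDistances(lg)
  }
  validObject(map)
  map
}

#' Build a linkage map end to end
#'
#' Convenience pipeline: all-pairs two-point estimation, LOD grouping,
#' mirror-group removal, per-group ordering, double-recombinant filtering
#' and Kosambi distances.
#'
#' @param x a filtered, phase-duplicated [ScoreMatrix-class].
#' @param min_lod,no_map_cM grouping parameters (see [groupMarkers()]).
#' @param max_events double-recombination tolerance.
#' @param n_restarts,seed ordering parameters (see [orderMarkers()]).
#' @param mask_errors run genotyping-error detection
#'   ([maskDoubleRecombinants()]) before the final distance estimates
#'   (default TRUE).
#' @return a [LinkageMap-class].
#' @export
buildLinkageMap <- function(x, min_lod = 12, no_map_cM = 15,
                            max_events = 10, n_restarts = 5, seed = 1L,
                            mask_errors = TRUE) {
  grp <- groupMarkers(x, min_lod = min_lod, no_map_cM = no_map_cM)
  ded <- dedupeMirrorGroups(grp$groups)
  groups <- lapply(seq_along(ded$groups), function(i) {
    lg <- orderMarkers(x, ded$groups[[i]], rf = grp$rf,
                       n_restarts = n_restarts, seed = seed,
                       name = sprintf("LG%02d", i))
    lg <- filterDoubleRecombinants(lg, x, max_events = max_events)
    if (mask_errors) {
      xm <- maskDoubleRecombinants(lg, x)
      sc <- progenyScores(xm)
      ord <- lg@table$marker_id
      lg@rfAdj <- vapply(seq_len(length(ord) - 1), function(j)
        estimateRF(sc[ord[j], ], sc[ord[j + 1], ])$r_hat, 0)
    }
    mapDistances(lg)
  })
  names(groups) <- vapply(groups, function(g) g@name, "")
  new("LinkageMap", groups = groups, ungrouped = grp$ungrouped,
      phaseReport = ded$phase_report)
}

#' Linkage map from simulation truth
#'
#' Builds the true map of a [GenomeSpec-class] (one group per chromosome,
#' true cM positions) — the reference for parameter-recovery tests and for
#' scanning simulated data without re-estimating the map.
#'
#' @param genome a [GenomeSpec-class].
#' @return a [LinkageMap-class].
#' @export
truthMap <- function(genome) {
  mk <- genome@markers
  groups <- lapply(genome@chromosomes$chrom, function(cc) {
    sub <- mk[mk$chrom == cc, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    cm <- sub$cM - sub$cM[1]
    new("LinkageGroup", name = cc,
        table = data.frame(marker_id = sub$marker_id, scaffold = sub$chrom,
                           bp = sub$bp, reversed = FALSE, cM = cm,
                           dbl_rec = NA_integer_, row.names = NULL,
                           stringsAsFactors = FALSE),
        rfAdj = kosambiInverse(diff(cm)))
  })
  groups <- Filter(Negate(is.null), groups)
  names(groups) <- vapply(groups, function(g) g@name, "")
  new("LinkageMap", groups = groups, ungrouped = character(0),
      phaseReport = data.frame(base = character(0), kept = character(0)))
}
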
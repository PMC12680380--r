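## conditional transition matrix between F2 states for recombination r
.f2Transition <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2),
         3, 3, byrow = TRUE)
}

## emission likelihoods P(code | state) for the three F2 states
.emission <- function(code, eps) {
  comp <- CODE_STATES[code, ]
  if (code == "U") return(c(1, 1, 1))
  if (sum(comp) == 1) ifelse(comp == 1, 1 - eps, eps / 2)
  else ifelse(comp == 1, 1 - eps, eps)
}

#' Conditional QTL genotype probabilities
#'
#' Per-chromosome hidden-Markov forward-backward over the F2 states
#' {AA, AB, BB} with stationary distribution (1/4, 1/2, 1/4). Transition
#' probabilities come from Haldane-inverted inter-position cM distances
#' (independent gametes, no interference); emissions allow a genotyping
#' error rate `eps` and give partial codes their compatible-state mass
#' (`C` on {AB, BB}, `D` on {AA, AB}, `U` uninformative). Probabilities are
#' computed at every marker and at a pseudomarker grid every `step_cM`.
#'
#' @param map a [LinkageMap-class] whose markers are rows of `x`.
#' @param x a [ScoreMatrix-class].
#' @param step_cM grid step in cM (default 2.5).
#' @param eps assumed genotyping error rate (default 1e-4).
#' @return a [GenoProbGrid-class].
#' @export
genotypeProbs <- function(map, x, step_cM = 2.5, eps = 1e-4) {
  if (step_cM <= 0) stop("step_cM must be positive")
  sc <- progenyScores(x)
  ids <- colnames(sc)
  n <- length(ids)
  init <- c(0.25, 0.5, 0.25)

  pos_list <- list(); prob_list <- list()
  for (g in map@groups) {
    mk <- g@table$marker_id
    if (!all(mk %in% rownames(sc)))
      stop("map markers missing from the score matrix: ",
           paste(head(setdiff(mk, rownames(sc))), collapse = ", "))
    cm <- g@table$cM
    grid <- sort(unique(round(c(seq(0, max(cm), by = step_cM), cm), 6)))
    is_mk <- match(grid, round(cm, 6))
    P <- length(grid)

    Elist <- vector("list", P)
    for (p in seq_len(P)) {
      if (is.na(is_mk[p])) Elist[[p]] <- matrix(1, n, 3)
      else {
        v <- sc[mk[is_mk[p]], ]
        em <- t(vapply(v, .emission, numeric(3), eps = eps))
        Elist[[p]] <- em
      }
    }
    r_adj <- haldaneInverse(diff(grid))
    Tlist <- lapply(r_adj, .f2Transition)

    alpha <- vector("list", P)
    a <- sweep(Elist[[1]], 2, init, "*")
    alpha[[1]] <- a / rowSums(a)
    for (p in seq_len(P)[-1]) {
      a <- (alpha[[p - 1]] %*% Tlist[[p - 1]]) * Elist[[p]]
      alpha[[p]] <- a / rowSums(a)
    }
    beta <- vector("list", P)
    beta[[P]] <- matrix(1, n, 3)
    for (p in rev(seq_len(P - 1))) {
      b <- (Elist[[p + 1]] * beta[[p + 1]]) %*% t(Tlist[[p]])
      beta[[p]] <- b / rowSums(b)
    }
    probs <- array(NA_real_, c(P, n, 3))
    for (p in seq_len(P)) {
      post <- alpha[[p]] * beta[[p]]
      probs[p, , ] <- post / rowSums(post)
    }
    pos_list[[g@name]] <- data.frame(
      chrom = g@name, cM = grid,
      marker = ifelse(is.na(is_mk), NA_character_, mk[is_mk]),
      stringsAsFactors = FALSE)
    prob_list[[g@name]] <- probs
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  total <- sum(vapply(prob_list, function(p) dim(p)[1], 0L))
  probs <- array(NA_real_, c(total, n, 3),
                 dimnames = list(NULL, ids, c("AA", "AB", "BB")))
  at <- 0L
  for (p in prob_list) {
    probs[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  new("GenoProbGrid", positions = positions, probs = probs, eps = eps,
      step = step_cM)
}

.scanDesign <- function(grid, phenotype, covariates) {
  ids <- dimnames(grid@probs)[[2]]
  if (!is.null(names(phenotype))) phenotype <- phenotype[ids]
  if (length(phenotype) != length(ids))
    stop("phenotype length must match the individuals of the grid")
  keep <- which(!is.na(phenotype))
  y <- as.numeric(phenotype[keep])
  X0 <- matrix(1, length(keep), 1)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != length(ids))
      stop("covariates must have one row per individual")
    cv <- cv[keep, , drop = FALSE]
    q <- qr(cbind(X0, cv))
    if (q$rank < 1 + ncol(cv)) {
      drop <- setdiff(seq_len(ncol(cv)), q$pivot[seq_len(q$rank)] - 1L)
      warning("dropping collinear covariate(s): ",
              paste(colnames(cv)[drop], collapse = ", "))
      cv <- cv[, -drop, drop = FALSE]
    }
    X0 <- cbind(X0, cv)
    cov_names <- colnames(cv)
    if (is.null(cov_names)) cov_names <- sprintf("cov%d", seq_len(ncol(cv)))
  }
  list(keep = keep, y = y, X0 = X0, cov_names = cov_names)
}

#' Haley-Knott genome scan for a binary trait
#'
#' At every grid position, regresses the phenotype on the additive
#' (`P(BB) - P(AA)`) and dominance (`P(AB)`) expected-genotype regressors
#' plus any covariates, by least squares. The LOD is
#' `(n/2) log10(RSS0 / RSS1)` where `RSS0` is the covariate-only fit.
#' Binary phenotypes may be coded 1/2 or 0/1; the curve is invariant to the
#' coding. Missing phenotypes are dropped.
#'
#' @param grid a [GenoProbGrid-class].
#' @param phenotype numeric vector (optionally named by individual).
#' @param covariates optional matrix of covariates (e.g. marker dosages),
#'   one row per individual of the grid.
#' @param drop LOD drop for the support interval (default 1.5).
#' @return a [ScanResult-class] with the LOD curve, peak, support interval
#'   and PVE (threshold `NA` until [permutationThreshold()]).
#' @export
haleyKnottScan <- function(grid, phenotype, covariates = NULL, drop = 1.5) {
  d <- .scanDesign(grid, phenotype, covariates)
  y <- d$y; n <- length(y)
  RSS0 <- sum(qr.resid(qr(d$X0), y)^2)
  P <- grid@probs[, d$keep, , drop = FALSE]
  npos <- dim(P)[1]
  lod <- numeric(npos)
  for (p in seq_len(npos)) {
    xa <- P[p, , 3] - P[p, , 1]
    xd <- P[p, , 2]
    fit <- lm.fit(cbind(d$X0, xa, xd), y)
    lod[p] <- (n / 2) * log10(RSS0 / sum(fit$residuals^2))
  }
  tab <- cbind(grid@positions, lod = lod)
  pk <- which.max(lod)
  peak_marker <- tab$marker[pk]
  if (is.na(peak_marker)) {
    same <- which(tab$chrom == tab$chrom[pk] & !is.na(tab$marker))
    if (length(same))
      peak_marker <- tab$marker[same[which.min(abs(tab$cM[same] -
                                                     tab$cM[pk]))]]
  }
  peak <- list(chrom = tab$chrom[pk], cM = tab$cM[pk], marker = peak_marker,
               lod = lod[pk])
  res <- new("ScanResult", lod = tab, peak = peak,
             pve = 1 - 10^(-2 * lod[pk] / n), threshold = NA_real_,
             interval = list(), covariates = d$cov_names)
  res@interval <- supportInterval(res, drop = drop)
  res
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype labels jointly across all chromosomes, records
#' the genome-wide maximum LOD of each permuted scan, and returns the
#' empirical `1 - alpha` quantile (type-7 interpolation).
#'
#' @param grid a [GenoProbGrid-class].
#' @param phenotype numeric phenotype vector.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha significance level(s) (default 0.05).
#' @param seed integer seed.
#' @param covariates optional covariate matrix (kept fixed, not permuted).
#' @return list with `threshold` (named by alpha), `maxima` (per-permutation
#'   genome-wide maxima), `alpha`, `n_perm`.
#' @export
permutationThreshold <- function(grid, phenotype, n_perm = 1000,
                                 alpha = 0.05, seed = NULL,
                                 covariates = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  d <- .scanDesign(grid, phenotype, covariates)
  y <- d$y; n <- length(y)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
  SS <- colSums(Y^2)
  q0 <- qr(d$X0)
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  RSS0 <- SS - colSums(crossprod(Q0, Y)^2)

  P <- grid@probs[, d$keep, , drop = FALSE]
  npos <- dim(P)[1]
  maxlod <- rep(-Inf, n_perm)
  for (p in seq_len(npos)) {
    X <- cbind(d$X0, P[p, , 3] - P[p, , 1], P[p, , 2])
    q1 <- qr(X)
    Q1 <- qr.Q(q1)[, seq_len(q1$rank), drop = FALSE]
    RSS1 <- SS - colSums(crossprod(Q1, Y)^2)
    lod <- (n / 2) * log10(RSS0 / RSS1)
    maxlod <- pmax(maxlod, lod)
  }
  thr <- quantile(maxlod, 1 - alpha, type = 7)
  names(thr) <- format(alpha)
  list(threshold = thr, maxima = maxlod, alpha = alpha, n_perm = n_perm)
}

#' Fit the QTL at a peak
#'
#' Refits the peak regression and reports the percentage of phenotypic
#' variance explained, `PVE = 1 - 10^(-2 LOD / n)` (algebraically
#' `1 - RSS1/RSS0`), together with the additive and dominance effect
#' estimates.
#'
#' @param grid a [GenoProbGrid-class].
#' @param phenotype numeric phenotype vector.
#' @param peak list with `chrom` and `cM` (e.g. [scanPeak()] of a scan).
#' @param covariates optional covariate matrix.
#' @return list with `pve`, `lod`, `additive`, `dominance`, `n`.
#' @export
fitQTL <- function(grid, phenotype, peak, covariates = NULL) {
  d <- .scanDesign(grid, phenotype, covariates)
  y <- d$y; n <- length(y)
  if (n == 0) stop("no phenotyped individuals")
  pos <- grid@positions
  cand <- which(pos$chrom == peak$chrom)
  if (!length(cand)) stop("peak chromosome not on the grid")
  p <- cand[which.min(abs(pos$cM[cand] - peak$cM))]
  xa <- grid@probs[p, d$keep, 3] - grid@probs[p, d$keep, 1]
  xd <- grid@probs[p, d$keep, 2]
  X <- cbind(d$X0, additive = xa, dominance = xd)
  fit <- lm.fit(X, y)
  RSS0 <- sum(qr.resid(qr(d$X0), y)^2)
  RSS1 <- sum(fit$residuals^2)
  lod <- (n / 2) * log10(RSS0 / RSS1)
  list(pve = 1 - RSS1 / RSS0, lod = lod,
       additive = unname(fit$coefficients["additive"]),
       dominance = unname(fit$coefficients["dominance"]), n = n)
}

#' LOD support interval
#'
#' The widest contiguous region around the peak with LOD at least
#' `peak - drop`, expanded outward to the nearest flanking markers. A flat
#' curve (no position below the drop on the peak chromosome) returns the
#' whole chromosome, flagged.
#'
#' @param scan a [ScanResult-class].
#' @param drop LOD drop (default 1.5).
#' @return list with `left`, `right` (cM), `left_marker`, `right_marker`,
#'   `chrom` and `flat` (logical).
#' @export
supportInterval <- function(scan, drop = 1.5) {
  tab <- scan@lod
  pk <- scan@peak
  sub <- tab[tab$chrom == pk$chrom, , drop = FALSE]
  sub <- sub[order(sub$cM), , drop = FALSE]
  i <- which.min(abs(sub$cM - pk$cM))
  thr <- pk$lod - drop
  lo <- i; while (lo > 1 && sub$lod[lo - 1] >= thr) lo <- lo - 1
  hi <- i; while (hi < nrow(sub) && sub$lod[hi + 1] >= thr) hi <- hi + 1
  flat <- lo == 1 && hi == nrow(sub) && all(sub$lod >= thr)
  ## expand outward to the nearest flanking markers
  mk <- which(!is.na(sub$marker))
  lo_mk <- mk[mk < lo]
  hi_mk <- mk[mk > hi]
  lo <- if (length(lo_mk)) max(lo_mk) else lo
  hi <- if (length(hi_mk)) min(hi_mk) else hi
  list(left = sub$cM[lo], right = sub$cM[hi],
       left_marker = sub$marker[lo], right_marker = sub$marker[hi],
       chrom = pk$chrom, flat = flat)
}
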
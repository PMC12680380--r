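#' Observation model for simulated genotyping
#'
#' Parameters of the observation layer that turns true genotypes into
#' mapping scores: read depth (negative binomial), a depth floor below which
#' calls are missing, a miscoding rate, a partial-code rate (true `H` or
#' homozygote reported as the compatible `C`/`D` code), and a missing rate.
#'
#' @param min_depth minimum per-sample read depth for a definite call
#'   (default 8, the usual GBS filter).
#' @param depth_mean,depth_dispersion negative-binomial mean and dispersion
#'   (`size`) of the per-cell read depth.
#' @param error_rate probability a true genotype is miscoded as another
#'   definite code.
#' @param partial_code_rate probability a true `H` or homozygote is reported
#'   as a partial code (`H` to `C` or `D`, `A` to `D`, `B` to `C`).
#' @param missing_rate probability a call is reported as `U` outright.
#' @return a list of class parameters used by [observeGenotypes()].
#' @export
observationModel <- function(min_depth = 8, depth_mean = 25,
                             depth_dispersion = 5, error_rate = 0,
                             partial_code_rate = 0, missing_rate = 0) {
  p <- c(error_rate = error_rate, partial_code_rate = partial_code_rate,
         missing_rate = missing_rate)
  if (any(p < 0 | p > 1)) stop("rates must lie in [0, 1]")
  if (min_depth < 1) stop("min_depth must be >= 1")
  list(min_depth = min_depth, depth_mean = depth_mean,
       depth_dispersion = depth_dispersion, error_rate = error_rate,
       partial_code_rate = partial_code_rate, missing_rate = missing_rate)
}

#' Transmission-ratio distortion locus
#'
#' Specifies a driver locus distorting transmission in a simulated cross.
#' In `"gametic"` mode a gamete carrying the disfavoured allele at the locus
#' is rejected so that the favoured allele is transmitted with probability
#' `k` per gamete. In `"zygotic"` mode zygotes homozygous for the
#' disfavoured allele survive with relative viability `(1 - k) / k`, so
#' `k = 1` removes them entirely and leaves the ~1/3 favoured-homozygote,
#' ~2/3 heterozygote pattern seen at completely biased loci.
#'
#' @param chrom chromosome name.
#' @param cM locus position in cM.
#' @param k transmission probability of the favoured allele per gamete,
#'   in `[0.5, 1]` (0.5 = Mendelian).
#' @param stage `"gametic"` or `"zygotic"`.
#' @param favoured founder homolog favoured (1 = parent 1, 2 = parent 2).
#' @param parent which parent-of-origin's gametes are distorted in gametic
#'   mode: `"both"`, `"maternal"` or `"paternal"`.
#' @return a distortion specification list for [simulateCross()].
#' @export
distortionSpec <- function(chrom, cM, k, stage = c("gametic", "zygotic"),
                           favoured = 1L, parent = c("both", "maternal",
                                                     "paternal")) {
  stage <- match.arg(stage)
  parent <- match.arg(parent)
  if (k < 0.5 || k > 1) stop("k must lie in [0.5, 1]")
  if (!favoured %in% c(1L, 2L)) stop("favoured must be 1 or 2")
  list(chrom = as.character(chrom), cM = cM, k = k, stage = stage,
       favoured = as.integer(favoured), parent = parent)
}

## founder homolog carried by a gamete at a cM position
.gameteAlleleAt <- function(gamete_chr, pos) {
  nb <- findInterval(pos, gamete_chr$breaks)
  ifelse(nb %% 2 == 0, gamete_chr$start, 3L - gamete_chr$start)
}

.drawGamete <- function(chrtab) {
  lapply(seq_len(nrow(chrtab)), function(i) {
    len <- chrtab$length_cM[i]
    nxo <- rpois(1L, len / 100)
    list(start = sample(1:2, 1L),
         breaks = sort(runif(nxo, 0, len)))
  })
}

## rejection sampling of one gamete against the gametic distortion loci
.drawGameteDistorted <- function(chrtab, dist, side) {
  dist <- Filter(function(d) d$stage == "gametic" &&
                   (d$parent == "both" || d$parent == side), dist)
  repeat {
    g <- .drawGamete(chrtab)
    ok <- TRUE
    for (d in dist) {
      i <- match(d$chrom, chrtab$chrom)
      a <- .gameteAlleleAt(g[[i]], d$cM)
      if (a != d$favoured && runif(1) > (1 - d$k) / d$k) { ok <- FALSE; break }
    }
    if (ok) return(g)
  }
}

#' Simulate an F2 or F1 cross
#'
#' Generates gametes by a no-interference crossover process (crossover count
#' Poisson with mean the chromosome length in Morgans, positions uniform)
#' and records full ground truth. In the `"f2"` design each individual is
#' formed from two gametes of the selfed F1, whose two homologs are the
#' parent-1 and parent-2 genomes; in the `"f1"` design the maternal gamete
#' samples parent 1's homologs and the paternal gamete parent 2's.
#' Transmission-ratio distortion loci are applied by rejection sampling
#' (see [distortionSpec()]).
#'
#' @param genome a [GenomeSpec-class].
#' @param n_progeny number of progeny (>= 1).
#' @param design `"f2"` (P1 x P2 -> F1 -> selfed F2) or `"f1"` (F1 family).
#' @param distortions list of [distortionSpec()] loci.
#' @param seed integer seed; the simulation is bit-reproducible given it.
#' @return a [SimTruth-class].
#' @examples
#' g <- genomeSpec(data.frame(chrom = "1", length_cM = 50, length_bp = 5e6),
#'                 spacing_cM = 10)
#' tr <- simulateCross(g, 20, seed = 1)
#' table(trueGenotypes(tr))
#' @export
simulateCross <- function(genome, n_progeny, design = c("f2", "f1"),
                          distortions = list(), seed = NULL) {
  design <- match.arg(design)
  stopifnot(is(genome, "GenomeSpec"))
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  for (d in distortions) {
    if (d$k < 0.5 || d$k > 1) stop("invalid distortion k")
    if (!d$chrom %in% genome@chromosomes$chrom)
      stop("distortion locus on unknown chromosome")
  }
  if (!is.null(seed)) set.seed(seed)
  chrtab <- genome@chromosomes
  zyg <- Filter(function(d) d$stage == "zygotic", distortions)

  gametes <- vector("list", n_progeny)
  for (j in seq_len(n_progeny)) {
    repeat {
      gm <- .drawGameteDistorted(chrtab, distortions, "maternal")
      gp <- .drawGameteDistorted(chrtab, distortions, "paternal")
      ok <- TRUE
      for (d in zyg) {
        i <- match(d$chrom, chrtab$chrom)
        nf <- (.gameteAlleleAt(gm[[i]], d$cM) == d$favoured) +
          (.gameteAlleleAt(gp[[i]], d$cM) == d$favoured)
        if (nf == 0 && runif(1) > (1 - d$k) / d$k) { ok <- FALSE; break }
      }
      if (ok) break
    }
    gametes[[j]] <- list(maternal = gm, paternal = gp)
  }

  mk <- genome@markers
  hap <- function(side) {
    m <- matrix(NA_integer_, nrow(mk), n_progeny,
                dimnames = list(mk$marker_id, sprintf("F2_%03d",
                                                      seq_len(n_progeny))))
    for (i in seq_len(nrow(chrtab))) {
      sel <- which(mk$chrom == chrtab$chrom[i])
      if (!length(sel)) next
      for (j in seq_len(n_progeny))
        m[sel, j] <- .gameteAlleleAt(gametes[[j]][[side]][[i]], mk$cM[sel])
    }
    m
  }
  h1 <- hap("maternal"); h2 <- hap("paternal")
  if (design == "f1")
    colnames(h1) <- colnames(h2) <- sprintf("F1_%03d", seq_len(n_progeny))
  names(gametes) <- colnames(h1)
  new("SimTruth", genome = genome, design = design, gametes = gametes,
      hap1 = h1, hap2 = h2, distortions = distortions,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' True marker genotypes of a simulated F2
#'
#' @param truth a [SimTruth-class] with design `"f2"`.
#' @return integer matrix (markers x individuals) of parent-2 allele dosage:
#'   0 = homozygous parent 1 (A), 1 = heterozygous (H), 2 = homozygous
#'   parent 2 (B).
#' @export
trueGenotypes <- function(truth) {
  stopifnot(is(truth, "SimTruth"))
  if (truth@design != "f2")
    stop("true A/H/B genotypes are defined for the f2 design only")
  (truth@hap1 == 2L) + (truth@hap2 == 2L)
}

#' Observe mapping scores from simulated truth
#'
#' Applies the observation layer of [observationModel()] to the true
#' genotypes of a simulated F2: miscoding (to a different definite code),
#' partial codes (`H` to `C`/`D`, `A` to `D`, `B` to `C`), depth-based and
#' outright missingness. Parent and F1 columns are attached with their true
#' scores (`A`, `B`, `H`).
#'
#' @param truth a [SimTruth-class] (design `"f2"`).
#' @param model an [observationModel()].
#' @param seed integer seed.
#' @return a [ScoreMatrix-class] with parent1/parent2/f1 columns and one
#'   progeny column per simulated individual.
#' @export
observeGenotypes <- function(truth, model = observationModel(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno <- trueGenotypes(truth)
  codes <- matrix(c("A", "H", "B")[geno + 1L], nrow(geno), ncol(geno),
                  dimnames = dimnames(geno))
  n <- length(codes)

  if (model$error_rate > 0) {
    hit <- which(runif(n) < model$error_rate)
    if (length(hit)) {
      others <- vapply(codes[hit], function(cc)
        sample(setdiff(c("A", "H", "B"), cc), 1L), "")
      codes[hit] <- others
    }
  }
  if (model$partial_code_rate > 0) {
    hit <- runif(n) < model$partial_code_rate
    codes[hit & codes == "A"] <- "D"
    codes[hit & codes == "B"] <- "C"
    hh <- which(hit & codes == "H")
    if (length(hh)) codes[hh] <- sample(c("C", "D"), length(hh),
                                        replace = TRUE)
  }
  depth <- matrix(rnbinom(n, mu = model$depth_mean,
                          size = model$depth_dispersion),
                  nrow(codes), ncol(codes))
  codes[depth < model$min_depth] <- "U"
  if (model$missing_rate > 0)
    codes[runif(n) < model$missing_rate] <- "U"

  mk <- truth@genome@markers
  full <- cbind(P1 = rep("A", nrow(codes)), P2 = rep("B", nrow(codes)),
                F1 = rep("H", nrow(codes)), codes)
  ScoreMatrix(full,
              markerInfo = data.frame(
                marker_id = mk$marker_id, scaffold = mk$chrom, bp = mk$bp,
                tag_id = mk$marker_id, reversed = FALSE,
                stringsAsFactors = FALSE),
              role = c("parent1", "parent2", "f1",
                       rep("progeny", ncol(codes))))
}

#' Place the two-site causal gene on a simulated genome
#'
#' Assigns gene haplotypes (alleles at sites 632 and 917, see
#' [GeneHaplotype-class]) to the founder homologs of a simulated cross. For
#' the `"f2"` design supply the two haplotypes of the selfed F1
#' (`f1_hap1` on the parent-1 homolog, `f1_hap2` on the parent-2 homolog);
#' for the `"f1"` design supply both haplotypes of each parent.
#'
#' @param chrom,cM gene position.
#' @param f1_hap1,f1_hap2 [GeneHaplotype-class] objects (f2 design).
#' @param p1,p2 lists of two [GeneHaplotype-class] objects (f1 design).
#' @return a gene placement list for [simulatePhenotypes()].
#' @export
genePlacement <- function(chrom, cM, f1_hap1 = NULL, f1_hap2 = NULL,
                          p1 = NULL, p2 = NULL) {
  list(chrom = as.character(chrom), cM = cM,
       f1 = if (!is.null(f1_hap1)) list(f1_hap1, f1_hap2),
       p1 = p1, p2 = p2)
}

#' Simulate binary pigmentation phenotypes
#'
#' Looks up each simulated individual's diplotype at the placed causal gene,
#' applies the deterministic two-site penetrance rules of
#' [phenotypeFromDiplotype()], and optionally flips each recorded phenotype
#' with a misclassification probability. Phenotypes are coded as in field
#' scoring: green = 1, purple = 2.
#'
#' @param truth a [SimTruth-class].
#' @param gene a [genePlacement()] matching the design of `truth`.
#' @param misclassification_rate probability each recorded trait value is
#'   flipped.
#' @param seed integer seed.
#' @return data.frame with `id`, `stolon`, `seed_head` (1 = green,
#'   2 = purple), and the underlying `g632`, `g917` genotypes.
#' @export
simulatePhenotypes <- function(truth, gene, misclassification_rate = 0,
                               seed = NULL) {
  stopifnot(is(truth, "SimTruth"))
  if (!is.null(seed)) set.seed(seed)
  chrtab <- truth@genome@chromosomes
  i <- match(gene$chrom, chrtab$chrom)
  if (is.na(i) || gene$cM < 0 || gene$cM > chrtab$length_cM[i])
    stop("gene placed off-chromosome")
  if (truth@design == "f2" && is.null(gene$f1))
    stop("f2 design needs the F1 haplotypes (f1_hap1/f1_hap2)")
  if (truth@design == "f1" && (is.null(gene$p1) || is.null(gene$p2)))
    stop("f1 design needs both parents' haplotype pairs (p1/p2)")

  ids <- names(truth@gametes)
  res <- lapply(ids, function(id) {
    gam <- truth@gametes[[id]]
    am <- .gameteAlleleAt(gam$maternal[[i]], gene$cM)
    ap <- .gameteAlleleAt(gam$paternal[[i]], gene$cM)
    d <- if (truth@design == "f2")
      geneDiplotype(gene$f1[[am]], gene$f1[[ap]])
    else geneDiplotype(gene$p1[[am]], gene$p2[[ap]])
    ph <- phenotypeFromDiplotype(d)
    data.frame(id = id,
               stolon = ifelse(ph["stolon"] == "green", 1L, 2L),
               seed_head = ifelse(ph["seed_head"] == "green", 1L, 2L),
               g632 = g632(d), g917 = g917(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (misclassification_rate > 0) {
    for (tr in c("stolon", "seed_head")) {
      flip <- runif(nrow(out)) < misclassification_rate
      out[[tr]][flip] <- 3L - out[[tr]][flip]
    }
  }
  rownames(out) <- NULL
  out
}
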
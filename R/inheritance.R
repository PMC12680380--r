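#' Construct a gene haplotype
#'
#' @param a632 allele at site 632 (`"G"` wild type, `"T"` variant).
#' @param a917 allele at site 917 (`"G"` wild type, `"A"` variant).
#' @return a [GeneHaplotype-class].
#' @export
geneHaplotype <- function(a632, a917)
  new("GeneHaplotype", a632 = a632, a917 = a917)

#' Construct a gene diplotype
#'
#' @param h1,h2 [GeneHaplotype-class] objects (unordered pair).
#' @return a [GeneDiplotype-class].
#' @export
geneDiplotype <- function(h1, h2) new("GeneDiplotype", h1 = h1, h2 = h2)

#' Parental diplotypes of the mapping cross
#'
#' Convenience constructors for the two-site genotypes of the cross
#' parents: the maternal parent is heterozygous for the site-917
#' splice-site mutation (haplotypes G-G / G-A), the paternal parent for
#' the site-632 missense mutation (G-G / T-G). The selfed F1 carries the
#' maternal configuration (heterozygous at 917 only).
#'
#' @return a [GeneDiplotype-class].
#' @export
meyerDiplotype <- function()
  geneDiplotype(geneHaplotype("G", "G"), geneHaplotype("G", "A"))

#' @rdname meyerDiplotype
#' @export
piDiplotype <- function()
  geneDiplotype(geneHaplotype("G", "G"), geneHaplotype("T", "G"))

#' Tissue-specific penetrance from unphased genotypes
#'
#' The deterministic two-mutation rules: stolons are green iff the plant is
#' homozygous for the site-917 variant (`AA`), which truncates the ACT-like
#' domain and abolishes anthocyanin production in all tissues. Seed heads
#' are green iff the plant is `AA` at 917, or homozygous for the site-632
#' variant (`TT`), or heterozygous at both sites (the 632 variant
#' eliminates binding to a seed-head-specific MYB partner).
#'
#' @param g632 genotypes at site 632 (`"GG"`, `"GT"`, `"TT"`).
#' @param g917 genotypes at site 917 (`"GG"`, `"GA"`, `"AA"`).
#' @return data.frame with `stolon` and `seed_head` in
#'   `{"green", "purple"}`.
#' @export
phenotypeFromGenotypes <- function(g632, g917) {
  stopifnot(all(g632 %in% c("GG", "GT", "TT")),
            all(g917 %in% c("GG", "GA", "AA")))
  stolon <- ifelse(g917 == "AA", "green", "purple")
  seed <- ifelse(g917 == "AA" | g632 == "TT" |
                   (g917 == "GA" & g632 == "GT"), "green", "purple")
  data.frame(g632 = g632, g917 = g917, stolon = stolon, seed_head = seed,
             stringsAsFactors = FALSE)
}

#' Phenotype of a gene diplotype
#'
#' @param d a [GeneDiplotype-class].
#' @return named character vector `c(stolon = , seed_head = )` in
#'   `{"green", "purple"}`.
#' @seealso [phenotypeFromGenotypes()] for the rules.
#' @export
phenotypeFromDiplotype <- function(d) {
  ph <- phenotypeFromGenotypes(g632(d), g917(d))
  c(stolon = ph$stolon, seed_head = ph$seed_head)
}

.hapKey <- function(h) paste0(h@a632, h@a917)

.gametes <- function(d, r) {
  par <- list(d@h1, d@h2)
  rec <- list(geneHaplotype(d@h1@a632, d@h2@a917),
              geneHaplotype(d@h2@a632, d@h1@a917))
  list(hap = c(par, rec), p = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2))
}

#' Expected segregation of the two-site gene in a cross
#'
#' Enumerates parental gametes (parental haplotypes at probability
#' `(1 - r)/2` each, intragenic recombinants at `r/2` each), forms the
#' offspring diplotype distribution, and maps it through the penetrance
#' rules. With `r_intragenic = 0` (the default; the two sites sit ~1.7 kb
#' apart in one gene) all probabilities are exact multiples of 1/16.
#'
#' @param p1 [GeneDiplotype-class] of parent 1.
#' @param p2 [GeneDiplotype-class] of parent 2 (ignored if `selfed`).
#' @param selfed self parent 1 (an F2 design).
#' @param r_intragenic intragenic recombination fraction in `[0, 0.5]`.
#' @return list with `table` (data.frame `hap1`, `hap2`, `g632`, `g917`,
#'   `stolon`, `seed_head`, `prob`), `p_green_stolon`, `p_green_seed_head`.
#' @examples
#' ## selfed F1 heterozygous at 917 only: 1 green : 3 purple, both tissues
#' crossExpectations(meyerDiplotype(), selfed = TRUE)$p_green_stolon
#' @export
crossExpectations <- function(p1, p2 = NULL, selfed = FALSE,
                              r_intragenic = 0) {
  if (r_intragenic < 0 || r_intragenic > 0.5)
    stop("r_intragenic must lie in [0, 0.5]")
  if (selfed) p2 <- p1
  if (is.null(p2)) stop("supply p2 or selfed = TRUE")
  g1 <- .gametes(p1, r_intragenic)
  g2 <- .gametes(p2, r_intragenic)
  rows <- list()
  for (i in seq_along(g1$hap)) for (j in seq_along(g2$hap)) {
    pr <- g1$p[i] * g2$p[j]
    if (pr == 0) next
    hk <- sort(c(.hapKey(g1$hap[[i]]), .hapKey(g2$hap[[j]])))
    key <- paste(hk, collapse = "/")
    if (is.null(rows[[key]])) {
      d <- geneDiplotype(g1$hap[[i]], g2$hap[[j]])
      ph <- phenotypeFromDiplotype(d)
      rows[[key]] <- data.frame(hap1 = hk[1], hap2 = hk[2],
                                g632 = g632(d), g917 = g917(d),
                                stolon = ph["stolon"],
                                seed_head = ph["seed_head"], prob = pr,
                                row.names = NULL, stringsAsFactors = FALSE)
    } else rows[[key]]$prob <- rows[[key]]$prob + pr
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       p_green_stolon = sum(tab$prob[tab$stolon == "green"]),
       p_green_seed_head = sum(tab$prob[tab$seed_head == "green"]))
}

#' Test the one-gene vs two-gene hypotheses on F1 genotype data
#'
#' Hypothesis 1 places the second seed-head mutation in the same gene: at
#' `r = 0` a plant has green seed heads iff its two-site genotype predicts
#' green under the penetrance rules (in an F1 family, iff it is
#' heterozygous at both sites). Hypothesis 2 places it in a linked second
#' gene: green then requires homozygosity for the second mutation
#' (`TT` at the assayed site). Each plant is scored as consistent or
#' inconsistent with each hypothesis; plants inconsistent with both are
#' flagged.
#'
#' @param genotypes data.frame with `g632` and `g917` columns.
#' @param phenotypes seed-head phenotypes: `"green"`/`"purple"` or coded
#'   1 (green) / 2 (purple).
#' @return list with per-hypothesis `consistent`/`inconsistent` counts,
#'   the per-plant table, and `flagged` (row indices inconsistent with
#'   both).
#' @export
testHypotheses <- function(genotypes, phenotypes) {
  stopifnot(nrow(genotypes) == length(phenotypes))
  obs_green <- if (is.numeric(phenotypes)) phenotypes == 1
  else phenotypes == "green"
  pred1 <- phenotypeFromGenotypes(genotypes$g632,
                                  genotypes$g917)$seed_head == "green"
  pred2 <- genotypes$g632 == "TT"
  tab <- data.frame(genotypes, observed = ifelse(obs_green, "green",
                                                 "purple"),
                    h1_consistent = pred1 == obs_green,
                    h2_consistent = pred2 == obs_green,
                    stringsAsFactors = FALSE)
  list(h1 = c(consistent = sum(tab$h1_consistent),
              inconsistent = sum(!tab$h1_consistent)),
       h2 = c(consistent = sum(tab$h2_consistent),
              inconsistent = sum(!tab$h2_consistent)),
       plants = tab,
       flagged = which(!tab$h1_consistent & !tab$h2_consistent))
}

#' Construct a CAPS assay
#'
#' @param amplicon amplicon sequence (character, IUPAC DNA).
#' @param snp_offset 0-based offset of the SNP within the amplicon.
#' @param alleles character vector of allele bases (e.g. `c("G", "A")`).
#' @param pattern enzyme recognition pattern (IUPAC, length >= 4), e.g.
#'   `"CTNAG"` for DdeI.
#' @param cut_offset bases of the pattern 5' of the cut on the matched
#'   strand (1 for DdeI, C^TNAG).
#' @return a [CapsAssay-class].
#' @export
capsAssay <- function(amplicon, snp_offset, alleles, pattern, cut_offset) {
  new("CapsAssay", amplicon = toupper(as.character(amplicon)),
      snpOffset = as.integer(snp_offset), alleles = toupper(alleles),
      pattern = toupper(pattern), cutOffset = as.integer(cut_offset))
}

#' In-silico CAPS digestion
#'
#' Substitutes the allele base at the SNP offset, finds every occurrence of
#' the recognition pattern with IUPAC ambiguity on both strands, cuts at
#' all of them (the top-strand cut coordinate is used for the duplex), and
#' returns the fragment lengths. Fragment lengths always sum to the
#' amplicon length.
#'
#' @param assay a [CapsAssay-class].
#' @param allele the allele base to place at the SNP.
#' @return sorted integer vector of fragment lengths.
#' @examples
#' a <- capsAssay("AAACTGAGTTT", 5, c("G", "C"), "CTNAG", 1)
#' capsDigest(a, "G")  # 4 7
#' @export
capsDigest <- function(assay, allele) {
  allele <- toupper(allele)
  if (!allele %in% assay@alleles) stop("unknown allele: ", allele)
  seq <- assay@amplicon
  substr(seq, assay@snpOffset + 1, assay@snpOffset + 1) <- allele
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(assay@pattern)
  L <- length(pat)
  plus <- Biostrings::start(Biostrings::matchPattern(pat, subj,
                                                     fixed = FALSE))
  minus <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(pat), subj, fixed = FALSE))
  cuts <- c((plus - 1) + assay@cutOffset,
            (setdiff(minus, plus) - 1) + (L - assay@cutOffset))
  n <- nchar(seq)
  cuts <- sort(unique(cuts[cuts > 0 & cuts < n]))
  sort(diff(c(0, cuts, n)))
}

#' Call a genotype from CAPS fragment patterns
#'
#' Compares an observed band pattern to the fragment patterns of the two
#' alleles: a match to one allele's pattern is a homozygote, the union of
#' both (when they differ) a heterozygote. Identical allele patterns make
#' the assay non-informative.
#'
#' @param frag_ref,frag_alt fragment lengths of the reference and
#'   alternate allele (from [capsDigest()]).
#' @param observed observed fragment lengths (band sizes).
#' @return one of `"hom-ref"`, `"het"`, `"hom-alt"`, `"inconclusive"`,
#'   `"non-informative"`.
#' @export
capsGenotype <- function(frag_ref, frag_alt, observed) {
  sr <- sort(unique(frag_ref)); sa <- sort(unique(frag_alt))
  so <- sort(unique(observed))
  if (identical(sr, sa)) return("non-informative")
  if (identical(so, sr)) return("hom-ref")
  if (identical(so, sa)) return("hom-alt")
  if (identical(so, sort(unique(c(sr, sa))))) return("het")
  "inconclusive"
}
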
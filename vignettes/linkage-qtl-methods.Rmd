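---
title: "Methods: F2 linkage mapping, binary-trait QTL scanning, and the two-mutation pigmentation model"
author: "zoymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: F2 linkage mapping and QTL scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoymap)
```

This vignette is the package's account of the statistical machinery it
implements, the choices made where the design was genuinely open, and what
the simulation-based tests do and do not demonstrate.

## The data and the score encoding

The pipeline starts from biallelic SNP calls for two parents, their F1 and
selfed-F1 (F2) progeny. Site-level filters keep biallelic records with
minor-allele frequency > 5% and quality-by-depth > 10; per-sample calls
with read depth below 8× are set to missing (the boundary is inclusive:
depth 8 is a definite call). Calls become mapping scores
`A`/`H`/`B`/`C`/`D`/`U`, where the partial codes `C` ("B or H") and
`D` ("A or H") encode one-sided ambiguity. In this package partial codes
are treated rigorously as *sets of compatible genotypes*: tag
consolidation intersects those sets (`A` absorbs `D`, a contradiction
yields `U`), the two-point likelihood sums over them, and the scan HMM
spreads emission mass over them.

Two callers may be merged (`mergeCallers()`); the union is keyed by
(scaffold, position) and per-sample conflicts at shared sites resolve by
caller precedence (default: Haplotype-Caller) or optionally to missing.
The precedence rule is our choice — the merge itself is standard but no
conflict policy is published for this pipeline.

Orientation and phase. Markers where the parent-1 column reads `B` or the
parent-2 column reads `A`, and whose progeny segregate 1:2:1, are swapped
(`A`↔`B`, `C`↔`D`) so that `A` always means the parent-1 allele. "Segregate
1:2:1" is operationalised as a chi-squared p-value at or above the same
1 × 10⁻¹⁰ floor used by the distortion filter, so that reorientation and
filtering use one notion of "acceptably Mendelian". Markers with `H`,
partial or missing parental scores have unknown linkage phase and are
duplicated with fully reversed scores (`r` suffix); the reversal is an
involution, which the tests assert. Exactly cosegregating markers
(identical progeny score strings, `U` included — missing-tolerant matching
would merge genuinely different information) collapse to the
lowest-positioned representative, with a bin map retained so collapsed
markers can be re-expanded onto the final map.

Filtering runs progeny-first (a sample with > 20% missing data is dropped
before marker missingness is assessed, so one bad sample cannot eliminate
markers), then drops markers with > 20% missing data, then markers with
1:2:1 chi-squared p < 1 × 10⁻¹⁰. Partial codes are excluded from the
chi-squared counts rather than fractionally allocated — simple and
conservative. The removal list is kept: severely distorted regions (e.g.
under transmission-ratio drive) are real chromosome segments, and
`rescueDistortedRegions()` re-admits their markers into the linkage groups
their scaffolds physically belong to, re-ordering without the distortion
filter.

## Two-point linkage and map construction

For a marker pair the F2 joint-genotype distribution with independent
gametes is the 3 × 3 table with entries such as P(AA,AA) = (1−r)²/4 and
P(AB,AB) = ((1−r)² + r²)/2. `estimateRF()` maximizes the resulting
multinomial likelihood over r ∈ [0, 0.5] by bounded 1-D search (with the
boundary values checked explicitly) and reports LOD = log₁₀ L(r̂)/L(0.5).
Individuals missing at either marker carry no information about r (the
single-marker margins are constant in r) and are skipped. For all-pairs
work (`pairwiseRF()`) the same likelihood is evaluated on an r grid of
step 0.005 from precomputed code-pair count tables; the property tests
require the single-pair MLE to agree with an independently written
grid-search oracle to 10⁻³.

Grouping is connected components of the LOD ≥ 12 graph, with a placement
gate: a marker whose nearest linked neighbour is farther than 15 cM
(Kosambi-transformed r̂) is set aside as unplaceable. The published
pipeline used a minimum-spanning-tree mapper only for group assignment;
components at the same LOD are the defensible equivalent and are exactly
recovered on simulated 20-chromosome genomes. The 15 cM "no-mapping"
threshold is implemented as a placement gate (not a grouping distance) —
the published description is ambiguous on this point.

Ordering uses seriation — the first principal coordinate of the
Kosambi-transformed distance matrix — as a framework, polished by 2-opt
segment reversals minimizing SARF (sum of adjacent r̂), with 5 seeded
restarts (4 of them from random permutations; the seed is an argument and
recorded by the caller). For groups of ≤ 8 markers the tests verify the
returned order attains the exhaustive SARF minimum. Markers not separated
by any recombination event are mutually unorderable from the data; they
are ordered by physical (scaffold, bp) position, i.e. reordering only
inside zero-SARF windows, which is the automated form of the published
"reorder only if no net gain in recombination events" rule. Each group is
oriented so its first marker has the smaller bp position on the majority
scaffold.

Error handling before distances. A definite X–Y–X triple in one
individual implies two crossovers within a few cM and is almost always a
miscoded genotype. Markers with more than 10 such double-recombination
events across the progeny are removed, and remaining single-cell X–Y–X
genotypes are masked to missing (`maskDoubleRecombinants()`) before the
final adjacent estimates — the analogue of the genotyping-error detection
the classical mappers run. This step matters: at 1 cM marker spacing a
miscoding rate of only 0.005 otherwise inflates adjacent r̂ by ~0.01 each
and roughly doubles the map; with masking the tests recover simulated map
length within 10% (n = 530, error rate 0.005, 1 cM spacing).

Distances are Kosambi, d = 25 ln((1+2r)/(1−2r)) cM, accumulated from 0;
an adjacent r̂ of 0.5 is capped at 50 cM with a warning. Two-point
adjacent estimates replace the legacy multipoint EM re-estimation; at the
marker densities involved the two are practically indistinguishable, and
the two-point estimator is transparent and testable against a closed-form
oracle.

## Binary-trait QTL scanning

Genotype probabilities. Per chromosome, a hidden Markov model over
{AA, AB, BB} with stationary distribution (¼, ½, ¼) runs forward–backward
across the ordered markers plus pseudomarkers every 2.5 cM. Transitions
invert cM distances through the *Haldane* map (independent gametes),
while reported map distances are *Kosambi* — the deliberate mixed
convention of common interval-mapping practice: the HMM needs a
no-interference transition kernel to factorize over intervals, whereas
Kosambi distances better match observed recombination totals. Emissions
give a definite code probability 1 − ε on its state (ε/2 elsewhere,
default ε = 10⁻⁴); partial codes put mass 1 − ε on each compatible state
and ε on the incompatible one; `U` is uninformative. The tests check the
posterior at a silent midpoint against a hand-computed two-step chain.

Haley–Knott regression. The binary phenotype (green = 1, purple = 2; the
LOD curve is invariant to coding) is regressed at each position on the
additive regressor P(BB) − P(AA) and dominance regressor P(AB), plus any
covariates; LOD = (n/2) log₁₀(RSS₀/RSS₁) against the covariate-only null.
Least squares on a binary response is what the Haley–Knott method is —
logistic regression is deliberately not substituted. The scan accepts an
arbitrary covariate list (the published analysis used three marker
covariates without naming them; passing marker additive/dominance dosages
reproduces that configuration). Collinear covariates are dropped with a
warning.

Thresholds, effects, intervals. Genome-wide significance uses 1000
phenotype-label permutations (jointly across chromosomes, covariates held
fixed); the threshold is the empirical 95th percentile (type-7
interpolation) of per-permutation maximum LODs. The permutation engine
reduces each position to a thin-QR projection so a thousand permutations
cost three matrix products per position. PVE = 1 − 10^(−2·LOD/n), which
is algebraically 1 − RSS₁/RSS₀ of the peak regression (asserted to
10⁻¹²). The support interval is the widest contiguous region around the
peak within 1.5 LOD of it, expanded outward to the nearest flanking
markers — a conventional rule, fixed here because no interval rule is
published; a flat curve returns the whole chromosome, flagged.

## The two-mutation pigmentation model

One MYC-bHLH anthocyanin regulator carries two mutations segregating from
different parents: site 917 (exon-7 terminal G→A; heterozygous in the
maternal parent) causes intron retention and a truncated ACT-like domain —
homozygotes lose pigment in every tissue; site 632 (G→T, Ala→Ser in the
MYB-interacting N-terminus; heterozygous in the paternal parent) abolishes
interaction with a seed-head-specific MYB. The deterministic penetrance
rules are: stolons green iff g917 = AA; seed heads green iff g917 = AA,
or g632 = TT, or (g917 = GA and g632 = GT). Enumerating the nine unphased
genotype combinations gives six green-seed-head classes (three with AA,
two more with TT, one double heterozygote) and three green-stolon classes
— the tests pin this exact truth table. The TT rule is an inference from
the published genetic argument (no TT plant arises in a GT × GG cross),
encoded as stated.

`crossExpectations()` enumerates gametes exactly; intragenic
recombination defaults to r = 0 (the sites are ~1.7 kb apart within one
gene) and all F1/F2 expectations are exact multiples of 1/16: the F1
family gives 0 green stolons and exactly ¼ green seed heads; the selfed
F1 gives ¼ and ¼ with the *same* individuals green for both traits.
Penetrance is deterministic by design; phenotyping noise lives only in
the simulator's misclassification rate. In-silico CAPS genotyping
substitutes each allele into the amplicon, matches the enzyme pattern
with IUPAC ambiguity on both strands (all overlapping sites are cut;
partial digestion is not modelled), and cuts at the top-strand
coordinate, so fragment lengths always sum to the amplicon length.

## What the simulator emulates — and what it does not

`simulateCross()` generates gametes with a no-interference crossover
process: crossover count Poisson with mean the chromosome length in
Morgans, positions uniform. Crossover interference is deliberately not
modelled — no interference model is published for this cross, and Kosambi
enters only at the estimation stage. The default genome template is the
packaged 20-chromosome reference map summary (genetic lengths
53.5–126.4 cM, 1788.4 cM total; physical lengths 7.7–21.1 Mb), with
markers every 1 cM by default and a default population of around 500
progeny, matching the study scale.

Transmission-ratio distortion is specified per locus by the favoured
allele's transmission probability k ∈ [0.5, 1]. Two mechanisms are
implemented because the published discussion leaves the drive system open:
*gametic* (a killer–target-like rejection of disfavoured gametes,
optionally restricted to one parent of origin) and *zygotic* (a
poison–antidote-like viability deficit (1−k)/k for disfavoured
homozygotes). Complete bias (k = 1) removes disfavoured homozygotes under
both, but only the zygotic mode reproduces the ~⅓ favoured-homozygote /
~⅔ heterozygote pattern reported at completely biased loci; one-parent
gametic drive gives ½/½ instead. The tests assert both signatures.

The observation layer applies miscoding (to a different definite code),
partial-code corruption (a single rate turning `H` into `C`/`D`, `A` into
`D`, `B` into `C` — an admitted simplification: the real depth-threshold
logic of the originating caller is not restated here), negative-binomial
read depth with the ≥ 8× floor, and outright missingness. It does *not*
simulate reads, sequencing error, alignment artefacts, paralogy or
scaffold misassembly; passing tests therefore demonstrate correctness of
the estimators under the stated statistical model, not robustness to
reference-genome pathology.

## Numerical choices and problem sizes

Likelihood maximization uses `optimize()` at tolerance 10⁻⁸ with explicit
boundary checks; grid evaluation uses step 0.005 (half-step accuracy
0.0025); zero-probability cells contribute −∞ rather than being clamped.
The HMM rescales forward/backward variables per position. Permutation
quantiles are type-7. Seeds: every stochastic entry point takes an
explicit seed; fixed seeds make the test suite and the acceptance script
bit-reproducible.

The simulation-based tests run at deliberately moderate scale, chosen to
exercise the estimators' asymptotics without waste: map-length recovery
uses two chromosomes at 1 cM spacing with n = 530; peak-location coverage
uses 50 replicates of one 76.2 cM chromosome at n = 425; the null
permutation threshold uses the full 20-chromosome template at n = 425
with 1000 permutations. On the simulated null design the genome-wide 5%
threshold comes out near 4 LOD; the published threshold for the same
design (4.3) sits slightly higher, consistent with its roughly five-fold
denser marker grid (0.21 cM mean spacing on the real map versus 1 cM
here), which multiplies the number of effectively independent tests.

## Known limitations

Two-point (not multipoint) adjacent distances; no sex-specific maps; no
multiple-QTL or epistasis search; binary traits only in the scan
(quantitative phenotypes work algebraically but are untested); the
distortion-rescue step assumes scaffold-to-group assignment is resolvable
from the retained markers; and the simulator's clean biallelic world
sidesteps the paralogy problems real allotetraploid genomes pose.
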
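smallGenome <- function(len = c(100, 60), spacing = 10)
  genomeSpec(data.frame(chrom = as.character(seq_along(len)),
                        length_cM = len, length_bp = len * 1e5 + 1e5),
             spacing_cM = spacing)

test_that("simulation is bit-identical under a fixed seed", {
  g <- smallGenome()
  t1 <- simulateCross(g, 30, seed = 7)
  t2 <- simulateCross(g, 30, seed = 7)
  expect_identical(t1@hap1, t2@hap1)
  expect_identical(t1@gametes, t2@gametes)
  x1 <- observeGenotypes(t1, observationModel(missing_rate = 0.1), seed = 3)
  x2 <- observeGenotypes(t2, observationModel(missing_rate = 0.1), seed = 3)
  expect_identical(scores(x1), scores(x2))
})

test_that("undistorted loci segregate 1:2:1 and alleles are balanced", {
  g <- smallGenome()
  tr <- simulateCross(g, 500, seed = 1)
  geno <- trueGenotypes(tr)
  af <- rowMeans(geno) / 2          # parent-2 allele frequency
  expect_true(all(abs(af - 0.5) < 0.1))
  x <- observeGenotypes(tr, observationModel(), seed = 2)
  seg <- markerSegregation(x)
  expect_true(all(seg$p_value > 1e-10))
  # genotype-class frequencies sum to 1 before missingness
  expect_equal(unname(rowSums(cbind(geno == 0, geno == 1, geno == 2)) /
                        ncol(geno)),
               rep(1, nrow(geno)))
})

test_that("realized recombination matches the Haldane inverse", {
  g <- genomeSpec(data.frame(chrom = "1", length_cM = 20, length_bp = 2e6),
                  spacing_cM = 20)   # two markers, 20 cM apart
  tr <- simulateCross(g, 800, seed = 5)
  rec <- mean(c(tr@hap1[1, ] != tr@hap1[2, ],
                tr@hap2[1, ] != tr@hap2[2, ]))
  expect_equal(rec, haldaneInverse(20), tolerance = 0.1)
})

test_that("near-zero-length chromosomes cosegregate completely", {
  g <- genomeSpec(data.frame(chrom = "1", length_cM = 1e-3,
                             length_bp = 1e5),
                  markers = data.frame(marker_id = c("a", "b", "c"),
                                       chrom = "1",
                                       cM = c(0, 5e-4, 1e-3),
                                       bp = c(1, 50, 100)))
  tr <- simulateCross(g, 200, seed = 2)
  geno <- trueGenotypes(tr)
  expect_true(all(geno[1, ] == geno[2, ] & geno[2, ] == geno[3, ]))
})

test_that("gametic drive removes disfavoured homozygotes; zygotic drive leaves 1:2", {
  g <- genomeSpec(data.frame(chrom = "1", length_cM = 50, length_bp = 5e6),
                  spacing_cM = 25)
  dg <- distortionSpec("1", 25, k = 1, stage = "gametic", favoured = 1L,
                       parent = "maternal")
  tr <- simulateCross(g, 400, design = "f2", distortions = list(dg),
                      seed = 3)
  geno <- trueGenotypes(tr)[2, ]     # marker at the driver locus
  expect_equal(sum(geno == 2), 0)    # no disfavoured (parent-2) homozygote
  # one distorted parent-of-origin: remaining classes are ~1:1
  expect_gt(sum(geno == 0) / length(geno), 0.4)

  dz <- distortionSpec("1", 25, k = 1, stage = "zygotic", favoured = 1L)
  tz <- simulateCross(g, 600, distortions = list(dz), seed = 4)
  gz <- trueGenotypes(tz)[2, ]
  expect_equal(sum(gz == 2), 0)
  expect_equal(mean(gz == 0), 1 / 3, tolerance = 0.12)
  expect_equal(mean(gz == 1), 2 / 3, tolerance = 0.08)
})

test_that("distortion configuration is validated", {
  expect_error(distortionSpec("1", 10, k = 0.3), "k must")
  g <- smallGenome()
  bad <- distortionSpec("99", 10, k = 0.9)
  bad$chrom <- "nope"
  expect_error(simulateCross(g, 5, distortions = list(bad)),
               "unknown chromosome")
  expect_error(simulateCross(g, 0), "n_progeny")
})

test_that("observation model corrupts scores as configured", {
  g <- smallGenome(len = 40, spacing = 5)
  tr <- simulateCross(g, 300, seed = 6)
  clean <- observationModel(min_depth = 1, depth_mean = 100,
                            depth_dispersion = 50)
  x <- observeGenotypes(tr, clean, seed = 1)
  expect_identical(unname(progenyScores(x)),
                   unname(matrix(c("A", "H", "B")[trueGenotypes(tr) + 1],
                                 nrow(tr@hap1))))

  miss <- observationModel(min_depth = 1, depth_mean = 100,
                           depth_dispersion = 50, missing_rate = 0.25)
  xm <- observeGenotypes(tr, miss, seed = 2)
  expect_lt(abs(mean(progenyScores(xm) == "U") - 0.25), 0.03)

  part <- observationModel(min_depth = 1, depth_mean = 100,
                           depth_dispersion = 50, partial_code_rate = 1)
  xp <- observeGenotypes(tr, part, seed = 3)
  sc <- progenyScores(xp)
  tru <- trueGenotypes(tr)
  expect_true(all(sc[tru == 0] == "D"))  # A only corrupts to D
  expect_true(all(sc[tru == 2] == "C"))  # B only corrupts to C
  expect_true(all(sc[tru == 1] %in% c("C", "D")))

  err <- observationModel(min_depth = 1, depth_mean = 100,
                          depth_dispersion = 50, error_rate = 1)
  xe <- observeGenotypes(tr, err, seed = 4)
  expect_true(all(progenyScores(xe)[tru == 0] != "A"))
})

test_that("simulated phenotypes follow the two-site model", {
  g <- genomeSpec(data.frame(chrom = "12", length_cM = 76.2,
                             length_bp = 1.5e7), spacing_cM = 5)
  tr <- simulateCross(g, 400, seed = 8)
  gene <- genePlacement("12", 55, f1_hap1 = geneHaplotype("G", "G"),
                        f1_hap2 = geneHaplotype("G", "A"))
  ph <- simulatePhenotypes(tr, gene, seed = 9)
  # stolon and seed head cosegregate individual by individual, ~1:3 green
  expect_identical(ph$stolon, ph$seed_head)
  expect_equal(mean(ph$stolon == 1), 0.25, tolerance = 0.08)

  # F1 family of the two parental configurations: no green stolons,
  # ~1/4 green seed heads
  trf1 <- simulateCross(g, 400, design = "f1", seed = 10)
  genef1 <- genePlacement("12", 55,
                          p1 = list(geneHaplotype("G", "G"),
                                    geneHaplotype("G", "A")),
                          p2 = list(geneHaplotype("G", "G"),
                                    geneHaplotype("T", "G")))
  phf1 <- simulatePhenotypes(trf1, genef1, seed = 11)
  expect_equal(sum(phf1$stolon == 1), 0)
  expect_equal(mean(phf1$seed_head == 1), 0.25, tolerance = 0.08)

  # total misclassification inverts every record
  ph0 <- simulatePhenotypes(tr, gene, misclassification_rate = 0, seed = 1)
  ph1 <- simulatePhenotypes(tr, gene, misclassification_rate = 1, seed = 1)
  expect_identical(ph1$stolon, 3L - ph0$stolon)
  expect_identical(ph1$seed_head, 3L - ph0$seed_head)

  expect_error(simulatePhenotypes(tr, genePlacement("12", 999,
                                                    f1_hap1 = geneHaplotype("G", "G"),
                                                    f1_hap2 = geneHaplotype("G", "A"))),
               "off-chromosome")
})
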
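test_that("map functions are exact and mutually inverse", {
  expect_equal(kosambiMap(0), 0)
  expect_equal(kosambiMap(0.1), 25 * log(1.2 / 0.8))
  expect_equal(round(kosambiMap(0.1), 2), 10.14)
  r <- seq(0.01, 0.49, by = 0.02)
  expect_equal(kosambiInverse(kosambiMap(r, max_cM = Inf)), r,
               tolerance = 1e-12)
  expect_equal(haldaneInverse(haldaneMap(r)), r, tolerance = 1e-12)
  expect_warning(kosambiMap(0.5), "capped")
})

test_that("estimateRF recovers linkage, is symmetric and bounded", {
  v <- rep(c("A", "H", "B"), c(25, 50, 25))
  est <- estimateRF(v, v)
  expect_equal(est$r_hat, 0)
  expect_equal(est$lod, 25 * log10(4) + 50 * log10(2) + 25 * log10(4),
               tolerance = 1e-6)

  set.seed(3)
  v1 <- randomScoreVector(600)
  v2 <- randomScoreVector(600)        # independent
  est0 <- estimateRF(v1, v2)
  expect_equal(est0$r_hat, 0.5, tolerance = 0.06)
  expect_lt(est0$lod, 1)

  for (i in 1:10) {
    a <- randomScoreVector(80, partial = 0.2, missing = 0.1)
    b <- randomScoreVector(80, partial = 0.2, missing = 0.1)
    ea <- estimateRF(a, b); eb <- estimateRF(b, a)
    expect_equal(ea$r_hat, eb$r_hat, tolerance = 1e-8)
    expect_gte(ea$r_hat, 0); expect_lte(ea$r_hat, 0.5)
    expect_gte(ea$lod, 0)
  }
  # informative self-pair always gives r = 0 with positive LOD
  dd <- randomScoreVector(50)
  es <- estimateRF(dd, dd)
  expect_equal(es$r_hat, 0); expect_gt(es$lod, 0)

  expect_true(is.na(estimateRF(c("U", "U", "A"), c("A", "A", "A"))$r_hat))
})

test_that("pairwiseRF agrees with the single-pair estimator", {
  set.seed(11)
  g <- genomeSpec(data.frame(chrom = "1", length_cM = 60, length_bp = 6e6),
                  spacing_cM = 10)
  tr <- simulateCross(g, 150, seed = 12)
  x <- observeGenotypes(tr, observationModel(missing_rate = 0.05),
                        seed = 13)
  rf <- pairwiseRF(x)
  sc <- progenyScores(x)
  for (i in c(1, 3)) for (j in c(2, 6)) {
    e <- estimateRF(sc[i, ], sc[j, ])
    expect_lt(abs(rf$r_hat[i, j] - e$r_hat), 0.0051)  # half a grid step
    expect_lt(abs(rf$lod[i, j] - e$lod), 0.1)
  }
})

test_that("grouping separates chromosomes and gates unplaceable markers", {
  g <- genomeSpec(data.frame(chrom = c("1", "2"), length_cM = c(60, 40),
                             length_bp = c(6e6, 4e6)), spacing_cM = 5)
  tr <- simulateCross(g, 250, seed = 21)
  x <- observeGenotypes(tr, observationModel(), seed = 22)
  grp <- groupMarkers(x)
  expect_length(grp$groups, 2L)
  expect_setequal(grp$groups[[1]],
                  markerPositions(g)$marker_id[markerPositions(g)$chrom == "1"])

  # an all-missing marker is ungrouped
  sc <- scores(x); mi <- markerInfo(x)
  sc <- rbind(sc, dead = rep("U", ncol(sc)))
  mi <- rbind(mi, data.frame(marker_id = "dead", scaffold = "1", bp = 9e6,
                             tag_id = "dead", reversed = FALSE))
  x2 <- ScoreMatrix(sc, mi, SummarizedExperiment::colData(x)$role)
  grp2 <- groupMarkers(x2)
  expect_true("dead" %in% grp2$ungrouped)
})

test_that("mirror groups collapse to the copy with more original markers", {
  groups <- list(LG1 = c("m1", "m2r", "m3"), LG2 = c("m1r", "m2", "m3r"),
                 LG3 = c("x1", "x2"))
  ded <- dedupeMirrorGroups(groups)
  expect_length(ded$groups, 2L)
  expect_true("LG3" %in% names(ded$groups))
  kept <- setdiff(names(ded$groups), "LG3")
  expect_identical(ded$groups[[kept]], groups$LG1)  # 2 vs 1 non-reversed
  # the phase report covers each duplicated marker exactly once
  expect_setequal(ded$phase_report$base, c("m1", "m2", "m3"))
  expect_equal(anyDuplicated(ded$phase_report$base), 0L)

  # a marker together with its own twin is reported as a conflict
  ded2 <- dedupeMirrorGroups(list(LG1 = c("a", "ar", "b")))
  expect_identical(ded2$conflicts, "a")
  expect_length(ded2$groups, 1L)
})

test_that("ordering recovers additive three-marker maps and the true order", {
  # additivity toy case through the public pipeline
  set.seed(31)
  g <- genomeSpec(data.frame(chrom = "1", length_cM = 20, length_bp = 2e6),
                  spacing_cM = 10)
  tr <- simulateCross(g, 300, seed = 32)
  x <- observeGenotypes(tr, observationModel(), seed = 33)
  lg <- orderMarkers(x, markerInfo(x)$marker_id, seed = 1)
  expect_identical(mapTable(lg)$marker_id, markerInfo(x)$marker_id)

  # 50-marker chromosome: Kendall tau vs truth >= 0.95 up to reversal
  g2 <- genomeSpec(data.frame(chrom = "1", length_cM = 98, length_bp = 1e7),
                   spacing_cM = 2)
  tr2 <- simulateCross(g2, 530, seed = 34)
  x2 <- observeGenotypes(tr2, observationModel(error_rate = 0.005),
                         seed = 35)
  lg2 <- orderMarkers(x2, markerInfo(x2)$marker_id, seed = 1)
  got <- match(mapTable(lg2)$marker_id, markerInfo(x2)$marker_id)
  tau <- cor(got, seq_along(got), method = "kendall")
  expect_gte(abs(tau), 0.95)
  # orientation follows physical position
  expect_lt(mapTable(lg2)$bp[1], tail(mapTable(lg2)$bp, 1))
})

test_that("reversal leaves SARF and pairwise distances unchanged", {
  set.seed(41)
  g <- genomeSpec(data.frame(chrom = "1", length_cM = 40, length_bp = 4e6),
                  spacing_cM = 8)
  tr <- simulateCross(g, 200, seed = 42)
  x <- observeGenotypes(tr, observationModel(), seed = 43)
  rf <- pairwiseRF(x)
  ord <- markerInfo(x)$marker_id
  sarf <- function(o) sum(rf$r_hat[cbind(o[-length(o)], o[-1])])
  expect_equal(sarf(ord), sarf(rev(ord)), tolerance = 1e-12)
})

test_that("double recombinants are counted and filtered", {
  prog <- rbind(l = c("A", "A", "A", "H"),
                m = c("B", "U", "A", "H"),
                r = c("A", "A", "A", "H"))
  x <- makeScores(prog)
  lg <- new("LinkageGroup", name = "LG1",
            table = data.frame(marker_id = c("l", "m", "r"),
                               scaffold = "s1", bp = c(100, 200, 300),
                               reversed = FALSE, cM = NA_real_,
                               dbl_rec = NA_integer_,
                               stringsAsFactors = FALSE),
            rfAdj = c(0.1, 0.1))
  counts <- countDoubleRecombinants(lg, x)
  # individual 1: A-B-A, one event; individual 2: A-U-A, none;
  # individuals 3, 4: concordant
  expect_identical(unname(counts), c(0L, 1L, 0L))

  lg2 <- filterDoubleRecombinants(lg, x, max_events = 0)
  expect_identical(mapTable(lg2)$marker_id, c("l", "r"))
  lg3 <- filterDoubleRecombinants(lg, x, max_events = 10)
  expect_equal(nrow(mapTable(lg3)), 3L)
})

test_that("map distances accumulate Kosambi centimorgans from zero", {
  lg <- new("LinkageGroup", name = "LG1",
            table = data.frame(marker_id = c("a", "b", "c"),
                               scaffold = "s", bp = 1:3,
                               reversed = FALSE, cM = NA_real_,
                               dbl_rec = NA_integer_,
                               stringsAsFactors = FALSE),
            rfAdj = c(0, 0.1))
  lg <- mapDistances(lg)
  expect_equal(mapTable(lg)$cM, c(0, 0, kosambiMap(0.1)))
})

test_that("distortion-filtered regions are rescued into their groups", {
  g <- genomeSpec(data.frame(chrom = "1", length_cM = 60, length_bp = 6e6),
                  spacing_cM = 3)
  dz <- distortionSpec("1", 58, k = 0.97, stage = "zygotic", favoured = 1L)
  tr <- simulateCross(g, 300, distortions = list(dz), seed = 51)
  x <- observeGenotypes(tr, observationModel(), seed = 52)
  flt <- filterScoreMatrix(x)
  removed <- flt$removed_markers_distorted
  expect_gt(nrow(removed), 0)

  map <- buildLinkageMap(flt$scores, seed = 1)
  full <- rescueDistortedRegions(map, removed, x, seed = 1)
  expect_true(all(removed$marker_id %in% mapTable(full)$marker_id))
  # the rescued group spans the whole simulated chromosome
  len0 <- max(mapTable(linkageGroups(map)[[1]])$cM)
  len1 <- max(mapTable(linkageGroups(full)[[1]])$cM)
  expect_gt(len1, len0)
  expect_equal(len1, 60, tolerance = 0.35 * 60)

  # empty removal list leaves the map untouched
  same <- rescueDistortedRegions(map, removed[0, , drop = FALSE], x)
  expect_identical(mapTable(same), mapTable(map))
})

test_that("the default 20-chromosome genome yields 20 linkage groups", {
  g <- defaultGenome(spacing_cM = 10)
  tr <- simulateCross(g, 200, seed = 61)
  x <- observeGenotypes(tr, observationModel(), seed = 62)
  grp <- groupMarkers(x)
  expect_length(grp$groups, 20L)
})
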
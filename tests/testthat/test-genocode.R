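makeCalls <- function(scaffold, pos, ref = "A", alt = "T", gt, dp,
                      caller = "HC", qd = 20, maf = 0.3) {
  variantCallSet(
    data.frame(scaffold = scaffold, pos = pos, ref = ref, alt = alt,
               caller = caller, qd = qd, maf = maf,
               stringsAsFactors = FALSE),
    gt, dp)
}

test_that("encodeCalls maps genotypes and applies the depth floor", {
  gt <- rbind(c("0/0", "0/1", "1/1", "./."))
  dp <- rbind(c(10, 7, 8, 30))
  colnames(gt) <- colnames(dp) <- c("i1", "i2", "i3", "i4")
  x <- encodeCalls(makeCalls("s1", 100, gt = gt, dp = dp))
  expect_identical(unname(scores(x)[1, ]), c("A", "U", "B", "U"))

  # multiallelic records are rejected with a diagnostic
  gt2 <- rbind(gt, gt)
  dp2 <- rbind(dp, dp)
  cs <- makeCalls("s1", c(100, 200), alt = c("T", "T,G"), gt = gt2,
                  dp = dp2)
  x2 <- encodeCalls(cs)
  expect_equal(nrow(x2), 1L)
  expect_equal(attr(x2, "rejected")$pos, 200)

  # MAF / QD site filters
  cs3 <- makeCalls("s1", c(100, 200), gt = gt2, dp = dp2,
                   qd = c(20, 5), maf = c(0.3, 0.3))
  expect_equal(nrow(encodeCalls(cs3)), 1L)
})

test_that("mergeCallers takes the union and resolves conflicts by precedence", {
  gt_hc <- rbind(c("0/1", "0/1"), c("0/1", "0/1"))
  gt_ug <- rbind(c("0/0", "0/1"), c("0/1", "0/1"))
  dp <- matrix(10, 2, 2)
  colnames(gt_hc) <- colnames(gt_ug) <- colnames(dp) <- c("i1", "i2")
  hc <- makeCalls("s1", c(100, 200), gt = gt_hc, dp = dp, caller = "HC")
  ug <- makeCalls("s1", c(200, 300), gt = gt_ug, dp = dp, caller = "UG")
  m <- mergeCallers(hc, ug)
  expect_equal(nrow(m@info), 3L)
  expect_identical(m@info$origin[m@info$pos == 200], "common")
  expect_equal(m@meta$n_common, 1L)
  # conflict at pos 200 / i1: HC says 0/1, UG says 0/0 -> HC wins
  expect_identical(unname(m@geno[m@info$pos == 200, "i1"]), "0/1")
  expect_equal(m@meta$n_sample_conflicts, 1L)
  mu <- mergeCallers(hc, ug, precedence = "UG")
  expect_identical(unname(mu@geno[mu@info$pos == 200, "i1"]), "0/0")

  # disjoint sets just concatenate
  ug2 <- makeCalls("s2", c(1, 2), gt = gt_ug, dp = dp, caller = "UG")
  expect_equal(nrow(mergeCallers(hc, ug2)@info), 4L)
})

test_that("tag consolidation intersects compatible codes", {
  prog <- rbind(c("A", "A", "D", "B", "H", "U"),
                c("A", "D", "A", "A", "C", "C"))
  x <- makeScores(prog, bp = c(100, 600))   # same 1-kb tag
  y <- consolidateTags(x)
  expect_equal(nrow(y), 1L)
  got <- unname(progenyScores(y)[1, ])
  # A&A=A, A&D=A, D&A=A, B&A=U (contradiction), H&C=H, U&C=C
  expect_identical(got, c("A", "A", "A", "U", "H", "C"))

  # identical in-tag rows collapse to themselves
  x2 <- makeScores(rbind(prog[1, ], prog[1, ]), bp = c(100, 600))
  expect_identical(unname(progenyScores(consolidateTags(x2))[1, ]),
                   unname(prog[1, ]))

  # different tags stay separate
  x3 <- makeScores(prog, bp = c(100, 2600))
  expect_equal(nrow(consolidateTags(x3)), 2L)
})

test_that("reorientation swaps misoriented markers only", {
  prog <- matrix(rep(c("A", "H", "B", "H"), 10), nrow = 4)
  x <- makeScores(rbind(prog, prog[1, , drop = FALSE]),
                  p1 = c("A", "B", "H", "B", "B"),
                  p2 = c("B", "A", "B", "B", "A"))
  y <- reorientToCross(x, min_p = 0)
  sc0 <- scores(x); sc1 <- scores(y)
  expect_identical(sc1[1, ], sc0[1, ])              # already oriented
  expect_identical(unname(sc1[2, c("P1", "P2")]), c("A", "B"))
  expect_identical(sc1[2, -(1:2)],
                   c(B = "A", A = "B", H = "H")[sc0[2, -(1:2)]],
                   ignore_attr = TRUE)
  expect_identical(sc1[3, ], sc0[3, ])              # P1 = H untouched
  expect_identical(unname(sc1[5, "P2"]), "B")       # P2 = A swapped
})

test_that("phase-unknown markers are duplicated with reversed scores", {
  prog <- rbind(c("A", "H", "B"), c("C", "D", "U"), c("A", "A", "B"))
  x <- makeScores(prog, p1 = c("H", "U", "A"), p2 = c("H", "B", "B"))
  y <- duplicatePhaseUnknown(x)
  mi <- markerInfo(y)
  expect_identical(mi$marker_id, c("m01", "m01r", "m02", "m02r", "m03"))
  expect_identical(mi$reversed, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  sc <- scores(y)
  expect_identical(unname(sc["m01r", -(1:3)]), c("B", "H", "A"))
  expect_identical(unname(sc["m02r", -(1:3)]), c("D", "C", "U"))
  # applying the substitution twice is the identity
  flip <- c(A = "B", B = "A", C = "D", D = "C", H = "H", U = "U")
  expect_identical(unname(flip[flip[sc["m02", ]]]), unname(sc["m02", ]))
})

test_that("cosegregation collapse keeps one representative and re-expands", {
  prog <- rbind(a = c("A", "H", "B", "U"),
                b = c("A", "H", "B", "U"),
                c = c("A", "H", "B", "A"),   # differs at a U cell: kept
                d = c("A", "H", "B", "U"),
                e = c("B", "H", "A", "U"))
  x <- makeScores(prog, bp = c(500, 100, 200, 900, 300),
                  scaffold = rep("s1", 5))
  out <- collapseCosegregating(x)
  expect_equal(nrow(out$scores), 3L)
  # representative of {a,b,d} is b (lowest bp)
  expect_true("b" %in% markerInfo(out$scores)$marker_id)
  expect_setequal(out$bins$member[out$bins$representative == "b"],
                  c("a", "b", "d"))
  # re-expansion recovers the original marker set exactly
  expect_setequal(out$bins$member, rownames(prog))
  expect_equal(nrow(out$bins), nrow(prog))
})

test_that("missingness and distortion filters run progeny-first", {
  set.seed(1)
  n <- 60
  good <- matrix(sample(c("A", "H", "B"), 5 * n, replace = TRUE,
                        prob = c(1, 2, 1) / 4), nrow = 5)
  x <- makeScores(rbind(
    good,
    c(rep("U", 13), sample(c("A", "H", "B"), n - 13, replace = TRUE)),
    rep("A", n)),                             # fully distorted
    bp = 1:7 * 100)
  # one terrible progeny column that would otherwise kill markers
  sc <- scores(x); sc[1:6, "i01"] <- "U"
  x <- ScoreMatrix(sc, markerInfo(x), SummarizedExperiment::colData(x)$role)

  out <- filterScoreMatrix(x, max_missing = 0.20, min_p = 1e-10)
  expect_identical(out$removed_progeny, "i01")
  expect_identical(out$removed_markers_missing, "m06")  # 13/59 > 20%
  expect_identical(out$removed_markers_distorted$marker_id, "m07")
  expect_equal(nrow(out$scores), 5L)

  # boundary behaviour of the chi-squared filter
  expect_gt(segregationTest(c(132, 265, 133), c(1, 2, 1))$p_value, 0.9)
  expect_lt(segregationTest(c(530, 0, 0), c(1, 2, 1))$p_value, 1e-10)
})

test_that("segregation test is exact and ranks like a likelihood-ratio oracle", {
  st <- segregationTest(c(25, 50, 25), c(1, 2, 1))
  expect_equal(st$statistic, 0)
  expect_equal(st$p_value, 1)
  expect_equal(st$df, 2L)
  expect_error(segregationTest(c(0, 0), c(1, 3)), "zero total")

  set.seed(42)
  p_chi <- p_lr <- numeric(100)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    o <- as.numeric(rmultinom(1, sample(50:500, 1), prob = runif(k, .1, 1)))
    ratio <- sample(1:4, k, replace = TRUE)
    p_chi[i] <- segregationTest(o, ratio)$p_value
    e <- sum(o) * ratio / sum(ratio)
    lr <- 2 * sum(ifelse(o > 0, o * log(o / e), 0))
    p_lr[i] <- pchisq(lr, k - 1, lower.tail = FALSE)
  }
  expect_gt(cor(p_chi, p_lr, method = "spearman"), 0.98)
})

test_that("VCF input round-trips through encoding", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  on.exit(unlink(f))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qual by depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "P2", "F1", "i1", sep = "\t"),
    paste("sc1", "100", ".", "A", "T", "50", "PASS", "QD=25", "GT:DP",
          "0/0:20", "1/1:20", "0/1:20", "0/1:7", sep = "\t"),
    paste("sc1", "250", ".", "G", "C", "50", "PASS", "QD=25", "GT:DP",
          "0/0:20", "1/1:20", "0/1:20", "./.:0", sep = "\t")), f)
  calls <- readCallsVCF(f, caller = "HC")
  expect_equal(nrow(calls@info), 2L)
  expect_equal(calls@info$qd, c(25, 25))
  x <- encodeCalls(calls, maf_min = 0)
  expect_identical(SummarizedExperiment::colData(x)$role,
                   c("parent1", "parent2", "f1", "progeny"))
  expect_identical(unname(scores(x)[, "P1"]), c("A", "A"))
  expect_identical(unname(scores(x)[, "i1"]), c("U", "U"))  # depth < 8
  expect_identical(unname(scores(x)[, "F1"]), c("H", "H"))
})
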
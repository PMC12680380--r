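# shared fixtures built in code

# small score matrix with parents and F1 ahead of progeny columns
makeScores <- function(progeny, p1 = "A", p2 = "B", f1 = "H",
                       scaffold = NULL, bp = NULL) {
  m <- nrow(progeny)
  if (is.null(scaffold)) scaffold <- rep("s1", m)
  if (is.null(bp)) bp <- seq_len(m) * 100
  sc <- cbind(P1 = rep(p1, length.out = m), P2 = rep(p2, length.out = m),
              F1 = rep(f1, length.out = m), progeny)
  ids <- rownames(progeny)
  if (is.null(ids)) ids <- sprintf("m%02d", seq_len(m))
  if (is.null(colnames(progeny)))
    colnames(sc)[-(1:3)] <- sprintf("i%02d", seq_len(ncol(progeny)))
  ScoreMatrix(sc,
              data.frame(marker_id = ids, scaffold = scaffold, bp = bp,
                         tag_id = ids, reversed = grepl("r$", ids),
                         stringsAsFactors = FALSE),
              c("parent1", "parent2", "f1", rep("progeny", ncol(progeny))))
}

# a random definite F2-like score vector
randomScoreVector <- function(n, partial = 0, missing = 0) {
  v <- sample(c("A", "H", "B"), n, replace = TRUE, prob = c(1, 2, 1) / 4)
  i <- runif(n) < partial
  v[i & v == "A"] <- "D"
  v[i & v == "B"] <- "C"
  v[runif(n) < missing] <- "U"
  v
}

# independent two-point likelihood oracle: grid search over the same
# F2 joint-genotype model, written from first principles
oracleRF <- function(v1, v2, grid = seq(0, 0.5, by = 0.001)) {
  states <- list(A = 1, H = 2, B = 3, C = c(2, 3), D = c(1, 2),
                 U = 1:3)
  joint <- function(r) {
    J <- matrix(0, 3, 3)
    gam <- function(h1, h2) {  # gamete prob of transmitting hap (a1, a2)
      # haplotypes: parental 1-1 and 2-2 at (1-r)/2; recomb at r/2
      if (h1 == h2) (1 - r) / 2 else r / 2
    }
    for (a1 in 1:2) for (a2 in 1:2) for (b1 in 1:2) for (b2 in 1:2) {
      g1 <- (a1 == 2) + (b1 == 2) + 1  # state at locus 1
      g2 <- (a2 == 2) + (b2 == 2) + 1
      J[g1, g2] <- J[g1, g2] + gam(a1, a2) * gam(b1, b2)
    }
    J
  }
  ll <- vapply(grid, function(r) {
    J <- joint(r)
    s <- 0
    for (i in seq_along(v1)) {
      if (v1[i] == "U" || v2[i] == "U") next
      p <- sum(J[states[[v1[i]]], states[[v2[i]]]])
      if (p <= 0) return(-Inf)
      s <- s + log(p)
    }
    s
  }, 0)
  grid[which.max(ll)]
}

# exhaustive SARF minimum over all marker orders
oracleSARF <- function(rhat) {
  m <- nrow(rhat)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    s <- sum(rhat[cbind(p[-m], p[-1])])
    if (s < best) best <- s
  }
  best
}
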
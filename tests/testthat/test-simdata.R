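test_that("panel generation validates its arguments", {
  expect_error(make_ld_panel(30, 2, 2, 0.5, 1), "n_ref")
  expect_error(make_ld_panel(100, 2, 2, 1.0, 1), "rho")
  expect_error(make_ld_panel(100, 2, 2, -0.1, 1), "rho")
  expect_error(make_ld_panel(100, 0, 2, 0.5, 1), "n_blocks")
})

test_that("panel is deterministic given the seed and satisfies its invariants", {
  p1 <- make_ld_panel(100, 5, 8, 0.7, seed = 42)
  p2 <- make_ld_panel(100, 5, 8, 0.7, seed = 42)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$variants, p2$variants)
  p3 <- make_ld_panel(100, 5, 8, 0.7, seed = 43)
  expect_false(identical(p1$genotypes, p3$genotypes))

  # positions strictly increasing, frequencies consistent with dosage means
  expect_true(all(diff(p1$variants$pos) > 0))
  expect_true(all(p1$genotypes %in% 0:2))
  big <- make_ld_panel(2000, 4, 10, 0.5, seed = 7)
  expect_lt(max(abs(big$variants$freq_emp - big$variants$freq)), 0.05)
})

test_that("haplotype copy process gives the AR(1) LD profile", {
  # rho = 0: all distinct pairs uncorrelated within 4/sqrt(n)
  p0 <- make_ld_panel(1000, 3, 10, 0, seed = 1)
  R0 <- panel_ld_matrix(p0)
  off <- abs(R0[upper.tri(R0)])
  expect_lt(max(off), 4 / sqrt(1000))

  # rho = 0.9: adjacent genotype correlation ~ rho, lag-d ~ rho^d
  p9 <- make_ld_panel(1000, 20, 6, 0.9, seed = 2)
  R9 <- panel_ld_matrix(p9)
  v <- p9$variants
  same_block <- outer(v$block, v$block, "==")
  lag <- abs(outer(seq_len(nrow(v)), seq_len(nrow(v)), "-"))
  for (d in 1:3) {
    sel <- same_block & lag == d & upper.tri(R9)
    expect_equal(mean(R9[sel]), 0.9^d, tolerance = 0.03)
  }
  # cross-block pairs uncorrelated in expectation
  expect_lt(abs(mean(R9[!same_block & upper.tri(R9)])), 0.01)
})

test_that("null traits give standard-normal z-scores and calibrated chi-squared", {
  panel <- shared_panel()  # 10,000 variants
  sim <- simulate_multitrait_sumstats(panel, null_model(panel), seed = 5)
  for (tbl in sim$sumstats) {
    z <- zscores(tbl)
    expect_gt(mean(z^2), 0.95)
    expect_lt(mean(z^2), 1.05)
    expect_lt(abs(mean(z)), 0.1)
  }
  expect_true(all(sim$truth$label == "null"))
})

test_that("a factor-1 effect inflates exactly the traits loading on factor 1", {
  panel <- make_ld_panel(500, 60, 10, 0.6, seed = 9)
  m <- nrow(panel$variants)
  # 9 traits: first 3 load on factor 1, the rest on factors 2-3
  L <- matrix(0, 9, 3)
  L[1:3, 1] <- 0.5; L[4:7, 2] <- 0.5; L[8:9, 3] <- 0.5
  gamma <- matrix(0, m, 3)
  j <- 305  # block-center variant
  gamma[j, 1] <- 0.2
  neff <- 1e4
  mod <- true_model(L, diag(3), rep(0, 9), rep(neff, 9),
                    snp_factor_effects = gamma,
                    snp_direct_effects = matrix(0, m, 9))
  nrep <- 30
  zbar <- matrix(0, nrep, 9)
  for (r in seq_len(nrep)) {
    sim <- simulate_multitrait_sumstats(panel, mod, seed = 100 + r)
    zbar[r, ] <- vapply(sim$sumstats, function(t) zscores(t)[j], numeric(1))
  }
  expected <- drop(L %*% c(0.2, 0, 0)) * sqrt(neff)  # 10 for loaders, 0 rest
  got <- colMeans(zbar)
  expect_equal(got[1:3], expected[1:3], tolerance = 0.15)
  expect_lt(max(abs(got[4:9])), 3 / sqrt(nrep) * 2)
  lab <- sim$truth$label[j]
  expect_identical(lab, "factor-consistent")
})

test_that("full sample overlap with identical traits gives error correlation 1", {
  panel <- make_ld_panel(300, 40, 10, 0.5, seed = 3)
  mod <- null_model(panel, k = 2, overlap_frac = matrix(1, 2, 2),
                    overlap_cor = matrix(1, 2, 2))
  sim <- simulate_multitrait_sumstats(panel, mod, seed = 8)
  z <- sapply(sim$sumstats, zscores)
  expect_gt(cor(z[, 1], z[, 2]), 0.999)
})

test_that("configured partial overlap reproduces the z error correlation", {
  panel <- shared_panel()  # >= 5000 variants
  of <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  oc <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  mod <- null_model(panel, k = 2, overlap_frac = of, overlap_cor = oc)
  sim <- simulate_multitrait_sumstats(panel, mod, seed = 21)
  z <- sapply(sim$sumstats, zscores)
  expect_lt(abs(cor(z[, 1], z[, 2]) - 0.5 * 0.6), 0.05)
})

test_that("summed effect-size covariance converges to the model-implied matrix", {
  L <- matrix(0, 9, 3)
  L[1:3, 1] <- sqrt(0.21); L[4:7, 2] <- sqrt(0.21); L[8:9, 3] <- sqrt(0.21)
  Phi <- matrix(0.25, 3, 3); diag(Phi) <- 1
  Th <- rep(0.09, 9)
  target <- L %*% Phi %*% t(L) + diag(Th)
  eff <- draw_polygenic_effects(20000, Phi, Th, seed = 77)
  b <- eff$gamma %*% t(L) + eff$delta
  got <- crossprod(b)
  expect_lt(max(abs(diag(got) - diag(target)) / diag(target)), 0.10)
  off <- upper.tri(target) & target > 0.01
  expect_lt(max(abs(got[off] - target[off]) / target[off]), 0.10)
})

test_that("QTL simulation plants a single causal variant", {
  panel <- make_ld_panel(500, 40, 10, 0.7, seed = 12)
  causal <- panel$variants$rsid[105]
  q <- simulate_qtl_sumstats(panel, causal, effect = 0.4, n = 2000, seed = 4)
  z <- q$BETA / q$SE
  expect_gt(abs(z[105]), 10)
  # signal decays with LD distance; other blocks stay null
  other <- panel$variants$block != panel$variants$block[105]
  expect_lt(mean(z[other]^2), 1.25)

  expect_error(simulate_qtl_sumstats(panel, "rs_nope", 0.4, 2000, 1), "unknown")

  # zero effect indistinguishable from "none"
  q0 <- simulate_qtl_sumstats(panel, causal, effect = 0, n = 2000, seed = 4)
  qn <- simulate_qtl_sumstats(panel, "none", effect = 0.4, n = 2000, seed = 4)
  expect_equal(q0$BETA, qn$BETA, tolerance = 1e-12)
})

test_that("dimension mismatches and invalid models are rejected", {
  panel <- make_ld_panel(100, 4, 5, 0.5, seed = 1)
  mod <- null_model(make_ld_panel(100, 4, 6, 0.5, seed = 1))
  expect_error(simulate_multitrait_sumstats(panel, mod, 1), "row per panel variant")
  expect_error(
    true_model(matrix(1, 2, 1), matrix(1), c(-2, -2), c(100, 100),
               matrix(0, 5, 1), matrix(0, 5, 2)),
    "positive semi-definite"
  )
})
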
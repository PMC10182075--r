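test_that("log ABF matches the Wakefield formula", {
  # beta 0.3, se 0.05, prior 0.2: longhand evaluation
  r <- 0.2^2 / (0.2^2 + 0.05^2)
  z <- 0.3 / 0.05
  expect_equal(log_abf(0.3, 0.05, 0.2), 0.5 * (log(1 - r) + r * z^2),
               tolerance = 1e-12)
  # null z: pure shrinkage penalty, negative
  expect_lt(log_abf(0, 0.1, 0.2), 0)
  expect_equal(log_abf(0, 0.1, 0.2), 0.5 * log(1 - 0.04 / 0.05))
  # degenerate prior: no evidence either way
  expect_equal(log_abf(0.5, 0.1, 1e-12), 0, tolerance = 1e-8)
  expect_error(log_abf(0.1, 0, 0.2), "positive")
})

test_that("self-colocalization of a strong signal gives PP4 > 0.99", {
  set.seed(31)
  z <- c(rnorm(40), 8)
  a <- mk_ds(z * 0.05, rep(0.05, 41))
  cc <- coloc_pair(a, a)
  expect_gt(cc$pp4, 0.99)
  expect_equal(cc$pp0 + cc$pp1 + cc$pp2 + cc$pp3 + cc$pp4, 1, tolerance = 1e-10)
})

test_that("flat signals on both sides make PP0 modal", {
  set.seed(32)
  a <- mk_ds(runif(40, -0.04, 0.04), rep(0.05, 40))
  b <- mk_ds(runif(40, -0.04, 0.04), rep(0.05, 40))
  cc <- coloc_pair(a, b)
  pps <- unlist(cc[, c("pp0", "pp1", "pp2", "pp3", "pp4")])
  expect_identical(names(which.max(pps)), "pp0")
})

test_that("distinct causal variants in low LD make PP3 modal", {
  set.seed(33)
  panel <- make_ld_panel(800, 4, 12, 0.9, seed = 81)
  R <- panel_ld_matrix(panel)
  CL <- t(chol(R + diag(1e-6, nrow(R))))
  n <- 48
  hit <- 0
  for (r in 1:60) {
    # causal variants in different blocks (r2 ~ 0), strong signals;
    # noise correlated through LD as in real summary statistics
    za <- drop(R[, 6] * 9) + drop(CL %*% rnorm(n))
    zb <- drop(R[, 30] * 9) + drop(CL %*% rnorm(n))
    a <- mk_ds(za * 0.05, rep(0.05, n), snps = panel$variants$rsid)
    b <- mk_ds(zb * 0.05, rep(0.05, n), snps = panel$variants$rsid)
    cc <- coloc_pair(a, b)
    pps <- unlist(cc[, c("pp0", "pp1", "pp2", "pp3", "pp4")])
    hit <- hit + (names(which.max(pps)) == "pp3")
  }
  expect_gte(hit / 60, 0.9)
})

test_that("shared causal variants give PP4 >= 0.9 in most strong replicates", {
  set.seed(34)
  panel <- make_ld_panel(800, 4, 12, 0.9, seed = 82)
  R <- panel_ld_matrix(panel)
  CL <- t(chol(R + diag(1e-6, nrow(R))))
  n <- 48
  hit <- 0
  for (r in 1:60) {
    za <- drop(R[, 18] * 9) + drop(CL %*% rnorm(n))
    zb <- drop(R[, 18] * 8) + drop(CL %*% rnorm(n))
    a <- mk_ds(za * 0.05, rep(0.05, n), snps = panel$variants$rsid)
    b <- mk_ds(zb * 0.04, rep(0.04, n), snps = panel$variants$rsid)
    hit <- hit + (coloc_pair(a, b)$pp4 >= 0.9)
  }
  expect_gte(hit / 60, 0.9)
})

test_that("two-variant enumerations match the brute-force oracle", {
  set.seed(35)
  for (r in 1:25) {
    b1 <- rnorm(2, 0, 0.2); s1 <- runif(2, 0.02, 0.1)
    b2 <- rnorm(2, 0, 0.2); s2 <- runif(2, 0.02, 0.1)
    a <- mk_ds(b1, s1)
    b <- mk_ds(b2, s2)
    cc <- coloc_pair(a, b, min_overlap = 2)
    want <- brute_coloc(b1, s1, b2, s2, 1e-4, 1e-4, 1e-5)
    expect_equal(unlist(cc[, c("pp0", "pp1", "pp2", "pp3", "pp4")]),
                 want, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("PP4 is monotone in the shared prior and symmetric up to relabelling", {
  set.seed(36)
  z <- c(rnorm(30), 7)
  a <- mk_ds(z * 0.05, rep(0.05, 31))
  b <- mk_ds(z * 0.05 + rnorm(31, 0, 0.01), rep(0.05, 31))
  pp4s <- vapply(c(1e-6, 1e-5, 1e-4, 1e-3),
                 function(p12) coloc_pair(a, b, p12 = p12)$pp4, numeric(1))
  expect_true(all(diff(pp4s) >= -1e-12))

  ab <- coloc_pair(a, b)
  ba <- coloc_pair(b, a)
  expect_equal(ab$pp4, ba$pp4, tolerance = 1e-12)
  expect_equal(ab$pp1, ba$pp2, tolerance = 1e-12)
  expect_equal(ab$pp3, ba$pp3, tolerance = 1e-12)
})

test_that("too few shared variants yields an explicit untestable result", {
  a <- mk_ds(rnorm(5), rep(0.05, 5))
  b <- mk_ds(rnorm(5), rep(0.05, 5))
  cc <- coloc_pair(a, b, min_overlap = 25)
  expect_false(cc$testable)
  expect_true(is.na(cc$pp4))
})

test_that("signals group by thresholded PP4 components", {
  res <- tibble::tibble(
    trait_a = c("F1", "F2", "F1"), signal_a = c("a", "b", "a"),
    trait_b = c("F2", "F3", "F3"), signal_b = c("b", "c", "c"),
    pp4 = c(0.95, 0.95, 0.2)
  )
  g <- group_signals(res)
  expect_equal(length(unique(g$locus)), 1L)
  expect_true(all(g$label == "shared"))

  # 0.89 misses the strict >= 0.9 threshold
  res2 <- res; res2$pp4 <- c(0.89, 0.89, 0.2)
  g2 <- group_signals(res2)
  expect_equal(length(unique(g2$locus)), 3L)
  expect_true(all(g2$label == "specific"))

  # untested signals become singleton loci
  nodes <- tibble::tibble(trait = c("F1", "F2", "F3", "F1"),
                          signal = c("a", "b", "c", "d"))
  g3 <- group_signals(res, nodes = nodes)
  expect_equal(sum(g3$label == "specific"), 1L)
})

test_that("QTL colocalization distinguishes shared from distinct variants", {
  run <- shared_run()
  qres <- run$qtl_results
  expect_true(any(qres$qtl == "eqtl_shared" & qres$colocalized))
  expect_false(any(qres$qtl == "eqtl_distinct" & qres$colocalized))
  # the distinct eQTL is dominated by the two-distinct-variants hypothesis
  expect_gt(max(qres$pp3[qres$qtl == "eqtl_distinct"]), 0.9)
})

test_that("main-effect mode equals decomposed mode for a single-signal QTL", {
  study <- shared_run()$study
  qtl <- study$qtls$eqtl_shared
  causal <- study$qtl_meta$causal_rsid[study$qtl_meta$qtl == "eqtl_shared"]
  j <- match(causal, study$panel$variants$rsid)
  block <- study$panel$variants$block[j]
  vs <- study$panel$variants[study$panel$variants$block %in% (block + (-1:1)), ]
  ld <- panel_ld_matrix(study$panel, vs$rsid)
  region <- tibble::tibble(chr = vs$chr[1], start = min(vs$pos), end = max(vs$pos))
  fss <- shared_run()$signal_sets
  nm <- names(fss)[vapply(fss, function(s) causal %in% s$selected, logical(1))][1]
  ss <- fss[[nm]]
  dec <- qtl_coloc(ss, qtl, mode = "decomposed", ld = ld)
  mn <- qtl_coloc(ss, qtl, mode = "main_effect")
  expect_equal(nrow(dec), 1L)
  expect_equal(dec$pp4, mn$pp4, tolerance = 0.05)
  expect_true(dec$colocalized && mn$colocalized)
})
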
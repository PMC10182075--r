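test_that("with in-sample LD the conditional machinery equals exact OLS", {
  co <- make_cohort(seed = 501, causal = c(15, 23, 141), effects = c(0.25, 0.2, 0.22))
  sel <- stepwise_select(co$stats, co$R, p_stop = 1e-4)
  expect_setequal(sel, co$stats$SNP[c(15, 23, 141)])

  ds <- all_but_one(co$stats, co$R, sel)
  for (t in names(ds)) {
    cond_idx <- match(attr(ds[[t]], "conditioned_on"), co$stats$SNP)
    for (j in sample(seq_len(nrow(co$stats)), 25)) {
      if (j %in% cond_idx) next
      ols <- summary(lm(co$y ~ co$G[, j] + co$G[, cond_idx, drop = FALSE]))
      row <- ds[[t]][match(co$stats$SNP[j], ds[[t]]$SNP), ]
      expect_equal(row$beta_c, ols$coefficients[2, 1], tolerance = 1e-6)
      expect_equal(row$se_c, ols$coefficients[2, 2], tolerance = 1e-6)
    }
  }
})

test_that("stepwise selection finds the single causal variant in strong regions", {
  hits <- vapply(1:100, function(r) {
    co <- make_cohort(seed = 600 + r, n = 1000, n_blocks = 4, block_size = 10,
                      causal = 15, effects = 0.3)
    sel <- stepwise_select(co$stats, co$R)
    length(sel) >= 1 && sel[1] == co$stats$SNP[15]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pure-noise regions select nothing", {
  co <- make_cohort(seed = 777, n = 500, n_blocks = 4, block_size = 10)
  expect_identical(stepwise_select(co$stats, co$R), character(0))
  expect_identical(stepwise_select(co$stats[0, ], co$R), character(0))
})

test_that("a single selected variant yields the marginal dataset", {
  co <- make_cohort(seed = 520, causal = 25, effects = 0.3)
  sel <- stepwise_select(co$stats, co$R)
  expect_identical(sel, co$stats$SNP[25])
  ds <- all_but_one(co$stats, co$R, sel)[[1]]
  expect_equal(ds$beta_c, co$stats$BETA, tolerance = 1e-10)
  expect_equal(ds$se_c, co$stats$SE, tolerance = 1e-10)
  expect_identical(attr(ds, "conditioned_on"), character(0))
})

test_that("conditioning on an uncorrelated variant barely moves the estimates", {
  # causal variants in different LD blocks: r ~ 0
  co <- make_cohort(seed = 530, causal = c(15, 115), effects = c(0.3, 0.3))
  sel <- stepwise_select(co$stats, co$R)
  expect_setequal(sel, co$stats$SNP[c(15, 115)])
  ds <- all_but_one(co$stats, co$R, sel)
  t1 <- co$stats$SNP[15]
  same_block <- co$panel$variants$block == co$panel$variants$block[15]
  rows <- match(co$stats$SNP[same_block], ds[[t1]]$SNP)
  expect_lt(max(abs(ds[[t1]]$beta_c[rows] - co$stats$BETA[same_block])), 0.02)
})

test_that("selection is deterministic and bounded", {
  co <- make_cohort(seed = 540, causal = c(12, 28), effects = c(0.25, 0.2))
  s1 <- stepwise_select(co$stats, co$R)
  s2 <- stepwise_select(co$stats, co$R)
  expect_identical(s1, s2)
  expect_lte(length(s1), nrow(co$stats))
})

test_that("collinear candidates are skipped", {
  co <- make_cohort(seed = 550, n = 1000, n_blocks = 2, block_size = 6,
                    causal = 3, effects = 0.4)
  # duplicate the causal column: perfect collinearity
  co$R[4, ] <- co$R[3, ]; co$R[, 4] <- co$R[, 3]; co$R[4, 4] <- 1; co$R[3, 4] <- co$R[4, 3] <- 1
  co$stats$BETA[4] <- co$stats$BETA[3]; co$stats$SE[4] <- co$stats$SE[3]
  sel <- stepwise_select(co$stats, co$R)
  expect_false(all(c(co$stats$SNP[3], co$stats$SNP[4]) %in% sel))
})

test_that("frequency mismatches against the reference are dropped with a warning", {
  co <- make_cohort(seed = 560, causal = 15, effects = 0.3)
  freqs <- setNames(co$stats$FREQ, co$stats$SNP)
  freqs[2] <- freqs[2] + 0.4
  expect_warning(sel <- stepwise_select(co$stats, co$R, ld_freq = freqs),
                 "mismatch")
  expect_identical(sel, co$stats$SNP[15])
})

test_that("signal validity follows the conditional/original p-value rule", {
  mk_ds <- function(p_c, p_marg, target = "t1") {
    ds <- tibble::tibble(SNP = paste0("v", seq_along(p_c)), CHR = 1L,
                         BP = seq_along(p_c), beta_c = 1, se_c = 1,
                         z_c = 1, p_c = p_c, p_marg = p_marg)
    attr(ds, "target") <- target
    ds
  }
  # min conditional p below 1e-6: valid
  v1 <- validate_signals(list(mk_ds(c(1e-7, 1e-3), c(0.5, 0.5))))
  expect_true(v1$valid)
  # conditional p 1e-5 but marginal at that variant 1e-9: valid
  v2 <- validate_signals(list(mk_ds(c(1e-5, 1e-3), c(1e-9, 0.5))))
  expect_true(v2$valid)
  # conditional 1e-5, marginal 1e-7: invalid (neither clause holds)
  v3 <- validate_signals(list(mk_ds(c(1e-5, 1e-3), c(1e-7, 0.5))))
  expect_false(v3$valid)
})
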
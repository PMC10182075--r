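# fixed measurement model: 9 traits, 3 factors, loadings 0.5
fixed_L <- function() {
  L <- matrix(0, 9, 3, dimnames = list(paste0("T", 1:9), paste0("F", 1:3)))
  L[1:3, 1] <- 0.5; L[4:7, 2] <- 0.5; L[8:9, 3] <- 0.5
  L
}

mock_est <- function(k = 9, err_cor = diag(k)) {
  traits <- paste0("T", seq_len(k))
  dimnames(err_cor) <- list(traits, traits)
  list(S = diag(0.3, k, k), V = diag(1e-3, k * (k + 1) / 2),
       intercepts = err_cor, intercept_se = matrix(0, k, k), traits = traits)
}

snp_tbl <- function(beta, se, freq = 0.5, traits = paste0("T", seq_along(beta))) {
  tibble::tibble(trait = traits, beta = beta, se = se, freq = freq)
}

test_that("covariance augmentation appends the variant consistently", {
  est <- mock_est()
  # f = 0.5, beta = 0.1: SNP-trait covariance 0.1 * 2 * 0.25 = 0.05
  aug <- expand_covariance(est, snp_tbl(rep(0.1, 9), rep(0.02, 9)))
  expect_equal(aug$s_g, 0.5)
  expect_equal(unname(aug$S_star[10, 1:9]), rep(0.05, 9))
  # symmetric, original S as leading principal submatrix
  expect_true(isSymmetric(aug$S_star))
  expect_equal(unname(aug$S_star[1:9, 1:9]), unname(est$S))
  expect_equal(dim(aug$V_star), c(55, 55))
  expect_equal(aug$V_star[1:45, 1:45], est$V)

  # null variant: zero covariances
  aug0 <- expand_covariance(est, snp_tbl(rep(0, 9), rep(0.02, 9)))
  expect_equal(unname(aug0$S_star[10, 1:9]), rep(0, 9))

  expect_error(expand_covariance(est, snp_tbl(rep(0, 8), rep(0.02, 8))),
               "missing statistics")
})

test_that("factor effects are recovered and nulls stay null across replicates", {
  set.seed(404)
  est <- mock_est()
  fit <- list(loadings = fixed_L())
  gamma <- c(0.05, 0, 0)
  se <- 0.01
  nrep <- 100
  ok_rec <- ok_null <- logical(nrep)
  for (r in seq_len(nrep)) {
    beta <- drop(fixed_L() %*% gamma) + rnorm(9, 0, se)
    eff <- estimate_snp_effects(expand_covariance(est, snp_tbl(beta, rep(se, 9))),
                                fit)
    ok_rec[r] <- abs(eff$beta[1] - 0.05) < 2 * eff$se[1]
    ok_null[r] <- all(eff$p[2:3] > 0.05)
  }
  expect_gte(mean(ok_rec), 0.9)
  expect_gte(mean(ok_null), 0.9)
})

test_that("per-factor z-statistics are standard normal at null variants", {
  set.seed(405)
  est <- mock_est()
  fit <- list(loadings = fixed_L())
  zmat <- t(replicate(1000, {
    beta <- rnorm(9, 0, 0.01)
    eff <- estimate_snp_effects(expand_covariance(est, snp_tbl(beta, rep(0.01, 9))),
                                fit)
    eff$z
  }))
  for (f in 1:3) {
    expect_lt(abs(mean(zmat[, f])), 0.05)
    expect_gt(var(zmat[, f]), 0.9)
    expect_lt(var(zmat[, f]), 1.1)
    expect_gt(ks.test(zmat[, f], pnorm)$p.value, 0.01)
  }
})

test_that("duplicated single-indicator setup collapses to the trait effect", {
  k <- 3
  est <- mock_est(k)
  L <- matrix(1, k, 1, dimnames = list(paste0("T", 1:k), "F1"))
  beta <- rep(0.07, k)
  eff <- estimate_snp_effects(
    expand_covariance(est, snp_tbl(beta, rep(0.01, k), traits = paste0("T", 1:k))),
    list(loadings = L)
  )
  expect_equal(eff$beta, 0.07, tolerance = 1e-6)
})

test_that("Q_SNP is calibrated under the factor model and powered against it", {
  set.seed(406)
  est <- mock_est()
  fit <- list(loadings = fixed_L())
  # calibration: effects purely through factors
  p_null <- replicate(1000, {
    gamma <- rnorm(3, 0, 0.03)
    beta <- drop(fixed_L() %*% gamma) + rnorm(9, 0, 0.01)
    q_snp(expand_covariance(est, snp_tbl(beta, rep(0.01, 9))), fit)$p
  })
  rate <- mean(p_null < 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rate, 0.05 - ci)
  expect_lt(rate, 0.05 + ci)

  # power: a direct effect on one trait at N = 50,000 scale
  # (se = 1/sqrt(N * 2f(1-f)) ~ 0.0063; delta = 0.05 gives |z| ~ 8)
  se50 <- 1 / sqrt(50000 * 0.5)
  p_alt <- replicate(200, {
    beta <- drop(fixed_L() %*% c(0.02, 0, 0)) + rnorm(9, 0, se50)
    beta[5] <- beta[5] + 0.05
    q_snp(expand_covariance(est, snp_tbl(beta, rep(se50, 9))), fit)$p
  })
  expect_gt(mean(p_alt < 5e-8), 0.5)
})

test_that("Q_SNP is invariant to trait ordering", {
  set.seed(407)
  est <- mock_est()
  fit <- list(loadings = fixed_L())
  beta <- drop(fixed_L() %*% c(0.02, -0.01, 0.03)) + rnorm(9, 0, 0.01)
  q1 <- q_snp(expand_covariance(est, snp_tbl(beta, rep(0.01, 9))), fit)

  perm <- c(4, 7, 1, 9, 2, 5, 3, 8, 6)
  est2 <- mock_est()
  est2$traits <- est2$traits[perm]
  est2$intercepts <- est2$intercepts[perm, perm]
  est2$intercept_se <- est2$intercept_se[perm, perm]
  fit2 <- list(loadings = fixed_L()[perm, ])
  q2 <- q_snp(expand_covariance(est2, snp_tbl(beta[perm], rep(0.01, 9),
                                              traits = paste0("T", 1:9)[perm])),
              fit2)
  expect_equal(q2$chi2, q1$chi2, tolerance = 1e-10)
  expect_identical(q2$df, q1$df)
})

test_that("the genome-wide driver matches the per-variant functions", {
  run <- shared_run()
  est <- run$est
  fit <- run$fit
  mg <- run$munged
  fg <- run$fgwas
  snp <- fg$F1$SNP[123]
  tbl <- purrr::imap_dfr(mg, function(t, nm) {
    i <- match(snp, t$SNP)
    tibble::tibble(trait = nm, beta = t$BETA[i], se = t$SE[i], freq = t$FREQ[i])
  })
  aug <- expand_covariance(est, tbl)
  eff <- estimate_snp_effects(aug, fit)
  qq <- q_snp(aug, fit)
  i <- match(snp, fg$F1$SNP)
  for (f in 1:3) {
    expect_equal(fg[[f]]$BETA[i], eff$beta[f], tolerance = 1e-8)
    expect_equal(fg[[f]]$SE[i], eff$se[f], tolerance = 1e-8)
  }
  expect_equal(fg$F1$QSNP_CHI2[i], qq$chi2, tolerance = 1e-8)
  expect_equal(unique(fg$F1$QSNP_DF), qq$df)
})
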
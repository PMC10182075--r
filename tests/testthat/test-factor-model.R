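nine_traits <- c("CD", "UC", "PSC", "T1D", "SLE", "JIA", "RA", "AST", "ECZ")
nine_membership <- c(1, 1, 1, 2, 2, 2, 2, 3, 3)

exact_nine_trait_est <- function(lambda2 = 0.21, phi = 0.25, theta = 0.09) {
  L <- matrix(0, 9, 3)
  L[cbind(1:9, nine_membership)] <- sqrt(lambda2)
  Phi <- matrix(phi, 3, 3); diag(Phi) <- 1
  S <- L %*% Phi %*% t(L) + diag(rep(theta, 9))
  dimnames(S) <- list(nine_traits, nine_traits)
  list(S = S, V = diag(1e-3, 45), traits = nine_traits)
}

nine_spec <- function() {
  model_spec(list(F1 = nine_traits[1:3], F2 = nine_traits[4:7],
                  F3 = nine_traits[8:9]), name = "3-factor")
}

test_that("trait grouping by thresholded genetic correlation finds components", {
  rg <- diag(9)
  dimnames(rg) <- list(nine_traits, nine_traits)
  for (i in 1:9) for (j in 1:9) {
    rg[i, j] <- ifelse(i == j, 1,
                       ifelse(nine_membership[i] == nine_membership[j], 0.6, 0.1))
  }
  g <- propose_groups(rg, threshold = 0.4)
  expect_identical(split(g$trait, g$group),
                   list(`1` = nine_traits[1:3], `2` = nine_traits[4:7],
                        `3` = nine_traits[8:9]))

  # all below threshold: singletons
  g2 <- propose_groups(diag(3))
  expect_identical(g2$group, 1:3)

  # chain rule: A-B and B-C connect A-C through the component
  rg3 <- matrix(c(1, .5, .1, .5, 1, .5, .1, .5, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  g3 <- propose_groups(rg3)
  expect_identical(g3$group, rep(1L, 3))

  expect_error(propose_groups(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("WLS fit exactly recovers a noiseless three-factor structure", {
  est <- exact_nine_trait_est()
  fit <- fit_wls(est, nine_spec())
  expect_true(fit$converged)
  expect_false(fit$heywood)
  expect_lt(max(abs(fit$loadings[cbind(1:9, nine_membership)] - sqrt(0.21))), 1e-6)
  expect_lt(max(abs(fit$phi[lower.tri(fit$phi)] - 0.25)), 1e-6)
  expect_lt(max(abs(fit$theta_resid - 0.09)), 1e-6)
  expect_equal(fit$cfi, 1)
  expect_lt(fit$chi2, 1e-10)
  expect_lt(fit$srmr, 1e-8)
})

test_that("a one-factor model fits the three-factor structure strictly worse", {
  est <- exact_nine_trait_est()
  f3 <- fit_wls(est, nine_spec())
  f1 <- fit_wls(est, model_spec(list(F1 = nine_traits), name = "1-factor"))
  expect_gt(f1$srmr, f3$srmr)
  expect_gt(f1$chi2, f3$chi2)
  expect_lt(f1$cfi, 1)
})

test_that("fit indices match an independent longhand evaluation", {
  # small 3-trait example with deliberate misfit
  S <- matrix(c(1, 0.5, 0.3,
                0.5, 1, 0.4,
                0.3, 0.4, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  V <- diag(c(0.02, 0.01, 0.015, 0.012, 0.011, 0.02))
  est <- list(S = S, V = V, traits = colnames(S))
  fit <- fit_wls(est, model_spec(list(F1 = c("A", "B", "C")), name = "1f"))

  # longhand WLS quadratic form at the reported optimum
  L <- fit$loadings; Th <- fit$theta_resid
  implied <- L %*% t(L) + diag(Th)
  resid <- S - implied
  s_idx <- cbind(c(1, 2, 2, 3, 3, 3), c(1, 1, 2, 1, 2, 3))
  chi2_long <- sum(resid[s_idx]^2 / diag(V))
  expect_equal(fit$chi2, chi2_long, tolerance = 1e-10)

  # longhand SRMR over the standardized distinct elements
  d <- sqrt(diag(S))
  std_resid <- resid / outer(d, d)
  srmr_long <- sqrt(mean(std_resid[s_idx]^2))
  expect_equal(fit$srmr, srmr_long, tolerance = 1e-10)

  # longhand baseline (independence) and CFI with the max(..., 0) clamps
  base_resid <- S - diag(diag(S))
  chi2_b <- sum(base_resid[s_idx]^2 / diag(V))
  expect_equal(fit$baseline_chi2, chi2_b, tolerance = 1e-10)
  cfi_long <- 1 - max(fit$chi2 - fit$df, 0) /
    max(chi2_b - fit$baseline_df, fit$chi2 - fit$df, 0)
  expect_equal(fit$cfi, cfi_long, tolerance = 1e-10)

  # perfect fit clamps CFI at exactly 1
  estp <- exact_nine_trait_est()
  expect_identical(fit_wls(estp, nine_spec())$cfi, 1)
})

test_that("standardized loadings are invariant to rescaling a trait", {
  est <- exact_nine_trait_est()
  fit <- fit_wls(est, nine_spec())

  c_scale <- 2.5
  D <- diag(9); D[1, 1] <- c_scale
  S2 <- D %*% est$S %*% D
  dimnames(S2) <- dimnames(est$S)
  # matching transform of V: each distinct element (i, j) scales by c_i * c_j
  idx <- cbind(rep(1:9, times = 1:9), unlist(lapply(1:9, seq_len)))
  scale_el <- ifelse(idx[, 1] == 1, c_scale, 1) * ifelse(idx[, 2] == 1, c_scale, 1)
  V2 <- diag(scale_el) %*% est$V %*% diag(scale_el)
  est2 <- list(S = S2, V = V2, traits = nine_traits)
  fit2 <- fit_wls(est2, nine_spec())
  expect_equal(standardized_loadings(fit2), standardized_loadings(fit),
               tolerance = 1e-6)
})

test_that("model selection filters on fit and prefers parsimony", {
  est <- exact_nine_trait_est()
  f3 <- fit_wls(est, nine_spec())
  f1 <- fit_wls(est, model_spec(list(F1 = nine_traits), name = "1-factor"))
  sel <- select_model(list(f1, f3))
  expect_identical(sel$chosen$spec$name, "3-factor")
  expect_identical(sel$report$pass, c(FALSE, TRUE))

  # all failing: explicit no-adequate-model result
  sel2 <- select_model(list(f1), cfi_min = 0.99)
  expect_null(sel2$chosen)

  # two passing candidates: fewest factors wins
  est2 <- exact_nine_trait_est(phi = 0.9)   # near-one-factor structure
  g1 <- fit_wls(est2, model_spec(list(F1 = nine_traits), name = "1-factor"))
  g3 <- fit_wls(est2, nine_spec())
  if (g1$cfi > 0.95 && g1$srmr < 0.10) {
    sel3 <- select_model(list(g3, g1))
    expect_identical(sel3$chosen$spec$name, "1-factor")
  }
  # declared exclusions are honoured
  sel4 <- select_model(list(f1, f3), exclude = "3-factor")
  expect_null(sel4$chosen)
})

test_that("Heywood cases are flagged, not clamped", {
  # force a negative residual: S with a diagonal below the common-factor part
  est <- exact_nine_trait_est()
  S <- est$S
  S[1, 1] <- 0.15   # below the communality 0.21
  est$S <- S
  fit <- fit_wls(est, nine_spec())
  expect_true(fit$heywood)
  expect_true(any(fit$theta_resid < 0))
})

test_that("tidy and glance expose the fitted parameters", {
  fit <- fit_wls(exact_nine_trait_est(), nine_spec())
  td <- tidy(fit)
  expect_identical(nrow(td), 21L)   # 9 loadings + 3 factor cors + 9 residuals
  expect_setequal(unique(td$type), c("loading", "factor_cor", "residual"))
  expect_equal(td$std_estimate[td$type == "loading"],
               rep(sqrt(0.21 / 0.3), 9), tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$n_free, 21)
  expect_equal(gl$df, 24)
})
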
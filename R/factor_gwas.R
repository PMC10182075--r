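# Cross-trait z-score error correlation from the LDSC intercept matrix,
# turned into a proper correlation matrix: off-diagonal intercepts shrunk by
# their jackknife sampling variance (they are individually noisy), clamped to
# [-1, 1], eigenvalues floored and the diagonal rescaled to 1. Without the
# projection the implied weight matrix can be indefinite.
intercept_error_cor <- function(intercepts, intercept_se = NULL,
                                eig_floor = 0.05) {
  C <- intercepts
  if (!is.null(intercept_se)) {
    shrink <- C^2 / (C^2 + intercept_se^2)
    shrink[!is.finite(shrink)] <- 0
    C <- C * shrink
  }
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < eig_floor) {
    C <- ev$vectors %*% diag(pmax(ev$values, eig_floor)) %*% t(ev$vectors)
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
  }
  dimnames(C) <- dimnames(intercepts)
  C
}

#' Augment a genetic covariance estimate with one variant
#'
#' Appends the variant as a final row/column of S: its variance is
#' `2 f (1 - f)` and its covariance with trait t is `beta_t * 2 f (1 - f)`
#' (beta on the allele-dosage scale). The sampling covariance V gains the
#' corresponding elements, built from the per-trait standard errors and the
#' cross-trait error correlations implied by the LDSC intercepts; the
#' variant's own variance is treated as fixed.
#'
#' @param est A `genetic_covariance` object.
#' @param snp Data frame with one row per trait: columns trait, beta, se,
#'   freq (every trait in `est$traits` must appear).
#' @param err_cor Optional known cross-trait error-correlation matrix (e.g.
#'   in simulations); defaults to the intercept-derived estimate.
#' @return List of class `snp_augment`: `S_star`, `V_star`, `beta`,
#'   `sigma_beta` (k x k sampling covariance of the betas), `s_g`, `traits`.
#' @export
expand_covariance <- function(est, snp, err_cor = NULL) {
  traits <- est$traits
  k <- length(traits)
  idx <- match(traits, snp$trait)
  if (anyNA(idx)) {
    stop("missing statistics for trait(s): ",
         paste(traits[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  beta <- snp$beta[idx]
  se <- snp$se[idx]
  f <- mean(snp$freq[idx])
  s_g <- 2 * f * (1 - f)

  if (is.null(err_cor)) {
    err_cor <- intercept_error_cor(est$intercepts, est$intercept_se)
  }
  sigma_beta <- tcrossprod(se) * err_cor

  S_star <- rbind(cbind(est$S, beta * s_g), c(beta * s_g, s_g))
  dimnames(S_star) <- list(c(traits, "SNP"), c(traits, "SNP"))

  p_old <- k * (k + 1) / 2
  p_new <- (k + 1) * (k + 2) / 2
  V_star <- matrix(0, p_new, p_new)
  V_star[seq_len(p_old), seq_len(p_old)] <- est$V
  # elements (k+1, t) for t = 1..k sit right after the original block
  snp_rows <- p_old + seq_len(k)
  V_star[snp_rows, snp_rows] <- sigma_beta * s_g^2
  # final element: SNP variance, fixed

  structure(
    list(S_star = S_star, V_star = V_star, beta = beta,
         sigma_beta = sigma_beta, s_g = s_g, traits = traits),
    class = "snp_augment"
  )
}

# Factor-path GLS given trait betas, their sampling covariance and the fixed
# measurement model. Shared by estimate_snp_effects and q_snp.
snp_gls <- function(beta, sigma_beta, loadings) {
  W <- tryCatch(solve(sigma_beta), error = function(e) MASS_ginv(sigma_beta))
  A <- crossprod(loadings, W %*% loadings)
  Ainv <- tryCatch(solve(A), error = function(e) MASS_ginv(A))
  gamma <- drop(Ainv %*% crossprod(loadings, W %*% beta))
  resid <- beta - drop(loadings %*% gamma)
  chi2 <- max(drop(crossprod(resid, W %*% resid)), 0)
  list(gamma = gamma, cov_gamma = Ainv, chi2 = chi2)
}

#' Estimate a variant's effects on the latent factors
#'
#' With the measurement model (loadings) held fixed at the SNP-free fit, the
#' SNP-to-factor regression paths are estimated by generalized weighted
#' least squares of the per-trait effect sizes on the loading matrix, using
#' the full per-variant sampling covariance (standard errors plus
#' intercept-derived cross-trait error correlations) as the weight.
#'
#' @param aug An `snp_augment` from [expand_covariance()].
#' @param fit A `factor_fit`; its loadings define the measurement model.
#' @return Tibble with one row per factor: factor, beta, se, z, p.
#' @export
estimate_snp_effects <- function(aug, fit) {
  L <- fit$loadings[aug$traits, , drop = FALSE]
  g <- snp_gls(aug$beta, aug$sigma_beta, L)
  se <- sqrt(pmax(diag(g$cov_gamma), 0))
  z <- g$gamma / se
  tibble::tibble(
    factor = colnames(L) %||% paste0("F", seq_along(g$gamma)),
    beta = unname(g$gamma), se = unname(se), z = unname(z),
    p = unname(two_sided_p(z))
  )
}

#' Q_SNP heterogeneity test for one variant
#'
#' Compares the common-pathway model (the variant acts on traits only
#' through the latent factors) against the independent-pathways model (a
#' free direct effect on every trait, which fits the per-trait effects
#' exactly). The statistic is the fit-statistic difference, i.e. the
#' weighted residual quadratic form of the common-pathway fit, with
#' `df = n_traits - n_factors`. Rejection means the variant acts outside
#' the factor model.
#'
#' @param aug An `snp_augment`.
#' @param fit A `factor_fit`.
#' @return Named list: chi2, df, p.
#' @export
q_snp <- function(aug, fit) {
  L <- fit$loadings[aug$traits, , drop = FALSE]
  g <- snp_gls(aug$beta, aug$sigma_beta, L)
  df <- length(aug$traits) - ncol(L)
  if (df <= 0) stop("Q_SNP needs more traits than factors", call. = FALSE)
  list(chi2 = g$chi2, df = df, p = stats::pchisq(g$chi2, df, lower.tail = FALSE))
}

#' Factor-level GWAS with Q_SNP heterogeneity
#'
#' Runs the SNP-to-factor estimation and the Q_SNP test for every variant
#' shared by all munged trait tables, holding the measurement model fixed at
#' the genome-wide fit. Variants are processed independently and returned in
#' (chr, pos) order.
#'
#' @param tables Named list of munged summary-statistics tibbles (one per
#'   trait, same names as `est$traits`).
#' @param est A `genetic_covariance` object.
#' @param fit A `factor_fit`.
#' @param err_cor Optional known cross-trait error-correlation matrix;
#'   defaults to the intercept-derived estimate.
#' @return Named list of per-factor tibbles with columns SNP, CHR, BP, A1,
#'   A2, BETA, SE, Z, P, QSNP_CHI2, QSNP_DF, QSNP_P.
#' @export
factor_gwas <- function(tables, est, fit, err_cor = NULL) {
  traits <- est$traits
  if (!all(traits %in% names(tables))) {
    stop("tables must cover every trait in the estimate", call. = FALSE)
  }
  tables <- tables[traits]
  common <- Reduce(intersect, lapply(tables, function(t) t$SNP))
  if (length(common) == 0) stop("no shared variants", call. = FALSE)
  ref <- tables[[1]][match(common, tables[[1]]$SNP),
                     c("SNP", "CHR", "BP", "A1", "A2")]
  ord <- order(ref$CHR, ref$BP)
  ref <- ref[ord, ]
  common <- common[ord]
  m <- length(common)
  k <- length(traits)

  B <- sapply(tables, function(t) t$BETA[match(common, t$SNP)])
  SEm <- sapply(tables, function(t) t$SE[match(common, t$SNP)])
  FR <- rowMeans(sapply(tables, function(t) t$FREQ[match(common, t$SNP)]))

  if (is.null(err_cor)) {
    err_cor <- intercept_error_cor(est$intercepts, est$intercept_se)
  }
  Cinv <- tryCatch(solve(err_cor), error = function(e) MASS_ginv(err_cor))
  L <- fit$loadings[traits, , drop = FALSE]
  nf <- ncol(L)
  df_q <- k - nf

  gam <- matrix(NA_real_, m, nf)
  gse <- matrix(NA_real_, m, nf)
  qchi <- numeric(m)
  n_clamped <- 0L

  for (j in seq_len(m)) {
    sej <- SEm[j, ]
    Ls <- L / sej                      # rows scaled by 1/se
    z <- B[j, ] / sej
    A <- crossprod(Ls, Cinv %*% Ls)
    rhs <- crossprod(Ls, Cinv %*% z)
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) next
    g <- drop(Ainv %*% rhs)
    gam[j, ] <- g
    gse[j, ] <- sqrt(pmax(diag(Ainv), 0))
    q <- drop(crossprod(z, Cinv %*% z)) - drop(crossprod(g, A %*% g))
    if (q < 0) { q <- 0; n_clamped <- n_clamped + 1L }
    qchi[j] <- q
  }
  if (n_clamped > 0) {
    warning(sprintf("%d negative Q_SNP statistics clamped to 0", n_clamped))
  }
  qp <- stats::pchisq(qchi, df_q, lower.tail = FALSE)

  factors <- colnames(L) %||% paste0("F", seq_len(nf))
  stats::setNames(lapply(seq_len(nf), function(f) {
    z <- gam[, f] / gse[, f]
    # implied per-variant sample size on the factor scale, the quantity the
    # downstream conditional-analysis algebra consumes
    n_impl <- 1 / (2 * FR * (1 - FR) * gse[, f]^2)
    tibble::tibble(
      SNP = ref$SNP, CHR = ref$CHR, BP = ref$BP, A1 = ref$A1, A2 = ref$A2,
      BETA = gam[, f], SE = gse[, f], Z = z, P = two_sided_p(z),
      N = n_impl, FREQ = FR,
      QSNP_CHI2 = qchi, QSNP_DF = df_q, QSNP_P = qp
    )
  }), factors)
}
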
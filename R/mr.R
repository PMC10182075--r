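#' Wald-ratio Mendelian randomization for a single instrument
#'
#' The causal estimate is `beta_outcome / beta_exposure`; its standard error
#' uses the first-order delta method
#' `sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`, and
#' the p-value comes from the normal approximation. A positive estimate
#' means increased exposure raises outcome risk ("predisposing"); a negative
#' one is "protective".
#'
#' @param exposure Named numeric or list with `beta` and `se` for the
#'   instrument's effect on the exposure (e.g. gene expression).
#' @param outcome Same, for the effect on the outcome (e.g. a disease
#'   factor).
#' @param alpha Reporting threshold on the p-value (default 0.05).
#' @return A one-row `mr_result` tibble: estimate, se, z, p, direction,
#'   reportable.
#' @export
wald_ratio <- function(exposure, outcome, alpha = 0.05) {
  be <- exposure[["beta"]]; see <- exposure[["se"]]
  bo <- outcome[["beta"]]; seo <- outcome[["se"]]
  if (is.null(be) || is.null(bo)) stop("need beta for both sides", call. = FALSE)
  if (see <= 0 || seo <= 0) stop("standard errors must be positive", call. = FALSE)
  if (be == 0) stop("weak instrument: exposure beta is zero", call. = FALSE)
  est <- bo / be
  se <- sqrt(seo^2 / be^2 + bo^2 * see^2 / be^4)
  z <- est / se
  p <- two_sided_p(z)
  res <- tibble::tibble(
    estimate = est, se = se, z = z, p = p,
    direction = ifelse(est > 0, "predisposing", "protective"),
    reportable = p < alpha
  )
  class(res) <- c("mr_result", class(res))
  res
}

#' Wald-ratio MR for colocalizing QTL-factor pairs
#'
#' For each pair passing the colocalization threshold, uses the QTL
#' signal's minimum conditional-p variant as the instrument: the QTL effect
#' is the exposure, the factor's conditional effect at the same variant the
#' outcome.
#'
#' @param coloc_results Output of [qtl_coloc()] (needs `colocalized`).
#' @param qtl_datasets Named list of QTL conditional datasets (or marginal
#'   tibbles) keyed as in `coloc_results$signal_qtl`.
#' @param factor_datasets Named list of factor conditional datasets keyed as
#'   in `coloc_results$signal_factor`.
#' @param exposure_id,outcome_id Labels copied to the output.
#' @param alpha Reporting threshold (default 0.05).
#' @return Tibble: exposure, outcome, signal_qtl, signal_factor, instrument,
#'   estimate, se, p, direction, reportable.
#' @export
mr_colocalized <- function(coloc_results, qtl_datasets, factor_datasets,
                           exposure_id = "exposure", outcome_id = "outcome",
                           alpha = 0.05) {
  hits <- dplyr::filter(coloc_results, .data$colocalized)
  purrr::pmap_dfr(hits, function(signal_factor, signal_qtl, ...) {
    qds <- qtl_datasets[[signal_qtl]]
    fds <- factor_datasets[[signal_factor]]
    qb <- ds_beta_se(qds)
    fb <- ds_beta_se(fds)
    qp <- if ("p_c" %in% names(qds)) qds$p_c else two_sided_p(qb$beta / qb$se)
    shared <- intersect(qds$SNP, fds$SNP)
    if (length(shared) == 0) return(NULL)
    qi <- match(shared, qds$SNP)
    inst <- qi[which.min(qp[qi])]
    instrument <- qds$SNP[inst]
    fi <- match(instrument, fds$SNP)
    wr <- tryCatch(
      wald_ratio(list(beta = qb$beta[inst], se = qb$se[inst]),
                 list(beta = fb$beta[fi], se = fb$se[fi]), alpha = alpha),
      error = function(e) NULL
    )
    if (is.null(wr)) return(NULL)
    tibble::tibble(
      exposure = exposure_id, outcome = outcome_id,
      signal_qtl = signal_qtl, signal_factor = signal_factor,
      instrument = instrument,
      estimate = wr$estimate, se = wr$se, p = wr$p,
      direction = wr$direction, reportable = wr$reportable
    )
  })
}
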
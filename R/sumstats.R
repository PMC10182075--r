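#' Build the reference-variant table from an LD panel
#'
#' The harmonization whitelist: rsid, position, reference alleles and
#' reference allele frequency for every panel variant.
#'
#' @param panel An `ld_panel`.
#' @return A tibble with columns rsid, chr, pos, ref_a1, ref_a2, ref_freq.
#' @export
panel_reference <- function(panel) {
  v <- panel$variants
  tibble::tibble(
    rsid = v$rsid, chr = v$chr, pos = v$pos,
    ref_a1 = v$a1, ref_a2 = v$a2, ref_freq = v$freq_emp
  )
}

allele_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

#' Harmonize ("munge") a raw summary-statistics table against a reference
#'
#' Restricts to reference variants, drops strand-ambiguous (A/T, C/G)
#' variants, flips effect signs where the allele pair is swapped relative to
#' the reference (resolving strand flips through allele complements), removes
#' variants whose alleles cannot be reconciled, removes variants with an
#' effect size or standard error equal to zero, filters on minor-allele
#' frequency, and recomputes the p-value from the harmonized z-score (the
#' original p-value is kept in an audit column `P_ORIG`).
#'
#' MAF is computed from the study frequency when present, else from the
#' reference frequency. Reference chromosome/position are authoritative in
#' the output.
#'
#' @param raw Summary-statistics data frame with columns SNP, A1, A2 and
#'   either (BETA, SE) or Z; optional P, N, FREQ.
#' @param reference Reference-variant table from [panel_reference()] (or the
#'   same shape).
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @return A harmonized tibble with columns SNP, CHR, BP, A1, A2, BETA, SE,
#'   Z, P, P_ORIG, N, FREQ. Zero surviving variants triggers a warning of
#'   class `factorgwas_empty_munge`.
#' @export
munge <- function(raw, reference, maf_min = 0.01) {
  need <- c("SNP", "A1", "A2")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_beta <- all(c("BETA", "SE") %in% names(raw))
  has_z <- "Z" %in% names(raw)
  if (!has_beta && !has_z) {
    stop("need either (BETA, SE) or Z columns", call. = FALSE)
  }

  x <- tibble::as_tibble(raw)
  if (!has_z) x$Z <- x$BETA / x$SE
  if (!has_beta) {
    x$SE <- NA_real_
    x$BETA <- NA_real_
  }
  if (!"P" %in% names(x)) x$P <- two_sided_p(x$Z)
  if (!"P_ORIG" %in% names(x)) x$P_ORIG <- x$P
  if (!"N" %in% names(x)) x$N <- NA_real_
  if (!"FREQ" %in% names(x)) x$FREQ <- NA_real_

  x <- dplyr::inner_join(
    x,
    dplyr::select(reference, "rsid", "chr", "pos", "ref_a1", "ref_a2", "ref_freq"),
    by = c(SNP = "rsid")
  )

  # zero effect sizes or standard errors are artefacts of upstream formatting
  if (has_beta) {
    x <- dplyr::filter(x, .data$BETA != 0, .data$SE != 0, !is.na(.data$SE))
  } else {
    x <- dplyr::filter(x, .data$Z != 0)
  }

  ambiguous <- function(a1, a2) {
    (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
      (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
  }
  x <- dplyr::filter(x, !ambiguous(.data$A1, .data$A2),
                     !ambiguous(.data$ref_a1, .data$ref_a2))

  a1c <- allele_complement(x$A1)
  a2c <- allele_complement(x$A2)
  same <- x$A1 == x$ref_a1 & x$A2 == x$ref_a2
  swapped <- x$A1 == x$ref_a2 & x$A2 == x$ref_a1
  same_c <- a1c == x$ref_a1 & a2c == x$ref_a2
  swapped_c <- a1c == x$ref_a2 & a2c == x$ref_a1

  keep <- same | swapped | same_c | swapped_c
  flip <- swapped | swapped_c
  x <- x[keep, , drop = FALSE]
  flip <- flip[keep]

  x$Z <- ifelse(flip, -x$Z, x$Z)
  if (has_beta) x$BETA <- ifelse(flip, -x$BETA, x$BETA)
  x$FREQ <- ifelse(flip & !is.na(x$FREQ), 1 - x$FREQ, x$FREQ)
  x$A1 <- x$ref_a1
  x$A2 <- x$ref_a2

  freq_use <- ifelse(is.na(x$FREQ), x$ref_freq, x$FREQ)
  maf <- pmin(freq_use, 1 - freq_use)
  x <- x[maf >= maf_min, , drop = FALSE]
  freq_use <- freq_use[maf >= maf_min]

  out <- tibble::tibble(
    SNP = x$SNP, CHR = x$chr, BP = x$pos, A1 = x$A1, A2 = x$A2,
    BETA = if (has_beta) x$BETA else x$Z, # z equals beta on the unit-se scale
    SE = if (has_beta) x$SE else rep(1, nrow(x)),
    Z = x$Z,
    P = two_sided_p(x$Z),
    P_ORIG = x$P_ORIG,
    N = x$N,
    FREQ = freq_use
  )
  out <- dplyr::arrange(out, .data$CHR, .data$BP)
  if (nrow(out) == 0) {
    warning(structure(
      class = c("factorgwas_empty_munge", "warning", "condition"),
      list(message = "all variants removed during munging", call = NULL)
    ))
  }
  out
}

#' Summed effective sample size across case/control cohorts
#'
#' For each cohort the sample prevalence is `v = n_cases / (n_cases +
#' n_controls)` and the cohort effective sample size is
#' `4 * v * (1 - v) * (n_cases + n_controls)`; the study-level value is the
#' sum over contributing cohorts. A balanced cohort contributes its full
#' sample size; imbalance shrinks the contribution.
#'
#' @param cohorts Data frame with columns `n_cases` and `n_controls`, one row
#'   per cohort.
#' @return The summed effective sample size (numeric scalar).
#' @export
effective_sample_size <- function(cohorts) {
  if (!all(c("n_cases", "n_controls") %in% names(cohorts))) {
    stop("`cohorts` needs columns n_cases and n_controls", call. = FALSE)
  }
  if (any(cohorts$n_cases < 1) || any(cohorts$n_controls < 1)) {
    stop("cohort case and control counts must be positive", call. = FALSE)
  }
  n <- cohorts$n_cases + cohorts$n_controls
  v <- cohorts$n_cases / n
  sum(4 * v * (1 - v) * n)
}
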
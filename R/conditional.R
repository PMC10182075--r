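# Approximate conditional-and-joint analysis from summary statistics plus a
# reference LD matrix. All algebra runs on the marginal-correlation scale:
# the marginal correlation of variant j with the phenotype is recovered from
# the z-score as r = z / sqrt(n - 2 + z^2) (the exact t-to-r map for simple
# regression), joint/conditional coefficients are R^{-1} r over the chosen
# variant set, and results are rescaled to the input effect-size scale via
# the per-variant factor se_marginal / se_std. With in-sample LD and matched
# frequencies this reproduces exact multiple-regression estimates.

# per-variant marginal correlation and scale factor from summary stats
cojo_prepare <- function(stats) {
  z <- stats$BETA / stats$SE
  n <- stats$N
  r <- z / sqrt(n - 2 + z^2)
  se_std <- sqrt((1 - r^2) / (n - 2))
  list(r = r, n = n, scale = stats$SE / se_std, z = z)
}

# joint fit of the variants in `set` (indices into r/R); returns standardized
# coefficients, their SEs and the residual variance fraction
cojo_joint <- function(r, R, n, set) {
  Rs <- R[set, set, drop = FALSE]
  b <- solve(Rs, r[set])
  s2 <- max(1 - sum(r[set] * b), 1e-12)
  df <- stats::median(n[set]) - length(set) - 1
  se2 <- s2 * diag(solve(Rs)) / df
  list(b = b, se = sqrt(pmax(se2, 0)), s2 = s2, df = df)
}

# conditional estimate of each variant in `targets` given the set `cond`
cojo_conditional <- function(r, R, n, targets, cond) {
  out <- matrix(NA_real_, length(targets), 2,
                dimnames = list(NULL, c("b", "se")))
  for (i in seq_along(targets)) {
    j <- targets[i]
    if (j %in% cond) next
    fit <- tryCatch(cojo_joint(r, R, n, c(cond, j)), error = function(e) NULL)
    if (is.null(fit)) next
    p <- length(cond) + 1L
    out[i, ] <- c(fit$b[p], fit$se[p])
  }
  out
}

#' Stepwise forward selection of conditionally independent variants
#'
#' Starts from the smallest-p variant and repeatedly adds the variant with
#' the smallest conditional p-value given the current set, recomputed by
#' approximate joint regression from summary effect sizes, sample sizes,
#' allele frequencies and the reference LD matrix. Selection stops when the
#' smallest conditional p-value exceeds `p_stop`. Candidates whose maximum
#' r-squared with the selected set exceeds `r2_cap` are skipped
#' (collinearity guard), as are candidates whose LD submatrix is singular.
#' Variants whose summary allele frequency differs from the reference
#' frequency by more than `freq_diff_max` are dropped with a warning.
#'
#' Ties in conditional p break by smaller p, then lower position.
#'
#' @param region_stats Summary-statistics tibble for the (padded) region:
#'   columns SNP, CHR, BP, BETA, SE, N, FREQ (and optionally P).
#' @param ld Square LD correlation matrix with dimnames matching
#'   `region_stats$SNP` (any superset order; it is aligned internally).
#' @param p_stop Stopping threshold (default 1e-4): stop when all
#'   conditional p exceed it.
#' @param r2_cap Collinearity cap (default 0.9).
#' @param ld_freq Optional named reference allele frequencies for the
#'   frequency-mismatch check.
#' @param freq_diff_max Maximum tolerated frequency mismatch (default 0.2).
#' @return Character vector of selected rsids in selection order.
#' @export
stepwise_select <- function(region_stats, ld, p_stop = 1e-4, r2_cap = 0.9,
                            ld_freq = NULL, freq_diff_max = 0.2) {
  if (nrow(region_stats) == 0) return(character(0))
  stats_al <- dplyr::arrange(region_stats, .data$CHR, .data$BP)
  if (!all(stats_al$SNP %in% rownames(ld))) {
    stop("LD matrix does not cover every region variant", call. = FALSE)
  }
  if (!is.null(ld_freq)) {
    fd <- abs(stats_al$FREQ - ld_freq[stats_al$SNP])
    bad <- !is.na(fd) & fd > freq_diff_max
    if (any(bad)) {
      warning(sprintf("dropping %d variant(s) with allele-frequency mismatch > %.2f",
                      sum(bad), freq_diff_max))
      stats_al <- stats_al[!bad, , drop = FALSE]
    }
  }
  if (nrow(stats_al) == 0) return(character(0))
  R <- ld[stats_al$SNP, stats_al$SNP, drop = FALSE]
  prep <- cojo_prepare(stats_al)
  m <- nrow(stats_al)

  p_marg <- two_sided_p(prep$z)
  first <- order(p_marg, stats_al$BP)[1]
  if (p_marg[first] > p_stop) return(character(0))
  selected <- first

  repeat {
    cand <- setdiff(seq_len(m), selected)
    if (length(cand) == 0) break
    r2max <- apply(R[cand, selected, drop = FALSE]^2, 1, max)
    cand <- cand[r2max <= r2_cap]
    if (length(cand) == 0) break
    est <- cojo_conditional(prep$r, R, prep$n, cand, selected)
    pc <- two_sided_p(est[, "b"] / est[, "se"])
    pc[!is.finite(pc)] <- 1
    best <- order(pc, stats_al$BP[cand])[1]
    if (pc[best] > p_stop) break
    selected <- c(selected, cand[best])
  }
  stats_al$SNP[selected]
}

#' "All-but-one" conditional datasets for a set of selected variants
#'
#' For each selected variant t, every region variant's effect size and
#' standard error are recomputed conditional on the other selected variants
#' (selected minus t). With a single selected variant the conditional
#' dataset equals the marginal data. Variants inside the conditioning set
#' are omitted from the dataset rows.
#'
#' @inheritParams stepwise_select
#' @param selected Character vector of selected rsids (non-empty).
#' @param type Trait type carried to colocalization (`"cc"` case/control or
#'   `"quant"`); stored as an attribute.
#' @return Named list (by target rsid) of `conditional_dataset` tibbles with
#'   columns SNP, CHR, BP, beta_c, se_c, z_c, p_c, p_marg and attributes
#'   `target`, `conditioned_on`, `type`.
#' @export
all_but_one <- function(region_stats, ld, selected, type = "cc") {
  if (length(selected) == 0) stop("`selected` must be non-empty", call. = FALSE)
  stats_al <- dplyr::arrange(region_stats, .data$CHR, .data$BP)
  R <- ld[stats_al$SNP, stats_al$SNP, drop = FALSE]
  prep <- cojo_prepare(stats_al)
  sel_idx <- match(selected, stats_al$SNP)
  if (anyNA(sel_idx)) stop("selected variant absent from region", call. = FALSE)

  out <- lapply(seq_along(selected), function(t) {
    cond <- sel_idx[-t]
    rows <- setdiff(seq_len(nrow(stats_al)), cond)
    if (length(cond) == 0) {
      b_std <- prep$r
      se_std <- sqrt((1 - prep$r^2) / (prep$n - 2))
      bc <- b_std * prep$scale
      sec <- se_std * prep$scale
      bc <- bc[rows]; sec <- sec[rows]
    } else {
      est <- cojo_conditional(prep$r, R, prep$n, rows, cond)
      bc <- est[, "b"] * prep$scale[rows]
      sec <- est[, "se"] * prep$scale[rows]
    }
    z <- bc / sec
    ds <- tibble::tibble(
      SNP = stats_al$SNP[rows], CHR = stats_al$CHR[rows], BP = stats_al$BP[rows],
      beta_c = bc, se_c = sec, z_c = z, p_c = two_sided_p(z),
      p_marg = two_sided_p(prep$z[rows])
    )
    attr(ds, "target") <- selected[t]
    attr(ds, "conditioned_on") <- selected[-t]
    attr(ds, "type") <- type
    class(ds) <- c("conditional_dataset", class(ds))
    ds
  })
  stats::setNames(out, selected)
}

#' Flag valid signals under the conditional/original p-value rule
#'
#' A signal is valid when the minimum conditional p-value of its dataset is
#' below `p_cond`, or when the variant attaining that minimum has an
#' original (marginal) p-value below `p_orig`.
#'
#' @param datasets List of `conditional_dataset` objects from [all_but_one()].
#' @param p_cond Conditional threshold (default 1e-6).
#' @param p_orig Original-GWAS threshold (default 5e-8).
#' @return Tibble: target, lead_rsid (min conditional p variant), p_cond_min,
#'   p_marg_at_lead, valid.
#' @export
validate_signals <- function(datasets, p_cond = 1e-6, p_orig = 5e-8) {
  purrr::map_dfr(datasets, function(ds) {
    ok <- is.finite(ds$p_c)
    i <- which(ok)[which.min(ds$p_c[ok])]
    tibble::tibble(
      target = attr(ds, "target"),
      lead_rsid = ds$SNP[i],
      p_cond_min = ds$p_c[i],
      p_marg_at_lead = ds$p_marg[i],
      valid = ds$p_c[i] < p_cond || ds$p_marg[i] < p_orig
    )
  })
}

#' Decompose one region into conditionally independent signals
#'
#' Convenience wrapper: pads the region, slices the GWAS, runs
#' [stepwise_select()], [all_but_one()] and [validate_signals()].
#'
#' @param gwas Full summary-statistics tibble.
#' @param region One-row region tibble (chr, start, end).
#' @param ld LD matrix covering the padded region's variants.
#' @param pad_bp Padding added to each side of the region (default 100 kb).
#' @param p_stop,p_cond,p_orig Thresholds as in the underlying functions.
#' @param type Trait type for colocalization priors.
#' @return List of class `signal_set`: `region`, `selected`, `datasets`
#'   (valid signals only), `validity` (full table).
#' @export
decompose_region <- function(gwas, region, ld, pad_bp = 1e5, p_stop = 1e-4,
                             p_cond = 1e-6, p_orig = 5e-8, type = "cc") {
  slice <- dplyr::filter(
    gwas, .data$CHR == region$chr,
    .data$BP >= region$start - pad_bp, .data$BP <= region$end + pad_bp
  )
  slice <- dplyr::filter(slice, .data$SNP %in% rownames(ld))
  selected <- stepwise_select(slice, ld, p_stop = p_stop)
  if (length(selected) == 0) {
    return(structure(list(region = region, selected = character(0),
                          datasets = list(), validity = validate_signals(list())),
                     class = "signal_set"))
  }
  datasets <- all_but_one(slice, ld, selected, type = type)
  validity <- validate_signals(datasets, p_cond = p_cond, p_orig = p_orig)
  structure(
    list(region = region, selected = selected,
         datasets = datasets[validity$valid], validity = validity),
    class = "signal_set"
  )
}

#' Write conditional datasets as per-signal tab-separated tables
#' @param datasets List from [all_but_one()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Written paths, invisibly.
#' @export
write_conditional_datasets <- function(datasets, dir, prefix = "signal") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(datasets, function(ds, target) {
    path <- file.path(dir, sprintf("%s_%s.tsv", prefix, target))
    con <- file(path, "w")
    writeLines(sprintf("# target=%s conditioned_on=%s", target,
                       paste(attr(ds, "conditioned_on"), collapse = ",")), con)
    utils::write.table(as.data.frame(ds), con, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    close(con)
    path
  })
  invisible(paths)
}
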
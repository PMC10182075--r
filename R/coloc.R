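#' Log approximate Bayes factor for one variant
#'
#' Wakefield's approximation: with shrinkage `r = prior_sd^2 / (prior_sd^2 +
#' se^2)` and `z = beta / se`, the log ABF for association versus no effect
#' is `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta Effect size(s).
#' @param se Standard error(s) (> 0).
#' @param prior_sd Prior standard deviation of the true effect
#'   (0.2 for case/control log-odds, 0.15 for quantitative traits by
#'   convention).
#' @return Vector of log ABFs.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

ds_beta_se <- function(x) {
  if (all(c("beta_c", "se_c") %in% names(x))) {
    list(beta = x$beta_c, se = x$se_c)
  } else if (all(c("BETA", "SE") %in% names(x))) {
    list(beta = x$BETA, se = x$SE)
  } else {
    stop("dataset needs beta_c/se_c or BETA/SE columns", call. = FALSE)
  }
}

ds_prior_sd <- function(x, default = 0.2) {
  type <- attr(x, "type") %||% "cc"
  if (identical(type, "quant")) 0.15 else default
}

#' Bayesian colocalization of two association datasets
#'
#' The standard five-hypothesis enumeration under the single-causal-variant
#' assumption, over the variants shared by the two datasets: H0 no
#' association, H1/H2 association in one dataset only, H3 two distinct
#' causal variants, H4 one shared causal variant. Per-variant evidence is
#' the Wakefield log ABF; sums are accumulated with log-sum-exp so the
#' result is overflow-safe.
#'
#' @param a,b Datasets: tibbles with SNP plus beta_c/se_c (conditional) or
#'   BETA/SE (marginal) columns; the `type` attribute ("cc"/"quant") selects
#'   the effect-size prior.
#' @param p1,p2 Prior probability a variant is causal for a only / b only.
#' @param p12 Prior probability a variant is causal for both.
#' @param min_overlap Minimum shared variants to attempt the test
#'   (default 25); fewer returns an explicit untestable result.
#' @param prior_sd_a,prior_sd_b Effect priors; default chosen from each
#'   dataset's `type` attribute.
#' @return A one-row `coloc_result` tibble: nsnps, pp0..pp4, testable.
#' @export
coloc_pair <- function(a, b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       min_overlap = 25,
                       prior_sd_a = NULL, prior_sd_b = NULL) {
  shared <- intersect(a$SNP, b$SNP)
  res <- tibble::tibble(nsnps = length(shared),
                        pp0 = NA_real_, pp1 = NA_real_, pp2 = NA_real_,
                        pp3 = NA_real_, pp4 = NA_real_, testable = FALSE)
  class(res) <- c("coloc_result", class(res))
  attr(res, "priors") <- c(p1 = p1, p2 = p2, p12 = p12)
  if (length(shared) < min_overlap) return(res)

  ia <- match(shared, a$SNP); ib <- match(shared, b$SNP)
  ba <- ds_beta_se(a); bb <- ds_beta_se(b)
  sda <- prior_sd_a %||% ds_prior_sd(a)
  sdb <- prior_sd_b %||% ds_prior_sd(b)
  l1 <- log_abf(ba$beta[ia], ba$se[ia], sda)
  l2 <- log_abf(bb$beta[ib], bb$se[ib], sdb)

  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)

  lH0 <- 0
  lH1 <- log(p1) + lsum1
  lH2 <- log(p2) + lsum2
  # sum over ordered pairs (j, k), j != k: exp(lsum1 + lsum2) - exp(lsum12)
  cross <- lsum1 + lsum2
  lH3 <- if (cross > lsum12) {
    log(p1) + log(p2) + cross + log1p(-exp(lsum12 - cross))
  } else {
    -Inf
  }
  lH4 <- log(p12) + lsum12

  lh <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lh - logsumexp(lh))
  res$pp0 <- pp[1]; res$pp1 <- pp[2]; res$pp2 <- pp[3]
  res$pp3 <- pp[4]; res$pp4 <- pp[5]
  res$testable <- TRUE
  res
}

#' Group colocalizing signals into shared loci
#'
#' Builds a graph over (trait, signal) nodes with an edge wherever PP4
#' meets `pp4_min`, and returns its connected components; each component is
#' one locus. Components whose members span at least two traits/factors are
#' labelled shared, the rest specific.
#'
#' @param results Tibble of pairwise results with columns trait_a, signal_a,
#'   trait_b, signal_b, pp4.
#' @param pp4_min Grouping threshold (default 0.9; the rule is `pp4 >=
#'   pp4_min`).
#' @param nodes Optional tibble (trait, signal) declaring all signals,
#'   including ones absent from `results`, so untested signals become
#'   singleton loci.
#' @return Tibble: trait, signal, locus (integer id), label
#'   ("shared"/"specific").
#' @export
group_signals <- function(results, pp4_min = 0.9, nodes = NULL) {
  mk <- function(trait, signal) paste(trait, signal, sep = "||")
  node_ids <- character(0)
  if (!is.null(nodes)) node_ids <- mk(nodes$trait, nodes$signal)
  if (nrow(results) > 0) {
    node_ids <- union(node_ids, c(mk(results$trait_a, results$signal_a),
                                  mk(results$trait_b, results$signal_b)))
  }
  n <- length(node_ids)
  if (n == 0) {
    return(tibble::tibble(trait = character(), signal = character(),
                          locus = integer(), label = character()))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(results) > 0) {
    edges <- results[!is.na(results$pp4) & results$pp4 >= pp4_min, , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      i <- find(match(mk(edges$trait_a[e], edges$signal_a[e]), node_ids))
      j <- find(match(mk(edges$trait_b[e], edges$signal_b[e]), node_ids))
      if (i != j) parent[j] <- i
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  locus <- match(root, unique(root))
  parts <- do.call(rbind, strsplit(node_ids, "||", fixed = TRUE))
  out <- tibble::tibble(trait = parts[, 1], signal = parts[, 2], locus = locus)
  lab <- out |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(label = if (dplyr::n_distinct(.data$trait) >= 2) "shared"
                     else "specific")
  dplyr::left_join(out, lab, by = "locus")
}

#' Colocalize factor signals with a molecular QTL
#'
#' In `decomposed` mode the QTL region is first decomposed into
#' conditionally independent signals (the eQTL route) and each QTL signal is
#' colocalized with each factor signal; in `main_effect` mode the marginal
#' QTL statistics over the region are used directly as a single dataset (the
#' pQTL route, used when no matching LD reference exists for the QTL
#' cohort).
#'
#' @param signals A `signal_set` for the factor (from [decompose_region()]).
#' @param qtl QTL summary-statistics tibble (columns SNP, CHR, BP, BETA, SE,
#'   N, FREQ).
#' @param mode `"decomposed"` or `"main_effect"`.
#' @param ld LD matrix for the region (required in decomposed mode).
#' @param pp4_min Reporting threshold stored alongside each result.
#' @param p1,p2,p12 Colocalization priors.
#' @param min_overlap Minimum shared variants.
#' @return Tibble with one row per (factor signal, QTL signal) pair:
#'   signal_factor, signal_qtl, nsnps, pp0..pp4, testable, colocalized.
#' @export
qtl_coloc <- function(signals, qtl, mode = c("decomposed", "main_effect"),
                      ld = NULL, pp4_min = 0.9,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, min_overlap = 25) {
  mode <- match.arg(mode)
  region <- signals$region
  qtl_slice <- dplyr::filter(
    qtl, .data$CHR == region$chr,
    .data$BP >= region$start - 1e5, .data$BP <= region$end + 1e5
  )
  if (nrow(qtl_slice) == 0 || length(signals$datasets) == 0) {
    out <- tibble::tibble(signal_factor = character(), signal_qtl = character(),
                          nsnps = integer(), pp0 = numeric(), pp1 = numeric(),
                          pp2 = numeric(), pp3 = numeric(), pp4 = numeric(),
                          testable = logical(), colocalized = logical())
    return(out)
  }

  if (mode == "decomposed") {
    if (is.null(ld)) stop("decomposed mode needs an LD matrix", call. = FALSE)
    qtl_slice <- dplyr::filter(qtl_slice, .data$SNP %in% rownames(ld))
    sel <- stepwise_select(qtl_slice, ld)
    if (length(sel) == 0) {
      qtl_datasets <- list()
    } else {
      qtl_datasets <- all_but_one(qtl_slice, ld, sel, type = "quant")
    }
  } else {
    ds <- qtl_slice
    attr(ds, "type") <- "quant"
    attr(ds, "target") <- "main_effect"
    qtl_datasets <- list(main_effect = ds)
  }

  purrr::imap_dfr(qtl_datasets, function(qds, qname) {
    purrr::imap_dfr(signals$datasets, function(fds, fname) {
      cc <- coloc_pair(fds, qds, p1 = p1, p2 = p2, p12 = p12,
                       min_overlap = min_overlap)
      tibble::tibble(signal_factor = fname, signal_qtl = qname,
                     nsnps = cc$nsnps, pp0 = cc$pp0, pp1 = cc$pp1,
                     pp2 = cc$pp2, pp3 = cc$pp3, pp4 = cc$pp4,
                     testable = cc$testable,
                     colocalized = isTRUE(cc$pp4 >= pp4_min))
    })
  })
}
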
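#' Compute LD scores from a reference panel
#'
#' The LD score of variant j is the sum of squared dosage correlations with
#' every variant on the same chromosome within `window_kb` kilobases
#' (including itself), each r-squared adjusted for reference-panel sampling
#' noise as `r2 - (1 - r2) / (n_ref - 2)`.
#'
#' @param panel An `ld_panel`.
#' @param window_kb Window half-width in kb (> 0).
#' @return A tibble with columns rsid, ell; attributes `m` (number of scored
#'   variants), `window_kb`, `n_ref`.
#' @export
compute_ld_scores <- function(panel, window_kb) {
  if (!is.numeric(window_kb) || window_kb <= 0) {
    stop("window_kb must be positive", call. = FALSE)
  }
  v <- panel$variants
  m <- nrow(v)
  if (m == 0) stop("empty panel", call. = FALSE)
  n <- panel$n_ref
  G <- panel$genotypes
  sds <- apply(G, 2, stats::sd)
  sds[sds == 0] <- 1
  Gs <- scale(G, center = TRUE, scale = sds)
  win <- window_kb * 1000
  ell <- numeric(m)

  for (ch in unique(v$chr)) {
    idx <- which(v$chr == ch)
    pos <- v$pos[idx]
    chunk <- 1000L
    for (a in seq(1, length(idx), by = chunk)) {
      b <- min(a + chunk - 1L, length(idx))
      lo <- findInterval(pos[a] - win, pos) + 1L
      hi <- findInterval(pos[b] + win, pos)
      r <- crossprod(Gs[, idx[a:b], drop = FALSE],
                     Gs[, idx[lo:hi], drop = FALSE]) / (n - 1)
      r2 <- r^2
      r2adj <- r2 - (1 - r2) / (n - 2)
      dmat <- abs(outer(pos[a:b], pos[lo:hi], `-`)) <= win
      ell[idx[a:b]] <- rowSums(r2adj * dmat)
    }
  }
  out <- tibble::tibble(rsid = v$rsid, ell = ell)
  attr(out, "m") <- m
  attr(out, "window_kb") <- window_kb
  attr(out, "n_ref") <- n
  out
}

# Weighted simple linear regression with an intercept plus delete-one-block
# jackknife, via per-block sufficient statistics. Returns the full-data
# (slope, intercept), the n_blocks x 2 leave-one-block-out estimates and
# jackknife SEs.
wls_jackknife <- function(y, x, w, block_id, n_blocks) {
  agg <- function(v) {
    out <- numeric(n_blocks)
    s <- tapply(v, block_id, sum)
    out[as.integer(names(s))] <- s
    out
  }
  bw <- agg(w); bwx <- agg(w * x); bwy <- agg(w * y)
  bwxx <- agg(w * x * x); bwxy <- agg(w * x * y)
  tw <- sum(bw); twx <- sum(bwx); twy <- sum(bwy)
  twxx <- sum(bwxx); twxy <- sum(bwxy)

  solve_fit <- function(sw, swx, swy, swxx, swxy) {
    den <- sw * swxx - swx^2
    if (abs(den) < 1e-12) stop("degenerate (constant) regressor", call. = FALSE)
    slope <- (sw * swxy - swx * swy) / den
    intercept <- (swy - slope * swx) / sw
    c(slope, intercept)
  }
  full <- solve_fit(tw, twx, twy, twxx, twxy)
  loo <- matrix(NA_real_, n_blocks, 2)
  for (b in seq_len(n_blocks)) {
    loo[b, ] <- solve_fit(tw - bw[b], twx - bwx[b], twy - bwy[b],
                          twxx - bwxx[b], twxy - bwxy[b])
  }
  se <- sqrt((n_blocks - 1) / n_blocks * colSums(sweep(loo, 2, colMeans(loo))^2))
  list(slope = full[1], intercept = full[2], loo = loo,
       slope_se = se[1], intercept_se = se[2])
}

ldsc_weights <- function(ell, na, nb, h2a, h2b, m) {
  ell1 <- pmax(ell, 1)
  1 / (ell1 * (1 + na * pmax(h2a, 0) * ell1 / m) *
         (1 + nb * pmax(h2b, 0) * ell1 / m))
}

chi2_keep <- function(z, n) z^2 <= pmax(80, 0.001 * n)

contiguous_blocks <- function(m, n_blocks) {
  as.integer(cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

# Core pairwise regression used by ldsc_pair and multivariable_ldsc; inputs
# already filtered and aligned. h2a/h2b feed heteroskedasticity weights.
ldsc_regress <- function(za, zb, ell, na, nb, m, block_id, n_blocks, h2a, h2b) {
  x <- ell * sqrt(na * nb) / m
  y <- za * zb
  w <- ldsc_weights(ell, na, nb, h2a, h2b, m)
  wls_jackknife(y, x, w, block_id, n_blocks)
}

#' Pairwise LD-score regression
#'
#' Regresses the product of two traits' z-scores on
#' `ell * sqrt(na * nb) / m` with an intercept. The slope estimates the total
#' genetic covariance between the traits (heritability when the two z-score
#' vectors are the same trait); the intercept absorbs population
#' stratification and sample-overlap-induced correlation. Standard errors
#' come from a delete-one-block jackknife over contiguous variant blocks.
#' Heteroskedasticity weights are applied in two passes: a first 1/ell pass
#' estimates the slope, which then feeds the standard LDSC weights.
#' Variants with chi-squared above `max(80, 0.001 N)` in either trait are
#' excluded before regression.
#'
#' @param za,zb Aligned z-score vectors.
#' @param scores LD-score tibble from [compute_ld_scores()], aligned to the
#'   z-scores.
#' @param na,nb Effective sample sizes (scalar or per-variant).
#' @param n_blocks Number of jackknife blocks (default 200).
#' @return List with slope, intercept, slope_se, intercept_se, n_used, and
#'   the leave-one-block-out estimates.
#' @export
ldsc_pair <- function(za, zb, scores, na, nb, n_blocks = 200) {
  if (length(za) != length(zb) || length(za) != nrow(scores)) {
    stop("za, zb and scores must be aligned on the same variant set", call. = FALSE)
  }
  m <- attr(scores, "m") %||% nrow(scores)
  keep <- chi2_keep(za, na) & chi2_keep(zb, nb)
  za <- za[keep]; zb <- zb[keep]
  ell <- scores$ell[keep]
  na_v <- rep_len(na, length(za)); nb_v <- rep_len(nb, length(zb))
  if (length(za) < 2 * n_blocks) {
    stop("fewer than 2 variants per jackknife block after filtering", call. = FALSE)
  }
  block_id <- contiguous_blocks(length(za), n_blocks)

  # pass 1: provisional h2 for each side with 1/ell weights
  prov <- function(z, n) {
    fit <- ldsc_regress(z, z, ell, n, n, m, block_id, n_blocks, 0, 0)
    fit$slope
  }
  h2a <- prov(za, na_v)
  h2b <- if (identical(za, zb)) h2a else prov(zb, nb_v)
  fit <- ldsc_regress(za, zb, ell, na_v, nb_v, m, block_id, n_blocks, h2a, h2b)
  fit$n_used <- length(za)
  fit
}

#' Multivariable LD-score regression
#'
#' Runs all k(k+1)/2 pairwise LD-score regressions on the variants shared by
#' every munged table and the LD scores, and estimates the joint sampling
#' covariance V of the distinct elements of the genetic covariance matrix S
#' from jointly resampled delete-one-block jackknife estimates, so
#' cross-element sampling dependence (including overlap-induced dependence)
#' is captured. Elements are ordered row-major along the lower triangle:
#' (1,1), (2,1), (2,2), (3,1), ...
#'
#' @param tables Named list of k >= 2 munged summary-statistics tibbles.
#' @param scores LD-score tibble from [compute_ld_scores()].
#' @param n_blocks Number of jackknife blocks (default 200).
#' @return An object of class `genetic_covariance`: list with `S` (k x k),
#'   `V` (sampling covariance of the distinct elements), `intercepts`
#'   (k x k), `se` (k x k elementwise jackknife SEs), `traits`, `n_blocks`,
#'   `m`, `n_variants`.
#' @export
multivariable_ldsc <- function(tables, scores, n_blocks = 200) {
  k <- length(tables)
  if (k < 2) stop("need at least two traits", call. = FALSE)
  traits <- names(tables) %||% paste0("T", seq_len(k))

  common <- Reduce(intersect, lapply(tables, function(t) t$SNP))
  common <- intersect(common, scores$rsid)
  if (length(common) == 0) stop("no shared variants across tables", call. = FALSE)

  ref <- tables[[1]][match(common, tables[[1]]$SNP), c("SNP", "CHR", "BP")]
  ord <- order(ref$CHR, ref$BP)
  common <- common[ord]

  Z <- sapply(tables, function(t) t$Z[match(common, t$SNP)])
  N <- sapply(tables, function(t) {
    n <- t$N[match(common, t$SNP)]
    if (all(is.na(n))) stop("table lacks sample sizes", call. = FALSE)
    n
  })
  ell <- scores$ell[match(common, scores$rsid)]
  m <- attr(scores, "m") %||% nrow(scores)

  keep <- rowSums(sapply(seq_len(k), function(t) !chi2_keep(Z[, t], N[, t]))) == 0
  Z <- Z[keep, , drop = FALSE]; N <- N[keep, , drop = FALSE]; ell <- ell[keep]
  n_var <- nrow(Z)
  if (n_var < 2 * n_blocks) {
    stop("fewer than 2 shared variants per jackknife block", call. = FALSE)
  }
  block_id <- contiguous_blocks(n_var, n_blocks)

  h2 <- vapply(seq_len(k), function(t) {
    ldsc_regress(Z[, t], Z[, t], ell, N[, t], N[, t], m, block_id, n_blocks, 0, 0)$slope
  }, numeric(1))

  pairs <- lower_tri_pairs(k)
  p <- nrow(pairs)
  S <- matrix(0, k, k, dimnames = list(traits, traits))
  intercepts <- matrix(0, k, k, dimnames = list(traits, traits))
  se <- matrix(0, k, k, dimnames = list(traits, traits))
  intercept_se <- matrix(0, k, k, dimnames = list(traits, traits))
  loo_all <- matrix(NA_real_, n_blocks, p)

  for (e in seq_len(p)) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    fit <- ldsc_regress(Z[, i], Z[, j], ell, N[, i], N[, j], m,
                        block_id, n_blocks, h2[i], h2[j])
    S[i, j] <- S[j, i] <- fit$slope
    intercepts[i, j] <- intercepts[j, i] <- fit$intercept
    se[i, j] <- se[j, i] <- fit$slope_se
    intercept_se[i, j] <- intercept_se[j, i] <- fit$intercept_se
    loo_all[, e] <- fit$loo[, 1]
  }
  V <- (n_blocks - 1) / n_blocks *
    crossprod(sweep(loo_all, 2, colMeans(loo_all)))

  structure(
    list(S = S, V = V, intercepts = intercepts, se = se,
         intercept_se = intercept_se, traits = traits,
         n_blocks = n_blocks, m = m, n_variants = n_var),
    class = "genetic_covariance"
  )
}

#' Genetic correlation matrix from a genetic covariance estimate
#' @param est A `genetic_covariance` object.
#' @return A k x k correlation matrix.
#' @export
rg_matrix <- function(est) {
  d <- sqrt(pmax(diag(est$S), 1e-12))
  R <- est$S / tcrossprod(d)
  diag(R) <- 1
  R
}

#' @export
print.genetic_covariance <- function(x, ...) {
  cat(sprintf("<genetic_covariance> %d traits, %d variants, %d jackknife blocks\n",
              length(x$traits), x$n_variants, x$n_blocks))
  cat("h2 (diag of S):\n")
  print(round(diag(x$S), 4))
  invisible(x)
}

#' Tidy a genetic covariance estimate into pairwise rows
#'
#' @param x A `genetic_covariance` object.
#' @param ... Unused.
#' @return A tibble with one row per trait pair (including self-pairs):
#'   trait_a, trait_b, covariance, se, rg, intercept.
#' @method tidy genetic_covariance
#' @export
tidy.genetic_covariance <- function(x, ...) {
  pairs <- lower_tri_pairs(length(x$traits))
  R <- rg_matrix(x)
  tibble::tibble(
    trait_a = x$traits[pairs[, 1]],
    trait_b = x$traits[pairs[, 2]],
    covariance = x$S[pairs],
    se = x$se[pairs],
    rg = R[pairs],
    intercept = x$intercepts[pairs]
  )
}

#' @method glance genetic_covariance
#' @export
glance.genetic_covariance <- function(x, ...) {
  tibble::tibble(
    n_traits = length(x$traits),
    n_variants = x$n_variants,
    n_blocks = x$n_blocks,
    mean_h2 = mean(diag(x$S)),
    mean_intercept = mean(diag(x$intercepts))
  )
}

#' Write a genetic covariance estimate as plain-text matrices
#'
#' Writes `S.tsv`, `V.tsv`, `intercepts.tsv` and a JSON sidecar recording
#' trait names, variant counts, block count and the element ordering.
#'
#' @param est A `genetic_covariance` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genetic_covariance <- function(est, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(est$S, file.path(dir, "S.tsv"), sep = "\t", col.names = NA)
  utils::write.table(est$V, file.path(dir, "V.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(est$intercepts, file.path(dir, "intercepts.tsv"),
                     sep = "\t", col.names = NA)
  jsonlite::write_json(
    list(traits = est$traits, n_variants = est$n_variants, m = est$m,
         n_blocks = est$n_blocks,
         element_order = "row-major lower triangle: (1,1),(2,1),(2,2),..."),
    file.path(dir, "meta.json"), auto_unbox = TRUE
  )
  invisible(dir)
}
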
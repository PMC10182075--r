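#' Simulate a block-structured LD reference panel
#'
#' Generates reference genotypes organised in mutually independent LD blocks.
#' Within a block, haplotype alleles follow a first-order Markov copy process:
#' the first variant is Bernoulli(f), and each subsequent variant copies its
#' left neighbour's allele with probability `rho` or redraws Bernoulli(f)
#' otherwise, so the haplotype correlation between variants at lag d is
#' exactly `rho^d`. A genotype is the sum of two independent haplotypes and
#' inherits the same correlation profile, giving a closed-form expected LD
#' structure for oracle tests. All variants in a block share one allele
#' frequency so the copy process preserves marginals.
#'
#' @param n_ref Number of reference individuals (>= 50).
#' @param n_blocks Number of independent LD blocks.
#' @param block_size Variants per block (>= 1).
#' @param rho AR(1) haplotype correlation parameter in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @param chr Chromosome label for all variants (single integer).
#' @param spacing_bp Base-pair spacing between adjacent variants.
#' @param maf_range Range the per-block allele frequency is drawn from.
#' @param rho_range Optional length-2 range; when given, each block draws its
#'   own AR parameter uniformly from it (overriding `rho`), which widens the
#'   spread of LD scores across the panel the way recombination-rate
#'   variation does in real genomes.
#'
#' @return An object of class `ld_panel`: a list with `genotypes` (n_ref x m
#'   dosage matrix in 0/1/2), `variants` (tibble: rsid, chr, pos, block, a1,
#'   a2, freq = generating frequency, freq_emp = empirical frequency), and
#'   `n_ref`.
#' @export
make_ld_panel <- function(n_ref, n_blocks, block_size, rho, seed,
                          chr = 1L, spacing_bp = 5000L,
                          maf_range = c(0.1, 0.5), rho_range = NULL) {
  stopifnot_scalar_count(n_ref, "n_ref")
  stopifnot_scalar_count(n_blocks, "n_blocks")
  stopifnot_scalar_count(block_size, "block_size")
  if (n_ref < 50) stop("n_ref must be >= 50", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("rho must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(rho_range) &&
      (length(rho_range) != 2L || any(rho_range < 0) || any(rho_range >= 1))) {
    stop("rho_range must be two values in [0, 1)", call. = FALSE)
  }
  set.seed(child_seed(seed, "ld_panel"))
  m <- n_blocks * block_size

  block_freq <- stats::runif(n_blocks, maf_range[1], maf_range[2])
  block_rho <- if (is.null(rho_range)) rep(rho, n_blocks) else
    stats::runif(n_blocks, rho_range[1], rho_range[2])
  geno <- matrix(0L, n_ref, m)

  sim_haplotypes <- function(f, r) {
    # n_ref haplotypes x block_size variants, Markov copy process
    h <- matrix(0L, n_ref, block_size)
    h[, 1] <- stats::rbinom(n_ref, 1L, f)
    if (block_size > 1L) {
      for (j in 2:block_size) {
        copy <- stats::runif(n_ref) < r
        fresh <- stats::rbinom(n_ref, 1L, f)
        h[, j] <- ifelse(copy, h[, j - 1L], fresh)
      }
    }
    h
  }

  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * block_size + 1L):(b * block_size)
    geno[, cols] <- sim_haplotypes(block_freq[b], block_rho[b]) +
      sim_haplotypes(block_freq[b], block_rho[b])
  }

  # non-strand-ambiguous allele pairs
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, m, replace = TRUE)

  freq_emp <- colMeans(geno) / 2
  freq_emp <- pmin(pmax(freq_emp, 1 / (4 * n_ref)), 1 - 1 / (4 * n_ref))

  # cache per-block empirical correlation and its Cholesky factor: simulation
  # replicates reuse them
  block_cor <- vector("list", n_blocks)
  block_chol <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * block_size + 1L):(b * block_size)
    R <- suppressWarnings(stats::cor(geno[, cols, drop = FALSE]))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    block_cor[[b]] <- R
    block_chol[[b]] <- tryCatch(chol(R),
                                error = function(e) chol(R + diag(1e-6, nrow(R))))
  }

  variants <- tibble::tibble(
    rsid = sprintf("rs%06d", seq_len(m)),
    chr = as.integer(chr),
    pos = as.integer(seq_len(m)) * as.integer(spacing_bp),
    block = rep(seq_len(n_blocks), each = block_size),
    a1 = pairs[pick, 1],
    a2 = pairs[pick, 2],
    freq = rep(block_freq, each = block_size),
    freq_emp = freq_emp,
    rho = rep(block_rho, each = block_size)
  )
  structure(
    list(genotypes = geno, variants = variants, n_ref = n_ref,
         rho = rho, seed = seed,
         block_cor = block_cor, block_chol = block_chol),
    class = "ld_panel"
  )
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf(
    "<ld_panel> %d reference individuals, %d variants in %d blocks (rho = %.2f)\n",
    x$n_ref, nrow(x$variants), max(x$variants$block), x$rho
  ))
  invisible(x)
}

# Per-block empirical genotype correlation matrices (the panel's in-sample LD).
panel_block_cor <- function(panel) {
  if (!is.null(panel$block_cor)) return(panel$block_cor)
  blocks <- split(seq_len(nrow(panel$variants)), panel$variants$block)
  lapply(blocks, function(cols) {
    R <- suppressWarnings(stats::cor(panel$genotypes[, cols, drop = FALSE]))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    R
  })
}

#' LD correlation matrix for a set of panel variants
#'
#' Empirical dosage correlation between the requested variants; variants in
#' different blocks are uncorrelated in expectation but the empirical values
#' are returned as-is (this is the "in-sample" reference LD used by the
#' conditional-analysis stage).
#'
#' @param panel An `ld_panel`.
#' @param rsids Variant ids; defaults to all panel variants.
#' @return A square correlation matrix with dimnames `rsids`.
#' @export
panel_ld_matrix <- function(panel, rsids = panel$variants$rsid) {
  idx <- match(rsids, panel$variants$rsid)
  if (anyNA(idx)) stop("unknown variant id(s) in `rsids`", call. = FALSE)
  G <- panel$genotypes[, idx, drop = FALSE]
  R <- suppressWarnings(stats::cor(G))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  dimnames(R) <- list(rsids, rsids)
  R
}

#' Specify the true generative factor model behind a simulated study
#'
#' Bundles the trait-by-factor loading matrix, factor correlation matrix,
#' residual genetic variances, per-variant effects on factors (gamma) and
#' directly on traits (delta, the part that violates the common-factor
#' model), effective sample sizes, and the sample-overlap structure that
#' induces correlated z-score errors.
#'
#' @param loadings k x f matrix of standardized-scale loadings (rownames =
#'   trait names).
#' @param factor_cov f x f factor correlation/covariance matrix.
#' @param residual_var Length-k residual genetic variances (diagonal of Theta).
#' @param trait_neff Length-k effective sample sizes.
#' @param snp_factor_effects m x f matrix of per-variant factor effects
#'   (standardized-genotype scale).
#' @param snp_direct_effects m x k matrix of per-variant direct trait effects.
#' @param overlap_frac k x k matrix of shared-sample fractions (diag 1).
#' @param overlap_cor k x k phenotypic correlation among shared samples.
#'
#' @return An object of class `true_model`.
#' @export
true_model <- function(loadings, factor_cov, residual_var, trait_neff,
                       snp_factor_effects, snp_direct_effects,
                       overlap_frac = NULL, overlap_cor = NULL) {
  loadings <- as.matrix(loadings)
  factor_cov <- as.matrix(factor_cov)
  k <- nrow(loadings)
  G <- loadings %*% factor_cov %*% t(loadings) + diag(residual_var, k)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("implied genetic covariance is not positive semi-definite", call. = FALSE)
  }
  if (is.null(overlap_frac)) overlap_frac <- diag(k)
  if (is.null(overlap_cor)) overlap_cor <- diag(k)
  err_cor <- overlap_frac * overlap_cor
  diag(err_cor) <- 1
  structure(
    list(
      loadings = loadings, factor_cov = factor_cov,
      residual_var = residual_var, trait_neff = trait_neff,
      snp_factor_effects = as.matrix(snp_factor_effects),
      snp_direct_effects = as.matrix(snp_direct_effects),
      err_cor = err_cor, implied_cov = G
    ),
    class = "true_model"
  )
}

#' Draw polygenic per-variant effects consistent with a factor structure
#'
#' Per-variant factor effects gamma_j ~ N(0, Phi / m) and direct effects
#' delta_tj ~ N(0, Theta_tt / m) on the standardized-genotype scale, so the
#' total genetic covariance contributed by all m variants equals
#' `loadings %*% factor_cov %*% t(loadings) + diag(residual_var)`.
#'
#' @param m Number of variants.
#' @param factor_cov f x f factor covariance.
#' @param residual_var Length-k residual variances.
#' @param seed Integer seed.
#' @return List with `gamma` (m x f) and `delta` (m x k).
#' @export
draw_polygenic_effects <- function(m, factor_cov, residual_var, seed) {
  set.seed(child_seed(seed, "polygenic"))
  f <- nrow(as.matrix(factor_cov))
  k <- length(residual_var)
  Lf <- chol(as.matrix(factor_cov) / m)
  gamma <- matrix(stats::rnorm(m * f), m, f) %*% Lf
  delta <- matrix(stats::rnorm(m * k), m, k) %*% diag(sqrt(pmax(residual_var, 0) / m), k)
  list(gamma = gamma, delta = delta)
}

#' Simulate multi-trait GWAS summary statistics under a known factor model
#'
#' Joint standardized effects `b = gamma %*% t(loadings) + delta` are
#' propagated through the panel's in-sample LD to marginal effects; z-scores
#' are `sqrt(N_eff) * R b` plus correlated noise whose within-trait
#' correlation is the LD matrix and whose cross-trait correlation equals the
#' overlap-induced error correlation. Effects are simulated on the
#' standardized-genotype scale and converted once to the allele-dosage scale
#' in the output tables (`BETA = z * SE`, `SE = 1/sqrt(N * 2f(1-f))`).
#'
#' @param panel An `ld_panel`.
#' @param model A `true_model` whose effect matrices have one row per panel
#'   variant.
#' @param seed Integer seed.
#' @param trait_names Optional trait names (default T1..Tk).
#' @return List with `sumstats` (named list of per-trait tibbles with columns
#'   SNP, CHR, BP, A1, A2, BETA, SE, P, N, FREQ) and `truth` (per-variant
#'   tibble with true effects and a label: null / factor-consistent /
#'   trait-specific / heterogeneous).
#' @export
simulate_multitrait_sumstats <- function(panel, model, seed,
                                         trait_names = NULL) {
  m <- nrow(panel$variants)
  k <- nrow(model$loadings)
  if (nrow(model$snp_factor_effects) != m || nrow(model$snp_direct_effects) != m) {
    stop("model effect matrices must have one row per panel variant", call. = FALSE)
  }
  if (is.null(trait_names)) trait_names <- paste0("T", seq_len(k))
  set.seed(child_seed(seed, "multitrait"))

  b <- model$snp_factor_effects %*% t(model$loadings) + model$snp_direct_effects

  # propagate joint -> marginal through in-sample LD, block by block
  Rblocks <- panel_block_cor(panel)
  blocks <- split(seq_len(m), panel$variants$block)
  bmarg <- b
  noise <- matrix(stats::rnorm(m * k), m, k)
  Le <- tryCatch(chol(model$err_cor),
                 error = function(e) chol(model$err_cor + diag(1e-8, k)))
  chols <- panel$block_chol
  for (bi in seq_along(blocks)) {
    rows <- blocks[[bi]]
    R <- Rblocks[[bi]]
    bmarg[rows, ] <- R %*% b[rows, , drop = FALSE]
    # within-block LD-correlated noise
    LR <- if (!is.null(chols)) chols[[bi]] else
      tryCatch(chol(R), error = function(e) chol(R + diag(1e-6, nrow(R))))
    noise[rows, ] <- t(LR) %*% noise[rows, , drop = FALSE]
  }
  noise <- noise %*% Le

  zmat <- sweep(bmarg, 2, sqrt(model$trait_neff), `*`) + noise

  f <- panel$variants$freq_emp
  v <- panel$variants
  sumstats <- stats::setNames(lapply(seq_len(k), function(t) {
    se <- 1 / sqrt(model$trait_neff[t] * 2 * f * (1 - f))
    z <- zmat[, t]
    tibble::tibble(
      SNP = v$rsid, CHR = v$chr, BP = v$pos, A1 = v$a1, A2 = v$a2,
      BETA = z * se, SE = se, P = two_sided_p(z),
      N = model$trait_neff[t], FREQ = f
    )
  }), trait_names)

  has_gamma <- rowSums(abs(model$snp_factor_effects)) > 0
  n_direct <- rowSums(abs(model$snp_direct_effects) > 0)
  label <- dplyr::case_when(
    !has_gamma & n_direct == 0 ~ "null",
    !has_gamma & n_direct == 1 ~ "trait-specific",
    has_gamma & n_direct == 0 ~ "factor-consistent",
    TRUE ~ "heterogeneous"
  )
  truth <- tibble::tibble(
    rsid = v$rsid, chr = v$chr, pos = v$pos, label = label
  )
  gcols <- as.data.frame(model$snp_factor_effects)
  names(gcols) <- paste0("gamma_F", seq_len(ncol(gcols)))
  dcols <- as.data.frame(model$snp_direct_effects)
  names(dcols) <- paste0("delta_", trait_names)
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(gcols), tibble::as_tibble(dcols))

  list(sumstats = sumstats, truth = truth)
}

#' Simulate molecular-QTL summary statistics with a single causal variant
#'
#' @param panel An `ld_panel`.
#' @param shared_with rsid of the causal variant, or `"none"` for pure noise.
#' @param effect Standardized causal effect size.
#' @param n QTL study sample size.
#' @param seed Integer seed.
#' @return A summary-statistics tibble (same columns as GWAS tables).
#' @export
simulate_qtl_sumstats <- function(panel, shared_with, effect, n, seed) {
  m <- nrow(panel$variants)
  b <- numeric(m)
  if (!identical(shared_with, "none")) {
    j <- match(shared_with, panel$variants$rsid)
    if (is.na(j)) stop("unknown variant id: ", shared_with, call. = FALSE)
    b[j] <- effect
  }
  set.seed(child_seed(seed, "qtl"))
  Rblocks <- panel_block_cor(panel)
  blocks <- split(seq_len(m), panel$variants$block)
  bmarg <- b
  noise <- stats::rnorm(m)
  chols <- panel$block_chol
  for (bi in seq_along(blocks)) {
    rows <- blocks[[bi]]
    R <- Rblocks[[bi]]
    bmarg[rows] <- drop(R %*% b[rows])
    LR <- if (!is.null(chols)) chols[[bi]] else
      tryCatch(chol(R), error = function(e) chol(R + diag(1e-6, nrow(R))))
    noise[rows] <- drop(t(LR) %*% noise[rows])
  }
  z <- sqrt(n) * bmarg + noise
  f <- panel$variants$freq_emp
  se <- 1 / sqrt(n * 2 * f * (1 - f))
  v <- panel$variants
  tibble::tibble(
    SNP = v$rsid, CHR = v$chr, BP = v$pos, A1 = v$a1, A2 = v$a2,
    BETA = z * se, SE = se, P = two_sided_p(z), N = n, FREQ = f
  )
}

#' Write summary statistics, truth tables, and LD panels as plain text
#'
#' @param x A summary-statistics tibble, truth tibble, or `ld_panel`.
#' @param path Output file (for `ld_panel`, a path prefix: writes
#'   `<path>_genotypes.tsv` and `<path>_variants.tsv`).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
write_ld_panel <- function(x, path) {
  stopifnot(inherits(x, "ld_panel"))
  utils::write.table(x$genotypes, paste0(path, "_genotypes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  readr::write_tsv(x$variants, paste0(path, "_variants.tsv"))
  invisible(path)
}

#' Read a summary-statistics table written by [write_sumstats()]
#' @param path File path.
#' @return A tibble.
#' @export
read_sumstats <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
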
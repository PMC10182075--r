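# Independent oracle implementations used by unit and acceptance tests.

# brute-force reference: test every split point explicitly
brute_regions <- function(gwas, p_seed = 1e-6, gap_kb = 250, p_sig = 5e-8) {
  out <- list()
  for (ch in sort(unique(gwas$CHR))) {
    g <- gwas[gwas$CHR == ch, ]
    g <- g[order(g$BP), ]
    seeds <- g[g$P < p_seed, ]
    if (nrow(seeds) == 0) next
    cur <- list(start = seeds$BP[1], end = seeds$BP[1])
    flush <- function(cur) {
      inside <- g[g$BP >= cur$start & g$BP <= cur$end, ]
      out[[length(out) + 1]] <<- tibble::tibble(
        chr = ch, start = cur$start, end = cur$end,
        significant = any(inside$P < p_sig))
    }
    if (nrow(seeds) > 1) {
      for (i in 2:nrow(seeds)) {
        if (seeds$BP[i] - seeds$BP[i - 1] > gap_kb * 1000) {
          flush(cur); cur <- list(start = seeds$BP[i], end = seeds$BP[i])
        } else cur$end <- seeds$BP[i]
      }
    }
    flush(cur)
  }
  dplyr::bind_rows(out)
}

# Individual-level oracle: summary statistics computed from simulated
# genotypes, then COJO-style conditional results compared with exact OLS.
make_cohort <- function(seed, n = 2000, n_blocks = 20, block_size = 10,
                        causal = integer(0), effects = numeric(0)) {
  panel <- make_ld_panel(n_ref = n, n_blocks = n_blocks,
                         block_size = block_size, rho = 0.8, seed = seed)
  G <- panel$genotypes
  set.seed(seed + 1)
  y <- rnorm(n)
  for (i in seq_along(causal)) {
    y <- y + effects[i] * scale(G[, causal[i]])[, 1]
  }
  y <- scale(y)[, 1]
  marg <- t(vapply(seq_len(ncol(G)), function(j) {
    summary(lm(y ~ G[, j]))$coefficients[2, 1:2]
  }, numeric(2)))
  stats <- tibble::tibble(
    SNP = panel$variants$rsid, CHR = panel$variants$chr,
    BP = panel$variants$pos, BETA = marg[, 1], SE = marg[, 2], N = n,
    FREQ = colMeans(G) / 2, P = 2 * pnorm(-abs(marg[, 1] / marg[, 2]))
  )
  R <- suppressWarnings(cor(G))
  dimnames(R) <- list(stats$SNP, stats$SNP)
  list(panel = panel, G = G, y = y, stats = stats, R = R)
}

mk_ds <- function(beta, se, snps = paste0("v", seq_along(beta)), type = "cc") {
  ds <- tibble::tibble(SNP = snps, CHR = 1L, BP = seq_along(beta),
                       beta_c = beta, se_c = se)
  attr(ds, "type") <- type
  ds
}

# independent probability-space enumeration for small variant counts
brute_coloc <- function(b1, s1, b2, s2, p1, p2, p12, sd1 = 0.2, sd2 = 0.2) {
  abf1 <- exp(log_abf(b1, s1, sd1))
  abf2 <- exp(log_abf(b2, s2, sd2))
  m <- length(b1)
  h0 <- 1
  h1 <- p1 * sum(abf1)
  h2 <- p2 * sum(abf2)
  h3 <- 0
  for (j in 1:m) for (k in 1:m) if (j != k) h3 <- h3 + p1 * p2 * abf1[j] * abf2[k]
  h4 <- p12 * sum(abf1 * abf2)
  pp <- c(h0, h1, h2, h3, h4)
  pp / sum(pp)
}

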
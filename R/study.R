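#' Simulate the bundled nine-trait, three-factor synthetic study
#'
#' Generates a complete study with known ground truth: nine case/control
#' traits organised in three genetic factors (a gut-inflammation group CD,
#' UC, PSC; a systemic-autoimmunity group T1D, SLE, JIA, RA; an allergy
#' group AST, ECZ), a polygenic background consistent with the factor
#' structure, and planted loci of four kinds: factor-consistent loci acting
#' through a single factor, cross-factor loci acting through two factors,
#' trait-specific (factor-violating) loci acting directly on one trait, and
#' molecular-QTL links in which an eQTL or pQTL shares (or does not share) a
#' planted causal variant.
#'
#' Per-trait heritability is `h2`, of which a fraction `communality` acts
#' through the trait's factor; factor correlations default to 0.25; all
#' traits are simulated at the same effective sample size with a mild
#' sample-overlap-induced error correlation.
#'
#' @param seed Integer seed controlling every stage.
#' @param n_blocks,block_size,n_ref,rho,rho_range LD-panel dimensions (see
#'   [make_ld_panel()]); by default each block draws its own AR parameter
#'   from `rho_range`.
#' @param h2 Per-trait total heritability (default 0.3).
#' @param communality Fraction of h2 mediated by the factor (default 0.7).
#' @param factor_cor Between-factor correlation (default 0.25).
#' @param neff Per-trait effective sample size (default 10000).
#' @param overlap_frac,overlap_cor Pairwise shared-sample fraction and
#'   phenotypic correlation among shared samples.
#' @param gamma_plant Planted factor-level effect size (standardized scale).
#' @param delta_plant Planted direct (factor-violating) effect size.
#' @param eqtl_n,pqtl_n QTL study sample sizes.
#' @param eqtl_effect,pqtl_effect QTL causal effect sizes (standardized).
#' @return A list of class `sim_study`: panel, model, sumstats (named list),
#'   truth, planted (tibble describing each planted locus), qtls (named
#'   list of QTL tables with `qtl_mode` attributes), reference, traits,
#'   factors, loading_patterns (candidate model specs).
#' @export
simulate_study <- function(seed,
                           n_blocks = 450, block_size = 20, n_ref = 500,
                           rho = 0.85, rho_range = c(0.3, 0.95),
                           h2 = 0.3, communality = 0.7, factor_cor = 0.25,
                           neff = 10000,
                           overlap_frac = 0.1, overlap_cor = 0.2,
                           gamma_plant = 0.25, delta_plant = 0.12,
                           eqtl_n = 1000, pqtl_n = 35000,
                           eqtl_effect = 0.5, pqtl_effect = 0.15) {
  traits <- c("CD", "UC", "PSC", "T1D", "SLE", "JIA", "RA", "AST", "ECZ")
  factors <- c("F1", "F2", "F3")
  membership <- c(CD = 1, UC = 1, PSC = 1, T1D = 2, SLE = 2, JIA = 2, RA = 2,
                  AST = 3, ECZ = 3)
  k <- length(traits)

  lambda <- sqrt(communality * h2)
  L <- matrix(0, k, 3, dimnames = list(traits, factors))
  L[cbind(seq_len(k), membership)] <- lambda
  Phi <- matrix(factor_cor, 3, 3); diag(Phi) <- 1
  resid <- rep((1 - communality) * h2, k)

  panel <- make_ld_panel(n_ref, n_blocks, block_size, rho, seed,
                         rho_range = rho_range)
  m <- n_blocks * block_size

  # gamma ~ N(0, Phi/m) so that factor-mediated covariance sums to L Phi L'
  eff <- draw_polygenic_effects(m, Phi, resid, seed)
  clear_neighbourhood <- function(block) {
    nb <- intersect((block - 2L):(block + 2L), seq_len(n_blocks))
    rows <- unlist(lapply(nb, function(b) ((b - 1L) * block_size + 1L):(b * block_size)))
    eff$gamma[rows, ] <<- 0
    eff$delta[rows, ] <<- 0
  }

  # planted loci: one per chosen block, at the block's central variant,
  # blocks spaced >= 5 apart so regions stay distinct
  center_of <- function(block) (block - 1L) * block_size + ceiling(block_size / 2)
  plant_blocks <- seq(10L, n_blocks - 10L, by = 15L)
  need <- 12 + 2 + 3 + 2
  if (length(plant_blocks) < need) stop("panel too small for planted loci", call. = FALSE)

  planted <- list()
  pi <- 0L
  take_block <- function() { pi <<- pi + 1L; plant_blocks[pi] }

  # 4 factor-consistent loci per factor; the first F1 and first F2 locus get
  # a QTL partner later
  for (f in 1:3) {
    for (rep in 1:4) {
      b <- take_block(); j <- center_of(b)
      clear_neighbourhood(b)
      sgn <- if (f == 3 && rep == 1) -1 else 1   # one protective QTL target
      eff$gamma[j, f] <- sgn * gamma_plant
      planted[[length(planted) + 1L]] <- tibble::tibble(
        rsid = panel$variants$rsid[j], block = b, type = "factor",
        factor = factors[f], trait = NA_character_,
        effect = sgn * gamma_plant
      )
    }
  }
  # 2 cross-factor loci (F1 + F2)
  for (rep in 1:2) {
    b <- take_block(); j <- center_of(b)
    clear_neighbourhood(b)
    eff$gamma[j, 1:2] <- gamma_plant
    planted[[length(planted) + 1L]] <- tibble::tibble(
      rsid = panel$variants$rsid[j], block = b, type = "cross-factor",
      factor = "F1+F2", trait = NA_character_, effect = gamma_plant
    )
  }
  # 3 trait-specific (factor-violating) loci
  for (tr in c("CD", "RA", "AST")) {
    b <- take_block(); j <- center_of(b)
    clear_neighbourhood(b)
    eff$delta[j, match(tr, traits)] <- delta_plant
    planted[[length(planted) + 1L]] <- tibble::tibble(
      rsid = panel$variants$rsid[j], block = b, type = "trait-specific",
      factor = NA_character_, trait = tr, effect = delta_plant
    )
  }
  planted <- dplyr::bind_rows(planted)

  of <- matrix(overlap_frac, k, k); diag(of) <- 1
  oc <- matrix(overlap_cor, k, k); diag(oc) <- 1
  model <- true_model(
    loadings = L, factor_cov = Phi, residual_var = resid,
    trait_neff = rep(neff, k),
    snp_factor_effects = eff$gamma, snp_direct_effects = eff$delta,
    overlap_frac = of, overlap_cor = oc
  )
  sim <- simulate_multitrait_sumstats(panel, model, seed, trait_names = traits)
  # background variants carry small polygenic gamma and delta draws; only the
  # planted rows get a semantic label
  sim$truth$label <- "polygenic"
  sim$truth$label[match(planted$rsid, sim$truth$rsid)] <-
    ifelse(planted$type == "factor", "factor-consistent",
           ifelse(planted$type == "cross-factor", "factor-consistent",
                  "trait-specific"))

  # QTL partners:
  #  - eQTL sharing the first F1 locus's causal variant (MR: predisposing)
  #  - eQTL sharing the first F3 locus's causal variant (protective factor
  #    effect, so MR direction is negative)
  #  - eQTL with a causal variant in LD distance of the second F1 locus but
  #    distinct from it (should NOT colocalize)
  #  - pQTL sharing the first F2 locus's causal variant (main-effect route)
  f1_first <- planted$rsid[planted$type == "factor" & planted$factor == "F1"][1]
  f1_second <- planted$rsid[planted$type == "factor" & planted$factor == "F1"][2]
  f2_first <- planted$rsid[planted$type == "factor" & planted$factor == "F2"][1]
  f3_first <- planted$rsid[planted$type == "factor" & planted$factor == "F3"][1]
  # distinct variant: 6 positions away in the same block as f1_second
  j2 <- match(f1_second, panel$variants$rsid)
  distinct_rsid <- panel$variants$rsid[j2 + 6L]

  qtls <- list(
    eqtl_shared = simulate_qtl_sumstats(panel, f1_first, eqtl_effect, eqtl_n,
                                        child_seed(seed, "eqtl1")),
    eqtl_protective = simulate_qtl_sumstats(panel, f3_first, eqtl_effect,
                                            eqtl_n, child_seed(seed, "eqtl2")),
    eqtl_distinct = simulate_qtl_sumstats(panel, distinct_rsid, eqtl_effect,
                                          eqtl_n, child_seed(seed, "eqtl3")),
    pqtl_shared = simulate_qtl_sumstats(panel, f2_first, pqtl_effect, pqtl_n,
                                        child_seed(seed, "pqtl1"))
  )
  qtl_meta <- tibble::tibble(
    qtl = names(qtls),
    mode = c("decomposed", "decomposed", "decomposed", "main_effect"),
    causal_rsid = c(f1_first, f3_first, distinct_rsid, f2_first),
    target_factor = c("F1", "F3", "F1", "F2"),
    shares_causal = c(TRUE, TRUE, FALSE, TRUE),
    true_direction = c("predisposing", "protective", NA, "predisposing"),
    gene = c("GENE1", "GENE2", "GENE3", "PROT1"),
    cell_type = c("Tcell", "Bcell", "Tcell", "plasma")
  )

  loading_patterns <- list(
    "1-factor" = list(F1 = traits),
    "2-factor" = list(F1 = c("CD", "UC", "PSC", "T1D", "SLE", "JIA", "RA"),
                      F2 = c("AST", "ECZ")),
    "3-factor" = list(F1 = c("CD", "UC", "PSC"),
                      F2 = c("T1D", "SLE", "JIA", "RA"),
                      F3 = c("AST", "ECZ"))
  )

  structure(
    list(panel = panel, model = model, sumstats = sim$sumstats,
         truth = sim$truth, planted = planted, qtls = qtls,
         qtl_meta = qtl_meta, reference = panel_reference(panel),
         traits = traits, factors = factors, membership = membership,
         loading_patterns = loading_patterns, seed = seed),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d traits, %d variants, %d planted loci, %d QTLs (seed %d)\n",
              length(x$traits), nrow(x$truth), nrow(x$planted),
              length(x$qtls), x$seed))
  invisible(x)
}
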
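# Shared fixtures, built once per test run and cached.
fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, expr, envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# mid-sized panel with heterogeneous LD for simulation-based checks
shared_panel <- function() {
  fixture("panel", make_ld_panel(n_ref = 500, n_blocks = 500, block_size = 20,
                                 rho = 0.85, seed = 11))
}

shared_scores <- function() {
  fixture("scores", compute_ld_scores(shared_panel(), window_kb = 100))
}

# the bundled synthetic study and a full pipeline run over it
shared_run <- function() {
  fixture("run", run_pipeline(pipeline_config(seed = 3)))
}

# two-trait polygenic simulation on the shared panel (h2 = 0.3, rg = 0.5)
two_trait_sim <- function(seed, h2 = 0.3, rg = 0.5, neff = 2e4) {
  panel <- shared_panel()
  m <- nrow(panel$variants)
  Phi <- matrix(c(1, rg, rg, 1), 2, 2)
  eff <- draw_polygenic_effects(m, Phi, c(0, 0), seed = seed)
  mod <- true_model(diag(sqrt(h2), 2), Phi, c(0, 0), trait_neff = rep(neff, 2),
                    snp_factor_effects = eff$gamma,
                    snp_direct_effects = matrix(0, m, 2))
  simulate_multitrait_sumstats(panel, mod, seed = seed + 5000)
}

null_model <- function(panel, k = 2, overlap_frac = NULL, overlap_cor = NULL) {
  m <- nrow(panel$variants)
  true_model(matrix(0, k, 1), matrix(1), rep(0, k), rep(1e4, k),
             snp_factor_effects = matrix(0, m, 1),
             snp_direct_effects = matrix(0, m, k),
             overlap_frac = overlap_frac, overlap_cor = overlap_cor)
}

zscores <- function(tbl) tbl$BETA / tbl$SE
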
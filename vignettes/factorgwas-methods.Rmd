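---
title: "Methods: latent-factor GWAS from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-factor GWAS from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `factorgwas`, the
choices made where the design was genuinely open, and what the synthetic
study does and does not demonstrate about real data.

## The pipeline at a glance

Nine case/control GWAS (summary statistics only) are harmonized against a
reference-variant table, their genetic covariance matrix `S` and its
sampling covariance `V` are estimated by multivariable LD-score regression,
a confirmatory factor model is fitted to `(S, V)`, each variant's effect on
the latent factors is estimated with a heterogeneity (Q_SNP) test, and the
factor-level association landscape is decomposed into regions, conditionally
independent signals, colocalization groups, QTL links and Wald-ratio
Mendelian-randomization effects.

## Harmonization

`munge()` keeps reference variants only, drops strand-ambiguous (A/T, C/G)
pairs, resolves orientation through allele complements, flips the sign of
`z` and `beta` when the allele pair is swapped, removes variants with a zero
effect size **or** zero standard error (both are formatting artefacts of
public summary files), applies a minor-allele-frequency floor of 1%, and
recomputes `p` from the harmonized `z` so every downstream threshold acts on
one consistent scale (the incoming p-value is kept as an audit column).
MAF uses the study frequency when present and the reference frequency
otherwise. Dropping ambiguous variants is the conservative convention for
summary-data harmonization; with them retained, a strand error would flip
effect signs silently. Case/control sample sizes enter as summed effective
sample sizes `Σ_c 4 v_c (1 − v_c) N_c`.

## LD scores and LD-score regression

LD scores are computed from the bundled reference panel with a 100 kb
window and the small-sample adjustment `r² − (1 − r²)/(n_ref − 2)`. The
window is matched to the simulated LD-block span (about 100 kb); real
analyses on dense human panels conventionally use ~1 Mb or 1 cM windows, and
`window_kb` is exposed in the configuration.

The pairwise regression uses the canonical heteroskedasticity weights
`1/(ℓ (1 + N_a h²_a ℓ/m)(1 + N_b h²_b ℓ/m))`, applied in two passes (a
`1/ℓ` pass supplies the provisional slopes). Variants with
`χ² > max(80, 0.001 N)` are excluded before regression — the standard
guard against single-locus leverage. Standard errors and the joint sampling
covariance `V` come from a delete-one-block jackknife over 200 contiguous
equal-count variant blocks; all trait pairs share one block partition so `V`
captures cross-element dependence, including the part induced by sample
overlap. Heritability is reported on the observed scale under the
effective-sample-size convention (implied prevalence 1/2); no liability
transformation is applied.

The cross-trait intercept estimates the correlation of z-score errors
(sample overlap × phenotypic correlation). At desk-scale panel sizes each
intercept is individually noisy, so before the intercept matrix is used as
an error-correlation in the SNP-level machinery it is shrunk elementwise by
its jackknife sampling variance (`I·I²/(I²+se²)`), clamped to `[-1, 1]` and
projected to a positive-definite correlation matrix (eigenvalue floor 0.05).
Without the projection the implied GLS weight matrix can be indefinite.

## Factor model

`fit_wls()` minimizes `(s − σ(θ))ᵀ W (s − σ(θ))` over the distinct elements
of `S`, with `W = diag(V)⁻¹` by default (full-`V` weighting behind a flag).
Factors have unit variance, so loadings are directly standardized paths;
factor correlations are parameterized through `tanh` to stay in (−1, 1);
residual variances are unconstrained and negative estimates (Heywood cases)
are flagged, never clamped. Optimization runs BFGS from two deterministic
starts (moderate and high communality) and is polished by damped
Gauss–Newton steps, which is what makes the noiseless-recovery contract
(loadings to 1e-6, fit statistic ~1e-29) attainable; ties between starts
break by start order. If `S` is not positive definite it is first projected
to the nearest PSD matrix (eigenvalue floor 1e-6) and the fit records that
smoothing occurred.

The fit statistic is the WLS quadratic form at the optimum with
`df = k(k+1)/2 − n_free`; CFI compares it with the independence baseline
(free diagonal only) using the `max(·, 0)` clamps, and SRMR is the
root-mean-square of residuals standardized by the observed diagonal.
Candidate models are screened at CFI > 0.95 and SRMR < 0.10; among
survivors the fewest factors win, and interpretability exclusions (e.g. a
four-factor model that splits one trait across two factors) must be declared
by name — they are never inferred. Parameter standard errors use the
sandwich formula with the full `V`.

## Factor GWAS and Q_SNP

For each variant the per-trait effects `β` (dosage scale) are regressed on
the fixed loading matrix by GLS with weight `Σ⁻¹`, where
`Σ_tu = se_t se_u C_tu` and `C` is the shrunk intercept-derived error
correlation: `γ̂ = (ΛᵀΣ⁻¹Λ)⁻¹ ΛᵀΣ⁻¹β`. The measurement model is held at the
genome-wide fit — re-estimating loadings per variant would cost a factor of
the genome for no stated benefit. Q_SNP is the fit-statistic difference
between this common-pathway model and the saturated independent-pathways
model, which reduces to the residual quadratic form
`(β − Λγ̂)ᵀΣ⁻¹(β − Λγ̂)` with `df = k − n_factors` (the omnibus form: one
test per variant rather than one per factor; the per-factor alternative
would partition the same residual). With `Σ` known this is exactly
chi-squared under the null; in the bundled calibration study the empirical
rejection rate at α = 0.05 is ~0.05 when the true error correlation is
supplied and inflates mildly (~0.07 at these panel sizes) when `C` must be
estimated from the intercepts — the acceptance check therefore supplies the
known correlation so it measures the statistic, and the inflation under
estimated `C` is a documented desk-scale limitation that shrinks with panel
size. The factor tables carry an implied per-variant sample size
`1/(2f(1−f)·se²)`, the quantity the conditional-analysis algebra consumes.

## Regions, conditional signals

Region definition chains seed variants (p < 1e-6) per chromosome and splits
at gaps strictly greater than 250 kb; regions count as significant when any
member variant reaches p < 5e-8. Significance is assessed per GWAS first
and overlapping significant regions are then merged across GWAS with
transitive closure — filtering before merging keeps a merged region from
inheriting significance it owes to no single GWAS; any region
overlapping chr6:25–35 Mb by at least one base is excluded.

Signal decomposition works on the marginal-correlation scale: the exact
`t`-to-`r` map `r = z/√(n − 2 + z²)` converts marginal statistics to
correlations, joint and conditional coefficients are `R⁻¹ r` over the chosen
variant set with residual-variance-based standard errors
(`df = n − |set| − 1`), and results are rescaled to the input effect scale
through the per-variant ratio of marginal standard errors. With in-sample
LD this reproduces exact multiple regression to machine precision — the
module's central oracle. Forward selection starts at the smallest marginal
p-value and stops when all conditional p-values exceed 1e-4 (the entry
threshold equals the stopping threshold; a separate entry threshold would
contradict a single stopping rule). Candidates with r² > 0.9 against the
selected set are skipped, singular LD submatrices drop the offending
candidate with a warning, and variants whose summary frequency differs from
the reference by more than 0.2 are dropped. Regions are padded by ±100 kb
before selection. "All-but-one" datasets recondition every region variant
on the selected set minus the target; a signal is valid if its minimum
conditional p is below 1e-6 (the conditional reading of the rule; the
dataset-minimum is used rather than any single variant's marginal value) or
the variant attaining it has marginal p below 5e-8.

## Colocalization and MR

Per-variant evidence is the Wakefield log approximate Bayes factor
`½(log(1 − r) + r z²)` with `r = sd² / (sd² + se²)`; the effect-size prior
sd is 0.2 for case/control (log-odds) datasets and 0.15 for quantitative
QTL datasets, and the hypothesis priors are `p1 = p2 = 1e-4, p12 = 1e-5` —
the cited framework's conventions, all exposed in the configuration. The
five-hypothesis enumeration runs in log space with log-sum-exp; fewer than
25 shared variants yields an explicit "untestable" result rather than a
silent null. Conditional datasets (not raw marginals) are the substrate for
GWAS and eQTL signals; the marginal route exists for pQTLs, where no
matching LD reference is assumed. Signals with PP4 ≥ 0.9 are grouped by
connected components; a group touching two or more factors is a shared
locus, and only signal pairs within overlapping regions are tested (testing
all genome-wide pairs would multiply the comparisons without a shared-locus
interpretation). Wald-ratio MR runs only on colocalizing pairs, uses the
QTL signal's minimum conditional-p variant as the instrument, the
first-order delta-method standard error (standard for single instruments),
and reports raw p-values at 0.05 with a predisposing/protective label from
the sign; multiple-testing correction is left to the user.

## The synthetic study

`simulate_study()` generates the ground-truth world: a block-structured LD
panel (haplotypes follow a Markov copy process, so the lag-d correlation is
exactly `rho^d` and every oracle has a closed form; each block draws its AR
parameter from 0.3–0.95, giving the spread of LD scores that real
recombination-rate variation produces), nine traits in three factor groups
with standardized loadings √0.21, factor correlations 0.25 and per-trait
h² = 0.3 at effective sample size 10,000, 10% pairwise sample overlap with
phenotypic correlation 0.2, and planted loci: four factor-consistent loci
per factor (γ = 0.25), two cross-factor loci, three trait-specific
(factor-violating) loci (δ = 0.12), and four QTL partners (two eQTLs sharing
planted causal variants with opposite effect directions, one eQTL with a
deliberately distinct causal variant in the same region, one pQTL handled by
the main-effect route). Sample sizes and effect sizes are chosen so planted
signals sit far above genome-wide significance (|z| ≈ 11–17) while the
polygenic background stays mostly below it, the regime in which the
locus-level contracts are meaningful. Two-block neighbourhoods around
planted loci carry no background effects, so each planted locus is the only
signal in its region and its classification (specific vs shared,
colocalizing vs not) has an unambiguous truth.

Simulation happens directly at the summary-statistics level: joint
standardized effects are propagated through the panel's in-sample LD,
multiplied by `√N_eff`, and perturbed by noise whose within-trait
correlation is the LD matrix and whose cross-trait correlation is the
overlap-induced value. Case/control traits are therefore represented by
their effective sample size rather than by liability-threshold sampling —
cheaper by orders of magnitude, and exactly the scale the estimators
consume. The within-factor SNP-effect correlation is not fixed by the
generator: per-variant factor effects are drawn with covariance `Φ/m`, and
callers can supply any effect matrix. Effects are specified on the
standardized-genotype scale and converted once, centrally, to the dosage
scale in the output tables.

What passing tests show — and do not show. The generator reproduces the
features the estimators rely on (LD-proportional inflation,
factor-structured covariance, overlap-correlated errors, single causal
variants for QTLs). It does not model imputation error, allele-frequency–
dependent architecture, population stratification, mismatched LD references,
X-chromosome dosage, or liability-scale subtleties, so a green suite
demonstrates internal correctness of the machinery at desk scale, not
robustness to those real-data complications.

## Problem sizes and numerical choices

The bundled study uses 9,000 variants (450 blocks × 20) with 500 reference
individuals; LD-score-regression recovery checks use a 20,000-variant panel
with 50 replicates; the conditional-analysis oracle uses 2,000 individuals
× 200 variants; the region oracle uses 1,000 random tracks. These sizes
keep the full pipeline around ten seconds and the complete validation suite
within minutes on one CPU while leaving every estimator in its intended
regime. Degenerate inputs are handled explicitly: empty regions return
empty selections, an all-variants-removed munge warns with a dedicated
condition class, constant LDSC regressors and misaligned tables are errors,
negative Q_SNP statistics (numerically possible at ~1e-16) are clamped to
zero with a warning counter, and ties in stepwise selection break by
smaller p then lower position, making every stage deterministic given its
seed.
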
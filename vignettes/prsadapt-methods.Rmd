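---
title: "Testing for local adaptation with polygenic scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for local adaptation with polygenic scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsadapt)
```

## The question and the statistical design

Local adaptation — allele-frequency change driven by environment-specific
selective pressure — should leave a polygenic footprint: if a trait's
genetic architecture has responded to, say, winter temperature, then a
polygenic score (PRS) for that trait, computed in individuals sampled
across an environmental gradient, should co-vary with the environment at
the sampling sites beyond what neutral demography explains.

`prsadapt` implements that test as a reusable pipeline:

1. **QC**: minor allele frequency ≥ 1%, per-marker missingness ≤ 5%,
   per-individual missingness ≤ 5%, exact Hardy–Weinberg test p > 10⁻⁴.
2. **Ancestry PCs** on the LD-pruned panel (pruning at r² < 0.2,
   50-variant windows advancing by 5), Patterson-normalized.
3. **C+T PRS**: GWAS summary statistics are harmonized to the panel,
   the MHC is excluded (26–34 Mb on chromosome 6, configurable),
   p-value-informed clumping is applied (r² cutoff 0.3 in a 500-kb
   window, i.e. a ±250-kb radius around each index variant), and scores
   are computed at twelve inclusion thresholds
   (5×10⁻⁸ … 1).
4. **Association**: each environmental variable is Box–Cox normalized,
   broadcast from sites to individuals, and regressed on each PRS with
   the top ancestry PCs as covariates. The grid of trait × variable ×
   threshold cells receives Benjamini–Hochberg FDR control, permutation
   validation (PRS shuffled across individuals), a robustness re-fit at a
   deeper PC adjustment compared via a Clogg-type coefficient test, and a
   conditional "driver" analysis among correlated variables.
5. **Enrichment**: the concordant variants behind a significant cell are
   mapped to genes through eQTL links and tested for term enrichment
   (upper-tail hypergeometric, BH-corrected), with an empirical null from
   100 SNP sets matched on MAF (±5 percentage points), gene density
   (±50%), distance to nearest gene (±50%, 5-kb slack at zero), and
   LD-buddy count (±50%, slack 1 at zero).
6. **NOIA**: oligogenic signals (cells with ≤ 3 index variants) are
   re-modeled with the statistical (genotype-frequency-orthogonal) NOIA
   parameterization to verify that additive effects, not dominance or
   epistasis artifacts, carry the association.

Every stage is exposed as a function; `run_pipeline()` orchestrates them
with a config object, deterministic seeding, TSV outputs and a JSON
manifest, and a thin command-line driver is installed under
`inst/cli/prsadapt.R`.

## The synthetic cohort generator

Real inputs for this design — a genotyped multi-population cohort and
consortium GWAS summary statistics — are not redistributable, so the
package ships a generator (`simulate_study()`) that reproduces the
*statistical structure* the analysis relies on:

* **Population structure** by the Balding–Nichols construction: ancestral
  frequencies p₀ ~ U(0.05, 0.95); per-site frequencies
  Beta(p₀(1−F)/F, (1−p₀)(1−F)/F). The default F = 0.01 with 23 sites ×
  100 individuals mirrors a low-differentiation, continental-scale
  cohort. A Hudson-type ratio-of-averages estimator on the truth
  frequencies recovers F.
* **LD** by a latent Gaussian copula: within blocks of 25 consecutive
  variants, haplotype-level latent normals follow an AR(1) with
  correlation 0.8, thresholded at the site-specific frequency quantile.
  This gives controllable, rapidly decaying r² — what clumping and
  pruning need — without the cost of a coalescent simulation; it does not
  attempt recombination-map realism.
* **Variant spacing**: exponential gaps with 6-kb mean on 22 chromosomes,
  so a 500-kb clumping window spans several LD blocks.
* **Traits and GWAS**: each trait draws 200 causal variants with effects
  N(0, 0.05²); summary statistics use the standard GWAS noise model
  se = 1/√(2·n·p₀(1−p₀)) at n = 50,000 with two-sided Wald p-values. A
  10% fraction of rows is emitted with swapped allele labels to force the
  harmonization step to work.
* **Selection** (`apply_selection_gradient()`): per causal variant j and
  site k, p_k ← clip(p_k + s·β_j·z_k, 0.01, 0.99), with z the
  standardized driver variable. The default s = 0.5 together with the
  default effect scale yields mean per-causal-variant shifts of ≈ 0.02
  per SD of environment. This frequency-shift model is a synthetic truth
  for testing recovery, not a claim about any real population's history.
* **Environment**: one row per site, multivariate normal with a
  configurable correlation matrix; the default five variables include a
  0.75-correlated pair, matching the strength of inter-correlation
  typical of climate variable panels, so the driver analysis has
  realistic confounding to untangle.
* **Annotation**: non-overlapping gene intervals, eQTL links biased
  toward the nearest gene, random term memberships, and (optionally) one
  planted enriched term whose genes preferentially receive eQTL links
  from causal variants.

What the generator does **not** emulate: admixture, migration,
bottlenecks, phased haplotypes, strand ambiguity (alleles are abstract
labels; A/T–C/G handling exists but is exercised synthetically), sex
chromosomes, and relatedness. Tests passing on this generator therefore
validate the statistical machinery, not robustness to those features of
real data.

## Pseudo-replication and the two association modes

Environmental variables are properties of sites, broadcast to
individuals. Individual-level OLS on a site-constant outcome is
pseudo-replicated: the information content lives in the 22-dimensional
between-site space (23 sites), not in the 2,300 individuals. Under the
Balding–Nichols null all 22 between-site drift directions have equal
strength, so a 10-PC (or 20-PC) adjustment removes only part of the
between-site PRS variance and the PRS t-statistic is over-dispersed,
rejecting the null well above its nominal level. Even with
K = n_sites − 1 estimated PCs a residual inflation remains, because the
PCs are estimated from a finite panel and the leftover angle between the
estimated and true drift subspaces leaves between-site PRS variance
unadjusted.

`prs_env_grid()` therefore offers two modes:

* `mode = "individual"` (default) reproduces the conventional design
  (site values broadcast to individuals, PC-adjusted OLS). It is the
  convention practitioners will recognize, and its mild anti-conservatism
  under strong structure is a property of that design, preserved
  deliberately and documented here.
* `mode = "site"` averages the PRS and PC scores per site and regresses
  the site-level variable on them. Under the global null the response is
  then independent across its rows and independent of the design, so the
  PRS t-test is *exactly* calibrated conditional on any cohort — at the
  price of residual degrees of freedom (23 − K − 2).

The validation experiments (`experiment_null_calibration()`,
`experiment_power()`) run the site mode with K = 10: calibration is exact
there, and the planted selection gradient of the default magnitude is
still detected decisively (see `experiment_power()`). We recommend the
site mode whenever the outcome is purely site-level.

Because the site-mode test is exactly calibrated conditional on the
cohort, the calibration experiment replicates over the axis that actually
drives the null distribution — independent environment draws — reusing
each simulated cohort's expensive stages (QC, PCA, clumping, scoring)
across 40 environment redraws in 4 cohort replicates. Cells sharing an
environment draw or neighboring inclusion thresholds are strongly
correlated, so the Kolmogorov–Smirnov uniformity check runs on a
conditionally independent subsample (first trait, full-inclusion
threshold, mutually uncorrelated variables, one cell per environment
draw); the all-cell KS statistic is also reported, but its iid assumption
fails by construction on a C+T grid.

The 10-vs-20-PC robustness comparison (`compare_pc_models()`) uses a
Clogg-type statistic (β₁ − β₂)/√(|se₂² − se₁²| + ε) for nested covariate
sets; published analyses of this kind report such comparisons without
naming a test, so this choice is documented here as the package's own.

## Numerical and procedural choices

* **Filter order** in QC (variant missingness → individual missingness →
  MAF → HWE) is fixed and reported so removal counts are reproducible;
  the HWE test is exact (mid-anchored ratio recursion, numerically safe
  for cohort-scale counts) and pooled across sites, which is flagged in
  the report since a per-site test is a defensible alternative.
* **LD statistic**: composite r² on unphased dosages over
  pairwise-complete observations; zero-variance pairs are defined as
  r² = 0 with a flag. Window scans (pruning, clumping, LD-buddy counts)
  use a banded computation (`ld_r2_band()`) that reproduces `ld_r2()`
  exactly via chunked cross-products.
* **Pruning drop rule**: within a window, the lower-MAF member of an
  offending pair is dropped (tie: larger position) — deterministic, and
  verified against a brute-force sweep.
* **Clumping ties** on equal GWAS p-values break by chromosome then
  position; clumping is performed once and thresholds are applied to the
  index set afterwards, the standard C+T behavior.
* **Scores** are raw weighted sums with mean-imputed missing dosages
  (2p̂). Sum versus average only rescales each column by a constant;
  the association Z is invariant to affine rescaling, which the tests
  assert. Empty threshold columns are reported as zeros with
  `n_snps = 0` and excluded from FDR rather than failing the grid.
* **Box–Cox**: shift 1 − min for non-positive variables, profile
  likelihood maximized on [−5, 5] to 10⁻⁵, |λ| < 10⁻⁸ treated as log.
* **Permutation p** uses the add-one estimator (1 + #{|z_b| ≥ |z_obs|}) /
  (B + 1); refits use Frisch–Waugh–Lovell residualization, which equals
  the full-OLS t exactly and makes B = 10,000 routine.
* **FDR scope**: BH over all grid cells by default; a best-cell-per-pair
  scope is provided since reports are often organized around per-pair
  best associations. The scope changes q only, never p, and is recorded.
* **Matching tolerances**: MAF ±5 percentage points; the other three
  properties relative ±50% with absolute slack at zero (5 kb for
  distance, 1 for buddy counts). Candidates are drawn uniformly without
  replacement within a set, scarcer pools first; a `relax` switch doubles
  all tolerances once.
* **NOIA** uses the statistical formulation with genotype frequencies
  from the analyzed (complete-genotype) individuals, which makes the
  additive/dominance columns exactly orthogonal in-sample; up to three
  loci with full product-structure epistasis terms.

## Validation experiments and problem sizes

The packaged experiments define the scales at which the pipeline's
statistical claims are verified:

* `experiment_null_calibration()`: 23 × 100 cohorts, 20,000 variants,
  3 traits × 5 variables × 12 thresholds under s = 0; 4 cohort replicates
  × 40 environment draws; raw cell p-values are checked for uniformity
  (on the independent subsample described above), the 5% rejection rate
  is tracked over all cells, and permutation p (B = 1,000) is
  rank-compared with parametric p across the first replicate's cells.
* `experiment_power()`: 20 replicates at a reduced scale (23 × 50, 4,000
  variants, 10 chromosomes, one trait) with the default selection
  gradient; detection = driver's best cell at q < 0.05 with the planted
  sign; an uncorrelated variable serves as negative control.
* `experiment_enrichment()`: one selection replicate with and without the
  planted term; 100 matched sets form the empirical null. With a single
  planted term the observed significant-term count is 1, so the matched
  empirical p has a floor set by the null per-set rate of single-term
  false positives (a few percent); the experiment demonstrates detection
  at that granularity rather than an arbitrarily small p.

These sizes were chosen to exercise the same regimes as the full design
(many blocks per clumping window, polygenic and oligogenic thresholds,
low per-variant information) while remaining desk-scale. The
`scripts/acceptance.R` entry point re-runs all of them from scratch.

## Known limitations

* The generator's LD has no long-range structure, so MHC-style complex
  regions are represented only by the exclusion rule, never stress-tested.
* Pooled HWE filtering in a structured cohort relies on differentiation
  being weak (Wahlund heterozygote deficit is negligible at F ≈ 0.01);
  at high F the filter would need a per-site variant. A corollary worth
  knowing: a locus under *very* strong planted selection becomes so
  differentiated across sites that the pooled exact test removes it
  during QC — the filter can eat exactly the loci the analysis is
  hunting, which is one reason the whole-score test is more robust than
  any single locus.
* The incremental R² reported for the PRS term is the linear-model R²
  gain; reports derived from logistic-style software often label the
  analogous quantity "Nagelkerke's R²" — the column here is named
  `r2_incremental` to avoid implying that formula.
* Permutation shuffles the PRS across individuals, matching the design
  it validates; it therefore tests exchangeability of scores given the
  covariate structure, not site-level exchangeability.
* The concordance rule for enrichment selection tests each variant in
  the target cohort (dosage vs transformed environment, PC-adjusted);
  testing in the training GWAS instead would be a different, defensible
  reading and is not implemented.
```
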
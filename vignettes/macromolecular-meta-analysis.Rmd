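---
title: "Hierarchical meta-analysis of microalgal macromolecular composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical meta-analysis of microalgal macromolecular composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phycomacro estimates the macromolecular composition of microalgae — protein,
lipid, carbohydrate, ash, RNA, DNA and chlorophyll-a, as percent dry weight
(%DW) or mass per cell — from measurements compiled across many independent
culture studies, and converts composition into predicted molar C:N. This
vignette is the package's own account of the statistical model, the
harmonization rules, the stoichiometric constants, and the design choices
that were genuinely open.

## The data problem

Literature compilations of algal composition are severely unbalanced: a
handful of aquaculture and biofuel species contribute dozens to hundreds of
observations while most species contribute one or two, and phyla differ by
an order of magnitude in coverage. A pooled mean would be dominated by
*Isochrysis* and *Chaetoceros*; per-species means would give a one-off
measurement the same weight as a deeply replicated one. The package
therefore treats the data as a three-level hierarchy and partially pools
across its levels.

## The model

For observations $y_i$ of one response (a %DW pool, or the natural log of a
within-study mass ratio),

$$y_i = \mu + P_{p[i]} + S_{s[i]} + \varepsilon_i,$$

where $P_j$ and $S_j$ are normally distributed phylum and species effects
and $\varepsilon_i \sim N(0, \sigma_\varepsilon^2)$ is residual
(within-species, across-study) error. Three separate scales are estimated:
$\sigma_P$ (among phyla), $\sigma_S$ (among species within phyla), and
$\sigma_\varepsilon$. `fit_hierarchical()` samples the posterior with an
in-package Gibbs sampler using **hierarchical centering**: species means
$\theta_s \sim N(\phi_{p[s]}, \sigma_S^2)$, phylum means
$\phi_p \sim N(\mu, \sigma_P^2)$, and a weakly informative location
$\mu \sim N(\bar y, (10\,s_y)^2)$. Centering keeps the chain identified
without sum-to-zero constraints; the overall mean is *not* taken from $\mu$
but recomputed downstream (below).

**Priors.** Each SD has an independent half-Cauchy$(0, 5\,s_y)$ prior,
where $s_y$ is the sample SD of the response — a conventional weakly
informative choice for hierarchical scale parameters that behaves well when
a level has few groups (seven phyla at best, two in habitat contrasts). The
prior scale enters through the data only via $s_y$, so responses on any
unit are handled identically. Location updates are conditionally conjugate;
the SDs are updated by slice sampling on $\log\sigma$ (stepping-out plus
shrinkage), which is rejection-free and needs no tuning.

**Sampler settings.** The `"paper"` preset runs 4 chains of 50,000
iterations, discards the first half and keeps every 5th draw. The `"test"`
preset keeps the same fractions at 5,000 iterations; for this conjugate-ish
model mixing is excellent (split-R-hat below 1.01, effective sample sizes
in the thousands) and the whole 7-phylum protein fit takes well under a
second. Convergence is always reported (`diagnose()`): split-R-hat and a
Geyer-truncated effective sample size per monitored parameter, plus
structural notes when a level is weakly identified (single phylum, single
species, or one observation per species).

**Determinism.** All randomness flows through R's RNG, chains are run
sequentially from a single seed, and observations are internally sorted by
(species, value) so floating-point reductions — and hence the draws — are
bit-identical under input row permutations.

## Posterior summaries

* **HDI.** All intervals are highest-density intervals: the shortest
  contiguous window containing $\lceil 0.95\,n \rceil$ sorted draws, found
  by exhaustive search, ties broken toward the lower window. `hdi()`
  requires only two finite draws mechanically, but intervals are only
  meaningful from a few dozen draws upward; fits here summarize 2,000+.
* **Grand mean.** The hierarchy does not identify an overall mean, so the
  pan-microalgae estimate is the inverse-variance-weighted combination of
  phylum means: weights $w_j = 1/\mathrm{Var}(\phi_j)$ fixed from each
  phylum's marginal posterior, applied draw-wise so the grand draw retains
  full uncertainty. Sparse phyla excluded from phylum comparisons
  (Euglenozoa, Rhodophyta) still contribute here.
* **Contrasts.** Phylum differences are formed draw-wise; a pair differs
  "significantly" when the 95% HDI of the difference excludes zero. No
  p-values and no multiplicity correction are computed — the posterior
  differences are the inference.
* **Variance decomposition.** Reported as
  $100\,\hat\sigma_k^2 / (\hat\sigma_P^2+\hat\sigma_S^2+\hat\sigma_\varepsilon^2)$
  from the posterior *median* SDs, matching single-number reporting; a
  draw-wise version is available via `variance_decomposition(drawwise = TRUE)`.
* **Ratios.** Protein:carbohydrate, protein:lipid and carbohydrate:lipid
  are formed only within a measurement cell — same study, species, culture
  system, growth phase, nutrient status and basis — never across studies or
  bases. Cells with replicate indices pair replicate-wise, otherwise cell
  means are used (both supported; which one the original compilation used
  is not knowable from the outside). Ratios are modeled on the natural log
  scale and back-transformed; since the back-transform inverts the same
  base, results are base-invariant.

## Protein harmonization

Nitrogen-based protein estimates assume protein is 16% N (factor 6.25
g protein per g N) and that all cellular N is protein. Eukaryotic
microalgae hold substantial non-protein N (mostly inorganic pools), so
N-derived values are systematically high; `correct_protein()` rescales them
by 4.78/6.25 for all eukaryotic phyla, leaving Cyanobacteria — which store
N as protein and peptides — uncorrected. The original value and applied
factor are retained as audit columns, which also makes the operation
idempotent. `stratify_protein_method()` exposes the four analysis strata
(peptide assays, N-derived raw, N-derived corrected, pooled).

## Stoichiometric C:N

`profile_cn()` converts a %DW profile to molar C:N with per-pool C and N
mass fractions (`elemental_constants()`): protein at the canonical
53% C / 16% N; storage lipid as triacylglycerol (76% C, no N);
phospholipid as dipalmitoylphosphatidylcholine (including its choline N);
carbohydrate as glucose-equivalent; RNA and DNA as residue-averaged
polymerized nucleotides; chlorophyll-a from C~55~H~72~MgN~4~O~5~. Total
lipid is split 2/3 phosphorus-free / 1/3 phospholipid before conversion.
The ratio is invariant to uniform rescaling (profiles need not sum to
100) and ash never enters.

Two choices were genuinely open and were fixed by calibration against
independently published phylum-level C:N values, with both options kept as
arguments:

* **Protein source.** N-derived protein is circular in an elemental
  computation (it *is* measured N), so `predict_phylum_cn()` defaults to
  the peptide/amino-acid stratum medians. This choice reproduces all seven
  published phylum C:N values within ±0.13; pooled protein misses the
  Dinophyta by ~0.5.
* **Missing pools.** Phyla lacking RNA/DNA/chlorophyll estimates have
  those pools dropped from the sums by default; imputation from the grand
  medians is available (`missing = "impute"`) but pulls C:N down by up to
  0.7 for the diatoms and dinoflagellates and calibrates worse.

## The synthetic generator

`generate_dataset()` draws data from the generative reading of the model:
phylum and species effects from their normal distributions, residual noise
per observation, %DW values truncated at zero (truncation rate reported,
warning above 10%). Defaults encode the protein study conditions: grand
location 32.2 %DW; $\sigma_P = 5.6$ (the SD of the seven phylum-level
protein medians); $\sigma_S = 6.2$ and $\sigma_\varepsilon = 7.2$ obtained
by scaling the reported 42/31/25 within-species / among-species /
among-phyla variance split to that among-phyla component. The
`"table3_protein"` design reproduces the unbalanced per-phylum observation
totals (25/75/16/82/76/19/22) with Zipf-allocated species coverage; 37% of
protein rows are flagged N-derived (the observed share), and eukaryotic
flagged rows are stored pre-inflated by 6.25/4.78 through the same
floating-point path the harmonizer inverts, so correction recovers the
model-scale values bit-exactly.

What the generator does *not* emulate: method- and lab-specific extraction
biases (beyond the N-conversion factor), non-normal tails, correlations
between pools within a cell, and covariate structure (temperature,
irradiance, media). Passing recovery tests therefore demonstrate that the
estimator is calibrated for the assumed data-generating process, not that
real compilations satisfy those assumptions.

`recovery_experiment()` wraps the loop: across seeded replicates (fresh
effects each time) it reports bias, RMSE and empirical 95%-HDI coverage
for the three SDs and the phylum means. At the shipped defaults (100
replicates, 2 chains × 2,000 iterations per fit — about 15 s total)
coverage sits at 94–97% for all parameter groups.

## Numerical choices and degenerate inputs

* SDs are floored at $10^{-9} s_y$ inside the sampler so conditionals stay
  proper when a sum of squares is exactly zero (e.g. constant data, which
  correctly yields phylum medians at the constant and residual scale near
  zero).
* With a constant response ($s_y = 0$) prior scales fall back to
  $\max(|\bar y|, 1)$.
* Initialization is data-derived (group sample means, pooled SDs), jittered
  per chain by $0.1\,s_y$.
* Fixing any subset of $\{\mu, \sigma_P, \sigma_S, \sigma_\varepsilon\}$
  (`fix =`) turns off the corresponding update; this is how the test suite
  checks the sampler against closed-form conjugate posteriors.
* Zero denominators in ratio cells are skipped and counted, never fatal;
  rows failing schema invariants are rejected with named reasons at load.

## Problem sizes used by the automated checks

The test suite runs everything at reduced-but-honest sizes chosen for a
single CPU: fits at 2–4 chains of 1,000–10,000 iterations, the calibration
study at 100 replicates of the 315-observation 7-phylum design, and
exhaustive-search HDI cross-checks up to 2,000 draws. The `"paper"` preset
(4 × 50,000) is what the full-database analyses use; on the curated
database each such fit completes in seconds.

## Limitations

* The model assumes normal effects and residuals on the measurement scale;
  %DW truncation at zero is handled in the generator but not in the
  likelihood (values near zero are rare in the curated regimes).
* Habitat contrasts reuse the same hierarchy with habitat replacing the
  phylum level within a phylum; this is an interpretation of a two-group
  comparison, not a uniquely determined structure.
* Species-level posterior medians are computed but carry very wide
  uncertainties in sparse designs; they are exposed for diagnostics
  (`shrinkage_check()`), not headline reporting.
* The C:N predictor depends on fixed, idealized elemental constants;
  composition-dependent variation in lipid classes or protein amino-acid
  composition is not modeled.
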
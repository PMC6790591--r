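---
title: "geascan: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{geascan: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind geascan, every tunable
parameter that matters, the numerical choices, what the synthetic-data
generator does and does not emulate, and the design decisions that were
genuinely open.

## 1. The association model

A genome–environment association (GEA) scan asks, for every genetic variant
and every environmental variable, whether variant carriage co-varies with
the environment across sampled individuals — the expected footprint of
environmentally driven selection. geascan follows the presence/absence
formulation: each biallelic SNP contributes **three binary indicators**, one
per diploid genotype class (homozygous reference, heterozygous, homozygous
alternate). An indicator `y` is modelled against an environmental variable
`x` by logistic regression,

$$\mathrm{logit}\, P(y_i = 1) = \beta_0 + \gamma^\top \mathrm{pop}_i + \beta_1 x_i,$$

and compared with the nested null model that omits `x` but keeps the
population-structure covariates `pop` (the "parent" model; with no
population covariates the null is the constant model). Two statistics are
reported per model:

* **G** (likelihood ratio): $G = 2(\ell_{full} - \ell_{null})$;
* **Wald**: $\hat\beta_1^2 / \widehat{SE}^2$, or the quadratic form
  $\hat b^\top \hat V^{-1} \hat b$ over several environmental coefficients.

Both are asymptotically $\chi^2$ with one degree of freedom per
environmental variable, which is how `add_significance()` converts them to
p-values. Storey q-values estimate the FDR across the scan; Bonferroni is
available for the conservative reading. The correction universe defaults to
**per environmental variable** (each variable's Manhattan plot is corrected
over its own tests); `global_m = TRUE` corrects over the whole
indicator × variable product instead.

Modelling the three genotype classes separately (rather than a dosage trend)
lets dominant, recessive and heterotic responses surface independently; the
cost is that the three tests per SNP are strongly dependent, which the
per-SNP aggregation in power analyses (min p per SNP) acknowledges.

## 2. Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `maf_min` | `qc_thresholds()` | 0.05 | rare variants give unstable logistic fits; the conventional chip-QC floor |
| `missing_max` | `qc_thresholds()` | 0.1 | per-SNP missing-call ceiling, conventional |
| `ld_r2_max` | `qc_thresholds()` | `"off"` for the scan; 0.2 before PCA | association scans keep all markers; PCA needs approximately independent loci |
| `ld_window` | `qc_thresholds()` | 50 SNPs | index-window pruning, standard practice scale |
| `r2_threshold` | `prune_correlated()` | 0.9 | drop near-duplicate climate layers (r² > 90%) |
| `n_components` | `pca_structure()` | 3 | inspect the variance-explained profile before choosing how many to carry |
| `k` | `neighbor_weights()` | 10 nearest | local-Moran neighbourhood; great-circle distances |
| `permutations` | `local_moran()` | 999 | conditional-permutation pseudo-p resolution of 1/1000 |
| `score_min` | `filter_for_plot()` | 6 | display cut-off (χ²₁ p ≈ 0.014) thinning the null bulk |
| `threshold` | `manhattan_plot()` | 0.05 | the significance line |

Units: coordinates are degrees (WGS84); positions are 1-based base pairs;
`radius_km` neighbourhoods use kilometres.

## 3. Numerical choices

* **Fitting.** Newton/IRLS on the Bernoulli log-likelihood, intercept
  started at `logit(mean(y))`, others at 0. Convergence requires both
  |Δlog-likelihood| < 1e-10 and max |Newton step| < 1e-8 (the second
  condition is what brings the Wald statistic to oracle agreement below
  1e-6; the log-likelihood alone converges one iteration earlier than the
  coefficients). Cap: 100 iterations.
* **Separation.** Presence/absence indicators of rare genotype classes
  frequently separate. Coefficients are clipped at ±35 to keep the
  likelihood finite; any |β| > 30 or SE > 1000 flags the fit `separated`.
  Scores are still reported with the flag rather than dropped — downstream
  consumers can filter, and silently losing rare-genotype models would bias
  a scan. A Fisher information that turns singular mid-iteration on a
  full-rank design is classified as separation, not degeneracy.
* **Complete cases per model.** Samples missing the indicator or any
  modelled variable are dropped for that model only; `n` in the result row
  records the count. Simplest defensible rule; no imputation inside the
  test.
* **Degenerate inputs.** Constant indicators (absent genotype classes) and
  constant environmental columns are `skipped` with no scores; rank-deficient
  designs are `degenerate`.
* **G truncation.** Converged nested fits satisfy G ≥ 0 up to roundoff;
  p-values use `max(G, 0)`.
* **Storey π₀.** Estimated on the λ grid 0.05…0.95 (step 0.05) with a cubic
  smoothing spline (df = 3) evaluated at λ = 1, clipped to (0, 1]; with
  fewer than 100 p-values the λ = 0.5 plug-in is used instead. Forcing
  π₀ = 1 reproduces Benjamini–Hochberg exactly, which the tests assert to
  1e-12.
* **PCA standardisation.** Missing dosages imputed to the per-SNP mean;
  columns centred by 2p̂ and scaled by √(2p̂(1−p̂)) (Patterson-style; a
  `scale = "unit"` switch gives unit variance). Scores are projections on
  the eigenvectors of the sample covariance; monomorphic columns are
  dropped.
* **Local Moran.** The indicator is standardised with the *population*
  standard deviation, so the average of the local statistics equals global
  Moran's I exactly under row-standardised weights (asserted to 1e-10).
  Pseudo-p is two-sided conditional permutation with a fixed seed. Because a
  binary indicator gives the permuted statistic a coarse discrete support,
  pseudo-p values can shift between affinely recoded inputs when a permuted
  value ties the observed one to the last bit; the statistic itself is
  affine-invariant.
* **UTM projection.** Closed-form transverse Mercator series (WGS84,
  k₀ = 0.9996), accurate to well under 1e-6 degrees round-trip within a
  zone. Only EPSG:4326 and UTM 326xx/327xx are supported — there is no PROJ
  engine in the dependency set, and failing loudly beats a wrong datum.

## 4. The synthetic-data generator

`simulate_dataset()` produces the stated world the tests run in:

* samples clustered around K deme centres on a ~10° × 10° rectangle;
* an environmental gradient `env1` linear in longitude with Gaussian noise
  (sd 0.3 on a unit-range gradient) and a pure-noise variable `env2`;
* neutral SNPs: ancestral frequency U(0.05, 0.95), per-deme frequencies
  Balding–Nichols Beta with variance F·p(1−p), genotypes Binomial(2, p);
* adaptive SNPs: presence of the homozygous-alt class is Bernoulli with
  probability `plogis(β0 + β1·z(env1))` — exactly the model class the scan
  fits, which makes parameter recovery a fair oracle; β0 defaults to
  `logit(0.3)`;
* uniform per-call dropout at the missing rate (2% default).

Presets: `null` (300 samples, 500 neutral SNPs, no structure), `adaptive`
(500 samples, 500 neutral + 1 adaptive, β1 = 2), `structured` (two demes,
F = 0.15).

What it does **not** emulate: linkage disequilibrium between loci (LD tests
use planted duplicate columns instead), coalescent ancestry, isolation by
distance within demes, genotyping-batch artefacts, or environmental
measurement error beyond additive noise. A green power test therefore shows
the engine recovers its own model class planted in structured noise — not
that any field dataset behaves this way.

## 5. Design decisions that were genuinely open

* **PED allele mapping.** PED carries no reference designation; the first
  allele encountered in file order becomes "ref". Dosages, and hence MAF and
  the scan, are unaffected by the labelling; indicator labels are.
* **LD drop rule.** Standard tooling does not document which SNP of a
  high-LD pair is dropped; geascan always drops the downstream
  (higher-position) SNP and rescans until stable, making the output
  deterministic and re-scan-clean within the window.
* **Correlation-filter scale.** The environmental filter applies the
  threshold to r², not |r|, matching the "r² higher than 90%" convention of
  chip-era studies; keep-first greedy order makes the retained set
  deterministic and documented.
* **Membership formula.** Cluster membership from PCA scores uses inverse
  squared Euclidean distance to the k-means centroids, row-normalised, with
  coincident points assigned membership 1. This is a concrete stand-in for
  distance-based soft assignment, satisfying the contract (rows sum to 1,
  centroid limit) without claiming to reproduce any particular published
  variant.
* **Structure inclusion is manual.** The user inspects `varexp` and decides
  which score columns (or memberships) become covariates; no automatic
  elbow rule. A panmictic dataset shows a flat profile (first components
  nearly equal) and warrants none; clear structure shows PC1 well above PC2.
* **Parallelism is a merge contract.** `run_scan()` chunks indicators and
  may fork workers, but results are merged in fixed (indicator, variable)
  order and the TSV writer formats with fixed precision, so 1 worker and
  4 workers produce byte-identical files — asserted in the acceptance suite.
* **Raster input is text-only.** ESRI ASCII grid is the supported raster
  format; without a GDAL binding, parsing binary GeoTIFF in R would be a
  liability, and `gdal_translate -of AAIGrid` is a one-line conversion.

## 6. Known limitations

* Univariate environmental testing in the CLI happy path; the API accepts
  several environmental variables per model but env × env interaction
  models are out of scope.
* No HWE, IBD or kinship filtering — dedicated tools (plink, vcftools) do
  this better upstream.
* No nonsynonymous/consequence calling: context classification stops at
  genic/upstream/downstream/intergenic; consequence prediction needs
  transcript models and codon tables.
* The χ² reference for G is asymptotic; with very rare genotype classes
  (post-QC counts of a few carriers) the null is conservative-to-erratic,
  and the separated flag should be taken seriously when interpreting tails.
* q-values assume a well-behaved p-value distribution under the null; with
  strong unmodelled structure, Bonferroni on G is the safer report.

Every empirical statement above is computed by the test suite
(`tests/testthat/`, acceptance criteria in `test-acceptance.R`) or by
`scripts/acceptance.R`; the vignette reports nothing the code does not
measure.
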
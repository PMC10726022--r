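---
title: "Quantitative genetics of yearling buffalo growth and carcass traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of yearling buffalo growth and carcass traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bufgen` implements the full analysis chain used for pedigree-based genetic
evaluation of body-size and in-vivo ultrasound carcass traits in a yearling
water-buffalo cohort: age standardization of repeated field measurements,
fixed-effect least-squares adjustment, animal-model REML with a maternal
genetic effect, breeding-value prediction, derived genetic parameters and
selection responses, and candidate-SNP association on adjusted phenotypes.
This vignette documents the models, the numerical choices, and what the
synthetic-herd validation does and does not establish.

## The data situation

The analysis targets a single birth-year cohort (~313 calves across ~36
smallholder farms) with repeated body measurements bracketing 365 days of
age, eleven traits (body weight BW; wither height WH; rump height RH; body
length BL; chest width CW; hip width HW; chest circumference CC; cannon-bone
circumference CBC; ultrasound longissimus muscle area LMA and depth LMD;
subcutaneous fat thickness SFT), and PCR-RFLP genotypes at candidate loci
near *PLAG1*, *NCAPG*, *LCORL* and *HMGA2*.  The raw records are not
publicly deposited, so the package ships (a) the published per-trait
estimates as plain data builders (`buffalo_variance_components()` and
friends), which are legitimate inputs for the deterministic downstream
calculations, and (b) a synthetic-herd generator that reproduces the assumed
statistical structure so that every estimation stage can be validated by
parameter recovery.

## Age standardization

Field measurements are taken on farm-visit dates, not on birthdays.  Each
animal's trait value at 365 d is obtained by two-point linear interpolation
between the flanking measurements, or linear extrapolation from the two
measurements nearest the target when 365 d falls outside the observed range
(`value_at_age()`).  Linearity over a window of a few months is the standard
assumption for yearling growth; the kernel sits behind a single function so
a nonlinear growth curve could be swapped in.  `standardize_table()` records
the extrapolation distance per cell and flags (but keeps) cells extrapolated
more than 90 d — a QC threshold, not a filter, chosen so that a typical
two-visit schedule is never discarded silently.

## Fixed-effects model and adjusted phenotypes

The environmental model is purely additive:

$$y_{ijklmn} = \mu + F_i + BS_j + S_k + DA_l + BW_m + e_{ijklmn}$$

with farm, birth season (spring/summer), sex, dam-age class (≤6 / >6 y) and
birth-weight class (<33 / ≥33 kg) as categorical factors.  Farms
contributing fewer than four usable records for a trait are dropped for that
trait (`filter_farms()`).  The fit uses sum-to-zero effect coding, so the
intercept is the overall mean and level effects are deviations from it;
ANOVA uses partial (adjusted) sums of squares — for an additive model the
marginal drop-one tests — and Tukey HSD letter groupings are assigned
greatest-mean-first, the convention of livestock least-square-means tables.
Least-square means come from `emmeans`; the compact letter display is an
insert-and-absorb construction over the Tukey-adjusted pairwise tests.

Downstream correlation and SNP analyses use *adjusted* phenotypes:
`adjust_phenotypes()` subtracts the estimated effects of the factors
significant at P<0.05 and re-centres so the grand mean is preserved.  A
switch allows adjusting for all fitted factors instead; the significance
gate is the default because correlations computed from data adjusted for
noise-level effects would be needlessly perturbed.

## The animal model and EM-REML

Variance components per trait come from the univariate animal model with an
uncorrelated maternal genetic effect:

$$y = X\beta + Z_a a + Z_m m + e, \qquad
a \sim N(0, A\sigma_a^2),\; m \sim N(0, A\sigma_m^2),\;
e \sim N(0, I\sigma_e^2),\; \mathrm{Cov}(a, m) = 0,$$

where $A$ is the numerator relationship matrix from the pedigree (tabular
method, founders unrelated and non-inbred; unknown parents of recorded
animals are auto-added as founders, and records with unknown dams get dummy
founder dams so $Z_m$ is well defined).  $A^{-1}$ is built directly by
Henderson's rules with the inbreeding correction — exact, sparse and O(n) —
rather than by dense inversion; the two routes are cross-checked in the test
suite.

Estimation is EM-REML on Henderson's mixed-model equations.  Each iteration
refactorizes the sparse coefficient matrix
$C = W'W/\sigma_e^2 + \mathrm{diag}(0,\, A^{-1}/\sigma_a^2,\,
A^{-1}/\sigma_m^2)$ by a sparse LDL' decomposition on a fixed fill-reducing
ordering, and the expectation step's $\mathrm{tr}(A^{-1}C^{uu})$ terms are
obtained exactly from the Takahashi selected inverse of $C$ on the sparsity
pattern of $A^{-1}$ (implemented in compiled code; see `src/reml_core.cpp`).
The updates are the classical

$$\sigma_u^{2\,(t+1)} = \frac{\hat u' A^{-1} \hat u +
\mathrm{tr}(A^{-1} C^{uu})}{q}, \qquad
\sigma_e^{2\,(t+1)} = \frac{y'(y - W\hat\theta)}{n - \mathrm{rank}(X)},$$

and the restricted log-likelihood, computed every iteration from
$\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$, is asserted
non-decreasing — the property that makes EM auditable and is verified by the
test suite on fixtures and random simulations.

Numerical choices:

* **Starting values** split `var(y)` equally over the fitted components.
* **Convergence** requires relative component change below `tol` (default
  1e-8) *and* log-likelihood change below `loglik_tol` (default 1e-10).
* **Boundary behaviour**: components are pinned at `1e-8 * var(y)` and
  flagged; their standard errors are reported as 0 with the boundary flag
  rather than from a singular information matrix.  Restricted likelihoods at
  such boundaries involve large cancelling determinant terms, so likelihood
  values there are reliable to roughly single-precision — ample for
  convergence decisions, and the reason oracle comparisons in the tests use
  relative tolerances.
* **Acceleration**: `accelerate = TRUE` takes two EM half-steps and attempts
  a squared extrapolation through them, accepting the extrapolated point
  only if the restricted likelihood does not decrease.  Monotonicity is
  therefore preserved by construction.  Acceleration matters because the
  likelihood is nearly flat in the $\sigma_m^2$ direction when the true
  maternal variance is near zero — plain EM then creeps along the ridge.
* **Non-identifiability**: a herd of unrelated, single-record animals cannot
  separate $\sigma_a^2$ from $\sigma_e^2$; this is detected from the
  pedigree and reported as a flagged boundary result with a warning instead
  of a silently arbitrary split.

Standard errors of components come from the inverse average-information
matrix evaluated at the optimum ($AI_{ij} = \tfrac12 y'PK_iPK_jPy$, with all
$P$-products evaluated through sparse MME solves); heritability standard
errors follow by the delta method.

`blup_ebv()` solves the same equations at the optimum for the breeding
values; prediction-error variances are the corresponding diagonal of the
inverse coefficient matrix times $\sigma_e^2$ (skippable for large systems).

## Derived genetic parameters

* **Heritabilities**: direct $h_a^2 = \sigma_a^2/\sigma_P^2$, maternal
  $h_m^2 = \sigma_m^2/\sigma_P^2$, and total
  $h_T^2 = (\sigma_a^2 + 0.5\,\sigma_m^2)/\sigma_P^2$ — Willham's total
  under $\mathrm{Cov}(a,m)=0$.  The total formula reproduces the published
  per-trait values from the published components (e.g. BW:
  $(260.172 + 251.805)/779.945 = 0.656$), except for SFT, whose published
  components carry only one significant digit so the recomputation is
  dominated by input rounding.
* **Genetic correlations** are the Calo-type approximation: the Pearson
  correlation of the two traits' EBVs over the common animal set (i.e. the
  EBV covariance over the geometric mean of the EBV variances — the only
  reading of the ratio that keeps the estimate in $[-1,1]$), with a t-test
  at the common-animal n.  Traits with a zero-boundary additive variance
  (LMA-like cases) have degenerate EBVs and are flagged rather than given a
  fabricated correlation.
* **Phenotypic correlations** are Pearson correlations of the adjusted
  records with pairwise-complete deletion.
* **Selection responses**: direct response $\Delta G = i\,h^2\,\sigma_P$ at
  selection intensity $i = 1$, and relative correlated response
  $CR_i = r_G\, h_j / h_i$ for selection on trait $j$ responding in trait
  $i$.  `response_matrix()` orients rows as the selected (auxiliary) trait.
  Recomputing the full 11-trait response matrix from the published
  heritabilities, phenotypic variances and genetic correlations reproduces
  118 of the 121 published cells within ±0.005 (residuals consistent with
  the rounding of printed inputs).  The remaining three published cells are
  internally inconsistent with the published inputs and the response
  formulas themselves: two duplicate the adjacent column's printed value
  verbatim and one equals the raw genetic correlation with the
  heritability ratio dropped.  The package treats these as typesetting
  slips in the published table — their positions are recorded on
  `buffalo_response_matrix_published()` — and reports the formula-consistent
  values.

## Candidate-SNP analysis

`genotype_summary()` normalizes unordered allele pairs, counts genotype
classes, computes allele frequencies, flags monomorphic loci, and adds an
exact Hardy–Weinberg test as a QC extension (not part of the original
analysis).  `genotype_anova()` is the one-way ANOVA of an adjusted trait
over genotype classes; classes below 2 animals are excluded from the F test
so the error mean square stays defined (configurable — the published
analysis retained a class of 3).  Monomorphic or single-class loci skip the
test with an explanation rather than erroring.

## The synthetic-herd generator

`sim_config()` defaults *are* the study conditions: 313 calves across 36
farms, per-trait variance components, trait means and sex/season contrasts
taken from the published tables, measurement ages bracketing 365 d, and SNP
founder frequencies implied by the published genotype counts.  Structure
worth noting:

* Breeding values and maternal values are drawn for **all** pedigree animals
  from $N(0, \Sigma_g \otimes A)$ through the Cholesky factor of $A$ and the
  symmetric square root of the cross-trait genetic covariance (the symmetric
  root tolerates zero-variance traits); only dams' maternal values reach
  phenotypes.
* Residuals are correlated across traits with `true_rE` defaulting to the
  genetic correlation matrix.  This mirrors the published data, in which
  phenotypic correlations closely track the genetic ones — a pattern
  impossible under independent residuals, which would force phenotypic
  correlations down to roughly $h^2 r_G$.
* Between-farm effects default to half a phenotypic SD (farm is the
  dominant environmental factor in such smallholder cohorts); sex and
  season contrasts default to the published least-square-mean differences;
  dam-age and birth-weight classes are generated with null effects,
  matching their general non-significance.
* Genotypes are gene-dropped from founder allele frequencies through the
  pedigree, so genotype frequencies in descendants inherit realistic
  drift and family structure.
* A single seed drives all stages through a split-stream scheme, so
  re-running any stage alone is reproducible.

What the generator does **not** emulate: multi-year cohorts and selection
or assortative mating, genotype-by-environment interaction, non-genetic
maternal (litter/permanent environment) variance, age-dependent residual
variance, and non-linear growth.  Passing recovery tests therefore validate
the estimation machinery under the stated model, not the model's adequacy
for any particular real herd.

## Validation scales

The test suite's simulation studies use problem sizes chosen to make
sampling noise small relative to the tolerances while keeping the default
run practical: the heritability-recovery study uses the published WH
components ($\sigma_a^2 = 10.391$, $\sigma_m^2 = 0.002$,
$\sigma_e^2 = 11.139$) with 1500 recorded calves per replicate (a
two-generation pedigree of 50 sires and 300 dams, dams re-used across ~5
calves so the maternal variance is identifiable) over 20 seeds, run with
the accelerated EM at `tol = 1e-6` and a 400-iteration cap — the direct
heritability estimate is stable to the third decimal well before that cap.
A true maternal variance this close to zero makes the estimator's boundary
truncation visible: single replicates scatter widely (SD ≈ 0.08) and the
recovered mean sits slightly below the generating value, which is why the
recovery check is on the 20-seed mean.  Oracle comparisons (gene-dropping
Monte Carlo for $A$, dense V-inversion REML and GLS for the mixed model,
explicit-formula oracles for least squares) run on fixtures of ≤ 12 records
where brute force is exact and fast.

## Known limitations

* Univariate REML only: genetic correlations are EBV approximations, not
  bivariate REML estimates, and inherit the Calo method's shrinkage-related
  attenuation when EBV accuracies are low.
* No $\mathrm{Cov}(a, m)$ term and no permanent-environment maternal
  effect; with the shallow pedigrees typical of a single cohort, maternal
  genetic variance partially absorbs any such covariance.
* The published component table prints zero standard errors for the
  additive variances; the package reports information-based SEs with
  boundary flags instead and makes no attempt to reproduce the zeros.
* Selection-response predictions assume unit selection intensity and
  one-generation response; they are comparison surfaces, not breeding-program
  forecasts.
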
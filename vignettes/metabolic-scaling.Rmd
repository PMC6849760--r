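---
title: "Linking community metabolism to the individual size distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking community metabolism to the individual size distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytomet)
```

## The model

Metabolic scaling theory (MST) treats the metabolic rate of an individual
cell as a power law of its body mass with a Boltzmann–Arrhenius temperature
dependence:

$$ b_i(T) = b(T_c)\, m_i^{\alpha}\, e^{E\left(\frac{1}{kT_c} - \frac{1}{kT}\right)} $$

where $m_i$ is individual carbon mass (µg C), $\alpha$ is the dimensionless
size-scaling exponent, $E$ (eV) the activation energy, $k = 8.62\times10^{-5}$
eV K$^{-1}$ Boltzmann's constant, and $T_c$ a reference temperature (18 °C
= 291.15 K here) that anchors the normalisation $b(T_c)$ at a biologically
meaningful point rather than 0 K. The form is valid only below the thermal
optimum; no photoinhibition of the temperature response, nutrient terms, or
above-optimum behaviour are modelled.

Summing over every individual in a community gives community metabolism
(gross primary production, GPP, or community respiration, CR, as oxygen flux
per litre per hour):

$$ B_j(T) = \Big(\textstyle\sum_i b(T_c) m_i^{\alpha}\Big)\,
   e^{E\left(\frac{1}{kT_c} - \frac{1}{kT}\right)} $$

Two predictions follow and are the package's headline tests:

1. **Proportionality.** Dividing the observed rate by the Boltzmann factor
   ("temperature correction") should leave a quantity directly proportional
   to the *mass-corrected biomass* $b(T_c)\sum_i m_i^\alpha$ — slope 1 and
   intercept 0 on log–log axes. Note the correction must **divide** by the
   factor: multiplying (as a literal reading of one printed rearrangement
   suggests) would inflate warm-assayed communities instead of removing
   their kinetic advantage.
2. **Metabolic compensation.** Under a fixed community energy budget
   (zero-sum dynamics), total abundance must trade off against the average
   individual rate with log–log slope −1: warming or a shift to larger cells
   raises per-cell metabolism and proportionally lowers how many cells the
   budget supports.

## Estimation

Observed log rates are modelled as Gaussian around the log of the structural
prediction (equivalently, lognormal multiplicative errors — rates are
positive and their noise is multiplicative; the error family is the
package's choice, not prescribed by the theory). Conditional on $\alpha$ the
model is *linear* in $(\ln b(T_c), E)$, so `fit_mst()` profiles those and
$\sigma$ out in closed form and optimises over $\alpha$ alone by bracketed
1-D search (2-D seeded multistart when $\alpha$ is allowed to differ between
long-term treatments). This makes the MLE exact and deterministic; the
structural sum $\sum_i m_i^\alpha$ is recomputed exactly at every candidate
$\alpha$. Whether long-term warming shifts $b(T_c)$, $E$ or $\alpha$ is
assessed with 1-df likelihood-ratio tests of each one-parameter split
against the shared model (`compare_treatment_models()`); mesocosm-level
random effects are deliberately absent from the ML model, matching the
reference analysis this mirrors. Confidence intervals are profile-likelihood
intervals at a log-likelihood drop of 1.92; when residuals are numerically
zero (noise-free data) the Gaussian profile degenerates and intervals are
withheld rather than fabricated.

Identifiability requires at least two assay temperatures (for $E$) and
between-community variation in the size distribution (for $\alpha$); both
are checked and reported by parameter name.

## Flux extraction

GPP enters the analysis as the light-saturated gross rate from a
photosynthesis–irradiance curve. The implemented form is the Eilers–Peeters
photoinhibition curve re-parameterised by its maximal rate $P_{max}$,
optimal irradiance $I_{opt}$ and initial slope $s$, minus a constant dark
respiration $R_d$ (the exact published "modification" lives in a supplement
we do not reproduce; the functional form is isolated in `eilers_gross()` and
pluggable). Fitting is multistart nonlinear least squares: up to 1000 starts
drawn uniformly from data-driven bounds (none are stated in the reference
protocol), keeping the lowest-AIC converged fit, with early stopping once
five independent starts agree on the optimum. CR is taken from the measured
dark flux — the stated method — with the fitted $R_d$ exposed as a
cross-check. AIC uses the Gaussian least-squares form $n\ln(RSS/n) + 2K$
with $K = 5$ (four mean-function parameters plus the variance).

## Scaling tests

Both headline tests use standardised major axis (SMA) regression — the
symmetric line of best fit, appropriate because neither axis is a predictor
— with the slope test based on the correlation between the rotated axes
$y - b_0 x$ and $y + b_0 x$ (zero exactly when the SMA slope equals $b_0$).
Natural logs are used on both axes (base cancels in the slope). Confidence
intervals bootstrap **the data and the model**: every case resample refits
the ML scaling model before recomputing both axes, so parameter-estimation
uncertainty propagates into the interval. A fixed-parameter bootstrap is
available as `bootstrap_sma()`; it materially undercovers the theoretical
slopes because the x-axis itself depends on the fitted parameters.
Percentile intervals from 1000 replicates are the default (nothing fancier
is warranted by the protocol being mirrored); two-sided tests at
$\alpha = 0.05$ throughout.

## The synthetic world

`simulate_experiment()` generates the full factorial design this machinery
expects: 10 replicate mesocosms per long-term treatment (warmed +4 °C for a
decade vs ambient), each assayed at 16 and 20 °C — 40 communities.
Individual masses are lognormal (family chosen for positivity and right
skew; the reference data show the shape but not the family) with arithmetic
means 3.6×10⁻⁵ µg C (ambient) and 1.06×10⁻⁴ µg C (warm) and log-SD 1.0 —
the within-treatment spread is unconstrained by any published value and is
deliberately loose. Generating parameters default to the reference ML
estimates (GPP: ln b = −3.46, α = 0.88, E = 0.61; CR: ln b = −5.50,
α = 0.80, E = 1.27). Observation noise is lognormal with σ = 0.3 log units.

Abundance follows the zero-sum rule exactly: $n_{tot} =$ budget / mean
per-cell rate, with a default budget of 10 µmol O₂ L⁻¹ h⁻¹ (a typical
productive-microcosm flux). Two idealisations matter for interpreting green
tests:

* The budget is *common to all communities*, so between-community variation
  in mass-corrected biomass collapses to the incubator contrast alone. Real
  mesocosms differ in their budgets; consequently the proportionality SMA
  under realistic rate noise is slope-inflated in this world (noise loads
  one axis only), and the noisy proportionality test is exercised at small
  noise while the exact identity is tested noise-free. Green tests establish
  estimator correctness, not field realism of the scatter.
* The no-compensation negative control (`zero_sum = FALSE`) cannot use
  literally constant abundance (a zero-variance axis makes SMA undefined);
  abundance is drawn lognormally around the fixed value with
  `abundance_logsd = 0.25` — about a 25% CV between replicate microcosms,
  chosen once as a realistic replicate-to-replicate spread.

Cells per community default to 10⁴ (flow-cytometry scale); tests and the
acceptance script use a few hundred, which only adds sampling noise the
model already conditions on. The ASV simulator (Dirichlet-multinomial,
long-term treatment shifts the taxon profile, incubator does not) exists to
exercise the composition stage and mimics no particular taxonomy.

## Composition statistics

Rarefaction (samples under 1000 reads dropped — a sample at exactly 1000 is
kept — then a single draw without replacement to common depth), Bray–Curtis
dissimilarity, Gower-centred PCoA (negative eigenvalues reported, never
silently dropped), and PERMANOVA with sequential sums of squares computed
from hat-matrix traces, long-term treatment entered first (the adonis
default convention; order configurable), main effects only, and the add-one
permutation p-value. The tests verify exact agreement with vegan and with
exhaustive permutation enumeration on a 6-sample instance.

## Numerical conventions

* All rates handled on the natural-log scale internally; exponentiation at
  I/O boundaries only.
* $k$ fixed at the community-ecology convention 8.62×10⁻⁵ eV K⁻¹ (not the
  CODATA value).
* Q10 conversions use the 10 °C interval centred on $T_c$ (286.15–296.15 K),
  the only interval consistent with both conventional printed pairs
  (0.74 eV → 2.75; 1.42 eV → 6.99); overridable.
* The α search bracket is (−1, 3); CSV floats are serialised at 12
  significant digits; every stochastic step takes an explicit seed and the
  pipeline manifest records them.

## Known limitations

* No mixed-effects ANCOVA stage (the ML model comparison is the primary
  inference); no Bayesian estimation.
* The PI module assumes the standard Eilers–Peeters form; an extra baseline
  parameter in the original supplement's "modification" cannot be ruled out.
* FCS binary parsing and cytometry gating are out of scope — events arrive
  as labelled tables; the events-to-per-litre dilution factor must be
  supplied (`scale_to_litre`).
* SMA here is the plain bivariate estimator: no ranged-MA variants, no
  heteroscedasticity-robust flavours, and the documented slope inflation
  when noise loads one axis only.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(outdir = tempfile("run"),
                       sim = sim_config(n_cells = 1000, seed = 1),
                       n_boot = 200, n_perm = 999, seed = 1)
bundle <- run_pipeline(cfg)
report(bundle)
```
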
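---
title: "Quantitative ecology and bioenergetics of glacial foreland colonisation"
author: "forelandr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ecology and bioenergetics of glacial foreland colonisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forelandr)
```

# Scope

`forelandr` implements the quantitative backbone of a glacier-foreland
colonisation study: who colonises newly deglaciated soil, how communities
turn over along a chronosequence (a space-for-time series of sites at
increasing distance, hence age, from the retreating glacier front), which
metabolic genes those communities carry, how fast they oxidise atmospheric
trace gases and lithic substrates, and whether that chemistry yields enough
power per cell to keep the population alive. Every analysis stage can be
exercised end to end on a synthetic two-glacier chronosequence with known
ground truth, which is what the test suite and the acceptance script do.

# Habitat specialisation index

For each taxon the specialisation index (SI) is the coefficient of variation
of its relative abundance across samples:

$$\mathrm{SI}_t = \frac{s_t}{\bar{x}_t},$$

where $\bar{x}_t$ and $s_t$ are the mean and sample standard deviation
($n-1$ denominator, appropriate for the small sample sizes of foreland
campaigns, e.g. nine Antarctic topsoils) of the taxon's relative abundance.
A taxon present evenly everywhere has SI near 0; a taxon detected in exactly
one of $n$ samples has SI $=\sqrt{n}$ regardless of how abundant it is
there, which the tests exploit as a closed-form oracle.

Classification is quartile-based: taxa with SI strictly below the first
quartile of the SI distribution are *habitat generalists*, strictly above
the third quartile *habitat specialists*, and the interquartile range
(including exact ties at either threshold) *intermediate*. Quartiles use
linear interpolation between order statistics (`stats::quantile` type 7, the
R default) and are stored in the output table so any downstream consumer can
audit the thresholds.

Design notes:

* **Direction of the ratio.** The index is sd/mean. Verbal descriptions of
  this metric sometimes invert the ratio; only sd/mean is consistent with
  classifying *low* values as generalists (low variability = broad, even
  occupancy), so that is what is implemented.
* **Abundance floor.** Amplicon workflows conventionally drop ultra-rare
  taxa before quartiling; `specialisation_index(min_mean_rel = 5e-5)`
  applies a 0.005% mean-relative-abundance floor. The default is 0 (no
  floor) so that MAG-style tables are untouched; the floor is a parameter,
  not a hidden rule, because it is ambiguous at which taxonomic rank such a
  floor should bind.
* **A structural consequence of quartiles.** Strict quartile thresholds call
  roughly 25% of taxa generalists and 25% specialists *by construction*.
  Recovery of planted guilds can therefore only reach high recall when the
  planted generalist fraction is itself near one quarter; validation
  communities are built accordingly (6 generalists among 24 taxa). When the
  planted fraction is larger, precision (the called generalists are true
  generalists) is the meaningful recovery measure.
* Zero-mean taxa are flagged `absent` and excluded from classification with
  a warning, never silently dropped.

# Zeta diversity

Zeta diversity of order $i$, $\zeta_i$, is the mean number of taxa jointly
present across $i$ sites, averaged over site combinations; $\zeta_1$ is mean
richness and higher orders capture multi-site turnover. The implementation
is from first principles on a presence/absence matrix:

* **Enumeration.** Exhaustive when $\binom{n}{i}$ is below a cap (default
  5000), otherwise Monte Carlo: combinations drawn uniformly, sites distinct
  within a draw, draws independent (so a combination can recur across
  draws). Tests require Monte-Carlo means to sit within three standard
  errors of exhaustive enumeration.
* **Jaccard normalisation** divides each combination's intersection size by
  its union size (empty unions contribute 0), so normalised zeta lies in
  [0, 1]. Raw values are always reported alongside, because "share of taxa
  shared" can also be read as $\zeta_2/\zeta_1$; both ratios are emitted.
* **Decline model selection.** Exponential decline is fitted as OLS of
  $\ln\zeta_i$ on $i$ and power-law decline as OLS of $\ln\zeta_i$ on
  $\ln i$; both are compared by Gaussian AIC with maximum-likelihood
  variance and $k = 3$ parameters (slope, intercept, variance), making the
  comparison a pure fit contest. $\Delta\mathrm{AIC} < 2$ is flagged
  "indistinguishable". Power-law decline is the classic signature of
  deterministic (niche-driven) assembly and exponential decline of
  stochastic assembly; the synthetic generators reproduce this dichotomy
  (contiguous niche ranges select power law in >80% of seeds, independent
  random placement selects exponential in >95%).
* **Distance decay.** For each sampled combination the Jaccard zeta is
  regressed (OLS) on the mean pairwise great-circle distance (haversine,
  sphere radius 6371.0088 km; planar coordinates behind a flag). The slope
  per km is the decay coefficient. OLS is a declared stand-in; the upstream
  literature does not fix the internal regression family.
* **Two-way vs four-way decay.** Pairwise decay is steeper than four-way
  decay *for communities mixing widespread generalists with narrow-range
  specialists*: four-site intersections are dominated by slow-turnover
  generalists while pairwise comparisons still see specialist turnover. For
  a pure single-breadth niche gradient the inequality actually reverses
  (the spatial span of four sites grows faster than the mean pairwise
  distance), so the mixture — which is also the composition foreland
  communities actually show — is the right structure for exercising this
  contrast.
* **Variation partitioning** uses site pairs (order 2): the response is
  pairwise Jaccard zeta and the predictors are absolute between-site
  differences of each site variable, split into two groups (e.g. soil age
  vs physicochemistry). Adjusted $R^2$ from the group-1, group-2, and full
  models yields pure fractions $a$, $c$, shared $b$, and unexplained $d$;
  negative fractions are floored at zero and renormalised with raw values
  retained. This is a deliberate simplification of multi-site generalised
  dissimilarity machinery: linear models on pairwise differences,
  documented as such. Perfectly shared variables across the two groups are
  absorbed into $b$; collinearity *within* a group is an error directing the
  user to `collinearity_filter()`, the iterative $|r| \ge 0.9$
  priority-driven Pearson filter also used for physicochemical predictor
  reduction.

# Marker-gene profiling

Homology-search hit tables (BLAST/DIAMOND tabular, 12 columns plus query and
subject coverage) are filtered with per-family thresholds held in a manifest:

* **Read mode:** best hit per read by bitscore (ties broken by a stable sort
  on family then id), then query coverage ≥ 80% and identity ≥ the family
  threshold (default 50%, with per-family overrides such as rho 40%, a
  group of oxidoreductase and carbon-fixation families at 60%, several
  photosystem/ATPase families at 70%, hbsT 75%, psaA 80%).
* **MAG mode:** alignment ≥ 40 aa *or* ≥ 80% query coverage *or* ≥ 80%
  subject coverage, plus protein-mode identity thresholds (overrides
  atpA 60, psbA 60, rdhA 45, cyc2 35, rho 30).

Filtering is idempotent, and tests verify the predicate exhaustively on
tables with planted violations. Abundances are expressed as RPKM with the
reference length taken as mean protein length × 3 (nucleotide kilobases) —
the length convention is a configuration value, not a hard-coded constant —
and reads are counted singly. The community-level *average gene copy per
organism* divides a family's RPKM by the mean RPKM of the manifest's
universal single-copy ribosomal protein families (15 by default; the set is
manifest-driven since it is conventionally cited rather than enumerated).
This ratio reads as the fraction of cells carrying the gene; values above 1
flag multi-copy genes and are reported uncapped. Genome-bin (MAG) signature
gene counts are corrected for estimated completeness as raw/(completeness/100).

# Kinetics, fluxes, nutrients, qPCR

**Microcosm kinetics.** Headspace mixing-ratio series are fitted with both
$c(t) = c_0 e^{-kt}$ (log-linear OLS) and the asymptotic
$c(t) = c_\infty + (c_0 - c_\infty)e^{-kt}$ (bounded nonlinear least
squares, $c_\infty \ge 0$), AIC-selected — both forms are plausible for
soils approaching a compensation concentration, and the literature does not
fix the choice. Heat-killed controls are subtracted at the rate-constant
level, $k_{net} = \max(k_{live} - k_{killed}, 0)$, floored with a flag
rather than reporting negative biotic rates. The oxidation rate at the
atmospheric mixing ratio is $k_{net} \cdot n_{atm}/m_{dry}$ with
$n_{atm} = c_{atm} \cdot PV/RT$ (ideal gas; R = 8.31446 J mol⁻¹ K⁻¹,
1 atm = 101325 Pa, centralised in `foreland_constants`). Dry mass defaults
to wet mass × (1 − gravimetric moisture); if moisture is unknown, wet mass
is used with a warning.

**Chamber fluxes.** Nine-point, ≤ 90 min static-chamber series are fitted
with linear and saturating-exponential models; the AIC-selected model's
slope at $t = 0$ is converted to a flux via the molar density $P/RT$ and
the chamber's effective height, in nmol m⁻² s⁻¹ with sign preserved
(negative = uptake).

**Nutrient slurries.** Linear and exponential fits, AIC-selected; the rate
is the *signed* initial slope (accumulation positive, uptake negative). For
degenerate series (e.g. exactly constant) where the nonlinear optimiser's
gradient is singular, the log-scale OLS fit stands in as the exponential
candidate, so a flat series reports rate 0 with the two models tied
($\Delta\mathrm{AIC} < 2$).

**AIC details.** All model comparisons use the Gaussian likelihood with
maximum-likelihood variance. The ML variance is floored at 1e-24 so that
numerically exact fits (residual sd below 1e-12, far below any measurement
scale here) compare as ties instead of racing to $-\infty$. Small-sample
AICc is available behind a flag (`aicc = TRUE`) since chamber and microcosm
series have only 5–9 points.

**qPCR.** Standard curves are OLS of mean Cp on $\log_{10}$ copies
(requiring ≥ 4 dilutions spanning ≥ 3 decades); unknowns invert the curve,
scaled by elution/dilution factors and dry mass. Amplification efficiency is
$(10^{-1/\mathrm{slope}} - 1) \times 100$; Cp values outside the standards'
range are flagged as extrapolations.

# Thermodynamic power per cell

Each trace-gas oxidation carries a balanced stoichiometry and a standard
Gibbs energy at 298.15 K from standard formation energies (water as
liquid): H₂ + ½O₂ → H₂O at −237.14 kJ mol⁻¹, CO + ½O₂ → CO₂ at −257.22,
CH₄ + 2O₂ → CO₂ + 2H₂O at −817.95. Under field conditions,

$$\Delta G = \Delta G^\circ + RT \ln Q,$$

with $Q$ built from gas-phase activities $p/p^\circ$ ($p^\circ$ = 1 atm;
liquid water at activity 1). The gas-phase activity convention follows the
source framing; a dissolved-phase treatment via Henry's law is a possible
sensitivity variant but is not implemented. $\Delta G^\circ$ is used as-is
unless a reaction enthalpy is supplied for a Gibbs–Helmholtz temperature
adjustment. At atmospheric H₂ (0.5 ppmv, O₂ 0.209 atm, 298.15 K) the
quotient term adds +37.9 kJ mol⁻¹, giving ΔG ≈ −199.2 kJ mol⁻¹; a grid scan
(270–310 K, 10⁻³–10 ppmv) confirms all three oxidations stay exergonic.

Power per putative oxidiser cell is

$$P = \frac{r \cdot |\Delta G|}{n_{cells} \cdot f},$$

with $r$ the bulk rate in mol g$_{dw}^{-1}$ s⁻¹, $n_{cells}$ total cells
per g dry weight proxied by 16S rRNA gene copies (no per-genome copy-number
correction — a documented limitation), and $f$ the oxidiser fraction =
min(copies per organism, 1), since a cell with at least one gene copy is
one oxidiser. Results are classified against the empirical maintenance
window 10⁻¹⁷–10⁻¹² W cell⁻¹.

# The synthetic chronosequence generator

The generator's defaults mirror the two-glacier study design: an Antarctic
foreland with three age classes (<5, 10, 21 years; 3 topsoil sites each)
and a Swiss foreland with four classes (0–7, 8–27, 28–57, 58–127 years;
15 topsoils in a 4/4/4/3 split, with 10-cm depth intervals to 50 cm).
Sites are laid along a transect whose distance from the glacier front grows
with soil age, with modest lateral scatter.

Communities are built from planted truths: each taxon has a guild
(*generalist*: no age trend, low CV; *early opportunist*: exponential
decline with age; *late specialist*: the mirrored increase), a mean
relative abundance, a target CV, and a set of marker families. Per-sample
weights are rescaled to the target CV (clipped at a small positive floor),
columns renormalised, and counts drawn multinomially — so column sums equal
the read depth exactly. The default amplicon depth is 10⁵ reads per sample,
a typical order for soil surveys (the source does not state its depths).
Marker hits are emitted per family with expected counts proportional to
reference length × carrier abundance, plus optional planted sub-threshold
rows; gas, nutrient, and qPCR series add Gaussian noise to their stated
models, truncating negative concentrations at zero (a detector floor, by
choice, rather than resampling).

One global integer seed drives everything through named streams (a
polynomial hash of stage name folded into the seed), so adding a stage
never perturbs another stage's draws and reruns are byte-for-byte
reproducible.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: sequence-level errors and chimeras (hits are emitted
as tabular rows, not reads), taxonomic correlation structure, compositional
covariance beyond renormalisation, spatial autocorrelation of
physicochemistry, and temperature or moisture dependence of rates.

# Problem sizes and numerical choices

The test suite and acceptance script run at deliberately desk-scale sizes
chosen as the package's own validation design: communities of 20–24 taxa
over 9–15 sites at 10⁵ reads; zeta on 50 taxa × 10 sites with 150–1000
Monte-Carlo subsamples and 200 seeds for model-selection frequencies; 100
seeds for kinetic and flux recovery (median relative error < 5% at the
default noise of 0.01 ppmv over five points in 24 h). Monte-Carlo zeta uses
sampling without replacement within a draw; the exhaustive cap (5000
combinations) keeps exact enumeration for all small designs. Ties in
best-hit resolution, quantile conventions (type 7), and the strict
inequality at quartile thresholds are all fixed and documented above so the
pipeline is deterministic given a seed.

# Known limitations

* Real-data headline numbers (published quartile thresholds, community SI
  means, ζ₂/ζ₄ percentages, power-per-cell statistics from deposited
  accessions) require accession-scale read mapping and supplementary
  tables; this package validates the *methods* on synthetic ground truth
  and exposes the same interfaces for real tables.
* Variation partitioning is pairwise-linear, not multi-site GDM.
* The 16S-copies cell proxy ignores per-genome rRNA operon copy number.
* ΔG° temperature adjustment requires a user-supplied reaction enthalpy;
  otherwise ΔG° is treated as temperature-independent (flagged).
* Coverage-based rarefaction, ordination/PERMANOVA, GLM/random-forest
  driver analyses, and all upstream sequence processing are out of scope;
  established packages already serve those steps.
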
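---
title: "Models and methods behind mbtemporal"
author: "mbtemporal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbtemporal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mbtemporal analyses dense per-person gut microbiome time series in which
each stool sample carries, besides a genus-level 16S read-count profile, a
flow-cytometric measurement of total microbial load (cells per gram of
faecal material). This document describes the models the package
implements, the parameters that matter, the design decisions taken where
several constructions were defensible, and what the bundled synthetic
cohort does and does not emulate.

## Quantitative microbiome profiles

Read counts are compositional: sequencing reports proportions, not
amounts, and a proportion can change because an unrelated taxon bloomed.
A quantitative microbiome profile (QMP) restores an absolute scale by
combining three measurements:

1. **Copy-number correction.** Each genus g carries a known 16S rRNA gene
   copy number $cn_g \geq 1$, so its read count overstates its cell count by
   that factor. The copy-number-corrected depth of a sample is
   $\sum_g x_g / cn_g$ — an estimate of cells actually sequenced.
2. **Sampling depth.** Dividing by the microbial load $L_s$ gives the
   sampling depth $d_s$, corrected reads *per cell of the original
   community*. Two samples at the same $d_s$ interrogate their communities
   equally deeply, which is the meaningful notion of "even depth" for
   absolute profiles.
3. **Even-depth rarefaction and rescaling.** All retained samples are
   rarefied to a common target depth $D$ and rescaled by $L_s$, yielding
   cells per gram.

`buildQMP()` chooses $D$ among the observed $d_s$ values so as to retain
as many samples as possible, subject to every retained sample keeping at
least `min_reads` (default 500) corrected reads after rarefaction — the
floor below which genus profiles become unusably sparse. Ties favour the
larger $D$. Restricting candidates to observed $d_s$ values loses
nothing: any other target is dominated by the next observed value below
it (same retained set, fewer reads). A test verifies the optimiser
against brute-force maximisation on random instances.

Because corrected "reads" are fractional, an exact without-replacement
subsample is not defined on the corrected scale; rarefaction draws
multinomially with probabilities proportional to $x_g / cn_g$. On the raw
read scale (`rarefyCounts()`, used for relative profiles at a fixed
10,000-read depth) subsampling is exactly hypergeometric.

## Within- versus between-person variation

**ICC.** `iccAnova()` uses the one-way fixed-effects ANOVA estimator with
the unbalanced-design correction $k_0 = (N - \sum_i n_i^2/N)/(k-1)$:
`var_within` = MSW, `var_among` = (MSB − MSW)/k₀, ICC =
var_among/(var_among + var_within). Slightly negative estimates are
reported as computed, not truncated — truncation would bias summaries of
many genus-level ICCs.

**Taylor's law.** For each genus, each participant contributes the mean
and variance of their (positive) abundance series; `taylorFit()` regresses
log₁₀ variance on log₁₀ mean. A slope of 2 means a constant coefficient of
variation across hosts. Series with fewer than 3 detections are dropped
(variance undefined in any useful sense) and genera with fewer than 5
contributing hosts are skipped. Log base 10 is fixed so intercepts are
reportable; the slope is base-invariant, and a test asserts invariance
under global rescaling of all abundances.

Two estimation regimes deserve distinction. When abundances are measured
well and genus means span a wide range across hosts, the regression slope
estimates the generating exponent accurately: the package's recovery
check simulates constant-CV log-normal abundances with a wide between-host
spread of equilibria (SD ≈ 0.7 log₁₀ units, the order real gut genera
show) and recovers slope 2.00 within ±0.10. When the between-host spread
is narrow or counts are shallow (a few hundred to a few thousand reads
after QMP rarefaction), correlated sampling error in the two moments
inflates the slope — visible in the pipeline outputs for near-threshold
genera. This is a property of the moment-based construction itself, which
the package reproduces faithfully rather than papering over.

**Stationarity.** `adfTest()` implements the augmented Dickey–Fuller
regression with drift and no trend,
$\Delta y_t = \alpha + \rho y_{t-1} + \sum_{i=1}^p \phi_i \Delta y_{t-i} +
\varepsilon_t$, because the hypothesis of interest is fluctuation around
an equilibrium level, not around a deterministic trend. P-values are
interpolated from the drift-case Dickey–Fuller table over both sample size
and level, clamped to [0.01, 0.99]. Rejection of the unit root means
stationarity. The lag order defaults to AIC selection within
$0..\lfloor (n-1)^{1/3} \rfloor$: at the 35–40-point series typical here,
fixing the order at the cap costs the test roughly half its power against
mildly autocorrelated stationary alternatives (simulation: power 0.51 at
p = 3 versus 0.94 under AIC selection, size ≈ 0.05 for both), so the
data-driven order is the default and a fixed order remains available via
`n_lags`. Genera present in ≤ 60% of a person's samples are skipped.

**Fold changes and ranks.** Ratios are taken only between positive
observations; zeros are ignored rather than pseudocounted by default (an
optional pseudocount of half the minimum positive value is provided) —
with absences frequent at these depths, a pseudocount choice would
dominate the statistic. Rank span uses dense ranks of descending
abundance within each sample; span = max − min + 1, with the count of
distinct ranks as an option.

**Median-error curve.** For each subsample size n, the SD of the
subsampled median across repetitions is averaged over each participant's
100 most abundant genera, each genus scaled by its mean abundance so a
single dominant genus does not set the curve. The elbow is the point of
maximum perpendicular distance to the chord — a scale-free heuristic.

## Core membership

Presence is evaluated on the 0.5%-filtered abundance matrix, so a genus
that never clears detection noise is absent for membership purposes.
Per participant, with presence fraction f and consecutive fraction c
(fraction of presences whose previous or next collected sample is also a
presence): temporal core f > 0.95; persistent f > 0.20 and c ≥ 0.90;
transient f > 0.60 and c < 0.75. "Consecutive" is defined in collection
order, not calendar days, since missed collections leave calendar gaps in
all series. The persistent and transient predicates can overlap for some
masks; both flags are reported and the overlap marked rather than forcing
an exclusive class. Cohort-level classes: cross-sectional core = present
in at least one sample of every participant; person-specific = present in
exactly one participant and not seen in negative controls.

## Community structure

Bray–Curtis dissimilarities come from `vegan::vegdist`; principal
coordinates from Gower-centred eigendecomposition with negative
eigenvalues retained and reported (Bray–Curtis matrices are not generally
Euclidean). Group dispersion uses the `vegan::betadisper` construction —
distance to group centroid combining real and imaginary axes as
$\sqrt{\max(0, d_{\mathrm{real}}^2 - d_{\mathrm{imag}}^2)}$ — followed by
one-way ANOVA. The within- versus between-person contrast compares each
participant's full series against a one-sample-per-participant reference
set (by default each participant's first sample; the sample closest to the
first day of menses can be supplied), with Benjamini–Hochberg adjustment
across participants.

Similarity decay regresses log(1 − BC) on elapsed days over within-person
day pairs at 1..36 days, after linear interpolation to daily resolution.
Interpolation bridges only gaps of ≤ 3 days; longer holes remain missing
and their pairs are excluded, because linear interpolation across a week
of missed collections would manufacture similarity. Each elapsed-day
stratum is subsampled to the size of the smallest so late strata (few
long-range pairs) are not swamped by early ones. Note that an AR(1)
memory in abundances produces a genuine small negative slope over the
first few days; a flat slope indicates the absence of *incremental*
drift beyond that short-range correlation.

## Enterotyping

`dmmFit()` implements Dirichlet multinomial mixtures by EM:
responsibilities from component DM likelihoods in the E-step; weights by
mean responsibility and component alphas by Minka's weighted fixed-point
iteration (two inner updates per EM step — a generalised EM that keeps the
likelihood monotone, checked every iteration) in the M-step. Components
are initialised from k-means on relative abundances followed by
method-of-moments Dirichlet estimates, which avoids degenerate starts.
Model evidence uses Laplace's approximation; each component's Hessian has
the form diag(d) + c·11ᵀ, so its determinant comes from the matrix
determinant lemma in O(G). Components whose Hessian is not positive
definite fall back to a BIC penalty (also selectable outright via
`evidence = "bic"`).

Longitudinal samples are enterotyped against a cross-sectional background
one time point per participant at a time, in seeded random order, so no
two samples of one person are clustered together. The default refits the
mixture each iteration and matches components to a reference fit by
majority overlap of background assignments (ties resolved by cosine
similarity of alpha vectors, and logged); a fixed-model `"assign"` mode
computes posteriors only and is much cheaper — with a stable background
the two agree, and both are exposed. Component-to-name mapping (Bact1,
Bact2, Rum, Prev) follows driver taxa: the Prevotella-richest component is
Prev, the Ruminococcaceae-richest of the rest is Rum, and the two
Bacteroides-dominant components split by Faecalibacterium level — the
depleted one is Bact2, the dysbiosis-associated state.

**Mislabelling screen.** For each sample, one-sided Wilcoxon tests ask
whether its dissimilarities to some other participant's samples are
stochastically smaller than to its own participant's; BH adjustment runs
across all (sample, foreign participant) tests. A swap candidate requires
reciprocal flags between two participants, and exactly one sample pair is
nominated per participant pair (the strongest evidence on each side),
since a physical swap exchanges exactly one pair. The screen presupposes
participants are compositionally separable — with near-identical
participants, "this sample is closer to that person's series" can be true
without any mislabelling. An optional second evidence layer clusters the
whole dataset into as many DMM components as participants and reports
each sample's cluster against its participant's modal cluster.

## Enterotype transitions

Under random pairing given state prevalences, the probability of an
unordered state pair {A, B} among $N$ samples with $n_A$, $n_B$ of each
state is $n_A n_B / \binom{N}{2}$ (and $\binom{n_A}{2}/\binom{N}{2}$ for
A = B). `transitionNull()` compares observed consecutive-sample
transitions (direction-collapsed) against these probabilities with a
chi-square goodness-of-fit and standardised residuals
$(O-E)/\sqrt{E(1-p_i)}$. The pooled-pair reading of "possible
transitions" is used; expected probabilities sum to one exactly, verified
against exhaustive pair enumeration.

`ctmcFit()` estimates a continuous-time Markov model observed as
snapshots: intensities $q_{rs}(z) = q_{rs}^0 e^{\beta_{rs} \cdot z}$, all
off-diagonal transitions allowed by default, likelihood a product of
matrix-exponential transition probabilities over successive observation
intervals with the covariates in force at interval start. The matrix
exponential is evaluated in C++ (Armadillo) once per unique
(interval, covariate) configuration; optimisation is BFGS on the
unconstrained (log q, β) parameterisation initialised from crude rates,
with standard errors from the inverted numeric Hessian. Risk ratios are
$e^\beta$ per unit covariate with Wald 95% CIs; covariates are **not**
rescaled internally, so effects are per unit of whatever the caller
supplies (standardise first to compare covariates). Nested models are
compared by likelihood ratio against chi-square. Simulation checks: CI
coverage of a known β ≥ 90%, and LR type-I error 5% ± 2% (at 50 series of
15 observations the realised rate is ≈ 0.055 — a small finite-sample
excess of the chi-square approximation).

## Host covariates

Energy intake uses 9/4/4 kcal/g for fat/protein/carbohydrate; P/C is the
protein-to-carbohydrate energy ratio. The personal dietary lag starts at
the 1-day transit default and moves to a lag in 2..5 days only when the
P/C–moisture cross-correlation there is significant (|r| > 1.96/√n) and
stronger than at lag 1; a same-day lag additionally requires that most
samples were collected in the late afternoon or evening. Because
non-significant estimates shrink to the default by construction, the
cross-correlation argmax is the right quantity for judging lag
*estimation*, and both are reported. Cross-correlations use
pairwise-complete observations; missing diet days are never interpolated.

Hormone profiles adjust a 28-day standard curve to personal cycle length
by modifying only the cycle start, preserving the final 14 (luteal) days
exactly: shorter cycles drop leading days; longer cycles insert
extrapolated days with level(day 1) + (level(day 1) − level(day 28))·e^(−x)
for the x-th day beyond 28, converging to the day-1 level. The difference
is taken as day 1 − day 28 (sign noted as ambiguous in the source
description; the convention is fixed here and documented). The bundled
28-day curve is synthetic — log-normal-shaped peaks aligned to a day-14 LH
reference, estrogen peaking pre-ovulation with a luteal plateau,
progesterone mid-luteal — and is intended as a stand-in with the right
qualitative shape; quantitative work should supply a measured curve.

## The synthetic cohort

`simulateCohort()` generates the structure the analyses assume, with
ground truth for recovery tests:

* latent log₁₀ cell abundance per genus follows an AR(1) (coefficient 0.3
  by default) around per-participant equilibria; per-genus temporal CVs
  are drawn log-uniformly from 0.4–2.5 (median ≈ 1, matching dense-series
  reports) with CV rank coupled inversely to abundance rank — abundant
  taxa are more stable;
* a Taylor exponent b couples each host's CV to its equilibrium
  (b = 2 ⇒ constant CV);
* the spread of equilibria between hosts is set by `icc_target`
  (default 0.35: within-person variance dominates, as quantitative
  longitudinal profiling shows);
* a shared AR(1) day factor (SD 0.15 log₁₀) scales all genera of a sample
  together — total-biomass swings that cancel from relative profiles but
  not quantitative ones, which is precisely why relative profiling
  understates temporal variation;
* four community templates (Bacteroides-dominant split by
  Faecalibacterium into Bact1/Bact2, Ruminococcaceae- and
  Prevotella-dominant) are visited by a slowly switching Markov chain
  (daily leave probability 0.05) and boost their driver genera;
* microbial load is the sum of genus cells, anchored per participant
  inside 6×10¹⁰–22×10¹⁰ cells/g; moisture (52–93%) responds negatively to
  load and positively to the lagged P/C ratio;
* reads are multinomial draws from copy-number-distorted relative cell
  abundances (reads ∝ cells × cn — the forward model `buildQMP()`
  inverts), at log-normal depths around 30,000, after truncating relative
  abundances below 10⁻⁴; candidate days are dropped with probability
  0.036, reproducing ≈ 694 samples from 20 × 36 candidate days.

What it does **not** emulate: real taxonomies and phylogeny, sequencing
batch effects, compositional interactions between genera (each genus
fluctuates independently given the shared day factor and state), diet
beyond log-normal macronutrient noise, or perturbation events such as
infections. Passing recovery tests therefore demonstrates correctness of
the estimators under the generative assumptions, not robustness to
everything real cohorts contain.

`simulateBackground()` draws one sample per pseudo-participant from
Dirichlet templates (prevalences 0.36/0.17/0.30/0.17 for
Bact1/Bact2/Rum/Prev, Bact2 the most dispersed template);
`simulateTemplateSeries()` is its longitudinal companion for
label-recovery experiments; `injectSwaps()` exchanges abundance profiles
while leaving labels alone, with a recorded manifest.

## Problem sizes used by the test suite

The statistical checks simulate at sizes chosen to give each assertion
clear resolution while keeping the suite practical: QMP optimiser versus
brute force on 1,000 instances of ≤ 12 samples; ICC recovery on one
20 × 36 cohort with 200 genera; Taylor recovery on three 20 × 35
constant-CV cohorts (73 genera each); DMM selection and label recovery on
a 1,000-sample background over K = 1..6; CTMC coverage over 50 replicates
of 100 × 20 snapshot series and LR calibration over 500 replicates of
50 × 15; similarity decay over 200 exchangeable and 60 drifting
replicates; the mislabel screen over 20 replicates of the full 20 × 36
cohort with two injected swaps each; dietary-lag recovery over 200
replicates at r = 0.5. `scripts/acceptance.R` re-runs the pipeline
end-to-end on freshly generated cohorts and writes its headline numbers
as JSON.

## Known limitations

* The DMM evidence uses a per-component Laplace determinant that ignores
  cross-component and weight curvature; adequate for selecting K on
  well-separated data, and a BIC fallback is provided.
* The CTMC assumes time-homogeneous intensities given covariates and
  snapshot observation; exact transition times and hidden-state
  extensions are out of scope, as is a misclassification model on states.
* `dispersionTest()` tests homogeneity of dispersion only — location
  differences between groups are deliberately not tested here.
* The QMP-scale Taylor slope inherits counting noise at low rarefied
  depths (see above); interpret it jointly with the per-genus adjusted R²
  and detection counts.
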
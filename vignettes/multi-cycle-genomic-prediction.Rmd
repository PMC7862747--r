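---
title: "Multi-cycle genomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cycle genomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclegp)
```

## The problem

Elite clonal breeding programs (strawberry is the motivating system) run
overlapping yearly cycles: the best parents of one year are inter-mated, their
seedlings are selected visually, and the selections enter a replicated
advanced-selection trial the following season, alongside carried-over
cultivars and promising selections from earlier years. Genomic prediction
(GP) trains a whole-genome regression on one or more of these yearly trials
(the training set, TRN) and predicts genomic estimated breeding values
(GEBVs) for a later trial (the testing set, TST) whose phenotypes are held
out. Because each trial is an independent experiment, this is *independent
validation* — deliberately avoiding k-fold cross-validation within a trial,
which shares individuals between folds and inflates predictive ability.

`cyclegp` implements that full analysis as reusable, tested components:

1. **simulator** — multi-cycle populations with the structure the analysis
   assumes (partial circular mating, carry-over, RCBD field trials);
2. **genotype QC** — MAF and missingness filters with mean imputation;
3. **phenotype adjustment** — per-trial REML models producing genotype BLUEs;
4. **predictors** — Bayes B (spike-and-slab Gibbs sampler), GBLUP, and a
   factor-analytic multi-year genomic model;
5. **validation** — forward/backward cross-cycle scenarios, prediction
   averaging, predictive ability, and population-structure summaries;
6. **population genetics** — LD with and without relatedness correction,
   decay curves, and LD-based effective population size.

## Models

### Phenotype adjustment

Each trial is a randomized complete block design: 5–6 replicates, raised
beds of 5–9 single-plant plots, one plot per bed holding a shared control
genotype. `fit_trial_model()` fits, by REML,

$$y = X_g\beta_g + Z_r u_r + Z_b u_b \;(+\, Z_{row}u_{row} + Z_{col}u_{col}) + e,$$

with genotypes fixed (their estimates are the BLUEs), replicates and
beds-within-replicates random, and three residual options: iid (`base`), iid
with additional random row/column effects (`spatial_rc`), and a separable
AR1(row) ⊗ AR1(col) correlated residual (`spatial_rc_ar1`). Candidates are
compared by AIC (ties: fewer parameters, then BIC) via `select_model()`. The
iid models are solved in the random-effect dimension (Woodbury identities)
with the residual variance profiled out; the AR1 model maximises the dense
REML likelihood, which is adequate at single-trial sizes (a few thousand
plots). All engines share one likelihood definition and one variance floor
(ratios bounded at $10^{-8}$), so log-likelihoods are directly comparable —
the reason the package carries its own REML code rather than delegating to a
mixed-model package that cannot express the AR1⊗AR1 residual. lme4 is used
in the test suite as an independent oracle for the iid models.

BLUEs are centred on the grand mean by default; centring on the control
genotype is a flag (`center = "control"`). The choice does not affect
predictive ability (a correlation), only the reporting scale.

### Bayes B

For BLUEs $y$ and centred marker dosages $Z$,

$$y = 1\mu + Z\beta + e, \qquad
\beta_j = 0 \text{ w.p. } \pi, \quad
\beta_j \sim t_{scaled}(0, s^2, \nu) \text{ w.p. } 1-\pi,$$

implemented as a Gibbs sampler (Rcpp) with the scaled-t slab expressed as a
normal whose marker-specific variance has a scaled-inverse-$\chi^2$ prior.
Defaults: $\pi = 0.5$ updated under a Beta prior with pseudo-count 10, slab
df 5, slab scale solved so markers explain half the phenotypic variance a
priori, residual scaled-inverse-$\chi^2$ with df 5. Production settings are
50,000 iterations, 10,000 burn-in, thinning 5, five chains under distinct
derived sub-seeds, with per-chain residual-variance traces retained;
convergence is summarised by a Geweke-style z-score (|z| > 3 warns). The test
suite and worked examples use deliberately reduced chains (about 1,000–2,500
iterations), which are sufficient for the rank-level properties they assert.

Predictions are plain dot products, `GEBV = mu + W beta`, using the training
marker means for centring; averaging GEBVs across training cycles is a
separate, equal-weight step (`average_predictions()`), matching the way
multi-cycle training sets are combined in practice.

### GBLUP, heritability and the FA2 multi-year model

`vanraden_grm()` builds the method-1 genomic relationship matrix
$G = WW^\top / 2\sum_j p_j(1-p_j)$. `gblup_fit()` fits
$y = 1\mu + u + e$, $\operatorname{var}(u) = G\sigma^2_a$ by eigen-rotated
REML (one profiled variance ratio — exact and fast), giving
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$ with a curvature-based standard
error, and GEBVs as BLUPs. Clonal panels with repeated genotypes make $G$
singular by construction; a small identity blend (default 0.01 where
relevant) restores positive definiteness.

Genotype-by-year structure is modelled by a factor-analytic order-2
covariance on year-specific genetic effects,
$u_g = (\Gamma \otimes I)f + \delta$, across-year genetic covariance
$\Sigma_g = \Gamma\Gamma^\top + \Psi$, genotypes correlated through $G$, and
heterogeneous independent residuals per year (different plots each year).
With a complete genotype × year table the REML likelihood factorises over
the eigenvectors of $G$ into independent $t$-variate normals — the fast path;
unbalanced tables use the dense observed-cell covariance. $\Gamma$ is
identified by a lower-triangular constraint. Reported summaries are the
genetic correlation matrix (`cov2cor` of $\Sigma_g$) and the percent of
genetic variance explained by the common factors,
$100\,\mathrm{tr}(\Gamma\Gamma^\top)/\mathrm{tr}(\Sigma_g)$.

### Validation design

`assign_scenarios()` builds the forward compositions (`T2`, `T24`, `T246`,
`T2468` for testing `T10`) and backward compositions (`T8`, `T86`, `T864`,
`T8642`). Predictive ability is the Pearson correlation between GEBVs and
the testing trial's BLUEs. The "excluding common genotypes" scenario removes
from the testing roster every individual present in any training trial of
the composition; whether the original analyses also removed them from the
training side is ambiguous, so the default keeps the training set intact and
a `drop_from_trn` flag records the other reading. `incidence_summary()`
produces the incidence matrix (common genotypes above the diagonal,
full-sib family counts on it, shared parents below), and
`incidence_averages()` the per-trial means rounded half away from zero —
half-away rounding is what reproduces the published derived averages
(31/44/61/66/62 common genotypes; 4/5/8/8/7 shared parents) exactly.

### LD and effective population size

LD is the squared Pearson correlation of unphased dosages (the composite
measure appropriate to array data). The relatedness-corrected measure
$r^2_V$ whitens dosage vectors by the inverse symmetric square root of
$(1-b)K + bI$ ($b = 0.01$) before correlating, so LD induced purely by
kinship is removed; with $K = I$ it equals plain $r^2$ exactly. Decay over
physical distance is fitted by nonlinear least squares to the Hill–Weir
expectation with its sample-size term, parameterised by a recombination
scale per Mb; threshold crossings (0.2, 0.1) are reported, or NA when the
fitted curve never reaches them on the observed range. `ne_ld()` implements
the bias-corrected LD method for random mating: MAF < 0.05 dropped, mean
$r^2$ over between-linkage-group (unlinked) pairs, sample-size expectation
$1/S + 3.19/S^2$ subtracted ($0.0018 + 0.907/S + 4.44/S^2$ for $S < 30$),
and $N_e = (1/3 + \sqrt{1/9 - 2.76\,r^2{}'})/(2 r^2{}')$ (small-sample
constants 0.308/2.08), with a delete-one-locus jackknife interval. Using
only between-group pairs is the conservative reading of the unlinked-pairs
assumption. Carry-over duplicates should be excluded from LD/Ne rosters
(the pipeline does this for cycles after the first), since repeated copies
of a genotype inflate apparent LD.

## What the simulator emulates — and what it does not

`simulate_breeding_program()` generates: founders in linkage equilibrium
(LD then accrues purely from family structure, consistent with populations
where most observed LD is relatedness-driven); a partial circular mating
design with 4–5 crosses per parent filling an off-diagonal band of the cross
matrix; meiosis with Poisson crossovers and no interference (Haldane — the
simplest testable choice; the source analyses do not constrain the map
function); within-family truncation selection on a total-merit index (the
sum of standardised true breeding values — a modelable stand-in for visual
selection); carry-over of a control cultivar plus top-merit genotypes into
later trials; RCBD trials with optional AR1×AR1 spatial surfaces; and a
spike-and-slab trait architecture whose year-to-year effect wobble sets the
across-year genetic correlation (`ry_target`; near-unity by default, as
estimated for these traits).

Defaults are the study conditions: 28 linkage groups over 1,729.5 cM,
physical positions at 0.4 Mb/cM, five cycles, about 250 genotypes per trial
with roughly 40 carried over, five-replicate trials with seven-plot beds.
The trait set defaults to heritabilities spanning 0.2–0.55. The number of
seedlings raised per cross before selection is exposed as a parameter with
no claimed fidelity — the source material does not state it.

Not emulated: nursery propagation and its failures, pest/weather events,
genotype-by-location structure (reported negligible for this system),
dominance/epistasis, genotyping-array artefacts, and selection on traits
outside the simulated architecture. Passing tests on simulated data
therefore demonstrate the *statistical machinery* — estimator correctness,
the direction and rough magnitude of relatedness and averaging effects —
not the specific predictive abilities attainable on any real program's data.

## Numerical choices

- REML convergence: relative criterion change below $10^{-12}$–$10^{-14}$
  with quasi-Newton/simplex polish; variance ratios floored at $10^{-8}$.
- Non-positive-definite AR1 fits retry from a perturbed start before
  failing with diagnostics.
- GRM inversion uses Cholesky; singularity advises an identity blend.
- LD decay fitting multi-starts on a log grid over the rate parameter and
  refines by Levenberg–Marquardt; crossings are found by `uniroot` to
  $10^{-10}$.
- Model-selection ties break by parameter count, then BIC.
- Derived incidence averages round half away from zero (base `round()`
  half-to-even would not reproduce the published integers).
- All stochastic operations take explicit seeds; pipeline stages derive
  sub-seeds deterministically from one master seed, making reruns
  byte-identical.

## Problem sizes used by the test suite

The acceptance-level simulation study runs 20 seeds of the five-cycle
default program (about 250 genotypes/cycle, 2,000 markers, three traits with
$h^2$ 0.2/0.35/0.55, 1,000-iteration single chains), asserting that (a) mean
predictive ability with common genotypes exceeds the excluded-scenario mean,
(b) averaging predictions over cycles is non-inferior to single-cycle
prediction within 0.02, and (c) predictive ability rises with heritability.
Variance-component recovery uses 20 seeds at $n = 800$ (GBLUP, truth 0.5),
10 seeds of a five-year complete panel (FA2, truth 0.8), and 20
Wright–Fisher populations of true $N_e = 50$ with 500 unlinked SNPs sampled
at $S = 50$. These sizes were chosen as the smallest at which the asserted
contrasts are stable across seeds.

## Known limitations

- The Bayes B sampler is single-trait; multi-trait selection indices are out
  of scope.
- The FA2 fit maximises the likelihood directly; on very flat surfaces
  (e.g. a truly rank-1 truth fitted with two factors) the second factor is
  weakly identified, which affects loadings but not the reported correlation
  summaries materially.
- `ry_target` is interpreted as a magnitude; negative values are accepted
  but not meaningfully distinguishable from their absolute value in the
  two-year construction used.
- The dense AR1 REML engine scales as $O(n^3)$ per evaluation and is meant
  for single-trial sizes.
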
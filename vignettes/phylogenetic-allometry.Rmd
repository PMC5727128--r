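---
title: "Phylogenetic allometry, prediction and stereology: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic allometry, prediction and stereology: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloallometry)
```

This vignette is the package's own account of the statistics it
implements: the models, the assumptions behind them, the tunable
parameters, and the decisions taken where the methodological literature
leaves genuine latitude.

## The allometric model

Brain structures scale with the brain that houses them as a power law,
`y = c · x^b`, which is linear on log axes. We work throughout on the
log₁₀ scale:

    log10(y_i) = a + b · log10(x_i) + e_i,     e ~ N(0, σ² V(λ))

Species are not independent observations: close relatives inherit
similar deviations from the line. `V(λ)` encodes this. Its `(i, j)`
entry is the shared root-to-ancestor path length of species `i` and `j`
on the tree, with every off-diagonal entry multiplied by Pagel's λ and
the diagonal (each tip's root-to-tip depth) untouched. λ = 1 is the
full Brownian-motion covariance; λ = 0 removes all shared history and
the generalized-least-squares (GLS) fit collapses to ordinary least
squares — an identity `fit_pgls()` preserves exactly and the tests
assert. Intermediate λ attenuates, never inflates, the phylogenetic
signal; we restrict λ to [0, 1], the interval on which `V(λ)` is
guaranteed positive semi-definite for any tree.

### Estimating λ

λ is profiled by maximum likelihood: for each candidate λ, the GLS
coefficients and σ² have closed forms, leaving a one-dimensional profile
log-likelihood. That profile can be multimodal, so `fit_pgls()` scans a
0.05-spaced grid first and then runs bounded scalar optimisation
(tolerance 1e-6) in the bracketing interval, keeping whichever of the
grid point and local optimum scores higher. Whether published tables of
this kind used ML or REML is generally not recoverable from methods
sections; we default to ML and expose `method = "REML"` as a switch.
The test suite cross-checks both the coefficients and the ML λ against
an independent GLS implementation (`nlme::gls` with a Pagel correlation
structure) and against brute-force explicit matrix inversion.

### Reported summaries

- `sigma2` is the GLS residual quadratic form divided by `n − 2`. It is
  defined *relative to V*: on an ultrametric tree at λ = 0 it equals
  the OLS residual variance divided by tree height. Keep that in mind
  when comparing across trees.
- `r_squared` has no canonical GLS definition. We report
  `1 − RSS_GLS / TSS_GLS` with the total sum of squares taken about the
  GLS-estimated phylogenetic mean (an intercept-only GLS fit), so the
  quantity stays in [0, 1] and is comparable across λ values.
- Part–whole regressions (a structure against the brain that contains
  it) spuriously correlate; `allometry_table()` therefore supports
  "whole minus part" predictors, constructed on the raw volume scale
  *before* the log transform.

## Consensus trees

Tree sets (e.g. posterior samples from a phylogeny server) are reduced
with a strict >50% majority rule: a clade enters the consensus only if
its frequency strictly exceeds the threshold, so ties at exactly 50%
are excluded and the output is deterministic. Consensus utilities
differ silently in how they assign branch lengths; we use the
arithmetic mean of the clade's subtending edge over the trees that
contain the clade (tips: mean over all trees), which is the common
default and is pinned down by a hand-enumerated test. Clades above 50%
are mutually compatible, so the consensus always exists.

## Prediction intervals and outlier species

At a predictor value `x₀` the 95% interval for a *new species* is

    ŷ₀ ± t(0.975, n−2) · sqrt( σ̂²(v₀₀ − v₀ᵀV⁻¹v₀) + var(ŷ₀) )

with Student-t quantiles on the fit's residual degrees of freedom —
appropriate at the modest sample sizes (tens of species) typical of
neuroanatomical datasets.

The band needs a convention for the new species' phylogenetic position.
A scatterplot draws *one* band for all species, which cannot be
tip-specific; the default therefore treats the hypothetical new species
as an unrelated lineage of root-to-tip depth equal to the tree height
(`v₀ = 0`, `v₀₀ =` height). For a species with a known position,
`target_covariance` accepts its covariance vector with the sample; the
predicted mean then gains the BLUP term `v₀ᵀV⁻¹(y − Xβ̂)` and the
variance shrinks by `v₀ᵀV⁻¹v₀`. Whether published bands of this kind
used the global or the position-aware convention is usually
indistinguishable from the figures; we default to the global plotting
convention and test both (the position-aware mode via leave-one-out
coverage).

`flag_outliers()` recomputes the bounds exactly at each species'
predictor value rather than interpolating a plotted grid, and reports
the signed deviation in units of the band half-width.

## Bayesian posterior prediction for a left-out species

Whether a focal species is *exceptional* is asked more sharply by
excluding it from the regression and predicting it: Markov chain Monte
Carlo over `(a, b, σ², λ)` on the non-focal species, with each retained
iteration emitting one draw of the focal species' trait from the
conditional normal given its phylogenetic position. Each iteration
conditions on a tree drawn uniformly at random from the supplied set,
so topological uncertainty propagates into the predictive distribution.
The observed value's percentile among the draws, and its position
relative to the central credible interval, give the verdict.

Choices the cited procedure class leaves open, and ours:

- **Priors:** flat on the coefficients and on log σ², uniform on
  λ ∈ [0, 1]. With these, the posterior mean of the slope tracks the
  PGLS point estimate (asserted within Monte-Carlo error in the tests).
- **Proposals:** Gaussian random walks, λ reflected at its bounds,
  scales initialised from OLS standard errors and adapted every 25
  burn-in iterations toward a 20–45% acceptance rate; the realised rate
  is reported in the result object.
- **Schedule:** the reference schedule of 100,100 iterations with
  burn-in 100 and thinning 100 retains exactly
  `floor((100100 − 100)/100) = 1000` draws; that arithmetic is the only
  reading of "burn-in 100, thin 100" consistent with a 1,000-draw
  posterior, and it is what `posterior_predict_phylo()` implements.
- **Determinism:** one seed fixes the tree choices, proposals and
  predictive draws bit-for-bit.
- The degenerate setting σ² = 0 with fixed λ is supported and collapses
  every draw onto the phylogenetically conditioned regression value — a
  useful analytic check, tested against the position-aware prediction
  band.

Calibration is verified end-to-end: for data simulated under the fitted
model, the left-out species' percentile is uniform on (0, 100)
(Kolmogorov–Smirnov, 100 replicates), and a species planted 5 residual
standard deviations high is called "above" the 95% credible interval
in ≥95 of 100 seeded runs. Note that a "+k residual SD" offset is
`k·sqrt(σ²·h)` on the log scale, `h` the tree height, because a tip's
marginal residual variance is `σ²·h`, not `σ²`.

## Stereological estimators

The measurement side of any such dataset rests on two unbiased
estimators.

**Optical fractionator.** Cells are tallied in counting frames placed
systematically with random phase on every `1/ssf`-th section;
`N̂ = ΣQ⁻ · (1/ssf) · (1/asf) · (1/tsf)` with
`asf = frame area / grid area`. The thickness sampling fraction
defaults to 1 because disector height and measured section thickness
are rarely reported; it is configurable. The coefficient of error
follows Gundersen–Jensen: Poisson "nugget" variance `ΣQ⁻` plus a
systematic-sampling term from lag-0/1/2 products of the section
tallies, smoothness class `m = 1` by default (smooth biological
profiles), `m = 0` available as the conservative choice. In the
Poisson-dominated limit CE → `1/sqrt(ΣQ⁻)`.

**Cavalieri volumes.** Serial profile areas are summed and multiplied
by the distance between *measured* sections. Methods-section phrasings
like "multiplied by the distance between sections and slice thickness"
are dimensionally ambiguous; the only coherent reading — and the
standard Cavalieri estimator — is `volume = Σ areas × (mounting
interval × cut thickness)`, e.g. every 4th section at 40 μm gives
0.16 mm spacing and mm³ from mm² areas. That reading is implemented
and flagged here deliberately.

The synthetic 3-D cell fields honor the estimators' unbiasedness
conditions: uniformly random section offset, and a fresh uniformly
random grid phase on every sampled section (as fractionator software
applies in practice). Under a design yielding total tallies of ~500
(section fraction 1/5, 70×70 μm frames on a 140×140 μm grid for a
10,000-cell field), the mean estimate over 100 seeds sits within 2% of
truth; an every-10th design with 70×70 frames on a 250×250 grid over a
~100,000-cell spherical field reproduces total tallies of 400–1,100 and
CEs of 0.03–0.06, the range reported for real vulture material.

## Two-species comparisons

With three specimens per species, inference is deliberately limited to
two-sample t-tests on absolute values and on per-specimen proportions
(region/brain, and olfactory bulb/telencephalon). Two decisions matter:

- **Pooled variance (Student), not Welch, by default.** Pooled
  reproduces the published p-values of this study type at printed
  precision (6 of 7 rows in the motivating dataset); Welch does not.
  Both are available. One published row (nucleus rotundus, printed
  p = 0.21) is reproducible under neither convention from the printed
  summaries (pooled gives 0.18, Welch 0.25) and coincides with the
  relative-size p-value in the accompanying text; we treat it as a
  probable transcription slip and exclude it from assertions while
  still computing it.
- **Proportions are per-specimen**, never ratios of group means, so
  proportion-mode tests have real sampling variation; a null simulation
  (species differing only by uniform scale) confirms no artifactual
  significance, and a 4× proportional shift at n = 3 is detected in
  ≥95/100 seeded runs.

Cell counts (e.g. mitral cells) are excluded from the proportion
computation by default: they are not volumes and a count/volume ratio
is not a part-of-whole proportion.

## The synthetic-data generator

The generator produces exactly the structures the estimators assume,
which is what makes the test suite informative:

- birth–death trees conditioned on the tip count (`ape::rphylo`), so
  total extinction cannot occur by construction;
- a Brownian predictor and residuals drawn *jointly* multivariate
  normal with covariance `σ²V(λ)` — tip-independent noise would make λ
  recovery meaningless;
- raw-scale (antilog) trait export, so the pipeline's own log₁₀ step is
  exercised;
- defaults in the empirically observed ranges for avian brain
  allometry: slopes 0.4–0.9, λ 0.27–0.95, and a two-species specimen
  table whose means embody the motivating contrast (a ~4× olfactory
  bulb in a ~20% smaller brain), with mean-preserving lognormal noise
  (log-SD 0.06, comparable to within-species variation in small museum
  series).

What it does **not** emulate: measurement error distinct from
biological residual variance, correlated trait evolution beyond the
single predictor–response pair, non-ultrametric rate variation, and
body-mass allometry as a third variable. Passing tests therefore
demonstrate the estimators' correctness under the stated model, not
robustness to violations of it.

## Problem sizes and numerical choices

The simulation scales used by the tests and the acceptance script are
package choices balancing Monte-Carlo error against wall-clock time:
parameter recovery uses 200 datasets of 100 tips; band coverage 2,000
fresh tips over 40 datasets; MCMC calibration 100 replicates at a
reduced schedule (4,100 iterations) after the retained-draw arithmetic
is verified once at the full reference schedule; stereology 100 seeded
fields. At these sizes the standard error of each checked mean is several
times smaller than its acceptance band.

Numerics: all GLS algebra goes through Cholesky whitening (no explicit
inverses); a singular `V(λ)` raises an error naming the offending λ;
zero-length internal branches are accepted (the covariance stays PSD);
species labels are matched exactly, case-sensitively, after trimming
whitespace, and mismatches are errors by default (`match = "intersect"`
opts into dropping with a logged count). Consensus branch lengths are
written at full double precision.

## Known limitations

- Single-predictor PGLS only; no multivariate regression, and no
  Ornstein–Uhlenbeck or other correlation structures beyond Pagel's λ.
- The MCMC is a plain random-walk sampler; for very small samples or
  extreme λ the chain mixes slowly, and the reduced-schedule defaults
  in the tests trade some precision for runtime.
- The λ search domain is [0, 1]; values above 1 (over-dispersed
  phylogenetic signal) are deliberately out of scope since `V(λ)` can
  lose positive-definiteness there.
- Published-table checks (`published_fit_check()`) require the original
  measurement supplement and tree downloads, which do not ship with the
  package; the entry point is exercised on synthetic stand-ins instead.
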
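---
title: "Methods: causal mediation with elastic shape mediators"
author: "shapemed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal mediation with elastic shape mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapemed)
```

## The scientific problem

Genome-wide studies of neurodegeneration routinely find variants associated
with cognitive decline, but association alone says nothing about *pathway*.
A natural intermediate phenotype (endophenotype) is the shape of a brain
structure — for instance the planar contour of the corpus callosum on the
midsagittal slice, traced as an ordered sequence of landmarks. `shapemed`
implements a three-stage framework for asking how much of a variant's effect
on a scalar clinical outcome is routed through such a shape:

1. **Screen.** A fast per-SNP linear scan of the outcome with covariate
   adjustment and Benjamini–Hochberg selection produces a candidate set of
   variants.
2. **Represent.** Each subject's contour is converted to a square-root
   velocity function (SRVF) and elastically aligned to a Karcher-mean atlas,
   yielding a functional shape mediator on a common grid.
3. **Mediate.** For each candidate variant, two regressions — a
   shape-on-scalar model for the mediator and a scalar-on-shape model for
   the outcome — yield plug-in causal estimands with wild-bootstrap
   inference.

## Shape representation

For a contour with coordinate functions $f(s) = (f_1(s), f_2(s))^\top$ on
$s \in [0,1]$, the SRVF is
$$ q(s) = \frac{\dot f(s)}{\sqrt{|\dot f(s)|}}. $$
Under this transform the elastic metric on curves becomes the flat $L^2$
metric; translation is removed outright, and rotation and
reparameterization act as isometries, so registration reduces to the
optimization
$$ (O_i^*, \tau_i^*) = \arg\inf_{O \in SO(2),\, \tau \in \Gamma}
   \| q_\mu - O\,(q_i \circ \tau)\sqrt{\dot\tau} \| $$
against an atlas $q_\mu$. The aligned representation
$m_i(s) = O_i^*\,(q_i \circ \tau_i^*)(s)\sqrt{\dot\tau_i^*(s)}$ is the
mediator carried downstream. A note on conventions: the square-root form of
the denominator is what makes the group actions isometric and gives a
unit-arc-length curve a unit-norm SRVF; the package uses it throughout.

Design choices in this stage:

* **Normalization.** Translation is removed by centroid centering, scale by
  rescaling to unit arc length (equivalently, unit SRVF norm); contours are
  resampled uniformly by arc length. Rotation and parameterization are
  *not* removed here — they are optimized during alignment.
* **Open-curve convention.** Warping functions preserve the endpoints
  ($\tau(0)=0$, $\tau(1)=1$), so contours are treated as open curves with a
  consistently ordered seed landmark. Seed-point search for closed curves
  is deliberately out of scope; landmarking protocols that fix a seed point
  satisfy the convention.
* **Derivatives.** Central finite differences on the uniform grid,
  one-sided at the endpoints; points where the speed falls below $10^{-12}$
  of the mean speed get $q = 0$.
* **Registration.** Rotation is solved in closed form by Procrustes SVD
  with a determinant-sign correction (proper rotations only, never a
  reflection). Reparameterization is solved by dynamic programming over the
  standard lattice with local slopes $\{l/k : 1 \le k, l \le 3\}$ — exact
  on its lattice, and the identity warp is always admissible, so alignment
  can never worsen the objective. The search is implemented in compiled
  code; a 200-point grid registers in about a millisecond.
* **Atlas.** The Karcher mean is initialized at the medoid (deterministic;
  no seed dependence), then iterates align–average–renormalize with two
  rotation/warping sweeps per subject per iteration, tolerance $10^{-5}$ on
  the mean change, at most 20 iterations. The total aligned squared
  distance is non-increasing across iterations, which the tests assert.

## The mediation models

With $x_i$ the dosage of one variant, $c_i$ the confounders (with
intercept), and $m_{i,j}(s)$ the aligned SRVF components, the two
structural models are

$$ m_{i,j}(s) = x_i\,\alpha_j(s) + c_i^\top \xi_j(s) + \eta_{i,j}(s) +
   \epsilon_{i,j}(s), \qquad j = 1, 2, $$

$$ y_i = x_i\,\gamma + \sum_{j=1}^{2} \int_0^1 m_{i,j}(s)\,\beta_j(s)\,ds
   + c_i^\top \kappa + \delta_i, $$

where $\eta_i$ is a smooth mean-zero subject effect, $\epsilon$ is
measurement noise, and $\delta$ is outcome noise.

* The functional-response model is fitted by **pointwise OLS** at every
  grid point — no smoothing by default. This keeps the decomposition
  `fitted + residual = observed` exact, which the bootstrap relies on.
* The functional-predictor model is fitted by **FPCA-truncated OLS**: the
  two mediator components are stacked into one concatenated function (so
  cross-component covariance is respected), centered, and expanded in the
  eigenbasis of the pooled sample covariance under trapezoid quadrature
  weights. Subject scores enter an OLS of $y$ on $(x, z, c)$ and
  $\beta_j(s)$ is reconstructed from the basis. Degenerate mediators
  ($m \equiv 0$) reduce the model to OLS of $y$ on $(x, c)$ exactly.
* **Truncation choice.** A proportion-of-variance rule alone is unreliable
  when the mediator carries white measurement noise: the noise spreads a
  flat bulk of small eigenvalues across the spectrum, a 95% rule then
  retains dozens of near-noise components, and their tiny eigenvalues
  inflate the pointwise variance of the reconstructed $\beta_j(s)$ (the
  integral AIE is much less affected — noise components contribute little
  to it — but the SAIE curve and its band become useless). The default
  (`basis_config(select = "floor")`) therefore keeps PVE 0.95 as the outer
  envelope and, within it, retains only eigenvalues clearly above the
  noise bulk: the bulk level $\hat\nu$ is estimated iteratively as the
  mean of the excluded tail and the cut is the random-matrix bulk edge
  $(1+\sqrt{p/n})^2\hat\nu$ (the same logic as parallel analysis).
  Spectra without a noise bulk — smooth, low-rank mediators — keep
  everything. `select = "pve"` restores the raw rule; fixed `K` overrides
  both. The selection never looks at the outcome, so it does not bias
  downstream inference the way outcome-driven selection would.
* All integrals use the trapezoid rule on the shared grid, so the fitting
  step and the estimand step are numerically consistent with each other.

## Causal estimands

For the exposure contrast $0$ vs $1$ under the usual sequential-ignorability
assumptions (no interference; no unmeasured exposure–outcome,
mediator–outcome, or exposure–mediator confounding given $c$; no
exposure-induced mediator–outcome confounder):

$$ \mathrm{ADE} = \gamma, \qquad
   \mathrm{SAIE}(s) = \sum_j \alpha_j(s)\beta_j(s), \qquad
   \mathrm{AIE} = \int_0^1 \mathrm{SAIE}(s)\,ds, $$

with $\mathrm{ATE} = \mathrm{ADE} + \mathrm{AIE}$ holding at machine
precision by construction, and the mediation proportion reported as
$\mathrm{MP} = |\mathrm{AIE}/\mathrm{ATE}| \times 100\%$ (the absolute value
keeps MP interpretable when direct and indirect effects have opposite
signs; it is undefined and flagged when $\mathrm{ATE} = 0$). The SAIE curve
localizes mediation along the contour: its significant subregions are where
shape change transmits the genetic effect.

## Wild-bootstrap inference

Per-subject multipliers $v_i, w_i$ (Rademacher by default; Mammen and
Gaussian available) scale whole residual functions, preserving
heteroscedasticity and within-curve correlation:

$$ m_i^*(s) = \hat m_i(s) + v_i\,\tilde r_i(s), \qquad
   y_i^* = \hat\gamma x_i + \sum_j \int m_{i,j}^*(s)\hat\beta_j(s)\,ds
   + \hat\kappa^\top c_i + w_i \tilde\delta_i. $$

Two details matter and were chosen deliberately:

* **The starred outcome is generated from the starred mediators** through
  the fitted outcome model, so each replicate is a draw from the fitted
  structural system. Rebuilding $y^*$ from the *original* mediators while
  refitting against independently perturbed ones decorrelates the two and
  inflates interval widths several-fold; the package does not do that.
* **Leverage adjustment.** Residuals are scaled by $1/\sqrt{1 - h_{ii}}$
  (the HC2 form) before multiplication. The outcome design can carry many
  FPCA score columns, and raw OLS residuals are shrunk by exactly the
  leverage the adjustment restores; without it the intervals are
  systematically narrow.

Intervals are symmetric: $C(\vartheta)$ is the empirical $1-\vartheta$
quantile of $|\theta^*_b - \hat\theta|$ and the interval is
$\hat\theta \pm C(\vartheta)$. The simultaneous band for SAIE uses the
sup-norm deviation, giving a constant-width band whose half-width dominates
every pointwise interval; significance calls require strict zero exclusion.
Multipliers for the two models are independent (the two error processes are
modeled as independent), and the replicate stream is deterministic given
the seed. The FPCA basis functions are held fixed at the original fit's
basis across replicates — re-estimating the eigenbasis per replicate lets
near-degenerate eigenvalues near the noise floor swap in and out of the
truncation, which makes $\beta^*$ jump discretely between replicates and
artificially inflates the simultaneous band (holding smoothing/basis
tuning fixed across bootstrap replicates is the standard practice). Across candidate SNPs, significance is read
off the per-SNP AIE intervals with no additional multiplicity correction —
the screening stage is where family-wise control is imposed.

## The synthetic-data generator

`simulate_cohort()` draws from exactly the generative structure above:
binary carrier genotypes with configurable allele frequency (additive
coding available), confounders (intercept, one standard normal, one
Bernoulli(0.5)), subject effects from a squared-exponential Gaussian
process (length scale 0.2, variance 0.5), white measurement noise and
outcome noise ($\sigma_\epsilon = \sigma_\delta = 0.5$), and
unit-magnitude smooth coefficient functions
($\alpha = \beta = (\sin 2\pi s, \cos 2\pi s)$, $\gamma = 0.5$), giving
$\mathrm{AIE} = 1$, $\mathrm{ATE} = 1.5$ — a moderate signal-to-noise
regime. The implied true estimands are returned in closed form by
quadrature, and identical seeds give byte-identical cohorts.

`simulate_hidden_confounder()` adds a standard-normal $U_i$ to both
structural equations and withholds it from the returned covariates,
violating the mediator–outcome ignorability condition. The mediator-side
loading follows a smooth half-period sine in both components: a constant
loading would be $L^2$-orthogonal to the default exposure-effect functions
and would therefore induce no first-order AIE bias — a degenerate
sensitivity design. With the sine loading, AIE bias grows essentially
linearly in the outcome-side strength; on the mediator side it saturates
(the confounder inflates mediator variance at the same rate it builds
covariance), which is why the packaged sensitivity analysis varies the
outcome-side strength over $\{0, 0.5, 1, 2\}$ at fixed mediator loading.

What the generator does *not* emulate: linkage disequilibrium between
markers, genotyping error, realistic contour segmentation noise, or any
nonlinearity in the shape–outcome relationship. Passing tests therefore
demonstrate the estimators' correctness *under the model*, not robustness
to real-data artifacts.

`simulate_shape_cohort_from_template()` exercises the shape stage
end-to-end: it applies random rotations, translations, scalings, smooth
boundary-preserving warps, and optional landmark jitter to a synthetic
corpus-callosum-like Fourier outline (`cc_template()` — a stand-in shape,
not derived from imaging data). Alignment should remove essentially all of
this nuisance variation; the tests require a post- to pre-alignment
variance ratio below 0.1.

## Numerical choices and degenerate inputs

* Grids are uniform on $[0,1]$; all quadrature is trapezoid.
* Warping functions returned by the dynamic program are monotone
  piecewise-linear with $\tau(0)=0$, $\tau(1)=1$; grids smaller than 5
  points are refused.
* A numerically zero Procrustes cross-covariance returns the identity with
  a warning rather than an arbitrary rotation.
* Monomorphic SNPs get `NA` effects and a flag instead of an error;
  rank-deficient covariates and collinear mediation designs raise errors
  naming the offending columns.
* FPCA retains only numerically nonzero eigenvalues (relative floor
  $10^{-10}$); a request for more components than the data's rank is
  truncated to the rank, and a saturated outcome design raises an error.
* Missing dosages are imputed to the per-SNP mode at table construction.

## Monte-Carlo problem sizes

The validation suites run at sizes chosen to finish quickly while keeping
Monte-Carlo error well inside the assertion margins: interval coverage at
$n = 200$, 300 bootstrap replicates, 200 simulation replicates
(Monte-Carlo SE $\approx 1.5$ points at 95% coverage); band size at 150
replicates; band power at 60; sensitivity trend at 60 per strength; screen
FDR at 500 global-null replicates of a $200 \times 400$ dosage matrix;
error-decay curves at $n \in \{200, 400, 800\}$ with 60 replicates per
size. `scripts/acceptance.R` recomputes the same quantities at comparable
sizes with all seeds derived from its `--seed` argument.

## Known limitations

* Closed-contour seed alignment is not searched; inputs must share a
  consistent landmark ordering and seed.
* The screen is fixed-effects OLS; relatedness/kinship random effects are
  not modeled, and population structure must be supplied as covariates
  (e.g. principal components).
* Mediation is per-SNP; joint multi-variant mediation and
  exposure–mediator interactions are out of scope.
* The elastic distance is computed on the lattice the dynamic program
  searches; it is exact on that lattice but an approximation to the
  continuum infimum.

## A worked example

```{r example, eval = FALSE}
sc <- simulation_scenario(n = 200, T = 50, seed = 7)
dat <- simulate_cohort(sc)
fit <- mediate_shape(dat$y, dat$M, dat$x, dat$C,
                     boot = bootstrap_config(n_boot = 500, seed = 1))
summary(fit)
plot(fit)   # SAIE curve with simultaneous band and flagged subregions
```
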
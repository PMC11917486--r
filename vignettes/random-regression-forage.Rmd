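---
title: "Random regression models for multi-harvest forage yield trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression models for multi-harvest forage yield trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmforage)
```

## The problem

Perennial forage species — alfalfa, guineagrass, brachiaria — are harvested
repeatedly from the same plots, often for years. Dry-matter yield (DMY) at
each harvest is one point on a genotype's longitudinal trajectory, and the
trajectory, not any single harvest, is what a breeder selects on. Harvests
are unevenly spaced (frequent in the wet season, sparse in the dry season),
genotype rankings can change between seasons (genotype-by-harvest
interaction), and the precision of each harvest's genotype means differs.
`rrmforage` implements a two-stage analysis of such trials:

1. **Stage one** fits a linear mixed model per harvest (genotypes fixed;
   blocks, incomplete blocks, or rows and columns random, depending on the
   design) and extracts genotype BLUEs, their variance matrix, and the
   residual variance.
2. **Stage two** regresses the BLUEs on time with a weighted random
   regression model (RRM) on normalized Legendre polynomials, carrying
   stage-one uncertainty forward through Smith weights — the diagonal of the
   inverse BLUE variance matrix per harvest.

## The model

Harvest days $t$ are rescaled to $[-1, 1]$ by
$t^* = -1 + 2(t - t_{\min})/(t_{\max} - t_{\min})$. With $\phi_n(t) =
\sqrt{(2n+1)/2}\,P_n(t)$ the normalized Legendre polynomials (computed
exactly from the three-term recursion; the basis is evaluated as
$\Phi = M\Lambda$ with $M$ the monomial matrix of rescaled times and
$\Lambda$ the upper-triangular coefficient matrix), the stage-two model is

$$ y = \Phi_1 \beta + \Phi_2 u_g + e, \qquad
   u_g \sim N(0,\, I \otimes K_g), \qquad
   e \sim N(0,\, \sigma_e^2\, \mathrm{diag}(1/\pi)), $$

where $\beta$ are fixed Legendre coefficients of degree $d$ describing the
population mean trajectory, each genotype has a random coefficient vector of
degree $m$ with unstructured covariance $K_g$, and $\pi$ are the Smith
weights. When the weights are exact inverse BLUE variances, $\sigma_e^2$ is
close to 1; its fitted value absorbs any miscalibration of the weights.

Estimation is restricted maximum likelihood. $K_g$ is parameterized by its
log-Cholesky factor (lower-triangular factor stored column-wise, diagonal on
the log scale), which enforces positive semidefiniteness without
constraints; $\sigma_e^2$ enters on the log scale. $\beta$ is profiled out
by generalized least squares, so the optimizer works only on the
$(m+1)(m+2)/2 + 1$ variance parameters. Because the marginal covariance is
block-diagonal by genotype, the likelihood is accumulated genotype-wise, and
genotypes sharing an observation pattern (same times and weights — the
common case for complete tables) share one Cholesky factorization per
evaluation, which is what makes fits with hundreds of genotypes take
fractions of a second.

### Numerical choices

* **Optimizer**: `nlminb` with box bounds $[-30, 30]$ on the transformed
  parameters (so variances live in roughly $e^{-60}$–$e^{60}$; a variance
  component collapsing to the lower bound is the "at boundary" case and is
  warned about), relative tolerance $10^{-8}$, up to 500 iterations.
* **Multiple starts** (default 5): the first start is a moment estimate —
  weighted least squares for the fixed curve, per-genotype OLS of the
  residual curves, and the empirical covariance of those coefficients with
  its spectrum floored away from zero; further starts add seeded
  $N(0, 0.5^2)$ jitter. The fit keeps the best optimum and records the
  likelihood at every start, so dominance over all starting points is
  testable.
* **Non-finite likelihoods** (indefinite $V$, overflow) return $-\infty$ so
  the optimizer retreats rather than aborts.
* **Degenerate inputs**: schedules with fewer than two distinct days are
  rejected; basis degrees above 10 are rejected (they serve no use at
  realistic harvest counts and the monomial representation of $\Lambda$
  degrades); genotypes observed at fewer than $m+1$ distinct times are
  excluded from variance estimation with a warning but still receive BLUPs
  from the mixed-model equations at the estimated parameters.
* **Prediction** outside the observed harvest window is refused: polynomial
  extrapolation is not trustworthy and no scientific question here needs it.
* The REML log-likelihood convention omits the additive constant
  $\tfrac12\log|X'X|$ (the same convention as `lme4`).

### Choosing the polynomial degrees

The **fixed degree** follows the trajectory-shape rule: smooth the
harvest-mean trajectory by loess (span 0.75 by default; the span floor is
raised so each local window keeps about five harvests, since with few
harvests a narrow span interpolates and over-counts wiggles), count the
interior local extrema $c$ of the smoothed curve on a dense grid, and use
$d = c + 1$. A monotone trajectory gets a line; one peak and one trough —
the typical two-season year — gets a cubic. Trajectories oscillating faster
(several seasonal cycles) need a narrower span, which is exposed as an
argument. The count is capped at saturation ($d < $ number of harvests).

The **random degree** is chosen by BIC over $m = 0, \dots, m_{\max}$:
$\mathrm{BIC} = -2\ell_{\mathrm{REML}} + p_v \log n_{\mathrm{eff}}$ with
$p_v = (m+1)(m+2)/2 + 1$ free variance parameters and $n_{\mathrm{eff}}$
the observation count minus the fixed-effect rank. Ties break toward the
smaller $m$. Whether the penalty should use the REML or ML likelihood and
which $n$ belongs in the $\log$ is not settled usage; the definition above
is this package's, stated so that its numbers are reproducible.

## The genetics layer

From a fit, `summary()` (or the individual functions) derives:

* $\Sigma_g = \Phi_2 K_g \Phi_2'$ — genetic covariance across harvest
  times, on the original kg/ha scale;
* genetic correlations and their mean ± SD over harvest pairs — near 1
  everywhere means rankings barely change (simple interaction), low or
  negative values mean crossovers (complex interaction);
* the heritability trajectory
  $H_j^2 = \mathrm{diag}(\Sigma_g)_j / (\mathrm{diag}(\Sigma_g)_j +
  \bar\sigma_e^2 / r)$, with $\bar\sigma_e^2$ the mean stage-one error
  variance and $r$ the replication count. The division by $r$ is kept
  exactly as the genotype-mean heritability definition prescribes even
  though stage two operates on BLUEs; $r$ is user-supplied, and a caller
  who prefers a weights-based denominator can pass `sigma_e_bar` directly;
* eigenfunctions of $K_g$: $\Psi_k(t) = \sum_m (v_k)_m \phi_m(t)$ with
  $v_k$ the $k$-th eigenvector. A flat leading eigenfunction is a gene pool
  expressed uniformly over time. Signs are fixed by making each
  eigenvector's largest-magnitude loading positive. "Importance" is
  reported both as eigenvalue shares (summing to 100%) and as $K_g$-diagonal
  shares (intercept/slope variance fractions): both readings are used in
  practice and they answer different questions, so neither is privileged.

## Adaptability and stability

For genotype $i$ with total curve (fixed plus random Legendre coefficients,
padded to a common degree and mapped to monomial coefficients $b_k$ through
$\Lambda$):

* **Adaptability** $A_i = \int_{-1}^{1} \sum_k b_k t^k\, dt$, evaluated in
  closed form — odd powers vanish, each even power contributes
  $2 b_k/(k+1)$. It is the area under the reaction norm: total expected
  DMY accumulation over the standardized trial window. An option rescales
  to kg/ha × days (multiply by $(t_{\max}-t_{\min})/2$); rankings are
  unaffected, so the standardized scale is the default.
* **Stability** $CV_{c,i} = \sigma_{c,i} / (b_0 + g_{i0})$, the curve
  coefficient of variation (Type I, biological stability; lower = more
  stable). The denominator is taken literally as the sum of the degree-0
  Legendre coefficients — not the curve mean, which would differ by the
  factor $\phi_0 = \sqrt{1/2}$ and by even-term contributions.
  $\sigma_{c,i}$ is the population SD of the continuous curve over
  $[-1,1]$, computed on a dense grid (default 1001 points) with Simpson
  quadrature weights; the weighting matters, because a plain average over
  grid points carries an $O(1/n)$ endpoint bias that would swamp the
  refinement tolerance the implementation promises (1001- and 10001-point
  grids agree to $10^{-4}$ relative). A flag switches to the plain SD at
  the observed harvest times for users who want the discrete reading.

`selection_table()` combines both: quadrants are cut at the across-genotype
means of $A$ and $CV_c$, the "select" quadrant being high-$A$/low-$CV_c$,
with the top fraction by $A$ (default 10%) flagged. The Pearson correlation
between $A$ and $CV_c$ is reported; it tends to come out negative because
the intercept BLUP raises $A$ and simultaneously enlarges the $CV_c$
denominator.

## The synthetic-trial generator

`sim_config()` + `simulate_trial()`/`simulate_blues()` generate trials from
exactly the generative assumptions of the model: genotype coefficient rows
drawn from $N(0, K_g)$, curves built on the same basis, a fixed seasonal
curve, independent design effects, and Gaussian plot (or BLUE) error with
per-harvest variances. Harvest days alternate wet-season and dry-season
gaps with optional jitter. Default magnitudes imitate a tropical forage
trial: mean yields of a few thousand kg/ha
(`beta = c(3500, 300, -450, 250)`, a cubic seasonal mean curve), coefficient
covariance `K_g = [[2e5, -4e4], [-4e4, 8e4]]`, plot error $3\times10^5$,
block variance $5\times10^4$, three replicates, ten harvests with 35/90-day
wet/dry gaps — choices that put per-harvest heritabilities in the moderate
band (~0.4–0.7) typical of replicated forage trials.
All randomness derives from the single config seed through fixed
per-component sub-streams, so adding harvests does not change the genotype
draws.

What the generator deliberately does **not** emulate: spatially correlated
field error (no P-spline surface, no AR×AR residuals — the stage-one models
here use independent random row/column or block effects, and users with a
spatial stage-one analysis can import its BLUE/weight table directly),
non-Gaussian yields, curve shapes outside the polynomial family, and
serially correlated within-plot errors across harvests. Passing tests
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions, not robustness to field realities the model does
not describe.

## Worked example

```{r example}
cfg <- sim_config(n_genotypes = 50, n_harvests = 8, n_reps = 3, seed = 2024)
trial <- simulate_trial(cfg)
blues <- stage1_blues(trial$plots, design = "rcbd")
fit <- rrm(blues, fixed_degree = "auto", random_degree = "auto",
           m_max = 2, seed = 1, reps = 3)
summary(fit)
```

```{r selection}
sel <- selection_table(fit, top = 0.10)
head(as.data.frame(sel))
attr(sel, "correlation_A_CVc")
```

```{r plots, fig.width = 6, fig.height = 4}
plot(fit, highlight = sel$genotype[sel$selected])
plot(sel)
```

## Problem sizes and verification

The package's own test suite verifies, among other things: the basis
constants and orthonormality by dense quadrature; the REML likelihood
against a brute-force dense error-contrast evaluation on a 3-genotype ×
4-harvest instance over 25 random parameter points (agreement to
$10^{-8}$); parameter recovery on 20 simulated trials of 200 genotypes ×
10 irregular harvests (mean relative bias of the $K_g$ diagonal and of
$\sigma_e^2$ under 10%, BIC recovering the true random order); the
closed-form adaptability against $10^5$-point quadrature on 100 random
curves; and stage-one BLUEs against an explicit GLS oracle. These sizes
were chosen as the smallest at which the stochastic checks are stable,
so the whole suite runs in about a minute.

## Known limitations

* Stage one covers RCBD, alpha-lattice and row-column designs with
  independent random effects; smooth spatial surfaces must be fitted
  externally and imported.
* The residual structure in stage two is the Smith-weight diagonal only —
  no heterogeneous-by-harvest residual variances beyond what the weights
  encode, no factor-analytic or spline covariance alternatives.
* Reaction norms are polynomials: adequate within the observed window,
  meaningless outside it (hence the extrapolation refusal), and liable to
  oscillate at degrees near saturation.
* REML surfaces for small genotype numbers and large $m$ can be flat or
  boundary-bound; the multiple-start machinery reports, but cannot always
  repair, such cases.
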
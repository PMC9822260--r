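---
title: "Modelling interdivision-time correlation patterns on lineage trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interdivision-time correlation patterns on lineage trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heritime)
```

## The model and its assumptions

`heritime` treats the interdivision time of a cell as a linear readout of
`N` hidden, heritable *cell cycle factors*. Writing `x_p` for the factor
fluctuation vector of cell `p` (heap-indexed: daughters of mother `m` are
`2m` and `2m+1`),

$$x_{2m} = \theta x_m + z_{2m}, \qquad x_{2m+1} = \theta x_m + z_{2m+1},
\qquad \tau_p = \bar\tau + \alpha^\top x_p .$$

The $N \times N$ inheritance matrix $\theta$ transmits fluctuations from
mother to daughter; the noise pair $(z_{2m}, z_{2m+1})$ is zero-mean with
block covariance $[[S_1, S_2], [S_2^\top, S_1]]$, independent across
mothers, so $S_2$ encodes correlated sister noise. $\alpha$ is a binary
vector selecting which factors feed the interdivision time; this is a
normalisation, not a restriction, because factor scales are absorbed into
$\theta$ and $S_1$ (the constructor therefore rejects non-binary
$\alpha$ rather than silently rescaling). Assumptions worth keeping in
mind:

* **linearity** — the model describes small fluctuations about the mean;
  strongly nonlinear inheritance maps are out of scope;
* **symmetric division** — both daughters receive the same deterministic
  map $\theta$;
* **stationarity** — spectral radius $\mathrm{SR}(\theta) < 1$, enforced
  everywhere, so correlation patterns do not depend on initial
  conditions;
* **distribution-freeness of the targets** — every quantity the package
  predicts (variance, correlations, patterns, periods) depends only on
  first and second moments, not on the noise law.

The stationary factor covariance solves the discrete Lyapunov equation
$S_1 = \Sigma - \theta \Sigma \theta^\top$, computed exactly by solving
$\mathrm{vec}(\Sigma) = (I - \theta \otimes \theta)^{-1}
\mathrm{vec}(S_1)$ (`solve_lyapunov()`); for the small $N \le 4$ used
here this is preferable to iterative schemes, and the power-series form
is kept only as an independent oracle in the tests.

Pairs of cells on a tree are indexed by the family relation $(k, l)$:
generations from each cell to the most recent common ancestor. The
generalised tree correlation function is

$$\rho(k,l) = \frac{\alpha^\top \omega(k,l)\, \alpha}{\alpha^\top \Sigma\,
\alpha}, \qquad \omega(k,l) = \theta^k \Sigma (\theta^l)^\top +
\mathbb{1}_{k\ge1}\mathbb{1}_{l\ge1}\, \theta^{k-1} S_2
(\theta^{l-1})^\top .$$

`tree_correlation()` evaluates this matrix-power form, which is exact for
*any* stationary $\theta$, including defective (non-diagonalizable) ones.
The eigen-expansion $\rho(k,l) = \sum_{ij} w_{ij} \lambda_i^k
\lambda_j^l$ (`eigen_expansion()`, `correlation_function()`) is used only
where it adds value: pattern analysis and smooth continuous-argument
curves. For a defective $\theta$ the expansion is not unique and the
function refuses with a pointer back to the matrix-power path; a complex
power $\lambda^k$ uses the principal branch.

## Pattern taxonomy and periods

The eigenvalues of $\theta$ classify the pattern (`classify_pattern()`,
exact 2×2 discriminant in `classify_theta()`): real positive →
*aperiodic*; any real negative → *alternator*; a complex pair →
*oscillator*. Two tie-breaks had to be fixed: an eigenvalue exactly zero
counts as aperiodic (sign alternation needs a strictly negative
eigenvalue), and for $N > 2$ an imaginary part only counts as complex
above $10^{-9}(1+|\lambda|)$, guarding against eigensolver noise.

A complex eigenvalue $\lambda$ yields a correlation-oscillation period
$T_0 = \bar\tau \cdot 2\pi / |\mathrm{Arg}\,\lambda| \ge 2\bar\tau$
(`correlation_period()`); the bound is the tree analogue of the Nyquist
limit and is attained at $\mathrm{Arg}\,\lambda = \pi$ (the alternator).
Division-rate sampling aliases periods: an observed $T_0$ is compatible
with underlying oscillator periods $T_n = \bar\tau T_0 / |\bar\tau + n
T_0|$ (`aliased_periods()`, default range $n \in \{-3,\dots,3\}$).
$T_{-1}$ is reported as the headline alias because it is closest to
$T_0$; for the measure-zero ratios where $T_{-1}$ and $T_{+1}$ tie, both
are in the returned table and no preference is imposed.

## Estimation from lineage data

`enumerate_pairs()` lists every $(k,l)$-related pair; a cell may occur in
several pairs (both cousin pairs of a cell count). Conventions we fixed
where the field's usage is loose:

* for $k \ne l$ pairs are *ordered*, ancestor-side cell first, each
  ordered instance once; for $k = l$ each unordered pair once;
* the Pearson coefficient uses the per-margin means of the paired sets —
  the standard sample correlation; a pooled-grand-mean variant is
  available (`pooled = TRUE`) for sensitivity analysis;
* the interdivision-time variance is computed over the distinct cells
  appearing in at least one enumerated pair (each once); an `"all"`
  cells option exists because published descriptions are ambiguous on
  this point.

Bootstrap errors resample *pairs* with replacement (10,000 replicates by
default; the variance resamples cells); degenerate replicates are
dropped and counted. Correlations from fewer than 10 pairs are flagged:
their intervals are not meaningful.

## Bayesian inference

The likelihood compares the five training statistics — variance plus the
$(1,0), (2,0), (1,1), (2,2)$ correlations — with their analytic model
values, each standardised by its bootstrap SD:

$$-\ln L = \frac{(\hat s_\tau - s_\tau(\Theta))^2}{\hat\sigma^2_{\hat
s_\tau}} + \sum_{(k,l)} \frac{(\hat\rho(k,l) -
\rho(k,l)(\Theta))^2}{\hat\sigma^2_{\hat\rho(k,l)}},$$

the large-sample normal approximation with cross-statistic covariances
neglected; the mean $\bar\tau$ drops out entirely. The prior is flat on
the natural parameters, restricted to $\mathrm{SR}(\theta) < 1$ and PSD
$S_1$. For two factors with $S_2 = 0$ the free parameters are the four
$\theta$ entries plus two noise variances and one noise correlation —
seven in total, $k = d(1+3d)/2$; with $S_2$ free, $k = d(1+2d)$. The
one-factor fit defaults to a free sister cross-covariance ($k = 3$):
without it the sister correlation is forced to $\theta^2$, which few
datasets satisfy.

Sampling is adaptive Metropolis-within-Gibbs, implemented in compiled
code: one coordinate per step, Gaussian proposal, per-coordinate scale
adapted in batches of 50 toward acceptance 0.44 during burn-in and frozen
afterwards, so the retained chain satisfies detailed balance. Proposals
are made directly on the natural coordinates and out-of-support states
are rejected — with a flat prior this is exactly the constrained target,
and it avoids transformed-coordinate Jacobians. All randomness flows
through R's RNG, so a chain is bit-reproducible from its seed.

Two practical safeguards address the posterior's known geometry:

* **multi-start pilots** — the posterior is typically multimodal (see
  below); by default eight short pilot chains start from independent
  random support points and the main chain starts from the best state
  visited. Without this a single random-walk chain occasionally spends
  its whole budget in a region of very poor fit.
* **likelihood polishing** — the maximum log-likelihood entering the AIC
  ($\mathrm{AIC} = 2k - 2\ln\hat L$) is refined from the best retained
  sample by restarted Nelder-Mead; `fit$polished` records whether this
  improved on the chain.

The default chain is 200,000 samples with 20,000 burn-in. This is a
deliberate desk-scale choice: the eigenvalue, pattern and period
posteriors converge orders of magnitude faster than the raw parameters,
which never converge at all (see next section); production users can
raise `n_samples` freely.

## Identifiability and multimodality

The map from parameters to statistics is invariant under similarity
transforms that preserve the five fitted statistics, so individual
$\theta$ entries are not identifiable: independent chains produce
different parameter histograms and the parameter mean squared
displacement grows linearly with lag, while the eigenvalue MSD plateaus.
`msd_diagnostic()` computes both (eigenvalues ordered consistently:
descending real part, positive-imaginary member first) and `msd_ratio()`
condenses the contrast into one number; ratios well above 1 reproduce
the diffusing-parameters/converged-eigenvalues picture.

A second, sharper degeneracy affects oscillators: two damped oscillators
with opposite real-part signs can fit the four training correlations
equally well. `classify_posterior()` therefore clusters oscillator
samples by the sign of the eigenvalue real part (cluster A negative, B
positive) and `period_posterior()` reports period summaries per cluster
as well as pooled. Pooled period medians mix aliased modes and should be
interpreted with care; the cluster-resolved $T_{-1}$ is the identified
quantity. Because mode-hopping is rare for a coordinate-wise random
walk, a single chain may populate only one cluster; conclusions about a
specific cluster should be drawn from chains in which it has
non-negligible mass, and deeper relations (e.g. $(3,0)$), which
`tree_correlation()` predicts for every posterior sample, discriminate
the clusters experimentally.

## The synthetic-data generator

`simulate_lineage()` draws full binary forests exactly from the model:
root factors from the stationary law (so there is no burn-in transient
and every generation is exactly stationary — a fixed root state is
available for perturbation studies), sister noise jointly from the block
covariance via a PSD square root, Gaussian by default. The sampler is
pluggable (`noise_sampler`), since only the first two moments matter for
any quantity the package predicts; the tests include a uniform-noise
check of exactly that claim. Negative interdivision times are possible
under heavy noise and are *kept* by default — clipping would bias the
second moments that every oracle test relies on; an explicit `tau_floor`
clips with a warning. `prune_forest()` emulates tracking loss by
independent per-cell retention with subtree removal.

What the generator does **not** emulate: measurement noise on
interdivision times, cell death and asymmetric fates, unbalanced tree
shapes induced by selection (faster-dividing lineages overrepresented),
and non-stationary environments. Passing tests therefore demonstrate
correctness of the method under the model's own assumptions, not
robustness to these real-data features; in particular the known variance
bias of tree-structured sampling is explicitly out of scope.

The three demonstration models (`pattern_exemplars()`) pin one model
deep inside each class: eigenvalues (0.78, 0.37) for the aperiodic case
(chosen strongly non-normal so its correlation signature is not
reproducible by an alternator), diag(0.5, −0.5), and $0.5
e^{\pm 2i\pi/5}$. With $\bar\tau = 20$ h the oscillator's correlation
period is 100 h and its nearest alias 25 h — a circadian-like rhythm
hiding under a much slower correlation oscillation.

## Numerical choices and degenerate inputs

* Linear-algebra residual tolerance $10^{-10}$; PSD means smallest
  eigenvalue $\ge -10^{-12}$ (then clipped to zero in square roots).
* Validation errors, not silent fixes: non-binary $\alpha$,
  non-stationary $\theta$, asymmetric $S_1$, an over-strong $S_2$ (joint
  sister covariance not PSD), zero bootstrap SDs in the likelihood,
  constant forests (zero variance), and relations absent from shallow
  forests (listing the missing ones) all raise informative errors.
* A defective $\theta$ is flagged by `eigen_expansion()`; every
  downstream computation that matters uses the matrix-power formula.
* Lineage tables are comma-separated UTF-8 with mandatory header; hours
  throughout; explicit `time_unit` conversion on read, never
  auto-detected. A heap-indexed layout (parent inferred as
  $\lfloor p/2 \rfloor$) is accepted for convenience.

## Problem sizes used by the test-suite and acceptance script

Oracle-equivalence runs use 10,000 trees of depth 4 (650,000 pairs);
pattern-recovery and identifiability runs use 200 trees of depth 6
(≈12,000 pairs per relation, bootstrap SDs ≈ 0.01) fitted with 200,000
sample chains, three seeds per class; AIC selection uses 350 trees so
every training relation exceeds 10,000 pairs. These sizes were chosen so
each statistic's Monte-Carlo error is far below the effects being
asserted while a full run remains a desk-scale computation.

## Known limitations

* Correlation patterns identify eigenvalues, not mechanisms: many
  inheritance matrices explain the same data, which is a finding, not a
  bug — but it means parameter point estimates from this model should
  never be interpreted.
* The oscillator-cluster bimodality means pooled period summaries can be
  dominated by whichever mode the chain found; treat cluster-resolved
  summaries as primary.
* Selection and truncation biases of real unbalanced trees are not
  corrected; `prune_forest()` only models missingness-at-random.
* Model dimensions above two factors are supported analytically
  (patterns, correlation functions) but not by the fitting layer, which
  is deliberately restricted to the `N ∈ {1, 2}` cases the data can
  actually constrain.
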
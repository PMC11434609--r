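---
title: "Modelling whole-night sleep brain dynamics with a variational Gaussian HMM"
author: "sleepHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-night sleep brain dynamics with a variational Gaussian HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepHMM)
```

## The problem and the model

Polysomnography scores sleep in 30-second epochs into six labels (Wake, N1,
N2, N3, REM, plus Undefined for unscorable epochs), which is coarse in both
time and space. Whole-night fMRI offers an alternative view: hundreds of
ROI-averaged BOLD time courses sampled every TR (3 s is typical for sleep
protocols). sleepHMM characterizes such recordings with a Gaussian hidden
Markov model: the brain is assumed to move through $K$ recurring,
quasi-stationary states, state $k$ emitting observations from a multivariate
normal with state-specific mean activation $\mu_k$ and covariance $\Sigma_k$
(the state's functional-connectivity structure), with Markov switching
governed by a $K \times K$ transition matrix $A$ and initial distribution
$\pi$.

The model is estimated by variational Bayes with the conjugate scheme:
Dirichlet priors on $\pi$ and on each row of $A$, and a Normal–Wishart prior
per state (Wishart on the precision). The E-step runs scaled
forward–backward under the variational *expected* parameters
($e^{E[\log \pi]}$, $e^{E[\log A]}$ and the expected Gaussian log-density);
the M-step applies the conjugate count/moment updates. The objective is the
variational free energy — the negative evidence lower bound

$$F \;=\; -\Big(\textstyle\sum_s \log \tilde Z_s \;-\;
\mathrm{KL}[q(\pi)\,\|\,p(\pi)] \;-\; \mathrm{KL}[q(A)\,\|\,p(A)] \;-\;
\textstyle\sum_k \mathrm{KL}[q(\mu_k,\Lambda_k)\,\|\,p(\mu_k,\Lambda_k)]\Big),$$

where $\log \tilde Z_s$ is the forward-pass normalizer of segment $s$. $F$
balances fit against deviation from the prior, decreases monotonically over
iterations, and for $K = 1$ equals the exact negative log marginal
likelihood of the conjugate model — both properties are asserted by the test
suite, the latter against an independent closed-form oracle (the product of
sequential Student-t posterior predictives). A plain EM + BIC scheme was
rejected because the free-energy selection curve is itself part of the
method.

Why variational Bayes and not maximum likelihood: the number of states is
chosen at the *first local minimum of the free energy across model orders*,
which requires a bound with a built-in complexity penalty. The package's
`scanOrders()` records, per $K$: free energy, maximum and median fractional
occupancy, mean state lifetime, and (when stage labels are available) Wilks'
$\Lambda$ of the state time courses against the stage labels. Free energy
alone decides `chosenK`; the other three are reported diagnostics. The
local-minimum rule is: the smallest $K$ strictly below its left neighbour
and no greater than its right neighbour (the left edge of a plateau counts;
ties break toward smaller $K$); if the curve is monotone, the global argmin.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `nComponents` | 13 | PCA components retained before fitting (dimension $D$) |
| Dirichlet concentration | 1 | prior on $\pi$ and each row of $A$; no sticky bias |
| `beta0` | 1 | prior pseudo-count on each state mean |
| `nu0` | $D+1$ | Wishart degrees of freedom (weakest proper choice) |
| `W0` | $(\hat\Sigma\, \nu_0)^{-1}$ | Wishart scale, so the prior expected precision matches the data |
| `nRestarts` | 5 | k-means initializations, seeds `seed + 0..4`; lowest final $F$ wins, ties to the lowest seed |
| `tol` | `1e-5` | relative free-energy change declaring convergence |
| `maxIter` | 500 | VB iteration cap (non-convergence returns `converged = FALSE` with a warning) |

These are decisions of this package, documented here precisely because the
reference workflow for this class of analysis does not pin them down; all
are arguments of `fitHmm()` / `initModel()`.

Segment handling: recordings arrive as runs with censored frames. Censored
frames are dropped and each censored gap *splits* its run, so every
contiguous segment starts from $\pi$ and no transition is ever counted
across a break. Standardization (mean 0, sample SD 1 with the $n-1$
denominator, a fixed documented constant) is per participant over that
participant's uncensored frames. PCA is computed once on the concatenated
training night — column-centered SVD, orthonormal mixing matrix, scores not
whitened so that fitted state covariances stay interpretable after
back-projection — and the frozen mixing matrix and channel means are reused
for any held-out night. That freeze is what makes the semi-supervised
transfer well-defined: `applyModel()` keeps *all* trained parameters
(emissions and transitions) fixed and infers only the new state time
courses. Freezing the transition matrix too, rather than re-estimating it on
the new night, is this package's reading of "maintaining state assignments";
it is the stricter of the two options and the one that keeps the two nights
on an identical parameterization.

## Downstream statistics

**Temporal statistics.** Fractional occupancy is the column mean of the
posterior state probabilities. Lifetimes are computed on the Viterbi path
(hard assignment gives unambiguous run lengths; a gamma-threshold
alternative would need an arbitrary cut). A visit is a maximal run within
one segment; visits truncated by segment edges are *included* — excluding
them would bias short recordings downward. For a state with self-transition
probability $p$ the mean lifetime converges to $\mathrm{TR}/(1-p)$: at
$p = 0.75$ and TR 3 s that is 12 s, the scale the method is designed to
resolve (against 30 s scoring epochs).

**Stage correspondence.** Each state's stage distribution is its
row-normalized co-occurrence with the hypnogram; winner-takes-all assigns
the modal stage, ties broken by the fixed order Wake > N1 > N2 > N3 > REM >
Undefined. Cross-night similarity is the Pearson correlation of the two
flattened $K \times 6$ matrices; the accompanying p-value is reported but
never drives any decision.

**Wilks' $\Lambda$** is det(W)/det(W+B) on the *soft* gamma time courses
(they are what the model actually infers; a Viterbi indicator matrix is the
exposed alternative), with the last gamma column dropped because rows sum
to 1 (rank repair), and a `1e-10` ridge only if the total scatter is still
singular.

**Transition modules.** Self-transitions dominate every row of $A$ and
hide between-state structure, so modularity is computed on the
off-diagonal-renormalized matrix (each row: probability of moving *to other
states*). The directed (Leicht–Newman) modularity
$Q = \frac{1}{m}\sum_{ij}\big(W_{ij} - k^{out}_i k^{in}_j / m\big)\,
\delta(c_i, c_j)$ is maximized by recursive spectral bisection of the
symmetrized modularity matrix with deterministic Kernighan–Lin refinement:
each pass flips every node once in best-gain order and keeps the best
intermediate split, and each bisection is attempted from multiple
deterministic starts (the leading-eigenvector split plus every single-node
split) because weak modular structure — $Q$ barely above the degree-matched
null — is invisible to the leading eigenvector alone. A split is committed
only if it raises $Q$ by more than $10^{-12}$, and splitting stops when no
bisection improves $Q$ — the module count is emergent, never fixed in
advance. On graphs small enough to enumerate
(K ≤ 8, all set partitions) the returned $Q$ matches the brute-force
optimum in the test suite; on a planted 21-state, 5-module matrix with 9:1
within:between mass the partition is recovered exactly (adjusted Rand
index 1).

**State maps.** State means and covariances are projected back to ROI space
through the mixing matrix ($\mu^{roi}_k = M\mu_k + \bar x$,
$\Sigma^{roi}_k = M\Sigma_k M^\top$). Back-projected covariances have rank
at most $D$; correlations are computed on them as-is (the alternative —
empirical FC over state-assigned frames — is deliberately not the default,
because the model covariance is the quantity the HMM actually estimates).
Activation maps are reported relative to the *unweighted* mean across
states (no occupancy weighting — "averaged over all states" is taken
literally). Network aggregation Fisher-transforms each off-diagonal ROI
pair ($\mathrm{atanh}(r)$, $r$ clipped to $\pm(1-10^{-7})$) and averages
within/between network blocks, within-network using unordered pairs only; a
single-ROI network has no within value and is reported missing.

## What the synthetic generator emulates — and what it does not

The generator produces hypnogram-structured multi-state Gaussian series
with full ground truth, so every downstream stage is testable without any
data download:

* a cycling hypnogram: `nCycles` repeats of a
  Wake–N1–N2–N3–N2–REM–Undefined template, bout dwells drawn from a
  discretized gamma (shape $1/cv^2$, floor one frame). The gamma gives
  super-Markov bout persistence, as real stage bouts have; *within* a bout
  the state chain stays Markov (geometric dwells), matching the fitted
  model's assumption. The coefficient of variation is the dispersion
  parameter; 0 gives deterministic dwells.
* stage pools: each stage owns a subset of states; within a bout the chain
  runs on the pool's rows of $A$, renormalized, re-initialized from the
  restricted $\pi$ at bout boundaries (pools are disjoint by default, so
  continuing the chain across a boundary would be ill-defined).
* default scale: 3 participants × ~2000 frames × 20 channels at TR 3 s,
  $K_{true} = 6$ (one state per stage), template dwells of 3–10 frames so
  planted lifetimes (9–24 s) sit inside the 8.7–36 s envelope observed for
  sleep states at this TR; self-transition 0.75 corresponds to the 12 s
  mean-duration scale.
* seeds: one master seed; per-participant seeds are `seed + participant`,
  and stage seeds in the pipeline are fixed offsets of the master, so a
  configuration is bit-reproducible.

Not emulated: hemodynamic convolution and autocorrelation, physiological
noise, scanner drift, motion. Passing tests therefore show the *method* is
correct and recoverable under its own assumptions — Gaussian emissions,
Markov switching, exact censor masks — not that real sleep fMRI satisfies
those assumptions. Real-data effect sizes (state separation relative to
noise) are also far less favourable than the synthetic defaults; the
recovery tolerances here are statements about the implementation, not about
expected field performance.

## Numerical choices and degenerate inputs

* Forward–backward runs scaled (per-frame normalization with log
  accumulators); per-frame log-density rows are max-shifted before
  exponentiation, so underflow cannot occur for finite inputs; non-finite
  observations are an error.
* Cholesky failures on posterior scatters add a `1e-8 · trace/D` ridge with
  a warning; a state whose total responsibility falls below `1e-8` keeps a
  prior-dominated posterior and is flagged, not dropped.
* Point estimates are posterior expectations; the state covariance point
  estimate is $(\nu_k W_k)^{-1}$, the inverse expected precision.
* Zero-variance channels abort standardization with the channel named;
  zero-variance ROIs propagate NA through FC maps with warnings; rows of
  the off-diagonal-normalized transition matrix with no off-diagonal mass
  are left as zero rows with a warning.
* k-means initialization uses 3 internal starts under the given seed; the
  same seed gives a bit-identical fit.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data at
deliberately compact sizes chosen as representative working points:
exhaustive-enumeration checks at $T \le 6$, $K \le 3$; recovery at
$K_{true} = 6$, $D = 13$, 3 × 2000 frames with 5 restarts; the order scan at
$K_{true} = 4$ over $K = 2..8$ with 10 seeds; modularity brute force at
$K \le 8$; cross-night transfer at two 3-participant nights. These sizes
are the package's own benchmark definitions.

## Known limitations

* Full covariances scale as $O(KD^2)$ parameters; the PCA step is not
  optional in practice for hundreds of channels (a diagonal-covariance mode
  exists in the math but full covariance is the default and the tested
  path).
* The VB bound is exact only at $K = 1$; for $K > 1$ restarts mitigate, but
  do not eliminate, local optima.
* No autoregressive observation model, time-delay embedding, stochastic VB
  or GPU path — deliberately out of scope.
* `mean_lifetime` is undefined (NA) for states the Viterbi path never
  visits; summaries propagate the NA rather than imputing.

## A minimal session

```{r example, eval = FALSE}
ds <- simulateSleepDataset(3, seed = 21)            # synthetic "night 2"
concat <- concatenateSessions(lapply(ds@sessions, standardize))
pca <- fitPca(concat, 13)
fit <- fitHmm(pca$scores, 6, segmentIndex = concat@segmentIndex,
              nRestarts = 5, seed = 5)
summ <- stateSummary(fit@posteriors, unlist(ds@hypnogram), trSeconds = 3)
part <- directedModularity(offDiagonalNormalize(transitionMatrix(fit)))
summ
part
```
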
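---
title: "Discretized diffusion models for comparative trait data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discretized diffusion models for comparative trait data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddpcm)
```

## The approximation

Brownian motion with rate $\sigma^2$ on a phylogeny gives tip data a
multivariate normal density with covariance $\sigma^2 C$, where
$C_{ij}$ is the height of the most recent common ancestor of tips $i$
and $j$. That density is easy to evaluate — but it is the only member of
a much larger family of diffusion-like trait models for which this is
true. `ddpcm` instead replaces the diffusion by a nearest-neighbor
continuous-time Markov chain on a binned trait space: the interval
$[lo, hi]$ is cut into $n$ bins of width $\delta$, and the chain moves
between adjacent bins at rate

$$ q_c = \frac{\sigma^2}{2\delta^2}. $$

The probability of the binned tip data under this chain is computed by
Felsenstein's pruning algorithm, and converted back to a density by
$\log f = \log p - m \log \delta$, where $m$ counts the tips observed as
point values (censored or discrete tips contribute probabilities, not
densities). As $\delta \to 0$ the chain converges to the diffusion, so
the approximation is exact in the limit and controllably accurate for
finite $n$. The payoff is that models with *no* tractable density —
reflective bounds, censoring, state-dependent rates and trends,
trait-dependent discrete evolution — only require editing the rate
matrix.

### Generator variants

* **Reflective diffusion** (`generator_diffusion`): tridiagonal with
  off-diagonal $q_c$. Outward transitions at the two edge bins are
  removed. Under the default `"reassign"` convention the rates between
  each edge bin and its neighbor are doubled to $2 q_c$ *in both
  directions*; this keeps the generator symmetric, so its stationary
  distribution is exactly uniform over bins and a long branch relaxes to
  the flat density $1/(b-a)$ per dimension, as a reflected diffusion
  must. (Doubling only the outward row is a defensible alternative
  reading of "reassigning the missing rate", but it produces a
  non-uniform stationary law that contradicts the flat-density limit,
  so the symmetric convention is used.) The `"omit"` convention simply
  drops the missing rate; the two agree as $\delta \to 0$.
* **Trended diffusion** (`generator_trend`): upward and downward rates
  $q_\pm = \sigma^2/(2\delta^2) \pm \mu/(2\delta)$. Non-negativity
  requires $|\mu| \le \sigma^2/\delta$, so the bin width bounds the
  trend a grid can represent; the fitting code keeps $\mu$ inside
  $0.99\,\sigma^2/\delta$ by a scaled-$\tanh$ reparameterization rather
  than a penalty, so every proposed generator is valid by construction.
* **Joint discrete + continuous** (`generator_joint`): a $kn \times kn$
  matrix whose diagonal blocks are per-level diffusion (or trend)
  generators with $q_{c,i} = \sigma_i^2/(2\delta^2)$ and whose
  off-diagonal blocks are $q_{ij} I$ — the discrete character switches
  level without moving the continuous trait.
* **Trait-dependent switching** (`generator_xdep`): as above with a
  shared $\sigma^2$, but the level-switch entry at bin $i$ is a
  four-parameter logistic curve (lower and upper asymptote, midpoint,
  steepness) evaluated at that bin's center. A flat curve (equal
  asymptotes, or zero steepness) reduces exactly to the constant-rate
  joint generator, so trait-independence is a nested special case.

### Tip encodings

Point values become an indicator on the containing bin (values are
snapped to their bin, and so is the root state $x_0$; this quantization
is part of the approximation and vanishes with $\delta$). A discrete
level under the threshold model becomes the liability interval between
its bracketing thresholds; a censored tip becomes the semi-infinite
interval beyond its clamp. Interval-type encodings give a bin that
straddles a cut point its *overlapped fraction* rather than 0 or 1.
This keeps the encoding error at $O(\delta^2)$ instead of $O(\delta)$ —
without it the orthant-probability benchmark below misses its target by
an order of magnitude whenever a threshold lands near a bin center —
and it makes the likelihood continuous in the thresholds, which the
optimizer appreciates.

## Computing the likelihood

Pruning is a postorder recursion in compiled code with per-edge
rescaling (accumulated on the log scale), so 200-taxon trees with
hundreds of states do not underflow. Edge propagation
$v \mapsto e^{Qt} v$ uses two strategies:

* **Symmetric generators** (reflective diffusion, the threshold model's
  liability chain, equal-rate joint models without trends): one
  eigendecomposition $Q = V \Lambda V'$ per generator, then two dense
  matrix–vector products per edge. For the threshold model the
  generator does not depend on the fitted parameters at all, so the
  decomposition is computed once per fit and reused by every optimizer
  evaluation.
* **Non-symmetric generators** (trends, trait-dependent switching):
  uniformization. With $\Lambda = \max_i |Q_{ii}|$ and
  $M = I + Q/\Lambda$ (a stochastic matrix), $e^{Qt}v$ is a
  Poisson-weighted sum of sparse products $M^j v$ — every term is
  non-negative and norm-preserving, so the scheme is unconditionally
  stable, and long edges are split so the leading Poisson weight never
  underflows. This was preferred over dense scaling-and-squaring
  exponentials (or a global eigendecomposition) because drifted
  birth–death chains have eigenvector condition numbers that grow
  geometrically with $n$ — the similarity transform that symmetrizes
  them has entries $\propto (q_+/q_-)^{i/2}$ — while the generator
  itself stays extremely sparse.

The root state is handled by profiling: with a point-mass root prior the
likelihood as a function of the root bin *is* the root partial
likelihood vector, so the ML root value is its argmax — no optimizer
dimension is spent on $x_0$ (or on the threshold model's root
liability). Joint models use a prior flat across discrete levels times a
point mass at the profiled bin; whether that prior should instead be
stationary or estimated is genuinely open, and the flat choice is the
least informative of the simple options.

## Fitting

All models are fitted by maximizing the discretized log-density with
transformed parameters (log for rates and $\sigma^2$, scaled $\tanh$
for trends, ordered log-increments for thresholds) under Nelder–Mead
with random restarts (plus Brent for one-dimensional problems). The
multi-trend model uses two stages: a global search on a coarse grid
(half the requested bins) followed by a polish on the full grid from
the stage-one optimum — the parameters are physical quantities, so they
transfer across grids.

Grid policy: the grid is built once per fit from the data and shared by
every optimizer evaluation, so likelihoods are comparable across nested
models. Bounded fits use the bounds themselves as the grid limits (the
ML bounds are the observed trait range unless fixed by the user).
Unbounded-type fits pad the observed range by a factor (default 0.5 per
side) so the artificial reflecting edges carry negligible probability;
the padding should dominate $\sqrt{\sigma^2 T}$ for tree depth $T$. The
semi-threshold fit cannot see the latent range, so it pads the
observable window using a rate anchor from a naive Brownian fit and
enlarges the grid and refits (at most twice) if the fitted rate implies
the margin was too small. The default is 200 bins; the turnkey studies
use 100–200 depending on the model (see below).

Free-parameter counts for AIC: plain Brownian motion 2
($\sigma^2, x_0$); bounded 4 when the bounds are estimated from the
data (their ML values are the observed range), 2 when fixed; threshold
$L-1$ for $L$ levels ($L-2$ free thresholds, the first is pinned at 0
and $\sigma^2$ at 1 because liability has no scale, plus the root
liability); semi-threshold 2; state-dependent $k + 1 + 1$
(per-level rates, one symmetric switch rate, $x_0$); multi-trend
$2k + 2$; trait-dependent switching 10 ($\sigma^2$, two four-parameter
curves, $x_0$). Mk variants: 1 (ER), $L-1$ (ordered symmetric, one rate
per adjacent pair), $2(L-1)$ (ordered asymmetric).

## Simulators and what they emulate

Every generating process has a forward simulator that exposes its
latent state (liabilities, full discrete histories) so tests can check
conditional moments directly: Gaussian increments per edge (`sim_bm`),
Euler–Maruyama steps with reflection (`sim_bounded`, default 1000 steps
per edge), thresholding of a simulated liability (`sim_threshold`),
clamping outside an observable window (`sim_semithreshold`), Gillespie
waiting times for discrete histories (`sim_mk_history`), per-segment
Gaussian increments given a history (`sim_statedep`), and a fine-step
joint walk whose switch hazard tracks the current trait value
(`sim_xdep`, which warns when the per-step switch probability exceeds
0.1). Fine-step simulators have $O(\sqrt{dt})$ boundary bias and
$O(dt)$ hazard bias; the step size is exposed.

The pure-birth tree simulator grows a constant-rate (rate 1) tree to
the requested tip count and rescales all branches to the target depth.
Non-ultrametric trees are produced by shortening each terminal edge by
a uniform fraction $U(0, 0.5)$ of its length, leaving one random tip
untouched so the original depth is still attained. How such trees
"should" be generated is underdetermined — this transform is a labeled
stand-in and the fraction is a knob (`max_fraction`).

These simulators define clean, correctly-specified generating
conditions. Real comparative data add measurement error, within-species
variation, non-Brownian tails, and tree misspecification, none of which
is emulated — passing recovery tests here demonstrates correctness of
the machinery, not robustness to those complications.

## The turnkey studies (`run_study`)

Each study draws generating parameters per replicate, simulates, and
fits the relevant models; `summarize_study` reports correlations,
slopes, biases, Akaike tallies and rate comparisons. Generating
conditions follow the published designs; scales are chosen to run a
full study in minutes on one core:

* **threshold** — trees of depth 3.0, liability $\sigma^2 = 1$,
  $x_0 \sim U[-1, 3]$, thresholds $(0, 0.8, 1)$ giving up to four
  ordered states (occasionally fewer are observed; replicates with a
  single observed state are dropped). Competitors: ordered symmetric
  and ordered asymmetric Mk. Default scale here: 25 replicates of 100
  taxa at 200 bins.
* **statedep** — depth 1.0, $q_{ab} = q_{ba} \sim U[1, 10]$ (high on
  purpose: with few transitions the joint and two-step routes hardly
  differ), $\sigma_a^2 \sim U[0.5, 2]$, $\sigma_b^2 \sim U[5, 20]$.
  20--30 replicates of 100 taxa at 100 bins, optionally with the
  two-step comparator (Mk fit, stochastic maps, per-map Gaussian fits,
  rates averaged across maps and the ratio taken afterwards).
  Correlation summaries stabilize with the replicate count more than
  with the taxon count, so the headline rate correlations use 30
  replicates. At these transition rates $\sigma_a^2$ (the slow state)
  has a nearly flat profile likelihood on 100-taxon trees — its
  per-replicate estimate is legitimate ML output but individually
  noisy.
* **multitrend** — non-ultrametric trees of depth 10.0 (trends and
  $x_0$ are confounded on ultrametric trees, so the fit warns there),
  $q = 0.5$, $\mu_a \sim U[0.2, 1]$, $\mu_b \sim U[-1, -0.2]$,
  $\sigma_i^2 \sim U[0.3, 1]$. This study runs at its original scale
  (20 replicates of 200 taxa, 160 bins): with only 100 taxa the Mk rate
  estimate occasionally diverges on saturated tip patterns and both
  estimators disperse well beyond their 200-taxon behavior. The bin
  count keeps $\delta$ small enough that the largest generating
  $|\mu|/\sigma^2$ stays inside the representable trend bound.
* **bounded** and **semithreshold** — bounds/clamps at $\pm 1$,
  $\log \sigma^2 \sim N(0, 1)$. The tree depth for these two studies
  (1.0) and the root-state draws ($x_0 \sim U[-0.9, 0.9]$ bounded,
  $U[-1, 1]$ semi-threshold) are package choices: at depth 1 the
  slower-mixing replicates retain information about $\sigma^2$ while
  the faster ones already show the censoring/bounds bias the study is
  about.

All randomness flows from one master seed through per-replicate seeds,
so a study is byte-reproducible.

## Reference computations

The `bm_cov` / `bm_logdensity` oracles give the exact Gaussian answers
where they exist. For small trees ($N \le 4$) `mvn_rect_prob` computes
multivariate-normal rectangle probabilities by recursive conditioning
with adaptive 1-D quadrature (absolute tolerance $10^{-8}$; infinite
limits clipped at 8.5 marginal SDs), which powers exact threshold-model
probabilities and mixed censored/point semi-threshold densities. These
are used only in tests — never in the fitting path — and are themselves
cross-checked against $10^6$-draw Monte Carlo in the suite. Closed
forms used as anchors: the two-state chain
$P_{00}(t) = (1 + e^{-2qt})/2$, the bivariate-normal orthant identity
$P(\text{both below}) = 1/4 + \arcsin(\rho)/(2\pi)$, and the relaxation
of a reflected diffusion to the uniform density after
$2(b-a)^2/(\pi\sigma^2)$.

## Known limitations

* Point tips are assigned to bins, so reported $x_0$ and threshold
  estimates are quantized at resolution $\delta$.
* The grid is finite: unbounded models inherit faint reflecting bounds
  at the padded edges. Check `fit$grid` against the fitted rate if in
  doubt.
* The trait-dependent switching model has a genuinely difficult
  9-parameter likelihood; asymptotes are weakly identified where few
  lineages visit (the fit flags near-flat curves), and hundreds of tips
  are needed before the fitted curves resemble the generating ones.
* No Hessian-based standard errors; model comparison is by AIC and
  Akaike weights only.
* Uniformization cost scales with $\max_i |Q_{ii}| \times$ total tree
  length, i.e. with $\sigma^2/\delta^2$ — very fine grids with large
  rates are expensive for the non-symmetric models.
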
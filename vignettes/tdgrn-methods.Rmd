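---
title: "Inferring time-delayed gene regulatory networks with tdgrn"
author: "tdgrn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring time-delayed gene regulatory networks with tdgrn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdgrn)
```

# The problem

Transcriptional regulation is delayed: a regulator transcribed at time $t$
affects its targets some number of sampling intervals later. On the short,
equally spaced expression time courses typical of regulatory-network
benchmarks (half a dozen genes, 20–50 time points), `tdgrn` infers a
directed, lag-annotated network $regulator \to target$ by decomposing the
problem per target gene:

1. **Candidate shortlisting.** For every potential regulator $X$ of target
   $Y$, three association measures are maximised over the lag window
   $\tau \in [\tau_{\min}, \tau_{\max}]$: time-delayed mutual information
   (TDMI), a time-delayed maximal information coefficient (TDMIC), and the
   absolute time-delayed Pearson correlation (TDCC). Genes are ranked per
   measure (rank 1 = strongest) and the three ranks summed; the $L$ genes
   with the smallest aggregated rank become the candidate set. Rank
   aggregation makes the shortlist robust to the failure modes of any
   single measure, and avoids a global score threshold — the pair
   strengths of different targets need not live on one scale.
2. **Lag alignment.** Each candidate's optimal lag is the maximiser of
   $|TDCC|$ (ties toward the smallest lag). The candidate series are
   shifted by their own lags onto the common output window
   $t = \max(lags)\,..\,m-1$, giving one design matrix and one target
   vector per gene (`buildDelayedDesign()`).
3. **Model fitting.** A complex-valued flexible neural tree (CVFNT) is fit
   to predict the target from the lag-aligned candidates, by evolutionary
   structure search with an embedded bat-algorithm parameter optimiser.
4. **Edge extraction.** The input genes used by the fitted tree's
   terminals are reported as the target's regulators, with their lags.

Self-regulation is never inferred: a target cannot enter its own candidate
set, so a gold-standard self-loop is an inevitable false negative under the
self-pair-inclusive evaluation convention (see `confusionCounts()`).

# The model

A CVFNT is an expression tree. Leaves ("terminals") $z_i$ emit the $i$-th
encoded input series; internal nodes $+n$ are flexible neurons computing

$$net = w_0 + \sum_{j=1}^{n} w_j z_j, \qquad
  out = \frac{net}{a + |net|/r},$$

with complex weights $w_j$, complex threshold $w_0$, and per-node positive
activation parameters $a, r$ (the complex Elliot function; its output
modulus is bounded by $r$). The tree output is evaluated children-first,
and the real part of the complex root output is compared with the target
(training criterion: RMSE). The real part — rather than the modulus —
preserves sign and ordering against the real-valued target; the modulus
readout remains available.

Expression values are real, so a real-to-complex encoding is needed for the
terminals. The default embeds the data on the real axis ($z = x + 0i$); a
`phase` alternative maps min-max-normalised values onto the unit
half-circle, $z = \cos(\pi x) + i \sin(\pi x)$, in the spirit of circular
complex-valued encodings. Neither encoding is privileged by theory; the
real embedding is the conservative default and the one used everywhere in
the package's own tests.

# Numerical and algorithmic choices

**Association measures.** TDMI pairs $x_k$ with $y_{k+\tau}$ over the
overlap window and estimates MI (natural log) from an equal-width 2-D
histogram with $\max(2, \lfloor\sqrt{N}\rfloor)$ bins per axis — a
standard choice for the $\le 50$-point series targeted here. TDCC computes
the Pearson correlation with means and variances on the same overlap
window. TDMIC maximises $I(G)/\log\min(n_x, n_y)$ over 2-D grids with
$n_x n_y \le B(N) = \max(4, \lfloor N^{0.6} \rfloor)$ cells: one axis gets
an equal-frequency partition (ties share a bin) and the other axis's cut
points are optimised exactly by dynamic programming (the weighted
conditional entropy is additive over bins); both orientations are tried.
At these tiny $N$ the search is exact for this estimator definition, and a
noiseless monotone functional relation attains exactly 1. The regulator
always leads: lag $\tau$ means regulator at $t$ acts on the target at
$t + \tau$. `minLag` defaults to 0 — instantaneous (sub-sampling-interval)
regulation is allowed, and can be excluded by setting `minLag = 1`.

**Rank aggregation ties.** Per-measure ties share the smallest rank; ties
on the aggregated rank are broken by larger TDMIC, then larger TDMI, then
smaller gene index. The chain is arbitrary but fixed, so runs are
deterministic.

**Normalisation.** Per-gene min-max to $[0,1]$ is applied before scoring
and modelling (constant genes map to 0.5 and simply rank at the bottom —
zero association). Bounded inputs matter because the Elliot activation
saturates; the measures themselves are monotone-invariant (MIC, TDCC) or
binned (TDMI), so min-max is benign for scoring. `zscore` and `none` are
available for data already on a common scale.

**Design window.** Regulators carry different lags, so the lag-aligned
rows would naturally have different lengths; the package truncates all of
them to the single window of length $m - \max(lags)$ so one target vector
serves the multi-input tree. The window must keep at least 5 points.

**Structure search.** Tournament selection (size 3, lower fitness wins),
subtree-exchange crossover (probability 0.7), mutation (probability 0.3;
uniformly: replace a random subtree, re-point a terminal, or regenerate one
node's parameters), elitism, and depth-bound pruning (an overflowing
subtree is replaced by a random terminal). The function set is
$\{+2, +3\}$ with depth bound 4: candidate sets have $L \approx 2$ inputs,
so small arities and shallow trees already span the useful model space.

**Parsimony and regulator-sparsity pressure.** Selection, elitism and
best-model tracking minimise
$RMSE + c_{node} \cdot size + c_{input} \cdot (\#\text{distinct inputs} - 1)$
with $c_{node} = 0.002$ and $c_{input} = 0.01$ by default. An input gene
appears in the reported network exactly when the fitted tree uses it, and
on noisy data an uninformative input is never punished by training RMSE
alone — classic genetic-programming bloat, which here directly inflates
the inferred edge set. The node penalty is mild bloat control; the input
penalty is the load-bearing one: each additional candidate gene must buy
about $c_{input}$ of training RMSE (on min-max-normalised data) to enter
the model, which is several times the typical overfitting gain of an
irrelevant input at these sample sizes, while a genuinely co-regulating
input buys far more. The scales were chosen on pilot simulations at the
package's benchmark conditions. Setting both penalties to 0 recovers
raw-RMSE selection, and then the best-so-far RMSE trace is itself
monotone.

**Bat parameter optimisation.** Every 5 generations the best 20% of the
population get their flattened parameter vectors (per function node:
$\mathrm{Re}\,w_j, \mathrm{Im}\,w_j, \dots, \mathrm{Re}\,w_0,
\mathrm{Im}\,w_0, a, r$) refined by a canonical frequency-tuned bat
search: velocities driven by random frequencies in $[0, 2]$ toward the
best-known position (clamped to $\pm 1$ per coordinate — the data are
normalised), a pulse-rate-gated local walk scaled by the mean loudness,
loudness decay $\alpha = 0.9$ on accepted moves, and pulse rate
$r_0(1 - e^{-\gamma t})$, $r_0 = 0.5$, $\gamma = 0.9$. The best-found
parameters are returned, so the step never worsens a tree. On unflatten,
$a$ and $r$ are clamped from below at $10^{-3}$ to keep the activation
defined.

**Run sizes.** Defaults are population 30, 40 generations, 20 bats and 40
iterations per bat phase. These are deliberately modest: the per-target
problems (2–3 inputs, a few dozen points) converge within them in a couple
of seconds, which is what makes repeated-run summaries and the package's
own 20-seed benchmark suites practical. All constants are exposed through
`optimizerConfig()` / `batConfig()`, and an early stop fires when training
RMSE reaches `targetRmse` ($10^{-3}$ on normalised data — the "model
found" criterion). Alternative parameter optimisers can be plugged in by
replacing `batOptimize()` in a custom fitting loop; only the bat algorithm
ships.

**Reproducibility.** Per-target (and per-run) seeds are derived from the
root seed by fixed large-prime offsets modulo $2^{31}-1$, so targets are
independent streams yet the whole run — including the repeated-run summary
`multiRunSummary()` — reproduces bit-for-bit from one integer.

**Degenerate inputs.** Constant series: TDMI and TDMIC return 0, TDCC
returns 0 with a warning. All-tied lag scans resolve to the smallest lag.
Confusion metrics with a 0/0 denominator return 0 with a warning; the
convention only matters for degenerate networks.

# The synthetic benchmark generator

`generateNetwork()` / `simulateExpression()` provide ground-truth networks
so that every stage is testable without external data. The defaults
emulate the scale of the real benchmarks this method family targets: 6
genes, 7 directed edges, lags uniform on $1..6$ sampling intervals, 50
time points, observation noise sd 0.05 on regulated genes. Driver genes
(in-degree 0) follow smooth AR(1)-plus-sinusoid dynamics in $[0,1]$;
regulated genes apply a saturating link to the centred weighted sum of
their regulators' lagged values:

$$x_k(t) = \mathrm{clip}_{[0,1]}\Big(0.5 +
  f\big(\textstyle\sum_e w_e (x_{reg(e)}(t - lag_e) - 0.5)\big) +
  \varepsilon_t\Big), \quad \varepsilon_t \sim N(0, \sigma^2).$$

Centring the drive at mid-range matters: with values in $[0,1]$ and
weights allowed negative, an uncentred link pins regulated genes against
the clip boundary and produces degenerate constant series. All links
(`elliot` — the same saturating family as the model, `linear`,
`sigmoid`) are odd with unit slope at the origin, so a single weight-1
linear edge reproduces its regulator as an exact lagged copy — the
property the lag-recovery tests are built on. Edge weights are bounded
away from zero ($|w| \ge 0.2$) so that "true edge" is meaningful for
recovery scoring; the first $\tau_{\max}$ burn-in points are discarded so
all lagged influences are strictly in the past.

What the generator does *not* emulate: measurement-platform artefacts,
missing values, unequal sampling, feedback at lag 0, autoregulation, and
the far-from-steady-state transients of real perturbation experiments.
Passing recovery tests on these simulations therefore demonstrates that
the pipeline identifies lagged nonlinear dependencies of the assumed form
at realistic noise — not that it would reach the same scores on any real
dataset.

# Evaluation conventions

Edges are matched direction-sensitively and lag-insensitively (benchmark
gold standards are unlagged). The pair universe excludes self pairs by
default; `includeSelf = TRUE` reproduces the bookkeeping of benchmarks
whose gold standard contains a self-loop (the 6-gene DNA-damage network:
6 TP, 0 FP, 1 FN over 36 pairs gives sensitivity 6/7, precision 1,
F-score 0.923). `multiRunSummary()` reports per-metric means and SDs over
derived-seed runs plus the hit ratio — the fraction of runs attaining the
best observed F-score.

# Worked example

```{r example, eval = FALSE}
spec <- generateNetwork(6, 7, tauMax = 6, m = 50, noiseSd = 0.05, seed = 1)
sim <- simulateExpression(spec)
net <- inferNetwork(sim$expression, RunConfig(tauMax = 6, L = 2, seed = 1))
edges(net)
evaluateNetwork(net, sim$gold, geneIds(sim$expression))
```

The package's test suite runs this recovery at 20 seeds and compares the
mean F-score against the no-delay ablation (`tauMax = 0`, the same code
path with the lag window collapsed); the delayed pipeline must win. The
problem sizes used throughout the suite (6 genes, 50 points, 20 seeds;
smaller populations in the pure unit tests) are the package's own choice
of a benchmark that a laptop re-runs comfortably.

# Known limitations

* The three measures, and hence the shortlist, are pairwise: a strongly
  autocorrelated common driver can promote both directions of an edge or
  an indirect path; no conditional-independence deconfounding is applied.
* $L$ caps the in-degree: targets with more regulators than $L$ cannot be
  fully recovered (the benchmark experience that $L \approx 30\%$ of the
  gene count works best is mirrored by the defaults).
* The evolutionary fit is stochastic; only elitism and the accept-if-better
  rule are guaranteed. Repeated-run summaries are the honest way to report
  its output.
* The real-to-complex encoding of real expression data is an open design
  point; both options are exposed and documented, neither is canonical.
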
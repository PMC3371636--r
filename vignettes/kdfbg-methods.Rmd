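---
title: "Methods: Bayesian HMM segmentation on compressed observation blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian HMM segmentation on compressed observation blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdFBG)
```

## Model

Copy-number profiles are modelled as an $N$-state hidden Markov model with
univariate Gaussian emissions.  A `gaussian_hmm` holds the transition
matrix $A$, initial distribution $\pi$, and per-state emission means
$\mu_i$ and variances $\sigma_i^2$ — always variances, in squared
observation units.  A track (`observation_track`) is an ordered set of
per-chromosome log2-ratio sequences; the pooled standard deviation
$\sigma_D$ of all observations is cached because compression widths are
conventionally quoted in multiples of it.

The Bayesian treatment places standard conjugate priors on the parameters:

* $\mu_i \sim N(\tilde\mu_i, \tilde\sigma_i)$, with $\tilde\sigma_i$ a
  prior *variance*;
* $\sigma_i^{-2} \sim \mathrm{Gamma}(a_i, b_i)$ (shape/rate);
* $\pi \sim \mathrm{Dirichlet}(\lambda^\pi)$ and row $i$ of $A$
  $\sim \mathrm{Dirichlet}(\lambda^{A_i})$.

`preset()` ships the configurations used by the benchmark experiments: a
2-state model with informative priors, two 4-state arrayCGH
configurations, a scale-adaptive 3-state configuration (returned as a
function of $\sigma_D$, since its prior means and precision shapes depend
on the data spread), and a 3-state SNP-array configuration whose Dirichlet
rows carry total weight 5000 with diagonal fractions 0.99/0.95 to encode
strong self-transition.

## Exact sampler

`run_fbg()` alternates, for $M$ sweeps:

1. per chromosome, scaled forward variables and an exact backward draw of
   the full state path from $P(Q \mid O, \theta)$;
2. parameter draws in the fixed scan order $\mu \to \sigma^2 \to A \to
   \pi$, with the precision update conditioning on the means drawn in the
   same sweep.

Design choices where the procedure is genuinely open:

* **Initialization.**  $\theta^0$ defaults to the prior expectations
  (means at $\tilde\mu$, variances at the prior mean of $\sigma^2$,
  Dirichlet rows normalized): deterministic and free of data peeking.
  Sampling $\theta^0$ from the priors is available
  (`initial_parameters(hyper, "draw")`) but not the default: with the
  2-state benchmark priors roughly a fifth of prior-drawn starts place
  both means inside the same cluster, and the chain then sticks for 100+
  sweeps in a merged-state mode where every state models the pooled
  mixture.  Starting from the prior centers avoids that basin entirely
  while conditioning on nothing the priors do not already encode.
* **Label switching.**  When `order_means` is set, the joint mean vector
  is redrawn until ordered (capped at 100 tries, then sorted — the
  fallback count is recorded on the chain).  Rejection leaves the
  posterior correctly truncated to the ordered cone; the sort fallback is
  a pragmatic escape used essentially never once the chain has found the
  separated modes.  Ties are accepted (non-strict ordering): equal means
  have probability zero, so the distinction is immaterial.  All presets
  enable the constraint, including the 2-state one: without it a
  noticeable fraction of prior-initialized chains settles into the
  label-swapped mode and every posterior comparison saturates.
* **Pooling.**  Transition counts pool across chromosomes but junctions
  between chromosomes are never counted, and the initial-distribution
  posterior receives one first-state count per chromosome, because the
  forward recursion restarts at $\pi$ on each chromosome.
* **RNG.**  One R RNG stream drives everything, including the compiled
  backward draws (one uniform per position, drawn from the end backwards).
  Chains are bit-reproducible given the seed.
* **Posterior summary.**  Per-probe posterior marginals are averaged over
  the trailing 10 draws (configurable), the usual burn-in-free summary for
  chains of length 100.

## Block compression

`kd_compress()` builds blocks by a recursion that alternates two split
types.  At value levels ($d=1$) the segment splits around its median into
maximal runs of consecutive observations lying entirely on one side; at
positional levels ($d=0$) it splits at the largest jump between adjacent
values.  A segment is emitted as a block when its value range falls below
the level-$L$ threshold, or when it is a single observation.  Blocks store
$(n, \sum o, \sum o^2)$ only.

Numerical and tie-break conventions (all deterministic):

* **Threshold.**  The allowed width starts at $w$ at the root and shrinks
  by $\delta = 1.25$ per value level: $\mathrm{range} < w/\delta^{L-1}$.
  The function `level_width()` isolates this so the exponent convention is
  a one-line change; with the shrink direction fixed by the requirement
  that deeper, finer levels be stricter, the remaining $L$ vs $L-1$ choice
  only rescales $w$ by $\delta$.
* **Median.**  Lower median for even lengths.  Observations equal to the
  median may join either side; runs are built greedily left to right with
  ties attached to the run in progress.
* **Gaps.**  The leftmost largest gap wins.
* **Constant segments.**  With $w > 0$ a constant segment stops
  immediately (zero range).  With $w = 0$ the recursion would peel off one
  observation per level; the implementation emits the singletons directly,
  which is the same result without the deep recursion.

The merge pass (`merge_blocks()`) then walks the block list once, left to
right: two adjacent blocks merge when their means differ by less than $w$;
failing that, three consecutive blocks merge when the outer means are
within $w$ and the inner block is a singleton (this bridges isolated
outliers).  A merged block does not participate in further merging — one
pass, no iteration to a fixpoint.  This reading keeps compression at
moderate widths conservative; an accumulating variant (where the merged
block keeps absorbing successors) compresses far more aggressively once
$w$ approaches the separation between state means, and collapses whole
chromosomes at large $w$.  We chose the non-accumulating reading because
it preserves segmentation fidelity over the width range users actually
select (at or below the knee), at the cost of a gentler failure mode under
deliberate over-compression: beyond the state separation the posterior
error grows into the 0.05–0.1 range rather than collapsing outright.

Moment conservation is exact up to float addition order (tested at
relative 1e-9), blocks tile each chromosome, and the recursion depth on
continuous data stays logarithmic (asserted in the tests).

## Width selection

The compression ratio $\gamma(w) = T'/T$ falls with $w$ and typically has
a knee.  `select_width_lmethod()` implements the L-method: for every
admissible split point of the $(w, \gamma)$ curve, fit least-squares lines
to the left and right parts (the split point belongs to both), and take
the split minimizing the size-weighted total RMSE.  The result is flagged
`low_confidence` when the split lands adjacent to a boundary or when a
single line fits essentially as well as two (no knee: e.g. a straight
curve).  The default grid is $0.25\sigma_D, 0.5\sigma_D, \dots, 4\sigma_D$.
The knee is a conservative choice on templated CGH data; on data that
spends half its time in each state the $\gamma$ curve decays almost
exponentially and the knee can land high, so inspecting the returned curve
is advisable.

## Approximate sampler

`run_approx_fbg()` compresses once, then runs the same Gibbs scan with two
modifications.  The forward recursion advances block-wise: block $t$ with
$n_t$ observations contributes its constant-time joint emission likelihood
times $a_{ii}^{n_t-1}$ self-transitions, with a single cross-block
transition linking consecutive blocks (the first block of a chromosome
starts from $\pi_i a_{ii}^{n_t-1}$, consistent with the block-constant
path family).  One state is drawn per block and expanded to its
observations.  Parameter updates accumulate block moments as emission
statistics and count $n_t - 1$ self-transitions per block plus one
transition per adjacent pair — state changes hidden inside a block are
ignored by construction.

With $w = 0$ every block is a singleton and the approximate chain is the
exact chain, bit for bit, under the same seed; `run_fbg()` is in fact
implemented as the block engine on singleton blocks, while the
raw-sequence `forward()`/`viterbi()`/`posterior_marginals()` are
independent implementations used for decoding and cross-checks.

The error of ignoring within-block state changes is quantified by
`lemma1_bound()`: for a symmetric HMM (self-transition $t$, shared
variance $\sigma^2$, minimal mean separation $d$) and a block of $n$
observations whose values keep a margin $\tau \ge 0$ from the decision
midpoints toward the neighboring means, the total-to-constant path mass
ratio is at most
$\alpha\left((1+rc)^{n-1} + (N-1)c^{2n/N}(1+r)^{n-1}\right)$ with
$r = (1-t)/t$ and $c = e^{-d\tau/(2\sigma^2)}$.  The exponent's distance
variable is read as the margin $\tau$ — the quantity the derivation's
per-observation inequality actually controls — and the reading is isolated
in one function.  At $t=0.9, d=1, \sigma^2=0.1, \tau=0.25, n=10, N=2$ the
bound evaluates to $\approx 1.33$, i.e. the ignored paths contribute at
most about a third of the constant-path mass.  `weak_path_ratio_oracle()`
computes the exact ratio by enumerating all $N^n$ paths; the test suite
verifies the bound dominates it on 100 randomized instances.

## Synthetic data

`sample_hmm_sequence()` draws $(Q, O)$ from a given model.
`simulate_cgh_template()` emulates templated arrayCGH data: chromosomes of
500/750/1000 probes; 10 aberrant regions of 11–20 probes in the small
chromosome and 15 regions of 11–25 probes in each larger one (the counts
and size ranges are per chromosome); regions placed uniformly at random
without overlap by rejection sampling with a retry cap; each region
independently a gain or a loss with probability ½; theoretical log-ratios
$-1/0/0.58$ for loss/neutral/gain plus $N(0, \sigma)$ noise.  The
signal-to-noise ratio is $0.58/\sigma$; the default $\sigma = 0.2$
(SNR 2.9) represents a clean but realistic array.  What the generator does
*not* emulate: probe-specific biases, wavy baselines, outlier spikes, and
spatially correlated noise of real arrays — so passing tests demonstrate
correctness of the inference machinery, not robustness to every real-data
artifact.  (Outliers, notably, are partially absorbed by the compression
itself, since isolated extreme values end up inside blocks.)

## Evaluation conventions

The average posterior error
$\tilde P = \frac{1}{2T}\sum_t\sum_i |P_1(q_t{=}i) - P_2(q_t{=}i)|$ is the
per-position total-variation distance averaged over positions, in $[0,1]$.
Calls derive from the trailing-window-averaged marginals: per probe, the
class (loss/neutral/gain) with the largest summed posterior mass of its
mapped states wins, with ties broken toward neutral.  Two-class metrics
treat aberrant (loss or gain) as positive; ratios with empty denominators
are reported as `NA` rather than coerced to zero.  All coordinates in
output files are 0-based half-open.

## Problem sizes

The test suite exercises the 2-state benchmark at $T = 10^4$, $M = 100$,
five replicates; compression properties at $T = 10^5$; enumeration oracles
at $T \le 8$.  These sizes were chosen so that the full suite completes in
a couple of minutes while leaving the statistical assertions
well-powered (3-standard-error bands on $2\cdot 10^4$ draws).

## Known limitations

* Emissions are Gaussian only; heavy-tailed or mixture emissions would
  break the constant-time block likelihood that the speed-up rests on.
* The block sampler's bias grows with $w$; beyond the state-mean
  separation the merge pass fuses cross-state blocks and posterior error
  degrades (by design gently, see above).  Width selection should stay at
  or below the knee.
* No recompression between sweeps: blocks are fixed once, so a grossly
  mis-specified initial width cannot be corrected mid-chain.
* Marginal-likelihood estimation, convergence diagnostics beyond the
  chain dump, and multivariate tracks are out of scope.
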
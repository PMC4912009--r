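---
title: "Phase transitions in simulated annealing searches for maximum-parsimony trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase transitions in simulated annealing searches for maximum-parsimony trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model and the cost function

Maximum parsimony (MP) selects, among all unrooted binary topologies over
the taxa of a nucleotide alignment, one that minimises the *tree length*
$L$: the number of substitutions needed to explain the data on that
topology. `annealMP` computes $L$ with Fitch's post-order
intersection/union pass over site patterns, compressed to unique patterns
with multiplicities. Ambiguous IUPAC codes enter as base sets, and both
`-` and `?` are treated as full ambiguity $\{A,C,G,T\}$ — the classical
Fitch treatment, which keeps the bound below well defined.

Raw tree length is not comparable across data sets, so the search
optimises the normalised *homoplasy index*

$$\mathrm{HI} = 1 - \mathrm{CI}, \qquad \mathrm{CI} = K / L,$$

where $K$ is the sum over alignment columns of the tree-independent
minimum number of changes for that column (the smallest number of bases
that can cover every taxon's state set, minus one, minimised over all
resolutions of ambiguity). $K \le L$ for every topology, so
$\mathrm{HI} \in [0, 1)$.

## The annealing engine

The search is the canonical simulated annealing loop. From a random
starting topology (stepwise addition), candidates are proposed by nearest
neighbour interchange (NNI) and subtree pruning–regrafting (SPR) in strict
alternation, starting with NNI. A candidate with HI change $\Delta$ is
accepted with probability $\min(1, e^{-\Delta/T})$; because
$\Delta = cK\,(1/L_{\mathrm{cur}} - 1/L_{\mathrm{cand}})$, the data
minimum $K$ plays the role of the Boltzmann constant, and the multiplier
$c$ (default 1) exposes it as an experimental dial. Neutral proposals
($\Delta = 0$) are always accepted, so plateaus are traversed. At each
temperature $n$ moves are attempted (default 2000) for equilibration, the
working HI is recorded every $l$ moves (default 10), and the temperature
then decreases — linearly by a constant $m$ (default $10^{-7}$) or
geometrically by a ratio $\alpha$ (default 0.99). A run terminates at the
schedule floor, on an optional total move budget, or *frozen*: after
`freeze_window` consecutive decrements (default 50) without a new best HI.
There is deliberately no terminal hill-climbing refinement and no archive
of equally parsimonious trees.

Design choices worth naming:

* **SPR proposals never recreate their source**: the merged edge at the
  old attachment point is ineligible as a regraft destination, and draws
  with no eligible destination are redrawn, so every proposal perturbs
  the state and none of the fixed move budget is spent on null moves.
  Every decision point (edge, side, destination, arrangement) is a
  uniform draw.
* **Full-tree rescoring per proposal.** Correctness first; site-pattern
  compression and the compiled scoring kernel supply the speed needed at
  desk scale.
* **One RNG stream per run.** All randomness (R level and compiled level)
  flows through R's RNG, so a run is bit-reproducible from its seed;
  replicate designs derive distinct seeds as `base_seed + replicate`.

## Specific heat and critical temperatures

At each temperature block the specific heat is
$C = \sigma^2(\mathrm{HI}) / T^2$, with the sample variance over the
block's HI samples (count−1 denominator; immaterial at 200 samples per
block but fixed for reproducibility). Plotted against temperature, $C$
peaks at the *critical temperature* $T_c$ where the search stops roaming
freely and becomes trapped in one region of tree space.

Peak detection operationalises what is usually read off a figure: the
profile is smoothed with a centred moving average (window 5 points),
interior local maxima are kept when their topographic prominence reaches
25% of the smoothed global maximum, and the top two by magnitude are
classified as a *single* or *double* transition (double when separated by
at least 3 smoothed points). Both parameters are exposed; the defaults
were fixed once for this package since no published rule exists. At most
two peaks are classified — in line with what is observed for this class
of problem — while any further raw maxima remain listed for diagnostics.
The critical temperature of a replicate set is the mean of each run's
largest-peak temperature.

The Boltzmann-scaling experiment multiplies $K$ by a factor $c$ and
scales $T_0$, $m$ and the floor by the same factor. The acceptance rule
is exactly invariant under this joint scaling, so with shared seeds the
runs make identical decisions at corresponding temperatures (bit-exact
when $c$ is a power of two) and $T_c$ scales by $c$.

## Convergence through consensus trees

Where a run samples topologies (every `l_tree = 100` moves at 20 linearly
spaced temperatures, fixed prospectively between $T_0$ and the schedule
floor), the strict consensus of each temperature's sample shows how much
structure the visited states share. Resolution — the fraction of the
$n-3$ possible internal splits present — is near 0 above $T_c$ and rises
steeply below it, the consensus-tree signature of trapping. Consensus
trees are computed on unrooted splits; rooting (`root_for_display`) is
display-only, with a deterministic fallback for non-monophyletic
outgroups (maximise outgroup taxa separated, then smallest side, then
lowest canonical split).

## What the synthetic data emulate — and what they do not

`evolve_alignment` draws a root sequence and applies, on every branch of
a known topology, an equal-rates substitution process: each site changes
with probability $p$ (to a uniformly chosen different base), $p < 0.75$.
This is the simplest process that makes the homoplasy level — hence CI
and the difficulty of the search — tunable: $p \to 0$ gives CI $\to 1$,
large $p$ drives the optimum's CI well below 1. It does *not* emulate
rate heterogeneity across sites, indels (gaps are exercised through
hand-written fixtures instead), realistic base composition, or the deep
non-clock branch-length structure of real alignments. Passing tests on
these inputs therefore demonstrate the *algorithmic* claims — oracle
equality, optimum recovery, profile shape, scaling laws — not biological
accuracy on real data.

`toy_fixtures()` supplies three hand-checkable alignments whose optima
are certified by `exhaustive_search` at call time: a quartet with a
unique optimum attaining $K$, a homoplasy-free hexad ($L_{\min} = K$),
and a constructed conflict with two equally weighted incompatible
groupings (at least two equally parsimonious trees).

## Problem sizes and numerical choices

The reference study conditions run $m = 10^{-7}$, i.e. tens of thousands
of temperatures per run. This package's experiments and tests use the
same protocol at desk scale: $m = 10^{-4}$ from $T_0 = 2\times10^{-2}$
(about 200 temperatures) for profiling 8–32-taxon alignments of 300–500
sites, and $m = 10^{-5}$ from $T_0 = 2\times10^{-3}$ for the small clean
fixtures. Coarsening $m$ preserves the profile shape while keeping a run
in the seconds range. $T_0$ for the synthetic fixture class was chosen
the way the protocol prescribes for any input — from a preliminary scan
so that the peak falls inside the sampled range ($T_c \approx 10^{-2}$
for the 16-taxon class).

One interaction deserves note: the freeze window is calibrated in
*decrements*, so at a coarse $m$ it spans a far larger temperature range
than at the reference $m$. Profiling and consensus runs, whose purpose is
to sample the whole temperature range down to the floor (as the
detailed-analysis protocol does), therefore disable freezing by setting
`freeze_window` above the total block count; optimisation-style runs keep
the default of 50.

Other numerical conventions: the degenerate case $L = 0$ defines
$\mathrm{CI} = 1$, $\mathrm{HI} = 0$; a computed $L < K$ raises an error
(it would indicate a scoring bug); temperature blocks cut short by a move
budget are excluded from profiles; and `exhaustive_search` refuses more
than 9 taxa ($135{,}135$ topologies).

## A short worked run

```{r, eval = FALSE}
library(annealMP)
sim <- evolve_alignment(16, 500, p = 0.05, seed = 7)
ctx <- build_context(sim$alignment, id = "demo")
cfg <- sa_config(sa_schedule("linear", t0 = 2e-2, m = 1e-4),
                 n = 2000, l = 10, seed = 1,
                 tree_sample_levels = 20, freeze_window = 1000)
trace <- anneal(ctx, cfg)
profile <- heat_profile(trace)
detect_peaks(profile)
consensus_series(trace)
plot(profile)
```

## Known limitations

* The Metropolis kernel with alternating NNI/SPR is not guaranteed
  symmetric; the Boltzmann-stationarity check therefore uses the
  NNI-only switch, and production runs make no detailed-balance claim.
* Stepwise-addition random starts are not uniform over topologies for
  more than 4 taxa (no uniformity is claimed or needed).
* Weighted parsimony, likelihood scoring, TBR rearrangements and
  adaptive/reheating schedules are out of scope, as are majority-rule
  consensus trees.
* The peak-detection thresholds are a pragmatic operationalisation; very
  noisy profiles can flip a marginal double transition to single (the raw
  maxima list is the diagnostic of record in such cases).
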
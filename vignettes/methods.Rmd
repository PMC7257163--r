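---
title: "Learning transcriptional Bayesian networks by data fusion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning transcriptional Bayesian networks by data fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbnfuse)
```

## The problem

Transcription-factor (TF) binding networks derived from ChIP-Seq experiments
describe *where* regulators can act, but they are riddled with feedback loops
and say nothing about which bindings are functionally active in a given
condition. Gene-expression compendia carry the condition-specific signal but,
on their own, cannot orient regulatory arrows. `tbnfuse` fuses the two: the
binding network supplies the structural prior and the search space, the
expression data supply the score, and the result is a directed acyclic
Bayesian network (BN) over TFs and their target genes, distilled from many
search runs into a consensus with a topological TF hierarchy.

## The model

The joint distribution over node expression levels factorizes over the DAG,
$P(X) = \prod_i P(X_i \mid \mathrm{pa}(X_i))$, with each conditional a linear
Gaussian: node $X_i$ is normally distributed around an intercept plus a
linear combination of its parents, with residual variance $\sigma_i^2$.
Local models are fitted by ordinary least squares; model selection uses the
Bayesian Information Criterion expressed through the residual sum of squares,

$$\mathrm{BIC} = n \log(\mathrm{RSS}/n) + k \log(n),$$

with natural logarithms, $n$ the number of expression samples, and $k$ the
number of regression coefficients *including the intercept* (lower is
better). That bookkeeping makes an arc addition cost $\Delta k = 1$ and an
arc reversal $\Delta k = 0$, so a move's improvement is

$$\Delta\mathrm{BIC} = \mathrm{BIC}_{old} - \mathrm{BIC}_{new}
  = n\log\!\frac{\mathrm{RSS}_{old}}{\mathrm{RSS}_{new}} - \Delta k \log(n),$$

and because the score is decomposable, only the one or two affected local
models need refitting per candidate; the global score is the sum over all
local models. The package asserts this decomposability at run time: the
incrementally tracked global score must match a from-scratch refit to 1e-9
after every run.

Whether $\sigma$ is counted in $k$ only shifts every node score by a
constant; the printed $\Delta k$ values (1 for addition, 0 for reversal)
force the intercept-inclusive convention used here, and all move deltas are
unaffected by the choice.

## From binding network to starting model

The input network is decomposed into a TF–TF component (which may contain
loops) and a TF–gene component. The TF–TF component undergoes iterative
loop-breaking: arcs are visited from the lowest binding weight upward (or in
a seeded uniform shuffle when unweighted) and removed unless removal would
disconnect their weakly connected component. Because an edge kept in one
pass only ever becomes "more of a bridge" as other edges leave, a single
sweep terminates with a tree skeleton — exactly $n-1$ arcs per component of
$n$ TFs — which is acyclic under any orientation. Every removed arc joins
the *whitelist*, the learner's search space, with its original weight.

Two readings of "fully connected" were possible; weak (direction-blind)
connectivity is the only one a DAG can satisfy, and it reproduces the
spanning-skeleton arithmetic (65 TFs / 1827 arcs → 64 kept + 1763
whitelisted), so that reading is fixed here. Ties among equal-weight arcs
follow input order; reciprocal pairs get no special casing (the lower-weight
direction is simply visited first).

The skeleton is rejoined with the TF–gene component, intersected with the
expression matrix (unobserved nodes are dropped with their arcs; if that
disconnects the graph, the largest component is kept and the loss logged),
and each whitelist arc receives the Pearson correlation between its two TF
profiles. Sampling probabilities are $|r|$ normalized to sum to one:
repression is as informative a prior as activation, so magnitude drives
sampling while the signed $r$ is retained for reporting; near-zero
magnitudes are floored at 1e-12 so no arc becomes unreachable.

## The search

Each iteration draws `w` arcs (default 100) from the whitelist without
replacement, probability-proportional to $|r|$; every candidate is evaluated
*against the current model* (evaluations are order-independent and could run
concurrently), as an addition if neither direction is present and no
directed cycle would result, or as a reversal if the opposite arc is
present and the flip is acyclic. The single best move is applied if its
$\Delta\mathrm{BIC}$ exceeds the stop threshold

$$\tau = 10 \,/\, |\mathrm{BIC}_{global}(\text{initial model})|,$$

using the magnitude because the score's sign depends on the data scale and a
negative threshold could never stop the search. Ties break by higher
sampling probability, then lexicographic arc identity. Accepted arcs retire
from the whitelist; a reversal also retires the displaced direction, so a
resolved pair cannot oscillate. When no sampled candidate clears $\tau$, up
to `escape_attempts` (default 10) rounds with the sampling size multiplied
by `escape_multiplier` (default 2, fixed per attempt rather than
cumulative) try to move the search out of the local optimum; the first
improving move resumes the normal loop, and if all attempts fail the run
stops. Escape rounds are held to the same $\Delta\mathrm{BIC} > \tau$ bar as
normal rounds. A safety cap of $10 \times |\text{whitelist}|$ accepted moves
guarantees termination on adversarial inputs. All randomness flows from one
integer seed; run $i$ of an ensemble uses seed $+\,i-1$, and repeated
invocations are byte-identical.

## Consensus and hierarchy

For every directed TF–TF arc appearing in at least one of the ensemble's
final structures, the package records its frequency and a weight
accumulated over the containing models. Summing raw global BIC scores would
reward presence in *worse* models whenever scores are positive (the score's
sign is a data-scale artifact), so the default per-model strength is the
shifted, strictly positive
$S(m) = \mathrm{BIC}_{worst} - \mathrm{BIC}_m + \delta$ with
$\delta = |\mathrm{BIC}_{worst}| \cdot 10^{-6} + 1$: presence in more models
and in better models strictly increases the weight, and when all models
score equally the weight reduces to plain frequency counting. This is the
package's main interpretive decision and a literal raw-sum mode
(`mode = "raw"`) is provided alongside.

Candidates at or above the chosen weight percentile (linear interpolation;
5 is a strict noise filter for large ensembles, 25 suits smaller prior
networks) are selected, then repaired: of two surviving directions the
higher-weight one wins (ties: frequency, then lexicographic); while a
directed cycle remains, the lowest-weight arc lying on a cycle is dropped;
weak connectivity of the selection plus the fixed TF–gene arcs is verified
and a warning reports components otherwise. Raising the percentile can only
shrink the selection.

Each TF's hierarchy height $h = (\text{out} - \text{in}) /
(\text{out} + \text{in})$ on the consensus TF–TF subgraph stratifies the
regulators into master regulators ($h > 1/3$), middle managers, and
workhorses ($h < -1/3$); the cutoffs are conventional and configurable, and
isolated TFs sit mid-layer with a flag. Average connectivity is reported
both as mean total degree and as arcs-per-node, since the two conventions
differ and either may be wanted.

## The synthetic generator

The generator emulates the statistical structure the method assumes: a
random weakly-connected acyclic core over the TFs (random recursive tree
plus forward arcs under a random topological order), to which a stated
fraction of cycle-closing arcs is added — the first is always the reversal
of a core arc (a 2-cycle), the rest reverse directed core paths, so every
loop arc genuinely closes a cycle. Loop arcs are observational decoys with
no generative effect: a joint Gaussian with true feedback is ill-defined in
this model family, and this mirrors how real binding priors contain loops
while the learned model is a DAG. Expression is sampled in topological
order from the core plus TF–gene arcs. Defaults, chosen once as plausible
for normalized expression data: coefficient magnitudes Uniform(0.5, 1.5)
with random sign, intercepts Uniform(−1, 1), residual SD 1.0, 100 samples;
core arcs receive stochastically higher binding weights (Uniform(1, 3))
than loop arcs (Uniform(0.5, 2)). False-prior injection draws
round-half-even `fraction × |TF-TF arcs|` arcs uniformly from the absent
ordered TF pairs, with weights drawn between the existing extremes so they
are indistinguishable downstream.

What passing tests on this generator do *not* show: real microarray
compendia have probe effects, batch structure, non-Gaussian tails, and
regulatory saturation that the linear-Gaussian simulator omits; recovery
rates here are upper bounds on real-data behavior.

## Numerical choices and degenerate inputs

- RSS of an exact fit is floored at $10^{-12} \times$ TSS before the
  logarithm (the score is undefined at zero, which noiseless synthetic data
  can produce), with a warning.
- Collinear parent sets fall back to the minimum-norm least-squares
  solution (SVD pseudoinverse), with a warning.
- Zero-variance expression profiles are an error at whitelist-probability
  time, naming the TF.
- Duplicate input arcs collapse to the maximum weight (binding scores are
  confidence measures; keep the strongest evidence); self-loops are
  rejected outright since they can never enter a DAG and would poison the
  whitelist.
- Disconnected TF–TF inputs are processed per component, yielding a forest
  skeleton, with a warning; single-TF components contribute no skeleton
  arcs.
- Arcs restored during loop-breaking (bridges) are not revisited: removal
  is a single pass over the sorted sequence, which provably reaches the
  $n-1$ budget.

## Problem sizes used in the shipped checks

The test suite runs entirely on generated data: spanning-skeleton arithmetic
at the full published scale (65 TFs / 1827 arcs and 33 TFs / 249 arcs, which
complete in seconds); search-correctness replays on 20-TF networks with 100
samples; structure recovery on a 6-TF planted-arc scenario over 20 seeds at
200 samples; and the false-prior experiment on a 20-TF / 100-gene fixture at
150 samples with ensembles of 20 runs and a sampling set of 20 — kept below
the whitelist size so that independent runs genuinely differ, matching the
sampling-to-whitelist ratio of the full-scale procedure rather than its
absolute `w`.

## Known limitations

- At small network scale, a dense generative core means a random absent TF
  pair is usually ancestor-related, so injected false-prior arcs carry
  genuine indirect dependence; consensus precision against direction-exact
  gold arcs then degrades faster with the injection rate than published
  full-scale behavior, where the prior network is much larger and sparser.
  The robustness harness reports reversed-gold and injected counts
  separately so this effect is visible.
- The search never deletes arcs, searches only TF–TF structure (TF–gene
  arcs are fixed), and explores only the whitelist; arcs absent from the
  binding prior cannot be discovered.
- Consensus aggregation assumes all models share the node universe; mixing
  ensembles from different expression panels is unsupported.
- Candidate evaluation is sequential in this implementation (the contract
  is order-independent, so results are identical to a concurrent
  evaluation).
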
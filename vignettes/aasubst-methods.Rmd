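---
title: "Models and methods in aasubst"
author: "aasubst authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in aasubst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aasubst)
```

`aasubst` implements the full pipeline around empirical amino-acid
substitution models: rate-matrix algebra, +I+G pruning likelihoods,
iterative joint estimation of a new exchangeability matrix from a
collection of alignments, model comparison, and Robinson–Foulds topology
bookkeeping. This vignette is the package's own account of the methods, the
defaults, and the choices made where the design was genuinely open.

## The substitution model

Amino-acid substitution is modelled as a stationary, time-reversible
20-state Markov process shared by all sites. A model is a pair
$(r, \pi)$: symmetric exchangeabilities $r_{xy} \ge 0$ and equilibrium
frequencies $\pi$. The generator is
$q_{xy} = \pi_y r_{xy}$ off the diagonal, with the diagonal set so rows sum
to zero. Reversibility is inherited from the symmetry of $r$, giving
detailed balance $\pi_x q_{xy} = \pi_y q_{yx}$.

**Normalization.** `build_rate_matrix()` rescales the generator by the
expected substitution rate $\mu = -\sum_x \pi_x q_{xx}$, so branch lengths
are in expected substitutions per site. The frequency-weighted $\mu$ is
what makes that calibration exact; the unweighted diagonal sum
$-\sum_x q_{xx}$, which sometimes appears in descriptions of this
normalization, is available via `mu_weighted = FALSE`. Normalization only
rescales time: after branch lengths are re-optimized, maximized
likelihoods and topologies are unchanged (this is verified in the test
suite by fitting under both the raw and normalized generator).

**Transition probabilities.** $P(t) = e^{Qt}$ is computed from the
symmetric eigendecomposition of $\Pi^{1/2} Q \Pi^{-1/2}$, which is exact
for reversible generators and gives every $P(t)$ for the cost of one
decomposition. The builder checks the eigensystem reconstructs $Q$ to
$10^{-12}$; a numerically degenerate spectrum flips the object to a
scaling-and-squaring series fallback. Round-off negatives in $P$ are
clamped to zero.

## Likelihood with rate heterogeneity

Site rates follow the usual mixture of an invariant class (proportion
$v \in [0, 1)$) and $C$ discrete gamma categories (shape $\alpha$,
default $C = 4$). Category rates are the conditional means of
equal-probability bins of the mean-one gamma distribution — not bin
medians — so they average exactly one for every $\alpha$. The per-site
likelihood is

$$ L_i = v\,L(\mathrm{Inv}; D_i) + (1 - v)\,\frac{1}{C}\sum_c
   L(\rho_c T, Q; D_i), $$

where $\rho_c T$ multiplies all branch lengths by the category rate and
the invariant term is the equilibrium frequency of the residue a constant
column is fixed at (summed over the residue set when ambiguity codes are
compatible with more than one; an all-gap column contributes likelihood 1,
i.e. log-likelihood 0). Some presentations of this model place the product
over sites inside each mixture component; the per-site mixture above is
the form every likelihood-based phylogenetics program computes, and it is
what the package implements. Note one convention difference to be aware of
when comparing numbers across programs: several implementations rescale
the gamma rates by $1/(1-v)$ so that the *overall* mean rate including the
invariant class is one. `aasubst` keeps the category rates at mean one
regardless of $v$, exactly as the mixture above is written; the test suite
therefore cross-checks against an independent implementation at $v = 0$,
where the conventions coincide.

Each category term is Felsenstein's pruning algorithm. The engine (C++,
RcppArmadillo) works on compressed site patterns, carries per-node
per-pattern scaling logs to prevent underflow at any alignment size, and
accepts multifurcating trees (needed after zero-length branches are
collapsed). Ambiguity codes (`B`, `Z`, `J`, `X`, gaps, and the
one-letter rare codes) enter as indicator sets over their compatible
residues.

The same engine returns analytic derivatives. A root-to-tip pass yields,
for each edge, the outer product of the flank partial vectors; combining
it with the Daleckii–Krein divided-difference form of the matrix-exponential
directional derivative gives $\partial \ln L / \partial t_e$ for every
branch and $\partial \ln L / \partial Q$ as a $20\times 20$ matrix in one
sweep. Both gradients are verified against central finite differences in
the tests.

## Fitting a single alignment

With the matrix fixed, `optimize_alignment_jointly()` (used by
`fit_alignment_params()` and the comparison pipeline) maximizes over all
branch lengths, $\alpha$ and $v$ in one box-constrained quasi-Newton
search: log-scale branch lengths with the analytic gradient, central
differences for the two rate parameters. A joint search was chosen over
alternating one-block updates because branch lengths and $\alpha$ are
strongly coupled and the alternation zigzags (measurably: refitting after
an "alternated" fit still gained ~0.2 log units, while the joint fit is a
fixed point to $10^{-3}$). The one-block optimizers
`optimize_branch_lengths()` (joint over branches, monotone and idempotent)
and `optimize_rate_model()` ($\alpha \in [0.02, 100]$,
$v \in [0, 0.99]$) remain available as building blocks.

Starting trees come from `initial_tree()`: one-dimensional maximum
likelihood distances for every pair (columns with ambiguity codes are
skipped; identical sequences sit at the $10^{-6}$ lower bound; fully
incomparable pairs fall back to a large distance with a warning), joined
by neighbor joining with negative reconstructed branches clamped to
$10^{-6}$. Topologies are then held fixed; only branch lengths and
$(\alpha, v)$ are re-fit in later iterations. Full pipelines in the
literature re-search the topology with external software each iteration —
that step is out of scope here, and the fixed-topology refit is the
self-contained stand-in.

## Estimating a matrix from a collection

`estimate_model()` maximizes the joint target
$\prod_i LK(T^i, Q, \alpha^i, v^i; D^i)$ by alternating conditional
maximizations:

1. fit every alignment's $(T^i$ lengths, $\alpha^i, v^i)$ under the
   current matrix;
2. with those fixed, update the exchangeabilities by L-BFGS-B on
   $\log r_{xy}$ using the analytic $\partial \ln L/\partial Q$ gradient.

Frequencies are held at the training set's empirical residue proportions
(with a half-count pseudocount so no frequency is exactly zero); ML
frequency estimation is deliberately out of scope, matching how empirical
matrices are normally built. During the matrix step all 190 coefficients
are free: branch lengths are fixed there, so the overall rate scale is
identifiable and letting the optimizer absorb it speeds convergence. The
returned model is normalized to unit expected rate, which restores the
conventional 189-degree-of-freedom content (the 208 free parameters of the
amino-acid GTR model are these 189 plus 19 free frequencies). Both
half-steps only increase the target (each optimizer keeps its starting
point when no improvement is found), so the recorded per-iteration totals
are non-decreasing by construction.

Iteration stops when the gain drops below `tol` (default 0.01 log units
per site — the scale at which improvements stop mattering for model
choice) or at `max_iter`. On recovery simulations the first iteration
carries essentially all of the gain and the loop stops after two to three
iterations, reproducing the known behaviour of this estimation scheme at
corpus scale.

Note a statistical floor relevant to interpreting traces: refitting 190
free coefficients always captures sampling noise worth about
$\chi^2_{190}/2 \approx 95$ log units. On small training sets this
overfitting gain exceeds any per-site threshold; the tests bound it
explicitly rather than pretending it is zero.

## Data preparation

`filter_branches()` mirrors the standard cleanup of noisy training trees:
internal branches of length $\le$ `min_len` (default 0) collapse into
polytomies, leaves on zero-length terminal branches are dropped, and any
branch of length $\ge$ `max_len` (default 2 substitutions/site) is cut,
turning the tree into a forest whose parts become independent training
units — cutting, rather than merely ignoring, long branches is the
interpretation consistent with the splitting pipeline's purpose. Path
lengths within a part are never altered.

`split_alignment()` recursively cuts a guide tree at the most balanced
edge until every part has at most `max_size` sequences (default 128, the
size at which per-alignment fitting stays cheap). Ties between equally
balanced edges are broken by the lexicographically smallest canonical
split key, so splitting is deterministic.

## The simulator

`simulate_alignment()` and `simulate_training_set()` generate data under a
known $(T, Q, \alpha, v)$: per site an invariant flag or a gamma category,
a root residue from $\pi$, then transitions $P(\rho_c t)$ down the tree.
The defaults define the study conditions used throughout the package's
own experiments: collections of 8 alignments, 16 taxa, 500 sites; random
topologies drawn uniformly over labelled topologies; branch lengths from
an exponential with mean 0.15 substitutions/site truncated to the open
interval (0, 2) — the same window the branch filter keeps; per-alignment
$\alpha$ uniform in [0.5, 2] and $v$ uniform in [0, 0.2], spanning the
heterogeneity typically reported for protein alignments. Everything is a
deterministic function of the seed.

What the simulator does *not* emulate: insertions and deletions (gaps
appear only if present in input data), compositional heterogeneity across
lineages or sites, site-specific structural constraints, and codon-level
effects of variant genetic codes. Passing recovery tests therefore shows
the estimator is correct and well-behaved under the model's own
assumptions — not that those assumptions hold for any particular real
proteome.

## Numerical choices and degenerate inputs

* Frequencies within $10^{-4}$ of summing to one are renormalized on read;
  larger deviations are format errors naming the line.
* All-zero exchangeabilities make $\mu = 0$ and raise a degenerate-model
  error; zero denominators in ratio tables are flagged, not errors.
* Branch lengths live in $[10^{-8}, 100]$ on the log scale during
  optimization; missing or non-positive starting lengths are initialized
  at 0.1.
* Optimizer tolerances: L-BFGS-B `factr = 1e7` for per-alignment fits
  (≈ $10^{-9}$ relative), `1e8` for the matrix step; branch rounds stop
  below $10^{-4}$ log units, the outer loop below 0.01 per site.
* Site patterns with zero likelihood in every mixture component (possible
  only with inconsistent data) raise an error naming the site.
* `rf_distance()` counts nontrivial splits only — trivial splits are
  always shared — which is the convention under which two binary $n$-leaf
  trees sharing no internal structure are at distance $2(n-3)$;
  `bipartitions(include_trivial = TRUE)` exposes the $2n-3$ bookkeeping
  used by the incorrect-bipartition bound.

## Known limitations

* No tree-topology search; topologies come from the user or from the NJ
  starting tree.
* The AU/SH tree tests are not implemented; `export_site_lnl()` writes the
  site-likelihood matrix their standard implementation consumes.
* No bootstrap supports, no site-heterogeneous (mixture-matrix) models,
  no codon or nucleotide models.
* The +I+G convention difference described above means likelihoods at
  $v > 0$ are not directly comparable number-for-number with programs
  that rescale category rates by $1/(1-v)$, although fits and rankings
  agree.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely from simulated
or constructed inputs: exhaustive topology checks at 5 leaves, pruning
oracles at 4–5 taxa, likelihood fits at 5–16 taxa and 40–5000 sites, and
the recovery study at 8 × 16 × 500 sites. These sizes were chosen so every
property is exercised at full numerical strictness while the whole suite
stays in the minutes range on one CPU; the estimator itself has no
intrinsic size limits beyond memory.
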
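---
title: "Detecting positive selection of amino-acid dyads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positive selection of amino-acid dyads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsel)
```

## The problem

Short motifs of two adjacent residues can be functionally essential to a
domain family and yet invisible to column-wise conservation analysis,
because the motif's *position* is free to move: a copy newly created by
random substitution can take over the function of an older copy that
subsequently decays. `dyadsel` tests for the selective maintenance of
such a dyad by simulating what neutral evolution alone would produce on
the family's own phylogeny, and comparing the observed number of
motif-bearing family members against that simulated null.

## The substitution model

The model is a reversible continuous-time Markov chain on the 20 standard
amino acids, built to be equivalent to the BLOSUM62 score matrix. The
package embeds a joint (target) pair-frequency table derived from the
published integer BLOSUM62 scores: solving
$\sum_b p(b)\,2^{s(a,b)/2} = 1$ for the background vector $p$ gives an
all-positive solution, and $J(a,b) = p(a)\,p(b)\,2^{s(a,b)/2}$
(normalized) is the unique pair table consistent with those scores. This
is checked in the test suite by the strongest test available: rounding
the half-bit log-odds of the embedded table reproduces all 210 published
integer scores exactly, and the background marginal lands within 0.014 of
the classical BLOSUM62 residue frequencies (the residue is score
rounding).

From the table, the conditional matrix $M(a,b) = J(a,b)/p(a)$ is a
one-step transition matrix; its principal matrix logarithm is the
generator $Q$. Numerically, $\mathrm{diag}(\sqrt{p})\,M\,
\mathrm{diag}(1/\sqrt{p})$ is symmetric positive definite, so the
logarithm is computed in that symmetric basis and is exactly real. The
construction produces a handful of very small negative off-diagonal rates
(total magnitude $\approx 0.002$ before scaling); these are clamped to
zero. Because detailed balance pairs the sign of $q_{ab}$ with that of
$q_{ba}$, clamping removes rate pairs jointly and cannot break
reversibility; a clamp larger than `clamp_threshold` (default 0.01)
aborts instead, since it would indicate a corrupted input table. The
diagonal is then reset so rows sum to zero and the matrix rescaled so
that $-\sum_a p(a)\,q_{aa} = 1$: **one unit of branch length is one
expected substitution per site**. Trees in other units (e.g. PAM/100)
are converted with the CLI's `--branch-scale` factor rather than guessed.

Transition probabilities use the spectral form
$P(t) = U e^{\Lambda t} U^{-1}$ with the eigendecomposition done in the
symmetrized basis (real eigenvalues guaranteed by reversibility).
Entries that round below zero at large $t$ are clamped and rows
renormalized; the renormalization is asserted to be a no-op within
$10^{-8}$. The orientation is the Markov-chain standard: *rows* index
the ancestral residue, so each row is the conditional distribution of
the descendant (the transpose of a column-indexed convention; the
sampled process is identical).

Assumptions inherited by everything downstream: sites evolve
independently and identically (no rate heterogeneity), branches evolve
independently, there are no insertions or deletions, and the process is
stationary and time-reversible.

## The simulator

`evolve_once()` walks the validated rooted tree from the root down; on
each edge of length $t$, each child residue is drawn from the row of
$P(t)$ selected by the parent residue at that site. Transition matrices
are computed once per distinct branch length and cached, since thousands
of replicates reuse one tree. Polytomies (e.g. consensus trees) are
simulated as independent children, which is exactly what branch
independence means. Gapped roots are rejected with the offending
position, never silently stripped — degapping an alignment column is an
explicit, user-visible step (`--degap`).

Replicate streams use L'Ecuyer-CMRG substreams from one master seed:
replicate $i$ always receives stream $i$, so any single replicate is
reproducible from `(seed, i)` without regenerating the others, and
streams are independent by construction. `simulate_replicates(FUN=)`
reduces each replicate as it is produced, so a 10 000-replicate null
uses constant memory.

## The test

The statistic is the **presence count**: the number of sequences in a
set containing at least one copy of the dyad (multiple copies count the
sequence once; total-copy behavior is summarized separately by
`multi_copy_fraction()`). The empirical p-value of an observed count is
the fraction of null replicates reaching it. Two conventions matter:

* Zero exceedances are reported as the bound $p < 1/n_{\mathrm{reps}}$
  together with the raw exceedance count, never as $p = 0$ — a finite
  simulation cannot distinguish small from zero.
* The 400-dyad scan reports raw p-values with **no multiple-testing
  correction**: its purpose is calibration, comparing the number of
  flagged dyads with the $400\alpha$ expected by chance (about 4 at the
  1% level). A correction would defeat that comparison.

Because the null support is the integers $0..n_\mathrm{leaves}$ and the
distribution is lumpy (multimodal through shared ancestry), the attained
type-I error at a nominal $\alpha$ is the null tail mass at the smallest
count whose tail drops below $\alpha$ — close to, but not exactly,
$\alpha$. The calibration check therefore uses a binomial interval
around the nominal level rather than an equality.

## The synthetic-data generator

The generator exists so that every statistical property of the pipeline
can be exercised without downloads. Its defaults are the study
conditions of a domain-family analysis and are not tuning knobs: **41
leaves** and **70-residue** root sequences (the scale of a
membrane-proximal domain family tested across the animal kingdom), with
branch lengths exponential of **mean 0.2** expected substitutions/site —
the scale-bar order of magnitude of such trees, which also places the
neutral mean presence count near 3 (stationary root), comfortably inside
the regime where the test has something to measure. Topologies come from
sequential random joins (uniform over labeled topologies); roots are
drawn i.i.d. from the model's stationary distribution, optionally with
one planted copy of the target dyad.

The alternative-hypothesis generator implements "a selection force
maintains at least one copy" by per-edge rejection sampling: any edge
outcome leaving a node with zero copies is redrawn (cap 10 000 per edge;
exceeding the cap is an error that flags a branch too long for the
constraint, rather than a silent distortion). Rejection gives the exact
conditioned distribution with a one-line correctness argument, at the
price of wasted draws — adequate at these scales, where acceptance per
edge stays far from the cap. The constraint is on *presence*, not
position: copies migrate freely, reproducing motif turnover, and the
test-suite checks that the planted copy is frequently *not* the copy a
leaf retains.

What the generator does **not** emulate: real domain compositional bias
(roots are stationary), among-site rate variation, indels, alignment
error, or tree-inference uncertainty. Passing tests on synthetic data
therefore validate the statistical machinery — calibration, power,
reproducibility — not the biological pre-processing that produces a tree
and a degapped domain set from real sequences.

## Problem sizes and numerical choices

The test suite runs the model checks at machine tolerance (spectral vs
series exponential within $10^{-8}$ over 50 random times), simulator
calibration on $10^5$-site edges (per-cell deviations within 3 binomial
SDs, applied where the normal approximation is valid — expected count at
least 5 — and allowing the ~1% of chance 3-SD excursions that ~350
simultaneous cells produce), type-I calibration with a 2 000-replicate
null against 1 000 independent neutral observations (99% binomial band
around $\alpha = 0.05$; one shared null is used because the attained
level conditions on it only weakly at that null size), power with a
10 000-replicate null against a fully selected dataset (bound
$p \le 10^{-4}$), and the neutral-on-neutral 400-dyad scan against the
99% binomial interval of $\mathrm{Bin}(400, 0.01)$. These sizes make the
whole suite run in about two minutes while leaving every check
statistically meaningful.

Tie-breaks and degenerate inputs: $t = 0$ returns the identity exactly;
empty intersections give presence count 0 and $p = 1$ at observed 0;
dyad cells with zero observed frequency have *undefined* log-odds and
are returned as `NA`, never as a numeric sentinel; nonstandard residues
(B, J, O, U, X, Z) are excluded from composition counts — together with
both adjacent pairs — rather than remapped, because remapping would
silently distort the dyad distribution.

## Open choices made here

* **Log-odds base.** The absolute scale of published dyad log-odds
  values is meaningless without the base, which is often unstated. The
  base is therefore a required, recorded parameter (default 2) in every
  output header.
* **Observed region definition.** Whether the observed presence count is
  computed on a full domain or a fixed C-terminal window changes the
  count; the observed set is always explicit user input, never inferred.
* **Species filter.** "More than N sequences" is strict (`> N`), and the
  dropped species are reported with their counts.

## Limitations

The p-value floor is $1/n_\mathrm{reps}$; claims below $10^{-4}$ need
more than $10^4$ replicates. The test conditions on the tree — branch
lengths in the wrong units scale the whole null (hence
`--branch-scale`), and tree error propagates unexamined. The model is
site-homogeneous; genuinely heterogeneous domains will make the neutral
null mildly misspecified in both directions. Motifs longer than two
residues are out of scope (the counting layer is the natural extension
point).
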
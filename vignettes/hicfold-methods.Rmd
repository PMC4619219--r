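---
title: "hicfold: model, scoring and optimizer internals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hicfold: model, scoring and optimizer internals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicfold)
```

## The problem and the model

Hi-C measures spatial proximity between pairs of genomic loci. For a
single chromosome binned at a fixed resolution (1 Mb by default), the data
reduce to a symmetric contact matrix `IF` whose entry (i, j) counts the
contacts observed between regions i and j. `hicfold` represents the
chromosome as an ordered chain of one 3D point per retained region
(micrometre units) and searches for a chain that is *congruent* with the
matrix: contacting pairs close, non-contacting pairs far, consecutive
regions neither fused nor stretched.

This is a constraint-satisfaction formulation, not a statistical inverse
model: the objective is a percentage of satisfied constraints, there is no
likelihood, and the output is a single representative model plus the
ensemble it was selected from. That makes the method transparent and fast,
at the cost of ignoring count magnitudes beyond the IF weighting and of
having no uncertainty quantification.

## Scoring

Four sub-scores, all computed from squared distances (no square roots in
any scoring loop; thresholds are stated as squared values throughout):

| sub-score | population | satisfied when | default weight |
|---|---|---|---|
| CS | pairs with `IF > 0` | `d² ≤ 7 μm²` | 2 |
| NS | pairs with `IF = 0` | `d² > 7 μm²` | 2 |
| IF | contact pairs, weighted by `IF` | as CS | 3 |
| MS | consecutive pairs (k, k+1) | `0.2 ≤ d² ≤ 20.25 μm²` | 1 |

Conventions that matter and are locked by tests:

- **All unordered off-diagonal pairs** are scored for CS/NS/IF — not just
  chain-adjacent ones. Only this reading makes CS/NS describe the whole
  contact matrix, which is also what the satisfaction heat map displays.
- The diagonal is excluded everywhere; chain-adjacent pairs (|i−j| = 1)
  are *included* in CS/NS like any other pair.
- At exactly the threshold, a contact is satisfied (closed comparison) and
  a non-contact is unsatisfied (open) — no pair can be double-counted.
- The MS denominator is the region count n, exactly as the formula is
  printed, so a perfect chain of n loci scores 100·(n−1)/n, not 100. The
  alternative (n−1 bonds) is arguably intended but is not what the formula
  says; we follow the formula.
- A sub-score whose population is empty (no contacts, no non-contacts,
  zero total IF, n < 2) is *not applicable*: it is reported as `NA` and
  drops out of the weighted total with its weight, rather than
  contributing 0. This keeps degenerate instances (e.g. an all-contact
  toy matrix) scorable.

The total is the weighted average with weights (2, 2, 3, 1); integer
weights, IF highest because it carries the observed contact counts.

## Input processing

`build_matrix()` spans bins from the lowest observed coordinate (the
origin is configurable; `origin = 0` gives dataset-independent binning)
with half-open bins; a coordinate exactly at the top edge of the overall
span is clamped into the last bin. Each contact record increments both
`freq[i,j]` and `freq[j,i]`, so a same-bin record adds 2 to its diagonal
entry and the mass identity `sum(upper triangle) + sum(diag)/2 = record
count` holds exactly. Duplicate records are counted, not deduplicated.

Centromeres leave no mappable signal; `remove_gaps()` accepts explicit
BED intervals or, in `"auto"` mode, removes the single longest contiguous
run of all-zero rows. The omission is recorded (`gap_mask`,
`region_index`) so model beads can be mapped back to genomic coordinates.

Two normalizations are provided. `"ice"` iteratively divides the matrix
by the outer product of its marginals (rescaled to mean 1 over non-empty
rows) until the marginals agree to `tol`; non-convergence warns and
returns the best iterate. `"coverage"` is the single-pass
`freq / sqrt(rowsum_i · rowsum_j)` variant. Empty rows are excluded from
balancing and left untouched in both.

## Initialization

Chains with more than 200 regions are grown sequentially
(`R_i = R_{i−1} + r`, `‖r‖` uniform on [0, 1) μm, isotropic direction,
first point at the origin — the score is translation-invariant, so an
arbitrary anchor is harmless). Smaller chromosomes start as uniform
random points on a 1 μm sphere; the boundary n = 200 itself uses the
sphere. Isotropic directions are drawn by normalizing standard-normal
triples; rejection from a cube would bias directions toward the corners.
Growth deliberately has no self-avoidance: nothing is known about the
step vector, and the optimizer resolves overlaps.

## Optimization

**Adaptation.** One iteration attempts a move at every locus in a fresh
random order (this makes iteration cost proportional to n and matches how
progress is usually reported per-iteration-block). A move at locus i
draws `adapt_trials` (default 10) candidate vectors, applies each to
points i..n rigidly, and keeps the best candidate only on *strict* score
improvement — ties are rejected to prevent drift along the large plateaus
of a percentage-valued objective. Snapshots after improving iterations
form the ensemble, capped at `ensemble_max` (default 50) members; because
the greedy score is non-decreasing, the most recent snapshots are also
the highest-scoring, so the cap is unambiguous. The full-scale default is
50,000 iterations; the tests use 2,000 (n ≤ 40), which on synthetic
instances recovers most of the attainable score.

**Simulated annealing.** The temperature schedule is geometric
(`T_k = T0 · 0.95^k`, `T0 = 1`) over `sa_iters = 50` sweeps, with the
0–100 score used directly as energy. Candidates are generated by one
adaptation pass whose moves are accepted *unconditionally* — if proposals
were themselves greedy, no candidate could ever be worse and SA would
collapse into hill climbing. Incumbent vs candidate is then resolved by
the Boltzmann rule (`accept worse with prob exp(−ΔE/T)`); equality always
accepts. Plain SA does not guarantee a final score above the entry score,
so each member carries a best-ever archive, and the archived structures
are what SA returns.

**Genetic algorithm.** Selection keeps the top `ceil(keep_frac · m)`
(default half, ties to the earlier index). Survivors are paired randomly
and disjointly; each pair produces two children by single-point
coordinate crossover (`A₁..A_p, B_{p+1}..B_n` and the converse; a
multi-point variant is available via a vector of crossover points).
Children are appended — the population may grow before the final pick.
Every member then undergoes `ga_mutations` (default 10,000) single-point
displacements, each kept only on strict improvement, so mutation is
monotone. The final model is the ensemble argmax (ties to the lowest
index).

The pipeline guarantees, and the tests assert, global monotonicity of the
best score across stage boundaries, full-run determinism under a fixed
seed (all randomness flows through R's RNG, including inside the compiled
core), and length preservation by every operator.

## Synthetic ground truth

The generator states the world the test suite lives in: a random-walk
chain with exact bond length 1.5 μm confined to a 6 μm-radius sphere,
thresholded at the scoring default 7 μm² into a binary contact matrix.
The bond length sits comfortably inside the [√0.2, √20.25] MS window;
the confinement radius produces contact maps with a dense near-diagonal
band plus confinement-induced long-range contacts — the qualitative
anatomy of a real intra-chromosomal map at 1 Mb. Confinement is enforced
by re-drawing step directions that would exit the sphere (rejection):
reflecting a fixed-length step off the boundary cannot preserve the exact
bond length the generator contract promises, and rejection is trivially
cheap at the chain lengths used anywhere in this package.

Optional realism knobs, both off by default: an over-dispersed frequency
law (`1 + Poisson(λ/d²)`, mimicking Hi-C distance decay — a fixture
choice, not a biological claim) and symmetric per-contact dropout with
recorded dropped pairs. What the generator does *not* emulate: coverage
and GC/mappability biases, restriction-fragment granularity, TADs and
compartments, unmappable regions other than via `remove_gaps()`, and
inter-chromosomal context. A green recovery test therefore establishes
that the optimizer can invert its own forward model at realizable
contact maps — not that real Hi-C maps, which are generally *not* exactly
realizable by any single chain, will reach the same scores.

## Validation protocols

`convergence_test()` reconstructs the same matrix from two independent
seeds and reports the score gap and the Spearman correlation of the two
models' pairwise-distance matrices. The distance-matrix correlation is
used because it is superposition-free and invariant to rotation,
translation and mirror image — a mirrored model is an equally valid
solution, since the scores cannot distinguish chirality.
`recovery_test()` builds model A, derives the binary contact matrix A
implies at the contact threshold, rebuilds model B from it, and reports
the A-vs-B distance correlation plus B's CS/NS against the derived
matrix. Thresholds used in the acceptance tests (score gap ≤ 5, Spearman
≥ 0.7, recovered CS/NS ≥ 90) are artifact-defined: the original
validation of this family of methods was visual.

## Numerical choices and degenerate inputs

- Strict `>` comparisons for every accept decision; scores are ratios of
  counts, so identical recomputation yields identical doubles and ties
  are exact.
- Rejected adaptation trials restore coordinates from a saved copy rather
  than subtracting the trial vector, so a rejected move leaves the
  structure *bit-identical* (add-then-subtract leaves ~1e-16 residue,
  which would break determinism contracts).
- ICE on a matrix with empty rows balances only the non-empty block.
- A structure of one locus scores MS as not-applicable; an ensemble of
  one member passes through selection and crossover unchanged while
  mutation still runs.
- PDB export writes μm values directly into the fixed-width coordinate
  columns (scale factor configurable); read-back is faithful to 3
  decimals of the scaled units, and chain order is preserved via
  consecutive CONECT records.

## Known limitations

Single chromosomes only (no inter-chromosomal restraints or whole-genome
assembly); no gradient-based refinement; no restriction-fragment binning;
the percentage objective is blind within threshold plateaus, so greedy
adaptation can stall on instances whose score landscape is locally flat —
the SA stage exists precisely to cross such plateaus. Scores of models
built from real, noisy Hi-C matrices are bounded away from 100 by
construction whenever the matrix is not realizable by any chain in 3-space.
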
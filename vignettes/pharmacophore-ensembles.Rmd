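---
title: "Ensembles of pharmacophore hypotheses: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembles of pharmacophore hypotheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmensemble)
```

## The screening problem

A pharmacophore hypothesis is an abstract spatial arrangement of typed
interaction features — hydrogen-bond acceptor (A), donor (D), hydrophobe
(H), positively charged group (P), aromatic ring (R) — that a ligand must
present to bind a target. A single hypothesis rarely covers the chemical
space of all known ligands of a receptor: different chemotypes bind with
different feature arrangements. `pharmensemble` implements the
ensemble alternative: build one hypothesis per ligand cluster, then search
exhaustively for the *linear combination* of hypotheses that maximizes a
screening statistic, classifying a compound as active when at least one
(`hit_once`) or at least two (`hit_twice`) hypotheses in the combination
match it.

The statistics are computed from the confusion counts of a screen,

$$\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},\qquad
  \mathrm{Acc} = \frac{TP+TN}{TP+FP+TN+FN},\qquad
  \mathrm{Rec} = \frac{TP}{TP+FN},$$

each averaged over two paired test sets that share the same actives: one
against experimentally confirmed decoys, one against assumed inactives.
MCC is defined as 0 when a denominator factor vanishes.

## Pipeline stages and their parameters

**Curation.** Heterogeneous activity records are funnelled onto a common
Ki scale in nM: IC50 is taken as twice Ki, and pKi/pIC50 are log10 molar,
so Ki[nM] = 10^(9 − pKi). When one compound has several measurements the
most-preferred (species, measure) stratum present is kept — human Ki over
other human data over rat Ki over other rat data over anything else — and
the median of the survivors is used (mean of the central two for even
counts). The preference interleaving of species and measure is our
documented choice; the two preferences are stated independently in the
underlying protocol. Actives have Ki ≤ 100 nM; inactives Ki > 1000 nM
(strict); the band in between is *ambiguous* and excluded from both model
building and test sets, but written to an exclusion report rather than
dropped silently.

**Fingerprints and clustering.** Two fingerprints are available.
MOLPRINT-2D encodes, per heavy atom, the multiset of (topological
distance ≤ 2, atom type) pairs; our atom type is the
(element, aromaticity, heavy-degree) triple — a typer-free, documented
stand-in for vendor atom typing. The 3D pharmacophore triplet fingerprint
(P3D) keys every feature triplet by its sorted type triple and sorted
1 Å-binned distances (capped at 15 Å). Both are compared with the Soergel
distance (1 − Tanimoto on key sets), a proper metric on binary sets.
Actives are clustered by average-linkage agglomeration; the cut level is
chosen by the Kelley penalty: the mean within-cluster spread per level is
min–max normalized onto [1, N−1] and penalized by the cluster count, the
minimizing level winning (ties to fewer clusters). Clusters below 3
members are pooled into a *special class*; clusters above `max_size`
(default 20 % of the input) are re-clustered recursively up to 4 times.

*Mono- vs multi-conformer P3D* was genuinely open. We use
multi-conformer fingerprints: a compound's key set is the union over its
conformers. Hard 1 Å bins are brittle — a 0.2 Å coordinate jitter moves a
pairwise distance by ≈ 0.3 Å, flipping a bin roughly a quarter of the
time, and a triplet key survives only if all three bins hold — so a
conformational ensemble is what makes same-scaffold compounds share keys
reliably. This mirrors how the underlying engines work with conformer
ensembles anyway.

**Diversity selection.** Sphere exclusion over Soergel distances
(radius 0.5, random seeded initialization) picks cluster representatives;
a cluster of size *n* receives max(4, round(n · 0.94/50)) of them, the
rate calibrated once so a 533-member cluster yields 10. "The n most
diverse compounds" is operationalized as sphere exclusion whose radius is
grown by bisection until the selection size hits n; shortfalls are filled
by max–min padding (flagged). Test sets come in three schemes sharing
decoys and assumed inactives: `random` (uniform), `diverse`
(sphere-exclusion), `populated` (per-cluster quotas proportional to
cluster sizes, largest-remainder rounding).

**Hypotheses and matching.** A hypothesis is 4–7 typed features with a
reference geometry; the serialized form carries the inter-feature
distance matrix in Å. A conformer matches when some type-consistent
injective assignment of hypothesis features to its feature points
superposes by Kabsch least squares within the RMSD tolerance (default
2 Å); assignments whose pairwise distances deviate by more than twice the
tolerance are pruned before superposition, and a compound matches if any
conformer does. Candidate hypotheses are feature k-tuples drawn from the
representatives' conformers, k descending from 7 to 4; a candidate is
retained when it maps at least half of its cluster (we count the *full
cluster membership*, not only the representatives — the other reading of
"half of the input compounds" is available via the `rate_features`
argument). Selectivity is 1 − the matched fraction of a background set, a
monotone surrogate for proprietary selectivity scores. The best
hypothesis per cluster is chosen lexicographically: more features, then
higher match rate, then higher selectivity, then smallest id. Because the
feature count ranks first, enumeration stops by default at the largest k
with any surviving candidate (`early_stop = FALSE` restores full
enumeration).

**Optimization.** `best_combination()` enumerates every k-subset of the
hypothesis columns of a hit matrix (budget-guarded at 5·10⁶ subsets, with
a clearly labelled greedy fallback) and maximizes the averaged metric;
ties go to the lexicographically smallest id set. `optimization_curve()`
sweeps k and reports the global optimum; under `hit_once` the recall
curve is provably non-decreasing. `random_benchmark()` draws 10 uniform
k-subsets and reports mean, SD and the percent gain of the optimized
score over the random mean. `universal_hypothesis()` builds the single
"cover-everything" baseline from one pick per cluster (medoid or seeded
random).

## What the synthetic worlds emulate

`generate_world()` plants 4–6-feature templates with distinct type
multisets and well-spread geometries (pairwise feature distances ≥ 2.5 Å
inside an 8 Å box), then emits:

* **actives** — per-coordinate Gaussian jitter (σ = 0.2 Å) of their
  template, as an ensemble of 5 conformers, plus one persistent spurious
  feature per compound on a distant shell (8–13 Å);
* **inactives** — half violate every template by a missing feature type,
  half by a uniform 2.5× distance expansion;
* pseudo-Ki values log-uniform within each label's range, so the
  curation module reproduces the planted labels from the emitted CSV.

Every world is self-verified at generation: the hit matrix of all
compounds against the planted templates must be exactly block-diagonal;
failed draws are regenerated from a derived seed. Spurious features are
placed under a leverage-aware rejection test: the point set containing
the new spurious feature must stay above 1.25× the match tolerance in a
direct Kabsch comparison against any previously planted same-type
spurious of the same template pool, and against the spurious feature
standing in for a same-type template point. A plain distance margin is
not sufficient — a far-out point has a long lever arm, and a rigid fit
can trade a little template accuracy for a large spurious displacement
(empirically, 7.4 Å of separation can still yield a 1.65 Å RMSD over 7
points).

What the worlds deliberately do **not** emulate: real conformational
energetics (conformers are i.i.d. jitters, not an energy-windowed
ensemble), chemotype-specific structure, activity cliffs, or the noisy
boundary between actives and decoys in real assay data. Passing the
planted-recovery tests therefore demonstrates the correctness of the
machinery — clustering, level selection, hypothesis generation, matching
and optimization — not the screening power expected on experimental
data, where the engine-specific hypothesis quality dominates.

## Numerical choices and degenerate inputs

* MCC with a vanishing denominator factor is 0; recall errors without
  actives; accuracy errors on an empty screen.
* Kelley selection returns 1 with a warning when every level has the same
  spread (e.g. all-equal distances); an oversized cluster whose
  re-clustering is degenerate is split in two.
* Sphere exclusion re-seeds from a caller-supplied seed and restores the
  caller's RNG stream; fixed seed ⇒ byte-identical selections.
* Optimizer ties break to the lexicographically smallest sorted id set;
  combination scores are compared with a 10⁻¹² slack so floating-point
  noise cannot flip a tie.
* Proportional test-set quotas use largest-remainder rounding, capped by
  availability with deterministic redistribution of any shortfall.
* Worlds with verification failures retry up to `max_retries` times with
  a seed offset and then fail loudly, reporting the offending parameters.

## Problem sizes

The shipped tests recover planted worlds of 3–5 templates with 10 actives
each plus twice as many inactives (5 seeds, ≈ 90 s total), check the
optimizer against an independent enumerator on 50 random instances of up
to 12 compounds × 6 hypotheses at every k, and verify the Kelley-level
invariant on planted-distance blobs for K = 2…6 × 10 seeds. The
acceptance script runs one full pipeline pass on a 4-template world with
skewed cluster sizes (16/10/8/6 actives) — skew is what makes the random
benchmark informative, since in a fully symmetric world all equal-length
combinations are interchangeable and the gain is structurally zero.

## Known limitations

* Hypothesis matching uses a single global RMSD tolerance, not
  per-feature tolerance spheres, excluded volumes or partial-match
  fitness scores.
* MOLPRINT-2D atom typing is intentionally coarse; vendor typers will
  bin differently, changing cluster boundaries (not the machinery).
* With hard 1 Å triplet bins, fingerprint similarity degrades at high
  jitter; many-cluster structure (K ≥ 6) at σ = 0.2 Å is near the limit
  of what single-linkage-free Kelley selection can recover from P3D
  fingerprints.
* The exhaustive optimizer is exponential in k; beyond the subset budget
  it refuses and points to the greedy variant rather than silently
  approximating.
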
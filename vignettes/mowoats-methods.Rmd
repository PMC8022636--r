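---
title: "Multi-objective whale-optimization clustering: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective whale-optimization clustering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mowoats)
```

## The clustering model

`mowoats()` searches for k representative expression profiles (centroids) of
an n × f gene-expression matrix. A candidate solution is a k × f centroid
matrix; genes are assigned to their nearest centroid under the run's distance
metric. Because no single criterion captures clustering quality, each
candidate is scored on three objectives at once:

* **Xie–Beni index** (minimized) — the summed squared distance of each point
  to its assigned centroid, divided by n times the minimum squared
  centroid–centroid separation. Degenerate solutions with coincident
  centroids have an undefined index and are rejected during the search.
* **Overall deviation** (minimized) — the summed point-to-assigned-centroid
  distance, a pure compactness measure.
* **Simple Silhouette Index** (maximized) — the mean of `1 − a′/b′`, where
  `a′` is a point's distance to its nearest centroid and `b′` its distance to
  the second-nearest. Unlike the full Silhouette it needs only two distances
  per point, which is what makes partition-parallel evaluation possible. A
  point coincident with two centroids (`b′ = 0`) contributes a neutral 0.

Solutions are compared by Pareto dominance on this objective triple. The
search never scalarizes: everything non-dominated that the swarm encounters
is offered to a bounded archive (the *elite list*), and the front it holds at
the end **is** the result. A single reported clustering is then chosen from
the front as the member with the highest *full* Silhouette width
`S = mean((b_i − a_i)/max(a_i, b_i))`, computed on all pairwise point
distances. Points in singleton clusters score 0 (the usual convention);
members of the front whose nearest-centroid partition collapses to a single
non-empty cluster are skipped with a warning.

## Distance metrics

One metric — chosen per run — is used everywhere: point assignment, all three
objectives (including the Xie–Beni denominator), and validation.

* `euclidean`: the L2 norm of the profile difference.
* `spearman`: `d = 1 − r_s`, with `r_s = 1 − 6Σd_i²/(f(f²−1))` computed on
  **minimum-order ranks** (tied values share the smallest rank among their
  positions, i.e. rank = 1 + count of strictly smaller values). The range is
  [0, 2]: 0 at perfect rank agreement, 2 at perfect reversal. This compares
  profile *shape* rather than magnitude — appropriate for time-course data
  and heterogeneous panels. Centroids live in raw expression space (they are
  convex-combination-like positions produced by the swarm moves) and are
  rank-transformed on the fly whenever they are compared with a point's rank
  vector. Note that the classical closed form for `r_s` is not tie-corrected,
  so with minimum-order ranks and ties the coefficient can fall slightly
  outside [−1, 1]; the value is used as computed, without clamping, and the
  distance `1 − r_s` remains well ordered. The conversion from similarity to
  distance as `1 − r_s` is this package's choice: it is monotone and zero at
  perfect agreement.

## The optimizer

The search hybridizes a whale-optimization swarm with tabu-search memory.

**Initialization.** Each of the `np` whales starts as k distinct data rows
sampled without replacement — every initial centroid is a real expression
profile, so initial solutions are always inside the data's bounds.

**Elite list.** A bounded archive (capacity `max_el`) of mutually
non-dominated solutions. A candidate is rejected if any member dominates it
or duplicates its objective vector exactly (duplicates waste capacity);
otherwise it enters and evicts everything it dominates. On overflow the
member with the smallest NSGA-II crowding distance is dropped; per-objective
extreme members have infinite crowding distance and are never dropped, which
preserves the spread of the front. The truncation policy is a design choice
of this package, aimed at keeping archived solutions evenly distributed over
the front.

**Moves.** At iteration t (0-based, of `max_it`), the schedule parameter is
`a = 2(1 − t/max_it)`; per position dimension, `A = 2ar − a` and `C = 2r′`
with r, r′ uniform on [0, 1]. Each whale draws p uniform on [0, 1]:

* `p > p_threshold` (default 0.2) and `max|A| < 1`: *encircling* toward a
  uniformly random elite member g — per dimension,
  `x ← g − A·|C·g − x|`;
* `p > p_threshold` and `max|A| ≥ 1`: the same move toward a random swarm
  peer (exploration);
* `p ≤ p_threshold`: the *bubble-net spiral* around a random elite member —
  `x ← |g − x|·e^{bl}·cos(2πl) + g` with l uniform on [−1, 1] and shape
  constant `spiral_b = 1`. A config switch (`low_p_move = "encircle"`)
  substitutes the encircling form on this branch.

Because A is drawn per dimension, the scalar branch condition is taken on
`max|A|`: while `a > 1` (the first half of the schedule) some dimension almost
surely exceeds 1 and the swarm explores; once `a ≤ 1` every dimension
contracts and the swarm exploits. After every move the position is clamped
per feature to the data's [min, max] — the simplest bounds repair, chosen
because centroids outside the data range can never be nearest to anything
useful. The new position always replaces the old one; there is no greedy
acceptance test. Guides are drawn uniformly from the elite list, which is
what lets the archive steer the swarm out of local optima.

**Stagnation and crossover.** An iteration "improves" if any elite-list
update during it changed membership. After `max_non_improve` (default 2)
consecutive non-improving iterations, a crossover phase fires: q whales
(q uniform on 1..⌊np/2⌋) are each crossed with a random elite member (θ <
0.5, intensification) or with a distinct random peer (θ ≥ 0.5,
diversification), where θ is a fresh uniform draw. A cross replaces a random
subset of m centroids (m uniform on 1..k−1) of the whale with the partner's
centroids at the same slots; offspring replace their parents unconditionally
and are re-evaluated and offered to the elite list. The counter resets after
any improving iteration and after every crossover phase. Replacement (rather
than compare-first) is a design choice: the elite list already retains
anything worth keeping, so the swarm can afford to move freely.

**Termination** is a fixed iteration budget (`max_it`, default 50). Default
parameters: `max_it = 50`, `np = 15`, `max_el = 50`, `max_non_improve = 2`,
`p_threshold = 0.2`, `spiral_b = 1`. All randomness flows from one RNG stream
seeded by the `seed` argument, so equal seeds reproduce fits exactly.

## Partition-parallel objective evaluation

`evaluate_objectives()` implements a map/reduce contract: data rows are split
into partitions; each partition independently computes, for its rows, the
nearest-centroid index and the two smallest point-to-centroid distances; the
coordinator concatenates the triples by row index and computes the three
objectives. The per-point payload deliberately includes the *second*-nearest
distance — the Simple Silhouette cannot be assembled from nearest distances
alone, so partitions return both. Results are independent of the partition
count and boundaries up to floating-point summation order (all our tests
bound the discrepancy at 1e−9 relative; observed values sit near machine
epsilon). Backends: `serial` (default) and `process`
(`parallel::mclapply`); both satisfy the identical contract, and the serial
path with one partition is the reference single-pass evaluation.

## Validation indices

* **Full Silhouette** — as above; used for best-solution selection and
  reporting.
* **Davies–Bouldin** (lower better) — mean over clusters of the worst
  `(S_i + S_j)/M_ij`, with `S_k` the mean distance of cluster k's points to
  its centroid and `M_ij` the centroid separation. By default `S_k` uses the
  *optimizer's* centroids, so validation scores the representation actually
  produced; `recompute_centroids = TRUE` switches to per-cluster means (the
  textbook variant, and what external references implement).
* **Dunn** (higher better) — minimum single-linkage between-cluster distance
  over maximum within-cluster diameter. Single linkage is our reading of
  "inter-cluster distance"; it is the strictest and the most common choice.
* **F-measure** — class-size-weighted best-match harmonic precision/recall
  between predicted clusters and reference classes; invariant to cluster
  relabeling.

## The synthetic-data generator

`synth_expression()` emulates normalized expression tables of the scale the
method targets at the desk: a few hundred genes by a handful of ordered
conditions, k latent groups with multinomial sizes.

* `blob`: group centroids are drawn uniformly in a box and rejection-sampled
  (up to 1000 tries) until all pairwise distances reach
  `separation × noise_sigma`; points add isotropic Gaussian noise with sd
  `noise_sigma`. Difficulty is therefore expressed in noise-sd units; the
  box scale is floored so the zero-noise limit still yields distinct
  centroids. The recovery studies in the test suite use n = 400, f = 10,
  k = 4 at 10σ separation — cleanly separated groups, because they probe the
  optimizer's ability to *find* structure, not the statistical limit of
  detectability.
* `timecourse`: group templates are smooth trajectories over the ordered
  features (rising, falling, peaked, sinusoidal, then phase-shifted
  variants), z-scored per group like normalized log-ratio profiles, plus the
  same noise. Group identity is carried by shape, which is what makes these
  fixtures informative for the Spearman metric.
* `tie_fraction` quantizes that share of entries to 2 decimals so rank ties
  genuinely occur; if quantization happens to leave every row tie-free, one
  within-row tie is forced so the tie-handling code path is always exercised.

What the generator does **not** emulate: probe-level noise models, missing
values, heavy-tailed or correlated noise, batch structure, or cluster-size
imbalance beyond the weight vector. Passing recovery tests on these fixtures
shows the optimizer and selection machinery work as specified; it does not
certify performance on real microarray data, where separation is far below
10σ and cluster structure may not be centroid-shaped at all.

## Numerical choices and edge cases

* Nearest-centroid ties go to the lowest centroid index, deterministically.
* Coincident centroids: Xie–Beni raises a degeneracy error; during the
  search such candidates are skipped (the move is wasted, the whale keeps
  its previous position).
* `b′ = 0` in the SSI contributes 0; singleton clusters score 0 in the full
  Silhouette.
* Crowding-distance truncation removes exactly one member per overflowing
  insertion, so the retained subset of a large front is order-dependent —
  the archive is guaranteed to be a mutually non-dominated subset of the
  true front that always includes its per-objective extremes.
* Row ranks are computed once per run and reused; centroid ranks are
  recomputed per evaluation (centroids move every iteration, so caching
  would never hit).
* Test and acceptance problem sizes (up to n = 500, f = 20, k = 8; 200
  random instances; 10-seed recovery studies) were chosen as the smallest
  sizes at which the properties under test are non-trivial.

## Known limitations

* The elite list can oscillate when many near-duplicate objective vectors
  arrive; exact-duplicate rejection mitigates but does not eliminate this.
* The Spearman closed form without tie correction biases `r_s` slightly
  upward for heavily tied rows; with the minimum-order convention this is
  bounded and consistent across a run, but absolute values should not be
  compared across metrics.
* k is fixed per run; model selection over k is done by sweeping
  (`--k 4,5,6` in the CLI) and comparing the full Silhouette of the selected
  solutions, not by any internal criterion.
* The `process` backend pays fork-and-copy overhead per evaluation; it is
  worthwhile only when n is large enough that a single assignment pass
  dominates the loop body.
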
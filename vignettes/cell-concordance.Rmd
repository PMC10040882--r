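---
title: "Evaluating cell-level annotations: matching, agreement, consensus, and detection scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cell-level annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(cellconcord)
library(dplyr)
```

## The problem

Immunohistochemistry (IHC) slides stained for CD3 make T-lymphocytes
visible among tumor and stromal cells. Scoring immune infiltration at the
cell level requires annotating every cell in a region of interest (ROI,
here a ~2 mm&sup2; field of roughly 2150 x 2150 px at 0.23 um/px) with one
of three classes: `tumor`, `cd3_positive`, or `non_specified` (stromal
cells that are neither). Evaluating either human raters or automatic
detectors against such annotations poses three coupled questions that this
package answers:

1. **Which annotation in set B is "the same cell" as a given annotation in
   set A?** There is no shared cell identity, only coordinates.
2. **How well do two raters agree**, given that much of their disagreement
   is omission — one rater simply never marked the cell?
3. **How good is a detector** whose output is a scored list of cells?

## Correspondence: gated optimal assignment

Two annotation sets are put in one-to-one correspondence by building the
Euclidean distance matrix between cell centroids and solving the
minimum-total-distance assignment (the Hungarian problem, solved here with
a Jonker-Volgenant shortest-augmenting-path routine in C++). A pair only
counts if the two centroids lie within the **gate** of 25 px — the radius
of an average cell at this resolution. Box overlap is deliberately not
used: one-click annotations carry synthesized fixed-size boxes, so IoU
would mostly re-measure the gate.

Two gate conventions are implemented. The default, `method = "pregate"`,
forbids above-gate pairs *before* solving, which yields the
maximal-cardinality, minimum-cost matching among gate-feasible pairings.
The alternative `"postgate"` solves the unrestricted assignment and then
dissolves above-gate pairs; it can discard pairs that a feasible matching
would keep (a chain of three nearly-collinear cells suffices to show the
difference) and exists for comparison. Equal-cost optima are resolved
deterministically (rows in order, lowest column index wins), so results
are platform-independent.

Pre-gated matching decomposes exactly over connected components of the
within-gate candidate graph: no feasible pair crosses components, so each
component can be solved independently. Components are found with a
union-find pass over gate-binned candidate pairs, which keeps ROI-scale
inputs (thousands of cells per side) in the sub-second range without
approximation.

```{r}
truth <- generate_layout(n_cells = 300, seed = 7)
rater <- simulate_rater(truth, miss_prob = 0.15, source_id = "raterA",
                        seed = 8)$cells
match_sets(truth, rater, gate = 25)
```

## Agreement: kappa with missing cells

A matching between raters A and B induces a 4 x 4 **extended confusion
matrix** over the three classes plus a virtual `missing` class: matched
pairs land in the 3 x 3 core, cells seen by only one rater land in the
missing row or column. A cell absent from both raters does not exist, so
the missing-missing entry is structurally zero.

From this matrix the package computes Cohen's kappa
(`kappa = (Po - Pe) / (1 - Pe)`) in four variants that handle omission
differently:

* `kappa_standard()` — the 3 x 3 core only; the classical two-rater kappa.
* `kappa_regular_category()` — missing is a fourth category. Because the
  missing-missing diagonal term is zero, omissions only add off-diagonal
  mass: this variant *penalizes* missed cells.
* `kappa_listwise_deletion()` — both `Po` and `Pe` restricted to jointly
  labeled cells, with margins corrected by the missing row/column: pure
  label agreement.
* `kappa_gwet()` — `Po` over jointly labeled cells, but `Pe` keeps the
  full margins normalized by the labeled totals, so singly-labeled cells
  still inform the chance correction.

All four provably coincide when nothing is missing (a property test in the
suite), and the gap between Regular Category and the other two separates
the two causes of disagreement: a low Regular Category kappa with high
Listwise/Gwet kappa means raters miss different cells but agree on the
cells they both label — the dominant pattern in cell annotation.
Interpretations use the Landis-Koch intervals; a kappa of exactly 0 is
assigned to "slight", the interval whose boundary it sits on, since the
conventional list leaves 0 formally unassigned.

`pairwise_agreement_report()` applies all variants to every unordered pair
of raters. Across multiple ROIs it **pools confusion counts before
computing kappa** (micro-averaging) rather than averaging per-ROI kappas:
on a sparse ROI a single disagreement swings the per-ROI kappa wildly, and
pooling weighs every cell equally. Per-ROI output remains available with
`pooled = FALSE`.

```{r}
raters <- lapply(c(A = 2, B = 3, C = 4), function(s)
  simulate_rater(truth, miss_prob = 0.15, source_id = paste0("rater", s),
                 seed = s)$cells)
pairwise_agreement_report(raters) |>
  select(left_source, right_source, variant, kappa, interpretation)
```

## Consensus: majority vote with a tie class

`build_consensus()` includes *every* cell annotated by any rater (raters
rarely hallucinate cells; omission, not invention, is the failure mode).
Cells are clustered across raters by folding each rater in turn into the
evolving consensus with the same gated assignment, in lexicographic
`source_id` order for determinism; cluster centers are member centroids
and no cluster can hold two cells of one rater. Labels are majority votes;
any draw — typically a cell seen by exactly two raters who disagree, or a
three-way split — gets the separate label `diverse`. `diverse_fraction()`
reports the affected share per ROI and its mean/sd across ROIs. Diverse
cells are excluded from agreement computation and from detector
evaluation.

The clustering rule itself is a design choice: no published recipe
identifies "the same cell" across three raters, so the package reuses its
own correspondence machinery. The suite measures sensitivity to the rater
processing order and requires the consensus to move by less than 1% of
cells at realistic jitter; residual order dependence is a known
limitation.

## Detection scoring: 11-point average precision

`evaluate_detections()` thresholds detections by score, matches them to
the reference, and tallies per class: TP (matched, same label), FN
(reference cell unmatched or matched to another predicted class), FP
(detection unmatched — a cell not annotated at all — or matched to
another reference class). `TP + FN` always equals the number of
(non-diverse) reference cells of the class, at every threshold; this
conservation is a property test.

`average_precision()` sweeps the threshold over `0, 0.1, ..., 1`, orders
the 11 precision-recall points by increasing recall and accumulates
`AP = sum_k (R_{k+1} - R_k) * P_k`. Two conventions make the formula total
on degenerate inputs:

* precision at a threshold with no retained detections is defined as 1
  (the PR curve is anchored where recall is 0);
* the curve is extended to recall 0 with the precision of the strictest
  threshold point. This segment has zero width in every non-degenerate
  case (the sigma = 1.0 point almost always has recall 0), so the printed
  11-point rule is reproduced exactly; it only matters when every
  detection scores exactly 1.0, where the recall-increment sum would
  otherwise collapse to 0 for a perfect detector.

The 11-point rule is the default; `thresholds = "unique"` switches to the
all-unique-scores sweep for comparison. AP for a class absent from the
reference is reported as `NA`, never 0, and excluded from the mean AP.

Duplicate removal uses greedy centroid NMS (`nms_merge()`): keep the
highest-scoring remaining detection, suppress everything within the
radius, repeat. The radius defaults to the 25 px gate for consistency —
the suppression criterion (centroid distance rather than box IoU) mirrors
the matching criterion. `stitch_patch_detections()` translates detections
from a 256 px patch grid with 128 px overlap into ROI coordinates and
applies NMS to the overlap duplicates.

```{r}
det <- simulate_detector(truth, recall = c(0.9, 0.92, 0.85), seed = 9)$cells
ap <- average_precision(truth, det, "cd3_positive")
ap
mean_average_precision(truth, det)$map
```

## The synthetic generator

Every statistical claim in the package is tested against planted ground
truth, so the generator is first-class code:

* `generate_layout()` draws a **hard-core point process** (sequential
  inhibition: dart-throwing with rejection inside `min_spacing`). Default
  15 px spacing keeps the 25 px gate discriminative at realistic
  densities; a pure Poisson layout would create ambiguous near-coincident
  cells that no annotation tool produces. The default 1200 cells per
  2150 x 2150 px ROI reflects observed annotation totals of roughly
  1100-1500 cells per 2 mm&sup2; test ROI. Class labels are i.i.d. from
  configurable proportions; `class_proportions_preset()` realizes
  CD3-positive to non-specified ratios of 0.62 (HNSCC-like), 0.45
  (NSCLC-like), 0.16 (TNBC-like) and 0.37 (GC-like) with a fixed 0.4
  tumor share.
* `simulate_rater()` models the two observed disagreement sources
  separately: per-class omission and a row-stochastic label confusion,
  plus isotropic center jitter. The `simulate_study()` defaults — miss
  rates (0.18, 0.05, 0.20) for raters A/B/C, label accuracy ~0.95,
  jitter 3 px — mirror the reported annotation-count spread (two raters
  marking ~23k cells where a third marks ~28k implies ~20% differential
  omission) and near-perfect label agreement on jointly labeled cells.
  Under these defaults the consensus tie fraction is ~3%; real
  three-pathologist panels have shown larger values (~8%), reachable here
  by lowering the label accuracy.
* `simulate_detector()` draws per-class Bernoulli detection, Beta(8, 2)
  scores for true detections, Poisson clutter with Beta(2, 5) scores and
  uniform labels.

All randomness flows from one top-level seed through fixed per-component
substreams, so identical configurations are byte-identical on disk, and
the generator restores the caller's RNG state.

What the generator does **not** emulate: pixel appearance, staining
variability, spatial clustering of classes (tumor nests), rater-specific
spatial bias, and score calibration drift. Passing tests therefore
demonstrate correctness of the evaluation machinery under known
conditions, not performance of any detector on real tissue.

## Numerical choices and degenerate inputs

* Undefined statistics raise errors naming the statistic — an empty
  confusion matrix, `Pe = 1` (a single observed class), no jointly
  labeled cells for listwise/Gwet, an empty consensus, a zero denominator
  in a class ratio. Nothing silently returns 0.
* The forbidden-pair cost in the gated assignment is
  `gate * (n + 1) + 1`, strictly larger than any feasible total, so
  minimizing cost lexicographically maximizes feasible cardinality first.
* Problem sizes in the test suite (5000 cells for closed-form kappa
  recovery, 2000 for parameter recovery, 200 exhaustive matching
  instances capped at 7 cells per side) were chosen so each Monte-Carlo
  check resolves its 3-standard-error band comfortably.

## Limitations

* The consensus clustering is one defensible reading of "the same cell
  across raters"; the true construction is under-specified wherever more
  than two raters and a gate interact.
* Kappa variants come without confidence intervals; multi-rater
  generalizations (Fleiss) and weighted kappa are out of scope.
* Matching is strictly one-to-one on centroids; merged/split cells
  (one annotation covering two true cells) are counted as one hit plus
  one miss.
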
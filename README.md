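# cellconcord

Cell-level concordance and detection evaluation for pathology annotations.

## What problem this solves

Quantifying immune infiltration on immunohistochemistry (IHC) slides —
e.g. CD3-stained T-lymphocytes among tumor and stromal cells — requires
annotating every cell in a region of interest (ROI) with a class label
(`tumor`, `cd3_positive`, `non_specified`). Anyone validating such
annotations, whether from human raters or from a detection model, runs
into the same three problems:

1. **Correspondence.** Two annotation sets share no cell identity, only
   coordinates. `cellconcord` pairs them with a minimum-total-distance
   one-to-one assignment (Hungarian algorithm) on cell centroids, gated at
   25 px — the radius of an average cell at 0.23 um/px. Pairs beyond the
   gate do not exist; leftover cells are misses/false detections.
2. **Agreement with missing cells.** Plain Cohen's kappa,
   `κ = (P_o − P_e) / (1 − P_e)`, ignores that the dominant disagreement
   between cell annotators is *omission*. The package computes the
   standard kappa plus three missed-cell variants from an extended
   confusion matrix with a fourth `missing` class: **Regular Category**
   (missing is a class; omissions penalized), **Listwise Deletion**
   (jointly labeled cells only; pure label agreement) and **Gwet**
   (joint-cell `P_o`, full-margin `P_e`), each with its Landis–Koch
   interpretation.
3. **Detection scoring.** Scored detections are evaluated with per-class
   TP/FP/FN at any threshold and the 11-point average precision
   `AP = Σ_k (R_{k+1} − R_k) · P_k` over thresholds `0, 0.1, …, 1`, plus
   greedy centroid NMS for ensemble/patch-grid duplicate removal and
   stitching of overlapping-patch detections.

It also builds multi-rater **consensus** annotations (union of all
annotated cells, majority-vote labels, tie label `diverse`) and ships a
**synthetic generator** (hard-core cell layouts, simulated raters with
omission + label confusion + jitter, simulated detectors with clutter)
so every statistic can be verified against planted ground truth.

Audience: image-analysis groups validating cell detectors, and anyone
measuring inter-pathologist agreement on point/box cell annotations.

## Worked example

```r
library(cellconcord)

# a seeded synthetic study: ground truth (600 cells, HNSCC-like class mix),
# three simulated raters, one simulated detector
st     <- simulate_study(preset = "hnscc", n_cells = 600, seed = 42)
raters <- lapply(st$raters, `[[`, "cells")

pairwise_agreement_report(raters, gate = 25) |>
  dplyr::filter(variant != "standard") |>
  dplyr::select(left_source, right_source, variant, kappa, interpretation)
#>   left_source right_source           variant kappa interpretation
#> 1      raterA       raterB  regular_category 0.642    substantial
#> 2      raterA       raterB listwise_deletion 0.863 almost_perfect
#> 3      raterA       raterB              gwet 0.862 almost_perfect
#> 4      raterA       raterC  regular_category 0.500       moderate
#> 5      raterA       raterC listwise_deletion 0.854 almost_perfect
#> 6      raterA       raterC              gwet 0.853 almost_perfect
#> 7      raterB       raterC  regular_category 0.588       moderate
#> 8      raterB       raterC listwise_deletion 0.869 almost_perfect
#> 9      raterB       raterC              gwet 0.869 almost_perfect
```

The spread is the diagnostic: Listwise/Gwet near 0.86 say the raters
almost perfectly agree on cells they both labeled, while the much lower
Regular Category kappa says their disagreement is mostly cells one of
them missed (raters A and C omit ~20% of cells in this simulation, rater
B ~5%).

```r
cons <- build_consensus(raters)
diverse_fraction(cons)          # cells with no label plurality
#> [1] 0.0334

res <- mean_average_precision(st$truth, st$detector$cells)
res$per_class
#>     class_label    ap
#> 1         tumor 0.841
#> 2  cd3_positive 0.933
#> 3 non_specified 0.854
res$map
#> [1] 0.876

class_ratio(st$truth, "cd3_positive", "non_specified")
#> [1] 0.593
```

3.3% of consensus cells get the `diverse` tie label; the simulated
detector reaches a mean AP of 0.876; and the generated class mix
reproduces the configured HNSCC-like CD3⁺/non-specified ratio (0.62) up
to sampling noise.

Annotation I/O uses a plain CSV dialect (`read_annotation_csv()` /
`write_annotation_csv()`, box or point format), and a command-line
wrapper exposes the same operations as subcommands:

```sh
exec/cellconcord simulate --preset hnscc --seed 7 --out study/
exec/cellconcord kappa --sets study/raterA.csv,study/raterB.csv,study/raterC.csv --out kappa.csv
exec/cellconcord eval  --reference study/truth.csv --detections study/detector.csv --out report.json
```

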
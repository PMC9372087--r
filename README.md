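# rtseval

Geometric and dosimetric evaluation of auto-segmented radiotherapy
planning structures, in R.

## What it does, and for whom

Radiotherapy physicists and segmentation researchers who compare
algorithmic (deep-learning) contours against reference manual contours
need two complementary views of agreement:

1. **Geometry** — Dice similarity coefficient
   `DSC = 2|A∩B|/(|A|+|B|)`, Jaccard coefficient `JC = |A∩B|/|A∪B|`, and
   the Hausdorff surface distance
   `HD = max(h(A,B), h(B,A))`, `h(A,B) = max_{b∈B} min_{a∈A} ‖a−b‖`
   in physical millimetres, including the 95th-percentile variant (95%HD)
   that discounts the worst 5% of surface separations.
2. **Dosimetry** — what happens to the dose-volume indices (D_mean, D_max,
   V100, D_x%, D_0.03cc) when the auto contours are substituted into the
   *fixed* dose distribution that was planned on the manual contours,
   checked against the standard pelvic EBRT constraint table (e.g. spinal
   cord D_max < 4000 cGy, kidney D_mean < 1200 cGy, femoral head
   D_mean < 2000 cGy).

The two views are then linked statistically: Wilcoxon paired signed-rank
tests for systematic differences, Bland–Altman 95% limits of agreement
(bias ± 1.96·SD) for method agreement, and Spearman correlations between
each structure's geometric metrics and its per-case dosimetric difference
`Δ = |auto − manual|`.

Clinical images cannot ship with a package, so `rtseval` includes a
synthetic pelvic phantom generator (nine planning structures with a
calibrated auto-segmentation error model and a CTV-conformal dose
surrogate) and a compact 2D encoder-decoder segmentation network (three
encoders, three decoders, 3×3 convolutions with batch norm and ReLU,
max-pool downsampling, transposed-convolution upsampling, skip
connections), so the entire segment-then-evaluate workflow runs on
generated data. See the methods vignette (`vignettes/methods.Rmd`) for the
model details and design rationale.

## Worked example

```r
library(rtseval)

# a 10-case phantom cohort with the default (calibrated) error profile
report <- run_evaluation(run_config(n = 10, seed = 1))
report
```

Output (abridged; exact numbers for this seed):

```
<comparison_report> 10 cases, 9 structures

Mean geometric metrics per structure:
      structure mean_dsc mean_jc mean_hd_mm mean_hd95_mm
        Bladder    0.927   0.869       2.45         1.64
            CTV    0.798   0.675       6.56         4.71
 Femoral Head L    0.875   0.779       3.40         2.86
 Femoral Head R    0.874   0.784       4.12         3.30
       Kidney L    0.978   0.958       1.50         1.30
       Kidney R    0.955   0.918       2.58         1.80
    Pelvic Bone    0.671   0.511      15.69         8.45
         Rectum    0.736   0.591       5.17         3.89
    Spinal Cord    0.616   0.466       7.67         7.04

Paired dosimetric comparison (metric of record):
      structure metric manual_mean auto_mean        z       p
            CTV D_mean      4675.4    4675.5 -1.12122 0.27539
            CTV   V100       100.0     100.0  0.00000 1.00000
    Spinal Cord  D_max      1959.0    1750.6 -1.89552 0.05469
       Kidney L D_mean       290.7     282.8  0.00000 1.00000
        Bladder D_mean      3180.1    3085.6 -1.12122 0.27539
 Femoral Head L D_mean       315.7     343.0  1.22315 0.23242
    Pelvic Bone D_mean      1322.9    1304.0 -0.61158 0.55664
         Rectum D_mean      3052.2    2978.9 -0.40772 0.69531
            ...
```

Reading it: the kidneys/bladder/femoral heads keep high overlap
(DSC ≈ 0.87–0.98) and small 95%HD, the CTV sits near 0.80, and the
pelvic bone is among the weakest structures (DSC ≈ 0.67, 95%HD ≈ 8 mm)
— the fidelity ordering the error profile is calibrated to. On the
dosimetric side, substituting the auto contours into the fixed dose
grids leaves the organ-at-risk means statistically unchanged in this
small cohort (Wilcoxon `P > 0.05` throughout); the spinal cord D_max —
a point dose, most sensitive to boundary reach — comes closest to
significance (`P = 0.055`).

Individual building blocks are exported directly:

```r
ph   <- generate_phantom(seed = 7)            # image + manual contours
auto <- perturb_structures(ph$manual, seed = 8)
bone <- "Pelvic Bone"
dice(ph$manual$structures[[bone]], auto$structures[[bone]])           # 0.772
hausdorff(ph$manual$structures[[bone]], auto$structures[[bone]], 95)  # 5.66 mm
dose <- synth_dose(ph$manual, plan_config(4500), seed = 9)
pairs <- evaluate_dosimetry(dose, ph$manual, auto, plan_config(4500))$pairs
pairs[pairs$structure == bone, ]   # manual D_mean 1405.4, auto 1442.7 cGy
```

A thin command-line front end is installed at `inst/cli/rtseval`
(subcommands `generate-cohort`, `train-segmenter`, `evaluate`).

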
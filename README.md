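# mgmorph

Three-dimensional single-cell morphometry and marker quantification for
microglia imaged by confocal microscopy, with a synthetic ground-truth
generator that makes the whole chain testable.

Microglia report their activation state through shape: surveillant cells
are small-bodied and highly ramified; activated and aged cells de-ramify,
enlarge their somata, up-regulate the lysosomal marker CD68 and accumulate
autofluorescent lipofuscin. `mgmorph` is for labs quantifying those
phenotypes from Iba1-stained z-stacks. It reimplements a complete
single-cell analysis chain as tested, scriptable R:

- **Segmentation** — 8-bit conversion, maximum-intensity projection,
  0.5-fold scaling, Huang fuzzy-entropy auto-threshold (minimizing the
  count-weighted Shannon entropy of class-membership fuzziness), threshold
  application to the unmodified 3D image, and 26-connected particle
  filtering (minimum 10,000 voxels).
- **Morphometry** — per cell: volume `V`; iso-surface area `A` (marching
  tetrahedra + Taubin mesh smoothing); ramification index
  `RI = A / (4π ((3V)/(4π))^(2/3))` (1 for a sphere); polarity index
  `‖com − c_hull‖ / (2 ((3 V_hull)/(4π))^(1/3))` (0 for a symmetric
  arbor); mean Iba1 intensity; and skeleton metrics — branch number, tree
  length, average branch length — from topology-preserving,
  distance-ordered 3D thinning.
- **Puncta quantification** — soma size and mean gray value in polygon
  ROIs (ImageJ `.roi` or JSON), CD68 area fraction under a cohort-fixed
  reference threshold, lipofuscin particle counts/densities with the
  strict > 0.5 µm² size rule and 7-plane projection windows.
- **Behavior** — sociability `Tp/(Tp+Tc)·100` and preference
  `Tn/(Tf+Tn)·100` with the inclusive ≤ 55% sociability exclusion,
  one-sample chance-level t-tests, and a ROUT robust outlier screen
  (median + RSDR + step-down FDR at chosen Q).
- **Synthetic cohorts** — branched microglia-like cells rendered into
  noisy confocal-like TIFF stacks (0.18 µm/px, 0.5 µm z-step) with exact
  generative truth for every metric, plus `run_cohort()` to execute the
  full analysis over a cohort directory and emit per-cell/per-mouse/group
  tables with logged exclusions.

## A worked example

Generate one synthetic cell with known truth, image it with blur and shot
noise, and run the measurement chain:

```r
library(mgmorph)

cal   <- calibration()                     # 0.18 um/px, 0.5 um z-step
cell  <- generate_cell(cell_params(), seed = 11, center_um = c(20, 20, 12))
mask  <- rasterize_cell(cell$spec, cal, c(224, 224, 48))
stack <- render_stack(list(iba1 = mask), noise_model(seed = 11), cal)

cm  <- segment_cell(stack)
cm
#> cell mask: 20675 voxels in 1 component(s), threshold 58.56078
rec <- compute_morphometry(stack$voxels, cm, cell_id = "demo")
round(rec[, c("volume_um3", "ramification_index", "polarity_index",
              "branch_count", "tree_length_um")], 3)
#>   volume_um3 ramification_index polarity_index branch_count tree_length_um
#> 1    334.935              2.556           0.15           11         81.971
round(cell$truth[, c("volume_um3", "branch_count", "tree_length_um")], 3)
#>   volume_um3 branch_count tree_length_um
#> 1    320.886           11         83.794
```

The segmented cell recovers the generative truth: the branch count is
exact, and volume and tree length agree within a few percent (the noisy
Huang threshold sits slightly below the blur midpoint, so the mask runs
marginally wide). A ramification index of ~2.6 (versus 1.0 for a sphere)
and low polarity describe a fairly symmetric, ramified cell.

A full cohort run:

```r
design <- list(groups = list(list(name = "WT",  n_mice = 3),
                             list(name = "KO", n_mice = 3,
                                  effects = list(soma_size = 1.3))),
               cells_per_mouse = 4)
generate_cohort(design, "cohort", seed = 1)
run_cohort(cohort_config("cohort", "results"))
qc_report("results")
```

which writes `per_cell.csv`, `per_mouse.csv`, `group_summary.csv`
(mean ± SEM, median, quartiles per metric), `exclusions.csv` (every
ROUT-flagged cell, with reasons) and a machine-readable `run_log.json`.
A thin command-line front end with the same verbs (`simulate`, `segment`,
`morph`, `puncta`, `behavior`, `run-cohort`, `qc`) is installed at
`inst/scripts/mgmorph`.

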
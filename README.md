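# pancatlas

Tools for building a population-average abdominal CT atlas optimized for the
pancreas, and for quantifying how well it generalizes. Given a template scan
and a cohort of abdominal CT volumes with organ labels, the package:

1. normalizes each scan (RAS reorientation, CT-bed removal, soft-tissue
   window [-275, 275] HU) and crops a consistent abdominal field of view
   from per-slice body-part scores (window [-6, +5] on the -12..+12 scale);
2. registers each subject to the template in two stages — a 12-DOF affine
   estimated by block matching of self-similarity context (SSC) descriptors
   with trimmed least squares, then deformable **dense displacement
   sampling**: a five-level control-grid schedule (spacings 8..4 voxels,
   search radii 6..2 steps, quantizations 5..1 voxels, regularization 0.4)
   solved exactly per level by dynamic programming over a minimum spanning
   tree;
3. fuses the registered cohort into an atlas: a weighted sliding-window
   average (patch 96³, overlap 0.75, patch weights `1 / (||x − μ|| + ε)`),
   a variance map (zeroed outside the body), and a majority-vote organ
   label;
4. scores registration quality by **inverse label transfer**: atlas-space
   labels are mapped back into each subject's native space and compared with
   the subject's own labels by the Dice coefficient
   `2|P∩G| / (|P| + |G|)` and the (directed) Hausdorff distance
   `HD(P, G) = max_p min_g ||p − g||` in mm. Subjects with a pancreas Dice
   below 0.1 are excluded from atlas construction.

The SSC descriptor compares patches *within* a neighborhood of each voxel
(six face-neighbor patches, twelve non-opposite pairs,
`D = exp(−S/q²) ∈ (0, 1]` with a local noise estimate `q²`), quantized to a
48-bit code per voxel and compared across images by Hamming distance —
robust to noise and to the intensity shifts between contrast phases.

Clinical cohorts for this task are not public, so the package includes a
deterministic synthetic abdomen generator (`make_phantom()`, `make_cohort()`,
`make_score_profile()`, `make_smooth_warp()`) that emulates the study
conditions at desk scale: a soft-tissue body with smooth texture and
partial-volume blur, ellipsoidal organs including a small elongated pancreas
(label 11 of the standard 13-organ scheme), seeded smooth inter-subject
deformations, score profiles, and an optional CT bed. Every stage of the
pipeline is testable against known ground truth.

## Worked example

Simulate a small cohort, run the full pipeline, and inspect the evaluation:

```r
library(pancatlas)

co <- make_cohort(3, phantom_spec(shape = c(64L, 64L, 64L), seed = 7),
                  warp = list(max_disp = 6, knot_spacing = 20),
                  noise_sd = 3, seed = 7)
cfg_path <- write_cohort(co, "cohort_demo")

cfg <- read_pipeline_config(cfg_path)
cfg$atlas <- atlas_config(patch_size = 48L)
run <- run_pipeline(cfg)
print(run)
#> <atlas_run> 3 subject(s) kept, 0 excluded; 1 atlas phase(s)
#>   mean pancreas inverse Dice: 0.814
#>   run dir: cohort_demo/run

panc <- subset(run$report, organ_id == pancreas_label())
print(panc[, c("subject", "organ", "dice", "hd_mm")], row.names = FALSE)
#>  subject    organ      dice    hd_mm
#>      S01 pancreas 0.8965517 2.000000
#>      S02 pancreas 0.7407407 2.000000
#>      S03 pancreas 0.8045455 2.828427

print(run$atlases[["portal venous"]])
#> <atlas_bundle> phase "portal venous", 3 subject(s), 64x64x59 voxels
```

Each row of the report is one kept subject and organ: `dice` is the overlap
between the fused atlas label transferred back into that subject's space and
the subject's own label (1 = perfect, the clinical literature reports ~0.5
for the pancreas on real scans); `hd_mm` is the corresponding directed
Hausdorff distance in mm (here, a voxel or two — the synthetic subjects are
smooth deformations of one template, so registration recovers them almost
exactly). The run directory contains the per-phase atlas (average, variance,
fused label as NIfTI plus a JSON sidecar), a TSV/JSON report, and a log.

A thin command-line wrapper with `simulate`, `run` and `evaluate`
subcommands is installed at `inst/cli/pancatlas`.

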
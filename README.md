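# atlasseg

Multi-atlas segmentation of small skull-base structures in 3-D images, in R.

The motivating problem is localizing the **foramen ovale** — the few-mm canal
in the skull base through which a puncture needle reaches the trigeminal
ganglion in trigeminal-neuralgia treatment. Manual delineation on CT is slow
and subjective; deep models need data that rarely exists for such a niche
target. Multi-atlas segmentation instead transfers anatomical prior
knowledge directly: a library of already-segmented scans is deformed onto
the target scan and the deformed expert labels are fused into a consensus.

`atlasseg` implements the whole pipeline as composable pieces:

- **Atlas selection** by normalized cross-correlation
  (NCC = Σ(T−T̄)(F−F̄) / √Σ(T−T̄)² √Σ(F−F̄)²), keeping the top *k*
  (default 10) atlases;
- **Registration**: multiresolution affine, then multiresolution cubic
  B-spline free-form deformation
  (T(x, y) = Σₘ Σₙ Bₘ(u) Bₙ(v) φ_{i+m, j+n}, extended to 3-D), both
  maximizing sampled normalized mutual information
  (NMI = (H₁ + H₂)/H₁₂, 2000 random voxels per iteration) by seeded
  stochastic gradient ascent — implemented here from scratch, with the inner
  loops in C++;
- **Label fusion** by majority vote, STAPLE (binary EM over per-atlas
  sensitivity pⱼ and specificity qⱼ) or SIMPLE (selective iterative
  discarding of poorly agreeing atlases);
- **Evaluation**: Dice = 2|A∩B|/(|A|+|B|), 95% Hausdorff distance and
  average symmetric surface distance, all in physical mm;
- **I/O** for NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`/`.mhd`) with
  full spacing/origin/direction geometry;
- a **synthetic phantom generator** that emulates the study design (a base
  skull-like shell with two foramen-like canals; 20 atlas + 10 test members
  produced by random smooth B-spline deformations plus fresh noise) so the
  entire pipeline is reproducibly testable with known ground truth.

See the methods vignette (`vignettes/multiatlas-methods.Rmd`) for the models,
parameter choices and their rationale.

## Worked example

Generate a small phantom cohort, segment a held-out case with the top-4
NCC-selected atlases and STAPLE fusion, and evaluate against the known truth:

```r
library(atlasseg)

cohort <- file.path(tempdir(), "demo_cohort")
make_cohort(cohort_spec(n_atlases = 6, n_tests = 1), phantom_spec(), cohort)

fixed <- read_volume(file.path(cohort, "test_01_gray.nii.gz"))
truth <- read_labelmap(file.path(cohort, "test_01_label_left.nii.gz"))
fixed
#> <volume> 64x64x64 voxels, spacing 0.5x0.5x0.5 mm, origin (0, 0, 0) mm
#>   intensity range [-1028, 1219]

cfg <- pipeline_config(k = 4, side = "left", fusion = "staple", seed = 7)
res <- segment(fixed, cohort, cfg)
res$record$selection
#>   atlas_id       ncc
#> 1 atlas_02 0.9595539
#> 2 atlas_06 0.9299235
#> 3 atlas_03 0.9234584
#> 4 atlas_01 0.9184139
#> 5 atlas_04 0.9157904
#> 6 atlas_05 0.9092676

evaluate(res$label, truth)
#>        dice hd95_mm    asd_mm empty_prediction
#> 1 0.8821918     0.5 0.1247778            FALSE

res$record$performance      # STAPLE's estimated per-atlas sensitivity p / specificity q
#>   atlas_id         p         q
#> 1 atlas_02 0.9157996 0.9897891
#> 2 atlas_06 0.9110847 0.9666957
#> 3 atlas_03 0.8196711 0.9316510
#> 4 atlas_01 0.8941591 0.9773782
```

The selection table ranks all atlases by NCC (the four best are registered);
the evaluation row says the fused canal overlaps the ground truth with Dice
0.88, its boundary never strays more than half a millimetre at the 95th
percentile (hd95), and the average surface disagreement is ~0.12 mm — about
a quarter of a voxel.

A thin command-line wrapper over the same functions ships in
`inst/cli/atlasseg.R` with verbs `phantom`, `segment`, `evaluate` and
`benchmark`, e.g.

```sh
Rscript inst/cli/atlasseg.R phantom --out cohort/ --n-atlases 20 --n-tests 10 --seed 42
Rscript inst/cli/atlasseg.R segment --fixed cohort/test_01_gray.nii.gz \
    --atlas-dir cohort/ --out fused.nii.gz --fusion staple --k 10 \
    --selection-report selection.csv --record run.json
Rscript inst/cli/atlasseg.R benchmark --cohort-dir cohort/ --out-dir results/
```

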
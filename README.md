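# icaseed

Hybrid ICA-seed-based functional connectivity (FC) mapping for 4D
fMRI-like data.

## What it is for

Spatial independent component analysis (ICA) is a powerful exploratory tool
for finding temporally coherent brain networks, but its stochastic parsing
of variance into components makes per-subject IC maps hard to compare
across subjects and studies. Seed-based GLM mapping is stable and easy to
compare, but needs a seed. Hybrid methods get the best of both: ICA chooses
the seed, and the FC map itself always comes from a plain voxelwise GLM.

The package is aimed at neuroimaging methodologists who want to study,
validate or apply these hybrid estimators on data they control. It
implements, on the linear models

```
X = G beta + epsilon        (voxelwise GLM; X is t x v, G is t x s)
X = M C + E                 (probabilistic ICA; maps C spatially independent)
```

* PCA whitening with AIC/BIC/MDL model-order selection, fixed-point
  spatial ICA (logcosh contrast, symmetric decorrelation, seeded and
  deterministic), temporal-concatenation group ICA, and regular
  back-reconstruction of per-subject components;
* the five hybrid seed constructions: **SV** (single peak voxel), **FV**
  (voxels within 1 z-unit of the peak), **MV** (integer z threshold with
  voxel count nearest a target), **DRS** (dual regression on one IC map),
  **DRA** (dual regression on all IC maps, one of interest);
* voxelwise GLM with Gaussian haemodynamic regressors (peak lag 5 s,
  sigma 2.8 s), Gaussianised z maps, and one-tailed fixed-z / Bonferroni /
  FDR thresholding;
* evaluation statistics: Fisher-z spatial correlation,
  threshold-adjusted overlap (false positives = false negatives by
  construction), partial ROC AUC up to a largest acceptable false
  positive rate, and sensitivity/specificity against ground truth;
* a seeded synthetic BOLD phantom generator with complete ground truth,
  including a two-component signal-injection fixture (a square-wave
  "artificial" component over three triangular regions sharing one voxel
  with a block-design "natural" component) and multi-subject group
  templates with amplitude and spatial variability.

I/O uses NIfTI (`RNifti`) for images and masks, TSV for time courses and
JSON for metadata. A thin command-line wrapper over the package functions
ships in `inst/cli/icaseed.R` (subcommands `simulate`, `ica`, `group-ica`,
`seed`, `seed-fc`, `evaluate`, `experiment1`, `experiment-group`).

## A worked example

The signal-injection study, end to end — generate a phantom whose ground
truth is known, decompose it, and ask whether seed-based FC driven by the
ICA-chosen seed recovers the injected component exactly:

```r
library(icaseed)
rep <- experiment1(rng_seed = 1)
print(rep)
#> experiment1_report (seed 1)
#>   artificial IC (z > 3.1): sensitivity 100.0%, specificity 100.00%
#>   overlap-seed FC: sensitivity 88.3%, specificity 98.22%
#>   natural-seed FC: sensitivity 1.0%, specificity 98.22%
#>   artificial-seed FC: sensitivity 100.0%, specificity 100.00%
```

Reading the numbers: the thresholded map of the ICA component matched to
the injected signal flags exactly the injected voxels (100%/100%). A seed
placed at the *overlap* voxel — shared by both components — produces an FC
map that mixes the two networks (it covers most of the artificial mask
*and* the natural blob, hence the imperfect 88%/98%): this is the
classical failure mode of naive seed placement. A seed at the artificial
component's own peak, chosen from the IC map, recovers the injected
component perfectly under familywise-corrected thresholding. The
natural-peak seed, correctly, finds only the natural network (its 1%
"sensitivity" against the artificial truth is the single shared voxel).

For group studies, `experiment_group()` simulates a multi-subject phantom,
runs group ICA, derives per-subject FC maps by every requested method and
prints the criteria table (Fisher-z correlations, threshold-adjusted
overlap, partial AUC) per method.

## Documentation

Every exported function has a help page; the methods vignette
(`vignettes/hybrid-ica-seed-fc.Rmd`) describes the models, the tunable
parameters and their defaults, the phantom's calibration and what it does
and does not emulate, and the package's numerical conventions.
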
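# sialoquant

Quantitative salivary gland SPECT/CT with automated gland segmentation.

Salivary gland function is assessed clinically with Tc-99m pertechnetate
SPECT/CT: a pre-stimulation SPECT/CT about 20 min after injection, a
sialagogue (lemon powder), and a post-stimulation SPECT at 40 min. Two
imaging biomarkers summarise each gland g with voxel set V(g):

- percent injected dose, `%ID = 100 * sum_{v in V(g)} c_v * vol_v / A_ref`,
  where `c_v` is activity concentration (Bq/mL), `vol_v` voxel volume and
  `A_ref` the injected activity, decay-corrected to acquisition time
  (Tc-99m half-life 6.0058 h);
- percent excretion fraction,
  `%EF = 100 * (20-min %ID - 40-min %ID) / 20-min %ID`.

Delineating the four glands (left/right parotid and submandibular) on CT by
hand takes ~15 min per scan. `sialoquant` implements the full automated
pipeline at desk scale:

- **phantom**: synthetic head-and-neck CT/SPECT studies with known gland
  geometry, programmed %ID/%EF, PSF blur, Poisson counting noise,
  inter-timepoint rigid misalignment, and a simulated slice-wise manual
  rater — so every downstream stage is testable without patient data;
- **preprocess**: cropping of the CT to a fixed training matrix using the
  soft-tissue z-profile and maximum-intensity-projection bounds
  (soft-tissue window: level 40, width 400);
- **segmentation**: a configurable 3D U-Net (Rcpp/BLAS implementation,
  trained with Adam on a soft-Dice or Dice + weighted cross-entropy loss)
  that labels the four glands on CT;
- **registration**: rigid correction of the 40-min SPECT into the 20-min
  CT frame by normalized cross-correlation with multiresolution coordinate
  descent;
- **quantify**: per-gland VOI volume, %ID at both timepoints, %EF, and
  protocol radiation-dose accounting (DLP x region coefficient, tracer
  coefficient);
- **evaluate**: the agreement statistics used to validate automated against
  manual segmentation — Dice, MAPE, R², Bland–Altman limits, paired t and
  the two-way random single-measure absolute-agreement ICC.

## Worked example

```r
library(sialoquant)

spec   <- phantom_spec(seed = 42)          # the default study conditions
study  <- generate_study(spec, 1)
study$programmed
#>             gland code volume_mL     pid20      pid40       ef
#> 1       parotid_r    1  30.37461 0.4387222 0.17978708 59.02029
#> 2       parotid_l    2  17.85675 0.4411901 0.11137107 74.75667
#> 3 submandibular_r    3  12.77357 0.2661678 0.07905075 70.30041
#> 4 submandibular_l    4  18.08375 0.1376897 0.06506524 52.74502

# quantify with truth labels; the 40-min SPECT is first registered to the
# 20-min frame
quantify_study(study, correct = "estimate")
#>       study_id           gland   voi_mL     pid20      pid40       ef
#> 1 phantom-0001       parotid_r 30.41456 0.4527972 0.16592900 63.35467
#> 2 phantom-0001       parotid_l 17.81120 0.4660747 0.10443319 77.59303
#> 3 phantom-0001 submandibular_r 12.85504 0.2733805 0.06943236 74.60230
#> 4 phantom-0001 submandibular_l 18.06288 0.1297111 0.06355502 51.00263

# protocol dose bookkeeping
ct <- ct_effective_dose(60.31, 0.0031)     # 0.186961 -> printed 0.19 mSv
protocol_effective_dose(7.22, round(ct, 2))
#> [1] 7.41
```

The VOI volumes agree to a fraction of a voxel; the recovered %ID/%EF
differ from the programmed values through Poisson counting noise (a few
percent on a gland VOI sum) and the estimated misregistration correction.

An end-to-end run — generate a cohort, train the desk-scale network,
segment, register, quantify and compare against truth — is one call:

```r
cfg <- pipeline_config(n_studies = 12, n_train = 8,
                       unet = desk_unet_config(epochs = 8))
res <- run_protocol(cfg, out_dir = "run1")
res$agreement
#> <sq_agreement> 4 studies, 16 gland pairs
#>   DSC  0.804 +/- 0.152  [0.403, 0.937]
#>   %ID  MAPE 17.60 +/- 17.44 %, R^2 = 0.899
#>   Bland-Altman bias -0.05362, LoA [-0.2046, 0.0974]
#>   paired t = -2.784 (p = 0.01391)
#>   ICC %ID 0.8767, ICC volume 0.5039
```

(A small demonstration run — eight training studies and eight epochs; the
package's validation runs use 40 training studies and reach a mean DSC of
about 0.85, see `scripts/acceptance.R`.)

A thin command-line interface over the same functions is installed at
`inst/cli/sialoquant.R` (subcommands `phantom`, `preprocess`, `train`,
`predict`, `register`, `quantify`, `evaluate`, `run`).

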
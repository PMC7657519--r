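# antromap

Quantify gastric antral motility from dynamic (cine) MRI by spatio-temporal
motility mapping, and validate the imaging read-out against simultaneous
water-perfused manometry.

Manometry — intraluminal pressure from a multi-port perfused catheter — is the
reference method for gastric contractile activity, but it is invasive and
insensitive to non-occlusive contractions. Cine MRI of a plane through the
antrum captures the wall motion directly: after respiratory motion correction
and lumen contour propagation, the lumen diameter perpendicular to the organ
axis is mapped per node and frame, reduced to a contraction signal, and
integrated over each ~3.5-minute acquisition block,

- MRI outcome: AUC of the contraction signal, in **mm·s**, with the per-node
  resting calibre taken as the 90th diameter percentile of the block;
- manometry outcome: AUC of above-baseline pressure (zero-phase 0.12 Hz
  respiration filter, rolling 10th-percentile baseline), in **mmHg·s**.

Because participant recordings of simultaneous MRI + manometry are not
publicly available, the package ships a paired-modality phantom: both
modalities are generated from one peristaltic wall-motion model
`D(s,t) = B(s)·(1 − a·g(s − vt))` (Gaussian wave train at ~3 cycles/min,
2.5 mm/s), with pressure produced by a two-regime transduction — gentle
intrabolus hydrodynamic gain while the lumen is open, steep mucosal contact
gain once it closes onto the port (switching in the 15–35 mmHg band). This
coupling makes pressure grow faster than diameter loss at high occlusion, so
the simulated association between the modalities is strong but non-linear,
and the statistical layer — Pearson correlations of pooled and per-subject
AUCs, mixed-effects regression of MRI AUC on a natural-spline basis of
manometry AUC with subject/visit random effects, a 3-df likelihood-ratio test
for non-linearity, and correlation power simulations under within-modality
AR(1) autocorrelation — can be exercised end to end against known truth.

## Worked example

Simulate one acquisition block with a 60 %-occluding wave, breathing and
noise; run both measurement chains; compare with the analytic truth:

```r
library(antromap)

blk <- generate_cine(phantom_config(grid_size = 128),
                     wave_config(occlusion_frac = 0.6),
                     respiration_config(), seed = 42)
res <- analyze_cine_block(blk$stack)          # register, segment, map, integrate
tr  <- generate_pressure(blk$truth$true_wave_params, manometry_config(),
                         blk$truth, seed = 42)
mano <- mano_pipeline(tr)                     # filter, baseline, segment, AUC

sprintf("MRI AUC %.0f (truth %.0f); freq %.2f cpm; mano AUC %.0f (truth %.0f)",
        res$mri_auc, blk$truth$true_block_auc_mri, res$frequency_cpm,
        mano$mano_auc, tr$meta$true_block_auc_mano)
#> "MRI AUC 725 (truth 686); freq 3.00 cpm; mano AUC 1068 (truth 1034)"
```

The measured MRI AUC lands within ~6 % of the analytic ground truth and the
contraction frequency is recovered exactly; the manometry chain integrates to
within ~3 % of the generative pressure integral. `autoplot(res$diameter_map)`
draws the spatio-temporal motility map (contractions appear as diagonal
stripes), `autoplot(tr)` the port traces.

Design-stage precision of the correlation estimate:

```r
power_table(reps_iid = 10000, reps_kron = 2000, seed = 1)
#>   design                             n_subjects n_total rho_within     se
#> 1 iid subject means                          15      15        0.0 0.2699
#> 2 separable AR(1) x between-modality         15     421        0.5 0.0506
```

One number per subject gives a correlation SE of ~0.27 at n = 15; using all
421 time-resolved blocks under a separable AR(1) covariance shrinks it to
~0.05 — the quantitative argument for analysing blocks, not subject means.

A whole synthetic validation study (simulation, measurement, statistics,
report files) is one call:

```r
rep <- run_validation_study("my-run", study_config(n_subjects = 15))
rep$r_pooled; rep$r_subject_mean; rep$lrt
```

A thin command-line wrapper with `simulate` / `analyze` / `power` subcommands
is installed at `inst/cli/antromap`.

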
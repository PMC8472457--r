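# liverhsi

Scoring liver viability from intraoperative hyperspectral images.

When the hepatic artery is occluded the liver loses about half of its
oxygen supply; restoring flow can then aggravate the damage
(ischemia–reperfusion injury), and there is no routine intraoperative tool
that tells the surgeon whether a re-perfused liver is viable. Hyperspectral
imaging (HSI) records relative reflectance I/I₀ at 100 wavelengths
(500–995 nm, 5 nm steps) for every pixel, and haemoglobin's
oxygen-dependent absorption makes those spectra a contact-free window on
tissue perfusion.

`liverhsi` implements the full analysis pipeline:

- **Hypercube I/O**: ENVI (BSQ/BIL/BIP) and a bit-exact native archive;
  conversion to relative absorbance A = −ln(I/I₀).
- **Oxygenation index maps**: tissue oxygen saturation
  StO₂ = D_vis / (D_vis + D_nir), a ratio of mean spectral concavities
  (rectified negative Savitzky–Golay second derivatives) over the
  570–590 nm and 740–780 nm windows; and a NIR perfusion index from the
  825–925 nm minus 655–735 nm absorbance difference.
- **Two per-pixel classifiers** with identical architecture — a compact 3D
  spatio-spectral CNN (two 3×3×3 convolution stages of 20 and 35 channels,
  strided spectral convolutions as learned pooling, a small fully connected
  head; 32,444 trainable parameters) applied to the 5×5×100 subvolume
  around each pixel: one segments the organ, the other labels each organ
  pixel perfused (−1) or ischemic (+1).
- **Training protocol**: vertical concatenation of training images,
  class-balanced binary cross-entropy with inverse-median-frequency weights
  (w_i = m/f_i, so Σ w_i f_i = 1), Kaiming initialization, plain SGD with
  L2 weight decay, without-replacement subvolume epochs, and a
  leave-one-subject-out cross-validation harness with a leakage audit log.
- **Inference**: dense per-pixel prediction (bit-identical to a naive
  loop), post-segmentation filtering (largest connected component + hole
  fill), and the per-image **AI viability score** — the fraction of organ
  pixels classified perfused (0 = total ischemia, 1 = total perfusion).
- **Statistics**: pooled normalized confusion matrices, ROC curves,
  Pearson/Spearman correlations with one- or two-tailed p-values and an
  exact permutation option.
- **A synthetic phantom generator**: cohorts of subjects with
  haemoglobin-like Gaussian chromophore spectra, perfusion states spanning
  control / ischemia 30–90 min / reperfusion 1–5 h (with one
  benign-recovery subject), specular highlights, an undecidable border
  ring, and biomarker surrogates negatively coupled to oxygenation — so the
  whole pipeline runs and is tested without any animal data.

## A worked example

```r
library(liverhsi)

## a five-subject synthetic cohort, imaged at control and 30/60/90 min of
## ischemia, trained and evaluated with leave-one-subject-out CV, then the
## same subjects' reperfusion series scored with held-out-fold models
run <- run_full_experiment(seed = 1)
round(run$summary, 3)
#>           seg_sensitivity           seg_specificity                   seg_auc
#>                     0.995                     0.998                     1.000
#>          char_sensitivity          char_specificity                  char_auc
#>                     0.998                     0.969                     0.998
#>        mean_control_score   mean_injury_rep5h_score mean_recovery_rep5h_score
#>                     0.974                     0.004                     0.975
#>       spearman_ai_lactate        spearman_ai_suzuki
#>                    -0.852                    -0.898
```

Segmentation and tissue characterization generalize to held-out subjects
(sensitivity/specificity ≈ 0.97–1.0 here). The viability score of the four
injury-trajectory subjects collapses from ≈0.97 at control to ≈0.004 after
5 h of reperfusion, while the recovery-trajectory subject stays ≈0.98 —
and the score anticorrelates strongly with the capillary-lactate and
histology-score surrogates (Spearman −0.85 and −0.90), mirroring the
direction of the real intraoperative findings.

Single pieces are exposed too:

```r
scene <- make_scene(seed = 1, state = "isch90")   # one synthetic subject
a     <- to_absorbance(scene$cube)
sto2  <- sto2_map(a)                              # oxygen saturation map
res   <- score_image(scene$cube, seg_model, tissue_model)
res$ai_score
```

A thin command-line interface wraps the same functions
(`inst/cli/liverhsi.R`): `simulate`, `indices`, `train`, `predict`,
`score`, `evaluate`, and `e2e`.

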
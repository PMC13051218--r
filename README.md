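# vceCT

Virtual contrast-enhanced CT synthesis with a region-weighted SSIM
objective, at desk scale.

In pelvic radiotherapy planning, the clinical target volume (CTV) and organs
at risk are easiest to delineate on contrast-enhanced CT, but a substantial
group of patients cannot receive iodinated contrast. One remedy is to learn
a mapping from the noncontrast scan to a *virtual* contrast-enhanced scan
with a paired image-to-image translation network. `vceCT` implements the
building blocks of that approach in pure R, sized so every part can be
trained, evaluated and reproduced on a single CPU:

- **a paired phantom simulator** producing noncontrast / venous-phase CT
  volume pairs of a pelvic geometry (body, fat rind, muscle, vertebrae with
  marrow core, paraspinal vessels, bladder, rectum with gas, kidneys, liver
  cap, and a midline CTV) with per-organ binary masks and NIfTI output.
  Tissue HU means and venous-phase deltas for vessels, muscle, fat,
  vertebrae and bone marrow follow published cohort CT-value measurements
  (vessels 46.67 → 227.66 HU);
- **the region-weighted SSIM loss**

  ```
  L = 1 − Σ_{k∈κ} w_k · SSIM_{Ω_k}(X, Y),   w_k = (A_k + ε)^{-1} / Σ_j (A_j + ε)^{-1}
  ```

  over the mask set κ = {CTV, Rectum, Bladder, Kidney_Left, Kidney_Right,
  Liver, Body}, where A_k is the voxel area of region Ω_k. The weights are a
  convex combination and are inversely proportional to region area, so small
  clinically critical structures dominate the objective. Both a local
  (11×11 Gaussian, σ = 1.5) and a global single-statistic SSIM window are
  provided, with exact analytic gradients;
- **a translation network** (convolutional encoder, transformer bottleneck
  over 1×1 tokens of the deepest feature map, convolutional decoder with
  skip connections, global input-plus-delta residual head), implemented from
  scratch with hand-written backpropagation and AdamW, plus nnU-Net-style
  intensity normalisation and paired augmentation. `trans_layers = 0` gives
  a plain U-Net ablation;
- **the evaluation suite**: MSE, PSNR, UQI, SSIM (whole-image and
  ROI-restricted), Dice overlap, 95th-percentile Hausdorff distance in mm,
  per-organ CT statistics, line profiles, and an automated peri-target
  (±5 cm) hallucination screening proxy;
- **an end-to-end pipeline** (`runExperiment`) that simulates, splits,
  trains, infers and reports under one seed, bit-reproducibly.

## Worked example

```r
library(vceCT)

ph <- generatePhantom(phantomConfig(grid_shape = c(16, 64, 64), seed = 7))
ph
#> PairedSample: 16 x 64 x 64 (z y x), 12 masks

ctStatistics(noncontrast(ph), maskSet(ph),
             c("Vessels", "Muscle", "Fat", "Vertebrae", "Marrow"))
#>      tissue mean_hu sd_hu n_voxels present
#> 1   Vessels   57.88 7.572      384    TRUE
#> 2    Muscle   59.11 8.433    22181    TRUE
#> 3       Fat -103.13 8.609     8767    TRUE
#> 4 Vertebrae  471.47 8.270      832    TRUE
#> 5    Marrow   34.64 7.760      320    TRUE
```

The per-tissue means differ from the cohort table values because each
sample draws its own cohort-level tissue offsets (`tissue_jitter`) and
voxel noise; `noiseFreeConfig()` reproduces the table exactly.

```r
weightedSSIMLoss(voxelData(noncontrast(ph)), voxelData(enhanced(ph)),
                 maskSet(ph))
#> [1] 0.1679

round(regionWeights(maskSet(ph)@masks[kappaRegions()])$weights, 4)
#>          CTV       Rectum      Bladder  Kidney_Left Kidney_Right        Liver         Body
#>       0.3204       0.0979       0.0797       0.2320       0.2075       0.0612       0.0013
```

The loss between the unenhanced input and the enhanced target is 0.17 —
this is the gap the network is trained to close — and the inverse-area
weights show the CTV (the smallest region) carrying ~250× the weight of the
body outline.

A full seeded experiment (simulate → train → infer → evaluate → report):

```r
res <- runExperiment(runConfig(seed = 1), outDir = "run1")
res$reports                     # per test case MetricReport
read.csv("run1/reports/metrics.csv")
```

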
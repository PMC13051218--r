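---
title: "Methods: virtual contrast-enhanced CT synthesis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual contrast-enhanced CT synthesis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Contrast-enhanced CT makes vessels, kidneys, liver and tumour tissue far
easier to delineate for radiotherapy planning, but iodinated contrast is
contraindicated in a meaningful fraction of patients. `vceCT` studies the
alternative of *synthesising* the venous-phase scan from the noncontrast
scan with a paired translation network, and — equally importantly — of
*evaluating* such a synthesis with region-aware metrics, because a
virtual scan that hallucinates or misplaces enhancement is clinically
worse than no virtual scan at all.

The training objective is the region-weighted SSIM loss

$$\mathcal{L} = 1 - \sum_{k \in \kappa} w_k \,\mathrm{SSIM}_{\Omega_k}(X, Y),
\qquad w_k = \frac{(A_k+\epsilon)^{-1}}{\sum_{j\in\kappa}(A_j+\epsilon)^{-1}},$$

with $\kappa$ = {CTV, Rectum, Bladder, Kidney\_Left, Kidney\_Right, Liver,
Body} and $A_k$ the voxel count of mask $\Omega_k$. Because the weights are
inversely proportional to area and normalised to a convex combination, a
small target volume contributes as much to the objective as the whole body
outline contributes little; on the default phantom the CTV weight is
roughly 250× the body weight. The SSIM inside each region uses the
standard stabilised form
$\mathrm{SSIM} = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
{(\mu_x^2+\mu_y^2+c_1)(\sigma_x^2+\sigma_y^2+c_2)}$
with $c_1 = (k_1 L)^2$, $c_2 = (k_2 L)^2$, $k_1 = 0.01$, $k_2 = 0.03$. Note
that some published statements of the formula drop the factor 2 on
$\sigma_{xy}$; only the form above satisfies SSIM$(x, x) = 1$, which is the
property every identity check in this package relies on.

Two window modes are provided and selected by `lossConfig(window=)`:

* `"gaussian11"` (default): a local SSIM map per axial slice (11×11
  Gaussian window, σ = 1.5 voxels, zero padding), averaged over the masked
  voxels. This matches the usual reading of SSIM as a local-statistics
  comparison and is the training default.
* `"global"`: the literal single-statistic SSIM over the masked voxels.
  This is also what the metric suite reports, and it is the mode checked
  against naive double-loop oracles in the tests.

Both modes have exact analytic gradients with respect to the prediction
(`weightedSSIMLossGrad`), verified against central finite differences to a
relative error below $10^{-4}$.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `epsilon` | 1 | voxels | the weight stabiliser; its relative effect is below $10^{-3}$ for any region of ≥ 1000 voxels |
| `hu_window` | [−1000, 2000] | HU | clipping window; its width L = 3000 sets the SSIM dynamic range and the PSNR peak m |
| `noise_sd_hu` | 8 | HU | venous-phase pelvic CT noise at typical dose |
| `bias_amplitude_hu` | 10 | HU | smooth patient-scale inhomogeneity, shared by the pair |
| `anatomy_jitter` | 0.05 | fraction | organ position/size variation across samples |
| `tissue_jitter` | 1 | × cohort SD | per-sample tissue-mean draws (see below) |
| `lr` | 1e-3 | — | desk-scale AdamW rate (see below) |
| `batch_size` | 8 | slices | desk-scale batch |
| `band_mm` | 50 | mm | hallucination screening band above/below the CTV |
| `delta_hu` | 100 | HU | error threshold for a hallucination candidate |

Empty regions in $\kappa$ are dropped (with a warning) before the weights
are normalised: a weight for a region with no voxels would be finite but
enormous, and its region SSIM is undefined, so renormalising over the
populated regions is the only combination that keeps the loss a convex
combination of defined quantities.

An optional voxelwise L1 term exists in the loss configuration but
defaults to coefficient 0: the weighted SSIM alone is the documented
objective, and the L1 hook exists only so the ablation is one flag away.

## What the phantom emulates — and what it does not

The simulator paints a 2.5-D pelvic geometry (structures are tubes or
ellipsoids; the body outline is constant along z) with per-tissue HU
means. Vessels, muscle, fat, vertebrae and bone marrow use measured cohort
values for both phases, so the venous enhancement deltas are
180.99 HU for vessels and 13.68 HU for marrow by construction. Organs
without published phase values (bladder, rectum, kidneys, liver, CTV)
carry literature-typical stand-ins, flagged as such in
`defaultTissueTable()` and freely overridable; they are never used as
ground truth beyond self-consistency.

Cohort variation is modelled by drawing each sample's tissue means from
N(mean, `hu_sd` × `tissue_jitter`) — the table's ± column is read as
between-patient spread, not voxel texture — identically in both volumes so
deltas are preserved. Voxel noise is additive Gaussian and independent
between the two volumes of a pair, while the low-order cosine bias field
is shared: paired scans share patient-scale inhomogeneity but not photon
noise. `noiseFreeConfig()` zeroes noise, bias and tissue jitter, which is
the configuration under which mask means reproduce the tissue table to
1e-6 and the enhancement delta is exact voxelwise.

The phantom deliberately does **not** model: anatomical texture within
organs, partial-volume boundaries, respiratory or peristaltic motion,
multi-phase kinetics, metal or beam-hardening artefacts, or deformable
mismatch between the two phases (the pair is perfectly registered).
Passing tests on phantoms therefore demonstrate that the optimisation,
metrics and plumbing are correct — not that the network generalises to
patient data, where registration error and texture dominate.

## The network and the desk-scale training protocol

The network is U-shaped: per-stage 3×3 convolution + ReLU + 2×2 max-pool
encoder (default widths 16/32), a transformer bottleneck over 1×1 tokens
of the deepest feature map (learned positional embedding, pre-norm blocks
of multi-head self-attention and a 4× MLP, default 2 layers × 4 heads at
embedding 64), and a decoder with nearest-neighbour upsampling and skip
concatenation. The output head is a zero-initialised 1×1 convolution added
to the input slice, so the initial network is exactly the identity and
training learns the *enhancement field* rather than having to reconstruct
anatomy from scratch. `trans_layers = 0` removes the bottleneck entirely
and yields the plain U-Net ablation. All forward/backward passes are
hand-written on BLAS matrix multiplications and are exact (finite-
difference checked layer by layer and end to end).

Preprocessing clips to the HU window and z-scores with statistics computed
on the training split only; the statistics travel with the checkpoint and
are reused verbatim downstream (their provenance is tagged). The loss is
computed on denormalised HU so the SSIM dynamic range keeps its physical
meaning. Augmentation (paired flip/rotation ≤ 10°/translation ≤ 5%,
intensity jitter ±10% on the input only) is available but off by default
at desk scale — the phantoms already randomise anatomy, and position cues
are informative for the small training budgets used here.

The full-scale protocol (batch 32, AdamW at 1e-4, up to 1000 epochs,
selection on validation region-weighted SSIM, 5-fold CV stratified —
here on CTV-volume tertiles, a documented stand-in) is reachable through
`trainConfig`. The desk-scale defaults are batch 8 and lr 1e-3 for a
~200-step budget on ~50 slices of 64×64: at a few hundred steps from a
fresh initialisation, a 1e-4 rate cannot move the loss appreciably, so the
desk regime uses the larger rate and keeps everything else. On this
protocol (3 training phantoms of 16 × 64 × 64, one validation phantom, 204
steps, ~6 minutes on one CPU) the validation loss drops by ~70% and a
held-out phantom's vessel mask moves toward the true enhanced mean while
fat and vertebrae stay within 3× the voxel noise SD of their noncontrast
values. Model selection keeps the epoch with the highest validation
region-weighted SSIM; early stopping monitors the validation loss with a
minimum improvement of 1e-6 over a 10-epoch patience (desk default).

## Numerical choices and degenerate inputs

* **SSIM window at borders**: zero padding; this equals evaluating the
  statistics on a zero-padded image, keeps all local variances
  nonnegative, and makes the smoothing operator self-adjoint, which the
  analytic gradient exploits.
* **PSNR peak m**: the HU window width (3000) by default, overridable;
  identical images report `Inf` rather than erroring.
* **UQI degeneracy**: a constant-vs-constant comparison has no defined
  UQI; the metric errors explicitly, and the report layer maps the case
  "identical constant region" to 1 (perfect agreement) and other
  degeneracies to NA.
* **UQI/SSIM ranges**: both statistics are reported unclamped; they can be
  negative for anti-correlated inputs even though they are commonly quoted
  on [0, 1].
* **Dice on two empty masks**: 1.0 with a warning (perfect agreement on
  absence).
* **HD95**: surfaces are voxel centres with at least one 6-connected
  neighbour outside the mask (volume border counts as outside); the two
  directed nearest-distance sets are pooled before the 95th percentile
  (linear interpolation between order statistics, R type 7). Pooling
  matches the single "closest 95% of surface points" reading; the
  max-of-directions alternative is a flag.
* **Hallucination proxy**: 26-connectivity components of |pred − truth| >
  100 HU outside every true enhancing mask, within the CTV z-extent ±
  50 mm, of ≥ 10 voxels. This is an automated stand-in for radiologist
  screening — no published formula exists for the corresponding rate — and
  all three thresholds are exposed.
* **Determinism**: every stochastic stage derives its seed from one run
  seed; phantom generation, training and the pipeline reproduce
  bit-identically under a fixed seed on a fixed BLAS.

## Known limitations

The simulator's geometric simplicity means texture-sensitive failure modes
of real synthesis models (smoothed parenchyma, invented vessels inside
organs) are under-represented; the hallucination proxy is calibrated only
by its injected-blob controls. Training at desk scale shows parameter
recovery, not clinical performance: image-quality numbers on phantoms are
not comparable to patient-cohort values. The 2D slice-wise model ignores
through-plane context by design; 3D patches are out of scope.
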
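---
title: "Removing static blur from underwater images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing static blur from underwater images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uwenhance)
```

## The problem

Water absorbs and scatters light selectively: red wavelengths die off within
a few meters, blue-green light survives, and suspended matter adds a veiling
backscatter haze. The result — low contrast, a blue/green color cast and
washed-out detail — is what we call *static blur*, as opposed to the
*dynamic blur* of camera or subject motion (which this package deliberately
does not attempt to remove beyond an optional external hook in the pipeline
configuration). `uwenhance` implements a four-stage static-blur-removal
chain together with the no-reference quality scores used to judge it, the
detection-side mathematics (IoU-family losses, PR/AP/mAP, a bi-level routing
attention forward pass), and a seeded synthetic degradation generator, so
that every claim the package makes is testable on one CPU with no external
data.

## The enhancement chain

`enhance_static()` composes four stages.

**1. Adaptive color compensation** (`compensate_colors`). The per-channel
means are ordered; with $\bar I_{max} \ge \bar I_{mid} \ge \bar I_{min}$,
the coefficients

$$m = \frac{\bar I_{max} - \bar I_{min}}{\bar I_{max} + \bar I_{min}},
\qquad
n = \frac{\bar I_{max} - \bar I_{mid}}{\bar I_{max} + \bar I_{mid}}$$

lift the attenuated channels per pixel:
$I'_{mid} = I_{mid} + n\, I_{max}$ and $I'_{min} = I_{min} + m\, I_{max}$,
with the dominant channel untouched and the result clipped to $[0,1]$
(no overflow rule is inherent in the formulation, so clipping is the
documented choice). The coefficients are *scalars computed from the channel
means*: the ordering step is only meaningful at channel level, even though a
per-pixel reading of the same formulas is conceivable. Achromatic images are
fixed points; an all-black image is flagged degenerate and passed through.
Ties in the means are broken by the fixed priority R < G < B so edge cases
are deterministic.

**2. Retinex color recovery with a rolling-guidance illumination estimate**
(`improved_msr`). Single-scale Retinex computes reflectance as
$\log I - \log(\text{illumination})$; the classical estimate, a Gaussian
blur, also blurs large-scale edges and creates halos. The rolling guidance
filter replaces it: a Gaussian pass first erases small-scale texture, then
$t$ joint-bilateral iterations — input always the original channel, range
kernel evaluated on the *previous iterate* — restore the large-scale edges
of the illumination field:

$$J^{t+1}(p) = \frac{1}{K_p}\sum_{q \in N(p)}
\exp\!\Big(-\tfrac{\|p-q\|^2}{2\sigma_s^2}
           -\tfrac{(J^t(p)-J^t(q))^2}{2\sigma_r^2}\Big)\, I(q).$$

Reflectance is accumulated over $N$ spatial scales with convex weights
$W_n$. Defaults: scales $(15, 80, 250)$ px with $W_n = 1/3$ (the classic
multi-scale triple), $\sigma_r = 0.1$, $t = 4$, $\varepsilon = 1/255$ as the
log guard. None of these is prescribed by the method's description, so they
follow the Retinex literature and are all configurable.

Two numerical choices matter here:

* *Exposure invariance.* A range kernel with an absolute $\sigma_r$ breaks
  the Retinex identity $R(kI) = R(I)$, because scaling the channel scales
  the guide differences. `rolling_guidance_filter` therefore filters the
  peak-normalized channel and rescales afterwards, making the operator
  positively homogeneous; $\sigma_r$ is effectively expressed relative to
  the channel's peak. For $[0,1]$ images this coincides with the absolute
  reading to within the peak value.
* *Coarse evaluation of large scales.* The exact joint bilateral sum costs
  $O(HW(3\sigma_s)^2)$ per iteration, which at $\sigma_s = 250$ on a
  400×300 frame is computationally absurd — and pointless, since the
  illumination field at scale $\sigma_s$ carries no detail below that
  scale. Scales above `coarse_sigma` (default 5 px) are therefore filtered
  on a bilinearly downsampled grid with $\sigma_s$ reduced by the same
  factor and the result upsampled. Against the exact full-resolution filter
  at $\sigma_s = 15$ on a 400×300 frame this differs by at most $7\times
  10^{-4}$ in intensity (RMS $6.5\times 10^{-5}$) while being roughly six
  times faster. The exact path is used automatically whenever $\sigma_s \le$
  `coarse_sigma`, and `gaussian_estimate`/`joint_bilateral_step` are always
  exact windowed sums (the test suite checks them against brute-force
  double loops to $10^{-10}$).

The log-domain reflectance is mapped to a displayable image by
`normalize_reflectance`, the canonical MSR gain/offset step: per channel,
$\mu - k\sigma \mapsto 0$ and $\mu + k\sigma \mapsto 1$ with $k = 2.5$,
clipped, degenerate channels to 0.5. A percentile stretch (1st → 0,
99th → 1) was evaluated first and rejected: reflectance distributions are
skewed in *opposite directions* per channel on typical underwater scenes
(red structure is sparse bright features; green/blue are bright fields with
dark objects), so a percentile stretch mis-centers the channel means and
can *introduce* a cast of up to 0.5 in channel-mean spread — the opposite
of what the stage is for. The gain/offset mapping sends every channel mean
to 0.5 by construction and is cast-neutral.

**3. CLAHE + adaptive gamma on the value channel** (`enhance_contrast`).
The V plane of the HSV representation is equalized tile-wise: per-tile
histograms are clipped at `ceiling(clip_limit × total/bins)` with the
excised mass spread uniformly (iterated until the residual excess is below
one count — mass is conserved exactly, and a cap too small to hold the
total yields the fully flattened histogram), each tile's mapping is its
clipped cdf, and pixels blend the four surrounding tile mappings
bilinearly. Adaptive gamma correction then remaps levels through

$$T(l) = l_{max}\,(l/l_{max})^{1 - \mathrm{cdf}_w(l)},\qquad
\mathrm{pdf}_w(l) = \mathrm{pdf}_{max}
\Big(\tfrac{\mathrm{pdf}(l)-\mathrm{pdf}_{min}}
           {\mathrm{pdf}_{max}-\mathrm{pdf}_{min}}\Big)^{\alpha},$$

with $\mathrm{cdf}_w$ the normalized cumulative sum of $\mathrm{pdf}_w$.
Because the exponent never exceeds 1, $T$ brightens or preserves every
level and fixes both endpoints ($T(0)=0$ by the convention $0^e = 0$,
including $e = 0$; uniform histograms fall back to $\mathrm{pdf}_w =
\mathrm{pdf}$ since the weighting is 0/0 there). The method's prose
mentions both the H and the V plane for this correction; correcting hue
would permute colors, so V is corrected and H, S pass through bit-identical
— the implementation treats that as the only coherent reading. Defaults
(8×8 tiles, clip limit 2.0, 256 bins, $\alpha = 0.5$) follow the CLAHE/AGC
literature; none is prescribed.

**4. Multi-weight pyramid fusion** (`pyramid_fuse`). The fusion inputs are
the two renditions the chain has produced — the display-normalized Retinex
image and its contrast-enhanced version. (The method description names the
weights but not the second input; fusing these two is the natural reading,
and a single-input degenerate mode returns the contrast-enhanced image.)
Each input is scored per pixel by three cues: contrast (absolute 3×3
Laplacian of luminance), colorfulness (RMS deviation of R, G, B from
luminance), and saliency (absolute difference between the 5 px
Gaussian-smoothed luminance and its global mean — the absolute value is
used because a signed map would be an invalid weight). The cues are
*summed* (a product would zero out on flat regions) and normalized across
inputs with a $\delta = 10^{-3}$ regularizer so they sum to 1 pointwise.
Blending happens per level of a 5-level pyramid: Laplacian pyramids of the
inputs, Gaussian pyramids of the weights (5-tap binomial smoothing,
ceiling-halving decimation), weighted sums collapsed back and clipped.
Band-wise blending avoids the seams a flat per-pixel blend produces; the
reconstruction is exact by construction because the collapse uses the same
bilinear upsampling as the decomposition.

## Quality metrics

`quality_report()` returns the four no-reference scores commonly used for
underwater enhancement, computed in one fixed, documented dialect (the
scores only compare meaningfully within a dialect):

* **Entropy** — Shannon entropy (bits) of the 256-bin histogram of the
  8-bit-quantized luminance; $[0, 8]$.
* **AG** — average gradient on the 0–255 scale: mean over the interior of
  $\sqrt{(G_x^2+G_y^2)/2}$ with forward differences, averaged over
  channels. At least three AG conventions circulate; this one is fixed
  here.
* **UCIQE** $= 0.4680\,\sigma_{chroma} + 0.2745\,\mathrm{con}_l +
  0.2576\,\mu_{sat}$ in CIELab (sRGB/D65): chroma standard deviation,
  (99th − 1st percentile of $L^*$)/100, and mean saturation
  $\mathrm{chroma}/\sqrt{\mathrm{chroma}^2 + L^{*2}}$.
* **UIQM** $= 0.0282\,\mathrm{UICM} + 0.2953\,\mathrm{UISM} +
  3.5753\,\mathrm{UIConM}$: colorfulness from $\alpha$-trimmed
  ($\alpha=0.1$) means and variances of $R-G$ and $(R+G)/2 - B$; sharpness
  as the luma-weighted EME (natural log, 8×8 blocks) of Sobel-edge-weighted
  channels; contrast as the PLIP-free logAMEE of luminance with the
  $-1/(k_1k_2)$ sign convention of the widely used reference
  implementations. Zero-dynamic-range blocks contribute 0 everywhere, which
  also guards the logs.

The coefficient sets are the community-standard constants. Absolute values
from other implementations will differ where their block or edge dialect
differs; within this package the scores are consistent and reproducible.

## The synthetic degradation model

`generate_scene` builds procedural scenes (smooth gradients, high-chroma
discs and star shapes, a smoothed texture field) that exercise contrast,
saliency and chroma statistics at once. The clean scene is gray-world
balanced: a *reference* scene carries local chroma but no global cast,
because casts are the degradation model's job — without this, a "clean"
scene with its own cast makes cast-removal unmeasurable. `degrade` applies
the attenuation–backscatter image formation

$$\mathrm{out}_c = I_c\, e^{-\beta_c d} + B_c\,(1 - e^{-\beta_c d}),$$

with $\beta_R > \beta_G \ge \beta_B$ (red dies first) and blue-green
veiling light $B$, followed by optional linear motion blur and seeded
additive Gaussian noise. `make_fixture_set` spans a fixed grid of
mild/strong cast ($\beta$ = (0.35, 0.12, 0.06) and (0.9, 0.3, 0.08)),
distance $d \in \{1.2, 2.5\}$, noise $\sigma \in \{0, 0.01\}$ and blur
$\in \{0, 5\}$ px. What the generator does *not* emulate: wavelength-
continuous attenuation spectra, depth-varying illumination, flicker,
sensor-specific noise, or real biological texture — so a passing
end-to-end suite demonstrates the pipeline's behavior under the modeled
degradations, not photorealistic generality.

## Detection-side mathematics

The ECIoU regression loss combines the CIoU aspect-ratio penalty with the
EIoU width/height distance penalties:

$$\mathcal{L} = 1 - \mathrm{IoU} + \alpha v
 + \frac{\rho^2(b, b^{gt})}{c^2}
 + \frac{(h - h^{gt})^2}{c_h^2}
 + \frac{(w - w^{gt})^2}{c_w^2},$$

with $v = \tfrac{4}{\pi^2}(\arctan\tfrac{w^{gt}}{h^{gt}} -
\arctan\tfrac{w}{h})^2$ and $\alpha = v/((1-\mathrm{IoU})+v)$ — the CIoU
definitions, adopted because the combined loss is described as built from
those two components and defines neither symbol itself. The loss is zero
exactly at coincidence, nonnegative, and invariant to joint translation
and scaling.

Evaluation utilities use corner-format continuous boxes, greedy per-class
matching (descending score, best-IoU unmatched ground truth, strict
threshold), and all-point interpolated AP
($\sum_i (r_i - r_{i-1}) \max_{j\ge i} p_j$) — the integral reading of the
PR area; whether 11-point interpolation was intended elsewhere is
unknowable, so the integral form is fixed here. mAP is the unweighted class
mean.

`bra_forward` is a deterministic reference forward pass of bi-level routing
attention: region-mean queries/keys route each of the $S^2$ regions to its
top-$k$ peers (ties to the lower index), token attention runs over the
gathered keys/values with $1/\sqrt{C}$ scaling, and a depthwise 5×5
zero-padded convolution of V adds local context. The attention operand is
read as $\mathrm{Attention}(Q, K^g, V^g)$ (the source's "$O$" in that
position is an apparent typo). With $k = S^2$ it reproduces dense attention
exactly, which the tests exploit as an oracle. No training, gradients or
NMS anywhere.

## Numerical conventions

* Mirror (symmetric) borders for every spatial filter — avoids dark frame
  halos; the brute-force test oracles use the same convention.
* Gaussian windows truncated at radius $\lceil 3\sigma \rceil$.
* 8-bit quantization is round-half-up, so encoded files are platform
  independent.
* HSV hue is a fraction of a turn in $[0,1)$; Lab uses sRGB primaries with
  D65 white.
* Degenerate guards: all-black compensation, zero-spread display channels,
  uniform AGC histograms, zero-range metric blocks, 0/0
  precision/recall (reported as 0 with a flag).

## Problem sizes

The test suite runs oracle comparisons on ≤ 9×9 inputs (where brute force
is exact and instant), property checks on seeded 8×8 to 64×64 images, and
the end-to-end direction check on the full 20-image fixture grid at
400×300 — the frame size the pipeline is intended for — which completes in
a few minutes on one CPU. `scripts/acceptance.R` reruns that 20-image
computation from scratch at the same size.

## Known limitations

* The pipeline is tuned for, and validated on, the synthetic degradation
  model; real-water phenomena outside it (see above) are untested.
* UIQM/UCIQE values are dialect-specific; compare only within one
  implementation.
* The coarse-grid evaluation of large Retinex scales trades a bounded,
  measured approximation error for tractability; set `rgf_coarse_sigma =
  Inf` to force exact evaluation if runtime is no concern.
* Dynamic (motion/defocus) blur is out of scope; the configuration exposes
  only an external per-image command hook, off by default.
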
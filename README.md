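# uwenhance

Underwater photographs suffer *static blur*: water absorbs red light within
a few meters, scatters the rest, and suspended matter adds a veiling haze,
so frames come out blue-green, low-contrast and washed out. That degrades
both human inspection and downstream detection of benthic targets (urchins,
starfish, sea cucumbers) by autonomous vehicles. `uwenhance` is an R
toolbox for marine-imaging practitioners that removes static blur with a
four-stage pipeline and quantifies the result with the field's standard
no-reference scores:

1. **Adaptive color compensation** — with channel means ordered
   `Imax ≥ Imid ≥ Imin`, coefficients
   `m = (Imax − Imin)/(Imax + Imin)` and `n = (Imax − Imid)/(Imax + Imid)`
   lift the attenuated channels per pixel
   (`I'min = Imin + m·Imax`, `I'mid = Imid + n·Imax`).
2. **Improved multi-scale Retinex** — reflectance
   `R = Σn Wn [log(I+ε) − log(RGF(I; σs,n)+ε)]`, where the illumination
   estimate `RGF` is a rolling guidance filter (a Gaussian pass followed by
   joint-bilateral iterations guided by the previous iterate) instead of
   plain Gaussian blur, preserving large-scale edges; displayed via the
   canonical mean ± 2.5σ gain/offset mapping.
3. **CLAHE + adaptive gamma** on the HSV value channel —
   contrast-limited tile equalization, then
   `T(l) = lmax (l/lmax)^(1 − cdf_w(l))` built from a weighted histogram
   distribution.
4. **Multi-weight pyramid fusion** — contrast, colorfulness and saliency
   weights, normalized across the two renditions and blended per level of
   a 5-level Laplacian/Gaussian pyramid pair.

It also ships the quality metrics (UIQM, UCIQE, average gradient, entropy),
detection-side mathematics — IoU, the combined **ECIoU** regression loss
(`1 − IoU + αv + ρ²(b,b_gt)/c² + (h−h_gt)²/c_h² + (w−w_gt)²/c_w²`),
precision/recall, all-point-interpolated AP and mAP@0.5 with greedy IoU
matching, and a deterministic **bi-level routing attention** forward pass —
plus a seeded synthetic underwater degradation generator
(attenuation–backscatter model `out = I·e^{−βd} + B(1 − e^{−βd})` with
noise and motion blur), so everything is testable offline.

See `vignettes/underwater-enhancement.Rmd` for the full method and design
notes.

## Worked example

```r
library(uwenhance)

scene <- generate_scene(seed = 7, H = 300, W = 400)          # clean reference
deg   <- degrade(scene, degradation_params(beta = c(0.9, 0.3, 0.08), d = 2.5,
                                           background = c(0.08, 0.42, 0.52)))
enh   <- enhance_static(deg)                                  # full pipeline

channel_mean_spread(deg); channel_mean_spread(enh)
rbind(degraded = quality_report(deg), enhanced = quality_report(enh))
```

Output:

```
spread before: 0.372   after: 0.012
         uciqe  uiqm  uicm  uism uiconm    ag entropy
degraded 3.383 2.487 2.113 6.975  0.103 0.684   5.296
enhanced 9.656 3.200 8.492 6.364  0.303 7.704   7.223
```

The channel-mean spread (the color cast: max minus min channel mean) drops
from 0.372 to 0.012 — the blue-green cast is gone; entropy rises by ~1.9
bits (more usable tonal information), the average gradient by ~11× (edges
and texture recovered from the haze), and both composite underwater quality
scores (UCIQE, UIQM) increase.

## Command line

```sh
Rscript inst/cli/uwenhance.R synth --n 20 --seed 7 --out fixtures
Rscript inst/cli/uwenhance.R enhance fixtures/degraded_001.png out.png
Rscript inst/cli/uwenhance.R score fixtures --out scores.csv
Rscript inst/cli/uwenhance.R eval-det --pred pred.csv --gt gt.csv --iou 0.5
```

(When the package is installed, the script is at
`system.file("cli", "uwenhance.R", package = "uwenhance")`.)

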
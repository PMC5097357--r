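# dmar

Metal artifact reduction (MAR) for dental CT in R: projection-domain
metal-trace segmentation by global thresholding with adaptive local-threshold
refinement, prior-image generation by fusing a streak-free and a metal-free
reconstruction, sinogram replacement, and final iterative reconstruction.
The package also ships the full simulation machinery needed to evaluate the
method end to end — material-label phantoms, polychromatic forward
projection, FBP and SART reconstruction, and windowed SSIM on regions of
interest — so the whole study below regenerates from scratch with no
external data.

## Quick start

```r
library(dmar)

ph   <- bilateral_phantom(256L)              # material-label phantom
geom <- ct_geometry(256L, n_views = 360L)
sino <- peak_normalize(polychromatic_project(ph, geom, scan_spectrum(ph)))

fit <- mar(sino, mode = "proposed", threshold = 0.05)  # W = 30, a = 2,
print(fit)                                             # p = 10, c = 0.1

ref <- reference_image(ph, geom, scan_spectrum(ph))
summary(fit, reference = ref, rois = ph$rois)
plot(fit)
```

`mar()` returns a classed object with the final corrected image, the
uncorrected SART reconstruction, the configuration, stage timings and (by
default) all intermediates: seed and expanded masks, in-painted sinogram,
streak-free / metal-free / fused prior images, weight map, and the corrected
sinogram.

A command-line front end with `simulate` / `correct` / `evaluate`
subcommands is installed at `inst/scripts/dmar`.

## Simulation study

`scripts/acceptance.R` regenerates both phantoms at 512 x 512 with 720
views, corrects them with FP-MAR (global threshold only, at T = 0.05 and
T = 0.07) and with the adaptive method (T = 0.05, W = 30, a = 2, p = 10,
c = 0.1), and scores ROI SSIM against the artifact-free reference (same
SART settings everywhere, 20 iterations):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Values printed by that run (deterministic; about 6 minutes per phantom on
one CPU core):

| phantom   | ROI | uncorrected | FP-MAR T=0.05 | FP-MAR T=0.07 | proposed T=0.05 |
|-----------|-----|------------:|--------------:|--------------:|----------------:|
| bilateral | A   | 0.876       | 0.914         | 0.985         | 0.988           |
| bilateral | B   | 0.848       | 0.910         | 0.909         | 0.917           |
| dental    | A   | 0.937       | 0.919         | 0.956         | 0.974           |
| dental    | B   | 0.885       | 0.803         | 0.822         | 0.826           |

ROI A (between the implants, the streak/shadow zone) shows the expected
pattern on the bilateral phantom: a mis-segmenting threshold (T = 0.05
misses a thin titanium fringe) leaves residual streaks, a well-segmenting
one (T = 0.07) removes them, and the adaptive expansion recovers the
well-segmented result from the lower threshold. ROI B (a square annulus
hugging one implant) scores lower in every corrected arm: the dominant
residual there is in-painting error re-entering through the metal trace,
and on the dental phantom the implant traces additionally sweep the teeth
in most views. The SSIM convention here takes the dynamic range from the
metal-free reference, which is stricter than display-window SSIM; see the
vignette ("Evaluation") for the conventions and for what the simulation
does and does not model.

## Documentation

- `vignette("metal-artifact-reduction")` — the method, every equation's
  conventions and edge cases, the phantom/spectrum design rationale, and
  evaluation conventions.
- The test suite (`tests/testthat/`) includes brute-force oracles for every
  pipeline equation, property suites for segmentation and the forward/
  inverse models, and an acceptance file that re-runs the full-scale study.
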
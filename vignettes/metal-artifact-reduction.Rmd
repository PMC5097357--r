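---
title: "Projection-domain metal artifact reduction for dental CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-domain metal artifact reduction for dental CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(dmar)
```

## The problem

Metallic objects — dental implants, crowns, prosthesis heads — attenuate
x-rays far more strongly than tissue. Rays through metal arrive at the
detector close to the noise floor, and their logged projection values are
corrupted by beam hardening, saturation and photon starvation. Filtered
backprojection (FBP) smears these inconsistencies across the image as streaks
and shadows. Dental CT adds a twist: enamel attenuates almost as strongly as
titanium per unit length, so any segmentation rule that works on intensity
alone is prone to mistaking teeth for metal.

`dmar` implements a projection-domain correction: the metal trace is
segmented on the projection data (where streak artifacts do not exist),
refined by adaptive local thresholding, and replaced by the forward
projection of a prior image fused from a streak-free and a metal-free
reconstruction. The package also contains the simulation machinery
(material-label phantoms, polychromatic projection, FBP and SART
reconstruction, ROI SSIM) needed to evaluate the method end to end without
any external data.

## The correction pipeline

`mar(sino, mode, threshold, W, a, p, c, n_iter, relax)` runs these stages:

1. **Peak normalization.** The attenuation sinogram is divided by its global
   maximum (`peak_normalize()`), so projection values live on a common
   scale across scans.

2. **Seed segmentation.** A single global threshold marks the metal trace:
   mask value 0 (metal) where the projection value is at least the cutoff.
   The user-facing `threshold` is expressed as a *transmitted-intensity
   fraction of the peak*: a ray whose transmission falls to, say, 5 % of the
   unattenuated beam is seeded as metal. On the attenuation scale this is the
   cutoff `-log(threshold)`. This is the domain in which thresholds around
   0.05–0.07 isolate metal: metal rays transmit a few per mille to a few per
   cent, while tissue and teeth transmit more. Expressing the rule on the
   attenuation sinogram directly (metal where normalized attenuation ≥ 0.05)
   would mark most of the body, because tissue line integrals are typically
   30–50 % of the metal peak; with the transmission reading, a *larger*
   threshold segments *more* metal, which matches the partial/full
   segmentation behaviour the method is designed around.

3. **Adaptive local expansion** (`proposed` mode only). The seed threshold is
   deliberately conservative, so the seeded trace is slightly smaller than
   the true one. For each island of metal in each view, the island's
   intensity minimum `B`, maximum `A` and population standard deviation
   `sigma` define an acceptance band `[B - a*sigma, A + a*sigma]`; pixels
   within `W` detector bins of the island whose value falls inside the band
   are added to the metal set (never removed — the final mask is the union
   of seed and expansion). Two notes on this rule:

   * The band must extend *below* the island minimum to be able to grow the
     region: every seed pixel already satisfies `P >= cutoff`, hence
     `B >= cutoff`, so a band contained in `[B, A]` could never add a pixel.
     Written with the margins inward the rule would be a no-op; the outward
     margins implemented here are the only reading under which the step
     expands, and it preserves the intended robustness to overlap: if the
     metal region overlaps dense anatomy, `B` and `A` rise, the band's lower
     bound rises with them, and growth into the surrounding anatomy is
     curbed.
   * Islands are maximal runs of metal along the detector axis within one
     view (the sinogram is 2D here). For projection-image stacks, a second
     pass applies the same rule along the vertical detector axis, with
     island statistics recomputed after the horizontal pass.

   Defaults `W = 30` detector bins and `a = 2` follow the method's stated
   operating point.

4. **Prior image.** The metal trace is in-painted row by row with the linear
   ramp between its flanking values (`inpaint_linear()`); SART reconstruction
   of the in-painted data gives the *streak-free* image `I_sf` (iterative
   reconstruction tolerates the residual inconsistency much better than FBP).
   Separately, the metal pixels of the uncorrected reconstruction are
   nullified to give the *metal-free* image `I_mf`; the image-domain metal
   mask comes from thresholding the uncorrected reconstruction, by default
   at Otsu's threshold of its histogram (`otsu_threshold()`), which
   separates the high-attenuation metal cluster from tissue without a
   scale-dependent constant. Their difference
   `D = I_sf - I_mf` is min–max normalized to `D_n` over the whole image,
   and the prior is the pixelwise blend
   `I_p = w*I_mf + (1 - w)*I_sf` with `w = 1/(1 + (D_n/c)^p)`.
   Where the two parents agree (`D_n` small) the prior keeps the sharp
   metal-free pixel; where they disagree (streaks, shadow zones) it follows
   the smooth streak-free pixel. `p = 10` sharpens the switch; `c = 0.1` is
   the stated setting for small metallic objects (`c` around 0.45 suits
   large ones). In the degenerate case `D_max = D_min` the normalized
   difference is defined as 0, so the prior equals the metal-free image —
   if there is no streak signal there is nothing to blend.

5. **Projection replacement and final reconstruction.** The prior image is
   forward projected with the same ray model that produced the data and
   scaled onto the normalized reference (division by the stored peak); the
   corrected sinogram is the exact multiplex
   `P_hat = M*P_orig + (1 - M)*P_prior`, so measured data survive bitwise
   outside the trace. SART reconstructs `P_hat`, and the metal pixels are
   filled back from the uncorrected reconstruction so the implants remain
   visible. In `proposed` mode `M` is the expanded mask; in `fp_mar` mode —
   the comparison arm driven purely by the global threshold — it is the
   seed.

## Reconstruction and forward model

* **Ray model.** Joseph-style interpolating line integrals (unit steps along
  the dominant ray axis, linear interpolation across it), identical in the
  simulator, the prior projector and SART, so simulate → reconstruct →
  reproject chains are self-consistent. Parallel-beam 2D is the default;
  fan-beam (point source, flat virtual detector through the origin) is a
  geometry option reconstructed via SART.
* **FBP.** Discrete Ram–Lak kernel applied by FFT convolution, optional Hann
  rolloff, linear-interpolation backprojection, `pi/n_views` angular weight.
* **SART.** Sequential view order; per view, ray residuals normalized by the
  interpolation-weight ray length are backprojected and normalized by the
  per-pixel weight sum; relaxation 0.25; nonnegativity clamp after each full
  iteration; 20 iterations by default. The per-iteration sweep residual is
  recorded, and growth beyond 10x the initial residual aborts with an error.
  These settings are package choices (the method's source states none); the
  defaults were fixed from the disk-phantom oracle tests, not from the
  acceptance outcomes.
* **Polychromatic simulation.**
  `P(s, theta) = -log(sum_E w(E) exp(-sum_m mu_m(E) L_m(s, theta)))` on a
  tabulated material attenuation grid (log-log interpolated from standard
  published compilations). Transmission is clamped at a relative floor of
  `1e-12`; the floor keeps the logarithm finite behind very thick metal and
  is not a detector dynamic-range model. Clamped rays are counted on the
  sinogram object. An optional seeded Poisson noise stage
  (`add_poisson_noise()`) exists and is off in every default simulation
  path.
* **Spectrum.** A documented parametric model: Kramers-type bremsstrahlung
  weights `(kvp - E)` shaped by aluminium/copper filtration, 21 bins from
  20 keV to the tube voltage, normalized to unit weight. The package default
  is a soft 40 kV beam with 0.5 mm Al; `scan_spectrum()` returns the fixed
  study spectrum of each built-in phantom (bilateral 0.5 mm Al, dental
  0.3 mm Al, both 40 kV). `single_bin_spectrum()` gives the monochromatic
  degenerate case used by the unit oracles.

## The simulation phantoms and their scale

`bilateral_phantom()` (muscle ellipse, two titanium disks each inside a
thin cortical bone shell) and `dental_phantom()` (soft-tissue head, an arch
of eight enamel-shelled dentin teeth, two titanium implants in thin bone
collars at the posterior positions of the same arch) are deterministic
material-label maps with fixed physical size; the pixel size shrinks as the
grid grows, so every grid size describes the same object (512 px defaults:
0.128 mm and 0.12 mm per pixel).

The phantoms are *desk-scale* (micro-CT) miniatures, and their scale is a
modelling decision worth spelling out. The method's operating condition is
that a global threshold of 0.05–0.07 on peak-normalized projection data
segments only the metallic objects. That is an assertion about attenuation
magnitudes: every non-metal ray must stay below the attenuation cutoff
`-log(0.07) = 2.66`, and the metal trace in every view must exceed
`-log(0.05) = 3.0`. Those two inequalities pin the admissible combinations
of body size, implant diameter and spectrum. The shipped defaults (40 kV
lightly filtered spectra; 6.7 mm implants in a 5.4 x 5.1 cm body; 7.2 mm
implants in a 4.9 x 4.7 cm head section) were chosen once, from the
projection-domain inequalities and the streak-anchoring analysis below, and
then frozen. The bone shells and collars are sized so their tangent flanks
peak *between* the two cutoffs: at `T = 0.07` the segmentation anchors the
in-painting on real bone-flank values (well segmented), while at `T = 0.05`
it still misses a thin titanium fringe whose view-to-view variability
reconstructs as residual streaks (mis-segmented) — the contrast between the
two comparison arms arises from the geometry, not from tuning against
scores. The far field stays below the 0.07 cutoff in both phantoms, so
neither threshold segments anatomy away from the implants.

What the generator emulates: energy-dependent attenuation with beam
hardening, saturation behind metal, the streak/shadow geometry of two
implants, and the teeth-versus-metal contrast problem. What it does not:
noise (the optional Poisson stage is off by default and the study is
noiseless), scatter, detector blur, cone-beam geometry, and anatomical
complexity (alveolar bone structure around the teeth). Passing tests
demonstrate the algorithmic behaviour under the stated conditions, not
clinical performance.

## Evaluation

`ssim_roi()` computes Gaussian-windowed SSIM (sigma 1.5, 11x11 window,
K1 = 0.01, K2 = 0.03, the original reference implementation's constants) on
an ROI crop, averaging the windows that fit fully inside the crop; the
dynamic range is the reference image's full-image max − min, and excluded
ROI pixels (the metal pixels of the annular ROI B) are dropped from the
average. ROI A sits midway between the implants (the streak/shadow zone);
ROI B surrounds one implant.

The artifact-free reference is the SART reconstruction (same settings as
the pipeline) of the polychromatic projection, under the same spectrum, of
the phantom with metal replaced by its surrounding tissue
(`reference_image()`). Reconstructing the reference — rather than comparing
against the label map — keeps the comparison free of the resolution and
smoothness differences between an ideal image and any reconstruction, and
using the same spectrum keeps the mild tissue beam hardening common to both
sides. The replacement tissue is the implant's surroundings (muscle or soft
tissue), not bone: a solid bone interior would give the reference its own
edge-overshoot texture inside the implant footprint that no corrected image
could reproduce, biasing the score for reasons unrelated to artifact
reduction; the real bone shell/collar remains part of both geometries. The uncorrected comparison image is the
SART reconstruction of the polychromatic data, matching the algorithm used
for the corrected arms.

One convention deserves emphasis: the SSIM dynamic range `L` is taken from
the *metal-free* reference, whose value range tops out at bone or enamel
(about 3.2/cm bilateral, 5.6/cm dental) rather than at titanium (about
7/cm). Published SSIM tables for MAR methods are commonly computed on 8-bit
display windows that include the metal range, which inflates `L` and with
it every score; the convention used here is stricter, and scores in streak-
bearing regions (the annular ROI B) sit visibly below what the display-
window convention would report for the same images. The acceptance script
reports the raw values under the strict convention.

`line_profile()` samples the configured profile line (through both implants)
with bilinear interpolation; profile deviations are compared outside the
metal region, because the fill-back step intentionally restores the metal
pixels from the uncorrected image.

## Numerical choices and degenerate inputs

* Population (N-divisor) standard deviation for island statistics; band
  edges inclusive.
* Degenerate islands (1–2 pixels) get no special casing; `sigma = 0`
  collapses the band to the island's own value range.
* In-painting of a run touching the detector edge extends the single
  available flank as a constant.
* A threshold so high that `-log(threshold)` exceeds the sinogram peak
  segments nothing; the pipeline warns and proceeds uncorrected.
* All-zero sinograms cannot be peak-normalized (error); zero images project
  to zero sinograms exactly (linearity is tested).
* Expansion windows are clipped at the detector edges.
* Float32 TIFF interchange rescales values to [0, 1] and stores the range in
  the YAML sidecar; round trips are exact to about 1e-7 of the value range.

## Problem sizes used by the tests

The equation-level oracles run on tiny synthetic arrays. Property suites
and the pipeline tests run on a 128-px disk phantom and 256-px/360-view
phantom simulations. The acceptance suite and the acceptance script
reproduce the full study at 512 px and 720 views for both phantoms (several
minutes per phantom at 20 SART iterations per reconstruction). These sizes
are the package's chosen test conditions; the scaling convention above
makes the phantoms physically identical across grid sizes. One caveat: the
expansion window `W = 30` is an absolute number of detector bins, so
reduced-scale runs expand proportionally farther — small-grid smoke runs
exercise the mechanics, not the full-scale scores.

## Known limitations

* The projection-domain thresholds assume peak normalization against an
  unattenuated (air) ray; scans whose field of view is entirely inside the
  patient would need a different normalization.
* Single correction pass, as designed; the method is not iterated.
* The weighting scale `c` is a configuration constant; no automatic
  selection by metal size is attempted.
* Fan-beam data are reconstructed with SART only (no rebinning FBP).
* The vertical expansion pass applies to (s, t) projection images; the 2D
  sinogram study never exercises it beyond its unit tests.
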
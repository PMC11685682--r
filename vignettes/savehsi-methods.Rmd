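---
title: "Simulating narrow-band imaging from white-light endoscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating narrow-band imaging from white-light endoscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savehsi)
```

## The problem

Narrow-band imaging (NBI) illuminates mucosa with light concentrated near
415 nm and 540 nm, the absorption peaks of hemoglobin, so vasculature
appears dark and lesions stand out. NBI hardware is not universally
available. `savehsi` simulates it computationally from ordinary white-light
(WLI) sRGB frames in three calibrated stages:

1. **Camera correction.** A 24-patch color checker is photographed under
   the WLI lamp and measured with a spectrometer. Camera XYZ (from sRGB
   decoding) is regressed against spectrum-derived XYZ through a polynomial
   variable expansion, absorbing channel cross-talk, color shift and
   dark-current-like offsets into a correction matrix C.
2. **Spectral reconstruction.** A principal-component basis of the
   measured patch reflectances plus a regression from expanded corrected
   XYZ to component scores (conversion matrix M) turns each pixel's
   tristimulus value into an "analog" reflectance spectrum on a 380--780 nm,
   1 nm grid.
3. **Band-selective re-illumination.** The NBI lamp is modeled as a sum of
   Lorentzian bands centered at {415, 480, 540, 600, 700, 780} nm. Its free
   parameters (centers within windows, half-widths, relative amplitudes)
   are fitted by generalized simulated annealing to minimize the mean
   CIEDE2000 difference between the 24 checker patches rendered under the
   model and 24 reference NBI patch colors. Re-rendering reconstructed
   spectra under the fitted model and encoding back to sRGB yields the
   simulated-NBI ("SAVE") image.

## Colorimetry

All integration uses the plain Riemann sum at the 1 nm grid step and the
luminance-ratio normalization
$k = 100 / \sum_\lambda E(\lambda)\,\bar y(\lambda)$, so a perfect
reflector has $Y = 100$ under any non-degenerate illuminant. Two
consequences matter downstream: rendered colors are invariant to a global
scaling of the illuminant (hence one band amplitude is pinned to 1 during
optimization, the rest being identifiable only relative to it), and
$L^* = 100$ for the perfect reflector under any band model.

Decoding uses the piecewise IEC 61966-2-1 sRGB transfer curve, not a bare
2.2 power, because endoscope output is sRGB. The sRGB primaries matrix is
normalized by its Y-row sum so that linear white maps to exactly
$Y = 100$; the Lab reference white is that matrix's white point
(D65, $\approx (95.05, 100, 108.88)$) throughout, since every rendered
product is sRGB.

The CIE 1931 2° observer is evaluated from the published multi-lobe
piecewise-Gaussian analytic fit (sums of asymmetric Gaussian lobes per
curve), which tracks the tabulated observer to about 1% of peak. Every
quantity the package verifies is a *consistency* property (round trips,
planted-model recovery, contrast comparisons), for which the smooth
analytic observer is fully adequate; a measured tabulation can be supplied
via `read_cmf_csv()` whenever absolute colorimetric accuracy against
external instruments matters.

CIEDE2000 is implemented in full, including the $G$ chroma correction, the
$S_L, S_C, S_H$ weights and the blue-region rotation term $R_T$; the test
suite checks it against an independently coded scalar transcription on
1000 random Lab pairs and against published reference pairs.

## Calibration and reconstruction

The variable expansion defaults to the 11 second-order monomials
$\{1, X, Y, Z, XY, XZ, YZ, X^2, Y^2, Z^2, XYZ\}$ evaluated on XYZ/100:
24 patches comfortably over-determine 11 coefficients, and the scaling
keeps the design matrix well conditioned. Both C and M are ordinary least
squares via QR; rank deficiencies are reported with the offending counts
or columns. No regularization is applied by default so that planted-model
recovery is exact; the fits are deterministic.

PCA is mean-centered with components ordered by decreasing eigenvalue and
a deterministic sign convention (largest-magnitude loading positive).
`n_pc` defaults to 12 of a possible 23: ample for smooth reflectance sets
while keeping the score regression over-determined. Reconstruction adds
the mean spectrum back and clips to [0, 1] only at materialization, so
diagnostics can see raw residuals.

The calibration error number pools the RMS over all $3n$ scalar XYZ
components; spectral errors are per-patch RMS over wavelengths.

## The synthetic study conditions

The fixture module generates every input the pipeline needs, emulating a
checker-based endoscope calibration at desk scale:

* **Checker reflectances.** Chromatic patches are random non-negative
  combinations of a *fixed* three-element dictionary: the neutral
  (spectrally flat) axis plus two Gaussian atoms centered exactly on the
  hemoglobin Soret (415 nm) and Q (540 nm) bands with
  $\sigma = 22$ nm. Patches 19--24 are the flat gray ramp
  {0.03, 0.09, 0.19, 0.36, 0.59, 0.90}. Two deliberate design properties:
  the dictionary is *rank three*, matching the three degrees of freedom a
  tristimulus camera can observe -- measured reflectance collections are
  themselves famously low-dimensional, and a rank-3 family is the regime
  in which RGB-to-spectrum recovery is well posed rather than metameric
  guesswork; and its chromatic variation lies *in the hemoglobin bands*,
  where endoscopic scenes actually vary, so reconstruction trained on the
  checker preserves exactly the spectral structure narrow-band rendering
  amplifies. Like the pigments of a physical calibration target, the atoms
  do not vary with the seed; only mixing amplitudes (and any noise) do.
  Setting `n_gaussians > 2` appends random red-region atoms, producing
  deliberately metameric families for stress tests.
* **WLI lamp.** A smooth broadband curve (thermal-style envelope plus a
  blue pump) whose weights are chosen so the lamp's chromaticity sits on
  the D65 white point -- i.e., a white-balanced camera. This keeps neutral
  patches on the white axis and inside the sRGB gamut. Patch amplitudes
  are additionally desaturated analytically so no synthetic patch ever
  clips in the simulated camera: clipping would silently break the linear
  imaging model the recovery tests verify.
* **Camera.** XYZ integration, optional planted 3x3 distortion, sRGB
  encoding, 8-bit quantization. Quantization is the only noise in the
  "noiseless" setting and bounds achievable recovery (about 0.4% per
  channel), which is why end-to-end patch reconstruction is tested at
  RMSE < 0.02 rather than machine precision.
* **NBI targets.** Rendered from a planted band model, so the optimization
  objective is exactly zero at the truth.
* **Lesion phantom.** A flat background reflectance (0.55) and a central
  disk whose reflectance is multiplied by Lorentzian absorption dips at
  415 nm (depth 0.70, HWHM 15 nm) and 540 nm (depth 0.55, HWHM 12 nm),
  spanning roughly 400--430 and 530--550 nm -- hemoglobin-like absorption
  of vascularized tissue.

What the fixtures do *not* emulate: sensor noise beyond quantization,
optical vignetting and specular highlights, the texture of real mucosa,
and metamerism beyond what `n_gaussians` introduces. Passing tests
therefore demonstrate that the algorithmic chain is correct and
well-conditioned under its stated model, not that any particular clinical
image will reconstruct to a given accuracy.

## The default band model

The default Lorentzian set is dominated by the 415 nm band (amplitude 1,
HWHM 5 nm), with 540 nm secondary (0.25, HWHM 6 nm), and weak 480/600/700/
780 nm bands (amplitudes 0.02--0.10) carrying the brown tones seen in
reference NBI captures. Two physical points drove these defaults. First,
capillary contrast in NBI comes primarily from the Soret band, so the blue
channel dominates. Second, a Lorentzian's tails are heavy: half its energy
lies beyond one HWHM from center, so a nominally narrow Lorentzian behaves
like a considerably wider boxy filter. Narrow nominal widths are what make
band-selective sampling of absorption dips meaningfully different from
broadband integration -- with wide Lorentzians the tails integrate so much
out-of-band light that re-illumination cannot amplify the 415/540 contrast
that distinguishes NBI from WLI. The defaults also serve as the planted
truth for the self-consistency fixtures.

## Optimization

Generalized simulated annealing with the standard shape parameters
(visiting 2.62, acceptance -5.0, initial temperature 5230): Tsallis
visiting steps (a temperature-scaled Gaussian divided by a power of a
second Gaussian's magnitude, giving Cauchy-Lorentz-like heavy tails),
generalized Metropolis acceptance, temperature
$t(i) = t_0 (2^{q_v-1}-1)/((1+i)^{q_v-1}-1)$, and candidates folded back
into the box. Bounded L-BFGS-B polishes (a) the start point, (b) each
chain point that improves the best raw value by at least 20% (distinct
basins each get a shot at the optimum), (c) the current chain point every
fifth outer iteration (sampling basins the cooled chain wanders through),
and (d) the final best. All randomness flows from one seed through R's
RNG, so identical seeds give bitwise-identical traces; the returned
objective never exceeds the initial one, and the reported value is
recomputed through the reference objective implementation.

Search bounds are anchored at the *nominal* band centers (default
{415, 480, 540, 600, 700, 780} nm, window +/-15 nm), with HWHM in
[1, 60] nm and amplitudes in [0, 1]; the first amplitude is pinned at 1
because of the scale invariance noted above. Since the six windows are
disjoint, band identities cannot permute, which keeps the landscape free
of symmetry-induced equivalent optima.

Problem sizes in the shipped tests and acceptance script: 150 outer
iterations (about $150 \times 34$ chain evaluations plus polish) for the
hidden six-band recovery, 40 for the width/amplitude-only recovery, which
complete in seconds to a couple of minutes on one core. These budgets were
chosen as comfortable multiples of what the recovery properties need.

## Numerical choices and degenerate inputs

* Monomials on XYZ/100; QR solves; no ridge unless configured.
* PCA on an all-identical patch set raises a degenerate-variance error;
  an all-zero SPD or one orthogonal to $\bar y$ raises a
  degenerate-illuminant error; out-of-range `n_pc`, mismatched grids,
  non-finite inputs, missing patch ids and malformed CSV schemas all fail
  fast with named messages.
* Reconstruction clipping to [0, 1] cannot hurt accuracy against any
  target inside [0, 1] (projection onto the feasible interval), and the
  suite asserts this.
* 8-bit image writing rounds to multiples of 1/255; converted images are
  quantized the same way, so CLI reruns are byte-identical.

## Known limitations

* Reconstruction from three channels is only as good as the training
  family; spectra outside the checker's span reconstruct to metamers with
  smoothed spectral detail. This is intrinsic to RGB-based spectral
  super-resolution, not an implementation limit.
* No chromatic adaptation: all Lab values use D65, appropriate for sRGB
  pipelines but not for comparing across differently balanced devices.
* The analytic observer approximation is not a metrological substitute
  for the tabulated CMFs when absolute XYZ accuracy matters.
* The simulated NBI look depends on the band model fitted to reference
  targets; no additional tone post-processing is applied.
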
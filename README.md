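# savehsi

Simulated narrow-band imaging (NBI) from white-light endoscopy (WLI)
images, via calibrated RGB-to-hyperspectral reconstruction and
band-selective re-illumination.

NBI hardware illuminates mucosa near 415 nm and 540 nm — the hemoglobin
absorption peaks — so vasculature darkens and lesions gain contrast.
`savehsi` reproduces that effect computationally from ordinary 8-bit sRGB
frames:

1. **Camera correction.** Over a 24-patch color checker, camera XYZ
   (sRGB-decoded) is regressed on spectrometer-derived XYZ through an
   11-term second-order variable expansion
   `V(X,Y,Z) = (1, X, Y, Z, XY, XZ, YZ, X², Y², Z², XYZ)`, giving the
   correction matrix `C`: `XYZ_corrected = C · V(XYZ_camera)`.
2. **Spectral reconstruction.** A mean-centered PCA basis of the checker
   reflectances plus a conversion matrix `M` (least squares of PC scores
   on `V(XYZ_corrected)`) turn every pixel into an analog reflectance
   spectrum on a 380–780 nm grid at 1 nm:
   `R(λ) = μ(λ) + Σ_k [M·V]_k φ_k(λ)`, clipped to [0, 1].
3. **NBI simulation.** The narrow-band lamp is modeled as a sum of
   Lorentzian bands `a·γ²/((λ−λ₀)²+γ²)` centered near
   {415, 480, 540, 600, 700, 780} nm. Band centers, widths and amplitudes
   are fitted by seeded generalized simulated annealing to minimize the
   mean CIEDE2000 difference between the 24 patches rendered under the
   model and reference NBI patch colors. Re-illuminating the reconstructed
   spectra under the fitted lamp and encoding to sRGB yields the simulated
   NBI image.

A synthetic-fixture module (checker reflectances, broadband lamp, planted
NBI targets, checker mosaic, lesion phantom) makes the entire pipeline
runnable and testable with no clinical or spectrometer data.

## Worked example

```r
library(savehsi)

# Synthetic study conditions: checker + lamp + simulated 8-bit camera
fx    <- fixture_config(seed = 1)
refl  <- generate_checker_reflectances(fx)       # 24 x 401 reflectances
illum <- generate_wli_illuminant(fx$grid)
rgb   <- render_camera_rgb(refl, illum, config = fx)

# Stage 1-2: calibrate, then reconstruct the patch spectra
camera_xyz   <- srgb_to_xyz(srgb_decode(rgb / 255))
spectrum_xyz <- spectrum_to_xyz(refl, illum, cie1931_cmf(fx$grid))
correction   <- fit_correction(camera_xyz, spectrum_xyz)
corrected    <- apply_correction(correction, camera_xyz)
basis <- fit_pca(refl, n_pc = 12, grid = fx$grid)
conv  <- fit_conversion_matrix(project_scores(basis, refl), corrected)
rec   <- reconstruct_spectrum(basis, conv, corrected)

calibration_rmse(corrected, spectrum_xyz)   # 0.0860 (XYZ, 0-100 scale)
mean(sqrt(rowMeans((rec - refl)^2)))        # 0.00095 (reflectance units)

# Stage 3: recover a hidden band model from its rendered patch colors
targets <- generate_nbi_targets(refl, band_model())
set.seed(99)
init <- band_model(Map(lorentzian_band, default_nbi_band_centers(),
                       runif(6, 1, 60), c(1, runif(5, 0, 1))))
fit <- optimize_band_model(refl, targets, init = init,
                           config = optimization_config(seed = 7,
                                                        max_iterations = 60))
fit$initial_objective                       # 9.48  (mean dE2000 at start)
fit$objective                               # 0.084 (mean dE2000 after fit)

# Convert the lesion phantom and measure the contrast gain
ph <- generate_lesion_phantom(fx)
save_img <- convert_wli_to_save(ph$image, correction, basis, conv,
                                band_model())
```

The calibration error (about 0.09 XYZ units) is dominated by 8-bit
quantization; patch spectra reconstruct to well under 0.01 RMSE because
the fixture family is within the camera's observable span. The annealer
drives the band-matching objective from ~9.5 dE2000 at a random start to
~0.08, i.e. the hidden lamp is recovered to well below a perceptible
color difference. On the phantom, the lesion/background CIEDE2000
difference rises from 11.2 (WLI) to about 13.8 (simulated NBI) — the
band-selective re-illumination amplifies hemoglobin contrast.

A command-line front-end wrapping the same functions ships at
`inst/cli/savehsi` (subcommands `simulate`, `calibrate`, `fit-bands`,
`convert`; YAML config).

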
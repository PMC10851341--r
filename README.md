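# slscbf — short-lag spatial coherence beamforming for breast ultrasound

`slscbf` implements coherence-based ultrasound beamforming and the
reader-independent metrics used to distinguish **fluid** from **solid**
breast masses.  Hypoechoic fluid masses (simple and complicated cysts) and
solid masses can look alike in amplitude (B-mode) images, which drives
unnecessary biopsies.  They differ physically in the *spatial coherence* of
their echoes across the receive aperture: diffuse solid tissue produces
coherent backscatter (the van Cittert–Zernike triangle `1 − m/N` over
element lag `m`), while fluid interiors return mostly incoherent clutter.
Imaging that coherence makes fluid masses conspicuously dark.

The package is aimed at ultrasound beamforming researchers and provides:

* **Image formation** from time-delayed RF channel data (axial sample ×
  receive element × scan line): delay-and-sum B-mode (Hilbert envelope, log
  compression, 60-dB display) and four coherence beamformers —
  - **SLSC**: per-pixel sum of the normalized spatial-coherence function
    `R̂(m) = 1/(N−m) Σᵢ corr(sᵢ, sᵢ₊ₘ)` over short lags `m ≤ M = ⌈0.10 N⌉`;
  - **M-SLSC**: lags up to `⌈0.30 N⌉` with linearly decreasing weights
    `1 − (m−1)/M`;
  - **r-SLSC / R-SLSC**: robust-PCA denoising of the pixels-by-lags matrix
    (inexact augmented Lagrangian solver, sparsity weight `λ = 1`), without /
    with the lag weighting.
* **Pulse-inversion harmonic imaging**: fundamental frames are the
  normal-pulse echoes; harmonic frames are the normal + inverted sum, which
  cancels linear echoes and isolates even-order content.  Every beamformer
  runs on both bands (10 imaging modes total).
* **Metrics and classification**: contrast `20 log₁₀(μ_mass/μ_tissue)`,
  contrast difference (B-mode − coherence; positive ⇒ fluid), mean lag-one
  coherence (LOC) inside the mass, and the generalized contrast-to-noise
  ratio `gCNR = 1 − Σ min(h_mass, h_tissue)` with Wand's plug-in histogram
  bin count — classified against the fixed published thresholds 0.28 (LOC),
  0 dB (contrast difference) and 0.73 (gCNR), with sensitivity/specificity
  summaries.
* **A synthetic channel-data simulator** (point scatterers, focused sinc
  transmit beam, dynamic receive focusing, controllable mass echogenicity
  and internal coherence, pulse-inversion pairs with a depth-dependent
  even-order component) plus labelled cohort generation standing in for
  undeposited in vivo data.

## Worked example

Simulate a complicated cyst (hypoechoic, internally incoherent), beamform
both ways and classify:

```r
library(slscbf)

geom  <- acq_geometry(n_scan_lines = 48L, focal_depth = 11)
scene <- scene_config(mass_kind = "complicated_cyst",
                      mass_center = c(11, -0.8), mass_semi_axes = c(1.2, 0.9),
                      echogenicity_contrast = -18, internal_coherence = 0.1,
                      depth_extent_mm = 15, seed = 42)
pair  <- simulate_pulse_pair(NULL, scene, geom)

fund  <- make_fundamental(pair)
bmode <- envelope_detect(das_beamform(fund))
slsc  <- slsc_image(coherence_stack(fund, M = select_M(geom, 0.10)))

mass   <- ellipse_roi(c(11, -0.8), c(0.85, 0.65), role = "mass")
tissue <- ellipse_roi(c(11,  1.2), c(0.85, 0.65), role = "tissue")

contrast(bmode, mass, tissue)                      # -18.9 dB
contrast(slsc,  mass, tissue)                      # -32.0 dB
contrast_difference(bmode, slsc, mass, tissue)     # +13.1 dB
mean_loc(lag_one_coherence_map(fund), mass)        #  0.025
gcnr(slsc, mass, tissue)                           #  1.000 (26 bins)
```

The mass is 13 dB darker in SLSC than in B-mode (positive contrast
difference), its interior is incoherent (mean LOC 0.025 « 0.28) and its
SLSC pixel histogram is disjoint from tissue (gCNR 1.0 > 0.73) — all three
metrics classify it as fluid:

```r
classify_mass(list(mean_loc = 0.025, contrast_difference = 13.1, gcnr = 1.0))
#>            mean_loc contrast_difference                gcnr
#>             "fluid"             "fluid"             "fluid"
```

A full cohort comparison (all modes, both bands, confusion tables as CSV):

```r
cohort <- make_cohort(n_fluid = 7, n_solid = 28, seed = 1)
report <- run_comparison(run_config(cohort = cohort, output_dir = "out"))
report$confusion
```

On the default synthetic cohort, fundamental-band SLSC gCNR at the 0.73
threshold separates all 7 fluid from all 28 solid masses (sensitivity 1,
specificity 1); contrast differences are positive for every fluid mass
(+6.7 to +13.5 dB) and negative for every solid mass (−22 to −14 dB).

A command-line interface wraps the same pipeline:

```sh
Rscript -e 'slscbf::slscbf_cli()' report --config config.json --out results/
```

## Documentation

`vignettes/coherence-beamforming.Rmd` describes the estimators, the RPCA
solver, the simulator's physical model and its stated parameter choices,
known estimator biases, and what the synthetic tests do and do not
establish.
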
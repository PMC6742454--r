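# hemcyto

Quantitative imaging cytometry at very low magnification ("cell
astronomy"): at ~3 µm per pixel a single camera frame holds tens of
thousands of fluorescently labeled cells, but each cell maps to a bright
spot of only 3–4 pixels. `hemcyto` recovers, per cell, the two quantities a
flow cytometer would report — integrated fluorescence and physical
diameter — and resolves small cell clusters, so that scatter plots of
fluorescence against diameter separate cell populations (e.g. lymphocytes,
monocytes and granulocytes by CD45 staining) the way forward-scatter
plots do.

The pipeline is aimed at researchers building or evaluating low-cost,
high-throughput image cytometers, and at anyone needing careful photometry
of under-resolved spots on a noisy background.

## The method

1. **Spot detection.** Every 15×15 window is min–max normalized and scored
   by a two-class linear discriminant (shared, ridge-regularized
   covariance); thresholding the posterior map at a cross-validated cut
   (largest cut with CV true-positive rate ≥ 99%) and taking 8-connected
   components yields detection events.
2. **Heterogeneous EM.** Each event patch is fitted with a mixture of N
   bivariate Gaussians (one per cell) plus one *uniform* component for the
   local background. Responsibilities are computed once per pixel and every
   pixel enters the M-step weighted by its intensity I(x), maximizing
   L = Σₓ I(x) log( Σ_c π_c f_c(x) ).
3. **Measurement.** Fluorescence_c = Σₓ z_c(x) I(x) (the cell's share of
   patch intensity; attribution is exactly conservative), and
   diameter = pixel_size · 2√(2 ln 2) · |Σ_c|^(1/4) — the FWHM of the
   fitted Gaussian in physical units.
4. **Cluster refinement.** The widest Gaussian is split at
   μ ± √λ_max · v_max (leading eigenpair), the patch refitted, and the
   split kept only when the BIC (k ln Σ I − 2L, k = 6N) drops by more than
   a threshold and all components pass covariance QC. The recursion is
   deterministic — it uses image information only.

A seeded simulator (`render_field()`, `bead_series()`, `cluster_field()`,
`spot_field()`) renders pixel-integrated Gaussian spots with ground truth,
emulating the target regime (3 µm/px, 7.5 µm beads, SNR tiers 7.8 / 23.5 /
102), so the whole pipeline is testable offline.

## Worked example

```r
library(hemcyto)

# train + calibrate the detector on simulated labeled patches
train    <- simulated_training_set(n_images = 6, seed = 5)
detector <- train_detector(train$spots, train$background)
detector$threshold <- calibrate_threshold(train$spots, train$background)$threshold

# simulate a field of 12 spots (1000 photons each, SNR 25) and run everything
field  <- spot_field(12, image_size = c(128, 128), snr = 25, seed = 11)
events <- run_pipeline(field$image, detector)
dplyr::select(events, event_id, row, col, fluorescence, diameter_um, qc_status)
#> # A tibble: 12 × 6
#>   event_id   row   col fluorescence diameter_um qc_status
#>      <int> <dbl> <dbl>        <dbl>       <dbl> <chr>
#> 1        1  67.2  15.4        1031.        7.79 valid
#> 2        2 114.   19.4        1022.        8.04 valid
#> 3        3  14.1  25.0         995.        8.14 valid
#> 4        4  50.1  34.2        1051.        7.81 valid
#> 5        5  20.8  43.9         973.        7.60 valid
#> # ...
```

All 12 simulated spots are recovered; fluorescences cluster around the
true 1000 photons (the spread is Poisson noise plus background
attribution) and diameters around 7.8 µm — the true 7.5 µm bead size plus
the ~3.5% pixel-footprint bias discussed in the vignette. `autoplot(events)`
draws the cytometry-style fluorescence-vs-diameter scatter;
`write_event_table()` / `read_event_table()` round-trip the table
losslessly.

The calibration worked example reproduces the linearity of recovered bead
fluorescence against the manufacturer MESF reference values:

```r
bead_linearity_check(c(372.3, 1197.4, 4851.3),
                     mesf_bead_reference()$reference_mesf)
#> [1] 0.9998
```

A thin command-line front-end lives at `inst/scripts/hem`
(`hem run | simulate | train-detector | detect | check-linearity`).

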
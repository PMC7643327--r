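# pvq — vascular pulsatility and perivascular clearance quantification

`pvq` is an R package for quantifying how cerebral amyloid angiopathy (CAA)
and aging reshape vascular pulsation and perivascular clearance in the mouse
brain. It is aimed at labs doing in vivo two-photon line-scan imaging of
cortical vessels and ex vivo fluorescence imaging of tracer-injected brain
slices, who need the image-to-number steps of that workflow as tested,
scriptable functions rather than ad hoc ImageJ/MATLAB sessions.

The package covers four stages, each usable on its own:

1. **Vascular pulsatility from kymographs.** A line scan orthogonal to a
   vessel yields a space×time kymograph; `pvq` extracts the diameter trace
   D(t) by half-maximum wall detection with sub-pixel interpolation, forms
   the moving-average baseline d(t), and computes per 3000-ms epoch

   - pulsatility index = ∫₀³⁰⁰⁰ |D(t) − d(t)| dt  (µm·ms),
   - relative pulsatility index = ∫₀³⁰⁰⁰ |D(t) − d(t)| / mean(D) dt  (ms),

   where mean(D) is the static mean diameter of the record. The absolute
   index measures wall movement independent of vessel size; the relative
   index expresses it per unit caliber.
2. **Immunofluorescence coverage metrics.** Vessel-wall masks from merged
   SMA/MX04 channels; per-channel coverage percentages (smooth-muscle loss
   vs vascular amyloid); collagen-IV vascular density in a fixed
   0.4 mm × 0.4 mm ROI; parenchymal plaque burden
   (thresholded MX04 pixels / region size × 100); sub-pixel line intensity
   profiles.
3. **Clearance mapping.** Counts of tracer-positive periarterial drainage
   arteries (SMA ∧ tracer colocalization over connected components),
   whole-slice background-subtracted CSF-influx signal, counts of
   penetrating vessels perpendicular to the cortex, dorsal/lateral/ventral
   partition of the cortical band, and linearization of the band along
   arclength from the dorsal midline.
4. **Statistics.** OLS regression of influx on amyloid burden (broom-style
   `tidy()`/`glance()`), and per-group mean ± SEM tables ready for external
   ANOVA.

Because the microscopy datasets such studies produce are rarely deposited,
`pvq` ships a first-class synthetic-data module (`make_kymograph()`,
`make_slice_image()`, `make_cortical_slice()`, `make_regional_dataset()`)
that renders all of these inputs with known ground truth, so every stage is
verifiable end to end without any download.

## Worked example

Simulate a pulsating surface artery (12 µm baseline, 0.8 µm pulse at 7 Hz,
mild noise), extract its diameter trace and indices, then fit the
burden–influx regression on a synthetic regional cohort:

```r
library(pvq)

sim <- make_kymograph(
  kymograph_spec(baseline_diameter_um = 12, pulse_amplitude_um = 0.8,
                 pulse_frequency_hz = 7, duration_ms = 6000,
                 noise = list(type = "gaussian", sigma = 0.03), seed = 42),
  vessel_id = "sa1", vessel_type = "surface_artery")

trace <- extract_diameter_trace(sim$kymograph) |>
  moving_average_baseline(window_ms = 500)
pulsatility(trace)
#> # A tibble: 1 × 6
#>   pulsatility_index relative_pulsatility_index mean_diameter_um n_epochs window_ms edge_policy
#> 1             1640.                       137.             12.0        2       500 hold

tbl <- make_regional_dataset(regional_gradient_spec(seed = 42))
fit <- burden_influx_regression(tbl, influx = "influx_3k")
glance(fit)
#> # A tibble: 1 × 8
#>   slope intercept slope_se r_squared     p_value residual_sd     n slope_sign
#> 1 -5.65      34.0    0.730     0.759 0.000000273        4.32    21         -1
```

The pulsatility row says: over two complete 3000-ms epochs this vessel's
wall swept an absolute area of ≈1640 µm·ms between its diameter curve and
the 500-ms moving-average baseline — ≈137 ms after normalizing by its 12 µm
mean diameter. The regression row shows the expected negative association
between regional amyloid burden and 3-kDa tracer influx (slope −5.65 a.u.
per % burden, R² = 0.76 over 7 slices × 3 regions): influx is lowest where
plaque burden is highest.

`autoplot(trace)` and `autoplot(fit)` draw the diameter trace with its
baseline and the regression scatter with fitted line;
`run_demo(out_dir, seed)` executes the full simulate → quantify → map →
regress chain and writes per-stage CSVs plus a hash manifest.

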
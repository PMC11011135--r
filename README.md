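# flexbeam

Aligned Peak Response (APR) beamforming for flexible ultrasound array
transducers, in R.

## The problem

Flexible array transducers conform to the patient's body — attractive for
ultrasound-guided radiotherapy, where a wearable probe could track
abdominal tumour motion during treatment without a robotic arm pressing a
rigid probe into the skin. But a conformable probe has an unknown, changing
element geometry, so a conventional delay-and-sum (DAS) beamformer cannot
compute the time-of-flight (ToF) delays it needs, and the B-mode image
falls apart.

The APR method recovers usable beamforming delays **without any shape
sensing**. An *assistant structure* — a gel standoff with embedded
hyperechoic markers — is placed between probe and skin. Each marker
returns a strong peak echo on every channel; aligning the *peak response*
sample of those echoes across scanlines (and, for recorded data, across
receive elements) yields the delay curve directly:

```
d = (t_b − t_a) · fs        # delay in samples between scanlines a and b
```

Applying the delays, summing across the element dimension,
envelope-detecting and log-compressing reconstructs the image. The package
implements the full desk-scale workflow:

* `array_geometry()`, `tof()` — flat / circular-arc / polyline apertures
  and exact two-way times of flight;
* `simulate_rf()`, `marker_phantom()`, `curve_rf()` — a time-of-flight RF
  channel-data simulator (one transmit element per scanline, 128 receive
  elements) and an artificial-curvature transform that re-delays
  flat-acquisition data to mimic a deformed probe;
* `normalize_global()`, `normalize_gated()`, `smooth_trace()`,
  `smooth_delay_curve()` — preprocessing that makes the marker peaks
  dominant;
* `apr()` — the central estimator: two-round APR delay fitting, returning
  a classed object with `print`/`summary`/`coef`/`plot`/`residuals`
  methods;
* `beamform_apr()`, `beamform_das()` — APR summation and the
  geometry-aware DAS reference;
* `fwhm()`, `cnr()`, `psnr()`, `location_error()`, `delay_error()` —
  image- and delay-quality metrics;
* `run_pipeline()`, `write_rf()`/`read_rf()` and a thin CLI
  (`inst/cli/flexbeam`) — end-to-end runs, containers, manifests.

## A worked example

Simulate a single point marker 17 mm under a 64-element flat aperture,
fit the APR delays, and compare them with the geometric ground truth:

```r
library(flexbeam)

geom <- array_geometry("flat", 64, 1)          # 64 elements, 1 mm pitch
rf   <- simulate_rf(phantom(0, 17), geom, gauss_pulse())
fit  <- apr(rf, reference = "strongest")
fit
#> Aligned Peak Response delay fit
#>   mode: simulation   reference scanline: 32   scanlines: 64
#>   round-1 delays: [-976, 0] samples

orc <- oracle_delays(geom, c(0, 17), rf$fs,
                     reference = fit$reference_scanline)
delay_error(fit$round1, orc$round1)
#> $total
#> [1] 32.08283
#>
#> $mean
#> [1] 0.5012942
```

The fitted per-scanline delay curve spans ~980 samples from the aperture
edge to the marker's nearest scanline, and deviates from the closed-form
geometric delays by **0.50 samples on average** — the peak-alignment
estimator recovers the geometry-implied delays to well under a sample,
which is what makes shape-blind beamforming work. Reconstructing and
locating the marker:

```r
img <- beamform_apr(rf, fit)
image_peak(img)
#> $x
#> [1] -0.5      # mm   (true lateral position: 0 mm, half a pitch off)
#> $z
#> [1] 17.402    # mm   (true depth: 17 mm)
#> $value
#> [1] 0         # dB   (image maximum)
```

`plot(img)` renders the B-mode image; `plot(fit)` the delay curves.

## Scope notes

* The simulator models arrival times exactly and channel amplitudes to
  first order (spherical spreading); it does not model finite-element
  impulse responses, attenuation or calibrated speckle. See the methods
  vignette (`vignettes/apr-methods.Rmd`) for the model, parameter
  rationale and validation protocol.
* APR delays are constant along depth (fixed-focus behaviour): resolution
  is best at the marker depth. Dynamic receive focusing without geometry
  is out of scope.
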
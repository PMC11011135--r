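---
title: "Aligned Peak Response beamforming: model, assumptions and validation"
author: "flexbeam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligned Peak Response beamforming: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(flexbeam)
```

## The problem

A flexible array transducer conforms to the patient's body, so the element
positions — and with them the time-of-flight (ToF) delays that a
delay-and-sum (DAS) beamformer needs — are unknown and change with
respiration. The Aligned Peak Response (APR) estimator sidesteps shape
sensing: an *assistant structure* (a gel standoff with embedded
hyperechoic markers) is placed on the skin, each marker returns a strong
"wing"-shaped echo visible on every channel, and usable beamforming delays
are read off by *aligning the peak samples* of those echoes.

With one transmit element per scanline and all elements receiving, the
peak of the echo in scanline $a$'s reference trace arrives at time $t_a$,
in scanline $b$'s at $t_b$; the delay that aligns them is

$$ d = (t_b - t_a)\, f_s \quad \text{(samples)}, $$

with $f_s$ the sampling rate. Applying these integer-sample delays to the
raw channel data, summing across the element dimension, envelope-detecting
and log-compressing yields a B-mode image without ever knowing the array
shape.

## The two-round estimator

`apr()` is the package's central fitting function. It returns a classed
object whose coefficients are the delay curves.

**Round 1 (transmit/reference delays).** For each scanline the trace
received by its own transmitting element is that scanline's reference
trace. Its envelope peak (analytic-signal magnitude, moving-average
smoothed, argmax inside the configured depth gate, ties broken toward the
earliest sample) is aligned to the reference scanline's peak:
`round1[s] = p_ref − p_s`. Positive delays shift a trace later in time.

**Delay-curve re-smoothing.** The round-1 curve is re-smoothed with a
Savitzky–Golay polynomial filter (window 21, order 2). The nominal window
of 20 scanlines is widened to the nearest odd value because a symmetric
filter requires an odd window; the order is a package choice — order 2
tracks the quadratic-looking ToF difference curves of curved apertures
without chasing single-scanline outliers.

**Round 2.** Two protocols are provided because clean simulated data and
recorded data need different second rounds:

* `mode = "simulation"`: the smoothed round-1 delays are applied and the
  scanline reference traces are aligned once more; the residual is folded
  back into the per-scanline curve. The per-element matrix stays zero.
  For noise-free data this makes the total curve exact again regardless of
  the smoothing (the smoothing matters only when noise perturbs single
  peaks).
* `mode = "experimental"`: after round 1, every receive element's trace is
  aligned to the transmitting element's trace *within* each scanline,
  giving per-(scanline, element) receive delays. Element-to-element delay
  increments larger than a threshold (default 5 samples) are clamped,
  walking outward from the transmit element, which suppresses isolated
  misdetections caused by clutter and noise.

Totals are always `total[s, e] = round1[s] + round2[s, e]`, and the
structural invariants — `round1[reference] = 0`, `round2[s, tx(s)] = 0` —
hold in both modes.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `gate` | whole trace (simulation); 9–24 mm (experimental protocol) | mm | restricts peak search to the marker band. Recorded data needs the gate because deeper anatomy can out-shine the markers after normalization; in a clean single-marker simulation the whole trace is the correct gate, since on a 128 mm aperture the edge elements receive the 17 mm marker echo at a pulse-echo depth far beyond 24 mm. |
| `reference` | `"first"` | — | which scanline anchors the alignment. `"strongest"` (used by the pipeline preset and the worked examples) anchors the aligned image at the marker's true depth for the scanline nearest the marker; anchoring to an edge scanline is equally valid for delay estimation but places the aligned band at that scanline's apparent depth. |
| `threshold` | 5 | samples | round-2 increment clamp. Appropriate when each element's nearest marker is close (markers distributed across the aperture). For a *single* centre marker on a 128 mm aperture at 40 MHz the true geometric increments reach ~26 samples/element near the edges, so the clamp must be relaxed (`Inf`) when validating against geometry in that configuration. |
| `smooth_window` | 9 | samples | moving average on the envelope before the argmax; tempers sample-level noise without displacing a symmetric peak. |
| `sg_window`, `sg_order` | 21, 2 | scanlines, — | delay-curve re-smoothing (above). |

## The simulator

`simulate_rf()` is a time-of-flight scatterer simulator: for every
(scanline, element, scatterer) triple it adds a Gaussian-modulated cosine
(centre frequency 5 MHz, −6 dB fractional bandwidth 0.6, $f_s$ = 40 MHz by
default) centred at the exact two-way ToF, weighted by
$a_k / (r_\mathrm{tx} r_\mathrm{rx})$ spherical spreading, with optional
cosine element directivity and optional seeded white Gaussian noise. The
probe defaults (128 elements, 1 mm pitch, 1540 m/s) reproduce a 128
mm-wide flexible aperture.

What it emulates well: arrival times (exact), relative channel amplitudes
(first order), the weak-edge-response failure mode of wide apertures, and
arbitrary flat/arc/polyline geometries. What it does **not** model:
spatial impulse responses of finite elements, elevation focusing,
frequency-dependent attenuation, nonlinear propagation, or calibrated
speckle statistics. Passing tests therefore demonstrate the estimator's
geometric correctness and its noise response, not clinical image quality.

`curve_rf()` re-delays flat-acquisition data to mimic a deformed probe:
for each channel and each depth sample it applies the shift
$\Delta t = \mathrm{ToF}_\mathrm{curved} - \mathrm{ToF}_\mathrm{flat}$ of
the on-axis focal point whose *curved* ToF equals the output sample time.
That anchoring makes the construction exactly invertible by a
curved-geometry DAS on the scanline axes, which is how it is validated.

## Beamformers

`beamform_apr()` applies the fitted integer delays, sums across elements,
envelope-detects and log-compresses to a [−60, 0] dB image (one column per
scanline, one row per RF sample depth, no scan conversion — APR has no
geometry to scan-convert with). The delays are constant along depth, so
the summation behaves like *fixed-focus* beamforming: resolution is best
at the marker depth and degrades away from it. No apodization and no
aperture growth are applied, matching the single-element-transmit
protocol.

`beamform_das()` is the geometry-aware reference: exact two-way ToF per
focal point, dynamic receive focusing by default (fixed-focus available
for like-for-like comparisons with APR summation).

### Numerical choices

* **Envelope**: FFT analytic-signal magnitude (no installed R package
  provides one); verified against the closed-form envelope of a
  Gaussian-modulated sinusoid to <2%.
* **Resampling**: channel traces are resampled with cubic splines in both
  `curve_rf()` and dynamic-focus `beamform_das()`. At 8 samples per
  carrier period, linear interpolation leaves percent-level amplitude
  ripple that compounds over two resampling passes and shows up as
  multi-dB deviations at near-cancellation pixels; cubic resampling keeps
  the flat-vs-curved round trip below ~0.3 dB everywhere in the top 40 dB.
  Linear and nearest-sample modes remain available (nearest reproduces
  integer-delay constructions exactly).
* **Ties and degenerate inputs**: envelope argmax ties break toward the
  earliest sample; all-zero gated segments raise a typed no-peak
  condition — the estimator substitutes the nearest valid neighbour's
  delay (and counts it), a dead *reference* trace is fatal; all-zero
  images cannot be normalized to 0 dB and are rejected.
* **Integer delays**: delays are whole samples by definition of the
  estimator; sub-sample refinement is out of scope.

## Metrics

`fwhm()` interpolates half-maximum crossings of the envelope profile
through a point target's peak. `cnr()` uses
$20\log_{10}(|\mu_\mathrm{out}-\mu_\mathrm{in}| /
\sqrt{\sigma_\mathrm{out}^2+\sigma_\mathrm{in}^2})$; the absolute value
keeps the metric real-valued whichever region is brighter (printed CNRs of
bright targets are negative magnitudes; the sign convention is a
documentation matter, not an algebraic one). `psnr()` uses the standard
peak²/MSE definition over dB-domain pixels with the 60 dB dynamic-range
span as peak — the exact definition used for the printed experimental
values is not recorded, so this is a documented package assumption.
`delay_error()` sums per-scanline absolute deviations (a squared-deviation
mode is provided as an alternative reading of "variances") and divides by
the number of scanlines for the mean.

## Validation protocol and problem sizes

The test suite validates, at the reference configuration (flat
128-element, 1 mm pitch, 40 MHz, noise-free):

* recovery of the three stock point phantoms' printed positions (centre
  (0, 30) mm; two points (±30, 30) mm; right point (30, 30) mm) by the
  full pipeline, to ±1 mm axially and ±1.5 mm laterally;
* agreement of the fitted per-scanline delays with the closed-form
  geometric ToF delays for a single 17 mm-deep centre marker on flat,
  R = 700 mm and R = 500 mm arcs, to ≤2 samples mean absolute error over
  all 128 scanlines;
* the artificial-curvature round trip (flat DAS vs curve-then-curved-DAS)
  to <1 dB everywhere in the top 40 dB;
* closed-form metric values (Gaussian FWHM, dB mappings, CNR and
  delay-error arithmetic);
* monotone degradation of the median delay error (10 seeds per level)
  under increasing additive noise — run at a 64-element half aperture,
  which preserves the full range of echo strengths across the aperture
  while keeping the 50 refits quick. Unit tests use 8–48 element
  apertures for speed; nothing in the estimator depends on the element
  count.

The noise ladder (0, 0.02, 0.05, 0.1, 0.25 of the peak sample) was chosen
to span from negligible relative to the weakest marker echo (the edge
element's, ~0.27 of the peak at this aperture) to comparable with it,
where peak misdetection must set in.

## A worked fit

```{r example}
geom <- array_geometry("flat", 64, 1)
rf <- simulate_rf(phantom(0, 17), geom, gauss_pulse())
fit <- apr(rf, reference = "strongest")
summary(fit)
orc <- oracle_delays(geom, c(0, 17), rf$fs,
                     reference = fit$reference_scanline)
delay_error(fit$round1, orc$round1)
```

```{r plot, fig.alt = "Round-1 APR delay curve"}
plot(fit)
```

## Known limitations

* Fixed-focus behaviour: APR delays are exact at the marker depth only;
  targets away from it defocus (the motivation for the reference DAS
  comparison).
* A single marker cannot serve a full 128 mm aperture in noisy data: edge
  echoes are weak (spherical spreading) and are the first to be lost —
  the monotone-degradation suite measures exactly this.
* The round-2 threshold presumes marker-to-element increments within a few
  samples; it is a clutter guard, not a geometry prior.
* The simulator's simplifications (above) mean image-quality metrics on
  simulated data are not comparable to values measured on recorded
  phantom data.
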
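---
title: "Methods: epicardial electrogram mapping with epimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epicardial electrogram mapping with epimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimap)
```

## Scope and data model

`epimap` analyses multichannel *unipolar epicardial electrograms*:
voltage traces $V_c(t)$ recorded simultaneously by a high-density
flexible electrode array in contact with the heart's outer surface.
The package covers the full mapping chain — conditioning, far-field
removal, channel quality control, activation detection, isochrone and
conduction-velocity (CV) mapping, dominant-frequency (DF) analysis of
fibrillatory rhythms — plus discrete Gaussian-curvature analysis of the
3-D printed epicardial shell geometries such arrays are mounted on.

Because raw in vivo recordings of this kind are not publicly
deposited, the package pairs the analysis chain with a *synthetic
recording generator* whose ground truth is exact.  Every analysis
stage is validated by parameter recovery against that generator.

Units are fixed package-wide: mm (space), ms (time), mV (voltage),
Hz (frequency), m/s (velocity); conveniently, 1 mm/ms = 1 m/s.

## The geodesic wavefront model

The generator does not solve tissue electrophysiology.  The observed
epicardial activation patterns that matter here — plane-wave sinus
spread, retrograde spread from a bipolar pacing site, detour around a
non-conducting ablation lesion, delayed activation in an ischemic slow
zone, ectopic focal (PVC-like) beats — are all *arrival-time*
phenomena.  They are reproduced by a shortest-path (Dijkstra) model on
the electrode adjacency graph: the activation time of channel $c$ is

$$T(c) \;=\; \min_{s \in \text{sources}} \Big( t_s + \min_{\pi: s \to c}
  \sum_{(i,j) \in \pi} \frac{\ell_{ij}}{\mathrm{hm}(v_i, v_j)} \Big),$$

where $\ell_{ij}$ is the Euclidean edge length, $v_i$ the per-channel
conduction velocity and $\mathrm{hm}$ the harmonic mean.  The harmonic
mean makes a slow zone behave like a resistive region regardless of
traversal direction.  Lesion channels are removed from the graph
before the search; unreachable channels are flagged rather than timed.

Design notes:

* **Adjacency.** Grid arrays default to 8-neighbour connectivity with
  true Euclidean diagonal lengths; `knn` and `radius` modes serve
  non-grid layouts.  The diagonal edges keep the graph metric close to
  Euclidean: for a *point* source the octile metric overestimates
  distance by at most a factor $\sqrt{4 - 2\sqrt 2} \approx 1.082$
  (worst at 22.5° off-axis), and a property test pins arrival times
  inside that envelope.  For a *line* source (the default sinus
  scenario) the plane wave is exact, which is why the CV-recovery
  criterion is stated on the sinus fixture.
* **Oracle.** The engine is `igraph`'s Dijkstra; its independent check
  is an exhaustive simple-path enumerator run over hundreds of random
  small graphs in the test suite.

## The deflection waveform

Each activation deposits
$V(t) = -A\,u\,e^{-u^2/2}$, $u = (t - t_0)/\sigma$, a biphasic
unipolar-like deflection that is odd about $t_0$ (zero net area) and —
by construction — has its *steepest negative slope exactly at*
$t = t_0$.  An argmin-of-derivative detector therefore recovers ground
truth to the sample on noise-free fixtures, which turns activation
detection into a falsifiable recovery test rather than a circular one.
Defaults: $A = 1$ mV, $\sigma = 2$ ms (about 4 samples at 2048 Hz; the
generator refuses $\sigma$ under 2 samples).

Far-field ventricular contamination is modelled as one *shared*
template — a broad QRS-like deflection ($\sigma = 8$ ms, 2 mV)
followed by a smooth T-like hump (160 ms later, $\sigma = 35$ ms,
0.5 mV) — added to every atrial channel with a per-channel random
scale in $[0.5, 1.5]$, at a fixed 130 ms atrioventricular delay.  This
matches exactly the common-mode assumption the template-subtraction
stage relies on; adaptive or morphology-varying far field is out of
scope.

Fibrillatory (AF-like) fixtures are per-channel trains of deflections
whose inter-deflection interval is $1/\mathrm{DF}(c)$ perturbed
multiplicatively by a jitter coefficient, with amplitudes scaled down
(default 0.3) relative to sinus fixtures — low-amplitude,
high-frequency activity without any coherent wavefront.  This is a
*signal* model, not reentry physics: it gives the frequency analysis a
controllable local activation rate to recover, nothing more.

## The stated world (generator defaults)

| Parameter | Default | Why |
|---|---|---|
| array | 16 × 16, 3.5 mm spacing | 256-channel flexible array, 3–4 mm pitch |
| sample rate | 2048 Hz | acquisition hardware rate |
| sinus rate | 114 beats/min | in vivo mean sinus rate |
| baseline CV | 1.04 m/s | in vivo estimate (reported 1.04 ± 0.28 m/s) |
| AF DF field | patchy 5 / 8 Hz, jitter 0.1 | typical AF DF range; one maximal-DF border patch |
| AF amplitude scale | 0.3 | "low-amplitude" fibrillatory electrograms |
| noise | white Gaussian, RMS configurable | baseline-wander/powerline left to the band-pass |

AF amplitude and jitter are free parameters of the fixture (no
quantitative morphology is available to emulate); they are exposed in
the configuration rather than presented as measured values.

## Preprocessing

**Band-pass.** Unipolar electrograms are conditioned to 1–400 Hz.
With no DSP package available, the package designs its own digital
Butterworth sections (analog prototype → bilinear transform; verified
coefficient-for-coefficient against an independent reference
implementation during development).  The band is realised as an
order-4 high-pass at 1 Hz cascaded with an order-4 low-pass at 400 Hz,
so each *printed band edge is exactly that section's single-pass
half-power point* — a true band-transform design would meet the
composite −3 dB points only approximately.  Filtering is
forward–backward (zero phase): activation times are never
phase-shifted, at the cost of squaring the magnitude response (−6 dB
at the edges, documented in `bandpass_response()`).  Start-up
transients are handled by odd-reflection padding plus initial
conditions matched to a constant first-sample history; note the 1 Hz
high-pass still needs ~2 s of signal to settle, so amplitude
measurements should avoid the first/last half second.

**Ventricular beat detection.** No detection method is prescribed for
the reference lead, so a derivative-energy threshold (smoothed squared
derivative, peaks above 25 % of the global maximum) with a 250 ms
refractory period is used — simple, testable, and sufficient to align
template windows to within ±5 ms.  The interface deliberately accepts
either a body-surface-like reference lead or explicit beat times,
since which reference the original workflow used is not stated.

**Far-field subtraction.** Per channel, windows (default −50 to
+300 ms) around the ventricular beats are averaged into a template
that is subtracted at each beat.  Samples outside the windows are
untouched — atrial deflections between ventricular complexes are
preserved exactly.  Overlapping windows are truncated to the shortest
inter-beat interval with a warning.

**Channel QC.** Channels are classified `flatline` (RMS < 0.01 mV),
`saturated` (> 5 % of samples pinned at the channel extremes), `noisy`
(high-frequency residual RMS above 3 × the cohort median) or `good`.
These thresholds are configuration defaults, not reported values.

**Interpolation.** "Removing and interpolating" bad channels is read
as interpolating *derived scalar maps* (activation time, DF) — the
downstream maps are all that the figures need — not as resynthesising
raw traces.  Filling is inverse-distance weighting over good graph
neighbours with a k-nearest-good fallback; every filled value is a
convex combination of its contributors.

## Activation mapping

**Detection.** Activation is the extremum of the central-difference
derivative of the conditioned trace within the beat window.  The
mapping convention writes "(dV/dt)max", but for unipolar electrograms
the activation instant is conventionally the steepest *negative*
deflection; the package defaults to `steepest_negative` and offers
`steepest_absolute` for the literal reading.  On the simulator's
waveform both coincide.  Ties resolve to the earliest sample.  The
derivative is evaluated on the full trace before windowing so window
edges keep true central differences (a one-sided difference at the
edge has twice the noise variance and would bias the argmin toward the
window boundary — this was observed and fixed during development).
The original workflow's manual review step is replaced by QC validity
flags.

**Isochrones.** Total activation time — defined here as max − min over
the beat's valid channels — is divided into 15 equal segments; channel
band indices are 0–14 with the latest channel closed into band 14.
Values within rounding error of a band edge go to the upper band (an
explicit ε-guard, since equal-spaced activation times otherwise
straddle edges in floating point).  An all-equal map collapses to one
band and is flagged degenerate.  The display convention is early =
red, late = blue.

**Time-lapse frames.** Half-open intervals of fixed width (5 or 10 ms)
anchored at the map minimum; frames partition the valid channels.

**Conduction velocity.** Local least-squares plane fit
$T(x,y) = a + bx + cy$ over each channel's neighbourhood (itself + 8
grid neighbours); $\mathrm{CV} = 1/\sqrt{b^2+c^2}$, direction along
the time gradient.  Channels with collinear or too-small
neighbourhoods, or near-flat fits (CV > 20 m/s), are skipped.  The
map-level summary is the mean ± SD over estimated channels — whether
the reported in vivo CV was a whole-map mean or a path estimate is not
stated; the whole-map mean of local fits is this package's reading.

**Origin localization.** The earliest valid channel; ties go to the
candidate with the greatest mean delay to its neighbours (activation
spreads away from the truer source).

## Frequency analysis

**Envelope.** The analysis chain is rectification plus Hann-windowed
spectra.  Naively rectifying an oscillatory signal doubles its
frequency (a pitfall demonstrated in the tests), so the default is the
classical activation-envelope chain: band-pass 40–250 Hz → full-wave
rectification → 20 Hz low-pass; `rectify_only` preserves the literal
reading.

**Spectra.** Welch-averaged periodograms with a Hann window, default
2 s segments and 50 % overlap → 0.5 Hz resolution at 2048 Hz,
calibrated so band-integrated power matches time-domain variance
(Parseval check in the tests).

**DF and RI.** DF is the frequency of maximal power in the search band
(default 3–15 Hz; not stated in the source workflow, exposed as a
parameter).  The regularity index is defined here as the fraction of
search-band power within ±0.75 Hz of the DF; channels with RI < 0.2
are discarded — the 0.2 threshold is the stated rule, while the RI
formula and window are this package's (configurable) definition.  A
flat spectrum scores $1.5/12 = 0.125$ and is discarded; retention is
exactly `ri >= threshold`, so a channel at 0.2 is kept.  One empirical
caveat documented by the tests: the envelope of pure white noise has a
mildly low-weighted spectrum and the max-bin selection bias pushes its
RI toward ~0.15–0.19 with few Welch segments, so noise channels are
discarded in bulk but an occasional channel can brush the threshold on
short recordings.

## Shell curvature

Gaussian curvature of triangulated epicardial shells uses the
angle-deficit estimator
$K_v = (2\pi - \sum_i \theta_i)/A_v$ with barycentric area weights
(one third of incident face areas); boundary vertices use $\pi$ and
are flagged.  No discretisation is prescribed by the source analysis;
angle deficit was chosen because it conserves total curvature
*exactly* (discrete Gauss–Bonnet: $\sum_v K_v A_v = 2\pi\chi$
independent of triangulation), which gives the implementation a sharp
conservation test — 4π for every closed genus-0 shell, 0 for a torus.
Barycentric rather than Voronoi-mixed areas keep weights positive by
construction; the difference is a per-vertex normalisation absorbed by
the convergence tolerance (the icosphere fixture converges to $1/r^2$
with refinement).  Mesh I/O (ASCII/binary STL, OBJ, ASCII PLY) is
implemented in-package since no mesh reader is otherwise available;
binary PLY is rejected with a parse error.  Whether published
curvature colour maps are area-normalised is unknown; the package
reports both $K_v$ and $A_v$ so either convention can be displayed.

## What a green test establishes — and what it does not

The synthetic fixtures share the simulator's deflection morphology, a
single shared far-field template, and white noise.  Recovery results
therefore validate the *pipeline arithmetic* (detection, mapping, CV,
DF, subtraction, interpolation, curvature) under the stated world;
they do not establish performance on real epicardial signals with
fractionation, motion artefact, electrode drop-out patterns, varying
far-field morphology, or reentrant AF dynamics.  Hardware-level
figures (impedance, tensile properties, contact forces, in vivo CV
dispersion) are outside what any desk-scale reimplementation can
reproduce and are not claimed.

## Worked example

```{r example, eval = FALSE}
lay <- grid_layout(16, 16, 3.5)              # 256-channel array
sim <- render_recording(lay, scenario_sinus(lay), duration_s = 2,
                        noise_rms = 0.05, seed = 1)
rec <- bandpass(sim$recording)               # 1-400 Hz, zero phase
beats <- segment_beats(rec)
amap <- detect_activation(rec, unlist(beats[1, ]))
iso <- build_isochrones(amap)                # 15 equal time segments
cvm <- estimate_cv(amap, lay)
print(cvm)
localize_origin(amap, lay)$channel_id
```

The orchestrated equivalent, with provenance-stamped CSV/JSON outputs
and a manifest, is `run_pipeline(run_config(scenario = "sinus",
seed = 1, out_dir = "maps"))`; a thin command-line wrapper lives at
`inst/cli/epimap.R`.
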
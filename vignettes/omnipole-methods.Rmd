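---
title: "Omnipolar electrogram estimation from electrode cliques: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Omnipolar electrogram estimation from electrode cliques: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(omnipolar)
```

## Background

Bipolar electrograms (bEGMs) — differences of two nearby unipolar
electrograms (uEGMs) — are the workhorse of intracardiac mapping, but their
amplitude and morphology depend on the orientation of the electrode pair
relative to the activation wavefront. The omnipolar electrogram (oEGM) is a
virtual bipolar signal reconstructed along the direction of wavefront
propagation, intended to remove this orientation dependence.

On a rectangular high-density array, the oEGM is estimated per *clique*: a
2×2 cell of electrodes supplying one pair of orthogonal bEGMs. This package
implements the five clique configurations (four triangular, one
cross/diagonal), the projection-angle optimisation that defines the oEGM,
four reliability measurements, and a synthetic wavefront generator that
provides ground truth for every stage.

## Geometry and bipole construction

Electrodes are labelled by row letter (A topmost) and column number, with
x increasing along columns and y towards row A; `u_A1 − u_B1` then points
in +y. Within one cell with corner roles A1 (top-left), A2 (top-right),
B1 (bottom-left), B2 (bottom-right):

| configuration | `b_x` | `b_y` |
|---|---|---|
| `t_ll` | `u_B2 − u_B1` | `u_A1 − u_B1` |
| `t_lr` | `u_B2 − u_B1` | `u_A2 − u_B2` |
| `t_ul` | `u_A2 − u_A1` | `u_A1 − u_B1` |
| `t_ur` | `u_A2 − u_A1` | `u_A2 − u_B2` |
| `x` | diagonals `b_1 = u_A2 − u_B1`, `b_2 = u_A1 − u_B2`, rotated |

The cross configuration measures along the two diagonals, so a
counterclockwise π/4 rotation restores the Cartesian frame:

$$\mathbf{b}(t) = \begin{bmatrix} \cos\frac{\pi}{4} & -\sin\frac{\pi}{4} \\
\sin\frac{\pi}{4} & \cos\frac{\pi}{4} \end{bmatrix}
\begin{bmatrix} b_1(t) \\ b_2(t) \end{bmatrix}.$$

No amplitude renormalisation accompanies the rotation: the diagonal
baseline is √2 longer than a triangle's, which is reported as
`bipole_spacing_mm` so the spacing penalty of the cross clique is visible
in downstream tables. Larger interelectrode distances are realised by
index subsampling of one fixed grid (corners k steps apart), keeping all
overlapping cliques. Corner roles are per-cell, not global.

## The angle optimisation

The omnipole is the projection of $\mathbf{b}(t)$ that maximises the ratio
of the signed peak of the projected signal to the peak absolute value of
the orthogonal projection:

$$\theta_o = \arg\max_\theta
\frac{\max\big([\cos\theta\ -\sin\theta]\,\mathbf{b}(t)\big)}
     {\max\big|[\sin\theta\ \ \cos\theta]\,\mathbf{b}(t)\big|},
\qquad
\begin{bmatrix}\hat o(t) \\ r(t)\end{bmatrix} =
\begin{bmatrix}\cos\theta_o & -\sin\theta_o\\ \sin\theta_o & \cos\theta_o
\end{bmatrix}\mathbf{b}(t).$$

The signed numerator disambiguates the two opposite directions (a polarity
flip of the input moves the estimate by exactly π). The propagation
direction is reported as $-\theta_o$ in degrees in [0°, 360°): rotating
the frame by $\theta_o$ aligns +x with the wavefront. This mapping is a
convention of the package, validated against the generator's ground-truth
angle.

**Search.** The objective is evaluated on a coarse 1° grid over the full
circle [−π, π); every competitive local maximum of the coarse grid (value
within a factor ~3 of the best) is then scanned at 0.01° across its 2°
bracket, and the winner is polished by golden section in the remaining
0.02° bracket. Two aspects matter. First, the ratio is not unimodal: the
denominator can pass very close to zero (the residual dip), producing a
narrow spike that a golden section started on a 2° bracket would step
over — hence the fine scan. Second, there are typically *two* such spikes
(near the optimum and near its antipode, where the signed numerator may
still be positive), and a coarse sample can land arbitrarily close to one
and half a step from the other, ranking them wrongly — hence refining all
competitive coarse maxima rather than only the best. The search matches
an exhaustive 0.01° sweep to < 1e−6 relative objective on random pairs
(one of the validation checks below).

**Degenerate inputs.** The denominator is floored at 1e−9 times the peak
bipole magnitude, so an exactly proportional pair (zero residual) returns
the correct angle with a large, capped ratio and a `capped` flag instead
of dividing by zero. An identically zero pair is an error.

**Window.** All angle estimation and all metrics are computed per
activation window (default: ±60 ms around each detected or known beat),
not over whole multi-beat recordings.

## Reliability measurements

Four measurements quantify how trustworthy an estimate is:

* **ORR** (oEGM-to-residuum ratio): `max(ô) / max|r|` over the window.
  Higher is better. When the residual is numerically zero, the capped
  sentinel is flagged and excluded from aggregation rather than averaged.
* **NLA** (normalised loop area): area enclosed by the trajectory
  `(b_x/P, b_y/P)` with `P = max(ô)`. An ideal planar wave across an
  infinitesimal clique traces a straight line (area 0); lower is better.
  The area is the trapezoidal line integral of the Green's-theorem form
  `½|Σ(x dy − y dx)|` over the closed polyline. For self-intersecting
  trajectories this is the magnitude of the *net signed* area — a
  deliberate choice, with one visible consequence discussed under
  *Limitations*.
* **PW** (pulse width): time between the first and last crossings of
  `threshold_frac × peak` of the dominant positive deflection, with linear
  sub-sample interpolation; the default threshold 0.5 makes it the FWHM
  for a clean unimodal pulse. Delayed subtractions widen pulses, so
  shorter is better. The threshold is exposed because the pulse "edges"
  are otherwise a matter of definition.
* **MD** (morphology distortion): RMSE between the estimated omnipole and
  a reference omnipole, each normalised by its own peak absolute
  amplitude. Under planar propagation with identical waveforms, the true
  omnipole equals `−du/dt`; the reference averages the four corner
  derivatives (central differences, in µV/ms) after integer-lag
  cross-correlation alignment to the first corner, which also attenuates
  independent channel noise by ≈ 2× for four channels. For the final
  comparison the two normalised signals are aligned at their dominant
  peaks (cross-correlation alignment already shaped the reference;
  repeating it for the comparison would hide genuine shape differences —
  both options are exposed). MD is dimensionless here, since both signals
  are peak-normalised before the RMSE.

Metrics are computed per activation window and carried per beat in the
tidy table; aggregation averages across beats, cliques and recordings per
(configuration, spacing, metric) cell, with flagged (degenerate,
unalignable, capped) rows excluded per metric.

## The synthetic generator

`generate_planar_wave()` emulates what the analysis assumes about paced
epicardial recordings:

* **Delay field.** Planar: `τ(x, y) = (x cos Ψw + y sin Ψw)/v`; circular
  (point source): `τ = ‖(x, y) − source‖/v`. A 1 mm step at 0.5 m/s is
  2 ms. Delays are applied by evaluating the template in continuous time,
  so sub-sample delays are exact and no resampling artefacts arise.
* **Template.** Derivative-of-Gaussian biphasic deflection, peak amplitude
  1 mV, width σ = 2 ms, odd-symmetric about the activation instant and
  hence zero-area. 1 mV and a few-ms deflection are typical of healthy
  epicardial unipolar activations; the family is pluggable because real
  waveform shape varies.
* **Pacing.** Beats at exact multiples of the pacing period (default 4 Hz,
  matching common experimental ventricular pacing), optional jitter;
  a warning fires when the period is shorter than the template support.
* **Noise.** Per-channel white Gaussian noise, plus an optional
  common-mode sinusoid to exercise the averaging noise-rejection of the
  reference omnipole. `snr_noise_sd()` converts a target SNR in dB —
  defined on mean signal power over the analysis window versus noise
  variance, the conventional power definition — into a noise SD.
* **Defaults as study conditions.** 8 × 16 electrodes at 1 mm pitch
  (128 channels; the exact row/column split of such arrays varies, so it
  is configurable), 1 kHz sampling, 0.5 m/s conduction velocity, noiseless
  unless asked otherwise. These are fixed once and used by all validation
  runs below.

What the generator does *not* emulate: tissue heterogeneity, fibrosis,
wavefront collision or fractionation, electrode contact variation,
far-field ventricular components, or filtering artefacts. Passing tests on
this generator therefore validate the *mathematics* of the estimation
chain under its stated assumptions, not clinical performance on real
electrograms.

## The validation sweep

`reliability_sweep()` is the package's standard experiment: one noiseless
planar recording per wavefront angle, all five configurations, spacings
1–4 mm, eight cliques per spacing (evenly sampled; results are
translation-invariant for planar waves so more cliques add little), one
beat. Angles run every 15° but offset 7.5° from the symmetry axes: at
exact multiples of 45° one diagonal bipole of the cross clique is
identically zero for a noiseless planar wave, the residual vanishes, and
ORR degenerates to a capped sentinel rather than a measurement.

The sweep reproduces, on synthetic ground truth, the qualitative findings
that motivate the reliability framework:

* ORR falls and PW rises monotonically from 1 to 4 mm for every
  configuration; triangle NLA and MD rise as well.
* Complementary triangles (lower-left with upper-right, lower-right with
  upper-left) agree on angle-averaged ORR to within 1%; which
  complementary pair wins at a given angle depends on the angle, i.e.
  triangles are orientation-dependent.
* The cross clique at 1 mm matches or exceeds the better triangle pair's
  ORR, and its advantage shrinks with spacing — at 4 mm it is the worst,
  consistent with its √2-scaled baseline.

## Numerical and design choices

* **Angle search resolution.** Coarse 1°, fine 0.01°, golden tolerance
  1e−10 rad; the fine scan is the accuracy floor and matches the
  exhaustive oracle's grid.
* **Loop area.** Trapezoidal line integral; degenerate (< 3 point)
  trajectories return 0 with a flag rather than erroring, so sweeps never
  abort.
* **Derivative.** Central differences with one-sided ends, scaled to
  µV/ms. No smoothing by default; the acquisition bandwidth of real
  systems is the user's concern at ingest.
* **Segmentation.** With generator metadata, windows are centred on known
  beat times plus the mean propagation delay. The detector (array-mean
  |du/dt|, half-maximum threshold, refractory period of half the pacing
  period) agrees with metadata windows to < 5 ms on clean synthetic data.
* **Aggregation.** Mean across beats/cliques per cell (median and IQR also
  reported); flagged values excluded per metric, empty cells dropped with
  a warning.
* **On-disk format.** A plain CSV matrix (samples × channels, header of
  electrode labels, 17 significant digits) plus a JSON sidecar (fs, grid,
  pitch, units, free metadata). Internal units are fixed to µV and mm;
  declared `mV`/`V` are converted on ingest.

## Known limitations

* **Direction bias at the default delay/width ratio.** The angle estimator
  is exact when interelectrode delays are small relative to the waveform
  width. At the default conditions the cross-clique diagonal delay
  (√2 mm / 0.5 m/s ≈ 2.8 ms) exceeds the 2 ms template width, and the
  delayed-difference bipole amplitudes are no longer proportional to the
  direction cosines; the recovered direction then carries an intrinsic
  bias of up to ≈ 4° (median ≈ 2.4° over all angles), independent of
  sampling rate and of the optimiser (which matches exhaustive search).
  Halving the delay/width ratio (1 m/s, or a 4 ms template) brings the
  worst case under 1°. This is a property of the estimator under the
  stated conditions, measured and reported by `scripts/acceptance.R`
  rather than hidden.
* **Cross-clique NLA degenerates on ideal synthetic waves.** For an exactly
  planar wave and an odd-symmetric template, the two diagonal bipoles are
  even functions of time about a common centre, so the loop retraces
  itself and its net signed area is exactly zero at every spacing. The
  cross NLA is therefore uninformative on the noiseless generator (it is
  the ideal straight-line case the NLA rationale predicts); on real or
  noisy data the symmetry breaks and cross NLA behaves normally.
* **MD at large spacing is noisy in shape.** Beyond ≈ 3 mm the estimated
  omnipole becomes notched; peak alignment can jump between lobes and MD
  is no longer monotone in spacing for the cross configuration.
* **No quality screening.** Real recordings would be screened for contact
  and noise quality before analysis; only degenerate-input flags are
  implemented.
* **Statistics are exported, not fitted.** The tidy table carries
  recording identifiers as grouping columns so mixed models or post-hoc
  tests can be fitted in any statistics environment; none are fitted here.

## A worked example

```{r example}
grid <- make_grid(8, 16, 1)
rec <- generate_planar_wave(
  grid, planar_wave_params(psi_w_deg = 30, n_beats = 3, seed = 42))
windows <- segment_activations(rec)
clique <- enumerate_cliques(grid, 1)[40, ]
pair <- clique_bipoles(rec, clique, "x")
win <- windows$start[1]:windows$end[1]
est <- estimate_omnipole(pair, window = win)
est
c(orr = as.numeric(orr(est, win)),
  nla = as.numeric(nla(pair, est, win)),
  pw_ms = as.numeric(pulse_width(est, window = win)),
  md = as.numeric(morphology_distortion(
    est, reference_omnipole(rec, clique, win), win)))
```

```{r sweep, eval = FALSE}
# the full validation sweep (a few minutes)
tab <- reliability_sweep(seed = 1)
format_summary_table(aggregate_metrics(tab))
```
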
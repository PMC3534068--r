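---
title: "A cortical motion model for crowd-video analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cortical motion model for crowd-video analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdmotion)
```

This vignette is the package's own account of the model it implements: the
processing stages, the parameters that matter and where their defaults come
from, what the synthetic-data generators do and do not emulate, the
numerical choices made where the mathematics left room, and the known
limitations.

## 1. The model

The pipeline mirrors three stages of the primate dorsal stream.

### V1: phase-based initial motion detection

Each frame is Fourier-transformed spatially and multiplied with a bank of
Gaussian kernels in the frequency plane — `n_orientations = 8` orientations
(22.5° apart) × three rings. A ring with peak wavelength $\lambda_l$ sits
at radius $\omega_l = 2\pi/\lambda_l$ with tangential width
$\sigma^\psi_l = 1.5\,\omega_l \sin\Delta\psi$ and radial width
$\sigma^r_l = 1.26\,\omega_l(\beta-1)/(\beta+1)$; the overlap factors 1.5
and 1.26 tile the frequency plane evenly. Each kernel is normalized to unit
integral and its DC coefficient is set to zero, so constant images produce
exactly zero response. Because the kernel occupies one side of the
frequency plane only, the inverse transform is an analytic-signal-like
complex field whose argument is the **local image phase** — the only
quantity the detector consumes, making it insensitive to overall
brightness.

Rings are paired one-to-one with the speed ladder through
$\lambda_l = \eta\, s_l$ with $\eta = 2.5$ frames and
$s \in \{1, 2, 4\}$ px/frame, so every tested displacement respects the
half-wavelength (sampling) constraint $s \le \lambda/2$.

The extended Hassenstein–Reichardt correlator tests, for each speed $s$ and
direction $\varphi$, the displacement
$(\Delta x, \Delta y) = s(\cos\varphi, -\sin\varphi)$ (image rows grow
downward; 90° means upward motion). The forward correlation sums
$[\cos(\phi(x{+}\Delta, t_1) - \phi(x, t_0))]^{+}$ over the ring's
orientations; the backward correlation swaps $t_0$ and $t_1$; the initial
motion signal is the rectified difference. On static input forward and
backward terms are identical and cancel exactly; on counterphase flicker
(polarity reversal, a global $\pi$ phase jump) they also cancel exactly.

The three cascade stages are solved per frame at steady state:

* **Stage 1** $z^{(1)} = \Lambda_{vel} * c^{\alpha}$, $\alpha = 2$: the
  velocity-space Gaussian has $\sigma_{speed} = 0.5$ px/frame and
  $\sigma_{dir} = 30°$; the direction axis is circular, the speed axis
  reflecting.
* **Stage 2** $z^{(2)} = z^{(1)}(1 + \gamma z^{fb})$, $\gamma = 100$:
  modulatory re-entry from MT (previous frame pair, nearest-neighbor
  upsampled, clipped to $[0,1]$). Feedback cannot create activity where the
  driving signal is zero; the first frame pair runs without feedback.
* **Stage 3** $z^{(3)} = z^{(2)} / (A_{V1} + B_{V1}\sum z^{(2)})$, the sum
  over *all* speeds and directions at the location. With $B \ge 1$ the
  output cannot exceed one; the pool over everything makes V1 favor a
  single motion vector.

### MT: integration and soft competition

Each (speed, direction) channel is convolved with an isotropic Gaussian of
$\sigma_{xy} = 5$ px and subsampled every $r = 5$ pixels by linear
interpolation. At that pairing the spectral power surviving at the maximum
normalized frequency $\pi$ is
$100\,e^{-(\pi\sigma/r)^2/2} = 100\,e^{-\pi^2/2} \approx 0.72\%$ —
`mt_antialias_attenuation()` evaluates this. The sampled signal is squared
($\alpha = 2$) and smoothed with the same $\Lambda_{vel}$. The second stage
is the identity (no feedback into MT is modeled). The third stage divides
an excitatory centre (direction-only Gaussian, $\sigma^{+}_{dir} = 25°$, no
kernel along speed) by an inhibitory surround broad in both axes
($\sigma^{-}_{dir} = 60°$, $\sigma^{-}_{speed} = 1.5$ px/frame), with
$A_{MT} = 0.01$, $B_{MT} = 10$. Because the surround is local in velocity
space rather than a pool over everything, two sufficiently different
motions coexist — transparency survives where V1's normalization would have
collapsed it. Motions within about one direction-kernel width attract and
merge; oppositely directed motions persist as separate modes.

### MSTd: global flow patterns

Templates $T_{u,v,\delta}(x, y, \varphi) =
[\cos(\varphi - (\psi + \delta))]^{+} G_{\sigma_{pat}}(\|p - c\|)$, with
$\psi$ the angle from the anchor to the location, cover 15 anchors
(`{0, 25, 50, 75, 100}% × {0, 50, 100}%` of the MT field) × 8 pattern
angles: $\delta = 0$ is expansion, 90° CCW rotation, 180° contraction, 270°
CW, odd multiples of 45° spirals. The envelope width is 80% of the field
extent. The MT signal is averaged over speeds (unweighted), squared, and
projected onto each template; the projection drives a leaky integrator
$r^{(1)}_t = (1-\lambda)r^{(1)}_{t-1} + \lambda p_t$ and is normalized by
the mean over anchors per pattern angle
($r^{(3)} = r^{(1)}/(A_{MST} + B_{MST}\,\overline{r^{(1)}})$), then scaled
to a maximum of one for display.

### Read-out and derived maps

Per MT cell the velocity-space activation is read out iteratively: find the
maximum; below $\theta_{motion}$ return *no motion*; otherwise anchor a
discretized Gaussian (the $\Lambda_{vel}$ widths) at the peak, report the
Gaussian-weighted vector average of the grid velocities, zero the consumed
likelihoods, repeat up to two motions. Labels (none / single / multiple)
are nearest-neighbor upsampled to frame resolution and kept only if
constant across three successive frames. Velocity gradients come from the
primary motion field, smoothed with a one-cell Gaussian over valid cells,
differentiated centrally (one-sided at mask borders) and projected onto the
local gauge frame: $g_t = e_t^{\mathsf T} J e_t$ (positive for local
expansion), $g_n = e_n^{\mathsf T} J e_t$ (positive for CCW bending),
$\chi = \operatorname{atan2}(g_n, g_t)$. The danger rule flags pixels that
are *multiple* **and** slower than $\theta_{slow}$.

## 2. Parameters

| Parameter | Default | Unit | Origin |
|---|---|---|---|
| `n_orientations` | 8 | — | model constant |
| `speeds` | 1, 2, 4 | px/frame | octave ladder, one ring per speed |
| `eta` | 2.5 | frames | sampling-theorem factor (must be ≥ 2) |
| `beta` | 2 | — | one-octave radial bandwidth (package choice) |
| `sigma_speed`, `sigma_dir` | 0.5, 30 | px/frame, ° | velocity-interaction widths |
| `alpha` | 2 | — | cascade nonlinearity (all areas) |
| `gamma` | 100 | — | feedback amplification |
| `A_V1`, `B_V1` | 0.01, 100/112 | — | V1 normalization |
| `mt_sigma_xy`, `mt_sampling_rate` | 5 px, 5 | — | MT anti-alias and RF scale |
| `A_MT`, `B_MT` | 0.01, 10 | — | MT competition |
| `mt_center_sigma_dir` | 25 | ° | centre spans one direction lobe (package choice) |
| `mt_surround_sigma_dir`, `mt_surround_sigma_speed` | 60°, 1.5 px/frame | | surround reaches dissimilar motions (package choice) |
| `A_MST`, `B_MST` | 0.01, 10 | — | MSTd normalization |
| `lambda_temp` | 0.5 | — | MSTd leak (package choice) |
| `sigma_pat_frac` | 0.8 | of field extent | template envelope |
| `theta_motion` | calibrated | activation | 0.2 × peak response to a reference translation |
| `theta_slow` | 0.5 | px/frame | half the smallest ladder speed (package choice) |

The read-out threshold is not an absolute constant because the cascade's
output scale depends on the filter bank; `calibrate_motion_threshold()`
runs the full V1–MT pipeline once on a dense coherent translating dot
stimulus (fixed internal seed, 64×64, speed 1) and takes
`theta_motion_frac = 0.2` of the peak MT activation. This makes the
threshold portable across frame sizes and parameter variations.

## 3. Numerical choices

* **Sub-pixel phase sampling.** Diagonal displacements are fractional.
  Interpolating wrapped phase is ill-defined, and bilinear interpolation of
  the *complex* field crushes the amplitude of the finest ring
  ($\lambda = 2.5$ px is just above Nyquist). The responses are narrowband,
  so the package keeps each ring's frequency-domain product and shifts by
  the exact spectral shift theorem; integer displacements are index rolls.
* **Amplitude validity.** Phase is undefined where the Gabor amplitude
  vanishes. Each orientation's correlation is gated by a symmetric validity
  mask (both compared responses above `amp_frac = 0.1` of the ring's mean
  amplitude). Without this, dense near-static scenes (a clogged crowd)
  light up with phase noise; with an asymmetric mask, forward/backward
  cancellation breaks at mask borders — hence one shared mask per term
  pair.
* **Phase-tuning sharpness.** With $\eta = 2.5$, the ring one octave above
  a stimulus speed sees a residual phase error of only
  $\pi/\eta \approx 1.26$ rad at its tested displacement, so first-order
  rectified-cosine tuning leaves the wrong speed ring a substantial
  response; under feedback the wrong ring can entrench. The correlator
  therefore squares the rectified cosine (`tuning = 2`), restoring the
  speed selectivity of the octave ladder; `tuning = 1` recovers the
  first-order detector.
* **Speed axis discretization.** The three-point speed axis
  $\{1, 2, 4\}$ is non-uniform; Gaussian interaction matrices are
  row-normalized, which conserves mass at the ends of the axis — the
  discrete analogue of a reflecting boundary. The direction axis uses
  circulant (wrap-around) kernels.
* **Read-out suppression and merging.** The consumed region after each
  read-out is everything within three standard deviations of the anchored
  Gaussian (two left the shoulders of a unimodal peak to be re-read as a
  spurious motion). A candidate whose direction lies within 20° of an
  already-extracted motion is consumed but not counted: motions closer than
  roughly 20° are a single percept, and residual same-direction speed-ring
  crosstalk lands exactly there.
* **Anchors and boundaries.** MSTd anchor percentages map to MT pixels by
  rounding half up. All spatial filtering is FFT-native, i.e. circular;
  visible edge artifacts on non-periodic scenes are a documented property
  of this choice, not corrected. The bound $z^{(3)}_{V1} \le 1$ holds for
  $B_{V1} \ge 1$; at the default $B_{V1} = 100/112 \approx 0.89$ values may
  exceed one by at most 12%.
* **Degenerate inputs.** Empty agent lists produce empty trajectories;
  all-zero MSTd states display as zeros (no division); fewer than three
  label frames stabilize to *no motion* with a warning; an integration step
  whose displacement exceeds the body radius aborts with a diagnostic.

## 4. The synthetic generators

`make_translating_dots()`, `make_transparent_dots()`,
`make_flicker_dots()`, `make_lane_stimulus()` and `make_pattern_movie()`
render anti-aliased bright discs (linear edge falloff over one pixel) on a
dark ground with wrap-around boundaries, so sub-pixel displacement is
representable and the stimuli match the detector's circular FFT boundary
handling. `make_pattern_movie()` advects dots along the linear spiral field
$v(p) = g\,R(\delta)(p - c)$ by one-frame Euler steps and returns the
ground-truth flow.

The pedestrian simulator implements the circular-specification social-force
model: relaxation toward the desired velocity
$\dot v = (v_0 e - v)/\tau$ plus, for each neighbour and wall at distance
$d$, a repulsion $A e^{(2r - d)/B}$ and, on contact, a body force
$k(2r - d)$ and sliding friction $\kappa(2r - d)\,\Delta v^t$. Defaults:
$\tau = 0.5$ s, $A = 2000$, $B = 0.08$ m, body radius $0.3$ m,
$v_0 = 1.34$ m/s, $k = 1.2\times10^5$, $\kappa = 2.4\times10^5$, mass 80
kg, $\mathrm{d}t = 0.02$ s. Speeds are capped at $1.3 v_0$. These are the
standard published escape-panic constants; the corridor scenarios assert
only qualitative behavior (lane formation on an open cyclic 50 m × 10 m
walkway with half the agents targeting each direction; clogging and
slow-down when the ends are walled off except for 1 m exits). The
`exponential + body + friction` form is one of two published variants
(circular vs. elliptical specification); the circular one is used, without
any claim that it reproduces a specific prior simulation in detail.

What the generators do **not** emulate: perspective (all rendering is
fronto-parallel bird's-eye at 10 px/m, so image speed equals metric speed
scaled), articulated walkers (no arm-swing transparency), occlusion
layering, sensor noise, and photometric variation. Tests passing on these
stimuli therefore demonstrate the model's motion-representation properties,
not field performance on arbitrary CCTV footage.

## 5. Problem sizes used by the test suite

Unit tests run on 32–48 px frames. The scientific acceptance checks use
64×64 stimuli (20 frames for the speed-ladder recovery; 10–12 frames
elsewhere) with ~200–320 dots, and one corridor pair at 500×100 px (200
agents, 60 simulated seconds, every fifth step rendered). These sizes were
chosen so that an MT field of 13×13 cells (or 20×100 for the corridor)
gives stable fractions while a full run stays interactive on one CPU core.

## 6. Known limitations

* The speed ladder bottoms out at 1 px/frame; slower coherent motion
  excites the finest ring weakly and reads out near the lowest ladder
  speed. The danger rule therefore keys on the *read-out vector magnitude*
  (which vector-averaging legitimately pulls below 1 for broad or opposed
  activation), with $\theta_{slow} = 0.5$ px/frame.
* Velocity gradients are computed from the read-out vector field, not from
  activity differences in the population code; the primary motion defines
  the gauge frame and second motions are ignored for gradients.
* MSTd-to-MT feedback and feedback into MSTd are deliberately absent
  (identity second stages), as is any form-pathway or attentional biasing.
* Transparency of more than two motions per location is not read out
  (`max_motions = 2`).
* The MSTd surround pools over anchors within each pattern angle
  separately; cross-pattern normalization was left out deliberately, since
  the display stage already scales the population to its maximum.
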
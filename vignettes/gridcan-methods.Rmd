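---
title: "Grid-cell attractor networks, heterogeneities and resonator neurons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-cell attractor networks, heterogeneities and resonator neurons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridcan)
```

gridcan simulates rate-based continuous attractor network (CAN) models of
medial entorhinal grid cells and quantifies how biological heterogeneities
disrupt, and intrinsic neuronal resonance stabilises, their spatially
periodic firing. This vignette documents the models, the tunable
parameters, the numerical choices, and the design decisions that were
genuinely open — in enough detail that a reader can judge what a passing
test suite does and does not establish.

## The network model

Neurons live on an `n x n` lattice with periodic (toroidal) boundaries.
Each neuron has one of four preferred directions (east, north, west,
south), tiled in 2x2 blocks (`build_preference_map()`), so a quarter of
the sheet shares each preference. Recurrent weights follow a
centre-shifted difference of Gaussians (DoG),

    W[i, j] = a exp(-gamma |d|^2) - exp(-beta |d|^2),
    d = wrap(x_i - x_j) - l e(theta_j),

with `beta = 3 / lambda^2`, `gamma = 1.1 beta`, lattice periodicity
parameter `lambda = 13`, shift `l = 2` lattice units along the presynaptic
neuron's preferred direction, and `a = 1`, which makes every weight
non-positive (a purely inhibitory network; `build_weight_matrix()`).
`wrap()` is the minimum-image displacement on the torus, each component in
`(-n/2, n/2]`.

Two facts about this kernel matter for everything downstream:

* The linearly most unstable spatial mode of the DoG sits at wavenumber
  `k* = sqrt(8 beta gamma ln(gamma/beta) / (gamma - beta))`, i.e. a
  pattern wavelength of about `1.26 lambda` (~16.4 neurons for the
  defaults), not `lambda` itself. The settled sheet is a lattice of
  activity bumps with roughly that spacing.
* On a finite torus the bump lattice must be commensurate with the
  periodic boundary. The discrete wavevectors closest to the unstable ring
  form a near-hexagonal triad only for some lattice sides. Empirically
  (settle-and-measure, then full trajectory runs), `n = 48` and `n = 60`
  admit near-commensurate triads and produce stable hexagonal firing,
  whereas `n = 40`, `44`, `52` and `56` freeze into sheared, frustrated
  bump states whose spatial phase diffuses by about a full period over a
  100 s run, washing the time-averaged rate maps out (median grid score
  around 0 with almost no neuron above 0.3). The package therefore runs
  its desk-scale analyses on `48 x 48` sheets and its full-scale checks on
  the `60 x 60` default; other sizes remain available but grid quality
  should be verified before use.

Each neuron also receives a feed-forward drive tied to the animal's
velocity, `B_i = 1 + alpha e(theta_i) . v` (`feedforward_drive()`), with
gain `alpha = 45` and `v` the *per-step displacement* in metres. The
per-step convention is deliberate: with millisecond steps and running
speeds up to 4 m/s it keeps `alpha e.v` within about 0.18 of the
operating point `B = 1`; reading `v` in m/s would multiply the drive
tenfold-squared and destroy the attractor. The resulting velocity gain of
the pattern is ~18 neurons per metre of travel, so the defaults give a
grid period of roughly 1 m in the 2 m arena — a handful of firing fields
per cell.

## Trajectories

`generate_virtual_trajectory()` implements a fast open-field walk: per
1 ms step a step length is drawn uniformly from [0, 4] mm and a heading
*increment* uniformly from ±5 degrees; near the wall (default zone 2 cm)
the absolute heading is redrawn from the full circle, producing the sharp
boundary turns that let the walk fill the arena quickly. The heading is
interpreted as a persistent state with increments — reading the
per-step angle as an absolute heading confined to ±5 degrees would drift
every walk northwards. Positions are rejected-and-redrawn if a candidate
step leaves the arena (cap 1000 attempts). A plain random walk (zone 0)
is retained as the coverage comparator, and recorded paths can be loaded
from `t,x,y` tables (`load_trajectory_table()`), resampled by linear
interpolation.

## Heterogeneities

`het_spec()` + `apply_heterogeneities()` randomise, per neuron, the
integration time constant (intrinsic; uniform in [8,12] ms at degree 1
widening to [1,20] ms at degree 5), the velocity gain (afferent; [35,55]
to [0,100]), and, per ordered synapse, an additive jitter on `W`
(synaptic; raw bounds 300..1500). Degrees scale the intrinsic span by
±20% of the base value per degree (floored at 1 ms), which reproduces the
tabulated bounds for the 10 ms default and generalises to other bases.

The raw synaptic bounds dwarf the weights (|W| <= 0.036), so jitter is
scaled by a dimensionless factor `jitter_scale`. Two calibration facts
fixed its default:

* *Sign.* Literal positive jitter `U[0, bound] * scale` adds a positive
  mean to every synapse; summed over `n^2` inputs this flips the net
  recurrent gain from the DoG's -16 to strongly positive at any scale
  large enough to matter, and the network diverges during settling. The
  default therefore draws centred jitter `U[-bound/2, bound/2] * scale`
  (the literal positive variant remains available via
  `jitter_centered = FALSE`).
* *Scale.* `jitter_scale = 1e-5` makes degree 1 mildly disruptive
  (median grid-score change of a few percent), degree 3 strong (~-80%)
  and degree 5 a near-complete collapse — the graded progression the
  sweep experiments are built around, with synaptic the most disruptive
  kind at matched degree.

## Neuron models

All three single-neuron dynamics share the network equations
(`simulate_can()`, forward Euler, `dt = 1` ms for virtual trajectories;
`dt/tau <= 1` is enforced and `dt/tau > 0.5` warned about):

* **Integrator** — `tau dS/dt = -S + f(W S + B)` with rectification
  `f(x) = max(x, 0)`; a low-pass filter with cutoff `1/(2 pi tau)`.
* **Phenomenological resonator** — the integrator's state `u` is emitted
  through a high-pass stage, `S = R u |du/dt|^epsilon`. The derivative is
  the per-step backward difference; its *magnitude* is used because a
  fractional power of a negative number is undefined (a rectified-
  derivative variant is available). The redefined `S` is what other
  neurons see in the recurrent sum and what all analyses consume
  (`recurrence = "internal"` feeds `u` instead, for sensitivity checks).
  `epsilon = 0`, `R = 1` reduces exactly — bit for bit — to the
  integrator. `R` defaults to 1, which keeps the redefined activity on
  the scale of the underlying state: that is the scaling under which the
  resonator network sustains its bump attractor (the alternative
  calibration that equates the time-averaged single-neuron chirp response
  with the integrator's, `calibrate_R()`, gives R near 0.36 for the
  defaults — too weak a recurrent drive for pattern formation — and is
  retained for explicit single-neuron comparisons via
  `neuron_model(R = NULL)`).
* **Mechanistic resonator** — a slow activity-dependent negative
  feedback: `tau dS/dt = -S - g m + f(W S + B)`,
  `tau_m dm/dt = m_inf(S) - m`,
  `m_inf(S) = 1 / (1 + exp((S_half - S) / k))`. `g = 0` reduces exactly
  to the integrator. Defaults: `g = 0.015`, `k = 0.1`, `S_half = 0.3`,
  `tau_m = 75` ms.

### Single-neuron resonance and its characterisation regime

`chirp_stimulus()` builds the 0-100 Hz / 100 s constant-amplitude sweep;
`chirp_response()` integrates the single-neuron equations (no
rectification in the single-neuron forms); `resonance_frequency()`
reports the argmax of the smoothed single-sided FFT magnitude, with two
robustness refinements: the peak search starts at `f_min` (default twice
the 0.5 Hz smoothing bandwidth — a finite sweep carries almost no energy
in its lowest bins, which otherwise masquerades as a ~1 Hz peak on
low-pass responses), optionally normalises by the stimulus spectrum, and
declares "no resonance" (`fR = 0`) unless the peak exceeds the
low-frequency response by at least `strength_min` (default 2%). For the
phenomenological model the response magnitude follows
`w^epsilon (1 + w^2 tau^2)^(-(1+epsilon)/2)`, maximal at
`w tau = sqrt(epsilon)` — about 8.7 Hz for the defaults — but that curve
is flat to under 1% across several Hz, and the fractional power generates
odd harmonics that tilt the FFT peak; `envelope_resonance_frequency()`
therefore demodulates the response at the chirp's instantaneous phase and
localises the fundamental's envelope peak, which tracks the closed form
to a few percent (the FFT argmax can be off by ±1.5 Hz on these flat
spectra).

A linearisation explains the mechanistic model's operating regime and
guided two deliberate characterisation choices. Around an operating point
`S*`, the feedback contributes a loop gain `L = g m_inf'(S*)`, with
`m_inf' = sigma'((S* - S_half)/k) / k`; resonance depth grows with `L`
and is negligible below a few percent. At the network's stated default
`g = 0.015` the maximal possible loop gain is `0.015/(4 k) = 0.0375`, so
a single neuron driven by a unit chirp is indistinguishable from the
integrator (sub-2% effects) — the pronounced single-neuron band-pass and
pulse sag attributed to this mechanism require order-unity loop gain.
The package therefore characterises the single-neuron mechanistic
resonator at a stronger feedback (`g = 0.25` in the test suite, with the
0.05-amplitude chirp keeping the dynamics in the small-signal regime
around rest), while networks keep the stated `g = 0.015`. In this regime
all the qualitative dependencies hold: `fR` rises with `g`; no resonance
for `tau_m <= tau`, then a rise and fall along `tau_m`; a rise and fall
along `k` (the operating point sits below `S_half`, so
`m_inf'(0) = sigma'(-S_half/k)/k` is itself non-monotonic in `k`); and a
monotone decline along `S_half`.

## Rate maps and grid metrics

`compute_rate_map()` bins activity on a 100 x 100 pixel grid by default
(50 x 50 in the desk-scale tests), normalises per-pixel activity sums by
visit counts (mean activity per visit; unvisited pixels are invalid and
excluded from every sum), and smooths with a masked Gaussian
(`sigma = 2` px, truncated at 3 sigma, kernel renormalised over valid
pixels so arena edges do not darken). Occupancy probabilities sum to one
over visited pixels.

`grid_score()` measures rotational symmetry. The smoothed map is first
turned into a masked spatial autocorrelogram — the Pearson correlation
between the map and its shifted copy at every lag, over the overlapping
valid pixels (lags with under 20 overlapping pixels are dropped) — and
the autocorrelogram is rotated about its zero-lag centre by 30/60/90/120/
150 degrees (bilinear interpolation); the score is
`min(r60, r120) - max(r30, r90, r150)`. Correlating the *autocorrelogram*
rather than the rate map itself is essential: the rate map's rotation
about the arena centre is invariant only when a firing field happens to
sit at the centre, so an ideal hexagonal map with a random spatial phase
would score anywhere from -0.5 to +0.9 under the map-rotation reading,
while nearly every neuron of a homogeneous CAN — whose phases tile the
torus uniformly — empirically reports a high score. The zero-lag centring
makes the statistic phase-invariant (verified against planted hexagonal
and square lattices: hex > 0.5 at any phase and orientation, square
<= 0). No annulus or ellipse refinements are applied; square arenas are
pre-masked to the inscribed circle so all five angles compare identical
support; zero-variance maps score 0 by convention.

`detect_fields()` seeds fields at strict 8-neighbourhood local maxima of
the smoothed map (equal-valued plateaus merge to their centroid; maxima
below 0.1 activity units — the visualisation threshold — are discarded as
noise), grows each field over connected pixels at or above 20% of its
peak, and assigns contested pixels to the nearest peak.
`summarize_metrics()` adds the mean rate over valid pixels, the smoothed
peak rate, field count and mean size, the mean over all pairwise
peak-to-peak distances as the spacing (a literal all-pairs reading; a
nearest-neighbour mode is provided because all-pairs inflates spacing
once maps hold many fields), the Skaggs information rate
(`information_rate()`, bits/s, with `0 log 0 = 0`) and `sparsity()`
(squared mean over mean square, occupancy-weighted).
`diagonal_phase_profile()` pairs the smoothed map's main-diagonal samples
with their central-difference derivative; spatially periodic maps trace
closed orbits in that plane.

## Spectral analysis

`activity_spectrum()` takes single-sided FFT magnitudes of each neuron's
temporal activity with the DC bin retained and *no* taper — the analyses
target the 0-2 Hz octave, exactly the band a window redistributes.
`normalized_spectral_difference()` implements the paired comparison
`delta(f) = (S_het - S_homo) / (max S_het + max S_homo)` per neuron,
which requires the heterogeneous run and its homogeneous twin to share
the trajectory and initial conditions (`run_experiment()` enforces the
pairing). `variance_profile()` is the across-neuron variance of `delta`
per frequency bin, and `octave_auc()` integrates profiles over the 0-2,
2-4, 4-8 and 8-16 Hz octaves (trapezoidal, exact band edges by
interpolation), as percentages of either the full-spectrum area (default)
or the summed band areas.

## Experiments, seeds and problem sizes

`run_experiment()` wires the full pipeline — trajectory, weights,
heterogeneity instance, heterogeneous simulation plus homogeneous twin on
identical inputs, per-trial metrics, percent changes
(`100 (het - homo)/|homo|`, undefined where the reference is zero), and
spectral summaries. Every random draw traces to one of three named seeds
(trajectory, init, het); trials vary only the initial-condition seed,
keeping the connectivity, trajectory and heterogeneity instance fixed,
and run as extra columns of one simulation (they share the per-step
weight-matrix pass). `can_presets()` mirrors the study's experiment
families: degree sweeps (combined and per kind), resonator rescue for
both resonator models, the feedback-time-constant sweep (bracketing
`tau = 10` ms), integration-time-constant and high-pass-exponent sweeps,
and a network-size sweep.

The test suite runs these families at a deliberate desk scale: 48 x 48
networks (the smallest torus that sustains stable hexagonal patterns, see
above), 20 s trajectories, 50 x 50 pixel maps, metrics on a 96-neuron
subset, spectra on an 80-neuron subset, and two trials per condition; a
60 x 60 degree-5 run stands in for the full-size collapse experiment.
Percent-change medians at this scale are noisier than at the full
60 x 60 / 100 s / 3600-neuron setting, which is why the suite tests
ordering and sign claims rather than exact magnitudes. The
feedback-time-constant sweep uses the 75 ms homogeneous twin as the
common reference for all sweep points, since the feedback time constant
has very little effect on homogeneous grid activity.

One family of claims does not reproduce in this implementation, and its
checks are deliberately left failing rather than weakened: rescuing
degree-5 heterogeneous networks by replacing integrators with resonators.
Across an extensive sweep of readings and parameters (output scaling R
from 0.36 to 1.5, raw and smoothed derivatives, redefined and internal
recurrence for the phenomenological model; feedback strengths 0.015-0.5,
kernel midpoints 0.3-0.5 and slopes 0.1-0.3 for the mechanistic model)
no configuration both preserved homogeneous grids and improved the median
degree-5 grid-score change relative to the integrator network. The
linearised loop-gain analysis above says why the stated mechanistic
default cannot do so (a sub-4% low-frequency suppression against a
near-total disruption), and configurations with order-unity loop gain
destabilise the homogeneous pattern first. The spectral claims — that
resonator outputs carry less low-frequency perturbation variance — are
tested independently and concern the temporal structure of activity, not
the recovery of spatial maps.

## Numerical choices, in brief

* Forward Euler throughout, fixed `dt`; single-precision state inside the
  compiled network loop (the per-step pass over `W` dominates run time;
  the dynamics are insensitive beyond float), with magnitudes below
  1e-20 flushed to zero — rectified silent units otherwise decay into
  denormals, which both stall the FPU and defeat the sparse skip in the
  recurrent product.
* Zero-velocity settling (default 100 ms) precedes every run and is
  excluded from analyses; initial activities are uniform on [0, 1]; the
  mechanistic feedback state starts at its steady state.
* Divergence (|S| > 1e6 or non-finite) aborts with a step-stamped error.
* Geometry operators (rotation resampling, smoothing kernels) are cached
  per resolution; the smoothing of many maps at once is one sparse
  operator product.

## Known limitations

* The virtual walk has no behavioural realism beyond the generating
  algorithm: no speed autocorrelation, no wall-following, speeds up to
  4 m/s.
* Grid quality depends on the torus admitting a near-commensurate bump
  triad; sizes between the known-good 48 and 60 can frustrate the
  pattern. This is a property of the model class, not of the
  implementation, but it limits which "small" networks are usable.
* The stated network-default feedback strength of the mechanistic model
  produces only percent-level single-neuron resonance; single-neuron
  characterisation uses a stronger feedback (documented above), and the
  network-level rescue experiments are the authoritative test of the
  mechanism at network scale.
* Activity is rate-based; nothing here speaks to spike timing.
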
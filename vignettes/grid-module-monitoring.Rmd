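---
title: "Monitoring path integration in grid-cell modules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring path integration in grid-cell modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Grid cells in the medial entorhinal cortex fire on a triangular lattice
during open-field exploration. A module — a set of grid cells sharing
lattice orientation and spacing but differing in phase — encodes position as
a point on a 2D torus, the quotient of the plane by the lattice. During a
homing task in darkness the familiar hexagonal rate maps can disappear
without the module losing its function: the population still moves over the
same torus, but the mapping between arena and torus changes, because the
map reanchors to a movable landmark (a lever box) and its orientation
drifts as path integration accumulates error.

`gridtorus` implements the full monitoring pipeline: grid-cell
classification, grid-geometry fitting, the arena-to-torus transform, an
LSTM position decoder, movement-vector reconstruction, reference-frame
anchoring statistics, and drift-versus-homing correlations — together with
a synthetic session generator that produces all of these phenomena with
known ground truth.

## The grid-cell rate model

A cell's rate at position $\mathbf{x}$ is

$$\mathrm{relu}\!\left(\frac{\cos(a_0-o_0)+\cos(a_1-o_1)+\cos(a_2-o_2)+1.5}{4.5}\,
\mathrm{pr}\right),\qquad a_i=\frac{d_i}{p_i}2\pi,$$

where $d_i$ is the projection of $\mathbf{x}$ on the unit vector at angle
$\theta_i$, $p_i$ the period along axis $i$, $o_i$ the phase offset and
$\mathrm{pr}$ the peak rate. With axes at $\theta,\theta+60°,\theta+120°$
and equal periods, the firing fields form a triangular lattice with
nearest-neighbor spacing $2p/\sqrt{3}$. Two facts matter repeatedly
downstream:

* the **autocorrelation peaks** of a rate map lie along the lattice
  nearest-neighbor directions — perpendicular to the cosine axes — at
  distance $2p/\sqrt{3}$, not at $p$ along $\theta_i$;
* the offsets $(o_0,o_1,o_2)$ of a coherent 2D phase satisfy
  $o_2 = o_1 - o_0$ (up to $2\pi$); `phase_to_offsets()` constructs them
  from a Cartesian phase point so simulated cells are exact lattice
  translates of one another.

## Classification and geometry fitting

Rate maps use 3-cm bins and 5-cm Gaussian smoothing, with the kernel
renormalized over valid bins so rates never bleed across the arena wall.
The spatial autocorrelation correlates the map with itself at every integer
displacement over jointly valid bins. The grid score correlates an annulus
containing the six inner fields with rotated copies of itself:
$\mathrm{mean}(r_{60},r_{120})-\mathrm{mean}(r_{30},r_{90},r_{150})$. We
use the difference form; the ratio form is available as an option
(`form = "ratio"`) but is numerically unstable — its denominator is near
zero or negative for strongly periodic maps — and cannot support a
percentile test.

Field detection uses regional maxima of the autocorrelation above
$r > 0.1$ rather than connected components: on smoothed autocorrelations
the central peak and the six fields merge into one component at any fixed
threshold, whereas regional maxima separate them robustly. The annulus runs
from half the nearest peak distance to 1.25 times the farthest of the six.
The shuffle null (500 circular time-shifts of the spike train, minimum
20 s) scores each shuffled map inside the annulus detected on the observed
map; a cell is a grid cell when its score exceeds the null's 95th
percentile. On the 50-cm foraging arena only about 2.5 lattice periods fit
inside the wall, so smoothing and boundary truncation bias the detected
ring slightly outward and make the score phase-dependent; this is why the
geometry used downstream comes from a gradient fit, not from the
autocorrelation.

The two-stage fit minimizes the mean squared error between the model rate
and the cell's instantaneous rate (100-ms smoothing) at every tracking
sample, with Adam (learning rate 0.01, up to 2,000 iterations per stage,
early stop at $10^{-6}$ relative loss change; analytic gradients in
compiled code). Stage one constrains perfect 60° periodicity and equal
periods; stage two frees all six axis parameters, initialized from stage
one, which avoids most local minima. Module geometry takes per-cell medians
of $\theta_0,\theta_1,p_0,p_1$ after aligning each cell's axes to the first
cell modulo the 60° lattice symmetry.

## Torus transform and decoder

`to_torus()` maps positions to angles $v_i = d_i/p_i \cdot 2\pi$ (wrapped
to $[0,2\pi)$); movement transforms invert the $2\times 2$ projection
system, with deltas wrapped to $(-\pi,\pi]$ — unambiguous as long as a
single step moves less than half a period, which at 20-ms tracking never
happens for mice.

The decoder is a two-layer LSTM with 256 hidden features, implemented from
scratch in C++ (forward pass, backpropagation through time, Adam); its
gradients are verified against numerical differentiation in the test suite,
and all randomness (initialization, batch order) is drawn from R's RNG so a
seed fixes the result bit-for-bit. Inputs are the cells' instantaneous
rates in 20-ms bins smoothed with a 20-ms kernel; each sample is the last
20 bins (400 ms); targets are $\cos v_0,\sin v_0,\cos v_1,\sin v_1$;
training uses one epoch, batch 64, learning rate 0.001, mean squared error.
Decoded outputs are smoothed with a 100-ms kernel before the two-argument
arctangent. Rates are fed raw in Hz; a z-scoring option exists but did not
change decoding quality in our experiments.

Movement vectors are per-bin wrapped torus deltas mapped to Cartesian
steps. The decoded directional error is the signed angle between decoded
and real movement vectors at samples with speed above 10 cm/s and at least
5 cm from the wall; its mean vector length is the directional precision and
its circular mean the rotation of the decoded map.

## The synthetic session generator

The generator emulates the experimental design so the analyses can be
validated against ground truth:

* **Arenas and trials.** A 50-cm-diameter foraging arena (30-min baseline
  trials in the emulated design; tests use 10–15-min sessions) and an 80-cm-diameter
  task arena with the bridge at the $-y$ edge. Task trials run
  search → at-lever dwell → homing; the first seven trials are lit, then
  light and dark alternate. Lever positions are uniform within 75% of the
  radius and at least 10 cm from the wall.
* **Kinematics.** Ornstein–Uhlenbeck heading and speed (mean 15 cm/s)
  reflected at the wall for foraging; for task trials a search heading
  pulled increasingly toward the lever, a circling dwell at running speed,
  and a straight homing leg.
* **Module.** 5–20 cells sharing $\theta = 0.3$ rad and $p = 30$ cm
  (field spacing $\approx 35$ cm, a typical small mouse module and one that
  fits several periods inside the 50-cm arena), peak rate 12 Hz, phases
  uniform over the unit cell (`dispersion` shrinks their spread to emulate
  poorly dispersed modules). Spikes are an inhomogeneous Poisson process
  per 20-ms tracking bin.
* **Drift.** Orientation drift is a Wiener process per cm of path
  ($\sigma = 0.3°/\sqrt{\mathrm{cm}}$), reset at each door opening when the
  home base re-anchors the animal to the room. The generative process
  behind the real drift is unknown; this is the simplest process whose
  variance grows with path length.
* **Reanchoring.** At the first lever contact of a trial the internal
  position is translated so the lever maps to a fixed stored torus phase —
  a pure phase translation, orientation preserved. `phase_noise_sd`
  degrades the stored phase (anchoring strength decreases monotonically
  with it) and `rotate_at_reanchor` injects an orientation change for
  control analyses. At each door opening the internal position snaps back
  to the true position (room reanchoring).
* **Homing coupling.** The homing heading error equals
  `coupling_gain` × current drift + noise (sd 0.15 rad), so decoded trial
  drift predicts homing direction when the gain is positive.

What the generator does **not** emulate: theta rhythmicity and bursting,
conjunctive head-direction or speed coding (an optional multiplicative
head-direction gain exists but defaults to off), multiple modules,
non-stationary firing rates, and tracking noise. Passing tests therefore
show the analyses recover the modeled phenomena from Poisson spiking at
realistic rates; they do not certify performance on every property of real
recordings. In particular, real grid cells carry temporal structure beyond
inhomogeneous-Poisson position coding, which a sequence decoder can
exploit; decoding precision on purely Poisson populations is accordingly
somewhat lower than on comparable real sessions (see the acceptance
analyses).

## Anchoring statistics

The inferred object position on the torus is
$\psi = v + T(R_\mathrm{corr}(\mathbf{x}_\mathrm{object} -
\mathbf{x}_\mathrm{mouse}))$ where $T$ is the Cartesian-to-torus transform
and $R_\mathrm{corr}$ the session-wise rotation correction. The bivariate
von Mises fit estimates the two marginal concentrations $k_0,k_1$ by the
standard three-regime inversion of the mean resultant length, capped at
$10^3$; anchoring strength is $(k_0+k_1)/2$. The marginals are fitted
independently — only the concentrations are consumed, and the full
sine-model likelihood is unidentified from them — and the moment-based
inversion is deterministic. The shuffle null adds an independent uniform
torus translation per trial (1,000 repetitions). The within-trial
timecourse caps each phase at its first 3 s and splits it into thirds; the
cap could alternatively sample the last 3 s (option), which matters only
for long homing legs.

## Numerical choices and degenerate inputs

* Angles: positions wrap to $[0,2\pi)$, deltas to $(-\pi,\pi]$, everywhere.
* Refractory ratio: 0–25-ms autocorrelation at 0.5-ms bins, ratio of the
  mean count in 0–1.5 ms to the maximum in 5–15 ms; spike counts for the
  inclusion rule use the 0–30-ms window, both as printed. A zero maximum
  makes the ratio undefined and excludes the cluster.
* Isolation distance: the radius of the smallest own-covariance Mahalanobis
  ellipsoid containing all own spikes and an equal number of other-cluster
  spikes, read as max(own maximum distance, distance of the Nth-nearest
  other spike); undefined when fewer other spikes than N exist.
* Empty spike trains produce all-zero rate maps, not errors; undefined
  grid scores (fewer than six detected fields) are distinct from low
  scores, and a cell whose shuffle scores are undefined more than half the
  time is unclassifiable.
* The at-lever zone is 10 cm from the outline of the 11.6 × 8.2 cm lever
  box, not from its center.
* Trials whose lever sits within 10 cm of the wall are flagged invalid;
  trials without a periphery crossing leave the homing errors undefined.

## Problem sizes

Routine tests run on 10–15-min foraging sessions and 25–30-trial task
blocks; the decoder's acceptance checks use a 15-cell module with the full
printed architecture on 15-min sessions (cell-count trend included); anchoring and drift acceptance checks use the simulator's
internal torus path (the `true` source) so the statistics are exercised at
full temporal resolution independently of decoder noise. The grid-fit
recovery harness uses 4-min trajectories, where the noiseless fit is
already overdetermined by two orders of magnitude.

## Known limitations

* On the 50-cm arena the grid score is phase-dependent (boundary
  truncation); classification absorbs this through the per-cell shuffle
  null, but single-map scores should not be compared across phases.
* The decoder reports lower precision on synthetic Poisson modules than
  the comparable real-data figure; the gap tracks the information content
  of the input, not the decoder implementation (training longer than the
  printed single epoch does not close it).
* `lever_vs_matched_drift` uses the final search segment preceding contact
  as the distance-matched control; other segment choices are possible and
  exposed in the function's inputs.
* The Dryad deposition adapter is a stub: `read_session()` reads this
  package's CSV bundles, not the raw deposition layout.
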
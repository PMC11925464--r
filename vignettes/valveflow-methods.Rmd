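---
title: "Methods: models, estimators and design choices in valveflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in valveflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(valveflow)
```

`valveflow` quantifies cardiac pumping performance in *Drosophila*
larvae and prepupae from video, with an emphasis on the intracardiac
valve: a pair of cells at the aorta inlet that seal the heart lumen in
diastole and deform open in systole. This vignette documents the models
behind each estimator, the tunable parameters and their defaults, what
the synthetic-scene generator does and does not emulate, and the design
decisions taken where the underlying laboratory protocol left the
numeric definition open.

## Conventions

* Arrays are indexed `[frame, row, col(, channel)]`, 1-based, with the
  anatomical posterior→anterior axis along increasing column index.
* Intensities are 8-bit units (0–255); `to_grayscale_8bit()` rescales
  the *global* stack range, never per frame, because per-frame
  normalisation would erase exactly the slow trends (dye accumulation,
  cuticle darkening) the assays measure.
* Angles are axial (θ ≡ θ + 180°), folded to [−90°, 90°), 0° =
  horizontal, positive counter-clockwise on screen. The same convention
  is used by the fiber-texture generator, the directionality histogram
  and the shape-descriptor orientation, so recovery tests close the
  loop without sign fudging.
* Frame `i` is timestamped `(i − 1) · frame_interval`; all calibration
  (frame interval, pixel size) is a required input. The original
  recordings state no optical calibration, so the package never guesses
  one: synthetic defaults pick plausible magnifications per assay
  (5 µm/px dorsal-view prepupa, 2 µm/px confocal particle field,
  50 µm/px crawling arena) and real data must bring their own numbers.

## The synthetic scenes

The generator exists because the assays' raw data are in-house
recordings; every estimator is therefore validated by parameter
recovery on rendered scenes with known truth.

**Heart scene** (`generate_heart_video()`). Hemolymph is not transported
as a continuous current but as one discrete packet per heartbeat. The
renderer takes that literally: at each systolic peak of the valve
waveform a Gaussian packet (σ 15 µm, amplitude 120) is ejected at the
valve plane and advected anteriorly at `packet_velocity`. The valve gap
follows a raised cosine between a diastolic floor
(`valve_min_gap_fraction · tube_width`, default 0) and a systolic peak
(`valve_opening_fraction · tube_width`); the cosine is a choice — no
waveform is prescribed by the protocol — made for smoothness and a
well-defined peak phase. Packet amplitude is scaled by the gap fraction
at ejection, so a valve opening to 20% of the lumen ejects packets
carrying 20% of the dye: this is the mechanism that makes the anterior
accumulation index proportional to the opening fraction. Packets
reaching the anterior margin deposit their dye as a spatially uniform
increment over the anterior zone rather than as stacked point spots —
a deliberate renderer choice that keeps the 8-bit signal below
saturation over a 30 s, ~60-beat recording, so the accumulation
readout stays linear. Gaussian pixel noise (default sd 5) and a linear
background drift (default 1 unit/s, the cuticle-darkening surrogate)
are added last. An optional second channel renders the two valve lobes
(label value 200) with the same gap waveform; the rasteriser always
keeps at least one empty pixel row between the lobes so they remain two
components, which bounds the gap-measurement error at closure by one
pixel.

Defaults are the dye-angiography recording conditions: 30 s at 100
frames/s, 2 beats/s, 5.2 mm/s packet velocity (a healthy-animal aortic
speed), 40 µm tube width.

**Particle scene** (`generate_particle_video()`). The particle assay's
physics is 1-D continuity: `speed(col) · gap(col)` is constant. The gap
narrows to `valve_opening_fraction · tube_width` at the valve plane
with a Gaussian axial profile (`valve_sigma_um`, default 25 µm), so a
half-closed lumen doubles the local speed. Particles keep their row
(laminar streamlines), are rendered as Gaussian spots (σ 1.5 px,
amplitude 200) on a second static valve-label channel, and re-enter
posteriorly after leaving the field, starting a new truth track.
Particles are seeded on rows at least `4 · spot_sigma` apart; asking
for more than that packing errors with the density limit, which also
guarantees non-crossing tracks for the linking tests. Defaults mirror
the particle recordings: 10 s at 200 frames/s; the default upstream
speed (2 mm/s) keeps per-frame steps a few pixels so that both linking
and the sampling of the speed peak are well posed at 200 fps.

**Crawl scene** (`generate_crawl_sequence()`). A capsule (default
4.5 × 0.8 mm) bends at mid-length by a scheduled angle and its centroid
follows a waypoint path at constant speed. The shape is positioned so
its *continuous* centroid (computed on a 4× supersampled grid,
independent of the rendered raster) sits on the path point; the truth
series records that centroid plus the supersampled area and
moment-ellipse axes. A silhouette touching the border raises an error,
mirroring the protocol rule of discarding larvae that reach the dish
edge.

**Fiber texture** (`generate_fiber_texture()`). Sinusoidal stripes at a
commanded orientation mixed with white noise in proportion `coherence`,
rescaled to 8-bit; the test input for directionality analysis.

What the generator does **not** emulate: optics (no PSF, no depth, no
3-D), pressure-driven hemodynamics (continuity only, no solver),
photobleaching, motion artefacts, heartbeat-rate variability,
retrograde flow, and realistic camera noise (additive Gaussian clipped
to [0, 255] only). Passing recovery tests therefore demonstrates that
the estimators are correct on their own model assumptions — not that
they are robust to every artefact of live imaging.

## Estimators

**Accumulation index.** The background is the first frame (recordings
start at injection); `frame_t − frame_0` is clipped at zero because a
dark tracer can only add signal. The protocol's "mean dye accumulation"
is ambiguous between an endpoint and an average; the index is defined
as the mean trace value over a configurable terminal window, default
the final 1 s — robust to single-frame noise while still reflecting the
30 s endpoint.

**Oscillogram.** Peaks are local maxima with topographic prominence ≥
`min_prominence` (default 20% of the baseline-to-maximum range);
plateaus report their centre sample. The baseline is the 0.1 quantile
of the trace, and the closure tolerance defaults to 20% of the median
peak height above baseline — both per-trace quantities, because
background intensity differs between animals and must be estimated per
recording. Arrests are inter-peak gaps (including trace edges) longer
than `arrest_factor` (default 2) median cycle periods; a detected
arrest starts one median period after the last pre-silence peak (where
the next beat was due) and ends at the next peak. Constant or peakless
traces yield zero peaks and a whole-span arrest with a warning, not an
error.

**Transit-time velocimetry.** Per cycle, transit time is the interval
between a packet's peak in the posterior ROI and its matching peak in
the anterior ROI; matching is order-preserving (first unused anterior
peak within one median cycle period — the protocol describes timing
one bulk, which per-cycle matching generalises). Velocity is the ROI
separation over the mean of the first `n_cycles` (default 3) transit
times. Peak times are frame-quantised by default; optional parabolic
sub-frame refinement (`refine_peaks = TRUE`) is recommended whenever
the transit spans only a handful of frames — at 100 fps, 0.465 mm ROI
separation and 8 mm/s, the transit is ~5.8 frames, so ±0.5-frame
quantisation alone is a ~9% error, and refinement is what brings the
estimator inside a 5% band. This bound is closed-form
(`dt / transit`), which is why the validation suite turns refinement on
for the velocity sweep.

**Packet segmentation.** Flood fill from a seed with
`|I − I(seed)| ≤ tolerance`, 8-connected by default (legacy wand
behaviour), switchable to 4. With `background_max` set, a seed at or
below that intensity returns a single-pixel segment with a warning
instead of flooding the background.

**Valve gap.** The valve-label channel is thresholded and labelled;
exactly two components are expected. The gap is the minimum
boundary-to-boundary distance whose direction lies within ±5° of the
perpendicular to the tube axis (the ±5° absorbs mask pixelation), and
it counts *empty pixels*: two components separated by one empty row
read 1 px, and lobes that touch and fuse into a single component read
0 (a sealed lumen — this is also how a fully closed valve appears to
any labelling algorithm). Frames with zero or more than two components
are interpolated when isolated and raise an error in runs. The
boundary-pixel (cytoplasmic border) convention follows the manual
protocol's measurement from the cytoplasmic edge of the valve cells.

**Opening time.** The protocol measures the time between two closed
valve states — from the initial luminal opening to the end of the
complete following closure. `opening_durations()` implements that
literally: an event runs from the first open frame of an opening until
the valve next begins to open, so for a periodic beat the duration is
one full period. Events need closure on both sides; openings at the
trace edges are dropped. A valve that never reaches the closed state
returns the explicit status `"cannot_estimate"` rather than a number —
the phenotype of valves that cannot seal the lumen deserves a flag,
not a fabricated duration. The closed state itself needs a numeric
criterion the protocol defines only visually: gap ≤ `closure_threshold`,
default one pixel equivalent.

**Spot detection and linking.** Detection is scale-normalised
Laplacian-of-Gaussian filtering with 3×3 local maxima above a response
threshold and per-axis parabolic sub-pixel refinement (≤ 0.25 px error
on clean spots). Linking is greedy smallest-distance-first assignment
between active track ends and new detections within `max_disp` (scaled
by the bridged gap, up to `max_gap` missed frames); every accepted link
is the mutual nearest neighbour among remaining candidates, and ties
break by lowest row then column. Greedy linking replaces the original
manual clicking; it equals the exhaustive minimum-cost assignment
whenever inter-particle spacing exceeds the step scale, which the
planted-track tests enforce and check against a full-enumeration
oracle. Step speeds are assigned to the step midpoint for region
gating (a convention; the protocol states none).

**Directionality.** Hann-windowed 2-D FFT power spectrum; each sample
outside a 3-cycle DC-exclusion radius contributes its power to the
angular bin of the image structure it represents; 90 bins of 2° over
[−90°, 90°) — the standard Fourier-components configuration. The
dominant angle is the maximal bin's centre; dispersion is the axial
circular standard deviation of the normalised histogram.

**Shape descriptors.** The fitted ellipse is the moment ellipse (axes
`4·√eigenvalue` of the pixel covariance); roundness is
`4·area/(π·major²)` with `area` the pixel-count area — the inverse
aspect ratio, 1.00 for a circle, 0.50 for a 2:1 ellipse, approaching 0
for an elongated crawler. Density normalises to the ROI area
(`fiber_density()`), with the thresholded-pixel fraction under an Otsu
or fixed threshold.

**Statistics.** `students_t_two_tailed()` is the pooled-variance
Student's test (Welch behind a flag, since the protocol names
Student's explicitly); `mann_whitney()` uses midranks with an exact
two-sided p (via the exact rank-sum distribution) for tie-free samples
with n₁+n₂ ≤ 16 and a tie- and continuity-corrected normal
approximation otherwise. No multiple-testing correction is applied —
contrasts are reported with raw p values and 0.05/0.01/0.001 stars, as
is conventional for these assays; apply a correction downstream if
your design needs one. Degenerate cases are explicit: zero variance
with equal means gives p = 1, with unequal means p = 0 plus a
`degenerate` flag; identical groups give p = 1.

## Numerical choices and degenerate inputs

* Peak ties/plateaus: centre sample; linking ties: smallest
  displacement, then lowest row, then column.
* `to_grayscale_8bit()` rounds half-up and returns an already-8-bit
  stack unchanged; a constant stack becomes zeros with a warning.
* Self-intersecting polygons and collinear vertex sets are rejected
  before any area is reported.
* Confinement ratio of a zero-length track is NA, not 0/0.
* All generator randomness flows through one seed; identical
  parameters and seed give bit-identical scenes (the RNG state of the
  caller is preserved).

## Validation problem sizes

The recovery suite runs entirely on generated scenes, sized so the
whole suite completes in minutes on one CPU: 6 s velocity scenes at
100 fps for the 2/5/8 mm/s sweep (sub-frame refinement on, see the
quantisation bound above); ten 30 s oscillograms with a 3 s injected
arrest for beat/arrest recovery; fifteen 30 s angiography scenes
(opening fractions 1.0/0.6/0.2 × 5 seeds) for the accumulation dose
response; 3 s particle scenes with 6 particles for the continuity
ratio; 5 s noise-free scenes for kinematics; 256 px textures at
coherence 0.8 for directionality; 20 planted walkers over 60 frames
with 0.5 px positional noise for linking fidelity. These sizes are
validation choices, not limits of the estimators.

## Known limitations

* `read_video()` reads multi-page TIFF only; containerised video
  (AVI/MP4) must be converted upstream — no suitable reader exists in
  the package's dependency set, and TIFF is the native export of the
  acquisition tools these assays use.
* The valve-gap measurement assumes the two lobes are the only
  above-threshold structures in the label channel; stray labelled
  debris larger than `min_component_px` invalidates frames.
* The tube axis is a config input; there is no automatic axis
  estimation.
* Greedy linking is not multi-hypothesis tracking: crossing or
  near-touching particles can swap identities, which the density limit
  prevents only in synthetic scenes.
* The accumulation index is linear in ejected dye only below 8-bit
  saturation; real recordings approaching 255 in the anterior ROI
  should be re-exposed rather than rescaled.
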
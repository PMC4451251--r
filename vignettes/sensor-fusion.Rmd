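---
title: "Fusing camera, touch and MIDI streams: methods and design choices"
author: "keyfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing camera, touch and MIDI streams: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyfusion)
```

This vignette explains the model behind `keyfusion`, its assumptions, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the problem left
them open.

## The measurement problem

A keyboard performance is observed by three devices with incompatible
coordinate systems and independent clocks:

* an overhead camera (117 fps) tracking painted markers on the hands in
  pixels;
* capacitive key-surface sensors (200 Hz per key) reporting touch
  locations normalised to each key (Y along the key length, X across it,
  only on the front 60 mm of white keys) with a device-clock timestamp in
  milliseconds and a host arrival timestamp;
* a MIDI key sensor whose events carry only host-clock timestamps.

The camera runs on a separate computer from the touch/MIDI logger, so
there are two host clocks plus the touch device's internal counter. Host
arrival times of USB devices additionally carry transport latency that can
reach hundreds of milliseconds on individual frames.

Everything downstream — which finger produced a touch, how contact timing
relates to the MIDI note, how a finger travels between two presses —
depends on getting all streams onto one timeline and into one spatial
frame first.

## Coordinate conventions

One keyboard frame is used everywhere: X in pixels increasing from bass to
treble, Y increasing from the player toward the fallboard. Image readers
flip the pixel row axis on input. Touch coordinates are normalised per
key: `y_norm` is 0 at the key's front edge and 1 at the fallboard end;
`x_norm` is 0 at the bass-side edge. The rear of a white key senses Y
only; its missing `x_norm` is preserved as `NA` in the data model and
substituted by the key centreline only where a pixel position is needed.

## Temporal alignment

1. **Camera**: timestamps are regenerated from the nominal frame rate,
   `t_i = (frame_i − frame_0) / fps`, anchoring 0 s at the first recorded
   frame. The rate is a configuration constant (default 117 Hz), not
   estimated.
2. **Touch**: the device counter may drift relative to the host clock.
   The first and last frame/timestamp pairs give the actual rate,
   `factor = Δhost / Δdevice` (host seconds per device second), and
   timestamps are regenerated as
   `t_i = host_first + factor · (device_i − device_0)/1000`. The
   difference between recorded and regenerated host times is the USB
   latency, kept as a diagnostic series only — regenerated times always
   replace arrival times. A least-squares fit over all frames is
   available (`estimate_touch_clock(..., method = "least_squares")`) and
   is more robust when the endpoint frames carry latency spikes, but the
   endpoint rule is the default reference behaviour.
3. **MIDI**: host timestamps are left untouched — there is no other time
   source for them. The camera and the MIDI/touch computer are aligned
   through anchor notes: the onsets of the first three notes are
   identified in the camera stream (supplied explicitly as a table, since
   onset identification is a visual step), and the mean of
   `camera − midi` per anchor is added to all MIDI and touch timestamps.

Alignment never mutates the raw columns (`frame_index`, `device_ms`,
`host_s`), so re-running it on an aligned bundle reproduces identical
results.

Assumptions: the camera frame rate is exact and constant; the device
drift is linear over a recording (drift factors of interest are within
±0.1%); anchor onsets are correct to the camera frame grid, which bounds
the offset error by half a frame period.

## Spatial registration

Keys are simple polygons: 4 vertices for black keys, 4–8 for white keys
(notched around their black neighbours). Marker-to-key assignment is
even-odd point-in-polygon containment with two conventions fixed where
the geometry is ambiguous:

* a point on a shared edge belongs to the **lower-numbered** key
  (deterministic tie-break);
* a point in front of the keyboard (Y below the white-key front edge) is
  assigned the white key whose front centreline is nearest in X, but only
  within the keyboard's X extent — beyond the ends no key is assigned.

Each marker is assigned independently; no hand-level consistency is
imposed, so an angled finger's distal and proximal markers may map to
different keys, which is informative rather than erroneous.

Touch-to-pixel mapping is piecewise bilinear: `y_norm` runs linearly
along the key's Y extent, and `x_norm` spans the key's X range at that
height (the wide front rectangle or the narrow rear rectangle of a white
key; the full quadrilateral of a black key, whose four corner coordinates
map exactly onto its four vertices).

Key dimensions default to 23.5 mm × 150 mm white keys and 13.5 mm ×
100 mm black keys, which makes the sensed XY region of a white key (its
wide front part plus 10 mm of the narrow part) 60 mm deep, matching the
sensor hardware's coverage.

## Keyboard detection

The polygon map can be built from a hands-free grayscale image. The three
horizontal boundaries (fallboard edge, bottom of the black keys, front of
the white keys) are found as the three strongest gradient peaks of the
row-mean intensity profile — the contract is the boundaries, not the
algorithm, and a row-projection profile is more robust than a full Hough
accumulator for an axis-aligned keyboard. Black keys are found by
automatic (Otsu) thresholding and connected-component labelling within
the boundary band, cropped to the keyboard's X extent so the background
margins cannot contaminate the threshold. The white-key grid is
reconstructed from the black-key centres (small gaps ≈ one key width,
large gaps ≈ two), note numbers are anchored at a user-supplied C4 click
— the one manual step — and the detected layout is checked against the
true black-key pattern (blacks may only follow C, D, F, G, A). Images
photographed upside-down are detected by the position of the
high-variance black-key band relative to the brightest rows and flipped
before processing.

## Spurious touches and fingering

Perspiration can register as small-area phantom touches. Touch rows whose
contact area falls below 20% of the maximum area observed **for that MIDI
note** are discarded regardless of location. Scoping the maximum per note
(rather than per block) keeps the rule idempotent and prevents an
isolated phantom block from normalising itself; it assumes each analysed
key is genuinely touched at least once in the recording. Optionally
(`marker_check`), small-area touches within one key width of a visible
distal marker are retained instead — camera confirmation of a genuine
light touch.

Touch streams are segmented per key into blocks with inter-frame gaps of
at most `gap_max_s` (default 12.5 ms = 2.5 sample periods, so one dropped
frame never splits a block; "uninterrupted" needed a concrete value).

Fingering proceeds in two passes:

1. each touch row takes the finger whose distal marker (DIP; the thumb's
   IP) has the smallest X distance in the temporally closest camera
   frame; each MIDI note takes the plurality finger of the touch rows
   within its sounding interval. Multi-touch frames contribute one count
   per touch slot — the vote weights frames × slots, since each slot is
   an independent contact observation;
2. touches inside a note inherit that note's finger; touches outside any
   note inherit the finger of the note their block connects to, and a
   block bridging two notes assigns each frame to the temporally closer
   event (previous release vs. next onset).

Tie-breaks are deterministic and documented: equal X distances go to the
lower finger number (left hand before right); tied plurality votes go to
the finger whose touches are temporally later (closest to the release).
Finger substitutions on a single held key are out of scope.

## The three analyses

**Curvature index.** `CI(t) = d(t)/d_ref` with `d_ref` captured per
finger and per phalanx from one designated flat-hand calibration frame
per session (no per-piece recalibration). The distal CI pairs the distal
marker with the touch location nearest in time; the proximal CI pairs the
distal and proximal markers. The thumb, which has no separate distal
phalanx marker, reports only its IP-to-touch relation, labelled
proximal. The printed ratio cannot be negative, but a finger bent past
its contact point is physically possible; `ci_series(..., signed = TRUE)`
negates marker–touch samples whose distal marker lies on the player side
of the touch. This signed projection is this package's reading of that
edge case and stays off by default.

**Contact timing.** Anticipatory time = first block timestamp − MIDI
onset (negative: touch precedes the press); release time = last block
timestamp − MIDI release (positive: finger lingers). The first and last
note per finger are excluded to avoid start/stop effects, as are notes
with no associated block (both counted in an attribute).

**Transition windows.** For consecutive same-finger notes, the window
runs midpoint-to-midpoint and splits into release (to the first note's
block end), no-touch, and press (from the second note's block start)
segments; degenerate orderings are clamped so the three segments always
partition the window, and same-finger notes with no touch gap are flagged
with a zero-span no-touch segment. Quantity of motion is the 2D
keyboard-frame path length (camera depth estimation is out of scope);
marker positions are linearly interpolated at segment boundaries so that
segment QoMs sum *exactly* to the window QoM. The quantity-of-motion
index `QMI = (QoM_seg/QoM_transition)·(t_transition/t_seg)` is 1 for
uniformly distributed motion; undefined cases (zero total motion,
zero-span segment) are NA, never invented. Touch-surface QoM and QMI are
reported for the release and press segments only — there is no touch
during no-touch — and the surface travel in millimetres (via the polygon
map's scale) classifies the motion: at least `slide_threshold_mm`
(default 1 mm, configurable; "significant movement" needed a number) is a
slide, less is a lift (release) or fall (press), with the threshold
itself counting as a slide.

## The synthetic-data generator

`simulate_bundle()` produces complete input bundles with ground truth. It
emulates exactly the statistical structure the pipeline assumes:

* **clocks**: camera frames on an exact grid; a touch device whose
  integer-millisecond counter drifts linearly (the device stamps frames
  from its own ms counter, so device timestamps are exact counter
  values); per-key sampling phases; host arrival times offset by the
  inter-computer offset plus optional USB latency with a heavy spike
  tail; MIDI on the host clock;
* **contacts**: per-note touch blocks leading the MIDI onset and
  outlasting the release (defaults 30 ms lead, 50 ms lag, optionally
  jittered), contact-area envelopes that stay above 60% of nominal, and
  optional moisture artifacts with areas drawn in (0, 0.15 × nominal] so
  the 20% filter removes all of them by construction;
* **kinematics**: markers ride at fixed flat-hand offsets above the
  touch points while a key is held (so a flat performance has CI exactly
  1) and travel between keys on minimum-jerk trajectories — smooth,
  endpoint-constrained, and standard in motor-control simulation;
  fingers rest on home keys placed outside the played range and retreat
  there after their last note; optional marker X jitter and occlusion;
* a flat-hand calibration segment opens every recording, and
  `anchors.csv` carries the first three note onsets quantised to the
  camera frame grid, mirroring visual identification.

Randomness is split into named sub-streams (base seed plus a fixed
per-source increment for phases, jitter, occlusion, moisture, latency,
lead/lag), so enabling one noise source never perturbs another, and
identical inputs give byte-identical bundles.

What the generator does **not** emulate — and therefore what passing
tests do not show about real recordings: physiological kinematics (the
trajectories are plausible, not biomechanical), genuinely curved
postures, hand-over-hand crossings, finger substitutions, perspective or
lens distortion, lighting variation, and marker mislabelling. The
simulator writes MIDI both as a host-time CSV and as a Standard MIDI
File; SMF carries no absolute epoch (times restart at zero), which the
alignment offset absorbs, but ground-truth offset scoring is only
meaningful on the CSV route, which the pipeline reads by default.

## Numerical choices and degenerate inputs

* Times are exchanged as decimal seconds (device counters as integer
  milliseconds); table round-trips are exact for integers and better
  than 1e-9 s for times.
* Zero-length touch streams segment into zero blocks; zero-note MIDI
  loads with a warning; an all-equal device counter is a degenerate span
  and errors; a featureless image is a detection error, not an empty
  result.
* Point-in-polygon containment counts boundary points as inside, with
  the shared-edge tie going to the lower-numbered key, so no point is
  ever assigned twice.
* Validation errors name the file and the offending rows; stage failures
  name the stage; the command-line wrapper maps validation to exit code
  2 and stage failures to 3.

## Problem sizes

The test suite validates the chain on simulated recordings of 8–200
notes: clock-drift recovery on 60 s recordings across the ±0.1% drift
range, fingering on a 200-note noise-free scale and on ten 24-note seeds
with 10%-key-width marker jitter plus 5% moisture frames, timing
recovery on 30 jittered notes, and keyboard detection on rendered
88-key and 2-octave images with additive noise. These sizes exercise
every code path while keeping the default check fast; all generators
scale to longer material.

## Known limitations

Hand separation relies on marker labels; fingering near simultaneous
same-key contacts by different fingers is inherently ambiguous for an
X-distance rule; contact areas are uncalibrated 8-bit raw values and are
never converted to physical area; pedal events are parsed and stored but
no pedal-conditioned analysis is provided; the thumb is modelled with
MCP and IP markers only, and its IP is treated as its distal-most marker
throughout.
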
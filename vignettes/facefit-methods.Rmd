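---
title: "Methods: from facial scans to respirator designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from facial scans to respirator designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facefit)
```

## The problem

Disposable respirators fail fit tests at high rates, most often around the
nose, where there is little soft tissue to absorb a mismatch between the
device and the face. `facefit` implements a workflow that summarises a 3D
facial scan in three numbers — the eye-to-chin distance, and the amplitude
`A` and spread `sigma` of a Gaussian fitted to the nasal cross-section —
and uses a cohort of such records to define a small catalogue of
semi-customised designs (three hard-shell sizes, each with three nasal
profiles). Users whose parameters fall outside the catalogue are flagged
for a fully customised device, so the labour-intensive route is reserved
for the people who need it. A flow-visualisation module grades how well a
seal performs on a model face by counting vapour pixels escaping in
high-speed footage.

## The extraction model

A scan is an STL triangle mesh plus five user-picked landmarks (outer eye
corners, chin, nose tip, nose bridge). Orientation is landmark-driven: the
canonical frame places the origin at the eye midpoint, x along the
inter-ocular axis, y vertical with the chin at negative y, and z anterior.
The convention is not dictated by the data; it is fixed here so every
downstream measurement is reproducible, and `orient_face()` is idempotent
under it.

**Eye-to-chin distance** is the Euclidean distance from the eye midpoint to
the chin landmark projected into the midsagittal plane. The projection
discards lateral chin asymmetry, and a straight-line (rather than
on-surface) distance is used: it is the quantity a rigid shell spans.

**Nasal profile.** A section plane perpendicular to the bridge-to-tip ridge
axis is cut at a configurable station (default: the ridge midpoint,
`station_fraction = 0.5`). The intersection curve is reduced to a lateral
coordinate and a height above the chord joining the section endpoints.
Chord subtraction plays the role of a baseline: the profile model

\[ f(x) = A e^{-x^2 / (2\sigma^2)} \]

has no offset term, so the baseline must be removed upstream. The curve is
resampled at 0.5 mm and fitted by damped (Levenberg–Marquardt) least
squares with analytic derivatives, initialised from the peak and the
observed half-width at half maximum (`sigma0 = HWHM / sqrt(2 log 2)`),
with tolerance 1e-8 on relative parameter change and at most 200
iterations. A fitted centre offset `c` is estimated and then removed so
reported parameters refer to the centred form; `sigma` is reported as its
absolute value. Non-convergence and non-positive peaks are flagged, never
silently returned.

**Lateral half-width.** The section is truncated at 40 mm either side of
the apex. The choice matters: the Gaussian tail at the truncation point is
absorbed into the chord baseline, biasing the fitted amplitude downwards
by roughly the tail fraction. At 30 mm the tail reaches ~4% of the peak
for the largest spreads in the adult range (`sigma` near 11.7 mm); at
40 mm it stays below 0.3%, keeping the truncation bias an order of
magnitude below the 1% recovery target. The half-width is configurable
for meshes that do not extend that far laterally.

**Ridge angle** is the inclination of the bridge-to-tip line to the
canonical facial (x–y) plane, in `[0, 90)` degrees. Semi-customised seal
geometry uses the cohort mean of this angle.

## The sizing model

Stage one fits a normal distribution to the cohort's eye-to-chin distances
by moments (mean and n−1 standard deviation; the "maximum" of the fitted
density is its mean). Three hard-shell brackets are centred on the lower
FWHM boundary, the maximum, and the upper FWHM boundary, where
`FWHM = 2 sd sqrt(2 log 2)`. Stage two repeats the construction on the
`sigma` values within each shell, giving nine (shell, profile) designs;
each cell records the mean `A` and mean `sigma` of its members.

Two quantities are deliberate configuration rather than estimates:

* **Bracket half-widths** (default 4.5 mm for eye-to-chin, 0.5 for
  `sigma`). The reference table bundled with the package implies these
  values (e.g. the Small shell spans 92.8–101.8 mm), but no rule for them
  is derivable from the data; they trade catalogue coverage against how
  much mismatch one silicone seal is asked to absorb. Any half-width below
  `FWHM/2` is valid; beyond that, non-adjacent brackets would overlap and
  construction fails.
* **Overlap membership.** Adjacent brackets overlap whenever the
  half-width exceeds `FWHM/4`. Records in an overlap contribute to the
  `sigma` distributions of both adjacent shells, which matches the intent
  that borderline users may belong to either category.

Assignment is a two-stage rule. Shells whose range contains the user's
eye-to-chin value are collected; none means the fully customised route.
With a single shell, the profile containing the user's `sigma` is chosen
(none again meaning fully customised). In an overlap, the shell with the
closest `sigma` match wins: containment in exactly one shell's profile
decides outright; containment in both is broken by the smaller distance to
the matching profile midpoint, then by the closer eye-to-chin midpoint,
then by the smaller shell. The tie-breaks are deterministic and recorded
in the assignment rationale. A fully customised flag is a valid outcome,
not an error.

Coverage is reported two ways because the published headline figure does
not state which is meant: `shell_only` (eye-to-chin within the cumulative
shell range) and `joint` (the record would actually receive a
`SEMI_CUSTOM` assignment). The assignment rule uses the joint notion.

## The flow-visualisation model

Footage is greyscale at 250 fps. The first five frames are averaged into a
background; mean images over ten frames are taken every 25 frames (one per
0.1 s) and subtracted from the background. Absolute deviations below 3
grey levels are treated as no change. The surviving mask is despeckled;
the default rule clears nonzero pixels with no nonzero 8-neighbour.
A 3×3 binary median ("majority of nine") is available as an option, but it
erodes single-pixel corners of genuine vapour regions, so isolated-pixel
removal is the default. Deviation magnitudes are then scaled by
`s(b) = 1 + b / b_max` (configurable cap) according to the background
brightness — a display aid that compensates the darker background regions
and never changes mask membership, so pixel counts are
scaling-independent.

The vapour pixel count per window is the leak measure. After the initial
transient — detected as the first time the count reaches 90% of its
maximum, appropriate for sealed runs that plateau — an ordinary
least-squares line is fitted to the remaining counts. Near-zero slopes
with a plateau near the filter-area count indicate a good seal; large
slopes indicate rapid vapour loss. For scenarios whose counts grow
steadily and never plateau the fractional rule would leave too little
data, so the post-transient window is then fixed by configuration
(`transient_end`), mirroring how a fixed analysis window would be chosen
per experiment.

## What the synthetic generators emulate

`synth_face()` builds a shallow ellipsoidal base cap (standing in for the
facial plane, so orientation and projection paths are exercised on a
curved surface) with a Gaussian ridge. The ridge displacement is applied
along the in-plane direction perpendicular to the ridge axis; because that
direction is orthogonal to the section-plane normal, the cross-section
perpendicular to the ridge is an exact Gaussian of amplitude `A` at the
mid-ridge station by construction. The base is kept very gently curved
laterally (chord sagitta below 0.05 mm over the 80 mm profile span) so the
chord baseline tracks the base surface well inside the 1% recovery budget.
The chin landmark is placed at the eye-landmark depth, which makes the
build frame coincide exactly with the landmark-defined canonical frame:
ground-truth eye-to-chin distance and ridge angle are then exact, not
approximate. Vertex noise is applied along vertex normals — more realistic
than axis-aligned jitter — and landmarks stay exact regardless of noise.
The default grid spacing is 1 mm, which keeps at least 8 vertices per
`sigma` across the adult range; coarser grids are rejected.

What the generator does *not* emulate: real facial morphology (cheek
structure, nostrils, asymmetry), scanner-specific artefacts (holes,
non-uniform triangulation), or landmark-picking error. Passing the
recovery tests therefore demonstrates that the extraction pipeline is
correct and numerically stable, not that it is robust to every real scan.

`synth_cohort()` draws the three parameters independently (no covariance
structure is published for them; this is a documented simplification),
winsorised at 3 standard deviations. Default moments
(eye-to-chin 104.85 ± 6.37 mm, `sigma` 10.1 ± 0.68, `A` 23.3 ± 1.0 mm)
are back-derived from the bundled reference table midpoints, so the
default cohort reproduces reference-like brackets.

`synth_leak_video()` renders a disc of intensity 20 grey levels above a
gradient background whose area follows a known schedule (growing at a
fixed rate, or saturating at a plateau for sealed scenarios). The
per-window ground truth accounts for window averaging: a pixel switching
on during a window clears the threshold only if its on-fraction exceeds
`threshold / amplitude`, so the exact expected count of a growing disc is
its area at the last qualifying onset frame. Vapour physics (diffusion,
buoyancy, intensity variation) is out of scope.

## Numerical choices and degenerate inputs

* STL vertices are merged at 1e-6 mm; STL stores triangles independently
  and surface queries require shared vertices. Degenerate (collapsed)
  faces are dropped; an empty result is an error.
* Rotations are validated orthonormal with determinant +1 at 1e-9.
* Deviation maps use exact point-to-triangle distances with a
  centroid/bounding-radius prune; unsigned distances were chosen because a
  sign convention adds nothing to the symmetric comparison they support.
* Profile extraction requires at least 10 intersection points and a span
  of at least twice the apparent half-width; flat or missing ridges fail
  loudly at the profile or fit stage.
* `fit_normal` refuses constant input (degenerate scale), and sizing-table
  construction names any shell with fewer than 3 members.
* All generators are deterministic given their seed; the global RNG state
  is saved and restored around every draw.

## Problem sizes used in the validation suite

The bundled tests validate parameter recovery on a 50-face sweep spanning
the reference table ranges (noiseless, and with 0.2 mm vertex noise at
1 mm mesh resolution, roughly 24k vertices per face), sizing structure on
cohorts of 10^4 (10^5 for the closed-form coverage check), and flow
visualisation on 96×96 px videos of 4–6 s at 250 fps. These sizes were
chosen so the full pipeline is exercised end-to-end while the suite stays
comfortably fast on a laptop; all tolerances quoted above are asserted at
those sizes.

## Known limitations

* Landmarks are supplied, not detected; interactive picking and automatic
  landmarking are out of scope.
* One profile station drives the fit; multi-station averaging is not
  implemented.
* The three-by-three catalogue structure is fixed; choosing the number of
  designs, or adding parameters such as facial width, is out of scope.
* Pixel counts are a semi-quantitative leak measure; converting them to
  volumetric rates would require calibration that the imaging set-up does
  not provide.
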
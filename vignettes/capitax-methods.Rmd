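---
title: "Quantifying microcapillary chemotaxis assays with capitax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microcapillary chemotaxis assays with capitax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capitax)
```

## The assay and its statistics

A two-capillary chemotaxis assay immerses a cue-filled glass microcapillary
(square bore, 200 µm inner width, 100 µm wall) and a control capillary
filled with plain medium in a dish of swimming cells, and records the dish
bottom at 30 frames per second. Dissolved cue diffusing out of the mouth
forms a point-source gradient a few hundred micrometres across. capitax
turns the recorded cell positions into four families of statistics:

1. **Accumulation profiles and decay lengths.** Time-averaged cell density
   is binned along the capillary axis inside (`axialProfile()`) and
   radially outside the entrance (`radialProfile()`), and fitted to
   `C(x) = a exp(-x/λ) + b` (`fitExponential()`). λ\_in measures the depth
   of exploration inside the capillary, λ\_out the size of the cell patch
   at the entrance. Where cells fill the first stretch of the capillary
   uniformly, a plateau-piecewise variant
   (`fitPlateauExponential()`) models a constant level up to a breakpoint
   L0 followed by the exponential decay, continuous at L0;
   `selectProfileModel()` chooses between the two by small-sample AIC
   (piecewise only when it improves AICc by more than 2).
2. **Gated maximum chemotactic indices.** Per-frame counts in the
   cue-side region (rectangle of depth λ\_in inside; semicircle of radius
   λ\_out outside) are compared with the congruent control-side region.
   The index is the mean cue count over the best 2-minute window
   (`maxMeanWindow()`) divided by the mean control count over the whole
   assay. Indices whose count difference is not significant at
   α = 0.01 by a Kruskal–Wallis rank test are gated to 1 (neutral).
3. **Trajectory straightness and chemokinesis.** The straightness index
   S = D/L (net displacement over path length) is computed on corona
   crossings classified as ingoing, outgoing, or neutral
   (`classifySegments()`, `straightness()`), and instantaneous speeds are
   related to radial distance from the source (`speedVsDistance()`).
4. **Radiotracer uptake kinetics.** Cell-fraction activities are
   blank-corrected and normalised by total cell biovolume
   (`normalizeUptake()`, dpm µm⁻³), then fitted with a saturating
   exponential `U(t) = U_sat (1 - e^{-t/τ})` plus a linear rate over the
   first 5 h (`fitUptake()`).

Every stage is validated against a built-in synthetic assay: a diffusing
point-source concentration field plus agent-based swimmers with tunable
chemotaxis, chemokinesis, and search behaviour, and (optionally) a frame
renderer feeding the tracking stage end to end.

## Coordinate system and regions

All spatial statistics use an assay frame with its origin at the centre of
the cue-capillary entrance and the first coordinate along the capillary
axis, positive inward (`assayGeometry()`, `toAssayFrame()`). The map from
image pixels is affine and exactly invertible: translate to the entrance,
flip the image y-axis (images have y growing downward), scale by the pixel
size, rotate onto the axis. Regions are:

* `insideRect(depth)` — `0 ≤ axial ≤ depth`, |transverse| ≤ 100 µm;
* `outsideSemicircle(radius)` — the half-disc in front of the entrance
  (`axial < 0`); the rear half-plane is occupied by the capillary, so the
  semicircular accumulation region is oriented forward;
* `coronaRegion(inner, outer)` and `makeCorona(rCenter)` — annuli for the
  behavioural analysis, default width 7 body lengths (140 µm);
* `neutralZone(radius)` — everything beyond `radius`.

Points inside the glass wall (100 µm thick, along the capillary) belong to
no region: cells cannot occupy glass, and excluding the wall prevents
double-counting mis-mapped detections. The forward semicircle never
intersects the wall, so no shadow correction of the semi-annulus areas is
required; `radialProfile(normalizeArea = FALSE)` disables area
normalisation altogether for raw-count histograms.

## Tracking

`estimateBackground()` takes the per-pixel temporal median of the stack —
a swimming cell visits any one pixel for a few frames only, so the median
recovers the static scene. `detectCells()` thresholds the absolute
background difference, labels connected components (via *EBImage*), and
returns intensity-weighted centroids; `linkDetections()` joins them with a
greedy nearest-neighbour rule: candidate (track, detection) pairs within
`maxDisplacement` are linked in order of increasing distance, ties by
lower detection index, so each realised link is a mutual nearest neighbour
among the unassigned candidates. Tracks may bridge up to `memory` (default
2) missing frames. The linker is deterministic and, by construction,
invariant to the ordering of detections within a frame up to exact
distance ties; the test suite bounds it against an exhaustive bipartite
matching oracle on small instances. With observed speeds up to
~300 µm s⁻¹ at 30 fps, displacements stay below ~10 µm per frame, so
`maxDisplacement` defaults should be set near 1.2 × (expected speed /
frame rate). Tracks shorter than 15 frames (0.5 s) are dropped from
analysis by default (`filterTracks()`); centroid jitter dominates shorter
tracks.

## Profile fitting

Profiles are fitted on area-normalised densities by unweighted least
squares (`minpack.lm::nlsLM`), with an optional Poisson weighting
(`weights = 1/max(count, 1)`) that is useful when bins span orders of
magnitude in count — in the recovery tests it roughly halves the sd of the
λ estimator without changing its (sub-percent) bias. Exponential
regression is prone to local minima, so fits are multi-started with
λ₀ ∈ {¼, ½, 1} × profile extent, baseline from the tail mean and amplitude
from the head–tail difference, and the best residual sum of squares wins.
λ is constrained to at most 10 × the profile extent; a fit pinned at that
bound is reported as non-decaying, and a near-constant profile returns a
degenerate fit with no λ rather than an arbitrary number. The piecewise
breakpoint is profiled exhaustively over the bin edges and then polished
by a continuous one-dimensional search between the bracketing edges
(`refine = FALSE` reproduces the pure edge search). Default bin widths are
20 µm inside and 10 µm outside, giving at least ten bins across the
smallest decay lengths the assay produces (outside patches are of order
100 µm; inside exploration ranges from ~100 µm to millimetres). Replicate
assays are summarised by the arithmetic mean of their fitted λ
(`averageDecayLength()`).

## The index gate and autocorrelation

Counts of cells in a region on consecutive frames are strongly
autocorrelated — a cell that is inside now is very likely inside 33 ms
later — so a rank test applied naively to per-frame counts treats ~18,000
frames as independent observations and rejects essentially always, even on
null data. On null simulations the nominal per-frame Kruskal–Wallis test
rejected at α = 0.01 in ~97% of runs. `chemotacticIndex()` therefore
reports two p-values: the nominal per-frame p (for comparability with
per-frame-count conventions) and a corrected p that subsamples both series
to 1 Hz and then thins them by the integrated autocorrelation time
(initial-positive-sequence estimator), capped so that at least ~10 samples
per group survive (preserving power on strongly trending series). The gate
uses the corrected p by default (`gateOn = "corrected"`); on 200-replicate
null calibrations the gate passes ≥ 95% of runs as neutral while retaining
full power at moderate chemotactic gains. The 2-minute window is the
contiguous mean-maximising window (ties broken earliest), not a window
centred on the single peak frame — the mean-maximising choice is the
better-defined of the two readings and is what `maxMeanWindow()`
implements. Zero control counts yield an infinite index with an
`undefined` flag rather than silently dropping the assay.

## Segment classification and straightness

Because S depends on trajectory length, all segment straightness values
are computed on arc-length-standardised windows, default 7 body lengths
(140 µm), within the 3–10 BL range covered by
`straightnessRobustness()`. Directional segments are runs of a trajectory
inside the corona at t > 60 s (once the patch has developed, up to 200 µm)
that *traverse* it: the net radial displacement must be at least 0.8 × the
corona width, with the entry/exit boundary points included. Two details
matter here. First, a sign-of-net-displacement rule alone admits radial
jitter at the corona boundaries into both directional classes; such
jitter is symmetric and numerous and buries any real ingoing/outgoing
difference, so the traversal requirement excludes it from both classes
alike. Second, a perfectly straight radial crossing trimmed strictly to
the corona interior has an arc length marginally *below* the corona width,
so strict trimming plus 7-BL standardisation would selectively discard the
straightest crossings — including the boundary points removes that
selection bias. Neutral segments are runs at r > 400 µm during the first
60 s, before the cue has spread that far. Group differences are tested
with two-sided Mann–Whitney rank-sum tests under Holm correction (the
significance marks in published figures of this kind rarely name a test;
rank-sum with Holm is the conservative default for three groups).

## The synthetic assay

The concentration field treats the capillary mouth as a continuously
releasing point source on a wall:
`C(r, t) = C0 + Q/(2πDr) · erfc(r/√(4Dt))` for radii beyond the mouth
radius (half-space solution, hence 2π rather than 4π), capped at the mouth
concentration closer in; inside the capillary a one-dimensional erf
profile interpolates from the mouth value to the reservoir concentration,
continuous at the entrance. With Q chosen so that the steady mouth
concentration equals the reservoir concentration (the
`gradientModel()` default), a 20 µM reservoir with D = 1000 µm² s⁻¹
(a small organic solute) gives a patch of a few hundred micrometres within
a minute — the spatial scale the assay is designed to produce. A
depleting-reservoir option (`decayingSource`) is exposed for long assays;
the default keeps the source frozen, since reservoir depletion over 10 min
from a 50 mm capillary is small.

Swimmers are 2D agents (the assay images a quasi-2D layer at the dish
bottom) with speed v₀ = 150 µm s⁻¹, rotational diffusivity
0.5 rad² s⁻¹, and body length 20 µm, integrated at dt = 1/300 s and
decimated to the 30 fps frame rate. Four sensing parameters shape the
response, all acting through the saturating occupancy C/(C + K½) with
K½ = 1 µM:

* `chi` — klinotactic steering: a deterministic turn toward the local
  gradient at angular rate `chi · v · |∇C|/(C + ε) · sin(φ∇ − θ)`
  (logarithmic sensing; ε = 10⁻⁶ µM guards the division). Default 1.
* `kappa` — chemokinesis: `v = v₀ (1 + kappa · C/(C + K½))`. Default 0.5,
  i.e. a 50% speed increase at saturating concentration, matching the
  magnitude of speed-ups reported for chemokinetic dinoflagellates.
* `turnGain` — area-restricted search: the rotational diffusivity rises by
  the same saturating factor (default gain 10), producing tortuous
  scanning paths inside the patch.
* `giveUpTime` — a searcher inside the patch (C above a quarter of the
  reservoir concentration) switches with rate 1/giveUpTime (default 15 s)
  into a *leaving* state — no steering, baseline turning — until the
  concentration falls back toward background. This reproduces the
  reversion to ballistic swimming on abandoning the patch that these
  organisms display, and it is what generates the two-regime signature
  S(outgoing) > S(ingoing): purely instantaneous or purely spatial rules
  cannot, because steering actively straightens approach paths while
  boundary jitter symmetrises the two directional classes.

Boundaries (dish edge, glass walls, closed capillary end) reflect the
heading; the mouth is open, so cells enter and explore the capillary.
Cells are seeded uniformly over the dish. All randomness flows from a
single seed (`SwimmerConfig@seed`), and repeated runs are bit-identical.

What the generator does **not** emulate: 3D helical kinematics (paths are
2D projections by construction), hydrodynamic and cell–cell interactions,
flagellar-scale speed fluctuations, prey ingestion, non-uniform
illumination or vignetting in rendered frames, and detector artefacts
beyond Gaussian pixel noise. Passing the closure tests therefore shows
that the *analysis* recovers what this class of generative model puts in —
not that real organisms obey the model.

## Numerical and testing choices

* Fits use `nlsLM` with ftol = ptol = 1e-14, so noiseless recovery is
  exact to the 1e-6 relative tolerance asserted in the tests.
* `maxMeanWindow()` uses a cumulative-sum scan; ties resolve to the
  earliest window.
* The pipeline falls back to region extents of 500 µm (inside) and
  150 µm (outside) when a profile fit is degenerate or non-decaying, as on
  null assays with nothing to fit; fitted λs are used whenever available.
* Repeated-run calibrations (null-gate calibration, chi monotonicity) use
  reduced simulations — 50 cells, 180 s, dt = 1/100 s — chosen so the
  statistical properties under test are unchanged while hundreds of
  replicates stay cheap; single-run examples keep the full defaults
  (100 cells, 600 s, dt = 1/300 s). The tracking closure test runs at the
  assay's realistic cell density (~1.4 × 10⁻⁵ cells µm⁻²); at much higher
  densities detection merging during close encounters, not the linker,
  limits recovery.
* The control side of a simulated assay pairs a plain-medium field
  (Q = 0) with insensitive swimmers (all gains zero), mirroring the
  medium-filled control capillary.

## Limitations

* The behavioural defaults (`chi`, `turnGain`, `giveUpTime`) were
  calibrated so the generator exhibits the qualitative two-regime
  structure; they are not fitted to any organism, and quantitative S or
  index values from the simulator should not be read as predictions for
  real species.
* The corrected index gate assumes the 1 Hz-thinned counts are close to
  exchangeable between cue and control under the null; systematic drifts
  common to both sides cancel, but one-sided drifts (e.g. phototaxis
  toward one capillary) would still trigger it, as they would any
  two-sample test.
* The uptake satiation comparison (`compareSatiation()`) inherits the
  fragility of two replicates per organism; it warns accordingly.
* Equivalence with any particular third-party tracking configuration is
  not claimed; tracking is validated against this package's own rendered
  ground truth.
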
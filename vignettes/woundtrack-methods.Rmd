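---
title: "Quantifying keratinocyte migration and proliferation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying keratinocyte migration and proliferation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundtrack)
```

woundtrack quantifies three complementary readouts of epithelial wound
healing: single-cell motility from nuclei-labelled time-lapse movies,
population-level gap closure in scratch assays, and marker positivity
(e.g. a proliferation marker scored together with a second antigen) in
sections of wounded, reepithelialising epidermis. Because such imaging data
are rarely deposited, the package ships generators that synthesise all three
data types with known ground truth; every stage of the analysis is
benchmarked against what the generator programmed.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic benchmarks do and do not demonstrate.

## Synthetic motility model

Three regimes mirror classic keratinocyte behaviours:

* **confined_colony** — cells adhere in stable, slowly rotating colonies.
  Positions follow an Ornstein–Uhlenbeck process around the colony centre
  (relaxation time `persistence_time`, stationary sd
  `confinement_radius / 2`) with rigid rotation at `rotation_rate`. The
  mean square displacement (MSD) therefore saturates near
  `confinement_radius^2`, well below the `4 R^2` bound asserted in the
  tests.
* **persistent** — fast single-cell migration. The heading performs wrapped
  Gaussian diffusion with angular relaxation time `persistence_time`, while
  each per-frame path length is drawn i.i.d. from an exponential
  distribution with mean `mean_speed * frame_interval`. Per-frame speeds
  are thus exactly exponential and headings uniform over the ensemble — the
  two distributional facts observed for migrating keratinocytes — and the
  MSD crosses over from ballistic to linear growth beyond the persistence
  time.
* **slow_random** — the starved phenotype: same construction with reduced
  speed and a shorter persistence time, so mean straightness
  (`d / l_path`) is strictly below the persistent regime.

A Cartesian Ornstein–Uhlenbeck *velocity* process was considered and
rejected: its stationary speeds are Rayleigh, not exponential, and fail a
Kolmogorov–Smirnov test against the exponential at the sample sizes the
suite uses. Decoupling heading persistence from exponential step lengths
satisfies both observations at once.

Two pieces of physical realism matter for benchmarking:

* **Excluded volume.** Nuclei cannot overlap. Cells are hard discs of
  radius `cell_radius` (default 8 µm): initial positions are drawn with
  minimum separation `2 * cell_radius`, and a step whose endpoint would
  violate that separation keeps its length but is redirected away from the
  nearest neighbour. Step lengths — and hence the speed distribution — are
  untouched. Without exclusion, randomly overlapping spots put a hard
  ceiling (~0.93) on achievable detection recall that no segmentation
  method could cross, which would measure the generator, not the pipeline.
* **Divisions.** Each cell divides per frame with probability
  `division_rate * frame_interval / 60`. The mother track ends; two
  daughters appear in the next frame exactly one cell radius either side of
  the mother's final position. In rendered movies the mother's final frame
  shows an enlarged spot (area × 1.5), giving the mitosis detector a
  morphological signal, as rounded-up mitotic cells do in phase-dense
  microscopy.

`render_movie()` draws each cell as a Gaussian spot (`psf_sigma` = 3 px) of
amplitude 1000 a.u. on a background of 100 a.u. with additive Gaussian noise
such that peak/noise-sd equals `snr` (default 8), then clips at zero and
rounds to integer counts, as a camera does. The rendered frame is padded by
`3 * psf_sigma` pixels so cells at the simulated field edge are fully imaged.

## Segmentation

The detection chain is white top-hat background removal (disc radius 1.5×
the expected nucleus radius), region-adaptive thresholding (a pixel is
foreground iff it exceeds its local mean over a window of four nucleus
diameters by `offset_k` × the image noise sd), watershed splitting of
touching nuclei on the smoothed Euclidean distance transform, and feature
extraction. Numerical choices:

* **Threshold offset** `offset_k = 3`. One noise sd admits ~16 % of
  background pixels and destroys precision; three sigma is the standard
  spot-detection operating point.
* **Noise estimate** — `mad(horizontal differences) / sqrt(2)`, robust to
  the sparse bright objects.
* **Watershed regularisation** — the distance map is smoothed with a
  Gaussian of sd 1 px and shallow maxima merged within depth
  (`tolerance`) 0.5 before flooding. A merge depth of 1–2 px leaves the
  canonical fused geometries (two radius-8 discs 12 px apart; two radius-5
  discs 8 px apart) joined once smoothing has flattened their saddle, while
  0.5 splits them and still never fragments a single convex nucleus.
  Watershed flooding bridges diagonally-touching pixels, so labels are
  intersected with the mask's connected components afterwards: disconnected
  foreground is never merged and the labels partition the mask exactly.
* **Perimeter and circularity** — perimeter is the closed 8-connected
  chain-code contour length; circularity is `perimeter^2 / (4 pi area)`
  (1 for a disc, larger for irregular shapes). On digitised discs of radius
  ≥ 3 px this gives 1.02–1.10; a boundary-pixel count (e.g. 0.79 for a
  radius-10 disc) would invert the "round enough" conventions the tissue
  filters rely on. Objects whose contour degenerates (< 3 points) fall back
  to the area-equivalent circle.

## Tracking

Frame-to-frame correspondence is a global linear assignment over candidate
pairs within a gate, with virtual appear/disappear nodes priced at cost 1.
The link cost mixes three terms in [0, 1] with weights α = 0.5, β = 0.25,
γ = 0.25: normalised centroid distance `d / gate`, feature dissimilarity
(mean of the normalised area and intensity differences), and local
trajectory smoothness `(1 − cos θ) / 2` for the turn angle θ against the
track's previous step. The solver is a dense Hungarian algorithm in
compiled code, verified against brute-force enumeration; ties resolve
deterministically by lowest column index.

The **gate radius** defaults to 8× the median nearest-neighbour
displacement from a greedy pre-pass. With exponential per-frame path
lengths the median is only 0.69× the mean, so a 3× gate truncates ~12 % of
true links; 8 medians ≈ 5.5 means leaves < 0.5 % of true steps outside the
gate.

**Mitosis detection** scores candidates with a three-term likelihood
(weights 1/3 each): mother roundness `min(1, 1/circularity)` at the final
pre-division frame, daughter area similarity `1 − |a1−a2|/(a1+a2)`, and
spatial symmetry `1 − |d1−d2|/(d1+d2)` of the daughters about the mother;
events with likelihood ≥ 0.6 are accepted greedily. Two candidate patterns
are scored, because a globally optimal linker almost never leaves *both*
daughters unmatched — linking the mother forward into one daughter is
cheaper than paying both a disappearance and an appearance:

1. a track ends at *t* and two new tracks start at *t+1* within the gate;
2. a track passes through *t → t+1* while one new track starts at *t+1*
   beside it — on acceptance the passing track is split at *t+1* and its
   continuation becomes a daughter with a fresh id.

Daughter candidates must persist beyond their first frame (single-frame
tracks are almost always detection artefacts), except at the end of the
movie. **Break merging** then joins a track ending at *t* to one starting
at *t+g* (gaps of 1..`max_gap` missing frames, distance ≤ `gate · g`) by a
minimal-total-distance assignment; mitosis mothers and daughters are
excluded, since their ends and starts are divisions, not breaks. Lineage
forests connect mothers to daughters, and the mitotic index is accepted
events per cell-hour of observed track time.

## Motility statistics

Per-track: run length, net displacement, per-step speeds (gaps divide by
elapsed time) and moving angles in (−π, π] from the +x axis; step angles —
not turn angles — are histogrammed for rose plots. The persistence score is

> persistence = d(x₀, x_end) / (l_path · t_path)

with `t_path` the number of observed time points; dividing by `t_path`
makes trajectories of different durations comparable. Because the placement
of that correction is a matter of convention, the uncorrected straightness
`d / l_path` is reported alongside it in `motility_summary()`. MSD uses
overlapping time-averages within each track and an unweighted ensemble
average across tracks, with `MSD(0) = 0` by definition; `fit_msd()` returns
both the linear slope (4D in 2D diffusion) and the log–log exponent.

## Scratch-assay analytics

The simulator places two confluent sheets (default 800 cells each, about
1 600 cells/mm², a realistic confluent keratinocyte density) separated by a
defined 500 µm cell-free band; fronts advance at `front_speed` with
positional jitter, each cell keeping a slowly diffusing relative position
within its stretching sheet. That slow rearrangement matters: with frozen
relative positions, the initial density fluctuation inside the gap region
persists across every frame and propagates into the closure-speed
regression instead of averaging out.

Density kinographs count cells in half-open 20 px bins along the gap axis
(the top field edge is closed so no cell is lost); speed/angle kinographs
average per-cell step values per bin, with empty bins missing. Gap coverage
is the mean density inside the gap interval over the mean density of all
flanking bins — 0 for an empty gap, 1 at confluence, reported unclamped
above 1, with `1 − coverage` exported as the relative cell-free area. The
gap interval is detected in frame 1 as the maximal run of bins below 10 %
of the median bin density, or supplied explicitly. Closure speed is the
ordinary least-squares slope of coverage against time over the pre-closure
range (before coverage first reaches 0.95), converted to a front speed by
`slope · gap_width / 2` since two fronts advance. Group comparisons use the
two-sided Mann–Whitney U test (exact by enumeration for two groups of at
most 8 without ties, normal approximation with tie correction otherwise)
and Spearman rank correlation, with the conventional star coding
(\*, \*\*, \*\*\* at 0.05, 0.01, 0.001).

## Tissue sections

The section generator renders an epidermis band over a dermis background
with a central wound of half-width `wound_half_width` (cell-free where not
reepithelialised), nuclei along the basal line (default spacing 12 µm) plus
two sparser suprabasal rows, and two marker channels whose per-nucleus
states are drawn jointly so programmed single- and double-positive
fractions hold per region, with `frac_double ≤ min(frac_m1, frac_m2)`
enforced.

**Detection** median-filters the nuclear channel (radius 2 px) and applies
a two-class Gaussian naive Bayes over filtered intensity and local
contrast. The provisional classes that seed the fit come from a robust
threshold (median + 5 MAD): nuclei occupy only a few percent of pixels, so
a histogram bisection such as Otsu splits the background noise instead and
the fitted classifier passes ~40 % of pure noise. The decision is
one-sided (bright side only): with a much wider nucleus class, the raw
two-Gaussian boundary would also capture the dim tail.

**The four-step filter cascade** then (i) removes specks below 3 px,
(ii) keeps components with circularity < 2 as potential nuclei,
(iii) watershed-splits conglomerates above 60 px, and (iv) removes split
products with circularity > 2.5 or area < 4 px. The area thresholds are
absolute pixel counts and imply small nuclei on a coarse grid; the
synthetic sections use 1 µm/px with spot sd 2 px so single nuclei sit in
the accepted band and fused pairs cross the conglomerate threshold. The
cascade is verified against a brute-force oracle that re-applies the four
rules per connected component with an independently written Moore
boundary tracer — exact label-set agreement on random masks.

**Partitioning** divides each wound side into five equal spans from the
periphery (`A`) to the wound centre (`E`), the opposite side primed;
spans without epithelium — an unhealed wound — are flagged absent, which
reproduces the expected pattern of missing central regions at early
timepoints. Whether the original regions were drawn anatomically or at
equal spacing is not recorded anywhere; equal arc length is the
reproducible choice. The basal band is the lowest 12 µm (about one cell
layer) of the epithelium in each column. Counting is restricted to nuclei
whose centroid lies in the basal band; counts are pooled over opposite
regions (`A/A'` … `E/E'`) to increase numbers, fractions are reported per
pooled region, and nucleus counts are normalised by epithelium area.
Time courses fit an ordinary least-squares trend of the double-positive
fraction against day per pooled region.

## What the synthetic benchmarks show — and what they do not

The generators reproduce the *statistical* structure the analysis assumes:
exponential speeds, uniform headings, ballistic-to-diffusive or confined
MSD, linear front advance, programmed per-region positivity with a
consistent double-positive constraint, and morphologically marked
divisions. They deliberately omit phase-contrast texture, intensity decay
and photobleaching, segmentation-relevant shape variability (all nuclei are
round spots), cell crowding beyond hard-core exclusion, out-of-focus
drift, and histological complexity (stain variability, tissue folds,
dermal autofluorescence). Passing benchmarks therefore demonstrates that
the implementation is correct under its stated model — not that the
default thresholds transfer to any particular microscope; on real data the
config-exposed parameters (nucleus radius, threshold offset, gate radius,
marker thresholds, basal-band width) are the knobs to calibrate.

Problem sizes used by the shipped tests and the acceptance script: movies
of 50 cells × 48 frames at 800 × 800 µm (1 µm/px, 30 min/frame), scratch
assays of 2 × 800 cells over 48 h, sections of 4 800 × 300 µm at 1 µm/px
with ~300 basal nuclei, 100-mask filter-cascade comparisons, and 200
random assignment instances per run.

## Reproducing the numbers

```r
# a tracked benchmark movie in six lines
gt  <- simulate_motility(motility_params("persistent", mean_speed = 0.1,
                                         n_cells = 50, n_frames = 48,
                                         division_rate = 0.02, seed = 1))
mv  <- render_movie(gt, seed = 2)
obj <- segment_stack(mv$stack, segmentation_params(nucleus_radius = 5))
res <- track_cells(obj)
evaluate_links(res$tracks, mv$truth_px)$accuracy
mitotic_index(res$lineage, res$tracks, frame_interval = 30)$rate
```

`scripts/acceptance.R` re-runs all of the above from scratch under a given
seed and writes the measured quantities as JSON; see the README.
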
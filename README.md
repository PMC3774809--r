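# woundtrack

Quantitative image analysis of epithelial wound healing in R: nuclei
segmentation and cell tracking for time-lapse movies, single-cell motility
statistics, scratch-assay gap-closure analytics, and marker-positivity
scoring of wounded-tissue sections — together with synthetic ground-truth
generators so that every stage can be benchmarked without external data.

## Who it is for

Groups measuring keratinocyte (or other epithelial cell) behaviour in
wound-healing experiments: time-lapse movies of nuclei-labelled cells,
culture-insert scratch assays with a defined cell-free gap, and stained
sections of wounded epidermis where proliferating cells are counted per
region of the healing tissue.

## What it computes

**Segmentation.** Per frame: white top-hat background removal, region-
adaptive thresholding (local mean + *k*·noise sd), watershed splitting of
touching nuclei on the smoothed Euclidean distance transform, and an object
table of centroids, areas, intensities, perimeters (chain-code contour
length) and circularity *P*²/(4π·*A*).

**Tracking.** Globally optimal frame-to-frame assignment (Hungarian
algorithm, compiled) under a cost mixing centroid distance, feature
similarity and trajectory smoothness:

cost = α·d/gate + β·feat + γ·(1 − cos θ)/2,  α + β + γ = 1

with gated candidates and unit-priced track births/deaths. Mitoses are
scored by a morphology likelihood (mother roundness, daughter area
similarity, spatial symmetry; accept at L ≥ 0.6), trajectory breaks are
re-merged by minimal total distance, and mother→daughter edges form lineage
trees from which the mitotic index (events per cell-hour) follows.

**Motility.** Recentred trajectories, per-step speeds and moving angles,
rose-plot histograms, time- and ensemble-averaged MSD with slope/exponent
fits, and the persistence score *d*(x₀, x_end)/(l_path · t_path) alongside
the plain straightness *d*/l_path.

**Gap analysis.** Time × position kinographs of cell density and speed,
per-frame gap coverage (gap density over flanking density), closure speed by
least squares on the pre-closure coverage ramp (front speed =
slope · gap/2), Mann-Whitney U (exact for small samples) and Spearman
statistics with star coding.

**Tissue quantification.** Median filter + Gaussian naive-Bayes nuclei
detection, the four-step size/circularity filter cascade (speck removal,
circularity < 2, conglomerate splitting at > 60 px, product re-testing),
ten-region partitioning of the epithelium around the wound with absent
regions flagged, basal-layer single/double marker positivity per pooled
region normalised by epithelium area, and time-course trends.

**Synthetic data.** Ground-truthed generators for all three data types:
persistent / slow / colony-confined motility (exponential per-frame speeds,
uniform headings, divisions as a Poisson process), rendered movies with
controlled SNR, closing scratch assays, and stained wound sections with
programmed per-region positive fractions.

## Worked example

```r
library(woundtrack)

gt  <- simulate_motility(motility_params("persistent", mean_speed = 0.1,
                                         n_cells = 50, n_frames = 48,
                                         division_rate = 0.02, seed = 1))
mv  <- render_movie(gt, pixel_size = 1, psf_sigma = 3, snr = 8, seed = 2)
obj <- segment_stack(mv$stack, segmentation_params(nucleus_radius = 5))
res <- track_cells(obj)

evaluate_detection(obj, mv$truth_px)[c("recall", "precision", "rmse")]
#> $recall    [1] 1
#> $precision [1] 0.9996865
#> $rmse      [1] 0.2921883
evaluate_links(res$tracks, mv$truth_px)$accuracy
#> [1] 0.9931707
mitotic_index(res$lineage, res$tracks, frame_interval = 30)$rate
#> [1] 0.02028796
```

The movie programs 50 cells dividing at 0.02 events/cell/h, imaged every
30 min for 24 h at SNR 8. Detection finds every nucleus with sub-pixel
centroid error at precision 0.9997, tracking recovers 99.3 % of the true
frame-to-frame links, and the mitotic index recovered from the
reconstructed lineage (0.0203 events/cell/h, 31 accepted events against 32
programmed divisions) estimates the programmed rate of 0.02.

For a scratch assay:

```r
scr <- simulate_scratch(gap_width = 500, front_speed = 10, n_frames = 97,
                        frame_interval = 30, seed = 5)
kin <- build_kinograph(scr$trajectories, field_width = 1700,
                       bin_width = 20, frame_interval = 30)
ser <- coverage_series(kin, frame_interval = 30)
closure_speed(ser, gap_width = diff(attr(ser, "gap_interval")))$front_speed_um_h
#> [1] 9.867099
```

a recovered front speed within 1.5 % of the programmed 10 µm/h.

## Documentation

The methods vignette (`vignettes/woundtrack-methods.Rmd`) describes the
models, parameter defaults and their rationale, numerical choices, and the
limits of what the synthetic benchmarks demonstrate.
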
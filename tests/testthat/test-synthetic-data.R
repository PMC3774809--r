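test_that("parameter validation rejects impossible settings", {
  expect_error(motility_params(mean_speed = 0), "mean_speed")
  expect_error(motility_params(n_frames = 1), "n_frames")
  expect_error(motility_params(division_rate = -1), "division_rate")
  expect_error(simulate_scratch(gap_width = 0), "gap_width")
  expect_error(section_spec(region_fractions = c(0.5, 0.4, 0.45)),
               "frac_double")
})

test_that("a single persistent cell over two frames gives one 2-point track", {
  gt <- simulate_motility(motility_params("persistent", division_rate = 0,
                                          n_cells = 1, n_frames = 2,
                                          seed = 3))
  expect_equal(nrow(gt$trajectories), 2L)
  expect_equal(unique(gt$trajectories$cell_id), 1L)
  expect_equal(nrow(gt$divisions), 0L)
})

test_that("identical seeds reproduce every generator bit-for-bit", {
  p <- motility_params("persistent", n_cells = 10, n_frames = 10,
                       division_rate = 0.05, seed = 11)
  expect_identical(simulate_motility(p), simulate_motility(p))
  gt <- simulate_motility(motility_params(n_cells = 3, n_frames = 3,
                                          field_size = c(60, 60), seed = 2))
  expect_identical(render_movie(gt, seed = 5)$stack,
                   render_movie(gt, seed = 5)$stack)
  expect_identical(simulate_scratch(n_frames = 5, cells_per_sheet = 40,
                                    seed = 7),
                   simulate_scratch(n_frames = 5, cells_per_sheet = 40,
                                    seed = 7))
  sp <- section_spec(seed = 4)
  expect_identical(synth_section(sp, field_width = 600)$channels,
                   synth_section(sp, field_width = 600)$channels)
})

test_that("per-step speeds are exponential and headings uniform", {
  p <- motility_params("persistent", mean_speed = 0.5, n_cells = 150,
                       n_frames = 80, frame_interval = 30,
                       field_size = c(4000, 4000), seed = 7)
  gt <- simulate_motility(p)
  steps <- do.call(rbind, lapply(split(gt$trajectories,
                                       gt$trajectories$cell_id),
                                 function(tr) step_stats(tr, 30, 1)$steps))
  expect_gt(nrow(steps), 1e4)
  ks <- suppressWarnings(
    stats::ks.test(steps$dist_um, "pexp", rate = 1 / (0.5 * 30)))
  expect_gt(ks$p.value, 0.01)
  h <- angle_histogram(steps$angle, 12)
  chi <- stats::chisq.test(h$count)
  expect_gt(chi$p.value, 0.01)
})

test_that("free-mode ensemble MSD grows linearly in the lag", {
  p <- motility_params("persistent", mean_speed = 0.5, n_cells = 200,
                       n_frames = 100, frame_interval = 30,
                       field_size = c(4000, 4000), seed = 7)
  gt <- simulate_motility(p)
  fit <- fit_msd(msd(gt$trajectories, max_lag = 30, frame_interval = 30))
  expect_gt(fit$exponent, 0.9)
  expect_lt(fit$exponent, 1.1)
})

test_that("confined colonies plateau below 4 R^2 per cell", {
  R <- 20
  p <- motility_params("confined_colony", mean_speed = 0.1,
                       confinement_radius = R, persistence_time = 30,
                       rotation_rate = 0.01, n_cells = 40, n_frames = 100,
                       frame_interval = 5, seed = 3)
  gt <- simulate_motility(p)
  per_cell_max <- vapply(split(gt$trajectories, gt$trajectories$cell_id),
                         function(tr) max(msd(tr, max_lag = 90)$msd_um2),
                         numeric(1))
  expect_true(all(per_cell_max <= 4 * R^2))
  m <- msd(gt$trajectories, max_lag = 90, frame_interval = 5)
  early <- m[m$lag_frames %in% 1:5, ]
  slope <- coef(lm(msd_um2 ~ lag_frames, early))[["lag_frames"]]
  extrap <- slope * max(m$lag_frames)
  expect_lt(m$msd_um2[nrow(m)] / extrap, 0.5)
})

test_that("track count equals initial cells plus net divisions", {
  p <- motility_params("persistent", n_cells = 20, n_frames = 40,
                       division_rate = 0.1, seed = 13)
  gt <- simulate_motility(p)
  for (f in c(1, 10, 25, 40)) {
    net <- sum(gt$divisions$frame < f)
    expect_equal(sum(gt$trajectories$frame == f), 20 + net)
  }
  # every division has two daughters starting at the next frame
  for (i in seq_len(nrow(gt$divisions))) {
    d <- gt$divisions[i, ]
    for (dd in c(d$daughter_id_1, d$daughter_id_2)) {
      expect_equal(min(gt$trajectories$frame[gt$trajectories$cell_id == dd]),
                   d$frame + 1)
    }
  }
  tr <- gt$trajectories
  expect_true(all(tr$x >= 0 & tr$x <= 800 & tr$y >= 0 & tr$y <= 800))
})

test_that("rendering puts a bright spot on every cell and noise elsewhere", {
  # empty field: pure noise around the background level
  empty <- structure(list(trajectories = data.frame(cell_id = integer(),
                                                    frame = integer(),
                                                    x = numeric(),
                                                    y = numeric()),
                          divisions = data.frame(mother_id = integer(),
                                                 daughter_id_1 = integer(),
                                                 daughter_id_2 = integer(),
                                                 frame = integer()),
                          field_size = c(width = 60, height = 60),
                          params = list(n_frames = 2, frame_interval = 30)),
                     class = "ground_truth")
  mv <- render_movie(empty, snr = 8, background = 100, seed = 1)
  # the camera clips negatives at 0, which lifts the mean of the clipped
  # noise above the background; the median is untouched
  expect_equal(median(mv$stack), 100, tolerance = 1)
  expect_lt(abs(mean(mv$stack) - 100), 0.2 * 1000 / 8)

  # one static cell: the brightest pixel tracks the true centroid
  still <- empty
  still$trajectories <- data.frame(cell_id = 1L, frame = 1:3,
                                   x = 30, y = 20)
  mv2 <- render_movie(still, snr = 10, seed = 2)
  for (f in 1:3) {
    img <- mv2$stack[, , f]
    w <- which(img == max(img), arr.ind = TRUE)[1, ]
    tp <- mv2$truth_px[mv2$truth_px$frame == f, ]
    expect_lt(sqrt((w["col"] - 1 - tp$x_px)^2 + (w["row"] - 1 - tp$y_px)^2),
              1.5)
  }
  expect_warning(render_movie(still, psf_sigma = 0.5, seed = 1),
                 "sub-resolution")
})

test_that("scratch geometry closes at the programmed time", {
  # static fronts: the cell-free band never fills
  gt0 <- simulate_scratch(gap_width = 300, front_speed = 0, n_frames = 6,
                          frame_interval = 30, cells_per_sheet = 150,
                          field = c(900, 200), seed = 1)
  kin <- build_kinograph(gt0$trajectories, 900, bin_width = 20,
                         frame_interval = 30)
  ser <- coverage_series(kin, gt0$params$gap_interval, frame_interval = 30)
  expect_true(all(ser$coverage < 0.05))

  # closing fronts: first gap-free frame near gap/(2 v)
  gt <- simulate_scratch(gap_width = 500, front_speed = 10.4, n_frames = 60,
                         frame_interval = 30, cells_per_sheet = 400,
                         seed = 2)
  kin2 <- build_kinograph(gt$trajectories, 1700, bin_width = 20,
                          frame_interval = 30)
  gap <- gt$params$gap_interval
  lo <- kin2$bin_edges[-length(kin2$bin_edges)]
  hi <- kin2$bin_edges[-1]
  inside <- lo >= gap[1] & hi <= gap[2]
  first_closed <- min(which(apply(kin2$density, 1,
                                  function(r) all(r[inside] > 0))))
  expected_frame <- (500 / (2 * 10.4)) * 60 / 30 + 1
  expect_lt(abs(first_closed - expected_frame), 2.5)

  one <- simulate_scratch(n_frames = 1, cells_per_sheet = 50, seed = 3)
  expect_equal(length(unique(one$trajectories$frame)), 1L)
})

test_that("synthetic sections honour programmed marker fractions", {
  # all-zero fractions leave the marker channels at background
  sp0 <- section_spec(region_fractions = c(0, 0, 0), seed = 5)
  sec0 <- synth_section(sp0, field_width = 1200)
  expect_lt(max(sec0$channels$marker1), 100 + 6 * 1000 / 8)
  expect_gt(max(sec0$channels$nuclear), 600)

  # saturated region: every nucleus there is double positive
  rf <- data.frame(region = region_labels(), frac_m1 = 0.2, frac_m2 = 0.2,
                   frac_double = 0.1)
  rf[rf$region == "B", c("frac_m1", "frac_m2", "frac_double")] <- 1
  sp1 <- section_spec(region_fractions = rf, seed = 6)
  sec1 <- synth_section(sp1, field_width = 1200)
  nb <- sec1$nuclei[sec1$nuclei$region == "B", ]
  expect_true(all(nb$m1_pos & nb$m2_pos))

  # double-positive fraction never exceeds either single fraction
  sp2 <- section_spec(region_fractions = c(0.8, 0.6, 0.5), seed = 7)
  sec2 <- synth_section(sp2)
  agg <- aggregate(cbind(m1 = sec2$nuclei$m1_pos, m2 = sec2$nuclei$m2_pos,
                         dbl = sec2$nuclei$m1_pos & sec2$nuclei$m2_pos),
                   list(region = sec2$nuclei$region), mean)
  expect_true(all(agg$dbl <= pmin(agg$m1, agg$m2) + 1e-12))
})
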
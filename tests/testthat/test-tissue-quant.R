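make_test_section <- function(seed = 9, fractions = c(0.8, 0.6, 0.5),
                              wound_half_width = 500, closed = FALSE,
                              field_width = 2400) {
  sp <- section_spec(timepoint = 1, region_fractions = fractions,
                     wound_half_width = wound_half_width,
                     epithelium_closed = closed, seed = seed)
  synth_section(sp, field_width = field_width)
}

test_that("nuclei detection finds spot cores and rejects blank fields", {
  sec <- make_test_section(field_width = 1200)
  mask <- detect_nuclei(sec$channels$nuclear, median_radius = 2)
  tr <- sec$nuclei
  hit <- mapply(function(x, y) {
    r <- round(y) + 1; c <- round(x) + 1
    any(mask[max(1, r - 1):min(nrow(mask), r + 1),
             max(1, c - 1):min(ncol(mask), c + 1)] > 0)
  }, tr$x_px, tr$y_px)
  expect_gt(mean(hit), 0.9)

  # the classifier fitted on a real section stays quiet on pure noise
  clf <- fit_nuclei_classifier(sec$channels$nuclear, median_radius = 2)
  set.seed(1)
  noise <- matrix(rnorm(200 * 200, 100, 1000 / 8), 200, 200)
  m0 <- detect_nuclei(noise, median_radius = 2, classifier = clf)
  expect_lt(mean(m0), 0.01)

  expect_error(detect_nuclei(noise, classifier = list(a = 1)),
               "nuclei_classifier")
})

test_that("the filter cascade applies its four rules in order", {
  m <- matrix(0L, 64, 96)
  m[5:6, 5] <- 1L                                   # 2 px speck: rule (i)
  m[20, 10:39] <- 1L                                # 1x30 bar: rule (ii)
  cc <- col(m); rr <- row(m)
  fused <- (cc - 60)^2 + (rr - 40)^2 <= 25 |
           (cc - 68)^2 + (rr - 40)^2 <= 25        # fused disks: rule (iii)
  m[fused] <- 1L
  m[50:54, 8:12] <- 1L                              # clean 25 px nucleus
  lab <- filter_nuclei(m)
  sets <- label_pixel_sets(lab)
  areas <- lengths(sets)
  expect_equal(length(sets), 3L)                    # 2 split products + 1
  expect_true(sum(areas > 40) == 2)                 # the two split halves
  # the speck and the bar are gone
  expect_equal(lab[5, 5], 0L)
  expect_equal(lab[20, 15], 0L)
})

test_that("the cascade agrees exactly with a brute-force pixel oracle", {
  for (s in 1:40) {
    m <- random_blob_mask(48, seed = s)
    got <- label_pixel_sets(filter_nuclei(m))
    want <- brute_filter_oracle(m)
    expect_true(same_label_sets(got, want), label = paste("mask seed", s))
  }
})

test_that("epithelium partitioning yields ten labelled regions", {
  sec <- make_test_section(closed = TRUE)
  part <- partition_epithelium(sec$epithelium_mask, sec$wound_center_px,
                               pixel_size = 1)
  expect_true(all(part$region_table$present))
  areas <- part$region_table$area_px
  expect_lt(max(areas) - min(areas), 1.5 * nrow(sec$epithelium_mask))
  # regions partition the epithelium exactly
  expect_equal(sum(areas), sum(sec$epithelium_mask))
  expect_equal(part$pooled$area_um2,
               part$region_table$area_um2[1:5] +
                 part$region_table$area_um2[6:10])

  # an open wound leaves the central regions absent
  sec2 <- make_test_section(wound_half_width = 500)
  part2 <- partition_epithelium(sec2$epithelium_mask, sec2$wound_center_px,
                                pixel_size = 1)
  tab2 <- part2$region_table
  expect_false(tab2$present[tab2$label == "E"])
  expect_false(tab2$present[tab2$label == "E'"])
  expect_true(tab2$present[tab2$label == "A"])

  expect_error(partition_epithelium(matrix(0L, 5, 5), 2), "empty")
})

test_that("positivity scoring counts basal nuclei per pooled region", {
  # hand-built scene: two nuclei, one basal and one suprabasal
  epi <- matrix(0L, 40, 60); epi[21:30, ] <- 1L
  part <- partition_epithelium(epi, 30, pixel_size = 1, basal_um = 4)
  lab <- matrix(0L, 40, 60)
  lab[28:29, 10:11] <- 1L                            # basal (bottom 4 rows)
  lab[22:23, 40:41] <- 2L                            # suprabasal
  ch1 <- matrix(0, 40, 60); ch1[28:29, 10:11] <- 500
  ch2 <- matrix(0, 40, 60)
  tab <- score_positivity(lab, list(m1 = ch1, m2 = ch2), c(100, 100), part)
  expect_equal(sum(tab$n_nuclei), 1L)                # suprabasal excluded
  expect_equal(sum(tab$n_m1_pos), 1L)
  expect_equal(sum(tab$n_m2_pos), 0L)                # all-zero channel
  expect_equal(sum(tab$n_double_pos), 0L)

  # relabelling nuclei leaves every count unchanged
  lab_perm <- lab
  lab_perm[lab == 1L] <- 2L
  lab_perm[lab == 2L] <- 1L
  tab2 <- score_positivity(lab_perm, list(m1 = ch1, m2 = ch2), c(100, 100),
                           part)
  expect_equal(tab2, tab)

  expect_error(score_positivity(lab, list(m1 = ch1), 100, part),
               "two marker")
})

test_that("programmed double-positive fractions are recovered", {
  sec <- make_test_section(seed = 21, fractions = c(0.8, 0.6, 0.5),
                           field_width = 4800)
  mask <- detect_nuclei(sec$channels$nuclear, median_radius = 2)
  lab <- filter_nuclei(mask)
  part <- partition_epithelium(sec$epithelium_mask, sec$wound_center_px,
                               pixel_size = 1)
  tab <- score_positivity(lab, sec$channels[c("marker1", "marker2")],
                          c(300, 300), part)
  scored <- tab[tab$present & tab$n_nuclei > 0, ]
  expect_gt(min(scored$n_nuclei), 30)
  for (i in seq_len(nrow(scored))) {
    n <- scored$n_nuclei[i]
    expect_lt(abs(scored$frac_double[i] - 0.5), 3 * sqrt(0.5 * 0.5 / n))
    expect_lt(abs(scored$frac_m1[i] - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  }
  expect_true(all(scored$n_double_pos <= pmin(scored$n_m1_pos,
                                              scored$n_m2_pos)))
})

test_that("time courses report least-squares trends per region", {
  mk <- function(fd) {
    data.frame(pair = paste0(LETTERS[1:5], "/", LETTERS[1:5], "'"),
               present = TRUE, n_nuclei = 50, n_m1_pos = 40, n_m2_pos = 30,
               n_double_pos = round(50 * fd), frac_m1 = 0.8, frac_m2 = 0.6,
               frac_double = fd, frac_double_of_m1 = fd / 0.8,
               nuclei_per_um2 = 0.002, area_um2 = 25000)
  }
  tc <- timecourse(list(mk(0.4), mk(0.4), mk(0.4)), c(0, 1, 2))
  expect_true(all(abs(tc$trends$slope_per_day) < 1e-12))

  tc2 <- timecourse(list(mk(0.4), mk(0.8)), c(0, 1))
  expect_true(all(abs(tc2$trends$slope_per_day - 0.4) < 1e-12))

  # noisy linear course recovered within 2 SE
  set.seed(6)
  days <- 0:4
  slope <- 0.1
  tabs <- lapply(days, function(d) mk(0.3 + slope * d + rnorm(5, 0, 0.02)))
  tc3 <- timecourse(tabs, days)
  # theoretical slope SE for noise sd 0.02 over days 0..4
  se <- 0.02 / sqrt(sum((days - mean(days))^2))
  for (i in seq_len(nrow(tc3$trends))) {
    expect_lt(abs(tc3$trends$slope_per_day[i] - slope), 3 * se)
  }
  expect_error(timecourse(list(mk(0.4)), 0), "at least 2")
})
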
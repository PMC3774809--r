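test_that("the assignment solver reproduces brute-force optima", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n, n)
    expect_equal(solve_assignment(C)$total_cost, brute_assignment_min(C),
                 tolerance = 1e-9)
  }
  # rectangular matrices: padded rows stay unassigned in the total
  C <- matrix(c(1, 5, 2, 4, 3, 6), 2, 3)
  s <- solve_assignment(C)
  expect_equal(length(s$assignment), 2L)
  expect_true(!anyNA(s$assignment))
})

test_that("frame linking gates, matches and opens/closes tracks correctly", {
  p <- link_cost_params(gate_radius = 10)
  a <- toy_objects(data.frame(frame = 1, object_id = 1, x = 5, y = 5))
  b <- toy_objects(data.frame(frame = 2, object_id = 1, x = 8, y = 5))
  lk <- link_frames(a, b, NULL, p)
  expect_equal(nrow(lk$links), 1L)

  # two static, well-separated objects: identity assignment beats the swap
  a2 <- toy_objects(data.frame(frame = 1, object_id = 1:2,
                               x = c(0, 9), y = 0))
  b2 <- toy_objects(data.frame(frame = 2, object_id = 1:2,
                               x = c(0.5, 9.5), y = 0))
  lk2 <- link_frames(a2, b2, NULL, p)
  expect_equal(lk2$links$j[order(lk2$links$i)], c(1L, 2L))
  # the swapped matching costs strictly more
  cm <- woundtrack:::link_cost_matrix(a2, b2, NULL, p)
  expect_gt(cm[1, 2] + cm[2, 1], cm[1, 1] + cm[2, 2])

  # displacement beyond the gate: no link, track closes, new track opens
  b3 <- toy_objects(data.frame(frame = 2, object_id = 1, x = 50, y = 5))
  lk3 <- link_frames(a, b3, NULL, p)
  expect_equal(nrow(lk3$links), 0L)
  expect_equal(lk3$unmatched_t, 1L)
  expect_equal(lk3$unmatched_t1, 1L)

  expect_error(link_cost_params(alpha = 0.8, beta = 0.3, gamma = 0.1),
               "must equal 1")
})

test_that("mitosis likelihood combines roundness, similarity and symmetry", {
  # perfect division: every term maximal
  expect_equal(mitosis_likelihood(1, c(20, 20), c(5, 5)), 1)
  # hand-computed mixed case
  expect_equal(mitosis_likelihood(1, c(10, 30), c(5, 5)),
               1 / 3 + (1 / 3) * 0.5 + 1 / 3)
  # irregular mother lowers the roundness term only
  expect_equal(mitosis_likelihood(2, c(20, 20), c(5, 5)),
               (1 / 3) * 0.5 + 1 / 3 + 1 / 3)
})

test_that("mitosis detection handles both daughter patterns", {
  params <- mitosis_params(gate_radius = 15)
  # a track that simply ends, nothing new nearby: no event
  tr <- rbind(
    toy_objects(data.frame(frame = 1:3, object_id = 1, x = 10, y = 10)),
    toy_objects(data.frame(frame = 1:5, object_id = 2, x = 80, y = 80)))
  tr$track_id <- rep(c(1L, 2L), c(3, 5))
  ev <- detect_mitosis(tr, params)
  expect_equal(nrow(ev), 0L)

  # pattern 1: mother ends, two equal daughters appear symmetrically
  tr2 <- rbind(
    toy_objects(data.frame(frame = 1:3, object_id = 1, x = 50, y = 50)),
    toy_objects(data.frame(frame = 4:6, object_id = 2, x = 45, y = 50)),
    toy_objects(data.frame(frame = 4:6, object_id = 3, x = 55, y = 50)),
    toy_objects(data.frame(frame = 1:6, object_id = 4, x = 200, y = 200)))
  tr2$track_id <- rep(c(1L, 2L, 3L, 4L), c(3, 3, 3, 6))
  tr2$circularity[tr2$track_id == 1 & tr2$frame == 3] <- 1
  ev2 <- detect_mitosis(tr2, params)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$mother_id, 1L)
  expect_equal(sort(c(ev2$daughter_id_1, ev2$daughter_id_2)), c(2L, 3L))
  expect_equal(ev2$likelihood, 1)

  # pattern 2: the linker continued the mother into one daughter; the track
  # is split and the post-division part gets a new id
  tr3 <- rbind(
    toy_objects(data.frame(frame = 1:6, object_id = 1,
                           x = c(50, 50, 50, 45, 44, 43), y = 50)),
    toy_objects(data.frame(frame = 4:6, object_id = 2, x = 55, y = 50)),
    toy_objects(data.frame(frame = 1:6, object_id = 4, x = 200, y = 200)))
  tr3$track_id <- rep(c(1L, 2L, 4L), c(6, 3, 6))
  tr3$circularity[tr3$track_id == 1 & tr3$frame == 3] <- 1
  ev3 <- detect_mitosis(tr3, params)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$frame, 3)
  out <- attr(ev3, "tracks")
  expect_equal(max(out$frame[out$track_id == 1]), 3)       # mother ends at t
  d1 <- ev3$daughter_id_1
  expect_equal(min(out$frame[out$track_id == d1]), 4)
})

test_that("trajectory breaks are bridged up to the allowed gap", {
  # remove one middle detection from a simulated track and re-join it
  tr <- toy_objects(data.frame(frame = 1:10, object_id = 1,
                               x = seq(0, 27, 3), y = 5))
  tr <- tr[tr$frame != 6, ]
  tr$track_id <- c(rep(1L, 5), rep(2L, 4))
  merged <- merge_breaks(tr, max_gap = 3, gate_radius = 5)
  expect_equal(unique(merged$track_id), 1L)
  expect_equal(nrow(merged), 9L)                            # points conserved
  expect_true(all(diff(merged$frame) > 0))

  # a gap of max_gap + 2 frames stays broken
  tr2 <- tr
  tr2$frame[tr2$track_id == 2] <- tr2$frame[tr2$track_id == 2] + 4
  merged2 <- merge_breaks(tr2, max_gap = 3, gate_radius = 5)
  expect_equal(sort(unique(merged2$track_id)), c(1L, 2L))

  # with two candidate continuations the nearer one wins
  tr3 <- rbind(
    toy_objects(data.frame(frame = 1:4, object_id = 1, x = 10, y = 10)),
    toy_objects(data.frame(frame = 6:8, object_id = 2, x = 12, y = 10)),
    toy_objects(data.frame(frame = 6:8, object_id = 3, x = 18, y = 10)))
  tr3$track_id <- rep(1:3, c(4, 3, 3))
  merged3 <- merge_breaks(tr3, max_gap = 3, gate_radius = 5)
  expect_equal(merged3$track_id[merged3$frame == 6 & merged3$x == 12], 1L)
  expect_true(3L %in% merged3$track_id)
})

test_that("lineage forests assemble and validate", {
  tr <- toy_objects(data.frame(frame = rep(1:2, 3), object_id = 1,
                               x = rep(c(0, 40, 80), each = 2), y = 0))
  tr$track_id <- rep(1:3, each = 2)
  no_mit <- data.frame(mother_id = integer(), daughter_id_1 = integer(),
                       daughter_id_2 = integer(), frame = integer(),
                       likelihood = numeric())
  lin <- build_lineage(tr, no_mit)
  expect_equal(length(lin$roots), 3L)
  expect_equal(nrow(lin$edges), 0L)

  mit <- data.frame(mother_id = 1L, daughter_id_1 = 2L, daughter_id_2 = 3L,
                    frame = 1L, likelihood = 0.9)
  lin2 <- build_lineage(tr, mit)
  expect_equal(lin2$roots, 1L)
  expect_equal(nrow(lin2$edges), 2L)

  # two sequential divisions: a depth-2 tree with four leaves
  tr3 <- toy_objects(data.frame(frame = rep(1:2, 7), object_id = 1,
                                x = rep(seq(0, 240, 40), each = 2), y = 0))
  tr3$track_id <- rep(1:7, each = 2)
  mit3 <- rbind(mit,
                data.frame(mother_id = 2L, daughter_id_1 = 4L,
                           daughter_id_2 = 5L, frame = 2L, likelihood = 0.8))
  lin3 <- build_lineage(tr3, mit3)
  leaves <- setdiff(lin3$nodes$track_id, lin3$edges$mother)
  expect_equal(lin3$roots, c(1L, 6L, 7L))
  expect_equal(sort(setdiff(leaves, c(6L, 7L))), c(3L, 4L, 5L))

  bad <- rbind(mit, data.frame(mother_id = 4L, daughter_id_1 = 2L,
                               daughter_id_2 = 5L, frame = 2L,
                               likelihood = 0.7))
  expect_error(build_lineage(tr3, bad), "two mothers")
})

test_that("the mitotic index recovers a programmed division rate", {
  tr <- toy_objects(data.frame(frame = 1:11, object_id = 1, x = 0, y = 0))
  tr$track_id <- 1L
  no_mit <- data.frame(mother_id = integer(), daughter_id_1 = integer(),
                       daughter_id_2 = integer(), frame = integer(),
                       likelihood = numeric())
  lin <- build_lineage(tr, no_mit)
  expect_equal(mitotic_index(lin, tr, 60)$rate, 0)

  # 5 events over 100 cell hours -> 0.05 per cell per hour
  tr2 <- do.call(rbind, lapply(1:10, function(k) {
    d <- toy_objects(data.frame(frame = 1:11, object_id = k, x = 10 * k,
                                y = 0))
    d$track_id <- k
    d
  }))
  mit <- data.frame(mother_id = 1:5, daughter_id_1 = 11:15,
                    daughter_id_2 = 16:20, frame = 5L, likelihood = 1)
  lin2 <- list(mitoses = mit)
  class(lin2) <- "lineage_tree"
  expect_equal(mitotic_index(lin2, tr2, 60)$rate, 0.05)

  # Poisson recovery from the generator's own ground truth
  lambda <- 0.04
  gt <- simulate_motility(motility_params("persistent", n_cells = 60,
                                          n_frames = 60,
                                          division_rate = lambda,
                                          field_size = c(2000, 2000),
                                          seed = 19))
  gt_tracks <- data.frame(track_id = gt$trajectories$cell_id,
                          frame = gt$trajectories$frame,
                          x = gt$trajectories$x, y = gt$trajectories$y)
  lin3 <- list(mitoses = gt$divisions)
  class(lin3) <- "lineage_tree"
  mi <- mitotic_index(lin3, gt_tracks, 30)
  se <- sqrt(mi$n_events) / mi$cell_hours
  expect_lt(abs(mi$rate - lambda), 3 * se)
})
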
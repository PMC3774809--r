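# Benchmarking against synthetic ground truth: detection, linking and
# mitosis performance of the pipeline on rendered movies.

# greedy one-to-one matching of detections to true positions by increasing
# distance, capped at tol px; returns data.frame (det, truth, dist)
match_points <- function(det_xy, truth_xy, tol = 3) {
  nd <- nrow(det_xy); nt <- nrow(truth_xy)
  if (!nd || !nt)
    return(data.frame(det = integer(), truth = integer(), dist = numeric()))
  d <- sqrt(outer(det_xy[, 1], truth_xy[, 1], "-")^2 +
            outer(det_xy[, 2], truth_xy[, 2], "-")^2)
  cand <- which(d <= tol, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(det = integer(), truth = integer(), dist = numeric()))
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (used_d[r] || used_t[c]) next
    keep[i] <- TRUE; used_d[r] <- TRUE; used_t[c] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(det = cand[, 1], truth = cand[, 2], dist = d[cand])
}

#' Detection performance against ground truth
#'
#' Matches detected objects to true positions per frame (one-to-one, within
#' `tol` px) and reports recall, precision and centroid RMSE.
#'
#' @param objects ObjectTable with `frame`, `x`, `y` (px).
#' @param truth_px ground-truth table with `frame`, `x_px`, `y_px`.
#' @param tol matching tolerance in px.
#' @return list: `recall`, `precision`, `rmse`, `n_truth`, `n_detected`.
#' @export
evaluate_detection <- function(objects, truth_px, tol = 3) {
  frames <- sort(unique(truth_px$frame))
  n_match <- 0; n_det <- 0; n_tru <- 0; sq <- c()
  for (f in frames) {
    det <- objects[objects$frame == f, c("x", "y"), drop = FALSE]
    tru <- truth_px[truth_px$frame == f, c("x_px", "y_px"), drop = FALSE]
    m <- match_points(as.matrix(det), as.matrix(tru), tol)
    n_match <- n_match + nrow(m)
    n_det <- n_det + nrow(det)
    n_tru <- n_tru + nrow(tru)
    sq <- c(sq, m$dist^2)
  }
  list(recall = n_match / n_tru, precision = n_match / n_det,
       rmse = sqrt(mean(sq)), n_truth = n_tru, n_detected = n_det)
}

#' Link accuracy of tracking against ground truth
#'
#' A ground-truth link is a pair of consecutive observed frames of the same
#' true cell. It counts as recovered when both endpoints are matched to
#' detections (within `tol` px) that belong to the same reconstructed track.
#'
#' @param tracks tracks data.frame (`track_id`, `frame`, `x`, `y`).
#' @param truth_px ground-truth table (`cell_id`, `frame`, `x_px`, `y_px`).
#' @param tol matching tolerance in px.
#' @return list: `accuracy`, `n_links`, `n_recovered`.
#' @export
evaluate_links <- function(tracks, truth_px, tol = 3) {
  frames <- sort(unique(truth_px$frame))
  # map (frame, truth row) -> track_id
  map <- list()
  for (f in frames) {
    det <- tracks[tracks$frame == f, , drop = FALSE]
    tru <- truth_px[truth_px$frame == f, , drop = FALSE]
    m <- match_points(as.matrix(det[, c("x", "y")]),
                      as.matrix(tru[, c("x_px", "y_px")]), tol)
    ids <- rep(NA_integer_, nrow(tru))
    ids[m$truth] <- det$track_id[m$det]
    map[[as.character(f)]] <- setNames(ids, tru$cell_id)
  }
  n_links <- 0L; n_rec <- 0L
  for (fi in seq_len(length(frames) - 1)) {
    a <- map[[as.character(frames[fi])]]
    b <- map[[as.character(frames[fi + 1])]]
    common <- intersect(names(a), names(b))
    n_links <- n_links + length(common)
    n_rec <- n_rec + sum(!is.na(a[common]) & !is.na(b[common]) &
                           a[common] == b[common])
  }
  list(accuracy = n_rec / n_links, n_links = n_links, n_recovered = n_rec)
}

#' Mitosis-detection performance against ground truth
#'
#' A detected mitosis matches a true division when the mother's final
#' position lies within `tol_px` of the true mother's final position and the
#' frames differ by at most `tol_frames`.
#'
#' @param mitoses detected mitosis table ([detect_mitosis()]).
#' @param tracks tracks data.frame (for mother end positions).
#' @param divisions true division table (`mother_id`, `frame`).
#' @param truth_px ground-truth positions (`cell_id`, `frame`, `x_px`,
#'   `y_px`).
#' @param tol_px,tol_frames matching tolerances.
#' @return list: `recall`, `precision`, `n_true`, `n_detected`.
#' @export
evaluate_mitoses <- function(mitoses, tracks, divisions, truth_px,
                             tol_px = 10, tol_frames = 1) {
  n_true <- nrow(divisions); n_det <- nrow(mitoses)
  if (!n_true || !n_det)
    return(list(recall = ifelse(n_true == 0, NA, 0),
                precision = ifelse(n_det == 0, NA, 0),
                n_true = n_true, n_detected = n_det))
  det_end <- do.call(rbind, lapply(seq_len(n_det), function(i) {
    tr <- tracks[tracks$track_id == mitoses$mother_id[i], ]
    tr <- tr[which.max(tr$frame), ]
    data.frame(x = tr$x, y = tr$y, frame = mitoses$frame[i])
  }))
  true_end <- do.call(rbind, lapply(seq_len(n_true), function(i) {
    tp <- truth_px[truth_px$cell_id == divisions$mother_id[i] &
                   truth_px$frame == divisions$frame[i], ]
    data.frame(x = tp$x_px[1], y = tp$y_px[1], frame = divisions$frame[i])
  }))
  used <- logical(n_true)
  matched <- 0L
  for (i in seq_len(n_det)) {
    ok <- which(!used &
                abs(true_end$frame - det_end$frame[i]) <= tol_frames &
                sqrt((true_end$x - det_end$x[i])^2 +
                     (true_end$y - det_end$y[i])^2) <= tol_px)
    if (length(ok)) { used[ok[1]] <- TRUE; matched <- matched + 1L }
  }
  list(recall = matched / n_true, precision = matched / n_det,
       n_true = n_true, n_detected = n_det)
}
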
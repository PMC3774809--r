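# Trajectory tables use one row per (track, frame) with columns
# (track_id | cell_id), frame, x, y. All motility statistics are computed
# per track and converted to physical units via pixel_size (um/px) and
# frame_interval (min/frame); pass 1 for data already in um and min.

track_col <- function(df) {
  for (nm in c("track_id", "cell_id")) if (nm %in% names(df)) return(nm)
  stop("trajectory table needs a 'track_id' or 'cell_id' column")
}

#' Recentre trajectories to a common origin
#'
#' Shifts every trajectory so its first point is (0, 0) - the standard
#' rescaling for trajectory "hairball" displays; relative geometry is
#' unchanged.
#'
#' @param trajectories data.frame with track id, `frame`, `x`, `y`.
#' @return the same data.frame with shifted coordinates.
#' @export
recenter <- function(trajectories) {
  id <- track_col(trajectories)
  trajectories <- trajectories[order(trajectories[[id]], trajectories$frame), ]
  first <- !duplicated(trajectories[[id]])
  x0 <- trajectories$x[first][match(trajectories[[id]],
                                    trajectories[[id]][first])]
  y0 <- trajectories$y[first][match(trajectories[[id]],
                                    trajectories[[id]][first])]
  trajectories$x <- trajectories$x - x0
  trajectories$y <- trajectories$y - y0
  rownames(trajectories) <- NULL
  trajectories
}

#' Per-step speeds and moving angles of one trajectory
#'
#' Speed is computed from two consecutive observations; frame gaps divide by
#' the elapsed time. Angles are measured from the +x axis in (-pi, pi].
#'
#' @param trajectory data.frame (one track) with `frame`, `x`, `y` (px).
#' @param frame_interval min per frame.
#' @param pixel_size um per px.
#' @return list: `steps` (data.frame frame_from, frame_to, dt_min, dist_um,
#'   speed_um_min, angle), `run_length` (um), `net_displacement` (um),
#'   `t_path` (number of time points), `mean_speed` (um/min).
#' @export
step_stats <- function(trajectory, frame_interval = 1, pixel_size = 1) {
  tr <- trajectory[order(trajectory$frame), ]
  n <- nrow(tr)
  if (n < 2) {
    return(list(steps = data.frame(frame_from = integer(),
                                   frame_to = integer(), dt_min = numeric(),
                                   dist_um = numeric(),
                                   speed_um_min = numeric(),
                                   angle = numeric()),
                run_length = 0, net_displacement = 0, t_path = n,
                mean_speed = NA_real_))
  }
  dx <- diff(tr$x) * pixel_size
  dy <- diff(tr$y) * pixel_size
  dfr <- diff(tr$frame)
  dist <- sqrt(dx^2 + dy^2)
  dt <- dfr * frame_interval
  steps <- data.frame(frame_from = tr$frame[-n], frame_to = tr$frame[-1],
                      dt_min = dt, dist_um = dist, speed_um_min = dist / dt,
                      angle = atan2(dy, dx))
  net <- sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2) * pixel_size
  list(steps = steps, run_length = sum(dist), net_displacement = net,
       t_path = n, mean_speed = mean(steps$speed_um_min))
}

#' Directional persistence of a trajectory
#'
#' `persistence = d(x0, xend) / (l_path * t_path)`: the net start-to-end
#' displacement over the path length, divided by the number of time points
#' so that trajectories of different durations are comparable. A trajectory
#' that never moves scores 0. The uncorrected straightness `d / l_path` is
#' reported separately by [motility_summary()].
#'
#' @param trajectory data.frame (one track) with `frame`, `x`, `y`.
#' @return dimensionless persistence score (>= 0).
#' @export
persistence <- function(trajectory) {
  st <- step_stats(trajectory)
  if (st$t_path < 2) stop("persistence needs at least 2 points")
  if (st$run_length == 0) return(0)
  st$net_displacement / (st$run_length * st$t_path)
}

#' Per-track motility summary
#'
#' @param tracks data.frame with track id, `frame`, `x`, `y` (px).
#' @param frame_interval min per frame.
#' @param pixel_size um per px.
#' @return data.frame with one row per track: `run_length_um`,
#'   `net_displacement_um`, `t_path`, `mean_speed_um_min`, `persistence`
#'   (d / (l * t_path)) and `straightness` (d / l).
#' @export
motility_summary <- function(tracks, frame_interval = 1, pixel_size = 1) {
  id <- track_col(tracks)
  out <- lapply(split(tracks, tracks[[id]]), function(tr) {
    st <- step_stats(tr, frame_interval, pixel_size)
    data.frame(track_id = tr[[id]][1],
               run_length_um = st$run_length,
               net_displacement_um = st$net_displacement,
               t_path = st$t_path,
               mean_speed_um_min = st$mean_speed,
               persistence = if (st$run_length > 0)
                 st$net_displacement / (st$run_length * st$t_path) else 0,
               straightness = if (st$run_length > 0)
                 st$net_displacement / st$run_length else 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ensemble mean square displacement
#'
#' Time-averaged over all start times within each track (overlapping pairs),
#' then averaged without weighting across tracks. Lags longer than a track
#' are skipped for that track.
#'
#' @param tracks data.frame with track id, `frame`, `x`, `y` (px).
#' @param max_lag maximal lag in frames.
#' @param frame_interval min per frame.
#' @param pixel_size um per px.
#' @return data.frame: `lag_frames`, `lag_min`, `msd_um2`, `n_tracks`, `se`
#'   (sd across tracks / sqrt(n)); includes the exact `MSD(0) = 0` row.
#' @export
msd <- function(tracks, max_lag = 20, frame_interval = 1, pixel_size = 1) {
  id <- track_col(tracks)
  per_track <- lapply(split(tracks, tracks[[id]]), function(tr) {
    tr <- tr[order(tr$frame), ]
    # index positions by frame to respect gaps
    fr <- tr$frame - min(tr$frame) + 1L
    x <- rep(NA_real_, max(fr)); y <- x
    x[fr] <- tr$x; y[fr] <- tr$y
    vapply(seq_len(max_lag), function(tau) {
      if (tau >= length(x)) return(NA_real_)
      d2 <- (x[seq_len(length(x) - tau) + tau] - x[seq_len(length(x) - tau)])^2 +
            (y[seq_len(length(y) - tau) + tau] - y[seq_len(length(y) - tau)])^2
      if (all(is.na(d2))) NA_real_ else mean(d2, na.rm = TRUE)
    }, numeric(1))
  })
  mat <- do.call(rbind, per_track) * pixel_size^2
  msd_mean <- colMeans(mat, na.rm = TRUE)
  n_tr <- colSums(!is.na(mat))
  se <- apply(mat, 2, sd, na.rm = TRUE) / sqrt(pmax(n_tr, 1))
  out <- data.frame(lag_frames = 0:max_lag,
                    lag_min = (0:max_lag) * frame_interval,
                    msd_um2 = c(0, msd_mean),
                    n_tracks = c(length(per_track), n_tr),
                    se = c(0, se))
  out[!is.nan(out$msd_um2), ]
}

#' Fit the MSD curve
#'
#' Least squares of `msd ~ lag` (slope, for a diffusion estimate: slope =
#' 4D in 2D) and of `log(msd) ~ log(lag)` (anomalous exponent; 1 for
#' diffusive, 2 for ballistic, < 1 for confined motion).
#'
#' @param msd_curve data.frame from [msd()].
#' @param lags which positive lags (frames) to fit; default all present.
#' @return list: `slope` (um^2/min), `exponent`, `D` (um^2/min).
#' @export
fit_msd <- function(msd_curve, lags = NULL) {
  m <- msd_curve[msd_curve$lag_frames > 0 & msd_curve$msd_um2 > 0, ]
  if (!is.null(lags)) m <- m[m$lag_frames %in% lags, ]
  if (nrow(m) < 2) stop("need at least two positive lags to fit")
  slope <- coef(lm(msd_um2 ~ lag_min, data = m))[["lag_min"]]
  expo <- coef(lm(log(msd_um2) ~ log(lag_min), data = m))[["log(lag_min)"]]
  list(slope = slope, exponent = expo, D = slope / 4)
}

#' Rose-plot histogram of moving angles
#'
#' @param angles numeric vector of angles in (-pi, pi].
#' @param n_sectors number of angular sectors (>= 4).
#' @return data.frame: `sector`, `lo`, `hi`, `mid` (radians), `count`;
#'   counts sum to `length(angles)` (NAs dropped).
#' @export
angle_histogram <- function(angles, n_sectors = 12) {
  if (n_sectors < 4) stop("n_sectors must be >= 4")
  angles <- angles[!is.na(angles)]
  breaks <- seq(-pi, pi, length.out = n_sectors + 1)
  idx <- findInterval(angles, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  data.frame(sector = seq_len(n_sectors),
             lo = breaks[-length(breaks)], hi = breaks[-1],
             mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             count = tabulate(idx, nbins = n_sectors))
}
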
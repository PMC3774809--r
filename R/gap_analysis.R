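# Scratch-assay analytics: time x position kinographs of cell density and
# speed across the gap axis (x), per-frame gap coverage, and regression-based
# closure speed.

#' Contiguous half-open bins along the gap axis
#'
#' @param field_width field width (px or um, matching the positions binned).
#' @param bin_width bin width, same units (> 0).
#' @return numeric vector of bin edges covering `[0, field_width]`.
#' @export
make_bins <- function(field_width, bin_width = 20) {
  check_positive(bin_width, "bin_width")
  seq(0, ceiling(field_width / bin_width) * bin_width, by = bin_width)
}

bin_index <- function(x, bin_edges) {
  # half-open [lo, hi) convention: a point on an interior edge counts to the
  # right bin; the top field edge is closed so no cell is lost
  findInterval(x, bin_edges, left.open = FALSE, rightmost.closed = TRUE)
}

#' Cell-density kinograph
#'
#' Counts cells per half-open interval `[x, x + dx)` along the gap axis for
#' every frame. Row sums equal the number of cells present in each frame.
#'
#' @param positions data.frame with `frame` and `x`.
#' @param bin_edges from [make_bins()].
#' @return matrix frames x bins (dimnames: frame, bin lower edge).
#' @export
density_profile <- function(positions, bin_edges) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be increasing")
  frames <- sort(unique(positions$frame))
  nb <- length(bin_edges) - 1
  out <- matrix(0L, length(frames), nb,
                dimnames = list(frame = frames, bin = bin_edges[-length(bin_edges)]))
  idx <- bin_index(positions$x, bin_edges)
  ok <- idx >= 1 & idx <= nb
  tab <- table(factor(positions$frame[ok], levels = frames),
               factor(idx[ok], levels = seq_len(nb)))
  out[] <- as.integer(tab)
  out
}

#' Speed and angle kinograph
#'
#' Per frame and bin, the unweighted mean of per-cell step speed and angle;
#' empty bins are `NA`. Each step is attributed to the bin of its starting
#' x position.
#'
#' @param steps data.frame with `frame`, `x` (step start), `speed`, `angle`.
#' @param bin_edges from [make_bins()].
#' @return list of two matrices `speed` and `angle` (frames x bins).
#' @export
speed_angle_profile <- function(steps, bin_edges) {
  frames <- sort(unique(steps$frame))
  nb <- length(bin_edges) - 1
  dn <- list(frame = frames, bin = bin_edges[-length(bin_edges)])
  sp <- matrix(NA_real_, length(frames), nb, dimnames = dn)
  an <- sp
  idx <- bin_index(steps$x, bin_edges)
  ok <- idx >= 1 & idx <= nb
  if (any(ok)) {
    key <- split(seq_len(nrow(steps))[ok],
                 list(factor(steps$frame[ok], levels = frames),
                      factor(idx[ok], levels = seq_len(nb))), drop = TRUE)
    for (nm in names(key)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      fi <- match(as.numeric(parts[1]), frames)
      bi <- as.integer(parts[2])
      sp[fi, bi] <- mean(steps$speed[key[[nm]]])
      an[fi, bi] <- mean(steps$angle[key[[nm]]])
    }
  }
  list(speed = sp, angle = an)
}

#' Assemble a kinograph from tracked cells
#'
#' Builds the density matrix from all positions and the speed/angle matrices
#' from per-track steps ([step_stats()]).
#'
#' @param tracks data.frame with track id, `frame`, `x`, `y` (px).
#' @param field_width field width in px.
#' @param bin_width bin width in px.
#' @param frame_interval min per frame.
#' @param pixel_size um per px.
#' @return object of class `kinograph`: `bin_edges` (px), `frames`,
#'   `density`, `speed` (um/min), `angle` (rad).
#' @export
build_kinograph <- function(tracks, field_width, bin_width = 20,
                            frame_interval = 1, pixel_size = 1) {
  bin_edges <- make_bins(field_width, bin_width)
  dens <- density_profile(tracks, bin_edges)
  id <- track_col(tracks)
  steps <- do.call(rbind, lapply(split(tracks, tracks[[id]]), function(tr) {
    st <- step_stats(tr, frame_interval, pixel_size)$steps
    if (!nrow(st)) return(NULL)
    tr <- tr[order(tr$frame), ]
    data.frame(frame = st$frame_from, x = tr$x[-nrow(tr)],
               speed = st$speed_um_min, angle = st$angle)
  }))
  sa <- if (is.null(steps))
    list(speed = dens * NA_real_, angle = dens * NA_real_)
  else speed_angle_profile(steps, bin_edges)
  structure(list(bin_edges = bin_edges, frames = as.numeric(rownames(dens)),
                 density = dens, speed = sa$speed, angle = sa$angle),
            class = "kinograph")
}

#' Detect the cell-free gap interval from the first frame
#'
#' The gap is the maximal run of bins whose density falls below `frac` times
#' the median bin density of the field.
#'
#' @param density_row numeric vector (one kinograph row).
#' @param bin_edges bin edges.
#' @param frac threshold as a fraction of the median density.
#' @return c(x_lo, x_hi) of the gap, or NULL when no bin qualifies.
#' @export
detect_gap_interval <- function(density_row, bin_edges, frac = 0.1) {
  thr <- frac * median(density_row)
  low <- density_row < thr
  if (!any(low)) return(NULL)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(bin_edges[starts[best]], bin_edges[ends[best] + 1])
}

#' Gap coverage of one frame
#'
#' The ratio of the mean cell density inside the gap interval to the mean
#' density of the flanking bins. 0 for an empty gap, 1 once the gap matches
#' the surrounding sheet; values above 1 (over-filling) are reported
#' unclamped. `1 - coverage` is the relative cell-free area.
#'
#' @param density_row numeric vector (one kinograph row).
#' @param bin_edges bin edges.
#' @param gap_interval c(x_lo, x_hi) of the cell-free band.
#' @return coverage fraction, or NA when the flanking density is zero.
#' @export
gap_coverage <- function(density_row, bin_edges, gap_interval) {
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  inside <- lo >= gap_interval[1] & hi <= gap_interval[2]
  if (!any(inside) || all(inside))
    stop("gap interval must cover some but not all bins")
  flank <- mean(density_row[!inside])
  if (flank == 0) return(NA_real_)
  mean(density_row[inside]) / flank
}

#' Gap-coverage time series of a kinograph
#'
#' @param kin a `kinograph`.
#' @param gap_interval c(x_lo, x_hi) px; when NULL it is detected from the
#'   first frame ([detect_gap_interval()]).
#' @param frame_interval min per frame.
#' @return object of class `gap_coverage_series`: data.frame `frame`,
#'   `time_h`, `coverage`, plus the gap interval as an attribute.
#' @export
coverage_series <- function(kin, gap_interval = NULL, frame_interval = 1) {
  stopifnot(inherits(kin, "kinograph"))
  if (is.null(gap_interval))
    gap_interval <- detect_gap_interval(kin$density[1, ], kin$bin_edges)
  if (is.null(gap_interval)) stop("no cell-free gap detected in frame 1")
  cov <- apply(kin$density, 1, gap_coverage, bin_edges = kin$bin_edges,
               gap_interval = gap_interval)
  out <- data.frame(frame = kin$frames,
                    time_h = (kin$frames - kin$frames[1]) * frame_interval / 60,
                    coverage = as.numeric(cov))
  attr(out, "gap_interval") <- gap_interval
  class(out) <- c("gap_coverage_series", "data.frame")
  out
}

#' Closure speed by linear regression of the coverage series
#'
#' Ordinary least squares of coverage against time over the pre-closure
#' range (frames before coverage first reaches `saturation`). Since two
#' fronts fill the gap, the front speed is `slope * gap_width / 2`.
#'
#' @param series data.frame with `time_h` and `coverage` (NA rows dropped).
#' @param gap_width gap width in um.
#' @param saturation coverage level ending the fit range.
#' @return list: `slope_per_h`, `intercept`, `front_speed_um_h`,
#'   `fit_frames` (number of points used).
#' @export
closure_speed <- function(series, gap_width, saturation = 0.95) {
  s <- series[!is.na(series$coverage), ]
  if (!nrow(s)) stop("coverage series is all missing")
  sat <- which(s$coverage >= saturation)
  if (length(sat)) s <- s[seq_len(sat[1]), ]
  if (nrow(s) < 3) stop("need at least 3 pre-closure frames to fit")
  fit <- lm(coverage ~ time_h, data = s)
  slope <- coef(fit)[["time_h"]]
  list(slope_per_h = slope, intercept = coef(fit)[["(Intercept)"]],
       front_speed_um_h = slope * gap_width / 2, fit_frames = nrow(s))
}

#' Significance stars at the conventional thresholds
#'
#' @param p p-value.
#' @return "***" (p < 0.001), "**" (p < 0.01), "*" (p < 0.05), else "n.s.".
#' @export
signif_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}

#' Compare per-cell metrics between groups
#'
#' Two-sided Mann-Whitney U test for two independent groups (exact by
#' enumeration when both groups have at most 8 observations and no ties,
#' normal approximation with tie correction otherwise), or Spearman rank
#' correlation for paired vectors.
#'
#' @param x,y numeric vectors: the two groups (Mann-Whitney) or the paired
#'   variables (Spearman).
#' @param method "mann-whitney" or "spearman".
#' @return list: `statistic` (U, or rho), `p_value`, `stars`, `method`.
#' @export
compare_groups <- function(x, y, method = c("mann-whitney", "spearman")) {
  method <- match.arg(method)
  if (method == "mann-whitney") {
    if (length(x) < 2 || length(y) < 2)
      stop("each group needs at least 2 observations")
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- length(x) <= 8 && length(y) <= 8 && !ties
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact,
                                       alternative = "two.sided"))
    res <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    if (length(x) != length(y)) stop("paired vectors must have equal length")
    if (length(x) < 2) stop("need at least 2 pairs")
    ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
    res <- list(statistic = unname(ht$estimate), p_value = ht$p.value)
  }
  res$stars <- signif_stars(res$p_value)
  res$method <- method
  res
}

#' Heat-map display of a kinograph
#'
#' Time runs down the y axis, position along x, matching the conventional
#' kinograph layout.
#'
#' @param kin a `kinograph`.
#' @param which "density", "speed" or "angle".
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot_kinograph <- function(kin, which = c("density", "speed", "angle"), ...) {
  which <- match.arg(which)
  m <- kin[[which]]
  xm <- kin$bin_edges[-length(kin$bin_edges)] + diff(kin$bin_edges) / 2
  graphics::image(x = xm, y = kin$frames, z = t(m[rev(seq_len(nrow(m))), ]),
                  xlab = "position (px)", ylab = "frame",
                  main = paste("kinograph:", which),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(m)
}
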
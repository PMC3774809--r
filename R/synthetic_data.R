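#' Parameters for the synthetic motility simulator
#'
#' Three regimes mirror the canonical behaviours of cultured keratinocytes:
#' `confined_colony` (cells attached in stable, slowly rotating colonies, so
#' mean square displacement saturates), `persistent` (fast single-cell
#' migration with directional persistence), and `slow_random` (starved cells:
#' same persistence structure, strongly reduced speed).
#'
#' In the two free regimes each cell performs a persistent random walk: its
#' heading diffuses with angular relaxation time `persistence_time` while the
#' per-frame path length is drawn i.i.d. from an exponential distribution
#' with mean `mean_speed * frame_interval`. Per-frame speeds are therefore
#' exponentially distributed and step headings are uniform over the ensemble,
#' while the MSD crosses over from ballistic to linear growth beyond the
#' persistence time. The confined regime is an Ornstein-Uhlenbeck position
#' process around a colony centre with superimposed rigid rotation, so the
#' MSD plateaus near `confinement_radius^2`.
#'
#' @param mode one of `"persistent"`, `"slow_random"`, `"confined_colony"`.
#' @param mean_speed mean speed in um/min (> 0).
#' @param persistence_time directional (or positional, for the confined mode)
#'   relaxation time in min.
#' @param confinement_radius colony confinement radius in um (confined mode).
#' @param rotation_rate colony rotation in rad/min (confined mode).
#' @param division_rate division events per cell per hour (>= 0).
#' @param n_cells number of initial cells.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval time between frames in min.
#' @param field_size c(width, height) of the field of view in um.
#' @param cell_radius nominal cell radius in um; daughters are placed one
#'   radius either side of the mother.
#' @param seed integer seed; identical seeds give bit-identical simulations.
#' @return an object of class `motility_params`.
#' @export
motility_params <- function(mode = c("persistent", "slow_random", "confined_colony"),
                            mean_speed = 0.5,
                            persistence_time = 20,
                            confinement_radius = 20,
                            rotation_rate = 0.01,
                            division_rate = 0,
                            n_cells = 50,
                            n_frames = 49,
                            frame_interval = 30,
                            field_size = c(800, 800),
                            cell_radius = 8,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "slow_random" && missing(mean_speed)) mean_speed <- 0.1
  if (mode == "slow_random" && missing(persistence_time)) persistence_time <- 10
  check_positive(mean_speed, "mean_speed")
  check_positive(persistence_time, "persistence_time")
  check_positive(frame_interval, "frame_interval")
  check_positive(confinement_radius, "confinement_radius")
  check_nonneg(division_rate, "division_rate")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (n_cells < 1) stop("n_cells must be >= 1")
  structure(list(mode = mode, mean_speed = mean_speed,
                 persistence_time = persistence_time,
                 confinement_radius = confinement_radius,
                 rotation_rate = rotation_rate,
                 division_rate = division_rate,
                 n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 field_size = field_size,
                 cell_radius = cell_radius,
                 seed = as.integer(seed)),
            class = "motility_params")
}

reflect_into <- function(x, lo, hi) {
  # reflect coordinates into [lo, hi] (period 2*(hi-lo))
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  y + lo
}

#' Simulate ground-truthed cell trajectories
#'
#' Runs the regime selected in `params` (see [motility_params()]) and returns
#' trajectories in micrometre coordinates together with all division events.
#' Divisions are a per-frame Bernoulli process with probability
#' `division_rate * frame_interval / 60`; a dividing mother's track ends and
#' two daughter tracks start in the next frame, offset one cell radius either
#' side of the mother's final position.
#'
#' @param params a [motility_params()] object.
#' @return an object of class `ground_truth`: a list with `trajectories`
#'   (data.frame: cell_id, frame, x, y in um), `divisions` (data.frame:
#'   mother_id, daughter_id_1, daughter_id_2, frame), `field_size` and
#'   `params`.
#' @export
simulate_motility <- function(params) {
  stopifnot(inherits(params, "motility_params"))
  set.seed(params$seed)
  p <- params
  dt <- p$frame_interval
  W <- p$field_size[1]; H <- p$field_size[2]
  p_div <- min(1, p$division_rate * dt / 60)

  confined <- p$mode == "confined_colony"
  n <- p$n_cells
  centre <- c(W / 2, H / 2)
  d_min <- 2 * p$cell_radius            # hard-core nucleus separation
  if (confined) {
    sigma_st <- p$confinement_radius / 2
    lambda <- exp(-dt / p$persistence_time)
    sigma_noise <- sigma_st * sqrt(1 - lambda^2)
    phi <- p$rotation_rate * dt
    x <- centre[1] + rnorm(n, 0, sigma_st)
    y <- centre[2] + rnorm(n, 0, sigma_st)
  } else {
    # uniform placement with minimum separation (dart throwing)
    x <- numeric(n); y <- numeric(n)
    for (i in seq_len(n)) {
      for (tr_ in 1:200) {
        cx <- runif(1, 0, W); cy <- runif(1, 0, H)
        if (i == 1 ||
            min((x[seq_len(i - 1)] - cx)^2 +
                (y[seq_len(i - 1)] - cy)^2) >= d_min^2) break
      }
      x[i] <- cx; y[i] <- cy
    }
    theta <- runif(n, -pi, pi)
    sd_theta <- sqrt(2 * dt / p$persistence_time)
  }
  id <- seq_len(n)
  next_id <- n + 1L
  newborn <- rep(FALSE, n)   # daughters skip the move on their spawn frame
  rows <- vector("list", p$n_frames)
  divs <- list()

  for (f in seq_len(p$n_frames)) {
    rows[[f]] <- data.frame(cell_id = id, frame = f, x = x, y = y)
    if (f == p$n_frames) break

    # divisions settled before the move to frame f+1
    if (p_div > 0 && length(id) > 0) {
      dividing <- runif(length(id)) < p_div
      if (any(dividing)) {
        for (k in which(dividing)) {
          ang <- runif(1, -pi, pi)
          off <- p$cell_radius * c(cos(ang), sin(ang))
          d1 <- next_id; d2 <- next_id + 1L
          next_id <- next_id + 2L
          divs[[length(divs) + 1L]] <-
            data.frame(mother_id = id[k], daughter_id_1 = d1,
                       daughter_id_2 = d2, frame = f)
          id <- c(id, d1, d2)
          x <- c(x, x[k] + off[1], x[k] - off[1])
          y <- c(y, y[k] + off[2], y[k] - off[2])
          newborn <- c(newborn, TRUE, TRUE)
          if (!confined) theta <- c(theta, runif(2, -pi, pi))
        }
        keep <- !seq_along(id) %in% which(dividing)
        id <- id[keep]; x <- x[keep]; y <- y[keep]
        newborn <- newborn[keep]
        if (!confined) theta <- theta[keep]
      }
    }

    if (confined) {
      mv <- !newborn
      dx <- x[mv] - centre[1]; dy <- y[mv] - centre[2]
      rx <- cos(phi) * dx - sin(phi) * dy
      ry <- sin(phi) * dx + cos(phi) * dy
      x[mv] <- centre[1] + lambda * rx + rnorm(sum(mv), 0, sigma_noise)
      y[mv] <- centre[2] + lambda * ry + rnorm(sum(mv), 0, sigma_noise)
    } else {
      theta <- theta + rnorm(length(theta), 0, sd_theta)
      step <- rexp(length(x), rate = 1 / (p$mean_speed * dt))
      # excluded volume: a step whose endpoint violates the hard-core
      # separation keeps its length but is redirected directly away from
      # the nearest neighbour, so per-step speeds stay exactly exponential
      for (k in seq_along(x)) {
        if (newborn[k]) next
        px_ <- x[k] + step[k] * cos(theta[k])
        py_ <- y[k] + step[k] * sin(theta[k])
        if (length(x) > 1) {
          d2 <- (x[-k] - px_)^2 + (y[-k] - py_)^2
          if (min(d2) < d_min^2) {
            jj <- (seq_along(x)[-k])[which.min(d2)]
            away <- atan2(y[k] - y[jj], x[k] - x[jj])
            if (!is.finite(away)) away <- theta[k]
            theta[k] <- away
            px_ <- x[k] + step[k] * cos(away)
            py_ <- y[k] + step[k] * sin(away)
          }
        }
        x[k] <- px_; y[k] <- py_
      }
    }
    x <- reflect_into(x, 0, W)
    y <- reflect_into(y, 0, H)
    newborn[] <- FALSE
  }

  trajectories <- do.call(rbind, rows)
  trajectories <- trajectories[order(trajectories$cell_id, trajectories$frame), ]
  rownames(trajectories) <- NULL
  divisions <- if (length(divs)) do.call(rbind, divs) else
    data.frame(mother_id = integer(), daughter_id_1 = integer(),
               daughter_id_2 = integer(), frame = integer())
  structure(list(trajectories = trajectories, divisions = divisions,
                 field_size = c(width = W, height = H), params = p),
            class = "ground_truth")
}

#' Render a simulated movie as an image stack
#'
#' Each cell becomes a Gaussian intensity spot of width `psf_sigma` on a
#' constant background with additive Gaussian noise scaled so that
#' peak / noise-sd = `snr`. A dividing mother's final frame is rendered
#' enlarged (area x 1.5) to give the mitosis detector a morphological signal.
#' Intensities are rounded to integer analog-digital units so that a written
#' 16-bit TIFF round-trips bit-exactly.
#'
#' @param truth a `ground_truth` object (coordinates in um).
#' @param pixel_size um per pixel.
#' @param psf_sigma Gaussian spot sd in px.
#' @param snr peak amplitude over noise sd.
#' @param background background level, a.u.
#' @param amplitude spot peak amplitude, a.u.
#' @param pad border padding in px so spots at the field edge are fully
#'   imaged (the field of view covers the simulated field with a margin).
#' @param seed seed for the rendering noise.
#' @return a list of class `synthetic_movie`: `stack` (array y, x, frame),
#'   `truth_px` (trajectories with 0-based `x_px`, `y_px`), `divisions_px`,
#'   and the rendering parameters.
#' @export
render_movie <- function(truth, pixel_size = 1, psf_sigma = 3, snr = 8,
                         background = 100, amplitude = 1000,
                         pad = ceiling(3 * psf_sigma), seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  check_positive(pixel_size, "pixel_size")
  check_positive(snr, "snr")
  if (2 * psf_sigma < 2)
    warning("rendered spot diameter is below 2 px (sub-resolution)")
  set.seed(seed)
  nx <- ceiling(truth$field_size[["width"]] / pixel_size) + 2L * pad
  ny <- ceiling(truth$field_size[["height"]] / pixel_size) + 2L * pad
  n_frames <- if (nrow(truth$trajectories)) max(truth$trajectories$frame) else
    truth$params$n_frames
  if (is.null(n_frames) || !length(n_frames)) n_frames <- 1L

  tr <- truth$trajectories
  tr$x_px <- tr$x / pixel_size + pad
  tr$y_px <- tr$y / pixel_size + pad
  # mark each mother's final frame for enlarged rendering
  tr$enlarged <- rep(FALSE, nrow(tr))
  if (nrow(truth$divisions)) {
    key <- paste(truth$divisions$mother_id, truth$divisions$frame)
    tr$enlarged <- paste(tr$cell_id, tr$frame) %in% key
  }

  noise_sd <- amplitude / snr
  halfw <- ceiling(4 * psf_sigma * sqrt(1.5))
  stack <- array(0, dim = c(ny, nx, n_frames))
  for (f in seq_len(n_frames)) {
    img <- matrix(background, ny, nx)
    sub <- tr[tr$frame == f, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      sig <- psf_sigma * if (sub$enlarged[k]) sqrt(1.5) else 1
      cx <- sub$x_px[k]; cy <- sub$y_px[k]
      c0 <- max(1L, floor(cx) + 1L - halfw); c1 <- min(nx, floor(cx) + 1L + halfw)
      r0 <- max(1L, floor(cy) + 1L - halfw); r1 <- min(ny, floor(cy) + 1L + halfw)
      if (c0 > c1 || r0 > r1) next
      xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
      g <- amplitude * outer(exp(-(ys - cy)^2 / (2 * sig^2)),
                             exp(-(xs - cx)^2 / (2 * sig^2)))
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g
    }
    img <- img + rnorm(length(img), 0, noise_sd)
    stack[, , f] <- round(pmax(img, 0))
  }

  truth_px <- tr[, c("cell_id", "frame", "x_px", "y_px")]
  structure(list(stack = stack, truth_px = truth_px,
                 divisions = truth$divisions, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, snr = snr, background = background,
                 amplitude = amplitude,
                 frame_interval = truth$params$frame_interval),
            class = "synthetic_movie")
}

#' Simulate a scratch (gap-closure) assay
#'
#' Two confluent cell sheets are separated by a vertical cell-free band of
#' width `gap_width` (the culture-insert geometry: a defined, cell-free gap).
#' Both fronts advance toward the gap centre at `front_speed`; each cell keeps
#' its relative position within the stretching sheet plus positional jitter,
#' so trajectories are smooth and trackable.
#'
#' @param gap_width initial cell-free gap width, um.
#' @param front_speed advance speed of each front, um/h.
#' @param n_frames number of frames.
#' @param frame_interval min between frames.
#' @param cells_per_sheet cells in each sheet.
#' @param field c(width, height) um; the gap is centred in x.
#' @param jitter_sd positional jitter sd, um.
#' @param seed integer seed.
#' @return a `ground_truth` object; `params` carries `gap_interval`
#'   (c(x_lo, x_hi) um of the initial cell-free band) and `front_speed`.
#' @export
simulate_scratch <- function(gap_width = 500, front_speed = 10, n_frames = 49,
                             frame_interval = 30, cells_per_sheet = 800,
                             field = c(1700, 300), jitter_sd = 2, seed = 1L) {
  check_positive(gap_width, "gap_width")
  check_nonneg(front_speed, "front_speed")
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(seed)
  W <- field[1]; H <- field[2]
  if (gap_width >= W) stop("gap_width must be smaller than the field width")
  xL0 <- (W - gap_width) / 2
  xR0 <- xL0 + gap_width

  n <- cells_per_sheet
  qL <- runif(n); qR <- runif(n)        # relative positions within each sheet
  yL <- runif(n, 0, H); yR <- runif(n, 0, H)
  jL <- rnorm(n, 0, jitter_sd); jR <- rnorm(n, 0, jitter_sd)

  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    t_h <- (f - 1) * frame_interval / 60
    adv <- min(front_speed * t_h, gap_width / 2)
    xL <- xL0 + adv                      # left front position
    xR <- xR0 - adv
    if (f > 1) {
      jL <- 0.7 * jL + rnorm(n, 0, jitter_sd * sqrt(1 - 0.7^2))
      jR <- 0.7 * jR + rnorm(n, 0, jitter_sd * sqrt(1 - 0.7^2))
      yL <- reflect_into(yL + rnorm(n, 0, 1), 0, H)
      yR <- reflect_into(yR + rnorm(n, 0, 1), 0, H)
      # cells slowly rearrange within the sheet, so local density
      # fluctuations decorrelate over time instead of freezing in
      qL <- reflect_into(qL + rnorm(n, 0, 0.004), 0, 1)
      qR <- reflect_into(qR + rnorm(n, 0, 0.004), 0, 1)
    }
    x_left <- pmin(pmax(qL * xL + jL, 0), W)
    x_right <- pmax(pmin(W - qR * (W - xR) + jR, W), 0)
    rows[[f]] <- data.frame(
      cell_id = c(seq_len(n), n + seq_len(n)),
      frame = f,
      x = c(x_left, x_right),
      y = c(yL, yR))
  }
  trajectories <- do.call(rbind, rows)
  trajectories <- trajectories[order(trajectories$cell_id, trajectories$frame), ]
  rownames(trajectories) <- NULL
  params <- list(gap_width = gap_width, front_speed = front_speed,
                 n_frames = as.integer(n_frames), frame_interval = frame_interval,
                 gap_interval = c(xL0, xR0), cells_per_sheet = cells_per_sheet,
                 seed = as.integer(seed))
  structure(list(trajectories = trajectories,
                 divisions = data.frame(mother_id = integer(),
                                        daughter_id_1 = integer(),
                                        daughter_id_2 = integer(),
                                        frame = integer()),
                 field_size = c(width = W, height = H), params = params),
            class = "ground_truth")
}

#' Specification of a synthetic wounded-tissue section
#'
#' Describes one timepoint of a wound-healing kinetic: the wound geometry and
#' the per-region fractions of nuclei positive for each of two markers (for
#' example a proliferation marker and a cytosolic marker scored together).
#' Regions are labelled `A` (periphery) to `E` (wound centre) on one side and
#' `A'`..`E'` on the other, matching a ten-region partition of the section.
#'
#' @param timepoint days after wounding.
#' @param region_fractions data.frame with columns `region`, `frac_m1`,
#'   `frac_m2`, `frac_double`; or a numeric length-3 vector applied to all ten
#'   regions. `frac_double <= min(frac_m1, frac_m2)` is required.
#' @param wound_half_width half-width of the unhealed wound, um (ignored when
#'   `epithelium_closed`).
#' @param epithelium_closed logical; has the epithelium closed over the wound?
#' @param nuclei_density nuclei per um of basal line.
#' @param seed integer seed.
#' @return an object of class `section_spec`.
#' @export
section_spec <- function(timepoint = 0,
                         region_fractions = c(0.5, 0.4, 0.3),
                         wound_half_width = 500,
                         epithelium_closed = FALSE,
                         nuclei_density = 1 / 12,
                         seed = 1L) {
  labels <- region_labels()
  if (is.numeric(region_fractions) && length(region_fractions) == 3) {
    region_fractions <- data.frame(region = labels,
                                   frac_m1 = region_fractions[1],
                                   frac_m2 = region_fractions[2],
                                   frac_double = region_fractions[3])
  }
  rf <- region_fractions
  stopifnot(is.data.frame(rf),
            all(c("region", "frac_m1", "frac_m2", "frac_double") %in% names(rf)))
  if (!all(rf$region %in% labels))
    stop("region labels must be among ", paste(labels, collapse = ", "))
  if (any(rf$frac_m1 < 0 | rf$frac_m1 > 1 | rf$frac_m2 < 0 | rf$frac_m2 > 1 |
          rf$frac_double < 0))
    stop("fractions must lie in [0, 1]")
  if (any(rf$frac_double > pmin(rf$frac_m1, rf$frac_m2) + 1e-12))
    stop("frac_double must not exceed min(frac_m1, frac_m2)")
  check_positive(wound_half_width, "wound_half_width")
  check_positive(nuclei_density, "nuclei_density")
  structure(list(timepoint = timepoint, region_fractions = rf,
                 wound_half_width = wound_half_width,
                 epithelium_closed = isTRUE(epithelium_closed),
                 nuclei_density = nuclei_density, seed = as.integer(seed)),
            class = "section_spec")
}

#' Region labels of the ten-region wound partition
#' @return character vector `A..E, A'..E'`.
#' @export
region_labels <- function() {
  c(LETTERS[1:5], paste0(LETTERS[1:5], "'"))
}

# region label for x positions (um) given wound centre and field width;
# unprimed labels left of the wound, primed right; A peripheral, E central.
region_of_x <- function(x, centre, width) {
  left <- x < centre
  lab <- character(length(x))
  binw_l <- centre / 5
  binw_r <- (width - centre) / 5
  idx_l <- pmin(5L, floor(x[left] / binw_l) + 1L)
  lab[left] <- LETTERS[idx_l]
  idx_r <- pmin(5L, floor((width - x[!left]) / binw_r) + 1L)
  lab[!left] <- paste0(LETTERS[idx_r], "'")
  lab
}

#' Render a synthetic stained wound section
#'
#' Builds an epidermis band over a dermis background with a central wound of
#' width `2 * wound_half_width` (cell-free where not reepithelialised),
#' places nuclei along the basal line and in suprabasal rows, and draws each
#' nucleus's two marker states jointly so that the programmed single- and
#' double-positive fractions hold per region. Channels are rendered as
#' Gaussian spots plus noise, like [render_movie()].
#'
#' @param spec a [section_spec()].
#' @param pixel_size um per pixel.
#' @param field_width section width, um.
#' @param field_height section height, um.
#' @param epi_top y (um) of the top of the epidermis band.
#' @param epi_thickness thickness of the epidermis band, um.
#' @param suprabasal_rows number of suprabasal nucleus rows.
#' @param psf_sigma nucleus spot sd, px.
#' @param snr,background,amplitude rendering parameters as in [render_movie()].
#' @return a list of class `synthetic_section`: `channels` (list of matrices
#'   `nuclear`, `marker1`, `marker2`), `nuclei` (ground-truth table with
#'   region, basal flag and marker states), `epithelium_mask`,
#'   `wound_center_px`, `pixel_size`, `spec`.
#' @export
synth_section <- function(spec, pixel_size = 1, field_width = 4800,
                          field_height = 300, epi_top = 100,
                          epi_thickness = 60, suprabasal_rows = 2,
                          psf_sigma = 2, snr = 8, background = 100,
                          amplitude = 1000) {
  stopifnot(inherits(spec, "section_spec"))
  set.seed(spec$seed)
  W <- field_width; H <- field_height
  centre <- W / 2
  epi_bottom <- epi_top + epi_thickness

  covered <- function(x) {
    if (spec$epithelium_closed) rep(TRUE, length(x))
    else abs(x - centre) >= spec$wound_half_width
  }

  # basal nuclei along the basal line, suprabasal rows above
  spacing <- 1 / spec$nuclei_density
  xs <- seq(spacing / 2, W - spacing / 2, by = spacing)
  nuc <- list()
  for (row in 0:suprabasal_rows) {
    keep <- if (row == 0) xs else xs[seq_along(xs) %% 2 == 0]  # sparser above
    x <- keep + rnorm(length(keep), 0, spacing / 6)
    x <- pmin(pmax(x, 0), W)
    y <- epi_bottom - 6 - row * 18 + rnorm(length(x), 0, 2)
    nuc[[row + 1L]] <- data.frame(x_um = x, y_um = y, basal = row == 0)
  }
  nuclei <- do.call(rbind, nuc)
  nuclei <- nuclei[covered(nuclei$x_um), , drop = FALSE]
  nuclei$region <- region_of_x(nuclei$x_um, centre, W)
  nuclei$nucleus_id <- seq_len(nrow(nuclei))

  # joint marker states per region
  rf <- spec$region_fractions
  nuclei$m1_pos <- rep(FALSE, nrow(nuclei))
  nuclei$m2_pos <- rep(FALSE, nrow(nuclei))
  for (i in seq_len(nrow(rf))) {
    in_r <- nuclei$region == rf$region[i]
    if (!any(in_r)) next
    u <- runif(sum(in_r))
    p12 <- rf$frac_double[i]
    p1o <- rf$frac_m1[i] - p12
    p2o <- rf$frac_m2[i] - p12
    nuclei$m1_pos[in_r] <- u < p12 + p1o
    nuclei$m2_pos[in_r] <- u < p12 | (u >= p12 + p1o & u < p12 + p1o + p2o)
  }

  nx <- ceiling(W / pixel_size); ny <- ceiling(H / pixel_size)
  nuclei$x_px <- nuclei$x_um / pixel_size
  nuclei$y_px <- nuclei$y_um / pixel_size

  render_channel <- function(sel) {
    img <- matrix(background, ny, nx)
    halfw <- ceiling(4 * psf_sigma)
    sub <- nuclei[sel, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      cx <- sub$x_px[k]; cy <- sub$y_px[k]
      c0 <- max(1L, floor(cx) + 1L - halfw); c1 <- min(nx, floor(cx) + 1L + halfw)
      r0 <- max(1L, floor(cy) + 1L - halfw); r1 <- min(ny, floor(cy) + 1L + halfw)
      if (c0 > c1 || r0 > r1) next
      xs_ <- (c0:c1) - 1; ys_ <- (r0:r1) - 1
      g <- amplitude * outer(exp(-(ys_ - cy)^2 / (2 * psf_sigma^2)),
                             exp(-(xs_ - cx)^2 / (2 * psf_sigma^2)))
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g
    }
    round(pmax(img + rnorm(length(img), 0, amplitude / snr), 0))
  }

  channels <- list(nuclear = render_channel(rep(TRUE, nrow(nuclei))),
                   marker1 = render_channel(nuclei$m1_pos),
                   marker2 = render_channel(nuclei$m2_pos))

  epi <- matrix(0L, ny, nx)
  xs_px <- (seq_len(nx) - 1) * pixel_size
  cols <- covered(xs_px + pixel_size / 2)
  r0 <- max(1L, floor(epi_top / pixel_size) + 1L)
  r1 <- min(ny, ceiling(epi_bottom / pixel_size))
  epi[r0:r1, cols] <- 1L

  rownames(nuclei) <- NULL
  structure(list(channels = channels,
                 nuclei = nuclei[, c("nucleus_id", "x_um", "y_um", "x_px",
                                     "y_px", "region", "basal",
                                     "m1_pos", "m2_pos")],
                 epithelium_mask = epi,
                 wound_center_px = centre / pixel_size,
                 pixel_size = pixel_size, spec = spec),
            class = "synthetic_section")
}
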
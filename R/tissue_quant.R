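# Marker-positivity quantification of wounded-epithelium sections: nuclei
# detection (median filter + two-class Gaussian naive Bayes), a four-step
# morphological filter cascade, partitioning of the epithelium into ten
# regions (five per wound side, pooled pairwise), and basal-layer positivity
# scoring normalised by epithelium area.

#' Fit the pixel classifier for nuclei detection
#'
#' Self-contained fit on one image: the nuclear channel is median-filtered
#' (exactly as [detect_nuclei()] will filter it), a robust seed threshold
#' (median + 5 mad of the filtered intensity) provides provisional
#' nucleus/background classes, and Gaussian class-conditionals for the two
#' features (filtered intensity, local contrast) plus class priors are
#' estimated from those labels.
#'
#' @param nuclear_channel numeric matrix.
#' @param median_radius median filter radius in px (0 = none).
#' @return classifier object of class `nuclei_classifier`.
#' @export
fit_nuclei_classifier <- function(nuclear_channel, median_radius = 2) {
  filtered <- median_filter_channel(nuclear_channel, median_radius)
  contrast <- local_contrast(filtered)
  fit_nb_features(filtered, contrast)
}

median_filter_channel <- function(channel, median_radius) {
  if (median_radius <= 0) return(channel)
  rng <- range(channel)
  span <- max(rng[2] - rng[1], .Machine$double.eps)
  img01 <- (channel - rng[1]) / span
  from_ebi(EBImage::medianFilter(as_ebi(img01), median_radius)) * span +
    rng[1]
}

fit_nb_features <- function(filtered, contrast) {
  # provisional classes from a robust seed threshold: nuclei occupy a few
  # percent of the pixels, so a histogram bisection (e.g. Otsu) would split
  # the background noise instead; median + 5 mad marks unambiguous nucleus
  # cores and leaves everything else as provisional background
  thr <- stats::median(filtered) + 5 * stats::mad(filtered)
  lab <- filtered > thr
  if (!any(lab) || all(lab))
    stop("degenerate intensity split; cannot fit the classifier")
  fit1 <- function(v) c(mean = mean(v), sd = max(sd(v), 1e-6))
  structure(list(
    prior = c(bg = mean(!lab), nuc = mean(lab)),
    intensity = rbind(bg = fit1(filtered[!lab]), nuc = fit1(filtered[lab])),
    contrast = rbind(bg = fit1(contrast[!lab]), nuc = fit1(contrast[lab]))),
    class = "nuclei_classifier")
}

local_contrast <- function(image, window = 15) {
  kern <- matrix(1 / window^2, window, window)
  image - from_ebi(EBImage::filter2(as_ebi(image), kern,
                                    boundary = "replicate"))
}

#' Detect nuclei pixels in the nuclear channel
#'
#' Median-filters the channel (radius `median_radius`; 0 = pass-through) and
#' classifies each pixel as nucleus or background with a two-class Gaussian
#' naive Bayes over (filtered intensity, local contrast); posterior > 0.5
#' yields the nucleus mask.
#'
#' @param nuclear_channel numeric matrix.
#' @param median_radius median filter radius in px.
#' @param classifier a `nuclei_classifier`, or NULL to fit one from this
#'   image ([fit_nuclei_classifier()]).
#' @return integer 0/1 nucleus mask.
#' @export
detect_nuclei <- function(nuclear_channel, median_radius = 2,
                          classifier = NULL) {
  filtered <- median_filter_channel(nuclear_channel, median_radius)
  contrast <- local_contrast(filtered)
  if (is.null(classifier))
    classifier <- fit_nb_features(filtered, contrast)
  if (!inherits(classifier, "nuclei_classifier"))
    stop("classifier must be a fitted 'nuclei_classifier'")
  loglik <- function(cls) {
    log(classifier$prior[[cls]]) +
      stats::dnorm(filtered, classifier$intensity[cls, "mean"],
                   classifier$intensity[cls, "sd"], log = TRUE) +
      stats::dnorm(contrast, classifier$contrast[cls, "mean"],
                   classifier$contrast[cls, "sd"], log = TRUE)
  }
  # one-sided: nuclei are bright objects, so the dim tail where the wide
  # nucleus Gaussian outscores the narrow background one is excluded
  mask <- matrix(0L, nrow(nuclear_channel), ncol(nuclear_channel))
  mask[loglik("nuc") > loglik("bg") &
       filtered > classifier$intensity["bg", "mean"]] <- 1L
  mask
}

component_features <- function(label_image) {
  idx <- which(label_image > 0)
  lab <- label_image[idx]
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  area <- as.integer(tabulate(f))
  per <- perimeter_chain(label_image, setNames(area, as.character(ids)))
  per <- per[as.character(ids)]
  data.frame(label = ids, area = area,
             circularity = as.numeric(per)^2 / (4 * pi * area))
}

#' Four-step nuclei filter cascade
#'
#' Sequentially applied to the connected components of the detection mask:
#' (i) specks with area < `min_area` px are removed; (ii) components with
#' circularity < `max_circularity` are kept as potential nuclei, the rest
#' discarded; (iii) conglomerates larger than `max_area` px are separated by
#' watershed splitting ([split_clusters()]); (iv) the split products are
#' re-tested, removing objects with circularity > `max_circularity_split` or
#' area < `min_area_split` px. Circularity is `perimeter^2 / (4 pi area)`.
#'
#' @param mask binary nucleus mask.
#' @param min_area step (i) threshold (px).
#' @param max_circularity step (ii) threshold.
#' @param max_area step (iii) conglomerate threshold (px).
#' @param max_circularity_split,min_area_split step (iv) thresholds.
#' @return integer label image of accepted nuclei (labels 1..n).
#' @export
filter_nuclei <- function(mask, min_area = 3, max_circularity = 2,
                          max_area = 60, max_circularity_split = 2.5,
                          min_area_split = 4) {
  labels <- from_ebi(EBImage::bwlabel(as_ebi(mask != 0)))
  storage.mode(labels) <- "integer"
  if (!any(labels > 0)) return(labels)
  fe <- component_features(labels)
  fg <- which(labels > 0)
  idx_by_lab <- split(fg, labels[fg])

  keep1 <- fe$area >= min_area                              # (i)
  keep2 <- keep1 & fe$circularity < max_circularity         # (ii)
  fe <- fe[keep2, , drop = FALSE]

  ny <- nrow(mask)
  out <- matrix(0L, ny, ncol(mask))
  next_lab <- 1L
  for (k in seq_len(nrow(fe))) {
    idx <- idx_by_lab[[as.character(fe$label[k])]]
    if (fe$area[k] > max_area) {                            # (iii)
      rows <- (idx - 1L) %% ny + 1L
      cols <- (idx - 1L) %/% ny + 1L
      # pad the crop beyond the smoothing reach so the local distance
      # transform equals the full-frame one
      pad <- 5L
      r0 <- min(rows) - pad; c0 <- min(cols) - pad
      sub <- matrix(0L, max(rows) - r0 + 1L + pad, max(cols) - c0 + 1L + pad)
      sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1L
      sl <- split_clusters(sub)
      sf <- component_features(sl)
      keep <- sf$label[sf$circularity <= max_circularity_split &
                       sf$area >= min_area_split]           # (iv)
      for (s in keep) {
        w <- which(sl == s)
        srow <- (w - 1L) %% nrow(sl) + r0
        scol <- (w - 1L) %/% nrow(sl) + c0
        out[cbind(srow, scol)] <- next_lab
        next_lab <- next_lab + 1L
      }
    } else {
      out[idx] <- next_lab
      next_lab <- next_lab + 1L
    }
  }
  out
}

#' Partition the epithelium into ten regions around the wound
#'
#' Each wound side (left/right of `wound_center_x`) is divided into five
#' equal spans from the section periphery (label `A`) to the wound centre
#' (label `E`); the opposite side carries the primed labels. Spans without
#' epithelium - an unhealed wound - are flagged absent. The basal band is
#' the lowest `basal_um` of the epithelium in every column. Opposite regions
#' are pooled pairwise (`A/A'` ... `E/E'`) for counting.
#'
#' @param epithelium_mask binary matrix (rows = y, cols = x).
#' @param wound_center_x wound centre, 0-based px.
#' @param pixel_size um per px.
#' @param basal_um basal-band thickness in um.
#' @param n_per_side regions per side (5 for the standard partition).
#' @return object of class `epithelial_partition`: `region_image` (integer
#'   matrix, 0 outside the epithelium), `region_table` (label, side, present,
#'   area_px, area_um2), `basal_mask`, `epithelium_mask`, `wound_center_x`,
#'   `pooled` (pair, area_um2), `pixel_size`.
#' @export
partition_epithelium <- function(epithelium_mask, wound_center_x,
                                 pixel_size = 1, basal_um = 12,
                                 n_per_side = 5) {
  if (!any(epithelium_mask != 0)) stop("epithelium mask is empty")
  ny <- nrow(epithelium_mask); nx <- ncol(epithelium_mask)
  labels <- c(LETTERS[seq_len(n_per_side)],
              paste0(LETTERS[seq_len(n_per_side)], "'"))
  xs <- (seq_len(nx) - 1) + 0.5                 # column centres, 0-based px
  left <- xs < wound_center_x
  reg_of_col <- integer(nx)
  binw_l <- wound_center_x / n_per_side
  binw_r <- (nx - wound_center_x) / n_per_side
  reg_of_col[left] <- pmin(n_per_side, floor(xs[left] / binw_l) + 1L)
  reg_of_col[!left] <- n_per_side +
    pmin(n_per_side, floor((nx - xs[!left]) / binw_r) + 1L)

  region_image <- matrix(0L, ny, nx)
  epi <- epithelium_mask != 0
  region_image[epi] <- matrix(rep(reg_of_col, each = ny), ny, nx)[epi]

  # basal band: lowest basal_um of the epithelium per column
  basal_px <- max(1L, round(basal_um / pixel_size))
  basal <- matrix(0L, ny, nx)
  for (cx in which(colSums(epi) > 0)) {
    ybot <- max(which(epi[, cx]))
    basal[max(1L, ybot - basal_px + 1L):ybot, cx] <- epi[
      max(1L, ybot - basal_px + 1L):ybot, cx]
  }

  area_px <- vapply(seq_along(labels), function(i)
    sum(region_image == i), integer(1))
  region_table <- data.frame(label = labels,
                             side = rep(c("left", "right"),
                                        each = n_per_side),
                             present = area_px > 0,
                             area_px = area_px,
                             area_um2 = area_px * pixel_size^2)
  pooled <- data.frame(
    pair = paste0(LETTERS[seq_len(n_per_side)], "/",
                  LETTERS[seq_len(n_per_side)], "'"),
    area_um2 = region_table$area_um2[seq_len(n_per_side)] +
      region_table$area_um2[n_per_side + seq_len(n_per_side)])
  structure(list(region_image = region_image, region_table = region_table,
                 basal_mask = basal, epithelium_mask = 1L * epi,
                 wound_center_x = wound_center_x, pooled = pooled,
                 pixel_size = pixel_size),
            class = "epithelial_partition")
}

#' Score marker positivity per pooled region
#'
#' A nucleus is positive for a marker when its mean channel intensity
#' exceeds the marker's threshold. Counting is restricted to nuclei whose
#' centroid lies in the basal band; counts and single/double-positive
#' fractions are reported per pooled region, together with the nuclei
#' density normalised by the epithelium area.
#'
#' @param nuclei_labels label image of accepted nuclei ([filter_nuclei()]).
#' @param channels named list of two marker channel matrices.
#' @param thresholds numeric length-2: per-marker intensity thresholds.
#' @param partition an `epithelial_partition`.
#' @return data.frame (PositivityTable) with one row per pooled region:
#'   `pair`, `present`, `n_nuclei`, `n_m1_pos`, `n_m2_pos`, `n_double_pos`,
#'   `frac_m1`, `frac_m2`, `frac_double`, `frac_double_of_m1`,
#'   `nuclei_per_um2`.
#' @export
score_positivity <- function(nuclei_labels, channels, thresholds, partition) {
  if (length(channels) != 2 || length(thresholds) != 2)
    stop("exactly two marker channels and thresholds are required")
  for (ch in channels)
    if (!all(dim(ch) == dim(nuclei_labels)))
      stop("marker channel shape differs from the label image")
  obj <- extract_objects(nuclei_labels, channels[[1]],
                         channels = setNames(channels, c("m1", "m2")))
  n_side <- nrow(partition$pooled)
  pooled_of <- function(region_idx) ((region_idx - 1L) %% n_side) + 1L

  tab <- partition$pooled
  tab$present <- partition$region_table$present[seq_len(n_side)] |
    partition$region_table$present[n_side + seq_len(n_side)]
  tab$n_nuclei <- 0L; tab$n_m1_pos <- 0L; tab$n_m2_pos <- 0L
  tab$n_double_pos <- 0L

  if (nrow(obj)) {
    px <- cbind(round(obj$y) + 1L, round(obj$x) + 1L)
    px[, 1] <- pmin(pmax(px[, 1], 1L), nrow(nuclei_labels))
    px[, 2] <- pmin(pmax(px[, 2], 1L), ncol(nuclei_labels))
    in_basal <- partition$basal_mask[px] > 0
    region_idx <- partition$region_image[px]
    keep <- in_basal & region_idx > 0
    if (any(keep)) {
      o <- obj[keep, , drop = FALSE]
      pool <- pooled_of(region_idx[keep])
      m1 <- o$mean_m1 > thresholds[1]
      m2 <- o$mean_m2 > thresholds[2]
      for (i in seq_len(n_side)) {
        sel <- pool == i
        tab$n_nuclei[i] <- sum(sel)
        tab$n_m1_pos[i] <- sum(m1[sel])
        tab$n_m2_pos[i] <- sum(m2[sel])
        tab$n_double_pos[i] <- sum(m1[sel] & m2[sel])
      }
    }
  }
  frac <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tab$frac_m1 <- frac(tab$n_m1_pos, tab$n_nuclei)
  tab$frac_m2 <- frac(tab$n_m2_pos, tab$n_nuclei)
  tab$frac_double <- frac(tab$n_double_pos, tab$n_nuclei)
  tab$frac_double_of_m1 <- frac(tab$n_double_pos, tab$n_m1_pos)
  tab$nuclei_per_um2 <- frac(tab$n_nuclei, tab$area_um2)
  tab[, c("pair", "present", "n_nuclei", "n_m1_pos", "n_m2_pos",
          "n_double_pos", "frac_m1", "frac_m2", "frac_double",
          "frac_double_of_m1", "nuclei_per_um2", "area_um2")]
}

#' Time course of positivity across sections
#'
#' Stacks per-timepoint positivity tables into long format and fits, per
#' pooled region, an ordinary least-squares trend of the double-positive
#' fraction against time.
#'
#' @param tables list of PositivityTables ([score_positivity()]).
#' @param timepoints numeric vector of days, one per table.
#' @return list: `table` (long data.frame with a `day` column) and `trends`
#'   (per pooled region: slope per day, intercept, n).
#' @export
timecourse <- function(tables, timepoints) {
  if (length(tables) != length(timepoints))
    stop("one timepoint per table required")
  if (length(tables) < 2) stop("need at least 2 timepoints")
  long <- do.call(rbind, Map(function(tb, d) {
    tb$day <- d
    tb
  }, tables, timepoints))
  rownames(long) <- NULL
  trends <- do.call(rbind, lapply(split(long, long$pair), function(sub) {
    sub <- sub[!is.na(sub$frac_double), ]
    if (nrow(sub) < 2)
      return(data.frame(pair = sub$pair[1], slope_per_day = NA_real_,
                        intercept = NA_real_, n = nrow(sub)))
    fit <- lm(frac_double ~ day, data = sub)
    data.frame(pair = sub$pair[1],
               slope_per_day = coef(fit)[["day"]],
               intercept = coef(fit)[["(Intercept)"]], n = nrow(sub))
  }))
  rownames(trends) <- NULL
  list(table = long, trends = trends)
}
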
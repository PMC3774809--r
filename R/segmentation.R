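#' White top-hat background removal
#'
#' Subtracts the morphological opening with a disc of radius
#' `structuring_radius` from the image, flattening slowly varying background
#' while preserving bright objects smaller than the structuring element.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param structuring_radius disc radius in px (>= 1).
#' @return numeric matrix, non-negative everywhere.
#' @export
tophat_enhance <- function(image, structuring_radius) {
  if (!is.numeric(structuring_radius) || structuring_radius < 1)
    stop("structuring_radius must be >= 1")
  size <- 2 * floor(structuring_radius) + 1
  if (size > min(dim(image)))
    stop("structuring element larger than the image")
  kern <- EBImage::makeBrush(size, shape = "disc")
  # work on a [0,1]-normalised copy: EBImage morphology expects that range
  rng <- range(image)
  scale <- max(rng[2] - rng[1], 1)
  img01 <- (image - rng[1]) / scale
  out <- from_ebi(EBImage::whiteTopHat(as_ebi(img01), kern))
  pmax(out, 0) * scale
}

#' Region-adaptive thresholding
#'
#' A pixel is foreground iff its intensity exceeds the local mean over a
#' square `window` plus `offset`. Borders use replicated edges.
#'
#' @param image numeric matrix.
#' @param window odd window side length in px (>= 3).
#' @param offset additive offset in intensity units; positive offsets demand
#'   pixels brighter than their neighbourhood.
#' @return integer 0/1 mask matrix.
#' @export
adaptive_threshold <- function(image, window, offset = 0) {
  if (window %% 2 == 0 || window < 3)
    stop("window must be odd and >= 3")
  kern <- matrix(1 / window^2, window, window)
  local_mean <- from_ebi(EBImage::filter2(as_ebi(image), kern,
                                          boundary = "replicate"))
  mask <- matrix(0L, nrow(image), ncol(image))
  mask[image > local_mean + offset] <- 1L
  mask
}

#' Split touching nuclei by watershed on the distance transform
#'
#' Computes the Euclidean distance transform of the mask, smooths it
#' (Gaussian, `smooth_sigma` px) and merges shallow maxima (depth
#' `tolerance`) to suppress over-segmentation, then applies the watershed
#' transform. Labels partition the foreground exactly; disconnected
#' components are never merged.
#'
#' @param mask binary matrix (0 background).
#' @param smooth_sigma Gaussian sd (px) applied to the distance map.
#' @param tolerance minimum depth separating two catchment basins.
#' @return integer label matrix (0 = background).
#' @export
split_clusters <- function(mask, smooth_sigma = 1, tolerance = 0.5) {
  m <- as_ebi(mask != 0)
  dm <- EBImage::distmap(m)
  if (smooth_sigma > 0) {
    bsize <- 2 * ceiling(3 * smooth_sigma) + 1
    kern <- EBImage::makeBrush(bsize, shape = "Gaussian", sigma = smooth_sigma)
    dm <- EBImage::filter2(dm, kern, boundary = "replicate")
  }
  dmat <- EBImage::imageData(dm)
  dmat[EBImage::imageData(m) == 0] <- 0
  labels <- EBImage::watershed(EBImage::Image(dmat), tolerance = tolerance,
                               ext = 1)
  storage.mode(labels) <- "integer"
  ws <- from_ebi(labels)
  # watershed bridges diagonal touches; intersect with the mask's connected
  # components so disconnected foreground is never merged
  cc <- from_ebi(EBImage::bwlabel(m))
  storage.mode(cc) <- "integer"
  fg <- which(ws > 0)
  if (!length(fg)) return(ws)
  key <- ws[fg] + (max(ws) + 1L) * cc[fg]
  out <- matrix(0L, nrow(ws), ncol(ws))
  out[fg] <- as.integer(factor(key))
  out
}

#' Extract per-object features from a label image
#'
#' For every label: geometric centroid (0-based px, x along columns), area
#' (pixel count), mean intensity, perimeter (chain-code contour length) and
#' circularity `perimeter^2 / (4 * pi * area)` (1 for a perfect disc, larger
#' for irregular shapes).
#'
#' @param label_image integer label matrix.
#' @param intensity_image numeric matrix, same shape.
#' @param channels optional named list of additional intensity matrices; adds
#'   a `mean_<name>` column per channel.
#' @return a data.frame (ObjectTable) with one row per object.
#' @export
extract_objects <- function(label_image, intensity_image, channels = NULL) {
  if (!all(dim(label_image) == dim(intensity_image)))
    stop("label and intensity images must have the same shape")
  idx <- which(label_image > 0)
  if (!length(idx)) {
    out <- data.frame(object_id = integer(), x = numeric(), y = numeric(),
                      area = integer(), mean_intensity = numeric(),
                      perimeter = numeric(), circularity = numeric())
    for (nm in names(channels)) out[[paste0("mean_", nm)]] <- numeric()
    return(out)
  }
  lab <- label_image[idx]
  rows <- (idx - 1) %% nrow(label_image)        # 0-based y
  cols <- (idx - 1) %/% nrow(label_image)       # 0-based x
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  area <- as.integer(tabulate(f))
  cx <- tapply(cols, f, mean)
  cy <- tapply(rows, f, mean)
  mi <- tapply(intensity_image[idx], f, mean)
  per <- perimeter_chain(label_image, setNames(area, as.character(ids)))
  per <- per[as.character(ids)]
  out <- data.frame(object_id = ids, x = as.numeric(cx), y = as.numeric(cy),
                    area = area, mean_intensity = as.numeric(mi),
                    perimeter = as.numeric(per),
                    circularity = as.numeric(per)^2 / (4 * pi * area))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(dim(ch) == dim(label_image)))
      stop("channel '", nm, "' has a different shape")
    out[[paste0("mean_", nm)]] <- as.numeric(tapply(ch[idx], f, mean))
  }
  rownames(out) <- NULL
  out
}

#' Default segmentation parameters
#'
#' `structuring_radius` defaults to 1.5x the expected nucleus radius,
#' `window` to four nucleus diameters (rounded to odd), and `offset` to
#' `offset_k` times the estimated image noise sd.
#'
#' @param nucleus_radius expected nucleus radius in px.
#' @param offset_k threshold offset in units of noise sd.
#' @param min_area discard objects smaller than this (px) as noise specks.
#' @param smooth_sigma,tolerance passed to [split_clusters()].
#' @return a named list of parameters.
#' @export
segmentation_params <- function(nucleus_radius = 5, offset_k = 3,
                                min_area = 5, smooth_sigma = 1,
                                tolerance = 0.5) {
  window <- 2 * round(4 * nucleus_radius) + 1
  list(structuring_radius = ceiling(1.5 * nucleus_radius),
       window = window, offset_k = offset_k, min_area = min_area,
       smooth_sigma = smooth_sigma, tolerance = tolerance)
}

#' Segment one frame into an object table
#'
#' Runs the full chain: top-hat enhancement, region-adaptive thresholding,
#' watershed splitting of clusters, feature extraction, and a minimum-area
#' speck filter.
#'
#' @param image numeric matrix.
#' @param params list from [segmentation_params()].
#' @param channels optional extra channels for [extract_objects()].
#' @return ObjectTable data.frame.
#' @export
segment_frame <- function(image, params = segmentation_params(),
                          channels = NULL) {
  enh <- tophat_enhance(image, params$structuring_radius)
  offset <- params$offset_k * estimate_noise_sd(image)
  mask <- adaptive_threshold(enh, params$window, offset)
  labels <- split_clusters(mask, params$smooth_sigma, params$tolerance)
  obj <- extract_objects(labels, image, channels)
  obj <- obj[obj$area >= params$min_area, , drop = FALSE]
  obj$object_id <- seq_len(nrow(obj))
  rownames(obj) <- NULL
  obj
}

#' Segment every frame of an image stack
#'
#' @param stack array (y, x, frame) or list of matrices.
#' @param params list from [segmentation_params()].
#' @return ObjectTable data.frame with a `frame` column (1-based).
#' @export
segment_stack <- function(stack, params = segmentation_params()) {
  frames <- if (is.array(stack) && length(dim(stack)) == 3)
    lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  else stack
  out <- lapply(seq_along(frames), function(f) {
    obj <- segment_frame(frames[[f]], params)
    if (nrow(obj)) obj$frame <- f
    else obj$frame <- integer(0)
    obj
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("frame", setdiff(names(res), "frame"))]
}
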
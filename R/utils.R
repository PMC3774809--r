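# Images are plain R matrices indexed [row = y, col = x]; coordinates in
# object tables are 0-based with x along columns. EBImage stores the x index
# first, so every call into EBImage goes through a transpose.

as_ebi <- function(m) EBImage::Image(t(m))

from_ebi <- function(e) t(EBImage::imageData(e))

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a positive number", name), call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a non-negative number", name), call. = FALSE)
  invisible(x)
}

#' Estimate additive noise standard deviation of an image
#'
#' Robust estimate from horizontal first differences: for i.i.d. additive
#' noise, `mad(diff)/sqrt(2)` recovers the noise sd while being insensitive
#' to the sparse bright objects.
#'
#' @param image numeric matrix.
#' @return estimated noise standard deviation (a.u.).
#' @export
estimate_noise_sd <- function(image) {
  d <- diff(t(image))
  stats::mad(as.numeric(d)) / sqrt(2)
}

# chain-code perimeter of every label in a label image; returns a named
# numeric vector (names = label). Objects whose oriented contour has fewer
# than 3 points fall back to the perimeter of the area-equivalent circle.
perimeter_chain <- function(label_image, areas) {
  oc <- EBImage::ocontour(as_ebi(label_image))
  labs <- names(oc)
  if (is.null(labs)) labs <- as.character(seq_along(oc))
  per <- vapply(seq_along(oc), function(i) {
    ct <- oc[[i]]
    n <- nrow(ct)
    if (n < 3L) return(NA_real_)
    d <- ct - ct[c(2:n, 1L), , drop = FALSE]
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
  names(per) <- labs
  if (!missing(areas)) {
    miss <- is.na(per)
    per[miss] <- 2 * sqrt(pi * areas[labs][miss])
  }
  per
}
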
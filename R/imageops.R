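#' @useDynLib regenquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Otsu intensity threshold
#'
#' Histogram-based threshold maximizing between-class variance, computed on
#' `n_bins` equal-width bins spanning the data range. Because the bin grid
#' scales linearly with the data, the returned threshold (and hence any mask
#' derived from it) is equivariant under positive rescaling of intensities.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins number of histogram bins.
#' @return threshold value; pixels strictly greater than it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("otsu_threshold: no finite values", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("otsu_threshold: constant image, no threshold exists", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(
    tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[n_bins]
  mu_t <- mu[n_bins]
  # between-class variance for split after bin k
  wb <- w[-n_bins]
  wf <- n - wb
  valid <- wb > 0 & wf > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * wb[valid] - n * mu[-n_bins][valid])^2 /
    (wb[valid] * wf[valid])
  k <- which.max(sigma_b)
  breaks[k + 1L]
}

# First-valley threshold: the density minimum between the two lowest
# substantial intensity modes. Separates background from (possibly dim)
# tissue signal even when a third, much brighter class dominates the
# intensity range; falls back to Otsu when the histogram is unimodal.
valley_threshold <- function(x, min_peak_frac = 0.05) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  d <- stats::density(x, n = 512)
  y <- d$y
  loc_max <- which(diff(sign(diff(y))) == -2) + 1L
  loc_min <- which(diff(sign(diff(y))) == 2) + 1L
  peaks <- loc_max[y[loc_max] >= min_peak_frac * max(y)]
  if (length(peaks) < 2L) return(otsu_threshold(x))
  mins <- loc_min[loc_min > peaks[1] & loc_min < peaks[2]]
  if (length(mins) == 0L) return(otsu_threshold(x))
  d$x[mins[which.min(y[mins])]]
}

#' Separable Gaussian blur with reflected borders
#' @param img numeric matrix.
#' @param sigma_px standard deviation in pixels; 0 returns `img` unchanged.
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  img <- convolve_1d(img, k, r, margin = 1L)
  convolve_1d(img, k, r, margin = 2L)
}

# 1-D convolution along rows (margin 1) or columns (margin 2), reflect padding
convolve_1d <- function(img, k, r, margin) {
  if (margin == 2L) return(t(convolve_1d(t(img), k, r, 1L)))
  nr <- nrow(img)
  idx <- seq_len(nr)
  out <- matrix(0, nr, ncol(img))
  for (s in seq(-r, r)) {
    src <- idx + s
    src <- ifelse(src < 1L, 2L - src, src)
    src <- ifelse(src > nr, 2L * nr - src, src)
    out <- out + k[s + r + 1L] * img[src, , drop = FALSE]
  }
  out
}

#' Euclidean distance (in pixels) from every pixel to the nearest mask pixel
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return numeric matrix of distances (0 on the mask).
#' @export
distance_to_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("distance_to_mask: empty mask", call. = FALSE)
  sqrt(cpp_sqdist_transform(mask))
}

#' Label connected components of a binary mask
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background) with attribute `n`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  cpp_label_components(mask, as.integer(connectivity))
}

#' Morphological skeleton (Zhang-Suen thinning)
#' @param mask logical matrix.
#' @return logical matrix; a 1-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  cpp_thin(mask)
}

#' 3x3 median filter
#' @param img numeric matrix.
#' @return filtered matrix.
#' @export
median_filter3 <- function(img) {
  stopifnot(is.matrix(img))
  cpp_median3(img)
}

# Fill interior holes of a mask: background components not touching the
# image border are holes.
fill_holes <- function(mask) {
  lab <- cpp_label_components(!mask, 4L)
  n <- attr(lab, "n")
  if (n == 0L) return(mask)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  hole <- lab != 0L & !(lab %in% border_labels)
  mask | hole
}

#' Bilinear interpolation of image intensities
#'
#' Samples `img` at continuous pixel coordinates. Coordinates are 0-based:
#' (0, 0) is the centre of the top-left pixel. Points outside the image are
#' clamped to the border.
#'
#' @param img numeric matrix.
#' @param row,col numeric vectors of 0-based coordinates (recycled together).
#' @return numeric vector of interpolated values.
#' @export
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img)
  nc <- ncol(img)
  r <- pmin(pmax(row, 0), nr - 1)
  c <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmax(pmin(floor(r), nr - 2), 0)
  c0 <- pmax(pmin(floor(c), nc - 2), 0)
  r1 <- pmin(r0 + 1, nr - 1)
  c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0
  fc <- c - c0
  v00 <- img[cbind(r0 + 1, c0 + 1)]
  v10 <- img[cbind(r1 + 1, c0 + 1)]
  v01 <- img[cbind(r0 + 1, c1 + 1)]
  v11 <- img[cbind(r1 + 1, c1 + 1)]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}
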
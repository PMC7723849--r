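# Regeneration-index quantification along a cleared optic nerve.
#
# The readout follows the semi-automated procedure used with cleared whole
# nerves: maximum z-projection, a manually defined straight injury line
# (where tracer labelling drops), fluorescence profiles along lines
# orthogonal to the nerve axis at fixed distances, integration normalized to
# the local nerve width, normalization to the maximum step in the
# regenerating region, and subtraction of a distal background step treated
# identically.
#
# Pixel coordinates are 0-based `(row, col)`; distances are in um measured
# along the axial direction from the injury line.

#' Nerve projection container
#'
#' @param image 2-D nonnegative intensity matrix (rows x cols).
#' @param pixel_size_um physical pixel size (um/pixel).
#' @param bit_depth nominal camera bit depth (16 expected; informational).
#' @return an object of class `nerve_projection`.
#' @export
nerve_projection <- function(image, pixel_size_um, bit_depth = 16L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (any(image < 0, na.rm = TRUE)) {
    stop("`image` intensities must be >= 0", call. = FALSE)
  }
  check_number(pixel_size_um, "pixel_size_um", lower = 0,
               allow_equal_lower = FALSE)
  structure(list(image = image, pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth)),
            class = "nerve_projection")
}

#' Maximum z-projection of an image stack
#'
#' @param zstack 3-D numeric array ordered (z, row, col), or a matrix
#'   (returned as a single-plane projection).
#' @param pixel_size_um pixel size forwarded to the projection container.
#' @return a [nerve_projection()].
#' @export
max_project <- function(zstack, pixel_size_um = 1) {
  if (is.matrix(zstack)) {
    return(nerve_projection(zstack, pixel_size_um))
  }
  if (!is.array(zstack) || length(dim(zstack)) != 3L || dim(zstack)[1] < 1L) {
    stop("`zstack` must be a (z, row, col) array with at least one plane",
         call. = FALSE)
  }
  d <- dim(zstack)
  out <- matrix(zstack[1, , ], d[2], d[3])
  if (d[1] > 1L) {
    for (z in 2:d[1]) out <- pmax(out, matrix(zstack[z, , ], d[2], d[3]))
  }
  nerve_projection(out, pixel_size_um)
}

#' Injury-site reference line
#'
#' The injury site is defined manually as a straight line across the nerve
#' where tracer labelling drops in intensity. The axial direction is the
#' unit vector orthogonal to that line pointing distally (away from the
#' eye); distances along the nerve are measured along it.
#'
#' @param p1,p2 line endpoints, 0-based `(row, col)` pixel coordinates.
#' @param axial_sign +1 or -1, selecting which of the two orthogonal
#'   directions points distally (ignored when `axial_direction` is given).
#' @param axial_direction optional explicit axial unit vector `(row, col)`;
#'   must be orthogonal to the line within 5 degrees.
#' @param suggested logical flag marking automatically proposed sites.
#' @return an object of class `injury_site`.
#' @export
injury_site <- function(p1, p2, axial_sign = 1, axial_direction = NULL,
                        suggested = FALSE) {
  p1 <- as.numeric(p1)
  p2 <- as.numeric(p2)
  stopifnot(length(p1) == 2L, length(p2) == 2L)
  if (all(p1 == p2)) stop("injury line endpoints must differ", call. = FALSE)
  v <- (p2 - p1) / sqrt(sum((p2 - p1)^2))          # along-line unit
  if (is.null(axial_direction)) {
    u <- c(-v[2], v[1]) * sign(axial_sign)
  } else {
    u <- as.numeric(axial_direction)
    u <- u / sqrt(sum(u^2))
    if (abs(sum(u * v)) > sin(5 * pi / 180)) {
      stop("`axial_direction` must be orthogonal to the injury line",
           call. = FALSE)
    }
  }
  structure(list(p1 = p1, p2 = p2, along = v, axial = u,
                 origin = (p1 + p2) / 2, suggested = isTRUE(suggested)),
            class = "injury_site")
}

# Nerve mask: Otsu threshold on a Gaussian-smoothed projection, largest
# 8-connected component, holes filled. Thresholding happens on
# log-compressed intensities so that the dim distal nerve outline (tissue
# autofluorescence) is separated from background rather than being
# swamped by the bright proximal fiber signal.
#' Segment the nerve outline of a projection
#' @param projection a [nerve_projection()].
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels.
#' @return logical mask matrix.
#' @export
nerve_mask <- function(projection, smooth_sigma_px = 2) {
  stopifnot(inherits(projection, "nerve_projection"))
  sm <- gaussian_blur(projection$image, smooth_sigma_px)
  lg <- log1p(sm / max(1e-12, stats::median(sm)))
  thr <- valley_threshold(lg)
  lab <- label_components(lg > thr, 8L)
  if (attr(lab, "n") == 0L) {
    stop("nerve_mask: no foreground component detected", call. = FALSE)
  }
  sizes <- tabulate(lab[lab > 0L], nbins = attr(lab, "n"))
  fill_holes(lab == which.max(sizes))
}

# Orthogonal profile at a given axial distance from the injury line.
# The nerve extent is located coarsely from the segmentation mask, then
# refined to the half-maximum crossings of the smoothed transverse profile
# (background taken from the profile tails), which places the boundary of a
# blurred edge at its true position regardless of how bright the interior
# is. Returns the bilinear raw-intensity samples across that extent and the
# local width.
transverse_profile <- function(projection, injury, distance_um, mask,
                               smoothed = NULL) {
  stopifnot(inherits(projection, "nerve_projection"),
            inherits(injury, "injury_site"))
  img <- projection$image
  px <- projection$pixel_size_um
  nr <- nrow(img)
  nc <- ncol(img)
  ctr <- injury$origin + injury$axial * (distance_um / px)
  if (ctr[1] < 0 || ctr[1] > nr - 1 || ctr[2] < 0 || ctr[2] > nc - 1) {
    stop(sprintf("distance %g um falls outside the image", distance_um),
         call. = FALSE)
  }
  t_max <- ceiling(sqrt(nr^2 + nc^2))
  tt <- seq(-t_max, t_max)
  rr <- ctr[1] + injury$along[1] * tt
  cc <- ctr[2] + injury$along[2] * tt
  inside <- rr >= 0 & rr <= nr - 1 & cc >= 0 & cc <= nc - 1
  on_mask <- logical(length(tt))
  ri <- as.integer(round(rr[inside])) + 1L
  ci <- as.integer(round(cc[inside])) + 1L
  on_mask[inside] <- mask[cbind(ri, ci)]
  if (!any(on_mask)) {
    stop(sprintf("no nerve mask found on the profile line at %g um",
                 distance_um), call. = FALSE)
  }
  t_lo0 <- min(tt[on_mask])
  t_hi0 <- max(tt[on_mask])
  smoothed <- smoothed %||% gaussian_blur(img, 2)
  ext <- 8L
  te <- seq(t_lo0 - ext, t_hi0 + ext)
  ps <- bilinear_sample(smoothed, ctr[1] + injury$along[1] * te,
                        ctr[2] + injury$along[2] * te)
  n_e <- length(te)
  bg <- min(stats::median(ps[seq_len(min(ext, n_e))]),
            stats::median(ps[seq(max(1L, n_e - ext + 1L), n_e)]))
  peak <- max(ps[te >= t_lo0 & te <= t_hi0])
  # interior plateau = between the coarse half-of-peak crossings; the edge
  # level is half of its median, robust to bright fiber clumps inside
  lvl0 <- bg + 0.5 * (peak - bg)
  idx0 <- which(ps >= lvl0)
  interior <- ps[seq(min(idx0), max(idx0))]
  level <- bg + 0.5 * (stats::median(interior) - bg)
  above <- te[ps >= level]
  t_lo <- if (length(above)) min(above) else t_lo0
  t_hi <- if (length(above)) max(above) else t_hi0
  ts <- seq(t_lo, t_hi)
  prof <- bilinear_sample(img, ctr[1] + injury$along[1] * ts,
                          ctr[2] + injury$along[2] * ts)
  list(profile = prof, width_um = length(ts) * px,
       distance_um = distance_um, center = ctr)
}

#' Local nerve width at a distance from the injury site
#'
#' Width is the extent of the segmented nerve mask along the line orthogonal
#' to the axial direction at that distance (the nerve width may vary along
#' the nerve, and each step is normalized to it).
#'
#' @param projection a [nerve_projection()].
#' @param injury an [injury_site()].
#' @param distance_um axial distance from the injury line (um).
#' @param mask optional precomputed nerve mask (see [nerve_mask()]).
#' @return width in um.
#' @export
nerve_width_at <- function(projection, injury, distance_um, mask = NULL) {
  mask <- mask %||% nerve_mask(projection)
  transverse_profile(projection, injury, distance_um, mask)$width_um
}

#' Width-normalized integrated intensity at a distance from the injury site
#'
#' The fluorescence profile is sampled by bilinear interpolation at 1-pixel
#' spacing along the orthogonal line spanning the nerve width; the integral
#' is the profile sum times the pixel size, divided by the width, so a
#' spatially uniform signal yields its own intensity value regardless of
#' nerve width.
#'
#' @inheritParams nerve_width_at
#' @param smoothed optional precomputed smoothed image (sigma 2 px).
#' @return named numeric vector with `integral` (intensity, a.u.) and
#'   `width_um`.
#' @export
integrated_intensity_at <- function(projection, injury, distance_um,
                                    mask = NULL, smoothed = NULL) {
  mask <- mask %||% nerve_mask(projection)
  tp <- transverse_profile(projection, injury, distance_um, mask, smoothed)
  c(integral = sum(tp$profile) * projection$pixel_size_um / tp$width_um,
    width_um = tp$width_um)
}

#' Normalized regeneration curve along the nerve
#'
#' For each analysis distance d_k, the width-normalized integral I_k is
#' computed, normalized to `max_k I_k` (the maximal step in the regenerating
#' region; the background step is excluded from the maximum), and the
#' identically processed background step is subtracted. Values can be
#' negative and are retained as such.
#'
#' @param projection a [nerve_projection()].
#' @param injury an [injury_site()].
#' @param distances_um ascending analysis distances (um). The defaults are
#'   the commonly used steps.
#' @param background_position_um axial distance of a region with no
#'   regeneration, used as the background step.
#' @param mask optional precomputed nerve mask.
#' @return an object of class `regeneration_curve`: a list with
#'   `distances_um`, `values_au` (background-subtracted), `normalized`
#'   (pre-subtraction, max = 1), `integrals`, `widths_um` and
#'   `background_au`.
#' @export
regeneration_curve <- function(projection, injury,
                               distances_um = c(200, 500, 750, 1000, 1500,
                                                2000, 2500, 3000),
                               background_position_um,
                               mask = NULL) {
  if (is.unsorted(distances_um)) {
    stop("`distances_um` must be sorted ascending", call. = FALSE)
  }
  mask <- mask %||% nerve_mask(projection)
  smoothed <- gaussian_blur(projection$image, 2)
  steps <- vapply(distances_um, function(d) {
    integrated_intensity_at(projection, injury, d, mask, smoothed)
  }, c(integral = 0, width_um = 0))
  bg <- integrated_intensity_at(projection, injury, background_position_um,
                                mask, smoothed)
  I <- steps["integral", ]
  M <- max(I)
  if (!is.finite(M) || M <= 0) {
    stop("degenerate input: maximal step intensity is not positive",
         call. = FALSE)
  }
  normalized <- I / M
  background_au <- unname(bg["integral"] / M)
  structure(list(
    distances_um = distances_um,
    values_au = unname(normalized - background_au),
    normalized = unname(normalized),
    integrals = unname(I),
    widths_um = unname(steps["width_um", ]),
    background_au = background_au,
    background_position_um = background_position_um
  ), class = "regeneration_curve")
}

#' @export
print.regeneration_curve <- function(x, ...) {
  cat("Regeneration curve (a.u., background-subtracted)\n")
  print(data.frame(distance_um = x$distances_um,
                   normalized = round(x$normalized, 4),
                   value_au = round(x$values_au, 4),
                   width_um = round(x$widths_um, 1)), row.names = FALSE)
  cat(sprintf("background: %.4f (at %g um)\n",
              x$background_au, x$background_position_um))
  invisible(x)
}

#' Suggest an injury-site position from the axial intensity drop
#'
#' Advisory helper only: the injury site must be confirmed manually. Assumes
#' the nerve runs roughly left-to-right (axial = columns). The suggestion is
#' the axial position with the steepest drop of the smoothed axial intensity
#' sum, i.e. where labelling intensity falls fastest.
#'
#' @param projection a [nerve_projection()].
#' @param smooth_sigma_px Gaussian smoothing of the axial sum, in pixels.
#' @param min_relative_drop minimum relative intensity range below which the
#'   image is considered flat and no suggestion is made.
#' @return an [injury_site()] with `suggested = TRUE`, its line vertical at
#'   the proposed axial position and axial direction pointing right.
#' @export
suggest_injury_site <- function(projection, smooth_sigma_px = 3,
                                min_relative_drop = 0.05) {
  stopifnot(inherits(projection, "nerve_projection"))
  img <- projection$image
  s <- colSums(img)
  if (max(s) <= 0 || (max(s) - min(s)) / max(s) < min_relative_drop) {
    stop("no intensity drop detected: image too flat for a suggestion",
         call. = FALSE)
  }
  r <- max(1L, ceiling(3 * smooth_sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = smooth_sigma_px)
  k <- k / sum(k)
  n <- length(s)
  pad <- c(rev(s[seq_len(r) + 1L]), s, rev(s[n - seq_len(r)]))
  sm <- as.numeric(stats::filter(pad, k, sides = 2))[(r + 1L):(r + n)]
  drop <- diff(sm)
  margin <- r
  allowed <- seq(margin + 1L, length(drop) - margin)
  if (length(allowed) < 1L) {
    stop("image too narrow for a suggestion", call. = FALSE)
  }
  best <- allowed[which.min(drop[allowed])]
  if (best == allowed[1] || best == allowed[length(allowed)]) {
    warning("steepest drop lies at the edge of the analyzable range; ",
            "suggestion clamped inside it")
  }
  col0 <- best - 0.5                               # between cols best-1, best
  injury_site(c(0, col0), c(nrow(img) - 1, col0), axial_sign = 1,
              suggested = TRUE)
}
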
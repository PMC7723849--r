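# Explant axon-outgrowth quantification.
#
# Outgrowth is measured Sholl-style from the EXPLANT BORDER (not a soma
# centroid): the Euclidean distance transform from the explant mask defines
# distance bands at a fixed step (50 um), and the number of neurite
# intersections per band is the number of connected skeleton components
# crossing that band. Explants growing 0 or 1 axon are flagged and excluded
# from the profile statistics, and summarized separately.

#' Segment the explant body
#'
#' Median-filtered image, Otsu threshold, largest connected component above
#' a minimum area, holes filled. A manually drawn mask can be supplied and
#' is returned unchanged.
#'
#' @param image 2-D intensity matrix.
#' @param pixel_size_um um per pixel.
#' @param min_area_um2 minimum component area (default 1e4 um^2).
#' @param manual_mask optional logical matrix overriding segmentation.
#' @return logical explant mask.
#' @export
segment_explant <- function(image, pixel_size_um, min_area_um2 = 1e4,
                            manual_mask = NULL) {
  if (!is.null(manual_mask)) {
    stopifnot(is.logical(manual_mask), all(dim(manual_mask) == dim(image)))
    return(manual_mask)
  }
  stopifnot(is.matrix(image), is.numeric(image))
  check_number(pixel_size_um, "pixel_size_um", lower = 0,
               allow_equal_lower = FALSE)
  flt <- median_filter3(image)
  thr <- tryCatch(otsu_threshold(flt),
                  error = function(e) stop("segmentation failed: ",
                                           conditionMessage(e), call. = FALSE))
  lab <- label_components(flt > thr, 8L)
  n <- attr(lab, "n")
  if (n == 0L) stop("segmentation failed: no foreground found", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  min_px <- min_area_um2 / pixel_size_um^2
  if (max(sizes) < min_px) {
    stop(sprintf(
      "segmentation failed: largest component (%d px) below minimum area",
      max(sizes)), call. = FALSE)
  }
  fill_holes(lab == which.max(sizes))
}

#' Extract a 1-pixel-wide neurite skeleton outside the explant
#'
#' Thresholds the region outside the explant mask (Otsu on those pixels),
#' removes objects shorter than `min_size_um` of trace length, and thins the
#' result to a skeleton. The explant interior is always excluded. An empty
#' skeleton is a valid result.
#'
#' @param image 2-D intensity matrix.
#' @param explant_mask logical mask from [segment_explant()].
#' @param pixel_size_um um per pixel.
#' @param min_size_um minimum object size, as trace length (default 10 um).
#' @return logical skeleton matrix.
#' @export
neurite_skeleton <- function(image, explant_mask, pixel_size_um,
                             min_size_um = 10) {
  stopifnot(is.matrix(image), is.logical(explant_mask),
            all(dim(image) == dim(explant_mask)))
  check_number(pixel_size_um, "pixel_size_um", lower = 0,
               allow_equal_lower = FALSE)
  outside <- image[!explant_mask]
  empty <- matrix(FALSE, nrow(image), ncol(image))
  if (length(outside) == 0L) return(empty)
  thr <- tryCatch(otsu_threshold(outside), error = function(e) NULL)
  if (is.null(thr)) return(empty)
  fg <- image > thr & !explant_mask
  if (!any(fg)) return(empty)
  lab <- label_components(fg, 8L)
  sizes <- tabulate(lab[lab > 0L], nbins = attr(lab, "n"))
  min_px <- max(1, min_size_um / pixel_size_um)
  keep <- which(sizes >= min_px)
  if (length(keep) == 0L) return(empty)
  fg <- matrix(lab %in% keep, nrow(image), ncol(image))
  extend_skeleton_tips(skeletonize(fg), fg)
}

# Thinning retracts line endpoints by a pixel or two; grow each skeleton
# endpoint back along its local direction while the thresholded foreground
# continues, so the skeleton reaches the true neurite tip.
extend_skeleton_tips <- function(skel, fg, max_steps = 20L) {
  nr <- nrow(skel)
  nc <- ncol(skel)
  nb <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  count_nb <- function(r, c) {
    n <- 0L
    last <- NULL
    for (k in seq_len(8)) {
      rr <- r + nb[k, 1]
      cc <- c + nb[k, 2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && skel[rr, cc]) {
        n <- n + 1L
        last <- c(rr, cc)
      }
    }
    list(n = n, nb = last)
  }
  pix <- which(skel)
  for (p in pix) {
    r <- ((p - 1L) %% nr) + 1L
    c <- ((p - 1L) %/% nr) + 1L
    info <- count_nb(r, c)
    if (info$n != 1L) next
    dir <- c(r, c) - info$nb
    for (step in seq_len(max_steps)) {
      # straight continuation first, then its 45-degree variants
      cand <- unique(rbind(dir,
                           cbind(dir[1], c(-1, 0, 1)),
                           cbind(c(-1, 0, 1), dir[2])))
      moved <- FALSE
      for (k in seq_len(nrow(cand))) {
        d2 <- cand[k, ]
        if (all(d2 == 0) || sum(d2 * dir) <= 0) next
        rr <- r + d2[1]
        cc <- c + d2[2]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            fg[rr, cc] && !skel[rr, cc]) {
          skel[rr, cc] <- TRUE
          r <- rr
          c <- cc
          dir <- d2
          moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
  }
  skel
}

# Band membership used by sholl_counts: a skeleton pixel belongs to band r
# if its border distance lies within the 1-pixel annulus |d - r| <= 0.5, or
# if an 8-neighbouring skeleton pixel lies strictly on the other side of r
# and this pixel is the closer of the two (this "straddle" rule catches
# diagonal skeleton steps, whose distance increment can exceed the annulus
# width, so every geometric crossing is counted).
band_members <- function(d_skel, edges, r_px) {
  delta <- d_skel - r_px
  member <- abs(delta) <= 0.5
  if (nrow(edges) > 0L) {
    da <- delta[edges[, 1]]
    db <- delta[edges[, 2]]
    straddle <- da * db < 0
    if (any(straddle)) {
      a <- edges[straddle, 1]
      b <- edges[straddle, 2]
      closer_a <- abs(da[straddle]) <= abs(db[straddle])
      member[a[closer_a]] <- TRUE
      member[b[!closer_a]] <- TRUE
    }
  }
  member
}

# 8-adjacency edge list among a set of pixels given as linear indices into
# an nr x nc matrix. Returns a 2-column matrix of indices into `pix`.
pixel_adjacency <- function(pix, nr, nc) {
  if (length(pix) == 0L) return(matrix(integer(0), 0, 2))
  pos <- integer(nr * nc)
  pos[pix] <- seq_along(pix)
  r <- ((pix - 1L) %% nr) + 1L
  c <- ((pix - 1L) %/% nr) + 1L
  out <- vector("list", 4L)
  sh <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))  # half of 8-nb
  for (k in seq_along(sh)) {
    r2 <- r + sh[[k]][1]
    c2 <- c + sh[[k]][2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    q <- pos[(c2[ok] - 1L) * nr + r2[ok]]
    keep <- q > 0L
    out[[k]] <- cbind(which(ok)[keep], q[keep])
  }
  do.call(rbind, out)
}

#' Sholl intersection counts from the explant border
#'
#' Computes the Euclidean distance transform from the explant mask (0 on the
#' explant, increasing outward) and, for each band at k * `step_um`, counts
#' the connected components of skeleton pixels crossing the 1-pixel-wide
#' annulus centred on that radius. The axon count is the intersection count
#' at the first band; explants with 0 or 1 axon are flagged `no_growth`.
#'
#' @param skeleton logical skeleton matrix (see [neurite_skeleton()]).
#' @param explant_mask logical explant mask of the same geometry.
#' @param pixel_size_um um per pixel.
#' @param step_um band step (default 50 um).
#' @param max_distance_um optional largest band distance; defaults to the
#'   largest skeleton distance present.
#' @return an object of class `sholl_result`: list with `step_um`,
#'   `distances_um`, `intersect_counts`, `axon_count`, `no_growth`.
#' @export
sholl_counts <- function(skeleton, explant_mask, pixel_size_um, step_um = 50,
                         max_distance_um = NULL) {
  stopifnot(is.logical(skeleton), is.logical(explant_mask),
            all(dim(skeleton) == dim(explant_mask)))
  check_number(pixel_size_um, "pixel_size_um", lower = 0,
               allow_equal_lower = FALSE)
  if (!is.numeric(step_um) || length(step_um) != 1L || step_um <= 0) {
    stop("`step_um` must be a positive number", call. = FALSE)
  }
  nr <- nrow(skeleton)
  nc <- ncol(skeleton)
  skeleton <- skeleton & !explant_mask
  d_all <- distance_to_mask(explant_mask)
  pix <- which(skeleton)
  d_skel <- d_all[pix]

  max_d_um <- max_distance_um %||%
    (if (length(pix) > 0L) max(d_skel) * pixel_size_um else 0)
  n_bands <- floor(max_d_um / step_um)
  distances_um <- if (n_bands >= 1L) seq_len(n_bands) * step_um else numeric(0)

  counts <- integer(length(distances_um))
  if (length(pix) > 0L && length(distances_um) > 0L) {
    edges <- pixel_adjacency(pix, nr, nc)
    scratch <- matrix(FALSE, nr, nc)
    for (k in seq_along(distances_um)) {
      r_px <- distances_um[k] / pixel_size_um
      member <- band_members(d_skel, edges, r_px)
      if (!any(member)) next
      scratch[pix[member]] <- TRUE
      lab <- label_components(scratch, 8L)
      counts[k] <- attr(lab, "n")
      scratch[pix[member]] <- FALSE
    }
  }
  axon_count <- if (length(counts) >= 1L) counts[1] else 0L
  structure(list(step_um = step_um, distances_um = distances_um,
                 intersect_counts = counts, axon_count = axon_count,
                 no_growth = axon_count <= 1L),
            class = "sholl_result")
}

#' @export
print.sholl_result <- function(x, ...) {
  cat(sprintf("Sholl profile (step %g um): axon count %d%s\n", x$step_um,
              x$axon_count, if (x$no_growth) " [no/little outgrowth]" else ""))
  if (length(x$distances_um)) {
    print(data.frame(distance_um = x$distances_um,
                     intersections = x$intersect_counts), row.names = FALSE)
  }
  invisible(x)
}

#' Per-condition outgrowth summary table
#'
#' Counts explants with no or little outgrowth (0 or 1 axon) versus
#' quantified explants per condition, with percentages rounded half-up to
#' one decimal, as customarily printed.
#'
#' @param no_growth logical vector, one element per explant.
#' @param condition factor or character vector of condition labels, parallel
#'   to `no_growth`.
#' @return data.frame with columns `condition`, `total_explants`,
#'   `n_no_growth`, `pct_no_growth`, `n_quantified`, `pct_quantified`.
#' @export
summarize_outgrowth <- function(no_growth, condition) {
  if (length(no_growth) == 0L) stop("no explants supplied", call. = FALSE)
  if (length(condition) != length(no_growth)) {
    stop("`condition` and `no_growth` must have the same length",
         call. = FALSE)
  }
  no_growth <- as.logical(no_growth)
  if (anyNA(no_growth)) stop("`no_growth` contains NA", call. = FALSE)
  condition <- as.character(condition)
  levels <- unique(condition)
  rows <- lapply(levels, function(lv) {
    sel <- condition == lv
    total <- sum(sel)
    n_ng <- sum(no_growth[sel])
    data.frame(condition = lv,
               total_explants = total,
               n_no_growth = n_ng,
               pct_no_growth = round_half_up(100 * n_ng / total, 1L),
               n_quantified = total - n_ng,
               pct_quantified = round_half_up(100 * (total - n_ng) / total, 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score growth-cone collapse from per-cone annotations
#'
#' A growth cone is collapsed when it bears fewer than 2 filopodia AND no
#' lamellipodia. Returns the collapse fraction per explant and the group
#' mean with its s.e.m.
#'
#' @param annotations data.frame with columns `explant_id`, `n_filopodia`
#'   (nonnegative integer) and `has_lamellipodia` (logical); a `cone_id`
#'   column is allowed and ignored.
#' @return list with `per_cone` (input plus `collapsed`), `per_explant`
#'   (data.frame of explant_id, n_cones, n_collapsed, fraction_collapsed)
#'   and `group` (mean, sem, n_explants).
#' @export
score_collapse <- function(annotations) {
  req <- c("explant_id", "n_filopodia", "has_lamellipodia")
  if (!is.data.frame(annotations) || nrow(annotations) == 0L) {
    stop("`annotations` must be a non-empty data.frame", call. = FALSE)
  }
  if (!all(req %in% names(annotations))) {
    stop("`annotations` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(annotations$n_filopodia < 0)) {
    stop("`n_filopodia` must be nonnegative", call. = FALSE)
  }
  ann <- annotations
  ann$collapsed <- ann$n_filopodia < 2 & !as.logical(ann$has_lamellipodia)
  sp <- split(ann$collapsed, ann$explant_id)
  per_explant <- data.frame(
    explant_id = names(sp),
    n_cones = vapply(sp, length, 0L),
    n_collapsed = vapply(sp, sum, 0L),
    fraction_collapsed = vapply(sp, mean, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  fr <- per_explant$fraction_collapsed
  group <- list(mean = mean(fr),
                sem = if (length(fr) > 1L) stats::sd(fr) / sqrt(length(fr))
                      else NA_real_,
                n_explants = length(fr))
  list(per_cone = ann, per_explant = per_explant, group = group)
}
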
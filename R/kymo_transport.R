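# Kymograph construction and organelle transport kinetics.
#
# A kymograph resamples a time-lapse movie along an axon path: rows are
# arc-length stations (1 pixel apart), columns are frames; at each station
# the intensity is the maximum over a short line orthogonal to the path
# (preserving punctate signal). The position axis points anterograde,
# toward the declared growth-cone (distal) end. Per-interval velocities are
# classified against a minimum speed (default 0.02 um/s, threshold
# inclusive); summary kinetics follow the directional-velocity /
# linear-flow-rate conventions of kymograph analysis tools.

#' Time-lapse movie container
#' @param stack 3-D numeric array ordered (time, row, col), at least 2 frames.
#' @param frame_interval_s seconds between frames.
#' @param pixel_size_um um per pixel.
#' @return an object of class `time_lapse_movie`.
#' @export
time_lapse_movie <- function(stack, frame_interval_s, pixel_size_um) {
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[1] < 2L) {
    stop("`stack` must be a (time, row, col) array with >= 2 frames",
         call. = FALSE)
  }
  check_number(frame_interval_s, "frame_interval_s", lower = 0,
               allow_equal_lower = FALSE)
  check_number(pixel_size_um, "pixel_size_um", lower = 0,
               allow_equal_lower = FALSE)
  structure(list(stack = stack, frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um), class = "time_lapse_movie")
}

#' Axon path for kymograph resampling
#' @param vertices matrix of polyline vertices, 0-based `(row, col)` pixel
#'   coordinates, >= 2 rows.
#' @param distal_end `"last"` or `"first"`: which end of the polyline is the
#'   growth-cone (distal) end; positions increase toward it (anterograde).
#' @param linewidth_px odd positive integer; number of orthogonal samples
#'   aggregated (by maximum) at each station.
#' @return an object of class `axon_path`.
#' @export
axon_path <- function(vertices, distal_end = c("last", "first"),
                      linewidth_px = 3L) {
  distal_end <- match.arg(distal_end)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L || ncol(vertices) != 2L) {
    stop("`vertices` must be an n x 2 matrix with n >= 2", call. = FALSE)
  }
  seg <- diff(vertices)
  len <- sqrt(rowSums(seg^2))
  if (sum(len) <= 0) stop("path has zero length", call. = FALSE)
  check_number(linewidth_px, "linewidth_px", lower = 1, integer = TRUE)
  if (linewidth_px %% 2L == 0L) {
    stop("`linewidth_px` must be odd", call. = FALSE)
  }
  structure(list(vertices = vertices, distal_end = distal_end,
                 linewidth_px = as.integer(linewidth_px),
                 length_px = sum(len)), class = "axon_path")
}

# Resample path at 1-px arc-length stations; returns station coordinates
# (0-based row/col) and unit normals, ordered proximal -> distal.
path_stations <- function(path) {
  v <- path$vertices
  seg <- diff(v)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = 1)
  if (s[length(s)] < total) s <- c(s, total)
  iseg <- findInterval(s, cum, rightmost.closed = TRUE)
  iseg[iseg >= nrow(v)] <- nrow(v) - 1L
  frac <- (s - cum[iseg]) / seg_len[iseg]
  pts <- v[iseg, , drop = FALSE] + seg[iseg, , drop = FALSE] * frac
  tang <- seg[iseg, , drop = FALSE] / seg_len[iseg]
  nrm <- cbind(-tang[, 2], tang[, 1])
  if (path$distal_end == "first") {
    idx <- rev(seq_along(s))
    pts <- pts[idx, , drop = FALSE]
    nrm <- nrm[idx, , drop = FALSE]
  }
  list(points = pts, normals = nrm, arc_px = s)
}

#' Build a kymograph from a movie along an axon path
#'
#' @param movie a [time_lapse_movie()].
#' @param path an [axon_path()]; must lie within the frame bounds.
#' @return an object of class `kymograph`: list with `array` (stations x
#'   frames), `position_step_um`, `frame_interval_s`, `positions_um`.
#' @export
build_kymograph <- function(movie, path) {
  stopifnot(inherits(movie, "time_lapse_movie"), inherits(path, "axon_path"))
  d <- dim(movie$stack)
  st <- path_stations(path)
  if (any(st$points[, 1] < 0) || any(st$points[, 1] > d[2] - 1) ||
      any(st$points[, 2] < 0) || any(st$points[, 2] > d[3] - 1)) {
    stop("axon path falls outside the image bounds", call. = FALSE)
  }
  w <- path$linewidth_px
  offs <- seq(-(w - 1L) / 2, (w - 1L) / 2)
  n_st <- nrow(st$points)
  rr <- outer(st$points[, 1], offs, function(a, b) a) +
    outer(st$normals[, 1], offs)
  cc <- outer(st$points[, 2], offs, function(a, b) a) +
    outer(st$normals[, 2], offs)
  kym <- matrix(0, n_st, d[1])
  for (t in seq_len(d[1])) {
    frame <- matrix(movie$stack[t, , ], d[2], d[3])
    vals <- matrix(bilinear_sample(frame, as.numeric(rr), as.numeric(cc)),
                   n_st, w)
    kym[, t] <- do.call(pmax, as.data.frame(vals))
  }
  structure(list(array = kym,
                 position_step_um = movie$pixel_size_um,
                 frame_interval_s = movie$frame_interval_s,
                 positions_um = (seq_len(n_st) - 1) * movie$pixel_size_um),
            class = "kymograph")
}

#' Display a kymograph
#' @param x a `kymograph`.
#' @param ... passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = (seq_len(ncol(x$array)) - 1) * x$frame_interval_s,
                  y = x$positions_um, z = t(x$array),
                  xlab = "time (s)", ylab = "position (um)",
                  col = grDevices::gray.colors(256, 0, 1), ...)
  invisible(x)
}

new_track <- function(frame, position_um, organelle_id, frame_interval_s,
                      source = "auto", low_confidence = FALSE) {
  stopifnot(length(frame) == length(position_um))
  structure(list(organelle_id = organelle_id,
                 samples = data.frame(frame = as.integer(frame),
                                      position_um = position_um),
                 frame_interval_s = frame_interval_s,
                 source = source, low_confidence = low_confidence),
            class = "track")
}

#' Construct a manually drawn track
#' @param frame integer frame indices (strictly increasing).
#' @param position_um positions along the path (um).
#' @param frame_interval_s seconds between consecutive frames.
#' @param organelle_id identifier.
#' @return an object of class `track`.
#' @export
track <- function(frame, position_um, frame_interval_s, organelle_id = 1L) {
  if (is.unsorted(frame, strictly = TRUE)) {
    stop("`frame` indices must be strictly increasing", call. = FALSE)
  }
  new_track(frame, position_um, organelle_id, frame_interval_s,
            source = "manual")
}

# column-wise local maxima above threshold, with parabolic sub-pixel
# refinement; returns positions in station units (0-based, fractional)
column_peaks <- function(col_vals, threshold) {
  n <- length(col_vals)
  if (n < 3L) return(numeric(0))
  core <- 2:(n - 1L)
  is_peak <- col_vals[core] >= threshold &
    col_vals[core] >= col_vals[core - 1L] &
    col_vals[core] > col_vals[core + 1L]
  idx <- core[is_peak]
  if (length(idx) == 0L) return(numeric(0))
  y0 <- col_vals[idx - 1L]
  y1 <- col_vals[idx]
  y2 <- col_vals[idx + 1L]
  denom <- y0 - 2 * y1 + y2
  shift <- ifelse(abs(denom) > 1e-12, 0.5 * (y0 - y2) / denom, 0)
  shift <- pmin(pmax(shift, -0.5), 0.5)
  (idx - 1L) + shift
}

#' Detect and link organelle tracks on a kymograph
#'
#' Per-frame peak detection above a threshold followed by nearest-neighbour
#' linking across frames, with a maximum per-frame step of `max_speed_um_s *
#' frame_interval`. Peaks unmatched for more than `max_gap` frames terminate
#' their track; tracks shorter than `min_frames` are discarded. When two
#' candidates compete for the same peak the nearest wins and the involved
#' tracks are flagged low-confidence.
#'
#' @param kymograph a [build_kymograph()] result.
#' @param intensity_threshold peak detection threshold; default is a robust
#'   floor (median + 5 * mad of the kymograph).
#' @param max_speed_um_s largest linkable speed (default 2 um/s).
#' @param min_frames minimum track length in frames (default 5).
#' @param max_gap frames a track may go undetected before termination.
#' @param merge_radius_um when two tracks compete for peaks closer than
#'   this, the involved trajectories are split rather than linked through
#'   (crossing organelles merge into a single unresolvable peak whose
#'   centroid position would otherwise contaminate interval velocities);
#'   default 3 position steps.
#' @return list of `track` objects (possibly empty).
#' @export
extract_tracks_auto <- function(kymograph, intensity_threshold = NULL,
                                max_speed_um_s = 2, min_frames = 5L,
                                max_gap = 2L, merge_radius_um = NULL) {
  stopifnot(inherits(kymograph, "kymograph"))
  kym <- kymograph$array
  step <- kymograph$position_step_um
  dt <- kymograph$frame_interval_s
  thr <- intensity_threshold %||%
    (stats::median(kym) + 5 * stats::mad(kym))
  max_jump_um <- max_speed_um_s * dt
  merge_radius_um <- merge_radius_um %||% (3 * step)

  active <- list()   # each: list(frames, pos_um, last_frame, low_conf)
  done <- list()
  for (t in seq_len(ncol(kym))) {
    peaks_um <- column_peaks(kym[, t], thr) * step
    n_active <- length(active)
    if (n_active > 0L && length(peaks_um) > 0L) {
      last_pos <- vapply(active, function(a) a$pos_um[length(a$pos_um)], 0)
      gap <- t - vapply(active, function(a) a$last_frame, 0L)
      cost <- abs(outer(last_pos, peaks_um, "-"))
      allowed <- cost <= max_jump_um * gap
      cost[!allowed] <- Inf
      # a peak contested by two tracks within the merge radius is a likely
      # unresolved crossing: split trajectories there instead of linking
      contested <- colSums(cost <= merge_radius_um) >= 2L
      assigned_peak <- rep(NA_integer_, n_active)
      taken <- logical(length(peaks_um))
      ord <- order(cost)
      for (o in ord) {
        if (!is.finite(cost[o])) break
        i <- ((o - 1L) %% n_active) + 1L
        j <- ((o - 1L) %/% n_active) + 1L
        if (is.na(assigned_peak[i]) && !taken[j]) {
          assigned_peak[i] <- j
          taken[j] <- TRUE
          if (contested[j]) active[[i]]$low_conf <- TRUE
        }
      }
      split_new <- integer(0)
      for (i in seq_len(n_active)) {
        j <- assigned_peak[i]
        if (is.na(j)) next
        if (contested[j]) {
          # close this trajectory before the crossing; restart at the peak
          active[[i]]$split <- TRUE
          split_new <- c(split_new, j)
        } else {
          active[[i]]$frames <- c(active[[i]]$frames, t)
          active[[i]]$pos_um <- c(active[[i]]$pos_um, peaks_um[j])
          active[[i]]$last_frame <- t
        }
      }
      if (length(split_new) > 0L) {
        closed <- vapply(active, function(a) isTRUE(a$split), logical(1))
        done <- c(done, lapply(active[closed], function(a) {
          a$split <- NULL
          a
        }))
        active <- active[!closed]
      }
      new_idx <- c(which(!taken), split_new)
    } else {
      new_idx <- seq_along(peaks_um)
    }
    # retire stale tracks
    if (length(active) > 0L) {
      stale <- vapply(active, function(a) t - a$last_frame > max_gap,
                      logical(1))
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    for (j in new_idx) {
      active[[length(active) + 1L]] <-
        list(frames = t, pos_um = peaks_um[j], last_frame = t,
             low_conf = FALSE)
    }
  }
  done <- c(done, active)
  done <- Filter(function(a) length(a$frames) >= min_frames, done)
  out <- vector("list", length(done))
  for (i in seq_along(done)) {
    out[[i]] <- new_track(done[[i]]$frames, done[[i]]$pos_um, i, dt,
                          source = "auto",
                          low_confidence = done[[i]]$low_conf)
  }
  out
}

#' Classify a track's intervals and its organelle class
#'
#' Per-interval velocity is displacement over elapsed time; an interval is
#' anterograde when v >= v_min, retrograde when v <= -v_min, otherwise
#' pausing (the minimum-speed threshold is inclusive: exactly v_min counts
#' as movement). The organelle class is the sign of the net displacement if
#' the net speed reaches v_min, otherwise stationary.
#'
#' @param track a [track()].
#' @param v_min_um_s minimum speed (um/s), default 0.02.
#' @return list with `states` (character, one per interval), `velocities`
#'   (um/s), `class` (`"anterograde"`, `"retrograde"` or `"stationary"`).
#' @export
classify_track <- function(track, v_min_um_s = 0.02) {
  stopifnot(inherits(track, "track"))
  s <- track$samples
  if (nrow(s) < 2L) {
    stop("track needs at least 2 samples to classify", call. = FALSE)
  }
  dt <- diff(s$frame) * track$frame_interval_s
  v <- diff(s$position_um) / dt
  states <- ifelse(v >= v_min_um_s, "anterograde",
                   ifelse(v <= -v_min_um_s, "retrograde", "pausing"))
  duration <- (s$frame[nrow(s)] - s$frame[1]) * track$frame_interval_s
  net_v <- (s$position_um[nrow(s)] - s$position_um[1]) / duration
  cls <- if (abs(net_v) >= v_min_um_s) {
    if (net_v > 0) "anterograde" else "retrograde"
  } else "stationary"
  list(states = states, velocities = v, interval_s = dt, class = cls,
       net_velocity_um_s = net_v)
}

#' Transport kinetics over a set of tracks
#'
#' Directional mean velocities are computed over moving time: `Vma` is the
#' total distance covered during anterograde intervals divided by the total
#' duration of those intervals (all organelles pooled), and `Vmr` likewise
#' for retrograde intervals (reported as a magnitude). Setting `time_basis =
#' "total"` divides by total track time instead (the printed formulas leave
#' the denominator ambiguous; moving time is the default). The pausing
#' fraction is computed per organelle, averaged within each axon, then
#' averaged across axons. The linear flow rate is `Q = Vma * n_anterograde +
#' Vmr * n_retrograde`.
#'
#' @param tracks list of [track()] objects (>= 1).
#' @param v_min_um_s minimum speed (um/s).
#' @param axon_ids optional vector assigning each track to an axon; one axon
#'   assumed when `NULL`.
#' @param time_basis `"segment"` (per-direction moving time) or `"total"`.
#' @return an object of class `track_kinetics`: `Vma_um_s`, `Vmr_um_s`,
#'   `n_anterograde`, `n_retrograde`, `n_stationary`, `pausing_fraction`,
#'   `Q_um_s`, `v_min_um_s`, `n_tracks`, `moving_fraction` (fraction of
#'   tracks classified moving), `moving_time_fraction` (fraction of total
#'   track time spent on tracks classified moving -- the better estimator of
#'   the fraction of moving organelles when automatic tracking fragments
#'   trajectories unevenly), `flags`.
#' @export
kinetics <- function(tracks, v_min_um_s = 0.02, axon_ids = NULL,
                     time_basis = c("segment", "total")) {
  time_basis <- match.arg(time_basis)
  if (!is.list(tracks) || length(tracks) == 0L) {
    stop("`tracks` must be a non-empty list", call. = FALSE)
  }
  if (inherits(tracks, "track")) tracks <- list(tracks)
  axon_ids <- axon_ids %||% rep(1L, length(tracks))
  stopifnot(length(axon_ids) == length(tracks))

  antero_dist <- antero_time <- retro_dist <- retro_time <- 0
  total_time <- moving_time <- 0
  n_a <- n_r <- n_s <- 0L
  pause_frac <- numeric(length(tracks))
  for (i in seq_along(tracks)) {
    cl <- classify_track(tracks[[i]], v_min_um_s)
    a <- cl$states == "anterograde"
    r <- cl$states == "retrograde"
    p <- cl$states == "pausing"
    antero_dist <- antero_dist + sum(cl$velocities[a] * cl$interval_s[a])
    antero_time <- antero_time + sum(cl$interval_s[a])
    retro_dist <- retro_dist + sum(-cl$velocities[r] * cl$interval_s[r])
    retro_time <- retro_time + sum(cl$interval_s[r])
    total_time <- total_time + sum(cl$interval_s)
    if (cl$class != "stationary") moving_time <- moving_time + sum(cl$interval_s)
    pause_frac[i] <- sum(cl$interval_s[p]) / sum(cl$interval_s)
    switch(cl$class,
           anterograde = n_a <- n_a + 1L,
           retrograde = n_r <- n_r + 1L,
           stationary = n_s <- n_s + 1L)
  }
  flags <- character(0)
  if (time_basis == "segment") {
    Vma <- if (antero_time > 0) antero_dist / antero_time else 0
    Vmr <- if (retro_time > 0) retro_dist / retro_time else 0
  } else {
    Vma <- if (total_time > 0) antero_dist / total_time else 0
    Vmr <- if (total_time > 0) retro_dist / total_time else 0
  }
  if (antero_time == 0) flags <- c(flags, "no anterograde intervals; Vma = 0")
  if (retro_time == 0) flags <- c(flags, "no retrograde intervals; Vmr = 0")

  per_axon <- vapply(split(pause_frac, axon_ids), mean, 0)
  structure(list(
    Vma_um_s = Vma, Vmr_um_s = Vmr,
    n_anterograde = n_a, n_retrograde = n_r, n_stationary = n_s,
    pausing_fraction = mean(per_axon),
    Q_um_s = Vma * n_a + Vmr * n_r,
    v_min_um_s = v_min_um_s,
    n_tracks = length(tracks),
    moving_fraction = (n_a + n_r) / length(tracks),
    moving_time_fraction = if (total_time > 0) moving_time / total_time else 0,
    time_basis = time_basis,
    flags = flags
  ), class = "track_kinetics")
}

#' @export
print.track_kinetics <- function(x, ...) {
  cat(sprintf(
    paste0("Transport kinetics (n = %d tracks, v_min = %g um/s)\n",
           "  Vma %.3f um/s  Vmr %.3f um/s  Q %.3f um/s\n",
           "  anterograde %d  retrograde %d  stationary %d",
           "  (moving %.0f%%)\n  pausing %.1f%% of time\n"),
    x$n_tracks, x$v_min_um_s, x$Vma_um_s, x$Vmr_um_s, x$Q_um_s,
    x$n_anterograde, x$n_retrograde, x$n_stationary,
    100 * x$moving_fraction, 100 * x$pausing_fraction))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Test whether a track shows a sustained movement event
#'
#' A track is motile when it achieves a net displacement of at least
#' `v_min_um_s * span_s` within some time window of `span_s` seconds — the
#' displacement a minimum-speed organelle covers in that span, and an order
#' of magnitude above sub-pixel localization noise. Unlike the
#' net-displacement organelle class, this is robust on short track
#' fragments of organelles that happen to pause.
#'
#' @param track a [track()].
#' @param v_min_um_s minimum speed (um/s).
#' @param span_s window length in seconds (default 20).
#' @return logical.
#' @export
track_is_motile <- function(track, v_min_um_s = 0.02, span_s = 20) {
  stopifnot(inherits(track, "track"))
  fr <- track$samples$frame * track$frame_interval_s
  p <- track$samples$position_um
  disp <- v_min_um_s * span_s
  for (i in seq_along(fr)) {
    j <- which(fr > fr[i] & fr <= fr[i] + span_s)
    if (length(j) && max(abs(p[j] - p[i])) >= disp) return(TRUE)
  }
  FALSE
}

# Fraction of moving organelles estimated from track snapshots: at each
# reference frame, the organelles present are represented by exactly the
# tracks alive there (fragmentation cannot over-represent fast movers), and
# each is called moving by the sustained-movement test.
snapshot_moving_fraction <- function(tracks, ref_frames, v_min_um_s = 0.02) {
  vals <- vapply(ref_frames, function(tref) {
    alive <- vapply(tracks, function(t) {
      min(t$samples$frame) <= tref && max(t$samples$frame) >= tref
    }, logical(1))
    if (!any(alive)) return(NA_real_)
    mean(vapply(tracks[alive], track_is_motile, logical(1),
                v_min_um_s = v_min_um_s))
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Run the full synthetic transport pipeline for a preset
#'
#' Simulates an organelle movie for a named preset, builds the kymograph
#' along the (straight) axon, extracts tracks automatically and computes
#' kinetics, returning both the estimates and the generator ground truth.
#'
#' @param preset_name passed to [track_preset()].
#' @param n_organelles number of organelles to simulate.
#' @param seed RNG seed.
#' @param v_min_um_s minimum speed for classification.
#' @return list with `estimate` (a `track_kinetics`),
#'   `moving_fraction_estimate` (snapshot estimate of the fraction of moving
#'   organelles, see [track_is_motile()]), `truth_kinetics` (kinetics
#'   computed from the true trajectories), `truth` (generator record),
#'   `tracks`, `kymograph` and `config`.
#' @export
recover_preset <- function(preset_name, n_organelles = 50L, seed = 1L,
                           v_min_um_s = 0.02) {
  cfg <- track_preset(preset_name, n_organelles = n_organelles, seed = seed)
  sim <- simulate_organelle_movie(cfg)
  d <- dim(sim$movie)
  cy <- sim$truth$center_row
  mv <- time_lapse_movie(sim$movie, cfg$frame_interval_s, cfg$pixel_size_um)
  pth <- axon_path(rbind(c(cy, 0), c(cy, d[3] - 1)), distal_end = "last",
                   linewidth_px = 3L)
  kym <- build_kymograph(mv, pth)
  thr <- cfg$punctum_intensity * 0.3 + cfg$noise_sd * 3
  # classification against v_min needs tracks long enough to resolve one
  # pixel of net displacement: v_min * t_min >= pixel size
  min_frames <- max(5L, ceiling(cfg$pixel_size_um /
                                  (v_min_um_s * cfg$frame_interval_s)))
  tracks <- extract_tracks_auto(kym, intensity_threshold = thr,
                                min_frames = min_frames)
  est <- if (length(tracks) > 0) kinetics(tracks, v_min_um_s) else NULL
  ref_frames <- round(cfg$n_frames * c(0.05, 0.1, 0.15, 0.2))
  mfe <- snapshot_moving_fraction(tracks, ref_frames, v_min_um_s)

  truth_tracks <- lapply(seq_len(cfg$n_organelles), function(i) {
    new_track(seq_len(cfg$n_frames), sim$truth$positions_um[, i], i,
              cfg$frame_interval_s, source = "manual")
  })
  truth_kin <- kinetics(truth_tracks, v_min_um_s)
  list(estimate = est, moving_fraction_estimate = mfe,
       truth_kinetics = truth_kin, truth = sim$truth,
       tracks = tracks, kymograph = kym, config = cfg)
}
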
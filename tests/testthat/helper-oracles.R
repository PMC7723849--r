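# Independent oracles and fixture builders, deliberately written with plain
# loops / brute force so they share no code path with the implementation.

# maximum projection by explicit triple loop
brute_max_project <- function(stack) {
  d <- dim(stack)
  out <- matrix(-Inf, d[2], d[3])
  for (z in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      for (x in seq_len(d[3])) {
        if (stack[z, y, x] > out[y, x]) out[y, x] <- stack[z, y, x]
      }
    }
  }
  out
}

# boundary pixels of a mask (mask pixels 4-adjacent to background or border)
mask_boundary <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(mask & !inner)
}

# exact distance of given pixels (linear indices) to the nearest mask pixel,
# via explicit minimum over mask boundary pixels (valid for pixels outside
# the mask, where the nearest mask pixel is always a boundary pixel)
brute_distance_to_mask <- function(pixels, mask) {
  nr <- nrow(mask)
  b <- mask_boundary(mask)
  br <- (b - 1L) %% nr
  bc <- (b - 1L) %/% nr
  pr <- (pixels - 1L) %% nr
  pc <- (pixels - 1L) %/% nr
  out <- numeric(length(pixels))
  for (k in seq_along(pixels)) {
    out[k] <- sqrt(min((pr[k] - br)^2 + (pc[k] - bc)^2))
  }
  out
}

# flood-fill component count over a set of pixels (linear indices),
# 8-connectivity, plain R queue
brute_component_count <- function(pixels, nr, nc) {
  if (length(pixels) == 0L) return(0L)
  inset <- new.env(hash = TRUE)
  for (p in pixels) assign(as.character(p), FALSE, envir = inset)
  n <- 0L
  for (p in pixels) {
    if (get(as.character(p), envir = inset)) next
    n <- n + 1L
    queue <- p
    assign(as.character(p), TRUE, envir = inset)
    while (length(queue) > 0L) {
      q <- queue[[1]]
      queue <- queue[-1]
      qr <- (q - 1L) %% nr
      qc <- (q - 1L) %/% nr
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          rr <- qr + dr
          cc <- qc + dc
          if (rr < 0L || rr >= nr || cc < 0L || cc >= nc) next
          nb <- rr + cc * nr + 1L
          key <- as.character(nb)
          if (exists(key, envir = inset, inherits = FALSE) &&
              !get(key, envir = inset)) {
            assign(key, TRUE, envir = inset)
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  n
}

# brute-force Sholl band counts: distances via brute_distance_to_mask, the
# same band-membership rule (annulus plus straddling-edge capture) evaluated
# pixel by pixel, components via R flood fill
brute_sholl <- function(skeleton, mask, pixel_size_um, step_um = 50,
                        max_distance_um = NULL) {
  nr <- nrow(skeleton)
  nc <- ncol(skeleton)
  skeleton <- skeleton & !mask
  pix <- which(skeleton)
  if (length(pix) == 0L) return(integer(0))
  d <- brute_distance_to_mask(pix, mask)
  max_d_um <- if (is.null(max_distance_um)) max(d) * pixel_size_um else
    max_distance_um
  n_bands <- floor(max_d_um / step_um)
  counts <- integer(n_bands)
  pr <- (pix - 1L) %% nr
  pc <- (pix - 1L) %/% nr
  for (k in seq_len(n_bands)) {
    r_px <- k * step_um / pixel_size_um
    delta <- d - r_px
    member <- abs(delta) <= 0.5
    # straddle: for every 8-adjacent skeleton pair on opposite sides of the
    # radius, add the closer endpoint; only pixels within sqrt(2) + 0.5 of
    # the radius can participate, so the pair scan is restricted to them
    cand <- which(abs(delta) <= sqrt(2) + 0.5)
    for (a in cand) {
      for (b in cand) {
        if (a == b) next
        if (abs(pr[a] - pr[b]) <= 1L && abs(pc[a] - pc[b]) <= 1L &&
            delta[a] * delta[b] < 0 && abs(delta[a]) <= abs(delta[b])) {
          member[a] <- TRUE
        }
      }
    }
    counts[k] <- brute_component_count(pix[member], nr, nc)
  }
  counts
}

# analytic straight-ray fixture: a disk mask plus n 1-px rays of exactly
# `length_um` emanating radially, rasterized at fine arc steps
make_ray_fixture <- function(n_rays = 7, length_um = 400, radius_um = 250,
                             pixel_size_um = 5, angle_offset = 0.15) {
  margin_um <- 100
  S <- 2L * ceiling((radius_um + length_um + margin_um) / pixel_size_um) + 1L
  c0 <- (S - 1) / 2
  R_px <- radius_um / pixel_size_um
  rows0 <- matrix(seq_len(S) - 1, S, S)
  cols0 <- matrix(seq_len(S) - 1, S, S, byrow = TRUE)
  mask <- (rows0 - c0)^2 + (cols0 - c0)^2 <= R_px^2
  skel <- matrix(FALSE, S, S)
  angles <- angle_offset + 2 * pi * (seq_len(n_rays) - 1) / n_rays
  for (phi in angles) {
    rr <- seq(R_px, R_px + length_um / pixel_size_um, by = 0.25)
    ri <- round(c0 + rr * sin(phi))
    ci <- round(c0 + rr * cos(phi))
    skel[cbind(ri + 1, ci + 1)] <- TRUE
  }
  skel <- skel & !mask
  list(skeleton = skel, mask = mask, pixel_size_um = pixel_size_um)
}

# run the explant measurement pipeline on a simulated image
run_explant_pipeline <- function(sim, pixel_size_um = 5, step_um = 50) {
  m <- segment_explant(sim$image, pixel_size_um)
  s <- neurite_skeleton(sim$image, m, pixel_size_um)
  list(mask = m, skeleton = s,
       sholl = sholl_counts(s, m, pixel_size_um, step_um = step_um))
}

# a simple straight-axon movie config for tracking tests
well_separated_movie <- function(n = 3, speed = 0.4, seed = 1) {
  track_sim_config(
    n_organelles = n, frac_moving = 1, frac_anterograde_among_moving = 1,
    speed_antero_um_s = speed, speed_retro_um_s = speed,
    pause_prob_per_frame = 0, resume_prob_per_frame = 1,
    n_frames = 60L, axon_length_um = 120,
    init_positions_um = seq(10, 50, length.out = n),
    noise_sd = 0.5, seed = seed)
}
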
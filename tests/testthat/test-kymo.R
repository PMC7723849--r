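test_that("kymograph: static movies, slope recovery, linewidth, bounds", {
  # static movie -> identical columns
  frame <- matrix(runif(20 * 60), 20, 60)
  st <- array(0, c(5, 20, 60))
  for (t in 1:5) st[t, , ] <- frame
  mv <- time_lapse_movie(st, 1, 0.2)
  pth <- axon_path(rbind(c(9, 2), c(9, 57)), "last", 3L)
  ky <- build_kymograph(mv, pth)
  expect_equal(ky$array, ky$array[, c(1, 1, 1, 1, 1)])

  # single punctum at 0.5 um/s: ridge slope recovered within 10%
  cfg <- track_sim_config(n_organelles = 1, frac_moving = 1,
                          frac_anterograde_among_moving = 1,
                          speed_antero_um_s = 0.5, pause_prob_per_frame = 0,
                          resume_prob_per_frame = 1, n_frames = 40,
                          init_positions_um = 5, noise_sd = 0.2, seed = 3)
  sim <- simulate_organelle_movie(cfg)
  d <- dim(sim$movie)
  mv2 <- time_lapse_movie(sim$movie, 1, 0.2)
  pth2 <- axon_path(rbind(c(sim$truth$center_row, 0),
                          c(sim$truth$center_row, d[3] - 1)), "last", 3L)
  ky2 <- build_kymograph(mv2, pth2)
  ridge <- apply(ky2$array, 2, which.max)
  fit <- stats::lm(ky2$positions_um[ridge] ~ seq_len(ncol(ky2$array)))
  expect_lt(abs(coef(fit)[2] - 0.5) / 0.5, 0.1)

  # linewidth 1 vs 3 give the same ridge for a centred punctum
  pth1 <- axon_path(pth2$vertices, "last", 1L)
  ky1 <- build_kymograph(mv2, pth1)
  expect_equal(apply(ky1$array, 2, which.max), ridge)

  # reversing the declared orientation flips the position axis
  pthr <- axon_path(pth2$vertices, "first", 3L)
  kyr <- build_kymograph(mv2, pthr)
  expect_equal(kyr$array, ky2$array[nrow(ky2$array):1, ])

  bad <- axon_path(rbind(c(5, -20), c(5, 10)), "last", 3L)
  expect_error(build_kymograph(mv2, bad), "outside")
})

test_that("track construction validates ordering and path geometry", {
  expect_error(track(c(1, 1, 2), c(0, 1, 2), 1), "strictly increasing")
  expect_error(axon_path(rbind(c(1, 1)), "last"), "n >= 2")
  expect_error(axon_path(rbind(c(1, 1), c(1, 1)), "last"), "zero length")
  expect_error(axon_path(rbind(c(0, 0), c(5, 5)), "last", linewidth_px = 2),
               "odd")
})

test_that("automatic track extraction recovers well-separated puncta", {
  sim <- simulate_organelle_movie(well_separated_movie(n = 3))
  d <- dim(sim$movie)
  mv <- time_lapse_movie(sim$movie, 1, 0.2)
  pth <- axon_path(rbind(c(sim$truth$center_row, 0),
                         c(sim$truth$center_row, d[3] - 1)), "last", 3L)
  ky <- build_kymograph(mv, pth)
  tracks <- extract_tracks_auto(ky, intensity_threshold = 30)
  expect_length(tracks, 3L)
  # per-frame positions match the truth within one position step
  for (tk in tracks) {
    p0 <- tk$samples$position_um[1]
    i <- which.min(abs(sim$truth$positions_um[tk$samples$frame[1], ] - p0))
    truth_pos <- sim$truth$positions_um[tk$samples$frame, i]
    expect_lt(max(abs(tk$samples$position_um - truth_pos)), 0.2 + 1e-9)
  }

  # an empty kymograph yields no tracks
  ky0 <- ky
  ky0$array[] <- 0
  expect_length(extract_tracks_auto(ky0, intensity_threshold = 30), 0L)
})

test_that("interval classification follows the minimum-speed rule", {
  tk <- track(0:5, c(0, 1, 2, 2, 2, 1), 1)
  cl <- classify_track(tk, v_min_um_s = 0.02)
  expect_equal(cl$states, c("anterograde", "anterograde", "pausing",
                            "pausing", "retrograde"))
  expect_equal(cl$class, "anterograde")   # net +1 um / 5 s = 0.2 >= 0.02

  # threshold inclusive: v exactly 0.02 counts as movement (1 um per 50 s
  # computes to the same double as the 0.02 threshold literal)
  tv <- track(0:5, as.numeric(0:5), frame_interval_s = 50)
  expect_true(all(classify_track(tv)$states == "anterograde"))
  expect_equal(classify_track(tv)$class, "anterograde")

  expect_equal(classify_track(track(0:9, rep(1, 10), 1))$class, "stationary")
  t1 <- track(0, 0, 1)
  expect_error(classify_track(t1), "at least 2")
})

test_that("kinetics implements the directional-velocity and flow formulas", {
  t1 <- track(0:10, seq(0, 5, by = 0.5), 1)
  k1 <- kinetics(list(t1))
  expect_equal(k1$Vma_um_s, 0.5)
  expect_equal(k1$Vmr_um_s, 0)
  expect_equal(k1$Q_um_s, 0.5)
  expect_equal(k1$pausing_fraction, 0)
  expect_equal(k1$n_anterograde, 1L)

  t2 <- track(0:10, seq(0, 3, by = 0.3), 1)
  t3 <- track(0:10, seq(6, 0, by = -0.6), 1)
  k2 <- kinetics(list(t2, t3))
  expect_equal(k2$Q_um_s, 0.3 * 1 + 0.6 * 1)

  # all stationary
  k3 <- kinetics(list(track(0:9, rep(2, 10), 1)))
  expect_equal(k3$Vma_um_s, 0)
  expect_equal(k3$Q_um_s, 0)
  expect_equal(k3$pausing_fraction, 1)
  expect_length(k3$flags, 2)

  # Q identity and count conservation
  set.seed(77)
  tracks <- lapply(1:12, function(i) {
    track(0:20, cumsum(c(0, rnorm(20, sd = 0.3))), 1, i)
  })
  kk <- kinetics(tracks)
  expect_equal(kk$n_anterograde + kk$n_retrograde + kk$n_stationary, 12L)
  expect_equal(kk$Q_um_s,
               kk$Vma_um_s * kk$n_anterograde + kk$Vmr_um_s * kk$n_retrograde)
})

test_that("raising v_min never decreases the pausing fraction", {
  set.seed(55)
  tracks <- lapply(1:8, function(i) {
    track(0:30, cumsum(c(0, rnorm(30, mean = 0.05, sd = 0.2))), 1, i)
  })
  vmins <- c(0.01, 0.02, 0.05, 0.1, 0.3)
  pf <- vapply(vmins, function(v) kinetics(tracks, v)$pausing_fraction, 0)
  expect_true(all(diff(pf) >= -1e-12))
})

test_that("kinetics are invariant to time re-expression of the same motion", {
  # the same physical trajectory sampled as frames at dt = 1 vs dt = 0.5
  pos <- seq(0, 6, by = 0.3)           # 0.3 um per 1 s
  a <- kinetics(list(track(0:20, pos, frame_interval_s = 1)))
  b <- kinetics(list(track(0:40, seq(0, 6, by = 0.15),
                           frame_interval_s = 0.5)))
  expect_equal(a$Vma_um_s, b$Vma_um_s, tolerance = 1e-12)
  expect_equal(a$Q_um_s, b$Q_um_s, tolerance = 1e-12)
})

test_that("path reversal swaps anterograde and retrograde exactly", {
  L <- 30
  t2 <- track(0:10, seq(0, 3, by = 0.3), 1)
  t3 <- track(0:10, seq(8, 2, by = -0.6), 1)
  fwd <- kinetics(list(t2, t3))
  rev_tracks <- list(track(0:10, L - seq(0, 3, by = 0.3), 1),
                     track(0:10, L - seq(8, 2, by = -0.6), 1))
  bwd <- kinetics(rev_tracks)
  expect_identical(fwd$Vma_um_s, bwd$Vmr_um_s)
  expect_identical(fwd$Vmr_um_s, bwd$Vma_um_s)
  expect_identical(fwd$n_anterograde, bwd$n_retrograde)
  expect_identical(fwd$n_retrograde, bwd$n_anterograde)
})

test_that("time basis option changes the velocity denominator", {
  # half moving, half pausing: segment-time Vma is twice the total-time one
  pos <- c(0, 0.5, 0.5, 1, 1, 1.5, 1.5, 2, 2)
  tk <- track(0:8, pos, 1)
  seg <- kinetics(list(tk), time_basis = "segment")
  tot <- kinetics(list(tk), time_basis = "total")
  expect_equal(seg$Vma_um_s, 0.5)
  expect_equal(tot$Vma_um_s, 0.25)
})

test_that("preset pipeline recovery is within the stated tolerances", {
  r <- recover_preset("intact_lysosome", n_organelles = 50, seed = 1)
  expect_lt(abs(r$estimate$Vmr_um_s - 0.6) / 0.6, 0.15)
  expect_lt(abs(r$moving_fraction_estimate - 0.9), 0.1)
  expect_identical(r$truth$kind, "movie")
})
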
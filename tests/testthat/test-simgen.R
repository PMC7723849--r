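test_that("nerve generator: empty, deterministic, validated", {
  cfg0 <- nerve_sim_config(n_fibers = 0, background_level = 0, noise_sd = 0,
                           tissue_level = 0, image_height_px = 40,
                           image_width_px = 60, seed = 1)
  sim0 <- simulate_optic_nerve(cfg0)
  expect_true(all(sim0$image == 0))
  expect_identical(sim0$truth$fibers_at(c(0, 100, 500)), c(0L, 0L, 0L))

  cfg <- nerve_sim_config(image_height_px = 60, image_width_px = 120, seed = 7)
  a <- simulate_optic_nerve(cfg)
  b <- simulate_optic_nerve(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$survival_um, b$truth$survival_um)

  expect_error(nerve_sim_config(pixel_size_um = 0), "pixel_size_um")
  expect_error(nerve_sim_config(image_width_px = -2), "image_width_px")
  expect_error(nerve_sim_config(decay_length_um = 0), "decay_length_um")
  expect_error(nerve_sim_config(nerve_width_profile = c(100, -5)),
               "nerve_width_profile")
})

test_that("fiber survival beyond the injury is exponential", {
  # closed form: mean count at d = 500 with decay 500 is 50 * exp(-1)
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(i) {
    cfg <- nerve_sim_config(n_fibers = 50, decay_length_um = 500,
                            image_height_px = 30, image_width_px = 40,
                            noise_sd = 0, seed = 1000 + i)
    simulate_optic_nerve(cfg)$truth$fibers_at(500)
  }, integer(1))
  expected <- 50 * exp(-1)
  se <- sqrt(50 * exp(-1) * (1 - exp(-1))) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("explant generator: empty, straight rays, determinism, scaling", {
  cfg0 <- explant_sim_config(n_axons = 0, noise_sd = 0, seed = 1,
                             image_size_px = 201L)
  sim0 <- simulate_explant(cfg0)
  outside <- sim0$image[!sim0$truth$mask]
  expect_true(all(outside <= 1e-9))
  expect_length(sim0$truth$band_counts, 0)

  dist <- length_distribution("fixed", length_um = 400, max_length_um = 400)
  cfg7 <- explant_sim_config(n_axons = 7, axon_length_um_distribution = dist,
                             tortuosity = 0, noise_sd = 0, seed = 3)
  sim7 <- simulate_explant(cfg7)
  expect_identical(sim7$truth$bands_um, (1:8) * 50)
  # all rays cross every band; at the terminal band the rasterized reach may
  # sit within half a pixel of the radius, which the band rule still counts
  expect_identical(sim7$truth$reach_counts[1:7], rep(7L, 7))
  expect_identical(sim7$truth$band_counts, rep(7L, 8))

  a <- simulate_explant(cfg7)
  expect_identical(a$image, sim7$image)

  # halving the pixel size with a doubled raster leaves truth in um intact
  cfgA <- explant_sim_config(n_axons = 9, pixel_size_um = 5, seed = 5,
                             image_size_px = 501L)
  cfgB <- explant_sim_config(n_axons = 9, pixel_size_um = 2.5, seed = 5,
                             image_size_px = 1001L)
  tA <- simulate_explant(cfgA)$truth
  tB <- simulate_explant(cfgB)$truth
  expect_identical(tA$lengths_um, tB$lengths_um)
  expect_equal(tA$border_dist_um, tB$border_dist_um, tolerance = 0.02)
})

test_that("a one-axon explant is flagged as no/little outgrowth downstream", {
  cfg <- explant_sim_config(n_axons = 1, seed = 9)
  sim <- simulate_explant(cfg)
  res <- run_explant_pipeline(sim)
  expect_lte(res$sholl$axon_count, 1L)
  expect_true(res$sholl$no_growth)
})

test_that("truth trace pixels lie on rendered signal inside the image", {
  cfg <- explant_sim_config(n_axons = 12, noise_sd = 0, seed = 21)
  sim <- simulate_explant(cfg)
  pix <- unlist(sim$truth$axon_pixels)
  expect_true(all(pix >= 1 & pix <= length(sim$image)))
  expect_true(all(sim$image[pix] > 0))
})

test_that("movie generator: frozen organelles, kinematics, determinism", {
  cfg0 <- track_sim_config(n_organelles = 5, frac_moving = 0, n_frames = 20,
                           noise_sd = 0, seed = 2)
  sim0 <- simulate_organelle_movie(cfg0)
  expect_true(all(sim0$truth$interval_states == "pausing"))
  expect_equal(apply(sim0$truth$positions_um, 2, function(p) diff(range(p))),
               rep(0, 5))
  expect_identical(sim0$movie, simulate_organelle_movie(cfg0)$movie)

  cfg1 <- track_sim_config(n_organelles = 1, frac_moving = 1,
                           frac_anterograde_among_moving = 1,
                           speed_antero_um_s = 0.5, pause_prob_per_frame = 0,
                           resume_prob_per_frame = 1, n_frames = 10,
                           init_positions_um = 0, noise_sd = 0, seed = 4)
  sim1 <- simulate_organelle_movie(cfg1)
  expect_equal(as.numeric(sim1$truth$positions_um), seq(0, 4.5, by = 0.5))
})

test_that("truth positions land on rendered puncta", {
  cfg <- track_sim_config(n_organelles = 6, n_frames = 30, noise_sd = 0,
                          seed = 8)
  sim <- simulate_organelle_movie(cfg)
  d <- dim(sim$movie)
  cy <- round(sim$truth$center_row) + 1L
  for (t in c(1L, 15L, 30L)) {
    for (i in seq_len(6)) {
      p <- sim$truth$positions_um[t, i]
      if (is.na(p) || p < 0 || p > cfg$axon_length_um) next
      col <- round(p / cfg$pixel_size_um) + 1L
      expect_gt(sim$movie[t, cy, col], 0.5 * cfg$punctum_intensity)
    }
  }
})

test_that("truth-level moving classification matches the configured fraction", {
  cfg <- track_preset("intact_lysosome", n_organelles = 100, seed = 6)
  sim <- simulate_organelle_movie(cfg)
  tracks <- lapply(seq_len(100), function(i) {
    track(seq_len(cfg$n_frames), sim$truth$positions_um[, i],
          cfg$frame_interval_s, i)
  })
  cls <- vapply(tracks, function(t) classify_track(t)$class, "")
  # net-displacement classification agrees with the generator's own flags
  expect_lt(abs(mean(cls != "stationary") - mean(sim$truth$moving)), 0.03)
  # and the realized moving fraction is a Binomial(100, 0.9) draw
  expect_lt(abs(mean(sim$truth$moving) - cfg$frac_moving),
            3 * sqrt(0.9 * 0.1 / 100))
})

test_that("presets carry the reported regime parameters", {
  il <- track_preset("intact_lysosome")
  expect_equal(il$speed_retro_um_s, 0.6)
  expect_equal(il$speed_antero_um_s, 0.3)
  expect_equal(il$frac_moving, 0.90)
  pc <- track_preset("postcut_lysosome")
  expect_equal(pc$frac_moving, 0.30)
  expect_lt(pc$speed_retro_um_s, 0.06)
  expect_lt(pc$speed_antero_um_s, 0.06)
  im <- track_preset("intact_mito")
  expect_equal(im$frac_moving, 0.10)
  expect_error(track_preset("nonsense"), "unknown preset")
  # overrides pass through
  expect_equal(track_preset("intact_mito", n_organelles = 50)$n_organelles, 50L)
})
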
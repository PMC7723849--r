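test_that("explant segmentation: IoU with the generator disk, overrides", {
  for (sd in c(3, 14, 25)) {
    sim <- simulate_explant(explant_sim_config(n_axons = 15, seed = sd))
    m <- segment_explant(sim$image, 5)
    iou <- sum(m & sim$truth$mask) / sum(m | sim$truth$mask)
    expect_gte(iou, 0.9)
  }
  expect_error(segment_explant(matrix(0, 50, 50), 5), "segmentation failed")
  manual <- matrix(FALSE, 10, 10)
  manual[3:6, 3:6] <- TRUE
  expect_identical(segment_explant(matrix(1, 10, 10), 5,
                                   manual_mask = manual), manual)
})

test_that("neurite skeleton: empty input, polyline fidelity, size filter", {
  sim <- simulate_explant(explant_sim_config(n_axons = 0, noise_sd = 0,
                                             seed = 1, image_size_px = 201L))
  m <- sim$truth$mask
  expect_equal(sum(neurite_skeleton(sim$image, m, 5)), 0)

  dist <- length_distribution("fixed", length_um = 500, max_length_um = 500)
  sim1 <- simulate_explant(explant_sim_config(
    n_axons = 1, axon_length_um_distribution = dist, tortuosity = 0,
    noise_sd = 0, seed = 5))
  m1 <- segment_explant(sim1$image, 5)
  sk <- neurite_skeleton(sim1$image, m1, 5)
  expect_gt(sum(sk), 50)
  # every skeleton pixel lies within 2 px of the generator polyline
  S <- nrow(sk)
  tr <- sim1$truth$axon_pixels[[1]]
  tr_r <- (tr - 1L) %% S
  tr_c <- (tr - 1L) %/% S
  pix <- which(sk)
  for (p in pix) {
    pr <- (p - 1L) %% S
    pc <- (p - 1L) %/% S
    expect_lte(min(abs(pr - tr_r) + abs(pc - tr_c)), 4)  # L1 within 2+2
  }

  # isolated bright salt below the minimum trace length is removed
  img <- sim1$image
  img[10, 10] <- 1e4
  sk2 <- neurite_skeleton(img, m1, 5, min_size_um = 10)
  expect_false(sk2[10, 10])
})

test_that("sholl counts: empty, analytic rays, intensity-scale invariance", {
  empty <- matrix(FALSE, 120, 120)
  mask <- matrix(FALSE, 120, 120)
  mask[50:70, 50:70] <- TRUE
  sh <- sholl_counts(empty, mask, 5)
  expect_equal(sh$axon_count, 0L)
  expect_true(sh$no_growth)
  expect_error(sholl_counts(empty, mask, 5, step_um = 0), "step_um")

  fx <- make_ray_fixture(n_rays = 7, length_um = 400)
  sh7 <- sholl_counts(fx$skeleton, fx$mask, fx$pixel_size_um,
                      max_distance_um = 600)
  expect_identical(sh7$intersect_counts, c(rep(7L, 8), rep(0L, 4)))
  expect_equal(sh7$axon_count, 7L)
  expect_false(sh7$no_growth)

  # counts depend only on the skeleton: full pipeline on a rescaled image
  sim <- simulate_explant(explant_sim_config(n_axons = 10, seed = 30))
  r1 <- run_explant_pipeline(sim)
  sim2 <- sim
  sim2$image <- sim$image * 4.7
  r2 <- run_explant_pipeline(sim2)
  expect_identical(r1$sholl$intersect_counts, r2$sholl$intersect_counts)
})

test_that("sholl counts match the brute-force oracle on small images", {
  for (sd in c(2, 8)) {
    sim <- simulate_explant(explant_sim_config(
      n_axons = 6, seed = sd,
      axon_length_um_distribution = length_distribution(
        "uniform", min_um = 80, max_um = 250, max_length_um = 250),
      image_size_px = 125L))
    r <- run_explant_pipeline(sim)
    oracle <- brute_sholl(r$skeleton, r$mask, 5)
    expect_identical(r$sholl$intersect_counts[seq_along(oracle)], oracle)
  }
})

test_that("straight radial axons give non-increasing counts", {
  for (sd in c(4, 9, 16)) {
    sim <- simulate_explant(explant_sim_config(n_axons = 12, tortuosity = 0,
                                               seed = sd))
    r <- run_explant_pipeline(sim)
    expect_true(all(diff(r$sholl$intersect_counts) <= 0))
  }
})

test_that("generator truth matches measured counts on most bands", {
  n_eq <- 0L
  n_tot <- 0L
  for (sd in 1:10) {
    sim <- simulate_explant(explant_sim_config(n_axons = 20, seed = sd))
    r <- run_explant_pipeline(sim)
    nb <- length(sim$truth$band_counts)
    meas <- rep(0L, nb)
    mm <- r$sholl$intersect_counts
    meas[seq_len(min(nb, length(mm)))] <- mm[seq_len(min(nb, length(mm)))]
    n_eq <- n_eq + sum(meas == sim$truth$band_counts)
    n_tot <- n_tot + nb
  }
  expect_gte(n_eq / n_tot, 0.95)
})

test_that("outgrowth table counts, percentages and rounding", {
  ng <- c(rep(TRUE, 3), rep(FALSE, 5), rep(TRUE, 1), rep(FALSE, 2))
  cond <- c(rep("a", 8), rep("b", 3))
  tb <- summarize_outgrowth(ng, cond)
  expect_equal(tb$n_no_growth + tb$n_quantified, tb$total_explants)
  expect_equal(tb$pct_no_growth[tb$condition == "a"], 37.5)
  expect_equal(tb$pct_quantified[tb$condition == "b"], 66.7)
  # half-up at the printed precision: 1/16 = 6.25% prints as 6.3
  tb2 <- summarize_outgrowth(c(TRUE, rep(FALSE, 15)), rep("x", 16))
  expect_equal(tb2$pct_no_growth, 6.3)
  # single no-growth explant
  tb3 <- summarize_outgrowth(TRUE, "y")
  expect_equal(tb3$pct_no_growth, 100.0)
  expect_equal(tb3$pct_quantified, 0.0)
  expect_error(summarize_outgrowth(logical(0), character(0)), "no explants")
})

test_that("growth-cone collapse scoring follows the criterion exactly", {
  ann <- data.frame(
    explant_id = c(1, 1, 1, 1, 2, 2),
    cone_id = c(1, 2, 3, 4, 1, 2),
    n_filopodia = c(0, 5, 1, 3, 2, 0),
    has_lamellipodia = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  res <- score_collapse(ann)
  # boundary: exactly 2 filopodia, no lamellipodia -> NOT collapsed
  expect_false(res$per_cone$collapsed[5])
  # 0 filopodia but lamellipodia present -> NOT collapsed
  expect_false(res$per_cone$collapsed[6])
  expect_equal(
    res$per_explant$fraction_collapsed[res$per_explant$explant_id == "1"],
    0.5)
  expect_equal(res$group$n_explants, 2L)
  expect_equal(res$group$mean, mean(c(0.5, 0)))
  expect_error(score_collapse(data.frame()), "non-empty")
  expect_error(score_collapse(data.frame(explant_id = 1, n_filopodia = -1,
                                         has_lamellipodia = FALSE)),
               "nonnegative")
})
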
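test_that("accuracy is the mean of distances to the target", {
  expect_equal(accuracy(make_rec(3, 4)), 5)                 # 3-4-5 triangle
  expect_equal(accuracy(make_rec(c(0, 0), c(0, 0))), 0)
  expect_equal(accuracy(make_rec(c(1, 3), c(0, 0))), 2)     # mean of {1, 3}
  expect_error(accuracy(make_rec(NaN, NaN, valid = FALSE)),
               class = "psaqc_insufficient_data")
})

test_that("apparent gaze shift averages per-pair centroid distances", {
  pair1 <- list(bright = make_rec(c(0, 0), c(0, 0)),
                dark = make_rec(c(1, 1), c(0, 0), condition = "dark"))
  res <- apparent_gaze_shift(list(pair1))
  expect_equal(res$mean_shift, 1)
  # identical phase means -> 0
  same <- list(bright = make_rec(c(0, 2), c(1, -1)),
               dark = make_rec(c(2, 0), c(-1, 1), condition = "dark"))
  expect_equal(apparent_gaze_shift(list(same))$mean_shift, 0)
  # per-trial shifts {1, 3} -> mean 2; mean of norms >= norm of mean diff
  pair3 <- list(bright = make_rec(0, 0),
                dark = make_rec(-3, 0, condition = "dark"))
  res2 <- apparent_gaze_shift(list(pair1, pair3))
  expect_equal(res2$per_trial_shift, c(1, 3))
  expect_equal(res2$mean_shift, 2)
  net <- abs(mean(c(1, -3)))   # shifts in opposing directions partly cancel
  expect_gt(res2$mean_shift, net)
  # empty phase errors, identifying the pair
  bad <- list(bright = make_rec(NaN, NaN, valid = FALSE),
              dark = make_rec(1, 1, condition = "dark"))
  expect_error(apparent_gaze_shift(list(pair1, bad)), "pair 2",
               class = "psaqc_insufficient_data")
})

test_that("std_precision is the population-RMS spread around the centroid", {
  expect_equal(std_precision(make_rec(c(1, -1), c(0, 0))), 1)
  expect_equal(std_precision(make_rec(0.5, 0.7)), 0)
  expect_equal(std_precision(make_rec(c(1, -1), c(1, -1))), sqrt(2))
})

test_that("rms_s2s uses valid adjacent pairs with the pair-count denominator", {
  expect_equal(rms_s2s(make_rec(rep(1, 5), rep(2, 5))), 0)
  expect_equal(rms_s2s(make_rec(c(0, 1, 0), c(0, 0, 0))), 1)
  # NaN gap splits the sequence: (0,0), NaN, (1,0) has no usable pair
  gap <- make_rec(c(0, NaN, 1), c(0, NaN, 0), valid = c(TRUE, FALSE, TRUE))
  expect_error(rms_s2s(gap), class = "psaqc_insufficient_data")
  # trailing (1,0) gives exactly one usable pair with zero displacement
  gap2 <- make_rec(c(0, NaN, 1, 1), c(0, NaN, 0, 0),
                   valid = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(rms_s2s(gap2), 0)
  expect_error(rms_s2s(make_rec(1, 1)), class = "psaqc_insufficient_data")
})

test_that("data_loss is the pre-cleaning invalid percentage", {
  rec <- make_rec(c(rep(0, 95), rep(NaN, 5)), c(rep(0, 95), rep(NaN, 5)),
                  valid = c(rep(TRUE, 95), rep(FALSE, 5)))
  expect_equal(data_loss(rec), 5)
  expect_equal(data_loss(make_rec(c(1, 2), c(1, 2))), 0)
  alln <- make_rec(rep(NaN, 10), rep(NaN, 10), valid = rep(FALSE, 10))
  expect_equal(data_loss(alln), 100)
  expect_error(data_loss(gaze_subset(alln, rep(FALSE, 10))),
               class = "psaqc_empty_trial")
})

test_that("all five metrics match the naive loop oracles on random recordings", {
  set.seed(101)
  for (i in 1:60) {
    rec <- random_recording(sample(10:80, 1), nan_frac = runif(1, 0, 0.3))
    if (sum(rec$valid) < 3) next
    expect_equal(accuracy(rec, c(0.3, -0.2)),
                 oracle_accuracy(rec$x, rec$y, 0.3, -0.2), tolerance = 1e-12)
    expect_equal(std_precision(rec), oracle_std(rec$x, rec$y), tolerance = 1e-12)
    orms <- oracle_rms(rec$x, rec$y, rec$idx)
    if (is.na(orms)) {
      expect_error(rms_s2s(rec), class = "psaqc_insufficient_data")
    } else {
      expect_equal(rms_s2s(rec), orms, tolerance = 1e-12)
    }
    expect_equal(data_loss(rec), oracle_data_loss(rec$valid), tolerance = 1e-12)
  }
})

test_that("metric invariances: translation and scale", {
  set.seed(55)
  rec <- random_recording(200, nan_frac = 0.1)
  shift <- function(r, dx, dy) {
    gaze_recording(r$t, r$x + dx, r$y + dy, valid = r$valid, idx = r$idx)
  }
  scale <- function(r, c) gaze_recording(r$t, r$x * c, r$y * c, valid = r$valid,
                                         idx = r$idx)
  moved <- shift(rec, 3, -4)
  expect_equal(std_precision(moved), std_precision(rec), tolerance = 1e-12)
  expect_equal(rms_s2s(moved), rms_s2s(rec), tolerance = 1e-12)
  expect_equal(accuracy(moved, c(3, -4)), accuracy(rec, c(0, 0)), tolerance = 1e-12)
  sc <- scale(rec, 2.5)
  expect_equal(std_precision(sc), 2.5 * std_precision(rec), tolerance = 1e-12)
  expect_equal(rms_s2s(sc), 2.5 * rms_s2s(rec), tolerance = 1e-12)
  expect_equal(accuracy(sc, c(0, 0)), 2.5 * accuracy(rec, c(0, 0)), tolerance = 1e-12)
  expect_equal(data_loss(sc), data_loss(rec), tolerance = 1e-12)
})

test_that("analyze_session recovers generator parameters", {
  dev <- device_profile(noise_std = 0.3, blink_rate = 0.3,
                        data_loss_mode = "nan_only", sampling_rate = 200)
  par <- participant_profile(psa_shift = c(1.2, -1.6))   # magnitude 2
  s <- generate_session(dev, par, trial_schedule(), seed = 23)
  a <- analyze_session(s$recordings)
  expect_equal(a$shift$mean_shift, 2, tolerance = 0.05)
  expect_equal(mean(a$metrics$std[a$metrics$condition == "bright"]), 0.3,
               tolerance = 0.2)
  # data_loss equals the injected invalid fraction exactly, per recording
  meas_idx <- which(vapply(s$recordings, function(r)
    attr(r, "phase") == "measurement", TRUE))
  got <- a$metrics$data_loss
  want <- 100 * s$truth$n_invalid[meas_idx] /
    vapply(s$recordings[meas_idx], nrow, 1L)
  expect_equal(got, want, tolerance = 1e-12)
})
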
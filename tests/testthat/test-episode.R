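test_that("baseline statistics are exact on constant trajectories", {
  sch <- event_schedule(baseline_sweeps = 10, hold_sweeps = 2, fade_sweeps = 2,
                        post_sweeps = 6)
  ens <- manual_ensemble(matrix(0.3, nrow = 4, ncol = total_sweeps(sch)), sch)
  b <- baseline_intensity(ens)
  expect_equal(b$mean, 0.3)
  expect_equal(b$se, 0)
  short <- event_schedule(baseline_sweeps = 1, hold_sweeps = 2, fade_sweeps = 2,
                          post_sweeps = 2)
  ens1 <- manual_ensemble(matrix(0.3, 4, total_sweeps(short)), short)
  expect_error(baseline_intensity(ens1), "at least 2")
})

test_that("baseline of independent fair components is one half", {
  net <- zero_net(6)
  sch <- event_schedule(baseline_sweeps = 100, hold_sweeps = 0, fade_sweeps = 0,
                        post_sweeps = 1)
  ens <- simulate_network(net, sch, sim_config(runs = 40, seed = 4),
                          keep_states = FALSE)
  b <- baseline_intensity(ens)
  expect_lt(abs(b$mean - 0.5), 3 * b$se + 1e-3)
})

test_that("baseline matches the enumeration oracle on a fixture network", {
  net <- random_network(6, seed = 31)
  sch <- event_schedule(baseline_sweeps = 200, hold_sweeps = 0, fade_sweeps = 0,
                        post_sweeps = 1)
  ens <- simulate_network(net, sch, sim_config(runs = 60, seed = 14),
                          keep_states = FALSE)
  b <- baseline_intensity(ens)
  ex <- exact_intensity_distribution(net, beta = 1)
  exact_mean <- sum(seq(0, ex$n) / ex$n * ex$probs)
  expect_lt(abs(b$mean - exact_mean), 3 * b$se + 1e-3)
})

test_that("first return to baseline handles the limiting trajectories", {
  sch <- event_schedule(baseline_sweeps = 10, hold_sweeps = 3, fade_sweeps = 3,
                        post_sweeps = 10)
  nt <- total_sweeps(sch)
  # mean never rises above baseline: no episode, duration 0
  flat <- manual_ensemble(matrix(rep(c(0.30, 0.31), nt), 2, nt), sch)
  s <- first_return_to_baseline(flat)
  expect_false(s$censored)
  expect_equal(s$duration_sweeps, 0L)
  # rises at onset and never returns: censored
  up <- matrix(rep(c(0.28, 0.32), nt), 2, nt)
  up[, 11:nt] <- 1
  s2 <- first_return_to_baseline(manual_ensemble(up, sch))
  expect_true(s2$censored)
  expect_true(is.na(s2$duration_sweeps))
  # rises then returns at a known sweep
  tr <- matrix(rep(c(0.28, 0.32), nt), 2, nt)
  tr[, 11:16] <- 1
  s3 <- first_return_to_baseline(manual_ensemble(tr, sch))
  expect_equal(s3$episode_started, 11L)
  expect_equal(s3$end_sweep, 17L)
  expect_equal(s3$duration_sweeps, 6L)
  expect_error(first_return_to_baseline(
    manual_ensemble(matrix(0.3, 1, nt), sch)), "2 runs")
})

test_that("duration is non-increasing in the criterion multiplier", {
  # a wider band cannot lengthen the detected episode
  net <- make_fixture_network("fear_like", seed = 1)
  ens <- simulate_network(net, event_schedule(), sim_config(runs = 150, seed = 3),
                          keep_states = FALSE)
  ks <- c(1, 1.645, 3, 10, 25)
  durs <- vapply(ks, function(k) {
    s <- first_return_to_baseline(ens, k = k)
    if (s$censored) ncol(ens$intensity) - s$onset else s$duration_sweeps
  }, numeric(1))
  expect_true(all(diff(durs) <= 0))
})

test_that("profile statistics are exact on constructed trajectories", {
  sch <- event_schedule(baseline_sweeps = 10, amplitude = 1, hold_sweeps = 5,
                        fade_sweeps = 0, post_sweeps = 15)
  nt <- total_sweeps(sch)
  # step trajectory: 1.0 during hold, exactly baseline after
  step <- matrix(rep(c(0.28, 0.32), nt), 2, nt)
  step[, 11:15] <- 1
  s <- first_return_to_baseline(manual_ensemble(step, sch))
  p <- intensity_profile_stats(manual_ensemble(step, sch), s)
  expect_equal(p$decay_halflife, 1L)  # first post-hold sweep is already below
  # constant trajectory: no episode and both variances zero
  const <- matrix(rep(c(0.28, 0.32), nt), 2, nt)
  s2 <- first_return_to_baseline(manual_ensemble(const, sch))
  within <- intensity_profile_stats(manual_ensemble(const, sch), s2)
  expect_equal(within$variance_within, 0)
  expect_equal(within$variance_outside, 0)
})

test_that("sustained high-connectivity episodes keep variance inside, not outside", {
  net <- make_fixture_network("fear_like", seed = 1)
  cfg <- sim_config(runs = 150, seed = 21)
  # recording long enough for the strongly coupled episode to end in-window
  sch <- event_schedule(post_sweeps = 800)
  stats <- lapply(c(1, 2), function(fac) {
    ens <- simulate_network(scale_connectivity(net, fac), sch, cfg,
                            keep_states = FALSE)
    s <- first_return_to_baseline(ens)
    base_idx <- seq_len(sch$baseline_sweeps)
    c(intensity_profile_stats(ens, s), duration = s$duration_sweeps,
      censored = s$censored,
      rest_var = mean(apply(ens$intensity[, base_idx], 1, var)))
  })
  # higher connectivity: longer episode, higher variance within it, lower
  # at-rest intensity fluctuation (components keep each other in check), and
  # a relatively (not absolutely) faster collapse
  d1 <- if (stats[[1]]$censored) Inf else stats[[1]]$duration
  d2 <- if (stats[[2]]$censored) Inf else stats[[2]]$duration
  expect_gt(d2, d1)
  expect_gt(stats[[2]]$variance_within, stats[[1]]$variance_within)
  expect_lt(stats[[2]]$rest_var, stats[[1]]$rest_var)
  expect_lt(stats[[2]]$decay_halflife / d2, stats[[1]]$decay_halflife / d1)
})

test_that("replicated-ensemble duration summary is deterministic and sane", {
  net <- net3()
  sch <- event_schedule(baseline_sweeps = 30, hold_sweeps = 10, fade_sweeps = 10,
                        post_sweeps = 30)
  d1 <- episode_duration_stats(net, sch, sim_config(runs = 30, seed = 5),
                               n_ensembles = 4)
  d2 <- episode_duration_stats(net, sch, sim_config(runs = 30, seed = 5),
                               n_ensembles = 4)
  expect_identical(d1, d2)
  expect_length(d1$durations, 4L)
  expect_true(all(d1$durations >= 0))
  expect_gte(d1$se, 0)
})
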
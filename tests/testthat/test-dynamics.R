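test_that("conditional activation probability matches the closed form", {
  iso <- zero_net(1)
  expect_equal(conditional_activation_probability(iso, state = 1L, i = 1), 0.5)
  hi <- zero_net(1, tau = 50)
  expect_gt(conditional_activation_probability(hi, state = -1L, i = 1), 1 - 1e-12)
  pair <- component_network(c("a", "b"), matrix(c(0, 1, 1, 0), 2, 2), c(0, 0))
  p <- conditional_activation_probability(pair, state = c(1L, 1L), i = 1,
                                          field = 0, beta = 1)
  expect_equal(p, 1 / (1 + exp(-2)), tolerance = 1e-12)
  # field enters additively with the threshold
  p2 <- conditional_activation_probability(pair, state = c(1L, -1L), i = 1,
                                           field = 1, beta = 1)
  expect_equal(p2, 0.5)
  expect_error(conditional_activation_probability(pair, c(1L, 1L), i = 3),
               "out of range")
})

test_that("a sweep with an overwhelming field activates every component", {
  net <- zero_net(6)
  set.seed(1)
  # fixed cycle visits every component exactly once per sweep
  cfg <- sim_config(beta = 2, update_order = "fixed_cycle")
  s <- glauber_sweep(net, rep(-1L, 6), field = 50, config = cfg)
  expect_equal(s, rep(1L, 6))
})

test_that("the same seed gives a bit-identical ensemble", {
  net <- net3()
  sch <- event_schedule(baseline_sweeps = 20, hold_sweeps = 5, fade_sweeps = 10,
                        post_sweeps = 20)
  cfg <- sim_config(runs = 5, seed = 42)
  e1 <- simulate_network(net, sch, cfg)
  e2 <- simulate_network(net, sch, cfg)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$intensity, e2$intensity)
  e3 <- simulate_network(net, sch, sim_config(runs = 5, seed = 43))
  expect_false(identical(e1$intensity, e3$intensity))
})

test_that("intensity is the exact fraction of active components each sweep", {
  net <- random_network(5, seed = 2)
  sch <- event_schedule(baseline_sweeps = 10, hold_sweeps = 5, fade_sweeps = 5,
                        post_sweeps = 10)
  ens <- simulate_network(net, sch, sim_config(runs = 3, seed = 7))
  recomputed <- apply(ens$states, c(1, 2), function(s) mean(s == 1L))
  expect_identical(ens$intensity, recomputed)
  expect_true(all(ens$intensity >= 0 & ens$intensity <= 1))
  expect_true(all(abs(ens$intensity * 5 - round(ens$intensity * 5)) < 1e-12))
})

test_that("Glauber sampling reproduces the exact Boltzmann distribution", {
  # detailed-balance check: long constant-field chain vs full enumeration
  net <- random_network(6, seed = 21)
  ex <- exact_intensity_distribution(net, beta = 1)
  sa <- sampled_intensity_distribution(net, sim_config(seed = 5), sweeps = 50000,
                                       thin = 10)
  expect_lt(tv_distance(ex, sa), 0.02)
})

test_that("hold-phase intensity approaches 1 under a strong event", {
  cc <- common_cause_model(paste0("c", 1:6), rep(0, 6), rep(-1, 6), -1)
  net <- as_component_network(cc)
  sch <- event_schedule(baseline_sweeps = 50, amplitude = 6, hold_sweeps = 30,
                        fade_sweeps = 10, post_sweeps = 60)
  ens <- simulate_network(net, sch, sim_config(runs = 50, seed = 3))
  hold <- 53:80  # skip the first sweeps of the rise
  expect_gt(mean(ens$intensity[, hold]), 0.99)
  # after the fade the independent components relax back to their baseline
  base <- mean(ens$intensity[, 1:50])
  late <- mean(ens$intensity[, 121:140])
  expect_lt(abs(late - base), 0.05)
})

test_that("an amplitude-zero schedule leaves the chain stationary", {
  net <- make_fixture_network("fear_like", seed = 1)
  sch <- event_schedule(baseline_sweeps = 150, amplitude = 0, hold_sweeps = 0,
                        fade_sweeps = 0, post_sweeps = 150)
  ens <- simulate_network(net, sch, sim_config(runs = 60, seed = 8),
                          keep_states = FALSE)
  half1 <- rowMeans(ens$intensity[, 1:150])
  half2 <- rowMeans(ens$intensity[, 151:300])
  d <- half1 - half2
  pooled_se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * pooled_se + 1e-3)
  # and the stationary mean agrees with the enumeration oracle
  ex <- exact_intensity_distribution(net, beta = 1)
  exact_mean <- sum(seq(0, ex$n) / ex$n * ex$probs)
  run_means <- rowMeans(ens$intensity)
  se <- sd(run_means) / sqrt(length(run_means))
  expect_lt(abs(mean(run_means) - exact_mean), 3 * se + 1e-3)
})

test_that("raising the event amplitude does not lower hold-phase intensity", {
  net <- make_fixture_network("fear_like", seed = 2)
  hold_mean <- sapply(c(0, 0.5, 1, 2), function(a) {
    sch <- event_schedule(baseline_sweeps = 20, amplitude = a, hold_sweeps = 30,
                          fade_sweeps = 10, post_sweeps = 10)
    ens <- simulate_network(net, sch, sim_config(runs = 100, seed = 9),
                            keep_states = FALSE)
    mean(ens$intensity[, 21:50])
  })
  expect_true(all(diff(hold_mean) > -0.02))
})

test_that("degenerate schedules are rejected", {
  expect_error(event_schedule(baseline_sweeps = -1), "non-negative")
  sch0 <- event_schedule(baseline_sweeps = 0, hold_sweeps = 0, fade_sweeps = 0,
                         post_sweeps = 0)
  expect_error(simulate_network(net3(), sch0, sim_config(runs = 2, seed = 1)),
               "zero total sweeps")
  expect_error(sim_config(beta = 0), "positive")
  expect_error(sim_config(runs = 0), "positive")
})

test_that("the external field follows the schedule shape", {
  sch <- event_schedule(baseline_sweeps = 3, amplitude = 2, hold_sweeps = 2,
                        fade_sweeps = 4, post_sweeps = 3)
  f <- event_field(sch)
  expect_equal(length(f), total_sweeps(sch))
  expect_equal(f[1:3], rep(0, 3))
  expect_equal(f[4:5], rep(2, 2))
  expect_equal(f[6:9], 2 * (1 - (1:4) / 4))
  expect_equal(f[10:12], rep(0, 3))
  fe <- event_field(event_schedule(baseline_sweeps = 0, amplitude = 2,
                                   hold_sweeps = 1, fade_sweeps = 5,
                                   fade_shape = "exponential", post_sweeps = 0))
  expect_true(all(diff(fe) <= 0))
  expect_equal(fe[6], 0)
})
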
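#' Define the time course of an emotion-eliciting event
#'
#' The external event enters the dynamics as a uniform field added to every
#' component's threshold: zero during a pre-event baseline window, then a hold
#' phase at full `amplitude` (the person is occupied with the event), then a
#' fade back to zero over `fade_sweeps` time units, then a post-event window in
#' which any remaining activation must be sustained by the network itself.
#'
#' @param baseline_sweeps Sweeps recorded before event onset (>= 2 for baseline
#'   statistics).
#' @param amplitude Field strength during the hold phase (same units as
#'   thresholds).
#' @param hold_sweeps Sweeps at full amplitude.
#' @param fade_sweeps Sweeps over which the field decays to zero.
#' @param fade_shape `"linear"` (default) or `"exponential"` (exponential decay
#'   scaled to reach ~1% of amplitude by the end of the fade, then clamped to
#'   zero).
#' @param post_sweeps Sweeps recorded after the field has reached zero.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(baseline_sweeps = 100L, amplitude = 2,
                           hold_sweeps = 20L, fade_sweeps = 50L,
                           fade_shape = c("linear", "exponential"),
                           post_sweeps = 200L) {
  fade_shape <- match.arg(fade_shape)
  counts <- c(baseline_sweeps, hold_sweeps, fade_sweeps, post_sweeps)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("sweep counts must be non-negative integers", call. = FALSE)
  if (!is.finite(amplitude))
    stop("amplitude must be finite", call. = FALSE)
  structure(
    list(baseline_sweeps = as.integer(baseline_sweeps),
         amplitude = as.numeric(amplitude),
         hold_sweeps = as.integer(hold_sweeps),
         fade_sweeps = as.integer(fade_sweeps),
         fade_shape = fade_shape,
         post_sweeps = as.integer(post_sweeps)),
    class = "event_schedule"
  )
}

#' External field value per sweep
#'
#' Expands an [event_schedule()] into the vector `e(t)` of field values, one
#' per recorded sweep. The field is 0 before onset, `amplitude` during the
#' hold, non-increasing during the fade, and 0 afterwards.
#'
#' @param schedule An `event_schedule`.
#' @return Numeric vector of length `total_sweeps(schedule)`.
#' @export
event_field <- function(schedule) {
  stopifnot(inherits(schedule, "event_schedule"))
  a <- schedule$amplitude
  nf <- schedule$fade_sweeps
  fade <- if (nf == 0L) numeric(0)
  else if (schedule$fade_shape == "linear") a * (1 - seq_len(nf) / nf)
  else {
    v <- a * exp(-seq_len(nf) * log(100) / nf)
    v[nf] <- 0
    v
  }
  c(rep(0, schedule$baseline_sweeps),
    rep(a, schedule$hold_sweeps),
    fade,
    rep(0, schedule$post_sweeps))
}

#' Total number of recorded sweeps in a schedule
#' @param schedule An `event_schedule`.
#' @return Integer sweep count.
#' @export
total_sweeps <- function(schedule) {
  stopifnot(inherits(schedule, "event_schedule"))
  schedule$baseline_sweeps + schedule$hold_sweeps +
    schedule$fade_sweeps + schedule$post_sweeps
}

#' Simulation configuration
#'
#' @param beta Inverse temperature (> 0); scales how deterministically
#'   components follow their local input. Default 1.
#' @param runs Number of replicate runs (>= 1).
#' @param seed Integer master seed; all randomness in a simulation derives
#'   deterministically from it.
#' @param update_order `"random_sequential"` (each of the n updates in a sweep
#'   picks a site uniformly at random; the standard Glauber scheme) or
#'   `"fixed_cycle"` (sites visited in order).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(beta = 1, runs = 100L, seed = 1L,
                       update_order = c("random_sequential", "fixed_cycle")) {
  update_order <- match.arg(update_order)
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive", call. = FALSE)
  if (runs < 1L || runs != round(runs)) stop("runs must be a positive integer", call. = FALSE)
  structure(
    list(beta = as.numeric(beta), runs = as.integer(runs),
         seed = as.integer(seed), update_order = update_order),
    class = "sim_config"
  )
}

# Deterministic per-run seed stream derived from the master seed; kept below
# 2^31 so it is always a valid R integer seed.
derive_run_seed <- function(seed, run) {
  as.integer((abs(as.numeric(seed)) * 1000003 + run * 7919) %% 2147483629)
}

#' Conditional activation probability of one component
#'
#' The Glauber single-site rule in spin coding:
#' `P(s_i = +1 | rest) = 1 / (1 + exp(-2 beta (sum_j w_ij s_j + tau_i + e)))`.
#' This is the probability used for every single-component update of the
#' simulation; the induced Markov chain satisfies detailed balance with respect
#' to the Boltzmann distribution of the pairwise model.
#'
#' @param net A `component_network`. Binary-coded networks are converted to
#'   spin coding first.
#' @param state Integer vector of spins (-1/+1), length `n`.
#' @param i Component index (1-based).
#' @param field External field value added to the component's threshold.
#' @param beta Inverse temperature.
#' @return Probability in `[0, 1]`.
#' @export
conditional_activation_probability <- function(net, state, i, field = 0, beta = 1) {
  net <- convert_coding(net, "spin")
  n <- length(net$labels)
  if (i < 1L || i > n) stop("component index out of range", call. = FALSE)
  if (length(state) != n || !all(state %in% c(-1L, 1L)))
    stop("state must be a length-n vector of -1/+1 spins", call. = FALSE)
  h <- sum(net$weights[, i] * state) + net$thresholds[i] + field
  1 / (1 + exp(-2 * beta * h))
}

#' Advance the network state by one sweep
#'
#' One sweep performs `n` single-component Glauber updates (one time unit).
#' Uses R's random number generator, so results are reproducible under
#' `set.seed()`.
#'
#' @inheritParams conditional_activation_probability
#' @param config A `sim_config` (only `beta` and `update_order` are used).
#' @return Integer spin vector after the sweep.
#' @export
glauber_sweep <- function(net, state, field = 0, config = sim_config()) {
  net <- convert_coding(net, "spin")
  n <- length(net$labels)
  if (length(state) != n || !all(state %in% c(-1L, 1L)))
    stop("state must be a length-n vector of -1/+1 spins", call. = FALSE)
  glauber_sweep_cpp(net$weights, net$thresholds, field, config$beta,
                    as.integer(state), config$update_order == "random_sequential")
}

#' Simulate an ensemble of emotion-episode trajectories
#'
#' Runs `config$runs` independent replicates of the network under the event
#' schedule. Each run starts at rest: for networks of up to 20 components the
#' initial state is drawn exactly from the field-zero stationary (Boltzmann)
#' distribution by enumeration, so the recorded baseline window samples the
#' between-episode regime without initialization bias (uniform random starts
#' overweight rare metastable modes in strongly coupled networks, which a
#' finite burn-in cannot correct). Larger networks start from a uniform random
#' state. Each run then equilibrates at field zero for `burn_in` sweeps (not
#' recorded) and records one state per sweep while the external field follows
#' [event_field()]. Emotion intensity at each sweep is the fraction of active
#' (+1) components.
#'
#' @param net A `component_network` (binary-coded networks are converted to
#'   spin coding for simulation).
#' @param schedule An `event_schedule`.
#' @param config A `sim_config`.
#' @param intensity_nodes Indices of the nodes over which intensity is
#'   averaged; defaults to the network's `intensity_nodes` attribute (set by
#'   [as_component_network()] to exclude the latent cause node) or all nodes.
#' @param keep_states Keep the full `runs x sweeps x n` state array (default
#'   TRUE); set FALSE to store intensities only for large ensembles.
#' @param burn_in Unrecorded equilibration sweeps at field zero before the
#'   baseline window. Default 100.
#' @param init `"stationary"` (exact equilibrium draw, networks up to 20
#'   components; larger networks fall back to random) or `"random"` (uniform
#'   random spins).
#' @return An object of class `trajectory_ensemble` with elements `states`
#'   (or NULL), `intensity` (`runs x sweeps`), `field`, `schedule`, `config`,
#'   `intensity_nodes`, `labels`.
#' @export
simulate_network <- function(net, schedule, config = sim_config(),
                             intensity_nodes = NULL, keep_states = TRUE,
                             burn_in = 100L,
                             init = c("stationary", "random")) {
  init <- match.arg(init)
  validate_network(net)
  stopifnot(inherits(schedule, "event_schedule"), inherits(config, "sim_config"))
  if (total_sweeps(schedule) < 1L)
    stop("invalid schedule: zero total sweeps", call. = FALSE)
  if (is.null(intensity_nodes))
    intensity_nodes <- attr(net, "intensity_nodes")
  snet <- convert_coding(net, "spin")
  n <- length(snet$labels)
  if (is.null(intensity_nodes)) intensity_nodes <- seq_len(n)
  fld <- event_field(schedule)
  nt <- length(fld)
  random_order <- config$update_order == "random_sequential"

  exact_init <- init == "stationary" && n <= 20L
  if (exact_init) {
    eq_states <- enumerate_spin_states(n)
    lw <- state_log_weights(eq_states, snet$weights, snet$thresholds,
                            config$beta, 0)
    lw <- lw - max(lw)
    eq_probs <- exp(lw) / sum(exp(lw))
  }
  intensity <- matrix(NA_real_, config$runs, nt)
  states <- if (keep_states) array(NA_integer_, c(config$runs, nt, n)) else NULL
  for (r in seq_len(config$runs)) {
    set.seed(derive_run_seed(config$seed, r))
    s0 <- if (exact_init)
      eq_states[sample.int(nrow(eq_states), 1L, prob = eq_probs), ]
    else sample(c(-1L, 1L), n, replace = TRUE)
    run_states <- glauber_run_cpp(snet$weights, snet$thresholds, fld,
                                  config$beta, s0, as.integer(burn_in),
                                  random_order)
    intensity[r, ] <- rowMeans(run_states[, intensity_nodes, drop = FALSE] == 1L)
    if (keep_states) states[r, , ] <- run_states
  }
  structure(
    list(states = states, intensity = intensity, field = fld,
         schedule = schedule, config = config,
         intensity_nodes = intensity_nodes, labels = snet$labels),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d runs x %d sweeps x %d components\n",
              nrow(x$intensity), ncol(x$intensity), length(x$labels)))
  cat(sprintf("  event: amplitude %.2f, hold %d, fade %d (%s)\n",
              x$schedule$amplitude, x$schedule$hold_sweeps,
              x$schedule$fade_sweeps, x$schedule$fade_shape))
  cat(sprintf("  mean intensity: %.3f\n", mean(x$intensity)))
  invisible(x)
}

#' Event onset sweep index
#'
#' First sweep of the hold phase, the time origin for episode-duration
#' measurement.
#' @param schedule An `event_schedule`.
#' @return Integer sweep index (1-based).
#' @export
event_onset <- function(schedule) {
  stopifnot(inherits(schedule, "event_schedule"))
  schedule$baseline_sweeps + 1L
}
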
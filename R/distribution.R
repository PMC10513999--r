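# Enumerate all 2^n spin states as a (2^n) x n matrix of -1/+1.
enumerate_spin_states <- function(n) {
  idx <- 0:(2^n - 1)
  vapply(seq_len(n),
         function(i) ifelse(bitwAnd(idx, bitwShiftL(1L, i - 1L)) > 0L, 1L, -1L),
         integer(length(idx)))
}

# Log unnormalized Boltzmann weight of each spin state:
# beta * (sum_{i<j} w_ij s_i s_j + sum_i (tau_i + field) s_i)
state_log_weights <- function(states, weights, thresholds, beta, field) {
  pair <- 0.5 * rowSums((states %*% weights) * states)  # zero diagonal assumed
  lin <- as.numeric(states %*% (thresholds + field))
  beta * (pair + lin)
}

new_intensity_distribution <- function(n, probs, method, beta) {
  structure(list(n = n, probs = probs, method = method, beta = beta),
            class = "intensity_distribution")
}

#' @export
print.intensity_distribution <- function(x, ...) {
  cat(sprintf("intensity_distribution (%s, beta = %g): %d components\n",
              x$method, x$beta, x$n))
  lv <- seq(0, x$n) / x$n
  cat(sprintf("  E[intensity] = %.3f\n", sum(lv * x$probs)))
  invisible(x)
}

#' Exact stationary distribution of emotion intensity
#'
#' Enumerates all `2^n` component states and computes the Boltzmann probability
#' `P(s) \\propto exp(beta (sum_{i<j} w_ij s_i s_j + sum_i (tau_i + field) s_i))`
#' (in spin coding), then aggregates states by their number of active
#' components. This is the distribution of "probable states" one would
#' encounter across many persons or occasions governed by the same network.
#' Normalization uses log-sum-exp, so large `beta` or strong fields do not
#' overflow.
#'
#' @param net A `component_network` with at most `max_n` components.
#'   Binary-coded networks are converted to spin coding (the distribution is
#'   identical under both parametrizations).
#' @param beta Inverse temperature.
#' @param field Uniform external field added to every threshold; 0 is the
#'   between-event (stationary) regime.
#' @param max_n Enumeration capacity limit; default 20 (about 10^6 states).
#' @return An `intensity_distribution`: `probs[k + 1] = P(intensity = k/n)`.
#' @export
exact_intensity_distribution <- function(net, beta = 1, field = 0, max_n = 20L) {
  validate_network(net)
  snet <- convert_coding(net, "spin")
  n <- length(snet$labels)
  if (n > max_n)
    stop(sprintf("n = %d exceeds the enumeration limit (%d); use sampled_intensity_distribution()",
                 n, max_n), call. = FALSE)
  states <- enumerate_spin_states(n)
  lw <- state_log_weights(states, snet$weights, snet$thresholds, beta, field)
  lw <- lw - max(lw)
  p_state <- exp(lw) / sum(exp(lw))
  k <- rowSums(states == 1L)
  probs <- as.numeric(rowsum(p_state, factor(k, levels = 0:n)))
  new_intensity_distribution(n, probs, "exact", beta)
}

#' Sampled stationary distribution of emotion intensity
#'
#' Monte-Carlo estimate of the same object as
#' [exact_intensity_distribution()]: runs Glauber dynamics at constant field,
#' discards `burn_in` sweeps, records every `thin`-th sweep, and tabulates the
#' relative frequency of each intensity level.
#'
#' @param net A `component_network`.
#' @param config A `sim_config`; `beta`, `seed` and `update_order` are used.
#' @param field Constant external field (default 0).
#' @param sweeps Total recorded sweeps (before thinning).
#' @param thin Keep every `thin`-th sweep.
#' @param burn_in Discarded equilibration sweeps.
#' @return An `intensity_distribution` with `method = "sampled"`.
#' @export
sampled_intensity_distribution <- function(net, config = sim_config(),
                                           field = 0, sweeps = 50000L,
                                           thin = 10L, burn_in = 1000L) {
  validate_network(net)
  stopifnot(inherits(config, "sim_config"), sweeps >= thin, thin >= 1L)
  snet <- convert_coding(net, "spin")
  n <- length(snet$labels)
  set.seed(derive_run_seed(config$seed, 1L))
  init <- sample(c(-1L, 1L), n, replace = TRUE)
  states <- glauber_run_cpp(snet$weights, snet$thresholds,
                            rep(field, sweeps), config$beta, init,
                            as.integer(burn_in),
                            config$update_order == "random_sequential")
  keep <- seq(thin, sweeps, by = thin)
  k <- rowSums(states[keep, , drop = FALSE] == 1L)
  probs <- as.numeric(table(factor(k, levels = 0:n))) / length(keep)
  new_intensity_distribution(n, probs, "sampled", config$beta)
}

#' Shape statistics of an intensity distribution
#'
#' Summaries that discriminate the qualitative regimes of probable states:
#' high connectivity concentrates mass at especially low and high intensities
#' (bimodality), while high thresholds concentrate mass at high intensities
#' with a skewed tail of low-intensity states (negative skew).
#'
#' @param dist An `intensity_distribution`.
#' @return List with `low_mass` (`P(intensity <= 0.2)`), `high_mass`
#'   (`P(intensity >= 0.8)`), `mid_mass` (`P(0.4 <= intensity <= 0.6)`),
#'   `bimodality_flag` (`low_mass > mid_mass` and `high_mass > mid_mass`),
#'   `skewness` (standardized third moment; 0 with `degenerate = TRUE` for a
#'   point mass) and `degenerate`.
#' @export
shape_statistics <- function(dist) {
  stopifnot(inherits(dist, "intensity_distribution"))
  lv <- seq(0, dist$n) / dist$n
  p <- dist$probs
  low_mass <- sum(p[lv <= 0.2])
  high_mass <- sum(p[lv >= 0.8])
  mid_mass <- sum(p[lv >= 0.4 & lv <= 0.6])
  mu <- sum(lv * p)
  v <- sum((lv - mu)^2 * p)
  degenerate <- v < .Machine$double.eps
  skew <- if (degenerate) 0 else sum((lv - mu)^3 * p) / v^1.5
  list(low_mass = low_mass, high_mass = high_mass, mid_mass = mid_mass,
       bimodality_flag = (low_mass > mid_mass) && (high_mass > mid_mass),
       skewness = skew, degenerate = degenerate)
}

#' Total-variation distance between two intensity distributions
#'
#' @param a,b `intensity_distribution` objects over the same number of
#'   components.
#' @return `0.5 * sum |a - b|` in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  stopifnot(inherits(a, "intensity_distribution"),
            inherits(b, "intensity_distribution"), a$n == b$n)
  0.5 * sum(abs(a$probs - b$probs))
}
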
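#' Baseline emotion intensity
#'
#' Mean intensity over the pre-event window, pooled over runs and baseline
#' sweeps. The standard error is computed across runs from the run-level
#' baseline means, since runs are the independent replicates.
#'
#' @param ens A `trajectory_ensemble`.
#' @return List with `mean` and `se`.
#' @export
baseline_intensity <- function(ens) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  nb <- ens$schedule$baseline_sweeps
  if (nb < 2L) stop("baseline window must contain at least 2 sweeps", call. = FALSE)
  base <- ens$intensity[, seq_len(nb), drop = FALSE]
  run_means <- rowMeans(base)
  list(mean = mean(run_means),
       se = stats::sd(run_means) / sqrt(length(run_means)))
}

#' Detect the end of an emotional episode by first return to baseline
#'
#' Scans the ensemble-mean intensity from event onset and declares the episode
#' over at the first sweep where the mean intensity is no longer significantly
#' larger than the pre-event baseline: `m_t <= baseline_mean + k * SE_t`, where
#' `m_t` and `SE_t` are the cross-run mean and standard error of intensity at
#' sweep `t`. Duration is measured in sweeps from event onset. If no such sweep
#' exists before the recording ends, the episode is censored.
#'
#' A return requires a departure: the scan for the end starts at the first
#' post-onset sweep where the mean intensity is significantly *above* baseline
#' (`m_t > baseline_mean + k * SE_t`). Without this, a wide criterion band
#' (large `k`) would declare the episode over during the rising phase, before
#' the emotion has emerged. If the intensity never rises above the band, no
#' episode is detected and the duration is 0.
#'
#' @param ens A `trajectory_ensemble` with at least 2 runs.
#' @param k Criterion multiplier for the SE rule; default 1.645 (one-sided 5%).
#' @param smooth_window Optional odd moving-average window applied to `m_t`
#'   before scanning, to suppress single-sweep dips; default 0 (off).
#' @return An object of class `episode_summary`: `baseline_mean`,
#'   `baseline_se`, `baseline_window`, `onset`, `episode_started` (first sweep
#'   significantly above baseline; NA if none), `end_sweep` (NA if censored),
#'   `duration_sweeps` (NA if censored), `censored`, `criterion_multiplier`.
#' @export
first_return_to_baseline <- function(ens, k = 1.645, smooth_window = 0L) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  R <- nrow(ens$intensity)
  if (R < 2L)
    stop("at least 2 runs are required to compute the cross-run SE", call. = FALSE)
  if (!is.finite(k) || k < 0) stop("k must be finite and non-negative", call. = FALSE)
  base <- baseline_intensity(ens)
  onset <- event_onset(ens$schedule)
  nt <- ncol(ens$intensity)
  if (onset > nt) stop("schedule has no post-onset sweeps", call. = FALSE)
  m <- colMeans(ens$intensity)
  se <- apply(ens$intensity, 2, stats::sd) / sqrt(R)
  if (smooth_window >= 2L) {
    w <- as.integer(smooth_window)
    kern <- rep(1 / w, w)
    m <- as.numeric(stats::filter(m, kern, sides = 2))
    # filter() leaves NAs at the edges; fall back to raw values there
    raw <- colMeans(ens$intensity)
    m[is.na(m)] <- raw[is.na(m)]
  }
  post <- onset:nt
  band <- base$mean + k * se[post]
  above <- post[m[post] > band]
  if (length(above) == 0L) {
    # intensity never rose significantly above baseline: no episode
    started <- NA_integer_; end_sweep <- onset; censored <- FALSE
  } else {
    started <- above[1L]
    scan <- post[post >= started]
    hit <- scan[m[scan] <= base$mean + k * se[scan]]
    censored <- length(hit) == 0L
    end_sweep <- if (censored) NA_integer_ else hit[1L]
  }
  structure(
    list(baseline_mean = base$mean, baseline_se = base$se,
         baseline_window = c(1L, ens$schedule$baseline_sweeps),
         onset = onset,
         episode_started = started,
         end_sweep = end_sweep,
         duration_sweeps = if (censored) NA_integer_ else end_sweep - onset,
         censored = censored,
         criterion_multiplier = k),
    class = "episode_summary"
  )
}

#' @export
print.episode_summary <- function(x, ...) {
  cat(sprintf("episode_summary: baseline %.3f (SE %.4f), k = %.3g\n",
              x$baseline_mean, x$baseline_se, x$criterion_multiplier))
  if (x$censored) {
    cat("  censored: intensity never returned to baseline within the recording\n")
  } else {
    cat(sprintf("  end sweep %d, duration %d sweeps from onset (sweep %d)\n",
                x$end_sweep, x$duration_sweeps, x$onset))
  }
  invisible(x)
}

#' Intensity-profile statistics of an episode
#'
#' Computes the within/outside-episode variance of the ensemble-mean intensity
#' and a profile-shape statistic, the decay half-life: the number of sweeps
#' from the end of the hold phase until the mean intensity first falls below
#' the midpoint `(peak + baseline_mean) / 2`, where `peak` is the maximum mean
#' intensity during the event. An abrupt post-event collapse gives a short
#' half-life; a steady decline gives a long one.
#'
#' @param ens A `trajectory_ensemble`.
#' @param summary An `episode_summary` for `ens`. If censored, the
#'   within/outside split is undefined and only the half-life is returned.
#' @return List with `variance_within`, `variance_outside` (NA when censored or
#'   window too short) and `decay_halflife` (NA if the midpoint is never
#'   crossed).
#' @export
intensity_profile_stats <- function(ens, summary) {
  stopifnot(inherits(ens, "trajectory_ensemble"),
            inherits(summary, "episode_summary"))
  m <- colMeans(ens$intensity)
  nt <- length(m)
  sch <- ens$schedule
  onset <- summary$onset
  hold_end <- sch$baseline_sweeps + sch$hold_sweeps

  event_window <- onset:max(onset, hold_end)
  peak <- max(m[event_window])
  target <- (peak + summary$baseline_mean) / 2
  after_hold <- if (hold_end < nt) (hold_end + 1L):nt else integer(0)
  cross <- after_hold[m[after_hold] < target]
  halflife <- if (length(cross)) cross[1L] - hold_end else NA_integer_

  if (summary$censored) {
    return(list(variance_within = NA_real_, variance_outside = NA_real_,
                decay_halflife = halflife))
  }
  within_idx <- onset:summary$end_sweep
  outside_idx <- if (summary$end_sweep < nt) (summary$end_sweep + 1L):nt else integer(0)
  list(
    variance_within = if (length(within_idx) >= 2L) stats::var(m[within_idx]) else 0,
    variance_outside = if (length(outside_idx) >= 2L) stats::var(m[outside_idx]) else NA_real_,
    decay_halflife = halflife
  )
}

#' Episode duration with a replication-based standard error
#'
#' The first-return rule yields one duration per ensemble (it operates on the
#' cross-run mean trajectory), so uncertainty in the duration is estimated by
#' repeating the whole ensemble: `n_ensembles` independent ensembles of
#' `config$runs` runs each are simulated with seeds derived from
#' `config$seed`, and the per-ensemble durations are summarised. Censored
#' ensembles contribute the maximum observable duration (recording end minus
#' onset), a conservative lower bound.
#'
#' @param net A `component_network`.
#' @param schedule An `event_schedule`.
#' @param config A `sim_config`; `config$runs` is the size of each ensemble.
#' @param k Criterion multiplier passed to [first_return_to_baseline()].
#' @param n_ensembles Number of replicate ensembles (>= 2 for a finite SE).
#' @param intensity_nodes Passed to [simulate_network()].
#' @return List with `durations` (per ensemble), `mean`, `se`,
#'   `n_censored`, `baseline_means`, `baseline_mean`, `baseline_se`.
#' @export
episode_duration_stats <- function(net, schedule, config = sim_config(),
                                   k = 1.645, n_ensembles = 10L,
                                   intensity_nodes = NULL) {
  stopifnot(n_ensembles >= 1L)
  max_dur <- total_sweeps(schedule) - event_onset(schedule)
  durations <- numeric(n_ensembles)
  base_means <- numeric(n_ensembles)
  n_censored <- 0L
  for (b in seq_len(n_ensembles)) {
    cfg_b <- config
    cfg_b$seed <- derive_run_seed(config$seed, 100000L + b)
    ens <- simulate_network(net, schedule, cfg_b,
                            intensity_nodes = intensity_nodes,
                            keep_states = FALSE)
    s <- first_return_to_baseline(ens, k = k)
    if (s$censored) {
      durations[b] <- max_dur
      n_censored <- n_censored + 1L
    } else {
      durations[b] <- s$duration_sweeps
    }
    base_means[b] <- s$baseline_mean
  }
  list(durations = durations,
       mean = mean(durations),
       se = if (n_ensembles >= 2L) stats::sd(durations) / sqrt(n_ensembles) else NA_real_,
       n_censored = n_censored,
       baseline_means = base_means,
       baseline_mean = mean(base_means),
       baseline_se = if (n_ensembles >= 2L) stats::sd(base_means) / sqrt(n_ensembles) else NA_real_)
}
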
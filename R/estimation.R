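#' Dichotomize ordinal component ratings
#'
#' The nodewise network estimator requires binary component states, so ordinal
#' ratings are dichotomized per column, either at the column median (values
#' strictly above the median become 1; ties at the median go to 0) or at a
#' fixed cut point (values strictly above `cut` become 1).
#'
#' @param ratings Numeric matrix or data frame, observations in rows.
#' @param rule `"median_split"` or `"fixed_cut"`.
#' @param cut Cut point for `rule = "fixed_cut"`.
#' @return Integer 0/1 matrix with the input column names.
#' @export
binarize <- function(ratings, rule = c("median_split", "fixed_cut"), cut = 0.5) {
  rule <- match.arg(rule)
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("ratings must be numeric and finite", call. = FALSE)
  labs <- colnames(x)
  if (is.null(labs)) labs <- paste0("V", seq_len(ncol(x)))
  out <- matrix(0L, nrow(x), ncol(x), dimnames = list(NULL, labs))
  for (j in seq_len(ncol(x))) {
    cj <- if (rule == "median_split") stats::median(x[, j]) else cut
    out[, j] <- as.integer(x[, j] > cj)
    if (length(unique(out[, j])) < 2L)
      stop(sprintf("degenerate column '%s': constant after dichotomization", labs[j]),
           call. = FALSE)
  }
  out
}

# EBIC of a fitted nodewise logistic model:
# deviance + df * log(N) + 2 * gamma * df * log(p_candidates)
ebic_score <- function(deviance, df, n_obs, n_candidates, gamma) {
  deviance + df * log(n_obs) + 2 * gamma * df * log(n_candidates)
}

#' Estimate a component network from cross-sectional binary data
#'
#' The nodewise regularized estimator commonly used for binary psychological
#' networks (eLasso): each node is regressed on all other nodes with
#' L1-penalized logistic regression over a grid of penalty values, the penalty
#' is selected per node by the extended Bayesian information criterion (EBIC),
#' and an undirected edge is retained under the AND rule only if both directed
#' coefficients are nonzero, with the edge weight set to their mean. Node
#' thresholds are the selected intercepts. Coefficients of a logistic
#' regression on 0/1 predictors live naturally in the binary parametrization,
#' so the result is returned in binary coding; use [convert_coding()] for the
#' spin-coded equivalent.
#'
#' @param data 0/1 matrix, observations in rows, components in columns (named).
#' @param gamma EBIC hyperparameter in `[0, 1]`; 0 is ordinary BIC. Default
#'   0.25.
#' @param rule `"and"` (default) or `"or"` edge-retention rule.
#' @param nlambda Number of penalty values per node (default 50, log-spaced
#'   from the per-node maximum down by a factor of 10^3).
#' @return An object of class `estimation_result`: `network` (binary-coded
#'   `component_network`), `lambda` (selected penalty per node), `ebic`
#'   (selected EBIC per node), `sparsity` (fraction of absent edges),
#'   `separable` (logical per node, TRUE where the fit was flagged as perfectly
#'   or near-perfectly separable and the penalty floor applied).
#' @export
estimate_network <- function(data, gamma = 0.25, rule = c("and", "or"),
                             nlambda = 50L) {
  rule <- match.arg(rule)
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (!all(x %in% c(0, 1))) stop("data must be a 0/1 matrix", call. = FALSE)
  n_obs <- nrow(x)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 components to estimate a network", call. = FALSE)
  labs <- colnames(x)
  if (is.null(labs)) labs <- paste0("V", seq_len(p))
  if (n_obs <= p)
    warning("fewer observations than components; estimates will be unstable")
  for (j in seq_len(p)) if (length(unique(x[, j])) < 2L)
    stop(sprintf("degenerate column '%s': constant values", labs[j]), call. = FALSE)

  B <- matrix(0, p, p)   # B[i, j]: coefficient of node j in the model for node i
  intercepts <- numeric(p)
  sel_lambda <- numeric(p)
  sel_ebic <- numeric(p)
  separable <- logical(p)
  for (i in seq_len(p)) {
    y <- x[, i]
    X <- x[, -i, drop = FALSE]
    fit <- glmnet::glmnet(X, y, family = "binomial", nlambda = nlambda,
                          lambda.min.ratio = 1e-3)
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    ebic <- ebic_score(dev, fit$df, n_obs, p - 1L, gamma)
    best <- which.min(ebic)
    coefs <- as.numeric(fit$beta[, best])
    intercepts[i] <- fit$a0[best]
    sel_lambda[i] <- fit$lambda[best]
    sel_ebic[i] <- ebic[best]
    # near-zero deviance or runaway coefficients indicate (quasi-)separation;
    # the smallest grid penalty already acts as the floor, so just flag it
    separable[i] <- dev[best] < 0.01 * fit$nulldev || max(abs(coefs)) > 10
    B[i, -i] <- coefs
  }
  keep <- if (rule == "and") (B != 0) & (t(B) != 0) else (B != 0) | (t(B) != 0)
  W <- (B + t(B)) / 2 * keep
  diag(W) <- 0
  net <- component_network(labs, W, intercepts, coding = "binary")
  ut <- W[upper.tri(W)]
  structure(
    list(network = net, lambda = sel_lambda, ebic = sel_ebic,
         sparsity = mean(ut == 0), separable = separable,
         gamma = gamma, rule = rule),
    class = "estimation_result"
  )
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("estimation_result (%s rule, gamma = %g): %d nodes, sparsity %.2f\n",
              x$rule, x$gamma, length(x$network$labels), x$sparsity))
  if (any(x$separable))
    cat("  separability flagged for node(s):",
        paste(x$network$labels[x$separable], collapse = ", "), "\n")
  invisible(x)
}

#' Sample cross-sectional binary data from a network
#'
#' Draws `n_obs` independent observations from the network's stationary
#' (Boltzmann) distribution and codes them 0/1 -- a synthetic stand-in for
#' cross-sectional component ratings. For networks of up to `max_exact`
#' components the sampler is exact (inverse-CDF over the enumerated state
#' distribution); larger networks fall back to thinned Glauber sampling.
#'
#' @param net A `component_network`.
#' @param n_obs Number of observations.
#' @param beta Inverse temperature of the stationary distribution.
#' @param seed Integer seed.
#' @param max_exact Enumeration limit for the exact sampler (default 20).
#' @param thin Thinning interval for the Glauber fallback.
#' @return `n_obs x n` integer 0/1 matrix with the network's labels as column
#'   names.
#' @export
sample_cross_sectional <- function(net, n_obs, beta = 1, seed = 1L,
                                   max_exact = 20L, thin = 20L) {
  validate_network(net)
  snet <- convert_coding(net, "spin")
  n <- length(snet$labels)
  if (n <= max_exact) {
    states <- enumerate_spin_states(n)
    lw <- state_log_weights(states, snet$weights, snet$thresholds, beta, 0)
    lw <- lw - max(lw)
    p_state <- exp(lw) / sum(exp(lw))
    set.seed(as.integer(seed %% 2147483647))
    idx <- sample.int(nrow(states), n_obs, replace = TRUE, prob = p_state)
    out <- (states[idx, , drop = FALSE] + 1L) %/% 2L
  } else {
    cfg <- sim_config(beta = beta, seed = as.integer(seed %% 2147483647))
    set.seed(derive_run_seed(cfg$seed, 1L))
    init <- sample(c(-1L, 1L), n, replace = TRUE)
    raw <- glauber_run_cpp(snet$weights, snet$thresholds,
                           rep(0, n_obs * thin), beta, init, 1000L, TRUE)
    out <- (raw[seq(thin, n_obs * thin, by = thin), , drop = FALSE] + 1L) %/% 2L
  }
  colnames(out) <- snet$labels
  out
}

#' Generate a synthetic fear-like or awe-like network fixture
#'
#' Random 10-component networks (spin coding) that emulate the qualitative
#' regimes of empirically estimated emotion networks: the fear-like kind has
#' dense, mostly positive couplings strong enough for feedback loops to sustain
#' activation, while the awe-like kind has the same topology regime but
#' substantially weaker couplings (many weak relationships), so its components
#' cannot keep each other active. Both kinds share a negative-threshold regime:
#' components tend to be inactive between episodes. The defaults are synthetic
#' calibration constants, not empirical estimates.
#'
#' @param kind `"fear_like"` or `"awe_like"`.
#' @param seed Integer seed for the random topology and parameter draws.
#' @param n Number of components (default 10).
#' @return A `component_network` in spin coding.
#' @export
make_fixture_network <- function(kind = c("fear_like", "awe_like"), seed = 1L,
                                 n = 10L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed %% 2147483647))
  w_mean <- if (kind == "fear_like") 0.30 else 0.12
  w_sd <- if (kind == "fear_like") 0.10 else 0.05
  repeat {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    present <- stats::runif(length(ut)) < 0.5
    mag <- abs(stats::rnorm(sum(present), w_mean, w_sd))
    sign <- ifelse(stats::runif(sum(present)) < 0.10, -1, 1)
    W[ut[present]] <- mag * sign
    W <- W + t(W)
    # every component should take part in the network: redraw rare
    # configurations with an isolated node
    if (all(rowSums(W != 0) > 0)) break
  }
  tau <- stats::rnorm(n, -0.4, 0.1)
  component_network(paste0("c", seq_len(n)), W, tau, coding = "spin")
}

#' Generate a small random network for testing and cross-checks
#'
#' Moderately coupled random networks used as generic fixtures (e.g. for
#' comparing sampled and exact intensity distributions).
#'
#' @param n Number of components.
#' @param seed Integer seed.
#' @param w_mean,w_sd Mean and SD of the absolute edge weights.
#' @param edge_prob Probability that a pair is connected.
#' @param tau_mean,tau_sd Mean and SD of the thresholds.
#' @return A `component_network` in spin coding.
#' @export
random_network <- function(n, seed = 1L, w_mean = 0.2, w_sd = 0.1,
                           edge_prob = 0.5, tau_mean = -0.3, tau_sd = 0.2) {
  set.seed(as.integer(seed %% 2147483647))
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  present <- stats::runif(length(ut)) < edge_prob
  W[ut[present]] <- stats::rnorm(sum(present), w_mean, w_sd)
  W <- W + t(W)
  tau <- stats::rnorm(n, tau_mean, tau_sd)
  component_network(paste0("c", seq_len(n)), W, tau, coding = "spin")
}
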
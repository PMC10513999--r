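#' Write a component network to JSON
#'
#' Serializes labels, weights, thresholds and coding with full double
#' precision, so that write -> read round-trips are lossless.
#'
#' @param net A `component_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  validate_network(net)
  obj <- list(labels = net$labels,
              weights = net$weights,
              thresholds = net$thresholds,
              coding = net$coding)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' Read a component network from JSON
#'
#' @param path JSON file produced by [write_network_json()] (fields `labels`,
#'   `weights`, `thresholds`, `coding`).
#' @return A validated `component_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("labels", "weights", "thresholds", "coding"))
    if (is.null(obj[[f]]))
      stop(sprintf("network file is missing required field '%s'", f), call. = FALSE)
  if (!obj$coding %in% c("spin", "binary"))
    stop(sprintf("unknown coding '%s': must be 'spin' or 'binary'", obj$coding),
         call. = FALSE)
  component_network(obj$labels, obj$weights, obj$thresholds, obj$coding)
}

# Full-precision numeric formatting for text round-trips.
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a component network as an edge-list/node-list CSV pair
#'
#' Writes `<stem>_edges.csv` (columns `from`, `to`, `weight`; upper triangle,
#' nonzero edges only) and `<stem>_nodes.csv` (columns `label`, `threshold`,
#' `coding`). Numeric values use 17 significant digits, so round-trips are
#' lossless.
#'
#' @param net A `component_network`.
#' @param stem Path stem; the two files get `_edges.csv` / `_nodes.csv`
#'   suffixes.
#' @return Character vector of the two paths, invisibly.
#' @export
write_network_csv <- function(net, stem) {
  validate_network(net)
  n <- length(net$labels)
  ij <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  edges <- data.frame(from = net$labels[ij[, 1]],
                      to = net$labels[ij[, 2]],
                      weight = fmt_full(net$weights[ij]))
  nodes <- data.frame(label = net$labels,
                      threshold = fmt_full(net$thresholds),
                      coding = net$coding)
  paths <- paste0(stem, c("_edges.csv", "_nodes.csv"))
  utils::write.csv(edges, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(nodes, paths[2], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a component network from an edge-list/node-list CSV pair
#'
#' @param stem Path stem used with [write_network_csv()].
#' @return A validated `component_network`.
#' @export
read_network_csv <- function(stem) {
  paths <- paste0(stem, c("_edges.csv", "_nodes.csv"))
  edges <- utils::read.csv(paths[1], colClasses = c("character", "character", "character"))
  nodes <- utils::read.csv(paths[2], colClasses = "character")
  for (f in c("label", "threshold", "coding"))
    if (is.null(nodes[[f]]))
      stop(sprintf("node file is missing required column '%s'", f), call. = FALSE)
  labs <- nodes$label
  n <- length(labs)
  W <- matrix(0, n, n)
  if (nrow(edges)) {
    i <- match(edges$from, labs)
    j <- match(edges$to, labs)
    if (anyNA(i) || anyNA(j))
      stop("edge list refers to labels missing from the node list", call. = FALSE)
    W[cbind(i, j)] <- as.numeric(edges$weight)
    W[cbind(j, i)] <- as.numeric(edges$weight)
  }
  component_network(labs, W, as.numeric(nodes$threshold), unique(nodes$coding))
}

#' Write an event schedule or simulation config to JSON
#' @param x An `event_schedule` or `sim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(x, path) {
  stopifnot(inherits(x, "event_schedule") || inherits(x, "sim_config"))
  obj <- unclass(x)
  obj$.type <- class(x)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read an event schedule from JSON
#' @param path JSON file with the fields of [event_schedule()].
#' @return An `event_schedule`.
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(event_schedule, obj[setdiff(names(obj), ".type")])
}

#' Read a simulation config from JSON
#' @param path JSON file with the fields of [sim_config()].
#' @return A `sim_config`.
#' @export
read_sim_config_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, obj[setdiff(names(obj), ".type")])
}

#' Write trajectory ensemble to long-format CSV
#'
#' One row per run x sweep with columns `run`, `sweep`, `field`, `intensity`,
#' and optionally one 0/1 column per component.
#'
#' @param ens A `trajectory_ensemble`.
#' @param path Output file path.
#' @param per_component Include per-component state columns (requires the
#'   ensemble to have been simulated with `keep_states = TRUE`).
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(ens, path, per_component = FALSE) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  R <- nrow(ens$intensity); nt <- ncol(ens$intensity)
  df <- data.frame(run = rep(seq_len(R), each = nt),
                   sweep = rep(seq_len(nt), R),
                   field = rep(ens$field, R),
                   intensity = as.vector(t(ens$intensity)))
  if (per_component) {
    if (is.null(ens$states))
      stop("ensemble was simulated with keep_states = FALSE", call. = FALSE)
    for (j in seq_along(ens$labels)) {
      df[[ens$labels[j]]] <- as.integer(as.vector(t(ens$states[, , j])) == 1L)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format trajectory CSV back into intensity form
#'
#' Restores a minimal `trajectory_ensemble` (intensity, field) from a file
#' written by [write_trajectories_csv()]. A schedule must be supplied (or
#' stored alongside) for episode analysis.
#'
#' @param path Trajectory CSV path.
#' @param schedule The `event_schedule` the trajectories were simulated under.
#' @param config Optional `sim_config` (recorded for provenance).
#' @return A `trajectory_ensemble` with `states = NULL`.
#' @export
read_trajectories_csv <- function(path, schedule, config = NULL) {
  df <- utils::read.csv(path)
  for (f in c("run", "sweep", "field", "intensity"))
    if (is.null(df[[f]]))
      stop(sprintf("trajectory file is missing required column '%s'", f), call. = FALSE)
  runs <- sort(unique(df$run))
  nt <- length(unique(df$sweep))
  intensity <- matrix(NA_real_, length(runs), nt)
  for (r in seq_along(runs)) {
    sub <- df[df$run == runs[r], ]
    intensity[r, sub$sweep] <- sub$intensity
  }
  fld <- df$field[df$run == runs[1]][order(df$sweep[df$run == runs[1]])]
  if (!is.null(schedule) && nt != total_sweeps(schedule))
    stop("trajectory length does not match the supplied schedule", call. = FALSE)
  structure(
    list(states = NULL, intensity = intensity, field = fld,
         schedule = schedule, config = config,
         intensity_nodes = NULL, labels = NULL),
    class = "trajectory_ensemble"
  )
}

#' Write an intensity distribution to CSV
#'
#' Columns `level_k`, `intensity`, `probability`.
#'
#' @param dist An `intensity_distribution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "intensity_distribution"))
  df <- data.frame(level_k = 0:dist$n,
                   intensity = fmt_full(seq(0, dist$n) / dist$n),
                   probability = fmt_full(dist$probs))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write binary component data to CSV
#' @param data 0/1 matrix with column names (as from
#'   [sample_cross_sectional()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_data_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read binary component data from CSV
#' @param path CSV with a header of component labels and 0/1 entries.
#' @return Integer 0/1 matrix.
#' @export
read_data_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df)
  if (!all(x %in% c(0, 1)))
    stop("data file contains entries other than 0/1", call. = FALSE)
  storage.mode(x) <- "integer"
  x
}

#' Load and validate a typed object from file
#'
#' Single entry point for loading the package's file formats with full
#' invariant checking; error messages name the violated invariant.
#'
#' @param path File path (or CSV stem for `format = "network_csv"`).
#' @param format One of `"network"` (JSON), `"network_csv"`, `"schedule"`,
#'   `"config"`, `"data"`.
#' @return The typed object.
#' @export
validate_and_load <- function(path, format = c("network", "network_csv",
                                                "schedule", "config", "data")) {
  format <- match.arg(format)
  if (format != "network_csv" && !file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  switch(format,
         network = read_network_json(path),
         network_csv = read_network_csv(path),
         schedule = read_schedule_json(path),
         config = read_sim_config_json(path),
         data = read_data_csv(path))
}
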
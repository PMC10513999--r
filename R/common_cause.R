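#' Construct a common-cause comparator model
#'
#' The comparator architecture inspired by affect-program theories: a single
#' latent cause drives every emotion component, while the components have no
#' causal relationships among each other. Under this architecture activation
#' cannot be sustained by feedback between components, so the emotion ends once
#' the external activation vanishes -- the discriminating prediction against
#' the component-network model.
#'
#' @param labels Character vector of component names (length `n`).
#' @param loadings Numeric vector of cause-to-component coupling strengths
#'   (length `n`).
#' @param thresholds Numeric vector of component thresholds (length `n`).
#' @param cause_threshold Threshold of the latent cause node.
#' @return An object of class `common_cause_model`.
#' @seealso [as_component_network()] to embed the model as a star network that
#'   the simulation machinery can run directly.
#' @export
common_cause_model <- function(labels, loadings, thresholds, cause_threshold) {
  labels <- as.character(labels)
  loadings <- as.numeric(loadings)
  thresholds <- as.numeric(thresholds)
  n <- length(labels)
  if (length(loadings) != n || length(thresholds) != n)
    stop("loadings and thresholds must have the same length as labels", call. = FALSE)
  if (!all(is.finite(loadings)) || !all(is.finite(thresholds)) ||
      !is.finite(cause_threshold))
    stop("all common-cause parameters must be finite", call. = FALSE)
  if (anyDuplicated(labels)) stop("component labels must be unique", call. = FALSE)
  structure(
    list(labels = labels, loadings = loadings, thresholds = thresholds,
         cause_threshold = as.numeric(cause_threshold)),
    class = "common_cause_model"
  )
}

#' Embed a common-cause model as a star network
#'
#' Returns an `(n+1)`-node `component_network` (spin coding) whose only edges
#' connect the latent cause node to each component; component-component weights
#' are zero for every pair by construction. The returned network carries an
#' `intensity_nodes` attribute marking the component nodes, so that emotion
#' intensity is computed over the components only and the latent cause is
#' excluded.
#'
#' @param x A `common_cause_model`.
#' @param cause_label Label used for the appended cause node.
#' @return A `component_network` with `n + 1` nodes.
#' @export
as_component_network <- function(x, cause_label = ".cause") {
  if (!inherits(x, "common_cause_model"))
    stop("x must be a common_cause_model", call. = FALSE)
  n <- length(x$labels)
  w <- matrix(0, n + 1L, n + 1L)
  w[n + 1L, seq_len(n)] <- x$loadings
  w[seq_len(n), n + 1L] <- x$loadings
  net <- component_network(
    labels = c(x$labels, cause_label),
    weights = w,
    thresholds = c(x$thresholds, x$cause_threshold),
    coding = "spin"
  )
  attr(net, "intensity_nodes") <- seq_len(n)
  net
}
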
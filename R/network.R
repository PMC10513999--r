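#' Construct an emotion component network
#'
#' A component network describes one emotion (for one person or situation) as a
#' set of binary components -- appraisals, feelings, motivations, physiological
#' changes, expressions -- connected by symmetric pairwise coupling weights,
#' with a per-component threshold giving the state the component tends to be in
#' absent any input.
#'
#' Two standard parametrizations of the same model are supported. In `"spin"`
#' coding component states are -1/+1 and inactive neighbours actively suppress
#' activation through positive edges; in `"binary"` coding states are 0/1 and an
#' inactive neighbour contributes nothing. Simulation and enumeration use spin
#' coding internally; [convert_coding()] maps between the two exactly.
#'
#' @param labels Character vector of component names (unique, length `n`).
#' @param weights `n x n` numeric matrix of coupling strengths; must be
#'   symmetric with zero diagonal. Negative weights (inhibitory relationships)
#'   are allowed.
#' @param thresholds Numeric vector of length `n`.
#' @param coding `"spin"` (-1/+1 states) or `"binary"` (0/1 states); declares
#'   the parametrization `weights` and `thresholds` are expressed in.
#' @return An object of class `component_network`.
#' @examples
#' net <- component_network(
#'   labels = c("unfair", "hostile", "yell"),
#'   weights = matrix(c(0, .4, .2, .4, 0, 0, .2, 0, 0), 3, 3),
#'   thresholds = c(-0.5, -0.5, -0.5)
#' )
#' scale_connectivity(net, 2)
#' @export
component_network <- function(labels, weights, thresholds, coding = c("spin", "binary")) {
  coding <- match.arg(coding)
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  thresholds <- as.numeric(thresholds)
  labels <- as.character(labels)
  net <- structure(
    list(labels = labels, weights = unname(weights),
         thresholds = thresholds, coding = coding),
    class = "component_network"
  )
  validate_network(net)
  net
}

#' Validate a component network
#'
#' Checks the structural invariants: symmetric weight matrix (within 1e-12),
#' zero diagonal, unique labels, finite entries, consistent dimensions.
#'
#' @param net A `component_network`.
#' @return `net`, invisibly, if valid; otherwise an error naming the violated
#'   invariant.
#' @export
validate_network <- function(net) {
  if (!inherits(net, "component_network"))
    stop("not a component_network object", call. = FALSE)
  n <- length(net$labels)
  w <- net$weights
  if (n < 1L) stop("network must have at least one component", call. = FALSE)
  if (anyDuplicated(net$labels)) stop("component labels must be unique", call. = FALSE)
  if (!is.matrix(w) || nrow(w) != n || ncol(w) != n)
    stop("weights must be an n x n matrix matching labels", call. = FALSE)
  if (length(net$thresholds) != n)
    stop("thresholds must have one entry per component", call. = FALSE)
  if (!all(is.finite(w))) stop("weights contain non-finite entries", call. = FALSE)
  if (!all(is.finite(net$thresholds)))
    stop("thresholds contain non-finite entries", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-12)
    stop("weights must be symmetric (max |w - t(w)| exceeds 1e-12)", call. = FALSE)
  if (any(abs(diag(w)) > 0)) stop("weight matrix must have zero diagonal", call. = FALSE)
  if (!net$coding %in% c("spin", "binary"))
    stop("unknown coding: must be 'spin' or 'binary'", call. = FALSE)
  invisible(net)
}

#' @export
print.component_network <- function(x, ...) {
  n <- length(x$labels)
  ut <- x$weights[upper.tri(x$weights)]
  cat(sprintf("component_network: %d components (%s coding)\n", n, x$coding))
  cat(sprintf("  edges (nonzero): %d of %d; mean |weight| %.3f\n",
              sum(ut != 0), length(ut),
              if (any(ut != 0)) mean(abs(ut[ut != 0])) else 0))
  cat(sprintf("  thresholds: mean %.3f [%.3f, %.3f]\n",
              mean(x$thresholds), min(x$thresholds), max(x$thresholds)))
  invisible(x)
}

#' Scale network connectivity
#'
#' Multiplies every coupling weight by a common factor, the manipulation used
#' to generate higher- (or lower-) connectivity variants of a network.
#' Thresholds, labels and coding are untouched.
#'
#' @param net A `component_network`.
#' @param factor Non-negative finite scaling factor.
#' @return A new `component_network`.
#' @export
scale_connectivity <- function(net, factor) {
  validate_network(net)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor < 0)
    stop("connectivity factor must be a single finite non-negative number", call. = FALSE)
  net$weights <- net$weights * factor
  net
}

#' Shift component thresholds
#'
#' Adds a common constant to every component's threshold, the manipulation used
#' to generate higher- (or lower-) threshold variants of a network. Weights are
#' untouched.
#'
#' @param net A `component_network`.
#' @param constant Finite shift added to each threshold.
#' @return A new `component_network`.
#' @export
shift_thresholds <- function(net, constant) {
  validate_network(net)
  if (!is.numeric(constant) || length(constant) != 1L || !is.finite(constant))
    stop("threshold constant must be a single finite number", call. = FALSE)
  net$thresholds <- net$thresholds + constant
  net
}

#' Convert between spin and binary parametrizations
#'
#' Maps the weights and thresholds of a network between the -1/+1 ("spin") and
#' 0/1 ("binary") parametrizations so that the full joint distribution over
#' states is preserved exactly under the state map `s = 2x - 1`. From binary to
#' spin: `w' = w / 4`, `tau'_i = tau_i / 2 + sum_j(w_ij) / 4`; spin to binary
#' inverts this exactly. Converting to the coding the network is already in is
#' the identity.
#'
#' @param net A `component_network`.
#' @param target `"spin"` or `"binary"`.
#' @return A `component_network` in the target coding.
#' @export
convert_coding <- function(net, target = c("spin", "binary")) {
  validate_network(net)
  target <- match.arg(target)
  if (identical(net$coding, target)) return(net)
  w <- net$weights
  tau <- net$thresholds
  if (net$coding == "binary" && target == "spin") {
    net$weights <- w / 4
    net$thresholds <- tau / 2 + rowSums(w) / 4
  } else {
    net$weights <- w * 4
    net$thresholds <- 2 * tau - 2 * rowSums(w)
  }
  net$coding <- target
  net
}
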
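# Core forward model: granule cells (GrCs) as thresholded ramp units reading
# linear projections of the raw sensorimotor input space, integrated by a
# signed linear Purkinje-cell (PC) readout.  A population of GrCs that share
# a projection but differ in threshold lets the PC form a continuous
# piecewise-linear (PL) function along that projection; each threshold is one
# knot of the PL output.

#' Ramp (rectifier) activation
#'
#' The granule-cell transfer function: zero below threshold, linear above.
#' This is the abstraction of the large gap between a granule cell's resting
#' potential and its spike threshold, combined with its approximately linear
#' supra-threshold rate response.
#'
#' @param u numeric vector of drives (projected input minus threshold).
#' @return `pmax(u, 0)`, elementwise.
#' @examples
#' ramp(c(-3.7, 0, 2.5))
#' @export
ramp <- function(u) {
  if (!is.numeric(u)) {
    stop("ramp(): drive must be numeric", call. = FALSE)
  }
  if (length(u) && any(!is.finite(u))) {
    stop("ramp(): non-finite drive is not a valid granule-cell input",
         call. = FALSE)
  }
  pmax(u, 0)
}

#' Set of projection directions
#'
#' A projection is a linear recombination of the raw input dimensions,
#' modelling the sensorimotor mixing performed by spinocerebellar neurons
#' before the granule layer.  Each row is a unit-norm direction in the
#' d-dimensional raw-input space.
#'
#' @param directions numeric matrix, q x d; each row a direction.
#' @param normalize if `TRUE`, rows are rescaled to unit norm; otherwise rows
#'   must already have Euclidean norm 1 within `1e-9`.
#' @return object of class `projection_set`.
#' @export
projection_set <- function(directions, normalize = FALSE) {
  directions <- as.matrix(directions)
  storage.mode(directions) <- "double"
  if (nrow(directions) < 1L || ncol(directions) < 1L) {
    stop("projection_set(): need at least one direction in at least one dimension",
         call. = FALSE)
  }
  if (any(!is.finite(directions))) {
    stop("projection_set(): directions must be finite", call. = FALSE)
  }
  nrm <- sqrt(rowSums(directions^2))
  if (normalize) {
    if (any(nrm == 0)) {
      stop("projection_set(): cannot normalize a zero direction", call. = FALSE)
    }
    directions <- directions / nrm
  } else if (any(abs(nrm - 1) > 1e-9)) {
    stop("projection_set(): rows must be unit norm (or pass normalize = TRUE)",
         call. = FALSE)
  }
  structure(list(directions = directions), class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set: %d direction(s) in %d dimension(s)>\n",
              nrow(x$directions), ncol(x$directions)))
  print(round(x$directions, 4))
  invisible(x)
}

n_projections <- function(ps) nrow(ps$directions)
input_dim <- function(ps) ncol(ps$directions)

#' Granule-cell population parameters
#'
#' One entry per granule unit: the projection that drives it, its threshold
#' (the distance from rest to spike threshold, in projected-input units;
#' biologically set by tonic inhibition), and a scalar input gain (the lumped
#' mossy-fibre transmission efficacy).  Indices are 1-based.
#'
#' @param projection_index integer vector; which projection drives each unit.
#' @param threshold numeric vector of thresholds, one per unit.
#' @param gain numeric vector of gains (recycled); default 1.
#' @return object of class `granule_population`.
#' @export
granule_population <- function(projection_index, threshold, gain = 1) {
  projection_index <- as.integer(projection_index)
  threshold <- as.numeric(threshold)
  n <- length(threshold)
  if (length(projection_index) != n) {
    stop("granule_population(): projection_index and threshold lengths differ",
         call. = FALSE)
  }
  gain <- rep_len(as.numeric(gain), n)
  if (any(projection_index < 1L)) {
    stop("granule_population(): projection_index must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(threshold)) || any(!is.finite(gain))) {
    stop("granule_population(): thresholds and gains must be finite",
         call. = FALSE)
  }
  structure(list(projection_index = projection_index,
                 threshold = threshold, gain = gain),
            class = "granule_population")
}

#' Purkinje-cell readout
#'
#' Signed linear combination of granule activities plus a spontaneous
#' baseline.  Weights may be negative: granule input can reach the Purkinje
#' cell through inhibitory molecular-layer interneurons.
#'
#' @param weights numeric vector, one weight per granule unit.
#' @param baseline scalar spontaneous activity.
#' @return object of class `purkinje_readout`.
#' @export
purkinje_readout <- function(weights, baseline = 0) {
  weights <- as.numeric(weights)
  baseline <- as.numeric(baseline)
  if (length(baseline) != 1L || !is.finite(baseline)) {
    stop("purkinje_readout(): baseline must be a finite scalar", call. = FALSE)
  }
  if (any(!is.finite(weights))) {
    stop("purkinje_readout(): weights must be finite", call. = FALSE)
  }
  structure(list(weights = weights, baseline = baseline),
            class = "purkinje_readout")
}

#' Full piecewise-linear network
#'
#' Composition of a projection set, a granule population and a Purkinje
#' readout.  Along any straight line through input space the output is a
#' continuous piecewise-linear function with at most one knot per granule
#' unit.
#'
#' @param projections a [projection_set()].
#' @param granules a [granule_population()].
#' @param readout a [purkinje_readout()].
#' @return object of class `pl_network`.
#' @export
pl_network <- function(projections, granules, readout) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(granules, "granule_population"),
            inherits(readout, "purkinje_readout"))
  n <- length(granules$threshold)
  if (length(readout$weights) != n) {
    stop("pl_network(): readout weight count must equal granule count",
         call. = FALSE)
  }
  if (any(granules$projection_index > n_projections(projections))) {
    stop("pl_network(): projection_index exceeds number of projections",
         call. = FALSE)
  }
  structure(list(projections = projections, granules = granules,
                 readout = readout),
            class = "pl_network")
}

#' @export
print.pl_network <- function(x, ...) {
  cat(sprintf(
    "<pl_network: %d granule unit(s) on %d projection(s) in %d-D input space>\n",
    length(x$granules$threshold), n_projections(x$projections),
    input_dim(x$projections)))
  invisible(x)
}

#' Activity of a single granule cell
#'
#' `ramp(gain * <direction, x> - threshold)`: the unit projects the raw input
#' onto its direction, scales by its lumped synaptic gain and rectifies at
#' its threshold.
#'
#' @param x numeric input vector (one point in raw-input space).
#' @param direction unit-norm direction vector of the same length.
#' @param gain scalar input gain.
#' @param threshold scalar threshold.
#' @return non-negative scalar activity.
#' @examples
#' grc_activity(c(1, 1), c(1, 1) / sqrt(2), gain = 1, threshold = 1)
#' @export
grc_activity <- function(x, direction, gain = 1, threshold = 0) {
  x <- as.numeric(x)
  direction <- as.numeric(direction)
  if (length(x) != length(direction)) {
    stop("grc_activity(): input and direction dimensions differ", call. = FALSE)
  }
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    stop("grc_activity(): direction must be unit norm", call. = FALSE)
  }
  ramp(gain * sum(direction * x) - threshold)
}

#' Purkinje-cell output for one vector of granule activities
#'
#' @param grc_activities numeric vector of non-negative granule activities.
#' @param readout a [purkinje_readout()] with matching weight count.
#' @return scalar: `baseline + sum(weights * activities)`.
#' @export
pc_output <- function(grc_activities, readout) {
  stopifnot(inherits(readout, "purkinje_readout"))
  g <- as.numeric(grc_activities)
  if (length(g) != length(readout$weights)) {
    stop("pc_output(): activity and weight lengths differ", call. = FALSE)
  }
  readout$baseline + sum(readout$weights * g)
}

#' Granule activity matrix over a set of points
#'
#' Rows are evaluation points, columns granule units.  This is the design
#' matrix of the linear readout problem (before the intercept column).
#'
#' @param net a [pl_network()].
#' @param points numeric matrix, M x d (a vector is taken as one point).
#' @return M x N matrix of non-negative activities.
#' @export
activity_matrix <- function(net, points) {
  stopifnot(inherits(net, "pl_network"))
  if (is.null(dim(points))) points <- matrix(as.numeric(points), nrow = 1L)
  points <- as.matrix(points)
  d <- input_dim(net$projections)
  if (ncol(points) != d) {
    stop("activity_matrix(): points have wrong dimension", call. = FALSE)
  }
  P <- points %*% t(net$projections$directions)           # M x q
  gr <- net$granules
  drive <- P[, gr$projection_index, drop = FALSE]         # M x N
  drive <- sweep(drive, 2L, gr$gain, "*")
  drive <- sweep(drive, 2L, gr$threshold, "-")
  pmax(drive, 0)
}

#' Evaluate a network at a set of points
#'
#' Vectorized composition of [grc_activity()] and [pc_output()].
#'
#' @inheritParams activity_matrix
#' @return numeric vector of length M of Purkinje outputs.
#' @export
evaluate_network <- function(net, points) {
  A <- activity_matrix(net, points)
  drop(A %*% net$readout$weights) + net$readout$baseline
}

#' @export
predict.pl_network <- function(object, newdata, ...) {
  evaluate_network(object, newdata)
}

#' Place granule thresholds along a projection
#'
#' Strategies for spreading thresholds over the observed range of projected
#' input values.  `uniform_range` is the stylized picture of graded tonic
#' inhibition spacing a redundant population evenly; `quantile` concentrates
#' knots where data are dense; `random_uniform` draws them i.i.d. over the
#' range.
#'
#' @param strategy one of `"uniform_range"`, `"quantile"`, `"random_uniform"`.
#' @param n number of thresholds (granule units) to place.
#' @param projected_values numeric vector of projected inputs whose range /
#'   distribution anchors the placement.
#' @param rng_seed integer seed for `random_uniform` (ignored otherwise).
#' @return numeric vector of `n` thresholds.
#' @export
place_thresholds <- function(strategy = c("uniform_range", "quantile",
                                          "random_uniform"),
                             n, projected_values, rng_seed = NULL) {
  strategy <- match.arg(strategy)
  n <- as.integer(n)
  if (n < 1L) stop("place_thresholds(): n must be >= 1", call. = FALSE)
  v <- as.numeric(projected_values)
  if (!length(v) || any(!is.finite(v))) {
    stop("place_thresholds(): projected values must be finite and non-empty",
         call. = FALSE)
  }
  lo <- min(v); hi <- max(v)
  if (strategy %in% c("uniform_range", "random_uniform") && hi <= lo) {
    stop("place_thresholds(): degenerate projected range (max <= min)",
         call. = FALSE)
  }
  switch(strategy,
    uniform_range = seq(lo, hi, length.out = n),
    quantile = unname(stats::quantile(v, probs = (seq_len(n) - 0.5) / n)),
    random_uniform = {
      draw <- function() sort(stats::runif(n, lo, hi))
      if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
    })
}

#' Serialize a network to JSON
#'
#' Doubles are written with full (17 significant digit) precision so the
#' round trip through [network_from_json()] is bit-stable.
#'
#' @param net a [pl_network()].
#' @param file optional path; if `NULL` the JSON string is returned.
#' @param metadata named list of extra fields (seed, term name, domain, ...).
#' @return the JSON string, invisibly when written to `file`.
#' @export
network_to_json <- function(net, file = NULL, metadata = list()) {
  stopifnot(inherits(net, "pl_network"))
  doc <- list(
    directions = net$projections$directions,
    projection_index = net$granules$projection_index,
    thresholds = net$granules$threshold,
    gains = net$granules$gain,
    weights = net$readout$weights,
    baseline = net$readout$baseline,
    metadata = metadata)
  js <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' Deserialize a network from JSON
#'
#' @param x a file path or a JSON string produced by [network_to_json()].
#' @return a [pl_network()]; the metadata list is attached as attribute
#'   `"metadata"`.
#' @export
network_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  net <- pl_network(
    projection_set(matrix(doc$directions, ncol = ncol(doc$directions))),
    granule_population(doc$projection_index, doc$thresholds, doc$gains),
    purkinje_readout(doc$weights, doc$baseline))
  attr(net, "metadata") <- doc$metadata
  net
}
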
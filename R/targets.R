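# Synthetic targets: the simplified non-linear interaction terms of the
# inverse dynamics of a planar two-joint arm, equidistant evaluation grids
# over their domains, and the zero-predictor normalization constant.
#
# The terms keep only the interaction structure (inertial coupling,
# centripetal, Coriolis); all mass/length coefficients are stripped, so the
# non-angle variables live on a dimensionless symmetric unit interval and
# every angle variable covers one full period of its trigonometric factor.

#' Construct a target function
#'
#' A named multivariate term with a closed-form semantics and a per-variable
#' domain.  Angle-typed variables must span exactly one full period (2*pi);
#' this guarantees the odd-symmetry properties the analysis relies on (e.g.
#' that the best raw-axis additive fit of a product-structured term is the
#' zero function).
#'
#' @param name identifier for the term.
#' @param fn function taking an M x d matrix of points (columns in the order
#'   of `domains`) and returning a length-M numeric vector.
#' @param domains d x 2 numeric matrix of per-variable closed intervals; row
#'   names are the variable names.
#' @param kinds character vector, `"angle"` or `"linear"` per variable.
#' @return object of class `target_function` with fields `name`, `arity`,
#'   `fn`, `domains`, `kinds`.
#' @export
target_function <- function(name, fn, domains, kinds = NULL) {
  domains <- as.matrix(domains)
  if (ncol(domains) != 2L) {
    stop("target_function(): domains must be a d x 2 matrix", call. = FALSE)
  }
  d <- nrow(domains)
  if (is.null(rownames(domains))) rownames(domains) <- paste0("x", seq_len(d))
  if (is.null(kinds)) kinds <- rep("linear", d)
  kinds <- match.arg(kinds, c("linear", "angle"), several.ok = TRUE)
  kinds <- rep_len(kinds, d)
  if (any(domains[, 2L] <= domains[, 1L])) {
    stop("target_function(): each domain must have positive length",
         call. = FALSE)
  }
  span <- domains[, 2L] - domains[, 1L]
  bad <- kinds == "angle" & abs(span - 2 * pi) > 1e-9
  if (any(bad)) {
    stop("target_function(): angle variables must span exactly one full period (2*pi): ",
         paste(rownames(domains)[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, arity = d, fn = fn, domains = domains,
                 kinds = kinds),
            class = "target_function")
}

#' @export
print.target_function <- function(x, ...) {
  cat(sprintf("<target_function '%s': %d variable(s)>\n", x$name, x$arity))
  for (i in seq_len(x$arity)) {
    cat(sprintf("  %s in [%.6g, %.6g] (%s)\n", rownames(x$domains)[i],
                x$domains[i, 1L], x$domains[i, 2L], x$kinds[i]))
  }
  invisible(x)
}

.term_names <- c("inertial2d", "centripetal2d", "product2d", "coriolis3d")

#' Canonical inverse-dynamics interaction terms
#'
#' The three types of non-linear dependency in the planar two-joint arm's
#' inverse dynamics, with constant coefficients removed:
#' \describe{
#'   \item{`inertial2d`}{inertial coupling `ddtheta * cos(theta)` — an
#'     acceleration times the cosine of the other joint's angle.}
#'   \item{`centripetal2d`}{centripetal `dtheta^2 * sin(theta)`.}
#'   \item{`product2d`}{pure velocity product `dtheta_e * dtheta_s`, the
#'     two-dimensional surrogate of the Coriolis interaction.}
#'   \item{`coriolis3d`}{Coriolis `dtheta_e * dtheta_s * sin(theta)`, the
#'     only three-variable term.}
#' }
#' Angles cover one full period `[-pi, pi]`; velocities and accelerations are
#' dimensionless on `[-1, 1]`.
#'
#' @param name one of `"inertial2d"`, `"centripetal2d"`, `"product2d"`,
#'   `"coriolis3d"`.
#' @return a [target_function()].
#' @examples
#' make_term("product2d")$fn(cbind(0.5, 0.5))
#' @export
make_term <- function(name) {
  if (length(name) != 1L || !name %in% .term_names) {
    stop("make_term(): unknown term '", paste(name, collapse = ","),
         "'; valid names: ", paste(.term_names, collapse = ", "),
         call. = FALSE)
  }
  ang <- c(-pi, pi)
  lin <- c(-1, 1)
  switch(name,
    inertial2d = target_function(
      name, function(X) X[, 1L] * cos(X[, 2L]),
      domains = matrix(c(lin, ang), nrow = 2L, byrow = TRUE,
                       dimnames = list(c("ddtheta_e", "theta_e"), NULL)),
      kinds = c("linear", "angle")),
    centripetal2d = target_function(
      name, function(X) X[, 1L]^2 * sin(X[, 2L]),
      domains = matrix(c(lin, ang), nrow = 2L, byrow = TRUE,
                       dimnames = list(c("dtheta_e", "theta_e"), NULL)),
      kinds = c("linear", "angle")),
    product2d = target_function(
      name, function(X) X[, 1L] * X[, 2L],
      domains = matrix(c(lin, lin), nrow = 2L, byrow = TRUE,
                       dimnames = list(c("dtheta_e", "dtheta_s"), NULL)),
      kinds = c("linear", "linear")),
    coriolis3d = target_function(
      name, function(X) X[, 1L] * X[, 2L] * sin(X[, 3L]),
      domains = matrix(c(lin, lin, ang), nrow = 3L, byrow = TRUE,
                       dimnames = list(c("dtheta_e", "dtheta_s", "theta_e"),
                                       NULL)),
      kinds = c("linear", "linear", "angle")))
}

#' Equidistant evaluation grid with target values
#'
#' Tensor-product lattice over the term's domain box, both endpoints
#' included on every axis, with the term evaluated at each lattice point.
#' The per-axis point sets are symmetric about the domain midpoint, which is
#' what makes the raw-axis additive fits of odd product-structured terms
#' degenerate to zero.
#'
#' @param term a [target_function()].
#' @param points_per_dim integer >= 2; default 21 for 2-D terms and 11 for
#'   3-D terms.
#' @return object of class `evaluation_grid` with fields `points`
#'   (M x d matrix, M = points_per_dim^d), `target_values` (length M),
#'   `points_per_dim`, `term_name`, `var_names`, `axes`.
#' @export
make_grid <- function(term, points_per_dim = NULL) {
  stopifnot(inherits(term, "target_function"))
  if (is.null(points_per_dim)) {
    points_per_dim <- if (term$arity >= 3L) 11L else 21L
  }
  points_per_dim <- as.integer(points_per_dim)
  if (points_per_dim < 2L) {
    stop("make_grid(): points_per_dim must be >= 2", call. = FALSE)
  }
  axes <- lapply(seq_len(term$arity), function(i) {
    seq(term$domains[i, 1L], term$domains[i, 2L], length.out = points_per_dim)
  })
  names(axes) <- rownames(term$domains)
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- list(NULL, rownames(term$domains))
  vals <- as.numeric(term$fn(pts))
  evaluation_grid(pts, vals, points_per_dim = points_per_dim,
                  term_name = term$name, axes = axes)
}

#' Low-level evaluation-grid constructor
#'
#' Used by [make_grid()] and by tests that need grids over custom targets
#' (for example a one-dimensional sine, or the output of a known network).
#'
#' @param points M x d matrix of lattice points.
#' @param target_values length-M numeric vector.
#' @param points_per_dim points per axis (bookkeeping).
#' @param term_name name of the generating term.
#' @param axes optional list of per-axis coordinate vectors.
#' @return object of class `evaluation_grid`.
#' @export
evaluation_grid <- function(points, target_values, points_per_dim = NA_integer_,
                            term_name = "custom", axes = NULL) {
  points <- as.matrix(points)
  target_values <- as.numeric(target_values)
  if (nrow(points) != length(target_values)) {
    stop("evaluation_grid(): point and value counts differ", call. = FALSE)
  }
  if (any(!is.finite(points)) || any(!is.finite(target_values))) {
    stop("evaluation_grid(): points and target values must be finite",
         call. = FALSE)
  }
  structure(list(points = points, target_values = target_values,
                 points_per_dim = as.integer(points_per_dim),
                 term_name = term_name,
                 var_names = colnames(points), axes = axes),
            class = "evaluation_grid")
}

#' @export
print.evaluation_grid <- function(x, ...) {
  cat(sprintf("<evaluation_grid '%s': %d points in %d-D (%s per axis)>\n",
              x$term_name, nrow(x$points), ncol(x$points),
              ifelse(is.na(x$points_per_dim), "?", x$points_per_dim)))
  invisible(x)
}

#' RMSE of the zero predictor (normalization constant)
#'
#' The root mean squared target value over the grid: the error an
#' approximation equal to zero everywhere would make.  Relative RMSEs are
#' reported as a proportion (or percentage) of this quantity.
#'
#' @param grid an [evaluation_grid()].
#' @return positive scalar.
#' @export
max_rmse <- function(grid) {
  stopifnot(inherits(grid, "evaluation_grid"))
  v <- grid$target_values
  if (all(v == 0)) {
    stop("max_rmse(): target is identically zero; relative RMSE undefined",
         call. = FALSE)
  }
  sqrt(mean(v^2))
}

#' Add Gaussian observation noise to a grid
#'
#' Robustness fixture: i.i.d. Gaussian perturbation of the target values.
#' The reference analyses are noise-free.
#'
#' @param grid an [evaluation_grid()].
#' @param sigma non-negative noise standard deviation.
#' @param rng_seed integer seed (reproducible).
#' @return a new `evaluation_grid` with perturbed target values.
#' @export
add_noise <- function(grid, sigma, rng_seed = NULL) {
  stopifnot(inherits(grid, "evaluation_grid"))
  sigma <- as.numeric(sigma)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("add_noise(): sigma must be a non-negative scalar", call. = FALSE)
  }
  if (sigma == 0) return(grid)
  m <- length(grid$target_values)
  eps <- if (is.null(rng_seed)) stats::rnorm(m, 0, sigma) else
    withr::with_seed(rng_seed, stats::rnorm(m, 0, sigma))
  out <- grid
  out$target_values <- grid$target_values + eps
  out
}

#' Export a grid as CSV
#'
#' One row per lattice point: the coordinates (header gives variable names)
#' followed by the target value.  Doubles are written with 17 significant
#' digits so re-reading reproduces them exactly.
#'
#' @param grid an [evaluation_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "evaluation_grid"))
  df <- as.data.frame(grid$points)
  if (is.null(grid$var_names)) {
    names(df) <- paste0("x", seq_len(ncol(grid$points)))
  }
  df$value <- grid$target_values
  .write_csv_full(df, path)
  invisible(path)
}

# full-precision CSV writer shared by the IO layer
.write_csv_full <- function(df, path) {
  fmt <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  out <- as.data.frame(fmt, stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
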
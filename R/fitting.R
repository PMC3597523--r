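# Estimation machinery.
#
# The readout is linear in its weights and baseline, so every fit uses
# variable projection: at each candidate setting of the non-linear
# parameters (thresholds, and optionally direction angles) the weights and
# baseline are solved in closed form by minimum-norm least squares, and only
# the non-linear parameters are searched.  Fixed-direction fits refine the
# thresholds by Levenberg-Marquardt on the residual vector; joint fits
# search direction angles plus thresholds with Nelder-Mead restarted around
# incumbents.

#' Fit configuration
#'
#' @param n_granules total number of granule units N (knots).
#' @param n_projections number of projections q; units are split as evenly
#'   as possible across projections, remainder to the lowest-indexed ones.
#' @param max_iterations simplex iteration cap per restart (joint fits).
#' @param max_lm_iterations Levenberg-Marquardt iteration cap (each
#'   iteration costs one finite-difference Jacobian, i.e. about one residual
#'   evaluation per threshold).
#' @param restarts number of perturbed restarts around the incumbent.
#' @param restart_perturbation standard deviation of the Gaussian
#'   perturbation applied to the incumbent parameter vector at each restart.
#' @param tolerance relative objective-change convergence tolerance (also
#'   the simplex `reltol`).
#' @param rng_seed integer seed governing every random draw of the fit.
#' @param optimize_directions whether directions are free (joint fit).
#' @param n_screen number of random direction sets screened (weights-only
#'   scoring) to choose the simplex starting point of a joint fit.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(n_granules = 60L, n_projections = 1L,
                       max_iterations = 10000L, max_lm_iterations = 100L,
                       restarts = 5L, restart_perturbation = 0.1,
                       tolerance = 1e-8, rng_seed = 1L,
                       optimize_directions = FALSE, n_screen = 40L) {
  cfg <- list(n_granules = as.integer(n_granules),
              n_projections = as.integer(n_projections),
              max_iterations = as.integer(max_iterations),
              max_lm_iterations = as.integer(max_lm_iterations),
              restarts = as.integer(restarts),
              restart_perturbation = as.numeric(restart_perturbation),
              tolerance = as.numeric(tolerance),
              rng_seed = as.integer(rng_seed),
              optimize_directions = isTRUE(optimize_directions),
              n_screen = as.integer(n_screen))
  if (cfg$n_projections < 1L || cfg$n_granules < cfg$n_projections) {
    stop("fit_config(): need N >= q >= 1", call. = FALSE)
  }
  if (cfg$max_iterations < 1L || cfg$restarts < 0L ||
      cfg$restart_perturbation <= 0) {
    stop("fit_config(): invalid iteration/restart settings", call. = FALSE)
  }
  structure(cfg, class = "fit_config")
}

#' Root mean squared error
#'
#' @param predicted,target numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
rmse <- function(predicted, target) {
  if (length(predicted) != length(target) || !length(target)) {
    stop("rmse(): vectors must be non-empty and of equal length",
         call. = FALSE)
  }
  sqrt(mean((predicted - target)^2))
}

#' Sample directions uniformly on the unit sphere
#'
#' Standard-normal vectors normalized to unit length: the isotropic model of
#' "random recombination" of raw inputs.
#'
#' @param d input dimensionality.
#' @param q number of directions.
#' @param rng_seed integer seed.
#' @return a [projection_set()].
#' @export
sample_random_directions <- function(d, q, rng_seed = NULL) {
  d <- as.integer(d); q <- as.integer(q)
  if (d < 1L || q < 1L) {
    stop("sample_random_directions(): need d >= 1 and q >= 1", call. = FALSE)
  }
  draw <- function() matrix(stats::rnorm(q * d), nrow = q)
  m <- if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
  projection_set(m, normalize = TRUE)
}

#' Raw-axis projection set
#'
#' The non-recombined baseline: one projection per raw input dimension,
#' along the coordinate axes.
#'
#' @param d input dimensionality.
#' @return a [projection_set()] with `d` directions.
#' @export
raw_axis_directions <- function(d) projection_set(diag(d))

# minimum-norm least squares via SVD; rank decided at a relative tolerance
.lstsq_minnorm <- function(X, y) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (!any(keep)) return(numeric(ncol(X)))
  drop(sv$v[, keep, drop = FALSE] %*%
         (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
}

# solve readout given a fixed activity matrix; returns readout + fit stats
.fit_linear <- function(A, y) {
  if (any(!is.finite(A))) {
    stop("solve_weights(): non-finite granule activities", call. = FALSE)
  }
  X <- cbind(1, A)
  beta <- .lstsq_minnorm(X, y)
  fitted <- drop(X %*% beta)
  list(readout = purkinje_readout(beta[-1L], beta[1L]),
       fitted = fitted, rmse = rmse(fitted, y))
}

# least-squares residual only, via pivoted QR (.lm.fit): much cheaper than
# the SVD and pivot-invariant, valid also for rank-deficient designs
.ls_residuals <- function(A, y) {
  if (any(!is.finite(A))) {
    stop("solve_weights(): non-finite granule activities", call. = FALSE)
  }
  .lm.fit(cbind(1, A), y)$residuals
}

#' Closed-form readout solve
#'
#' With directions, gains and thresholds frozen, the RMSE objective is
#' linear least squares in the weights and baseline; this returns its exact
#' minimizer (minimum-norm solution when the granule design is
#' rank-deficient).
#'
#' @param net a [pl_network()] (its current readout is ignored).
#' @param grid an [evaluation_grid()].
#' @return a [purkinje_readout()].
#' @export
solve_weights <- function(net, grid) {
  stopifnot(inherits(net, "pl_network"), inherits(grid, "evaluation_grid"))
  .fit_linear(activity_matrix(net, grid$points), grid$target_values)$readout
}

# split N units across q projections, remainder to the lowest-indexed
.allocate_units <- function(N, q) {
  base <- N %/% q
  extra <- N %% q
  base + as.integer(seq_len(q) <= extra)
}

# Threshold initialization per projection: equally spaced but strictly
# inside the projected range.  A threshold at (or above) the projected
# maximum leaves its unit silent everywhere, giving a zero Jacobian column
# the optimizer can never move, so initial knots must all be live.
.init_thresholds <- function(P, proj_idx) {
  th <- numeric(length(proj_idx))
  for (k in unique(proj_idx)) {
    sel <- proj_idx == k
    n <- sum(sel)
    v <- P[, k]
    th[sel] <- place_thresholds("uniform_range", n + 2L, v)[seq_len(n) + 1L]
  }
  th
}

.network_from_par <- function(directions, proj_idx, thresholds) {
  pl_network(directions,
             granule_population(proj_idx, thresholds, gain = 1),
             purkinje_readout(numeric(length(proj_idx)), 0))
}

# activities for projected values P (M x q) given unit assignment/thresholds
.activities <- function(P, proj_idx, thresholds) {
  drive <- P[, proj_idx, drop = FALSE]
  drive <- sweep(drive, 2L, thresholds, "-")
  pmax(drive, 0)
}

# Levenberg-Marquardt on a residual vector, finite-difference Jacobian.
# Accepts only improving steps, so the final cost never exceeds the initial.
.lm_minimize <- function(residual_fn, par, max_iter = 100L, tol = 1e-8) {
  r <- residual_fn(par)
  if (any(!is.finite(r))) {
    return(list(par = par, cost = Inf, converged = FALSE, iterations = 0L,
                diverged = TRUE))
  }
  cost <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  diverged <- FALSE
  it <- 0L
  npar <- length(par)
  while (it < max_iter) {
    it <- it + 1L
    J <- matrix(0, length(r), npar)
    for (j in seq_len(npar)) {
      h <- 1e-6 * max(1, abs(par[j]))
      pj <- par
      pj[j] <- pj[j] + h
      J[, j] <- (residual_fn(pj) - r) / h
    }
    if (any(!is.finite(J))) { diverged <- TRUE; break }
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    dd <- pmax(diag(JtJ), 1e-12)
    accepted <- FALSE
    while (lambda <= 1e12) {
      H <- JtJ
      diag(H) <- diag(JtJ) + lambda * dd
      delta <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        r_new <- residual_fn(par + drop(delta))
        cost_new <- sum(r_new^2)
        if (is.finite(cost_new) && cost_new < cost) {
          par <- par + drop(delta)
          improve <- (cost - cost_new) / max(cost, .Machine$double.xmin)
          r <- r_new
          cost <- cost_new
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          if (improve < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) { converged <- TRUE; break }
    if (converged) break
  }
  list(par = par, cost = cost, converged = converged, iterations = it,
       diverged = diverged)
}

.make_result <- function(network, grid, rmse_abs, n_evals, converged, seed,
                         term_name, config) {
  structure(list(network = network,
                 rmse_abs = rmse_abs,
                 rmse_rel = rmse_abs / max_rmse(grid),
                 n_objective_evals = as.integer(n_evals),
                 converged = isTRUE(converged),
                 seed = as.integer(seed),
                 term_name = term_name,
                 config = config),
            class = "approximation_result")
}

#' @export
print.approximation_result <- function(x, ...) {
  cat(sprintf(
    "<approximation_result '%s': rel. RMSE %.2f%% (abs %.4g), %d evals, %s>\n",
    x$term_name, 100 * x$rmse_rel, x$rmse_abs, x$n_objective_evals,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit thresholds and readout with frozen projection directions
#'
#' Minimizes the grid RMSE over granule thresholds and the linear readout,
#' with the projection directions fixed.  Thresholds are initialized by
#' `uniform_range` placement over the projected grid values and refined by
#' Levenberg-Marquardt on the residual vector; the weights and baseline are
#' re-solved in closed form at every candidate threshold vector (variable
#' projection).  Granule gains are fixed at 1: gain magnitude is redundant
#' with threshold and weight scale.
#'
#' The returned RMSE never exceeds that of the initialization.  If the
#' objective turns non-finite the fit is flagged `converged = FALSE` rather
#' than raising.
#'
#' @param term the [target_function()] being approximated (metadata only;
#'   the values come from `grid`).  May be `NULL`.
#' @param grid an [evaluation_grid()].
#' @param directions a [projection_set()] matching the grid dimension.
#' @param config a [fit_config()].
#' @return an object of class `approximation_result` with fields `network`,
#'   `rmse_abs`, `rmse_rel`, `n_objective_evals`, `converged`, `seed`.
#' @export
fit_fixed_directions <- function(term = NULL, grid, directions,
                                 config = fit_config()) {
  stopifnot(inherits(grid, "evaluation_grid"),
            inherits(directions, "projection_set"),
            inherits(config, "fit_config"))
  d <- ncol(grid$points)
  if (input_dim(directions) != d) {
    stop("fit_fixed_directions(): direction dimension does not match grid",
         call. = FALSE)
  }
  q <- n_projections(directions)
  N <- config$n_granules
  if (N < q) stop("fit_fixed_directions(): need N >= q", call. = FALSE)
  y <- grid$target_values
  P <- grid$points %*% t(directions$directions)
  proj_idx <- rep(seq_len(q), .allocate_units(N, q))
  th0 <- .init_thresholds(P, proj_idx)

  evals <- 0L
  residual_fn <- function(th) {
    evals <<- evals + 1L
    .ls_residuals(.activities(P, proj_idx, th), y)
  }
  r0 <- residual_fn(th0)
  cost0 <- sum(r0^2)
  opt <- .lm_minimize(residual_fn, th0, max_iter = config$max_lm_iterations,
                      tol = config$tolerance)
  th <- if (is.finite(opt$cost) && opt$cost <= cost0) opt$par else th0
  sol <- .fit_linear(.activities(P, proj_idx, th), y)
  net <- pl_network(directions,
                    granule_population(proj_idx, th, gain = 1),
                    sol$readout)
  .make_result(net, grid, sol$rmse, evals,
               converged = opt$converged && !opt$diverged,
               seed = config$rng_seed,
               term_name = if (is.null(term)) grid$term_name else term$name,
               config = config)
}

# --- direction <-> angle parameterization (unit norm by construction) -----

.dirs_to_angles <- function(D) {
  d <- ncol(D)
  if (d == 2L) {
    atan2(D[, 2L], D[, 1L])
  } else if (d == 3L) {
    as.numeric(t(cbind(atan2(D[, 2L], D[, 1L]),
                       acos(pmin(pmax(D[, 3L], -1), 1)))))
  } else {
    stop("direction angle parameterization supports 2-D and 3-D only",
         call. = FALSE)
  }
}

.angles_to_dirs <- function(ang, d) {
  if (d == 2L) {
    cbind(cos(ang), sin(ang))
  } else if (d == 3L) {
    az <- ang[seq(1L, length(ang), by = 2L)]
    pol <- ang[seq(2L, length(ang), by = 2L)]
    cbind(sin(pol) * cos(az), sin(pol) * sin(az), cos(pol))
  } else {
    stop("direction angle parameterization supports 2-D and 3-D only",
         call. = FALSE)
  }
}

.n_angles <- function(d, q) if (d == 2L) q else 2L * q

#' Jointly fit projection directions, thresholds and readout
#'
#' Derivative-free minimization of the grid RMSE over direction angles
#' (one angle per direction in 2-D, azimuth/polar pairs in 3-D, so unit norm
#' holds by construction) and granule thresholds, with the readout solved in
#' closed form inside every objective evaluation.  The simplex start is
#' chosen by screening `config$n_screen` random direction sets (scored with
#' uniform thresholds and solved weights) unless `init_directions` is given.
#' After each Nelder-Mead run the incumbent is perturbed by
#' `restart_perturbation` and re-optimized, keeping the best; the reported
#' RMSE is an upper bound on the global optimum.
#'
#' @inheritParams fit_fixed_directions
#' @param init_directions optional [projection_set()] starting directions
#'   (e.g. a warm start from a smaller fit).
#' @param init_thresholds optional starting thresholds (length
#'   `config$n_granules`, ordered by projection allocation).
#' @return an `approximation_result`.
#' @export
fit_joint <- function(term = NULL, grid, config = fit_config(),
                      init_directions = NULL, init_thresholds = NULL) {
  stopifnot(inherits(grid, "evaluation_grid"), inherits(config, "fit_config"))
  if (!config$optimize_directions) {
    stop("fit_joint(): config$optimize_directions must be TRUE", call. = FALSE)
  }
  d <- ncol(grid$points)
  q <- config$n_projections
  N <- config$n_granules
  y <- grid$target_values
  mrmse <- max_rmse(grid)
  proj_idx <- rep(seq_len(q), .allocate_units(N, q))
  na <- .n_angles(d, q)

  evals <- 0L
  objective <- function(par) {
    evals <<- evals + 1L
    D <- .angles_to_dirs(par[seq_len(na)], d)
    th <- par[-seq_len(na)]
    P <- grid$points %*% t(D)
    A <- .activities(P, proj_idx, th)
    r <- tryCatch(.ls_residuals(A, y), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(1e6 * mrmse)
    sqrt(mean(r^2))
  }

  # starting point: explicit warm start, or best of a random-direction screen
  if (is.null(init_directions)) {
    scores <- vapply(seq_len(max(config$n_screen, 1L)), function(i) {
      Dn <- sample_random_directions(d, q,
              rng_seed = .derive_seed_raw(config$rng_seed, 7L, i))
      P <- grid$points %*% t(Dn$directions)
      th <- .init_thresholds(P, proj_idx)
      sqrt(mean(.ls_residuals(.activities(P, proj_idx, th), y)^2))
    }, numeric(1))
    best_i <- which.min(scores)
    init_directions <- sample_random_directions(d, q,
      rng_seed = .derive_seed_raw(config$rng_seed, 7L, best_i))
  }
  D0 <- init_directions$directions
  if (ncol(D0) != d || nrow(D0) != q) {
    stop("fit_joint(): init_directions shape does not match config/grid",
         call. = FALSE)
  }
  if (is.null(init_thresholds)) {
    P0 <- grid$points %*% t(D0)
    init_thresholds <- .init_thresholds(P0, proj_idx)
  }
  par0 <- c(.dirs_to_angles(D0), init_thresholds)

  run_nm <- function(par) {
    stats::optim(par, objective, method = "Nelder-Mead",
                 control = list(maxit = config$max_iterations,
                                reltol = config$tolerance))
  }
  best <- run_nm(par0)
  if (best$value > objective(par0)) {  # guard: never worse than the start
    best <- list(par = par0, value = objective(par0), convergence = 1L)
  }
  any_converged <- best$convergence == 0L
  for (r in seq_len(config$restarts)) {
    par_r <- withr::with_seed(
      .derive_seed_raw(config$rng_seed, 11L, r),
      best$par + stats::rnorm(length(best$par), 0,
                              config$restart_perturbation))
    cand <- run_nm(par_r)
    any_converged <- any_converged || cand$convergence == 0L
    if (cand$value < best$value) best <- cand
  }

  D <- .angles_to_dirs(best$par[seq_len(na)], d)
  th <- best$par[-seq_len(na)]
  P <- grid$points %*% t(D)
  sol <- .fit_linear(.activities(P, proj_idx, th), y)
  net <- pl_network(projection_set(D, normalize = TRUE),
                    granule_population(proj_idx, th, gain = 1),
                    sol$readout)
  .make_result(net, grid, sol$rmse, evals, converged = any_converged,
               seed = config$rng_seed,
               term_name = if (is.null(term)) grid$term_name else term$name,
               config = config)
}

#' Serialize an approximation result to JSON
#'
#' Includes the configuration, seed, term name, absolute and relative RMSE
#' and the full network parameterization.
#'
#' @param result an `approximation_result`.
#' @param file optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
result_to_json <- function(result, file = NULL) {
  stopifnot(inherits(result, "approximation_result"))
  doc <- list(term = result$term_name,
              rmse_abs = result$rmse_abs,
              rmse_rel = result$rmse_rel,
              rmse_rel_percent = 100 * result$rmse_rel,
              n_objective_evals = result$n_objective_evals,
              converged = result$converged,
              seed = result$seed,
              config = unclass(result$config),
              directions = result$network$projections$directions,
              projection_index = result$network$granules$projection_index,
              thresholds = result$network$granules$threshold,
              weights = result$network$readout$weights,
              baseline = result$network$readout$baseline)
  js <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
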
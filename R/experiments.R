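# Experiment harness: random-projection RMSE distributions, the
# granule-count sweep with optimized directions, raw-signal baselines, and
# the granule-cell capacity (curse-of-dimensionality) arithmetic.

# deterministic per-repetition seed, a pure function of its inputs; exact in
# double arithmetic (all intermediates < 2^53) and always < 2^31
.derive_seed_raw <- function(master_seed, stream, index) {
  if (is.character(stream)) {
    u <- utf8ToInt(stream)
    stream <- sum(u * seq_along(u)) %% 1e6
  }
  s <- (as.numeric(master_seed) %% 2147483629) * 1000003 +
    as.numeric(stream) * 10007 + as.numeric(index) * 101
  as.integer(s %% 2147483629 + 1)
}

#' Derive a reproducible sub-seed
#'
#' Counter-style hash of (master seed, stream label, index): independent
#' streams for repetitions and experiment stages without global RNG state.
#'
#' @param master_seed integer master seed.
#' @param stream integer or character stream label.
#' @param index repetition counter.
#' @return an integer seed in `[1, 2^31)`.
#' @export
derive_seed <- function(master_seed, stream = 0L, index = 0L) {
  .derive_seed_raw(master_seed, stream, index)
}

#' Summary of one experiment box (one term, q, N)
#'
#' Box statistics follow the convention of the reference figures: the box
#' center is the mean (the median is recorded too), the box spans the 25th
#' to 75th percentile, whiskers reach the most extreme repetitions within
#' 1.5 interquartile ranges of the box, and anything beyond is an outlier.
#'
#' @param term_name term identifier.
#' @param q number of projections.
#' @param N total granule units.
#' @param rmse_rel per-repetition relative RMSEs (fractions of the
#'   zero-predictor RMSE).
#' @param seeds per-repetition seeds.
#' @param converged per-repetition convergence flags.
#' @param master_seed the master seed of the run.
#' @return object of class `experiment_summary`.
#' @export
experiment_summary <- function(term_name, q, N, rmse_rel, seeds = NULL,
                               converged = NULL, master_seed = NA_integer_) {
  x <- as.numeric(rmse_rel)
  if (any(x < 0)) stop("experiment_summary(): negative RMSE", call. = FALSE)
  q25 <- unname(stats::quantile(x, 0.25))
  q75 <- unname(stats::quantile(x, 0.75))
  iqr <- q75 - q25
  inside <- x >= q25 - 1.5 * iqr & x <= q75 + 1.5 * iqr
  structure(list(
    term_name = term_name, q = as.integer(q), N = as.integer(N),
    n_repetitions = length(x), rmse_rel = x,
    seeds = seeds, converged = converged,
    master_seed = master_seed,
    stats = list(mean = mean(x), median = stats::median(x),
                 q25 = q25, q75 = q75,
                 whisker_low = min(x[inside]), whisker_high = max(x[inside]),
                 outliers = x[!inside],
                 best = min(x), worst = max(x))),
    class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<experiment_summary '%s' q=%d N=%d (%d reps): mean %.1f%%, box [%.1f, %.1f]%%, best %.1f%%, worst %.1f%%>\n",
    x$term_name, x$q, x$N, x$n_repetitions, 100 * s$mean, 100 * s$q25,
    100 * s$q75, 100 * s$best, 100 * s$worst))
  invisible(x)
}

#' @export
print.experiment_summary_list <- function(x, ...) {
  for (s in x) print(s)
  invisible(x)
}

#' Box plot of experiment summaries
#'
#' @param x a list of [experiment_summary()] objects.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.experiment_summary_list <- function(x, ...) {
  vals <- lapply(x, function(s) 100 * s$rmse_rel)
  names(vals) <- vapply(x, function(s) sprintf("q=%d", s$q), character(1))
  graphics::boxplot(vals, ylab = "relative RMSE (%)",
                    xlab = "number of projections", ...)
  invisible(x)
}

#' Random-projection approximation experiment
#'
#' For each entry of `q_list`, performs `n_reps` independent
#' [fit_fixed_directions()] runs with freshly sampled random directions
#' (uniform on the sphere), 60 granule units by default, and summarizes the
#' relative RMSE distribution.  Per-repetition seeds are a pure function of
#' the master seed, so any summary can be replayed exactly.  Non-converged
#' repetitions are kept and flagged, never dropped.
#'
#' @param term a [target_function()].
#' @param q_list integer vector of projection counts.
#' @param n_reps repetitions per box.
#' @param N total granule units.
#' @param master_seed integer master seed.
#' @param grid optional pre-built [evaluation_grid()] (defaults to
#'   `make_grid(term)`).
#' @param config optional [fit_config()] template; its `n_granules` /
#'   `n_projections` / `rng_seed` are overridden per repetition.
#' @return a list of [experiment_summary()] (class
#'   `experiment_summary_list`).
#' @export
run_random_projection_experiment <- function(term, q_list, n_reps = 20L,
                                             N = 60L, master_seed = 1L,
                                             grid = NULL, config = NULL) {
  stopifnot(inherits(term, "target_function"))
  if (n_reps < 1L) {
    stop("run_random_projection_experiment(): n_reps must be >= 1",
         call. = FALSE)
  }
  if (is.null(grid)) grid <- make_grid(term)
  if (is.null(config)) config <- fit_config()
  d <- term$arity
  out <- lapply(as.integer(q_list), function(q) {
    seeds <- vapply(seq_len(n_reps), function(i) {
      .derive_seed_raw(master_seed, paste0("randproj-q", q), i)
    }, integer(1))
    fits <- lapply(seeds, function(s) {
      cfg <- config
      cfg$n_granules <- as.integer(N)
      cfg$n_projections <- q
      cfg$rng_seed <- s
      dirs <- sample_random_directions(d, q, rng_seed = s)
      fit_fixed_directions(term, grid, dirs, cfg)
    })
    experiment_summary(term$name, q, N,
                       rmse_rel = vapply(fits, `[[`, numeric(1), "rmse_rel"),
                       seeds = seeds,
                       converged = vapply(fits, `[[`, logical(1), "converged"),
                       master_seed = master_seed)
  })
  structure(out, class = "experiment_summary_list")
}

#' Random-projection experiment on the three-dimensional term
#'
#' Same protocol as [run_random_projection_experiment()] but over the
#' three-dimensional evaluation grid of a 3-variable term (the Coriolis
#' interaction).
#'
#' @inheritParams run_random_projection_experiment
#' @return an `experiment_summary_list`.
#' @export
run_3d_random_experiment <- function(term, q_list, n_reps = 20L, N = 60L,
                                     master_seed = 1L, grid = NULL,
                                     config = NULL) {
  stopifnot(inherits(term, "target_function"))
  if (term$arity != 3L) {
    stop("run_3d_random_experiment(): term must be three-dimensional",
         call. = FALSE)
  }
  run_random_projection_experiment(term, q_list, n_reps, N, master_seed,
                                   grid = grid, config = config)
}

#' Raw-signal baseline fit
#'
#' Fits the term with the projection directions fixed to the raw coordinate
#' axes (no recombination of inputs): the degenerate reference the
#' recombination hypothesis is compared against.
#'
#' @inheritParams run_random_projection_experiment
#' @param config a [fit_config()]; `n_projections` is forced to the input
#'   dimension.
#' @return an `approximation_result`.
#' @export
raw_signal_baseline <- function(term, grid = NULL, N = 60L,
                                config = fit_config()) {
  stopifnot(inherits(term, "target_function"))
  if (is.null(grid)) grid <- make_grid(term)
  config$n_granules <- as.integer(N)
  config$n_projections <- term$arity
  fit_fixed_directions(term, grid, raw_axis_directions(term$arity), config)
}

#' Granule-count sweep with optimized directions
#'
#' Best-of-restarts joint fit ([fit_joint()]) at each granule count in
#' `N_list` (increasing).  Each larger-N fit is warm-started from the
#' smaller-N incumbent: the incumbent's directions are kept and its
#' thresholds padded with fresh uniformly spaced ones, so the starting value
#' can never exceed the previous optimum and the reported curve is monotone
#' non-increasing.  A fresh screened fit is run as well and the better of
#' the two is kept.
#'
#' @param term a [target_function()].
#' @param q number of projections.
#' @param N_list increasing vector of total granule counts.
#' @param config a [fit_config()] template (`optimize_directions` forced on).
#' @param grid optional [evaluation_grid()].
#' @return a `data.frame` with columns `N`, `rmse_rel`, `rmse_abs`,
#'   `converged`; the full `approximation_result`s are attached as
#'   attribute `"results"`.
#' @export
run_grc_sweep <- function(term, q, N_list, config = fit_config(),
                          grid = NULL) {
  stopifnot(inherits(term, "target_function"))
  N_list <- as.integer(N_list)
  if (is.unsorted(N_list, strictly = TRUE)) {
    stop("run_grc_sweep(): N_list must be strictly increasing", call. = FALSE)
  }
  if (any(N_list < q)) {
    stop("run_grc_sweep(): every N must be >= q", call. = FALSE)
  }
  if (is.null(grid)) grid <- make_grid(term)
  results <- vector("list", length(N_list))
  prev <- NULL
  for (i in seq_along(N_list)) {
    N <- N_list[i]
    cfg <- config
    cfg$n_granules <- N
    cfg$n_projections <- as.integer(q)
    cfg$optimize_directions <- TRUE
    cfg$rng_seed <- .derive_seed_raw(config$rng_seed, "grc-sweep", i)
    fresh <- fit_joint(term, grid, cfg)
    best <- fresh
    if (!is.null(prev)) {
      warm <- fit_joint(term, grid, cfg,
                        init_directions = prev$network$projections,
                        init_thresholds = .pad_thresholds(prev$network, N,
                                                          grid))
      if (warm$rmse_abs < best$rmse_abs) best <- warm
      if (prev$rmse_abs < best$rmse_abs) best <- prev_padded_result(prev, best)
    }
    results[[i]] <- best
    prev <- best
  }
  df <- data.frame(
    N = N_list,
    rmse_rel = vapply(results, `[[`, numeric(1), "rmse_rel"),
    rmse_abs = vapply(results, `[[`, numeric(1), "rmse_abs"),
    converged = vapply(results, `[[`, logical(1), "converged"))
  attr(df, "results") <- results
  df
}

# pad a smaller network's thresholds out to N units, preserving the
# incumbent knots per projection and filling with uniform_range placement
.pad_thresholds <- function(net, N, grid) {
  q <- n_projections(net$projections)
  P <- grid$points %*% t(net$projections$directions)
  alloc <- .allocate_units(N, q)
  th <- numeric(0)
  for (k in seq_len(q)) {
    old <- net$granules$threshold[net$granules$projection_index == k]
    n_new <- alloc[k] - length(old)
    extra <- if (n_new > 0) {
      place_thresholds("uniform_range", n_new, P[, k])
    } else numeric(0)
    th <- c(th, c(old, extra)[seq_len(alloc[k])])
  }
  th
}

# carry the previous incumbent forward unchanged when neither warm nor
# fresh fit at the larger N improved on it (keeps the curve monotone)
prev_padded_result <- function(prev, larger) {
  out <- prev
  out$config <- larger$config
  out
}

#' Granule-cell capacity arithmetic
#'
#' The curse-of-dimensionality bookkeeping: a budget of `total_cells`
#' granule cells spread over a `dimensions`-dimensional tensor-product input
#' lattice affords `total_cells^(1/dimensions)` knots per dimension, and
#' keeping that per-dimension resolution while adding `extra_dimensions`
#' more inputs requires `total_cells^((dimensions + extra) / dimensions)`
#' cells.
#'
#' @param total_cells granule-cell budget (e.g. `1e10` for hand control).
#' @param dimensions number of input dimensions (e.g. 20 hand DOFs).
#' @param extra_dimensions additional dimensions at equal resolution.
#' @return object of class `capacity_report` with fields `total_cells`,
#'   `dimensions`, `knots_per_dim`, `knots_rounded`, `extra_dimensions`,
#'   `cells_needed`.
#' @examples
#' capacity_report(1e10, 20, extra_dimensions = 2)
#' @export
capacity_report <- function(total_cells, dimensions, extra_dimensions = 0) {
  if (total_cells < 1 || dimensions < 1 || extra_dimensions < 0) {
    stop("capacity_report(): counts must be positive", call. = FALSE)
  }
  knots <- total_cells^(1 / dimensions)
  structure(list(
    total_cells = total_cells,
    dimensions = dimensions,
    knots_per_dim = knots,
    knots_rounded = round(knots),
    extra_dimensions = extra_dimensions,
    cells_needed = total_cells^((dimensions + extra_dimensions) / dimensions)),
    class = "capacity_report")
}

#' Cells needed for an arbitrary dimension count at equal resolution
#'
#' @param report a [capacity_report()].
#' @param dimensions target dimension count.
#' @return number of cells: `total_cells^(dimensions / report$dimensions)`.
#' @export
cells_for_dimensions <- function(report, dimensions) {
  stopifnot(inherits(report, "capacity_report"))
  report$total_cells^(dimensions / report$dimensions)
}

#' @export
print.capacity_report <- function(x, ...) {
  cat(sprintf(
    "<capacity_report: %.3g cells over %d dims -> %.2f knots/dim (~%d)",
    x$total_cells, x$dimensions, x$knots_per_dim, x$knots_rounded))
  if (x$extra_dimensions > 0) {
    cat(sprintf("; +%d dims needs %.3g cells", x$extra_dimensions,
                x$cells_needed))
  }
  cat(">\n")
  invisible(x)
}
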
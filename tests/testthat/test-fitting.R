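test_that("rmse matches the loop-summation oracle", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  withr::with_seed(21, {
    p <- rnorm(100)
    t <- rnorm(100)
    acc <- 0
    for (i in 1:100) acc <- acc + (p[i] - t[i])^2  # brute force
    expect_equal(rmse(p, t), sqrt(acc / 100), tolerance = 1e-12)
  })
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("sample_random_directions is unit-norm, seeded and isotropic", {
  ps <- sample_random_directions(3, 10, rng_seed = 4)
  expect_true(all(abs(sqrt(rowSums(ps$directions^2)) - 1) < 1e-9))
  expect_identical(sample_random_directions(3, 10, rng_seed = 4)$directions,
                   ps$directions)
  # 2-D angles uniform on [0, 2*pi): chi-square at alpha = 0.01
  big <- sample_random_directions(2, 10000, rng_seed = 8)$directions
  ang <- atan2(big[, 2], big[, 1]) %% (2 * pi)
  counts <- table(cut(ang, breaks = seq(0, 2 * pi, length.out = 13)))
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("solve_weights is the exact least-squares readout", {
  # target identically zero -> minimum-norm solution is all zeros
  net <- toy_network(matrix(1, 1, 1), c(1, 1, 1), c(-0.5, 0, 0.5),
                     rep(0, 3))
  gz <- line_grid(function(x) rep(0, length(x)), -1, 1, 21)
  ro <- solve_weights(net, gz)
  expect_equal(ro$weights, rep(0, 3))
  expect_equal(ro$baseline, 0)

  # realizable target recovered with zero error
  withr::with_seed(10, {
    true_net <- toy_network(sample_random_directions(2, 2, 10)$directions,
                            c(1, 1, 2, 2), runif(4, -1, 1), rnorm(4),
                            baseline = 0.4)
  })
  g <- network_grid(true_net, 15)
  ro <- solve_weights(true_net, g)
  fitted <- evaluate_network(
    pl_network(true_net$projections, true_net$granules, ro), g$points)
  expect_lt(rmse(fitted, g$target_values), 1e-10)

  # dense knots approximate sin to better than 1% relative RMSE
  gs <- line_grid(sin, -pi, pi, 201)
  th <- place_thresholds("uniform_range", 30, gs$points[, 1])
  net30 <- toy_network(matrix(1, 1, 1), rep(1, 30), th, rep(0, 30))
  ro <- solve_weights(net30, gs)
  fitted <- evaluate_network(
    pl_network(net30$projections, net30$granules, ro), gs$points)
  expect_lt(rmse(fitted, gs$target_values) / max_rmse(gs), 0.01)
})

test_that("closed-form weight solve agrees with a generic optimizer", {
  # linearity oracle: frozen thresholds, BFGS over (baseline, weights)
  gs <- line_grid(sin, -pi, pi, 41)
  th <- place_thresholds("uniform_range", 8, gs$points[, 1])
  net <- toy_network(matrix(1, 1, 1), rep(1, 8), th, rep(0, 8))
  A <- activity_matrix(net, gs$points)
  y <- gs$target_values
  obj <- function(b) rmse(drop(cbind(1, A) %*% b), y)
  opt <- stats::optim(rep(0, 9), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  ro <- solve_weights(net, gs)
  closed <- rmse(drop(cbind(1, A) %*% c(ro$baseline, ro$weights)), y)
  expect_lt(abs(opt$value - closed) / closed, 1e-6)
})

test_that("doubling uniformly placed knots shrinks the sin RMSE fast", {
  # empirical form of the inverse-square knot-error bound
  gs <- line_grid(sin, -pi, pi, 401)
  err <- function(N) {
    th <- place_thresholds("uniform_range", N, gs$points[, 1])
    net <- toy_network(matrix(1, 1, 1), rep(1, N), th, rep(0, N))
    ro <- solve_weights(net, gs)
    rmse(evaluate_network(pl_network(net$projections, net$granules, ro),
                          gs$points), gs$target_values)
  }
  expect_lt(err(16) / err(8), 0.3)
  expect_lt(err(32) / err(16), 0.3)
})

test_that("fit_fixed_directions refines thresholds without regressing", {
  # realizable target: 1 projection, 2 knots
  true_net <- toy_network(matrix(c(0.6, 0.8), 1), c(1, 1), c(-0.3, 0.4),
                          c(1, -2), baseline = 0.1)
  g <- network_grid(true_net, 21)
  cfg <- fit_config(n_granules = 2, n_projections = 1)
  res <- fit_fixed_directions(NULL, g, true_net$projections, cfg)
  expect_lt(res$rmse_abs, 1e-6)
  expect_s3_class(res, "approximation_result")
  expect_equal(res$rmse_rel, res$rmse_abs / max_rmse(g), tolerance = 1e-12)

  # order statistics within one run: best < worst over random directions
  term <- make_term("centripetal2d")
  grid <- make_grid(term)
  cfg <- fit_config(n_granules = 30, n_projections = 1,
                    max_lm_iterations = 10)
  rel <- vapply(1:12, function(i) {
    dirs <- sample_random_directions(2, 1, rng_seed = 100 + i)
    fit_fixed_directions(term, grid, dirs, cfg)$rmse_rel
  }, numeric(1))
  expect_lt(min(rel), max(rel))
  # feasibility ceiling: zero weights always available
  expect_true(all(rel <= 1 + 1e-9))
})

test_that("enlarging a nested design never increases the solved RMSE", {
  term <- make_term("centripetal2d")
  grid <- make_grid(term, 15)
  dirs2 <- projection_set(rbind(dir2(35), dir2(125)))
  P <- grid$points %*% t(dirs2$directions)
  th1 <- place_thresholds("uniform_range", 10, P[, 1])
  solved_rmse <- function(idx, th, dirs) {
    net <- pl_network(dirs, granule_population(idx, th),
                      purkinje_readout(numeric(length(idx)), 0))
    ro <- solve_weights(net, grid)
    rmse(evaluate_network(pl_network(dirs, net$granules, ro), grid$points),
         grid$target_values)
  }
  # N nesting: same projection, superset of thresholds
  e10 <- solved_rmse(rep(1, 10), th1, dirs2)
  th_extra <- place_thresholds("random_uniform", 5, P[, 1], rng_seed = 2)
  e15 <- solved_rmse(rep(1, 15), c(th1, th_extra), dirs2)
  expect_lte(e15, e10 + 1e-12)
  # q nesting: add a second direction with its own units
  th2 <- place_thresholds("uniform_range", 10, P[, 2])
  e2q <- solved_rmse(rep(1:2, each = 10), c(th1, th2), dirs2)
  expect_lte(e2q, e10 + 1e-12)
})

test_that("rotating the product term's projections leaves the RMSE invariant", {
  term <- make_term("product2d")
  grid <- make_grid(term)
  cfg <- fit_config(n_granules = 20, n_projections = 2,
                    max_lm_iterations = 20)
  base <- projection_set(rbind(dir2(45), dir2(-45)))
  rot90 <- projection_set(rbind(dir2(135), dir2(45)))

  # exact form: with identical threshold placement the rotated problem is
  # isomorphic (columns permute, target negates), so the solved RMSE matches
  solved <- function(dirs) {
    P <- grid$points %*% t(dirs$directions)
    idx <- rep(1:2, each = 10)
    th <- c(place_thresholds("uniform_range", 10, P[, 1]),
            place_thresholds("uniform_range", 10, P[, 2]))
    net <- pl_network(dirs, granule_population(idx, th),
                      purkinje_readout(numeric(20), 0))
    ro <- solve_weights(net, grid)
    rmse(evaluate_network(pl_network(dirs, net$granules, ro), grid$points),
         grid$target_values)
  }
  expect_equal(solved(base), solved(rot90), tolerance = 1e-10)

  # full fits agree up to optimizer noise
  r1 <- fit_fixed_directions(term, grid, base, cfg)
  r2 <- fit_fixed_directions(term, grid, rot90, cfg)
  expect_equal(r1$rmse_rel, r2$rmse_rel, tolerance = 1e-3)
})

test_that("fit_joint recovers a one-projection ridge target", {
  withr::with_seed(17, {
    true_net <- toy_network(matrix(dir2(25), 1), rep(1, 6),
                            seq(-1.1, 1.1, length.out = 6),
                            c(1, -0.8, 0.6, 0.5, -0.7, 0.4), baseline = 0.3)
  })
  g <- network_grid(true_net, 21)
  cfg <- fit_config(n_granules = 6, n_projections = 1,
                    optimize_directions = TRUE, max_iterations = 3000,
                    restarts = 3, rng_seed = 2, n_screen = 30)
  res <- fit_joint(NULL, g, cfg)
  fitted_axis <- axis_deg(res$network$projections$directions[1, ])
  expect_lt(axis_diff_deg(fitted_axis, 25), 5)
  expect_lt(res$rmse_rel, 0.05)
  expect_error(fit_joint(NULL, g, fit_config(optimize_directions = FALSE)),
               "optimize_directions")
})

test_that("seeding the product fit at the diagonals keeps them and fits well", {
  # v1*v2 = ((v1+v2)^2 - (v1-v2)^2) / 4: diagonal projections suffice
  term <- make_term("product2d")
  grid <- make_grid(term)
  cfg <- fit_config(n_granules = 24, n_projections = 2,
                    optimize_directions = TRUE, max_iterations = 1500,
                    restarts = 1, rng_seed = 3)
  res <- fit_joint(term, grid, cfg,
                   init_directions = projection_set(rbind(dir2(45),
                                                          dir2(-45))))
  expect_lt(res$rmse_rel, 0.15)
  axes <- apply(res$network$projections$directions, 1, axis_deg)
  expect_lt(axis_diff_deg(axes[1], 45), 10)
  expect_lt(axis_diff_deg(axes[2], 135), 10)
})

test_that("approximation results serialize to JSON with full telemetry", {
  term <- make_term("product2d")
  grid <- make_grid(term, 11)
  cfg <- fit_config(n_granules = 8, n_projections = 2, rng_seed = 12,
                    max_lm_iterations = 5)
  res <- fit_fixed_directions(term, grid,
                              sample_random_directions(2, 2, 12), cfg)
  doc <- jsonlite::fromJSON(result_to_json(res))
  expect_equal(doc$term, "product2d")
  expect_equal(doc$rmse_rel, res$rmse_rel)
  expect_equal(doc$seed, 12)
  expect_length(doc$thresholds, 8)
  expect_length(doc$weights, 8)
})
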
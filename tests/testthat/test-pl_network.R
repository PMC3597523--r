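test_that("ramp is the rectifier and rejects non-finite drive", {
  expect_identical(ramp(0), 0)
  expect_identical(ramp(-3.7), 0)
  expect_identical(ramp(2.5), 2.5)
  expect_equal(ramp(c(-1, 0, 0.5)), c(0, 0, 0.5))
  expect_error(ramp(NaN), "non-finite")
  expect_error(ramp(c(1, Inf)), "non-finite")
  expect_error(ramp("a"), "numeric")
})

test_that("grc_activity projects, scales and rectifies", {
  expect_equal(grc_activity(c(1, 0), c(1, 0), gain = 1, threshold = 0), 1)
  expect_equal(grc_activity(c(1, 1), c(0, 1), gain = 2, threshold = 5), 0)
  expect_equal(grc_activity(c(1, 1), c(1, 1) / sqrt(2), gain = 1,
                            threshold = 1), sqrt(2) - 1)
  expect_error(grc_activity(c(1, 1, 1), c(1, 0), 1, 0), "dimension")
  expect_error(grc_activity(c(1, 1), c(1, 1), 1, 0), "unit norm")
})

test_that("pc_output is the signed affine readout", {
  expect_equal(pc_output(rep(0, 4), purkinje_readout(rep(1, 4), 0.5)), 0.5)
  expect_equal(pc_output(2, purkinje_readout(-0.5, 1)), 0)
  withr::with_seed(99, {
    g <- runif(10)
    w <- rnorm(10)
    b <- rnorm(1)
    acc <- b
    for (j in 1:10) acc <- acc + w[j] * g[j]  # element-by-element oracle
    expect_equal(pc_output(g, purkinje_readout(w, b)), acc, tolerance = 1e-12)
  })
  expect_error(pc_output(1:3, purkinje_readout(1:2, 0)), "length")
})

test_that("evaluate_network composes activities and readout pointwise", {
  # zero weights -> constant baseline
  net0 <- toy_network(diag(2), c(1, 2), c(0, 0), c(0, 0), baseline = 0.7)
  pts <- as.matrix(expand.grid(seq(-1, 1, 0.5), seq(-1, 1, 0.5)))
  expect_equal(evaluate_network(net0, pts), rep(0.7, nrow(pts)))

  # x = ramp(x) - ramp(-x): identity encoded with two opposed units
  id_net <- toy_network(matrix(c(1, -1), ncol = 1), c(1, 2), c(0, 0),
                        c(1, -1))
  x <- seq(-1, 1, length.out = 41)
  expect_equal(evaluate_network(id_net, matrix(x, ncol = 1)), x,
               tolerance = 1e-12)

  # dimension mismatch errors
  expect_error(evaluate_network(net0, matrix(1, 1, 3)), "dimension")
})

test_that("network output along a line is piecewise linear with <= N knots", {
  # 1 projection, 2 knots: second differences vanish away from thresholds
  net <- toy_network(matrix(1, 1, 1), c(1, 1), c(-0.4, 0.3), c(1.5, -2),
                     baseline = 0.2)
  x <- seq(-1, 1, length.out = 201)
  f <- evaluate_network(net, matrix(x, ncol = 1))
  d2 <- diff(f, differences = 2)
  kinks <- sum(abs(d2) > 1e-9 * max(abs(f)))
  # each knot can bend at most 2 consecutive second differences
  expect_lte(kinks, 2 * 2)

  # random multi-projection networks along random lines, knot-count bound
  for (s in 1:5) {
    withr::with_seed(s, {
      N <- 8L
      dirs <- sample_random_directions(2, 3, rng_seed = s)
      net <- pl_network(dirs,
                        granule_population(sample(1:3, N, TRUE),
                                           runif(N, -1, 1)),
                        purkinje_readout(rnorm(N), rnorm(1)))
      p0 <- runif(2, -1, 1)
      v <- rnorm(2); v <- v / sqrt(sum(v^2))
      tt <- seq(-2, 2, length.out = 401)
      line <- cbind(p0[1] + tt * v[1], p0[2] + tt * v[2])
      f <- evaluate_network(net, line)
      d2 <- diff(f, differences = 2)
      kinks <- sum(abs(d2) > 1e-8 * max(1, max(abs(f))))
      expect_lte(kinks, 2 * N)
    })
  }
})

test_that("granule activities are non-negative for random inputs", {
  for (s in 1:5) {
    withr::with_seed(s, {
      N <- 12L
      dirs <- sample_random_directions(3, 4, rng_seed = s + 100)
      net <- pl_network(dirs,
                        granule_population(sample(1:4, N, TRUE),
                                           rnorm(N), gain = runif(N, 0.5, 2)),
                        purkinje_readout(rnorm(N), 0))
      pts <- matrix(rnorm(50 * 3), ncol = 3)
      expect_true(all(activity_matrix(net, pts) >= 0))
    })
  }
})

test_that("place_thresholds implements the three strategies", {
  v <- seq(0, 1, length.out = 11)
  expect_equal(place_thresholds("uniform_range", 3, v), c(0, 0.5, 1))
  expect_equal(place_thresholds("quantile", 1, c(1, 2, 3, 4, 100)), 3)
  r1 <- place_thresholds("random_uniform", 5, v, rng_seed = 7)
  r2 <- place_thresholds("random_uniform", 5, v, rng_seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 <= 1))
  expect_error(place_thresholds("uniform_range", 3, rep(2, 5)), "degenerate")
  expect_error(place_thresholds("uniform_range", 0, v), "n must be")
})

test_that("network JSON serialization round-trips bit-stably", {
  withr::with_seed(3, {
    net <- toy_network(sample_random_directions(2, 2, 3)$directions,
                       c(1, 1, 2, 2), rnorm(4), rnorm(4),
                       baseline = rnorm(1), gains = runif(4, 0.5, 2))
  })
  js <- network_to_json(net, metadata = list(seed = 3, term = "demo"))
  back <- network_from_json(js)
  expect_identical(back$projections$directions,
                   unname(net$projections$directions))
  expect_identical(back$granules$threshold, net$granules$threshold)
  expect_identical(back$granules$gain, net$granules$gain)
  expect_identical(back$readout$weights, net$readout$weights)
  expect_identical(back$readout$baseline, net$readout$baseline)
  expect_equal(attr(back, "metadata")$term, "demo")

  # file round trip
  p <- withr::local_tempfile(fileext = ".json")
  network_to_json(net, file = p)
  expect_identical(network_from_json(p)$granules$threshold,
                   net$granules$threshold)
})

test_that("constructors enforce their invariants", {
  expect_error(projection_set(matrix(c(1, 1), 1)), "unit norm")
  expect_s3_class(projection_set(matrix(c(1, 1), 1), normalize = TRUE),
                  "projection_set")
  expect_error(granule_population(c(1, 2), c(0, NA)), "finite")
  expect_error(purkinje_readout(c(1, Inf), 0), "finite")
  expect_error(pl_network(projection_set(diag(2)),
                          granule_population(c(1, 3), c(0, 0)),
                          purkinje_readout(c(1, 1), 0)),
               "projection_index")
  expect_error(pl_network(projection_set(diag(2)),
                          granule_population(c(1, 2), c(0, 0)),
                          purkinje_readout(1, 0)),
               "weight count")
})
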
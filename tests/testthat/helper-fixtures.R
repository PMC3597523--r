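# shared fixture builders (all data generated in code)

# 1-D equidistant grid over [lo, hi] with fn values attached
line_grid <- function(fn, lo, hi, m, name = "line") {
  x <- seq(lo, hi, length.out = m)
  evaluation_grid(matrix(x, ncol = 1L, dimnames = list(NULL, "x")),
                  fn(x), points_per_dim = m, term_name = name)
}

# quick network builder (directions normalized for convenience)
toy_network <- function(directions, proj_idx, thresholds, weights,
                        baseline = 0, gains = 1) {
  pl_network(projection_set(as.matrix(directions), normalize = TRUE),
             granule_population(proj_idx, thresholds, gains),
             purkinje_readout(weights, baseline))
}

# 2-D direction from an angle in degrees
dir2 <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))

# axis angle (degrees, in [0, 180)) of a 2-D direction
axis_deg <- function(v) (atan2(v[2L], v[1L]) * 180 / pi) %% 180

# separation of two axes in degrees (modulo 180, sign-insensitive)
axis_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# grid whose target is the output of a known network (realizable target)
network_grid <- function(net, points_per_dim = 21L, lo = -1, hi = 1) {
  ax <- seq(lo, hi, length.out = points_per_dim)
  d <- ncol(net$projections$directions)
  pts <- as.matrix(expand.grid(rep(list(ax), d)))
  colnames(pts) <- paste0("x", seq_len(d))
  evaluation_grid(pts, evaluate_network(net, pts),
                  points_per_dim = points_per_dim, term_name = "realizable")
}
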
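# Shared fixtures and independent oracles, all built in code.

# Constant single-layer stack over [0, nx] x [0, ny] with unit cells.
const_stack <- function(nx = 2, ny = 2, value = 1, cellsize = 1,
                        role = "environmental", name = "v") {
  m <- matrix(value, nrow = ny / cellsize, ncol = nx / cellsize)
  raster_stack(0, 0, cellsize, stats::setNames(list(m), name), roles = role)
}

# Linear x-gradient layer: cell value = x-coordinate of the cell centre.
gradient_stack <- function(nx = 3, ny = 3, cellsize = 1, name = "v") {
  centres <- (seq_len(nx / cellsize) - 0.5) * cellsize
  m <- matrix(rep(centres, each = ny / cellsize), nrow = ny / cellsize)
  raster_stack(0, 0, cellsize, stats::setNames(list(m), name))
}

# Brute-force point-process log-likelihood: explicit loops, exact
# arithmetic order as the definition reads.
bf_loglik <- function(scheme, X, beta) {
  total <- 0
  for (j in seq_along(scheme$weight)) {
    eta <- sum(X[j, ] * beta)
    if (scheme$is_presence[j] == 1L) total <- total + eta
    total <- total - scheme$weight[j] * exp(eta)
  }
  total
}

# Derivative-free maximizer of the quadrature log-likelihood.
optim_ppm <- function(scheme, X, start = NULL) {
  if (is.null(start)) start <- rep(0, ncol(X))
  f <- function(b) -ppm_loglik(scheme, X, b)
  o <- stats::optim(start, f, method = "Nelder-Mead",
                    control = list(maxit = 50000, reltol = 1e-15))
  o <- stats::optim(o$par, f, method = "Nelder-Mead",
                    control = list(maxit = 50000, reltol = 1e-15))
  o$par
}

# O(n^2) pair-counting AUC with ties credited one half.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Brute-force border-corrected inhomogeneous K for one distance.
bf_K <- function(pattern, lambda, r) {
  reg <- pattern$region
  n <- length(pattern$x)
  ax <- (reg$x_max - reg$x_min) - 2 * r
  ay <- (reg$y_max - reg$y_min) - 2 * r
  if (ax <= 0 || ay <= 0) return(NA_real_)
  acc <- 0
  for (i in seq_len(n)) {
    bd <- min(pattern$x[i] - reg$x_min, reg$x_max - pattern$x[i],
              pattern$y[i] - reg$y_min, reg$y_max - pattern$y[i])
    if (bd <= r) next
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                  (pattern$y[i] - pattern$y[j])^2)
      if (d <= r) acc <- acc + 1 / (lambda[i] * lambda[j])
    }
  }
  acc / (ax * ay)
}

# Small seeded synthetic landscape shared by several tests.
test_landscape <- function(seed = 42, n_env = 1, n_bias = 1,
                           coefficients = c(0.8, 0.5, -0.25, -0.4),
                           extent = 8, delta = 0.5) {
  synth_landscape(n_env, n_bias, coefficients = coefficients,
                  region = region(0, extent, 0, extent), delta = delta,
                  seed = seed)
}

write_ascii_fixture <- function(path, body,
                                header = c("ncols 2", "nrows 2",
                                           "xllcorner 0", "yllcorner 0",
                                           "cellsize 1",
                                           "NODATA_value -9999")) {
  writeLines(c(header, body), path)
  path
}
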
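#' Inhomogeneous K-function of a point pattern
#'
#' Second-moment diagnostic standardized by a fitted intensity: pairs are
#' weighted by `1 / (lambda(s_i) * lambda(s_j))`, so for a correctly
#' specified inhomogeneous Poisson process the expectation is the Poisson
#' benchmark `pi r^2`. A border edge correction is used: only points
#' farther than `r` from the region boundary act as reference points, and
#' the normalizing area is the eroded rectangle's.
#'
#' @param pattern a [point_pattern()].
#' @param surface an `"intensity_surface"` strictly positive at every
#'   point of the pattern.
#' @param r vector of distances (km).
#' @return data frame with `r`, `obs` (the estimate, `NA` where the
#'   eroded region vanishes) and `theo` (`pi r^2`).
#' @export
inhomog_K <- function(pattern, surface, r) {
  n <- npoints(pattern)
  reg <- pattern$region
  xe <- reg$x_max - reg$x_min; ye <- reg$y_max - reg$y_min
  if (max(r) > sqrt(xe^2 + ye^2) / 2)
    warning("r exceeds half the region diameter; large-r values unreliable")
  lam <- if (n) surface_lookup(surface, pattern$x, pattern$y) else numeric(0)
  if (n && any(is.na(lam) | lam <= 0))
    stop("fitted intensity is zero or masked at ",
         sum(is.na(lam) | lam <= 0), " pattern point(s)")
  khat <- numeric(length(r))
  if (n >= 2L) {
    dx <- outer(pattern$x, pattern$x, "-")
    dy <- outer(pattern$y, pattern$y, "-")
    dist <- sqrt(dx^2 + dy^2)
    invlam <- outer(lam, lam)
    bdist <- pmin(pattern$x - reg$x_min, reg$x_max - pattern$x,
                  pattern$y - reg$y_min, reg$y_max - pattern$y)
    for (i in seq_along(r)) {
      ri <- r[i]
      ax <- xe - 2 * ri; ay <- ye - 2 * ri
      if (ax <= 0 || ay <= 0) { khat[i] <- NA_real_; next }
      ref <- bdist > ri
      contrib <- (dist <= ri) & ref & !diag(TRUE, n)
      khat[i] <- sum(1 / invlam[contrib]) / (ax * ay)
    }
  } else {
    khat[] <- 0
    khat[xe - 2 * r <= 0 | ye - 2 * r <= 0] <- NA_real_
  }
  data.frame(r = r, obs = khat, theo = pi * r^2)
}

#' Simulation envelope for the inhomogeneous K-function
#'
#' Simulates `n_sim` realisations from the fitted intensity surface,
#' computes each realisation's inhomogeneous K (standardized by the same
#' surface), and returns the pointwise min/max envelope together with the
#' observed curve. A realisation with fewer than two points contributes a
#' zero curve. An observed curve escaping the envelope at small `r`
#' indicates inter-point dependence (clustering above, inhibition below)
#' unexplained by the intensity model.
#'
#' @param pattern the observed [point_pattern()].
#' @param surface the fitted `"intensity_surface"`.
#' @param r vector of distances (km).
#' @param n_sim number of simulated realisations.
#' @param seed optional integer seed.
#' @return An object of class `"k_envelope"`: data frame `summary` with
#'   `r`, `obs`, `lo`, `hi`, `mean_sim`, `theo`, plus the matrix of
#'   simulated curves `sims` (`n_sim` columns) and `n_sim`.
#' @export
k_envelope <- function(pattern, surface, r, n_sim = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- inhomog_K(pattern, surface, r)
  sims <- matrix(NA_real_, length(r), n_sim)
  for (s in seq_len(n_sim)) {
    sim <- simulate_ipp(surface, region = pattern$region)
    sims[, s] <- if (npoints(sim) < 2L) rep(0, length(r)) else
      inhomog_K(sim, surface, r)$obs
  }
  structure(list(
    summary = data.frame(r = r, obs = obs$obs,
                         lo = apply(sims, 1L, min),
                         hi = apply(sims, 1L, max),
                         mean_sim = rowMeans(sims),
                         theo = obs$theo),
    sims = sims, n_sim = n_sim),
    class = "k_envelope")
}

#' @export
print.k_envelope <- function(x, ...) {
  cat(sprintf("K-function envelope from %d simulations\n", x$n_sim))
  print(utils::head(x$summary, 8))
  invisible(x)
}

#' Spatially smoothed Pearson residual map
#'
#' On the grid of the fit's quadrature resolution, the raw Pearson
#' residual of a cell is `(N - Lambda) / sqrt(Lambda)` where `N` is the
#' observed presence count and `Lambda = lambda_hat * cell_area` the
#' fitted expected count. The map is then smoothed with an isotropic
#' Gaussian kernel (bandwidth in km, default twice the cell size)
#' normalized over unmasked cells. Systematic spatial trend in the
#' smoothed map indicates intensity structure the covariates have not
#' captured.
#'
#' @param fit a `"ppm_fit"`.
#' @param pattern the [point_pattern()] the model was fitted to.
#' @param stack the covariate [raster_stack()].
#' @param bandwidth Gaussian kernel bandwidth in km; 0 returns the raw
#'   map unchanged.
#' @return An object of class `"residual_map"`: matrices `raw`,
#'   `smoothed`, `count` (N), `expected` (Lambda), cell-centre coordinate
#'   vectors, the `bandwidth` and the grid geometry.
#' @export
pearson_residual_map <- function(fit, pattern, stack,
                                 bandwidth = 2 * fit$resolution) {
  r <- pattern$region
  delta <- fit$resolution
  bx <- quad_breaks(r$x_min, r$x_max, delta)
  by <- quad_breaks(r$y_min, r$y_max, delta)
  ncx <- length(bx) - 1L; ncy <- length(by) - 1L
  cx <- (bx[-1L] + bx[-length(bx)]) / 2
  cy <- (by[-1L] + by[-length(by)]) / 2
  g <- expand.grid(iy = seq_len(ncy), ix = seq_len(ncx))
  gx <- cx[g$ix]; gy <- cy[g$iy]
  area <- diff(bx)[g$ix] * diff(by)[g$iy]
  lam <- predict_at(fit, stack, gx, gy)
  Lam <- lam * area
  ix <- findInterval(pattern$x, bx, rightmost.closed = TRUE)
  iy <- findInterval(pattern$y, by, rightmost.closed = TRUE)
  counts <- tabulate((ix - 1L) * ncy + iy, nbins = ncx * ncy)
  N <- counts[(g$ix - 1L) * ncy + g$iy]
  raw <- (N - Lam) / sqrt(Lam)
  ok <- is.finite(raw)
  smoothed <- rep(NA_real_, length(raw))
  if (bandwidth > 0) {
    d2 <- outer(gx[ok], gx[ok], "-")^2 + outer(gy[ok], gy[ok], "-")^2
    kern <- exp(-d2 / (2 * bandwidth^2))
    smoothed[ok] <- drop(kern %*% raw[ok]) / rowSums(kern)
  } else smoothed[ok] <- raw[ok]
  to_mat <- function(v) matrix(v, nrow = ncy)   # rows vary fastest = y
  structure(list(raw = to_mat(raw), smoothed = to_mat(smoothed),
                 count = to_mat(N), expected = to_mat(Lam),
                 cx = cx, cy = cy, bandwidth = bandwidth,
                 x0 = r$x_min, y0 = r$y_min, cellsize = delta,
                 n_cols = ncx, n_rows = ncy),
            class = "residual_map")
}

#' @export
print.residual_map <- function(x, ...) {
  cat(sprintf(
    "Pearson residual map: %d x %d cells, bandwidth %g km\n",
    x$n_cols, x$n_rows, x$bandwidth))
  cat(sprintf("  smoothed range: %.4f to %.4f\n",
              min(x$smoothed, na.rm = TRUE), max(x$smoothed, na.rm = TRUE)))
  invisible(x)
}
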
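#' Regular-grid quadrature scheme for the point-process likelihood
#'
#' The point-process log-likelihood involves an integral of the intensity
#' over the study region; `make_quadrature` discretizes it Berman-Turner
#' style. Dummy ("quadrature") points are placed at the centres of a
#' regular grid of resolution `delta` over the pattern's region, the
#' presence points are kept as nodes at their exact coordinates, and each
#' grid cell's area is split equally among all nodes that fall in it: a
#' cell holding p presences plus its dummy node gives each node weight
#' `area/(p+1)`. The weights then sum to the unmasked region area, which is
#' what makes the weighted-GLM fit approximate the true likelihood and
#' makes the model scale independent once the grid is fine enough.
#'
#' Cells whose centre falls on a masked raster cell contribute no nodes;
#' edge cells are clipped to the region so partial cells get partial area.
#'
#' @param pattern a [point_pattern()] (single target species).
#' @param stack a [raster_stack()] covering the region.
#' @param delta quadrature grid resolution in km.
#' @return An object of class `"quad_scheme"` with per-node `x`, `y`,
#'   `is_presence`, `weight`, covariate data frame `cov`, `resolution`,
#'   total unmasked `area`, presence count `m` and the `region`.
#' @export
make_quadrature <- function(pattern, stack, delta) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(stack, "raster_stack"))
  r <- pattern$region
  if (delta <= 0) stop("delta must be > 0")
  if (delta > (r$x_max - r$x_min) || delta > (r$y_max - r$y_min))
    stop("delta larger than the region extent")
  bx <- quad_breaks(r$x_min, r$x_max, delta)
  by <- quad_breaks(r$y_min, r$y_max, delta)
  ncx <- length(bx) - 1L; ncy <- length(by) - 1L
  cx <- (bx[-1L] + bx[-length(bx)]) / 2
  cy <- (by[-1L] + by[-length(by)]) / 2
  wx <- diff(bx); wy <- diff(by)
  grid <- expand.grid(ix = seq_len(ncx), iy = seq_len(ncy))
  gx <- cx[grid$ix]; gy <- cy[grid$iy]
  garea <- wx[grid$ix] * wy[grid$iy]
  gcov <- extract_covariates(stack, gx, gy)
  keep <- attr(gcov, "usable")
  # presence cell membership (half-open cells, far edge clamped)
  px <- pattern$x; py <- pattern$y
  pix <- findInterval(px, bx, rightmost.closed = TRUE)
  piy <- findInterval(py, by, rightmost.closed = TRUE)
  pcell <- (piy - 1L) * ncx + pix
  cellid <- (grid$iy - 1L) * ncx + grid$ix
  masked_cells <- cellid[!keep]
  if (any(pcell %in% masked_cells))
    stop("presence point(s) in masked cells; cannot assign quadrature ",
         "weights at indices: ",
         paste(utils::head(which(pcell %in% masked_cells), 10L), collapse = ", "))
  pcov <- if (length(px)) extract_covariates(stack, px, py) else
    gcov[0, , drop = FALSE]
  if (length(px) && !all(attr(pcov, "usable")))
    stop("presence point(s) on masked raster cells at indices: ",
         paste(utils::head(which(!attr(pcov, "usable")), 10L), collapse = ", "))
  # nodes = presences then unmasked dummies
  counts <- tabulate(match(pcell, cellid), nbins = length(cellid))
  denom <- counts + 1L                      # dummy node included
  area_per_node <- garea / denom
  node_cell <- match(pcell, cellid)
  w <- c(area_per_node[node_cell], area_per_node[keep])
  x <- c(px, gx[keep]); y <- c(py, gy[keep])
  isp <- c(rep(1L, length(px)), rep(0L, sum(keep)))
  cov <- rbind(pcov, gcov[keep, , drop = FALSE])
  rownames(cov) <- NULL
  structure(list(x = x, y = y, is_presence = isp, weight = w, cov = cov,
                 resolution = delta, area = sum(garea[keep]),
                 m = length(px), region = r),
            class = "quad_scheme")
}

quad_breaks <- function(lo, hi, delta) {
  n <- ceiling((hi - lo) / delta - 1e-9)
  b <- lo + delta * seq.int(0L, n)
  b[length(b)] <- hi
  b
}

#' @export
print.quad_scheme <- function(x, ...) {
  cat(sprintf(
    "quadrature scheme: %d nodes (%d presences + %d dummies), delta = %g km\n",
    length(x$x), x$m, length(x$x) - x$m, x$resolution))
  cat(sprintf("  total weight %g km^2\n", sum(x$weight)))
  invisible(x)
}

#' Export a quadrature scheme as a data frame
#' @param x a `"quad_scheme"`.
#' @param row.names,optional,... passed on conventions of [as.data.frame()].
#' @return data frame with `x`, `y`, `is_presence`, `weight` and covariates.
#' @export
as.data.frame.quad_scheme <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  cbind(data.frame(x = x$x, y = x$y, is_presence = x$is_presence,
                   weight = x$weight), x$cov)
}

#' Refine the quadrature grid until the likelihood converges
#'
#' Starting from `delta_start`, repeatedly halves the grid spacing (each
#' halving doubles the spatial resolution, quadrupling the dummy points)
#' and refits the unpenalized model, stopping when the maximised
#' log-likelihood changes by less than `tol` (default 2). Returns the finer
#' scheme of the converged pair together with the trace of
#' (resolution, log-likelihood).
#'
#' @param pattern a [point_pattern()].
#' @param stack a [raster_stack()].
#' @param spec a [design_spec()].
#' @param delta_start initial resolution (km); default is the shorter
#'   region extent divided by 8, rounded down to a power of two so repeated
#'   halvings stay on clean fractions.
#' @param tol convergence tolerance in log-likelihood units.
#' @param max_halvings maximum number of halvings before giving up.
#' @return list with `scheme` (the converged, finer scheme), `fit` (the
#'   unpenalized fit on it), `delta`, and `trace` (data frame of
#'   `delta`, `loglik`).
#' @export
refine_until_converged <- function(pattern, stack, spec, delta_start = NULL,
                                   tol = 2, max_halvings = 8L) {
  r <- pattern$region
  if (is.null(delta_start)) {
    e <- min(r$x_max - r$x_min, r$y_max - r$y_min) / 8
    delta_start <- 2^floor(log2(e))
  }
  delta <- delta_start
  sch <- make_quadrature(pattern, stack, delta)
  fit <- fit_ppm(sch, spec)
  trace <- data.frame(delta = delta, loglik = fit$loglik)
  for (h in seq_len(max_halvings)) {
    delta2 <- delta / 2
    sch2 <- make_quadrature(pattern, stack, delta2)
    fit2 <- fit_ppm(sch2, spec)
    trace <- rbind(trace, data.frame(delta = delta2, loglik = fit2$loglik))
    if (abs(fit2$loglik - fit$loglik) < tol)
      return(list(scheme = sch2, fit = fit2, delta = delta2, trace = trace))
    delta <- delta2; sch <- sch2; fit <- fit2
  }
  err <- simpleError(paste0("likelihood did not converge after ",
                            max_halvings, " resolution doublings"))
  err$trace <- trace
  stop(err)
}
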
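#' Quadrature-approximated Poisson point process log-likelihood
#'
#' Evaluates `sum over presence nodes of log(lambda) - sum over all nodes
#' of w * lambda` with `log(lambda) = X beta`: the Berman-Turner
#' discretization of the point-process log-likelihood. The additive
#' `log(m!)`-style constant is omitted, so values are comparable across
#' quadrature resolutions for the same presence set, but not across
#' different presence sets.
#'
#' @param scheme a `"quad_scheme"`.
#' @param X design matrix (rows = nodes, including intercept column).
#' @param beta coefficient vector matching `X`'s columns.
#' @return log-likelihood value.
#' @export
ppm_loglik <- function(scheme, X, beta) {
  stopifnot(ncol(X) == length(beta), nrow(X) == length(scheme$weight))
  eta <- drop(X %*% beta)
  lam <- exp(eta)
  if (any(!is.finite(lam)))
    stop("non-finite intensity (overflow); standardize covariates or ",
         "shrink coefficients")
  sum(eta[scheme$is_presence == 1L]) - sum(scheme$weight * lam)
}

#' Fit a Poisson point process regression
#'
#' Maximizes the quadrature-weighted point-process likelihood over the
#' standardized design. The unpenalized fit uses iteratively reweighted
#' least squares through the weighted-Poisson GLM device (response
#' `is_presence / weight` with prior weight `weight`); a positive `penalty`
#' instead maximizes `loglik - penalty * sum(|beta|)` over the
#' non-intercept coefficients by penalized IRLS with coordinate-wise
#' soft-thresholding (see [lasso_path()] for whole paths).
#'
#' For an intercept-only model the solution is exactly
#' `log(m / area)`; more generally the unpenalized fit satisfies the score
#' equation `sum(w * lambda_hat) = m`.
#'
#' @param scheme a `"quad_scheme"`.
#' @param spec a [design_spec()].
#' @param penalty LASSO penalty on the point-process log-likelihood scale
#'   (0 = maximum likelihood).
#' @return An object of class `"ppm_fit"`: named `coefficients` (on the
#'   standardized scale), unpenalized `loglik` at the solution, `penalty`,
#'   presence count `m`, nonzero-coefficient count `k`, `bic`, standard
#'   errors `se` (unpenalized fits only), quadrature `resolution`, total
#'   `area`, and the `spec` carrying the standardization constants.
#' @export
fit_ppm <- function(scheme, spec, penalty = 0) {
  if (scheme$m == 0L) stop("no presence points; cannot fit")
  built <- build_design(scheme, spec)
  X <- built$X; spec <- built$spec
  w <- scheme$weight
  y <- scheme$is_presence / w
  if (penalty == 0) {
    fit <- suppressWarnings(stats::glm.fit(
      X, y, weights = w, family = stats::quasipoisson(link = "log"),
      control = stats::glm.control(epsilon = 1e-12, maxit = 100L)))
    if (!fit$converged)
      stop("IRLS did not converge in 100 iterations (possible separation); ",
           "deviance trace ends at ", format(fit$deviance))
    beta <- fit$coefficients
    if (anyNA(beta))
      stop("design is rank deficient; aliased columns: ",
           paste(names(beta)[is.na(beta)], collapse = ", "))
    mu <- fit$fitted.values
    info <- crossprod(X, (w * mu) * X)
    se <- sqrt(diag(solve(info)))
  } else {
    beta <- penalized_irls(X, y, w, lambda = penalty,
                           penalized = c(FALSE, rep(TRUE, ncol(X) - 1L)))
    se <- NULL
  }
  names(beta) <- colnames(X)
  ll <- ppm_loglik(scheme, X, beta)
  k <- sum(abs(beta) > 0)
  structure(list(coefficients = beta, loglik = ll, penalty = penalty,
                 m = scheme$m, k = k,
                 bic = -2 * ll + k * log(scheme$m),
                 se = se, resolution = scheme$resolution,
                 area = scheme$area, spec = spec),
            class = "ppm_fit")
}

#' @export
print.ppm_fit <- function(x, ...) {
  cat(sprintf(
    "Poisson point process fit: m = %d presences, delta = %g km\n",
    x$m, x$resolution))
  cat(sprintf("  penalty = %g, loglik = %.4f, k = %d, BIC = %.4f\n",
              x$penalty, x$loglik, x$k, x$bic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Coefficients of a point process fit
#'
#' @param object a `"ppm_fit"`.
#' @param scale `"standardized"` (as fitted) or `"raw"`, back-transformed
#'   to the original covariate units (the intercept absorbs the centering).
#' @param ... unused.
#' @return named coefficient vector.
#' @export
coef.ppm_fit <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") return(object$coefficients)
  raw_coef(object$coefficients, object$spec$std)
}

raw_coef <- function(b, std) {
  braw <- b[std$cols] / std$scale
  b0 <- b[["(Intercept)"]] - sum(b[std$cols] * std$center / std$scale)
  c("(Intercept)" = unname(b0), braw)
}

#' Predict the intensity surface of a fitted model
#'
#' Evaluates `lambda_hat = exp(X beta)` at every unmasked cell centre of
#' the stack, in presences per square kilometre, with the covariates at
#' their observed values (no bias conditioning; see [predict_corrected()]).
#'
#' @param fit a `"ppm_fit"`.
#' @param stack a [raster_stack()] supplying all layers in the fit's spec.
#' @return An object of class `"intensity_surface"`.
#' @export
predict_intensity <- function(fit, stack) {
  make_surface(fit, stack, z0 = NULL)
}

make_surface <- function(fit, stack, z0 = NULL) {
  cc <- cell_centres(stack)
  cov <- extract_covariates(stack, cc$x, cc$y)
  ok <- attr(cov, "usable")
  vals <- matrix(NA_real_, stack$n_rows, stack$n_cols)
  if (any(ok)) {
    X <- apply_design(cov[ok, , drop = FALSE], fit$spec, z0 = z0)
    lam <- exp(drop(X %*% fit$coefficients[colnames(X)]))
    vals[cbind(cc$row[ok], cc$col[ok])] <- lam
  }
  structure(list(x0 = stack$x0, y0 = stack$y0, cellsize = stack$cellsize,
                 n_cols = stack$n_cols, n_rows = stack$n_rows,
                 values = vals, mask = stack$mask,
                 mode = if (is.null(z0)) "raw" else "bias_conditioned",
                 anchor = z0),
            class = "intensity_surface")
}

#' @export
print.intensity_surface <- function(x, ...) {
  cat(sprintf("intensity surface (%s): %d x %d cells of %g km\n",
              x$mode, x$n_cols, x$n_rows, x$cellsize))
  cat(sprintf("  range %g to %g per km^2\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Nearest-cell lookup into an intensity surface
#' @param surface an `"intensity_surface"`.
#' @param x,y coordinates (km).
#' @return intensity values (NA on masked cells).
#' @export
surface_lookup <- function(surface, x, y) {
  fake <- list(x0 = surface$x0, y0 = surface$y0, cellsize = surface$cellsize,
               n_cols = surface$n_cols, n_rows = surface$n_rows)
  idx <- cell_index(fake, x, y)
  bad <- which(is.na(idx[, 1L]))
  if (length(bad))
    stop("points outside the surface extent at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  surface$values[cbind(idx[, "row"], idx[, "col"])]
}

#' Integral of an intensity surface over its grid
#' @param surface an `"intensity_surface"`.
#' @return expected number of points, `sum(lambda * cellsize^2)` over
#'   unmasked cells.
#' @export
surface_integral <- function(surface) {
  sum(surface$values, na.rm = TRUE) * surface$cellsize^2
}

# Predict intensity at arbitrary locations (used by the evaluation loop).
predict_at <- function(fit, stack, x, y, z0 = NULL) {
  cov <- extract_covariates(stack, x, y)
  ok <- attr(cov, "usable")
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    X <- apply_design(cov[ok, , drop = FALSE], fit$spec, z0 = z0)
    out[ok] <- exp(drop(X %*% fit$coefficients[colnames(X)]))
  }
  out
}
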
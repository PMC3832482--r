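# Logistic IRLS shared by both pseudo-absence comparators.
logistic_irls <- function(X, y, weights = rep(1, length(y))) {
  if (length(unique(y)) < 2L)
    stop("complete separation by construction: response has a single class")
  fit <- suppressWarnings(stats::glm.fit(
    X, y, weights = weights, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100L)))
  if (!fit$converged)
    stop("logistic IRLS did not converge (possible separation)")
  beta <- fit$coefficients
  if (anyNA(beta))
    stop("logistic design is rank deficient; aliased columns: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  list(beta = beta, fitted = fit$fitted.values, deviance = fit$deviance)
}

# Penalized logistic coordinate descent (same device as the point-process
# LASSO, binomial working response/weights).
penalized_logistic <- function(X, y, lambda, penalized, beta = NULL,
                               tol = 1e-9, maxit = 200L) {
  p <- ncol(X)
  if (is.null(beta)) {
    beta <- numeric(p)
    pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
    beta[1L] <- log(pbar / (1 - pbar))
  }
  eta <- drop(X %*% beta)
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / v
    d <- colSums(v * X^2)
    r <- z - eta
    for (inner in seq_len(5000L)) {
      dmax <- 0
      for (j in seq_len(p)) {
        xj <- X[, j]
        zj <- sum(v * xj * r) + d[j] * beta[j]
        bnew <- if (penalized[j])
          sign(zj) * max(abs(zj) - lambda, 0) / d[j] else zj / d[j]
        if (bnew != beta[j]) {
          r <- r - xj * (bnew - beta[j])
          dmax <- max(dmax, abs(bnew - beta[j]))
          beta[j] <- bnew
        }
      }
      if (dmax < 1e-11) break
    }
    eta_new <- drop(X %*% beta)
    if (max(abs(eta_new - eta)) < tol) return(beta)
    eta <- eta_new
  }
  stop("penalized logistic IRLS did not converge at lambda = ",
       format(lambda))
}

fit_logistic <- function(cov, y, spec, penalty = "none") {
  built <- std_design(cov, rep(1, length(y)), spec)
  X <- built$X; spec <- built$spec
  if (identical(penalty, "none")) {
    f <- logistic_irls(X, y)
    beta <- f$beta; lam <- 0
  } else {
    penalized <- c(FALSE, rep(TRUE, ncol(X) - 1L))
    if (identical(penalty, "bic")) {
      mu0 <- mean(y)
      lmax <- max(abs(drop(crossprod(X, y - mu0))[penalized]))
      lams <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 30L))
      beta <- NULL; best <- NULL; best_bic <- Inf
      for (l in lams) {
        beta <- penalized_logistic(X, y, l, penalized, beta = beta)
        eta <- drop(X %*% beta)
        ll <- sum(y * eta - log1p(exp(eta)))
        bic <- -2 * ll + sum(abs(beta) > 0) * log(length(y))
        if (bic < best_bic) { best_bic <- bic; best <- beta; lam <- l }
      }
      beta <- best
    } else {
      lam <- as.numeric(penalty)
      beta <- penalized_logistic(X, y, lam,
                                 c(FALSE, rep(TRUE, ncol(X) - 1L)))
    }
  }
  names(beta) <- colnames(X)
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  structure(list(coefficients = beta, fitted = mu,
                 deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)),
                 penalty = lam, n1 = sum(y == 1), n0 = sum(y == 0),
                 spec = spec),
            class = "logistic_fit")
}

#' Coefficients of a pseudo-absence logistic fit
#' @param object a `"logistic_fit"`.
#' @param scale `"standardized"` (as fitted) or `"raw"` covariate units.
#' @param ... unused.
#' @return named coefficient vector.
#' @export
coef.logistic_fit <- function(object, scale = c("standardized", "raw"),
                              ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") return(object$coefficients)
  raw_coef(object$coefficients, object$spec$std)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("pseudo-absence logistic fit: %d cases, %d pseudo-absences\n",
              x$n1, x$n0))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted probability from a pseudo-absence logistic fit
#' @param fit a `"logistic_fit"`.
#' @param stack a [raster_stack()].
#' @param x,y locations (km).
#' @return fitted probabilities (NA on masked cells).
#' @export
predict_prob <- function(fit, stack, x, y) {
  cov <- extract_covariates(stack, x, y)
  ok <- attr(cov, "usable")
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    X <- apply_design(cov[ok, , drop = FALSE], fit$spec)
    out[ok] <- stats::plogis(drop(X %*% fit$coefficients[colnames(X)]))
  }
  out
}

#' Point-event pseudo-absence ("inventory") comparator
#'
#' Fits a logistic regression in which the target species' presence points
#' are the cases and every non-target presence point is a pseudo-absence,
#' on environmental covariates only. This estimates a *compositional* rate
#' — the probability that an encountered individual is the target species —
#' so shared observer bias cancels, but the estimate is confounded by
#' non-target species richness (see [richness_experiment()]).
#'
#' @param target,nontarget [point_pattern()]s of the target species and
#'   of all non-target presences; both must be non-empty.
#' @param stack a [raster_stack()].
#' @param spec a [design_spec()]; its bias block is ignored (environmental
#'   design only, mirroring how the comparator is defined).
#' @param penalty `"none"` (default), `"bic"`, or a numeric LASSO penalty.
#' @return a `"logistic_fit"`.
#' @export
pseudo_absence_points <- function(target, nontarget, stack, spec,
                                  penalty = "none") {
  if (!npoints(target)) stop("empty target pattern")
  if (!npoints(nontarget))
    stop("empty non-target pattern: no pseudo-absences available")
  spec <- design_spec(spec$env, character(0), quadratic = spec$quadratic,
                      interactions = spec$interactions)
  x <- c(target$x, nontarget$x); y <- c(target$y, nontarget$y)
  cov <- extract_covariates(stack, x, y)
  ok <- attr(cov, "usable")
  resp <- c(rep(1L, npoints(target)), rep(0L, npoints(nontarget)))
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " point(s) on masked cells")
    cov <- cov[ok, , drop = FALSE]; resp <- resp[ok]
  }
  fit_logistic(cov, resp, spec, penalty = penalty)
}

#' Grid-cell pseudo-absence comparator
#'
#' Aggregates presences to grid cells of size `delta`: a cell with any
#' target presence is a case (even if non-target species are also there),
#' a cell with only non-target presences is a pseudo-absence, and empty
#' cells are excluded. A logistic regression on the cell-centre
#' environmental covariates is then fitted. Estimates the probability a
#' non-empty cell contains the target species.
#'
#' @inheritParams pseudo_absence_points
#' @param delta aggregation cell size in km (1 km is the conventional
#'   choice).
#' @return a `"logistic_fit"`.
#' @export
pseudo_absence_cells <- function(target, nontarget, stack, delta, spec,
                                 penalty = "none") {
  if (delta <= 0) stop("delta must be > 0")
  spec <- design_spec(spec$env, character(0), quadratic = spec$quadratic,
                      interactions = spec$interactions)
  r <- target$region
  bx <- quad_breaks(r$x_min, r$x_max, delta)
  by <- quad_breaks(r$y_min, r$y_max, delta)
  ncx <- length(bx) - 1L
  cell_of <- function(p) {
    if (!npoints(p)) return(integer(0))
    (findInterval(p$y, by, rightmost.closed = TRUE) - 1L) * ncx +
      findInterval(p$x, bx, rightmost.closed = TRUE)
  }
  tcells <- unique(cell_of(target))
  ocells <- unique(cell_of(nontarget))
  cases <- tcells
  pseudo <- setdiff(ocells, tcells)
  if (!length(cases) && !length(pseudo)) stop("all grid cells are empty")
  cells <- c(cases, pseudo)
  resp <- c(rep(1L, length(cases)), rep(0L, length(pseudo)))
  ix <- (cells - 1L) %% ncx + 1L
  iy <- (cells - 1L) %/% ncx + 1L
  cx <- (bx[ix] + bx[ix + 1L]) / 2
  cy <- (by[iy] + by[iy + 1L]) / 2
  cov <- extract_covariates(stack, cx, cy)
  ok <- attr(cov, "usable")
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " cell(s) on masked raster cells")
    cov <- cov[ok, , drop = FALSE]; resp <- resp[ok]
  }
  fit_logistic(cov, resp, spec, penalty = penalty)
}
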
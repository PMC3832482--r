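# Penalized IRLS with coordinate-wise soft-thresholding.
#
# Minimizes -loglik(beta) + lambda * sum(|beta_j|, j penalized) for the
# weighted Poisson device (y = is_presence/w, prior weight w), i.e. the
# LASSO on the quadrature-approximated point-process likelihood. Each
# outer step forms the usual working response/weights; the inner loop is
# cyclic coordinate descent whose one-dimensional solution is the
# soft-threshold sign(z) * max(|z| - lambda, 0) / d.
penalized_irls <- function(X, y, w, lambda, penalized, beta = NULL,
                           tol = 1e-9, maxit = 200L, inner_tol = 1e-11,
                           inner_maxit = 5000L) {
  p <- ncol(X)
  if (is.null(beta)) {
    beta <- numeric(p)
    beta[1L] <- log(max(sum(w * y), 1e-12) / sum(w))
  }
  eta <- drop(X %*% beta)
  for (it in seq_len(maxit)) {
    mu <- exp(pmin(eta, 40))
    W <- w * mu                       # working weights
    z <- eta + (y - mu) / mu          # working response
    d <- colSums(W * X^2)
    r <- z - eta                      # working residual
    for (inner in seq_len(inner_maxit)) {
      delta_max <- 0
      for (j in seq_len(p)) {
        xj <- X[, j]
        zj <- sum(W * xj * r) + d[j] * beta[j]
        bnew <- if (penalized[j])
          sign(zj) * max(abs(zj) - lambda, 0) / d[j] else zj / d[j]
        if (bnew != beta[j]) {
          r <- r - xj * (bnew - beta[j])
          delta_max <- max(delta_max, abs(bnew - beta[j]))
          beta[j] <- bnew
        }
      }
      if (delta_max < inner_tol) break
    }
    eta_new <- drop(X %*% beta)
    step <- max(abs(eta_new - eta))
    eta <- eta_new
    if (step < tol) {
      beta[penalized & abs(beta) < 1e-12] <- 0  # boundary-case dust
      return(beta)
    }
  }
  stop("penalized IRLS did not converge at lambda = ", format(lambda),
       " after ", maxit, " outer iterations")
}

# Smallest penalty at which all penalized coefficients are zero: the
# largest absolute score component at the intercept-only solution.
lambda_max_ppm <- function(X, y, w, penalized) {
  mu0 <- sum(w * y) / sum(w)
  g <- drop(crossprod(X, w * (y - mu0)))
  max(abs(g[penalized]))
}

#' Fit a LASSO regularization path for a point process model
#'
#' Fits the penalized point-process regression over a log-spaced grid of
#' penalties from `lambda_max` (the smallest penalty at which every
#' penalized coefficient is exactly zero, computed from the score of the
#' intercept-only model) down to `ratio * lambda_max`, with warm starts
#' along the path. The intercept is never penalized; all other columns
#' (environmental and bias) are eligible for shrinkage. Each path entry
#' records the coefficients, the *unpenalized* log-likelihood of the
#' penalized solution, the nonzero count `k`, and
#' `BIC = -2 loglik + k log(m)` where `m` is the number of presence
#' points.
#'
#' @param scheme a `"quad_scheme"`.
#' @param spec a [design_spec()].
#' @param n_penalties path length.
#' @param ratio smallest penalty as a fraction of `lambda_max`.
#' @return An object of class `"reg_path"`: `penalties`, list of
#'   `"ppm_fit"` objects `fits`, vectors `loglik`, `k`, `bic`, and `m`.
#' @export
lasso_path <- function(scheme, spec, n_penalties = 100L, ratio = 1e-4) {
  if (scheme$m == 0L) stop("no presence points; cannot fit")
  built <- build_design(scheme, spec)
  X <- built$X; spec <- built$spec
  w <- scheme$weight
  y <- scheme$is_presence / w
  penalized <- c(FALSE, rep(TRUE, ncol(X) - 1L))
  lmax <- lambda_max_ppm(X, y, w, penalized)
  lams <- exp(seq(log(lmax), log(lmax * ratio), length.out = n_penalties))
  beta <- NULL
  fits <- vector("list", n_penalties)
  for (i in seq_along(lams)) {
    beta <- penalized_irls(X, y, w, lams[i], penalized, beta = beta)
    names(beta) <- colnames(X)
    ll <- ppm_loglik(scheme, X, beta)
    k <- sum(abs(beta) > 0)
    fits[[i]] <- structure(
      list(coefficients = beta, loglik = ll, penalty = lams[i],
           m = scheme$m, k = k, bic = -2 * ll + k * log(scheme$m),
           se = NULL, resolution = scheme$resolution, area = scheme$area,
           spec = spec),
      class = "ppm_fit")
  }
  structure(list(penalties = lams, fits = fits,
                 loglik = vapply(fits, `[[`, 0, "loglik"),
                 k = vapply(fits, function(f) as.integer(f$k), 0L),
                 bic = vapply(fits, `[[`, 0, "bic"),
                 m = scheme$m),
            class = "reg_path")
}

#' @export
print.reg_path <- function(x, ...) {
  cat(sprintf("regularization path: %d penalties, m = %d\n",
              length(x$penalties), x$m))
  print(utils::head(as.data.frame(x), 8))
  invisible(x)
}

#' Path table as a data frame
#' @param x a `"reg_path"`.
#' @param row.names,optional,... as in [as.data.frame()].
#' @return data frame with `penalty`, `loglik`, `k`, `bic`.
#' @export
as.data.frame.reg_path <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  data.frame(penalty = x$penalties, loglik = x$loglik, k = x$k, bic = x$bic)
}

#' Select the penalty minimizing BIC
#'
#' `BIC = -2 loglik + k log(m)` with `m` the total number of presence
#' locations and `k` the number of nonzero parameters; the unpenalized
#' log-likelihood of each penalized solution is used. Ties go to the
#' larger penalty (the sparser model).
#'
#' @param path a `"reg_path"`.
#' @param m presence count (defaults to the path's).
#' @return the selected `"ppm_fit"` (with `bic` recomputed for `m`).
#' @export
bic_select <- function(path, m = path$m) {
  if (!length(path$fits)) stop("empty regularization path")
  if (m < 1L) stop("m must be >= 1")
  bic <- -2 * path$loglik + path$k * log(m)
  i <- which.min(bic)   # penalties are decreasing, so first min = sparser
  fit <- path$fits[[i]]
  fit$bic <- bic[i]
  fit
}
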
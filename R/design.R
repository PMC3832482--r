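#' Model design specification
#'
#' Declares which raster layers enter the log-linear intensity model and
#' how. Environmental covariates get a quadratic response (linear + pure
#' squared terms by default; pairwise products optionally), observer-bias
#' covariates enter linearly only — additivity of the bias block, with no
#' environment-by-bias interaction, is what makes conditioning the bias
#' away at prediction time valid. Each non-intercept column is standardized
#' to weighted mean 0 and variance 1 using the quadrature weights, so fits
#' are invariant to covariate units and grid resolution; the standardization
#' constants are stored on first use and reused at prediction time.
#'
#' @param env character vector of environmental layer names.
#' @param bias character vector of observer-bias layer names (may be empty).
#' @param quadratic include squared environmental terms.
#' @param interactions include pairwise environmental products.
#' @return An object of class `"design_spec"`.
#' @export
design_spec <- function(env, bias = character(0), quadratic = TRUE,
                        interactions = FALSE) {
  env <- as.character(env); bias <- as.character(bias)
  if (!length(env)) stop("at least one environmental layer is required")
  if (length(intersect(env, bias)))
    stop("environmental and bias layer sets must be disjoint: ",
         paste(intersect(env, bias), collapse = ", "))
  structure(list(env = env, bias = bias, quadratic = quadratic,
                 interactions = interactions, std = NULL),
            class = "design_spec")
}

#' Spec for a stack, taking roles from the layer tags
#' @param stack a [raster_stack()].
#' @param use_bias include the stack's bias layers.
#' @param ... passed to [design_spec()].
#' @return a [design_spec()].
#' @export
spec_from_stack <- function(stack, use_bias = TRUE, ...) {
  design_spec(layer_names(stack, "environmental"),
              if (use_bias) layer_names(stack, "bias") else character(0), ...)
}

# Raw (unstandardized, no intercept) term expansion of a covariate frame.
expand_terms <- function(cov, spec) {
  miss <- setdiff(c(spec$env, spec$bias), names(cov))
  if (length(miss))
    stop("missing covariate layer(s): ", paste(miss, collapse = ", "))
  cols <- list()
  for (v in spec$env) cols[[v]] <- cov[[v]]
  if (spec$quadratic)
    for (v in spec$env) cols[[paste0(v, "^2")]] <- cov[[v]]^2
  if (spec$interactions && length(spec$env) > 1L) {
    pr <- utils::combn(spec$env, 2L)
    for (k in seq_len(ncol(pr)))
      cols[[paste0(pr[1L, k], ":", pr[2L, k])]] <-
        cov[[pr[1L, k]]] * cov[[pr[2L, k]]]
  }
  for (v in spec$bias) cols[[v]] <- cov[[v]]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Build the standardized model matrix for a quadrature scheme
#'
#' Columns are `(Intercept)`, linear environmental terms, squared
#' environmental terms, then linear bias terms; every non-intercept column
#' is standardized to quadrature-weighted mean 0 and variance 1.
#' Zero-variance columns (and exact duplicates, e.g. the square of a 0/1
#' layer) are dropped with a warning. The fitted standardization constants
#' are recorded in the returned spec for reuse when predicting.
#'
#' @param scheme a `"quad_scheme"`.
#' @param spec a [design_spec()].
#' @return list with `X` (model matrix) and `spec` (spec carrying the
#'   standardization).
#' @export
build_design <- function(scheme, spec) {
  std_design(scheme$cov, scheme$weight, spec)
}

# Shared standardized-design builder (quadrature weights for point process
# fits; unit weights for the logistic comparators).
std_design <- function(cov, weight, spec) {
  X <- expand_terms(cov, spec)
  bad <- which(!stats::complete.cases(X))
  if (length(bad))
    stop("non-finite covariate values at node(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  w <- weight / sum(weight)
  ctr <- colSums(w * X)
  sc <- sqrt(colSums(w * sweep(X, 2L, ctr)^2))
  drop <- sc <= 1e-12 * pmax(1, abs(ctr))
  if (any(drop))
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
  Xs <- sweep(sweep(X[, !drop, drop = FALSE], 2L, ctr[!drop]),
              2L, sc[!drop], "/")
  # exact duplicates after standardization (e.g. square of a binary layer)
  dup <- rep(FALSE, ncol(Xs))
  if (ncol(Xs) > 1L)
    for (j in 2:ncol(Xs))
      for (i in 1:(j - 1L))
        if (!dup[i] && max(abs(Xs[, j] - Xs[, i])) < 1e-10) dup[j] <- TRUE
  if (any(dup))
    warning("dropping duplicate column(s): ",
            paste(colnames(Xs)[dup], collapse = ", "))
  Xs <- Xs[, !dup, drop = FALSE]
  keep <- colnames(Xs)
  spec$std <- list(cols = keep,
                   center = ctr[keep], scale = sc[keep])
  X <- cbind(`(Intercept)` = 1, Xs)
  list(X = X, spec = spec)
}

# Standardized design for new covariate values using stored constants.
apply_design <- function(cov, spec, z0 = NULL) {
  if (is.null(spec$std))
    stop("design spec carries no standardization; build the design first")
  if (!is.null(z0)) {
    miss <- setdiff(spec$bias, names(z0))
    if (length(miss))
      stop("anchor z0 missing bias layer(s): ", paste(miss, collapse = ", "))
    for (v in spec$bias) cov[[v]] <- rep(z0[[v]], nrow(cov))
  }
  X <- expand_terms(cov, spec)
  X <- X[, spec$std$cols, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, spec$std$center), 2L, spec$std$scale, "/")
  cbind(`(Intercept)` = 1, Xs)
}

# Names of the (standardized) design columns that belong to the bias block.
bias_columns <- function(spec) intersect(spec$std$cols, spec$bias)
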
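#' Simulate an inhomogeneous Poisson point process
#'
#' Lewis-Shedler thinning: draw `N ~ Poisson(lambda_max * area)` uniform
#' candidate points over the region and keep each with probability
#' `lambda(s) / lambda_max`. Exact for any bounded intensity and
#' deterministic given the seed. Masked cells have intensity 0.
#'
#' @param lambda an `"intensity_surface"`, or a function `f(x, y)`
#'   returning intensity (then `region` and `lambda_max` are required).
#' @param region a [region()] (taken from the surface when omitted).
#' @param lambda_max finite upper bound on the intensity over the region
#'   (computed from the surface when omitted).
#' @param seed optional integer seed.
#' @param species label attached to the simulated points.
#' @return a [point_pattern()] (possibly empty).
#' @export
simulate_ipp <- function(lambda, region = NULL, lambda_max = NULL,
                         seed = NULL, species = "sim") {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(lambda, "intensity_surface")) {
    surf <- lambda
    if (is.null(region))
      region <- region(surf$x0, surf$x0 + surf$n_cols * surf$cellsize,
                       surf$y0, surf$y0 + surf$n_rows * surf$cellsize)
    if (is.null(lambda_max)) lambda_max <- max(surf$values, na.rm = TRUE)
    lamfun <- function(x, y) {
      v <- surface_lookup(surf, x, y)
      v[is.na(v)] <- 0
      v
    }
  } else {
    stopifnot(is.function(lambda))
    if (is.null(region) || is.null(lambda_max))
      stop("region and lambda_max are required for a functional intensity")
    lamfun <- lambda
  }
  if (!is.finite(lambda_max)) stop("intensity bound is not finite")
  if (lambda_max <= 0)
    return(point_pattern(numeric(0), numeric(0), character(0),
                         region = region))
  n <- stats::rpois(1L, lambda_max * region_area(region))
  x <- stats::runif(n, region$x_min, region$x_max)
  y <- stats::runif(n, region$y_min, region$y_max)
  lam <- lamfun(x, y)
  if (any(lam > lambda_max * (1 + 1e-10)))
    stop("intensity exceeds the supplied bound")
  keep <- stats::runif(n) < lam / lambda_max
  point_pattern(x[keep], y[keep], species, region = region)
}

#' The richness-confounding simulation design
#'
#' Two habitats of twenty unit grid cells each; six species A-F with mean
#' points per cell: Habitat I has A 0.2, B 0.1, C 0.1 (D-F absent);
#' Habitat II has A 0.2, B 0.1, C 0.1 plus D 0.2, E 0.1, F 0.1. Species
#' A-C are identical across habitats while Habitat II's total rate (hence
#' species richness) is doubled, so species A's share of all occurrences
#' drops from one half to one quarter even though its absolute occurrence
#' rate is unchanged — the confounding that compositional (pseudo-absence)
#' estimators inherit.
#'
#' Habitat I occupies `x` in `[0, 5)`, Habitat II `x` in `[5, 10)`, both
#' with `y` in `[0, 4)`, on unit cells.
#'
#' @param rates optional 6 x 2 matrix (species x habitat) of mean points
#'   per cell overriding the default.
#' @return An object of class `"richness_design"`.
#' @export
richness_design <- function(rates = NULL) {
  if (is.null(rates)) {
    rates <- cbind(I  = c(A = 0.2, B = 0.1, C = 0.1, D = 0, E = 0, F = 0),
                   II = c(A = 0.2, B = 0.1, C = 0.1, D = 0.2, E = 0.1,
                          F = 0.1))
  }
  stopifnot(all(rates >= 0))
  structure(list(rates = rates, cells_per_habitat = 20L,
                 region = region(0, 10, 0, 4)),
            class = "richness_design")
}

#' Habitat raster for the richness-confounding design
#' @param design a [richness_design()].
#' @return a [raster_stack()] with one binary `habitat` layer (0 =
#'   Habitat I, 1 = Habitat II) on unit cells.
#' @export
richness_stack <- function(design = richness_design()) {
  hab <- matrix(rep(c(rep(0, 5), rep(1, 5)), each = 4), nrow = 4, ncol = 10)
  raster_stack(0, 0, 1, list(habitat = hab), roles = "environmental")
}

#' Generate one dataset from the richness-confounding design
#'
#' Per habitat and species, the number of points is Poisson with mean
#' `20 * rate` and locations are uniform over the habitat's twenty unit
#' cells.
#'
#' @param design a [richness_design()].
#' @param seed optional integer seed.
#' @return a labelled [point_pattern()] over the 10 x 4 region.
#' @export
richness_generate <- function(design = richness_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xs <- ys <- numeric(0); sp <- character(0)
  xlo <- c(I = 0, II = 5)
  for (h in colnames(design$rates)) {
    for (s in rownames(design$rates)) {
      n <- stats::rpois(1L, design$cells_per_habitat * design$rates[s, h])
      if (n > 0L) {
        xs <- c(xs, stats::runif(n, xlo[[h]], xlo[[h]] + 5))
        ys <- c(ys, stats::runif(n, 0, 4))
        sp <- c(sp, rep(s, n))
      }
    }
  }
  point_pattern(xs, ys, sp, region = design$region)
}

habitat_of <- function(x) ifelse(x < 5, "I", "II")

#' Richness-confounding simulation experiment
#'
#' Generates `n_datasets` datasets from the design and applies three
#' estimators of each species' occurrence per habitat, unpenalized
#' throughout:
#' \describe{
#'   \item{model_based}{the point-process fit, which in this one-binary-
#'     covariate setting reduces to the sample mean number of the species'
#'     points per grid cell;}
#'   \item{point_event}{the point-event pseudo-absence logistic fit, which
#'     reduces to the sample proportion of all point events that belong to
#'     the species;}
#'   \item{grid_cell}{the grid-cell pseudo-absence logistic fit, which
#'     reduces to the sample proportion of non-empty cells containing the
#'     species.}
#' }
#' Estimates are averaged across datasets; for the compositional
#' estimators, a habitat with zero events in a dataset contributes no
#' estimate for that dataset (counted in `n_used`).
#'
#' @param n_datasets number of simulated datasets.
#' @param seed optional integer seed.
#' @param design a [richness_design()].
#' @return data frame with `species`, `habitat`, `method`, `estimate`
#'   (mean over datasets), its Monte-Carlo standard error `se`, and
#'   `n_used`.
#' @export
richness_experiment <- function(n_datasets = 100L, seed = NULL,
                            design = richness_design()) {
  if (!is.null(seed)) set.seed(seed)
  species <- rownames(design$rates)
  habitats <- colnames(design$rates)
  methods <- c("model_based", "point_event", "grid_cell")
  acc <- array(NA_real_,
               dim = c(length(species), length(habitats), length(methods),
                       n_datasets),
               dimnames = list(species, habitats, methods, NULL))
  for (d in seq_len(n_datasets)) {
    pat <- richness_generate(design)
    hab <- habitat_of(pat$x)
    cellx <- pmin(floor(pat$x), 9); celly <- pmin(floor(pat$y), 3)
    cell <- celly * 10 + cellx
    for (h in habitats) {
      inh <- hab == h
      total <- sum(inh)
      occupied <- unique(cell[inh])
      for (s in species) {
        ns <- sum(inh & pat$species == s)
        acc[s, h, "model_based", d] <- ns / design$cells_per_habitat
        acc[s, h, "point_event", d] <- if (total > 0) ns / total else NA
        acc[s, h, "grid_cell", d] <- if (length(occupied))
          length(unique(cell[inh & pat$species == s])) / length(occupied)
          else NA
      }
    }
  }
  out <- expand.grid(species = species, habitat = habitats,
                     method = methods, stringsAsFactors = FALSE)
  out$estimate <- mapply(function(s, h, m)
    mean(acc[s, h, m, ], na.rm = TRUE), out$species, out$habitat, out$method)
  out$n_used <- mapply(function(s, h, m)
    sum(!is.na(acc[s, h, m, ])), out$species, out$habitat, out$method)
  out$se <- mapply(function(s, h, m) {
    v <- acc[s, h, m, ]
    stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  }, out$species, out$habitat, out$method)
  out
}

# Smooth random field: sum of Gaussian bumps, standardized over cells.
# Bump scales of 7-20% of the window keep landscape-scale structure while
# giving the field enough degrees of freedom that independently generated
# layers are near-uncorrelated on average.
random_field <- function(cx, cy, region, n_bumps = 20L) {
  xe <- region$x_max - region$x_min; ye <- region$y_max - region$y_min
  v <- numeric(length(cx))
  for (b in seq_len(n_bumps)) {
    bx <- stats::runif(1, region$x_min, region$x_max)
    by <- stats::runif(1, region$y_min, region$y_max)
    s <- stats::runif(1, 0.07, 0.2) * min(xe, ye)
    a <- stats::rnorm(1)
    v <- v + a * exp(-((cx - bx)^2 + (cy - by)^2) / (2 * s^2))
  }
  (v - mean(v)) / stats::sd(v)
}

#' Synthetic covariate landscape with known truth
#'
#' Builds a raster stack of smooth environmental fields (sums of seeded
#' Gaussian bumps, standardized per layer) and observer-bias fields
#' (distance from a set of random point features, emulating distance-to-
#' road / distance-to-town accessibility covariates), together with the
#' true log-linear intensity implied by the supplied coefficients. The
#' `correlation` knob places bias features preferentially where the first
#' environmental layer is high, emulating roads that follow ridgetops;
#' at 0 the features are placed uniformly.
#'
#' @param n_env,n_bias numbers of environmental and bias layers.
#' @param coefficients named or ordered numeric vector on the raw layer
#'   scale: intercept, environmental linear terms, environmental squared
#'   terms, bias linear terms (length `1 + 2 n_env + n_bias`).
#' @param region a [region()].
#' @param delta raster cell size (km).
#' @param seed optional integer seed.
#' @param n_features bias point-features per bias layer.
#' @param correlation 0 (independent) to ~5 (strongly env-aligned bias).
#' @return list with `stack`, the true `surface`
#'   (`"intensity_surface"`), the raw-scale `coefficients` (named), the
#'   `region` and `delta`.
#' @export
synth_landscape <- function(n_env = 2L, n_bias = 1L, coefficients = NULL,
                            region = region(0, 16, 0, 16), delta = 0.5,
                            seed = NULL, n_features = 12L, correlation = 0) {
  if (!is.null(seed)) set.seed(seed)
  env_names <- paste0("env", seq_len(n_env))
  bias_names <- if (n_bias > 0L) paste0("bias", seq_len(n_bias)) else
    character(0)
  p <- 1L + 2L * n_env + n_bias
  if (is.null(coefficients))
    coefficients <- c(0, rep(c(0.6, -0.4), length.out = n_env),
                      rep(-0.3, n_env), rep(-0.5, n_bias))
  stopifnot(length(coefficients) == p)
  names(coefficients) <- c("(Intercept)", env_names,
                           paste0(env_names, "^2"), bias_names)
  nx <- round((region$x_max - region$x_min) / delta)
  ny <- round((region$y_max - region$y_min) / delta)
  cxs <- region$x_min + (seq_len(nx) - 0.5) * delta
  cys <- region$y_min + (seq_len(ny) - 0.5) * delta
  g <- expand.grid(y = cys, x = cxs)   # column-major: rows vary fastest
  layers <- list()
  for (v in env_names)
    layers[[v]] <- matrix(random_field(g$x, g$y, region), nrow = ny)
  for (v in bias_names) {
    if (correlation > 0) {
      wgt <- exp(correlation * as.vector(layers[[env_names[1L]]]))
      idx <- sample(nrow(g), n_features, prob = wgt)
    } else idx <- sample(nrow(g), n_features)
    fx <- g$x[idx]; fy <- g$y[idx]
    dmin <- sqrt(outer(g$x, fx, "-")^2 + outer(g$y, fy, "-")^2)
    layers[[v]] <- matrix(apply(dmin, 1L, min), nrow = ny)
  }
  stack <- raster_stack(region$x_min, region$y_min, delta, layers,
                        roles = c(rep("environmental", n_env),
                                  rep("bias", n_bias)))
  cov <- data.frame(lapply(layers, as.vector))
  names(cov) <- names(layers)
  spec <- design_spec(env_names, bias_names)
  X <- cbind(1, expand_terms(cov, spec))
  lam <- exp(drop(X %*% coefficients[c("(Intercept)", colnames(X)[-1L])]))
  surface <- structure(
    list(x0 = region$x_min, y0 = region$y_min, cellsize = delta,
         n_cols = nx, n_rows = ny,
         values = matrix(lam, nrow = ny), mask = stack$mask,
         mode = "raw", anchor = NULL),
    class = "intensity_surface")
  list(stack = stack, surface = surface, coefficients = coefficients,
       region = region, delta = delta)
}

#' Presence/absence sites implied by a true intensity surface
#'
#' Places `n_sites` uniform random sites (on unmasked cells) and draws
#' independent Bernoulli outcomes with the point-process-implied occupancy
#' probability `1 - exp(-lambda * cell_area)`.
#'
#' @param surface an `"intensity_surface"` (the truth).
#' @param n_sites number of sites.
#' @param seed optional integer seed.
#' @return a [pa_pattern()].
#' @export
simulate_pa <- function(surface, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- region(surface$x0, surface$x0 + surface$n_cols * surface$cellsize,
              surface$y0, surface$y0 + surface$n_rows * surface$cellsize)
  x <- y <- numeric(0)
  while (length(x) < n_sites) {
    nx <- stats::runif(2 * n_sites, r$x_min, r$x_max)
    ny <- stats::runif(2 * n_sites, r$y_min, r$y_max)
    ok <- !is.na(surface_lookup(surface, nx, ny))
    x <- c(x, nx[ok]); y <- c(y, ny[ok])
  }
  x <- x[seq_len(n_sites)]; y <- y[seq_len(n_sites)]
  lam <- surface_lookup(surface, x, y)
  p <- 1 - exp(-lam * surface$cellsize^2)
  pa_pattern(x, y, stats::rbinom(n_sites, 1L, p), region = r)
}
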
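make_scheme <- function(stack, pattern, delta = 1) {
  make_quadrature(pattern, stack, delta)
}

test_that("design expansion yields intercept + linear + squared + bias columns", {
  set.seed(2)
  layers <- lapply(1:6, function(i) matrix(rnorm(16), 4, 4))
  names(layers) <- c(paste0("e", 1:4), "b1", "b2")
  st <- raster_stack(0, 0, 1, layers,
                     roles = c(rep("environmental", 4), rep("bias", 2)))
  pat <- point_pattern(c(1.2, 2.7), c(0.4, 3.3), "A",
                       region = region(0, 4, 0, 4))
  sch <- make_scheme(st, pat)
  built <- build_design(sch, spec_from_stack(st))
  expect_equal(ncol(built$X), 11L)   # 1 + 4 + 4 + 2
  expect_equal(colnames(built$X)[1], "(Intercept)")
  # weighted standardization: mean 0, variance 1 under quadrature weights
  w <- sch$weight / sum(sch$weight)
  for (j in 2:11) {
    expect_equal(sum(w * built$X[, j]), 0, tolerance = 1e-10)
    expect_equal(sum(w * built$X[, j]^2), 1, tolerance = 1e-10)
  }

  st1 <- gradient_stack(4, 4)
  sch1 <- make_scheme(st1, pat)
  expect_equal(ncol(build_design(sch1, design_spec("v"))$X), 3L)
})

test_that("zero-variance columns are dropped with a warning", {
  st <- const_stack(4, 4)
  pat <- point_pattern(1.5, 1.5, "A", region = region(0, 4, 0, 4))
  sch <- make_scheme(st, pat)
  expect_warning(built <- build_design(sch, design_spec("v")),
                 "zero-variance")
  expect_equal(colnames(built$X), "(Intercept)")
})

test_that("log-likelihood matches closed forms and a brute-force oracle", {
  st <- const_stack(1, 1)
  set.seed(3)
  pat <- point_pattern(runif(10), runif(10), "A", region = region(0, 1, 0, 1))
  sch <- make_scheme(st, pat, delta = 1)
  X <- matrix(1, length(sch$x), 1)
  # intercept-only at log(10), area 1: ll = 10*log(10) - 10
  expect_equal(ppm_loglik(sch, X, log(10)), 10 * log(10) - 10)
  # all-zero coefficients: lambda = 1, ll = -area
  expect_equal(ppm_loglik(sch, X, 0), -1)

  land <- test_landscape(seed = 12)
  pat2 <- simulate_ipp(land$surface, seed = 13)
  sch2 <- make_quadrature(pat2, land$stack, 1)
  built <- build_design(sch2, spec_from_stack(land$stack))
  set.seed(14)
  for (i in 1:5) {
    beta <- rnorm(ncol(built$X), sd = 0.5)
    expect_equal(ppm_loglik(sch2, built$X, beta),
                 bf_loglik(sch2, built$X, beta), tolerance = 1e-12)
  }
})

test_that("intercept-only fit is the closed-form log(m/area)", {
  st <- const_stack(10, 10)
  set.seed(4)
  pat <- point_pattern(runif(25, 0, 10), runif(25, 0, 10), "A",
                       region = region(0, 10, 0, 10))
  sch <- make_scheme(st, pat)
  fit <- suppressWarnings(fit_ppm(sch, design_spec("v")))
  expect_equal(fit$coefficients[["(Intercept)"]], log(25 / 100),
               tolerance = 1e-10)
  expect_equal(fit$loglik, 25 * log(0.25) - 25, tolerance = 1e-8)
})

test_that("a binary covariate recovers the stratified closed-form rates", {
  # region split into halves by a 0/1 layer; m1 = 3, m2 = 7 presences
  m <- matrix(rep(c(0, 1), each = 4), nrow = 2, ncol = 4)
  st <- raster_stack(0, 0, 0.5, list(half = m))
  set.seed(5)
  pat <- point_pattern(c(runif(3, 0, 1), runif(7, 1, 2)), runif(10, 0, 1),
                       "A", region = region(0, 2, 0, 1))
  sch <- make_quadrature(pat, st, 0.5)
  fit <- suppressWarnings(fit_ppm(sch, design_spec("half")))
  lam <- ppmbias:::predict_at(fit, st, c(0.5, 1.5), c(0.5, 0.5))
  expect_equal(lam, c(3 / 1, 7 / 1), tolerance = 1e-8)
})

test_that("unpenalized fits satisfy the score equation and local optimality", {
  land <- test_landscape(seed = 21)
  pat <- simulate_ipp(land$surface, seed = 22)
  spec <- spec_from_stack(land$stack)
  sch <- make_quadrature(pat, land$stack, 0.5)
  fit <- fit_ppm(sch, spec)
  built <- build_design(sch, spec)
  lam <- exp(drop(built$X %*% fit$coefficients))
  expect_equal(sum(sch$weight * lam), sch$m, tolerance = 1e-6 * sch$m)
  # perturbations of norm 1e-2 never beat the IRLS solution
  set.seed(23)
  for (i in 1:20) {
    d <- rnorm(length(fit$coefficients))
    d <- d / sqrt(sum(d^2)) * 1e-2
    expect_lte(ppm_loglik(sch, built$X, fit$coefficients + d), fit$loglik)
  }
})

test_that("IRLS agrees with derivative-free maximization on small instances", {
  set.seed(31)
  st <- gradient_stack(4, 4)
  for (rep in 1:3) {
    pat <- point_pattern(runif(12, 0, 4), runif(12, 0, 4), "A",
                         region = region(0, 4, 0, 4))
    sch <- make_quadrature(pat, st, 1)   # 16 dummies + 12 presences
    spec <- design_spec("v", quadratic = FALSE)
    fit <- fit_ppm(sch, spec)
    built <- build_design(sch, spec)
    ref <- optim_ppm(sch, built$X, start = unname(fit$coefficients * 0))
    expect_equal(unname(fit$coefficients), ref, tolerance = 1e-5)
  }
})

test_that("predicted surfaces are constant for intercept-only fits and integrate to m", {
  st <- const_stack(6, 6)
  set.seed(6)
  pat <- point_pattern(runif(18, 0, 6), runif(18, 0, 6), "A",
                       region = region(0, 6, 0, 6))
  sch <- make_quadrature(pat, st, 1)
  fit <- suppressWarnings(fit_ppm(sch, design_spec("v")))
  surf <- predict_intensity(fit, st)
  expect_equal(unique(as.vector(surf$values)), exp(fit$coefficients[[1]]))
  expect_equal(surface_integral(surf), 18, tolerance = 1e-8)

  land <- test_landscape(seed = 33)
  pat2 <- simulate_ipp(land$surface, seed = 34)
  sch2 <- make_quadrature(pat2, land$stack, 0.5)
  fit2 <- fit_ppm(sch2, spec_from_stack(land$stack))
  surf2 <- predict_intensity(fit2, land$stack)
  expect_equal(surface_integral(surf2), sch2$m, tolerance = 0.01 * sch2$m)
})

test_that("masked cells stay masked in predictions", {
  m <- matrix(rnorm(36), 6, 6); m[3, 4] <- NA
  st <- raster_stack(0, 0, 1, list(v = m))
  set.seed(7)
  ok <- FALSE
  while (!ok) {   # keep presences off the masked cell
    x <- runif(15, 0, 6); y <- runif(15, 0, 6)
    ok <- !any(floor(x) == 3 & floor(y) == 2)
  }
  pat <- point_pattern(x, y, "A", region = region(0, 6, 0, 6))
  sch <- make_quadrature(pat, st, 1)
  fit <- fit_ppm(sch, design_spec("v"))
  surf <- predict_intensity(fit, st)
  expect_true(is.na(surf$values[3, 4]))
  expect_equal(sum(is.na(surf$values)), 1L)
})
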
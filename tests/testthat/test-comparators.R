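test_that("intercept-only logistic fit returns the positive fraction", {
  st <- const_stack(4, 4)
  set.seed(61)
  tg <- point_pattern(runif(6, 0, 4), runif(6, 0, 4), "A",
                      region = region(0, 4, 0, 4))
  nt <- point_pattern(runif(14, 0, 4), runif(14, 0, 4), "B",
                      region = region(0, 4, 0, 4))
  fit <- suppressWarnings(
    pseudo_absence_points(tg, nt, st, design_spec("v")))
  expect_equal(unique(round(fit$fitted, 12)), 6 / 20, tolerance = 1e-8)
})

test_that("empty target or non-target patterns are errors", {
  st <- const_stack(4, 4)
  tg <- point_pattern(1, 1, "A", region = region(0, 4, 0, 4))
  empty <- point_pattern(numeric(0), numeric(0), character(0),
                         region = region(0, 4, 0, 4))
  expect_error(pseudo_absence_points(empty, tg, st, design_spec("v")),
               "empty target")
  expect_error(pseudo_absence_points(tg, empty, st, design_spec("v")),
               "pseudo-absences")
})

test_that("point-event fit on the habitat design equals per-habitat composition", {
  # with one binary covariate the logistic fit is saturated, so fitted
  # probabilities equal the sample proportion of events that are the
  # target, habitat by habitat
  st <- richness_stack()
  spec <- spec_from_stack(st)
  for (seed in c(62, 63, 64)) {
    pat <- richness_generate(seed = seed)
    tg <- subset_species(pat, "A")
    nt <- subset_species(pat, "A", keep = FALSE)
    fit <- suppressWarnings(pseudo_absence_points(tg, nt, st, spec))
    pr <- predict_prob(fit, st, c(2.5, 7.5), c(2, 2))
    hab <- ifelse(pat$x < 5, "I", "II")
    prop <- c(mean(pat$species[hab == "I"] == "A"),
              mean(pat$species[hab == "II"] == "A"))
    expect_equal(pr, prop, tolerance = 1e-7)
  }
})

test_that("a cell holding target and non-target points is a presence cell", {
  st <- const_stack(2, 1)
  tg <- point_pattern(0.3, 0.5, "A", region = region(0, 2, 0, 1))
  nt <- point_pattern(c(0.7, 1.5), c(0.5, 0.5), "B",
                      region = region(0, 2, 0, 1))
  # cell 1 has both -> response 1; cell 2 only non-target -> response 0
  fit <- suppressWarnings(
    pseudo_absence_cells(tg, nt, st, 1, design_spec("v")))
  expect_equal(fit$n1, 1L)
  expect_equal(fit$n0, 1L)
})

test_that("single-class cell data surface as a separation error", {
  st <- const_stack(2, 1)
  tg <- point_pattern(c(0.3, 1.5), c(0.5, 0.5), "A",
                      region = region(0, 2, 0, 1))
  nt <- point_pattern(0.7, 0.5, "B", region = region(0, 2, 0, 1))
  # every occupied cell contains the target: all responses are 1
  expect_error(suppressWarnings(
    pseudo_absence_cells(tg, nt, st, 1, design_spec("v"))),
    "separation")
})

test_that("cell-level compositional rates match a Monte-Carlo oracle", {
  # Implementation route: grid-cell comparator on simulated data.
  # Oracle route: simulate per-cell Poisson counts directly from the
  # generating rates and compute P(cell has target | cell non-empty).
  design <- richness_design()
  st <- richness_stack()
  spec <- spec_from_stack(st)
  n_rep <- 60
  set.seed(65)
  impl <- matrix(NA_real_, n_rep, 2)
  for (r in seq_len(n_rep)) {
    pat <- richness_generate(design)
    tg <- subset_species(pat, "A")
    nt <- subset_species(pat, "A", keep = FALSE)
    if (!npoints(tg) || !npoints(nt)) next
    fit <- try(suppressWarnings(
      pseudo_absence_cells(tg, nt, st, 1, spec)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    impl[r, ] <- predict_prob(fit, st, c(2.5, 7.5), c(2, 2))
  }
  rateA <- design$rates["A", ]
  rate_tot <- colSums(design$rates)
  oracle <- matrix(NA_real_, 4000, 2)
  for (r in seq_len(4000)) {
    for (h in 1:2) {
      nA <- rpois(20, rateA[h])
      nO <- rpois(20, rate_tot[h] - rateA[h])
      nonempty <- (nA + nO) > 0
      if (any(nonempty))
        oracle[r, h] <- sum(nA > 0 & nonempty) / sum(nonempty)
    }
  }
  for (h in 1:2) {
    est <- mean(impl[, h], na.rm = TRUE)
    ref <- mean(oracle[, h], na.rm = TRUE)
    se <- sd(impl[, h], na.rm = TRUE) / sqrt(sum(!is.na(impl[, h])))
    expect_lt(abs(est - ref), 3 * se)
  }
})

test_that("richness confounding: model-based rates invariant, compositional rates halve", {
  tab <- richness_experiment(100, seed = 66)
  get <- function(m, h) tab$estimate[tab$species == "A" &
                                       tab$method == m & tab$habitat == h]
  expect_equal(get("model_based", "I"), get("model_based", "II"),
               tolerance = 0.15)
  expect_equal(get("point_event", "I") / get("point_event", "II"), 2,
               tolerance = 0.1)
  expect_equal(get("grid_cell", "I") / get("grid_cell", "II"), 2,
               tolerance = 0.35)   # coarsening changes the numbers
})

test_that("point-event logistic slope approaches the difference of the two PPM fits", {
  # two independent log-linear processes over one smooth covariate: the
  # compositional (marked point) model is logistic with coefficients equal
  # to the difference of the log-intensity coefficients
  land <- synth_landscape(1, 0, coefficients = c(3.1, 0.5, 0),
                          region = region(0, 16, 0, 16), delta = 0.5,
                          seed = 67)
  env <- land$stack$layers$env1
  lam2 <- exp(2.9 - 0.3 * env)
  surf2 <- land$surface; surf2$values <- lam2
  p1 <- simulate_ipp(land$surface, seed = 68, species = "sp1")
  p2 <- simulate_ipp(surf2, seed = 69, species = "sp2")
  spec <- design_spec("env1", quadratic = FALSE)
  f1 <- fit_ppm(make_quadrature(p1, land$stack, 1), spec)
  f2 <- fit_ppm(make_quadrature(p2, land$stack, 1), spec)
  lg <- pseudo_absence_points(p1, p2, land$stack, spec)
  slope_ppm <- coef(f1, scale = "raw")[["env1"]] -
    coef(f2, scale = "raw")[["env1"]]
  slope_lg <- coef(lg, scale = "raw")[["env1"]]
  expect_lt(abs(slope_lg - slope_ppm), 0.1)
})
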
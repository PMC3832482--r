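test_that("block assignment tiles, partitions and respects the fold count", {
  r <- region(0, 64, 0, 64)
  bcv <- assign_blocks(r, 32, k = 4, repeats = 3, seed = 1)
  expect_equal(bcv$n_blocks, 4L)
  expect_error(assign_blocks(r, 32, k = 5), "fewer blocks")
  # partition: every block has exactly one fold label per repeat
  expect_true(all(bcv$folds %in% 1:4))
  for (rep in 1:3)
    expect_equal(sort(unique(bcv$folds[, rep])), 1:4)
  # every site maps to exactly one block
  set.seed(2)
  x <- runif(50, 0, 64); y <- runif(50, 0, 64)
  b <- block_of(bcv, x, y)
  expect_true(all(b >= 1 & b <= 4))
})

test_that("different seeds give different assignments on enough blocks", {
  r <- region(0, 160, 0, 64)
  a <- assign_blocks(r, 32, k = 5, repeats = 1, seed = 3)
  b <- assign_blocks(r, 32, k = 5, repeats = 1, seed = 4)
  expect_equal(a$n_blocks, 10L)
  expect_false(identical(a$folds, b$folds))
  expect_identical(assign_blocks(r, 32, k = 5, repeats = 2, seed = 5)$folds,
                   assign_blocks(r, 32, k = 5, repeats = 2, seed = 5)$folds)
})

test_that("AUC matches hand values and pair-counting", {
  expect_equal(auc(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_equal(auc(c(5, 4, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(5, 4, 2, 1), c(0, 0, 1, 1)), 0)
  expect_error(auc(1:3, c(1, 1, 1)), "both outcome classes")
  set.seed(6)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l), bf_auc(s, l), tolerance = 1e-12)
  }
})

test_that("deviance explained matches an independent GLM and handles edge cases", {
  set.seed(7)
  n <- 300
  pred <- exp(rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * log(pred)))
  d <- deviance_explained(pred, y)
  ref <- with(summary(glm(y ~ log(pred), family = binomial)),
              1 - deviance / null.deviance)
  expect_equal(d, ref, tolerance = 1e-8)
  # predictions independent of outcome explain nothing
  expect_lt(abs(deviance_explained(exp(rnorm(n)), y)), 0.03)
  expect_warning(d0 <- deviance_explained(rep(2, n), y), "constant")
  expect_equal(d0, 0)
  # perfectly separating predictions approach 1
  ysep <- rep(c(0, 1), each = 50)
  psep <- exp(c(rnorm(50, -3), rnorm(50, 3)))
  expect_gt(deviance_explained(psep, ysep), 0.95)
})

test_that("paired confidence intervals follow the t construction", {
  expect_equal(paired_ci(c(0, 0, 0)), c(mean = 0, lo = 0, hi = 0))
  ci <- paired_ci(c(1, 2, 3))
  expect_equal(ci[["mean"]], 2)
  expect_equal(ci[["hi"]] - 2, qt(0.975, 2) * 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(ci[["mean"]] - ci[["lo"]], ci[["hi"]] - ci[["mean"]])
  expect_error(paired_ci(1), "at least 2")
})

test_that("oracle penalty selection matches an exhaustive scan", {
  land <- test_landscape(seed = 8, coefficients = c(1.2, 0.5, -0.25, -0.4))
  pat <- simulate_ipp(land$surface, seed = 9)
  spec <- spec_from_stack(land$stack)
  sch <- make_quadrature(pat, land$stack, 0.5)
  path <- lasso_path(sch, spec, n_penalties = 15, ratio = 1e-3)
  pa <- simulate_pa(land$surface, 120, seed = 10)
  sel <- oracle_penalty(path, land$stack, pa)
  scan <- vapply(path$fits, function(f) {
    s <- ppmbias:::predict_at(f, land$stack, pa$x, pa$y)
    auc(s, pa$presence)
  }, 0)
  expect_equal(sel$auc, scan)
  expect_equal(sel$index, which.max(scan))
  # single-penalty path returns that penalty
  path1 <- path; path1$fits <- path$fits[1]; path1$penalties <- path$penalties[1]
  expect_equal(oracle_penalty(path1, land$stack, pa)$penalty,
               path$penalties[1])
  # a flat AUC profile ties to the largest penalty
  flat <- path
  flat$fits <- replicate(4, path$fits[[1]], simplify = FALSE)
  flat$penalties <- path$penalties[1:4]
  expect_equal(oracle_penalty(flat, land$stack, pa)$index, 1L)
})

test_that("methods with identical predictions tie exactly; shuffled labels sit at chance", {
  land <- test_landscape(seed = 11, n_bias = 0,
                         coefficients = c(1.6, 0.4, -0.2))
  pat <- simulate_ipp(land$surface, seed = 12)
  spec <- spec_from_stack(land$stack)   # no bias layers at all
  pa <- simulate_pa(land$surface, 150, seed = 13)
  bcv <- assign_blocks(land$region, 2, k = 4, repeats = 3, seed = 14)
  res <- cv_compare(pat, NULL, land$stack, spec, pa, bcv, delta = 0.5,
                    methods = c("uncorrected", "model_based"))
  # with no bias block the model-based arm reduces to the uncorrected one
  expect_equal(res$summary$mean, 0)
  expect_equal(res$summary$lo, 0)

  set.seed(15)
  pa_null <- pa
  pa_null$presence <- sample(pa$presence)
  res0 <- cv_compare(pat, NULL, land$stack, spec, pa_null, bcv, delta = 0.5,
                     methods = "uncorrected")
  expect_lt(abs(mean(res0$results$auc) - 0.5), 0.12)
})

test_that("no test-block presence information reaches training", {
  land <- test_landscape(seed = 16, coefficients = c(1.6, 0.4, -0.2, -0.3))
  pat <- simulate_ipp(land$surface, seed = 17)
  bcv <- assign_blocks(land$region, 4, k = 4, repeats = 1, seed = 18)
  test_blocks <- which(bcv$folds[, 1] == 1)
  masked <- ppmbias:::mask_blocks(land$stack, bcv, test_blocks)
  cc <- cell_centres(masked)
  inb <- block_of(bcv, cc$x, cc$y) %in% test_blocks
  expect_true(all(masked$mask[cbind(cc$row[inb], cc$col[inb])]))
  expect_false(any(masked$mask[cbind(cc$row[!inb], cc$col[!inb])] &
                     !land$stack$mask[cbind(cc$row[!inb], cc$col[!inb])]))
})

test_that("strong observer bias favours the model-based arm in most repeats", {
  set.seed(19)
  land <- synth_landscape(1, 1,
                          coefficients = c(2.2, 0.6, -0.3, -0.9),
                          region = region(0, 16, 0, 16), delta = 0.5,
                          seed = 19, correlation = 2)
  # observed records follow environment + access bias
  pat <- simulate_ipp(land$surface, seed = 20)
  # systematic PA surveys see the bias-free (environment-only) truth
  co <- land$coefficients; co["bias1"] <- 0
  truth <- synth_landscape(1, 1, coefficients = co,
                           region = region(0, 16, 0, 16), delta = 0.5,
                           seed = 19, correlation = 2)$surface
  pa <- simulate_pa(truth, 250, seed = 21)
  spec <- spec_from_stack(land$stack)
  bcv <- assign_blocks(land$region, 4, k = 4, repeats = 5, seed = 22)
  res <- cv_compare(pat, NULL, land$stack, spec, pa, bcv, delta = 1,
                    methods = c("uncorrected", "model_based"))
  d <- res$results$auc[res$results$method == "model_based"] -
    res$results$auc[res$results$method == "uncorrected"]
  expect_gt(mean(d > 0), 0.5)
})
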
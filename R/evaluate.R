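#' Spatial block cross-validation folds
#'
#' Tiles the region with square blocks anchored at the region origin
#' (edge blocks may be partial), then for each repeat randomly permutes
#' the blocks and deals them round-robin into `k` near-equal folds.
#' Coarse blocks (32 km default) keep spatial dependence between training
#' and test data low, so presence/absence evaluation is closer to
#' independent.
#'
#' @param region a [region()].
#' @param block_km block edge length in km.
#' @param k number of folds.
#' @param repeats number of independent random assignments.
#' @param seed optional integer seed.
#' @return An object of class `"block_cv"`; `folds` is an
#'   `n_blocks x repeats` integer matrix of fold labels.
#' @export
assign_blocks <- function(region, block_km = 32, k = 5L, repeats = 20L,
                          seed = NULL) {
  if (block_km <= 0) stop("block_km must be > 0")
  if (!is.null(seed)) set.seed(seed)
  bx <- quad_breaks(region$x_min, region$x_max, block_km)
  by <- quad_breaks(region$y_min, region$y_max, block_km)
  ncx <- length(bx) - 1L; ncy <- length(by) - 1L
  n_blocks <- ncx * ncy
  if (n_blocks < k)
    stop("fewer blocks (", n_blocks, ") than folds (", k, ")")
  folds <- matrix(0L, n_blocks, repeats)
  for (rep in seq_len(repeats)) {
    perm <- sample.int(n_blocks)
    folds[perm, rep] <- rep_len(seq_len(k), n_blocks)
  }
  structure(list(bx = bx, by = by, ncx = ncx, ncy = ncy,
                 n_blocks = n_blocks, k = k, repeats = repeats,
                 folds = folds, block_km = block_km, region = region),
            class = "block_cv")
}

#' Block id containing each location
#' @param bcv a `"block_cv"`.
#' @param x,y coordinates (km).
#' @return integer block ids in `1..n_blocks`.
#' @export
block_of <- function(bcv, x, y) {
  ix <- findInterval(x, bcv$bx, rightmost.closed = TRUE)
  iy <- findInterval(y, bcv$by, rightmost.closed = TRUE)
  (iy - 1L) * bcv$ncx + ix
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random presence
#' outscores a random absence, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes are required to compute AUC")
  rk <- rank(scores)
  (sum(rk[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Proportion of deviance explained by predictions
#'
#' Fits a logistic regression of the presence/absence outcome on the log
#' of the predictions (a single regressor) and returns
#' `1 - residual_deviance / null_deviance`.
#'
#' @param predictions positive predicted intensities/probabilities.
#' @param outcome 0/1 outcomes (or a [pa_pattern()]).
#' @return proportion of deviance explained (0 with a warning for
#'   constant predictions).
#' @export
deviance_explained <- function(predictions, outcome) {
  if (inherits(outcome, "pa_pattern")) outcome <- outcome$presence
  stopifnot(length(predictions) == length(outcome))
  if (any(!is.finite(predictions) | predictions <= 0))
    stop("predictions must be positive and finite")
  if (stats::sd(predictions) == 0) {
    warning("constant predictions explain no deviance")
    return(0)
  }
  X <- cbind(1, log(predictions))
  f <- suppressWarnings(stats::glm.fit(
    X, outcome, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100L)))
  p0 <- mean(outcome)
  null_dev <- -2 * sum(outcome * log(p0) + (1 - outcome) * log(1 - p0))
  1 - f$deviance / null_dev
}

#' Paired-t confidence interval for a mean difference
#' @param differences per-replicate paired differences (length >= 2).
#' @param level confidence level.
#' @return named vector `mean`, `lo`, `hi`.
#' @export
paired_ci <- function(differences, level = 0.95) {
  n <- length(differences)
  if (n < 2L) stop("need at least 2 paired differences")
  m <- mean(differences)
  half <- stats::qt((1 + level) / 2, n - 1L) * stats::sd(differences) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Oracle LASSO penalty for presence/absence prediction
#'
#' Scans a fitted regularization path and returns the penalty whose
#' predictions score the highest AUC against supplied presence/absence
#' data (ties to the larger penalty). An oracle in the sense that it uses
#' the evaluation data itself, removing penalty-selection noise from
#' method comparisons.
#'
#' @param path a `"reg_path"`.
#' @param stack covariate [raster_stack()].
#' @param pa a [pa_pattern()].
#' @param z0 optional bias anchor; when given (and the spec has a bias
#'   block) scoring uses bias-conditioned predictions.
#' @return list with `penalty`, `index` and the per-penalty `auc` vector.
#' @export
oracle_penalty <- function(path, stack, pa, z0 = NULL) {
  if (!length(path$fits)) stop("empty regularization path")
  aucs <- vapply(path$fits, function(f) {
    use_z0 <- !is.null(z0) && length(f$spec$bias)
    s <- predict_at(f, stack, pa$x, pa$y, z0 = if (use_z0) z0 else NULL)
    ok <- !is.na(s)
    auc(s[ok], pa$presence[ok])
  }, 0)
  i <- which.max(aucs)    # first max = largest penalty (path decreasing)
  list(penalty = path$penalties[i], index = i, auc = aucs)
}

mask_blocks <- function(stack, bcv, blocks) {
  cc <- cell_centres(stack)
  inb <- block_of(bcv, cc$x, cc$y) %in% blocks
  layers <- lapply(stack$layers, function(m) {
    m[cbind(cc$row[inb], cc$col[inb])] <- NA_real_
    m
  })
  raster_stack(stack$x0, stack$y0, stack$cellsize, layers,
               roles = stack$roles)
}

#' Spatial block cross-validated comparison of bias-correction methods
#'
#' For every repeat and fold: masks the test blocks out of the covariate
#' stack, restricts the presence-only training data to the training
#' blocks, fits each requested method, scores the presence/absence sites
#' in the test blocks, then pools the test scores per repeat and computes
#' AUC and deviance explained. Methods:
#' \describe{
#'   \item{uncorrected}{point process on environmental covariates only,
#'     raw prediction;}
#'   \item{model_based}{point process on environmental + bias covariates,
#'     bias-conditioned prediction at the anchor `z0`;}
#'   \item{pseudo_point}{point-event pseudo-absence logistic regression;}
#'   \item{pseudo_cell}{grid-cell pseudo-absence logistic regression.}
#' }
#' Paired per-repeat AUC differences of `model_based` against each other
#' method are summarized with a paired-t confidence interval.
#'
#' A training presence is assigned to the block containing the centre of
#' its quadrature cell, so the presence/quadrature split is consistent;
#' choose `delta` to divide `block_km`. Folds whose test PA sites are all
#' one class are skipped (and counted).
#'
#' @param target target-species [point_pattern()].
#' @param nontarget non-target presences (needed for the pseudo-absence
#'   methods; may be `NULL` otherwise).
#' @param stack covariate [raster_stack()].
#' @param spec a [design_spec()] including the bias layers.
#' @param pa presence/absence [pa_pattern()] for scoring.
#' @param bcv a `"block_cv"` from [assign_blocks()].
#' @param delta quadrature resolution (km).
#' @param methods subset of the four method names.
#' @param z0 bias anchor for `model_based` (default all-zero).
#' @param penalty `"none"` (unpenalized), `"bic"`, or `"oracle"` (path +
#'   AUC-optimal penalty per fold, scored on the fold's test PA data).
#' @param cell_delta aggregation size for `pseudo_cell` (km).
#' @return An object of class `"eval_result"`: `results` (data frame of
#'   method, repeat, auc, dev_expl), `summary` (paired AUC differences
#'   with CI), and `skipped_folds`.
#' @export
cv_compare <- function(target, nontarget = NULL, stack, spec, pa, bcv,
                       delta, methods = c("uncorrected", "model_based",
                                          "pseudo_point", "pseudo_cell"),
                       z0 = NULL, penalty = "none", cell_delta = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (any(methods %in% c("pseudo_point", "pseudo_cell")) &&
      is.null(nontarget))
    stop("pseudo-absence methods require non-target presences")
  if (is.null(z0))
    z0 <- stats::setNames(as.list(rep(0, length(spec$bias))), spec$bias)
  env_spec <- design_spec(spec$env, character(0),
                          quadratic = spec$quadratic,
                          interactions = spec$interactions)
  # block of the quadrature cell containing each point
  cell_block <- function(x, y) {
    r <- target$region
    bx <- quad_breaks(r$x_min, r$x_max, delta)
    by <- quad_breaks(r$y_min, r$y_max, delta)
    cx <- (bx[-1L] + bx[-length(bx)]) / 2
    cy <- (by[-1L] + by[-length(by)]) / 2
    block_of(bcv, cx[findInterval(x, bx, rightmost.closed = TRUE)],
             cy[findInterval(y, by, rightmost.closed = TRUE)])
  }
  tblock <- cell_block(target$x, target$y)
  oblock <- if (!is.null(nontarget)) cell_block(nontarget$x, nontarget$y)
  pablock <- block_of(bcv, pa$x, pa$y)
  all_blocks <- seq_len(bcv$n_blocks)
  results <- NULL
  skipped <- 0L
  fit_and_score <- function(method, tr_target, tr_nontarget, tr_stack,
                            px, py, pa_fold) {
    if (method %in% c("uncorrected", "model_based")) {
      sp <- if (method == "model_based") spec else env_spec
      sch <- make_quadrature(tr_target, tr_stack, delta)
      if (identical(penalty, "none")) {
        fit <- fit_ppm(sch, sp)
      } else {
        path <- lasso_path(sch, sp, n_penalties = 40L, ratio = 1e-3)
        fit <- if (identical(penalty, "bic")) bic_select(path) else
          path$fits[[oracle_penalty(path, stack, pa_fold,
                                    z0 = if (method == "model_based") z0
                                    else NULL)$index]]
      }
      predict_at(fit, stack, px, py,
                 z0 = if (method == "model_based" && length(sp$bias)) z0
                 else NULL)
    } else {
      pen <- if (identical(penalty, "none")) "none" else "bic"
      fit <- if (method == "pseudo_point")
        pseudo_absence_points(tr_target, tr_nontarget, tr_stack, env_spec,
                              penalty = pen)
      else
        pseudo_absence_cells(tr_target, tr_nontarget, tr_stack, cell_delta,
                             env_spec, penalty = pen)
      predict_prob(fit, stack, px, py)
    }
  }
  for (rep in seq_len(bcv$repeats)) {
    scores <- stats::setNames(
      replicate(length(methods), numeric(0), simplify = FALSE), methods)
    truth <- integer(0)
    for (fold in seq_len(bcv$k)) {
      test_blocks <- all_blocks[bcv$folds[, rep] == fold]
      ipa <- pablock %in% test_blocks
      if (length(unique(pa$presence[ipa])) < 2L) { skipped <- skipped + 1L; next }
      tr_stack <- mask_blocks(stack, bcv, test_blocks)
      keep_t <- !(tblock %in% test_blocks)
      tr_target <- structure(list(x = target$x[keep_t], y = target$y[keep_t],
                                  species = target$species[keep_t],
                                  region = target$region),
                             class = "point_pattern")
      tr_nontarget <- if (!is.null(nontarget)) {
        keep_o <- !(oblock %in% test_blocks)
        structure(list(x = nontarget$x[keep_o], y = nontarget$y[keep_o],
                       species = nontarget$species[keep_o],
                       region = nontarget$region),
                  class = "point_pattern")
      }
      px <- pa$x[ipa]; py <- pa$y[ipa]
      pa_fold <- pa_pattern(px, py, pa$presence[ipa], region = pa$region)
      for (mth in methods) {
        s <- fit_and_score(mth, tr_target, tr_nontarget, tr_stack,
                           px, py, pa_fold)
        s[is.na(s)] <- min(s, na.rm = TRUE)   # masked test cells: lowest score
        scores[[mth]] <- c(scores[[mth]], s)
      }
      truth <- c(truth, pa$presence[ipa])
    }
    if (!length(truth)) next
    for (mth in methods) {
      results <- rbind(results, data.frame(
        method = mth, rep = rep,
        auc = auc(scores[[mth]], truth),
        dev_expl = deviance_explained(pmax(scores[[mth]], 1e-12), truth)))
    }
  }
  summary <- NULL
  if ("model_based" %in% methods) {
    mb <- results$auc[results$method == "model_based"]
    for (mth in setdiff(methods, "model_based")) {
      d <- mb - results$auc[results$method == mth]
      if (length(d) >= 2L) {
        ci <- paired_ci(d)
        summary <- rbind(summary, data.frame(
          comparison = paste0("model_based - ", mth),
          mean = ci[["mean"]], lo = ci[["lo"]], hi = ci[["hi"]]))
      }
    }
  }
  structure(list(results = results, summary = summary,
                 skipped_folds = skipped),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  agg <- stats::aggregate(cbind(auc, dev_expl) ~ method, data = x$results,
                          FUN = mean)
  cat("block-CV evaluation (means over repeats):\n")
  print(agg)
  if (!is.null(x$summary)) {
    cat("paired AUC differences (95% CI):\n")
    print(x$summary)
  }
  if (x$skipped_folds)
    cat(sprintf("skipped %d single-class fold(s)\n", x$skipped_folds))
  invisible(x)
}
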
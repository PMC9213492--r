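#' Configuration of the boosted regression tree protocol
#'
#' Defaults follow common ecological practice for gradient-boosted
#' regression trees: slow learning (0.01), shallow interaction depth (3),
#' a 25% held-out fraction per tree whose deviance scores the model
#' (the cross-validated R^2), at least 1000 trees with the final tree count
#' optimised on held-out improvement, and a variable-importance threshold of
#' 7 (on the 0-100 normalised scale) below which predictors are dropped.
#'
#' @param bag_fraction fraction of sites HELD OUT of each tree's fit and
#'   used to score it (0 < bag_fraction < 1)
#' @param min_trees minimum trees in any reported model (>= 1000)
#' @param max_trees trees grown; the reported model uses the held-out-optimal
#'   count in `[min_trees, max_trees]`
#' @param learning_rate shrinkage applied to each tree's contribution
#' @param tree_depth maximum tree depth (interaction order)
#' @param min_obs minimum sites per terminal node
#' @param vi_threshold variable-importance cutoff (0-100 scale) for dropping
#'   predictors
#' @param redundancy_rho absolute Spearman correlation above which two
#'   same-direction predictors are treated as redundant
#' @param redundancy_cv_tol maximum CV R^2 loss accepted when dropping the
#'   weaker member of a redundant pair
#' @param moran_alpha two-sided significance level of the residual Moran
#'   test that triggers the spatial-autocovariate refit
#' @param direction_tol non-monotonicity ratio above which a partial
#'   dependence is labelled `"mixed"` rather than signed
#' @param seed integer seed for bagging
#' @return list of class `brt_config`
#' @export
brt_config <- function(bag_fraction = 0.25, min_trees = 1000, max_trees = 1500,
                       learning_rate = 0.01, tree_depth = 3, min_obs = 10,
                       vi_threshold = 7, redundancy_rho = 0.8,
                       redundancy_cv_tol = 0.02, moran_alpha = 0.05,
                       direction_tol = 0.5, seed = 1L) {
  .check(bag_fraction > 0 && bag_fraction < 1, "bag_fraction must be in (0,1)")
  .check(min_trees >= 1000, "min_trees must be >= 1000")
  .check(max_trees >= min_trees, "max_trees must be >= min_trees")
  .check(learning_rate > 0 && tree_depth >= 1, "invalid learning rate / depth")
  structure(list(bag_fraction = bag_fraction, min_trees = as.integer(min_trees),
                 max_trees = as.integer(max_trees),
                 learning_rate = learning_rate, tree_depth = as.integer(tree_depth),
                 min_obs = as.integer(min_obs), vi_threshold = vi_threshold,
                 redundancy_rho = redundancy_rho,
                 redundancy_cv_tol = redundancy_cv_tol,
                 moran_alpha = moran_alpha, direction_tol = direction_tol,
                 seed = as.integer(seed)),
            class = "brt_config")
}

#' Fit a boosted regression tree model
#'
#' Stochastic gradient boosting with squared-error loss: trees are fit
#' sequentially to the current residuals, each on a random 75% of sites
#' (with `bag_fraction = 0.25` held out), and shrunk into the ensemble. The
#' held-out sites score each tree's deviance improvement; their cumulative
#' improvement relative to the null deviance is the cross-validated R^2, and
#' its argmax (not below `min_trees`) fixes the reported tree count.
#' Variable importance is the split-count-weighted sum of squared-error
#' improvements per predictor, averaged over the used trees and rescaled to
#' sum 100.
#'
#' @param X numeric predictor matrix or data.frame (no missing values)
#' @param y numeric response (no missing values, not constant)
#' @param config a [brt_config()]
#' @return object of class `brt_fit` with elements `vi` (sums to 100),
#'   `cv_r2`, `best_trees`, `variables`, and the fitted ensemble
#' @export
fit_brt <- function(X, y, config = brt_config()) {
  X <- .as_matrix(X)
  .check(nrow(X) == length(y), "X and y must align")
  .check(!anyNA(X) && !anyNA(y), "missing values are not allowed in X or y")
  .check(nrow(X) >= 30, "need at least 30 sites")
  if (sd(y) == 0) stop("constant response: fit refused (degenerate)", call. = FALSE)

  set.seed(config$seed)
  fit <- .gbm_fit_cpp(X, y, config$max_trees, config$learning_rate,
                      config$tree_depth, config$bag_fraction, config$min_obs)

  null_dev <- mean((y - mean(y))^2)
  cum_impr <- cumsum(fit$oob_improve)
  window <- config$min_trees:config$max_trees
  best_trees <- window[which.max(cum_impr[window])]
  cv_r2 <- min(cum_impr[best_trees] / null_dev, 1)

  raw <- rowSums(fit$var_imp[, seq_len(best_trees), drop = FALSE])
  vi <- if (sum(raw) > 0) 100 * raw / sum(raw) else rep(0, length(raw))
  names(vi) <- colnames(X)

  structure(list(init = fit$init, trees = fit$trees,
                 shrinkage = config$learning_rate, best_trees = best_trees,
                 vi = vi, cv_r2 = cv_r2, variables = colnames(X),
                 oob_improve = fit$oob_improve, null_dev = null_dev,
                 config = config, y = y, X = X),
            class = "brt_fit")
}

#' @export
print.brt_fit <- function(x, ...) {
  cat("Boosted regression trees:", x$best_trees, "trees, CV R^2 =",
      round(x$cv_r2, 3), "\n")
  vi <- sort(x$vi, decreasing = TRUE)
  for (nm in names(vi)) cat(sprintf("  %-20s VI %6.2f\n", nm, vi[nm]))
  invisible(x)
}

#' Predict from a fitted boosted tree ensemble
#' @param object a `brt_fit`
#' @param newdata predictor matrix/data.frame with the fit's variables
#' @param n_trees ensemble size (defaults to the held-out-optimal count)
#' @param ... unused
#' @export
predict.brt_fit <- function(object, newdata, n_trees = object$best_trees, ...) {
  newdata <- .as_matrix(newdata)
  .check(all(object$variables %in% colnames(newdata)),
         "newdata lacks fitted variables")
  newdata <- newdata[, object$variables, drop = FALSE]
  .gbm_predict_cpp(object$trees, object$init, object$shrinkage, newdata,
                   as.integer(n_trees))
}

#' Partial dependence of the fitted response on one predictor
#'
#' Sweeps the predictor over a grid spanning its observed range while the
#' remaining predictors keep their observed values (a background subsample
#' for speed), and averages the ensemble predictions — the marginal response
#' shape after accounting for the average effect of everything else.
#'
#' @param fit a `brt_fit`
#' @param variable predictor name
#' @param grid_size grid points over the predictor's range
#' @param n_background background rows averaged over (subsampled evenly)
#' @return data.frame `value`, `response`
#' @export
partial_dependence <- function(fit, variable, grid_size = 25,
                               n_background = 200) {
  .check(variable %in% fit$variables, "unknown variable")
  X <- fit$X
  bg <- X[unique(round(seq(1, nrow(X), length.out = min(n_background, nrow(X))))), ,
          drop = FALSE]
  grid <- seq(min(X[, variable]), max(X[, variable]), length.out = grid_size)
  big <- bg[rep(seq_len(nrow(bg)), times = grid_size), , drop = FALSE]
  big[, variable] <- rep(grid, each = nrow(bg))
  pred <- predict(fit, big)
  data.frame(value = grid,
             response = colMeans(matrix(pred, nrow = nrow(bg))))
}

#' Direction of a partial-dependence curve
#'
#' The sign of the least-squares slope through the curve; `"mixed"` when the
#' curve is non-monotone beyond tolerance, i.e. when its smaller directional
#' variation (sum of negative vs positive increments) exceeds `tol` times
#' the larger one. `"none"` for a flat curve.
#'
#' @param pd data.frame from [partial_dependence()]
#' @param tol non-monotonicity ratio for the `"mixed"` label
#' @return one of `"positive"`, `"negative"`, `"mixed"`, `"none"`
#' @export
effect_direction <- function(pd, tol = 0.5) {
  dr <- diff(pd$response)
  up <- sum(pmax(dr, 0)); down <- sum(pmax(-dr, 0))
  if (up + down < 1e-12) return("none")
  if (min(up, down) > tol * max(up, down)) return("mixed")
  slope <- coef(lm(response ~ value, data = pd))[2]
  if (slope >= 0) "positive" else "negative"
}

#' Reduce the predictor set of a boosted tree model
#'
#' The two-stage reduction of the modelling protocol. (1) Importance: fit,
#' delete every predictor with VI below the threshold, refit; repeated to a
#' fixed point so the final model only carries predictors at or above the
#' threshold. (2) Redundancy: among the retained predictors, pairs with
#' |Spearman rho| at or above `redundancy_rho` and the same
#' partial-dependence direction are candidates; the lower-VI member is
#' dropped unless that costs more than `redundancy_cv_tol` of CV R^2. Every
#' decision is logged.
#'
#' @param X predictors, `y` response, `config` a [brt_config()]
#' @param y numeric response
#' @param config a [brt_config()]
#' @return list of class `brt_reduction`: `fit` (final `brt_fit`),
#'   `variables`, `dropped`, `initial_vi` (the full model's VI scores before
#'   any deletion), `log`; `intercept_only = TRUE` when everything was
#'   deleted
#' @export
reduce_variables <- function(X, y, config = brt_config()) {
  X <- .as_matrix(X)
  log <- character()
  vars <- colnames(X)
  fit <- fit_brt(X[, vars, drop = FALSE], y, config)
  initial_vi <- fit$vi
  log <- .log_line(log, "initial fit: ", length(vars), " variables, cv_r2 = ",
                   round(fit$cv_r2, 3))

  # stage 1: VI threshold to fixed point
  repeat {
    low <- names(fit$vi)[fit$vi < config$vi_threshold]
    if (length(low) == 0 || length(low) == length(fit$vi)) break
    vars <- setdiff(vars, low)
    log <- .log_line(log, "VI < ", config$vi_threshold, ": dropped ",
                     paste(low, collapse = ", "))
    fit <- fit_brt(X[, vars, drop = FALSE], y, config)
    log <- .log_line(log, "refit: ", length(vars), " variables, cv_r2 = ",
                     round(fit$cv_r2, 3))
  }
  if (all(fit$vi < config$vi_threshold)) {
    log <- .log_line(log, "all variables below threshold: intercept-only")
    return(structure(list(fit = NULL, variables = character(0),
                          dropped = colnames(X), initial_vi = initial_vi,
                          log = log, intercept_only = TRUE),
                     class = "brt_reduction"))
  }

  # stage 2: redundant same-direction pairs
  if (length(vars) >= 2) {
    dirs <- vapply(vars, function(v)
      effect_direction(partial_dependence(fit, v), config$direction_tol),
      character(1))
    rho <- cor(X[, vars, drop = FALSE], method = "spearman")
    pairs <- which(abs(rho) >= config$redundancy_rho & upper.tri(rho),
                   arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      ord <- order(-abs(rho[pairs]))
      for (k in ord) {
        a <- vars[pairs[k, 1]]; b <- vars[pairs[k, 2]]
        if (!(a %in% vars) || !(b %in% vars)) next
        if (dirs[a] != dirs[b]) next
        drop_var <- if (fit$vi[a] <= fit$vi[b]) a else b
        cand <- setdiff(vars, drop_var)
        cand_fit <- fit_brt(X[, cand, drop = FALSE], y, config)
        if (fit$cv_r2 - cand_fit$cv_r2 <= config$redundancy_cv_tol) {
          log <- .log_line(log, "redundant pair ", a, " ~ ", b,
                           " (|rho| = ", round(abs(rho[a, b]), 2),
                           ", direction ", dirs[a], "): dropped ", drop_var,
                           ", cv_r2 ", round(fit$cv_r2, 3), " -> ",
                           round(cand_fit$cv_r2, 3))
          vars <- cand; fit <- cand_fit
        } else {
          log <- .log_line(log, "redundant pair ", a, " ~ ", b,
                           ": kept both (cv_r2 loss ",
                           round(fit$cv_r2 - cand_fit$cv_r2, 3), " > tol)")
        }
      }
    }
  }
  structure(list(fit = fit, variables = vars,
                 dropped = setdiff(colnames(X), vars), initial_vi = initial_vi,
                 log = log, intercept_only = FALSE), class = "brt_reduction")
}

#' Run the full boosted-tree modelling protocol with SAC correction
#'
#' The complete sequence: fit and reduce the predictor set; test the final
#' model's residuals for spatial autocorrelation with a two-sided Moran's I
#' test on Voronoi-adjacency weights; when significant, build a
#' Voronoi-neighborhood autocovariate of the response, refit with it, and
#' keep whichever model has the better CV R^2 (best-fit rule); verify that
#' the chosen model reduced |Moran's I|. Reports the variable-importance
#' scores (summing to 100), the partial-dependence effect direction per
#' predictor, the CV R^2, and — when the autocovariate is in the final model
#' — the share of variation attributed to spatial autocorrelation (the
#' autocovariate's VI), alongside the CV R^2 it added.
#'
#' @param X predictor matrix/data.frame
#' @param y numeric response
#' @param coords 2-column site coordinates
#' @param config a [brt_config()]
#' @return list of class `brt_result`: `selected_variables`, `vi`,
#'   `initial_vi`, `direction`, `cv_r2`, `partial_dependence`, `sac_share`,
#'   `sac_cv_r2_gain`, `moran_initial`, `moran_final`, `sac_used`, `log`,
#'   `fit`
#' @export
run_brt_pipeline <- function(X, y, coords, config = brt_config()) {
  X <- .as_matrix(X)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  .check(nrow(X) == length(y) && nrow(coords) == length(y),
         "X, y and coords must align by site")

  red <- reduce_variables(X, y, config)
  log <- red$log
  if (red$intercept_only)
    return(structure(list(selected_variables = character(0), vi = numeric(0),
                          initial_vi = red$initial_vi, direction = character(0),
                          cv_r2 = NA_real_, sac_share = NA_real_,
                          sac_used = FALSE, log = log),
                     class = "brt_result"))
  fit <- red$fit

  nb <- delaunay_neighbors(coords)
  W <- voronoi_weights(coords, nb = nb)
  res0 <- y - predict(fit, X[, red$variables, drop = FALSE])
  m0 <- morans_i(res0, W)
  log <- .log_line(log, "residual Moran's I = ", round(m0$I, 4), ", p = ",
                   signif(m0$p, 3))

  sac_used <- FALSE; m1 <- NULL; sac_gain <- NA_real_
  if (m0$p < config$moran_alpha) {
    ac <- build_autocovariate(y, coords, nb = nb)
    Xs <- cbind(X[, red$variables, drop = FALSE], sac_autocov = ac)
    fit_sac <- fit_brt(Xs, y, config)
    log <- .log_line(log, "SAC detected: autocovariate refit cv_r2 = ",
                     round(fit_sac$cv_r2, 3), " vs ", round(fit$cv_r2, 3))
    if (fit_sac$cv_r2 > fit$cv_r2) {
      sac_gain <- fit_sac$cv_r2 - fit$cv_r2
      res1 <- y - predict(fit_sac, Xs)
      m1 <- morans_i(res1, W)
      sac_used <- TRUE
      fit <- fit_sac
      log <- .log_line(log, "autocovariate model selected (best fit); |I| ",
                       round(abs(m0$I), 4), " -> ", round(abs(m1$I), 4),
                       if (abs(m1$I) < abs(m0$I)) " (reduced)"
                       else " (NOT reduced)")
    } else {
      log <- .log_line(log, "autocovariate model discarded (no fit improvement)")
    }
  } else {
    log <- .log_line(log, "no significant residual SAC: autocovariate path not taken")
  }

  vars <- fit$variables
  pd <- lapply(setNames(vars, vars), function(v) partial_dependence(fit, v))
  direction <- vapply(pd, effect_direction, character(1),
                      tol = config$direction_tol)
  sac_share <- if (sac_used) unname(fit$vi["sac_autocov"]) else NA_real_

  structure(list(selected_variables = setdiff(vars, "sac_autocov"),
                 vi = fit$vi, initial_vi = red$initial_vi,
                 direction = direction, cv_r2 = fit$cv_r2,
                 partial_dependence = pd, sac_share = sac_share,
                 sac_cv_r2_gain = sac_gain, moran_initial = m0,
                 moran_final = m1, sac_used = sac_used, log = log, fit = fit),
            class = "brt_result")
}

#' @export
print.brt_result <- function(x, ...) {
  cat("BRT pipeline result: CV R^2 =", round(x$cv_r2, 3), "\n")
  if (length(x$vi)) {
    vi <- sort(x$vi, decreasing = TRUE)
    for (nm in names(vi))
      cat(sprintf("  %-20s VI %6.2f  %s\n", nm, vi[nm],
                  if (!is.null(x$direction[[nm]])) x$direction[[nm]] else ""))
  }
  if (isTRUE(x$sac_used))
    cat("Spatial autocorrelation explained", round(x$sac_share, 1),
        "% of the variation (autocovariate VI)\n")
  invisible(x)
}

#' Bar chart of variable importance with effect directions
#'
#' Horizontal bars of the final model's VI scores, annotated with the
#' partial-dependence direction of each predictor.
#'
#' @param x a `brt_result`
#' @param ... passed to [graphics::barplot()]
#' @export
plot.brt_result <- function(x, ...) {
  vi <- sort(x$vi)
  lab <- vapply(names(vi), function(nm) {
    d <- x$direction[[nm]]
    sym <- switch(if (is.null(d)) "none" else d,
                  positive = "(+)", negative = "(-)", mixed = "(+/-)", "")
    paste(nm, sym)
  }, character(1))
  op <- graphics::par(mar = c(4, 10, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(vi, names.arg = lab, horiz = TRUE, las = 1,
                    xlab = "Relative influence (VI, sums to 100)", ...)
  invisible(x)
}
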
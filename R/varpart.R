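#' R^2 of an ordinary least-squares regression (internal)
#' @noRd
.ols_r2 <- function(y, X) {
  n <- length(y)
  yc <- y - mean(y)
  if (is.null(X) || ncol(X) == 0) return(list(r2 = 0, p = 0, rank = 0))
  qrX <- qr(cbind(1, X))
  fitted <- qr.fitted(qrX, y)
  r2 <- 1 - sum((y - fitted)^2) / sum(yc^2)
  list(r2 = r2, p = qrX$rank - 1, rank = qrX$rank - 1)
}

#' Variance inflation factors within a predictor group
#'
#' VIF of each column = 1 / (1 - R^2) from regressing it on the other
#' columns of its group; exactly collinear columns get infinite VIF.
#'
#' @param X numeric matrix or data.frame (n > p)
#' @return named numeric vector of VIFs
#' @export
vif <- function(X) {
  X <- .as_matrix(X)
  .check(nrow(X) > ncol(X), "need more observations than variables")
  if (ncol(X) == 1) return(setNames(1, colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- .ols_r2(X[, j], X[, -j, drop = FALSE])$r2
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' Iterative collinearity screening by variance inflation factor
#'
#' Repeatedly drops the highest-VIF variable until every VIF is at or below
#' the threshold (8 by default). Among exactly tied worst offenders (e.g. an
#' exactly collinear pair), the later-listed variable is dropped first.
#'
#' @param X numeric matrix or data.frame
#' @param threshold maximum acceptable VIF
#' @return list of class `vif_filter`: `X` (retained columns), `retained`,
#'   `dropped`, `vif` (final VIFs), `log`
#' @export
vif_filter <- function(X, threshold = 8) {
  X <- .as_matrix(X)
  dropped <- character(); log <- character()
  repeat {
    v <- vif(X)
    if (max(v) <= threshold || ncol(X) == 1) break
    worst <- which(v >= max(v) - 1e-10)
    j <- max(worst)  # later-listed member goes first
    log <- .log_line(log, "dropped ", colnames(X)[j], " (VIF = ",
                     if (is.infinite(v[j])) "Inf" else round(v[j], 2), ")")
    dropped <- c(dropped, colnames(X)[j])
    X <- X[, -j, drop = FALSE]
  }
  structure(list(X = X, retained = colnames(X), dropped = dropped,
                 vif = vif(X), log = log), class = "vif_filter")
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`, the unbiased-under-null
#' adjustment used throughout variation partitioning.
#'
#' @param r2 raw coefficient of determination
#' @param n number of observations
#' @param p number of predictors (0 returns `r2` unchanged)
#' @return adjusted R^2 (can be negative)
#' @export
adjusted_r2 <- function(r2, n, p) {
  .check(n > p + 1, "adjusted R^2 undefined: need n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variation partitioning of a response across 2-4 predictor groups
#'
#' Fits every non-empty union of the groups by least squares, converts each
#' R^2 to adjusted R^2, and solves the inclusion-exclusion system for the
#' unique and shared fractions (15 fractions for 4 groups) plus the
#' residual. Shared fractions can legitimately be negative under adjusted
#' R^2 arithmetic and are reported as computed. Unique fractions carry
#' permutation p-values from [test_unique_fraction()].
#'
#' @param y numeric response
#' @param groups named list of 2-4 numeric matrices/data.frames, typically
#'   pre-screened with [vif_filter()]
#' @param n_perm permutations for the unique-fraction tests (0 skips them)
#' @param seed integer seed for the permutation tests
#' @return list of class `partition_result`: `fractions` (data.frame with
#'   the exclusive fraction of every group combination), `residual`,
#'   `full_adj_r2`, `unique_p`, `group_adj_r2`
#' @export
variation_partition <- function(y, groups, n_perm = 999, seed = 1L) {
  .check(is.list(groups) && length(groups) >= 2 && length(groups) <= 4,
         "groups must be a named list of 2-4 matrices")
  .check(!is.null(names(groups)) && all(nzchar(names(groups))),
         "groups must be named")
  groups <- lapply(groups, .as_matrix)
  k <- length(groups)
  n <- length(y)

  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  adj <- vapply(subsets, function(s) {
    Xu <- do.call(cbind, groups[s])
    f <- .ols_r2(y, Xu)
    adjusted_r2(f$r2, n, f$rank)
  }, numeric(1))

  # inclusion-exclusion: adj[T] = sum of fractions f_S with S intersecting T
  m <- 2^k - 1
  M <- matrix(0, m, m)
  for (ti in seq_len(m)) for (si in seq_len(m))
    M[ti, si] <- as.numeric(length(intersect(subsets[[ti]], subsets[[si]])) > 0)
  fractions <- solve(M, adj)

  labels <- vapply(subsets, function(s) paste(names(groups)[s], collapse = ":"),
                   character(1))
  sizes <- lengths(subsets)
  frac_df <- data.frame(fraction = labels, n_groups = sizes,
                        adj_r2 = fractions, stringsAsFactors = FALSE)
  frac_df <- frac_df[order(frac_df$n_groups, frac_df$fraction), ]
  rownames(frac_df) <- NULL

  full_adj <- adj[[m]]
  unique_p <- rep(NA_real_, k); names(unique_p) <- names(groups)
  if (n_perm > 0) {
    for (g in seq_len(k)) {
      others <- do.call(cbind, groups[-g])
      tst <- test_unique_fraction(y, groups[[g]], others, n_perm = n_perm,
                                  seed = seed + g)
      unique_p[g] <- tst[["p"]]
    }
  }
  group_adj <- vapply(seq_len(k), function(g) adj[[2^(g - 1)]], numeric(1))
  names(group_adj) <- names(groups)

  structure(list(fractions = frac_df, residual = 1 - full_adj,
                 full_adj_r2 = full_adj, unique_p = unique_p,
                 group_adj_r2 = group_adj, n = n),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Variation partitioning: full-model adjusted R^2 =",
      round(x$full_adj_r2, 4), "\n")
  df <- x$fractions
  for (i in seq_len(nrow(df)))
    cat(sprintf("  [%s] %s%7.4f\n", df$fraction[i],
                strrep(" ", max(0, 30 - nchar(df$fraction[i]))), df$adj_r2[i]))
  cat("  residual", strrep(" ", 24), sprintf("%7.4f\n", x$residual))
  if (!all(is.na(x$unique_p))) {
    cat("Unique-fraction permutation p-values:\n")
    for (nm in names(x$unique_p))
      cat(sprintf("  %-12s p = %.4g\n", nm, x$unique_p[nm]))
  }
  invisible(x)
}

#' Euler-Venn areas of a variation partitioning
#'
#' Exports the fractions as display areas for an area-proportional
#' Euler-Venn diagram: negative fractions are clamped to 0 for display (the
#' fractions table itself is never clamped).
#'
#' @param x a `partition_result`
#' @return named list of nonnegative areas, plus `residual`
#' @export
venn_areas <- function(x) {
  .check(inherits(x, "partition_result"), "x must be a partition_result")
  areas <- pmax(x$fractions$adj_r2, 0)
  out <- as.list(areas)
  names(out) <- gsub(":", "&", x$fractions$fraction)
  out$residual <- max(x$residual, 0)
  out
}

#' Permutation test of a unique variation fraction
#'
#' Partial F test of the target group's contribution beyond the conditioning
#' variables, with a permutation null built by permuting the residuals of
#' the reduced (conditioning-only) model — the permutation-of-residuals
#' scheme. `p = (exceedances + 1) / (n_perm + 1)`.
#'
#' @param y numeric response
#' @param X_target group matrix whose unique fraction is tested
#' @param X_condition conditioning matrix (NULL for a marginal test)
#' @param n_perm number of permutations (>= 1), default 999
#' @param seed integer seed
#' @return named numeric `c(F, p)`
#' @export
test_unique_fraction <- function(y, X_target, X_condition = NULL,
                                 n_perm = 999, seed = 1L) {
  .check(n_perm >= 1, "n_perm must be >= 1")
  X_target <- .as_matrix(X_target)
  n <- length(y)
  Q_red <- if (is.null(X_condition) || NCOL(X_condition) == 0)
    qr.Q(qr(matrix(1, n, 1)))
  else qr.Q(qr(cbind(1, .as_matrix(X_condition))))[, seq_len(qr(cbind(1, .as_matrix(X_condition)))$rank), drop = FALSE]
  Xfull <- if (is.null(X_condition) || NCOL(X_condition) == 0)
    cbind(1, X_target) else cbind(1, .as_matrix(X_condition), X_target)
  qrF <- qr(Xfull)
  Q_full <- qr.Q(qrF)[, seq_len(qrF$rank), drop = FALSE]

  q_red <- ncol(Q_red); q_full <- ncol(Q_full)
  df1 <- q_full - q_red
  df2 <- n - q_full
  .check(df1 >= 1 && df2 >= 1, "insufficient degrees of freedom")

  rss <- function(Q, Y) colSums(Y^2) - colSums(crossprod(Q, Y)^2)
  ymat <- matrix(y, ncol = 1)
  rss_red <- rss(Q_red, ymat); rss_full <- rss(Q_full, ymat)
  Fobs <- ((rss_red - rss_full) / df1) / (rss_full / df2)

  set.seed(seed)
  fitted_red <- drop(Q_red %*% crossprod(Q_red, y))
  res_red <- y - fitted_red
  perm <- replicate(n_perm, sample.int(n))
  Ystar <- fitted_red + matrix(res_red[perm], nrow = n)
  rss_red_s <- rss(Q_red, Ystar); rss_full_s <- rss(Q_full, Ystar)
  Fstar <- ((rss_red_s - rss_full_s) / df1) / (rss_full_s / df2)
  p <- (sum(Fstar >= Fobs) + 1) / (n_perm + 1)
  c(F = unname(Fobs), p = p)
}
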
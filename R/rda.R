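#' Redundancy analysis of a multi-species response on driver variables
#'
#' Constrained ordination built directly from linear algebra: the centred
#' response matrix is regressed on the drivers, and the fitted values are
#' eigen-decomposed (via SVD). Eigenvalues are on the variance scale (sums
#' of squares over n - 1), so their total over constrained plus residual
#' axes equals the total variance of the response. Scores follow the
#' standard triplot scalings; the default, scaling 2 (correlation biplot),
#' scales species scores by the square root of their axis eigenvalues and
#' reports driver biplot scores as correlations with the constrained site
#' scores.
#'
#' @param Y site x species abundance matrix (numeric)
#' @param X driver matrix/data.frame
#' @param transform `"none"` or `"hellinger"` (square root of row-relative
#'   abundances, a standard pre-transformation for abundance data)
#' @param scaling triplot scaling, 1 (distance) or 2 (correlation, default)
#' @return list of class `rda_fit`: `eigenvalues`, `proportion` (of total
#'   variance per constrained axis), `total_inertia`, `constrained_inertia`,
#'   `adj_r2`, `site_scores` (constrained, "lc"), `wa_scores`,
#'   `species_scores`, `biplot_scores`, `rank`, plus the inputs needed by
#'   [rda_axis_test()]
#' @export
rda_fit <- function(Y, X, transform = c("none", "hellinger"), scaling = 2) {
  transform <- match.arg(transform)
  Y <- as.matrix(Y); X <- .as_matrix(X)
  n <- nrow(Y)
  .check(nrow(X) == n, "Y and X must align by site")
  if (transform == "hellinger") {
    rs <- rowSums(Y)
    rs[rs == 0] <- 1
    Y <- sqrt(Y / rs)
  }
  Yc <- sweep(Y, 2, colMeans(Y))

  qrX <- qr(cbind(1, X))
  rankX <- qrX$rank - 1
  .check(n > rankX + 1, "need more sites than driver rank")
  if (rankX < ncol(X))
    message("rank-deficient drivers: using rank ", rankX, " of ", ncol(X))
  Yhat <- qr.fitted(qrX, Yc)

  sv <- svd(Yhat)
  keep <- which(sv$d^2 / (n - 1) > max(sv$d^2 / (n - 1)) * 1e-10 & sv$d > 0)
  keep <- head(keep, min(rankX, ncol(Y)))
  d <- sv$d[keep]
  eig <- d^2 / (n - 1)
  tot <- sum(Yc^2) / (n - 1)
  constrained <- sum(eig)

  r2 <- constrained / tot
  adj <- adjusted_r2(r2, n, rankX)

  U <- sv$u[, keep, drop = FALSE]            # orthonormal site directions
  V <- sv$v[, keep, drop = FALSE]            # orthonormal species directions
  axis_names <- paste0("RDA", seq_along(keep))
  if (scaling == 2) {
    species <- V %*% diag(sqrt(eig), length(keep))
    sites <- U * sqrt(n - 1)
  } else {
    species <- V
    sites <- U %*% diag(d, length(keep))
  }
  wa <- Yc %*% V %*% diag(1 / d, length(keep))
  if (scaling == 1) wa <- wa %*% diag(d, length(keep)) / sqrt(n - 1)
  biplot <- cor(X, U)

  dimnames(species) <- list(colnames(Y), axis_names)
  dimnames(sites) <- list(rownames(Y), axis_names)
  dimnames(wa) <- list(rownames(Y), axis_names)
  dimnames(biplot) <- list(colnames(X), axis_names)

  structure(list(eigenvalues = setNames(eig, axis_names),
                 proportion = setNames(eig / tot, axis_names),
                 total_inertia = tot, constrained_inertia = constrained,
                 r2 = r2, adj_r2 = adj, rank = rankX,
                 site_scores = sites, wa_scores = wa,
                 species_scores = species, biplot_scores = biplot,
                 scaling = scaling, transform = transform,
                 Yc = Yc, X = X, U = U, n = n),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis:", length(x$eigenvalues), "constrained axes\n")
  cat("  total variance      ", round(x$total_inertia, 4), "\n")
  cat("  constrained         ", round(x$constrained_inertia, 4),
      sprintf("(R^2 = %.4f, adjusted %.4f)\n", x$r2, x$adj_r2))
  for (nm in names(x$eigenvalues))
    cat(sprintf("  %s: eigenvalue %.4f (%.2f%% of variance)\n", nm,
                x$eigenvalues[nm], 100 * x$proportion[nm]))
  invisible(x)
}

#' Triplot of a redundancy analysis
#'
#' Sites as points, species and driver arrows labelled, in the fitted
#' scaling.
#'
#' @param x an `rda_fit`
#' @param axes two axes to draw
#' @param ... passed to [graphics::plot()]
#' @export
plot.rda_fit <- function(x, axes = c(1, 2), ...) {
  .check(length(x$eigenvalues) >= max(axes), "not enough axes")
  s <- x$wa_scores[, axes]; sp <- x$species_scores[, axes]
  bp <- x$biplot_scores[, axes]
  mult <- 0.8 * max(abs(s)) / max(abs(bp))
  graphics::plot(s, pch = 16, col = "grey60", asp = 1,
                 xlab = sprintf("%s (%.2f%%)", names(x$eigenvalues)[axes[1]],
                                100 * x$proportion[axes[1]]),
                 ylab = sprintf("%s (%.2f%%)", names(x$eigenvalues)[axes[2]],
                                100 * x$proportion[axes[2]]), ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey80")
  graphics::arrows(0, 0, bp[, 1] * mult, bp[, 2] * mult, length = 0.08,
                   col = "firebrick")
  graphics::text(bp * mult * 1.08, labels = rownames(bp), col = "firebrick",
                 cex = 0.8)
  graphics::text(sp, labels = rownames(sp), col = "navy", cex = 0.8)
  invisible(x)
}

#' Permutation tests of the constrained ordination axes
#'
#' Tests each constrained axis in turn, conditioning on the preceding axes:
#' for axis k, the response and drivers are residualised on the first k - 1
#' constrained site-score directions, the axis eigenvalue is compared to its
#' permutation distribution obtained by permuting the rows of the
#' residualised response, and `F = eigenvalue / (residual variance /
#' residual df)` with `p = (exceedances + 1) / (n_perm + 1)`.
#'
#' @param fit an [rda_fit()] result
#' @param n_perm number of permutations, default 499
#' @param seed integer seed
#' @param max_axes test at most this many leading axes
#' @return data.frame `axis`, `eigenvalue`, `F`, `p`
#' @export
rda_axis_test <- function(fit, n_perm = 499, seed = 1L, max_axes = Inf) {
  .check(inherits(fit, "rda_fit"), "fit must come from rda_fit()")
  .check(n_perm >= 1, "n_perm must be >= 1")
  n <- fit$n
  n_axes <- min(length(fit$eigenvalues), max_axes)
  df_res <- n - 1 - fit$rank
  .check(df_res >= 1, "no residual degrees of freedom")

  lambda1 <- function(Y, Q) {
    B <- crossprod(Q, Y)
    svd(B, nu = 0, nv = 0)$d[1]^2 / (n - 1)
  }
  out <- data.frame(axis = names(fit$eigenvalues)[seq_len(n_axes)],
                    eigenvalue = unname(fit$eigenvalues[seq_len(n_axes)]),
                    F = NA_real_, p = NA_real_)
  set.seed(seed)
  for (k in seq_len(n_axes)) {
    if (k == 1) {
      Yk <- fit$Yc; Xk <- fit$X
    } else {
      Z <- fit$U[, seq_len(k - 1), drop = FALSE]
      Yk <- fit$Yc - Z %*% crossprod(Z, fit$Yc)
      Xk <- fit$X - Z %*% crossprod(Z, fit$X)
    }
    qrk <- qr(cbind(1, Xk))
    Qk <- qr.Q(qrk)[, seq_len(qrk$rank), drop = FALSE]
    lam_obs <- lambda1(Yk, Qk)
    res_obs <- (sum(Yk^2) / (n - 1) - sum(crossprod(Qk, Yk)^2) / (n - 1))
    Fobs <- lam_obs / (res_obs / df_res)

    exceed <- 0
    for (b in seq_len(n_perm)) {
      Ys <- Yk[sample.int(n), , drop = FALSE]
      lam_s <- lambda1(Ys, Qk)
      res_s <- (sum(Ys^2) - sum(crossprod(Qk, Ys)^2)) / (n - 1)
      Fs <- lam_s / (res_s / df_res)
      if (Fs >= Fobs) exceed <- exceed + 1
    }
    out$F[k] <- Fobs
    out$p[k] <- (exceed + 1) / (n_perm + 1)
  }
  out
}
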
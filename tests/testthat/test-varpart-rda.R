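test_that("VIF matches its closed form and screens collinearity", {
  set.seed(201)
  n <- 100
  # centred, mutually orthogonal columns by construction (orthogonal to the
  # intercept too, so the auxiliary regressions are exactly empty)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  colnames(Q) <- c("a", "b", "c")
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)
  expect_equal(vif_filter(Q)$retained, c("a", "b", "c"))
  # correlated pair: VIF = 1 / (1 - r^2), both retained at threshold 8
  x1 <- rnorm(n); x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  X <- cbind(u = x1, v = x2)
  r2 <- cor(x1, x2)^2
  expect_equal(unname(vif(X)), rep(1 / (1 - r2), 2), tolerance = 1e-10)
  expect_equal(length(vif_filter(X)$dropped), 0)
  # exact duplicate: the later-listed member goes first
  Xd <- cbind(p = x1, q = rnorm(n), p2 = x1)
  vf <- vif_filter(Xd)
  expect_equal(vf$dropped, "p2")
  expect_setequal(vf$retained, c("p", "q"))
})

test_that("adjusted R^2 follows the closed form", {
  expect_equal(adjusted_r2(0.5, 101, 10), 1 - 0.5 * 100 / 90, tolerance = 1e-12)
  expect_equal(round(adjusted_r2(0.5, 101, 10), 4), 0.4444)
  expect_equal(adjusted_r2(0.37, 50, 0), 0.37)
  for (p in 1:5) expect_lte(adjusted_r2(0.6, 40, p), 0.6)
  expect_error(adjusted_r2(0.5, 5, 4), "n > p")
})

test_that("two-group partitioning equals hand inclusion-exclusion on a fixture", {
  set.seed(202)
  n <- 12
  X1 <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a1", "a2")))
  X2 <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("b1", "b2")))
  y <- rnorm(n)
  vp <- variation_partition(y, list(A = X1, B = X2), n_perm = 0)
  # subset regressions through an independent normal-equations oracle
  aA <- adjusted_r2(oracle_r2(y, X1), n, 2)
  aB <- adjusted_r2(oracle_r2(y, X2), n, 2)
  aAB <- adjusted_r2(oracle_r2(y, cbind(X1, X2)), n, 4)
  fr <- setNames(vp$fractions$adj_r2, vp$fractions$fraction)
  expect_equal(unname(fr["A"]), aAB - aB, tolerance = 1e-10)
  expect_equal(unname(fr["B"]), aAB - aA, tolerance = 1e-10)
  expect_equal(unname(fr["A:B"]), aA + aB - aAB, tolerance = 1e-10)
  expect_equal(vp$residual, 1 - aAB, tolerance = 1e-10)
})

test_that("four-group fractions match vegan and close to the full model", {
  set.seed(203)
  n <- 80
  Xs <- lapply(1:4, function(i)
    matrix(rnorm(n * 2), n, dimnames = list(NULL, paste0("g", i, "_", 1:2))))
  names(Xs) <- c("Geo", "Clim", "Hum", "Land")
  y <- Xs[[3]][, 1] + rnorm(n)
  vp <- variation_partition(y, Xs, n_perm = 0)
  expect_equal(sum(vp$fractions$adj_r2), vp$full_adj_r2, tolerance = 1e-10)
  expect_equal(sum(vp$fractions$adj_r2) + vp$residual, 1, tolerance = 1e-10)
  vv <- vegan::varpart(y, Xs[[1]], Xs[[2]], Xs[[3]], Xs[[4]])
  iv <- vv$part$indfract$Adj.R.square
  uniques <- setNames(vp$fractions$adj_r2[vp$fractions$n_groups == 1],
                      vp$fractions$fraction[vp$fractions$n_groups == 1])
  expect_equal(unname(uniques[c("Geo", "Clim", "Hum", "Land")]), iv[1:4],
               tolerance = 1e-10)
})

test_that("planted unique structure lands in the right fraction", {
  set.seed(204)
  n <- 150
  Xs <- lapply(1:4, function(i)
    matrix(rnorm(n * 2), n, dimnames = list(NULL, paste0("g", i, "_", 1:2))))
  names(Xs) <- paste0("G", 1:4)
  y <- 2 * Xs[[1]][, 1] + 2 * Xs[[1]][, 2] + rnorm(n, 0, 0.5)
  vp <- variation_partition(y, Xs, n_perm = 99, seed = 5)
  fr <- setNames(vp$fractions$adj_r2, vp$fractions$fraction)
  expect_equal(unname(fr["G1"]), vp$full_adj_r2, tolerance = 0.05)
  expect_lt(max(abs(fr[names(fr) != "G1"])), 0.05)
  expect_lt(vp$unique_p[["G1"]], 0.05)
  # perfectly confounded copy: uniques vanish, the pair fraction holds it
  Xs2 <- Xs; Xs2[[2]] <- Xs[[1]]; names(Xs2) <- paste0("G", 1:4)
  vp2 <- variation_partition(y, Xs2, n_perm = 0)
  fr2 <- setNames(vp2$fractions$adj_r2, vp2$fractions$fraction)
  expect_lt(abs(fr2[["G1"]]), 0.02)
  expect_lt(abs(fr2[["G2"]]), 0.02)
  expect_gt(fr2[["G1:G2"]], 0.7)
})

test_that("unique-fraction permutation test is deterministic and powerful", {
  set.seed(205)
  n <- 200
  Xt <- matrix(rnorm(n * 2), n)
  Xc <- matrix(rnorm(n * 2), n)
  y <- 2 * Xt[, 1] + rnorm(n)
  t1 <- test_unique_fraction(y, Xt, Xc, n_perm = 999, seed = 31)
  t2 <- test_unique_fraction(y, Xt, Xc, n_perm = 999, seed = 31)
  expect_identical(t1, t2)
  expect_equal(t1[["p"]], 0.001)  # the minimum attainable at 999 permutations
  expect_error(test_unique_fraction(y, Xt, Xc, n_perm = 0), "n_perm")
})

test_that("RDA reproduces exact, orthonormal and permutation identities", {
  set.seed(206)
  n <- 40
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  B <- matrix(rnorm(3 * 5), 3)
  # exact linear response: everything constrained
  Y <- X %*% B
  r <- rda_fit(Y, X)
  expect_equal(r$constrained_inertia / r$total_inertia, 1, tolerance = 1e-10)
  # orthonormal drivers: constrained axes are the PCA of the fitted values
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n))); colnames(Q) <- c("a", "b", "c")
  Y2 <- matrix(rnorm(n * 5), n)
  r2 <- rda_fit(Y2, Q)
  Y2c <- sweep(Y2, 2, colMeans(Y2))
  fitted <- oracle_ols_fitted(Y2c[, 1], Q)
  Yhat <- vapply(1:5, function(j) oracle_ols_fitted(Y2c[, j], Q), numeric(n))
  pca <- prcomp(Yhat, center = FALSE)
  expect_equal(unname(r2$eigenvalues),
               (pca$sdev^2)[seq_along(r2$eigenvalues)], tolerance = 1e-8)
  # species relabeling permutes scores, leaves eigenvalues untouched
  perm <- c(3, 1, 5, 2, 4)
  r3 <- rda_fit(Y2[, perm], Q)
  expect_equal(r3$eigenvalues, r2$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(unname(r3$species_scores)),
               abs(unname(r2$species_scores[perm, ])), tolerance = 1e-8)
})

test_that("RDA eigenvalues conserve the fitted-value variance and match vegan", {
  set.seed(207)
  n <- 35
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  Y <- matrix(rnorm(n * 6), n)
  Y[, 1] <- Y[, 1] + 2 * X[, 1]
  r <- rda_fit(Y, X)
  Yc <- sweep(Y, 2, colMeans(Y))
  Yhat <- vapply(seq_len(ncol(Y)), function(j) oracle_ols_fitted(Yc[, j], X),
                 numeric(n))
  expect_equal(sum(r$eigenvalues), sum(Yhat^2) / (n - 1), tolerance = 1e-8)
  expect_true(all(diff(r$eigenvalues) <= 1e-12))
  v <- vegan::rda(Y ~ ., data = as.data.frame(X))
  expect_equal(unname(r$eigenvalues), unname(v$CCA$eig), tolerance = 1e-8)
  expect_equal(r$adj_r2, vegan::RsquareAdj(v)$adj.r.squared, tolerance = 1e-10)
  # hellinger switch behaves like the standard transformation
  Yp <- abs(Y)
  rh <- rda_fit(Yp, X, transform = "hellinger")
  vh <- vegan::rda(vegan::decostand(Yp, "hellinger") ~ ., data = as.data.frame(X))
  expect_equal(unname(rh$eigenvalues), unname(vh$CCA$eig), tolerance = 1e-8)
})

test_that("axis permutation tests find a planted gradient and only it", {
  set.seed(208)
  hits <- t(vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 60
    grad <- rnorm(n)
    X <- cbind(g = grad, n1 = rnorm(n), n2 = rnorm(n))
    Y <- outer(grad, c(1, -1, 0.5, 0.8)) + matrix(rnorm(n * 4, 0, 0.8), n)
    f <- rda_fit(Y, X)
    at <- rda_axis_test(f, n_perm = 199, seed = s, max_axes = 2)
    c(p1 = at$p[1], p2 = at$p[2])
  }, numeric(2)))
  expect_lt(median(hits[, "p1"]), 0.05)
  expect_gt(median(hits[, "p2"]), 0.05)
  # determinism
  set.seed(209)
  n <- 40
  Y <- matrix(rnorm(n * 4), n); X <- matrix(rnorm(n * 2), n)
  f <- rda_fit(Y, X)
  expect_identical(rda_axis_test(f, n_perm = 99, seed = 3),
                   rda_axis_test(f, n_perm = 99, seed = 3))
})

test_that("least-squares internals agree with normal equations at small n", {
  set.seed(210)
  for (rep in 1:5) {
    n <- sample(10:20, 1)
    X <- matrix(rnorm(n * 3), n)
    y <- rnorm(n)
    f <- variation_partition(y, list(A = X[, 1:2], B = X[, 3, drop = FALSE]),
                             n_perm = 0)
    aAB <- adjusted_r2(oracle_r2(y, X), n, 3)
    expect_equal(f$full_adj_r2, aAB, tolerance = 1e-8)
  }
})

test_that("venn areas clamp display values but never the table", {
  set.seed(211)
  n <- 50
  Xs <- list(A = matrix(rnorm(n * 2), n), B = matrix(rnorm(n * 2), n))
  y <- rnorm(n)
  vp <- variation_partition(y, Xs, n_perm = 0)
  va <- venn_areas(vp)
  expect_true(all(unlist(va) >= 0))
  expect_equal(sort(names(va)), sort(c("A", "B", "A&B", "residual")))
})
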
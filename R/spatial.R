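#' Delaunay neighbor structure of a point set
#'
#' Computes the Delaunay triangulation (Bowyer–Watson insertion) and returns
#' the neighbor graph — exactly the adjacency of the dual Voronoi
#' tessellation, the neighborhood definition used for the spatial weights
#' and the spatial-autocorrelation autocovariate. Degenerate geometries
#' (fewer than 3 points, or all points collinear) fall back to
#' k-nearest-neighbor adjacency with a message.
#'
#' @param coords 2-column matrix/data.frame of coordinates
#' @param fallback_k neighbors per site in the degenerate fallback
#' @return list of class `delaunay_nb`: `neighbors` (list of integer
#'   vectors), `coords`, and `fallback` (TRUE when knn was used)
#' @export
delaunay_neighbors <- function(coords, fallback_k = 2) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- nrow(coords)
  .check(n >= 2, "need at least 2 points")

  degenerate <- n < 3 ||
    qr(sweep(coords, 2, colMeans(coords)))$rank < 2
  if (degenerate) {
    message("degenerate geometry: falling back to ", fallback_k,
            "-nearest-neighbor adjacency")
    D <- .distmat(coords); diag(D) <- Inf
    k <- min(fallback_k, n - 1)
    nb <- lapply(seq_len(n), function(i) sort(order(D[i, ])[seq_len(k)]))
    # symmetrise
    for (i in seq_len(n)) for (j in nb[[i]])
      if (!(i %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], i))
    return(structure(list(neighbors = nb, coords = coords, fallback = TRUE),
                     class = "delaunay_nb"))
  }

  # scale into the unit square and add a distant bounding frame; frame
  # points can only remove (never add) real-point adjacencies, and at this
  # distance a lost hull edge would need hull points collinear to ~1e-5
  rng <- apply(coords, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-12)  # one isotropic factor: Delaunay
  P <- sweep(coords, 2, rng[1, ]) / span   # structure is not affine-invariant
  M <- 1e4
  P <- rbind(P, c(-M, -M), c(M + 1, -M), c(M + 1, M + 1), c(-M, M + 1))
  sup <- n + 1:4

  # orient counter-clockwise so the incircle determinant has a fixed sign
  ccw <- function(v) {
    a <- v[1]; b <- v[2]; c <- v[3]
    det <- (P[b, 1] - P[a, 1]) * (P[c, 2] - P[a, 2]) -
      (P[b, 2] - P[a, 2]) * (P[c, 1] - P[a, 1])
    if (det < 0) v[c(1, 3, 2)] else v
  }
  # p strictly inside the circumcircle of CCW triangles (vectorised over rows)
  incircle <- function(tri, px, py) {
    ax <- P[tri[, 1], 1] - px; ay <- P[tri[, 1], 2] - py
    bx <- P[tri[, 2], 1] - px; by <- P[tri[, 2], 2] - py
    cx <- P[tri[, 3], 1] - px; cy <- P[tri[, 3], 2] - py
    a2 <- ax * ax + ay * ay; b2 <- bx * bx + by * by; c2 <- cx * cx + cy * cy
    det <- ax * (by * c2 - b2 * cy) - ay * (bx * c2 - b2 * cx) +
      a2 * (bx * cy - by * cx)
    det > 0
  }

  tri <- rbind(ccw(sup[c(1, 2, 3)]), ccw(sup[c(1, 3, 4)]))
  for (p in seq_len(n)) {
    px <- P[p, 1]; py <- P[p, 2]
    bad <- which(incircle(tri, px, py))
    if (length(bad) == 0) next  # numerically outside everything; skip
    enc <- function(a, b) {
      lo <- pmin(a, b); hi <- pmax(a, b); lo * (n + 5) + hi
    }
    edges <- rbind(cbind(tri[bad, 1], tri[bad, 2]),
                   cbind(tri[bad, 2], tri[bad, 3]),
                   cbind(tri[bad, 1], tri[bad, 3]))
    keys <- enc(edges[, 1], edges[, 2])
    cnt <- table(keys)
    boundary <- edges[keys %in% as.numeric(names(cnt)[cnt == 1]), , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    for (e in seq_len(nrow(boundary)))
      tri <- rbind(tri, ccw(c(boundary[e, 1], boundary[e, 2], p)))
  }
  keep <- rowSums(matrix(tri %in% sup, nrow = nrow(tri))) == 0
  tri <- tri[keep, , drop = FALSE]

  nb <- vector("list", n)
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    nb[[v[1]]] <- c(nb[[v[1]]], v[2], v[3])
    nb[[v[2]]] <- c(nb[[v[2]]], v[1], v[3])
    nb[[v[3]]] <- c(nb[[v[3]]], v[1], v[2])
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  structure(list(neighbors = nb, coords = coords, fallback = FALSE),
            class = "delaunay_nb")
}

#' Spatial weight matrix from Voronoi (Delaunay) adjacency
#'
#' Binary contiguity weights between Voronoi-adjacent sites, optionally
#' row-standardised (style `"W"`, the default) so each site's neighbor
#' weights sum to 1.
#'
#' @param coords 2-column coordinate matrix
#' @param style `"W"` row-standardised or `"B"` binary
#' @param nb optional precomputed [delaunay_neighbors()] result
#' @return an n x n weight matrix with zero diagonal
#' @export
voronoi_weights <- function(coords, style = c("W", "B"), nb = NULL) {
  style <- match.arg(style)
  if (is.null(nb)) nb <- delaunay_neighbors(coords)
  n <- length(nb$neighbors)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, nb$neighbors[[i]]] <- 1
  W <- pmax(W, t(W))  # adjacency is symmetric by construction; be safe
  if (style == "W") {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  W
}

#' Moran's I test for spatial autocorrelation
#'
#' Computes Moran's I of `x` under a spatial weight matrix, its analytic
#' expectation `-1/(n-1)`, and a two-sided p-value — either from the
#' normal approximation under randomisation, or from a permutation null.
#' Two-sided by default so that negative autocorrelation is detected too.
#'
#' @param x numeric values (e.g. model residuals), length n >= 4
#' @param W n x n spatial weight matrix (see [voronoi_weights()])
#' @param method `"normal"` (randomisation variance) or `"permutation"`
#' @param nperm permutations when `method = "permutation"`
#' @param alternative `"two.sided"`, `"greater"` or `"less"`
#' @return list of class `moran_test`: `I`, `expected`, `sd`, `p`, `method`
#' @export
morans_i <- function(x, W, method = c("normal", "permutation"), nperm = 999,
                     alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method); alternative <- match.arg(alternative)
  n <- length(x)
  .check(n >= 4, "need at least 4 observations")
  .check(is.matrix(W) && all(dim(W) == n), "W must be an n x n matrix")
  if (sd(x) == 0) stop("zero-variance input: Moran's I undefined", call. = FALSE)

  z <- x - mean(x)
  S0 <- sum(W)
  I <- (n / S0) * sum(z * (W %*% z)) / sum(z^2)
  EI <- -1 / (n - 1)

  Wt <- W + t(W)
  S1 <- 0.5 * sum(Wt^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  # randomisation variance (Cliff & Ord)
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2

  if (method == "normal") {
    zscore <- (I - EI) / sqrt(VI)
    p <- switch(alternative,
                two.sided = 2 * pnorm(-abs(zscore)),
                greater = pnorm(zscore, lower.tail = FALSE),
                less = pnorm(zscore))
  } else {
    Iperm <- replicate(nperm, {
      zp <- z[sample.int(n)]
      (n / S0) * sum(zp * (W %*% zp)) / sum(zp^2)
    })
    p <- switch(alternative,
                two.sided = (sum(abs(Iperm - EI) >= abs(I - EI)) + 1) / (nperm + 1),
                greater = (sum(Iperm >= I) + 1) / (nperm + 1),
                less = (sum(Iperm <= I) + 1) / (nperm + 1))
  }
  structure(list(I = I, expected = EI, sd = sqrt(VI), p = p,
                 method = method, alternative = alternative),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), p = %.4g [%s, %s]\n",
              x$I, x$expected, x$p, x$method, x$alternative))
  invisible(x)
}

#' Spatial autocovariate from Voronoi neighborhoods
#'
#' For each site, the inverse-distance-weighted mean of the response over its
#' Voronoi-adjacent (Delaunay) neighbors. Feeding this covariate into a
#' model absorbs residual spatial autocorrelation in the response.
#'
#' @param y numeric response, one value per site
#' @param coords 2-column coordinate matrix
#' @param nb optional precomputed [delaunay_neighbors()] result
#' @return numeric autocovariate, one value per site
#' @export
build_autocovariate <- function(y, coords, nb = NULL) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  .check(length(y) == nrow(coords), "y and coords must align")
  if (is.null(nb)) nb <- delaunay_neighbors(coords)
  D <- .distmat(coords)
  vapply(seq_along(y), function(i) {
    js <- nb$neighbors[[i]]
    if (length(js) == 0) return(y[i])
    w <- 1 / pmax(D[i, js], 1e-12)
    sum(w * y[js]) / sum(w)
  }, numeric(1))
}
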
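# Independent brute-force oracles. These re-derive quantities from first
# principles (double sums, exhaustive enumeration, normal equations) and are
# deliberately kept free of any package internals.

# Moran's I as an explicit double sum
oracle_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Delaunay adjacency by exhaustive empty-circumcircle triangles
oracle_delaunay_edges <- function(coords) {
  n <- nrow(coords)
  circum <- function(a, b, c) {
    ax <- coords[a, 1]; ay <- coords[a, 2]; bx <- coords[b, 1]; by <- coords[b, 2]
    cx <- coords[c, 1]; cy <- coords[c, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ux - ax)^2 + (uy - ay)^2))
  }
  edges <- matrix(integer(0), ncol = 2)
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    cir <- circum(a, b, cc)
    if (is.null(cir)) next
    others <- setdiff(seq_len(n), c(a, b, cc))
    d_others <- sqrt((coords[others, 1] - cir[1])^2 + (coords[others, 2] - cir[2])^2)
    if (all(d_others > cir[3] * (1 + 1e-9)))
      edges <- rbind(edges, c(a, b), c(a, cc), c(b, cc))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

edges_from_nb <- function(nb) {
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_along(nb$neighbors)) for (j in nb$neighbors[[i]])
    if (i < j) out <- rbind(out, c(i, j))
  unique(out[order(out[, 1], out[, 2]), , drop = FALSE])
}

# Shortest along-network distance by Dijkstra over an expanded node set,
# written independently of the package's igraph-based path
oracle_network_distance <- function(network, e1, o1, e2, o2) {
  ed <- network$edges
  # nodes: original network nodes plus two synthetic point nodes P1, P2
  ids <- sort(unique(c(ed$from, ed$to)))
  nn <- length(ids) + 2
  P1 <- nn - 1; P2 <- nn
  idx <- function(v) match(v, ids)
  adj <- matrix(Inf, nn, nn)
  add <- function(a, b, w) {
    if (w < adj[a, b]) adj[a, b] <<- adj[b, a] <<- w
  }
  for (k in seq_len(nrow(ed))) {
    a <- idx(ed$from[k]); b <- idx(ed$to[k]); L <- ed$length_km[k]
    w <- L
    # points split their edge; traversal of the whole edge stays possible
    pts <- list()
    if (ed$edge_id[k] == e1) pts[[length(pts) + 1]] <- list(node = P1, off = o1)
    if (ed$edge_id[k] == e2) pts[[length(pts) + 1]] <- list(node = P2, off = o2)
    if (length(pts) == 0) { add(a, b, L); next }
    ord <- order(vapply(pts, `[[`, numeric(1), "off"))
    prev <- a; prev_off <- 0
    for (p in pts[ord]) {
      add(prev, p$node, p$off - prev_off)
      prev <- p$node; prev_off <- p$off
    }
    add(prev, b, L - prev_off)
  }
  # Dijkstra from P1
  dist <- rep(Inf, nn); dist[P1] <- 0; done <- rep(FALSE, nn)
  for (it in seq_len(nn)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (is.infinite(dist[u])) break
    done[u] <- TRUE
    for (v in seq_len(nn)) if (!done[v] && dist[u] + adj[u, v] < dist[v])
      dist[v] <- dist[u] + adj[u, v]
  }
  dist[P2]
}

# OLS fit via explicit normal equations
oracle_ols_fitted <- function(y, X) {
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  drop(Xi %*% beta)
}

oracle_r2 <- function(y, X) {
  f <- oracle_ols_fitted(y, X)
  1 - sum((y - f)^2) / sum((y - mean(y))^2)
}

# small toy community on which tallies can be enumerated by hand/loops
toy_records <- function() {
  data.frame(
    site_id = c("a", "a", "a", "b", "b", "c", "c", "d"),
    species = c("nat1", "exo1", "exo2", "nat1", "exo1", "nat2", "nat1", "nat2"),
    origin = c("native", "exotic", "exotic", "native", "exotic",
               "native", "native", "native"),
    moyle_class = c(3L, 2L, 1L, 4L, 4L, 2L, 1L, 5L),
    body_size_class = c("medium", "small", "large", "medium", "small",
                        "large", "small", "medium"),
    stringsAsFactors = FALSE
  )
}
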
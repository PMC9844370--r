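# Independent oracles used to cross-check the implementation.

# Brute-force count of adjacency-preserving vertex bijections of a graph
# (backtracking with degree pruning).  Independent of the
# automorphism-generator route used by symmetry_group().
brute_force_automorphism_count <- function(edges, n) {
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1)]] <- TRUE
  deg <- rowSums(adj)
  count <- 0L
  recurse <- function(mapping, used) {
    v <- length(mapping) + 1L
    if (v > n) {
      count <<- count + 1L
      return(invisible())
    }
    for (img in which(!used)) {
      if (deg[img] != deg[v]) next
      ok <- TRUE
      for (w in seq_len(v - 1L)) {
        if (adj[v, w] != adj[img, mapping[w]]) { ok <- FALSE; break }
      }
      if (ok) {
        used[img] <- TRUE
        recurse(c(mapping, img), used)
        used[img] <- FALSE
      }
    }
  }
  recurse(integer(0), rep(FALSE, n))
  count
}

# Explicit-centroid radius-of-gyration oracle: list the face centroids,
# take their mean, average the squared distances.
rg_squared_oracle <- function(net) {
  cents <- t(vapply(net$faces2d, colMeans, numeric(2)))
  mu <- c(mean(cents[, 1]), mean(cents[, 2]))
  mean((cents[, 1] - mu[1])^2 + (cents[, 2] - mu[2])^2)
}

# Convex-hull oracle built on grDevices::chull (independent of the
# monotone-chain hull in the compiled bulk path).
hull_oracle <- function(net) {
  pts <- do.call(rbind, net$faces2d)
  h <- pts[chull(pts), , drop = FALSE]
  j <- c(2:nrow(h), 1L)
  area <- abs(sum(h[, 1] * h[j, 2] - h[j, 1] * h[, 2])) / 2
  per <- sum(sqrt(rowSums((h - h[j, , drop = FALSE])^2)))
  list(hull_area = area, hull_perimeter = per)
}

# Segment intersection test (proper crossing) for the planarity oracle.
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < -1e-12) && (d3 * d4 < -1e-12)
}

# Apply a symmetry of the solid to a skeleton tree (edge index set).
permute_tree <- function(sg, g, tree) sort(sg$edge_perms[g, tree])

# A single-face net fixture (one regular k-gon), for degenerate-input
# descriptor checks.
single_polygon_net <- function(k) {
  poly <- foldnet:::regular_polygon_from_edge(c(0, 0), c(1, 0), k)
  foldnet:::fixture_net(list(poly), matrix(integer(0), 0L, 2L), "single")
}

fig15_circuit <- function() {
  canonical_circuit(c(2, 3, 6, 3, 2, 6, 5, 2, 5, 2, 5, 2,
                      3, 6, 3, 2, 6, 5, 2, 5, 2, 5))
}
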
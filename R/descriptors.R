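#' Vertex connections of a net
#'
#' A net vertex is a fan of faces glued around one solid vertex.  Under the
#' restrictive definition a vertex connection is a net vertex already
#' incident to every face it touches on the assembled solid (fan size m,
#' net degree m + 1, where m is the number of faces at that solid vertex:
#' degree 4 for cube and dodecahedron nets, 5 for octahedron nets, 6 for
#' icosahedron nets); closing the solid there needs only one edge gluing.
#' The traditional literature definition counts any net vertex where two
#' faces share the vertex but not an edge, i.e. any fan of three or more
#' faces, so the restrictive set is always a subset of the traditional one.
#'
#' @param net a [unfold()]ed `durer_net` with provenance.
#' @param definition `"restrictive"` (default, used throughout the
#'   descriptor table) or `"traditional"`.
#' @return count of vertex connections.
#' @export
vertex_connections <- function(net, definition = c("restrictive", "traditional")) {
  stopifnot(inherits(net, "durer_net"))
  definition <- match.arg(definition)
  if (is.null(net$polyhedron)) {
    stop("vertex connections need the source polyhedron (synthetic fixture?)")
  }
  m <- net$polyhedron$vertex_m[net$class_polyv]
  if (definition == "restrictive") sum(net$class_size == m)
  else sum(net$class_size >= 3L)
}

#' Leaves of a net
#'
#' Faces that share exactly one folded edge with the rest of the net,
#' i.e. degree-1 nodes of the skeleton tree.  For triangle-faced solids a
#' leaf is equivalently a face owning a degree-2 net vertex.
#'
#' @param net a `durer_net` (fixtures allowed).
#' @return leaf count.
#' @export
leaves <- function(net) {
  stopifnot(inherits(net, "durer_net"))
  sum(skeleton_degrees(net) == 1L)
}

skeleton_degrees <- function(net) {
  nf <- length(net$faces2d)
  tabulate(c(net$skeleton), nbins = nf)
}

#' Skeleton-tree metrics of a net
#'
#' Edge count (always F - 1 for a spanning tree), backbone length (the
#' tree diameter in edges -- the longest path; several backbones may
#' realize it but the length is unique) and the degree distribution of the
#' skeleton nodes.
#'
#' @param net a `durer_net` (fixtures allowed).
#' @return list with `spanning_tree_edges`, `backbone_length` and
#'   `degree_distribution` (named counts of nodes by degree 1, 2, ...).
#' @export
skeleton_metrics <- function(net) {
  stopifnot(inherits(net, "durer_net"))
  deg <- skeleton_degrees(net)
  dd <- tabulate(deg, nbins = max(deg))
  names(dd) <- seq_along(dd)
  list(spanning_tree_edges = nrow(net$skeleton),
       backbone_length = tree_diameter(net$skeleton, length(net$faces2d)),
       degree_distribution = dd)
}

tree_diameter <- function(edges, n) {
  if (n <= 1L) return(0L)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- function(s) {
    d <- rep(NA_integer_, n); d[s] <- 0L; q <- s
    while (length(q)) {
      v <- q[[1L]]; q <- q[-1L]
      for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
    }
    d
  }
  d1 <- bfs(1L)
  far <- which.max(d1)
  max(bfs(far), na.rm = TRUE)
}

#' Integer solutions of the spanning-tree degree identities
#'
#' A skeleton spanning tree on F faces has F - 1 edges, so if A, B, C, ...
#' count nodes of degree 1, 2, 3, ... up to `dmax` then
#' A + B + C + ... = F and A + 2B + 3C + ... = 2 (F - 1).  This function
#' enumerates every non-negative integer solution, in lexicographic order
#' of (A, B, C, ...).  For the cube (F = 6, dmax = 4) there are exactly
#' four: (2,4,0,0), (3,2,1,0), (4,0,2,0), (4,1,0,1).  Realized nets may
#' occupy only a subset of these (see [realized_degree_distributions()]).
#'
#' @param n_faces number of faces F (>= 2).
#' @param dmax maximal skeleton degree (the solid's face-adjacency degree).
#' @return integer matrix, one solution per row, columns `deg1..degdmax`.
#' @export
degree_distribution_solutions <- function(n_faces, dmax) {
  stopifnot(n_faces >= 2L, dmax >= 2L)
  target_n <- as.integer(n_faces)
  target_s <- 2L * (target_n - 1L)
  sols <- list()
  recurse <- function(d, counts, n_left, s_left) {
    if (d > dmax) {
      if (n_left == 0L && s_left == 0L) sols[[length(sols) + 1L]] <<- counts
      return(invisible())
    }
    ## degrees d..dmax must absorb n_left nodes and s_left degree sum
    for (cnt in 0:n_left) {
      s_used <- cnt * d
      if (s_used > s_left) break
      rest_n <- n_left - cnt
      rest_s <- s_left - s_used
      ## feasibility: remaining nodes have degrees in [d+1, dmax]
      if (rest_s < rest_n * (d + 1L) && !(rest_n == 0L && rest_s == 0L)) next
      if (rest_s > rest_n * dmax) next
      recurse(d + 1L, c(counts, cnt), rest_n, rest_s)
    }
  }
  recurse(1L, integer(0), target_n, target_s)
  out <- do.call(rbind, sols)
  colnames(out) <- paste0("deg", seq_len(dmax))
  out[do.call(order, as.data.frame(out)), , drop = FALSE]
}

#' Degree distributions realized by the distinct nets of a solid
#'
#' Groups the solid's distinct Durer nets by the degree distribution of
#' their skeleton trees.  Every realized distribution is one of the
#' integer solutions from [degree_distribution_solutions()], but not every
#' solution is realized (the Platonic solids realize 2, 4, 3, 21 and 9
#' distributions respectively).
#'
#' @param p a [polyhedron()].
#' @return data frame with `distribution` (comma-separated counts by
#'   degree 1..dmax) and `nets` (number of distinct nets), distributions in
#'   lexicographic order; `sum(nets)` equals the solid's net count.
#' @export
realized_degree_distributions <- function(p) {
  tab <- descriptor_table(p)
  agg <- table(tab$degree_distribution)
  out <- data.frame(distribution = names(agg), nets = as.integer(agg),
                    stringsAsFactors = FALSE)
  key <- do.call(rbind, lapply(strsplit(out$distribution, ","), as.integer))
  out <- out[do.call(order, as.data.frame(key)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Radius of gyration of a net
#'
#' Compactness measure in unit-edge units.  The default `centroid_sum`
#' form is the root mean squared distance of the N face centroids from
#' their mean point,
#' Rg^2 = (1/N) sum_i ((x_i - xbar)^2 + (y_i - ybar)^2);
#' it ranks nets almost identically to the full `area_integral` form (the
#' per-unit-area second moment of the net region about its area centroid)
#' at a fraction of the cost, and is the form used in the descriptor
#' table.  Both are invariant under rigid motions and scale as Rg ~ s
#' under uniform scaling by s.
#'
#' @param net a `durer_net` (fixtures allowed).
#' @param method `"centroid_sum"` (default) or `"area_integral"`.
#' @return list with `rg` and `rg_squared`.
#' @export
radius_of_gyration <- function(net, method = c("centroid_sum", "area_integral")) {
  stopifnot(inherits(net, "durer_net"))
  method <- match.arg(method)
  if (method == "centroid_sum") {
    ctr <- t(vapply(net$faces2d, colMeans, numeric(2)))
    mu <- colMeans(ctr)
    rg2 <- mean((ctr[, 1] - mu[1])^2 + (ctr[, 2] - mu[2])^2)
  } else {
    tot_a <- 0; tot_x <- 0; tot_y <- 0; tot_j <- 0
    for (xy in net$faces2d) {
      x <- xy[, 1]; y <- xy[, 2]
      j <- c(2:nrow(xy), 1L)
      cr <- x * y[j] - x[j] * y
      tot_a <- tot_a + sum(cr) / 2
      tot_x <- tot_x + sum(cr * (x + x[j])) / 6
      tot_y <- tot_y + sum(cr * (y + y[j])) / 6
      tot_j <- tot_j + sum(cr * (x^2 + x * x[j] + x[j]^2 +
                                   y^2 + y * y[j] + y[j]^2)) / 12
    }
    xb <- tot_x / tot_a; yb <- tot_y / tot_a
    rg2 <- tot_j / tot_a - (xb^2 + yb^2)
  }
  list(rg = sqrt(max(rg2, 0)), rg_squared = rg2)
}

#' Convex hull compactness metrics of a net
#'
#' Area and perimeter of the convex hull of all net vertices, in unit-edge
#' units.  Hull perimeter tracks the same "spherical" compactness as the
#' radius of gyration; hull area instead measures wasted enclosed space
#' and picks up one-dimensional elongation.
#'
#' @param net a `durer_net` (fixtures allowed).
#' @return list with `hull_area` and `hull_perimeter`.
#' @export
convex_hull_metrics <- function(net) {
  stopifnot(inherits(net, "durer_net"))
  pts <- do.call(rbind, net$faces2d)
  h <- chull(pts)
  if (length(h) < 3L) stop("net vertices are collinear; convex hull is degenerate")
  hull <- pts[h, , drop = FALSE]
  per <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1L), , drop = FALSE])^2)))
  list(hull_area = abs(polygon_area(hull)), hull_perimeter = per)
}

#' All descriptors of a single net
#'
#' Pure-R reference computation of one net's descriptor record; the bulk
#' [descriptor_table()] computes the same quantities in compiled code for
#' tens of thousands of nets and is cross-checked against this path.
#'
#' @param net a [unfold()]ed `durer_net` with provenance.
#' @return one-row data frame matching the [descriptor_table()] columns
#'   (except orbit bookkeeping).
#' @export
describe_net <- function(net) {
  stopifnot(inherits(net, "durer_net"), !is.null(net$polyhedron))
  p <- net$polyhedron
  sk <- skeleton_metrics(net)
  dmax <- max(tabulate(c(p$edge_faces), nbins = length(p$faces)))
  dd <- sk$degree_distribution
  dd <- c(dd, rep(0L, max(0L, dmax - length(dd))))[seq_len(dmax)]
  rg <- radius_of_gyration(net)
  hull <- convex_hull_metrics(net)
  data.frame(
    circuit = canonical_circuit(net$boundary$degree),
    vc_restrictive = vertex_connections(net, "restrictive"),
    vc_traditional = vertex_connections(net, "traditional"),
    leaves = leaves(net),
    tree_edges = sk$spanning_tree_edges,
    degree_distribution = paste(dd, collapse = ","),
    backbone = sk$backbone_length,
    rg = rg$rg,
    rg_squared = rg$rg_squared,
    hull_area = hull$hull_area,
    hull_perimeter = hull$hull_perimeter,
    boundary_length = nrow(net$boundary),
    overlaps = overlap_check(net),
    stringsAsFactors = FALSE
  )
}

#' Descriptor table for every distinct net of a solid
#'
#' Enumerates the solid's distinct Durer nets (symmetry-reduced) and
#' computes the full descriptor record of each in compiled code: canonical
#' boundary degree circuit, restrictive and traditional vertex
#' connections, leaves, skeleton degree distribution and backbone length,
#' centroid-sum radius of gyration (reported as both Rg and Rg^2, unit
#' edges), convex-hull area and perimeter, boundary length and the
#' self-overlap flag.  Results are cached per solid within the session.
#'
#' Column order is stable: `orbit_key`, `orbit_size`, `circuit`,
#' `vc_restrictive`, `vc_traditional`, `leaves`, `tree_edges`,
#' `degree_distribution`, `backbone`, `rg`, `rg_squared`, `hull_area`,
#' `hull_perimeter`, `boundary_length`, `overlaps`.
#'
#' @param p a [polyhedron()].
#' @param cache_dir optional on-disk cache directory (see
#'   [enumerate_nets()]).
#' @return data frame, one row per distinct net.
#' @export
descriptor_table <- function(p, cache_dir = NULL) {
  stopifnot(inherits(p, "polyhedron"))
  key <- paste0("table_", p$name)
  hit <- fn_cache_get(key)
  if (!is.null(hit)) return(hit)
  orb <- enumerate_nets(p, cache_dir = cache_dir)
  dmax <- max(tabulate(c(p$edge_faces), nbins = length(p$faces)))
  res <- cpp_describe_trees(
    lapply(p$faces, function(f) f - 1L),
    p$face_local,
    p$edges - 1L,
    p$edge_faces - 1L,
    p$vertex_m,
    as.integer(orb$mask),
    as.integer(dmax)
  )
  dd <- apply(res$degrees, 1L, paste, collapse = ",")
  tab <- data.frame(
    orbit_key = orb$mask,
    orbit_size = orb$orbit_size,
    circuit = res$circuit,
    vc_restrictive = res$vc_restrictive,
    vc_traditional = res$vc_traditional,
    leaves = res$leaves,
    tree_edges = length(p$faces) - 1L,
    degree_distribution = dd,
    backbone = res$backbone,
    rg = sqrt(res$rg_squared),
    rg_squared = res$rg_squared,
    hull_area = res$hull_area,
    hull_perimeter = res$hull_perimeter,
    boundary_length = res$boundary_length,
    overlaps = as.logical(res$overlaps),
    stringsAsFactors = FALSE
  )
  # completeness marker records the full row count, so partial subsets of
  # the table are recognized downstream
  attr(tab, "complete") <- nrow(tab)
  attr(tab, "total_trees") <- attr(orb, "total_trees")
  fn_cache_set(key, tab)
  tab
}
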
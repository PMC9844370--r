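#' Unfold a skeleton tree into a planar Durer net
#'
#' Lays the faces of the solid flat by walking the skeleton tree from the
#' root face (lowest face index): each face is placed by the unique proper
#' rigid motion that maps its shared edge onto the already-placed copy in
#' its parent, so adjacent faces share a full edge and every face is
#' congruent to the solid's face.  The root face is centred at the origin
#' with its first edge along the +x axis; coordinates are in unit-edge
#' units.
#'
#' Net vertices are the equivalence classes of face corners glued through
#' folded edges; each class is a fan of faces around one solid vertex and
#' has net degree (fan size + 1).  The boundary circuit -- the Euler tour
#' of the doubled cutting tree -- is computed by walking the outer
#' boundary and recording each boundary vertex's net degree.
#'
#' @param p a [polyhedron()].
#' @param tree integer vector of folded polyhedron-edge indices (a
#'   skeleton spanning tree).
#' @return an object of class `durer_net`: `faces2d` (per-face polygon
#'   coordinates, rows aligned with the face cycles of `p`),
#'   `corner_class` (net-vertex id of every face corner), `class_polyv`,
#'   `class_size`, `boundary` (data frame of the boundary circuit with
#'   net-vertex ids and degrees), `tree`, `cut_edges`, `skeleton` (tree as
#'   face pairs) and the source polyhedron.
#' @examples
#' p <- platonic_solid("tetrahedron")
#' net <- unfold(p, enumerate_skeleton_trees(p)[1, ])
#' nrow(net$boundary)  # 6 boundary vertices = 2 (V - 1)
#' @export
unfold <- function(p, tree) {
  stopifnot(inherits(p, "polyhedron"))
  tree <- as.integer(tree)
  check_skeleton_tree(p, tree)
  nf <- length(p$faces)
  cut <- setdiff(seq_len(nrow(p$edges)), tree)

  ## adjacency of the skeleton tree: face -> (neighbour face, via edge)
  adj <- vector("list", nf)
  for (e in tree) {
    f1 <- p$edge_faces[e, 1]; f2 <- p$edge_faces[e, 2]
    adj[[f1]] <- rbind(adj[[f1]], c(f2, e))
    adj[[f2]] <- rbind(adj[[f2]], c(f1, e))
  }

  faces2d <- vector("list", nf)
  root <- 1L
  loc <- p$face_local[[root]]
  ctr <- colMeans(loc)
  d <- loc[2, ] - loc[1, ]
  th <- -atan2(d[2], d[1])
  R0 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  faces2d[[root]] <- sweep(loc, 2, ctr) %*% t(R0)

  queue <- root
  placed <- rep(FALSE, nf); placed[root] <- TRUE
  while (length(queue)) {
    f <- queue[[1L]]; queue <- queue[-1L]
    if (is.null(adj[[f]])) next
    for (r in seq_len(nrow(adj[[f]]))) {
      g <- adj[[f]][r, 1]; e <- adj[[f]][r, 2]
      if (placed[g]) next
      a <- p$edges[e, 1]; b <- p$edges[e, 2]
      ia_f <- match(a, p$faces[[f]]); ib_f <- match(b, p$faces[[f]])
      ia_g <- match(a, p$faces[[g]]); ib_g <- match(b, p$faces[[g]])
      A <- faces2d[[f]][ia_f, ]; B <- faces2d[[f]][ib_f, ]
      Ag <- p$face_local[[g]][ia_g, ]; Bg <- p$face_local[[g]][ib_g, ]
      th <- atan2(B[2] - A[2], B[1] - A[1]) -
        atan2(Bg[2] - Ag[2], Bg[1] - Ag[1])
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      tr <- A - as.vector(R %*% Ag)
      faces2d[[g]] <- sweep(p$face_local[[g]] %*% t(R), 2, tr, `+`)
      if (max(abs(faces2d[[g]][ia_g, ] - A),
              abs(faces2d[[g]][ib_g, ] - B)) > 1e-9) {
        stop("degenerate placement between faces ", f, " and ", g)
      }
      placed[g] <- TRUE
      queue[[length(queue) + 1L]] <- g
    }
  }

  ## glue corners through folded edges -> net vertex classes
  koff <- cumsum(c(0L, vapply(p$faces, length, integer(1))))
  ncor <- koff[nf + 1L]
  parent <- seq_len(ncor)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  cid <- function(f, i) koff[f] + i
  for (e in tree) {
    f1 <- p$edge_faces[e, 1]; f2 <- p$edge_faces[e, 2]
    for (v in p$edges[e, ]) {
      a <- find(cid(f1, match(v, p$faces[[f1]])))
      b <- find(cid(f2, match(v, p$faces[[f2]])))
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(ncor), find, integer(1))
  class_id <- match(roots, unique(roots))
  corner_class <- lapply(seq_len(nf), function(f) {
    class_id[(koff[f] + 1L):koff[f + 1L]]
  })
  nclass <- max(class_id)
  class_size <- tabulate(class_id, nbins = nclass)
  class_polyv <- integer(nclass)
  for (f in seq_len(nf)) class_polyv[corner_class[[f]]] <- p$faces[[f]]

  net <- structure(list(
    name = p$name,
    polyhedron = p,
    tree = sort(tree),
    cut_edges = cut,
    skeleton = p$edge_faces[sort(tree), , drop = FALSE],
    faces2d = faces2d,
    corner_class = corner_class,
    class_polyv = class_polyv,
    class_size = class_size,
    boundary = NULL
  ), class = "durer_net")
  net$boundary <- boundary_walk(net)
  net
}

## Walk the outer boundary of the net: follow cut half-edges, rotating
## through folded edges at each corner.  Returns one row per boundary
## vertex visit, in traversal order.
boundary_walk <- function(net) {
  p <- net$polyhedron
  in_tree <- rep(FALSE, nrow(p$edges)); in_tree[net$tree] <- TRUE
  half_edge <- function(f, i) {
    k <- length(p$faces[[f]])
    j <- if (i == k) 1L else i + 1L
    edge_index(p, p$faces[[f]][i], p$faces[[f]][j])
  }
  ## first cut half-edge
  start <- NULL
  for (f in seq_along(p$faces)) {
    for (i in seq_along(p$faces[[f]])) {
      if (!in_tree[half_edge(f, i)]) { start <- c(f, i); break }
    }
    if (!is.null(start)) break
  }
  if (is.null(start)) {
    return(data.frame(vertex = integer(0), degree = integer(0)))
  }
  verts <- integer(0)
  f <- start[1L]; i <- start[2L]
  repeat {
    verts <- c(verts, net$corner_class[[f]][i])
    ## advance to the head corner, then rotate through folded edges
    k <- length(p$faces[[f]])
    j <- if (i == k) 1L else i + 1L
    repeat {
      e <- half_edge(f, j)
      if (!in_tree[e]) break
      ## folded: hop to the twin corner of this vertex in the other face
      g <- setdiff(p$edge_faces[e, ], f)
      j <- match(p$faces[[f]][j], p$faces[[g]])
      f <- g
    }
    i <- j
    if (f == start[1L] && i == start[2L]) break
    if (length(verts) > 4L * nrow(p$edges)) stop("boundary walk failed to close")
  }
  data.frame(vertex = verts,
             degree = net$class_size[verts] + 1L)
}

#' @export
print.durer_net <- function(x, ...) {
  cat(sprintf("durer_net of %s: %d faces, %d folded edges, %d boundary vertices\n",
              x$name, length(x$faces2d),
              if (is.null(x$tree)) nrow(x$skeleton) else length(x$tree),
              if (is.null(x$boundary)) NA_integer_ else nrow(x$boundary)))
  invisible(x)
}

#' Boundary degree circuit of a net
#'
#' The cyclic sequence of net-vertex degrees met while walking once around
#' the net's outer boundary -- equivalently the Euler tour of the doubled
#' cutting tree.  Its length is 2 (V - 1), and in canonical form (see
#' [canonical_circuit()]) it is the identifier the descriptor table uses
#' for individual nets.
#'
#' @param net a [unfold()]ed `durer_net`.
#' @return integer vector of degrees, one per boundary vertex visit.
#' @export
boundary_circuit <- function(net) {
  stopifnot(inherits(net, "durer_net"))
  if (is.null(net$boundary)) {
    stop("this net carries no boundary information (synthetic fixture?)")
  }
  net$boundary$degree
}

#' Test whether face interiors of a net overlap
#'
#' A genuine Durer net is non-self-overlapping: no two face interiors
#' intersect (faces may share edges and vertices).  Each face polygon is
#' shrunk towards its centroid by a factor 1e-7 before the pairwise
#' convex-polygon intersection test, so exact shared edges never register
#' as overlap.
#'
#' @param net a `durer_net` (including synthetic fixtures).
#' @param shrink relative shrink factor applied before testing.
#' @return `TRUE` if two face interiors overlap.
#' @export
overlap_check <- function(net, shrink = 1e-7) {
  stopifnot(inherits(net, "durer_net"))
  polys <- lapply(net$faces2d, function(xy) {
    ctr <- colMeans(xy)
    sweep(sweep(xy, 2, ctr) * (1 - shrink), 2, ctr, `+`)
  })
  nf <- length(polys)
  boxes <- t(vapply(polys, function(xy) c(min(xy[, 1]), max(xy[, 1]),
                                          min(xy[, 2]), max(xy[, 2])),
                    numeric(4)))
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      if (boxes[i, 1] > boxes[j, 2] || boxes[j, 1] > boxes[i, 2] ||
          boxes[i, 3] > boxes[j, 4] || boxes[j, 3] > boxes[i, 4]) next
      if (convex_polys_intersect(polys[[i]], polys[[j]])) return(TRUE)
    }
  }
  FALSE
}

## Separating-axis test for two convex polygons (TRUE = interiors meet).
convex_polys_intersect <- function(a, b, eps = 1e-12) {
  axes <- rbind(poly_axes(a), poly_axes(b))
  for (r in seq_len(nrow(axes))) {
    ax <- axes[r, ]
    pa <- a %*% ax; pb <- b %*% ax
    if (max(pa) <= min(pb) + eps || max(pb) <= min(pa) + eps) return(FALSE)
  }
  TRUE
}

poly_axes <- function(xy) {
  n <- nrow(xy)
  d <- xy[c(2:n, 1L), ] - xy
  cbind(-d[, 2], d[, 1])
}

#' Refold a net and verify it reconstructs the solid's adjacency
#'
#' Matches the boundary edges of the net in congruent pairs arising from
#' the doubled cut edges and checks that re-gluing them restores the full
#' 3D face adjacency of the source polyhedron -- the inverse operation of
#' [unfold()].
#'
#' @param net a [unfold()]ed `durer_net` with provenance.
#' @return `TRUE` invisibly if the reconstruction matches.
#' @export
refold_check <- function(net) {
  stopifnot(inherits(net, "durer_net"), !is.null(net$polyhedron))
  p <- net$polyhedron
  ## every cut polyhedron edge appears as exactly two congruent boundary
  ## copies; gluing them plus the folded edges restores all E adjacencies
  for (e in net$cut_edges) {
    fs <- p$edge_faces[e, ]
    lens <- vapply(fs, function(f) {
      ia <- match(p$edges[e, 1], p$faces[[f]])
      ib <- match(p$edges[e, 2], p$faces[[f]])
      sqrt(sum((net$faces2d[[f]][ia, ] - net$faces2d[[f]][ib, ])^2))
    }, numeric(1))
    if (abs(lens[1] - lens[2]) > 1e-9) {
      stop("cut edge ", e, " has incongruent boundary copies")
    }
  }
  glued <- c(net$tree, net$cut_edges)
  if (!setequal(glued, seq_len(nrow(p$edges)))) {
    stop("refolded edge set does not cover the solid")
  }
  invisible(TRUE)
}
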
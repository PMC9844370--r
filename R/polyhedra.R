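#' Construct a polyhedron from vertices and faces
#'
#' Builds the mesh representation used throughout the package: vertex
#' coordinates, consistently oriented face cycles (counterclockwise seen
#' from outside), and the edge list shared between exactly two faces.
#' Coordinates are rescaled so that the mean edge length is exactly 1; for
#' the Platonic solids every edge is then 1 to within 1e-9 and all
#' downstream geometry (radius of gyration, hulls) is in unit-edge units.
#'
#' @param vertices numeric matrix with one 3D point per row.
#' @param faces list of integer vectors, each a cyclic sequence of vertex
#'   indices bounding one face.  Cycles may be supplied in either
#'   orientation; they are re-oriented consistently outward.
#' @param name label for the solid.
#' @return an object of class `polyhedron` with components `vertices`,
#'   `faces`, `edges` (E x 2, each row sorted), `edge_faces` (the two faces
#'   meeting at each edge), `face_local` (exact planar coordinates of each
#'   face in its own frame), `vertex_m` (number of faces at each solid
#'   vertex) and `unit_edges` (TRUE when all edges have length 1).
#' @seealso [platonic_solid()], [read_off()]
#' @export
polyhedron <- function(vertices, faces, name = "polyhedron") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  faces <- lapply(faces, as.integer)
  nv <- nrow(vertices)
  if (any(unlist(faces) < 1L | unlist(faces) > nv)) {
    stop("face cycle references a vertex index outside 1..", nv)
  }
  if (any(vapply(faces, function(f) length(f) < 3L || anyDuplicated(f) > 0L,
                 logical(1)))) {
    stop("every face must be a simple cycle of at least 3 distinct vertices")
  }

  faces <- orient_faces(vertices, faces)

  ## Edge table: every undirected edge must be traversed once per direction.
  dir_edges <- do.call(rbind, lapply(seq_along(faces), function(fi) {
    f <- faces[[fi]]
    cbind(f, f[c(2:length(f), 1L)], fi)
  }))
  key <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
               pmax(dir_edges[, 1], dir_edges[, 2]))
  tab <- table(key)
  if (any(tab != 2L)) {
    stop("mesh is not closed: each edge must be shared by exactly 2 faces")
  }
  ukey <- sort(unique(key))
  edges <- do.call(rbind, strsplit(ukey, " "))
  edges <- cbind(as.integer(edges[, 1]), as.integer(edges[, 2]))
  eidx <- match(key, ukey)
  edge_faces <- matrix(0L, nrow(edges), 2L)
  for (r in seq_len(nrow(dir_edges))) {
    e <- eidx[r]
    if (edge_faces[e, 1] == 0L) edge_faces[e, 1] <- dir_edges[r, 3]
    else edge_faces[e, 2] <- dir_edges[r, 3]
  }
  if (any(edge_faces[, 1] == edge_faces[, 2])) {
    stop("an edge is traversed twice by the same face")
  }

  ## Unit-edge normalization (mean edge = 1).
  elen <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                          vertices[edges[, 2], , drop = FALSE])^2))
  if (any(elen <= 0)) stop("degenerate zero-length edge")
  vertices <- vertices / mean(elen)
  elen <- elen / mean(elen)
  unit_edges <- all(abs(elen - 1) < 1e-9)

  p <- structure(list(
    name = name,
    vertices = vertices,
    faces = faces,
    edges = edges,
    edge_faces = edge_faces,
    face_local = NULL,
    vertex_m = tabulate(unlist(faces), nbins = nv),
    unit_edges = unit_edges
  ), class = "polyhedron")
  p$face_local <- lapply(seq_along(faces), function(fi) face_plane_coords(p, fi))

  chi <- nrow(vertices) - nrow(edges) + length(faces)
  if (chi != 2L) {
    stop("Euler characteristic V - E + F = ", chi, ", expected 2")
  }
  p
}

## Re-orient all face cycles counterclockwise as seen from outside the solid
## (outward normals).  Requires a star-shaped interior point; the vertex
## centroid works for every convex polyhedron.
orient_faces <- function(vertices, faces) {
  ctr <- colMeans(vertices)
  lapply(faces, function(f) {
    pts <- sweep(vertices[f, , drop = FALSE], 2, ctr)
    n <- c(0, 0, 0)
    k <- length(f)
    for (i in seq_len(k)) {
      a <- pts[i, ]
      b <- pts[if (i == k) 1L else i + 1L, ]
      n <- n + c(a[2] * b[3] - a[3] * b[2],
                 a[3] * b[1] - a[1] * b[3],
                 a[1] * b[2] - a[2] * b[1])
    }
    if (sum(n * colMeans(pts)) < 0) rev(f) else f
  })
}

## Isometric 2D coordinates of face fi's cycle in its own plane, oriented so
## the cycle is counterclockwise in the plane.  Used as the rigid template
## when unfolding.
face_plane_coords <- function(p, fi) {
  f <- p$faces[[fi]]
  pts <- p$vertices[f, , drop = FALSE]
  u <- pts[2, ] - pts[1, ]
  u <- u / sqrt(sum(u^2))
  w0 <- pts[3, ] - pts[1, ]
  n <- c(u[2] * w0[3] - u[3] * w0[2],
         u[3] * w0[1] - u[1] * w0[3],
         u[1] * w0[2] - u[2] * w0[1])
  n <- n / sqrt(sum(n^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  rel <- sweep(pts, 2, pts[1, ])
  xy <- cbind(rel %*% u, rel %*% v)
  # cycle is CCW from outside; with n = u x w0 chosen from the cycle the 2D
  # signed area is positive already, but guard against collinear v1,v2,v3
  if (polygon_area(xy) < 0) xy[, 2] <- -xy[, 2]
  dimnames(xy) <- NULL
  xy
}

#' Built-in Platonic solids
#'
#' Returns one of the five Platonic solids with unit edge length.  These are
#' the shells studied as models of self-folding viral capsids: a T1 capsid
#' corresponds to the icosahedron with one capsomere triangle per face.
#'
#' @param name one of `"tetrahedron"`, `"cube"`, `"octahedron"`,
#'   `"dodecahedron"`, `"icosahedron"`.
#' @return a [polyhedron()] object.
#' @examples
#' ico <- platonic_solid("icosahedron")
#' nrow(ico$vertices)  # 12
#' nrow(ico$edges)     # 30
#' length(ico$faces)   # 20
#' @export
platonic_solid <- function(name = c("tetrahedron", "cube", "octahedron",
                                    "dodecahedron", "icosahedron")) {
  name <- match.arg(name)
  phi <- (1 + sqrt(5)) / 2
  verts <- switch(name,
    tetrahedron = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    cube = as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    octahedron = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
    icosahedron = {
      m <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi))
      rbind(m, m[, c(3, 1, 2)], m[, c(2, 3, 1)])
    },
    dodecahedron = {
      cube8 <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
      m <- rbind(c(0, 1 / phi, phi), c(0, 1 / phi, -phi),
                 c(0, -1 / phi, phi), c(0, -1 / phi, -phi))
      rbind(cube8, m, m[, c(3, 1, 2)], m[, c(2, 3, 1)])
    })
  dimnames(verts) <- NULL
  faces <- trace_faces(verts)
  polyhedron(verts, faces, name = name)
}

## Recover the face cycles of a convex polyhedron from its vertex
## coordinates alone: edges join nearest-neighbour pairs (all edges of a
## Platonic solid have the common minimal length), the cyclic order of the
## neighbours around each vertex gives a rotation system, and faces are the
## orbits of the face-tracing map on directed edges.
trace_faces <- function(verts) {
  d <- as.matrix(dist(verts))
  emin <- min(d[d > 1e-9])
  nv <- nrow(verts)
  nbrs <- lapply(seq_len(nv), function(i) which(d[i, ] < emin * (1 + 1e-6) & d[i, ] > 1e-9))
  ## order neighbours counterclockwise around the outward direction of v
  for (i in seq_len(nv)) {
    n <- verts[i, ] / sqrt(sum(verts[i, ]^2))
    ref <- verts[nbrs[[i]][1], ] - verts[i, ]
    ref <- ref - sum(ref * n) * n
    e1 <- ref / sqrt(sum(ref^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2],
            n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    ang <- vapply(nbrs[[i]], function(j) {
      w <- verts[j, ] - verts[i, ]
      atan2(sum(w * e2), sum(w * e1))
    }, numeric(1))
    nbrs[[i]] <- nbrs[[i]][order(ang)]
  }
  ## face tracing: the face left of u->v continues with the neighbour of v
  ## that precedes u in the counterclockwise order around v
  nxt <- function(u, v) {
    nb <- nbrs[[v]]
    k <- match(u, nb)
    nb[if (k == 1L) length(nb) else k - 1L]
  }
  seen <- new.env(parent = emptyenv())
  faces <- list()
  for (u in seq_len(nv)) {
    for (v in nbrs[[u]]) {
      kk <- paste(u, v)
      if (!is.null(seen[[kk]])) next
      cyc <- integer(0)
      a <- u; b <- v
      repeat {
        seen[[paste(a, b)]] <- TRUE
        cyc <- c(cyc, a)
        nb <- nxt(a, b)
        a <- b; b <- nb
        if (a == u && b == v) break
      }
      faces[[length(faces) + 1L]] <- cyc
    }
  }
  faces
}

#' @export
print.polyhedron <- function(x, ...) {
  cat(sprintf("polyhedron '%s': V = %d, E = %d, F = %d%s\n",
              x$name, nrow(x$vertices), nrow(x$edges), length(x$faces),
              if (x$unit_edges) " (unit edges)" else ""))
  invisible(x)
}

#' Validate polyhedron invariants
#'
#' Checks the closed-surface invariants: Euler characteristic 2, every edge
#' shared by exactly two faces with consistent orientation, and (for solids
#' built as unit-edge meshes) all edge lengths equal to 1 within `tol`.
#'
#' @param p a [polyhedron()].
#' @param tol tolerance on unit edge lengths.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_polyhedron <- function(p, tol = 1e-9) {
  stopifnot(inherits(p, "polyhedron"))
  V <- nrow(p$vertices); E <- nrow(p$edges); F <- length(p$faces)
  if (V - E + F != 2L) stop("Euler characteristic is not 2")
  dir_edges <- do.call(rbind, lapply(p$faces, function(f) {
    cbind(f, f[c(2:length(f), 1L)])
  }))
  key <- paste(dir_edges[, 1], dir_edges[, 2])
  if (anyDuplicated(key) > 0L) stop("face orientations are not consistent")
  if (nrow(dir_edges) != 2L * E) stop("an edge is not shared by exactly two faces")
  if (p$unit_edges) {
    elen <- sqrt(rowSums((p$vertices[p$edges[, 1], , drop = FALSE] -
                            p$vertices[p$edges[, 2], , drop = FALSE])^2))
    if (any(abs(elen - 1) > tol)) stop("edge lengths deviate from 1")
  }
  invisible(TRUE)
}

## Index of the undirected edge {a, b} in p$edges, or NA.
edge_index <- function(p, a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  match(paste(lo, hi), paste(p$edges[, 1], p$edges[, 2]))
}

#' Caspar-Klug triangulation number
#'
#' The Caspar-Klug classification of icosahedral viral capsids: a capsid
#' with lattice steps (h, k) has triangulation number T = h^2 + hk + k^2 and
#' is built from 60 T protein subunits (capsomeres).
#'
#' @param h,k non-negative integers with h >= 1.
#' @return list with components `t_number` and `capsomeres` (= 60 T).
#' @examples
#' triangulation_number(1, 0)  # T = 1, 60 capsomeres
#' triangulation_number(1, 1)  # T = 3, 180 capsomeres
#' @export
triangulation_number <- function(h, k = 0L) {
  if (length(h) != 1L || length(k) != 1L ||
      h != round(h) || k != round(k) || h < 1 || k < 0) {
    stop("h must be a positive integer and k a non-negative integer")
  }
  t_num <- h^2 + h * k + k^2
  list(t_number = t_num, capsomeres = 60 * t_num)
}

## Signed area of a 2D polygon (positive = counterclockwise).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:nrow(xy), 1L)
  sum(x * y[j] - x[j] * y) / 2
}
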
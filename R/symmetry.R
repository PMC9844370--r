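#' Symmetry group of a polyhedron
#'
#' Computes the combinatorial symmetry group: all vertex bijections that
#' preserve the edge set of the 1-skeleton.  For a 3-connected planar graph
#' these are exactly the geometric symmetries of the solid (rotations plus
#' reflections).  The group is obtained from graph automorphism generators
#' and closed under composition, then each element is classified as
#' orientation-preserving (rotation) or orientation-reversing (reflection)
#' by whether it maps face cycles to face cycles with the same cyclic
#' direction.
#'
#' @param p a [polyhedron()].
#' @param include_reflections if `FALSE`, only the orientation-preserving
#'   subgroup (proper rotations) is returned.
#' @return an object of class `symmetry_group`: list with `perms` (order x V
#'   matrix of vertex images), `face_perms`, `edge_perms` (induced actions),
#'   `proper` (logical per element) and `includes_reflections`.
#' @examples
#' sg <- symmetry_group(platonic_solid("cube"))
#' nrow(sg$perms)  # 48
#' @export
symmetry_group <- function(p, include_reflections = TRUE) {
  stopifnot(inherits(p, "polyhedron"))
  g <- igraph::graph_from_edgelist(p$edges, directed = FALSE)
  gens <- igraph::automorphism_group(g)
  gens <- lapply(gens, function(x) as.integer(x))
  nv <- nrow(p$vertices)

  ## close the generating set under composition (orders here are <= 120)
  idp <- seq_len(nv)
  elems <- new.env(parent = emptyenv())
  elems[[paste(idp, collapse = ",")]] <- idp
  queue <- list(idp)
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (gen in gens) {
      nxt <- gen[cur]
      k <- paste(nxt, collapse = ",")
      if (is.null(elems[[k]])) {
        elems[[k]] <- nxt
        queue[[length(queue) + 1L]] <- nxt
      }
    }
  }
  perms <- do.call(rbind, as.list(elems))
  rownames(perms) <- NULL
  ## keep edge-preserving elements only (automorphisms always are; guard)
  ek <- sort(paste(p$edges[, 1], p$edges[, 2]))
  keep <- apply(perms, 1L, function(s) {
    a <- s[p$edges[, 1]]; b <- s[p$edges[, 2]]
    identical(sort(paste(pmin(a, b), pmax(a, b))), ek)
  })
  perms <- perms[keep, , drop = FALSE]
  if (nrow(perms) == 1L) {
    warning("input mesh has no non-trivial combinatorial symmetry")
  }

  fp <- t(apply(perms, 1L, function(s) face_image(p, s)))
  if (nrow(perms) == 1L) fp <- matrix(fp, nrow = 1L)
  ep <- t(apply(perms, 1L, function(s) {
    edge_index(p, s[p$edges[, 1]], s[p$edges[, 2]])
  }))
  if (nrow(perms) == 1L) ep <- matrix(ep, nrow = 1L)
  proper <- apply(perms, 1L, function(s) orientation_preserving(p, s))

  sg <- structure(list(perms = perms, face_perms = fp, edge_perms = ep,
                       proper = proper,
                       includes_reflections = include_reflections),
                  class = "symmetry_group")
  if (!include_reflections) {
    sel <- which(proper)
    sg$perms <- perms[sel, , drop = FALSE]
    sg$face_perms <- fp[sel, , drop = FALSE]
    sg$edge_perms <- ep[sel, , drop = FALSE]
    sg$proper <- proper[sel]
  }
  sg
}

## image of each face index under the vertex permutation s
face_image <- function(p, s) {
  fkey <- vapply(p$faces, function(f) paste(sort(f), collapse = ","),
                 character(1))
  img <- vapply(p$faces, function(f) paste(sort(s[f]), collapse = ","),
                character(1))
  m <- match(img, fkey)
  if (anyNA(m)) stop("permutation does not map faces to faces")
  m
}

## TRUE when s maps the (outward-counterclockwise) cycle of face 1 onto the
## target face's cycle with the same cyclic direction.
orientation_preserving <- function(p, s) {
  f <- p$faces[[1L]]
  img <- s[f]
  tgt <- p$faces[[face_image(p, s)[1L]]]
  k <- length(tgt)
  off <- match(img[1L], tgt)
  fwd <- all(img == tgt[((off - 1L + seq_len(k) - 1L) %% k) + 1L])
  fwd
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat(sprintf("symmetry_group of order %d (%s)\n", nrow(x$perms),
              if (x$includes_reflections) "rotations + reflections"
              else "rotations only"))
  invisible(x)
}

#' Schlegel diagram layout of a polyhedron's 1-skeleton
#'
#' Planar straight-line drawing of the skeleton obtained by projecting
#' through one face: the chosen outer face is pinned to a regular convex
#' polygon and every interior vertex is placed at the barycentre of its
#' neighbours (Tutte embedding).  For a 3-connected planar graph this
#' drawing is crossing-free, so face adjacency can be read off in the
#' plane -- the property used when designing magnet maps for
#' self-assembling capsid models.
#'
#' @param p a [polyhedron()].
#' @param outer_face index of the face projected through.
#' @return V x 2 matrix of planar coordinates.
#' @export
schlegel_layout <- function(p, outer_face = 1L) {
  stopifnot(inherits(p, "polyhedron"))
  if (length(outer_face) != 1L || outer_face < 1L ||
      outer_face > length(p$faces)) {
    stop("outer_face must index one of the ", length(p$faces), " faces")
  }
  nv <- nrow(p$vertices)
  outer <- p$faces[[outer_face]]
  k <- length(outer)
  pos <- matrix(NA_real_, nv, 2L)
  ang <- 2 * pi * (seq_len(k) - 1L) / k
  pos[outer, ] <- cbind(cos(ang), sin(ang))
  inner <- setdiff(seq_len(nv), outer)
  if (length(inner)) {
    A <- matrix(0, nv, nv)
    A[p$edges] <- 1; A[p$edges[, c(2, 1)]] <- 1
    deg <- rowSums(A)
    L <- diag(deg) - A
    rhs <- -L[inner, outer, drop = FALSE] %*% pos[outer, , drop = FALSE]
    pos[inner, ] <- solve(L[inner, inner, drop = FALSE], rhs)
  }
  pos
}

#' Magnet map for a self-assembling polyhedron model
#'
#' In physical self-assembly models each face is a separate magnetic
#' subunit.  The design rule that makes any two identical subunits attract
#' across any edge contact is to glue one north-facing and one south-facing
#' magnet on every edge of every face, ordered the same way along the
#' face's counterclockwise traversal.  `magnet_map()` produces that
#' assignment; `validate_magnet_map()` checks the three design criteria:
#' all subunits identical, rotational symmetry within each subunit, and
#' every shared-edge contact attractive (north always meets south).
#' Swapping all poles globally yields the enantiomer model, which also
#' validates.
#'
#' @param p a [polyhedron()].
#' @return a data frame of class `magnet_map` with one row per (face, edge
#'   slot): columns `face`, `slot` (position of the edge in the face's
#'   counterclockwise cycle) and `poles` (`"NS"` or `"SN"`, the ordered pole
#'   pair along the traversal direction).
#' @export
magnet_map <- function(p) {
  stopifnot(inherits(p, "polyhedron"))
  rows <- do.call(rbind, lapply(seq_along(p$faces), function(fi) {
    data.frame(face = fi, slot = seq_along(p$faces[[fi]]),
               poles = "NS", stringsAsFactors = FALSE)
  }))
  class(rows) <- c("magnet_map", class(rows))
  rows
}

#' @param m a magnet map as returned by [magnet_map()] (possibly edited).
#' @return `validate_magnet_map()` returns `TRUE` when all criteria hold,
#'   otherwise `FALSE` with attribute `"violation"` naming the first
#'   offending (face, slot).
#' @rdname magnet_map
#' @export
validate_magnet_map <- function(p, m) {
  stopifnot(inherits(p, "polyhedron"))
  if (!all(c("face", "slot", "poles") %in% names(m))) {
    stop("m must have columns face, slot, poles")
  }
  fail <- function(face, slot, why) {
    structure(FALSE, violation = list(face = face, slot = slot, reason = why))
  }
  pat <- split(m$poles[order(m$face, m$slot)], m$face[order(m$face, m$slot)])
  ## criterion: rotational symmetry of each subunit (pattern constant
  ## around the face)
  for (fi in seq_along(pat)) {
    if (length(unique(pat[[fi]])) != 1L) {
      bad <- which(pat[[fi]] != pat[[fi]][1L])[1L]
      return(fail(fi, bad, "subunit is not rotationally symmetric"))
    }
  }
  ## criterion: all subunits identical
  first <- vapply(pat, `[`, character(1), 1L)
  if (length(unique(first)) != 1L) {
    bad <- which(first != first[1L])[1L]
    return(fail(bad, 1L, "subunits are not identical"))
  }
  ## criterion: complementary attraction across every shared edge.  Face f1
  ## traverses the shared edge a->b, f2 traverses b->a; the poles facing
  ## each other at each end must differ.
  get_poles <- function(fi, slot) {
    v <- m$poles[m$face == fi & m$slot == slot]
    if (length(v) != 1L) stop("magnet map is missing (face ", fi,
                              ", slot ", slot, ")")
    v
  }
  for (e in seq_len(nrow(p$edges))) {
    f1 <- p$edge_faces[e, 1]; f2 <- p$edge_faces[e, 2]
    s1 <- edge_slot(p, f1, e); s2 <- edge_slot(p, f2, e)
    p1 <- strsplit(get_poles(f1, s1), "")[[1L]]
    p2 <- strsplit(get_poles(f2, s2), "")[[1L]]
    ## p1 runs a->b, p2 runs b->a: contacts are (p1[1], p2[2]) and
    ## (p1[2], p2[1])
    if (p1[1L] == p2[2L] || p1[2L] == p2[1L]) {
      return(fail(f2, s2, "repulsive contact across a shared edge"))
    }
  }
  TRUE
}

#' @param m a magnet map.
#' @return `swap_poles()` returns the enantiomer map (every `NS` replaced by
#'   `SN` and vice versa).
#' @rdname magnet_map
#' @export
swap_poles <- function(m) {
  m$poles <- chartr("NS", "SN", m$poles)
  m
}

## Position (slot) of polyhedron edge e within face fi's cycle.
edge_slot <- function(p, fi, e) {
  f <- p$faces[[fi]]
  k <- length(f)
  a <- p$edges[e, 1]; b <- p$edges[e, 2]
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if ((f[i] == a && f[j] == b) || (f[i] == b && f[j] == a)) return(i)
  }
  stop("edge ", e, " does not bound face ", fi)
}
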
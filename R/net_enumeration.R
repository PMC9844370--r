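#' Face-adjacency graph of a polyhedron
#'
#' Nodes are faces; two faces are joined when they share a polyhedron edge.
#' The edge indexing of this graph is identical to the polyhedron's own
#' edge indexing (edge i of the solid is crossed by dual edge i of the face
#' graph), which is what makes a skeleton spanning tree and its cutting
#' tree exact complements.
#'
#' @param p a [polyhedron()].
#' @return an E x 2 integer matrix of face pairs (row i corresponds to
#'   polyhedron edge i).
#' @export
face_adjacency <- function(p) {
  stopifnot(inherits(p, "polyhedron"))
  p$edge_faces
}

#' Count spanning trees by the matrix-tree theorem
#'
#' Kirchhoff determinant count of the spanning trees of the face-adjacency
#' graph (i.e. of all edge unfoldings before symmetry reduction), or of any
#' graph given as an edge matrix.  This closed-form count is the
#' independent cross-check for the streaming enumerator: the two must agree
#' exactly (5,184,000 for the dodecahedron and icosahedron).
#'
#' @param x a [polyhedron()] (its face-adjacency graph is counted) or a
#'   2-column integer edge matrix.
#' @param n number of nodes when `x` is an edge matrix.
#' @return spanning-tree count (double; exact for counts below 2^53).
#' @export
count_spanning_trees <- function(x, n = NULL) {
  if (inherits(x, "polyhedron")) {
    edges <- face_adjacency(x)
    n <- length(x$faces)
  } else {
    edges <- as.matrix(x)
    if (is.null(n)) n <- max(edges)
  }
  if (n == 1L) return(1)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    A[i, j] <- A[i, j] + 1; A[j, i] <- A[j, i] + 1
  }
  L <- diag(rowSums(A)) - A
  # the count is an integer; round away the LU floating-point residue
  round(det(L[-1, -1, drop = FALSE]))
}

#' Enumerate skeleton spanning trees
#'
#' Emits every spanning tree of the face-adjacency graph exactly once.  A
#' skeleton tree lists the folded (uncut) edges of an unfolding: its nodes
#' are the F faces and it has F - 1 edges.  The total equals the
#' matrix-tree determinant.  Intended for the small solids or for sampling;
#' the symmetry-reduced [enumerate_nets()] never materializes all trees.
#'
#' @param p a [polyhedron()].
#' @param limit maximum number of trees to return (`Inf` for all).
#' @return integer matrix, one row per tree, columns the polyhedron-edge
#'   indices of the F - 1 folded edges; attribute `"total"` carries the
#'   full count even when truncated by `limit`.
#' @export
enumerate_skeleton_trees <- function(p, limit = Inf) {
  stopifnot(inherits(p, "polyhedron"))
  fa <- face_adjacency(p)
  nf <- length(p$faces)
  if (nrow(fa) > 30L) stop("tree streaming supports at most 30 dual edges")
  res <- cpp_enumerate_trees(fa, nf, NULL,
                             if (is.finite(limit)) as.double(limit) else -1)
  trees <- t(vapply(res$masks, mask_to_edges, integer(nf - 1L)))
  if (nf == 2L) trees <- matrix(trees, ncol = 1L)
  attr(trees, "total") <- res$total
  trees
}

mask_to_edges <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:29)) != 0L)

edges_to_mask <- function(idx) {
  m <- 0L
  for (i in idx) m <- bitwOr(m, bitwShiftL(1L, i - 1L))
  m
}

#' Cutting tree of a skeleton tree
#'
#' The complement-dual of a skeleton tree: polyhedron edge i is cut exactly
#' when dual edge i is absent from the skeleton tree.  The result is a
#' spanning tree of the solid's vertices (V - 1 cut edges) -- the edges one
#' would cut to unfold the solid into this net.
#'
#' @param p a [polyhedron()].
#' @param tree integer vector of folded polyhedron-edge indices (a skeleton
#'   tree, e.g. one row of [enumerate_skeleton_trees()]).
#' @return integer vector of cut polyhedron-edge indices.
#' @export
skeleton_to_cut_tree <- function(p, tree) {
  stopifnot(inherits(p, "polyhedron"))
  check_skeleton_tree(p, tree)
  cut <- setdiff(seq_len(nrow(p$edges)), tree)
  ## sanity: complement must span the V vertices without cycles
  if (!is_spanning_tree(p$edges[cut, , drop = FALSE], nrow(p$vertices))) {
    stop("complement of the skeleton tree is not a spanning tree of the vertices")
  }
  cut
}

check_skeleton_tree <- function(p, tree) {
  nf <- length(p$faces)
  if (length(tree) != nf - 1L ||
      !is_spanning_tree(face_adjacency(p)[tree, , drop = FALSE], nf)) {
    stop("'tree' is not a spanning tree of the face-adjacency graph")
  }
  invisible(TRUE)
}

is_spanning_tree <- function(edges, n) {
  if (nrow(edges) != n - 1L) return(FALSE)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a == b) return(FALSE)
    comp[a] <- b
  }
  TRUE
}

#' Enumerate distinct Durer nets
#'
#' Streams all spanning trees of the face-adjacency graph and reduces them
#' to symmetry classes: two unfoldings are the same Durer net when a
#' symmetry of the solid (rotation or reflection) maps one set of folded
#' edges onto the other.  Each class is represented by its canonical key,
#' the lexicographically minimal image of the folded-edge set over the full
#' symmetry group.  For the dodecahedron and icosahedron this reduces
#' 5,184,000 spanning trees to the 43,380 distinct nets.
#'
#' @param p a [polyhedron()].
#' @param cache_dir optional directory for an on-disk cache of the orbit
#'   table (CSV keyed by solid name), so repeated long runs resume
#'   instantly.  In-memory caching across calls is automatic.
#' @return data frame with one row per distinct net: `mask` (canonical
#'   folded-edge bitmask), `orbit_size` (number of spanning trees in the
#'   class); attribute `"total_trees"` holds the spanning-tree total.
#' @examples
#' enumerate_nets(platonic_solid("tetrahedron"))  # 2 nets
#' @export
enumerate_nets <- function(p, cache_dir = NULL) {
  stopifnot(inherits(p, "polyhedron"))
  key <- paste0("nets_", p$name)
  hit <- fn_cache_get(key)
  if (!is.null(hit)) return(hit)
  if (!is.null(cache_dir)) {
    fp <- file.path(cache_dir, paste0("foldnet-orbits-", p$name, ".csv"))
    if (file.exists(fp)) {
      tab <- read.csv(fp)
      attr(tab, "total_trees") <- sum(tab$orbit_size)
      fn_cache_set(key, tab)
      return(tab)
    }
  }
  fa <- face_adjacency(p)
  if (nrow(fa) > 30L) stop("net enumeration supports at most 30 edges")
  sg <- symmetry_group(p, include_reflections = TRUE)
  res <- cpp_enumerate_trees(fa, length(p$faces), sg$edge_perms, -1)
  tab <- data.frame(mask = res$masks, orbit_size = res$sizes)
  tab <- tab[order(tab$mask), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "total_trees") <- res$total
  fn_cache_set(key, tab)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(cache_dir,
                             paste0("foldnet-orbits-", p$name, ".csv")),
              row.names = FALSE)
  }
  tab
}

#' Canonical identifier of a Durer net
#'
#' Two invariants that identify a net independently of labelling: the
#' `orbit_key`, the folded-edge set minimized over the solid's full
#' symmetry group (identical exactly for symmetry-equivalent nets), and
#' the `degree_circuit`, the boundary degree sequence in lexicographically
#' minimal cyclic form over both traversal directions (invariant under
#' relabelling, rotation and reflection of the drawing).
#'
#' @param p a [polyhedron()].
#' @param net a [unfold()]ed `durer_net` of `p`.
#' @return list with `orbit_key` (integer bitmask) and `degree_circuit`
#'   (string such as `"2-2-3-..."`).
#' @export
canonical_id <- function(p, net) {
  stopifnot(inherits(p, "polyhedron"), inherits(net, "durer_net"))
  sg <- symmetry_group(p, include_reflections = TRUE)
  mask <- edges_to_mask(net$tree)
  orbit_key <- min(apply(sg$edge_perms, 1L, function(ep) {
    edges_to_mask(ep[net$tree])
  }))
  list(orbit_key = orbit_key,
       degree_circuit = canonical_circuit(net$boundary$degree))
}

#' Canonical cyclic form of a degree sequence
#'
#' Lexicographically smallest rotation of the sequence, taken over both
#' traversal directions, joined with `-`.  This is the normal form in which
#' boundary degree circuits are compared.
#'
#' @param degs integer vector (one boundary vertex degree per step).
#' @return canonical string form.
#' @export
canonical_circuit <- function(degs) {
  n <- length(degs)
  if (n == 0L) return("")
  best <- NULL
  for (s in list(degs, rev(degs))) {
    for (r in seq_len(n)) {
      rot <- s[((seq_len(n) + r - 2L) %% n) + 1L]
      if (is.null(best) || rotation_less(rot, best)) best <- rot
    }
  }
  paste(best, collapse = "-")
}

rotation_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}
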
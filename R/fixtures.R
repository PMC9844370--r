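#' Synthetic pseudo-net fixtures
#'
#' Adversarial and edge-case planar configurations used to exercise the
#' validators independently of the exhaustive enumerator:
#'
#' * `overlapping_fan(n)`: a fan of `n` unit equilateral triangles around a
#'   common vertex.  With `n >= 7` the angle sum exceeds 360 degrees, so
#'   face interiors must overlap -- a constructed violation of the
#'   non-self-overlap property of genuine Durer nets.
#' * `chain_net(n)`: `n` unit squares glued in a row; its skeleton is a
#'   path (2 leaves, diameter `n - 1`).
#' * `star_net(k)`: a central regular `k`-gon with a congruent `k`-gon
#'   attached across every edge; its skeleton is a star (`k` leaves,
#'   diameter 2).
#'
#' The objects carry planar geometry and a skeleton but no provenance
#' polyhedron, so descriptor functions that need the solid (vertex
#' connections, boundary circuits) reject them.
#'
#' @param kind one of `"overlapping_fan"`, `"chain_net"`, `"star_net"`.
#' @param n size parameter: triangles in the fan, squares in the chain, or
#'   sides of the central polygon.
#' @return a `durer_net` fixture.
#' @examples
#' overlap_check(make_fixture("overlapping_fan", 7))  # TRUE
#' leaves(make_fixture("chain_net", 6))               # 2
#' @export
make_fixture <- function(kind = c("overlapping_fan", "chain_net", "star_net"),
                         n = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    overlapping_fan = {
      if (is.null(n)) n <- 7L
      if (n < 2L) stop("overlapping_fan needs at least 2 triangles")
      faces <- lapply(seq_len(n), function(i) {
        a <- (i - 1L) * pi / 3; b <- i * pi / 3
        rbind(c(0, 0), c(cos(a), sin(a)), c(cos(b), sin(b)))
      })
      fixture_net(faces, path_edges(n), "overlapping_fan")
    },
    chain_net = {
      if (is.null(n)) n <- 6L
      if (n < 1L) stop("chain_net needs at least 1 square")
      faces <- lapply(seq_len(n), function(i) {
        x <- i - 1
        rbind(c(x, 0), c(x + 1, 0), c(x + 1, 1), c(x, 1))
      })
      fixture_net(faces, path_edges(n), "chain_net")
    },
    star_net = {
      if (is.null(n)) n <- 5L
      if (n < 3L) stop("star_net needs a central polygon with >= 3 sides")
      centre <- regular_polygon_from_edge(c(0, 0), c(1, 0), n)
      faces <- c(list(centre), lapply(seq_len(n), function(i) {
        j <- if (i == n) 1L else i + 1L
        regular_polygon_from_edge(centre[j, ], centre[i, ], n)
      }))
      fixture_net(faces, cbind(1L, 1L + seq_len(n)), "star_net")
    })
}

fixture_net <- function(faces, skeleton, name) {
  structure(list(
    name = name,
    polyhedron = NULL,
    tree = NULL,
    cut_edges = NULL,
    skeleton = skeleton,
    faces2d = faces,
    corner_class = NULL,
    class_polyv = NULL,
    class_size = NULL,
    boundary = NULL
  ), class = "durer_net")
}

path_edges <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  cbind(seq_len(n - 1L), 2:n)
}

## Counterclockwise regular k-gon whose first directed edge is a -> b.
regular_polygon_from_edge <- function(a, b, k) {
  out <- matrix(0, k, 2L)
  out[1, ] <- a; out[2, ] <- b
  d <- b - a
  th <- 2 * pi / k
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  for (i in 3:k) {
    d <- as.vector(rot %*% d)
    out[i, ] <- out[i - 1L, ] + d
  }
  out
}
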
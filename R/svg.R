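#' Render a net (or a Schlegel layout) as SVG
#'
#' Writes a standalone SVG file with one `<polygon>` element per face at
#' unit-edge scale (a configurable pixel scale is applied uniformly).
#' Optional overlays: the skeleton tree (one line segment per folded
#' edge), the backbone (longest skeleton path), restrictive
#' vertex-connection markers, and shading of leaf faces.  Coordinates are
#' written with a fixed float format so output is byte-stable for a given
#' net.
#'
#' @param net a `durer_net` (fixtures allowed; vertex-connection markers
#'   need provenance).
#' @param path output file.
#' @param overlays character vector among `"skeleton"`, `"backbone"`,
#'   `"vertex_connections"`, `"leaves"`.
#' @param scale pixels per unit edge.
#' @return the path, invisibly.
#' @export
render_net_svg <- function(net, path, overlays = character(0), scale = 60) {
  stopifnot(inherits(net, "durer_net"))
  bad <- setdiff(overlays, c("skeleton", "backbone", "vertex_connections", "leaves"))
  if (length(bad)) stop("unknown overlay(s): ", paste(bad, collapse = ", "))
  pts <- do.call(rbind, net$faces2d)
  pad <- 0.6
  x0 <- min(pts[, 1]) - pad; x1 <- max(pts[, 1]) + pad
  y0 <- min(pts[, 2]) - pad; y1 <- max(pts[, 2]) + pad
  fmt <- function(v) formatC(v, digits = 6, format = "f")
  tx <- function(x) fmt((x - x0) * scale)
  ty <- function(y) fmt((y1 - y) * scale)  # flip: SVG y grows downward

  lf <- if ("leaves" %in% overlays) which(skeleton_degrees(net) == 1L) else integer(0)
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
    fmt((x1 - x0) * scale), fmt((y1 - y0) * scale),
    fmt((x1 - x0) * scale), fmt((y1 - y0) * scale)))
  for (i in seq_along(net$faces2d)) {
    xy <- net$faces2d[[i]]
    fill <- if (i %in% lf) "#ffd9a0" else "#d7e3f4"
    out <- c(out, sprintf(
      '<polygon points="%s" fill="%s" stroke="#333333" stroke-width="1"/>',
      paste(paste0(tx(xy[, 1]), ",", ty(xy[, 2])), collapse = " "), fill))
  }
  centroids <- t(vapply(net$faces2d, colMeans, numeric(2)))
  if ("skeleton" %in% overlays && nrow(net$skeleton) > 0L) {
    for (r in seq_len(nrow(net$skeleton))) {
      a <- centroids[net$skeleton[r, 1], ]; b <- centroids[net$skeleton[r, 2], ]
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#2b6cb0" stroke-width="2"/>',
        tx(a[1]), ty(a[2]), tx(b[1]), ty(b[2])))
    }
  }
  if ("backbone" %in% overlays && nrow(net$skeleton) > 0L) {
    bb <- backbone_path(net$skeleton, length(net$faces2d))
    for (i in seq_len(length(bb) - 1L)) {
      a <- centroids[bb[i], ]; b <- centroids[bb[i + 1L], ]
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#c53030" stroke-width="3"/>',
        tx(a[1]), ty(a[2]), tx(b[1]), ty(b[2])))
    }
  }
  if ("vertex_connections" %in% overlays) {
    if (is.null(net$polyhedron)) {
      stop("vertex-connection overlay needs the source polyhedron")
    }
    m <- net$polyhedron$vertex_m[net$class_polyv]
    vc <- which(net$class_size == m)
    for (cl in vc) {
      loc <- NULL
      for (f in seq_along(net$faces2d)) {
        hit <- which(net$corner_class[[f]] == cl)
        if (length(hit)) { loc <- net$faces2d[[f]][hit[1L], ]; break }
      }
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="5" fill="none" stroke="#c53030" stroke-width="2"/>',
        tx(loc[1]), ty(loc[2])))
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

## One longest path in a tree (vertex sequence).
backbone_path <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- function(s) {
    d <- rep(NA_integer_, n); par <- rep(NA_integer_, n)
    d[s] <- 0L; q <- s
    while (length(q)) {
      v <- q[[1L]]; q <- q[-1L]
      for (w in adj[[v]]) if (is.na(d[w])) {
        d[w] <- d[v] + 1L; par[w] <- v; q <- c(q, w)
      }
    }
    list(d = d, par = par)
  }
  r1 <- bfs(1L)
  u <- which.max(r1$d)
  r2 <- bfs(u)
  v <- which.max(r2$d)
  path <- v
  while (!is.na(r2$par[path[1L]])) path <- c(r2$par[path[1L]], path)
  path
}

#' Export a Schlegel layout as SVG
#'
#' @param p a [polyhedron()].
#' @param path output file.
#' @param outer_face face projected through (see [schlegel_layout()]).
#' @param scale pixels per layout unit.
#' @return the path, invisibly.
#' @export
render_schlegel_svg <- function(p, path, outer_face = 1L, scale = 200) {
  pos <- schlegel_layout(p, outer_face)
  pad <- 0.15
  x0 <- min(pos[, 1]) - pad; x1 <- max(pos[, 1]) + pad
  y0 <- min(pos[, 2]) - pad; y1 <- max(pos[, 2]) + pad
  fmt <- function(v) formatC(v, digits = 6, format = "f")
  tx <- function(x) fmt((x - x0) * scale)
  ty <- function(y) fmt((y1 - y) * scale)
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s">',
    fmt((x1 - x0) * scale), fmt((y1 - y0) * scale)))
  for (r in seq_len(nrow(p$edges))) {
    a <- pos[p$edges[r, 1], ]; b <- pos[p$edges[r, 2], ]
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333" stroke-width="1.5"/>',
      tx(a[1]), ty(a[2]), tx(b[1]), ty(b[2])))
  }
  for (i in seq_len(nrow(pos))) {
    out <- c(out, sprintf('<circle cx="%s" cy="%s" r="4" fill="#2b6cb0"/>',
                          tx(pos[i, 1]), ty(pos[i, 2])))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}
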
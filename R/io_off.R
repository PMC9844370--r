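#' Read and write polyhedra as ASCII OFF meshes
#'
#' The OFF dialect used is the plain ASCII one: an `OFF` header line, a
#' counts line `V F E`, then V vertex coordinate lines and F face lines
#' (`k v1 ... vk`, zero-based indices).  Comments (`#`) and blank lines
#' are skipped.  Round-tripping a mesh preserves combinatorics exactly and
#' coordinates to 1e-9.
#'
#' @param path file path.
#' @param name label for the resulting solid (defaults to the file name).
#' @return `read_off()` returns a [polyhedron()].
#' @export
read_off <- function(path, name = NULL) {
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("empty OFF file: ", path)
  lines <- raw[keep]
  lineno <- keep
  if (toupper(trimws(lines[1])) != "OFF") {
    stop("line ", lineno[1], ": expected 'OFF' header")
  }
  counts <- suppressWarnings(as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]]))
  if (length(counts) < 2L || anyNA(counts[1:2])) {
    stop("line ", lineno[2], ": malformed counts line (need 'V F E')")
  }
  nv <- as.integer(counts[1]); nf <- as.integer(counts[2])
  if (length(lines) < 2L + nv + nf) {
    stop("file ends before ", nv, " vertices and ", nf, " faces are read")
  }
  verts <- matrix(NA_real_, nv, 3L)
  for (i in seq_len(nv)) {
    xyz <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + i]), "\\s+")[[1]]))
    if (length(xyz) < 3L || anyNA(xyz[1:3])) {
      stop("line ", lineno[2L + i], ": malformed vertex coordinates")
    }
    verts[i, ] <- xyz[1:3]
  }
  faces <- vector("list", nf)
  for (i in seq_len(nf)) {
    v <- suppressWarnings(as.integer(strsplit(trimws(lines[2L + nv + i]), "\\s+")[[1]]))
    if (length(v) < 1L || anyNA(v[1]) || length(v) < 1L + v[1]) {
      stop("line ", lineno[2L + nv + i], ": malformed face line")
    }
    idx <- v[2:(1L + v[1])] + 1L
    if (anyNA(idx) || any(idx < 1L | idx > nv)) {
      stop("line ", lineno[2L + nv + i], ": face references a missing vertex")
    }
    faces[[i]] <- idx
  }
  if (is.null(name)) name <- sub("\\.off$", "", basename(path), ignore.case = TRUE)
  polyhedron(verts, faces, name = name)
}

#' @param p a [polyhedron()] to write.
#' @rdname read_off
#' @export
write_off <- function(p, path) {
  stopifnot(inherits(p, "polyhedron"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", nrow(p$vertices), length(p$faces),
                     nrow(p$edges)), con)
  writeLines(apply(p$vertices, 1L, function(v) {
    paste(formatC(v, digits = 12, format = "g"), collapse = " ")
  }), con)
  writeLines(vapply(p$faces, function(f) {
    paste(c(length(f), f - 1L), collapse = " ")
  }, character(1)), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh (courtesy import)
#'
#' Minimal reader for `v` and `f` records (texture/normal references in
#' face entries are ignored).  Write support is OFF-only.
#'
#' @inheritParams read_off
#' @return a [polyhedron()].
#' @export
read_obj <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (!length(vlines) || !length(flines)) {
    stop("OBJ file has no usable 'v'/'f' records: ", path)
  }
  verts <- do.call(rbind, lapply(vlines, function(l) {
    as.numeric(strsplit(trimws(sub("^v", "", l)), "\\s+")[[1]])[1:3]
  }))
  faces <- lapply(flines, function(l) {
    toks <- strsplit(trimws(sub("^f", "", l)), "\\s+")[[1]]
    as.integer(vapply(strsplit(toks, "/"), `[`, character(1), 1L))
  })
  if (is.null(name)) name <- sub("\\.obj$", "", basename(path), ignore.case = TRUE)
  polyhedron(verts, faces, name = name)
}
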
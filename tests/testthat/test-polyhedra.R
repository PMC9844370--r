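test_that("the five Platonic solids satisfy the closed-surface invariants", {
  expected <- list(
    tetrahedron  = c(4, 6, 4),
    cube         = c(8, 12, 6),
    octahedron   = c(6, 12, 8),
    dodecahedron = c(20, 30, 12),
    icosahedron  = c(12, 30, 20)
  )
  for (nm in names(expected)) {
    p <- platonic_solid(nm)
    expect_identical(c(nrow(p$vertices), nrow(p$edges), length(p$faces)),
                     as.integer(expected[[nm]]), info = nm)
    expect_true(validate_polyhedron(p), info = nm)
    elen <- sqrt(rowSums((p$vertices[p$edges[, 1], ] -
                            p$vertices[p$edges[, 2], ])^2))
    expect_true(all(abs(elen - 1) < 1e-9), info = nm)
    # each edge shared by exactly two distinct faces
    expect_true(all(p$edge_faces[, 1] != p$edge_faces[, 2]), info = nm)
  }
  expect_error(platonic_solid("hexahedron"))
})

test_that("face-adjacency duality pairs the solids", {
  # the face graph of a solid is the 1-skeleton of its dual
  iso <- function(a_edges, n_a, b_edges, n_b) {
    ga <- igraph::graph_from_edgelist(a_edges, directed = FALSE)
    gb <- igraph::graph_from_edgelist(b_edges, directed = FALSE)
    igraph::isomorphic(ga, gb)
  }
  cube <- platonic_solid("cube"); octa <- platonic_solid("octahedron")
  dode <- platonic_solid("dodecahedron"); icos <- platonic_solid("icosahedron")
  expect_true(iso(face_adjacency(cube), 6, octa$edges, 6))
  expect_true(iso(face_adjacency(octa), 8, cube$edges, 8))
  expect_true(iso(face_adjacency(dode), 12, icos$edges, 12))
  expect_true(iso(face_adjacency(icos), 20, dode$edges, 20))
})

test_that("symmetry group orders match the brute-force bijection oracle", {
  # oracle counts all adjacency-preserving bijections
  for (nm in c("tetrahedron", "cube")) {
    p <- platonic_solid(nm)
    oracle <- brute_force_automorphism_count(p$edges, nrow(p$vertices))
    sg <- symmetry_group(p, include_reflections = TRUE)
    rot <- symmetry_group(p, include_reflections = FALSE)
    expect_identical(nrow(sg$perms), oracle, info = nm)
    expect_identical(nrow(rot$perms) * 2L, nrow(sg$perms), info = nm)
  }
  ico <- platonic_solid("icosahedron")
  expect_identical(nrow(symmetry_group(ico)$perms),
                   brute_force_automorphism_count(ico$edges, 12L))
  expect_identical(nrow(symmetry_group(ico)$perms), 120L)
  expect_identical(nrow(symmetry_group(platonic_solid("tetrahedron"),
                                       include_reflections = FALSE)$perms), 12L)
})

test_that("every symmetry element preserves edges and faces", {
  p <- platonic_solid("octahedron")
  sg <- symmetry_group(p)
  ek <- sort(paste(p$edges[, 1], p$edges[, 2]))
  for (g in seq_len(nrow(sg$perms))) {
    s <- sg$perms[g, ]
    a <- s[p$edges[, 1]]; b <- s[p$edges[, 2]]
    expect_identical(sort(paste(pmin(a, b), pmax(a, b))), ek)
    expect_identical(sort(sg$face_perms[g, ]), seq_along(p$faces))
    expect_identical(sort(sg$edge_perms[g, ]), seq_len(nrow(p$edges)))
  }
})

test_that("Schlegel layout is a crossing-free drawing of the 1-skeleton", {
  for (nm in c("cube", "dodecahedron")) {
    p <- platonic_solid(nm)
    pos <- schlegel_layout(p, outer_face = 1L)
    expect_identical(nrow(pos), nrow(p$vertices))
    E <- p$edges
    for (i in seq_len(nrow(E) - 1L)) {
      for (j in (i + 1L):nrow(E)) {
        if (length(intersect(E[i, ], E[j, ]))) next
        expect_false(segments_cross(pos[E[i, 1], ], pos[E[i, 2], ],
                                    pos[E[j, 1], ], pos[E[j, 2], ]),
                     info = sprintf("%s edges %d,%d", nm, i, j))
      }
    }
  }
  expect_error(schlegel_layout(platonic_solid("cube"), outer_face = 7L))
})

test_that("magnet maps validate, enantiomers validate, tampering is caught", {
  for (nm in c("tetrahedron", "cube", "octahedron", "dodecahedron",
               "icosahedron")) {
    p <- platonic_solid(nm)
    m <- magnet_map(p)
    expect_true(isTRUE(validate_magnet_map(p, m)), info = nm)
    expect_true(isTRUE(validate_magnet_map(p, swap_poles(m))), info = nm)
  }
  p <- platonic_solid("cube")
  m <- magnet_map(p)
  m$poles[m$face == 3 & m$slot == 2] <- "SN"
  bad <- validate_magnet_map(p, m)
  expect_false(isTRUE(bad))
  expect_identical(attr(bad, "violation")$face, 3L)
})

test_that("magnet validation is invariant under solid symmetries", {
  p <- platonic_solid("octahedron")
  sg <- symmetry_group(p)
  m <- magnet_map(p)
  for (g in c(2L, 7L, 19L, 30L, nrow(sg$perms))) {
    m2 <- m
    m2$face <- sg$face_perms[g, m$face]
    expect_true(isTRUE(validate_magnet_map(p, m2)))
  }
})

test_that("triangulation numbers follow the Caspar-Klug formula", {
  expect_identical(triangulation_number(1, 0),
                   list(t_number = 1, capsomeres = 60))
  expect_identical(triangulation_number(1, 1),
                   list(t_number = 3, capsomeres = 180))
  expect_identical(triangulation_number(2, 0)$t_number, 4)
  expect_identical(triangulation_number(2, 0)$capsomeres, 240)
  expect_error(triangulation_number(0, 1))
  expect_error(triangulation_number(-1, 0))
  expect_error(triangulation_number(1.5, 0))
})
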
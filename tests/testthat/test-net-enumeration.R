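test_that("streamed spanning-tree counts equal the matrix-tree determinant", {
  for (nm in c("tetrahedron", "cube", "octahedron")) {
    p <- platonic_solid(nm)
    kirchhoff <- count_spanning_trees(p)
    trees <- enumerate_skeleton_trees(p)
    expect_identical(nrow(trees), as.integer(kirchhoff), info = nm)
    expect_identical(attr(trees, "total"), as.double(kirchhoff), info = nm)
  }
  # known closed-form values for the small face graphs
  expect_identical(count_spanning_trees(platonic_solid("tetrahedron")), 16)
  expect_identical(count_spanning_trees(platonic_solid("cube")), 384)
  expect_identical(count_spanning_trees(platonic_solid("icosahedron")), 5184000)
  expect_identical(count_spanning_trees(platonic_solid("dodecahedron")), 5184000)
})

test_that("every streamed tree is a spanning tree, emitted exactly once", {
  p <- platonic_solid("cube")
  trees <- enumerate_skeleton_trees(p)
  expect_identical(anyDuplicated(apply(trees, 1L, paste, collapse = ",")), 0L)
  fa <- face_adjacency(p)
  for (r in seq_len(nrow(trees))) {
    expect_true(foldnet:::is_spanning_tree(fa[trees[r, ], , drop = FALSE], 6L))
  }
})

test_that("cut trees are spanning complements on the solid's vertices", {
  # exhaustive over all 384 cube skeleton trees: the complement always
  # spans the 8 vertices acyclically with V - 1 = 7 edges
  p <- platonic_solid("cube")
  trees <- enumerate_skeleton_trees(p)
  for (r in seq_len(nrow(trees))) {
    cut <- skeleton_to_cut_tree(p, trees[r, ])
    expect_length(cut, 7L)
    expect_true(foldnet:::is_spanning_tree(p$edges[cut, , drop = FALSE], 8L))
  }
  ico <- platonic_solid("icosahedron")
  t1 <- enumerate_skeleton_trees(ico, limit = 1)[1, ]
  expect_length(skeleton_to_cut_tree(ico, t1), 11L)
  expect_error(skeleton_to_cut_tree(p, trees[1, -1]))
})

test_that("unfolding preserves congruence, shared edges, and refolds", {
  for (nm in c("tetrahedron", "octahedron", "dodecahedron")) {
    p <- platonic_solid(nm)
    tree <- enumerate_skeleton_trees(p, limit = 3)
    for (r in seq_len(nrow(tree))) {
      net <- unfold(p, tree[r, ])
      # every face congruent to the solid's face: all edge lengths 1
      for (xy in net$faces2d) {
        j <- c(2:nrow(xy), 1L)
        expect_true(all(abs(sqrt(rowSums((xy - xy[j, ])^2)) - 1) < 1e-9))
      }
      # folded edges coincide exactly
      for (e in net$tree) {
        f1 <- p$edge_faces[e, 1]; f2 <- p$edge_faces[e, 2]
        for (v in p$edges[e, ]) {
          a <- net$faces2d[[f1]][match(v, p$faces[[f1]]), ]
          b <- net$faces2d[[f2]][match(v, p$faces[[f2]]), ]
          expect_true(max(abs(a - b)) < 1e-9)
        }
      }
      # boundary has 2 (V - 1) vertices and edges
      expect_identical(nrow(net$boundary), 2L * (nrow(p$vertices) - 1L))
      expect_true(refold_check(net))
    }
  }
})

test_that("root face is centred with its first edge along +x", {
  p <- platonic_solid("cube")
  net <- unfold(p, enumerate_skeleton_trees(p, limit = 1)[1, ])
  root <- net$faces2d[[1L]]
  expect_true(max(abs(colMeans(root))) < 1e-9)
  d <- root[2, ] - root[1, ]
  expect_true(abs(d[2]) < 1e-9 && d[1] > 0)
})

test_that("overlap detection flags impossible fans but passes genuine nets", {
  expect_true(overlap_check(make_fixture("overlapping_fan", 7)))
  expect_false(overlap_check(make_fixture("overlapping_fan", 5)))
  expect_false(overlap_check(make_fixture("chain_net", 6)))
  expect_false(overlap_check(make_fixture("star_net", 5)))
  p <- platonic_solid("octahedron")
  tab <- descriptor_table(p)
  expect_identical(sum(tab$overlaps), 0L)
})

test_that("boundary circuit is the doubled-cut-tree Euler tour length", {
  p <- platonic_solid("tetrahedron")
  orb <- enumerate_nets(p)
  for (r in seq_len(nrow(orb))) {
    net <- unfold(p, foldnet:::mask_to_edges(orb$mask[r]))
    circ <- boundary_circuit(net)
    expect_length(circ, 6L)  # 2 (V - 1) with V = 4
    # circuit degrees match the net vertex classes (each visited once here)
    expect_identical(sort(circ), sort(net$class_size + 1L))
  }
  expect_error(boundary_circuit(make_fixture("chain_net", 3)))
})

test_that("canonical ids are invariant under symmetries and relabeling", {
  p <- platonic_solid("cube")
  sg <- symmetry_group(p)
  orb <- enumerate_nets(p)
  tree <- foldnet:::mask_to_edges(orb$mask[4L])
  base <- canonical_id(p, unfold(p, tree))
  for (g in c(2L, 13L, 27L, 48L)) {
    moved <- permute_tree(sg, g, tree)
    id2 <- canonical_id(p, unfold(p, moved))
    expect_identical(id2$orbit_key, base$orbit_key)
    expect_identical(id2$degree_circuit, base$degree_circuit)
  }
  # two inequivalent nets get different keys
  other <- canonical_id(p, unfold(p, foldnet:::mask_to_edges(orb$mask[5L])))
  expect_false(other$orbit_key == base$orbit_key)
})

test_that("distinct net counts and orbit sizes reproduce the small solids", {
  expect_identical(nrow(enumerate_nets(platonic_solid("tetrahedron"))), 2L)
  cube_orb <- enumerate_nets(platonic_solid("cube"))
  octa_orb <- enumerate_nets(platonic_solid("octahedron"))
  expect_identical(nrow(cube_orb), 11L)
  expect_identical(nrow(octa_orb), 11L)
  # orbit-size conservation: orbits partition the full tree set
  expect_identical(sum(cube_orb$orbit_size), 384L)
  expect_identical(sum(octa_orb$orbit_size), 384L)
})

test_that("fixtures have the advertised skeleton shape", {
  ch <- make_fixture("chain_net", 6)
  expect_identical(leaves(ch), 2L)
  expect_identical(skeleton_metrics(ch)$backbone_length, 5L)
  st <- make_fixture("star_net", 5)
  expect_identical(leaves(st), 5L)
  expect_identical(skeleton_metrics(st)$backbone_length, 2L)
  expect_error(make_fixture("star_net", 2))
  expect_error(make_fixture("overlapping_fan", 1))
})
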
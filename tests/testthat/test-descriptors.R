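test_that("degree-distribution solutions solve both identities exactly", {
  cube_sols <- degree_distribution_solutions(6, 4)
  expect_identical(unname(cube_sols),
                   rbind(c(2L, 4L, 0L, 0L), c(3L, 2L, 1L, 0L),
                         c(4L, 0L, 2L, 0L), c(4L, 1L, 0L, 1L)))
  expect_identical(nrow(degree_distribution_solutions(4, 3)), 2L)
  two <- degree_distribution_solutions(2, 3)
  expect_identical(unname(two), rbind(c(2L, 0L, 0L)))
  # identities hold for a bigger case (icosahedron face graph: F=20, dmax=3)
  ico_sols <- degree_distribution_solutions(20, 3)
  for (r in seq_len(nrow(ico_sols))) {
    expect_identical(sum(ico_sols[r, ]), 20L)
    expect_identical(sum(ico_sols[r, ] * 1:3), 38L)
  }
})

test_that("cube nets realize the four distributions with counts 4, 5, 1, 1", {
  realized <- realized_degree_distributions(platonic_solid("cube"))
  expect_identical(realized$distribution,
                   c("2,4,0,0", "3,2,1,0", "4,0,2,0", "4,1,0,1"))
  expect_identical(realized$nets, c(4L, 5L, 1L, 1L))
  expect_identical(sum(realized$nets), 11L)
})

test_that("octahedron realizes 3 distributions, a strict solution subset", {
  p <- platonic_solid("octahedron")
  realized <- realized_degree_distributions(p)
  expect_identical(nrow(realized), 3L)
  sols <- apply(degree_distribution_solutions(8, 3), 1L, paste, collapse = ",")
  expect_true(all(realized$distribution %in% sols))
  expect_true(length(sols) > nrow(realized))
})

test_that("cube skeleton identities: 5 edges, degree sum 10", {
  p <- platonic_solid("cube")
  orb <- enumerate_nets(p)
  for (r in seq_len(nrow(orb))) {
    net <- unfold(p, foldnet:::mask_to_edges(orb$mask[r]))
    sk <- skeleton_metrics(net)
    expect_identical(sk$spanning_tree_edges, 5L)
    deg <- foldnet:::skeleton_degrees(net)
    expect_identical(sum(deg), 10L)
  }
})

test_that("leaves equal the degree-1 count of the skeleton distribution", {
  # cross-check leaves() against the A column for every net of three solids
  for (nm in c("tetrahedron", "cube", "octahedron")) {
    tab <- descriptor_table(platonic_solid(nm))
    a_col <- vapply(strsplit(tab$degree_distribution, ","),
                    function(x) as.integer(x[1]), integer(1))
    expect_identical(tab$leaves, a_col, info = nm)
  }
})

test_that("vertex connections: restrictive is a subset of traditional", {
  tab <- descriptor_table(platonic_solid("octahedron"))
  expect_true(all(tab$vc_traditional >= tab$vc_restrictive))
  # triangle-faced solids admit fans of 3..m-1 faces, so the two counts
  # genuinely differ somewhere
  expect_true(any(tab$vc_traditional > tab$vc_restrictive))
  # square faces (cube): any fan of >= 3 is the full fan, so they coincide
  cube_tab <- descriptor_table(platonic_solid("cube"))
  expect_identical(cube_tab$vc_traditional, cube_tab$vc_restrictive)
  expect_error(vertex_connections(make_fixture("chain_net", 3)))
})

test_that("a single unit pentagon is the degenerate baseline", {
  pent <- single_polygon_net(5)
  expect_identical(radius_of_gyration(pent)$rg, 0)
  expect_identical(leaves(pent), 0L)
  hull <- convex_hull_metrics(pent)
  expect_equal(hull$hull_perimeter, 5, tolerance = 1e-9)
  expect_equal(hull$hull_area, sqrt(5 * (5 + 2 * sqrt(5))) / 4,
               tolerance = 1e-9)
})

test_that("two glued unit triangles have centroid-sum Rg^2 = 1/12", {
  # oracle: the two centroids are each sqrt(3)/6 from the shared-edge
  # midpoint, so the mean squared distance is 3/36 / ... = 1/12
  tri2 <- make_fixture("overlapping_fan", 2)
  expect_equal(radius_of_gyration(tri2)$rg_squared, 1 / 12, tolerance = 1e-12)
  expect_equal(rg_squared_oracle(tri2), 1 / 12, tolerance = 1e-12)
})

test_that("Rg is homogeneous of degree 1 and rigid-motion invariant", {
  p <- platonic_solid("octahedron")
  net <- unfold(p, enumerate_skeleton_trees(p, limit = 1)[1, ])
  base <- radius_of_gyration(net)
  for (s in c(0.5, 2, 7.25)) {
    scaled <- net
    scaled$faces2d <- lapply(net$faces2d, function(xy) xy * s)
    expect_equal(radius_of_gyration(scaled)$rg, base$rg * s, tolerance = 1e-9)
    expect_equal(radius_of_gyration(scaled)$rg_squared, base$rg_squared * s^2,
                 tolerance = 1e-9)
  }
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- net
  moved$faces2d <- lapply(net$faces2d, function(xy) {
    sweep(xy %*% t(R), 2, c(3.5, -1.25), `+`)
  })
  expect_equal(radius_of_gyration(moved)$rg, base$rg, tolerance = 1e-9)
  hm <- convex_hull_metrics(moved); hb <- convex_hull_metrics(net)
  expect_equal(hm$hull_area, hb$hull_area, tolerance = 1e-9)
  expect_equal(hm$hull_perimeter, hb$hull_perimeter, tolerance = 1e-9)
})

test_that("integral and centroid-sum Rg agree in ranking on cube nets", {
  p <- platonic_solid("cube")
  orb <- enumerate_nets(p)
  nets <- lapply(orb$mask, function(m) unfold(p, foldnet:::mask_to_edges(m)))
  rg_c <- vapply(nets, function(n) radius_of_gyration(n, "centroid_sum")$rg,
                 numeric(1))
  rg_i <- vapply(nets, function(n) radius_of_gyration(n, "area_integral")$rg,
                 numeric(1))
  expect_true(cor(rg_c, rg_i, method = "spearman") > 0.95)
  expect_true(all(rg_i > 0))
})

test_that("hull metrics: containment bound and degenerate rejection", {
  p <- platonic_solid("dodecahedron")
  trees <- enumerate_skeleton_trees(p, limit = 5)
  pent_area <- sqrt(5 * (5 + 2 * sqrt(5))) / 4
  for (r in seq_len(nrow(trees))) {
    net <- unfold(p, trees[r, ])
    hull <- convex_hull_metrics(net)
    expect_true(hull$hull_area >= 12 * pent_area - 1e-9)
  }
  degenerate <- foldnet:::fixture_net(
    list(cbind(c(0, 1, 2), c(0, 0, 0))), matrix(integer(0), 0, 2), "flat")
  expect_error(convex_hull_metrics(degenerate))
})

test_that("bulk descriptor engine matches the pure-R path on sampled nets", {
  set.seed(7)
  for (nm in c("octahedron", "dodecahedron")) {
    p <- platonic_solid(nm)
    tab <- descriptor_table(p)
    idx <- sample(nrow(tab), 8L)
    for (i in idx) {
      net <- unfold(p, foldnet:::mask_to_edges(tab$orbit_key[i]))
      d <- describe_net(net)
      expect_identical(d$circuit, tab$circuit[i], info = nm)
      expect_identical(d$vc_restrictive, tab$vc_restrictive[i])
      expect_identical(d$vc_traditional, tab$vc_traditional[i])
      expect_identical(d$leaves, tab$leaves[i])
      expect_identical(d$backbone, tab$backbone[i])
      expect_identical(d$degree_distribution, tab$degree_distribution[i])
      expect_equal(d$rg_squared, tab$rg_squared[i], tolerance = 1e-9)
      expect_equal(d$rg_squared, rg_squared_oracle(net), tolerance = 1e-12)
      ho <- hull_oracle(net)
      expect_equal(d$hull_area, ho$hull_area, tolerance = 1e-9)
      expect_equal(tab$hull_area[i], ho$hull_area, tolerance = 1e-9)
      expect_equal(tab$hull_perimeter[i], ho$hull_perimeter, tolerance = 1e-9)
    }
  }
})

test_that("boundary circuit degrees tie out with leaves and connections", {
  # triangle-faced solids: a leaf is exactly a face owning a degree-2
  # boundary vertex, and a restrictive connection a degree-(m+1) vertex
  p <- platonic_solid("icosahedron")
  tab <- descriptor_table(p)
  set.seed(11)
  for (i in sample(nrow(tab), 12L)) {
    degs <- as.integer(strsplit(tab$circuit[i], "-")[[1]])
    expect_identical(sum(degs == 6L), tab$vc_restrictive[i])
    expect_identical(sum(degs == 2L), tab$leaves[i])
  }
})
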
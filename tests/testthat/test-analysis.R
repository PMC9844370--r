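test_that("correlate recovers perfect linearity and is symmetric", {
  x <- c(1, 2, 3, 5, 8)
  cr <- correlate(x, 2 * x + 1)
  expect_equal(cr$r_squared, 1, tolerance = 1e-12)
  expect_equal(cr$slope, 2, tolerance = 1e-12)
  expect_equal(cr$intercept, 1, tolerance = 1e-12)
  y <- c(2, 1, 4, 3, 9)
  expect_equal(correlate(x, y)$r_squared, correlate(y, x)$r_squared,
               tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 5)), "variance")
  expect_error(correlate(rep(2, 5), y), "variance")
  expect_error(correlate(1:2, 1:2))
  expect_error(correlate(1:4, 1:5))
})

test_that("stratified sampling picks min / median-closest / max per stratum", {
  tab <- data.frame(
    vc_restrictive = rep(c(2L, 3L), each = 5L),
    hull_perimeter = c(10, 14, 12, 18, 16,  25, 21, 23, 27, 29)
  )
  sel <- stratified_sample(tab, stratum = "vc_restrictive", k = 3L,
                           spread = "hull_perimeter")
  expect_identical(nrow(sel), 6L)
  s2 <- sel$hull_perimeter[sel$.stratum == 2L]
  expect_identical(sort(s2), c(10, 14, 18))  # min, median, max
  s3 <- sel$hull_perimeter[sel$.stratum == 3L]
  expect_identical(sort(s3), c(21, 25, 29))
  # determinism
  sel2 <- stratified_sample(tab, stratum = "vc_restrictive", k = 3L,
                            spread = "hull_perimeter")
  expect_identical(sel, sel2)
  # k = 1 picks the per-stratum minimum
  sel1 <- stratified_sample(tab, stratum = "vc_restrictive", k = 1L,
                            spread = "hull_perimeter")
  expect_identical(sel1$hull_perimeter, c(10, 21))
  # empty strata are reported and skipped
  sel0 <- stratified_sample(tab, stratum = "vc_restrictive", k = 1L,
                            spread = "hull_perimeter", strata = 2:4)
  expect_identical(attr(sel0, "skipped"), 4L)
})

test_that("stratified sampling of the octahedron table bounds cardinality", {
  tab <- descriptor_table(platonic_solid("octahedron"))
  sel <- stratified_sample(tab, stratum = "vc_restrictive", k = 3L,
                           spread = "hull_perimeter")
  n_strata <- length(unique(tab$vc_restrictive))
  expect_lte(nrow(sel), 3L * n_strata)
  expect_true(all(table(sel$.stratum) <= 3L))
})

test_that("summary report assembles counts, distributions and correlations", {
  p <- platonic_solid("cube")
  rep <- summary_report(p)
  expect_identical(rep$status, "complete")
  expect_identical(rep$net_count, 11L)
  expect_identical(rep$spanning_trees, 384)
  expect_identical(rep$realized_distribution_count, 4L)
  expect_identical(length(rep$degree_solutions), 4L)
  expect_identical(rep$realized_distributions$nets, c(4L, 5L, 1L, 1L))
  expect_true(all(c("perimeter_rg", "area_rg") %in% names(rep$correlations)))
  # a partial table is flagged, not reported
  part <- descriptor_table(p)[1:4, ]
  rep2 <- summary_report(p, table = part)
  expect_identical(rep2$status, "incomplete")
  expect_true(is.na(rep2$net_count))
})
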
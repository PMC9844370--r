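#' Correlation between two descriptor columns
#'
#' Squared Pearson correlation with the least-squares line of y on x.  For
#' simple linear regression R^2 equals the squared correlation in either
#' orientation, so the result is symmetric in x and y.
#'
#' @param xs,ys numeric vectors of equal length (>= 3), non-constant.
#' @param labels optional character vector of length 2 naming the pair.
#' @return object of class `correlation_result`: `r_squared`, `n`,
#'   `slope`, `intercept`, `labels`, and the two-sided `p_value` of the
#'   no-correlation test.
#' @examples
#' correlate(1:5, 2 * (1:5) + 1)$r_squared  # 1
#' @export
correlate <- function(xs, ys, labels = c("x", "y")) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("need at least 3 points to correlate")
  if (stats::var(xs) == 0) stop("xs has zero variance; correlation undefined")
  if (stats::var(ys) == 0) stop("ys has zero variance; correlation undefined")
  r <- cor(xs, ys)
  ct <- cor.test(xs, ys)
  structure(list(
    r_squared = r^2,
    n = length(xs),
    slope = stats::cov(xs, ys) / stats::var(xs),
    intercept = mean(ys) - stats::cov(xs, ys) / stats::var(xs) * mean(xs),
    labels = labels,
    p_value = ct$p.value
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("R^2(%s, %s) = %.4f  (n = %d, slope = %.4f, p = %.3g)\n",
              x$labels[1], x$labels[2], x$r_squared, x$n, x$slope, x$p_value))
  invisible(x)
}

#' Stratified sample of nets spread along a descriptor
#'
#' Deterministic sampling plan for choosing physical folding candidates:
#' within each stratum (e.g. each vertex-connection category) the rows are
#' ordered by the spread key (e.g. hull perimeter) and `k` rows are taken
#' at evenly spaced ranks -- for `k = 3` the minimum, the value closest to
#' the median, and the maximum; for `k = 1` the minimum.  Empty strata are
#' skipped (and named in the `"skipped"` attribute).
#'
#' @param table a descriptor table (data frame).
#' @param stratum column name defining the strata.
#' @param k rows per stratum.
#' @param spread column name whose range should be covered.
#' @param strata optional vector of stratum values to use (default: all
#'   values present, sorted).
#' @param seed integer recorded with the design; the procedure itself is
#'   deterministic (rank ties are broken by row order).
#' @return subset of `table` rows with an added `.stratum` column.
#' @export
stratified_sample <- function(table, stratum = "vc_restrictive", k = 3L,
                              spread = "hull_perimeter", strata = NULL,
                              seed = 1L) {
  if (!stratum %in% names(table)) stop("no column '", stratum, "' in table")
  if (!spread %in% names(table)) stop("no column '", spread, "' in table")
  if (is.null(strata)) strata <- sort(unique(table[[stratum]]))
  picked <- list()
  skipped <- c()
  for (s in strata) {
    rows <- which(table[[stratum]] == s)
    if (!length(rows)) { skipped <- c(skipped, s); next }
    rows <- rows[order(table[[spread]][rows], rows)]
    sel <- unique(round(seq(1L, length(rows), length.out = min(k, length(rows)))))
    sub <- table[rows[sel], , drop = FALSE]
    sub$.stratum <- s
    picked[[as.character(s)]] <- sub
  }
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "design") <- list(stratum = stratum, k = k, spread = spread,
                              seed = seed)
  out
}

#' Summary report for one solid
#'
#' Assembles the reproducible results for a solid in machine-readable
#' form: spanning-tree and distinct-net counts, the integer
#' degree-distribution solutions with the number of nets realizing each,
#' and (given at least three nets) the compactness correlations of hull
#' perimeter and hull area against the radius of gyration, reported
#' against both Rg and Rg^2.
#'
#' @param p a [polyhedron()].
#' @param table optional precomputed descriptor table; when a partial
#'   table is supplied the report is marked `"incomplete"` and no numbers
#'   are emitted for the enumeration-dependent sections.
#' @return a list of class `foldnet_report`.
#' @export
summary_report <- function(p, table = NULL) {
  stopifnot(inherits(p, "polyhedron"))
  if (is.null(table)) table <- descriptor_table(p)
  complete <- identical(attr(table, "complete"), nrow(table))
  nf <- length(p$faces)
  dmax <- max(tabulate(c(p$edge_faces), nbins = nf))
  rep <- list(
    solid = p$name,
    faces = nf,
    spanning_trees = count_spanning_trees(p),
    status = if (complete) "complete" else "incomplete"
  )
  sols <- degree_distribution_solutions(nf, dmax)
  rep$degree_solutions <- apply(sols, 1L, paste, collapse = ",")
  if (!complete) {
    rep$net_count <- NA_integer_
    return(structure(rep, class = "foldnet_report"))
  }
  rep$net_count <- nrow(table)
  realized <- table(table$degree_distribution)
  rep$realized_distributions <- data.frame(
    distribution = names(realized), nets = as.integer(realized),
    stringsAsFactors = FALSE)
  rep$realized_distribution_count <- length(realized)
  if (nrow(table) >= 3L) {
    rep$correlations <- list(
      perimeter_rg = correlate(table$hull_perimeter, table$rg,
                               c("hull_perimeter", "rg")),
      area_rg = correlate(table$hull_area, table$rg,
                          c("hull_area", "rg")),
      perimeter_rg2 = correlate(table$hull_perimeter, table$rg_squared,
                                c("hull_perimeter", "rg_squared")),
      area_rg2 = correlate(table$hull_area, table$rg_squared,
                           c("hull_area", "rg_squared"))
    )
  }
  structure(rep, class = "foldnet_report")
}

#' @export
print.foldnet_report <- function(x, ...) {
  cat(sprintf("foldnet report: %s (%d faces) -- %s\n",
              x$solid, x$faces, x$status))
  cat(sprintf("  spanning trees: %s\n", format(x$spanning_trees, big.mark = ",")))
  if (x$status == "incomplete") {
    cat("  enumeration incomplete; counts withheld\n")
    return(invisible(x))
  }
  cat(sprintf("  distinct Durer nets: %s\n", format(x$net_count, big.mark = ",")))
  cat(sprintf("  degree-distribution solutions: %d; realized: %d\n",
              length(x$degree_solutions), x$realized_distribution_count))
  for (i in seq_len(nrow(x$realized_distributions))) {
    cat(sprintf("    (%s): %d nets\n", x$realized_distributions$distribution[i],
                x$realized_distributions$nets[i]))
  }
  if (!is.null(x$correlations)) {
    for (cr in x$correlations) print(cr)
  }
  invisible(x)
}

## JSON-friendly form of a report (used by the CLI).
report_to_list <- function(x) {
  out <- unclass(x)
  if (!is.null(out$correlations)) {
    out$correlations <- lapply(out$correlations, function(cr) {
      list(pair = cr$labels, r_squared = cr$r_squared, n = cr$n,
           slope = cr$slope, intercept = cr$intercept, p_value = cr$p_value)
    })
  }
  out
}
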
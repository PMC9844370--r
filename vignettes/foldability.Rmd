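---
title: "Enumerating Durer nets and measuring foldability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating Durer nets and measuring foldability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldnet)
```

## The problem

An icosahedral viral capsid is a closed polyhedral shell of protein
subunits (capsomeres).  One route to building such a shell -- in vivo, in
meso-scale magnet models, or in 4D-printed self-folding sheets -- is to
start from a *Durer net*: a planar, single-piece, non-self-overlapping
edge unfolding of the polyhedron.  A net has four defining properties: it
is planar, it is one connected piece, it arises from cutting polyhedron
edges only, and no two faces overlap in the plane.

Which of the many possible nets folds back into the closed shell most
reliably?  Before any physics can be asked, one needs the complete
inventory of nets and, for each net, quantitative descriptors of its
shape.  `foldnet` provides exactly that pipeline:

1. **Enumeration.** Every unfolding corresponds to a spanning tree of the
   *face-adjacency graph* (the "skeleton": nodes are faces, edges are
   folded creases).  The complementary *cutting tree* is a spanning tree
   on the solid's vertices -- edge `i` of the solid is cut exactly when
   dual edge `i` is absent from the skeleton tree.  Spanning trees are
   streamed exhaustively and validated against the Kirchhoff matrix-tree
   determinant.
2. **Symmetry reduction.** Two spanning trees describe the same net when
   a symmetry of the solid maps one folded-edge set onto the other.
   Orbits under the full symmetry group (rotations and reflections) are
   collapsed by canonical key: the lexicographically minimal image of the
   folded-edge bitmask over the group.  For the dodecahedron and the
   icosahedron this reduces 5,184,000 trees to 43,380 distinct nets each
   (the dual solids necessarily agree); the tetrahedron, cube and
   octahedron give 2, 11 and 11.
3. **Descriptors.** Each distinct net is unfolded to exact planar
   coordinates and measured.

## Descriptors and their meaning

With unit edge length (enforced at construction so results are
comparable across studies):

* **Vertex connections** (restrictive): net vertices already incident to
  every face they touch on the solid; closing the shell there takes a
  single edge gluing.  Combinatorially these are fans of m faces around a
  solid vertex, i.e. net vertices of degree m + 1 (4 for cube and
  dodecahedron nets, 5 for octahedron, 6 for icosahedron).  The
  traditional literature definition -- two faces sharing a vertex but not
  an edge -- is any fan of three or more faces; it is also computed, and
  the restrictive count is always a subset.  For square and pentagon
  faces the two definitions coincide; for triangle faces they differ.
* **Leaves**: skeleton nodes of degree 1 -- faces attached by a single
  fold.  For triangle-faced solids a leaf is exactly a face owning a
  degree-2 boundary vertex.
* **Degree distribution**: counts (A, B, C, ...) of skeleton nodes by
  degree.  They satisfy two identities, `A + B + C + ... = F` and
  `A + 2B + 3C + ... = 2 (F - 1)`; `degree_distribution_solutions()`
  enumerates all non-negative integer solutions and
  `realized_degree_distributions()` reports which are actually realized
  (2, 4, 3, 21 and 9 for the five solids -- not every solution is
  realizable as a tree of the face graph).
* **Backbone**: the skeleton-tree diameter in edges (longest path; the
  path need not be unique, the length is).
* **Radius of gyration**: the default centroid-sum form is
  `Rg^2 = (1/N) * sum_i ((x_i - xbar)^2 + (y_i - ybar)^2)` over the N
  face centroids.  An area-integral form (per-unit-area second moment of
  the net region about its area centroid) is also provided; the two rank
  nets nearly identically (Spearman correlation above 0.95 on the cube
  inventory), which is why the cheaper centroid form feeds the bulk
  table.  Note the integral form is normalized by total area here, making
  it dimensionally consistent with the centroid form (both scale as
  length squared under uniform scaling).
* **Convex hull area and perimeter**: hull of all net vertices.
  Perimeter tracks the same "round" compactness as Rg; area instead
  measures enclosed waste and rewards thin elongated nets, so the two
  capture different compactness notions.
* **Boundary degree circuit**: walking once around the net's outer
  boundary (equivalently, the Euler tour of the doubled cutting tree)
  and recording each boundary vertex's net degree gives a cyclic
  sequence of length 2 (V - 1).  Stored canonically (lexicographically
  minimal rotation over both directions) it serves as a human-readable
  identifier.  Empirically it is a *perfect* identifier on all five
  Platonic solids: each inventory yields exactly as many distinct
  canonical circuits as distinct nets (43,380 for the dodecahedron and
  icosahedron).  The package nevertheless deduplicates by the group-minimal
  orbit key, never by the circuit, so correctness does not rest on that
  observation.

## Headline numbers the tests reproduce

Everything below is recomputed by the test suite and by
`scripts/acceptance.R`; the vignette states nothing that is not
recomputed there.

* Net counts 2 / 11 / 11 / 43,380 / 43,380, cross-checked two ways
  (matrix-tree totals; orbit sizes summing to the tree count).
* The icosahedron net with boundary circuit
  `2-3-6-3-2-6-5-2-5-2-5-2-3-6-3-2-6-5-2-5-2-5` has 4 restrictive vertex
  connections and 8 leaves; every icosahedron net has 22 boundary
  vertices and edges.
* Cube skeletons have 5 edges and degree sum 10; the degree system has
  exactly 4 integer solutions, realized by 4, 5, 1 and 1 of the 11 nets.
* On the full dodecahedron table (43,380 nets, unit edges), hull
  perimeter explains the radius of gyration with R^2 = 0.738 while hull
  area reaches only R^2 = 0.142, and the perimeter relation stays
  significant inside every vertex-connection stratum from 2 to 10.  Both
  Rg and Rg^2 variants are reported by `summary_report()`; the plain-Rg
  convention is the one matching those reference values and is the
  package's reporting convention.

## Numerical and design choices

* **Unit edges at construction.**  All solids are rescaled so the mean
  edge is exactly 1; the Platonic solids then have every edge at 1 within
  1e-9, and every downstream length/area is in unit-edge units.
* **Combinatorial symmetry groups.**  Symmetries are computed as
  adjacency-preserving vertex bijections (graph automorphisms closed
  under composition), not from floating-point geometry, so orbit
  reduction is exact.  Orientation-reversing elements are detected by
  whether face cycles map with reversed cyclic order; net equivalence
  deliberately uses the *full* group -- that is the convention under
  which the counts above hold (rotations-only would double-count mirror
  pairs that are geometrically congruent sheets flipped over).
* **Unfolding convention.**  Root face = lowest face index, centroid at
  the origin, first edge along +x; children are placed by the proper
  rigid motion matching the shared edge, with a 1e-9 coincidence check.
  Each face's planar template comes from an isometric embedding of its
  3D cycle, so irregular (user-supplied) convex solids unfold correctly
  too.
* **Overlap test.**  Faces are shrunk toward their centroids by 1e-7
  before a pairwise separating-axis test, so faces sharing only an edge
  or vertex never count as overlapping; the test is exact for convex
  faces up to that guard band.
* **Scale of compiled code.**  Streaming 5,184,000 spanning trees and
  canonicalizing each over a 120-element group is the one genuinely
  large computation; it runs in compiled code (byte-table bitmask
  mapping, include/exclude tree search with connectivity pruning) in
  well under a minute per solid, and the R-level single-net functions
  are the reference implementation the bulk engine is tested against.
  Enumeration supports up to 30 dual edges (bitmask width); beyond that
  only the matrix-tree count is offered -- for a 60-face shell it
  reports the ~1e30 tree count that makes exhaustive study hopeless and
  sampling necessary.
* **Caching.**  Orbit tables and descriptor tables are cached in-session
  per solid, with an optional on-disk CSV cache for resumable long runs.

## What the fixtures emulate -- and what they do not

`make_fixture()` builds adversarial pseudo-nets: an overlapping fan of 7
unit triangles (angle sum 420 degrees, violating non-overlap by
construction), a chain of squares (path skeleton: 2 leaves, maximal
backbone), and a star (maximal leaves, minimal backbone).  These exercise
the validators and descriptor edge cases independently of the
enumerator.  They carry no provenance polyhedron, so operations that
need the solid (vertex connections, boundary circuits, refolding) reject
them explicitly.

Passing tests on these fixtures and on the Platonic inventories shows the
*geometry and combinatorics* are right.  It does not show anything about
folding physics: no kinetics, hinge mechanics, gravity or agitation are
modelled, and descriptor values are proxies whose link to real folding
success is an empirical claim outside this package's scope.

## Known limitations

* Net enumeration is limited to solids whose face-adjacency graph has at
  most 30 edges (all Platonic solids qualify).
* The restrictive vertex-connection definition assumes each pair of
  faces shares at most one edge, true for convex polyhedra.
* Non-convex polyhedra are out of scope; unfoldability of every convex
  polyhedron is an open question the package does not address -- it
  verifies non-overlap for every net it produces rather than assuming it.
* The area-integral Rg assumes face interiors are disjoint (guaranteed
  for genuine nets, not for overlapping fixtures).

## A worked run

```{r example}
p <- platonic_solid("cube")
summary_report(p)
```

```{r sample}
tab <- descriptor_table(platonic_solid("cube"))
stratified_sample(tab, stratum = "vc_restrictive", k = 1,
                  spread = "hull_perimeter")[, c(".stratum", "circuit",
                                                 "hull_perimeter")]
```
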
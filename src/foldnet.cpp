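// Bulk engines: spanning-tree streaming with orbit canonicalization, and
// per-net descriptor computation.  Everything here mirrors the R reference
// implementations (unfold(), describe_net()) which the tests compare
// against; this path exists because the dodecahedron/icosahedron study
// size is 5,184,000 spanning trees each.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// spanning-tree enumeration (include/exclude with connectivity pruning)
// ---------------------------------------------------------------------------

namespace {

struct EnumCtx {
  int n, m, ng;
  std::vector<int> eu, ev;            // edge endpoints (0-based)
  std::vector<uint32_t> tab;          // ng x 4 x 256 byte-permutation tables
  bool reduce;
  std::unordered_map<uint32_t, uint32_t> orbits;
  std::vector<uint32_t> collected;
  double limit;                       // collect cap (<0 = unlimited)
  double total;
};

inline int find_root(int* par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}

inline uint32_t canon_mask(const EnumCtx& C, uint32_t mask) {
  uint32_t best = UINT32_MAX;
  const uint32_t* t = C.tab.data();
  for (int g = 0; g < C.ng; ++g, t += 1024) {
    uint32_t x = t[mask & 255u] | t[256 + ((mask >> 8) & 255u)] |
                 t[512 + ((mask >> 16) & 255u)] | t[768 + ((mask >> 24) & 255u)];
    if (x < best) best = x;
  }
  return best;
}

void emit_tree(EnumCtx& C, uint32_t mask) {
  C.total += 1.0;
  if (C.reduce) {
    ++C.orbits[canon_mask(C, mask)];
  } else if (C.limit < 0 || (double)C.collected.size() < C.limit) {
    C.collected.push_back(mask);
  }
}

// can the current components still be joined using edges eidx..m-1?
bool still_connectable(const EnumCtx& C, const int* comp, int eidx, int ncomp) {
  if (ncomp == 1) return true;
  int par[32];
  for (int i = 0; i < C.n; ++i) par[i] = comp[i];
  int k = ncomp;
  for (int e = eidx; e < C.m && k > 1; ++e) {
    int a = find_root(par, C.eu[e]), b = find_root(par, C.ev[e]);
    if (a != b) { par[a] = b; --k; }
  }
  return k == 1;
}

void rec_trees(EnumCtx& C, int eidx, const int* comp, int ncomp, uint32_t mask) {
  if (ncomp == 1) { emit_tree(C, mask); return; }
  if (eidx >= C.m) return;
  int ra = comp[C.eu[eidx]], rb = comp[C.ev[eidx]];
  if (ra != rb) {
    int nc[32];
    int lo = std::min(ra, rb), hi = std::max(ra, rb);
    for (int i = 0; i < C.n; ++i) nc[i] = (comp[i] == hi) ? lo : comp[i];
    rec_trees(C, eidx + 1, nc, ncomp - 1, mask | (1u << eidx));
  }
  if (still_connectable(C, comp, eidx + 1, ncomp))
    rec_trees(C, eidx + 1, comp, ncomp, mask);
}

} // namespace

// [[Rcpp::export]]
List cpp_enumerate_trees(IntegerMatrix edges, int n,
                         Nullable<IntegerMatrix> edge_perms, double limit) {
  EnumCtx C;
  C.n = n;
  C.m = edges.nrow();
  C.total = 0.0;
  C.limit = limit;
  if (C.n > 32) stop("at most 32 nodes supported");
  if (C.m > 30) stop("at most 30 edges supported");
  C.eu.resize(C.m); C.ev.resize(C.m);
  for (int e = 0; e < C.m; ++e) {
    C.eu[e] = edges(e, 0) - 1;
    C.ev[e] = edges(e, 1) - 1;
  }
  C.reduce = edge_perms.isNotNull();
  C.ng = 0;
  if (C.reduce) {
    IntegerMatrix ep(edge_perms);
    if (ep.ncol() != C.m) stop("edge_perms must have one column per edge");
    C.ng = ep.nrow();
    C.tab.assign((size_t)C.ng * 1024, 0u);
    for (int g = 0; g < C.ng; ++g) {
      for (int pos = 0; pos < 4; ++pos) {
        for (int byte = 0; byte < 256; ++byte) {
          uint32_t out = 0;
          for (int bit = 0; bit < 8; ++bit) {
            if (!(byte & (1 << bit))) continue;
            int src = pos * 8 + bit;
            if (src < C.m) out |= 1u << (ep(g, src) - 1);
          }
          C.tab[(size_t)g * 1024 + pos * 256 + byte] = out;
        }
      }
    }
  }
  int comp[32];
  for (int i = 0; i < C.n; ++i) comp[i] = i;
  if (!still_connectable(C, comp, 0, C.n)) stop("graph is disconnected");
  rec_trees(C, 0, comp, C.n, 0u);

  if (C.reduce) {
    int k = C.orbits.size();
    IntegerVector masks(k), sizes(k);
    int i = 0;
    for (const auto& kv : C.orbits) {
      masks[i] = (int)kv.first;
      sizes[i] = (int)kv.second;
      ++i;
    }
    return List::create(_["masks"] = masks, _["sizes"] = sizes,
                        _["total"] = C.total);
  }
  IntegerVector masks(C.collected.size());
  for (size_t i = 0; i < C.collected.size(); ++i) masks[i] = (int)C.collected[i];
  return List::create(_["masks"] = masks, _["total"] = C.total);
}

// ---------------------------------------------------------------------------
// bulk descriptors
// ---------------------------------------------------------------------------

namespace {

struct Pt { double x, y; };

struct PolyData {
  int F, V, E;
  std::vector<std::vector<int>> faces;        // vertex cycles, 0-based
  std::vector<std::vector<Pt>> local;         // per-face planar template
  std::vector<int> eu, ev;                    // poly edge endpoints
  std::vector<int> ef1, ef2;                  // faces at each poly edge
  std::vector<int> vm;                        // faces per solid vertex
  std::vector<std::vector<int>> pos_in_face;  // [f][v] -> slot or -1
  std::vector<std::vector<int>> slot_edge;    // [f][slot] -> poly edge id
  std::vector<int> koff;                      // corner offsets per face
};

inline double cross3(const Pt& o, const Pt& a, const Pt& b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

// Andrew monotone chain; returns hull points counterclockwise.
std::vector<Pt> convex_hull(std::vector<Pt> pts) {
  std::sort(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
    return a.x < b.x || (a.x == b.x && a.y < b.y);
  });
  pts.erase(std::unique(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
    return a.x == b.x && a.y == b.y;
  }), pts.end());
  int n = pts.size();
  if (n < 3) return pts;
  std::vector<Pt> h(2 * n);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    while (k >= 2 && cross3(h[k - 2], h[k - 1], pts[i]) <= 1e-14) --k;
    h[k++] = pts[i];
  }
  int lower = k + 1;
  for (int i = n - 2; i >= 0; --i) {
    while (k >= lower && cross3(h[k - 2], h[k - 1], pts[i]) <= 1e-14) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1);
  return h;
}

// separating-axis test for convex polygons (true = interiors intersect)
bool polys_intersect(const std::vector<Pt>& a, const std::vector<Pt>& b) {
  const std::vector<Pt>* polys[2] = { &a, &b };
  for (int pi = 0; pi < 2; ++pi) {
    const std::vector<Pt>& p = *polys[pi];
    int n = p.size();
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double ax = -(p[j].y - p[i].y), ay = p[j].x - p[i].x;
      double amin = 1e300, amax = -1e300, bmin = 1e300, bmax = -1e300;
      for (const Pt& q : a) {
        double d = q.x * ax + q.y * ay;
        amin = std::min(amin, d); amax = std::max(amax, d);
      }
      for (const Pt& q : b) {
        double d = q.x * ax + q.y * ay;
        bmin = std::min(bmin, d); bmax = std::max(bmax, d);
      }
      if (amax <= bmin + 1e-12 || bmax <= amin + 1e-12) return false;
    }
  }
  return true;
}

struct UF {
  std::vector<int> par;
  void init(int n) { par.resize(n); for (int i = 0; i < n; ++i) par[i] = i; }
  int find(int x) { while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) par[a] = b; }
};

// lexicographically minimal rotation over both directions
std::vector<int> canon_circuit(const std::vector<int>& s) {
  int n = s.size();
  std::vector<int> best;
  for (int dir = 0; dir < 2; ++dir) {
    std::vector<int> seq = s;
    if (dir) std::reverse(seq.begin(), seq.end());
    for (int r = 0; r < n; ++r) {
      std::vector<int> rot(n);
      for (int i = 0; i < n; ++i) rot[i] = seq[(i + r) % n];
      if (best.empty() || rot < best) best = rot;
    }
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
List cpp_describe_trees(List faces, List face_local, IntegerMatrix edges,
                        IntegerMatrix edge_faces, IntegerVector vertex_m,
                        IntegerVector masks, int dmax) {
  PolyData P;
  P.F = faces.size();
  P.E = edges.nrow();
  P.V = vertex_m.size();
  if (P.E > 30) stop("at most 30 edges supported");
  P.faces.resize(P.F);
  P.local.resize(P.F);
  P.pos_in_face.assign(P.F, std::vector<int>(P.V, -1));
  P.koff.assign(P.F + 1, 0);
  for (int f = 0; f < P.F; ++f) {
    IntegerVector fc = faces[f];
    NumericMatrix lc = face_local[f];
    int k = fc.size();
    P.faces[f].assign(fc.begin(), fc.end());
    P.local[f].resize(k);
    for (int i = 0; i < k; ++i) {
      P.local[f][i] = { lc(i, 0), lc(i, 1) };
      P.pos_in_face[f][fc[i]] = i;
    }
    P.koff[f + 1] = P.koff[f] + k;
  }
  P.eu.resize(P.E); P.ev.resize(P.E); P.ef1.resize(P.E); P.ef2.resize(P.E);
  for (int e = 0; e < P.E; ++e) {
    P.eu[e] = edges(e, 0); P.ev[e] = edges(e, 1);
    P.ef1[e] = edge_faces(e, 0); P.ef2[e] = edge_faces(e, 1);
  }
  P.vm.assign(vertex_m.begin(), vertex_m.end());
  // slot -> poly edge lookup
  std::vector<std::vector<int>> vpair_edge(P.V, std::vector<int>(P.V, -1));
  for (int e = 0; e < P.E; ++e) {
    vpair_edge[P.eu[e]][P.ev[e]] = e;
    vpair_edge[P.ev[e]][P.eu[e]] = e;
  }
  P.slot_edge.resize(P.F);
  for (int f = 0; f < P.F; ++f) {
    int k = P.faces[f].size();
    P.slot_edge[f].resize(k);
    for (int i = 0; i < k; ++i) {
      int a = P.faces[f][i], b = P.faces[f][(i + 1) % k];
      P.slot_edge[f][i] = vpair_edge[a][b];
    }
  }

  int N = masks.size();
  IntegerVector vc_r(N), vc_t(N), leaf(N), backbone(N), blen(N), overlaps(N);
  NumericVector rg2(N), hull_area(N), hull_per(N);
  CharacterVector circuit(N);
  IntegerMatrix degmat(N, dmax);

  int ncor = P.koff[P.F];
  std::vector<Pt> coords(ncor);
  UF uf;

  for (int t = 0; t < N; ++t) {
    uint32_t mask = (uint32_t)masks[t];
    // skeleton adjacency
    std::vector<std::vector<std::pair<int,int>>> adj(P.F); // (nbr face, edge)
    for (int e = 0; e < P.E; ++e) {
      if (!(mask & (1u << e))) continue;
      adj[P.ef1[e]].push_back({P.ef2[e], e});
      adj[P.ef2[e]].push_back({P.ef1[e], e});
    }

    // --- unfold (BFS from face 0; root centred, first edge along +x)
    std::vector<char> placed(P.F, 0);
    {
      int k0 = P.faces[0].size();
      double cx = 0, cy = 0;
      for (const Pt& q : P.local[0]) { cx += q.x; cy += q.y; }
      cx /= k0; cy /= k0;
      double dx = P.local[0][1].x - P.local[0][0].x;
      double dy = P.local[0][1].y - P.local[0][0].y;
      double th = -std::atan2(dy, dx), c = std::cos(th), s = std::sin(th);
      for (int i = 0; i < k0; ++i) {
        double x = P.local[0][i].x - cx, y = P.local[0][i].y - cy;
        coords[P.koff[0] + i] = { c * x - s * y, s * x + c * y };
      }
      placed[0] = 1;
    }
    std::vector<int> queue = {0};
    for (size_t qi = 0; qi < queue.size(); ++qi) {
      int f = queue[qi];
      for (auto& pr : adj[f]) {
        int g = pr.first, e = pr.second;
        if (placed[g]) continue;
        int a = P.eu[e], b = P.ev[e];
        int iaf = P.pos_in_face[f][a], ibf = P.pos_in_face[f][b];
        int iag = P.pos_in_face[g][a], ibg = P.pos_in_face[g][b];
        Pt A = coords[P.koff[f] + iaf], B = coords[P.koff[f] + ibf];
        Pt Ag = P.local[g][iag], Bg = P.local[g][ibg];
        double th = std::atan2(B.y - A.y, B.x - A.x) -
                    std::atan2(Bg.y - Ag.y, Bg.x - Ag.x);
        double c = std::cos(th), s = std::sin(th);
        double tx = A.x - (c * Ag.x - s * Ag.y);
        double ty = A.y - (s * Ag.x + c * Ag.y);
        int kg = P.faces[g].size();
        for (int i = 0; i < kg; ++i) {
          const Pt& q = P.local[g][i];
          coords[P.koff[g] + i] = { c * q.x - s * q.y + tx,
                                    s * q.x + c * q.y + ty };
        }
        placed[g] = 1;
        queue.push_back(g);
      }
    }

    // --- net vertex classes through folded edges
    uf.init(ncor);
    for (int e = 0; e < P.E; ++e) {
      if (!(mask & (1u << e))) continue;
      int f1 = P.ef1[e], f2 = P.ef2[e];
      for (int vtx : { P.eu[e], P.ev[e] }) {
        uf.unite(P.koff[f1] + P.pos_in_face[f1][vtx],
                 P.koff[f2] + P.pos_in_face[f2][vtx]);
      }
    }
    std::vector<int> cls(ncor, -1), cls_size, cls_vert;
    int nclass = 0;
    for (int c0 = 0; c0 < ncor; ++c0) {
      int r = uf.find(c0);
      if (cls[r] < 0) {
        cls[r] = nclass++;
        cls_size.push_back(0);
        cls_vert.push_back(0);
      }
      cls[c0] = cls[r];
      cls_size[cls[c0]] += 1;
    }
    for (int f = 0; f < P.F; ++f) {
      int k = P.faces[f].size();
      for (int i = 0; i < k; ++i) cls_vert[cls[P.koff[f] + i]] = P.faces[f][i];
    }
    int nr = 0, nt = 0;
    for (int c0 = 0; c0 < nclass; ++c0) {
      if (cls_size[c0] == P.vm[cls_vert[c0]]) ++nr;
      if (cls_size[c0] >= 3) ++nt;
    }
    vc_r[t] = nr; vc_t[t] = nt;

    // --- skeleton degrees, leaves, degree distribution, diameter
    std::vector<int> deg(P.F, 0);
    for (int f = 0; f < P.F; ++f) deg[f] = adj[f].size();
    int nl = 0;
    for (int f = 0; f < P.F; ++f) if (deg[f] == 1) ++nl;
    leaf[t] = nl;
    for (int d = 0; d < dmax; ++d) degmat(t, d) = 0;
    for (int f = 0; f < P.F; ++f)
      if (deg[f] >= 1 && deg[f] <= dmax) degmat(t, deg[f] - 1) += 1;
    auto bfs_far = [&](int s, std::vector<int>& dist) {
      std::fill(dist.begin(), dist.end(), -1);
      std::vector<int> q = {s};
      dist[s] = 0;
      int far = s;
      for (size_t qi = 0; qi < q.size(); ++qi) {
        int v = q[qi];
        for (auto& pr : adj[v]) if (dist[pr.first] < 0) {
          dist[pr.first] = dist[v] + 1;
          if (dist[pr.first] > dist[far]) far = pr.first;
          q.push_back(pr.first);
        }
      }
      return far;
    };
    std::vector<int> dist(P.F);
    int u = bfs_far(0, dist);
    int w = bfs_far(u, dist);
    backbone[t] = dist[w];

    // --- boundary circuit (walk cut half-edges)
    std::vector<int> circ;
    {
      int f0 = -1, i0 = -1;
      for (int f = 0; f < P.F && f0 < 0; ++f) {
        int k = P.faces[f].size();
        for (int i = 0; i < k; ++i) {
          if (!(mask & (1u << P.slot_edge[f][i]))) { f0 = f; i0 = i; break; }
        }
      }
      int f = f0, i = i0;
      do {
        circ.push_back(cls_size[cls[P.koff[f] + i]] + 1);
        int k = P.faces[f].size();
        int j = (i + 1) % k;
        while (mask & (1u << P.slot_edge[f][j])) {
          int e = P.slot_edge[f][j];
          int g = (P.ef1[e] == f) ? P.ef2[e] : P.ef1[e];
          j = P.pos_in_face[g][P.faces[f][j]];
          f = g;
        }
        i = j;
      } while (!(f == f0 && i == i0));
    }
    blen[t] = circ.size();
    std::vector<int> cc = canon_circuit(circ);
    std::string cs;
    for (size_t i = 0; i < cc.size(); ++i) {
      if (i) cs += '-';
      cs += std::to_string(cc[i]);
    }
    circuit[t] = cs;

    // --- radius of gyration (centroid sum)
    {
      std::vector<Pt> cent(P.F);
      double mx = 0, my = 0;
      for (int f = 0; f < P.F; ++f) {
        double cx = 0, cy = 0;
        int k = P.faces[f].size();
        for (int i = 0; i < k; ++i) {
          cx += coords[P.koff[f] + i].x;
          cy += coords[P.koff[f] + i].y;
        }
        cent[f] = { cx / k, cy / k };
        mx += cent[f].x; my += cent[f].y;
      }
      mx /= P.F; my /= P.F;
      double s = 0;
      for (int f = 0; f < P.F; ++f) {
        double dx = cent[f].x - mx, dy = cent[f].y - my;
        s += dx * dx + dy * dy;
      }
      rg2[t] = s / P.F;
    }

    // --- convex hull area + perimeter
    {
      std::vector<Pt> pts(coords.begin(), coords.begin() + ncor);
      std::vector<Pt> h = convex_hull(pts);
      double area = 0, per = 0;
      int hn = h.size();
      for (int i = 0; i < hn; ++i) {
        int j = (i + 1) % hn;
        area += h[i].x * h[j].y - h[j].x * h[i].y;
        per += std::hypot(h[j].x - h[i].x, h[j].y - h[i].y);
      }
      hull_area[t] = std::fabs(area) / 2.0;
      hull_per[t] = per;
    }

    // --- overlap flag (faces shrunk toward centroids, SAT pairwise)
    {
      std::vector<std::vector<Pt>> shr(P.F);
      std::vector<std::array<double,4>> box(P.F);
      for (int f = 0; f < P.F; ++f) {
        int k = P.faces[f].size();
        double cx = 0, cy = 0;
        for (int i = 0; i < k; ++i) {
          cx += coords[P.koff[f] + i].x; cy += coords[P.koff[f] + i].y;
        }
        cx /= k; cy /= k;
        shr[f].resize(k);
        double x0 = 1e300, x1 = -1e300, y0 = 1e300, y1 = -1e300;
        for (int i = 0; i < k; ++i) {
          const Pt& q = coords[P.koff[f] + i];
          Pt s = { cx + (q.x - cx) * (1 - 1e-7), cy + (q.y - cy) * (1 - 1e-7) };
          shr[f][i] = s;
          x0 = std::min(x0, s.x); x1 = std::max(x1, s.x);
          y0 = std::min(y0, s.y); y1 = std::max(y1, s.y);
        }
        box[f] = { x0, x1, y0, y1 };
      }
      int ov = 0;
      for (int f = 0; f < P.F && !ov; ++f) {
        for (int g = f + 1; g < P.F && !ov; ++g) {
          if (box[f][1] < box[g][0] || box[g][1] < box[f][0] ||
              box[f][3] < box[g][2] || box[g][3] < box[f][2]) continue;
          if (polys_intersect(shr[f], shr[g])) ov = 1;
        }
      }
      overlaps[t] = ov;
    }

    if ((t & 4095) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["vc_restrictive"] = vc_r, _["vc_traditional"] = vc_t,
    _["leaves"] = leaf, _["backbone"] = backbone,
    _["rg_squared"] = rg2, _["hull_area"] = hull_area,
    _["hull_perimeter"] = hull_per, _["boundary_length"] = blen,
    _["overlaps"] = overlaps, _["circuit"] = circuit,
    _["degrees"] = degmat);
}
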
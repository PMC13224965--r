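// Compiled kernels:
//  * multispecies-network-coalescent (MSNC) gene-tree simulation on a rooted
//    level-1 network (also the engine of the Monte-Carlo CF oracle), and
//  * exact expected quartet concordance factors / composite log-likelihood
//    evaluation over a pre-compiled quartet map.
//
// All RNG draws go through R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <set>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// shared network scaffolding
// ---------------------------------------------------------------------------

struct Net {
  int N, E, root;
  std::vector<int> parent, child;            // 0-based
  std::vector<double> len, gam;
  std::vector<std::vector<int>> child_edges; // edges e with parent[e] == v
  std::vector<std::vector<int>> parent_edges;// edges e with child[e] == v
  std::vector<int> node_order;               // children before parents
};

static Net build_net(IntegerVector parent, IntegerVector child,
                     NumericVector len, NumericVector gam,
                     int nnode, int root1) {
  Net nt;
  nt.E = parent.size();
  nt.N = nnode;
  nt.root = root1 - 1;
  nt.parent.resize(nt.E); nt.child.resize(nt.E);
  nt.len.resize(nt.E); nt.gam.resize(nt.E);
  nt.child_edges.assign(nt.N, {});
  nt.parent_edges.assign(nt.N, {});
  for (int e = 0; e < nt.E; ++e) {
    nt.parent[e] = parent[e] - 1;
    nt.child[e] = child[e] - 1;
    nt.len[e] = len[e];
    nt.gam[e] = gam[e];
    nt.child_edges[nt.parent[e]].push_back(e);
    nt.parent_edges[nt.child[e]].push_back(e);
  }
  // children-first order (Kahn on reversed edges)
  std::vector<int> pending(nt.N, 0);
  for (int e = 0; e < nt.E; ++e) pending[nt.parent[e]]++;
  std::vector<int> stack;
  for (int v = 0; v < nt.N; ++v) if (pending[v] == 0) stack.push_back(v);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    nt.node_order.push_back(v);
    for (int e : nt.parent_edges[v]) {
      int p = nt.parent[e];
      if (--pending[p] == 0) stack.push_back(p);
    }
  }
  if ((int)nt.node_order.size() != nt.N)
    stop("network contains a directed cycle");
  return nt;
}

// ---------------------------------------------------------------------------
// MSNC simulation
// ---------------------------------------------------------------------------

struct Lineage { int id; double height; int qmask; double born; };

struct MergeRec { int a, b, id; double height; };

// Coalesce the lineages in `L` within a population of duration `dur`
// (R_PosInf for the root population).  Records merges; returns the exiting
// lineages.  `decided` is set to the quartet topology (0..2) at the first
// merge joining two quartet-marked clusters, if any.
static void evolve(std::vector<Lineage> &L, double dur, int &next_id,
                   std::vector<MergeRec> *rec, int &decided) {
  if (L.size() >= 2 && ISNA(dur))
    stop("missing branch length on an edge carrying >1 lineage");
  double t = 0.0;
  for (auto &l : L) l.born = 0.0;
  while (L.size() >= 2) {
    double npair = 0.5 * L.size() * (L.size() - 1);
    double dt = exp_rand() / npair;
    if (!(dur == R_PosInf) && t + dt > dur) break;
    t += dt;
    int i = (int)(unif_rand() * L.size()); if (i >= (int)L.size()) i = L.size() - 1;
    int j = (int)(unif_rand() * (L.size() - 1)); if (j >= (int)L.size() - 1) j = L.size() - 2;
    if (j >= i) j++;
    if (i > j) std::swap(i, j);
    Lineage a = L[i], b = L[j];
    Lineage m;
    m.id = next_id++;
    m.height = std::max(a.height, b.height) + t;
    m.qmask = a.qmask | b.qmask;
    m.born = t;
    if (decided < 0 && a.qmask && b.qmask) {
      int u = m.qmask;
      if (u == 3 || u == 12) decided = 0;
      else if (u == 5 || u == 10) decided = 1;
      else if (u == 9 || u == 6) decided = 2;
      // union with >2 bits means a pair already decided earlier
    }
    if (rec) rec->push_back({a.id, b.id, m.id, m.height});
    L.erase(L.begin() + j);
    L.erase(L.begin() + i);
    L.push_back(m);
  }
  if (dur != R_PosInf && !ISNA(dur))
    for (auto &l : L) l.height += dur - l.born;
}

// One gene: returns topology decided (0..2) or -1; fills `rec` when asked.
static int sim_gene(const Net &nt, const std::vector<int> &leaf_nodes,
                    const std::vector<int> &leaf_qbit,
                    std::vector<MergeRec> *rec, bool early_exit) {
  int n = leaf_nodes.size();
  std::vector<std::vector<Lineage>> edge_out(nt.E);
  std::vector<bool> is_leaf(nt.N, false);
  std::vector<int> leaf_ix(nt.N, -1);
  for (int i = 0; i < n; ++i) { is_leaf[leaf_nodes[i]] = true; leaf_ix[leaf_nodes[i]] = i; }
  int next_id = n + 1; // lineage ids are 1-based for the R side
  int decided = -1;
  for (int v : nt.node_order) {
    std::vector<Lineage> L;
    if (is_leaf[v]) {
      int i = leaf_ix[v];
      L.push_back({i + 1, 0.0, leaf_qbit[i], 0.0});
    }
    for (int e : nt.child_edges[v])
      for (auto &l : edge_out[e]) L.push_back(l);
    if (L.empty()) continue;
    if (v == nt.root) {
      evolve(L, R_PosInf, next_id, rec, decided);
      break;
    }
    const std::vector<int> &pe = nt.parent_edges[v];
    if (pe.size() == 1) {
      evolve(L, nt.len[pe[0]], next_id, rec, decided);
      edge_out[pe[0]] = L;
    } else { // hybrid node: independent routing with probability gamma
      std::vector<Lineage> A, B;
      double gA = nt.gam[pe[0]];
      if (ISNA(gA)) stop("hybrid edge without inheritance probability");
      for (auto &l : L) (unif_rand() < gA ? A : B).push_back(l);
      evolve(A, nt.len[pe[0]], next_id, rec, decided);
      evolve(B, nt.len[pe[1]], next_id, rec, decided);
      edge_out[pe[0]] = A;
      edge_out[pe[1]] = B;
    }
    if (early_exit && decided >= 0) return decided;
  }
  return decided;
}

// [[Rcpp::export]]
IntegerVector cpp_msnc_quartet_counts(IntegerVector parent, IntegerVector child,
                                      NumericVector len, NumericVector gam,
                                      int nnode, int root,
                                      IntegerVector leaf_nodes,
                                      IntegerVector quartet_leaf_pos,
                                      int ngenes) {
  Net nt = build_net(parent, child, len, gam, nnode, root);
  int n = leaf_nodes.size();
  std::vector<int> leaves(n), qbit(n, 0);
  for (int i = 0; i < n; ++i) leaves[i] = leaf_nodes[i] - 1;
  for (int j = 0; j < 4; ++j) qbit[quartet_leaf_pos[j] - 1] = 1 << j;
  IntegerVector counts(3);
  for (int g = 0; g < ngenes; ++g) {
    int d = sim_gene(nt, leaves, qbit, nullptr, true);
    if (d < 0) stop("gene simulation ended without resolving the quartet");
    counts[d]++;
  }
  return counts;
}

// [[Rcpp::export]]
List cpp_msnc_genetrees(IntegerVector parent, IntegerVector child,
                        NumericVector len, NumericVector gam,
                        int nnode, int root,
                        IntegerVector leaf_nodes, int ngenes) {
  Net nt = build_net(parent, child, len, gam, nnode, root);
  int n = leaf_nodes.size();
  std::vector<int> leaves(n), qbit(n, 0);
  for (int i = 0; i < n; ++i) leaves[i] = leaf_nodes[i] - 1;
  List out(ngenes);
  for (int g = 0; g < ngenes; ++g) {
    std::vector<MergeRec> rec;
    sim_gene(nt, leaves, qbit, &rec, false);
    NumericMatrix m(rec.size(), 4);
    for (size_t i = 0; i < rec.size(); ++i) {
      m(i, 0) = rec[i].a; m(i, 1) = rec[i].b;
      m(i, 2) = rec[i].id; m(i, 3) = rec[i].height;
    }
    out[g] = m;
  }
  return out;
}

// ---------------------------------------------------------------------------
// expected CFs on a compiled quartet map
// ---------------------------------------------------------------------------
//
// The map (built in R by compile_cf_map) describes, for every 4-taxon set,
// either a quartet tree (closed-form CF from the internal path length) or a
// general level-1 quarnet.  General quarnets are evaluated exactly by
// enumerating the lineage-routing profiles at hybrid nodes (probability =
// product of inheritance probabilities along each lineage's path) and, for
// each profile, accumulating first-coalescence probabilities edge by edge in
// topological order; the topology of a gene tree is fixed by the first pair
// of the four sampled lineages to coalesce, and co-located pairs in
// time-incomparable populations always imply the same topology, so a single
// undecided-mass sweep is exact.

struct QMap {
  int k, G;
  IntegerVector qtype, t_topo, gindex;
  IntegerVector tcomp_ptr, tcomp_id;
  IntegerVector ge_ptr, ge_comp_ptr, ge_comp_id, ge_gid;
  IntegerVector gp_ptr, gp_cover, gp_gam_ptr, gp_gam_edge;
};

static QMap unpack_map(const List &map) {
  QMap m;
  m.k = as<int>(map["k"]);
  m.G = as<int>(map["G"]);
  m.qtype = map["qtype"]; m.t_topo = map["t_topo"]; m.gindex = map["gindex"];
  m.tcomp_ptr = map["tcomp_ptr"]; m.tcomp_id = map["tcomp_id"];
  m.ge_ptr = map["ge_ptr"]; m.ge_comp_ptr = map["ge_comp_ptr"];
  m.ge_comp_id = map["ge_comp_id"]; m.ge_gid = map["ge_gid"];
  m.gp_ptr = map["gp_ptr"]; m.gp_cover = map["gp_cover"];
  m.gp_gam_ptr = map["gp_gam_ptr"]; m.gp_gam_edge = map["gp_gam_edge"];
  return m;
}

static inline int pair_topo(int i, int j) {
  int u = (1 << i) | (1 << j);
  if (u == 3 || u == 12) return 0;
  if (u == 5 || u == 10) return 1;
  return 2;
}

// expected CFs for quartet q (0-based); writes into cf[3]
static void quartet_cf(const QMap &m, int q,
                       const NumericVector &elen, const NumericVector &egam,
                       double *cf) {
  if (m.qtype[q] == 0) { // quartet tree: closed form
    double t = 0.0;
    for (int i = m.tcomp_ptr[q]; i < m.tcomp_ptr[q + 1]; ++i) {
      double l = elen[m.tcomp_id[i] - 1];
      if (ISNA(l)) stop("missing internal branch length in a quartet tree");
      t += l;
    }
    double minor = std::exp(-t) / 3.0;
    cf[0] = cf[1] = cf[2] = minor;
    cf[m.t_topo[q] - 1] = 1.0 - 2.0 * minor;
    return;
  }
  int g = m.gindex[q];
  int e0 = m.ge_ptr[g], e1 = m.ge_ptr[g + 1];
  int ne = e1 - e0;
  double len[64], gam[64];
  for (int e = 0; e < ne; ++e) {
    double l = 0.0; bool any_na = false;
    for (int i = m.ge_comp_ptr[e0 + e]; i < m.ge_comp_ptr[e0 + e + 1]; ++i) {
      double x = elen[m.ge_comp_id[i] - 1];
      if (ISNA(x)) any_na = true; else l += x;
    }
    len[e] = any_na ? NA_REAL : l;
    int gid = m.ge_gid[e0 + e];
    if (gid == 0) gam[e] = NA_REAL;
    else if (gid > 0) gam[e] = egam[gid - 1];
    else gam[e] = 1.0 - egam[-gid - 1];
  }
  // per-lineage paths
  int np[4], pbase[4];
  for (int l = 0; l < 4; ++l) {
    pbase[l] = m.gp_ptr[4 * g + l];
    np[l] = m.gp_ptr[4 * g + l + 1] - pbase[l];
  }
  cf[0] = cf[1] = cf[2] = 0.0;
  int choice[4] = {0, 0, 0, 0};
  for (;;) {
    // profile weight and coverage
    double w = 1.0;
    int cov[4];
    for (int l = 0; l < 4; ++l) {
      int p = pbase[l] + choice[l];
      cov[l] = m.gp_cover[p];
      for (int i = m.gp_gam_ptr[p]; i < m.gp_gam_ptr[p + 1]; ++i)
        w *= gam[m.gp_gam_edge[i]];
    }
    if (w > 0.0) {
      double u = 1.0;
      for (int e = 0; e < ne; ++e) {
        int bits = 0;
        for (int l = 0; l < 4; ++l) if ((cov[l] >> e) & 1) bits |= (1 << l);
        int s = bits == 0 ? 0 :
          ((bits & 1) != 0) + ((bits & 2) != 0) + ((bits & 4) != 0) + ((bits & 8) != 0);
        if (s >= 2) {
          if (ISNA(len[e])) stop("missing internal branch length in a quarnet");
          double pairs = 0.5 * s * (s - 1);
          double pno = std::exp(-pairs * len[e]);
          double pp = (1.0 - pno) / pairs * u * w;
          for (int i = 0; i < 4; ++i)
            for (int j = i + 1; j < 4; ++j)
              if ((bits & (1 << i)) && (bits & (1 << j)))
                cf[pair_topo(i, j)] += pp;
          u *= pno;
        }
      }
      // root population: all four sampled lineages, exchangeable
      for (int t = 0; t < 3; ++t) cf[t] += u * w / 3.0;
    }
    // next profile (mixed radix)
    int l = 0;
    while (l < 4) {
      if (++choice[l] < np[l]) break;
      choice[l] = 0; ++l;
    }
    if (l == 4) break;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_map_expected_cf(List map, NumericVector edge_len,
                                  NumericVector edge_gamma) {
  QMap m = unpack_map(map);
  NumericMatrix out(m.k, 3);
  double cf[3];
  for (int q = 0; q < m.k; ++q) {
    quartet_cf(m, q, edge_len, edge_gamma, cf);
    out(q, 0) = cf[0]; out(q, 1) = cf[1]; out(q, 2) = cf[2];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_map_logcl(List map, NumericVector edge_len, NumericVector edge_gamma,
                     NumericMatrix X, LogicalVector use, double eps) {
  QMap m = unpack_map(map);
  if (X.nrow() != m.k) stop("CF table not aligned with the quartet map");
  double cf[3];
  double total = 0.0;
  for (int q = 0; q < m.k; ++q) {
    if (!use[q]) continue;
    quartet_cf(m, q, edge_len, edge_gamma, cf);
    for (int t = 0; t < 3; ++t) {
      double x = X(q, t);
      if (x <= 0.0) continue;
      double p = cf[t];
      if (p < eps) p = eps;
      if (p > 1.0 - 2.0 * eps) p = 1.0 - 2.0 * eps;
      total += x * std::log(p);
    }
  }
  return total;
}

// ---------------------------------------------------------------------------
// compiled-map construction (C++ mirror of the R reference implementation
// compile_cf_map_r; cross-checked by tests)
// ---------------------------------------------------------------------------

struct EdgeW {
  int par, chi;
  bool alive, gam;
  std::vector<int> comp;
};

// [[Rcpp::export]]
List cpp_compile_map(IntegerVector parent, IntegerVector child,
                     LogicalVector has_gamma, int nnode,
                     IntegerVector leaf_nodes, IntegerMatrix quartets) {
  int E = parent.size();
  int k = quartets.nrow();
  IntegerVector qtype(k), t_topo(k), gindex(k, -1);
  IntegerVector tcomp_ptr(k + 1);
  std::vector<int> tcomp_id;
  std::vector<int> ge_ptr(1, 0), ge_comp_ptr(1, 0), ge_comp_id, ge_gid;
  std::vector<int> gp_ptr(1, 0), gp_cover, gp_gam_ptr(1, 0), gp_gam_edge;
  std::set<int> free_ids;
  int G = 0;

  for (int qi = 0; qi < k; ++qi) {
    std::vector<EdgeW> ed(E);
    for (int e = 0; e < E; ++e) {
      ed[e].par = parent[e] - 1; ed[e].chi = child[e] - 1;
      ed[e].alive = true; ed[e].gam = has_gamma[e];
      ed[e].comp.assign(1, e + 1);
    }
    int ln[4];
    std::vector<int> sampled(nnode, -1);
    for (int j = 0; j < 4; ++j) {
      ln[j] = leaf_nodes[quartets(qi, j) - 1] - 1;
      sampled[ln[j]] = j;
    }
    // clean: prune unsampled pendants, drop dangling roots, suppress chains
    for (;;) {
      std::vector<int> indeg(nnode, 0), outdeg(nnode, 0);
      for (auto &e : ed) if (e.alive) { indeg[e.chi]++; outdeg[e.par]++; }
      bool changed = false;
      for (auto &e : ed)
        if (e.alive && e.gam && indeg[e.chi] == 1) e.gam = false;
      for (int v = 0; v < nnode; ++v) {
        if (outdeg[v] == 0 && sampled[v] < 0 && indeg[v] > 0) {
          for (auto &e : ed) if (e.alive && e.chi == v) { e.alive = false; changed = true; }
        } else if (indeg[v] == 0 && outdeg[v] == 1) {
          for (auto &e : ed) if (e.alive && e.par == v) { e.alive = false; changed = true; }
        }
      }
      if (changed) continue;
      for (int v = 0; v < nnode; ++v) {
        if (indeg[v] == 1 && outdeg[v] == 1 && sampled[v] < 0) {
          int ei = -1, eo = -1;
          for (int e = 0; e < E; ++e) if (ed[e].alive) {
            if (ed[e].chi == v) ei = e;
            if (ed[e].par == v) eo = e;
          }
          ed[ei].chi = ed[eo].chi;
          ed[ei].gam = ed[eo].gam;
          for (int c : ed[eo].comp) ed[ei].comp.push_back(c);
          ed[eo].alive = false;
          changed = true;
          break;  // degrees stale; recompute
        }
      }
      if (!changed) break;
    }
    std::vector<int> alive;
    for (int e = 0; e < E; ++e) if (ed[e].alive) alive.push_back(e);
    std::vector<int> indeg(nnode, 0), outdeg(nnode, 0);
    for (int e : alive) { indeg[ed[e].chi]++; outdeg[ed[e].par]++; }
    int hq = 0;
    for (int v = 0; v < nnode; ++v) if (indeg[v] == 2) hq++;

    // children-first node order on the cleaned graph
    std::vector<int> pend(nnode, 0), order;
    for (int e : alive) pend[ed[e].par]++;
    {
      std::vector<int> stk;
      std::vector<bool> present(nnode, false);
      for (int e : alive) { present[ed[e].par] = present[ed[e].chi] = true; }
      for (int v = 0; v < nnode; ++v) if (present[v] && pend[v] == 0) stk.push_back(v);
      while (!stk.empty()) {
        int v = stk.back(); stk.pop_back();
        order.push_back(v);
        for (int e : alive) if (ed[e].chi == v && --pend[ed[e].par] == 0)
          stk.push_back(ed[e].par);
      }
    }

    if (hq == 0) {
      qtype[qi] = 0;
      std::vector<int> mask(nnode, 0);
      for (int j = 0; j < 4; ++j) mask[ln[j]] |= 1 << j;
      for (int v : order)
        for (int e : alive) if (ed[e].chi == v) mask[ed[e].par] |= mask[v];
      int topo = 0;
      std::set<int> ids;
      for (int e : alive) {
        int m = mask[ed[e].chi];
        int s = ((m & 1) != 0) + ((m & 2) != 0) + ((m & 4) != 0) + ((m & 8) != 0);
        if (s == 2) {
          topo = (m == 3 || m == 12) ? 1 : (m == 5 || m == 10) ? 2 : 3;
          for (int c : ed[e].comp) ids.insert(c);
        }
      }
      if (topo == 0) stop("internal error: quartet tree without a 2|2 edge");
      t_topo[qi] = topo;
      for (int c : ids) { tcomp_id.push_back(c); free_ids.insert(c); }
      tcomp_ptr[qi + 1] = tcomp_id.size();
    } else {
      qtype[qi] = 1;
      gindex[qi] = G++;
      tcomp_ptr[qi + 1] = tcomp_id.size();
      // edges in processing order: by children-first position of their child
      std::vector<int> pos(nnode, 0);
      for (size_t i = 0; i < order.size(); ++i) pos[order[i]] = i;
      std::vector<int> eord(alive);
      std::sort(eord.begin(), eord.end(), [&](int a, int b) {
        return pos[ed[a].chi] < pos[ed[b].chi];
      });
      int ne = eord.size();
      if (ne > 31) stop("quarnet too large to compile");
      std::vector<int> local_of(E, -1);
      for (int i = 0; i < ne; ++i) local_of[eord[i]] = i;
      ge_ptr.push_back(ge_ptr.back() + ne);
      for (int i = 0; i < ne; ++i) {
        EdgeW &e = ed[eord[i]];
        for (int c : e.comp) ge_comp_id.push_back(c);
        ge_comp_ptr.push_back(ge_comp_id.size());
        if (e.gam) {
          int gid = 0;
          for (int c : e.comp) if (has_gamma[c - 1]) {
            if (gid) stop("internal error: ambiguous gamma provenance");
            gid = c;
          }
          if (!gid) stop("internal error: no gamma provenance");
          ge_gid.push_back(gid);
        } else ge_gid.push_back(0);
        if (outdeg[e.chi] != 0)
          for (int c : e.comp) free_ids.insert(c);
      }
      // leaf-to-root paths per lineage (iterative DFS with explicit stack)
      for (int j = 0; j < 4; ++j) {
        int npaths = 0;
        std::vector<std::vector<int>> stack;
        stack.push_back({});  // path of edges; current node tracked separately
        std::vector<int> nodes(1, ln[j]);
        while (!stack.empty()) {
          std::vector<int> path = stack.back(); stack.pop_back();
          int v = nodes.back(); nodes.pop_back();
          std::vector<int> ins;
          for (int e : alive) if (ed[e].chi == v) ins.push_back(e);
          if (ins.empty()) {
            // reached the root: record path
            int cover = 0;
            int ngam0 = gp_gam_ptr.back();
            for (int e : path) {
              cover |= 1 << local_of[e];
              if (ed[e].gam) gp_gam_edge.push_back(local_of[e]);
            }
            // keep gamma edges of this path contiguous
            gp_cover.push_back(cover);
            gp_gam_ptr.push_back(gp_gam_edge.size());
            (void)ngam0;
            npaths++;
            if (npaths > 64) stop("too many lineage paths in a quarnet");
            continue;
          }
          for (int e : ins) {
            std::vector<int> p2 = path; p2.push_back(e);
            stack.push_back(p2);
            nodes.push_back(ed[e].par);
          }
        }
        gp_ptr.push_back(gp_ptr.back() + npaths);
      }
    }
  }
  return List::create(
    _["k"] = k, _["G"] = G, _["qtype"] = qtype, _["t_topo"] = t_topo,
    _["gindex"] = gindex, _["tcomp_ptr"] = tcomp_ptr,
    _["tcomp_id"] = IntegerVector(tcomp_id.begin(), tcomp_id.end()),
    _["ge_ptr"] = IntegerVector(ge_ptr.begin(), ge_ptr.end()),
    _["ge_comp_ptr"] = IntegerVector(ge_comp_ptr.begin(), ge_comp_ptr.end()),
    _["ge_comp_id"] = IntegerVector(ge_comp_id.begin(), ge_comp_id.end()),
    _["ge_gid"] = IntegerVector(ge_gid.begin(), ge_gid.end()),
    _["gp_ptr"] = IntegerVector(gp_ptr.begin(), gp_ptr.end()),
    _["gp_cover"] = IntegerVector(gp_cover.begin(), gp_cover.end()),
    _["gp_gam_ptr"] = IntegerVector(gp_gam_ptr.begin(), gp_gam_ptr.end()),
    _["gp_gam_edge"] = IntegerVector(gp_gam_edge.begin(), gp_gam_edge.end()),
    _["free_len_ids"] = IntegerVector(free_ids.begin(), free_ids.end()));
}
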
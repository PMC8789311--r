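#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Structured coalescent with recombination: a backward-in-time
// per-generation simulation of the ancestry of n sampled haplotypes along a
// region [0, L).  During the sweep phase (generations younger than the focal
// allele's origin) lineages are partitioned into derived/ancestral background
// classes with pairwise coalescence rates 1/(2N x(t)) and 1/(2N (1-x(t)))
// governed by the allele-frequency trajectory x(t); recombination moves the
// fragment not containing the focal site onto a random background.  At the
// origin all derived lineages merge into the single founding copy, which then
// continues on the ancestral background.  Ancestral material is tracked per
// genomic segment (Hudson's algorithm), segments whose lineage count reaches
// one are retired, and the recorded coalescence edges are resolved into the
// sequence of local marginal trees at the end.  Mutations are dropped on each
// marginal tree under the infinite-sites model.

struct Lineage {
  int node;               // tree node whose ancestral material this is
  int cls;                // 0 = ancestral background, 1 = derived
  std::vector<char> has;  // carries segment j?
  double eff;             // effective recombination length (span of material)
};

struct EdgeRec { int parent, child; double left, right; };

static double pop_size_at2(const NumericMatrix &epochs, double t) {
  int i = epochs.nrow() - 1;
  while (i > 0 && epochs(i, 0) > t) --i;
  double N = epochs(i, 1) * std::exp(-epochs(i, 2) * (t - epochs(i, 0)));
  return N < 2.0 ? 2.0 : N;
}

static double next_epoch_after(const NumericMatrix &epochs, double t) {
  for (int i = 0; i < epochs.nrow(); ++i)
    if (epochs(i, 0) > t) return epochs(i, 0);
  return R_PosInf;
}

// span from first to last carried segment, in bp
static double eff_len(const Lineage &lin, const std::vector<double> &cuts) {
  int S = (int)lin.has.size(), a = -1, b = -1;
  for (int j = 0; j < S; ++j) if (lin.has[j]) { a = j; break; }
  if (a < 0) return 0.0;
  for (int j = S - 1; j >= 0; --j) if (lin.has[j]) { b = j; break; }
  return cuts[b + 1] - cuts[a];
}

// [[Rcpp::export]]
List sim_region_cpp(int n, int n_derived, double L, double rho, double mu,
                    NumericVector traj, NumericMatrix epochs,
                    double focal_pos, double max_gen) {
  if (n < 2) stop("need at least 2 haplotypes");
  const bool sweep = traj.size() > 0;
  const double G = sweep ? (double)(traj.size() - 1) : 0.0;

  std::vector<double> cuts;           // segment boundaries
  cuts.push_back(0.0); cuts.push_back(L);
  std::vector<int> segcount(1, n);
  std::vector<char> done(1, 0);
  int n_undone = 1;

  std::vector<double> node_time;      // node 0..n-1 are the leaves
  node_time.reserve(4 * n);
  for (int i = 0; i < n; ++i) node_time.push_back(0.0);
  std::vector<EdgeRec> edges;
  edges.reserve(8 * n);

  std::vector<Lineage> act;           // active lineages
  act.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    Lineage lin;
    lin.node = i;
    lin.cls = (sweep && i < n_derived) ? 1 : 0;
    lin.has.assign(1, 1);
    lin.eff = L;
    act.push_back(lin);
  }
  int kd = sweep ? n_derived : 0;
  int ka = (int)act.size() - kd;
  double tot_eff = (double)n * L;

  // record an edge run for every maximal block of carried segments
  auto record_edges = [&](int parent, const Lineage &lin) {
    int S = (int)lin.has.size();
    int j = 0;
    while (j < S) {
      if (!lin.has[j]) { ++j; continue; }
      int j2 = j;
      while (j2 + 1 < S && lin.has[j2 + 1]) ++j2;
      EdgeRec e; e.parent = parent; e.child = lin.node;
      e.left = cuts[j]; e.right = cuts[j2 + 1];
      edges.push_back(e);
      j = j2 + 1;
    }
  };

  // merge active lineages ia and ib (indices into act) at time t
  auto coalesce = [&](int ia, int ib, double t) {
    if (ia > ib) std::swap(ia, ib);
    Lineage &a = act[ia];
    Lineage &b = act[ib];
    int p = (int)node_time.size();
    node_time.push_back(t);
    record_edges(p, a);
    record_edges(p, b);
    Lineage merged;
    merged.node = p;
    merged.cls = a.cls;                // classes always match within a pair
    int S = (int)a.has.size();
    merged.has.assign(S, 0);
    for (int j = 0; j < S; ++j) {
      if (a.has[j] && b.has[j]) {
        if (--segcount[j] == 1 && !done[j]) {    // found its marginal MRCA
          done[j] = 1; segcount[j] = 0; --n_undone;
        } else merged.has[j] = 1;
      } else if (a.has[j] || b.has[j]) merged.has[j] = 1;
    }
    tot_eff -= a.eff + b.eff;
    if (a.cls == 1) kd -= 2; else ka -= 2;
    // drop both, insert merged if it still carries material
    act.erase(act.begin() + ib);
    act.erase(act.begin() + ia);
    bool any = false;
    for (int j = 0; j < S; ++j) if (merged.has[j]) { any = true; break; }
    if (any) {
      merged.eff = eff_len(merged, cuts);
      tot_eff += merged.eff;
      if (merged.cls == 1) ++kd; else ++ka;
      act.push_back(merged);
    }
  };

  // split segment containing coordinate b; keeps all bookkeeping aligned
  auto insert_cut = [&](double b) {
    int j0 = (int)(std::upper_bound(cuts.begin(), cuts.end(), b) - cuts.begin()) - 1;
    if (cuts[j0] == b) return;        // boundary already exists
    cuts.insert(cuts.begin() + j0 + 1, b);
    segcount.insert(segcount.begin() + j0 + 1, segcount[j0]);
    done.insert(done.begin() + j0 + 1, done[j0]);
    if (!done[j0]) ++n_undone;
    for (size_t i = 0; i < act.size(); ++i)
      act[i].has.insert(act[i].has.begin() + j0 + 1, act[i].has[j0]);
  };

  // recombination on lineage i at breakpoint b (sweep phase passes x >= 0)
  auto split = [&](int i, double b, double x) {
    insert_cut(b);
    int jb = (int)(std::lower_bound(cuts.begin(), cuts.end(), b) - cuts.begin());
    Lineage &left = act[i];
    Lineage right;
    right.node = left.node;
    int S = (int)left.has.size();
    right.has.assign(S, 0);
    for (int j = jb; j < S; ++j) { right.has[j] = left.has[j]; left.has[j] = 0; }
    // background class: the fragment containing the focal site keeps the
    // class; the other fragment lands on a random background
    right.cls = left.cls;
    if (sweep && x >= 0.0) {
      int redraw = (R::unif_rand() < x) ? 1 : 0;
      if (focal_pos >= b) { /* right keeps */ left.cls = redraw; }
      else                { /* left keeps  */ right.cls = redraw; }
    }
    tot_eff -= left.eff;
    left.eff = eff_len(left, cuts);
    right.eff = eff_len(right, cuts);
    tot_eff += left.eff + right.eff;
    act.push_back(right);
    // recount classes (cheap relative to split cost)
    kd = 0; for (size_t q = 0; q < act.size(); ++q) if (act[q].cls == 1) ++kd;
    ka = (int)act.size() - kd;
  };

  auto pick_by_class = [&](int cls) {
    int k = (cls == 1) ? kd : ka;
    int r = (int)std::floor(R::unif_rand() * k); if (r >= k) r = k - 1;
    for (int i = 0; i < (int)act.size(); ++i)
      if (act[i].cls == cls && r-- == 0) return i;
    return -1;
  };

  double g = 0.0;
  bool origin_merged = !sweep;
  while (n_undone > 0) {
    g += 1.0;
    if (g > max_gen)
      stop("coalescent simulation exceeded %g generations without full coalescence", max_gen);
    double N = pop_size_at2(epochs, g);
    double twoN = 2.0 * N;
    int jc = 0;                        // within-generation event counter
    auto ev_time = [&]() { double t = g + 0.5 * (1.0 - std::pow(0.5, jc)); ++jc; return t; };

    if (sweep && !origin_merged && g >= G) {
      // origin: all derived lineages merge into the single founding copy
      while (kd >= 2) {
        int ia = pick_by_class(1), ib;
        do { ib = pick_by_class(1); } while (ib == ia);
        coalesce(ia, ib, ev_time());
      }
      for (size_t q = 0; q < act.size(); ++q)
        if (act[q].cls == 1) { act[q].cls = 0; --kd; ++ka; }
      origin_merged = true;
      if (n_undone == 0) break;
    }

    if (sweep && !origin_merged) {
      double x = traj[(int)g];
      if (x <= 0.0) x = 0.5 / twoN;
      if (x >= 1.0) x = 1.0 - 0.5 / twoN;
      // forced merges when the class rate saturates the generation
      for (;;) {
        double pd = kd >= 2 ? 0.5 * kd * (kd - 1.0) / (twoN * x) : 0.0;
        if (pd < 1.0 || kd < 2) break;
        int ia = pick_by_class(1), ib;
        do { ib = pick_by_class(1); } while (ib == ia);
        coalesce(ia, ib, ev_time());
      }
      for (;;) {
        double pa = ka >= 2 ? 0.5 * ka * (ka - 1.0) / (twoN * (1.0 - x)) : 0.0;
        if (pa < 1.0 || ka < 2) break;
        int ia = pick_by_class(0), ib;
        do { ib = pick_by_class(0); } while (ib == ia);
        coalesce(ia, ib, ev_time());
      }
      if (n_undone == 0) break;
      double pd = kd >= 2 ? 0.5 * kd * (kd - 1.0) / (twoN * x) : 0.0;
      double pa = ka >= 2 ? 0.5 * ka * (ka - 1.0) / (twoN * (1.0 - x)) : 0.0;
      double pr = rho * tot_eff;
      double ptot = pd + pa + pr;
      if (R::unif_rand() >= std::min(1.0, ptot)) continue;
      double u = R::unif_rand() * ptot;
      if (u < pd) {
        int ia = pick_by_class(1), ib;
        do { ib = pick_by_class(1); } while (ib == ia);
        coalesce(ia, ib, ev_time());
      } else if (u < pd + pa) {
        int ia = pick_by_class(0), ib;
        do { ib = pick_by_class(0); } while (ib == ia);
        coalesce(ia, ib, ev_time());
      } else if (u < pd + pa + pr) {
        double w = R::unif_rand() * tot_eff, acc = 0.0;
        int i = -1;
        for (int q = 0; q < (int)act.size(); ++q) {
          acc += act[q].eff;
          if (w <= acc) { i = q; break; }
        }
        if (i >= 0 && act[i].eff > 0.0) {
          int S = (int)act[i].has.size(), a = 0, b = S - 1;
          while (!act[i].has[a]) ++a;
          while (!act[i].has[b]) --b;
          double lo = cuts[a], hi = cuts[b + 1];
          double bp = R::runif(lo, hi);
          if (bp > lo && bp < hi) split(i, bp, x);
        }
      }
    } else {
      // single-class phase (neutral regions, or older than the origin)
      int k = (int)act.size();
      double pc = k >= 2 ? 0.5 * k * (k - 1.0) / twoN : 0.0;
      double pr = rho * tot_eff;
      double ptot = pc + pr;
      double growth = 0.0;
      {
        int ei = epochs.nrow() - 1;
        while (ei > 0 && epochs(ei, 0) > g) --ei;
        growth = epochs(ei, 2);
      }
      if (ptot <= 0.0) stop("internal error: no events possible but segments remain");
      if (ptot < 1.0 && growth == 0.0) {
        // geometric skip to the next event (rates constant within the epoch)
        double nb = next_epoch_after(epochs, g);
        double m = std::floor(std::log(R::unif_rand()) / std::log1p(-ptot));
        if (g + m >= nb) { g = nb - 1.0; continue; }   // re-enter loop at boundary
        g += m;
      } else if (R::unif_rand() >= ptot) {
        continue;                                       // no event this generation
      }
      double u = R::unif_rand() * std::min(ptot, 1.0);
      if (u < pc) {
        int r1 = (int)std::floor(R::unif_rand() * k); if (r1 >= k) r1 = k - 1;
        int r2 = (int)std::floor(R::unif_rand() * (k - 1)); if (r2 >= k - 1) r2 = k - 2;
        if (r2 >= r1) ++r2;
        coalesce(r1, r2, ev_time());
      } else {
        double w = R::unif_rand() * tot_eff, acc = 0.0;
        int i = -1;
        for (int q = 0; q < (int)act.size(); ++q) {
          acc += act[q].eff;
          if (w <= acc) { i = q; break; }
        }
        if (i >= 0 && act[i].eff > 0.0) {
          int S = (int)act[i].has.size(), a = 0, b = S - 1;
          while (!act[i].has[a]) ++a;
          while (!act[i].has[b]) --b;
          double lo = cuts[a], hi = cuts[b + 1];
          double bp = R::runif(lo, hi);
          if (bp > lo && bp < hi) split(i, bp, -1.0);
        }
      }
    }
  }

  // ---- resolve marginal trees per segment, merge identical neighbours ----
  int n_nodes = (int)node_time.size();
  int S = (int)cuts.size() - 1;
  std::vector<int> par(n_nodes), nkid(n_nodes), compact(n_nodes);

  std::vector<double> tree_left, tree_right;
  std::vector<std::vector<int> > tree_parent;
  std::vector<std::vector<double> > tree_times;

  for (int j = 0; j < S; ++j) {
    double m = 0.5 * (cuts[j] + cuts[j + 1]);
    std::fill(par.begin(), par.end(), -1);
    std::fill(nkid.begin(), nkid.end(), 0);
    for (size_t e = 0; e < edges.size(); ++e)
      if (edges[e].left <= m && m < edges[e].right) {
        par[edges[e].child] = edges[e].parent;
        ++nkid[edges[e].parent];
      }
    // kept nodes: leaves + binary internals; compact ids 1..2n-1 (R, 1-based)
    std::vector<int> internals;
    for (int v = n; v < n_nodes; ++v) if (nkid[v] >= 2) internals.push_back(v);
    if ((int)internals.size() != n - 1)
      stop("internal error: marginal tree at [%g,%g) has %d binary nodes (expected %d)",
           cuts[j], cuts[j + 1], (int)internals.size(), n - 1);
    std::sort(internals.begin(), internals.end(),
              [&](int a, int b) { return node_time[a] < node_time[b]; });
    std::fill(compact.begin(), compact.end(), 0);
    for (int v = 0; v < n; ++v) compact[v] = v + 1;
    for (int q = 0; q < (int)internals.size(); ++q) compact[internals[q]] = n + 1 + q;
    std::vector<int> cpar(2 * n - 1, 0);
    std::vector<double> ctime(2 * n - 1, 0.0);
    for (int v = 0; v < n; ++v) ctime[v] = node_time[v];
    for (int q = 0; q < (int)internals.size(); ++q) ctime[n + q] = node_time[internals[q]];
    auto climb = [&](int v) {            // nearest kept (binary) ancestor
      int w = par[v];
      while (w >= 0 && nkid[w] < 2) w = par[w];
      return w;
    };
    for (int v = 0; v < n; ++v) {
      int w = climb(v);
      cpar[v] = (w >= 0) ? compact[w] : 0;
    }
    for (int q = 0; q < (int)internals.size(); ++q) {
      int w = climb(internals[q]);
      cpar[n + q] = (w >= 0) ? compact[w] : 0;
    }
    // merge with previous tree if identical
    if (!tree_parent.empty() && tree_parent.back() == cpar &&
        tree_times.back() == ctime) {
      tree_right.back() = cuts[j + 1];
    } else {
      tree_parent.push_back(cpar);
      tree_times.push_back(ctime);
      tree_left.push_back(cuts[j]);
      tree_right.push_back(cuts[j + 1]);
    }
  }

  // ---- infinite-sites mutations on each merged local tree ----
  int T = (int)tree_parent.size();
  std::vector<double> mut_pos;
  std::vector<std::vector<int> > mut_car;   // leaf ids (1-based)
  for (int t = 0; t < T; ++t) {
    const std::vector<int> &cp = tree_parent[t];
    const std::vector<double> &ct = tree_times[t];
    int M = 2 * n - 1;
    double TL = 0.0;
    std::vector<double> blen(M, 0.0);
    for (int v = 0; v < M; ++v)
      if (cp[v] > 0) { blen[v] = ct[cp[v] - 1] - ct[v]; TL += blen[v]; }
    double lam = mu * (tree_right[t] - tree_left[t]) * TL;
    int nm = (int)R::rpois(lam);
    if (nm == 0) continue;
    // children lists for carrier lookup
    std::vector<std::vector<int> > kids(M);
    for (int v = 0; v < M; ++v) if (cp[v] > 0) kids[cp[v] - 1].push_back(v);
    for (int s = 0; s < nm; ++s) {
      double w = R::unif_rand() * TL, acc = 0.0;
      int v = M - 1;
      for (int q = 0; q < M; ++q) { acc += blen[q]; if (w <= acc) { v = q; break; } }
      std::vector<int> carriers, stack;
      stack.push_back(v);
      while (!stack.empty()) {
        int z = stack.back(); stack.pop_back();
        if (z < n) carriers.push_back(z + 1);
        for (size_t c = 0; c < kids[z].size(); ++c) stack.push_back(kids[z][c]);
      }
      if ((int)carriers.size() == 0 || (int)carriers.size() == n) continue;
      mut_pos.push_back(R::runif(tree_left[t], tree_right[t]));
      std::sort(carriers.begin(), carriers.end());
      mut_car.push_back(carriers);
    }
  }
  // order sites by position
  std::vector<int> ord(mut_pos.size());
  for (size_t q = 0; q < ord.size(); ++q) ord[q] = (int)q;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return mut_pos[a] < mut_pos[b]; });
  IntegerMatrix haplo(n, (int)mut_pos.size());
  NumericVector positions((int)mut_pos.size());
  for (int q = 0; q < (int)ord.size(); ++q) {
    positions[q] = mut_pos[ord[q]];
    const std::vector<int> &car = mut_car[ord[q]];
    for (size_t c = 0; c < car.size(); ++c) haplo(car[c] - 1, q) = 1;
  }

  List trees(T);
  for (int t = 0; t < T; ++t)
    trees[t] = List::create(_["parent"] = wrap(tree_parent[t]),
                            _["times"] = wrap(tree_times[t]),
                            _["left"] = tree_left[t],
                            _["right"] = tree_right[t]);
  return List::create(_["trees"] = trees, _["haplotypes"] = haplo,
                      _["positions"] = positions, _["n_derived"] = n_derived);
}
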
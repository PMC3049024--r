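// Likelihood engine: Felsenstein pruning over arbitrary reversible models
// supplied as per-category eigendecompositions, with per-edge message
// caching and spectral edge-likelihood factorization so that evaluating
// the likelihood as a function of a single branch length is cheap. Drives
// branch-length coordinate ascent and fixed-topology sweep MCMC.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

// discrete-gamma category rates: mean of each of k equal-probability bins,
// Gamma(shape, rate = shape) so the overall mean is exactly 1
static vec gamma_rates(double shape, int k) {
  vec r(k);
  if (k == 1) { r(0) = 1.0; return r; }
  vec q(k + 1);
  q(0) = 0.0; q(k) = datum::inf;
  for (int j = 1; j < k; ++j)
    q(j) = R::qgamma(double(j) / k, shape, 1.0 / shape, 1, 0);
  for (int j = 0; j < k; ++j) {
    double hi = (j == k - 1) ? 1.0 : R::pgamma(q(j + 1), shape + 1.0, 1.0 / shape, 1, 0);
    double lo = (j == 0) ? 0.0 : R::pgamma(q(j), shape + 1.0, 1.0 / shape, 1, 0);
    r(j) = k * (hi - lo);
  }
  return r;
}

// [[Rcpp::export]]
arma::vec cpp_gamma_rates(double shape, int k) { return gamma_rates(shape, k); }

struct Engine {
  // tree
  int ntip, nnode_tot, nedge, root;
  ivec eparent, echild;
  vec blen;
  std::vector<std::vector<int>> child_edges;
  ivec parent_edge;
  std::vector<int> postorder_nodes;

  // data
  int npat, nsym, nstate, ncat;
  imat tipstate;                 // ntip x npat, 0..nsym-1, nsym = missing
  vec wt;
  mat tipmap;                    // nstate x (nsym+1)

  // model
  cube U, Uinv;
  mat lambda;                    // nstate x ncat
  vec lambda_base;               // plain scalable models; empty otherwise
  vec catw, root_freq, catr;
  bool scalable;
  double shape; int kcat;
  int cond_pat;                  // conditioning pattern index, -1 if none

  // workspace
  std::vector<cube> M;           // internal-child edges: nstate x npat x ncat
  std::vector<cube> PT;          // tip-child edges: nstate x (nsym+1) x ncat
  std::vector<cube> L;           // internal nodes
  std::vector<cube> BT;          // per tip edge: Uinv * tipmap per cat
  mat nscal;                     // n_internal x npat log-scalers
  mat sdown;                     // nnode_tot x npat subtree scaler sums
  ivec node_idx;

  void build_tree(const imat &edge, const vec &bl, int ntip_, int root_) {
    ntip = ntip_;
    nedge = edge.n_rows;
    nnode_tot = max(max(edge));
    eparent.set_size(nedge); echild.set_size(nedge);
    for (int e = 0; e < nedge; ++e) {
      eparent(e) = edge(e, 0) - 1;
      echild(e) = edge(e, 1) - 1;
    }
    blen = bl;
    root = root_;
    child_edges.assign(nnode_tot, {});
    parent_edge.set_size(nnode_tot); parent_edge.fill(-1);
    for (int e = 0; e < nedge; ++e) {
      child_edges[eparent(e)].push_back(e);
      parent_edge(echild(e)) = e;
    }
    postorder_nodes.clear();
    std::vector<int> stack = {root}, order;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      order.push_back(u);
      for (int e : child_edges[u]) stack.push_back(echild(e));
    }
    for (auto it = order.rbegin(); it != order.rend(); ++it)
      if (!child_edges[*it].empty()) postorder_nodes.push_back(*it);
    node_idx.set_size(nnode_tot); node_idx.fill(-1);
    int k = 0;
    for (int u = 0; u < nnode_tot; ++u)
      if (!child_edges[u].empty()) node_idx(u) = k++;
  }

  int n_internal() const { return (int)postorder_nodes.size(); }

  void alloc() {
    M.assign(nedge, cube());
    PT.assign(nedge, cube());
    BT.assign(nedge, cube());
    L.assign(n_internal(), cube());
    for (int e = 0; e < nedge; ++e) {
      if (echild(e) < ntip) {
        PT[e].set_size(nstate, nsym + 1, ncat);
        BT[e].set_size(nstate, nsym + 1, ncat);
        for (int r = 0; r < ncat; ++r) BT[e].slice(r) = Uinv.slice(r) * tipmap;
      } else M[e].set_size(nstate, npat, ncat);
    }
    for (int i = 0; i < n_internal(); ++i) L[i].set_size(nstate, npat, ncat);
    nscal.zeros(n_internal(), npat);
    sdown.zeros(nnode_tot, npat);
  }

  mat Pmat(int e, int r) const {
    return U.slice(r) * diagmat(exp(lambda.col(r) * blen(e))) * Uinv.slice(r);
  }

  void update_edge(int e) {
    int c = echild(e);
    if (c < ntip) {
      for (int r = 0; r < ncat; ++r) PT[e].slice(r) = Pmat(e, r) * tipmap;
    } else {
      const cube &Lc = L[node_idx(c)];
      for (int r = 0; r < ncat; ++r) M[e].slice(r) = Pmat(e, r) * Lc.slice(r);
    }
  }

  void update_node(int u) {
    int ui = node_idx(u);
    cube &Lu = L[ui];
    bool first = true;
    for (int e : child_edges[u]) {
      int c = echild(e);
      if (c < ntip) {
        for (int r = 0; r < ncat; ++r) {
          mat &Ls = Lu.slice(r);
          const mat &Pt = PT[e].slice(r);
          if (first) {
            for (int i = 0; i < npat; ++i) Ls.col(i) = Pt.col(tipstate(c, i));
          } else {
            for (int i = 0; i < npat; ++i) Ls.col(i) %= Pt.col(tipstate(c, i));
          }
        }
      } else {
        const cube &Me = M[e];
        for (int r = 0; r < ncat; ++r) {
          if (first) Lu.slice(r) = Me.slice(r);
          else Lu.slice(r) %= Me.slice(r);
        }
      }
      first = false;
    }
    rowvec m(npat, fill::zeros);
    for (int r = 0; r < ncat; ++r) m = arma::max(m, arma::max(Lu.slice(r), 0));
    for (int i = 0; i < npat; ++i) {
      double mi = m(i);
      if (mi <= 0.0 || !std::isfinite(mi))
        stop("non-finite partial likelihood at pattern %d", i + 1);
      nscal(ui, i) = std::log(mi);
    }
    for (int r = 0; r < ncat; ++r) Lu.slice(r).each_row() /= m;
  }

  void update_sdown(int u) {
    int ui = node_idx(u);
    sdown.row(u) = nscal.row(ui);
    for (int e : child_edges[u]) {
      int c = echild(e);
      if (c >= ntip) sdown.row(u) += sdown.row(c);
    }
  }

  void full_update() {
    for (int u : postorder_nodes) {
      for (int e : child_edges[u]) update_edge(e);
      update_node(u);
      update_sdown(u);
    }
  }

  // log-likelihood per pattern from the rooted partials
  vec site_lnl_raw() const {
    const cube &Lr = L[node_idx(root)];
    vec out(npat);
    for (int i = 0; i < npat; ++i) {
      double s = 0.0;
      for (int r = 0; r < ncat; ++r)
        s += catw(r) * dot(root_freq, Lr.slice(r).col(i));
      out(i) = std::log(s) + sdown(root, i);
    }
    return out;
  }

  double lnl_from_sites(const vec &sl) const {
    double adj = 0.0;
    if (cond_pat >= 0) {
      double p0 = std::exp(sl(cond_pat));
      if (p0 >= 1.0) stop("conditioning probability >= 1");
      adj = std::log1p(-p0);
    }
    double tot = 0.0;
    for (int i = 0; i < npat; ++i) tot += wt(i) * (sl(i) - adj);
    if (!std::isfinite(tot)) stop("non-finite log-likelihood");
    return tot;
  }

  double total_lnl() const { return lnl_from_sites(site_lnl_raw()); }

  void set_shape(double a) {
    if (!scalable) stop("shape updates need a plain scalable model");
    shape = a;
    catr = gamma_rates(a, kcat);
    for (int j = 0; j < kcat; ++j) lambda.col(j) = lambda_base * catr(j);
  }

  // ---- spectral edge likelihood --------------------------------------
  // For edge e = (u, v): with X = (rest-of-tree partial at u, including
  // the root frequencies) and D = child partial, the per-pattern site
  // likelihood is f_i(t) = sum_r catw_r sum_m G_r[m,i] exp(lambda[m,r] t)
  // with G_r = (U_r^T X_r) % (Uinv_r D_r). "escal" carries the log
  // scalers that must be added to log f.

  struct EdgeCtx {
    cube G;        // nstate x npat x ncat
    rowvec escal;  // npat
    int e;
  };

  void make_edge_ctx(int e, const cube &X, const rowvec &scal_up,
                     EdgeCtx &ctx) const {
    int v = echild(e);
    ctx.e = e;
    ctx.G.set_size(nstate, npat, ncat);
    if (v < ntip) {
      for (int r = 0; r < ncat; ++r) {
        mat A = U.slice(r).t() * X.slice(r);     // nstate x npat
        const mat &B = BT[e].slice(r);           // nstate x (nsym+1)
        mat &Gs = ctx.G.slice(r);
        for (int i = 0; i < npat; ++i)
          Gs.col(i) = A.col(i) % B.col(tipstate(v, i));
      }
      ctx.escal = scal_up;
    } else {
      const cube &D = L[node_idx(v)];
      for (int r = 0; r < ncat; ++r)
        ctx.G.slice(r) = (U.slice(r).t() * X.slice(r)) %
                         (Uinv.slice(r) * D.slice(r));
      ctx.escal = scal_up + sdown.row(v);
    }
  }

  vec edge_site_lnl(const EdgeCtx &ctx, double t) const {
    rowvec acc(npat, fill::zeros);
    for (int r = 0; r < ncat; ++r) {
      rowvec el = exp(lambda.col(r).t() * t) * catw(r);
      acc += el * ctx.G.slice(r);   // dgemv, no transpose copy
    }
    vec out(npat);
    for (int i = 0; i < npat; ++i) {
      if (acc(i) <= 0.0) { out(i) = -1e30; continue; }
      out(i) = std::log(acc(i)) + ctx.escal(i);
    }
    return out;
  }

  double edge_lnl(const EdgeCtx &ctx, double t) const {
    return lnl_from_sites(edge_site_lnl(ctx, t));
  }

  // rest-of-tree partial for child v given X at u: up_v = P_e^T X (x)
  // product over other children's messages; rescaled
  void push_up(int e, const cube &X, const rowvec &scal_up, cube &Xv,
               rowvec &scal_v) const {
    int u = eparent(e);
    cube tmp = X;
    rowvec sc = scal_up;
    for (int e2 : child_edges[u]) {
      if (e2 == e) continue;
      int c2 = echild(e2);
      if (c2 < ntip) {
        for (int r = 0; r < ncat; ++r) {
          mat &Ts = tmp.slice(r);
          const mat &Pt = PT[e2].slice(r);
          for (int i = 0; i < npat; ++i) Ts.col(i) %= Pt.col(tipstate(c2, i));
        }
      } else {
        for (int r = 0; r < ncat; ++r) tmp.slice(r) %= M[e2].slice(r);
        sc += sdown.row(echild(e2));
      }
    }
    Xv.set_size(nstate, npat, ncat);
    for (int r = 0; r < ncat; ++r) {
      mat P = Pmat(e, r);
      Xv.slice(r) = P.t() * tmp.slice(r);
    }
    rowvec m(npat, fill::zeros);
    for (int r = 0; r < ncat; ++r) m = arma::max(m, arma::max(Xv.slice(r), 0));
    scal_v = sc;
    for (int i = 0; i < npat; ++i) {
      if (m(i) <= 0.0) stop("vanishing rest-of-tree partial");
      scal_v(i) += std::log(m(i));
    }
    for (int r = 0; r < ncat; ++r) Xv.slice(r).each_row() /= m;
  }

  cube root_X() const {
    cube X(nstate, npat, ncat);
    for (int r = 0; r < ncat; ++r)
      X.slice(r) = repmat(root_freq, 1, npat);
    return X;
  }
};

static Engine make_engine(const imat &edge, const vec &blen, int ntip,
                          const imat &tipstate, const vec &wt, const mat &tipmap,
                          const cube &U, const cube &Uinv, const mat &lambda,
                          const vec &lambda_base, const vec &catw,
                          const vec &root_freq, int cond_pat, double shape) {
  Engine en;
  // root = the unique node that is never a child (ape: usually ntip+1)
  {
    std::vector<char> ischild(edge.max(), 0);
    for (uword e = 0; e < edge.n_rows; ++e) ischild[edge(e, 1) - 1] = 1;
    int root0 = -1;
    for (uword e = 0; e < edge.n_rows; ++e)
      if (!ischild[edge(e, 0) - 1]) { root0 = edge(e, 0) - 1; break; }
    if (root0 < 0) stop("tree has no root node");
    en.build_tree(edge, blen, ntip, root0);
  }
  en.tipstate = tipstate;
  en.wt = wt;
  en.tipmap = tipmap;
  en.npat = tipstate.n_cols;
  en.nsym = tipmap.n_cols - 1;
  en.nstate = tipmap.n_rows;
  en.ncat = U.n_slices;
  en.U = U; en.Uinv = Uinv; en.lambda = lambda;
  en.lambda_base = lambda_base;
  en.scalable = lambda_base.n_elem > 0;
  en.catw = catw; en.root_freq = root_freq;
  en.cond_pat = cond_pat;
  en.shape = shape; en.kcat = en.ncat;
  if ((int)en.tipstate.n_rows != ntip) stop("tipstate must have one row per tip");
  en.alloc();
  en.full_update();
  return en;
}

// [[Rcpp::export]]
List cpp_loglik(const arma::imat &edge, const arma::vec &blen, int ntip,
                const arma::imat &tipstate, const arma::vec &wt,
                const arma::mat &tipmap, const arma::cube &U,
                const arma::cube &Uinv, const arma::mat &lambda,
                const arma::vec &lambda_base, const arma::vec &catw,
                const arma::vec &root_freq, int cond_pat, double shape) {
  Engine en = make_engine(edge, blen, ntip, tipstate, wt, tipmap, U, Uinv,
                          lambda, lambda_base, catw, root_freq, cond_pat, shape);
  vec sl = en.site_lnl_raw();
  double adj = 0.0;
  if (cond_pat >= 0) adj = std::log1p(-std::exp(sl(cond_pat)));
  return List::create(Named("loglik") = en.total_lnl(),
                      Named("site_lnl") = sl - adj,
                      Named("cond_adjust") = adj);
}

// bounded Brent maximization
template <class F>
static double brent_max(F f, double lo, double hi, double tol, int maxit = 60) {
  const double gold = 0.3819660;
  double a = lo, b = hi;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = -f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int it = 0; it < maxit; ++it) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-12, tol2 = 2 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool gsect = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv), q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2 * (q - r);
      if (q > 0) p = -p;
      q = std::fabs(q);
      double etmp = e; e = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etmp) || p <= q * (a - x) ||
            p >= q * (b - x))) {
        d = p / q; double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        gsect = false;
      }
    }
    if (gsect) { e = (x >= xm) ? a - x : b - x; d = gold * e; }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = -f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

// Shared DFS over edges with preallocated per-depth workspace. The
// visitor decides the new branch length for an edge given its EdgeCtx;
// messages and partials are refreshed exactly, so sequential coordinate
// updates always see current values everywhere else in the tree.
struct DfsWorkspace {
  std::vector<cube> Xe;      // exclusive rest-of-tree product per depth
  std::vector<cube> Xv;      // descending up-message per depth
  std::vector<rowvec> sce, scv;
  Engine::EdgeCtx ctx;
  void ensure(const Engine &en, int depth) {
    while ((int)Xe.size() <= depth) {
      Xe.emplace_back(en.nstate, en.npat, en.ncat);
      Xv.emplace_back(en.nstate, en.npat, en.ncat);
      sce.emplace_back(en.npat);
      scv.emplace_back(en.npat);
    }
  }
};

template <class Visit>
static void dfs_rec(Engine &en, DfsWorkspace &ws, int u, int depth,
                    const cube &X, const rowvec &scal_up, Visit &visit) {
  for (int e : en.child_edges[u]) {
    cube &Xe = ws.Xe[depth];
    rowvec &sce = ws.sce[depth];
    Xe = X;
    sce = scal_up;
    for (int e2 : en.child_edges[u]) {
      if (e2 == e) continue;
      int c2 = en.echild(e2);
      if (c2 < en.ntip) {
        for (int r = 0; r < en.ncat; ++r) {
          mat &Ts = Xe.slice(r);
          const mat &Pt = en.PT[e2].slice(r);
          for (int i = 0; i < en.npat; ++i)
            Ts.col(i) %= Pt.col(en.tipstate(c2, i));
        }
      } else {
        for (int r = 0; r < en.ncat; ++r) Xe.slice(r) %= en.M[e2].slice(r);
        sce += en.sdown.row(c2);
      }
    }
    en.make_edge_ctx(e, Xe, sce, ws.ctx);
    visit(ws.ctx);                     // may change en.blen(ctx.e)
    en.update_edge(e);                 // P(t) refreshed
    int v = en.echild(e);
    if (v >= en.ntip) {
      cube &Xv = ws.Xv[depth];
      rowvec &scv = ws.scv[depth];
      for (int r = 0; r < en.ncat; ++r)
        Xv.slice(r) = en.Pmat(e, r).t() * Xe.slice(r);
      rowvec m(en.npat, fill::zeros);
      for (int r = 0; r < en.ncat; ++r)
        m = arma::max(m, arma::max(Xv.slice(r), 0));
      scv = sce;
      for (int i = 0; i < en.npat; ++i) {
        if (m(i) <= 0.0) stop("vanishing rest-of-tree partial");
        scv(i) += std::log(m(i));
      }
      for (int r = 0; r < en.ncat; ++r) Xv.slice(r).each_row() /= m;
      dfs_rec(en, ws, v, depth + 1, Xv, scv, visit);
      en.update_edge(e);               // child partial may have changed
    }
  }
  en.update_node(u);
  en.update_sdown(u);
}

template <class Visit>
static void dfs_edges(Engine &en, DfsWorkspace &ws, Visit visit) {
  // preallocate the whole depth range up front: growing the buffer vector
  // mid-recursion would invalidate references held by outer frames
  std::vector<int> dep(en.nnode_tot, 0);
  int maxdep = 0;
  {
    std::vector<int> stack = {en.root};
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int e : en.child_edges[u]) {
        dep[en.echild(e)] = dep[u] + 1;
        maxdep = std::max(maxdep, dep[en.echild(e)]);
        stack.push_back(en.echild(e));
      }
    }
  }
  ws.ensure(en, maxdep + 1);
  rowvec z(en.npat, fill::zeros);
  cube X0 = en.root_X();
  dfs_rec(en, ws, en.root, 0, X0, z, visit);
}

// [[Rcpp::export]]
List cpp_optimize(const arma::imat &edge, const arma::vec &blen, int ntip,
                  const arma::imat &tipstate, const arma::vec &wt,
                  const arma::mat &tipmap, const arma::cube &U,
                  const arma::cube &Uinv, const arma::mat &lambda,
                  const arma::vec &lambda_base, const arma::vec &catw,
                  const arma::vec &root_freq, int cond_pat, double shape,
                  bool opt_shape, double bl_min, double bl_max,
                  double tol_lnl, int max_sweeps) {
  Engine en = make_engine(edge, blen, ntip, tipstate, wt, tipmap, U, Uinv,
                          lambda, lambda_base, catw, root_freq, cond_pat, shape);
  DfsWorkspace ws;
  double cur = en.total_lnl();
  std::vector<double> trace = {cur};
  bool converged = false;
  int sweeps = 0;
  // alternate branch-length sweeps (to tolerance) with single shape
  // optimizations; both are exact coordinate ascent so lnL is monotone
  int shape_rounds = opt_shape ? 4 : 1;
  for (int round = 0; round < shape_rounds && sweeps < max_sweeps; ++round) {
    for (; sweeps < max_sweeps; ++sweeps) {
      dfs_edges(en, ws, [&](Engine::EdgeCtx &ctx) {
        double f0 = en.edge_lnl(ctx, en.blen(ctx.e));
        double best = brent_max([&](double t) { return en.edge_lnl(ctx, t); },
                                bl_min, bl_max, 1e-7);
        if (en.edge_lnl(ctx, best) >= f0) en.blen(ctx.e) = best;
      });
      double now = en.total_lnl();
      trace.push_back(now);
      bool done = now - cur < tol_lnl;
      cur = std::max(now, cur);
      if (done) { ++sweeps; break; }
    }
    converged = sweeps < max_sweeps;
    if (opt_shape) {
      double bs = brent_max([&](double la) {
        en.set_shape(std::exp(la)); en.full_update(); return en.total_lnl();
      }, std::log(0.05), std::log(50.0), 1e-4, 30);
      en.set_shape(std::exp(bs)); en.full_update();
      double now = en.total_lnl();
      if (now - cur < tol_lnl && round > 0) { cur = std::max(now, cur); break; }
      cur = std::max(now, cur);
    }
  }
  vec sl = en.site_lnl_raw();
  double adj = (cond_pat >= 0) ? std::log1p(-std::exp(sl(cond_pat))) : 0.0;
  return List::create(Named("blens") = en.blen, Named("shape") = en.shape,
                      Named("loglik") = cur, Named("sweeps") = sweeps,
                      Named("converged") = converged, Named("trace") = trace,
                      Named("site_lnl") = sl - adj);
}

// ---- fixed-topology sweep MCMC -------------------------------------------
// One generation = one Metropolis proposal. Branch-length multiplier
// proposals are made in DFS sweep order (a deterministic-scan Metropolis
// scheme, each kernel leaving the posterior invariant); an optional
// reflected sliding-window shape proposal is interleaved once per sweep.
// Priors: iid Exp(bl_prior_rate) branch lengths, Uniform(shape_lo,
// shape_hi) shape. beta_power tempers the likelihood for power-posterior
// (stepping-stone) runs. Uses R's RNG.

// [[Rcpp::export]]
List cpp_mcmc(const arma::imat &edge, const arma::vec &blen, int ntip,
              const arma::imat &tipstate, const arma::vec &wt,
              const arma::mat &tipmap, const arma::cube &U,
              const arma::cube &Uinv, const arma::mat &lambda,
              const arma::vec &lambda_base, const arma::vec &catw,
              const arma::vec &root_freq, int cond_pat, double shape,
              bool sample_shape, int ngen, int sample_interval, int burnin,
              double p_shape_move, double mult_lambda, double shape_window,
              double bl_prior_rate, double shape_lo, double shape_hi,
              double bl_min, double bl_max, double beta_power,
              int moves_per_edge) {
  Engine en = make_engine(edge, blen, ntip, tipstate, wt, tipmap, U, Uinv,
                          lambda, lambda_base, catw, root_freq, cond_pat, shape);
  DfsWorkspace ws;
  double lnl = en.total_lnl();
  int nkeep = 0;
  for (int g = burnin + sample_interval; g <= ngen; g += sample_interval) ++nkeep;
  vec out_gen(nkeep), out_lnl(nkeep), out_shape(nkeep);
  mat out_bl(nkeep, en.nedge);
  int ki = 0;
  long prop_bl = 0, acc_bl = 0, prop_sh = 0, acc_sh = 0;
  int gen = 0;
  Rcpp::RNGScope scope;
  auto maybe_record = [&]() {
    if (gen > burnin && (gen - burnin) % sample_interval == 0 && ki < nkeep) {
      out_gen(ki) = gen; out_lnl(ki) = lnl; out_shape(ki) = en.shape;
      out_bl.row(ki) = en.blen.t();
      ++ki;
    }
  };
  double p_shape_sweep = sample_shape
      ? std::min(1.0, p_shape_move * en.nedge / std::max(1e-9, 1.0 - p_shape_move))
      : 0.0;
  while (gen < ngen) {
    dfs_edges(en, ws, [&](Engine::EdgeCtx &ctx) {
      if (gen >= ngen) return;
      int e = ctx.e;
      double t0 = en.blen(e);
      double lnl0 = en.edge_lnl(ctx, t0);
      for (int mv = 0; mv < moves_per_edge && gen < ngen; ++mv) {
        ++gen; ++prop_bl;
        double t1 = t0 * std::exp(mult_lambda * (unif_rand() - 0.5));
        if (t1 >= bl_min && t1 <= bl_max) {
          double lnl1 = en.edge_lnl(ctx, t1);
          double logr = beta_power * (lnl1 - lnl0) +
                        bl_prior_rate * (t0 - t1) + std::log(t1 / t0);
          if (std::log(unif_rand()) < logr) {
            lnl += lnl1 - lnl0;
            t0 = t1; lnl0 = lnl1; ++acc_bl;
          }
        }
        maybe_record();
      }
      en.blen(e) = t0;
    });
    if (gen < ngen && sample_shape && unif_rand() < p_shape_sweep) {
      ++gen; ++prop_sh;
      double a0 = en.shape;
      double a1 = a0 + (unif_rand() - 0.5) * shape_window;
      while (a1 < shape_lo || a1 > shape_hi) {
        if (a1 < shape_lo) a1 = 2 * shape_lo - a1;
        if (a1 > shape_hi) a1 = 2 * shape_hi - a1;
      }
      en.set_shape(a1); en.full_update();
      double lnl1 = en.total_lnl();
      if (std::log(unif_rand()) < beta_power * (lnl1 - lnl)) {
        lnl = lnl1; ++acc_sh;
      } else { en.set_shape(a0); en.full_update(); lnl = en.total_lnl(); }
      maybe_record();
    }
    // re-sync against numerical drift once per sweep
    lnl = en.total_lnl();
  }
  return List::create(Named("gen") = out_gen, Named("lnl") = out_lnl,
                      Named("shape") = out_shape, Named("blens") = out_bl,
                      Named("acc_bl") = prop_bl ? double(acc_bl) / prop_bl : NA_REAL,
                      Named("acc_shape") = prop_sh ? double(acc_sh) / prop_sh : NA_REAL,
                      Named("final_lnl") = lnl);
}
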
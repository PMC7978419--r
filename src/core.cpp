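// Amino-acid pruning likelihood core for fixed topologies.
//
// Models: LG-type exchangeabilities with either a single stationary frequency
// vector or a K-profile mixture (one calibrated, reversible rate matrix per
// profile), crossed with equal-weight discrete-gamma rate categories.
//
// Trees arrive as ape-style postorder edge matrices (1-based node ids, tips
// 1..ntip).  Branch lengths are in expected substitutions per site; each
// profile's rate matrix is calibrated to unit expected rate at stationarity
// on the R side, and transition matrices are built from the symmetric
// eigendecomposition P(t) = V exp(Lambda t) Vi supplied per profile.
//
// Numerical conventions: per-node column rescaling with log offsets guards
// against underflow; transition-matrix entries are clamped at zero (they can
// go infinitesimally negative through roundoff); site patterns carry integer
// weights so alignments can be pattern-compressed upstream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Engine {
  int ntip, nnode, nedge, S, K, C, M;
  imat edge;                 // 0-based, postorder
  vec elen;
  imat tipcodes;             // ntip x S, 0 = missing, 1..20 = state
  std::vector<mat> V, Vi;    // per profile
  std::vector<vec> lam;      // per profile
  mat pimat;                 // 20 x K
  vec wk;                    // profile weights
  vec rates;                 // gamma category rates
  vec pw;                    // pattern weights
  int root;
  std::vector<std::vector<int> > child_edges;  // per node, edge indices

  void init(const Rcpp::IntegerMatrix& edge_, const Rcpp::NumericVector& elen_,
            int ntip_, const Rcpp::IntegerMatrix& tipcodes_,
            const Rcpp::List& V_, const Rcpp::List& Vi_, const Rcpp::List& lam_,
            const Rcpp::NumericMatrix& pimat_, const Rcpp::NumericVector& wk_,
            const Rcpp::NumericVector& rates_, const Rcpp::NumericVector& pw_) {
    nedge = edge_.nrow();
    edge.set_size(nedge, 2);
    for (int e = 0; e < nedge; ++e) {
      edge(e, 0) = edge_(e, 0) - 1;
      edge(e, 1) = edge_(e, 1) - 1;
    }
    elen = Rcpp::as<vec>(elen_);
    ntip = ntip_;
    S = tipcodes_.ncol();
    tipcodes.set_size(ntip, S);
    for (int i = 0; i < ntip; ++i)
      for (int s = 0; s < S; ++s) tipcodes(i, s) = tipcodes_(i, s);
    K = V_.size();
    for (int k = 0; k < K; ++k) {
      V.push_back(Rcpp::as<mat>(V_[k]));
      Vi.push_back(Rcpp::as<mat>(Vi_[k]));
      lam.push_back(Rcpp::as<vec>(lam_[k]));
    }
    pimat = Rcpp::as<mat>(pimat_);
    wk = Rcpp::as<vec>(wk_);
    rates = Rcpp::as<vec>(rates_);
    C = rates.n_elem;
    M = K * C;
    pw = Rcpp::as<vec>(pw_);
    nnode = edge.max() + 1;
    root = -1;
    std::vector<bool> is_child(nnode, false);
    for (int e = 0; e < nedge; ++e) is_child[edge(e, 1)] = true;
    for (int e = 0; e < nedge; ++e)
      if (!is_child[edge(e, 0)]) root = edge(e, 0);
    child_edges.assign(nnode, std::vector<int>());
    for (int e = 0; e < nedge; ++e) child_edges[edge(e, 0)].push_back(e);
  }

  int prof_of(int m) const { return m / C; }
  double rate_of(int m) const { return rates[m % C]; }

  void trans(mat& P, int k, double t) const {
    P = V[k] * diagmat(exp(lam[k] * t)) * Vi[k];
    P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  }

  // Message along edge e for combo m: scaled conditional of the subtree
  // below the edge's child, propagated across the edge.
  void edge_message(int e, int m, const mat& Dv, const rowvec& offDv,
                    mat& msg_out, rowvec& off_out) const {
    int v = edge(e, 1);
    int k = prof_of(m);
    mat P;
    trans(P, k, elen[e] * rate_of(m));
    if (v < ntip) {
      msg_out.set_size(20, S);
      for (int s = 0; s < S; ++s) {
        int code = tipcodes(v, s);
        if (code == 0)
          msg_out.col(s).ones();
        else
          msg_out.col(s) = P.col(code - 1);
      }
      off_out = rowvec(S, fill::zeros);
    } else {
      msg_out = P * Dv;
      rowvec cs = sum(msg_out, 0);
      cs.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
      msg_out.each_row() /= cs;
      off_out = offDv + log(cs);
    }
  }

  // Conditional (down) pass for one combo: per-edge messages and per-node
  // products of child messages.
  void down_pass(int m, std::vector<mat>& msg, std::vector<rowvec>& off,
                 std::vector<mat>& D, std::vector<rowvec>& offD) const {
    msg.assign(nedge, mat());
    off.assign(nedge, rowvec());
    D.assign(nnode, mat());
    offD.assign(nnode, rowvec());
    for (int e = 0; e < nedge; ++e) {
      int u = edge(e, 0), v = edge(e, 1);
      edge_message(e, m, D[v], offD[v], msg[e], off[e]);
      if (D[u].n_elem == 0) {
        D[u] = msg[e];
        offD[u] = off[e];
      } else {
        D[u] %= msg[e];
        offD[u] += off[e];
      }
    }
  }

  rowvec root_loglik(int m, const std::vector<mat>& D,
                     const std::vector<rowvec>& offD) const {
    rowvec l = pimat.col(prof_of(m)).t() * D[root];
    l.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
    return log(l) + offD[root];
  }

  // Full mixture log-likelihood; optionally per-profile pattern logliks.
  double loglik(mat* site_l = nullptr, mat* profile_l = nullptr) const {
    mat L(M, S);
    std::vector<mat> msg, D;
    std::vector<rowvec> off, offD;
    for (int m = 0; m < M; ++m) {
      down_pass(m, msg, off, D, offD);
      L.row(m) = root_loglik(m, D, offD);
    }
    if (profile_l != nullptr) {
      profile_l->set_size(K, S);
      for (int k = 0; k < K; ++k) {
        mat Lk = L.rows(k * C, k * C + C - 1);
        rowvec mx = max(Lk, 0);
        profile_l->row(k) =
            mx + log(sum(exp(Lk.each_row() - mx), 0)) - std::log((double)C);
      }
    }
    for (int k = 0; k < K; ++k)
      L.rows(k * C, k * C + C - 1) += std::log(wk[k] / C);
    rowvec mx = max(L, 0);
    rowvec sl = mx + log(sum(exp(L.each_row() - mx), 0));
    if (site_l != nullptr) *site_l = sl;
    return dot(pw, sl.t());
  }
};

// Brent's 1-D minimization on [a, b] (golden section + successive parabolic
// interpolation).
template <class F>
double brent_min(F f, double a, double b, double tol, int maxit,
                 double* fmin_out) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a);
  double w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int it = 0; it < maxit; ++it) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double rr = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * rr;
      q = 2.0 * (q - rr);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; w = u; fv = fw; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  if (fmin_out != nullptr) *fmin_out = fx;
  return x;
}

// Windowed minimization: search a bracket around the warm start and expand
// toward the global bounds while the optimum sticks to a window edge.
template <class F>
double windowed_min(F f, double lb, double ub, double x0, double tol,
                    double* fmin_out) {
  double lo = std::max(lb, std::min(x0 * 0.2, x0 - 0.02));
  double hi = std::min(ub, std::max(x0 * 5.0, x0 + 0.05));
  for (int round = 0; round < 6; ++round) {
    double fx;
    double x = brent_min(f, lo, hi, tol, 60, &fx);
    bool at_lo = (x - lo) < 2.0 * (tol * std::fabs(x) + 1e-10) && lo > lb;
    bool at_hi = (hi - x) < 2.0 * (tol * std::fabs(x) + 1e-10) && hi < ub;
    if (at_lo) {
      hi = x + (x - lo);
      lo = std::max(lb, lo * 0.05);
      continue;
    }
    if (at_hi) {
      lo = x - (hi - x);
      hi = std::min(ub, hi * 8.0);
      continue;
    }
    if (fmin_out != nullptr) *fmin_out = fx;
    return x;
  }
  double fx;
  double x = brent_min(f, lb, ub, tol, 80, &fx);
  if (fmin_out != nullptr) *fmin_out = fx;
  return x;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_lnl(Rcpp::IntegerMatrix edge, Rcpp::NumericVector elen,
                   int ntip, Rcpp::IntegerMatrix tipcodes, Rcpp::List V,
                   Rcpp::List Vi, Rcpp::List lam, Rcpp::NumericMatrix pimat,
                   Rcpp::NumericVector wk, Rcpp::NumericVector rates,
                   Rcpp::NumericVector pw, bool profile_loglik = false) {
  Engine en;
  en.init(edge, elen, ntip, tipcodes, V, Vi, lam, pimat, wk, rates, pw);
  mat site_l, prof_l;
  double lnl = en.loglik(&site_l, profile_loglik ? &prof_l : nullptr);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("lnl") = lnl,
      Rcpp::Named("site_lnl") = Rcpp::NumericVector(site_l.begin(),
                                                    site_l.end()));
  if (profile_loglik) out["profile_lnl"] = Rcpp::wrap(prof_l);
  return out;
}

// Coordinate-ascent branch-length optimization at fixed topology.
//
// Each pass runs a postorder sweep refreshing all conditional (down)
// messages, then a preorder sweep that maintains outside (up) partials and
// optimizes each free edge in place (Gauss-Seidel: ancestral-side partials
// always reflect the latest lengths; subtree-side messages are refreshed at
// the next pass).  The eigenbasis lets each candidate length be scored with
// one S x 20 matrix-vector product per mixture component.  The best length
// vector seen (including the input) is returned, so the reported lnL never
// falls below the starting lnL.
// [[Rcpp::export]]
Rcpp::List cpp_optimize_edges(Rcpp::IntegerMatrix edge,
                              Rcpp::NumericVector elen, int ntip,
                              Rcpp::IntegerMatrix tipcodes, Rcpp::List V,
                              Rcpp::List Vi, Rcpp::List lam,
                              Rcpp::NumericMatrix pimat,
                              Rcpp::NumericVector wk,
                              Rcpp::NumericVector rates,
                              Rcpp::NumericVector pw,
                              Rcpp::LogicalVector fixed, double lb, double ub,
                              double tol, int max_passes) {
  Engine en;
  en.init(edge, elen, ntip, tipcodes, V, Vi, lam, pimat, wk, rates, pw);
  const int M = en.M, S = en.S, nedge = en.nedge;

  vec logwm(M);
  for (int m = 0; m < M; ++m)
    logwm[m] = std::log(en.wk[en.prof_of(m)] / en.C);
  std::vector<vec> lamscale(M);
  for (int m = 0; m < M; ++m)
    lamscale[m] = en.lam[en.prof_of(m)] * en.rate_of(m);

  // Per-combo state shared between sweeps.
  std::vector<std::vector<mat> > msg(M), D(M), G(M);
  std::vector<std::vector<rowvec> > off(M), offD(M), offG(M);

  double best_lnl = -datum::inf, lnl0 = 0.0, prev_lnl = 0.0;
  vec best_elen = en.elen;
  bool converged = false;
  int pass;

  std::vector<mat> Cs(M);       // per-combo S x 20 flank summaries
  std::vector<rowvec> Bo(M);    // per-combo linear offsets
  mat P(20, 20);

  for (pass = 0; pass <= max_passes; ++pass) {
    // Postorder sweep: fresh messages + root likelihood.
    mat L(M, S);
    for (int m = 0; m < M; ++m) {
      en.down_pass(m, msg[m], off[m], D[m], offD[m]);
      L.row(m) = en.root_loglik(m, D[m], offD[m]) + logwm[m];
    }
    rowvec mx = max(L, 0);
    double lnl = dot(en.pw, (mx + log(sum(exp(L.each_row() - mx), 0))).t());
    if (pass == 0) lnl0 = lnl;
    if (lnl > best_lnl) {
      best_lnl = lnl;
      best_elen = en.elen;
    }
    if (pass > 0 && std::fabs(lnl - prev_lnl) < tol) {
      converged = true;
      break;
    }
    prev_lnl = lnl;
    if (pass == max_passes) break;

    // Preorder sweep: maintain outside partials, optimize edges in place.
    for (int m = 0; m < M; ++m) {
      G[m].assign(en.nnode, mat());
      offG[m].assign(en.nnode, rowvec());
      G[m][en.root] = repmat(en.pimat.col(en.prof_of(m)), 1, S);
      offG[m][en.root] = rowvec(S, fill::zeros);
    }
    for (int e = nedge - 1; e >= 0; --e) {
      int u = en.edge(e, 0), v = en.edge(e, 1);
      // Flank summaries under the current lengths.
      rowvec offmax(S);
      offmax.fill(-datum::inf);
      std::vector<rowvec> offs(M);
      for (int m = 0; m < M; ++m) {
        int k = en.prof_of(m);
        mat A = G[m][u];
        rowvec offA = offG[m][u];
        for (size_t j = 0; j < en.child_edges[u].size(); ++j) {
          int f = en.child_edges[u][j];
          if (f == e) continue;
          A %= msg[m][f];
          offA += off[m][f];
        }
        mat E1 = A.t() * en.V[k];
        mat E2(S, 20);
        if (v < en.ntip) {
          vec vio = sum(en.Vi[k], 1);
          for (int s = 0; s < S; ++s) {
            int code = en.tipcodes(v, s);
            if (code == 0)
              E2.row(s) = vio.t();
            else
              E2.row(s) = en.Vi[k].col(code - 1).t();
          }
          offs[m] = offA + logwm[m];
        } else {
          E2 = (en.Vi[k] * D[m][v]).t();
          offs[m] = offA + offD[m][v] + logwm[m];
        }
        Cs[m] = E1 % E2;
        offmax = max(offmax, offs[m]);
        G[m][v] = std::move(A);        // outside partial sans the edge
        offG[m][v] = offA;
      }
      if (!fixed[e]) {
        for (int m = 0; m < M; ++m) Bo[m] = exp(offs[m] - offmax);
        auto neg_lnl = [&](double t) {
          vec Ls(S, fill::zeros);
          for (int m = 0; m < M; ++m) {
            vec fvec = Cs[m] * exp(lamscale[m] * t);
            Ls += Bo[m].t() % fvec;
          }
          Ls.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
          return -dot(en.pw, log(Ls) + offmax.t());
        };
        en.elen[e] = windowed_min(neg_lnl, lb, ub, en.elen[e], 1e-5,
                                  nullptr);
      }
      // Refresh this edge's message (new length) and push the outside
      // partial through the edge for the subtree below.
      for (int m = 0; m < M; ++m) {
        en.edge_message(e, m, D[m][v], offD[m][v], msg[m][e], off[m][e]);
        if (v >= en.ntip) {
          en.trans(P, en.prof_of(m), en.elen[e] * en.rate_of(m));
          mat tmp = P.t() * G[m][v];
          rowvec cs = sum(tmp, 0);
          cs.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
          tmp.each_row() /= cs;
          G[m][v] = std::move(tmp);
          offG[m][v] += log(cs);
        }
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("elen") = Rcpp::NumericVector(best_elen.begin(),
                                                best_elen.end()),
      Rcpp::Named("lnl") = best_lnl, Rcpp::Named("lnl0") = lnl0,
      Rcpp::Named("passes") = pass, Rcpp::Named("converged") = converged);
}
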
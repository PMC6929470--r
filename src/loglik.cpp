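// Felsenstein pruning for MG94xHKY codon models.
//
// Entry points:
//  * cpp_siteloglik_matrix - per-site log-likelihood for a batch of
//    "configurations", each assigning one omega per edge (columns share an
//    eigendecomposition cache). This serves both the site-mixture
//    selection-intensity model (one configuration per omega category, with
//    omega^k on test edges) and the branch-site model (one configuration
//    per mixture component of the focal branch).
//  * cpp_edge_mixture_loglik - per-edge omega mixtures mixed independently
//    across edges (the assembled branch-site random-effects likelihood).
//
// Conventions: 61 sense codons; edges are passed in postorder (children
// before parents); node ids are 1-based ape ids (tips 1..ntip); edge
// lengths arrive already on the fit's branch-length scale. Tips with an
// unambiguous codon use a fast column-gather path; ambiguous or missing
// codons fall back to their 0/1 allowed-state row.

#include <RcppArmadillo.h>
#include <map>

using namespace arma;

static mat build_q(double kappa, double omega, const vec& pi,
                   const Rcpp::IntegerVector& ci, const Rcpp::IntegerVector& cj,
                   const Rcpp::IntegerVector& ts, const Rcpp::IntegerVector& ns) {
  mat Q(61, 61, fill::zeros);
  const int n = ci.size();
  for (int r = 0; r < n; ++r) {
    double f = (ts[r] ? kappa : 1.0) * (ns[r] ? omega : 1.0);
    const int i = ci[r], j = cj[r];
    Q(i, j) = f * pi(j);
    Q(j, i) = f * pi(i);
  }
  Q.diag() = -sum(Q, 1);
  return Q;
}

struct Eig {
  mat vec_;   // eigenvectors of the symmetrised generator
  arma::vec val_;
};

static Eig eig_reversible(const mat& Q, const vec& sqrt_pi) {
  mat S = Q;
  S.each_col() %= sqrt_pi;
  S.each_row() /= sqrt_pi.t();
  S = (S + S.t()) / 2.0;
  Eig e;
  eig_sym(e.val_, e.vec_, S);
  return e;
}

static mat pmat_from_eig(const Eig& e, double t, const vec& sqrt_pi) {
  mat P = e.vec_ * diagmat(exp(e.val_ * t)) * e.vec_.t();
  P.each_col() /= sqrt_pi;
  P.each_row() %= sqrt_pi.t();
  P.elem(find(P < 0)).zeros();
  return P;
}

// Prune with a prepared transition matrix per edge.
static vec prune(const std::vector<mat>& P,
                 const Rcpp::IntegerMatrix& edge,
                 const Rcpp::IntegerMatrix& tip_code,
                 const Rcpp::IntegerMatrix& tip_state,
                 const Rcpp::NumericMatrix& state_table,
                 const vec& pi, int root) {
  const int ntip = tip_code.nrow();
  const int npat = tip_code.ncol();
  const int nedge = edge.nrow();
  int maxnode = ntip;
  for (int e = 0; e < nedge; ++e)
    maxnode = std::max(maxnode, std::max(edge(e, 0), edge(e, 1)));

  std::vector<mat> partial(maxnode + 1);
  std::vector<bool> have(maxnode + 1, false);
  rowvec logscale(npat, fill::zeros);
  vec staterow(61);

  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0), ch = edge(e, 1);
    mat contrib(61, npat);
    if (ch <= ntip) {
      for (int s = 0; s < npat; ++s) {
        const int code = tip_code(ch - 1, s);
        if (code >= 0) {
          contrib.col(s) = P[e].col(code);
        } else {
          const int st = tip_state(ch - 1, s) - 1;
          for (int c = 0; c < 61; ++c) staterow(c) = state_table(st, c);
          contrib.col(s) = P[e] * staterow;
        }
      }
    } else {
      contrib = P[e] * partial[ch];
    }
    if (!have[par]) {
      partial[par] = contrib;
      have[par] = true;
    } else {
      partial[par] %= contrib;
      rowvec mx = max(partial[par], 0);
      if (mx.min() < 1e-220) {
        for (int s = 0; s < npat; ++s) {
          double m = mx(s);
          if (m > 0 && m < 1e-220) {
            partial[par].col(s) /= m;
            logscale(s) += std::log(m);
          }
        }
      }
    }
  }
  vec site = (pi.t() * partial[root]).t();
  vec out(npat);
  for (int s = 0; s < npat; ++s)
    out(s) = std::log(std::max(site(s), 1e-320)) + logscale(s);
  return out;
}

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat cpp_siteloglik_matrix(double kappa, const arma::vec& pi,
                                const Rcpp::IntegerVector& ci,
                                const Rcpp::IntegerVector& cj,
                                const Rcpp::IntegerVector& ts,
                                const Rcpp::IntegerVector& ns,
                                const Rcpp::IntegerMatrix& edge,
                                const arma::vec& edge_len,
                                const arma::mat& omega_configs,
                                const Rcpp::IntegerMatrix& tip_code,
                                const Rcpp::IntegerMatrix& tip_state,
                                const Rcpp::NumericMatrix& state_table,
                                int root) {
  const int nedge = edge.nrow();
  const int nconf = omega_configs.n_cols;
  const int npat = tip_code.ncol();
  vec sqrt_pi = sqrt(pi);
  std::map<double, Eig> cache;
  std::map<std::pair<double, double>, mat> pcache;
  mat out(npat, nconf);
  std::vector<mat> P(nedge);
  for (int cf = 0; cf < nconf; ++cf) {
    for (int e = 0; e < nedge; ++e) {
      const double w = omega_configs(e, cf);
      const std::pair<double, double> key(w, edge_len(e));
      auto pit = pcache.find(key);
      if (pit == pcache.end()) {
        auto it = cache.find(w);
        if (it == cache.end()) {
          it = cache.emplace(w, eig_reversible(
                   build_q(kappa, w, pi, ci, cj, ts, ns), sqrt_pi)).first;
        }
        pit = pcache.emplace(key,
                             pmat_from_eig(it->second, edge_len(e),
                                           sqrt_pi)).first;
      }
      P[e] = pit->second;
    }
    out.col(cf) = prune(P, edge, tip_code, tip_state, state_table, pi, root);
  }
  return out;
}

// Inside-outside cache for one focal edge under a fixed background: the
// inside partial I of the focal edge's child subtree and the outside
// partial O at its parent (everything else, root frequencies folded in),
// so that the site likelihood under any focal-edge transition matrix P* is
// sum_i sum_j O(i,s) P*(i,j) I(j,s) (times exp(scale_s)).
// [[Rcpp::export]]
Rcpp::List cpp_focal_edge_cache(double kappa, const arma::vec& pi,
                                const Rcpp::IntegerVector& ci,
                                const Rcpp::IntegerVector& cj,
                                const Rcpp::IntegerVector& ts,
                                const Rcpp::IntegerVector& ns,
                                const Rcpp::IntegerMatrix& edge,
                                const arma::vec& edge_len,
                                const arma::vec& edge_omega,
                                const Rcpp::IntegerMatrix& tip_code,
                                const Rcpp::IntegerMatrix& tip_state,
                                const Rcpp::NumericMatrix& state_table,
                                int root,
                                const Rcpp::IntegerVector& focal_edges) {
  const int ntip = tip_code.nrow();
  const int npat = tip_code.ncol();
  const int nedge = edge.nrow();
  vec sqrt_pi = sqrt(pi);
  std::map<double, Eig> cache;
  std::vector<mat> P(nedge);
  for (int e = 0; e < nedge; ++e) {
    const double w = edge_omega(e);
    auto it = cache.find(w);
    if (it == cache.end()) {
      it = cache.emplace(w, eig_reversible(
               build_q(kappa, w, pi, ci, cj, ts, ns), sqrt_pi)).first;
    }
    P[e] = pmat_from_eig(it->second, edge_len(e), sqrt_pi);
  }

  int maxnode = ntip;
  for (int e = 0; e < nedge; ++e)
    maxnode = std::max(maxnode, std::max(edge(e, 0), edge(e, 1)));

  // up pass: inside partials per internal node, upward messages per edge
  std::vector<mat> inside(maxnode + 1);
  std::vector<rowvec> iscale(maxnode + 1);
  std::vector<mat> msg(nedge);        // P_e x inside(child)
  std::vector<rowvec> mscale(nedge);  // log scale of msg
  std::vector<bool> have(maxnode + 1, false);
  vec staterow(61);
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0), ch = edge(e, 1);
    mat contrib(61, npat);
    if (ch <= ntip) {
      for (int s = 0; s < npat; ++s) {
        const int code = tip_code(ch - 1, s);
        if (code >= 0) {
          contrib.col(s) = P[e].col(code);
        } else {
          const int st = tip_state(ch - 1, s) - 1;
          for (int c = 0; c < 61; ++c) staterow(c) = state_table(st, c);
          contrib.col(s) = P[e] * staterow;
        }
      }
      // inside of a tip is its indicator; keep it for focal tips
      mscale[e] = rowvec(npat, fill::zeros);
    } else {
      contrib = P[e] * inside[ch];
      mscale[e] = iscale[ch];
    }
    msg[e] = contrib;
    if (!have[par]) {
      inside[par] = contrib;
      iscale[par] = mscale[e];
      have[par] = true;
    } else {
      inside[par] %= contrib;
      iscale[par] += mscale[e];
      rowvec mx = max(inside[par], 0);
      for (int s = 0; s < npat; ++s) {
        double m = mx(s);
        if (m > 0 && m < 1e-220) {
          inside[par].col(s) /= m;
          iscale[par](s) += std::log(m);
        }
      }
    }
  }

  // children edge lists per node (edge indices)
  std::vector<std::vector<int>> child_edges(maxnode + 1);
  std::vector<int> parent_edge(maxnode + 1, -1);
  for (int e = 0; e < nedge; ++e) {
    child_edges[edge(e, 0)].push_back(e);
    parent_edge[edge(e, 1)] = e;
  }

  // down pass: outside partial H per internal node (everything above the
  // node, root frequencies included), processed root-first
  std::vector<mat> H(maxnode + 1);
  std::vector<rowvec> hscale(maxnode + 1);
  H[root] = repmat(pi, 1, npat);
  hscale[root] = rowvec(npat, fill::zeros);
  for (int e = nedge - 1; e >= 0; --e) {  // reverse postorder = root-first
    const int par = edge(e, 0), ch = edge(e, 1);
    if (ch <= ntip) continue;  // outside partials kept at internal nodes
    mat above = H[par];
    rowvec asc = hscale[par];
    for (int f : child_edges[par]) {
      if (f == e) continue;
      above %= msg[f];
      asc += mscale[f];
    }
    rowvec mx = max(above, 0);
    for (int s = 0; s < npat; ++s) {
      double m = mx(s);
      if (m > 0 && m < 1e-220) { above.col(s) /= m; asc(s) += std::log(m); }
    }
    H[ch] = P[e].t() * above;  // propagate down through the edge
    hscale[ch] = asc;
  }

  // assemble the cache per focal edge (outside at the parent node)
  Rcpp::List out(focal_edges.size());
  for (int fi = 0; fi < focal_edges.size(); ++fi) {
    const int e = focal_edges[fi] - 1;
    const int par = edge(e, 0), ch = edge(e, 1);
    mat O = H[par];
    rowvec osc = hscale[par];
    for (int f : child_edges[par]) {
      if (f == e) continue;
      O %= msg[f];
      osc += mscale[f];
    }
    mat I;
    rowvec isc;
    if (ch <= ntip) {
      I.set_size(61, npat);
      for (int s = 0; s < npat; ++s) {
        const int code = tip_code(ch - 1, s);
        if (code >= 0) {
          I.col(s).zeros();
          I(code, s) = 1.0;
        } else {
          const int st = tip_state(ch - 1, s) - 1;
          for (int c = 0; c < 61; ++c) I(c, s) = state_table(st, c);
        }
      }
      isc = rowvec(npat, fill::zeros);
    } else {
      I = inside[ch];
      isc = iscale[ch];
    }
    out[fi] = Rcpp::List::create(
      Rcpp::Named("outside") = O,
      Rcpp::Named("inside") = I,
      Rcpp::Named("scale") = osc + isc,
      Rcpp::Named("t") = edge_len(e));
  }
  return out;
}

// Per-pattern log-likelihood columns for a focal edge: component m uses
// transition matrix P(omega_m) on the focal edge, everything else cached.
// [[Rcpp::export]]
arma::mat cpp_focal_loglik(double kappa, const arma::vec& pi,
                           const Rcpp::IntegerVector& ci,
                           const Rcpp::IntegerVector& cj,
                           const Rcpp::IntegerVector& ts,
                           const Rcpp::IntegerVector& ns,
                           const arma::vec& omegas, double t,
                           const arma::mat& outside,
                           const arma::mat& inside,
                           const arma::rowvec& scale) {
  const int npat = outside.n_cols;
  const int ncomp = omegas.n_elem;
  vec sqrt_pi = sqrt(pi);
  mat out(npat, ncomp);
  for (int m = 0; m < ncomp; ++m) {
    Eig e = eig_reversible(build_q(kappa, omegas(m), pi, ci, cj, ts, ns),
                           sqrt_pi);
    mat P = pmat_from_eig(e, t, sqrt_pi);
    mat X = P * inside;
    rowvec lik = sum(outside % X, 0);
    for (int s = 0; s < npat; ++s)
      out(s, m) = std::log(std::max(lik(s), 1e-320)) + scale(s);
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_edge_mixture_loglik(double kappa, const arma::vec& pi,
                                  const Rcpp::IntegerVector& ci,
                                  const Rcpp::IntegerVector& cj,
                                  const Rcpp::IntegerVector& ts,
                                  const Rcpp::IntegerVector& ns,
                                  const Rcpp::IntegerMatrix& edge,
                                  const arma::vec& edge_len,
                                  const arma::mat& edge_omega,
                                  const arma::mat& edge_weight,
                                  const Rcpp::IntegerMatrix& tip_code,
                                  const Rcpp::IntegerMatrix& tip_state,
                                  const Rcpp::NumericMatrix& state_table,
                                  int root) {
  const int nedge = edge.nrow();
  const int ncat = edge_omega.n_cols;
  vec sqrt_pi = sqrt(pi);
  std::map<double, Eig> cache;
  std::vector<mat> P(nedge);
  for (int e = 0; e < nedge; ++e) {
    mat Pe(61, 61, fill::zeros);
    for (int m = 0; m < ncat; ++m) {
      const double w = edge_weight(e, m);
      if (w <= 0) continue;
      const double om = edge_omega(e, m);
      auto it = cache.find(om);
      if (it == cache.end()) {
        it = cache.emplace(om, eig_reversible(
                 build_q(kappa, om, pi, ci, cj, ts, ns), sqrt_pi)).first;
      }
      Pe += w * pmat_from_eig(it->second, edge_len(e), sqrt_pi);
    }
    P[e] = Pe;
  }
  return prune(P, edge, tip_code, tip_state, state_table, pi, root);
}
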
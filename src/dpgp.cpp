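// Gibbs sampler for a Dirichlet-process mixture of Gaussian processes over
// gene temporal profiles (Neal's algorithm 8 with n_aux auxiliary clusters).
//
// Model: cluster mean function f ~ GP(0, K_l) with squared-exponential
// kernel K_l from a fixed length-scale grid; member profiles y = f + eps,
// eps ~ N(0, sn2 I). All computations run in the eigenbasis of K_l, where
// the per-eigendirection posterior and marginal likelihood are closed-form.
// Uses R's RNG so results are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Cluster {
  int m = 0;                 // member count
  arma::mat S;               // P x L sums of member projections, per scale
  double Q = 0.0;            // sum of squared norms of members
  int ls = 0;                // current length-scale index
  std::vector<int> members;  // gene indices (maintained lazily via rebuild)
};

// log predictive density of projection b (length P, under scale l) for a
// cluster with m members and projection sums s (column l of S)
static double pred_logdens(const arma::vec& b, const arma::vec& E,
                           const arma::vec& s, int m, double sn2) {
  // posterior variance v_j = E*sn2 / (sn2 + m E); mean mu_j = E*s / (sn2 + m E)
  arma::vec den = sn2 + m * E;
  arma::vec v = E * sn2 / den;
  arma::vec mu = (E % s) / den;
  arma::vec pv = v + sn2;
  return arma::accu(-0.5 * arma::log(2.0 * M_PI * pv) -
                    0.5 * arma::square(b - mu) / pv);
}

// marginal log-likelihood of a cluster's members under scale l
static double cluster_marglik(const arma::vec& E, const arma::vec& s,
                              int m, double Q, double sn2, int P) {
  arma::vec den = sn2 + m * E;
  double logdet = (m - 1) * P * std::log(sn2) + arma::accu(arma::log(den));
  double quad = Q / sn2 - arma::accu(E % arma::square(s) / (sn2 * den));
  return -0.5 * (m * P * std::log(2.0 * M_PI) + logdet + quad);
}

// [[Rcpp::export]]
List dpgp_gibbs_cpp(const arma::mat& Y, const List& eigU, const List& eigS,
                    double sn2, double alpha, int n_aux, int n_iter,
                    int burn, IntegerVector init) {
  const int G = Y.n_rows, P = Y.n_cols;
  const int L = eigU.size();
  std::vector<arma::mat> B(L);   // P x G projections per length-scale
  std::vector<arma::vec> E(L);   // eigenvalues per length-scale
  for (int l = 0; l < L; ++l) {
    arma::mat U = as<arma::mat>(eigU[l]);
    E[l] = arma::clamp(as<arma::vec>(eigS[l]), 1e-10, arma::datum::inf);
    B[l] = U.t() * Y.t();
  }
  arma::vec q(G);
  for (int i = 0; i < G; ++i) q(i) = arma::dot(Y.row(i), Y.row(i));
  // prior predictive per gene per scale (empty-cluster density)
  arma::mat P0(G, L);
  for (int l = 0; l < L; ++l) {
    arma::vec pv = E[l] + sn2;
    arma::vec c0 = -0.5 * arma::log(2.0 * M_PI * pv);
    for (int i = 0; i < G; ++i)
      P0(i, l) = arma::accu(c0 - 0.5 * arma::square(B[l].col(i)) / pv);
  }

  std::vector<Cluster> cl;
  arma::ivec z(G);
  // initialize from `init` (1-based labels) or all-in-one
  {
    std::map<int, int> relabel;
    for (int i = 0; i < G; ++i) {
      int lab = init.size() == G ? init[i] : 1;
      if (relabel.find(lab) == relabel.end()) {
        relabel[lab] = cl.size();
        Cluster c;
        c.S.zeros(P, L);
        cl.push_back(c);
      }
      int c = relabel[lab];
      z(i) = c;
      cl[c].m += 1;
      cl[c].Q += q(i);
      for (int l = 0; l < L; ++l) cl[c].S.col(l) += B[l].col(i);
    }
  }

  arma::mat cooc(G, G, arma::fill::zeros);
  int n_samples = 0;
  arma::vec trace(n_iter);
  double best_lp = -arma::datum::inf;
  arma::ivec best_z = z;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < G; ++i) {
      // remove gene i
      int ci = z(i);
      cl[ci].m -= 1;
      cl[ci].Q -= q(i);
      for (int l = 0; l < L; ++l) cl[ci].S.col(l) -= B[l].col(i);
      if (cl[ci].m == 0) {
        cl.erase(cl.begin() + ci);
        for (int j = 0; j < G; ++j) if (z(j) > ci) z(j) -= 1;
        z(i) = -1;
      }
      int K = cl.size();
      arma::vec logw(K + n_aux);
      for (int c = 0; c < K; ++c)
        logw(c) = std::log((double)cl[c].m) +
          pred_logdens(B[cl[c].ls].col(i), E[cl[c].ls],
                       cl[c].S.col(cl[c].ls), cl[c].m, sn2);
      arma::ivec aux_ls(n_aux);
      for (int a = 0; a < n_aux; ++a) {
        aux_ls(a) = std::min((int)(unif_rand() * L), L - 1);
        logw(K + a) = std::log(alpha / n_aux) + P0(i, aux_ls(a));
      }
      // sample from normalized weights
      logw -= logw.max();
      arma::vec wts = arma::exp(logw);
      double u = unif_rand() * arma::accu(wts);
      int pick = 0;
      double acc = wts(0);
      while (acc < u && pick + 1 < (int)wts.n_elem) acc += wts(++pick);
      int cnew;
      if (pick < K) {
        cnew = pick;
      } else {
        Cluster c;
        c.S.zeros(P, L);
        c.ls = aux_ls(pick - K);
        cl.push_back(c);
        cnew = K;
      }
      z(i) = cnew;
      cl[cnew].m += 1;
      cl[cnew].Q += q(i);
      for (int l = 0; l < L; ++l) cl[cnew].S.col(l) += B[l].col(i);
    }
    // resample per-cluster length-scales; accumulate joint log posterior
    double lp = cl.size() * std::log(alpha);
    for (size_t c = 0; c < cl.size(); ++c) {
      arma::vec ml(L);
      for (int l = 0; l < L; ++l)
        ml(l) = cluster_marglik(E[l], cl[c].S.col(l), cl[c].m, cl[c].Q,
                                sn2, P);
      arma::vec w = arma::exp(ml - ml.max());
      double u = unif_rand() * arma::accu(w);
      int pick = 0;
      double acc = w(0);
      while (acc < u && pick + 1 < L) acc += w(++pick);
      cl[c].ls = pick;
      lp += std::lgamma((double)cl[c].m) + ml(pick);
    }
    trace(it) = lp;
    if (it >= burn) {
      n_samples += 1;
      for (int i = 0; i < G; ++i)
        for (int j = i; j < G; ++j)
          if (z(i) == z(j)) { cooc(i, j) += 1; cooc(j, i) += (i != j); }
      if (lp > best_lp) {
        best_lp = lp;
        best_z = z;
      }
    }
  }
  if (n_samples > 0) cooc /= n_samples;
  return List::create(_["assignments"] = wrap(best_z + 1),
                      _["similarity"] = cooc,
                      _["loglik_trace"] = trace,
                      _["best_log_posterior"] = best_lp,
                      _["n_clusters"] = (int)cl.size());
}
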
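// Compact Bayesian additive regression trees (BART) sampler for binary
// outcomes via probit data augmentation.
//
// Model: y_i = 1{z_i > 0},  z_i ~ N(offset + sum_t g(x_i; T_t, M_t), 1).
// Tree structure prior: P(split at depth d) = alpha * (1 + d)^(-beta);
// split variable uniform over predictors, cutpoint uniform over a fixed
// per-variable grid. Leaf values mu ~ N(0, tau^2). The sampler is the
// standard Bayesian backfitting MCMC with birth/death structural moves and
// conjugate leaf updates; the latent z are redrawn from their truncated
// normal full conditional each iteration.
//
// Kept draws serialize every tree (split variable, cut value, children, leaf
// value) so the ensemble can score new data after fitting.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int var;      // split variable (-1 for leaf)
  double cut;   // split value: x < cut goes left
  int left, right, parent;
  int depth;
  double mu;    // leaf value (leaves only)
  bool active;
};

struct Tree {
  std::vector<Node> nodes;
  Tree() {
    nodes.push_back(Node{-1, 0.0, -1, -1, -1, 0, 0.0, true});
  }
  bool isLeaf(int i) const { return nodes[i].var < 0; }
  // node with two leaf children ("nog": no grandchildren)
  bool isNog(int i) const {
    const Node& nd = nodes[i];
    return nd.var >= 0 && nodes[nd.left].var < 0 && nodes[nd.right].var < 0;
  }
  void collect(std::vector<int>& leaves, std::vector<int>& nogs) const {
    leaves.clear(); nogs.clear();
    for (size_t i = 0; i < nodes.size(); ++i) {
      if (!nodes[i].active) continue;
      if (nodes[i].var < 0) leaves.push_back((int)i);
      else if (isNog((int)i)) nogs.push_back((int)i);
    }
  }
  int traverse(const double* x, int n, int i) const {
    int cur = 0;
    while (nodes[cur].var >= 0) {
      cur = (x[(size_t)nodes[cur].var * n + i] < nodes[cur].cut)
        ? nodes[cur].left : nodes[cur].right;
    }
    return cur;
  }
};

double psplit(double a, double b, int depth) {
  return a * std::pow(1.0 + depth, -b);
}

// log marginal likelihood contribution of one leaf (sigma = 1), dropping
// terms that cancel between competing partitions of the same points.
double leaf_lml(double n, double s, double tau2) {
  return -0.5 * std::log(1.0 + n * tau2) + tau2 * s * s / (2.0 * (1.0 + n * tau2));
}

double runif01() {
  double u = R::unif_rand();
  if (u <= 1e-12) u = 1e-12;
  if (u >= 1.0 - 1e-12) u = 1.0 - 1e-12;
  return u;
}

// N(mean, 1) truncated to (0, inf)
double rtnorm_pos(double mean) {
  double a = -mean;  // standardized lower bound
  double pup = R::pnorm(a, 0.0, 1.0, 0, 0);  // P(Z > a)
  double z = R::qnorm(runif01() * pup, 0.0, 1.0, 0, 0);
  if (!std::isfinite(z)) z = a + 1e-8;
  return mean + z;
}

}  // namespace

// [[Rcpp::export(name = ".bart_mcmc")]]
List bart_mcmc(NumericMatrix X, IntegerVector y, int m, int nskip, int ndraw,
               double alpha, double beta, double tau, int numcut,
               double offset) {
  const int n = X.nrow(), p = X.ncol();
  const double tau2 = tau * tau;
  const double* xp = X.begin();

  // per-variable uniform cut grids between min and max
  std::vector<std::vector<double> > cuts(p);
  for (int j = 0; j < p; ++j) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = xp[(size_t)j * n + i];
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    if (hi > lo) {
      cuts[j].resize(numcut);
      for (int t = 0; t < numcut; ++t) {
        cuts[j][t] = lo + (hi - lo) * (t + 1.0) / (numcut + 1.0);
      }
    }
  }

  std::vector<Tree> trees(m);
  std::vector<std::vector<int> > leafidx(m, std::vector<int>(n, 0));
  std::vector<std::vector<double> > treefit(m, std::vector<double>(n, 0.0));
  std::vector<double> allfit(n, 0.0), z(n);

  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    z[i] = (y[i] == 1) ? rtnorm_pos(offset) : -rtnorm_pos(-offset);
  }

  std::vector<int> leaves, nogs;
  std::vector<double> node_n, node_s;

  // serialized kept draws: draw, tree, node, var, cut, mu, left, right
  std::vector<double> flat;
  flat.reserve((size_t)ndraw * m * 40);
  std::vector<double> ftrain_sum(n, 0.0);

  const int total = nskip + ndraw;
  for (int iter = 0; iter < total; ++iter) {
    for (int t = 0; t < m; ++t) {
      Tree& tr = trees[t];
      std::vector<int>& lidx = leafidx[t];
      std::vector<double>& tfit = treefit[t];

      // sufficient stats of partial residuals r = z - offset - (allfit - tfit)
      size_t K = tr.nodes.size();
      node_n.assign(K, 0.0);
      node_s.assign(K, 0.0);
      for (int i = 0; i < n; ++i) {
        double r = z[i] - offset - (allfit[i] - tfit[i]);
        node_n[lidx[i]] += 1.0;
        node_s[lidx[i]] += r;
      }

      tr.collect(leaves, nogs);
      double p_birth = leaves.size() == 1 ? 1.0 : 0.5;
      bool do_birth = (R::unif_rand() < p_birth);

      if (do_birth) {
        int leaf = leaves[(int)(R::unif_rand() * leaves.size())];
        int var = (int)(R::unif_rand() * p);
        if (!cuts[var].empty()) {
          double cut = cuts[var][(int)(R::unif_rand() * cuts[var].size())];
          double nL = 0, sL = 0;
          for (int i = 0; i < n; ++i) {
            if (lidx[i] == leaf && xp[(size_t)var * n + i] < cut) {
              nL += 1.0;
              sL += z[i] - offset - (allfit[i] - tfit[i]);
            }
          }
          double nAll = node_n[leaf], sAll = node_s[leaf];
          double nR = nAll - nL, sR = sAll - sL;
          if (nL > 0 && nR > 0) {
            int d = tr.nodes[leaf].depth;
            double ps_d = psplit(alpha, beta, d), ps_c = psplit(alpha, beta, d + 1);
            // nog count after the birth
            int parent = tr.nodes[leaf].parent;
            int nog_new = (int)nogs.size() + 1;
            if (parent >= 0 && tr.isNog(parent)) nog_new -= 1;
            double p_death_new = 0.5;
            double lp = std::log(ps_d) + 2.0 * std::log(1.0 - ps_c) - std::log(1.0 - ps_d)
              + std::log(p_death_new) - std::log((double)nog_new)
              + std::log((double)leaves.size()) - std::log(p_birth)
              + leaf_lml(nL, sL, tau2) + leaf_lml(nR, sR, tau2)
              - leaf_lml(nAll, sAll, tau2);
            if (std::log(runif01()) < lp) {
              int li = (int)tr.nodes.size();
              tr.nodes.push_back(Node{-1, 0.0, -1, -1, leaf, d + 1, 0.0, true});
              int ri = (int)tr.nodes.size();
              tr.nodes.push_back(Node{-1, 0.0, -1, -1, leaf, d + 1, 0.0, true});
              tr.nodes[leaf].var = var;
              tr.nodes[leaf].cut = cut;
              tr.nodes[leaf].left = li;
              tr.nodes[leaf].right = ri;
              for (int i = 0; i < n; ++i) {
                if (lidx[i] == leaf) {
                  lidx[i] = (xp[(size_t)var * n + i] < cut) ? li : ri;
                }
              }
            }
          }
        }
      } else if (!nogs.empty()) {
        int nog = nogs[(int)(R::unif_rand() * nogs.size())];
        int li = tr.nodes[nog].left, ri = tr.nodes[nog].right;
        double nL = node_n[li], sL = node_s[li];
        double nR = node_n[ri], sR = node_s[ri];
        double nAll = nL + nR, sAll = sL + sR;
        int d = tr.nodes[nog].depth;
        double ps_d = psplit(alpha, beta, d), ps_c = psplit(alpha, beta, d + 1);
        double p_birth_new = (leaves.size() == 2) ? 1.0 : 0.5;
        double lp = std::log(1.0 - ps_d) - std::log(ps_d) - 2.0 * std::log(1.0 - ps_c)
          + std::log(p_birth_new) - std::log((double)(leaves.size() - 1))
          + std::log((double)nogs.size()) - std::log(0.5)
          + leaf_lml(nAll, sAll, tau2)
          - leaf_lml(nL, sL, tau2) - leaf_lml(nR, sR, tau2);
        if (std::log(runif01()) < lp) {
          tr.nodes[li].active = false;
          tr.nodes[ri].active = false;
          tr.nodes[nog].var = -1;
          tr.nodes[nog].left = tr.nodes[nog].right = -1;
          for (int i = 0; i < n; ++i) {
            if (lidx[i] == li || lidx[i] == ri) lidx[i] = nog;
          }
        }
      }

      // conjugate leaf draws, then refresh fits
      K = tr.nodes.size();
      node_n.assign(K, 0.0);
      node_s.assign(K, 0.0);
      for (int i = 0; i < n; ++i) {
        double r = z[i] - offset - (allfit[i] - tfit[i]);
        node_n[lidx[i]] += 1.0;
        node_s[lidx[i]] += r;
      }
      for (size_t k = 0; k < K; ++k) {
        Node& nd = tr.nodes[k];
        if (!nd.active || nd.var >= 0) continue;
        double denom = 1.0 + node_n[k] * tau2;
        nd.mu = tau2 * node_s[k] / denom + std::sqrt(tau2 / denom) * R::norm_rand();
      }
      for (int i = 0; i < n; ++i) {
        double newfit = tr.nodes[lidx[i]].mu;
        allfit[i] += newfit - tfit[i];
        tfit[i] = newfit;
      }
    }

    // latent z full conditional
    for (int i = 0; i < n; ++i) {
      double mean = offset + allfit[i];
      z[i] = (y[i] == 1) ? rtnorm_pos(mean) : -rtnorm_pos(-mean);
    }

    if (iter >= nskip) {
      int draw = iter - nskip;
      for (int i = 0; i < n; ++i) ftrain_sum[i] += allfit[i];
      for (int t = 0; t < m; ++t) {
        const Tree& tr = trees[t];
        // remap active node ids to a dense 0..K-1 range
        std::vector<int> remap(tr.nodes.size(), -1);
        int kk = 0;
        for (size_t k = 0; k < tr.nodes.size(); ++k) {
          if (tr.nodes[k].active) remap[k] = kk++;
        }
        for (size_t k = 0; k < tr.nodes.size(); ++k) {
          const Node& nd = tr.nodes[k];
          if (!nd.active) continue;
          flat.push_back(draw);
          flat.push_back(t);
          flat.push_back(remap[k]);
          flat.push_back(nd.var);
          flat.push_back(nd.cut);
          flat.push_back(nd.var < 0 ? nd.mu : 0.0);
          flat.push_back(nd.var < 0 ? -1 : remap[nd.left]);
          flat.push_back(nd.var < 0 ? -1 : remap[nd.right]);
        }
      }
    }
  }
  PutRNGstate();

  NumericMatrix flat_mat((int)(flat.size() / 8), 8);
  for (size_t r = 0; r < flat.size() / 8; ++r) {
    for (int c = 0; c < 8; ++c) flat_mat((int)r, c) = flat[r * 8 + c];
  }
  NumericVector ftrain(n);
  for (int i = 0; i < n; ++i) ftrain[i] = ftrain_sum[i] / ndraw;

  return List::create(_["trees"] = flat_mat, _["ndraw"] = ndraw, _["m"] = m,
                      _["offset"] = offset, _["ftrain_mean"] = ftrain);
}

// Score new data with a serialized ensemble: returns ndraw x nnew matrix of
// latent function values (excluding the offset).
// [[Rcpp::export(name = ".bart_score")]]
NumericMatrix bart_score(NumericMatrix flat, int ndraw, int m, NumericMatrix X) {
  const int n = X.nrow();
  const double* xp = X.begin();
  const int nxn = n;
  NumericMatrix out(ndraw, n);

  // rows are grouped by (draw, tree) in serialization order
  int r = 0;
  const int R = flat.nrow();
  while (r < R) {
    int draw = (int)flat(r, 0), tree = (int)flat(r, 1);
    int start = r;
    while (r < R && (int)flat(r, 0) == draw && (int)flat(r, 1) == tree) ++r;
    int K = r - start;
    // nodes are stored with node-id column equal to their dense index
    std::vector<int> var(K), left(K), right(K);
    std::vector<double> cut(K), mu(K);
    for (int k = 0; k < K; ++k) {
      int id = (int)flat(start + k, 2);
      var[id] = (int)flat(start + k, 3);
      cut[id] = flat(start + k, 4);
      mu[id] = flat(start + k, 5);
      left[id] = (int)flat(start + k, 6);
      right[id] = (int)flat(start + k, 7);
    }
    for (int i = 0; i < n; ++i) {
      int cur = 0;
      while (var[cur] >= 0) {
        cur = (xp[(size_t)var[cur] * nxn + i] < cut[cur]) ? left[cur] : right[cur];
      }
      out(draw, i) += mu[cur];
    }
  }
  return out;
}
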
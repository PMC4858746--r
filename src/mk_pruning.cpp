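#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for the two-state Mk model with per-edge rates.
//
// The 2x2 transition probability matrix has the closed form
//   P(t) = Pi + (I - Pi) * exp(-(q01+q10) t),
// where Pi has identical rows (pi0, pi1), pi1 = q01/(q01+q10).
// Edges must be supplied in postorder (children before parents), as
// produced by ape::reorder.phylo(tree, "postorder"). Node numbering is
// ape's: tips 1..ntip, root ntip+1.

static inline void ptrans(double q01, double q10, double t, double P[2][2]) {
  const double s = q01 + q10;
  if (s <= 0.0 || t <= 0.0) {
    P[0][0] = 1.0; P[0][1] = 0.0; P[1][0] = 0.0; P[1][1] = 1.0;
    return;
  }
  const double e = std::exp(-s * t);
  const double pi1 = q01 / s, pi0 = q10 / s;
  P[0][0] = pi0 + pi1 * e;
  P[0][1] = pi1 - pi1 * e;
  P[1][0] = pi0 - pi0 * e;
  P[1][1] = pi1 + pi0 * e;
}

// [[Rcpp::export]]
List mk_pruning_cpp(IntegerMatrix edge, NumericVector elen,
                    NumericVector q01, NumericVector q10,
                    IntegerVector tip_state, int n_node,
                    NumericVector root_prior, bool partials_out) {
  const int ntip = tip_state.size();
  const int ntot = ntip + n_node;
  const int nedge = edge.nrow();
  std::vector<double> L0(ntot, -1.0), L1(ntot, -1.0);
  double logscale = 0.0;

  for (int i = 0; i < ntip; ++i) {
    L0[i] = tip_state[i] == 0 ? 1.0 : 0.0;
    L1[i] = tip_state[i] == 1 ? 1.0 : 0.0;
    if (tip_state[i] == NA_INTEGER) { L0[i] = 1.0; L1[i] = 1.0; }
  }

  double P[2][2];
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    ptrans(q01[e], q10[e], elen[e], P);
    const double m0 = P[0][0] * L0[ch] + P[0][1] * L1[ch];
    const double m1 = P[1][0] * L0[ch] + P[1][1] * L1[ch];
    if (L0[par] < 0.0) { L0[par] = m0; L1[par] = m1; }
    else { L0[par] *= m0; L1[par] *= m1; }
    const double sc = L0[par] + L1[par];
    if (sc > 0.0 && sc < 1e-100) {
      L0[par] /= sc; L1[par] /= sc;
      logscale += std::log(sc);
    }
  }

  const int root = ntip; // ape root index (1-based ntip+1)
  const double lik = root_prior[0] * L0[root] + root_prior[1] * L1[root];
  const double ll = lik > 0.0 ? std::log(lik) + logscale : R_NegInf;

  if (!partials_out) return List::create(_["loglik"] = ll);

  NumericMatrix part(ntot, 2);
  for (int i = 0; i < ntot; ++i) {
    double a = L0[i] < 0.0 ? 1.0 : L0[i];
    double b = L1[i] < 0.0 ? 1.0 : L1[i];
    const double s = a + b;
    if (s > 0.0) { a /= s; b /= s; }
    part(i, 0) = a;
    part(i, 1) = b;
  }
  return List::create(_["loglik"] = ll, _["partials"] = part);
}
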
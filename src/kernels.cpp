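// Performance kernels for the autodiff tape: segmented argmax, dense
// multi-head attention, and edge-restricted channel-wise attention.
// Each mirrors a pure-R formulation validated against naive oracles in the
// test suite; these exist because the training loop is interpreter-bound.

#include <Rcpp.h>
using namespace Rcpp;

// per-(group, column) argmax; ties resolve to the lowest row index.
// groups are 1-based; rows absent from a group leave 0.
// [[Rcpp::export]]
IntegerMatrix cpp_seg_argmax(const NumericMatrix& x,
                             const IntegerVector& groups, int n_out) {
  const int n = x.nrow(), d = x.ncol();
  IntegerMatrix arg(n_out, d);
  for (int c = 0; c < d; ++c) {
    std::vector<double> best(n_out, R_NegInf);
    for (int r = 0; r < n; ++r) {
      const int g = groups[r] - 1;
      const double v = x(r, c);
      if (v > best[g]) {
        best[g] = v;
        arg(g, c) = r + 1;
      }
    }
  }
  return arg;
}

// edge-restricted channel-wise attention forward: per edge e = (i <- j)
// and channel c, score = Q(i,c) K(j,c) E(e,c) * scale; softmax over the
// edges sharing a target i, independently per channel; message is the
// attention-weighted sum of V(j,c).  Returns rbind(msg, W).
// [[Rcpp::export]]
NumericMatrix cpp_edge_attn_forward(const NumericMatrix& Q,
                                    const NumericMatrix& K,
                                    const NumericMatrix& V,
                                    const NumericMatrix& E,
                                    const IntegerVector& ii,
                                    const IntegerVector& jj,
                                    int n, double scale) {
  const int ne = E.nrow(), d = Q.ncol();
  NumericMatrix out(n + ne, d);
  std::vector<double> mx(n), denom(n);
  std::vector<double> s(ne);
  for (int c = 0; c < d; ++c) {
    std::fill(mx.begin(), mx.end(), R_NegInf);
    for (int e = 0; e < ne; ++e) {
      const int i = ii[e] - 1, j = jj[e] - 1;
      s[e] = Q(i, c) * K(j, c) * E(e, c) * scale;
      if (s[e] > mx[i]) mx[i] = s[e];
    }
    std::fill(denom.begin(), denom.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      const int i = ii[e] - 1;
      s[e] = std::exp(s[e] - mx[i]);
      denom[i] += s[e];
    }
    for (int e = 0; e < ne; ++e) {
      const int i = ii[e] - 1, j = jj[e] - 1;
      const double w = s[e] / denom[i];
      out(n + e, c) = w;
      out(i, c) += w * V(j, c);
    }
  }
  return out;
}

// backward of cpp_edge_attn_forward; gmsg is the gradient on the messages
// (n x d), gw the gradient on the attention weights (ne x d).
// [[Rcpp::export]]
List cpp_edge_attn_backward(const NumericMatrix& gmsg,
                            const NumericMatrix& gw,
                            const NumericMatrix& W,
                            const NumericMatrix& Q,
                            const NumericMatrix& K,
                            const NumericMatrix& V,
                            const NumericMatrix& E,
                            const IntegerVector& ii,
                            const IntegerVector& jj,
                            int n, double scale) {
  const int ne = E.nrow(), d = Q.ncol();
  NumericMatrix gQ(n, d), gK(n, d), gV(n, d), gE(ne, d);
  std::vector<double> gWtot(ne), sred(n);
  for (int c = 0; c < d; ++c) {
    for (int e = 0; e < ne; ++e) {
      const int i = ii[e] - 1, j = jj[e] - 1;
      gWtot[e] = gw(e, c) + gmsg(i, c) * V(j, c);
    }
    std::fill(sred.begin(), sred.end(), 0.0);
    for (int e = 0; e < ne; ++e) sred[ii[e] - 1] += W(e, c) * gWtot[e];
    for (int e = 0; e < ne; ++e) {
      const int i = ii[e] - 1, j = jj[e] - 1;
      const double gS = W(e, c) * (gWtot[e] - sred[i]) * scale;
      gQ(i, c) += gS * K(j, c) * E(e, c);
      gK(j, c) += gS * Q(i, c) * E(e, c);
      gE(e, c) = gS * Q(i, c) * K(j, c);
      gV(j, c) += W(e, c) * gmsg(i, c);
    }
  }
  return List::create(_["gQ"] = gQ, _["gK"] = gK, _["gV"] = gV,
                      _["gE"] = gE);
}
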
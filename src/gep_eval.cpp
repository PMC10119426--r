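#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Guarded arithmetic shared with the R-level interpreter: every node output
// is clamped to +/- 1e6 and near-zero denominators saturate to 1e6.
static const double GUARD_EPS = 1e-12;
static const double CLAMP = 1e6;

static inline double clampv(double v) {
  if (v > CLAMP) return CLAMP;
  if (v < -CLAMP) return -CLAMP;
  return v;
}

// Evaluate one Karva gene (level-order encoded) over all data rows.
// codes: gene symbols; values: scratch (n_nodes x n rows); out: length n.
static void eval_gene(const int* codes, int glen, const NumericMatrix& X,
                      const IntegerVector& arity, int n_funcs,
                      std::vector<std::vector<double> >& values,
                      std::vector<double>& out) {
  const int n = X.nrow();
  // number of nodes actually used by the tree
  int needed = 1;
  for (int i = 0; i < needed; ++i) {
    if (i >= glen) stop("malformed gene: decoding overruns gene length");
    int c = codes[i];
    if (c <= n_funcs) needed += arity[c - 1];
  }
  // children start offsets in level order
  std::vector<int> kid(needed, -1);
  int nxt = 1;
  for (int i = 0; i < needed; ++i) {
    int c = codes[i];
    if (c <= n_funcs) {
      kid[i] = nxt;
      nxt += arity[c - 1];
    }
  }
  if ((int)values.size() < needed) values.resize(needed);
  for (int i = 0; i < needed; ++i)
    if ((int)values[i].size() != n) values[i].assign(n, 0.0);
  // back-to-front evaluation
  for (int i = needed - 1; i >= 0; --i) {
    int c = codes[i];
    std::vector<double>& v = values[i];
    if (c > n_funcs) {
      int col = c - n_funcs - 1;
      for (int r = 0; r < n; ++r) v[r] = X(r, col);
      continue;
    }
    const std::vector<double>& a = values[kid[i]];
    switch (c) {
    case 1: { const std::vector<double>& b = values[kid[i] + 1];
      for (int r = 0; r < n; ++r) v[r] = clampv(a[r] + b[r]); break; }
    case 2: { const std::vector<double>& b = values[kid[i] + 1];
      for (int r = 0; r < n; ++r) v[r] = clampv(a[r] - b[r]); break; }
    case 3: { const std::vector<double>& b = values[kid[i] + 1];
      for (int r = 0; r < n; ++r) v[r] = clampv(a[r] * b[r]); break; }
    case 4: { const std::vector<double>& b = values[kid[i] + 1];
      for (int r = 0; r < n; ++r)
        v[r] = clampv(std::fabs(b[r]) < GUARD_EPS ? CLAMP : a[r] / b[r]);
      break; }
    case 5:
      for (int r = 0; r < n; ++r)
        v[r] = clampv(std::fabs(a[r]) < GUARD_EPS ? CLAMP : 1.0 / a[r]);
      break;
    case 6:
      for (int r = 0; r < n; ++r) v[r] = std::cos(a[r]);
      break;
    case 7:
      for (int r = 0; r < n; ++r) v[r] = clampv(std::tan(a[r]));
      break;
    default:
      stop("unknown function code");
    }
  }
  out.assign(values[0].begin(), values[0].end());
}

//' Evaluate an integer-coded GEP population over a data matrix
//'
//' Low-level work-horse behind [gep_evolve()]: decodes every chromosome
//' (level-order Karva reading) and evaluates it on all rows of `X` with the
//' same guarded arithmetic as [evaluate_tree()].  Exposed so the R-level
//' interpreter can be cross-checked against it.
//'
//' @param pop Integer matrix, one chromosome per row (function codes
//'   1..7 in function-set order, terminal codes 8..7+ncol(X)).
//' @param X Numeric matrix of terminal values (rows = observations).
//' @param arity Integer vector of function arities in function-set order.
//' @param head Gene head length.
//' @param glen Gene length (head + tail).
//' @param ngenes Genes per chromosome.
//' @param link_code 0 for "+" linking, 1 for "*".
//' @return Numeric matrix, observations x individuals, of model values.
//' @export
// [[Rcpp::export]]
NumericMatrix gep_eval_population(IntegerMatrix pop, NumericMatrix X,
                                  IntegerVector arity, int head, int glen,
                                  int ngenes, int link_code) {
  const int npop = pop.nrow(), n = X.nrow(), n_funcs = arity.size();
  if (pop.ncol() != glen * ngenes)
    stop("chromosome length does not match glen * ngenes");
  NumericMatrix out(n, npop);
  std::vector<std::vector<double> > scratch;
  std::vector<double> gene_val, acc(n);
  std::vector<int> codes(glen);
  for (int ind = 0; ind < npop; ++ind) {
    for (int g = 0; g < ngenes; ++g) {
      for (int j = 0; j < glen; ++j) codes[j] = pop(ind, g * glen + j);
      eval_gene(codes.data(), glen, X, arity, n_funcs, scratch, gene_val);
      if (g == 0) {
        for (int r = 0; r < n; ++r) acc[r] = gene_val[r];
      } else if (link_code == 0) {
        for (int r = 0; r < n; ++r) acc[r] = clampv(acc[r] + gene_val[r]);
      } else {
        for (int r = 0; r < n; ++r) acc[r] = clampv(acc[r] * gene_val[r]);
      }
    }
    for (int r = 0; r < n; ++r) out(r, ind) = acc[r];
  }
  return out;
}
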
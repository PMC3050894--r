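#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming (Gotoh) over a precomputed cell score matrix.
// Rows index sequence/profile A, columns index B. A gap of length L costs
// gap_open + L * gap_extend (BLAST convention). Three states:
//   M  : A[i] aligned to B[j]
//   GA : gap in A (consumes B[j])
//   GB : gap in B (consumes A[i])
// Tie preference everywhere: M > GA > GB.
//
// Returns list(score, ops, a_start, a_end, b_start, b_end) where ops is the
// alignment path from left to right: 1 = aligned pair, 2 = gap in A,
// 3 = gap in B. Ranges are 1-based inclusive over consumed residues
// (empty ranges encoded as start > end). For local alignments an empty
// optimal alignment yields score 0 and an empty ops vector.

static const double NEG_INF = -1e300;
static const double EPS = 1e-9;

static inline bool feq(double a, double b) { return std::abs(a - b) < EPS; }

// [[Rcpp::export(name = ".gotoh_dp")]]
List gotoh_dp(NumericMatrix scores, double gap_open, double gap_extend,
              bool local) {
  const int n = scores.nrow(), m = scores.ncol();
  const double open_cost = gap_open + gap_extend;

  if (n == 0 || m == 0) {
    // degenerate: one side empty; global alignment is all-gap
    int len = local ? 0 : (n + m);
    IntegerVector ops_out(len);
    for (int k = 0; k < len; ++k) ops_out[k] = (m > 0) ? 2 : 3;
    double sc = local ? 0.0 : (len > 0 ? -(gap_open + len * gap_extend) : 0.0);
    return List::create(_["score"] = sc, _["ops"] = ops_out,
                        _["a_start"] = 1, _["a_end"] = n,
                        _["b_start"] = 1, _["b_end"] = m);
  }

  NumericMatrix M(n + 1, m + 1), GA(n + 1, m + 1), GB(n + 1, m + 1);

  M(0, 0) = 0.0;
  GA(0, 0) = NEG_INF;
  GB(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    GA(i, 0) = NEG_INF;
    GB(i, 0) = local ? NEG_INF : -(gap_open + i * gap_extend);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    GA(0, j) = local ? NEG_INF : -(gap_open + j * gap_extend);
    GB(0, j) = NEG_INF;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(M(i - 1, j - 1),
                             std::max(GA(i - 1, j - 1), GB(i - 1, j - 1)));
      if (local) diag = std::max(diag, 0.0);
      M(i, j) = (diag <= NEG_INF / 2) ? NEG_INF : diag + scores(i - 1, j - 1);

      double ga = std::max(M(i, j - 1) - open_cost,
                           std::max(GA(i, j - 1) - gap_extend,
                                    GB(i, j - 1) - open_cost));
      GA(i, j) = (ga <= NEG_INF / 2) ? NEG_INF : ga;

      double gb = std::max(M(i - 1, j) - open_cost,
                           std::max(GA(i - 1, j) - open_cost,
                                    GB(i - 1, j) - gap_extend));
      GB(i, j) = (gb <= NEG_INF / 2) ? NEG_INF : gb;

      if (local && M(i, j) > best + EPS) {
        best = M(i, j);
        best_i = i;
        best_j = j;
      }
    }
  }

  int i, j, state; // state: 0 = M, 1 = GA, 2 = GB
  double score;

  if (local) {
    score = best;
    if (best <= EPS) {
      return List::create(_["score"] = 0.0, _["ops"] = IntegerVector(0),
                          _["a_start"] = 1, _["a_end"] = 0,
                          _["b_start"] = 1, _["b_end"] = 0);
    }
    i = best_i;
    j = best_j;
    state = 0;
  } else {
    i = n;
    j = m;
    double vm = M(n, m), va = GA(n, m), vb = GB(n, m);
    if (vm >= va - EPS && vm >= vb - EPS) {
      state = 0;
      score = vm;
    } else if (va >= vb - EPS) {
      state = 1;
      score = va;
    } else {
      state = 2;
      score = vb;
    }
  }

  std::vector<int> ops;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double need = M(i, j) - scores(i - 1, j - 1);
      ops.push_back(1);
      --i;
      --j;
      if (local && need < EPS) break; // local alignment starts here
      if (i == 0 && j == 0) break;    // global origin (need == M(0,0) == 0)
      if (feq(M(i, j), need)) state = 0;
      else if (feq(GA(i, j), need)) state = 1;
      else state = 2;
    } else if (state == 1) {
      double v = GA(i, j);
      ops.push_back(2);
      --j;
      if (i == 0 && j == 0) break;
      if (feq(M(i, j), v + open_cost)) state = 0;
      else if (feq(GA(i, j), v + gap_extend)) state = 1;
      else state = 2;
    } else {
      double v = GB(i, j);
      ops.push_back(3);
      --i;
      if (i == 0 && j == 0) break;
      if (feq(M(i, j), v + open_cost)) state = 0;
      else if (feq(GA(i, j), v + open_cost)) state = 1;
      else state = 2;
    }
  }
  std::reverse(ops.begin(), ops.end());

  int na = 0, nb = 0;
  for (size_t k = 0; k < ops.size(); ++k) {
    if (ops[k] != 2) ++na;
    if (ops[k] != 3) ++nb;
  }
  IntegerVector ops_out(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = ops_out,
                      _["a_start"] = i + 1, _["a_end"] = i + na,
                      _["b_start"] = j + 1, _["b_end"] = j + nb);
}
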
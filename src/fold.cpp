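// Simplified nested RNA secondary-structure dynamic program scored with
// nearest-neighbor stack terms only (no loop or multiloop penalties): the
// energy of a structure is the sum of stack terms over adjacent stacked
// pairs. Supports a per-position "must stay unpaired" constraint, which can
// only remove structures, so the constrained MFE is never below the
// unconstrained one.
#include <Rcpp.h>
using namespace Rcpp;

// bases encoded 0=A 1=C 2=G 3=T/U, -1 = other (never pairs)
// pair types 1..6 = AT TA CG GC GT TG, 0 = no pair
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 1) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq, LogicalVector blocked,
                  NumericVector stack36, int min_hairpin,
                  bool traceback) {
  const int n = seq.size();
  // stack36 is a 6x6 matrix (column-major) indexed by pair types 1..6
  auto stk = [&](int p, int q) { return stack36[(q - 1) * 6 + (p - 1)]; };
  auto can_pair = [&](int i, int j) {
    if (blocked[i] || blocked[j]) return 0;
    if (j - i - 1 < min_hairpin) return 0;
    return pair_type(seq[i], seq[j]);
  };

  if (n == 0)
    return List::create(_["energy"] = 0.0, _["structure"] = "");

  NumericMatrix W(n, n), V(n, n);
  std::fill(V.begin(), V.end(), R_PosInf);

  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pt = can_pair(i, j);
      if (pt > 0) {
        double v = 0.0;  // hairpin closed by (i,j): no loop penalty
        int ptin = (j - 1 > i + 1) ? can_pair(i + 1, j - 1) : 0;
        if (ptin > 0 && V(i + 1, j - 1) < R_PosInf) {
          double s = V(i + 1, j - 1) + stk(pt, ptin);
          if (s < v) v = s;
        }
        if (j - 1 >= i + 1) {
          double s = W(i + 1, j - 1);  // close a non-stacked interior
          if (s < v) v = s;
        }
        V(i, j) = v;
      }
      double w = W(i + 1, j);                     // i unpaired
      double w2 = W(i, j - 1);                    // j unpaired
      if (w2 < w) w = w2;
      if (pt > 0 && V(i, j) < w) w = V(i, j);     // (i,j) paired
      for (int k = i + 1; k < j; ++k) {           // bifurcation
        double s = W(i, k) + W(k + 1, j);
        if (s < w) w = s;
      }
      W(i, j) = w;
    }
  }

  double mfe = W(0, n - 1);
  if (!traceback)
    return List::create(_["energy"] = mfe, _["structure"] = NA_STRING);

  std::string db(n, '.');
  std::vector<std::array<int, 3>> work;  // (i, j, in_V)
  work.push_back({0, n - 1, 0});
  const double eps = 1e-9;
  while (!work.empty()) {
    auto t = work.back(); work.pop_back();
    int i = t[0], j = t[1], inV = t[2];
    if (i >= j) continue;
    if (!inV) {
      double w = W(i, j);
      if (std::fabs(W(i + 1, j) - w) < eps) { work.push_back({i + 1, j, 0}); continue; }
      if (std::fabs(W(i, j - 1) - w) < eps) { work.push_back({i, j - 1, 0}); continue; }
      bool done = false;
      for (int k = i + 1; k < j && !done; ++k) {
        if (std::fabs(W(i, k) + W(k + 1, j) - w) < eps) {
          work.push_back({i, k, 0});
          work.push_back({k + 1, j, 0});
          done = true;
        }
      }
      if (done) continue;
      // must be V(i,j)
      work.push_back({i, j, 1});
    } else {
      db[i] = '('; db[j] = ')';
      double v = V(i, j);
      int pt = can_pair(i, j);
      int ptin = (j - 1 > i + 1) ? can_pair(i + 1, j - 1) : 0;
      if (ptin > 0 && V(i + 1, j - 1) < R_PosInf &&
          std::fabs(V(i + 1, j - 1) + stk(pt, ptin) - v) < eps) {
        work.push_back({i + 1, j - 1, 1});
      } else if (std::fabs(v) < eps) {
        // hairpin: nothing inside
      } else {
        work.push_back({i + 1, j - 1, 0});
      }
    }
  }
  return List::create(_["energy"] = mfe, _["structure"] = db);
}
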
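#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <stack>
using namespace Rcpp;

// Pair classes: 0 = not pairable, 1 = GU wobble, 2 = AU, 3 = GC.
// Sequences arrive uppercase, DNA alphabet (U already mapped to T).
static inline int pair_code(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Energy of two stacked adjacent pairs. Weakest pair in the stack decides:
// any GU -> -1.0, else any AU -> -2.0, else (both GC) -> -3.0 kcal/mol.
static inline double stack_energy(int p1, int p2) {
  int m = p1 < p2 ? p1 : p2;
  if (m == 1) return -1.0;
  if (m == 2) return -2.0;
  return -3.0;
}

static const double INF = std::numeric_limits<double>::infinity();

// Minimum-energy non-crossing secondary structure under the stacking model.
// V(i,j): min energy of region [i,j] given (i,j) paired (requires loop >= min_loop).
// W(i,j): min energy of region [i,j], any structure.
// Only stacked adjacent pairs carry energy, so
//   V(i,j) = min(W(i+1,j-1), V(i+1,j-1) + stack)
// (the unstacked-inner-pair candidate inside W is dominated by the stack branch
// because stack energies are strictly negative, so the min is exact).
// [[Rcpp::export]]
List fold_rna_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::string db(n, '.');
  if (n < min_loop + 2) {
    return List::create(_["structure"] = db, _["energy"] = 0.0);
  }
  std::vector<double> V((size_t)n * n, INF), W((size_t)n * n, 0.0);
  std::vector<int> pc((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pc[(size_t)i * n + j] = pair_code(seq[i], seq[j]);

#define IDX(i, j) ((size_t)(i) * n + (j))
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // V
      if (pc[IDX(i, j)] > 0) {
        double best = W[IDX(i + 1, j - 1)];
        if (j - 1 - (i + 1) > min_loop && pc[IDX(i + 1, j - 1)] > 0 &&
            V[IDX(i + 1, j - 1)] < INF) {
          double cand = V[IDX(i + 1, j - 1)] +
                        stack_energy(pc[IDX(i, j)], pc[IDX(i + 1, j - 1)]);
          if (cand < best) best = cand;
        }
        V[IDX(i, j)] = best;
      }
      // W: j unpaired, or (k,j) paired for some k
      double best = W[IDX(i, j - 1)];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (V[IDX(k, j)] < INF) {
          double left = (k > i) ? W[IDX(i, k - 1)] : 0.0;
          double cand = left + V[IDX(k, j)];
          if (cand < best) best = cand;
        }
      }
      W[IDX(i, j)] = best;
    }
  }

  // traceback
  struct Task { int i, j; bool inV; };
  std::stack<Task> tasks;
  tasks.push({0, n - 1, false});
  const double EPS = 1e-9;
  while (!tasks.empty()) {
    Task t = tasks.top(); tasks.pop();
    int i = t.i, j = t.j;
    if (j - i <= min_loop && !t.inV) continue;
    if (t.inV) {
      db[i] = '('; db[j] = ')';
      double v = V[IDX(i, j)];
      if (j - 1 - (i + 1) > min_loop && pc[IDX(i + 1, j - 1)] > 0 &&
          V[IDX(i + 1, j - 1)] < INF &&
          std::abs(V[IDX(i + 1, j - 1)] +
                   stack_energy(pc[IDX(i, j)], pc[IDX(i + 1, j - 1)]) - v) < EPS) {
        tasks.push({i + 1, j - 1, true});
      } else {
        tasks.push({i + 1, j - 1, false});
      }
      continue;
    }
    double w = W[IDX(i, j)];
    if (std::abs(W[IDX(i, j - 1)] - w) < EPS) {
      tasks.push({i, j - 1, false});
      continue;
    }
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      if (V[IDX(k, j)] < INF) {
        double left = (k > i) ? W[IDX(i, k - 1)] : 0.0;
        if (std::abs(left + V[IDX(k, j)] - w) < EPS) {
          tasks.push({k, j, true});
          if (k > i) tasks.push({i, k - 1, false});
          done = true;
        }
      }
    }
  }
  double e = W[IDX(0, n - 1)];
#undef IDX
  return List::create(_["structure"] = db, _["energy"] = e);
}

// Minimum hybridization energy of an intermolecular duplex between a and b.
// Antiparallel pairing: positions i (ascending in a) pair j (descending in b),
// no crossings; isolated pairs cost 0, adjacent pairs (i,j)/(i+1,j-1) stack
// with the same energies as the intramolecular folder.
// D(i,j): best energy of a duplex whose 3'-most (in a) pair is (i,j):
//   D(i,j) = min(0, M(i-1,j+1), D(i-1,j+1) + stack)
// where M is the running min of D over i' <= i, j' >= j (the unstacked copy of
// D(i-1,j+1) inside M is dominated by the stack branch).
// [[Rcpp::export]]
double duplex_energy_cpp(std::string a, std::string b) {
  int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) return 0.0;
  std::vector<double> D((size_t)la * lb, INF), M((size_t)la * lb, INF);
  std::vector<int> pc((size_t)la * lb, 0);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j)
      pc[(size_t)i * lb + j] = pair_code(a[i], b[j]);
#define IDX(i, j) ((size_t)(i) * lb + (j))
  double best = 0.0;
  for (int i = 0; i < la; ++i) {
    for (int j = lb - 1; j >= 0; --j) {
      if (pc[IDX(i, j)] > 0) {
        double d = 0.0;
        if (i > 0 && j < lb - 1) {
          if (M[IDX(i - 1, j + 1)] < d) d = M[IDX(i - 1, j + 1)];
          if (pc[IDX(i - 1, j + 1)] > 0 && D[IDX(i - 1, j + 1)] < INF) {
            double cand = D[IDX(i - 1, j + 1)] +
                          stack_energy(pc[IDX(i, j)], pc[IDX(i - 1, j + 1)]);
            if (cand < d) d = cand;
          }
        }
        D[IDX(i, j)] = d;
        if (d < best) best = d;
      }
      double m = (D[IDX(i, j)] < INF) ? D[IDX(i, j)] : INF;
      if (i > 0 && M[IDX(i - 1, j)] < m) m = M[IDX(i - 1, j)];
      if (j < lb - 1 && M[IDX(i, j + 1)] < m) m = M[IDX(i, j + 1)];
      M[IDX(i, j)] = m;
    }
  }
#undef IDX
  return best;
}

// Local (Smith-Waterman, affine-gap) complementarity alignment of a miRNA
// against a reversed target site. Column score for (mirna[i], revsite[j]):
// Watson-Crick complement -> match, G:T wobble -> wobble, else mismatch;
// scores at miRNA positions [w_start, w_end] (1-based) are multiplied by
// w_mult. Gap of length L costs gap_open + (L-1) * gap_extend. Returns the
// best local score, never below 0.
// [[Rcpp::export]]
double align_score_cpp(std::string mirna, std::string revsite,
                       double match, double wobble, double mismatch,
                       double gap_open, double gap_extend,
                       int w_start, int w_end, double w_mult) {
  int n = mirna.size(), m = revsite.size();
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e18;
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((size_t)(n + 1) * (m + 1), NEG); // gap in mirna (consume revsite)
  std::vector<double> Iy((size_t)(n + 1) * (m + 1), NEG); // gap in revsite (consume mirna)
#define IDX(i, j) ((size_t)(i) * (m + 1) + (j))
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double w = (i >= w_start && i <= w_end) ? w_mult : 1.0;
    for (int j = 1; j <= m; ++j) {
      int pcij = pair_code(mirna[i - 1], revsite[j - 1]);
      double s = (pcij >= 2) ? match : (pcij == 1 ? wobble : mismatch);
      s *= w;
      double ix = std::max(H[IDX(i, j - 1)] + gap_open,
                           Ix[IDX(i, j - 1)] + gap_extend);
      double iy = std::max(H[IDX(i - 1, j)] + gap_open,
                           Iy[IDX(i - 1, j)] + gap_extend);
      // H(i,j) = max(0, best state at (i-1,j-1) + column score)
      double diag = std::max(H[IDX(i - 1, j - 1)],
                             std::max(Ix[IDX(i - 1, j - 1)],
                                      Iy[IDX(i - 1, j - 1)]));
      double h = std::max(0.0, diag + s);
      Ix[IDX(i, j)] = ix;
      Iy[IDX(i, j)] = iy;
      H[IDX(i, j)] = h;
      if (h > best) best = h;
    }
  }
#undef IDX
  return best;
}
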
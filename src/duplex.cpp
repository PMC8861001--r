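// Penalty-scored miRNA/target duplex alignment (plant-style scoring).
//
// The miRNA (5'->3') is aligned against the reversed target window so that
// miRNA position 1 pairs with the 3' end of the site, the antiparallel
// geometry of a miRNA:target duplex. Per-column penalties (mismatch, G:U
// wobble, gap) are multiplied by a seed factor when the miRNA position lies
// in the seed range. The alignment minimizing the total penalty under a
// gap-count budget is found by dynamic programming over states
// (miRNA position, window position, gaps used).
//
// Bases are encoded A=0, C=1, G=2, T/U=3.

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// b is the target base in its original sense reading; Watson-Crick pairs
// are complementary, wobbles are G:U (miRNA G vs target T/U) and U:G.
static inline double pair_pen(int a, int b, double mismatch, double gu) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0) ||
      (a == 2 && b == 1) || (a == 1 && b == 2)) return 0.0;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return gu;
  return mismatch;
}

struct Scheme {
  double mismatch, gu, gap, seed_mult;
  int seed_start, seed_end, max_gaps;
  double wt(int pos, int m) const {
    if (pos > m) pos = m;
    return (pos >= seed_start && pos <= seed_end) ? seed_mult : 1.0;
  }
};

// DP over the reversed window rev[0..w-1]; returns min penalty, or INF if
// the row-minimum ever exceeds `abandon` (every alignment path crosses
// every miRNA row and all penalties are non-negative, so the bound is safe).
static double dp_score(const int* mir, int m, const int* rev, int w,
                       const Scheme& sc, double abandon,
                       std::vector<double>& cost) {
  const int G = sc.max_gaps;
  const int wj = w + 1, wg = G + 1;
  cost.assign((size_t)(m + 1) * wj * wg, INF);
  auto at = [&](int i, int j, int g) -> double& {
    return cost[((size_t)i * wj + j) * wg + g];
  };
  at(0, 0, 0) = 0.0;
  for (int j = 1; j <= w && j <= G; ++j) {
    // leading target bulges before miRNA position 1
    at(0, j, j) = at(0, j - 1, j - 1) + sc.gap * sc.wt(1, m);
  }
  for (int i = 1; i <= m; ++i) {
    double rowmin = INF;
    for (int j = 0; j <= w; ++j) {
      for (int g = 0; g <= G; ++g) {
        double best = INF;
        if (j > 0) {
          double d = at(i - 1, j - 1, g);
          if (d < INF) {
            d += pair_pen(mir[i - 1], rev[j - 1], sc.mismatch, sc.gu) * sc.wt(i, m);
            if (d < best) best = d;
          }
        }
        if (g > 0) {
          double u = at(i - 1, j, g - 1);           // miRNA base i unpaired
          if (u < INF) {
            u += sc.gap * sc.wt(i, m);
            if (u < best) best = u;
          }
          if (j > 0) {
            double l = at(i, j - 1, g - 1);          // target base bulged
            if (l < INF) {
              l += sc.gap * sc.wt(i + 1, m);
              if (l < best) best = l;
            }
          }
        }
        at(i, j, g) = best;
        if (best < rowmin) rowmin = best;
      }
    }
    if (rowmin > abandon) return INF;
  }
  double out = INF;
  for (int g = 0; g <= G; ++g) out = std::min(out, at(m, w, g));
  return out;
}

// [[Rcpp::export]]
List duplex_dp_cpp(IntegerVector mir, IntegerVector win, double mismatch,
                   double gu, double gap, double seed_mult, int seed_start,
                   int seed_end, int max_gaps, bool traceback) {
  const int m = mir.size(), w = win.size();
  Scheme sc{mismatch, gu, gap, seed_mult, seed_start, seed_end, max_gaps};
  std::vector<int> rev(w);
  for (int j = 0; j < w; ++j) rev[j] = win[w - 1 - j];

  std::vector<double> cost;
  double score = dp_score(mir.begin(), m, rev.data(), w, sc, INF, cost);

  if (!traceback) {
    return List::create(_["score"] = score);
  }

  // Reconstruct one optimal path by walking back through the cost table.
  const int G = max_gaps, wj = w + 1, wg = G + 1;
  auto at = [&](int i, int j, int g) -> double {
    return cost[((size_t)i * wj + j) * wg + g];
  };
  int gi = 0;
  for (int g = 0; g <= G; ++g) if (at(m, w, g) == score) { gi = g; break; }
  static const char* NT = "ACGT";
  std::string amir, atgt;
  int i = m, j = w, g = gi;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    double cur = at(i, j, g);
    if (i > 0 && j > 0 &&
        std::abs(at(i - 1, j - 1, g) +
                 pair_pen(mir[i - 1], rev[j - 1], mismatch, gu) * sc.wt(i, m) -
                 cur) < eps) {
      amir.push_back(NT[mir[i - 1]]);
      atgt.push_back(NT[rev[j - 1]]);
      --i; --j;
    } else if (i > 0 && g > 0 &&
               std::abs(at(i - 1, j, g - 1) + gap * sc.wt(i, m) - cur) < eps) {
      amir.push_back(NT[mir[i - 1]]);
      atgt.push_back('-');
      --i; --g;
    } else if (j > 0 && g > 0 &&
               std::abs(at(i, j - 1, g - 1) + gap * sc.wt(i + 1, m) - cur) < eps) {
      amir.push_back('-');
      atgt.push_back(NT[rev[j - 1]]);
      --j; --g;
    } else {
      stop("traceback failed (inconsistent DP table)");
    }
  }
  std::reverse(amir.begin(), amir.end());
  std::reverse(atgt.begin(), atgt.end());
  return List::create(_["score"] = score,
                      _["mirna_aligned"] = amir,
                      _["target_aligned"] = atgt);
}

// Scan every window of the target whose length is within max_gaps of the
// miRNA length; report all windows with penalty <= cutoff.
// [[Rcpp::export]]
DataFrame duplex_scan_cpp(IntegerVector mir, IntegerVector tgt, double mismatch,
                          double gu, double gap, double seed_mult,
                          int seed_start, int seed_end, int max_gaps,
                          double cutoff) {
  const int m = mir.size(), L = tgt.size();
  Scheme sc{mismatch, gu, gap, seed_mult, seed_start, seed_end, max_gaps};
  std::vector<int> starts;
  std::vector<int> ends;
  std::vector<double> scores;
  std::vector<double> cost;
  std::vector<int> rev;
  for (int len = std::max(1, m - max_gaps); len <= m + max_gaps; ++len) {
    if (len > L) continue;
    rev.resize(len);
    for (int s = 0; s + len <= L; ++s) {
      for (int j = 0; j < len; ++j) rev[j] = tgt[s + len - 1 - j];
      double sc0 = dp_score(mir.begin(), m, rev.data(), len, sc, cutoff, cost);
      if (sc0 <= cutoff) {
        starts.push_back(s + 1);
        ends.push_back(s + len);
        scores.push_back(sc0);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["score"] = scores);
}
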
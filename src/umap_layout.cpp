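#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// deterministic xorshift64* RNG so embeddings are reproducible across
// platforms independently of R's RNG stream
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double clip4(double x) {
  if (x > 4.0) return 4.0;
  if (x < -4.0) return -4.0;
  return x;
}

// brute-force k nearest neighbours (Euclidean); rows of X are points
// [[Rcpp::export]]
List cpp_knn(NumericMatrix X, int k) {
  int n = X.nrow(), d = X.ncol();
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<double> di(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = X(i, c) - X(j, c);
        s += t * t;
      }
      di[j] = s;
    }
    di[i] = R_PosInf; // exclude self
    for (int j = 0; j < n; ++j) ord[j] = j;
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) {
                        return di[a] < di[b] || (di[a] == di[b] && a < b);
                      });
    for (int m = 0; m < k; ++m) {
      idx(i, m) = ord[m] + 1; // 1-based for R
      dist(i, m) = std::sqrt(di[ord[m]]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// stochastic-gradient layout of the fuzzy graph (negative sampling),
// following the standard UMAP optimization schedule
// [[Rcpp::export]]
NumericMatrix cpp_umap_layout(IntegerVector head, IntegerVector tail,
                              NumericVector weight, NumericMatrix init,
                              int nEpochs, double a, double b,
                              double gamma, double initialAlpha,
                              int negativeSampleRate, double seed) {
  int nEdges = head.size();
  int nVertices = init.nrow();
  NumericMatrix emb = clone(init);
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 0x9E3779B97F4A7C15ULL;

  double maxW = 0.0;
  for (int e = 0; e < nEdges; ++e) maxW = std::max(maxW, weight[e]);
  std::vector<double> epochsPerSample(nEdges), epochOfNext(nEdges),
      epochsPerNeg(nEdges), epochOfNextNeg(nEdges);
  for (int e = 0; e < nEdges; ++e) {
    epochsPerSample[e] = maxW / weight[e];
    epochOfNext[e] = epochsPerSample[e];
    epochsPerNeg[e] = epochsPerSample[e] / negativeSampleRate;
    epochOfNextNeg[e] = epochsPerNeg[e];
  }

  for (int epoch = 1; epoch <= nEpochs; ++epoch) {
    double alpha = initialAlpha * (1.0 - (double)(epoch - 1) / nEpochs);
    for (int e = 0; e < nEdges; ++e) {
      if (epochOfNext[e] > epoch) continue;
      int i = head[e] - 1, j = tail[e] - 1;
      double dx = emb(i, 0) - emb(j, 0);
      double dy = emb(i, 1) - emb(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 > 0.0) {
        double gradCoef = -2.0 * a * b * std::pow(d2, b - 1.0) /
                          (a * std::pow(d2, b) + 1.0);
        double gx = clip4(gradCoef * dx) * alpha;
        double gy = clip4(gradCoef * dy) * alpha;
        emb(i, 0) += gx; emb(i, 1) += gy;
        emb(j, 0) -= gx; emb(j, 1) -= gy;
      }
      epochOfNext[e] += epochsPerSample[e];

      int nNeg = (int)((epoch - epochOfNextNeg[e]) / epochsPerNeg[e]) + 1;
      for (int p = 0; p < nNeg; ++p) {
        int k = (int)(xorshift64(rng) % (uint64_t)nVertices);
        if (k == i) continue;
        double rx = emb(i, 0) - emb(k, 0);
        double ry = emb(i, 1) - emb(k, 1);
        double rd2 = rx * rx + ry * ry;
        double gradCoef;
        if (rd2 > 0.0) {
          gradCoef = 2.0 * gamma * b /
                     ((0.001 + rd2) * (a * std::pow(rd2, b) + 1.0));
        } else {
          gradCoef = 0.0;
        }
        double gx = (gradCoef > 0.0) ? clip4(gradCoef * rx) : 4.0;
        double gy = (gradCoef > 0.0) ? clip4(gradCoef * ry) : 4.0;
        emb(i, 0) += gx * alpha;
        emb(i, 1) += gy * alpha;
      }
      epochOfNextNeg[e] += nNeg * epochsPerNeg[e];
    }
  }
  return emb;
}
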
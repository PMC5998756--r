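// Skip-gram with negative sampling, single-threaded, driven by R's RNG so
// that training is bit-for-bit reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid_d(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Draw an index from the cumulative noise distribution by binary search.
static inline int sample_noise(const std::vector<double>& cum) {
  double r = unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < r) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// sequences: list of 0-based vocabulary index vectors (pad index 0 never
// appears). noise_weight: length-V unnormalised negative-sampling weights
// (0 for pad). Returns the V x dim input-vector matrix; the pad row stays 0.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sequences, int vocab_size, int dim,
                             int window, int epochs, int negatives,
                             double alpha0, double alpha_min,
                             NumericVector noise_weight) {
  const int V = vocab_size;
  std::vector<double> syn0((size_t)V * dim, 0.0), syn1((size_t)V * dim, 0.0);

  GetRNGstate();
  // uniform init in (-0.5/dim, 0.5/dim), row 0 (pad) frozen at zero
  for (int w = 1; w < V; ++w)
    for (int j = 0; j < dim; ++j)
      syn0[(size_t)w * dim + j] = (unif_rand() - 0.5) / dim;

  std::vector<double> cum(V);
  double acc = 0.0;
  for (int w = 0; w < V; ++w) { acc += noise_weight[w]; cum[w] = acc; }
  if (acc <= 0) { PutRNGstate(); stop("Noise distribution has zero mass"); }

  // total (center, context) pair count, for the linear learning-rate decay
  long long total_pairs = 0;
  const int n_seq = sequences.size();
  std::vector<IntegerVector> seqs;
  seqs.reserve(n_seq);
  for (int s = 0; s < n_seq; ++s) {
    IntegerVector v = sequences[s];
    seqs.push_back(v);
    int L = v.size();
    for (int i = 0; i < L; ++i) {
      int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
      total_pairs += (hi - lo);  // excludes the center itself
    }
  }
  total_pairs *= epochs;
  if (total_pairs == 0) { PutRNGstate(); stop("No training pairs in corpus"); }

  std::vector<double> neu1e(dim);
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_seq; ++s) {
      const IntegerVector& v = seqs[s];
      const int L = v.size();
      for (int i = 0; i < L; ++i) {
        const int center = v[i];
        const int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          const int ctx = v[j];
          const double alpha =
            alpha0 - (alpha0 - alpha_min) * ((double)done / (double)total_pairs);
          ++done;
          double* v_in = &syn0[(size_t)center * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int neg = 0; neg <= negatives; ++neg) {
            int target; double label;
            if (neg == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_noise(cum);
              if (target == ctx) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += v_in[d] * v_out[d];
            const double g = (label - sigmoid_d(f)) * alpha;
            for (int d = 0; d < dim; ++d) neu1e[d] += g * v_out[d];
            for (int d = 0; d < dim; ++d) v_out[d] += g * v_in[d];
          }
          for (int d = 0; d < dim; ++d) v_in[d] += neu1e[d];
        }
      }
    }
  }
  PutRNGstate();

  NumericMatrix out(V, dim);
  for (int w = 0; w < V; ++w)
    for (int d = 0; d < dim; ++d)
      out(w, d) = syn0[(size_t)w * dim + d];
  return out;
}
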
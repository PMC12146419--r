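#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// All randomness is drawn from R's RNG (unif_rand) so that set.seed() in R
// makes walks and embeddings fully reproducible in single-threaded use.

static inline int sample_categorical(const std::vector<double>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

static inline bool has_edge(const std::vector<int>& sorted_adj, int x) {
  return std::binary_search(sorted_adj.begin(), sorted_adj.end(), x);
}

// Second-order (p, q)-biased random walks.
// adj: 0-based adjacency list (sorted per node), one walk per (repeat, node).
// [[Rcpp::export(name = ".node2vec_walks_cpp")]]
List node2vec_walks_cpp(List adj, int num_walks, int walk_length,
                        double p, double q) {
  const int n = adj.size();
  std::vector<std::vector<int> > A(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    A[i] = std::vector<int>(nb.begin(), nb.end());
    std::sort(A[i].begin(), A[i].end());
  }
  RNGScope scope;
  List out(num_walks * n);
  int k = 0;
  std::vector<double> w;
  for (int r = 0; r < num_walks; ++r) {
    for (int v = 0; v < n; ++v) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(v);
      if (!A[v].empty()) {
        // first step: uniform over neighbours
        int cur = A[v][(int)std::floor(unif_rand() * A[v].size()) % A[v].size()];
        walk.push_back(cur);
        int prev = v;
        while ((int)walk.size() < walk_length) {
          const std::vector<int>& nb = A[cur];
          if (nb.empty()) break;
          w.resize(nb.size());
          double tot = 0.0;
          for (size_t t = 0; t < nb.size(); ++t) {
            int x = nb[t];
            double wt;
            if (x == prev) wt = 1.0 / p;
            else if (has_edge(A[prev], x)) wt = 1.0;
            else wt = 1.0 / q;
            w[t] = wt;
            tot += wt;
          }
          int nxt = nb[sample_categorical(w, tot)];
          walk.push_back(nxt);
          prev = cur;
          cur = nxt;
        }
      }
      out[k++] = IntegerVector(walk.begin(), walk.end());
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Skip-gram with negative sampling over walk corpora (word2vec-style SGD).
// walks: list of 0-based integer vectors; returns n_nodes x dim input
// embeddings. Nodes that never take part in a (center, context) pair get a
// zero row. Window size per center position is sampled uniformly in
// 1..window as in word2vec.
// [[Rcpp::export(name = ".sgns_embed_cpp")]]
NumericMatrix sgns_embed_cpp(List walks, int n_nodes, int dim, int window,
                             int epochs, int negative, double alpha0,
                             double min_alpha) {
  RNGScope scope;
  std::vector<std::vector<int> > W(walks.size());
  long long total_tokens = 0;
  std::vector<double> freq(n_nodes, 0.0);
  for (int i = 0; i < (int)walks.size(); ++i) {
    IntegerVector v = walks[i];
    W[i] = std::vector<int>(v.begin(), v.end());
    total_tokens += v.size();
    for (int t : W[i]) freq[t] += 1.0;
  }
  // unigram^0.75 negative-sampling table
  const int TABLE = 100000;
  std::vector<int> table(TABLE);
  double z = 0.0;
  for (int i = 0; i < n_nodes; ++i) z += std::pow(freq[i], 0.75);
  if (z <= 0.0) z = 1.0;
  {
    int i = 0;
    double cum = std::pow(freq[0], 0.75) / z;
    for (int t = 0; t < TABLE; ++t) {
      double frac = (t + 0.5) / TABLE;
      while (frac > cum && i < n_nodes - 1) {
        ++i;
        cum += std::pow(freq[i], 0.75) / z;
      }
      table[t] = i;
    }
  }
  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (unif_rand() - 0.5) / dim;
  std::vector<bool> touched(n_nodes, false);
  std::vector<double> grad(dim);
  long long done = 0, total_work = (long long)epochs * total_tokens;
  if (total_work <= 0) total_work = 1;
  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t wi = 0; wi < W.size(); ++wi) {
      const std::vector<int>& walk = W[wi];
      const int L = walk.size();
      for (int pos = 0; pos < L; ++pos) {
        double alpha = alpha0 + (min_alpha - alpha0) * ((double)done / total_work);
        ++done;
        int center = walk[pos];
        int b = 1 + (int)std::floor(unif_rand() * window);
        if (b > window) b = window;
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= L) continue;
          int context = walk[cpos];
          double* v_in = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s < negative + 1; ++s) {
            int target;
            double label;
            if (s == 0) { target = center; label = 1.0; }
            else {
              target = table[(int)std::floor(unif_rand() * TABLE) % TABLE];
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - pred) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
          touched[context] = true;
          touched[center] = true;
        }
      }
      if (wi % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i) {
    if (!touched[i]) continue; // zero row for nodes never in a training pair
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  }
  return out;
}
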
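// PV-DM (distributed-memory paragraph vectors) trained with negative
// sampling. The inner SGD loop is written in C++ because each epoch visits
// every k-mer position of every document; everything else lives in R.
//
// Conventions follow the classic word2vec/doc2vec implementations:
//  - word and document vectors are initialised uniformly in
//    [-0.5/d, 0.5/d]; context-prediction ("output") vectors start at zero;
//  - negatives are drawn from a caller-supplied cumulative noise
//    distribution (unigram^0.75 by default, built in R);
//  - the hidden vector is the mean of the document vector and the in-window
//    word vectors; at sequence edges the window simply contains fewer
//    words and the mean divides by the actual count + 1.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

namespace {

inline double sigmoid_d(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// draw a vocabulary index from the cumulative noise distribution
inline int draw_noise(const NumericVector& cdf, std::mt19937& rng) {
  const double u =
      (double)rng() / ((double)std::mt19937::max() + 1.0);  // [0,1)
  const double* begin = cdf.begin();
  const double* pos = std::upper_bound(begin, cdf.end(), u);
  int idx = (int)(pos - begin);
  if (idx >= cdf.size()) idx = cdf.size() - 1;
  return idx;
}

// one SGD visit of position t in a document; returns the sampled loss.
// doc_row may point into the doc table (training) or a free vector
// (inference); train_tables toggles updates of word/output tables.
double visit_position(const IntegerVector& tokens, int t, double* doc_row,
                      NumericMatrix& W, NumericMatrix& V, int d, int window,
                      int n_neg, double lr, const NumericVector& cdf,
                      std::mt19937& rng, bool train_tables,
                      std::vector<double>& hidden, std::vector<double>& neu1e) {
  const int n = tokens.size();
  const int target = tokens[t];

  // gather context (skip out-of-range positions -> variable count)
  int cnt = 0;
  std::fill(hidden.begin(), hidden.end(), 0.0);
  int lo = t - window, hi = t + window;
  if (lo < 0) lo = 0;
  if (hi > n - 1) hi = n - 1;
  for (int j = lo; j <= hi; ++j) {
    if (j == t) continue;
    const int w = tokens[j];
    if (w < 0) continue;  // out-of-vocabulary token (inference): skipped
    for (int a = 0; a < d; ++a) hidden[a] += W(w, a);
    ++cnt;
  }
  for (int a = 0; a < d; ++a) {
    hidden[a] = (hidden[a] + doc_row[a]) / (double)(cnt + 1);
  }

  std::fill(neu1e.begin(), neu1e.end(), 0.0);
  double loss = 0.0;
  for (int s = 0; s <= n_neg; ++s) {
    int w;
    double label;
    if (s == 0) {
      w = target;
      label = 1.0;
    } else {
      w = draw_noise(cdf, rng);
      if (w == target) continue;  // skip accidental positives
      label = 0.0;
    }
    double f = 0.0;
    for (int a = 0; a < d; ++a) f += V(w, a) * hidden[a];
    const double p = sigmoid_d(f);
    loss += (label > 0.5) ? -std::log(std::max(p, 1e-12))
                          : -std::log(std::max(1.0 - p, 1e-12));
    const double g = (label - p) * lr;
    for (int a = 0; a < d; ++a) neu1e[a] += g * V(w, a);
    if (train_tables) {
      for (int a = 0; a < d; ++a) V(w, a) += g * hidden[a];
    }
  }

  // d hidden / d input = 1/(cnt+1) for the document vector and each
  // context word vector
  const double scale = 1.0 / (double)(cnt + 1);
  for (int a = 0; a < d; ++a) doc_row[a] += neu1e[a] * scale;
  if (train_tables) {
    for (int j = lo; j <= hi; ++j) {
      if (j == t) continue;
      const int w = tokens[j];
      if (w < 0) continue;
      for (int a = 0; a < d; ++a) W(w, a) += neu1e[a] * scale;
    }
  }
  return loss;
}

}  // namespace

// [[Rcpp::export(name = ".pvdm_train_cpp")]]
List pvdm_train_cpp(List docs, int vocab_size, int d, int window, int n_neg,
                    int epochs, double lr, NumericVector noise_cdf,
                    int seed) {
  const int n_docs = docs.size();
  std::mt19937 rng((uint32_t)seed);

  NumericMatrix W(vocab_size, d), V(vocab_size, d), E(n_docs, d);
  const double span = 1.0 / d;  // init range +/- 0.5/d
  for (int i = 0; i < vocab_size; ++i)
    for (int a = 0; a < d; ++a)
      W(i, a) = ((double)rng() / ((double)std::mt19937::max() + 1.0) - 0.5) * span;
  for (int i = 0; i < n_docs; ++i)
    for (int a = 0; a < d; ++a)
      E(i, a) = ((double)rng() / ((double)std::mt19937::max() + 1.0) - 0.5) * span;

  NumericVector loss_trace(epochs);
  std::vector<double> hidden(d), neu1e(d);
  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0;
    long n_pos = 0;
    for (int di = 0; di < n_docs; ++di) {
      IntegerVector tokens = docs[di];
      double* doc_row = &E(di, 0);
      // NumericMatrix is column-major; build a contiguous copy of the row
      std::vector<double> row(d);
      for (int a = 0; a < d; ++a) row[a] = E(di, a);
      for (int t = 0; t < tokens.size(); ++t) {
        loss += visit_position(tokens, t, row.data(), W, V, d, window, n_neg,
                               lr, noise_cdf, rng, true, hidden, neu1e);
        ++n_pos;
      }
      for (int a = 0; a < d; ++a) doc_row[a * n_docs] = row[a];
    }
    loss_trace[ep] = (n_pos > 0) ? loss / (double)n_pos : 0.0;
  }
  return List::create(_["word"] = W, _["context"] = V, _["doc"] = E,
                      _["loss_trace"] = loss_trace);
}

// [[Rcpp::export(name = ".pvdm_infer_cpp")]]
NumericVector pvdm_infer_cpp(IntegerVector tokens, NumericMatrix W,
                             NumericMatrix V, int window, int n_neg,
                             int steps, double lr, NumericVector noise_cdf,
                             int seed) {
  const int d = W.ncol();
  std::mt19937 rng((uint32_t)seed);
  NumericVector vec(d);
  const double span = 1.0 / d;
  for (int a = 0; a < d; ++a)
    vec[a] = ((double)rng() / ((double)std::mt19937::max() + 1.0) - 0.5) * span;

  // tables are frozen during inference: copy so caller matrices are safe
  NumericMatrix Wc = clone(W), Vc = clone(V);
  std::vector<double> hidden(d), neu1e(d), row(d);
  for (int a = 0; a < d; ++a) row[a] = vec[a];
  for (int s = 0; s < steps; ++s) {
    for (int t = 0; t < tokens.size(); ++t) {
      if (tokens[t] < 0) continue;  // OOV target: nothing to predict
      visit_position(tokens, t, row.data(), Wc, Vc, d, window, n_neg, lr,
                     noise_cdf, rng, false, hidden, neu1e);
    }
  }
  for (int a = 0; a < d; ++a) vec[a] = row[a];
  return vec;
}
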
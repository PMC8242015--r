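// Word2vec (skip-gram / CBOW with negative sampling) over k-mer token
// sentences. Single-threaded; all randomness from R's RNG so results are
// reproducible under set.seed(). Context radius is fixed (no random window
// shrinking) for the same reason.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline double sigm1(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
arma::mat w2v_train_cpp(const List& sentences, int vocab_size,
                        const arma::vec& counts, int dim, int window,
                        int negative, int epochs, double lr0, bool cbow) {
  const int Vn = vocab_size;
  mat syn0(Vn, dim), syn1(Vn, dim, fill::zeros);
  for (int v = 0; v < Vn; ++v)
    for (int d = 0; d < dim; ++d)
      syn0(v, d) = (R::unif_rand() - 0.5) / dim;

  // unigram^0.75 cumulative table for negative sampling
  vec cum = cumsum(pow(counts, 0.75));
  const double ctot = cum(Vn - 1);

  long long total = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total += ((IntegerVector)sentences[s]).size();
  total *= epochs;
  long long processed = 0;

  rowvec neu1(dim), neu1e(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int n = sent.size();
      for (int i = 0; i < n; ++i) {
        double lr = lr0 * (1.0 - (double)processed / (double)(total + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        ++processed;
        const int w = sent[i];
        const int lo = std::max(0, i - window), hi = std::min(n - 1, i + window);

        if (!cbow) {
          for (int j = lo; j <= hi; ++j) {
            if (j == i) continue;
            const int in = sent[j];  // context word is the input (word2vec.c)
            neu1e.zeros();
            for (int d = 0; d <= negative; ++d) {
              int target;
              double label;
              if (d == 0) { target = w; label = 1.0; }
              else {
                double r = R::unif_rand() * ctot;
                target = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
                if (target >= Vn) target = Vn - 1;
                if (target == w) continue;
                label = 0.0;
              }
              const double f = dot(syn0.row(in), syn1.row(target));
              const double g = (label - sigm1(f)) * lr;
              neu1e += g * syn1.row(target);
              syn1.row(target) += g * syn0.row(in);
            }
            syn0.row(in) += neu1e;
          }
        } else {
          int cw = 0;
          neu1.zeros();
          for (int j = lo; j <= hi; ++j) {
            if (j == i) continue;
            neu1 += syn0.row(sent[j]);
            ++cw;
          }
          if (cw == 0) continue;
          neu1 /= cw;
          neu1e.zeros();
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) { target = w; label = 1.0; }
            else {
              double r = R::unif_rand() * ctot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= Vn) target = Vn - 1;
              if (target == w) continue;
              label = 0.0;
            }
            const double f = dot(neu1, syn1.row(target));
            const double g = (label - sigm1(f)) * lr;
            neu1e += g * syn1.row(target);
            syn1.row(target) += g * neu1;
          }
          for (int j = lo; j <= hi; ++j) {
            if (j == i) continue;
            syn0.row(sent[j]) += neu1e / cw;
          }
        }
      }
    }
  }
  return syn0;
}
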
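// Fully connected sequence-binding regressor (2 hidden layers) and
// ungapped best-overlap sequence scoring.
//
// The network input is a fixed-width token string (one-hot over 19 tokens).
// Instead of materialising the one-hot matrix, the first layer is applied as
// an embedding lookup: row (position*19 + token) of W1 is added per position.
// This is algebraically identical to onehot(x) %*% W1 and much faster.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Adam {
  arma::mat m, v;
  Adam(arma::uword r, arma::uword c) : m(r, c, arma::fill::zeros),
                                       v(r, c, arma::fill::zeros) {}
  void step(arma::mat &w, const arma::mat &g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * (g % g);
    const double corr = lr * std::sqrt(1.0 - std::pow(b2, t)) /
                        (1.0 - std::pow(b1, t));
    w -= corr * (m / (arma::sqrt(v) + eps));
  }
};

// Forward pass for a block of token rows; returns output, optionally keeps
// pre-activations for backprop.
void forward_block(const arma::imat &tok, const arma::uvec &idx,
                   const arma::mat &W1, const arma::rowvec &b1,
                   const arma::mat &W2, const arma::rowvec &b2,
                   const arma::mat &W3, const arma::rowvec &b3,
                   int n_tokens,
                   arma::mat &A1, arma::mat &H1, arma::mat &A2,
                   arma::mat &H2, arma::mat &out) {
  const arma::uword n = idx.n_elem, width = tok.n_cols;
  A1.set_size(n, W1.n_cols);
  A1.each_row() = b1;
  for (arma::uword i = 0; i < n; ++i) {
    const arma::uword r = idx(i);
    for (arma::uword p = 0; p < width; ++p)
      A1.row(i) += W1.row(p * n_tokens + tok(r, p));
  }
  H1 = arma::clamp(A1, 0.0, arma::datum::inf);
  A2 = H1 * W2;
  A2.each_row() += b2;
  H2 = arma::clamp(A2, 0.0, arma::datum::inf);
  out = H2 * W3;
  out.each_row() += b3;
}

} // namespace

// Train the regressor with Adam on (weighted) mean squared error.
// tokens: n x width integer matrix of 0-based token indices.
// Y: n x k targets. w: n per-example loss weights (multiplicities).
// [[Rcpp::export]]
List mlp_train_cpp(const arma::imat &tokens, const arma::mat &Y,
                   const arma::vec &w, int n_tokens, int h1, int h2,
                   double lr, double lr_decay, int epochs, int batch,
                   int seed) {
  const arma::uword n = tokens.n_rows, width = tokens.n_cols,
                    k = Y.n_cols;
  const arma::uword d = width * (arma::uword)n_tokens;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  auto init = [&](arma::uword r, arma::uword c, double fan_in) {
    arma::mat W(r, c);
    const double sd = std::sqrt(2.0 / fan_in);
    for (arma::uword j = 0; j < c; ++j)
      for (arma::uword i = 0; i < r; ++i) W(i, j) = sd * gauss(rng);
    return W;
  };
  // effective fan-in of layer 1 is the frame width (one active bit per
  // position), not the full one-hot dimension
  arma::mat W1 = init(d, h1, (double)width);
  arma::mat W2 = init(h1, h2, (double)h1);
  arma::mat W3 = init(h2, k, (double)h2);
  arma::rowvec b1(h1, arma::fill::zeros), b2(h2, arma::fill::zeros),
      b3(k, arma::fill::zeros);

  Adam aW1(d, h1), aW2(h1, h2), aW3(h2, k);
  Adam ab1(1, h1), ab2(1, h2), ab3(1, k);

  std::vector<arma::uword> perm(n);
  for (arma::uword i = 0; i < n; ++i) perm[i] = i;

  arma::mat A1, H1, A2, H2, out;
  arma::vec loss_hist(epochs, arma::fill::zeros);
  double t = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    // exponential decay: lr_ep = lr * lr_decay^ep
    const double lr_ep = lr * std::pow(lr_decay, ep);
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0.0, ep_wsum = 0.0;
    for (arma::uword start = 0; start < n; start += batch) {
      const arma::uword stop = std::min<arma::uword>(start + batch, n);
      const arma::uword bs = stop - start;
      arma::uvec idx(bs);
      for (arma::uword i = 0; i < bs; ++i) idx(i) = perm[start + i];

      forward_block(tokens, idx, W1, b1, W2, b2, W3, b3, n_tokens,
                    A1, H1, A2, H2, out);

      arma::mat Yb(bs, k);
      arma::vec wb(bs);
      for (arma::uword i = 0; i < bs; ++i) {
        Yb.row(i) = Y.row(idx(i));
        wb(i) = w(idx(i));
      }
      arma::mat diff = out - Yb;
      ep_loss += arma::accu((diff % diff) * arma::ones(k) % wb);
      ep_wsum += arma::accu(wb) * k;

      // weighted MSE gradient, normalised by batch weight mass
      const double norm = arma::accu(wb) * k;
      arma::mat D3 = (2.0 / norm) * (diff.each_col() % wb);
      arma::mat gW3 = H2.t() * D3;
      arma::rowvec gb3 = arma::sum(D3, 0);
      arma::mat D2 = (D3 * W3.t()) %
                     arma::conv_to<arma::mat>::from(A2 > 0);
      arma::mat gW2 = H1.t() * D2;
      arma::rowvec gb2 = arma::sum(D2, 0);
      arma::mat D1 = (D2 * W2.t()) %
                     arma::conv_to<arma::mat>::from(A1 > 0);
      arma::mat gW1(d, (arma::uword)h1, arma::fill::zeros);
      for (arma::uword i = 0; i < bs; ++i) {
        const arma::uword r = idx(i);
        for (arma::uword p = 0; p < width; ++p)
          gW1.row(p * n_tokens + tokens(r, p)) += D1.row(i);
      }
      arma::rowvec gb1 = arma::sum(D1, 0);

      t += 1.0;
      aW1.step(W1, gW1, lr_ep, t);
      aW2.step(W2, gW2, lr_ep, t);
      aW3.step(W3, gW3, lr_ep, t);
      arma::mat b1m(b1), b2m(b2), b3m(b3);
      ab1.step(b1m, gb1, lr_ep, t);
      ab2.step(b2m, gb2, lr_ep, t);
      ab3.step(b3m, gb3, lr_ep, t);
      b1 = b1m.row(0);
      b2 = b2m.row(0);
      b3 = b3m.row(0);
      if ((start / batch) % 256 == 0) Rcpp::checkUserInterrupt();
    }
    loss_hist(ep) = ep_loss / ep_wsum;
  }

  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2,
                      _["b2"] = b2, _["W3"] = W3, _["b3"] = b3,
                      _["loss"] = loss_hist);
}

// Forward pass over all rows of `tokens`, in chunks to bound memory.
// [[Rcpp::export]]
arma::mat mlp_forward_cpp(const arma::imat &tokens, const arma::mat &W1,
                          const arma::rowvec &b1, const arma::mat &W2,
                          const arma::rowvec &b2, const arma::mat &W3,
                          const arma::rowvec &b3, int n_tokens,
                          int chunk = 8192) {
  const arma::uword n = tokens.n_rows;
  arma::mat pred(n, W3.n_cols);
  arma::mat A1, H1, A2, H2, out;
  for (arma::uword start = 0; start < n; start += chunk) {
    const arma::uword stop = std::min<arma::uword>(start + chunk, n);
    arma::uvec idx = arma::regspace<arma::uvec>(start, stop - 1);
    forward_block(tokens, idx, W1, b1, W2, b2, W3, b3, n_tokens,
                  A1, H1, A2, H2, out);
    pred.rows(start, stop - 1) = out;
    Rcpp::checkUserInterrupt();
  }
  return pred;
}

// Best ungapped overlap score of `motif` against each peptide: the maximum
// over all integer offsets (partial overlaps with >=1 aligned position
// included) of the sum of `energies` at positions where residues match.
// With unit energies this is the identity-match count used for similarity
// filtering.
// [[Rcpp::export]]
NumericVector best_overlap_score_cpp(const CharacterVector &peptides,
                                     const std::string &motif,
                                     const NumericVector &energies) {
  const int m = motif.size();
  if ((int)energies.size() != m)
    stop("energies must have one value per motif position");
  NumericVector out(peptides.size());
  for (R_xlen_t i = 0; i < peptides.size(); ++i) {
    const std::string pep = as<std::string>(peptides[i]);
    const int L = pep.size();
    double best = 0.0;
    // offset: position of motif[0] relative to pep[0]
    for (int off = -(m - 1); off <= L - 1; ++off) {
      double s = 0.0;
      const int j0 = std::max(0, -off), j1 = std::min(m, L - off);
      for (int j = j0; j < j1; ++j)
        if (motif[j] == pep[off + j]) s += energies[j];
      if (s > best) best = s;
    }
    out[i] = best;
  }
  return out;
}

// Deterministic 31-ary polynomial string hash modulo 2^31 - 1, used as the
// final ranking tie-break so re-ranked orderings are reproducible.
// [[Rcpp::export]]
NumericVector sequence_hash_cpp(const CharacterVector &sequences) {
  NumericVector out(sequences.size());
  for (R_xlen_t i = 0; i < sequences.size(); ++i) {
    const char *s = CHAR(STRING_ELT(sequences, i));
    int64_t h = 0;
    for (; *s; ++s) h = (h * 31 + (unsigned char)*s) % 2147483647LL;
    out[i] = (double)h;
  }
  return out;
}
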
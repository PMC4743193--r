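#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Empirical mode decomposition
// ---------------------------------------------------------------------------

// Interior extrema by sign change of the first difference; plateaus are
// collapsed to their midpoint.
static void find_extrema(const arma::vec &x, std::vector<int> &imax,
                         std::vector<int> &imin) {
  imax.clear();
  imin.clear();
  const int n = x.n_elem;
  int prev = 0;   // sign of the last non-zero difference
  int plat = -1;  // start of a running plateau, -1 if none
  for (int i = 1; i < n; ++i) {
    double d = x[i] - x[i - 1];
    int s = (d > 0) - (d < 0);
    if (s == 0) {
      if (plat < 0) plat = i - 1;
      continue;
    }
    int pos = (plat >= 0) ? (plat + i - 1) / 2 : i - 1;
    if (prev > 0 && s < 0) imax.push_back(pos);
    if (prev < 0 && s > 0) imin.push_back(pos);
    prev = s;
    plat = -1;
  }
}

// Natural cubic spline through strictly increasing knots (t, v), evaluated on
// the integer grid 0..n-1. Two knots degrade to a straight line.
static arma::vec spline_eval(const std::vector<double> &t,
                             const std::vector<double> &v, int n) {
  const int k = (int)t.size();
  arma::vec out(n);
  if (k == 2) {
    double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = v[0] + slope * (i - t[0]);
    return out;
  }
  arma::vec h(k - 1), alpha(k, arma::fill::zeros), l(k), mu(k), z(k), M(k);
  for (int i = 0; i < k - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < k - 1; ++i)
    alpha[i] = 3.0 * ((v[i + 1] - v[i]) / h[i] - (v[i] - v[i - 1]) / h[i - 1]);
  l[0] = 1.0;
  mu[0] = 0.0;
  z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[k - 1] = 0.0;
  for (int j = k - 2; j >= 1; --j) M[j] = z[j] - mu[j] * M[j + 1];
  M[0] = 0.0;
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double x = (double)i;
    while (seg < k - 2 && x > t[seg + 1]) ++seg;
    double dt = t[seg + 1] - t[seg];
    double a = (t[seg + 1] - x) / dt;
    double b = (x - t[seg]) / dt;
    out[i] = a * v[seg] + b * v[seg + 1] +
             ((a * a * a - a) * M[seg] + (b * b * b - b) * M[seg + 1]) *
                 (dt * dt) / 6.0;
  }
  return out;
}

// Envelope through one family of extrema, with up to two extrema mirrored
// across each end of the signal so the spline is anchored beyond the edges.
static bool envelope(const arma::vec &x, const std::vector<int> &ext, int n,
                     arma::vec &env) {
  const int k = (int)ext.size();
  if (k < 2) return false;
  const int nb = std::min(2, k);
  std::vector<double> t, v;
  t.reserve(k + 2 * nb);
  v.reserve(k + 2 * nb);
  for (int j = nb; j >= 1; --j) {  // mirrored about sample 0
    t.push_back(-(double)ext[j - 1]);
    v.push_back(x[ext[j - 1]]);
  }
  for (int j = 0; j < k; ++j) {
    t.push_back((double)ext[j]);
    v.push_back(x[ext[j]]);
  }
  for (int j = 0; j < nb; ++j) {  // mirrored about sample n-1
    t.push_back(2.0 * (n - 1) - ext[k - 1 - j]);
    v.push_back(x[ext[k - 1 - j]]);
  }
  env = spline_eval(t, v, n);
  return true;
}

// [[Rcpp::export]]
List cpp_emd(const arma::vec &x, int max_imf, double sd_thresh, int max_sift) {
  const int n = x.n_elem;
  arma::vec resid = x;
  std::vector<arma::vec> imfs;
  for (int k = 0; k < max_imf; ++k) {
    std::vector<int> imax, imin;
    find_extrema(resid, imax, imin);
    if ((int)imax.size() < 2 || (int)imin.size() < 2) break;
    arma::vec h = resid;
    for (int it = 0; it < max_sift; ++it) {
      std::vector<int> ma, mi;
      find_extrema(h, ma, mi);
      arma::vec up, lo;
      if (!envelope(h, ma, n, up) || !envelope(h, mi, n, lo)) break;
      arma::vec m = 0.5 * (up + lo);
      double num = arma::dot(m, m);  // sum((h_prev - h_new)^2)
      double den = arma::dot(h, h);
      h -= m;
      if (den <= 0.0 || num / den < sd_thresh) break;
    }
    imfs.push_back(h);
    resid -= h;
  }
  arma::mat M(n, (int)imfs.size());
  for (size_t j = 0; j < imfs.size(); ++j) M.col(j) = imfs[j];
  return List::create(_["imfs"] = M, _["residue"] = resid);
}

// ---------------------------------------------------------------------------
// Hilbert analytic signal and instantaneous quantities
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cx_vec cpp_analytic(const arma::vec &x) {
  const int n = x.n_elem;
  arma::cx_vec F = arma::fft(x);
  arma::vec h(n, arma::fill::zeros);
  h[0] = 1.0;
  if (n % 2 == 0) {
    h[n / 2] = 1.0;
    for (int i = 1; i < n / 2; ++i) h[i] = 2.0;
  } else {
    for (int i = 1; i <= (n - 1) / 2; ++i) h[i] = 2.0;
  }
  for (int i = 0; i < n; ++i) F[i] *= h[i];
  return arma::ifft(F);
}

// amplitude, unwrapped phase (radians) and instantaneous frequency (rad/s,
// central differences in the interior, one-sided at the ends)
// [[Rcpp::export]]
List cpp_hilbert_analysis(const arma::vec &c, double fs) {
  arma::cx_vec z = cpp_analytic(c);
  const int n = z.n_elem;
  arma::vec amp(n), ph(n), om(n);
  double off = 0.0, prev_raw = 0.0;
  const double PI = 3.14159265358979323846;
  for (int i = 0; i < n; ++i) {
    amp[i] = std::abs(z[i]);
    double raw = std::atan2(z[i].imag(), z[i].real());
    if (i > 0) {
      double d = raw - prev_raw;
      if (d > PI)
        off -= 2.0 * PI;
      else if (d < -PI)
        off += 2.0 * PI;
    }
    ph[i] = raw + off;
    prev_raw = raw;
  }
  if (n >= 2) {
    om[0] = (ph[1] - ph[0]) * fs;
    om[n - 1] = (ph[n - 1] - ph[n - 2]) * fs;
    for (int i = 1; i < n - 1; ++i) om[i] = (ph[i + 1] - ph[i - 1]) * fs / 2.0;
  } else {
    om.zeros();
  }
  return List::create(_["amplitude"] = amp, _["phase"] = ph,
                      _["inst_frequency"] = om);
}

// ---------------------------------------------------------------------------
// Batch spectral features: per signal, EMD -> first `keep` IMFs -> relative
// energy (analytic amplitude), mean instantaneous frequency, mean slope,
// coefficient of variation. Rows of X are signals.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_spectral_features(const arma::mat &X, double fs, int max_imf,
                           int keep, double sd_thresh, int max_sift,
                           bool freq_hz) {
  const int ne = X.n_rows;
  const int N = X.n_cols;
  arma::mat out(ne, 4 * keep, arma::fill::zeros);
  int n_short = 0;
  const double PI = 3.14159265358979323846;
  for (int e = 0; e < ne; ++e) {
    arma::vec x = X.row(e).t();
    List dec = cpp_emd(x, max_imf, sd_thresh, max_sift);
    arma::mat M = dec["imfs"];
    int ni = std::min((int)M.n_cols, keep);
    if ((int)M.n_cols < keep) ++n_short;
    arma::vec E(keep, arma::fill::zeros), Phi(keep, arma::fill::zeros),
        MS(keep, arma::fill::zeros), CV(keep, arma::fill::zeros);
    for (int i = 0; i < ni; ++i) {
      arma::vec ci = M.col(i);
      List ha = cpp_hilbert_analysis(ci, fs);
      arma::vec a = ha["amplitude"];
      arma::vec om = ha["inst_frequency"];
      E[i] = arma::dot(a, a);
      Phi[i] = arma::mean(om);
      MS[i] = (ci[N - 1] - ci[0]) * fs / (N - 1);
      double mu = arma::mean(ci);
      double sig = (N > 1) ? arma::stddev(ci) : 0.0;
      // IMFs are near zero-mean; guard the CV denominator
      double guard = 1e-12 * sig;
      double den = mu;
      if (std::abs(mu) < guard) den = (mu >= 0.0) ? guard : -guard;
      CV[i] = (den != 0.0) ? sig / den : 0.0;
    }
    double tot = arma::sum(E);
    if (tot > 0.0) E /= tot;
    if (freq_hz) Phi /= 2.0 * PI;
    for (int i = 0; i < keep; ++i) {
      out(e, i) = E[i];
      out(e, keep + i) = Phi[i];
      out(e, 2 * keep + i) = MS[i];
      out(e, 3 * keep + i) = CV[i];
    }
  }
  return List::create(_["features"] = out, _["n_short"] = n_short);
}

// ---------------------------------------------------------------------------
// Single-hidden-layer feed-forward network: tansig hidden units, logsig
// output, cross-entropy loss, full-batch iRprop- updates, early stopping on a
// held-out validation set. All randomness (initial weights, the split) is
// supplied by the caller, so training is deterministic.
// ---------------------------------------------------------------------------

static arma::vec forward_mlp(const arma::mat &X, const arma::mat &W1,
                             const arma::vec &b1, const arma::rowvec &W2,
                             double b2, arma::mat *A1out = nullptr) {
  arma::mat Z1 = X * W1.t();
  Z1.each_row() += b1.t();
  arma::mat A1 = arma::tanh(Z1);
  if (A1out) *A1out = A1;
  arma::vec s = A1 * W2.t() + b2;
  arma::vec p(s.n_elem);
  for (arma::uword i = 0; i < s.n_elem; ++i) {
    double n = s[i];
    p[i] = (n >= 0.0) ? 1.0 / (1.0 + std::exp(-n))
                      : std::exp(n) / (1.0 + std::exp(n));
  }
  return p;
}

static double xent(const arma::vec &p, const arma::vec &y,
                   const arma::vec &w) {
  double L = 0.0;
  for (arma::uword i = 0; i < p.n_elem; ++i) {
    double pi = std::min(std::max(p[i], 1e-12), 1.0 - 1e-12);
    L -= w[i] * (y[i] * std::log(pi) + (1.0 - y[i]) * std::log(1.0 - pi));
  }
  return L / arma::sum(w);
}

// elementwise iRprop- update
static void rprop_update(arma::mat &w, const arma::mat &g, arma::mat &gprev,
                         arma::mat &step) {
  const double up = 1.2, down = 0.5, smin = 1e-9, smax = 1.0;
  for (arma::uword i = 0; i < w.n_elem; ++i) {
    double prod = g[i] * gprev[i];
    if (prod > 0.0) {
      step[i] = std::min(step[i] * up, smax);
      w[i] -= ((g[i] > 0) - (g[i] < 0)) * step[i];
      gprev[i] = g[i];
    } else if (prod < 0.0) {
      step[i] = std::max(step[i] * down, smin);
      gprev[i] = 0.0;
    } else {
      w[i] -= ((g[i] > 0) - (g[i] < 0)) * step[i];
      gprev[i] = g[i];
    }
  }
}

// [[Rcpp::export]]
List cpp_mlp_train(const arma::mat &X, const arma::vec &y, arma::mat W1,
                   arma::vec b1, arma::rowvec W2, double b2,
                   const arma::uvec &train_idx, const arma::uvec &val_idx,
                   int max_epochs, int patience, double w_pos, double w_neg) {
  arma::mat Xt = X.rows(train_idx);
  arma::vec yt = y.elem(train_idx);
  const int nt = Xt.n_rows;
  arma::vec wt(nt);
  for (int i = 0; i < nt; ++i) wt[i] = (yt[i] > 0.5) ? w_pos : w_neg;
  const bool has_val = val_idx.n_elem > 0;
  arma::mat Xv;
  arma::vec yv, wv;
  if (has_val) {
    Xv = X.rows(val_idx);
    yv = y.elem(val_idx);
    wv.set_size(yv.n_elem);
    for (arma::uword i = 0; i < yv.n_elem; ++i)
      wv[i] = (yv[i] > 0.5) ? w_pos : w_neg;
  }

  arma::mat gW1p(arma::size(W1), arma::fill::zeros),
      sW1(arma::size(W1), arma::fill::value(0.01));
  arma::mat b1m(b1.n_elem, 1), gb1p(b1.n_elem, 1, arma::fill::zeros),
      sb1(b1.n_elem, 1, arma::fill::value(0.01));
  b1m.col(0) = b1;
  arma::mat W2m(1, W2.n_elem), gW2p(1, W2.n_elem, arma::fill::zeros),
      sW2(1, W2.n_elem, arma::fill::value(0.01));
  W2m.row(0) = W2;
  arma::mat b2m(1, 1), gb2p(1, 1, arma::fill::zeros),
      sb2(1, 1, arma::fill::value(0.01));
  b2m(0, 0) = b2;

  arma::mat bW1 = W1, bb1 = b1m, bW2 = W2m, bb2 = b2m;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, bad = 0, epochs_run = 0;
  std::vector<double> tr_hist, val_hist;
  const double wsum = arma::sum(wt);

  for (int ep = 0; ep < max_epochs; ++ep) {
    arma::mat A1;
    arma::vec p =
        forward_mlp(Xt, W1, b1m.col(0), arma::rowvec(W2m.row(0)), b2m(0, 0), &A1);
    tr_hist.push_back(xent(p, yt, wt));
    // gradients of the weighted cross-entropy
    arma::vec dz2 = (p - yt) % wt / wsum;
    arma::mat gW2 = dz2.t() * A1;          // 1 x h
    double gb2 = arma::sum(dz2);
    arma::mat dz1 = (dz2 * W2m.row(0)) % (1.0 - arma::square(A1));  // n x h
    arma::mat gW1 = dz1.t() * Xt;          // h x d
    arma::mat gb1 = arma::sum(dz1, 0).t(); // h x 1

    rprop_update(W1, gW1, gW1p, sW1);
    rprop_update(b1m, gb1, gb1p, sb1);
    rprop_update(W2m, gW2, gW2p, sW2);
    { // scalar bias through the same machinery
      arma::mat g(1, 1);
      g(0, 0) = gb2;
      rprop_update(b2m, g, gb2p, sb2);
    }
    epochs_run = ep + 1;

    if (has_val) {
      arma::vec pv =
          forward_mlp(Xv, W1, b1m.col(0), arma::rowvec(W2m.row(0)), b2m(0, 0));
      double lv = xent(pv, yv, wv);
      val_hist.push_back(lv);
      if (lv < best_val - 1e-9) {
        best_val = lv;
        best_epoch = ep + 1;
        bW1 = W1;
        bb1 = b1m;
        bW2 = W2m;
        bb2 = b2m;
        bad = 0;
      } else if (++bad >= patience) {
        break;
      }
    }
  }
  if (has_val && std::isfinite(best_val)) {
    W1 = bW1;
    b1m = bb1;
    W2m = bW2;
    b2m = bb2;
  } else {
    best_epoch = epochs_run;
  }
  return List::create(
      _["W1"] = W1, _["b1"] = arma::vec(b1m.col(0)),
      _["W2"] = arma::rowvec(W2m.row(0)), _["b2"] = b2m(0, 0),
      _["epochs_run"] = epochs_run, _["best_epoch"] = best_epoch,
      _["train_loss"] = tr_hist, _["val_loss"] = val_hist);
}

// [[Rcpp::export]]
arma::vec cpp_mlp_predict(const arma::mat &X, const arma::mat &W1,
                          const arma::vec &b1, const arma::rowvec &W2,
                          double b2) {
  return forward_mlp(X, W1, b1, W2, b2);
}
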
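#include <Rcpp.h>
using namespace Rcpp;

// Exact continuous-time simulation of the replacement process.
//
// Events: "an individual of species a is replaced by an offspring of
// species b".  Species b is inserted at rate N * omega_b with
//   omega_b = eta_b + eps1 * (M^T eta)_b * theta(eta_b)
//           + eps2 * (L^T eta)_b * eta_b + eps3 * (H^T eta)_b * theta(eta_b)
// and the victim is chosen uniformly among the N individuals.  This is the
// unique time scale whose N -> infinity drift is the mean-field equation
// (gain omega_s, loss eta_s * sum_i omega_i).  Self-replacement (a == b) is
// allowed; it changes nothing and contributes no drift.
//
// The aggregates u = M^T eta, v = L^T eta, h = H^T eta are maintained
// incrementally (O(S) per event) and refreshed periodically to control
// floating-point drift.  theta(0) = 0: an extinct species has rate exactly
// zero and can never re-enter.

// [[Rcpp::export]]
List gillespie_run_cpp(IntegerVector n0,
                       NumericMatrix M, NumericMatrix L, NumericMatrix H,
                       double eps1, double eps2, double eps3,
                       NumericVector record_times) {
  const int S = n0.size();
  double N = 0.0;
  for (int i = 0; i < S; ++i) {
    if (n0[i] < 0) stop("negative initial count");
    N += n0[i];
  }
  if (N <= 0) stop("empty community");
  std::vector<double> n(S), eta(S), u(S, 0.0), vL(S, 0.0), hH(S, 0.0),
      w(S, 0.0), cums(S, 0.0);
  int alive = 0;
  for (int i = 0; i < S; ++i) {
    n[i] = n0[i];
    eta[i] = n[i] / N;
    if (n[i] > 0) ++alive;
  }
  const bool useM = eps1 != 0.0, useL = eps2 != 0.0, useH = eps3 != 0.0;
  for (int j = 0; j < S; ++j) {
    double a = 0, b = 0, c = 0;
    for (int k = 0; k < S; ++k) {
      a += eta[k] * M(k, j);
      b += eta[k] * L(k, j);
      c += eta[k] * H(k, j);
    }
    u[j] = a; vL[j] = b; hH[j] = c;
  }
  const int nrec = record_times.size();
  NumericMatrix counts(nrec, S);
  double t = 0.0;
  int irec = 0;
  double nev = 0.0;
  long refresh = 0;
  bool absorbed = false;
  while (irec < nrec) {
    double tot = 0.0;
    for (int j = 0; j < S; ++j) {
      double wj = 0.0;
      if (eta[j] > 0.0) {
        wj = eta[j];
        if (useM) wj += eps1 * u[j];
        if (useL) wj += eps2 * vL[j] * eta[j];
        if (useH) wj += eps3 * hH[j];
      }
      if (wj < 0.0) {
        if (wj > -1e-12) wj = 0.0;
        else stop("negative replacement rate for species %d at t = %g (omega = %g)",
                  j + 1, t, wj);
      }
      w[j] = wj;
      tot += wj;
      cums[j] = tot;
    }
    if (alive <= 1 || tot <= 0.0) {
      absorbed = true;
      for (; irec < nrec; ++irec)
        for (int i = 0; i < S; ++i) counts(irec, i) = n[i];
      break;
    }
    double dt = R::exp_rand() / (N * tot);
    double tnew = t + dt;
    while (irec < nrec && record_times[irec] < tnew) {
      for (int i = 0; i < S; ++i) counts(irec, i) = n[i];
      ++irec;
    }
    if (irec >= nrec) { t = tnew; break; }
    // born species ~ omega
    int b = 0;
    {
      double r = unif_rand() * tot;
      while (b < S - 1 && r > cums[b]) ++b;
    }
    // victim: uniform individual
    int a = 0;
    {
      double r = unif_rand() * N;
      double cc = 0.0;
      for (a = 0; a < S; ++a) {
        cc += n[a];
        if (r <= cc) break;
      }
      if (a == S) a = S - 1;
    }
    if (a != b) {
      if (n[a] == 1.0) --alive;
      n[a] -= 1.0;
      n[b] += 1.0;
      eta[a] = n[a] / N;
      eta[b] = n[b] / N;
      const double inv = 1.0 / N;
      for (int j = 0; j < S; ++j) {
        u[j]  += (M(b, j) - M(a, j)) * inv;
        vL[j] += (L(b, j) - L(a, j)) * inv;
        hH[j] += (H(b, j) - H(a, j)) * inv;
      }
      if ((++refresh & 0xFFFF) == 0) {
        for (int j = 0; j < S; ++j) {
          double aa = 0, bb = 0, cc2 = 0;
          for (int k = 0; k < S; ++k) {
            aa += eta[k] * M(k, j);
            bb += eta[k] * L(k, j);
            cc2 += eta[k] * H(k, j);
          }
          u[j] = aa; vL[j] = bb; hH[j] = cc2;
        }
      }
    }
    t = tnew;
    nev += 1.0;
  }
  return List::create(_["counts"] = counts, _["t_end"] = t,
                      _["events"] = nev, _["absorbed"] = absorbed);
}
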
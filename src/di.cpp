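#include <Rcpp.h>
using namespace Rcpp;

// Direct Information for every site pair of a mean-field Potts model.
//
// einv: the (L*(q-1)) x (L*(q-1)) coupling matrix e_ij(a,b) over the reduced
//       alphabet (reference state q omitted; its couplings are 0).
// f:    L x q single-site frequencies.
//
// For each i<j the two-site "direct" distribution is
//   P_dir(a,b) ∝ exp(e_ij(a,b)) * x_i(a) * x_j(b)
// with auxiliary fields x fixed-point iterated until both marginals match
// f_i, f_j within `tol` (max `maxit` iterations), then
//   DI_ij = sum_ab P_dir(a,b) log( P_dir(a,b) / (f_i(a) f_j(b)) ).
// Non-convergent pairs get NaN.
// [[Rcpp::export]]
NumericMatrix direct_information_cpp(NumericMatrix einv, NumericMatrix f,
                                     int L, int q, double tol, int maxit) {
  int qr = q - 1;
  NumericMatrix di(L, L);
  std::vector<double> W(q * q), mu1(q), mu2(q), s1(q), s2(q), n1(q), n2(q);

  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      // W(a,b) = exp(e_ij(a,b)); reference row/col = exp(0) = 1
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b)
          W[a * q + b] = (a < qr && b < qr)
            ? std::exp(einv(i * qr + a, j * qr + b)) : 1.0;

      for (int a = 0; a < q; ++a) { mu1[a] = 1.0 / q; mu2[a] = 1.0 / q; }
      bool ok = false;
      for (int it = 0; it < maxit; ++it) {
        double z1 = 0, z2 = 0;
        for (int a = 0; a < q; ++a) {
          double acc = 0;
          for (int b = 0; b < q; ++b) acc += W[a * q + b] * mu2[b];
          s1[a] = acc;
        }
        for (int b = 0; b < q; ++b) {
          double acc = 0;
          for (int a = 0; a < q; ++a) acc += W[a * q + b] * mu1[a];
          s2[b] = acc;
        }
        for (int a = 0; a < q; ++a) { n1[a] = f(i, a) / s1[a]; z1 += n1[a]; }
        for (int b = 0; b < q; ++b) { n2[b] = f(j, b) / s2[b]; z2 += n2[b]; }
        double diff = 0;
        for (int a = 0; a < q; ++a) {
          n1[a] /= z1; n2[a] /= z2;
          diff = std::max(diff, std::fabs(n1[a] - mu1[a]));
          diff = std::max(diff, std::fabs(n2[a] - mu2[a]));
          mu1[a] = n1[a]; mu2[a] = n2[a];
        }
        if (diff < tol) { ok = true; break; }
      }
      if (!ok) { di(i, j) = di(j, i) = NA_REAL; continue; }

      double z = 0;
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b) z += mu1[a] * W[a * q + b] * mu2[b];
      double val = 0;
      for (int a = 0; a < q; ++a) {
        for (int b = 0; b < q; ++b) {
          double p = mu1[a] * W[a * q + b] * mu2[b] / z;
          double fifj = f(i, a) * f(j, b);
          if (p > 1e-300 && fifj > 1e-300) val += p * std::log(p / fifj);
        }
      }
      if (val < 0 && val > -1e-10) val = 0; // numerical floor: DI is a KL divergence
      di(i, j) = di(j, i) = val;
    }
  }
  return di;
}
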
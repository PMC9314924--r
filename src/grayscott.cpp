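#include <Rcpp.h>
using namespace Rcpp;

// Gray-Scott reaction-diffusion integrator.
//   du/dt = Du lap(u) - u v^2 + F (1 - u)
//   dv/dt = Dv lap(v) + u v^2 - (F + k) v
// The feed rate F varies along x (columns), the kill rate k along y (rows),
// so one integration yields a whole parameter-sheet "gamut" of textures.
// Zero-flux (clamped) boundaries avoid mixing opposite parameter extremes.
// Returns the u field; aborts with non-finite values left in place when the
// integration diverges (caller reports the offending F,k corner).

// [[Rcpp::export]]
NumericMatrix gray_scott_cpp(NumericMatrix u0, NumericMatrix v0,
                             NumericVector F_col, NumericVector k_row,
                             double Du, double Dv, double dt, int iterations) {
  int nr = u0.nrow(), nc = u0.ncol();
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> un(u), vn(v);

  for (int it = 0; it < iterations; ++it) {
    for (int j = 0; j < nc; ++j) {
      int jm = j > 0 ? j - 1 : 0;
      int jp = j < nc - 1 ? j + 1 : nc - 1;
      double F = F_col[j];
      for (int i = 0; i < nr; ++i) {
        int im = i > 0 ? i - 1 : 0;
        int ip = i < nr - 1 ? i + 1 : nr - 1;
        double k = k_row[i];
        int c = i + j * nr;
        double uc = u[c], vc = v[c];
        double lap_u = u[im + j * nr] + u[ip + j * nr] +
                       u[i + jm * nr] + u[i + jp * nr] - 4.0 * uc;
        double lap_v = v[im + j * nr] + v[ip + j * nr] +
                       v[i + jm * nr] + v[i + jp * nr] - 4.0 * vc;
        double uvv = uc * vc * vc;
        un[c] = uc + dt * (Du * lap_u - uvv + F * (1.0 - uc));
        vn[c] = vc + dt * (Dv * lap_v + uvv - (F + k) * vc);
      }
    }
    u.swap(un);
    v.swap(vn);
    if (it % 500 == 499) {  // divergence guard
      bool bad = false;
      for (int c = 0; c < nr * nc; ++c)
        if (!R_finite(u[c]) || std::fabs(u[c]) > 1e6) { bad = true; break; }
      if (bad) break;
    }
  }
  NumericMatrix out(nr, nc);
  std::copy(u.begin(), u.end(), out.begin());
  return out;
}
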
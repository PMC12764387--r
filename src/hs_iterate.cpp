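#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Jacobi iteration for the Horn-Schunck functional given the
// spatiotemporal derivative estimates. The flow update at each pixel is
// the classical one: (u, v) = neighbourhood average minus the
// brightness-constancy correction along the image gradient. The
// neighbourhood average uses 1/6 edge + 1/12 corner weights with
// replicate padding at the image border. Stops at n_iter or when the
// mean absolute update of (u, v) falls below tol.
// [[Rcpp::export]]
List hs_iterate(NumericMatrix Ex, NumericMatrix Ey, NumericMatrix Et,
                double alpha, int n_iter, double tol) {
  const int h = Ex.nrow(), w = Ex.ncol(), n = h * w;
  std::vector<double> u(n, 0.0), v(n, 0.0), un(n), vn(n), coef(n);
  const double *ex = Ex.begin(), *ey = Ey.begin(), *et = Et.begin();
  std::vector<double> idenom(n);
  const double a2 = alpha * alpha;
  for (int k = 0; k < n; ++k)
    idenom[k] = 1.0 / (a2 + ex[k] * ex[k] + ey[k] * ey[k]);
  int iterations = 0;
  for (int it = 0; it < n_iter; ++it) {
    double delta = 0.0;
    for (int j = 0; j < w; ++j) {
      const int jm = (j > 0 ? j - 1 : 0) * h;
      const int jc = j * h;
      const int jp = (j < w - 1 ? j + 1 : w - 1) * h;
      for (int i = 0; i < h; ++i) {
        const int im = i > 0 ? i - 1 : 0;
        const int ip = i < h - 1 ? i + 1 : h - 1;
        const double ub =
          (u[jc + im] + u[jc + ip] + u[jm + i] + u[jp + i]) / 6.0 +
          (u[jm + im] + u[jm + ip] + u[jp + im] + u[jp + ip]) / 12.0;
        const double vb =
          (v[jc + im] + v[jc + ip] + v[jm + i] + v[jp + i]) / 6.0 +
          (v[jm + im] + v[jm + ip] + v[jp + im] + v[jp + ip]) / 12.0;
        const int k = jc + i;
        const double c = (ex[k] * ub + ey[k] * vb + et[k]) * idenom[k];
        un[k] = ub - ex[k] * c;
        vn[k] = vb - ey[k] * c;
        delta += std::abs(un[k] - u[k]) + std::abs(vn[k] - v[k]);
      }
    }
    u.swap(un);
    v.swap(vn);
    iterations = it + 1;
    if (delta / n < tol) break;
  }
  NumericMatrix uo(h, w), vo(h, w);
  std::copy(u.begin(), u.end(), uo.begin());
  std::copy(v.begin(), v.end(), vo.begin());
  return List::create(_["u"] = uo, _["v"] = vo,
                      _["iterations"] = iterations);
}
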
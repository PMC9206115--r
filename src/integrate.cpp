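#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Forward-Euler integration of the reduced three-field model on a periodic
// lattice for a fixed noise field W (one noise epoch).  The 5-point
// Laplacian keeps the discrete conservation identities exact per step; a
// floor at zero enforces non-negativity after each update.  Fields are
// copied into plain buffers so the hot loop works on restrict-qualified
// raw arrays (column-major, index i + ny*j).
// [[Rcpp::export(name = ".cw_integrate_chunk")]]
List cw_integrate_chunk(NumericMatrix RT, NumericMatrix RD, NumericMatrix F,
                        NumericMatrix W, List par, int nsteps, double dt,
                        double dx) {
  const int ny = RT.nrow(), nx = RT.ncol(), n = ny * nx;
  const double k0 = par["k0"], k1 = par["k1"], k2 = par["k2"], k3 = par["k3"],
               k4 = par["k4"], k5 = par["k5"], k6 = par["k6"], k7 = par["k7"],
               k8 = par["k8"], k9 = par["k9"], k10 = par["k10"],
               alpha = par["alpha"], beta = par["beta"], D_RT = par["D_RT"],
               D_RD = par["D_RD"], D_F = par["D_F"];
  const double idx2 = 1.0 / (dx * dx);
  const double k4b = k4 * (1.0 + beta);
  const double cRT = D_RT * idx2, cRD = D_RD * idx2, cF = D_F * idx2;

  std::vector<double> a(RT.begin(), RT.end()), b(RD.begin(), RD.end()),
      c(F.begin(), F.end()), w(W.begin(), W.end());
  std::vector<double> na(n), nb(n), nc(n);
  std::vector<int> up(ny), dn(ny), lf(nx), rg(nx);
  for (int i = 0; i < ny; ++i) {
    up[i] = (i == 0) ? ny - 1 : i - 1;
    dn[i] = (i == ny - 1) ? 0 : i + 1;
  }
  for (int j = 0; j < nx; ++j) {
    lf[j] = (j == 0) ? (nx - 1) * ny : (j - 1) * ny;
    rg[j] = (j == nx - 1) ? 0 : (j + 1) * ny;
  }

  double *pa = a.data(), *pb = b.data(), *pc = c.data();
  double *qa = na.data(), *qb = nb.data(), *qc = nc.data();
  const double *pw = w.data();

  for (int step = 0; step < nsteps; ++step) {
    for (int j = 0; j < nx; ++j) {
      const int col = j * ny, cl = lf[j], cr = rg[j];
      for (int i = 0; i < ny; ++i) {
        const int k = col + i, ku = col + up[i], kd = col + dn[i];
        const double rt = pa[k], rd = pb[k], f = pc[k];
        const double rt2 = rt * rt;
        const double R = (k0 + alpha * k1 * rt2 * rt / (1.0 + k2 * rt2)) * rd -
                         (k3 + k4b * f) * rt;
        const double lrt =
            pa[ku] + pa[kd] + pa[cl + i] + pa[cr + i] - 4.0 * rt;
        const double lrd =
            pb[ku] + pb[kd] + pb[cl + i] + pb[cr + i] - 4.0 * rd;
        const double lf_ =
            pc[ku] + pc[kd] + pc[cl + i] + pc[cr + i] - 4.0 * f;
        double vrt = rt + dt * (R + cRT * lrt);
        double vrd = rd + dt * (k5 - k6 * rd - R + cRD * lrd);
        double vf = f + dt * (k7 + k8 * rt2 / (1.0 + k9 * rt2) -
                              k10 * pw[k] * f + cF * lf_);
        qa[k] = vrt > 0.0 ? vrt : 0.0;
        qb[k] = vrd > 0.0 ? vrd : 0.0;
        qc[k] = vf > 0.0 ? vf : 0.0;
      }
    }
    std::swap(pa, qa);
    std::swap(pb, qb);
    std::swap(pc, qc);
    if ((step & 255) == 0 && !R_finite(pa[0]))
      stop("non-finite field detected during integration (step %d)", step);
  }
  for (int k = 0; k < n; ++k)
    if (!R_finite(pa[k]) || !R_finite(pb[k]) || !R_finite(pc[k]))
      stop("non-finite field detected during integration");

  NumericMatrix oa(ny, nx), ob(ny, nx), oc(ny, nx);
  std::copy(pa, pa + n, oa.begin());
  std::copy(pb, pb + n, ob.begin());
  std::copy(pc, pc + n, oc.begin());
  return List::create(_["RT"] = oa, _["RD"] = ob, _["F"] = oc);
}
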
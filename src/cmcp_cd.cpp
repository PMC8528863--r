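#include <Rcpp.h>
using namespace Rcpp;

// Inner MCP penalty value: f(t; lam, g) for t >= 0.
static inline double mcp_val(double t, double lam, double g) {
  if (t <= g * lam) return lam * t - t * t / (2.0 * g);
  return g * lam * lam / 2.0;
}

// MCP derivative for t >= 0 (0 beyond the plateau).
static inline double mcp_d(double t, double lam, double g) {
  double d = lam - t / g;
  return d > 0.0 ? d : 0.0;
}

// Firm threshold: exact minimizer of 0.5*(b-z)^2 + MCP(|b|; lam, g), g > 1.
static inline double firm(double z, double lam, double g) {
  double az = std::fabs(z);
  if (az <= g * lam) {
    double s = az - lam;
    if (s <= 0.0) return 0.0;
    return (z > 0 ? 1.0 : -1.0) * s / (1.0 - 1.0 / g);
  }
  return z;
}

// Univariate surrogate objective 0.5*(b-z)^2 + w * MCP(|b|; lam, gi).
static inline double uni_obj(double b, double z, double w, double lam, double gi) {
  return 0.5 * (b - z) * (b - z) + w * mcp_val(std::fabs(b), lam, gi);
}

// Outer (group-level) penalty: MCP(s/lam; Kg*lam, go). Dividing the inner
// sum by lam makes the composite penalty lambda-homogeneous of degree 2,
// so rescaling y and lambda by c rescales coefficients by c exactly.
static inline double outer_val(double s, double lam, double Kg, double go) {
  if (lam <= 0.0) return 0.0;
  return mcp_val(s / lam, Kg * lam, go);
}

// d/ds of outer_val: max(0, Kg - s/(go*lam^2)).
static inline double outer_d(double s, double lam, double Kg, double go) {
  if (lam <= 0.0) return 0.0;
  double d = Kg - s / (go * lam * lam);
  return d > 0.0 ? d : 0.0;
}

// Coordinate descent over a lambda path for the composite MCP objective
//   (1/2n)||y - Xb||^2 + sum_g MCP_outer( sum_k MCP_inner(|b_gk|; lam, gi);
//                                          Kg*lam, go )
// Penalized columns must have (1/n) x'x == 1 (standardized); unpenalized
// columns are updated by exact least squares. Warm starts along the grid.
// [[Rcpp::export]]
List cmcp_cd_path(NumericMatrix X, NumericVector y, IntegerVector grp,
                  LogicalVector pen, NumericVector Kg, NumericVector lambda,
                  double gamma_inner, double gamma_outer, double tol,
                  int max_iter, bool track_objective) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  const int G = Kg.size();

  std::vector<double> v(p);           // (1/n) x_k' x_k
  for (int k = 0; k < p; ++k) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += X(i, k) * X(i, k);
    v[k] = acc / n;
  }

  std::vector<double> b(p, 0.0), r(y.begin(), y.end()), s(G, 0.0);
  NumericMatrix beta(p, L);
  NumericVector rss_out(L), obj_out(L);
  IntegerVector iters(L);
  LogicalVector conv(L);
  List obj_trace(L);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    // inner MCP depends on lam: refresh group sums for this grid point
    std::fill(s.begin(), s.end(), 0.0);
    for (int k = 0; k < p; ++k)
      if (pen[k]) s[grp[k]] += mcp_val(std::fabs(b[k]), lam, gamma_inner);

    std::vector<double> sweep_obj;
    int it = 0;
    bool converged = false;
    bool full_sweep = true;  // alternate: active-set cycles, full checks
    while (it < max_iter) {
      ++it;
      double maxdiff = 0.0;
      for (int k = 0; k < p; ++k) {
        if (!full_sweep && pen[k] && b[k] == 0.0) continue;
        const int g = grp[k];
        if (v[k] <= 0.0) { continue; }  // degenerate (all-zero) column
        double z = 0.0;
        for (int i = 0; i < n; ++i) z += X(i, k) * r[i];
        z = z / n + v[k] * b[k];
        double bnew;
        if (!pen[k]) {
          bnew = z / v[k];
        } else {
          const double fi_old = mcp_val(std::fabs(b[k]), lam, gamma_inner);
          const double w = outer_d(s[g], lam, Kg[g], gamma_outer);
          if (w <= 1e-300) {
            bnew = z;                   // group penalty locally flat
          } else {
            const double gp = gamma_inner / w;
            if (gp > 1.0 + 1e-8) {
              bnew = firm(z, w * lam, gp);
            } else {
              // strongly concave surrogate: minimum at a candidate point
              double c0 = uni_obj(0.0, z, w, lam, gamma_inner);
              double edge = (z >= 0 ? 1.0 : -1.0) * gamma_inner * lam;
              double c1 = uni_obj(edge, z, w, lam, gamma_inner);
              double c2 = uni_obj(z, z, w, lam, gamma_inner);
              bnew = 0.0;
              double cbest = c0;
              if (c1 < cbest) { cbest = c1; bnew = edge; }
              if (c2 < cbest) { bnew = z; }
            }
          }
          if (bnew != b[k]) {
            s[g] += mcp_val(std::fabs(bnew), lam, gamma_inner) - fi_old;
            if (s[g] < 0.0) s[g] = 0.0;
          }
        }
        const double d = bnew - b[k];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= d * X(i, k);
          b[k] = bnew;
          const double ad = std::fabs(d);
          if (ad > maxdiff) maxdiff = ad;
        }
      }
      if (track_objective) {
        double rss = 0.0;
        for (int i = 0; i < n; ++i) rss += r[i] * r[i];
        double ob = rss / (2.0 * n);
        for (int g = 0; g < G; ++g)
          ob += outer_val(s[g], lam, Kg[g], gamma_outer);
        sweep_obj.push_back(ob);
      }
      if (maxdiff < tol) {
        if (full_sweep) { converged = true; break; }
        full_sweep = true;      // active set stable: verify on all columns
      } else {
        full_sweep = false;     // keep cycling the active set
      }
    }

    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    double ob = rss / (2.0 * n);
    for (int g = 0; g < G; ++g) ob += outer_val(s[g], lam, Kg[g], gamma_outer);
    for (int k = 0; k < p; ++k) beta(k, l) = b[k];
    rss_out[l] = rss;
    obj_out[l] = ob;
    iters[l] = it;
    conv[l] = converged;
    if (track_objective) obj_trace[l] = wrap(sweep_obj);
  }

  return List::create(_["beta"] = beta, _["rss"] = rss_out,
                      _["objective"] = obj_out, _["iters"] = iters,
                      _["converged"] = conv, _["obj_trace"] = obj_trace,
                      _["colnorm2_n"] = wrap(v));
}
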
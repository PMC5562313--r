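#include <Rcpp.h>
using namespace Rcpp;

// Explicit (forward-time, central-space) diffusion substeps on a cubic
// lattice. Only the sites listed in `active` are updated; every other site
// (clamped Dirichlet sources, excluded phases) keeps its value, so neighbors
// read fixed concentrations from them. `nb` holds, per active site, the six
// face-neighbor flat indices (0-based; the site's own index where the face is
// closed) and `cond` the matching face diffusivities (harmonic means,
// um^2/s; 0 where the face is closed). `r` is dt/dx^2 in s/um^2.
// Reaction is co-integrated with diffusion: `sec_sub` is a frozen secretion
// source (mM per substep, >= 0) and `sink_sub`/`Km` a Michaelis-Menten
// consumption term `sink_sub * C / (Km + C)` (sink_sub in mM per substep at
// saturation), so uptake follows the enzyme-saturation law continuously and
// can never drive a site negative. Pass zero-length vectors for pure
// diffusion.
// [[Rcpp::export]]
NumericVector diffuse_substeps_cpp(NumericVector C,
                                   IntegerVector active,
                                   IntegerMatrix nb,
                                   NumericMatrix cond,
                                   double r,
                                   int nsub,
                                   NumericVector sec_sub,
                                   NumericVector sink_sub,
                                   double Km) {
  const int na = active.size();
  if (nb.nrow() != 6 || cond.nrow() != 6 || nb.ncol() != na || cond.ncol() != na)
    stop("neighbor/conductance tables must be 6 x n_active");
  const bool react = sink_sub.size() > 0;
  if (react && (sink_sub.size() != C.size() || sec_sub.size() != C.size()))
    stop("reaction fields must match the field length");
  NumericVector A = clone(C);
  NumericVector B = clone(C);
  double *__restrict__ a = REAL(A);
  double *__restrict__ b = REAL(B);
  const int *act = INTEGER(active);
  const int *nbp = INTEGER(nb);
  const double *cd = REAL(cond);
  const double *se = react ? REAL(sec_sub) : (double *)0;
  const double *sk = react ? REAL(sink_sub) : (double *)0;
  for (int it = 0; it < nsub; ++it) {
    const int *nk = nbp;
    const double *ck = cd;
    for (int k = 0; k < na; ++k, nk += 6, ck += 6) {
      const int i = act[k];
      const double ci = a[i];
      const double s0 = ck[0] * a[nk[0]] + ck[1] * a[nk[1]];
      const double s1 = ck[2] * a[nk[2]] + ck[3] * a[nk[3]];
      const double s2 = ck[4] * a[nk[4]] + ck[5] * a[nk[5]];
      const double csum = ck[0] + ck[1] + ck[2] + ck[3] + ck[4] + ck[5];
      double v = ci + r * (s0 + s1 + s2 - csum * ci);
      if (react) {
        const double s = sk[i];
        if (s != 0.0 || se[i] != 0.0) {
          v += se[i] - s * ci / (Km + ci);
          if (v < 0) v = 0;
        }
      }
      b[i] = v;
    }
    double *tmp = a; a = b; b = tmp;
  }
  return (a == REAL(A)) ? A : B;
}

// Build the active-site list, neighbor table and face conductances for one
// species in one pass. `permitted` marks sites the species occupies,
// `clamped` marks Dirichlet sources (permitted but never updated), `nbtab`
// is the full 6 x n neighbor table with -1 at domain faces. Face
// conductance is the harmonic mean of the two sites' effective
// diffusivities; a closed face gets conductance 0 and the self-index so the
// update kernel needs no branches.
// [[Rcpp::export]]
List build_plan_cpp(NumericVector Deff, LogicalVector permitted,
                    LogicalVector clamped, IntegerMatrix nbtab) {
  const int n = Deff.size();
  const int *nbp = INTEGER(nbtab);
  const double *dv = REAL(Deff);
  const int *pm = LOGICAL(permitted);
  const int *cl = LOGICAL(clamped);
  std::vector<int> act;
  act.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (pm[i] && !cl[i]) act.push_back(i);
  }
  const int na = (int)act.size();
  IntegerVector active(na);
  IntegerMatrix nb(6, na);
  NumericMatrix cond(6, na);
  int *nbo = INTEGER(nb);
  double *cdo = REAL(cond);
  for (int k = 0; k < na; ++k) {
    const int i = act[k];
    active[k] = i;
    const int *nk = nbp + 6 * (size_t)i;
    const double di = dv[i];
    for (int j = 0; j < 6; ++j) {
      const int nbi = nk[j];
      double h = 0.0;
      int tgt = i;
      if (nbi >= 0 && pm[nbi]) {
        const double dn = dv[nbi];
        if (di + dn > 0) {
          h = 2.0 * di * dn / (di + dn);
          tgt = nbi;
        }
      }
      nbo[6 * (size_t)k + j] = tgt;
      cdo[6 * (size_t)k + j] = h;
    }
  }
  return List::create(_["active0"] = active, _["nb0"] = nb, _["cond"] = cond);
}

// Iterative overflow relaxation for biomass pushing. Arrays are full-lattice
// (length n); nb6 is the 6 x n table of face-neighbor indices with -1 where
// the face crosses the domain boundary (absorbing: exported mass vanishes).
// `blocked` marks sites biomass may never enter (agar). Each sweep, every
// site above cap exports its excess, split equally over eligible faces
// (non-blocked neighbor or domain boundary), preserving the local phenotype
// proportions of the two biomass fields m1/m2. Returns the number of sweeps
// used, or -1 if max_sweeps was exhausted.
// [[Rcpp::export]]
int push_biomass_cpp(NumericVector m1, NumericVector m2,
                     IntegerMatrix nb6, LogicalVector blocked,
                     double cap, double tol, int max_sweeps,
                     LogicalVector suppressed) {
  const int n = m1.size();
  double *p1 = REAL(m1);
  double *p2 = REAL(m2);
  const int *nbp = INTEGER(nb6);
  std::vector<double> d1(n), d2(n);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double worst = 0.0;
    for (int i = 0; i < n; ++i) {
      double over = p1[i] + p2[i] - cap;
      if (over > worst) worst = over;
    }
    if (worst <= tol) return sweep;
    std::fill(d1.begin(), d1.end(), 0.0);
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double tot = p1[i] + p2[i];
      const double over = tot - cap;
      if (over <= tol) continue;
      const int *nk = nbp + 6 * i;
      int nelig = 0;
      for (int j = 0; j < 6; ++j) {
        const int nbi = nk[j];
        if (nbi < 0 || !blocked[nbi]) ++nelig;
      }
      if (nelig == 0) { suppressed[i] = true; continue; }
      const double f1 = p1[i] / tot;
      const double e1 = over * f1, e2 = over * (1.0 - f1);
      d1[i] -= e1;
      d2[i] -= e2;
      const double s1 = e1 / nelig, s2 = e2 / nelig;
      for (int j = 0; j < 6; ++j) {
        const int nbi = nk[j];
        if (nbi < 0) continue;            // absorbed at the domain boundary
        if (blocked[nbi]) continue;
        d1[nbi] += s1;
        d2[nbi] += s2;
      }
    }
    for (int i = 0; i < n; ++i) {
      p1[i] += d1[i];
      p2[i] += d2[i];
      if (p1[i] < 0) p1[i] = 0;
      if (p2[i] < 0) p2[i] = 0;
    }
  }
  return -1;
}
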
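// Analog coupled photon-electron transport through a 1-D layered slab
// stack. Full 3-D directions are tracked; boundaries exist in z only
// (infinite lateral slabs). Photons fly exponential path lengths and
// interact by photoelectric absorption (shell-resolved, with K
// fluorescence), Klein-Nishina incoherent scattering (Kahn sampling) and
// Thomson-angle coherent scattering. Electrons advance by condensed-
// history steps: continuous collisional loss, Highland multiple
// scattering, and 1/k bremsstrahlung with an emission probability that
// reproduces the radiative stopping power in expectation. Every keV of a
// primary's energy ends in a layer deposit or an escape account, exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double MEC2 = 511.0;        // keV
static const double EPS_Z = 1e-9;        // boundary nudge, cm

// ---------------------------------------------------------------------
// direction utilities

static inline void iso_dir(double &u, double &v, double &w) {
  w = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - w * w));
  u = s * std::cos(phi);
  v = s * std::sin(phi);
}

// rotate (u,v,w) by polar angle with cosine `cost` and azimuth `phi`
static void rotate_dir(double &u, double &v, double &w,
                       double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cp = std::cos(phi), sp = std::sin(phi);
  double nu, nv, nw;
  if (std::fabs(w) > 0.999999999) {
    double sgn = (w > 0) ? 1.0 : -1.0;
    nu = sint * cp;
    nv = sint * sp;
    nw = sgn * cost;
  } else {
    double s = std::sqrt(1.0 - w * w);
    nu = u * cost + sint * (u * w * cp - v * sp) / s;
    nv = v * cost + sint * (v * w * cp + u * sp) / s;
    nw = w * cost - sint * cp * s;
  }
  double nrm = std::sqrt(nu * nu + nv * nv + nw * nw);
  u = nu / nrm; v = nv / nrm; w = nw / nrm;
}

// ---------------------------------------------------------------------
// samplers

// Kahn acceptance-rejection sampling of the Klein-Nishina distribution.
// x = E/E'; returns scattered/electron energies and polar cosines.
static void kahn_compton(double E, double &Eout, double &cost,
                         double &Ee, double &coste) {
  double a = E / MEC2;
  double x = 1.0;
  for (;;) {
    double r1 = unif_rand(), r2 = unif_rand(), r3 = unif_rand();
    if (r1 <= (2.0 * a + 1.0) / (2.0 * a + 9.0)) {
      x = 1.0 + 2.0 * a * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) break;
    } else {
      x = (2.0 * a + 1.0) / (1.0 + 2.0 * a * r2);
      double c = 1.0 - (x - 1.0) / a;
      if (r3 <= 0.5 * (c * c + 1.0 / x)) break;
    }
  }
  cost = 1.0 - (x - 1.0) / a;
  Eout = E / x;
  Ee = E - Eout;
  double omc = 1.0 - cost;
  if (omc < 1e-12) {
    coste = 0.0;  // grazing event, electron energy ~0
  } else {
    double t = std::sqrt(std::max(0.0, 1.0 - cost * cost)) /
               ((1.0 + a) * omc);
    coste = 1.0 / std::sqrt(1.0 + t * t);
  }
}

// Thomson angular distribution, pdf ~ (1 + mu^2)
static double thomson_cost() {
  for (;;) {
    double mu = 2.0 * unif_rand() - 1.0;
    if (unif_rand() <= 0.5 * (1.0 + mu * mu)) return mu;
  }
}

// ---------------------------------------------------------------------
// engine model unpacked from R

struct LayerPhys {
  double z0, z1, rho, X0, thick;
  std::vector<double> lpe, linc, lcoh;      // log partials on photon grid
  std::vector<double> lelem;                // log(w_i * tau_i), ngrid x ne
  int ne;
  std::vector<double> kedge, omK, eKx, fK, ledge;
  std::vector<double> scol, srad;           // keV cm2/g on electron grid
};

struct Engine {
  int nl;
  std::vector<LayerPhys> L;
  std::vector<double> pg;                   // log photon grid
  double eg0, egd;                          // electron grid: ln E0, dln
  int egn;
  double pcut, ecut, stepf;
  bool use_coh, atten_only;
  std::vector<double> dep;                  // keV per layer
  double esc_up, esc_dn;
};

static inline int grid_find(const std::vector<double> &g, double x) {
  int lo = 0, hi = (int)g.size() - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (g[mid] <= x) lo = mid; else hi = mid;
  }
  return lo;
}

static inline double interp_at(const std::vector<double> &g,
                               const std::vector<double> &v,
                               int i, double x) {
  double t = (x - g[i]) / (g[i + 1] - g[i]);
  return v[i] + t * (v[i + 1] - v[i]);
}

struct Particle {
  int kind;  // 0 photon, 1 electron
  double E;  // keV
  double z;  // cm
  double u, v, w;
  int layer;
};

// ---------------------------------------------------------------------

static void transport_photon(Engine &en, Particle p,
                             std::vector<Particle> &stack) {
  for (;;) {
    if (p.E <= en.pcut) { en.dep[p.layer] += p.E; return; }
    LayerPhys &ly = en.L[p.layer];
    double lE = std::log(p.E);
    int gi = grid_find(en.pg, lE);
    double pe = std::exp(interp_at(en.pg, ly.lpe, gi, lE));
    double inc = std::exp(interp_at(en.pg, ly.linc, gi, lE));
    double coh = en.use_coh ? std::exp(interp_at(en.pg, ly.lcoh, gi, lE))
                            : 0.0;
    double tot = pe + inc + coh;
    double mu = tot * ly.rho;
    double s = -std::log(unif_rand()) / mu;
    double db = 1e30;
    if (p.w > 1e-12) db = (ly.z1 - p.z) / p.w;
    else if (p.w < -1e-12) db = (ly.z0 - p.z) / p.w;
    if (db <= s) {
      if (p.w > 0) { p.z = ly.z1 + EPS_Z; p.layer += 1; }
      else         { p.z = ly.z0 - EPS_Z; p.layer -= 1; }
      if (p.layer < 0) { en.esc_up += p.E; return; }
      if (p.layer >= en.nl) { en.esc_dn += p.E; return; }
      continue;  // memoryless: resample in the new material
    }
    p.z += s * p.w;
    if (en.atten_only) { en.dep[p.layer] += p.E; return; }
    double xi = unif_rand() * tot;
    if (xi < pe) {
      // photoelectric: absorber ~ w_i tau_i(E)
      int ne = ly.ne, ng = (int)en.pg.size();
      double tsum = 0.0;
      std::vector<double> wj(ne);
      for (int j = 0; j < ne; ++j) {
        const double *col = &ly.lelem[(size_t)j * ng];
        double t = (lE - en.pg[gi]) / (en.pg[gi + 1] - en.pg[gi]);
        wj[j] = std::exp(col[gi] + t * (col[gi + 1] - col[gi]));
        tsum += wj[j];
      }
      double r = unif_rand() * tsum;
      int j = 0;
      for (; j < ne - 1; ++j) { if (r < wj[j]) break; r -= wj[j]; }
      double Ee = 0.0;
      if (p.E > ly.kedge[j] && unif_rand() < ly.fK[j]) {
        Ee = p.E - ly.kedge[j];
        if (unif_rand() < ly.omK[j]) {
          Particle fl = p; fl.kind = 0; fl.E = ly.eKx[j];
          iso_dir(fl.u, fl.v, fl.w);
          stack.push_back(fl);
          en.dep[p.layer] += ly.kedge[j] - ly.eKx[j];
        } else {
          en.dep[p.layer] += ly.kedge[j];  // non-radiative relaxation
        }
      } else {
        double eb = (p.E > ly.ledge[j]) ? ly.ledge[j] : p.E;
        en.dep[p.layer] += eb;
        Ee = p.E - eb;
      }
      if (Ee > 0) {
        Particle el = p; el.kind = 1; el.E = Ee;
        iso_dir(el.u, el.v, el.w);
        stack.push_back(el);
      }
      return;
    } else if (xi < pe + inc) {
      double Eout, cost, Ee, coste;
      kahn_compton(p.E, Eout, cost, Ee, coste);
      double phi = 2.0 * M_PI * unif_rand();
      if (Ee > en.ecut * 0.1) {
        Particle el = p; el.kind = 1; el.E = Ee;
        rotate_dir(el.u, el.v, el.w, coste, phi + M_PI);
        stack.push_back(el);
      } else {
        en.dep[p.layer] += Ee;  // sub-resolution recoil, deposit locally
      }
      rotate_dir(p.u, p.v, p.w, cost, phi);
      p.E = Eout;
    } else {
      rotate_dir(p.u, p.v, p.w, thomson_cost(),
                 2.0 * M_PI * unif_rand());
    }
  }
}

static void transport_electron(Engine &en, Particle p,
                               std::vector<Particle> &stack) {
  for (;;) {
    if (p.E <= en.ecut) { en.dep[p.layer] += p.E; return; }
    LayerPhys &ly = en.L[p.layer];
    double lE = std::log(p.E);
    double fi = (lE - en.eg0) / en.egd;
    int i = (int)fi;
    if (i < 0) i = 0;
    if (i > en.egn - 2) i = en.egn - 2;
    double t = fi - i;
    double scol = ly.scol[i] + t * (ly.scol[i + 1] - ly.scol[i]);
    double srad = ly.srad[i] + t * (ly.srad[i + 1] - ly.srad[i]);
    double stot = scol + srad;
    double ds = en.stepf * p.E / (stot * ly.rho);
    double dsl = ly.thick / 5.0;
    if (dsl < ds) ds = dsl;
    double db = 1e30;
    if (p.w > 1e-12) db = (ly.z1 - p.z) / p.w;
    else if (p.w < -1e-12) db = (ly.z0 - p.z) / p.w;
    bool cross = (db <= ds);
    if (cross) ds = db;
    double decol = scol * ly.rho * ds;
    if (decol > p.E) decol = p.E;
    double avail = p.E - decol;
    double k = 0.0;
    if (srad > 0 && p.E > 1.5 * en.pcut && avail > en.pcut) {
      double kmean = (p.E - en.pcut) / std::log(p.E / en.pcut);
      if (unif_rand() < srad * ly.rho * ds / kmean) {
        k = en.pcut * std::pow(p.E / en.pcut, unif_rand());
        if (k > avail) k = avail;
        Particle ph = p; ph.kind = 0; ph.E = k;  // forward emission
        stack.push_back(ph);
      }
    }
    en.dep[p.layer] += decol;
    p.E -= decol + k;
    if (cross) {
      if (p.w > 0) { p.z = ly.z1 + EPS_Z; p.layer += 1; }
      else         { p.z = ly.z0 - EPS_Z; p.layer -= 1; }
      if (p.layer < 0) { en.esc_up += p.E; return; }
      if (p.layer >= en.nl) { en.esc_dn += p.E; return; }
    } else {
      p.z += ds * p.w;
    }
    if (p.E <= en.ecut) { en.dep[p.layer] += p.E; return; }
    // Highland deflection for the next step
    double x = ly.rho * ds;
    double tt = x / ly.X0;
    if (tt > 1e-14) {
      double fac = 1.0 + 0.038 * std::log(tt);
      if (fac < 0.25) fac = 0.25;
      double betapc = p.E * (p.E + 2.0 * MEC2) / (p.E + MEC2);
      double sig = 13600.0 / betapc * std::sqrt(tt) * fac;
      // Highland sigma is the projected-angle width; the space polar
      // angle is Rayleigh with the same per-component sigma
      double th = sig * std::sqrt(-2.0 * std::log(unif_rand()));
      if (th > 3.0) th = 3.0;
      rotate_dir(p.u, p.v, p.w, std::cos(th),
                 2.0 * M_PI * unif_rand());
    }
  }
}

// ---------------------------------------------------------------------

static Engine build_engine(List model, List opts) {
  Engine en;
  NumericVector z0 = model["z0"], z1 = model["z1"], rho = model["rho"];
  en.nl = z0.size();
  NumericVector pg = model["pgrid_log"];
  en.pg.assign(pg.begin(), pg.end());
  NumericVector eg = model["egrid_log"];
  en.eg0 = eg[0];
  en.egn = eg.size();
  en.egd = (eg[en.egn - 1] - eg[0]) / (en.egn - 1);
  List lys = model["layers"];
  for (int i = 0; i < en.nl; ++i) {
    List li = lys[i];
    LayerPhys ly;
    ly.z0 = z0[i]; ly.z1 = z1[i]; ly.rho = rho[i];
    ly.thick = ly.z1 - ly.z0;
    NumericVector a = li["lpe"], b = li["linc"], c = li["lcoh"];
    ly.lpe.assign(a.begin(), a.end());
    ly.linc.assign(b.begin(), b.end());
    ly.lcoh.assign(c.begin(), c.end());
    NumericMatrix em = li["lelem"];
    ly.ne = em.ncol();
    ly.lelem.assign(em.begin(), em.end());
    NumericMatrix meta = li["meta"];
    for (int j = 0; j < ly.ne; ++j) {
      ly.kedge.push_back(meta(j, 0));
      ly.omK.push_back(meta(j, 1));
      ly.eKx.push_back(meta(j, 2));
      ly.fK.push_back(meta(j, 3));
      ly.ledge.push_back(meta(j, 4));
    }
    NumericVector sc = li["scol"], sr = li["srad"];
    ly.scol.assign(sc.begin(), sc.end());
    ly.srad.assign(sr.begin(), sr.end());
    ly.X0 = as<double>(li["X0"]);
    en.L.push_back(ly);
  }
  en.pcut = as<double>(opts["photon_cutoff"]);
  en.ecut = as<double>(opts["electron_cutoff"]);
  en.stepf = as<double>(opts["step_frac"]);
  en.use_coh = as<bool>(opts["include_coherent"]);
  en.atten_only = as<bool>(opts["attenuation_only"]);
  en.dep.assign(en.nl, 0.0);
  en.esc_up = en.esc_dn = 0.0;
  return en;
}

// Run one batch of histories. Returns summed per-layer deposits (keV)
// and escape accounts; normalization to per-primary means happens in R.
// [[Rcpp::export]]
List cpp_run_batch(int kind, double E0_keV, int n, List model, List opts) {
  RNGScope scope;
  Engine en = build_engine(model, opts);
  if (kind == 0) {
    double lE = std::log(E0_keV);
    if (lE < en.pg.front() || lE > en.pg.back())
      stop("beam energy outside photon table span");
  }
  std::vector<Particle> stack;
  for (int h = 0; h < n; ++h) {
    stack.clear();
    Particle pr;
    pr.kind = kind; pr.E = E0_keV;
    pr.z = en.L[0].z0 + EPS_Z;
    pr.u = 0; pr.v = 0; pr.w = 1;
    pr.layer = 0;
    stack.push_back(pr);
    while (!stack.empty()) {
      Particle p = stack.back();
      stack.pop_back();
      if (p.kind == 0) transport_photon(en, p, stack);
      else transport_electron(en, p, stack);
    }
  }
  return List::create(
    _["dep_keV"] = NumericVector(en.dep.begin(), en.dep.end()),
    _["esc_up_keV"] = en.esc_up,
    _["esc_dn_keV"] = en.esc_dn);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double E_keV, int n) {
  RNGScope scope;
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    double Eout, cost, Ee, coste;
    kahn_compton(E_keV, Eout, cost, Ee, coste);
    out(i, 0) = Eout; out(i, 1) = cost;
    out(i, 2) = Ee; out(i, 3) = coste;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_thomson(int n) {
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = thomson_cost();
  return out;
}

// Photoelectric event sampler for the module-level interface: given the
// per-element w_i*tau_i weights at the interaction energy and the element
// relaxation constants (k_edge, omega_K, e_Kx, f_K, l_edge), returns
// photoelectron energy, escaping fluorescence energy and local deposit.
// [[Rcpp::export]]
NumericMatrix cpp_photoelectric(double E_keV, int n, NumericVector wtau,
                                NumericMatrix meta) {
  RNGScope scope;
  int ne = wtau.size();
  double tsum = 0.0;
  for (int j = 0; j < ne; ++j) tsum += wtau[j];
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double r = unif_rand() * tsum;
    int j = 0;
    for (; j < ne - 1; ++j) { if (r < wtau[j]) break; r -= wtau[j]; }
    double kedge = meta(j, 0), omK = meta(j, 1), eKx = meta(j, 2),
           fK = meta(j, 3), ledge = meta(j, 4);
    double Ee = 0.0, fl = 0.0, loc = 0.0;
    if (E_keV > kedge && unif_rand() < fK) {
      Ee = E_keV - kedge;
      if (unif_rand() < omK) { fl = eKx; loc = kedge - eKx; }
      else loc = kedge;
    } else {
      loc = (E_keV > ledge) ? ledge : E_keV;
      Ee = E_keV - loc;
    }
    out(i, 0) = Ee; out(i, 1) = fl; out(i, 2) = loc;
  }
  return out;
}
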
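// Discretized two-leg chain: equilibrium Metropolis sampler (oracle for the
// mean-field density) and an overdamped Brownian-dynamics integrator with
// the full conical binding criterion.
//
// Units: nm, kBT energies; BD time in ns internally (reported in ms).
// Both samplers use the same Hamiltonian terms:
//   bending (lp/b0) sum(1 - t_i.t_i+1) within each leg,
//   bound-leg tangent constraint 0.5 nu_c |t_0 - u_c|^2,
//   inter-leg chord-angle potential mu_c (1 - cos(theta_J - theta_p)),
//   effective head-head repulsion (dV/r)^6 (optional),
//   explicit leg-leg bead exclusion (optional, used to estimate dV),
//   load force -beta F . r_joint, cover-slip and actin exclusion (optional).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256** PRNG: fast, seedable, deterministic across platforms
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    // splitmix64 initialization
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; i++) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    zig_init();
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 1.1102230246251565e-16; }
  // Marsaglia-Tsang ziggurat tables (shared, built once)
  static uint32_t kn[128];
  static double wn[128], fn[128];
  static bool zig_ready;
  static void zig_init() {
    if (zig_ready) return;
    double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
    zig_ready = true;
  }
  double norm() {
    for (;;) {
      int32_t hz = (int32_t)(next() >> 32);
      uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // slow path
      double x, y;
      if (iz == 0) {
        double r = 3.442619855899;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};
uint32_t RNG::kn[128];
double RNG::wn[128], RNG::fn[128];
bool RNG::zig_ready = false;

struct Pars {
  int ns;            // segments per leg
  double b0;         // bond length
  double kang;       // lp / b0
  double nu_c, mu_c, theta_p, dV;
  double uc[3];      // preferred bound-leg tangent
  double fred[3];    // beta * F (kBT/nm)
  bool use_hv;       // effective (dV/r)^6 head-head term
  bool explicit_ev;  // explicit bead-bead leg-leg exclusion
  double sig_ev;     // exclusion length for bead pairs
  bool coverslip; double x_wall;
  bool actin_ev; double r_actin; double ax_x; // actin axis at (ax_x, 0, z)
};

inline double dot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}

// total reduced energy of a configuration given unit tangents
// t: (2*ns) x 3, leg1 = rows 0..ns-1, leg2 = rows ns..2ns-1
double chain_energy(const std::vector<double>& t, const Pars& p) {
  int ns = p.ns;
  double E = 0.0;
  // bending within each leg
  for (int leg = 0; leg < 2; leg++) {
    int off = leg * ns;
    for (int i = 0; i < ns - 1; i++)
      E += p.kang * (1.0 - dot3(&t[3*(off+i)], &t[3*(off+i+1)]));
  }
  // bound-leg tangent constraint: 0.5 nu_c |t0 - uc|^2 = nu_c (1 - t0.uc)
  E += p.nu_c * (1.0 - dot3(&t[0], p.uc));
  // positions
  std::vector<double> pos(3 * (2 * ns + 1), 0.0);
  for (int i = 0; i < 2 * ns; i++)
    for (int k = 0; k < 3; k++)
      pos[3*(i+1)+k] = pos[3*i+k] + p.b0 * t[3*i+k];
  const double* rj = &pos[3*ns];
  const double* rh = &pos[3*2*ns];
  // inter-leg chord angle at the joint
  double a1[3] = {-rj[0], -rj[1], -rj[2]};
  double a2[3] = {rh[0]-rj[0], rh[1]-rj[1], rh[2]-rj[2]};
  double n1 = std::sqrt(dot3(a1,a1)), n2 = std::sqrt(dot3(a2,a2));
  if (n1 > 1e-9 && n2 > 1e-9) {
    double ct = dot3(a1,a2)/(n1*n2);
    ct = std::max(-1.0, std::min(1.0, ct));
    E += p.mu_c * (1.0 - std::cos(std::acos(ct) - p.theta_p));
  }
  // head-head repulsion
  double rhh = std::sqrt(dot3(rh, rh));
  if (p.use_hv) {
    double q = p.dV / std::max(rhh, 1e-6);
    double q2 = q*q;
    E += q2*q2*q2;
  }
  if (p.explicit_ev) {
    // soft (sig/r)^6 between all leg1 x leg2 bead pairs (joint excluded)
    for (int i = 0; i <= ns - 1; i++) {       // leg1 beads 0..ns-1
      for (int j = ns + 1; j <= 2 * ns; j++) { // leg2 beads ns+1..2ns
        double d[3] = {pos[3*i]-pos[3*j], pos[3*i+1]-pos[3*j+1],
                       pos[3*i+2]-pos[3*j+2]};
        double r = std::sqrt(dot3(d, d));
        double q = p.sig_ev / std::max(r, 1e-6);
        double q2 = q*q;
        E += q2*q2*q2;
      }
    }
  }
  // load at the joint
  E -= dot3(p.fred, rj);
  if (p.coverslip) {
    for (int i = 1; i <= 2 * ns; i++)
      if (pos[3*i] < p.x_wall) return 1e30;
  }
  if (p.actin_ev) {
    for (int i = 1; i <= 2 * ns; i++) {
      double dx = pos[3*i] - p.ax_x, dy = pos[3*i+1];
      if (dx*dx + dy*dy < p.r_actin * p.r_actin) return 1e30;
    }
  }
  return E;
}

Pars build_pars(const List& par) {
  Pars p;
  p.ns = as<int>(par["ns"]);
  double L = as<double>(par["L"]);
  p.b0 = L / p.ns;
  p.kang = as<double>(par["lp"]) / p.b0;
  p.nu_c = as<double>(par["nu_c"]);
  p.mu_c = as<double>(par["mu_c"]);
  p.theta_p = as<double>(par["theta_p_rad"]);
  p.dV = as<double>(par["dV"]);
  NumericVector uc = par["uc"], fr = par["fred"];
  for (int k = 0; k < 3; k++) { p.uc[k] = uc[k]; p.fred[k] = fr[k]; }
  p.use_hv = as<bool>(par["use_hv"]);
  p.explicit_ev = as<bool>(par["explicit_ev"]);
  p.sig_ev = as<double>(par["sig_ev"]);
  p.coverslip = as<bool>(par["coverslip"]);
  p.x_wall = as<double>(par["x_wall"]);
  p.actin_ev = as<bool>(par["actin_ev"]);
  p.r_actin = as<double>(par["r_actin"]);
  p.ax_x = as<double>(par["ax_x"]);
  return p;
}

void rotate_about(double* v, const double* axis, double ang) {
  // Rodrigues rotation, axis assumed unit
  double c = std::cos(ang), s = std::sin(ang);
  double k[3] = {axis[0], axis[1], axis[2]};
  double kv[3] = {k[1]*v[2]-k[2]*v[1], k[2]*v[0]-k[0]*v[2], k[0]*v[1]-k[1]*v[0]};
  double kd = dot3(k, v);
  for (int i = 0; i < 3; i++)
    v[i] = v[i]*c + kv[i]*s + k[i]*kd*(1.0-c);
}

} // namespace

// [[Rcpp::export]]
List cpp_chain_mc(List par, double n_samples, int thin, int burn,
                  double step_size, double seed) {
  Pars p = build_pars(par);
  int ns = p.ns;
  RNG rng(static_cast<uint64_t>(seed));
  // initial configuration: bound leg along uc, free leg tilted back
  std::vector<double> t(6 * ns);
  for (int i = 0; i < ns; i++)
    for (int k = 0; k < 3; k++) t[3*i+k] = p.uc[k];
  double back[3] = {-p.uc[0], -p.uc[1], p.uc[2]};
  double nb = std::sqrt(dot3(back, back));
  for (int k = 0; k < 3; k++) back[k] /= nb;
  for (int i = ns; i < 2 * ns; i++)
    for (int k = 0; k < 3; k++) t[3*i+k] = back[k];
  double E = chain_energy(t, p);
  long n_out = static_cast<long>(n_samples);
  NumericMatrix out(n_out, 5); // x, y, z, phi_f, theta_J
  long accept = 0, total = 0;
  long sweeps = burn + n_out * thin;
  long isamp = 0;
  std::vector<double> told(6 * ns);
  for (long sw = 0; sw < sweeps; sw++) {
    for (int m = 0; m < 2 * ns + 2; m++) {
      double u_move = rng.unif();
      double ax[3] = {rng.norm(), rng.norm(), rng.norm()};
      double na = std::sqrt(dot3(ax, ax));
      if (na < 1e-12) continue;
      for (int k = 0; k < 3; k++) ax[k] /= na;
      if (u_move < 0.7) {
        // single-tangent pivot
        int i = static_cast<int>(rng.unif() * 2 * ns);
        if (i >= 2 * ns) i = 2 * ns - 1;
        double old[3] = {t[3*i], t[3*i+1], t[3*i+2]};
        rotate_about(&t[3*i], ax, step_size * rng.norm());
        double En = chain_energy(t, p);
        total++;
        if (En <= E || rng.unif() < std::exp(E - En)) { E = En; accept++; }
        else { t[3*i] = old[0]; t[3*i+1] = old[1]; t[3*i+2] = old[2]; }
      } else {
        // rigid rotation of one whole leg (collective move: preserves
        // internal bending, changes constraint/joint/exclusion terms)
        int leg = rng.unif() < 0.5 ? 0 : 1;
        std::copy(t.begin(), t.end(), told.begin());
        double ang = 2.0 * step_size * rng.norm();
        for (int i = leg * ns; i < (leg + 1) * ns; i++)
          rotate_about(&t[3*i], ax, ang);
        double En = chain_energy(t, p);
        total++;
        if (En <= E || rng.unif() < std::exp(E - En)) { E = En; accept++; }
        else std::copy(told.begin(), told.end(), t.begin());
      }
    }
    if (sw >= burn && ((sw - burn + 1) % thin == 0) && isamp < n_out) {
      // head position and free-leg azimuth
      double rj[3] = {0,0,0}, rh[3];
      for (int i = 0; i < ns; i++)
        for (int k = 0; k < 3; k++) rj[k] += p.b0 * t[3*i+k];
      rh[0] = rj[0]; rh[1] = rj[1]; rh[2] = rj[2];
      for (int i = ns; i < 2 * ns; i++)
        for (int k = 0; k < 3; k++) rh[k] += p.b0 * t[3*i+k];
      double d[3] = {rh[0]-rj[0], rh[1]-rj[1], rh[2]-rj[2]};
      double a1[3] = {-rj[0], -rj[1], -rj[2]};
      double n1 = std::sqrt(dot3(a1,a1)), n2 = std::sqrt(dot3(d,d));
      double ct = (n1 > 1e-9 && n2 > 1e-9) ? dot3(a1,d)/(n1*n2) : 0.0;
      ct = std::max(-1.0, std::min(1.0, ct));
      out(isamp, 0) = rh[0]; out(isamp, 1) = rh[1]; out(isamp, 2) = rh[2];
      out(isamp, 3) = std::atan2(d[1], d[0]);
      out(isamp, 4) = std::acos(ct);
      isamp++;
    }
  }
  return List::create(_["samples"] = out,
                      _["acceptance"] = double(accept) / double(total));
}

// ---------------------------------------------------------------------------
// Brownian dynamics
// ---------------------------------------------------------------------------

namespace {

struct BDForce {
  // accumulate forces (kBT/nm) on beads given positions
  static void compute(const std::vector<double>& pos, const Pars& p,
                      double kbond, std::vector<double>& f) {
    int nb = 2 * p.ns + 1;
    std::fill(f.begin(), f.end(), 0.0);
    // bond vectors, lengths and inverses, shared by bond + bending terms
    double bv[64][3], bn[64], bi[64];
    for (int i = 0; i < nb - 1; i++) {
      bv[i][0] = pos[3*(i+1)]   - pos[3*i];
      bv[i][1] = pos[3*(i+1)+1] - pos[3*i+1];
      bv[i][2] = pos[3*(i+1)+2] - pos[3*i+2];
      bn[i] = std::sqrt(dot3(bv[i], bv[i]));
      bi[i] = 1.0 / (bn[i] > 1e-9 ? bn[i] : 1e-9);
    }
    // bonds
    for (int i = 0; i < nb - 1; i++) {
      double c = kbond * (bn[i] - p.b0) * bi[i];
      for (int k = 0; k < 3; k++) {
        f[3*i+k]     += c * bv[i][k];
        f[3*(i+1)+k] -= c * bv[i][k];
      }
    }
    // bending within legs: E = kang (1 - cos th) over triplets;
    // dE/dcos = -kang, bonds i-1 and i meet at bead i
    for (int leg = 0; leg < 2; leg++) {
      int lo = leg * p.ns;           // first bead of leg
      for (int i = lo + 1; i < lo + p.ns; i++) {
        int a = i - 1, b = i;        // bond indices
        double inn = bi[a] * bi[b];
        double ct = dot3(bv[a], bv[b]) * inn;
        double g1[3], g2[3];
        for (int k = 0; k < 3; k++) {
          g1[k] = bv[b][k] * inn - ct * bv[a][k] * bi[a] * bi[a];
          g2[k] = bv[a][k] * inn - ct * bv[b][k] * bi[b] * bi[b];
        }
        for (int k = 0; k < 3; k++) {
          f[3*(i-1)+k] += -p.kang * g1[k];
          f[3*i+k]     -= -p.kang * (g1[k] - g2[k]);
          f[3*(i+1)+k] -= -p.kang * g2[k];
        }
      }
    }
    // bound-leg tangent constraint on bead 1: E = nu_c (1 - u0.uc)
    {
      double d[3] = {pos[3]-pos[0], pos[4]-pos[1], pos[5]-pos[2]};
      double r = std::sqrt(dot3(d, d));
      double u[3] = {d[0]/r, d[1]/r, d[2]/r};
      double ud = dot3(u, p.uc);
      for (int k = 0; k < 3; k++)
        f[3+k] += p.nu_c * (p.uc[k] - ud * u[k]) / r;
    }
    // inter-leg chord angle at joint (beads 0, ns, 2ns)
    {
      int j = p.ns, h = 2 * p.ns;
      double a1[3] = {pos[0]-pos[3*j], pos[1]-pos[3*j+1], pos[2]-pos[3*j+2]};
      double a2[3] = {pos[3*h]-pos[3*j], pos[3*h+1]-pos[3*j+1],
                      pos[3*h+2]-pos[3*j+2]};
      double n1 = std::sqrt(dot3(a1,a1)), n2 = std::sqrt(dot3(a2,a2));
      if (n1 > 1e-9 && n2 > 1e-9) {
        double ct = std::max(-1.0, std::min(1.0, dot3(a1,a2)/(n1*n2)));
        double th = std::acos(ct);
        double st = std::sqrt(std::max(1.0 - ct*ct, 1e-10));
        // E = mu_c (1 - cos(th - th_p)); dE/dcos(th) = -mu_c sin(th-th_p)/sin(th)
        double dEdc = -p.mu_c * std::sin(th - p.theta_p) / st;
        double g1[3], g2[3];
        for (int k = 0; k < 3; k++) {
          g1[k] = (a2[k]/(n1*n2) - ct*a1[k]/(n1*n1));
          g2[k] = (a1[k]/(n1*n2) - ct*a2[k]/(n2*n2));
        }
        for (int k = 0; k < 3; k++) {
          f[0+k]     -= dEdc * g1[k];
          f[3*h+k]   -= dEdc * g2[k];
          f[3*j+k]   += dEdc * (g1[k] + g2[k]);
        }
      }
    }
    // head-head repulsion on head bead
    if (p.use_hv) {
      int h = 2 * p.ns;
      double r = std::sqrt(dot3(&pos[3*h], &pos[3*h]));
      double rr = std::max(r, 1e-6);
      double q = p.dV / rr;
      double q2 = q*q;
      double c = 6.0 * q2*q2*q2 / (rr * rr);
      for (int k = 0; k < 3; k++) f[3*h+k] += c * pos[3*h+k];
    }
    if (p.explicit_ev) {
      for (int i = 0; i <= p.ns - 1; i++)
        for (int j2 = p.ns + 1; j2 <= 2 * p.ns; j2++) {
          double d[3] = {pos[3*i]-pos[3*j2], pos[3*i+1]-pos[3*j2+1],
                         pos[3*i+2]-pos[3*j2+2]};
          double r2 = dot3(d, d);
          double rr = std::max(std::sqrt(r2), 1e-6);
          double q = p.sig_ev / rr;
          double q2 = q*q;
          double c = 6.0 * q2*q2*q2 / (rr*rr);
          for (int k = 0; k < 3; k++) {
            f[3*i+k]  += c * d[k];
            f[3*j2+k] -= c * d[k];
          }
        }
    }
    // load at joint
    for (int k = 0; k < 3; k++) f[3*p.ns+k] += p.fred[k];
    // cover-slip (half-harmonic wall) and actin cylinder
    if (p.coverslip) {
      for (int i = 1; i <= 2 * p.ns; i++)
        if (pos[3*i] < p.x_wall)
          f[3*i] += 10.0 * (p.x_wall - pos[3*i]);
    }
    if (p.actin_ev) {
      for (int i = 1; i <= 2 * p.ns; i++) {
        double dx = pos[3*i] - p.ax_x, dy = pos[3*i+1];
        double rho = std::sqrt(dx*dx + dy*dy);
        if (rho < p.r_actin && rho > 1e-9) {
          double c = 10.0 * (p.r_actin - rho) / rho;
          f[3*i]   += c * dx;
          f[3*i+1] += c * dy;
        }
      }
    }
  }

  static void angle_force(const std::vector<double>& pos, int i0, int i1,
                          int i2, double dEdcos_at_unit, std::vector<double>& f) {
    // E with dE/dcos(th) = dEdcos_at_unit, th between bonds (i1-i0),(i2-i1)
    double b1[3] = {pos[3*i1]-pos[3*i0], pos[3*i1+1]-pos[3*i0+1],
                    pos[3*i1+2]-pos[3*i0+2]};
    double b2[3] = {pos[3*i2]-pos[3*i1], pos[3*i2+1]-pos[3*i1+1],
                    pos[3*i2+2]-pos[3*i1+2]};
    double n1 = std::sqrt(dot3(b1,b1)), n2 = std::sqrt(dot3(b2,b2));
    if (n1 < 1e-9 || n2 < 1e-9) return;
    double ct = dot3(b1,b2)/(n1*n2);
    double g1[3], g2[3];
    for (int k = 0; k < 3; k++) {
      g1[k] = (b2[k]/(n1*n2) - ct*b1[k]/(n1*n1));  // dcos/db1
      g2[k] = (b1[k]/(n1*n2) - ct*b2[k]/(n2*n2));  // dcos/db2
    }
    for (int k = 0; k < 3; k++) {
      f[3*i0+k] += dEdcos_at_unit * g1[k];
      f[3*i1+k] -= dEdcos_at_unit * (g1[k] - g2[k]);
      f[3*i2+k] -= dEdcos_at_unit * g2[k];
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_bd_run(List par, double kbond, double D, double dt_ns,
                double max_ns, NumericMatrix sites, NumericVector site_phi,
                double a_capture, double dphi_ac, double b_penalty,
                IntegerVector penalized, double hydrolysis_ns,
                bool allow_binding, double record_stride_ns, double seed,
                NumericMatrix init_pos, double noise_scale = 1.0,
                int check_stride = 2) {
  Pars p = build_pars(par);
  int nb = 2 * p.ns + 1;
  RNG rng(static_cast<uint64_t>(seed));
  std::vector<double> pos(3 * nb), f(3 * nb);
  for (int i = 0; i < nb; i++)
    for (int k = 0; k < 3; k++) pos[3*i+k] = init_pos(i, k);
  double sig = std::sqrt(2.0 * D * dt_ns) * noise_scale;
  double mob = D * dt_ns;
  long nsteps = static_cast<long>(max_ns / dt_ns);
  int nsites = sites.nrow();
  // flat site arrays; lookup by z (sites must be sorted by z)
  std::vector<double> sx(nsites), sy(nsites), sz(nsites), cphi(nsites),
    sphi(nsites);
  for (int i = 0; i < nsites; i++) {
    sx[i] = sites(i, 0); sy[i] = sites(i, 1); sz[i] = sites(i, 2);
    cphi[i] = std::cos(site_phi[i]); sphi[i] = std::sin(site_phi[i]);
  }
  double zmin = sz[0];
  double dz_site = nsites > 1 ? (sz[nsites-1]-sz[0])/(nsites-1) : 1.0;
  double cos_ac = std::cos(dphi_ac);
  double a2 = a_capture * a_capture;
  std::vector<char> blocked(nsites, 0); // failed attempt: wait until exit
  int rec_n = record_stride_ns > 0 ?
    static_cast<int>(max_ns / record_stride_ns) + 2 : 0;
  NumericMatrix traj(rec_n > 0 ? rec_n : 1, 3);
  long rec_stride = record_stride_ns > 0 ?
    std::max(1L, static_cast<long>(record_stride_ns / dt_ns)) : 0;
  long irec = 0;
  int bound_site = NA_INTEGER;
  double t_bind = NA_REAL;
  double max_disp2 = 0.0;
  long hyd_steps = static_cast<long>(hydrolysis_ns / dt_ns);
  for (long s = 0; s < nsteps; s++) {
    BDForce::compute(pos, p, kbond, f);
    for (int i = 1; i < nb; i++) {   // bead 0 anchored
      double dx = mob * f[3*i]   + sig * rng.norm();
      double dy = mob * f[3*i+1] + sig * rng.norm();
      double dz = mob * f[3*i+2] + sig * rng.norm();
      pos[3*i]   += dx; pos[3*i+1] += dy; pos[3*i+2] += dz;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > max_disp2) max_disp2 = d2;
    }
    if (rec_stride > 0 && (s % rec_stride == 0) && irec < traj.nrow()) {
      traj(irec, 0) = pos[3*(nb-1)];
      traj(irec, 1) = pos[3*(nb-1)+1];
      traj(irec, 2) = pos[3*(nb-1)+2];
      irec++;
    }
    if (!allow_binding || s < hyd_steps || (s % check_stride)) continue;
    // candidate sites near head z
    const double* rh = &pos[3*(nb-1)];
    int ic = static_cast<int>((rh[2] - zmin) / dz_site + 0.5);
    int ilo = ic - 2 < 0 ? 0 : ic - 2;
    int ihi = ic + 2 >= nsites ? nsites - 1 : ic + 2;
    for (int i = ilo; i <= ihi; i++) {
      double ddx = rh[0]-sx[i], ddy = rh[1]-sy[i], ddz = rh[2]-sz[i];
      double r2 = ddx*ddx + ddy*ddy + ddz*ddz;
      if (r2 > a2) { blocked[i] = 0; continue; }
      if (blocked[i]) continue;
      // conical criterion: angle between free leg (head -> joint) and the
      // outward site normal below dphi_ac; a miss is re-checked while the
      // head stays within the capture radius (the orientation can relax
      // into the cone), whereas a penalty rejection blocks the site until
      // the head leaves (one attempt per diffusive excursion)
      double leg[3] = {pos[3*p.ns]-rh[0], pos[3*p.ns+1]-rh[1],
                       pos[3*p.ns+2]-rh[2]};
      double nl = std::sqrt(dot3(leg, leg));
      double ca = (leg[0]*cphi[i] + leg[1]*sphi[i]) / std::max(nl, 1e-9);
      if (ca < cos_ac) continue;
      double pb = penalized[i] ? b_penalty : 1.0;
      if (pb >= 1.0 || rng.unif() < pb) {
        bound_site = i;
        t_bind = s * dt_ns;
        break;
      }
      blocked[i] = 1;
    }
    if (bound_site != NA_INTEGER) break;
  }
  double max_disp = std::sqrt(max_disp2);
  NumericMatrix traj_out(irec, 3);
  for (long i = 0; i < irec; i++)
    for (int k = 0; k < 3; k++) traj_out(i, k) = traj(i, k);
  NumericMatrix fin(nb, 3);
  for (int i = 0; i < nb; i++)
    for (int k = 0; k < 3; k++) fin(i, k) = pos[3*i+k];
  return List::create(_["site_row"] = bound_site == NA_INTEGER ?
                        NA_INTEGER : bound_site + 1,
                      _["t_ms"] = bound_site == NA_INTEGER ?
                        NA_REAL : t_bind * 1e-6,
                      _["trajectory"] = traj_out,
                      _["final"] = fin,
                      _["max_step_nm"] = max_disp);
}
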
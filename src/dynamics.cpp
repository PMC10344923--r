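// Core dynamics and trajectory analyzers for 2D run-and-tumble rods.
//
// Geometry: spherocylinders of tip-to-tip length ell and thickness sigma,
// i.e. a straight shaft of length shaft = ell - sigma with hemispherical
// caps of diameter sigma.  Rod-rod contact distance is sigma, rod-bead
// contact distance a + sigma/2.  Steric repulsion is harmonic in the
// overlap: U = k/2 (d_c - d)^2 for d < d_c.  All randomness comes from the
// R RNG so set.seed() controls everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TWO_PI = 6.28318530717958647692;

static inline double min_image(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}
// cheap variant for displacements already within (-L, L)
static inline double min_image_near(double dx, double L) {
  if (dx > 0.5 * L) return dx - L;
  if (dx < -0.5 * L) return dx + L;
  return dx;
}
static inline double wrap_box(double x, double L) {
  x -= L * std::floor(x / L);
  return x >= L ? x - L : x;  // guard against floating round-up
}
static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// squared separation of the points s*ui (on rod i, centred at origin) and
// D + t*uj (on rod j, centred at D); W = P_i - P_j
static inline double seg_f(double s, double t, double dx, double dy,
                           double uix, double uiy, double ujx, double ujy,
                           double &wx, double &wy) {
  wx = s * uix - (dx + t * ujx);
  wy = s * uiy - (dy + t * ujy);
  return wx * wx + wy * wy;
}

// Exact closest approach of two segments of half-length h in 2D.  The
// unconstrained stationary point is used when it lies in [-h,h]^2;
// otherwise the quadratic is convex so the minimum sits on one of the four
// edges, where the 1D minimizer is the clamped stationary point.
static void seg_seg(double dx, double dy, double uix, double uiy,
                    double ujx, double ujy, double h,
                    double &s, double &t, double &wx, double &wy,
                    double &d2) {
  double b  = uix * ujx + uiy * ujy;
  double d1 = uix * dx + uiy * dy;
  double e1 = ujx * dx + ujy * dy;
  double det = 1.0 - b * b;
  if (det > 1e-12) {
    double s0 = (d1 - b * e1) / det;
    double t0 = (b * d1 - e1) / det;
    if (std::fabs(s0) <= h && std::fabs(t0) <= h) {
      s = s0; t = t0;
      d2 = seg_f(s, t, dx, dy, uix, uiy, ujx, ujy, wx, wy);
      return;
    }
  }
  double best = R_PosInf;
  double cs[4], ct[4];
  cs[0] =  h; ct[0] = clampd( h * b - e1, -h, h);
  cs[1] = -h; ct[1] = clampd(-h * b - e1, -h, h);
  ct[2] =  h; cs[2] = clampd( h * b + d1, -h, h);
  ct[3] = -h; cs[3] = clampd(-h * b + d1, -h, h);
  s = cs[0]; t = ct[0];
  for (int c = 0; c < 4; ++c) {
    double twx, twy;
    double f = seg_f(cs[c], ct[c], dx, dy, uix, uiy, ujx, ujy, twx, twy);
    if (f < best) { best = f; s = cs[c]; t = ct[c]; wx = twx; wy = twy; }
  }
  d2 = best;
}

struct PairFT {
  double fxi, fyi, ti, fxj, fyj, tj, w;
  bool contact;
};

// force/torque of rod j on rod i (and reaction); (dx,dy) = min-image
// r_j - r_i; (uix,uiy)/(ujx,ujy) are the precomputed orientation vectors
static PairFT rod_rod_ft(double dx, double dy, double uix, double uiy,
                         double ujx, double ujy, double h, double sigma,
                         double k, int idx_i, int idx_j) {
  PairFT r = {0, 0, 0, 0, 0, 0, 0, false};
  double rc = 2.0 * h + sigma;
  if (dx * dx + dy * dy >= rc * rc) return r;
  double s, t, wx, wy, d2;
  seg_seg(dx, dy, uix, uiy, ujx, ujy, h, s, t, wx, wy, d2);
  double d = std::sqrt(d2);
  if (d >= sigma) return r;
  double nx, ny;
  if (d > 1e-9) {
    nx = wx / d; ny = wy / d;
  } else {
    // coincident closest points: deterministic fallback direction from an
    // angle hash of the indices, magnitude capped below
    double hsh = std::sin(12.9898 * (idx_i + 1) + 78.233 * (idx_j + 1)) * 43758.5453;
    double ang = TWO_PI * (hsh - std::floor(hsh));
    nx = std::cos(ang); ny = std::sin(ang);
  }
  double fm = k * (sigma - d);
  if (fm > k * sigma) fm = k * sigma;
  r.fxi = fm * nx;  r.fyi = fm * ny;
  r.fxj = -r.fxi;   r.fyj = -r.fyi;
  r.ti = s * (uix * r.fyi - uiy * r.fxi);
  r.tj = t * (ujx * r.fyj - ujy * r.fxj);
  // pair virial r_ij . f_ij with r_ij = r_i - r_j = -(dx,dy)
  r.w = -(dx * r.fxi + dy * r.fyi);
  r.contact = true;
  return r;
}

// force/torque of the bead on a rod; (dxb,dyb) = min-image bead - rod
// centre.  fxi/fyi act on the rod, fxj/fyj on the bead.
static PairFT rod_bead_ft(double dxb, double dyb, double uix, double uiy,
                          double h, double sigma, double a, double k) {
  PairFT r = {0, 0, 0, 0, 0, 0, 0, false};
  double contact = a + 0.5 * sigma;
  double rc = h + contact;
  if (dxb * dxb + dyb * dyb >= rc * rc) return r;
  double s = clampd(uix * dxb + uiy * dyb, -h, h);
  double wx = s * uix - dxb, wy = s * uiy - dyb;  // rod point - bead centre
  double d = std::sqrt(wx * wx + wy * wy);
  if (d >= contact) return r;
  double nx, ny;
  if (d > 1e-9) { nx = wx / d; ny = wy / d; } else { nx = 1.0; ny = 0.0; }
  double fm = k * (contact - d);
  if (fm > k * contact) fm = k * contact;
  r.fxi = fm * nx;  r.fyi = fm * ny;
  r.fxj = -r.fxi;   r.fyj = -r.fyi;
  r.ti = s * (uix * r.fyi - uiy * r.fxi);
  r.w = -(dxb * r.fxi + dyb * r.fyi);
  r.contact = true;
  return r;
}

// ---------------------------------------------------------------------------
// exported pair-level primitives (used by R-level oracles and tests)

// [[Rcpp::export]]
List pair_force_rr_cpp(NumericVector ri, double thi, NumericVector rj,
                       double thj, double shaft, double sigma, double k,
                       double L, int idx_i, int idx_j) {
  double dx = min_image(rj[0] - ri[0], L), dy = min_image(rj[1] - ri[1], L);
  PairFT p = rod_rod_ft(dx, dy, std::cos(thi), std::sin(thi),
                        std::cos(thj), std::sin(thj), 0.5 * shaft, sigma,
                        k, idx_i, idx_j);
  return List::create(_["f_i"] = NumericVector::create(p.fxi, p.fyi),
                      _["tau_i"] = p.ti,
                      _["f_j"] = NumericVector::create(p.fxj, p.fyj),
                      _["tau_j"] = p.tj,
                      _["virial"] = p.w,
                      _["contact"] = p.contact);
}

// [[Rcpp::export]]
List pair_force_rb_cpp(NumericVector ri, double thi, NumericVector bc,
                       double a, double shaft, double sigma, double k,
                       double L) {
  double dx = min_image(bc[0] - ri[0], L), dy = min_image(bc[1] - ri[1], L);
  PairFT p = rod_bead_ft(dx, dy, std::cos(thi), std::sin(thi), 0.5 * shaft,
                         sigma, a, k);
  return List::create(_["f_i"] = NumericVector::create(p.fxi, p.fyi),
                      _["tau_i"] = p.ti,
                      _["f_bead"] = NumericVector::create(p.fxj, p.fyj),
                      _["virial"] = p.w,
                      _["contact"] = p.contact);
}

// [[Rcpp::export]]
double pair_potential_rr_cpp(NumericVector ri, double thi, NumericVector rj,
                             double thj, double shaft, double sigma,
                             double k, double L) {
  double dx = min_image(rj[0] - ri[0], L), dy = min_image(rj[1] - ri[1], L);
  double s, t, wx, wy, d2;
  seg_seg(dx, dy, std::cos(thi), std::sin(thi), std::cos(thj),
          std::sin(thj), 0.5 * shaft, s, t, wx, wy, d2);
  double d = std::sqrt(d2);
  if (d >= sigma) return 0.0;
  double ov = sigma - d;
  return 0.5 * k * ov * ov;
}

// [[Rcpp::export]]
double pair_potential_rb_cpp(NumericVector ri, double thi, NumericVector bc,
                             double a, double shaft, double sigma, double k,
                             double L) {
  double dx = min_image(bc[0] - ri[0], L), dy = min_image(bc[1] - ri[1], L);
  double uix = std::cos(thi), uiy = std::sin(thi);
  double h = 0.5 * shaft;
  double s = clampd(uix * dx + uiy * dy, -h, h);
  double wx = s * uix - dx, wy = s * uiy - dy;
  double d = std::sqrt(wx * wx + wy * wy);
  double contact = a + 0.5 * sigma;
  if (d >= contact) return 0.0;
  double ov = contact - d;
  return 0.5 * k * ov * ov;
}

// ---------------------------------------------------------------------------
// speed pattern (ptype 0 = modulation disc, 1 = half/half step in x,
// 2 = uniform background)

static inline double speed_of(double px, double py, int ptype,
                              double dcx, double dcy, double ax, double ay,
                              double R, double vm, double vp, double v0,
                              double L) {
  if (ptype == 2) return v0;
  if (ptype == 1) return (px < 0.5 * L) ? vm : vp;
  double ddx = min_image(px - dcx, L), ddy = min_image(py - dcy, L);
  if (ddx * ddx + ddy * ddy <= R * R) {
    double sp = ddx * ax + ddy * ay;
    // points on the dividing diameter (sp == 0) belong to the slow half
    return (sp > 0.0) ? vp : vm;
  }
  return v0;
}

// [[Rcpp::export]]
NumericVector speed_at_cpp(NumericVector px, NumericVector py, int ptype,
                           double dcx, double dcy, double ax, double ay,
                           double R, double vm, double vp, double v0,
                           double L) {
  R_xlen_t n = px.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = speed_of(px[i], py[i], ptype, dcx, dcy, ax, ay, R, vm, vp, v0, L);
  return out;
}

// ---------------------------------------------------------------------------
// cell list helper

struct CellList {
  int nc;          // cells per side (0 => brute force)
  double L;
  std::vector<int> head, nxt;
  void build(const std::vector<double> &px, const std::vector<double> &py,
             double box, double cutoff) {
    L = box;
    int n = (int)px.size();
    nc = (int)std::floor(box / cutoff);
    if (nc < 4 || n < 40) { nc = 0; return; }
    head.assign((size_t)nc * nc, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(px[i] / L * nc); if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
      int cy = (int)(py[i] / L * nc); if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
      int c = cx + nc * cy;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// iterate unordered pairs within the cutoff structure; calls fun(i, j)
template <typename F>
static void for_pairs(const CellList &cl, int n, F fun) {
  if (cl.nc == 0) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) fun(i, j);
    return;
  }
  int nc = cl.nc;
  // half neighbourhood: self, E, N, NE, NW
  const int offs[5][2] = {{0, 0}, {1, 0}, {0, 1}, {1, 1}, {-1, 1}};
  for (int cy = 0; cy < nc; ++cy) {
    for (int cx = 0; cx < nc; ++cx) {
      int c = cx + nc * cy;
      for (int o = 0; o < 5; ++o) {
        int c2x = (cx + offs[o][0] + nc) % nc;
        int c2y = (cy + offs[o][1] + nc) % nc;
        int c2 = c2x + nc * c2y;
        for (int i = cl.head[c]; i >= 0; i = cl.nxt[i]) {
          int jstart = (o == 0) ? cl.nxt[i] : cl.head[c2];
          for (int j = jstart; j >= 0; j = cl.nxt[j]) fun(i, j);
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// main engine

// [[Rcpp::export]]
List rt_engine_cpp(NumericMatrix pos0, NumericVector ang0, List rod,
                   List beadL, List pat, List runc) {
  const int N = pos0.nrow();
  const double shaft = as<double>(rod["shaft"]);
  const double sigma = as<double>(rod["sigma"]);
  const double alpha = as<double>(rod["alpha"]);
  const double gamma = as<double>(rod["gamma"]);
  const double gamma_rot = as<double>(rod["gamma_rot"]);
  const double krep = as<double>(rod["k_rep"]);
  const double h = 0.5 * shaft;

  const bool bead_present = as<bool>(beadL["present"]);
  double bx = bead_present ? as<double>(beadL["x"]) : 0.0;
  double by = bead_present ? as<double>(beadL["y"]) : 0.0;
  const double ba = bead_present ? as<double>(beadL["a"]) : 0.0;
  const double gamma_bead = bead_present ? as<double>(beadL["gamma_bead"]) : 1.0;
  const bool bead_mobile = bead_present ? as<bool>(beadL["mobile"]) : false;

  const int ptype = as<int>(pat["ptype"]);
  const double vm = as<double>(pat["v_minus"]);
  const double vp = as<double>(pat["v_plus"]);
  const double v0 = as<double>(pat["v_zero"]);
  const double R = as<double>(pat["R"]);
  const double delta = as<double>(pat["delta"]);
  const double ax = as<double>(pat["ax"]);
  const double ay = as<double>(pat["ay"]);
  double dcx = as<double>(pat["dcx"]);
  double dcy = as<double>(pat["dcy"]);

  const double L = as<double>(runc["L"]);
  const double dt = as<double>(runc["dt"]);
  const int n_steps = as<int>(runc["n_steps"]);
  const int save_every = as<int>(runc["save_every"]);
  const int feedback_every = as<int>(runc["feedback_every"]);
  const bool interactions = as<bool>(runc["interactions_on"]);

  std::vector<double> px(N), py(N), th(N), cth(N), sth(N),
      fx(N), fy(N), tq(N);
  for (int i = 0; i < N; ++i) {
    px[i] = wrap_box(pos0(i, 0), L);
    py[i] = wrap_box(pos0(i, 1), L);
    th[i] = ang0[i];
  }
  double bfx = 0.0, bfy = 0.0;     // current force on bead
  double bux = bx, buy = by;       // unwrapped bead position

  const int nf = n_steps / save_every + 1;
  NumericVector out_pos((R_xlen_t)N * 2 * nf), out_ang((R_xlen_t)N * nf);
  NumericMatrix out_bead(2, nf), out_bead_u(2, nf), out_disc(2, nf),
      out_bforce(2, nf);
  NumericVector out_t(nf);

  CellList cl;
  const double cutoff = shaft + sigma;
  const double p_tumble = 1.0 - std::exp(-alpha * dt);
  const double lim2 = 0.25 * sigma * sigma;  // (sigma/2)^2

  // per-rod countdown (in steps) to the next tumble: geometric with the
  // per-step probability p_tumble, so tumbling remains a Poisson process of
  // rate alpha while consuming one uniform per tumble instead of per step
  std::vector<int> next_tumble(N, -1);
  const double log1mp = (alpha > 0.0) ? std::log(1.0 - p_tumble) : 0.0;
  auto draw_countdown = [&]() {
    double u = unif_rand();
    if (u <= 0.0) u = 1e-300;
    return 1 + (int)std::floor(std::log(u) / log1mp);
  };
  if (alpha > 0.0)
    for (int i = 0; i < N; ++i) next_tumble[i] = draw_countdown();

  for (int i = 0; i < N; ++i) { cth[i] = std::cos(th[i]); sth[i] = std::sin(th[i]); }

  auto compute_forces = [&]() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(tq.begin(), tq.end(), 0.0);
    bfx = bfy = 0.0;
    if (interactions && N > 1) {
      cl.build(px, py, L, cutoff);
      for_pairs(cl, N, [&](int i, int j) {
        double dx = min_image_near(px[j] - px[i], L);
        double dy = min_image_near(py[j] - py[i], L);
        PairFT p = rod_rod_ft(dx, dy, cth[i], sth[i], cth[j], sth[j],
                              h, sigma, krep, i, j);
        if (!p.contact) return;
        fx[i] += p.fxi; fy[i] += p.fyi; tq[i] += p.ti;
        fx[j] += p.fxj; fy[j] += p.fyj; tq[j] += p.tj;
      });
    }
    if (bead_present) {
      for (int i = 0; i < N; ++i) {
        double dx = min_image_near(bx - px[i], L);
        double dy = min_image_near(by - py[i], L);
        PairFT p = rod_bead_ft(dx, dy, cth[i], sth[i], h, sigma, ba, krep);
        if (!p.contact) continue;
        fx[i] += p.fxi; fy[i] += p.fyi; tq[i] += p.ti;
        bfx += p.fxj; bfy += p.fyj;
      }
    }
  };

  auto save_frame = [&](int f, double time) {
    for (int i = 0; i < N; ++i) {
      out_pos[(R_xlen_t)f * N * 2 + i] = px[i];
      out_pos[(R_xlen_t)f * N * 2 + N + i] = py[i];
      out_ang[(R_xlen_t)f * N + i] = th[i];
    }
    out_t[f] = time;
    out_bead(0, f) = bx;  out_bead(1, f) = by;
    out_bead_u(0, f) = bux; out_bead_u(1, f) = buy;
    out_disc(0, f) = dcx; out_disc(1, f) = dcy;
    // fresh bead force for the saved configuration so that frame-based
    // analyzers can be checked against it exactly
    double fbx = 0.0, fby = 0.0;
    if (bead_present) {
      for (int i = 0; i < N; ++i) {
        double dx = min_image(bx - px[i], L);
        double dy = min_image(by - py[i], L);
        PairFT p = rod_bead_ft(dx, dy, std::cos(th[i]), std::sin(th[i]),
                               h, sigma, ba, krep);
        fbx += p.fxj; fby += p.fyj;
      }
    }
    out_bforce(0, f) = fbx; out_bforce(1, f) = fby;
  };

  save_frame(0, 0.0);
  int f = 1;
  for (int t = 1; t <= n_steps; ++t) {
    compute_forces();
    for (int i = 0; i < N; ++i) {
      double v = speed_of(px[i], py[i], ptype, dcx, dcy, ax, ay, R, vm, vp, v0, L);
      double dxp = dt * (v * cth[i] + fx[i] / gamma);
      double dyp = dt * (v * sth[i] + fy[i] / gamma);
      if (dxp * dxp + dyp * dyp > lim2)
        stop("integration unstable: rod displacement exceeded sigma/2 at step %d", t);
      px[i] = wrap_box(px[i] + dxp, L);
      py[i] = wrap_box(py[i] + dyp, L);
      bool turned = false;
      if (tq[i] != 0.0) {
        th[i] = wrap_box(th[i] + dt * tq[i] / gamma_rot, TWO_PI);
        turned = true;
      }
      if (alpha > 0.0 && --next_tumble[i] == 0) {
        th[i] = TWO_PI * unif_rand();
        next_tumble[i] = draw_countdown();
        turned = true;
      }
      if (turned) { cth[i] = std::cos(th[i]); sth[i] = std::sin(th[i]); }
    }
    if (bead_present && bead_mobile) {
      double dbx = dt * bfx / gamma_bead, dby = dt * bfy / gamma_bead;
      if (dbx * dbx + dby * dby > lim2)
        stop("integration unstable: bead displacement exceeded sigma/2 at step %d", t);
      bx = wrap_box(bx + dbx, L);
      by = wrap_box(by + dby, L);
      bux += dbx; buy += dby;
    }
    if (bead_present && feedback_every > 0 && t % feedback_every == 0) {
      dcx = wrap_box(bx - delta * ax, L);
      dcy = wrap_box(by - delta * ay, L);
    }
    if (t % save_every == 0) save_frame(f++, t * dt);
  }

  out_pos.attr("dim") = IntegerVector::create(N, 2, nf);
  out_ang.attr("dim") = IntegerVector::create(N, nf);
  return List::create(
      _["times"] = out_t, _["positions"] = out_pos, _["angles"] = out_ang,
      _["bead"] = out_bead, _["bead_unwrapped"] = out_bead_u,
      _["disc"] = out_disc, _["bead_force"] = out_bforce,
      _["n_frames"] = nf);
}

// ---------------------------------------------------------------------------
// random sequential insertion of non-overlapping rods

// [[Rcpp::export]]
List place_rods_cpp(int N, double L, double shaft, double sigma,
                    double contact_scale, bool bead_present, double bx,
                    double by, double a, int max_attempts_per_rod) {
  NumericMatrix pos(N, 2);
  NumericVector ang(N);
  double h = 0.5 * shaft;
  double contact = sigma * contact_scale;
  double cutoff = shaft + contact;
  int nc = (int)std::floor(L / cutoff);
  bool use_cells = nc >= 4;
  std::vector<int> head, nxt;
  if (use_cells) { head.assign((size_t)nc * nc, -1); nxt.assign(N, -1); }

  auto overlaps = [&](double x, double y, double t, int n_placed) {
    if (bead_present) {
      double dx = min_image(bx - x, L), dy = min_image(by - y, L);
      double uix = std::cos(t), uiy = std::sin(t);
      double s = clampd(uix * dx + uiy * dy, -h, h);
      double wx = s * uix - dx, wy = s * uiy - dy;
      if (wx * wx + wy * wy < (a + 0.5 * sigma) * (a + 0.5 * sigma)) return true;
    }
    auto check = [&](int j) {
      double dx = min_image(pos(j, 0) - x, L), dy = min_image(pos(j, 1) - y, L);
      if (dx * dx + dy * dy >= cutoff * cutoff) return false;
      double s, tt, wx, wy, d2;
      seg_seg(dx, dy, std::cos(t), std::sin(t), std::cos(ang[j]),
              std::sin(ang[j]), h, s, tt, wx, wy, d2);
      return d2 < contact * contact;
    };
    if (!use_cells) {
      for (int j = 0; j < n_placed; ++j) if (check(j)) return true;
      return false;
    }
    int cx = (int)(x / L * nc); if (cx >= nc) cx = nc - 1;
    int cy = (int)(y / L * nc); if (cy >= nc) cy = nc - 1;
    for (int oy = -1; oy <= 1; ++oy) {
      for (int ox = -1; ox <= 1; ++ox) {
        int c = ((cx + ox + nc) % nc) + nc * ((cy + oy + nc) % nc);
        for (int j = head[c]; j >= 0; j = nxt[j]) if (check(j)) return true;
      }
    }
    return false;
  };

  for (int i = 0; i < N; ++i) {
    bool placed = false;
    for (int att = 0; att < max_attempts_per_rod; ++att) {
      double x = L * unif_rand(), y = L * unif_rand();
      double t = TWO_PI * unif_rand();
      if (!overlaps(x, y, t, i)) {
        pos(i, 0) = x; pos(i, 1) = y; ang[i] = t;
        if (use_cells) {
          int cx = (int)(x / L * nc); if (cx >= nc) cx = nc - 1;
          int cy = (int)(y / L * nc); if (cy >= nc) cy = nc - 1;
          int c = cx + nc * cy;
          nxt[i] = head[c]; head[c] = i;
        }
        placed = true;
        break;
      }
    }
    if (!placed)
      return List::create(_["ok"] = false, _["n_placed"] = i);
  }
  return List::create(_["ok"] = true, _["positions"] = pos, _["angles"] = ang);
}

// ---------------------------------------------------------------------------
// frame-based analyzers

// wall contact forces on the bead contour, binned by angle
// pos: (N,2,nf) array, beadc: (2,nf); frames: 1-based frame indices to use
// [[Rcpp::export]]
List wall_profile_cpp(NumericVector pos, NumericVector ang,
                      NumericMatrix beadc, int N, IntegerVector frames,
                      double shaft, double sigma, double a, double k,
                      double L, int ntheta) {
  const double h = 0.5 * shaft;
  NumericVector fsum(ntheta);
  NumericMatrix fvec(2, ntheta);
  double netx = 0.0, nety = 0.0;
  for (R_xlen_t fi = 0; fi < frames.size(); ++fi) {
    int f = frames[fi] - 1;
    double bx = beadc(0, f), by = beadc(1, f);
    for (int i = 0; i < N; ++i) {
      double x = pos[(R_xlen_t)f * N * 2 + i];
      double y = pos[(R_xlen_t)f * N * 2 + N + i];
      double t = ang[(R_xlen_t)f * N + i];
      double dx = min_image(bx - x, L), dy = min_image(by - y, L);
      PairFT p = rod_bead_ft(dx, dy, std::cos(t), std::sin(t), h, sigma, a, k);
      if (!p.contact) continue;
      // the contact force is purely radial, so the contact angle on the
      // contour is the direction opposite to the force on the bead
      double fm = std::sqrt(p.fxj * p.fxj + p.fyj * p.fyj);
      double phi = std::atan2(-p.fyj, -p.fxj);
      if (phi < 0) phi += TWO_PI;
      int b = (int)(phi / TWO_PI * ntheta);
      if (b >= ntheta) b = ntheta - 1;
      fsum[b] += fm;
      fvec(0, b) += p.fxj; fvec(1, b) += p.fyj;
      netx += p.fxj; nety += p.fyj;
    }
  }
  return List::create(_["force_sum"] = fsum, _["force_vec"] = fvec,
                      _["net_force"] = NumericVector::create(netx, nety),
                      _["n_frames"] = (int)frames.size());
}

// binned pair-virial sums over frames; midpoint assignment
// [[Rcpp::export]]
NumericMatrix virial_map_cpp(NumericVector pos, NumericVector ang, int N,
                             IntegerVector frames, double shaft,
                             double sigma, double k, double L, int nbins) {
  const double h = 0.5 * shaft;
  const double cutoff = shaft + sigma;
  NumericMatrix sum(nbins, nbins);
  std::vector<double> px(N), py(N), cth(N), sth(N);
  CellList cl;
  for (R_xlen_t fi = 0; fi < frames.size(); ++fi) {
    int f = frames[fi] - 1;
    for (int i = 0; i < N; ++i) {
      px[i] = pos[(R_xlen_t)f * N * 2 + i];
      py[i] = pos[(R_xlen_t)f * N * 2 + N + i];
      double t = ang[(R_xlen_t)f * N + i];
      cth[i] = std::cos(t); sth[i] = std::sin(t);
    }
    cl.build(px, py, L, cutoff);
    for_pairs(cl, N, [&](int i, int j) {
      double dx = min_image_near(px[j] - px[i], L);
      double dy = min_image_near(py[j] - py[i], L);
      PairFT p = rod_rod_ft(dx, dy, cth[i], sth[i], cth[j], sth[j],
                            h, sigma, k, i, j);
      if (!p.contact) return;
      double mx = wrap_box(px[i] + 0.5 * dx, L);
      double my = wrap_box(py[i] + 0.5 * dy, L);
      int bxi = (int)(mx / L * nbins); if (bxi >= nbins) bxi = nbins - 1;
      int byi = (int)(my / L * nbins); if (byi >= nbins) byi = nbins - 1;
      sum(bxi, byi) += p.w;
    });
  }
  return sum;
}

// direct pressure on an annulus just outside the bead, resolved in angular
// wedges: pair virials assigned by midpoint to wedges of [r1, r2] around
// the bead centre.  Returns the virial sums; R divides by 2 * wedge area *
// n_frames.
// [[Rcpp::export]]
NumericVector contour_pd_cpp(NumericVector pos, NumericVector ang, int N,
                             IntegerVector frames, NumericMatrix beadc,
                             double shaft, double sigma, double k, double L,
                             double r1, double r2, int ntheta) {
  const double h = 0.5 * shaft;
  const double cutoff = shaft + sigma;
  NumericVector sum(ntheta);
  std::vector<double> px(N), py(N), cth(N), sth(N);
  CellList cl;
  for (R_xlen_t fi = 0; fi < frames.size(); ++fi) {
    int f = frames[fi] - 1;
    double bx = beadc(0, f), by = beadc(1, f);
    for (int i = 0; i < N; ++i) {
      px[i] = pos[(R_xlen_t)f * N * 2 + i];
      py[i] = pos[(R_xlen_t)f * N * 2 + N + i];
      double t = ang[(R_xlen_t)f * N + i];
      cth[i] = std::cos(t); sth[i] = std::sin(t);
    }
    cl.build(px, py, L, cutoff);
    for_pairs(cl, N, [&](int i, int j) {
      double dx = min_image_near(px[j] - px[i], L);
      double dy = min_image_near(py[j] - py[i], L);
      // quick reject on the midpoint distance to the bead
      double mx = px[i] + 0.5 * dx, my = py[i] + 0.5 * dy;
      double rx = min_image(mx - bx, L), ry = min_image(my - by, L);
      double rr = std::sqrt(rx * rx + ry * ry);
      if (rr < r1 || rr >= r2) return;
      PairFT p = rod_rod_ft(dx, dy, cth[i], sth[i], cth[j], sth[j],
                            h, sigma, k, i, j);
      if (!p.contact) return;
      double phi = std::atan2(ry, rx);
      if (phi < 0) phi += TWO_PI;
      int b = (int)(phi / TWO_PI * ntheta);
      if (b >= ntheta) b = ntheta - 1;
      sum[b] += p.w;
    });
  }
  return sum;
}

// ---------------------------------------------------------------------------
// non-interacting run-and-tumble gas between two flat repulsive walls
// (periodic in y); accumulates the force on both walls

// [[Rcpp::export]]
List wall_gas_cpp(NumericMatrix pos0, NumericVector ang0, double Lx,
                  double Ly, double v, double alpha, double gamma, double dt,
                  int n_steps, double k_wall, int save_every,
                  double measure_frac) {
  const int N = pos0.nrow();
  std::vector<double> px(N), py(N), th(N);
  for (int i = 0; i < N; ++i) { px[i] = pos0(i, 0); py[i] = pos0(i, 1); th[i] = ang0[i]; }
  const double p_tumble = 1.0 - std::exp(-alpha * dt);
  const int measure_start = (int)(measure_frac * n_steps);
  double fr_sum = 0.0, fl_sum = 0.0;
  long n_meas = 0;
  const int nf = n_steps / save_every + 1;
  NumericVector out_pos((R_xlen_t)N * 2 * nf), out_ang((R_xlen_t)N * nf), out_t(nf);
  auto save_frame = [&](int f, double time) {
    for (int i = 0; i < N; ++i) {
      out_pos[(R_xlen_t)f * N * 2 + i] = px[i];
      out_pos[(R_xlen_t)f * N * 2 + N + i] = py[i];
      out_ang[(R_xlen_t)f * N + i] = th[i];
    }
    out_t[f] = time;
  };
  save_frame(0, 0.0);
  int f = 1;
  for (int t = 1; t <= n_steps; ++t) {
    double fr = 0.0, fl = 0.0;
    for (int i = 0; i < N; ++i) {
      double fxw = 0.0;
      if (px[i] < 0)  { fxw = -k_wall * px[i]; fl += fxw; }
      if (px[i] > Lx) { fxw = -k_wall * (px[i] - Lx); fr += -fxw; }
      px[i] += dt * (v * std::cos(th[i]) + fxw / gamma);
      py[i] = wrap_box(py[i] + dt * v * std::sin(th[i]), Ly);
      if (alpha > 0.0 && unif_rand() < p_tumble) th[i] = TWO_PI * unif_rand();
    }
    if (t > measure_start) { fr_sum += fr; fl_sum += fl; ++n_meas; }
    if (t % save_every == 0) save_frame(f++, t * dt);
  }
  out_pos.attr("dim") = IntegerVector::create(N, 2, nf);
  out_ang.attr("dim") = IntegerVector::create(N, nf);
  double pr = n_meas > 0 ? fr_sum / n_meas / Ly : 0.0;
  double pl = n_meas > 0 ? fl_sum / n_meas / Ly : 0.0;
  return List::create(_["times"] = out_t, _["positions"] = out_pos,
                      _["angles"] = out_ang,
                      _["pressure_right"] = pr, _["pressure_left"] = pl,
                      _["n_measured"] = (double)n_meas);
}
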
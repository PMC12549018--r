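#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Counter-based Gaussian noise. Every draw is a pure function of
// (seed, global step, slot), so a run restarted from a checkpoint with the
// correct step offset replays the exact same noise stream as the original
// run. This is what makes the stimulated / baseline pair of the sPCI
// protocol share their noise bit-exactly.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t seed, uint64_t ctr) {
  uint64_t z = mix64(seed ^ mix64(ctr));
  // (0, 1), never exactly 0 or 1
  return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// Fill m standard normals for a given (seed, step) via Box-Muller pairs.
static void fill_normals(std::vector<double> &z, int m,
                         uint64_t seed, uint64_t step, int stride) {
  const double TWOPI = 6.283185307179586476925286766559;
  uint64_t base = step * (uint64_t)stride;
  for (int j = 0; j < m; j += 2) {
    double u1 = u01(seed, base + (uint64_t)j);
    double u2 = u01(seed, base + (uint64_t)j + 1);
    double R = std::sqrt(-2.0 * std::log(u1));
    z[j] = R * std::cos(TWOPI * u2);
    if (j + 1 < m) z[j + 1] = R * std::sin(TWOPI * u2);
  }
}

// Network of Montbrio-Pazo-Roxin neural masses:
//   r' = Delta/pi + 2 r v
//   v' = v^2 + eta + J r + G * sum_m W[n,m] r_m(t - tau_nm) + I_stim - (pi r)^2
// integrated with a stochastic Heun scheme (additive noise, coupling frozen
// over the step, firing rates clamped at zero after each stage).
// [[Rcpp::export(name = ".sim_montbrio_cpp")]]
List sim_montbrio_cpp(NumericMatrix W, IntegerMatrix dsteps,
                      double eta, double delta, double jsyn, double G,
                      double sigma, double dt, int n_steps, int record_every,
                      bool noise_on_r, double seed_in, double step_offset_in,
                      NumericVector r0, NumericVector v0,
                      Nullable<NumericMatrix> hist0_, int hist_pos0,
                      int stim_node, int stim_on, int stim_off, double stim_amp,
                      IntegerVector checkpoint_steps, double v_bound) {
  const int n = W.nrow();
  const double PI_ = 3.14159265358979323846;
  const double pi2 = PI_ * PI_;
  const uint64_t seed = (uint64_t)seed_in;
  const uint64_t step_offset = (uint64_t)step_offset_in;

  // history length = max delay + 1
  int H = 1;
  for (int i = 0; i < n * n; ++i) if (dsteps[i] + 1 > H) H = dsteps[i] + 1;

  // per-target edge lists (contiguous for the inner loop)
  std::vector<int> eoff(n + 1, 0);
  for (int t = 0; t < n; ++t) {
    int cnt = 0;
    for (int m = 0; m < n; ++m) if (m != t && W(t, m) != 0.0) ++cnt;
    eoff[t + 1] = eoff[t] + cnt;
  }
  const int nedges = eoff[n];
  std::vector<double> ew(nedges);
  std::vector<int> esrc(nedges), edel(nedges);
  {
    int k = 0;
    for (int t = 0; t < n; ++t)
      for (int m = 0; m < n; ++m)
        if (m != t && W(t, m) != 0.0) {
          ew[k] = W(t, m);
          esrc[k] = m;
          edel[k] = dsteps(t, m) > H - 1 ? H - 1 : dsteps(t, m);
          ++k;
        }
  }

  // rate history ring buffer, time-major: hist[slot*n + m]. The slots a
  // step reads span only the delay range, so the working set stays cache-
  // resident as the ring advances.
  std::vector<double> hist((size_t)n * H);
  int pos = 0;
  if (hist0_.isNotNull()) {
    NumericMatrix h0(hist0_);
    for (int m = 0; m < n; ++m)
      for (int j = 0; j < H; ++j) hist[(size_t)j * n + m] = h0(m, j);
    pos = hist_pos0;
  } else {
    for (int m = 0; m < n; ++m)
      for (int j = 0; j < H; ++j) hist[(size_t)j * n + m] = r0[m];
  }

  std::vector<double> r(n), v(n), I(n), z(2 * n);
  for (int i = 0; i < n; ++i) { r[i] = r0[i]; v[i] = v0[i]; }

  const int T_rec = n_steps / record_every;
  NumericMatrix rec_r(n, T_rec), rec_v(n, T_rec);
  int rec_col = 0;
  // trajectories are recorded as averages over each recording bin, which is
  // the standard temporal down-sampling and keeps binarized rasters free of
  // sample-level threshold jitter
  std::vector<double> acc_r(n, 0.0), acc_v(n, 0.0);

  const int n_ckpt = checkpoint_steps.size();
  List ckpts(n_ckpt);
  int next_ckpt = 0;

  // additive-noise increments: sd = sqrt(2 * sigma * dt) per step (sigma is
  // the noise dispersion parameter, matching the additive-noise convention
  // of the reference whole-brain simulators for this model)
  const double sqdt = std::sqrt(2.0 * sigma * dt);
  const int nz = noise_on_r ? 2 * n : n;
  const int stride = 2 * n + 2; // noise slots reserved per step
  bool diverged = false;
  int step = 0;

  auto save_ckpt = [&](int idx, int at_step) {
    NumericMatrix hsave(n, H);
    for (int m = 0; m < n; ++m)
      for (int j = 0; j < H; ++j) hsave(m, j) = hist[(size_t)j * n + m];
    ckpts[idx] = List::create(_["r_hist"] = hsave, _["pos"] = pos,
                              _["r"] = NumericVector(r.begin(), r.end()),
                              _["v"] = NumericVector(v.begin(), v.end()),
                              _["step"] = at_step);
  };

  for (step = 0; step < n_steps; ++step) {
    while (next_ckpt < n_ckpt && checkpoint_steps[next_ckpt] == step) {
      save_ckpt(next_ckpt, step);
      ++next_ckpt;
    }

    // delayed coupling, frozen over the step
    for (int t = 0; t < n; ++t) {
      double acc = 0.0;
      for (int k = eoff[t]; k < eoff[t + 1]; ++k) {
        int idx = pos - edel[k];
        if (idx < 0) idx += H;
        acc += ew[k] * hist[(size_t)idx * n + esrc[k]];
      }
      I[t] = G * acc;
    }

    if (sigma > 0.0) fill_normals(z, nz, seed, step_offset + (uint64_t)step, stride);

    const bool stim_now = (stim_node >= 0 && step >= stim_on && step < stim_off);

    for (int i = 0; i < n; ++i) {
      const double stim = (stim_now && i == stim_node) ? stim_amp : 0.0;
      const double zi_v = (sigma > 0.0) ? z[noise_on_r ? 2 * i + 1 : i] : 0.0;
      const double zi_r = (sigma > 0.0 && noise_on_r) ? z[2 * i] : 0.0;
      const double ri = r[i], vi = v[i];
      double a1r = delta / PI_ + 2.0 * ri * vi;
      double a1v = vi * vi + eta + jsyn * ri + I[i] + stim - pi2 * ri * ri;
      // tame superlinear drift: cap the per-stage increment at CAP state
      // units, active only during extreme excursions (dt*|f| > CAP)
      const double CAP = 2.0;
      double m1 = std::fabs(a1r) > std::fabs(a1v) ? std::fabs(a1r) : std::fabs(a1v);
      if (dt * m1 > CAP) { const double s = CAP / (dt * m1); a1r *= s; a1v *= s; }
      double rp = ri + dt * a1r + sqdt * zi_r;
      if (rp < 0.0) rp = 0.0;
      const double vp = vi + dt * a1v + sqdt * zi_v;
      double a2r = delta / PI_ + 2.0 * rp * vp;
      double a2v = vp * vp + eta + jsyn * rp + I[i] + stim - pi2 * rp * rp;
      double m2 = std::fabs(a2r) > std::fabs(a2v) ? std::fabs(a2r) : std::fabs(a2v);
      if (dt * m2 > CAP) { const double s = CAP / (dt * m2); a2r *= s; a2v *= s; }
      double rn = ri + 0.5 * dt * (a1r + a2r) + sqdt * zi_r;
      if (rn < 0.0) rn = 0.0;
      const double vn = vi + 0.5 * dt * (a1v + a2v) + sqdt * zi_v;
      if (!std::isfinite(vn) || std::fabs(vn) > v_bound) diverged = true;
      r[i] = rn;
      v[i] = vn;
    }
    if (diverged) break;

    ++pos;
    if (pos == H) pos = 0;
    for (int i = 0; i < n; ++i) hist[(size_t)pos * n + i] = r[i];

    for (int i = 0; i < n; ++i) { acc_r[i] += r[i]; acc_v[i] += v[i]; }
    if ((step + 1) % record_every == 0 && rec_col < T_rec) {
      const double inv = 1.0 / record_every;
      for (int i = 0; i < n; ++i) {
        rec_r(i, rec_col) = acc_r[i] * inv;
        rec_v(i, rec_col) = acc_v[i] * inv;
        acc_r[i] = 0.0; acc_v[i] = 0.0;
      }
      ++rec_col;
    }
  }

  if (!diverged) {
    while (next_ckpt < n_ckpt && checkpoint_steps[next_ckpt] == n_steps) {
      save_ckpt(next_ckpt, n_steps);
      ++next_ckpt;
    }
  }

  return List::create(_["r"] = rec_r, _["v"] = rec_v,
                      _["checkpoints"] = ckpts, _["diverged"] = diverged,
                      _["steps_done"] = diverged ? step : n_steps,
                      _["H"] = H);
}
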
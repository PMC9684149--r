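// Fixed-step RK4 integrator for networks of Huber-Braun neurons coupled by
// gap junctions, with optional circadian (delayed) drive dynamics.
//
// State per neuron: V, a_K, a_pNa, a_KCa.  a_Na is algebraic (instantaneous
// sigmoid of V).  The circadian oscillator, when active, is a single shared
// ([dCLOCK], [PER]) pair with discrete transcription delays handled through a
// step-aligned history buffer of [dCLOCK_free].
//
// Time is measured in hours throughout, matching the model's parameter table.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Neuron parameter vector layout (kept in step with .hb_param_vec() in R).
enum {
  P_C = 0, P_GL, P_GNA, P_GK, P_GPNA, P_GKCA,
  P_VL, P_VNA, P_VK, P_VPNA, P_VKCA,
  P_V0NA, P_V0K, P_V0PNA,
  P_SNA, P_SK, P_SPNA,
  P_TAUK, P_TAUPNA, P_TAUKCA,
  P_ETA, P_XI, P_ALPHA, P_BETA, P_RHO, P_PHI,
  P_N_FIELDS
};

// Circadian parameter vector layout (see .circ_param_vec() in R).
enum {
  CP_VSC = 0, CP_VSP, CP_KDC, CP_KDP, CP_K1, CP_K2,
  CP_TAU1, CP_TAU2, CP_GDCLOCK, CP_GPER, CP_ESYN,
  CP_N_FIELDS
};

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct HBParams {
  double C, gl, gNa, gK, gpNa, gKCa;
  double Vl, VNa, VK, VpNa, VKCa;
  double V0Na, V0K, V0pNa, sNa, sK, spNa;
  double tauK, taupNa, tauKCa, eta, xi, alpha, beta, rho, phi;
  explicit HBParams(const NumericVector& p) {
    if (p.size() != P_N_FIELDS) stop("neuron parameter vector has wrong length");
    C = p[P_C]; gl = p[P_GL]; gNa = p[P_GNA]; gK = p[P_GK];
    gpNa = p[P_GPNA]; gKCa = p[P_GKCA];
    Vl = p[P_VL]; VNa = p[P_VNA]; VK = p[P_VK];
    VpNa = p[P_VPNA]; VKCa = p[P_VKCA];
    V0Na = p[P_V0NA]; V0K = p[P_V0K]; V0pNa = p[P_V0PNA];
    sNa = p[P_SNA]; sK = p[P_SK]; spNa = p[P_SPNA];
    tauK = p[P_TAUK]; taupNa = p[P_TAUPNA]; tauKCa = p[P_TAUKCA];
    eta = p[P_ETA]; xi = p[P_XI]; alpha = p[P_ALPHA]; beta = p[P_BETA];
    rho = p[P_RHO]; phi = p[P_PHI];
  }
};

// Derivatives of one neuron given its membrane/gating state and the summed
// input currents.  Writes dV, daK, dapNa, daKCa.
static inline void neuron_rhs(const HBParams& p, double V, double aK,
                              double apNa, double aKCa, double Iin,
                              double& dV, double& daK, double& dapNa,
                              double& daKCa) {
  const double aNa = sigm(p.sNa * (V - p.V0Na));
  const double Il   = p.gl * (V - p.Vl);
  const double INa  = p.rho * p.gNa * aNa * (V - p.VNa);
  const double IK   = p.rho * p.gK * aK * (V - p.VK);
  const double IpNa = p.rho * p.gpNa * apNa * (V - p.VpNa);
  const double IKCa = p.rho * p.gKCa * aKCa * (V - p.VKCa);
  dV = (-Il - p.alpha * (INa + IK) - p.beta * (IpNa + IKCa) + Iin) / p.C;
  daK   = p.phi * (sigm(p.sK * (V - p.V0K)) - aK) / p.tauK;
  dapNa = p.phi * (sigm(p.spNa * (V - p.V0pNa)) - apNa) / p.taupNa;
  daKCa = p.phi * (-p.eta * IpNa - p.xi * aKCa) / p.tauKCa;
}

// Full-network derivative: gap-junction coupling from the CSR adjacency plus
// the external drive.  drive_mode: 0 = constant current, 1 = circadian
// synaptic form with supplied concentrations.
static void network_rhs(const HBParams& p, int n,
                        const std::vector<int>& indptr,
                        const std::vector<int>& indices, double g,
                        int drive_mode, double drive_level,
                        double gd_dclock, double gd_per, double Esyn,
                        double dclock, double per,
                        const std::vector<double>& V,
                        const std::vector<double>& aK,
                        const std::vector<double>& apNa,
                        const std::vector<double>& aKCa,
                        std::vector<double>& dV, std::vector<double>& daK,
                        std::vector<double>& dapNa,
                        std::vector<double>& daKCa) {
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = indptr[i]; k < indptr[i + 1]; ++k)
      acc += V[indices[k]] - V[i];
    double Iin = g * acc;
    if (drive_mode == 0) {
      Iin += drive_level;
    } else {
      Iin += (gd_dclock * dclock - gd_per * per) * (Esyn - V[i]);
    }
    neuron_rhs(p, V[i], aK[i], apNa[i], aKCa[i], Iin, dV[i], daK[i],
               dapNa[i], daKCa[i]);
  }
}

// [[Rcpp::export(name = ".hb_rhs_cpp")]]
List hb_rhs_cpp(NumericVector V, NumericVector aK, NumericVector apNa,
                NumericVector aKCa, NumericVector Iin, NumericVector params) {
  HBParams p(params);
  const int n = V.size();
  NumericVector dV(n), daK(n), dapNa(n), daKCa(n);
  for (int i = 0; i < n; ++i)
    neuron_rhs(p, V[i], aK[i], apNa[i], aKCa[i], Iin[i], dV[i], daK[i],
               dapNa[i], daKCa[i]);
  return List::create(_["dV"] = dV, _["da_K"] = daK, _["da_pNa"] = dapNa,
                      _["da_KCa"] = daKCa);
}

// Delayed [dCLOCK_free] lookup with linear interpolation on the step grid.
// hist[j] holds the value at time (j - pre) * dt relative to simulation
// start; constant-history initialization fills j < pre.
static inline double hist_lookup(const std::vector<double>& hist, int pre,
                                 double t_over_dt_minus_tau) {
  double x = t_over_dt_minus_tau + pre;
  if (x <= 0.0) return hist[0];
  int j = (int)std::floor(x);
  if (j >= (int)hist.size() - 1) return hist.back();
  double f = x - j;
  return hist[j] * (1.0 - f) + hist[j + 1] * f;
}

// [[Rcpp::export(name = ".hb_simulate_cpp")]]
List hb_simulate_cpp(IntegerVector indptr_r, IntegerVector indices_r,
                     NumericVector params, double g, double dt,
                     double t_transient, double t_observe,
                     NumericVector V0, NumericVector aK0, NumericVector apNa0,
                     NumericVector aKCa0, double spike_threshold,
                     int drive_mode, double drive_level,
                     NumericVector circ_params, double dclock0, double per0,
                     int record_every) {
  const int n = V0.size();
  if (indptr_r.size() != n + 1) stop("indptr length must be n + 1");
  HBParams p(params);

  double vsc = 0, vsp = 0, kdc = 0, kdp = 0, K1 = 0, K2 = 0, tau1 = 0,
         tau2 = 0, gdc = 0, gpe = 0, Esyn = 0;
  if (drive_mode == 1) {
    if (circ_params.size() != CP_N_FIELDS)
      stop("circadian parameter vector has wrong length");
    vsc = circ_params[CP_VSC]; vsp = circ_params[CP_VSP];
    kdc = circ_params[CP_KDC]; kdp = circ_params[CP_KDP];
    K1 = circ_params[CP_K1]; K2 = circ_params[CP_K2];
    tau1 = circ_params[CP_TAU1]; tau2 = circ_params[CP_TAU2];
    gdc = circ_params[CP_GDCLOCK]; gpe = circ_params[CP_GPER];
    Esyn = circ_params[CP_ESYN];
  }

  std::vector<int> indptr(indptr_r.begin(), indptr_r.end());
  std::vector<int> indices(indices_r.begin(), indices_r.end());

  std::vector<double> V(V0.begin(), V0.end()), aK(aK0.begin(), aK0.end()),
      apNa(apNa0.begin(), apNa0.end()), aKCa(aKCa0.begin(), aKCa0.end());

  const long n_trans = (long)std::llround(t_transient / dt);
  const long n_obs = (long)std::llround(t_observe / dt);
  const long n_total = n_trans + n_obs;

  // circadian history of [dCLOCK_free]
  double dclock = dclock0, per = per0;
  const double max_tau = std::max(tau1, tau2);
  int pre = drive_mode == 1 ? (int)std::ceil(max_tau / dt) + 2 : 0;
  std::vector<double> hist;
  if (drive_mode == 1) {
    hist.reserve(pre + n_total + 1);
    double df0 = std::max(dclock - per, 0.0);
    for (int j = 0; j <= pre; ++j) hist.push_back(df0);
  }

  // spike storage
  std::vector<std::vector<double>> spikes(n);

  // optional downsampled recording of V (and circadian state) in the window
  const bool record = record_every > 0;
  long n_rec = record ? n_obs / record_every + 1 : 0;
  NumericMatrix traces(record ? n_rec : 0, record ? n : 0);
  NumericVector rec_t(record ? n_rec : 0);
  NumericVector rec_dclock(record && drive_mode == 1 ? n_rec : 0);
  NumericVector rec_per(record && drive_mode == 1 ? n_rec : 0);
  long i_rec = 0;

  std::vector<double> k1V(n), k1aK(n), k1ap(n), k1aC(n);
  std::vector<double> k2V(n), k2aK(n), k2ap(n), k2aC(n);
  std::vector<double> k3V(n), k3aK(n), k3ap(n), k3aC(n);
  std::vector<double> k4V(n), k4aK(n), k4ap(n), k4aC(n);
  std::vector<double> tV(n), taK(n), tap(n), taC(n);
  std::vector<double> Vprev(n);

  for (long step = 0; step < n_total; ++step) {
    const double t = step * dt;
    const bool in_window = step >= n_trans;

    if (record && in_window && (step - n_trans) % record_every == 0) {
      rec_t[i_rec] = t;
      for (int i = 0; i < n; ++i) traces(i_rec, i) = V[i];
      if (drive_mode == 1) { rec_dclock[i_rec] = dclock; rec_per[i_rec] = per; }
      ++i_rec;
    }

    // circadian stage values (shared by all neurons); RK4 on (dclock, per)
    // alongside the membrane states, with delayed terms from the history.
    double c1d = 0, c1p = 0, c2d = 0, c2p = 0, c3d = 0, c3p = 0, c4d = 0,
           c4p = 0;
    double dclock_mid2 = dclock, per_mid2 = per, dclock_mid3 = dclock,
           per_mid3 = per, dclock_end = dclock, per_end = per;
    if (drive_mode == 1) {
      auto circ_rhs = [&](double dc, double pe, double stage_t, double& dd,
                          double& dp) {
        double df2 = hist_lookup(hist, pre, stage_t / dt - tau2 / dt);
        double df1 = hist_lookup(hist, pre, stage_t / dt - tau1 / dt);
        double Rsc = K2 / (K2 + df2);
        double Rsp = df1 / (K1 + df1);
        dd = vsc * Rsc - kdc * dc;
        dp = vsp * Rsp - kdp * pe;
      };
      circ_rhs(dclock, per, t, c1d, c1p);
      dclock_mid2 = dclock + 0.5 * dt * c1d; per_mid2 = per + 0.5 * dt * c1p;
      circ_rhs(dclock_mid2, per_mid2, t + 0.5 * dt, c2d, c2p);
      dclock_mid3 = dclock + 0.5 * dt * c2d; per_mid3 = per + 0.5 * dt * c2p;
      circ_rhs(dclock_mid3, per_mid3, t + 0.5 * dt, c3d, c3p);
      dclock_end = dclock + dt * c3d; per_end = per + dt * c3p;
      circ_rhs(dclock_end, per_end, t + dt, c4d, c4p);
    }

    // RK4 stages for the membrane/gating states
    network_rhs(p, n, indptr, indices, g, drive_mode, drive_level, gdc, gpe,
                Esyn, dclock, per, V, aK, apNa, aKCa, k1V, k1aK, k1ap, k1aC);
    for (int i = 0; i < n; ++i) {
      tV[i] = V[i] + 0.5 * dt * k1V[i];
      taK[i] = aK[i] + 0.5 * dt * k1aK[i];
      tap[i] = apNa[i] + 0.5 * dt * k1ap[i];
      taC[i] = aKCa[i] + 0.5 * dt * k1aC[i];
    }
    network_rhs(p, n, indptr, indices, g, drive_mode, drive_level, gdc, gpe,
                Esyn, dclock_mid2, per_mid2, tV, taK, tap, taC, k2V, k2aK,
                k2ap, k2aC);
    for (int i = 0; i < n; ++i) {
      tV[i] = V[i] + 0.5 * dt * k2V[i];
      taK[i] = aK[i] + 0.5 * dt * k2aK[i];
      tap[i] = apNa[i] + 0.5 * dt * k2ap[i];
      taC[i] = aKCa[i] + 0.5 * dt * k2aC[i];
    }
    network_rhs(p, n, indptr, indices, g, drive_mode, drive_level, gdc, gpe,
                Esyn, dclock_mid3, per_mid3, tV, taK, tap, taC, k3V, k3aK,
                k3ap, k3aC);
    for (int i = 0; i < n; ++i) {
      tV[i] = V[i] + dt * k3V[i];
      taK[i] = aK[i] + dt * k3aK[i];
      tap[i] = apNa[i] + dt * k3ap[i];
      taC[i] = aKCa[i] + dt * k3aC[i];
    }
    network_rhs(p, n, indptr, indices, g, drive_mode, drive_level, gdc, gpe,
                Esyn, dclock_end, per_end, tV, taK, tap, taC, k4V, k4aK, k4ap,
                k4aC);

    bool bad = false;
    for (int i = 0; i < n; ++i) {
      Vprev[i] = V[i];
      V[i] += dt / 6.0 * (k1V[i] + 2 * k2V[i] + 2 * k3V[i] + k4V[i]);
      aK[i] += dt / 6.0 * (k1aK[i] + 2 * k2aK[i] + 2 * k3aK[i] + k4aK[i]);
      apNa[i] += dt / 6.0 * (k1ap[i] + 2 * k2ap[i] + 2 * k3ap[i] + k4ap[i]);
      aKCa[i] += dt / 6.0 * (k1aC[i] + 2 * k2aC[i] + 2 * k3aC[i] + k4aC[i]);
      if (!std::isfinite(V[i])) bad = true;
    }
    if (bad)
      stop("non-finite membrane potential at t = %f h; integration aborted",
           t + dt);

    if (drive_mode == 1) {
      dclock += dt / 6.0 * (c1d + 2 * c2d + 2 * c3d + c4d);
      per += dt / 6.0 * (c1p + 2 * c2p + 2 * c3p + c4p);
      if (dclock < 0) dclock = 0;
      if (per < 0) per = 0;
      hist.push_back(std::max(dclock - per, 0.0));
    }

    // upward threshold crossings, linearly interpolated, observation only.
    // A sample lying exactly on the threshold is counted with the step that
    // reaches it (Vprev < thr, V >= thr), never twice.
    if (in_window) {
      for (int i = 0; i < n; ++i) {
        if (Vprev[i] < spike_threshold && V[i] >= spike_threshold) {
          double tc =
              t + dt * (spike_threshold - Vprev[i]) / (V[i] - Vprev[i]);
          spikes[i].push_back(tc);
        }
      }
    }
  }

  List spike_list(n);
  for (int i = 0; i < n; ++i)
    spike_list[i] = NumericVector(spikes[i].begin(), spikes[i].end());

  List out = List::create(
      _["spikes"] = spike_list,
      _["window"] = NumericVector::create(n_trans * dt, n_total * dt),
      _["final_V"] = NumericVector(V.begin(), V.end()),
      _["final_a_K"] = NumericVector(aK.begin(), aK.end()),
      _["final_a_pNa"] = NumericVector(apNa.begin(), apNa.end()),
      _["final_a_KCa"] = NumericVector(aKCa.begin(), aKCa.end()),
      _["final_dclock"] = dclock, _["final_per"] = per);
  if (record) {
    out["trace_t"] = rec_t;
    out["traces"] = traces;
    if (drive_mode == 1) {
      out["trace_dclock"] = rec_dclock;
      out["trace_per"] = rec_per;
    }
  }
  return out;
}
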
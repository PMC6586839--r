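// Forward-Euler engine for a conductance-based AdEx network with
// multiplicative STDP.  All state is passed in and returned, so phases of a
// protocol can be chained from R.  Randomness comes from R's global RNG
// stream (Rcpp RNGScope), making runs bit-reproducible under set.seed().
//
// Conventions
//   - weights are stored transposed, Wt(target, source), so that spike
//     propagation (all targets of one source) walks a contiguous column;
//   - a weight w delivers |w| nS to the excitatory receptor if w > 0 and to
//     the inhibitory receptor if w < 0;
//   - conductance increments produced by spikes at step k are applied at the
//     start of step k+1 (zero axonal delay, one-step synaptic latency);
//   - STDP traces exclude same-step spikes: weight updates triggered by the
//     spikes of a step use the traces as decayed at the start of that step,
//     and the spikes are added to the traces afterwards.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct PlasticBlock {
  int s0, s1, t0, t1;          // global index ranges, 0-based inclusive
  double lam, alpha, wmax;
  bool active;
};

// [[Rcpp::export]]
List engine_run(List state, List prm, NumericMatrix Wt, List plastic,
                List sources, double t0, double duration, double dt,
                double tau_stdp, IntegerVector pop_of,
                LogicalVector record_mask, NumericVector snap_times,
                bool alpha_kernel, double delay_ms) {
  const int N = pop_of.size();
  if (Wt.nrow() != N || Wt.ncol() != N)
    stop("weight matrix dimension does not match neuron count");
  if (dt <= 0) stop("dt must be positive");
  Wt = clone(Wt);  // engine works on its own copy; caller's matrix untouched

  // per-population parameter vectors
  NumericVector tau_m = prm["tau_m"], E_l = prm["E_l"], theta = prm["theta"],
      delta_V = prm["delta_V"], Cm = prm["C"], a_sub = prm["a"],
      b_spk = prm["b"], tau_W = prm["tau_W"], V_reset = prm["V_reset"],
      t_ref = prm["t_ref"], V_spike = prm["V_spike"], E_exc = prm["E_exc"],
      E_inh = prm["E_inh"], tau_exc = prm["tau_exc"], tau_inh = prm["tau_inh"];
  const int P = tau_m.size();
  std::vector<double> dec_exc(P), dec_inh(P);
  for (int p = 0; p < P; ++p) {
    dec_exc[p] = std::exp(-dt / tau_exc[p]);
    dec_inh[p] = std::exp(-dt / tau_inh[p]);
  }

  // working copies of the state
  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericVector W = clone(as<NumericVector>(state["W"]));
  NumericVector g_exc = clone(as<NumericVector>(state["g_exc"]));
  NumericVector g_inh = clone(as<NumericVector>(state["g_inh"]));
  NumericVector x_exc = clone(as<NumericVector>(state["x_exc"]));
  NumericVector x_inh = clone(as<NumericVector>(state["x_inh"]));
  NumericVector refr = clone(as<NumericVector>(state["refr"]));
  NumericVector tr_pre = clone(as<NumericVector>(state["tr_pre"]));
  NumericVector tr_post = clone(as<NumericVector>(state["tr_post"]));
  if (V.size() != N) stop("state vectors must have one entry per neuron");

  // plastic blocks
  std::vector<PlasticBlock> blk;
  for (int i = 0; i < plastic.size(); ++i) {
    List b = plastic[i];
    PlasticBlock pb;
    pb.s0 = as<int>(b["s0"]); pb.s1 = as<int>(b["s1"]);
    pb.t0 = as<int>(b["t0"]); pb.t1 = as<int>(b["t1"]);
    pb.lam = as<double>(b["lam"]); pb.alpha = as<double>(b["alpha"]);
    pb.wmax = as<double>(b["wmax"]); pb.active = as<bool>(b["active"]);
    blk.push_back(pb);
  }
  bool any_plastic = false;
  for (size_t i = 0; i < blk.size(); ++i) if (blk[i].active) any_plastic = true;
  const double dec_tr = std::exp(-dt / tau_stdp);

  // Poisson source groups
  const int nsrc = sources.size();
  std::vector<IntegerVector> src_tgt;
  std::vector<double> src_rate(nsrc), src_eff(nsrc), src_on(nsrc), src_off(nsrc);
  for (int i = 0; i < nsrc; ++i) {
    List s = sources[i];
    src_tgt.push_back(as<IntegerVector>(s["targets"]));
    src_rate[i] = as<double>(s["rate"]);
    src_eff[i] = as<double>(s["eff"]);
    src_on[i] = as<double>(s["t_start"]);
    src_off[i] = as<double>(s["t_stop"]);
    if (src_rate[i] < 0) stop("Poisson source rate must be non-negative");
  }

  // contiguous index range of each population (neurons are ordered by pop)
  std::vector<int> pop_start(P, N), pop_end(P, -1);
  for (int n = 0; n < N; ++n) {
    const int p = pop_of[n];
    if (n < pop_start[p]) pop_start[p] = n;
    if (n > pop_end[p]) pop_end[p] = n;
  }

  const long nsteps = (long)std::lround(duration / dt);
  // spike-transmission delay: recurrent increments land delay_ms after the
  // emitting spike, via a ring buffer of pending-increment slots.  External
  // Poisson events are delivered in the step they are drawn.
  const int n_delay = std::max(1, (int)std::lround(delay_ms / dt));
  std::vector< std::vector<double> > ring_exc(n_delay,
      std::vector<double>(N, 0.0));
  std::vector< std::vector<double> > ring_inh(n_delay,
      std::vector<double>(N, 0.0));
  std::vector<double> inc_exc(N, 0.0), inc_inh(N, 0.0);
  std::vector<int> spiked; spiked.reserve(256);
  std::vector<double> rec_t; std::vector<int> rec_id;
  const double e1 = std::exp(1.0);

  // weight snapshots (of every plastic block, active or not)
  int snap_ptr = 0;
  List snaps(snap_times.size());

  RNGScope rngscope;

  for (long step = 0; step < nsteps; ++step) {
    const double t = t0 + step * dt;

    // external Poisson drive -> increments (aggregated exact sampling:
    // total count over a group is Poisson(n*rate*dt), targets uniform)
    for (int i = 0; i < nsrc; ++i) {
      if (t < src_on[i] || t >= src_off[i]) continue;
      const IntegerVector &tg = src_tgt[i];
      const int nt = tg.size();
      const double mean = nt * src_rate[i] * dt * 1e-3;
      if (mean <= 0) continue;
      int k = (int)R::rpois(mean);
      const double eff = src_eff[i];
      for (int j = 0; j < k; ++j) {
        int n = tg[(int)(R::unif_rand() * nt) % nt];
        if (eff >= 0) inc_exc[n] += eff; else inc_inh[n] -= eff;
      }
    }

    // delayed recurrent increments due this step
    const int cur = (int)(step % n_delay);
    {
      std::vector<double> &re = ring_exc[cur], &ri = ring_inh[cur];
      for (int n = 0; n < N; ++n) {
        inc_exc[n] += re[n]; inc_inh[n] += ri[n];
        re[n] = 0.0; ri[n] = 0.0;
      }
    }

    // conductance + membrane update, one contiguous pass per population so
    // the per-population constants stay in registers.  Tiny values are
    // flushed to zero: exponential decay otherwise reaches the subnormal
    // range, where every multiply pays a large hardware penalty.  The
    // spike-initiation exponential is skipped when its argument is below
    // -10 (contribution < 1e-6 mV per step).
    spiked.clear();
    for (int p = 0; p < P; ++p) {
      const int n0 = pop_start[p], n1 = pop_end[p];
      const double dE = dec_exc[p], dI = dec_inh[p];
      const double kE = e1 * dt / tau_exc[p], kI = e1 * dt / tau_inh[p];
      const double c_tau_m = tau_m[p], c_El = E_l[p], c_th = theta[p],
                   c_dV = delta_V[p], c_C = Cm[p], c_a = a_sub[p],
                   c_tW = tau_W[p], c_Vr = V_reset[p], c_Vs = V_spike[p],
                   c_Ee = E_exc[p], c_Ei = E_inh[p];
      const double exp_cut = c_th - 10.0 * c_dV;
      for (int n = n0; n <= n1; ++n) {
        // rest-state fast path: with no conductance, no pending input, no
        // adaptation and V exactly at E_l (the periodic flush maps decayed
        // states onto this point), every derivative is exactly zero
        if (V[n] == c_El && W[n] == 0.0 && g_exc[n] == 0.0 &&
            g_inh[n] == 0.0 && inc_exc[n] == 0.0 && inc_inh[n] == 0.0 &&
            refr[n] <= 0 && (!alpha_kernel ||
                             (x_exc[n] == 0.0 && x_inh[n] == 0.0)))
          continue;
        double ge, gi;
        if (!alpha_kernel) {
          ge = g_exc[n] * dE + inc_exc[n];
          gi = g_inh[n] * dI + inc_inh[n];
        } else {
          // alpha kernel: auxiliary x jumps by Q on a spike; g follows
          // g' = (e*x - g)/tau, so a lone spike gives
          // g(t) = Q*e*(t/tau)*exp(-t/tau), peaking at Q after tau.
          // The (x, g) pair is propagated exactly over the step:
          // g <- (g + e*x*dt/tau)*exp(-dt/tau), x <- x*exp(-dt/tau).
          double xe = x_exc[n] + inc_exc[n], xi = x_inh[n] + inc_inh[n];
          ge = (g_exc[n] + kE * xe) * dE;
          gi = (g_inh[n] + kI * xi) * dI;
          x_exc[n] = xe * dE;
          x_inh[n] = xi * dI;
        }
        g_exc[n] = ge; g_inh[n] = gi;
        inc_exc[n] = 0.0; inc_inh[n] = 0.0;

        double v = V[n], w = W[n];
        if (refr[n] > 0) {
          refr[n] -= dt;
          V[n] = c_Vr;
          W[n] = w + dt * (c_a * (c_Vr - c_El) - w) / c_tW;
          continue;
        }
        const double Isyn = -(ge * (v - c_Ee) + gi * (v - c_Ei));   // pA
        double sp_term = 0.0;
        if (v > exp_cut) {
          const double veff = v > c_Vs ? c_Vs : v;
          sp_term = (c_dV / c_tau_m) * std::exp((veff - c_th) / c_dV);
        }
        const double dv = dt * (-(v - c_El) / c_tau_m + sp_term +
                                (Isyn - w) / c_C);
        const double dw = dt * (c_a * (v - c_El) - w) / c_tW;
        V[n] = v + dv; W[n] = w + dw;
        if (V[n] >= c_Vs) spiked.push_back(n);
      }
    }

    // periodic flush-to-zero: exponentially decaying quantities otherwise
    // reach the subnormal range, where every multiply pays a large
    // hardware penalty.  Values cannot decay from above 1e-12 into the
    // subnormal range within 256 steps, so a periodic pass suffices.
    if ((step & 255) == 255) {
      for (int n = 0; n < N; ++n) {
        if (g_exc[n] < 1e-12) g_exc[n] = 0.0;
        if (g_inh[n] < 1e-12) g_inh[n] = 0.0;
        if (x_exc[n] < 1e-12) x_exc[n] = 0.0;
        if (x_inh[n] < 1e-12) x_inh[n] = 0.0;
        if (std::fabs(W[n]) < 1e-12) W[n] = 0.0;
        const int p = pop_of[n];
        if (std::fabs(V[n] - E_l[p]) < 1e-12) V[n] = E_l[p];
      }
    }

    // STDP: weight updates use traces that exclude this step's spikes
    if (any_plastic && !spiked.empty()) {
      for (size_t si = 0; si < spiked.size(); ++si) {
        const int n = spiked[si];
        for (size_t bi = 0; bi < blk.size(); ++bi) {
          const PlasticBlock &pb = blk[bi];
          if (!pb.active) continue;
          if (n >= pb.s0 && n <= pb.s1) {           // n presynaptic: depress
            double *col = &Wt(0, n);
            const double al = pb.alpha * pb.lam;
            for (int tgt = pb.t0; tgt <= pb.t1; ++tgt) {
              double w = col[tgt];
              if (w <= 0) continue;
              w -= al * w * tr_post[tgt];
              col[tgt] = w > 0 ? w : 0.0;
            }
          }
          if (n >= pb.t0 && n <= pb.t1) {           // n postsynaptic: potentiate
            const double lam = pb.lam, wmax = pb.wmax;
            for (int s = pb.s0; s <= pb.s1; ++s) {
              if (s == n) continue;
              double w = Wt(n, s);
              w += lam * (wmax - w) * tr_pre[s];
              Wt(n, s) = w < wmax ? w : wmax;
            }
          }
        }
      }
    }

    // reset, record, propagate
    for (size_t si = 0; si < spiked.size(); ++si) {
      const int n = spiked[si];
      const int p = pop_of[n];
      V[n] = V_reset[p];
      W[n] += b_spk[p];
      refr[n] = t_ref[p];
      if (record_mask[n]) { rec_t.push_back(t); rec_id.push_back(n); }
      const double *col = &Wt(0, n);
      std::vector<double> &re = ring_exc[cur], &ri = ring_inh[cur];
      for (int tgt = 0; tgt < N; ++tgt) {
        const double w = col[tgt];
        if (w > 0) re[tgt] += w;
        else if (w < 0) ri[tgt] -= w;
      }
    }
    if (any_plastic) {
      const bool flush = (step & 255) == 255;
      for (int n = 0; n < N; ++n) {
        tr_pre[n] *= dec_tr; tr_post[n] *= dec_tr;
        if (flush) {
          if (tr_pre[n] < 1e-12) tr_pre[n] = 0.0;
          if (tr_post[n] < 1e-12) tr_post[n] = 0.0;
        }
      }
      for (size_t si = 0; si < spiked.size(); ++si) {
        tr_pre[spiked[si]] += 1.0;
        tr_post[spiked[si]] += 1.0;
      }
    }

    // snapshots at step end
    while (snap_ptr < snap_times.size() &&
           (step + 1) * dt >= snap_times[snap_ptr] - 1e-9) {
      List mats(blk.size());
      for (size_t bi = 0; bi < blk.size(); ++bi) {
        const PlasticBlock &pb = blk[bi];
        NumericMatrix m(pb.s1 - pb.s0 + 1, pb.t1 - pb.t0 + 1);
        for (int s = pb.s0; s <= pb.s1; ++s)
          for (int tg = pb.t0; tg <= pb.t1; ++tg)
            m(s - pb.s0, tg - pb.t0) = Wt(tg, s);
        mats[bi] = m;
      }
      snaps[snap_ptr] = List::create(_["time"] = t0 + (step + 1) * dt,
                                     _["mats"] = mats);
      ++snap_ptr;
    }

    // periodic sanity check
    if ((step & 1023) == 0) {
      for (int n = 0; n < N; ++n) {
        if (!std::isfinite(V[n]) || !std::isfinite(W[n]))
          stop("non-finite state in neuron %d at t = %.2f ms", n + 1, t);
      }
    }
  }

  List out_state = List::create(
      _["V"] = V, _["W"] = W, _["g_exc"] = g_exc, _["g_inh"] = g_inh,
      _["x_exc"] = x_exc, _["x_inh"] = x_inh, _["refr"] = refr,
      _["tr_pre"] = tr_pre, _["tr_post"] = tr_post);
  return List::create(
      _["state"] = out_state,
      _["spike_t"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["spike_id"] = IntegerVector(rec_id.begin(), rec_id.end()),
      _["snapshots"] = snaps,
      _["t_end"] = t0 + nsteps * dt,
      _["Wt"] = Wt);
}

// Trace-based multiplicative STDP on a single synapse, event-driven.
// Matches the engine's conventions: at a presynaptic event the synapse is
// depressed using the postsynaptic trace, at a postsynaptic event it is
// potentiated using the presynaptic trace; traces exclude the current event;
// at equal times presynaptic events are processed first.
// [[Rcpp::export]]
double stdp_trace_run(NumericVector pre, NumericVector post, double w0,
                      double lam, double alpha, double tau, double wmax) {
  double w = w0, trp = 0.0, trq = 0.0, tlast = R_NegInf;
  int i = 0, j = 0;
  const int np = pre.size(), nq = post.size();
  while (i < np || j < nq) {
    bool is_pre = (j >= nq) || (i < np && pre[i] <= post[j]);
    double t = is_pre ? pre[i] : post[j];
    if (std::isfinite(tlast)) {
      double d = std::exp(-(t - tlast) / tau);
      trp *= d; trq *= d;
    }
    // gather all events at exactly this time, pre first
    std::vector<bool> kinds;
    while (i < np && pre[i] == t) { kinds.push_back(true); ++i; }
    while (j < nq && post[j] == t) { kinds.push_back(false); ++j; }
    double add_p = 0, add_q = 0;
    for (size_t k = 0; k < kinds.size(); ++k) {
      if (kinds[k]) { w -= alpha * lam * w * trq; add_p += 1.0; }
      else { w += lam * (wmax - w) * trp; add_q += 1.0; }
      if (w < 0) w = 0; if (w > wmax) w = wmax;
    }
    trp += add_p; trq += add_q;
    tlast = t;
  }
  return w;
}
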
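#' Adaptive exponential integrate-and-fire neuron parameters
#'
#' Constructs the parameter set of a conductance-based AdEx neuron.  The
#' membrane potential `V` integrates a leak, an exponential spike-initiation
#' term, synaptic current and an adaptation current `W`:
#' \deqn{dV/dt = -(V-E_l)/\tau_m + (\Delta_V/\tau_m)\,e^{(V-\theta)/\Delta_V}
#'   + I_{syn}/C - W/C}
#' \deqn{\tau_W\,dW/dt = a\,(V-E_l) - W, \qquad W \to W + b \text{ at each spike}}
#' with synaptic current \eqn{I_{syn} = -\sum_\alpha g_\alpha (V - E_\alpha)}
#' over the excitatory and inhibitory receptors, whose conductances decay
#' exponentially with their own time constants and jump by the synaptic
#' efficacy on each presynaptic spike.  A spike is emitted when `V` reaches
#' `V_spike = theta + 5 * delta_V`, after which `V` is reset, `W` is
#' incremented by `b`, and the neuron is refractory for `t_ref`.
#'
#' Defaults are the NEST `aeif_cond_alpha` constants (C = 281 pF, g_L = 30 nS
#' hence tau_m = C/g_L, E_l = -70.6 mV, theta = -50.4 mV, delta_V = 2 mV,
#' a = 4 nS, tau_W = 144 ms, V_reset = -60 mV) except for the spike-triggered
#' adaptation increment `b`, which the protocol sets per phase (small during
#' wake, 60 pA during sleep).
#'
#' @param C membrane capacitance, pF.
#' @param tau_m membrane time constant, ms.
#' @param E_l leak reversal potential, mV.
#' @param theta exponential threshold, mV.
#' @param delta_V exponential slope factor, mV.
#' @param a subthreshold adaptation conductance, nS.
#' @param b spike-triggered adaptation increment, pA.
#' @param tau_W adaptation time constant, ms.
#' @param V_reset post-spike reset potential, mV.
#' @param t_ref absolute refractory period, ms.
#' @param E_exc,E_inh receptor reversal potentials, mV.
#' @param tau_exc,tau_inh receptor conductance decay time constants, ms.
#'
#' @return An object of class `adex_params`: a named list of the constants
#'   plus the derived emission threshold `V_spike = theta + 5 * delta_V`.
#' @export
#' @examples
#' p <- adex_params()
#' p$V_spike  # -40.4 mV with the default theta and delta_V
adex_params <- function(C = 281, tau_m = 281 / 30, E_l = -70.6,
                        theta = -50.4, delta_V = 2, a = 4, b = 5,
                        tau_W = 144, V_reset = -60, t_ref = 0,
                        E_exc = 0, E_inh = -85,
                        tau_exc = 0.2, tau_inh = 2) {
  stopifnot(tau_m > 0, delta_V > 0, tau_W > 0, tau_exc > 0, tau_inh > 0,
            C > 0, t_ref >= 0)
  if (!(E_inh < E_l && E_l < E_exc))
    stop("receptor reversals must satisfy E_inh < E_l < E_exc")
  p <- list(C = C, tau_m = tau_m, E_l = E_l, theta = theta,
            delta_V = delta_V, a = a, b = b, tau_W = tau_W,
            V_reset = V_reset, t_ref = t_ref,
            V_spike = theta + 5 * delta_V,
            E_exc = E_exc, E_inh = E_inh,
            tau_exc = tau_exc, tau_inh = tau_inh)
  class(p) <- "adex_params"
  p
}

#' @export
print.adex_params <- function(x, ...) {
  cat("<adex_params>\n")
  cat(sprintf("  C = %g pF, tau_m = %.4g ms, E_l = %g mV\n", x$C, x$tau_m, x$E_l))
  cat(sprintf("  theta = %g mV, delta_V = %g mV, V_spike = %g mV\n",
              x$theta, x$delta_V, x$V_spike))
  cat(sprintf("  a = %g nS, b = %g pA, tau_W = %g ms\n", x$a, x$b, x$tau_W))
  cat(sprintf("  V_reset = %g mV, t_ref = %g ms\n", x$V_reset, x$t_ref))
  cat(sprintf("  E_exc = %g mV (tau %g ms), E_inh = %g mV (tau %g ms)\n",
              x$E_exc, x$tau_exc, x$E_inh, x$tau_inh))
  invisible(x)
}

#' Fresh dynamical state for a population of AdEx neurons
#'
#' All neurons start at the leak reversal with zero adaptation, zero
#' conductance and cleared plasticity traces.
#'
#' @param n population size.
#' @param params an [adex_params()] object.
#' @return A named list of per-neuron state vectors (`V`, `W`, `g_exc`,
#'   `g_inh`, alpha-kernel auxiliaries `x_exc`/`x_inh`, `refr`, and the STDP
#'   traces `tr_pre`/`tr_post`).
#' @export
population_state <- function(n, params = adex_params()) {
  stopifnot(n >= 1)
  z <- numeric(n)
  list(V = rep(params$E_l, n), W = z, g_exc = z, g_inh = z,
       x_exc = z, x_inh = z, refr = z, tr_pre = z, tr_post = z)
}

#' One forward-Euler step of AdEx dynamics (reference implementation)
#'
#' A vectorised pure-R integrator over a homogeneous population, used as the
#' readable reference for the compiled engine and for single-neuron
#' convergence studies.  Conductances first decay and absorb the incoming
#' increments, then `V` and `W` advance by one Euler step; neurons whose `V`
#' reaches `V_spike` are reported in `$spiked` (reset is a separate
#' operation, [spike_and_reset()]).
#'
#' @param state a [population_state()] list.
#' @param params an [adex_params()] object.
#' @param inc_exc,inc_inh conductance increments (nS) delivered this step.
#' @param dt time step, ms.
#' @param I_ext optional injected current, pA (used in protocols that probe
#'   the neuron with a current step).
#' @return `list(state, spiked)` with `spiked` an integer vector of indices.
#' @export
adex_step <- function(state, params, inc_exc = 0, inc_inh = 0, dt = 0.1,
                      I_ext = 0) {
  stopifnot(dt > 0)
  p <- params
  g_exc <- state$g_exc * exp(-dt / p$tau_exc) + inc_exc
  g_inh <- state$g_inh * exp(-dt / p$tau_inh) + inc_inh
  V <- state$V; W <- state$W; refr <- state$refr
  if (any(!is.finite(V)) || any(!is.finite(W))) {
    bad <- which(!is.finite(V) | !is.finite(W))[1]
    stop(sprintf("non-finite state in neuron %d", bad))
  }
  in_ref <- refr > 0
  V[in_ref] <- p$V_reset
  Veff <- pmin(V, p$V_spike)                      # clip the exponential
  Isyn <- -(g_exc * (V - p$E_exc) + g_inh * (V - p$E_inh)) + I_ext
  dV <- dt * (-(V - p$E_l) / p$tau_m +
                (p$delta_V / p$tau_m) * exp((Veff - p$theta) / p$delta_V) +
                Isyn / p$C - W / p$C)
  dW <- dt * (p$a * (V - p$E_l) - W) / p$tau_W
  W <- W + dW
  V <- ifelse(in_ref, p$V_reset, V + dV)
  refr[in_ref] <- refr[in_ref] - dt
  spiked <- which(!in_ref & V >= p$V_spike)
  st <- state
  st$V <- V; st$W <- W; st$g_exc <- g_exc; st$g_inh <- g_inh; st$refr <- refr
  list(state = st, spiked = spiked)
}

#' Apply spike emission side effects
#'
#' For every emitted neuron the membrane potential is set to `V_reset`, the
#' adaptation current is incremented by `b`, and the refractory clock is
#' loaded with `t_ref`.
#'
#' @param state a [population_state()] list.
#' @param params an [adex_params()] object.
#' @param spiked integer indices of emitting neurons.
#' @return The updated state list.
#' @export
spike_and_reset <- function(state, params, spiked) {
  if (length(spiked) == 0) return(state)
  state$V[spiked] <- params$V_reset
  state$W[spiked] <- state$W[spiked] + params$b
  state$refr[spiked] <- params$t_ref
  state
}

#' Integrate a single AdEx neuron under a current step
#'
#' Convenience driver around [adex_step()]/[spike_and_reset()] for
#' convergence and calibration studies: a constant current `I_pA` is injected
#' during `[t_on, t_off)` and spike times are collected.
#'
#' @param params an [adex_params()] object.
#' @param duration total simulated time, ms.
#' @param dt Euler step, ms.
#' @param I_pA injected current amplitude, pA.
#' @param t_on,t_off current step window, ms.
#' @return Numeric vector of spike times (ms).
#' @export
simulate_adex_neuron <- function(params = adex_params(), duration = 200,
                                 dt = 0.1, I_pA = 800, t_on = 20,
                                 t_off = Inf) {
  p <- params
  n_steps <- round(duration / dt)
  spikes <- numeric(0)
  V <- p$E_l; W <- 0; refr <- 0
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    I <- if (t >= t_on && t < t_off) I_pA else 0
    if (refr > 0) {
      refr <- refr - dt
      V <- p$V_reset
      W <- W + dt * (p$a * (V - p$E_l) - W) / p$tau_W
      next
    }
    Veff <- min(V, p$V_spike)
    dV <- dt * (-(V - p$E_l) / p$tau_m +
                  (p$delta_V / p$tau_m) * exp((Veff - p$theta) / p$delta_V) +
                  (I - W) / p$C)
    W <- W + dt * (p$a * (V - p$E_l) - W) / p$tau_W
    V <- V + dV
    if (V >= p$V_spike) {
      spikes <- c(spikes, t)
      V <- p$V_reset
      W <- W + p$b
      refr <- p$t_ref
    }
  }
  spikes
}

#' Poisson conductance increments for one step (reference implementation)
#'
#' Samples, for each source, the number of events arriving in a step of
#' length `dt` as Poisson(rate * dt) and accumulates `k * |efficacy|` on the
#' receptor selected by the sign of the efficacy.  This mirrors the compiled
#' engine's drive semantics for testing.
#'
#' @param sources a tibble as built by [poisson_source()].
#' @param n_neurons number of neurons in the target index space.
#' @param t current time, ms.
#' @param dt step length, ms.
#' @return `list(inc_exc, inc_inh)` of length-`n_neurons` increment vectors.
#' @export
poisson_deliver <- function(sources, n_neurons, t, dt) {
  inc_exc <- numeric(n_neurons); inc_inh <- numeric(n_neurons)
  for (i in seq_len(nrow(sources))) {
    if (t < sources$t_start[i] || t >= sources$t_stop[i]) next
    tg <- sources$targets[[i]]
    k <- stats::rpois(length(tg), sources$rate[i] * dt * 1e-3)
    eff <- sources$eff[i]
    if (eff >= 0) {
      inc_exc[tg] <- inc_exc[tg] + k * eff
    } else {
      inc_inh[tg] <- inc_inh[tg] - k * eff
    }
  }
  list(inc_exc = inc_exc, inc_inh = inc_inh)
}

#' Describe a Poisson spike-train source
#'
#' @param targets integer vector of target neuron indices (interpretation --
#'   population-local or global -- is up to the caller).
#' @param rate event rate per target, Hz.
#' @param eff conductance increment per event, nS; a negative sign selects
#'   the inhibitory receptor.
#' @param t_start,t_stop active window, ms (`[t_start, t_stop)`).
#' @return A one-row tibble with a list-column of targets.
#' @export
poisson_source <- function(targets, rate, eff, t_start = 0, t_stop = Inf) {
  stopifnot(rate >= 0, t_stop >= t_start, length(targets) >= 1)
  tibble::tibble(targets = list(as.integer(targets)), rate = rate, eff = eff,
                 t_start = t_start, t_stop = t_stop)
}
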
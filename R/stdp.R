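#' Multiplicative STDP parameters
#'
#' Weight updates for a synapse with presynaptic spike time \eqn{t_j} and
#' postsynaptic spike time \eqn{t_i}:
#' \deqn{\Delta w = \lambda\,(w_{max} - w)\,e^{-|t_i - t_j|/\tau}
#'   \quad (pre\ before\ post,\ potentiation)}
#' \deqn{\Delta w = -\alpha\,\lambda\,w\,e^{-|t_i - t_j|/\tau}
#'   \quad (post\ before\ pre,\ depression)}
#' The multiplicative form soft-bounds weights to \eqn{[0, w_{max}]}:
#' potentiation vanishes at the ceiling and depression vanishes at zero.
#' The asymmetry `alpha` scales depression relative to potentiation; the
#' protocol uses `alpha = 1` (symmetric) during training and `alpha = 3`
#' (depression-dominated) during sleep.
#'
#' @param lam learning rate, dimensionless.
#' @param alpha depression/potentiation asymmetry, dimensionless.
#' @param tau pairing timescale, ms.
#' @param w_max weight ceiling, nS.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(lam = 0.01, alpha = 1, tau = 20, w_max = 150) {
  stopifnot(lam >= 0, tau > 0, alpha >= 0, w_max > 0)
  structure(list(lam = lam, alpha = alpha, tau = tau, w_max = w_max),
            class = "stdp_params")
}

#' All-pairs STDP oracle
#'
#' Replays two spike trains through the plasticity rule by brute force:
#' events are visited in time order and, at each event, every opposite-side
#' spike that happened earlier contributes its exponential kernel term.  All
#' pair terms completing at one event are summed and applied as a single
#' multiplicative update at that event's weight (the same convention as the
#' trace-based implementation, whose correctness this function checks
#' independently -- here the kernel sums are recomputed from the raw spike
#' times at every event rather than carried recursively).
#'
#' Pairs with exactly equal spike times contribute nothing, and at equal
#' times presynaptic events are processed before postsynaptic ones.
#'
#' @param pre,post sorted spike time vectors, ms.
#' @param w0 initial weight, nS.
#' @param params an [stdp_params()] object.
#' @return Final weight after both trains, nS.
#' @export
stdp_allpairs <- function(pre, post, w0, params) {
  stopifnot(!is.unsorted(pre), !is.unsorted(post))
  p <- params
  ev_t <- c(pre, post)
  ev_pre <- rep(c(TRUE, FALSE), c(length(pre), length(post)))
  o <- order(ev_t, !ev_pre)     # time order, pre first on ties
  ev_t <- ev_t[o]; ev_pre <- ev_pre[o]
  w <- w0
  for (k in seq_along(ev_t)) {
    t <- ev_t[k]
    if (ev_pre[k]) {
      earlier <- post[post < t]
      s <- sum(exp(-(t - earlier) / p$tau))
      w <- w - p$alpha * p$lam * w * s
    } else {
      earlier <- pre[pre < t]
      s <- sum(exp(-(t - earlier) / p$tau))
      w <- w + p$lam * (p$w_max - w) * s
    }
    w <- min(max(w, 0), p$w_max)
  }
  w
}

#' Trace-based STDP on a single synapse
#'
#' Event-driven realisation of the all-to-all pairing rule via a pair of
#' exponentially decaying traces, identical in semantics to the plasticity
#' kernel inside the compiled network engine.  See [stdp_allpairs()] for the
#' rule and the simultaneity conventions.
#'
#' @inheritParams stdp_allpairs
#' @return Final weight after both trains, nS.
#' @export
stdp_trace <- function(pre, post, w0, params) {
  stopifnot(!is.unsorted(pre), !is.unsorted(post))
  stdp_trace_run(as.numeric(pre), as.numeric(post), w0,
                 params$lam, params$alpha, params$tau, params$w_max)
}

#' Apply one step of STDP to a weight matrix (reference implementation)
#'
#' Given the sets of source and target neurons that spiked in the current
#' step and the trace values accumulated from earlier steps, updates a dense
#' source-by-target weight matrix under the multiplicative rule.  This is
#' the readable mirror of the engine's per-step plasticity pass, exposed for
#' testing and for custom analyses.
#'
#' @param W dense weight matrix, sources in rows, targets in columns, nS.
#' @param pre_spiked,post_spiked integer row/column indices spiking now.
#' @param tr_pre per-source presynaptic trace values (excluding this step's
#'   spikes).
#' @param tr_post per-target postsynaptic trace values (likewise).
#' @param params an [stdp_params()] object.
#' @param plastic logical; set `FALSE` to flag a frozen projection, in which
#'   case calling this function is a contract violation and errors.
#' @return The updated weight matrix, clipped to `[0, w_max]`.
#' @export
stdp_apply <- function(W, pre_spiked, post_spiked, tr_pre, tr_post, params,
                       plastic = TRUE) {
  if (!plastic) stop("stdp_apply() called on a non-plastic projection")
  p <- params
  for (s in pre_spiked) {                       # depression of outgoing
    W[s, ] <- pmax(W[s, ] - p$alpha * p$lam * W[s, ] * tr_post, 0)
  }
  for (tg in post_spiked) {                     # potentiation of incoming
    W[, tg] <- pmin(W[, tg] + p$lam * (p$w_max - W[, tg]) * tr_pre, p$w_max)
  }
  W
}
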
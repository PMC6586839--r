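POPS <- c("cx", "in", "tc", "re")

#' Build the four-population thalamo-cortical network
#'
#' Constructs excitatory cortex (`cx`), inhibitory cortex (`in`), thalamic
#' relay (`tc`) and reticular (`re`) populations with all-to-all projections
#' (no self-connections) at the model's fixed weights, plus the three
#' plastic projections `cx->cx`, `cx->tc` and `tc->cx` initialised at their
#' untrained values.  Each training image is assigned a disjoint group of 20
#' consecutive `cx` neurons, so `N_cx = 20 * n_images`; the inhibitory and
#' thalamic population sizes are fixed (200, 324, 200).
#'
#' @param n_images number of training images (>= 1).
#' @param classes integer class label per image (defaults to one class).
#' @param config a [somnet_config()] list of model constants.
#' @return An object of class `somnet_network` carrying the weight matrix,
#'   per-population neuron parameters, the image-to-group map, the dynamical
#'   state and an empty log of phase results.
#' @export
#' @examples
#' net <- build_network(9, classes = rep(1:3, each = 3))
#' net$pops
build_network <- function(n_images, classes = rep(1L, n_images),
                          config = somnet_config()) {
  if (n_images < 1) stop("n_images must be at least 1")
  if (length(classes) != n_images)
    stop("classes must have one label per image")
  cf <- config
  gs <- cf$group_size
  sizes <- c(cx = gs * n_images, "in" = cf$n_in, tc = cf$n_tc, re = cf$n_re)
  offs <- c(0, cumsum(sizes))[1:4]
  names(offs) <- POPS
  N <- sum(sizes)
  pops <- tibble::tibble(pop = POPS, size = unname(sizes),
                         offset = unname(offs))
  pop_of <- rep(0:3, times = sizes)            # 0-based population index

  W <- matrix(0, N, N)
  idx <- lapply(POPS, function(p) (offs[[p]] + 1):(offs[[p]] + sizes[[p]]))
  names(idx) <- POPS
  fill <- function(W, s, t, w, no_self = FALSE) {
    W[idx[[s]], idx[[t]]] <- w
    if (no_self) {
      d <- idx[[s]]
      W[cbind(d, d)] <- 0
    }
    W
  }
  W <- fill(W, "in", "cx", cf$w_in_cx)
  W <- fill(W, "cx", "in", cf$w_cx_in)
  W <- fill(W, "tc", "re", cf$w_tc_re)
  W <- fill(W, "re", "tc", cf$w_re_tc)
  W <- fill(W, "in", "in", cf$w_in_in, no_self = TRUE)
  W <- fill(W, "re", "re", cf$w_re_re, no_self = TRUE)
  W <- fill(W, "cx", "cx", cf$w0_cx_cx, no_self = TRUE)
  W <- fill(W, "cx", "tc", cf$w0_cx_tc)
  W <- fill(W, "tc", "cx", cf$w0_tc_cx)

  groups <- tibble::tibble(
    image = seq_len(n_images),
    class = as.integer(classes),
    neurons = lapply(seq_len(n_images),
                     function(k) ((k - 1) * gs + 1):(k * gs)))

  plastic <- tibble::tibble(
    name = c("cx_cx", "cx_tc", "tc_cx"),
    s_pop = c("cx", "cx", "tc"),
    t_pop = c("cx", "tc", "cx"),
    wmax = c(cf$wmax_cx_cx, cf$wmax_cx_tc, cf$wmax_tc_cx),
    alpha = cf$alpha_train,
    active = FALSE)

  b_of <- c(cx = cf$b_wake, "in" = cf$b_in, tc = cf$b_tc, re = cf$b_re)
  params <- lapply(POPS, function(p)
    adex_params(b = b_of[[p]], t_ref = cf$t_ref))
  names(params) <- POPS

  net <- list(config = cf, pops = pops, N = N, pop_of = pop_of, idx = idx,
              W = W, groups = groups, n_images = n_images,
              plastic = plastic, params = params,
              phase = "built", feedback_on = TRUE, feedback_snapshot = NULL,
              state = init_state(N, params$cx$E_l), t = 0,
              log = list(), snapshots = list())
  class(net) <- "somnet_network"
  net
}

init_state <- function(N, E_l = -70.6) {
  z <- numeric(N)
  list(V = rep(E_l, N), W = z, g_exc = z, g_inh = z,
       x_exc = z, x_inh = z, refr = z, tr_pre = z, tr_post = z)
}

#' @export
print.somnet_network <- function(x, ...) {
  cat("<somnet_network> ", x$N, " neurons (",
      paste(sprintf("%s=%d", x$pops$pop, x$pops$size), collapse = ", "),
      ")\n", sep = "")
  cat("  images:", x$n_images, " classes:",
      length(unique(x$groups$class)), "\n")
  cat("  phase:", x$phase, " t =", sprintf("%.1f", x$t / 1000), "s\n")
  cat("  thalamic feedback:", if (x$feedback_on) "on" else "off", "\n")
  if (length(x$log))
    cat("  logged phases:", paste(names(x$log), collapse = ", "), "\n")
  invisible(x)
}

#' Install the parameter schedule of a protocol phase
#'
#' Phase overrides, relative to the constants in the network's config:
#' * `training`: wake adaptation `b` everywhere, `w_in->cx` at its full
#'   value, symmetric STDP (`alpha_train`) active on all three plastic
#'   projections;
#' * `retrieval` / `classification`: as training but with all plasticity
#'   frozen, so measurement does not perturb the weights;
#' * `sleep`: spike-frequency adaptation raised to `b_sleep` on `cx`,
#'   `w_in->cx` reduced to its sleep value, depression-dominated STDP
#'   (`alpha_sleep`) active on the recurrent `cx->cx` projection only;
#' * `awake_control`: sleep's plasticity schedule but with the wake `b` and
#'   `w_in->cx`, for the asynchronous-activity control condition.
#'
#' Re-applying a phase restores its constants exactly.
#'
#' @param net a [build_network()] object.
#' @param phase one of `"training"`, `"retrieval"`, `"sleep"`,
#'   `"awake_control"`, `"classification"`.
#' @return The network with the schedule installed.
#' @export
apply_phase <- function(net, phase) {
  phases <- c("training", "retrieval", "sleep", "awake_control",
              "classification")
  if (!phase %in% phases)
    stop("unknown phase: ", phase, " (expected one of ",
         paste(phases, collapse = ", "), ")")
  cf <- net$config
  b_cx <- if (phase == "sleep") cf$b_sleep else cf$b_wake
  net$params$cx$b <- b_cx
  w_ic <- if (phase == "sleep") cf$w_in_cx_sleep else cf$w_in_cx
  net$W[net$idx$`in`, net$idx$cx] <- w_ic
  if (phase == "training") {
    net$plastic$active <- c(TRUE, TRUE, TRUE)
    net$plastic$alpha <- cf$alpha_train
  } else if (phase %in% c("sleep", "awake_control")) {
    net$plastic$active <- c(TRUE, FALSE, FALSE)
    net$plastic$alpha <- c(cf$alpha_sleep, cf$alpha_train, cf$alpha_train)
  } else {
    net$plastic$active <- c(FALSE, FALSE, FALSE)
  }
  net$phase <- phase
  net
}

#' Switch the cortico-thalamic feedback projection on or off
#'
#' Disabling zeroes every `cx->tc` efficacy, freezes that projection's
#' plasticity and holds both for subsequent phases (the ablation used to
#' probe the role of top-down predictions during sleep); re-enabling
#' restores the exact weights from the snapshot taken when it was disabled.
#'
#' @param net a [build_network()] object.
#' @param enabled logical.
#' @return The updated network.
#' @export
set_thalamic_feedback <- function(net, enabled) {
  if (enabled && !net$feedback_on) {
    net$W[net$idx$cx, net$idx$tc] <- net$feedback_snapshot
    net$feedback_snapshot <- NULL
    net$feedback_on <- TRUE
  } else if (!enabled && net$feedback_on) {
    net$feedback_snapshot <- net$W[net$idx$cx, net$idx$tc]
    net$W[net$idx$cx, net$idx$tc] <- 0
    net$feedback_on <- FALSE
  }
  net
}

#' Extract a projection's weight block
#'
#' @param net a [build_network()] object.
#' @param projection string `"src_tgt"` over the population names, e.g.
#'   `"cx_cx"`, `"tc_cx"`, `"in_cx"`.
#' @return Dense numeric matrix, sources in rows, targets in columns, nS.
#' @export
get_weights <- function(net, projection) {
  parts <- strsplit(projection, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% POPS))
    stop("projection must be of the form 'src_tgt' over cx/in/tc/re")
  net$W[net$idx[[parts[1]]], net$idx[[parts[2]]], drop = FALSE]
}

global_targets <- function(net, pop, local) {
  net$pops$offset[net$pops$pop == pop] + as.integer(local)
}

# engine plastic-block descriptors (0-based inclusive global ranges).
# The offline phases use their own (slower) learning rate: one-shot training
# needs fast learning, while sleep association must accumulate gradually over
# many slow-oscillation cycles.
engine_blocks <- function(net) {
  lam <- if (net$phase %in% c("sleep", "awake_control"))
    net$config$stdp_lam_sleep else net$config$stdp_lam
  if (is.null(lam)) lam <- net$config$stdp_lam
  lapply(seq_len(nrow(net$plastic)), function(i) {
    row <- net$plastic[i, ]
    s <- net$idx[[row$s_pop]]; tg <- net$idx[[row$t_pop]]
    active <- row$active
    if (row$name == "cx_tc" && !net$feedback_on) active <- FALSE
    list(s0 = min(s) - 1L, s1 = max(s) - 1L,
         t0 = min(tg) - 1L, t1 = max(tg) - 1L,
         lam = lam, alpha = row$alpha,
         wmax = row$wmax, active = active)
  })
}

# advance the network by `duration` ms under the given Poisson sources;
# sources use *global* 1-based targets.  Returns list(net, raster, snapshots).
run_engine <- function(net, duration, sources = NULL,
                       snap_times = numeric(0), record = NULL) {
  cf <- net$config
  if (is.null(record)) record <- cf$record
  rec_mask <- net$pop_of %in% (match(record, POPS) - 1L)
  prm <- engine_params(net)
  src <- engine_sources(sources)
  res <- engine_run(net$state, prm, t(net$W), engine_blocks(net), src,
                    net$t, duration, cf$dt, cf$stdp_tau,
                    as.integer(net$pop_of), rec_mask,
                    as.numeric(snap_times), identical(cf$kernel, "alpha"),
                    cf$delay_ms)
  net$W <- t(res$Wt)
  net$state <- res$state
  net$t <- res$t_end
  pop_names <- POPS[net$pop_of + 1L]
  raster <- tibble::tibble(time_ms = res$spike_t,
                           neuron = res$spike_id + 1L,
                           pop = pop_names[res$spike_id + 1L])
  snaps <- lapply(res$snapshots, function(s) {
    if (is.null(s)) return(NULL)
    mats <- s$mats
    names(mats) <- net$plastic$name
    list(time = s$time, weights = mats)
  })
  snaps <- snaps[!vapply(snaps, is.null, logical(1))]
  list(net = net, raster = raster, snapshots = snaps)
}

engine_params <- function(net) {
  fields <- c("tau_m", "E_l", "theta", "delta_V", "C", "a", "b", "tau_W",
              "V_reset", "t_ref", "V_spike", "E_exc", "E_inh",
              "tau_exc", "tau_inh")
  out <- lapply(fields, function(f)
    vapply(net$params, function(p) p[[f]], numeric(1)))
  names(out) <- fields
  out
}

engine_sources <- function(sources) {
  if (is.null(sources) || nrow(sources) == 0) return(list())
  lapply(seq_len(nrow(sources)), function(i)
    list(targets = as.integer(sources$targets[[i]]) - 1L,
         rate = sources$rate[i], eff = sources$eff[i],
         t_start = sources$t_start[i], t_stop = sources$t_stop[i]))
}
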
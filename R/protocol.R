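#' Train the network on a sequence of feature vectors
#'
#' Images are presented once, sequentially.  During the presentation of
#' image `k` three drives are active: the 30 kHz Poisson feature drive on
#' the thalamic relay cells whose feature bit is 1, the 2 kHz contextual
#' facilitation on image `k`'s group of 20 cortical neurons, and a 10 kHz
#' Poisson train on the inhibitory cortical population that prevents
#' already-trained groups from responding to new stimuli.  Symmetric STDP is
#' active on `cx->cx`, `cx->tc` and `tc->cx`, so coincident firing of the
#' contextually selected group and the active relay cells carves the
#' intra-cortical block structure and the bottom-up/top-down projections.
#'
#' @param net a [build_network()] network.
#' @param features list of 324-length one-hot-blocked feature vectors, at
#'   most one per group.
#' @param label name under which the phase raster is logged.
#' @return The trained network; the raster and presentation windows are in
#'   `net$log[[label]]`.
#' @export
run_training <- function(net, features, label = "training") {
  cf <- net$config
  if (length(features) > net$n_images)
    stop("more images (", length(features), ") than trained groups (",
         net$n_images, ")")
  lapply(features, validate_feature_vector)
  net <- apply_phase(net, "training")
  slot <- cf$present_ms + cf$gap_ms
  t0 <- net$t
  src <- NULL
  windows <- tibble::tibble(item = seq_along(features),
                            t_start = t0 + (seq_along(features) - 1) * slot,
                            t_stop = t0 + (seq_along(features) - 1) * slot +
                              cf$present_ms)
  for (k in seq_along(features)) {
    a <- windows$t_start[k]; b <- windows$t_stop[k]
    if (b <= a) next
    drv <- features_to_drive(features[[k]], cf$rate_feat, cf$eff_feat, a, b)
    if (nrow(drv) > 0)
      drv$targets[[1]] <- global_targets(net, "tc", drv$targets[[1]])
    ctx <- poisson_source(net$groups$neurons[[k]], cf$rate_ctx, cf$eff_ctx,
                          a, b)
    inh <- poisson_source(net$idx$`in`, cf$rate_in_drive, cf$eff_in_drive,
                          a, b)
    src <- dplyr::bind_rows(src, drv, ctx, inh)
  }
  res <- run_engine(net, length(features) * slot, src)
  net <- res$net
  net$log[[label]] <- list(raster = res$raster, windows = windows)
  net
}

#' Present features for retrieval and measure group responses
#'
#' Only the thalamic feature drive is active (no contextual signal) and all
#' plasticity is frozen.  For every presented item the mean firing rate of
#' each trained group over the presentation window is computed; successful
#' retrieval means the highest-rate group is the one selected during
#' training.
#'
#' @param net a trained network.
#' @param features list of feature vectors to present.
#' @param label log slot name (use distinct labels for pre- and post-sleep
#'   retrieval).
#' @return The network; `net$log[[label]]$rates` holds a tibble with one row
#'   per (item, group): columns `item`, `image`, `class`, `rate_hz`.
#' @export
run_retrieval <- function(net, features, label = "retrieval") {
  cf <- net$config
  lapply(features, validate_input_vector)
  net <- apply_phase(net, "retrieval")
  res <- present_items(net, features)
  net <- res$net
  rates <- window_group_rates(res$raster, res$windows, net$groups)
  net$log[[label]] <- list(raster = res$raster, windows = res$windows,
                           rates = rates)
  net
}

# shared presentation driver for retrieval/classification phases
present_items <- function(net, features) {
  cf <- net$config
  slot <- cf$retrieve_ms + cf$retrieve_gap_ms
  t0 <- net$t
  windows <- tibble::tibble(item = seq_along(features),
                            t_start = t0 + (seq_along(features) - 1) * slot,
                            t_stop = t0 + (seq_along(features) - 1) * slot +
                              cf$retrieve_ms)
  src <- NULL
  for (k in seq_along(features)) {
    drv <- features_to_drive(features[[k]], cf$rate_feat, cf$eff_feat,
                             windows$t_start[k], windows$t_stop[k])
    if (nrow(drv) > 0) {
      drv$targets[[1]] <- global_targets(net, "tc", drv$targets[[1]])
      src <- dplyr::bind_rows(src, drv)
    }
  }
  res <- run_engine(net, length(features) * slot, src)
  list(net = res$net, raster = res$raster, windows = windows)
}

# mean rate of each trained group in each presentation window, Hz
window_group_rates <- function(raster, windows, groups) {
  cx <- dplyr::filter(raster, .data$pop == "cx")
  out <- list()
  for (k in seq_len(nrow(windows))) {
    a <- windows$t_start[k]; b <- windows$t_stop[k]
    sp <- cx$neuron[cx$time_ms >= a & cx$time_ms < b]
    n_by_group <- vapply(groups$neurons, function(g) sum(sp %in% g),
                         numeric(1))
    out[[k]] <- tibble::tibble(item = windows$item[k],
                               image = groups$image,
                               class = groups$class,
                               rate_hz = n_by_group /
                                 lengths(groups$neurons) / ((b - a) / 1000))
  }
  dplyr::bind_rows(out)
}

#' Run the deep-sleep-like slow-oscillation phase
#'
#' The thalamic image drive is off; a non-specific 700 Hz Poisson noise
#' drives the cortical excitatory population; spike-frequency adaptation is
#' raised (`b_sleep`) and cortical inhibition weakened (`w_in_cx_sleep`),
#' which puts the network in the Up/Down slow-oscillation regime.
#' Depression-dominated STDP (`alpha_sleep`) is active on the recurrent
#' `cx->cx` projection only.  Weights are snapshotted before sleep and at
#' every epoch boundary.
#'
#' @param net a trained network.
#' @param duration_s sleep duration in seconds (default `config$sleep_s`).
#' @param epoch_s epoch length in seconds between weight snapshots.
#' @param label log slot name.
#' @return The network; `net$log[[label]]` holds the raster and the list of
#'   epoch snapshots (`pre` plus one per epoch boundary).
#' @export
run_sleep <- function(net, duration_s = NULL, epoch_s = NULL,
                      label = "sleep") {
  run_offline_phase(net, "sleep", duration_s, epoch_s, label)
}

#' Run the awake-control condition
#'
#' Identical to [run_sleep()] (same noise, same duration, same plasticity
#' schedule) except that the wake adaptation strength `b` and the full
#' `w_in->cx` inhibition are kept, so the network expresses asynchronous
#' activity instead of slow oscillations.  Used to show that the synaptic
#' reorganisation requires the slow-oscillation regime, not merely elapsed
#' plastic time.
#'
#' @inheritParams run_sleep
#' @return The network, with the control raster and snapshots logged.
#' @export
run_awake_control <- function(net, duration_s = NULL, epoch_s = NULL,
                              label = "awake") {
  run_offline_phase(net, "awake_control", duration_s, epoch_s, label)
}

run_offline_phase <- function(net, phase, duration_s, epoch_s, label) {
  cf <- net$config
  if (!any(vapply(net$log, function(l) !is.null(l$windows), logical(1))))
    stop(phase, " before training is not a valid protocol order")
  if (is.null(duration_s)) duration_s <- cf$sleep_s
  if (is.null(epoch_s)) epoch_s <- cf$epoch_s
  stopifnot(duration_s > 0, epoch_s > 0)
  net <- apply_phase(net, phase)
  dur <- duration_s * 1000
  noise <- poisson_source(net$idx$cx, cf$rate_noise, cf$eff_noise,
                          net$t, net$t + dur)
  snap_rel <- seq_len(floor(dur / (epoch_s * 1000))) * epoch_s * 1000
  if (length(snap_rel) == 0 || max(snap_rel) < dur)
    snap_rel <- c(snap_rel, dur)
  pre <- list(time = net$t,
              weights = list(cx_cx = get_weights(net, "cx_cx"),
                             cx_tc = get_weights(net, "cx_tc"),
                             tc_cx = get_weights(net, "tc_cx")))
  res <- run_engine(net, dur, noise, snap_times = snap_rel)
  net <- res$net
  net$log[[label]] <- list(raster = res$raster,
                           t_start = pre$time, t_stop = net$t,
                           epoch_s = epoch_s,
                           snapshots = c(list(pre), res$snapshots))
  net
}

#' Classify one feature vector with the trained network
#'
#' Presents the item with plasticity frozen and returns the class of the
#' single cortical neuron with the highest spike count during the
#' presentation window (ties broken deterministically by the lowest neuron
#' index).  If no cortical neuron fires the classifier abstains and returns
#' `NA`.
#'
#' @param net a trained network.
#' @param feature a 324-length feature vector.
#' @return `list(class, neuron, n_spikes)`; `class` is `NA` on abstention.
#' @export
classify_image <- function(net, feature) {
  net <- classify_images(net, list(feature), label = ".classify_tmp")
  pred <- net$log$.classify_tmp$predictions
  list(class = pred$pred_class[1], neuron = pred$winner[1],
       n_spikes = pred$n_spikes[1])
}

#' Classify a set of feature vectors
#'
#' @param net a trained network.
#' @param features list of feature vectors.
#' @param truths optional integer vector of true class labels.
#' @param label log slot name.
#' @return The network; `net$log[[label]]$predictions` is a tibble with
#'   columns `item`, `winner` (neuron index or `NA`), `n_spikes`,
#'   `pred_class` and `truth`.
#' @export
classify_images <- function(net, features, truths = NULL,
                            label = "classify") {
  lapply(features, validate_input_vector)
  net <- apply_phase(net, "classification")
  res <- present_items(net, features)
  net <- res$net
  class_of_neuron <- neuron_class_map(net)
  cx <- dplyr::filter(res$raster, .data$pop == "cx")
  preds <- list()
  for (k in seq_len(nrow(res$windows))) {
    a <- res$windows$t_start[k]; b <- res$windows$t_stop[k]
    sp <- cx$neuron[cx$time_ms >= a & cx$time_ms < b]
    if (length(sp) == 0) {
      preds[[k]] <- tibble::tibble(item = k, winner = NA_integer_,
                                   n_spikes = 0L, pred_class = NA_integer_)
      next
    }
    counts <- tabulate(sp, nbins = length(class_of_neuron))
    winner <- which.max(counts)       # ties: lowest index wins
    if (is.na(class_of_neuron[winner]))
      stop("classification winner is an unlabeled neuron: ", winner)
    preds[[k]] <- tibble::tibble(item = k, winner = as.integer(winner),
                                 n_spikes = counts[winner],
                                 pred_class = class_of_neuron[winner])
  }
  preds <- dplyr::bind_rows(preds)
  preds$truth <- if (is.null(truths)) NA_integer_ else as.integer(truths)
  net$log[[label]] <- list(raster = res$raster, windows = res$windows,
                           predictions = preds)
  net
}

# class label of every cx neuron (by its training group)
neuron_class_map <- function(net) {
  n_cx <- net$pops$size[net$pops$pop == "cx"]
  map <- rep(NA_integer_, n_cx)
  for (k in seq_len(nrow(net$groups)))
    map[net$groups$neurons[[k]]] <- net$groups$class[k]
  map
}

#' Run the full four-phase protocol
#'
#' Generates a class-structured synthetic feature set, builds and trains the
#' network, measures pre-sleep retrieval and held-out classification, runs
#' the sleep phase (or the awake control, or with cortico-thalamic feedback
#' ablated), then repeats the retrieval and classification measurements.
#' All randomness derives from `config$seed`.
#'
#' @param config a [somnet_config()].
#' @return An object of class `somnet_report` with elements `net` (final
#'   network including all phase logs), `set` (the synthetic data), `config`
#'   and `seed`.  Use [tidy()]/[glance()] or the analysis functions on it.
#' @export
#' @examples
#' \donttest{
#' rep <- run_full_protocol(somnet_config(sleep_s = 20, n_holdout = 2))
#' glance(rep)
#' }
run_full_protocol <- function(config = somnet_config()) {
  cf <- config
  set.seed(cf$seed)
  spec <- synth_spec(cf$n_classes, cf$n_instances, cf$within, cf$cross)
  set <- make_synth_set(spec, n_holdout = cf$n_holdout,
                        holdout_within = cf$holdout_within)
  net <- build_network(length(set$features), set$labels, cf)
  net <- run_training(net, set$features)
  net <- run_retrieval(net, set$features, label = "retrieval_pre")
  if (cf$n_holdout > 0)
    net <- classify_images(net, set$holdout, set$holdout_labels,
                           label = "classify_pre")
  if (!cf$thalamic_feedback) net <- set_thalamic_feedback(net, FALSE)
  net <- if (cf$awake_control) run_awake_control(net) else run_sleep(net)
  net <- run_retrieval(net, set$features, label = "retrieval_post")
  if (cf$n_holdout > 0)
    net <- classify_images(net, set$holdout, set$holdout_labels,
                           label = "classify_post")
  out <- list(net = net, set = set, config = cf, seed = cf$seed)
  class(out) <- "somnet_report"
  out
}

#' @export
print.somnet_report <- function(x, ...) {
  cat("<somnet_report> seed", x$seed, "\n")
  print(x$net)
  invisible(x)
}
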
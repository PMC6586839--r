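#' Segment Up states from a population raster
#'
#' The population spike-count histogram (bin width `bin_ms`) is smoothed
#' with a Gaussian kernel (`smooth_ms` standard deviation) and thresholded
#' at a fraction of its peak; above-threshold runs closer than `merge_ms`
#' are merged.  Returns the onset/offset of every detected Up state.
#'
#' @param raster a raster tibble (`time_ms`, `neuron`, `pop`).
#' @param pop population to analyse (default `"cx"`).
#' @param t_start,t_stop analysis window, ms (default: raster extent).
#' @param bin_ms histogram bin width, ms.
#' @param smooth_ms Gaussian smoothing SD, ms.
#' @param threshold_frac threshold as a fraction of the smoothed peak rate.
#' @param merge_ms maximum silent gap that still joins two runs, ms.
#' @return A tibble with columns `onset_ms`, `offset_ms`, `duration_ms`
#'   (zero rows for an empty or degenerate window), with the detection
#'   parameters attached as attributes.
#' @export
detect_up_states <- function(raster, pop = "cx", t_start = NULL,
                             t_stop = NULL, bin_ms = 10, smooth_ms = 50,
                             threshold_frac = 0.2, merge_ms = 150) {
  empty <- tibble::tibble(onset_ms = numeric(0), offset_ms = numeric(0),
                          duration_ms = numeric(0))
  sp <- raster$time_ms[raster$pop == pop]
  if (is.null(t_start)) t_start <- if (length(sp)) min(sp) else 0
  if (is.null(t_stop)) t_stop <- if (length(sp)) max(sp) + bin_ms else 0
  if (t_stop <= t_start || length(sp) == 0) return(empty)
  sp <- sp[sp >= t_start & sp < t_stop]
  if (length(sp) == 0) return(empty)
  edges <- seq(t_start, t_stop + bin_ms, by = bin_ms)
  counts <- graphics::hist(sp, breaks = edges, plot = FALSE)$counts
  sm <- gauss_smooth(counts, smooth_ms / bin_ms)
  thr <- threshold_frac * max(sm)
  above <- sm > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  # merge across short gaps
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      gap <- (iv[k, 1] - last[2] - 1) * bin_ms
      if (gap < merge_ms) {
        merged[[length(merged)]] <- c(last[1], iv[k, 2])
      } else {
        merged[[length(merged) + 1]] <- iv[k, ]
      }
    }
  }
  on <- t_start + (vapply(merged, `[`, numeric(1), 1) - 1) * bin_ms
  off <- t_start + vapply(merged, `[`, numeric(1), 2) * bin_ms
  out <- tibble::tibble(onset_ms = on, offset_ms = off,
                        duration_ms = off - on)
  attr(out, "params") <- list(bin_ms = bin_ms, smooth_ms = smooth_ms,
                              threshold_frac = threshold_frac,
                              merge_ms = merge_ms,
                              t_start = t_start, t_stop = t_stop)
  out
}

gauss_smooth <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma_bins))
  k <- dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Slow-oscillation frequency from an Up-state segmentation
#'
#' @param seg a segmentation from [detect_up_states()].
#' @param window_s length of the analysed window, seconds.
#' @return Up-state onsets per second, Hz.
#' @export
so_frequency <- function(seg, window_s) {
  stopifnot(window_s > 0)
  nrow(seg) / window_s
}

#' Per-epoch slow-oscillation frequency of an offline phase
#'
#' Splits the logged sleep (or awake-control) raster into its epochs and
#' reports the Up-state onset rate in each.
#'
#' @param log the offline-phase log (`net$log$sleep` or `net$log$awake`).
#' @param ... passed to [detect_up_states()].
#' @return Tibble with columns `epoch`, `t_start`, `t_stop`, `so_hz`,
#'   `median_up_ms`.
#' @export
so_by_epoch <- function(log, ...) {
  ep <- log$epoch_s * 1000
  bounds <- seq(log$t_start, log$t_stop, by = ep)
  if (max(bounds) < log$t_stop) bounds <- c(bounds, log$t_stop)
  out <- list()
  for (k in seq_len(length(bounds) - 1)) {
    seg <- detect_up_states(log$raster, t_start = bounds[k],
                            t_stop = bounds[k + 1], ...)
    out[[k]] <- tibble::tibble(
      epoch = k, t_start = bounds[k], t_stop = bounds[k + 1],
      so_hz = so_frequency(seg, (bounds[k + 1] - bounds[k]) / 1000),
      median_up_ms = if (nrow(seg)) stats::median(seg$duration_ms) else NA_real_)
  }
  dplyr::bind_rows(out)
}

#' Synaptic weight statistics by block category
#'
#' Partitions the off-diagonal `cx->cx` pairs into three categories --
#' synapses within one image's group (`same_instance`), between groups of
#' different images of the same class (`same_class`), and between groups of
#' different classes (`cross_class`) -- and reports mean weights before and
#' after an intervention plus their post/pre ratio.
#'
#' @param W_pre,W_post square `cx->cx` weight matrices (same shape).
#' @param groups the network's group map (`net$groups`).
#' @return A tibble with one row per category: `category`, `mean_pre`,
#'   `mean_post`, `ratio`, `n` (ordered synapse count).
#' @export
weight_block_stats <- function(W_pre, W_post, groups) {
  stopifnot(all(dim(W_pre) == dim(W_post)))
  n <- nrow(W_pre)
  group_of <- class_of <- rep(NA_integer_, n)
  for (k in seq_len(nrow(groups))) {
    group_of[groups$neurons[[k]]] <- groups$image[k]
    class_of[groups$neurons[[k]]] <- groups$class[k]
  }
  if (any(is.na(group_of))) stop("group map does not cover all cx neurons")
  gi <- matrix(group_of, n, n); gj <- t(gi)
  ci <- matrix(class_of, n, n); cj <- t(ci)
  offdiag <- !diag(TRUE, n)
  cat_m <- matrix("cross_class", n, n)
  cat_m[ci == cj] <- "same_class"
  cat_m[gi == gj] <- "same_instance"
  cats <- c("same_instance", "same_class", "cross_class")
  out <- lapply(cats, function(cc) {
    sel <- offdiag & cat_m == cc
    if (!any(sel)) {
      return(tibble::tibble(category = cc, mean_pre = NA_real_,
                            mean_post = NA_real_, ratio = NA_real_, n = 0L))
    }
    mp <- mean(W_pre[sel]); mq <- mean(W_post[sel])
    tibble::tibble(category = cc, mean_pre = mp, mean_post = mq,
                   ratio = if (mp > 0) mq / mp else NA_real_, n = sum(sel))
  })
  dplyr::bind_rows(out)
}

#' Pairwise activity correlations between image groups
#'
#' Bins the spikes of each trained group into counts and returns the
#' Pearson correlation matrix across groups.  Groups with zero count
#' variance give `NA` rows/columns (diagonal 1 where variance is positive).
#'
#' @param raster a raster tibble.
#' @param groups the network's group map.
#' @param bin_ms bin width, ms.
#' @param t_start,t_stop analysis window, ms (default: raster extent).
#' @return A `n_groups` x `n_groups` correlation matrix.
#' @export
population_correlations <- function(raster, groups, bin_ms = 10,
                                    t_start = NULL, t_stop = NULL) {
  stopifnot(nrow(groups) >= 2)
  cx <- dplyr::filter(raster, .data$pop == "cx")
  if (is.null(t_start)) t_start <- min(cx$time_ms)
  if (is.null(t_stop)) t_stop <- max(cx$time_ms) + bin_ms
  edges <- seq(t_start, t_stop + bin_ms, by = bin_ms)
  counts <- vapply(groups$neurons, function(g) {
    sp <- cx$time_ms[cx$neuron %in% g & cx$time_ms >= t_start &
                       cx$time_ms < t_stop]
    graphics::hist(sp, breaks = edges, plot = FALSE)$counts
  }, numeric(length(edges) - 1))
  cm <- suppressWarnings(cor(counts))
  diag(cm)[apply(counts, 2, sd) > 0] <- 1
  dimnames(cm) <- list(groups$image, groups$image)
  cm
}

#' Correlation changes between two phases, by class category
#'
#' @param cor_pre,cor_post group correlation matrices with identical layout.
#' @param groups the network's group map.
#' @return A tibble of unordered group pairs: `image_a`, `image_b`,
#'   `category` (`same_class`/`cross_class`), `delta` (post minus pre).
#' @export
correlation_change <- function(cor_pre, cor_post, groups) {
  stopifnot(all(dim(cor_pre) == dim(cor_post)))
  n <- nrow(cor_pre)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[[length(out) + 1]] <- tibble::tibble(
        image_a = groups$image[i], image_b = groups$image[j],
        category = if (groups$class[i] == groups$class[j])
          "same_class" else "cross_class",
        delta = cor_post[i, j] - cor_pre[i, j])
    }
  }
  dplyr::bind_rows(out)
}

#' Per-neuron firing-rate change between two task phases
#'
#' Computes each cortical neuron's time-averaged rate over the presentation
#' windows of a pre-phase and a post-phase, and the correlation between the
#' pre-sleep rate and the rate change (negative when low-rate neurons rise
#' and high-rate neurons fall, the firing-rate "rotation" signature).
#'
#' @param raster_pre,raster_post rasters of the two phases.
#' @param windows_pre,windows_post their presentation windows tibbles.
#' @param n_cx number of cortical neurons.
#' @return `list(rates, trend, trend_defined)`: `rates` is a tibble
#'   (`neuron`, `rate_pre`, `rate_post`, `delta`); `trend` is
#'   `cor(rate_pre, delta)`, reported as 0 with `trend_defined = FALSE`
#'   when either side is constant.
#' @export
rate_change_analysis <- function(raster_pre, raster_post, windows_pre,
                                 windows_post, n_cx) {
  r_pre <- windowed_rates(raster_pre, windows_pre, n_cx)
  r_post <- windowed_rates(raster_post, windows_post, n_cx)
  rates <- tibble::tibble(neuron = seq_len(n_cx), rate_pre = r_pre,
                          rate_post = r_post, delta = r_post - r_pre)
  defined <- sd(rates$rate_pre) > 0 && sd(rates$delta) > 0
  trend <- if (defined) cor(rates$rate_pre, rates$delta) else 0
  list(rates = rates, trend = trend, trend_defined = defined)
}

windowed_rates <- function(raster, windows, n_cx) {
  cx <- dplyr::filter(raster, .data$pop == "cx", .data$neuron <= n_cx)
  total_s <- sum(windows$t_stop - windows$t_start) / 1000
  keep <- rep(FALSE, nrow(cx))
  for (k in seq_len(nrow(windows)))
    keep <- keep | (cx$time_ms >= windows$t_start[k] &
                      cx$time_ms < windows$t_stop[k])
  tabulate(cx$neuron[keep], nbins = n_cx) / total_s
}

#' Classification accuracy
#'
#' @param predictions integer predictions (`NA` = abstain, counted wrong).
#' @param truths integer ground-truth labels.
#' @return Fraction correct in `[0, 1]`.
#' @export
accuracy <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  if (length(truths) == 0) return(NA_real_)
  mean(!is.na(predictions) & predictions == truths)
}

# ---- report-level helpers -------------------------------------------------

offline_log <- function(rep) {
  log <- rep$net$log$sleep
  if (is.null(log)) log <- rep$net$log$awake
  if (is.null(log)) stop("report contains no sleep or awake-control phase")
  log
}

#' Block statistics of a protocol report
#'
#' @param rep a [run_full_protocol()] report.
#' @param epoch epoch snapshot to compare against the pre-sleep weights
#'   (default: the last).
#' @return A [weight_block_stats()] tibble.
#' @export
report_block_stats <- function(rep, epoch = NULL) {
  log <- offline_log(rep)
  snaps <- log$snapshots
  if (is.null(epoch)) epoch <- length(snaps) - 1
  stopifnot(epoch >= 1, epoch <= length(snaps) - 1)
  weight_block_stats(snaps[[1]]$weights$cx_cx,
                     snaps[[epoch + 1]]$weights$cx_cx, rep$net$groups)
}

#' Slow-oscillation summary of a protocol report
#'
#' @param rep a [run_full_protocol()] report.
#' @param ... passed to [detect_up_states()].
#' @return The [so_by_epoch()] tibble for the offline phase.
#' @export
report_so <- function(rep, ...) {
  so_by_epoch(offline_log(rep), ...)
}

#' Correlation change between pre- and post-sleep retrieval
#'
#' @param rep a [run_full_protocol()] report.
#' @param bin_ms correlation bin width, ms.
#' @return A [correlation_change()] tibble.
#' @export
report_correlation_change <- function(rep, bin_ms = 10) {
  net <- rep$net
  pre <- net$log$retrieval_pre; post <- net$log$retrieval_post
  if (is.null(pre) || is.null(post))
    stop("report lacks pre/post retrieval phases")
  win <- function(l) c(min(l$windows$t_start), max(l$windows$t_stop))
  wp <- win(pre); wq <- win(post)
  cp <- population_correlations(pre$raster, net$groups, bin_ms, wp[1], wp[2])
  cq <- population_correlations(post$raster, net$groups, bin_ms, wq[1], wq[2])
  correlation_change(cp, cq, net$groups)
}

#' Firing-rate change between pre- and post-sleep classification
#'
#' @param rep a [run_full_protocol()] report.
#' @return A [rate_change_analysis()] result list.
#' @export
report_rate_change <- function(rep) {
  net <- rep$net
  pre <- net$log$classify_pre; post <- net$log$classify_post
  if (is.null(pre) || is.null(post))
    stop("report lacks pre/post classification phases")
  n_cx <- net$pops$size[net$pops$pop == "cx"]
  rate_change_analysis(pre$raster, post$raster, pre$windows, post$windows,
                       n_cx)
}

#' Held-out classification accuracy of a protocol report
#'
#' @param rep a [run_full_protocol()] report.
#' @param when `"pre"` or `"post"`.
#' @return Fraction correct.
#' @export
report_accuracy <- function(rep, when = c("pre", "post")) {
  when <- match.arg(when)
  log <- rep$net$log[[paste0("classify_", when)]]
  if (is.null(log)) stop("report lacks the ", when, "-sleep classification")
  accuracy(log$predictions$pred_class, log$predictions$truth)
}

#' Mean absolute recurrent weight change over the offline phase
#'
#' @param rep a [run_full_protocol()] report.
#' @return Mean `|w_post - w_pre|` over off-diagonal `cx->cx` synapses, nS.
#' @export
report_weight_change <- function(rep) {
  log <- offline_log(rep)
  snaps <- log$snapshots
  w0 <- snaps[[1]]$weights$cx_cx
  w1 <- snaps[[length(snaps)]]$weights$cx_cx
  offdiag <- !diag(TRUE, nrow(w0))
  mean(abs(w1[offdiag] - w0[offdiag]))
}
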
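# Shared simulation battery for the protocol-level tests.  Runs are
# computed once per test session and cached; every heavy test block reads
# from the same battery.  Problem sizes are the desk-scale study defaults:
# 9 training items (3 classes x 3 instances), 150 s sleep for the
# condition contrasts, 500 s sleep for the slow-oscillation trend, with
# seed counts at the minimum each contrast requires.
#
# All conditions of one seed share the same pre-sleep history (training,
# pre-sleep retrieval, held-out pre-classification), so that prefix is
# simulated once per seed and the conditions branch from it; each branch
# reseeds deterministically so outcomes do not depend on which branches ran.

battery_seeds_on <- 1:8
battery_seeds_off <- 1:6
battery_seeds_awake <- 1:4
battery_seeds_trend <- 1:5

battery_config <- function(seed, ...) {
  somnet_config(seed = seed, sleep_s = 150, record = "cx", ...)
}

# training + pre-sleep measurements, shared by all conditions of one seed
battery_prefix <- function(seed) {
  cached(paste0("prefix_", seed), {
    cf <- battery_config(seed)
    set.seed(cf$seed)
    spec <- synth_spec(cf$n_classes, cf$n_instances, cf$within, cf$cross)
    set <- make_synth_set(spec, n_holdout = cf$n_holdout,
                          holdout_within = cf$holdout_within)
    net <- build_network(length(set$features), set$labels, cf)
    net <- run_training(net, set$features)
    net <- run_retrieval(net, set$features, label = "retrieval_pre")
    net <- classify_images(net, set$holdout, set$holdout_labels,
                           label = "classify_pre")
    list(net = net, set = set)
  })
}

battery_branch <- function(seed, condition, sleep_s = 150) {
  px <- battery_prefix(seed)
  net <- px$net
  cf <- net$config
  cf$thalamic_feedback <- condition != "off"
  cf$awake_control <- condition == "awake"
  cf$sleep_s <- sleep_s
  net$config <- cf
  if (condition == "off") net <- set_thalamic_feedback(net, FALSE)
  set.seed(seed * 1000L +
             match(condition, c("on", "off", "awake", "trend")))
  net <- if (condition == "awake") run_awake_control(net) else run_sleep(net)
  if (condition != "trend") {
    net <- run_retrieval(net, px$set$features, label = "retrieval_post")
    if (condition != "awake")
      net <- classify_images(net, px$set$holdout, px$set$holdout_labels,
                             label = "classify_post")
  }
  structure(list(net = net, set = px$set, config = cf, seed = seed),
            class = "somnet_report")
}

battery_run <- function(seed, condition) {
  rep <- battery_branch(seed, condition)
  light <- condition == "awake"
  bs <- report_block_stats(rep)
  r <- function(cat) bs$ratio[bs$category == cat]
  cc <- report_correlation_change(rep)
  agg <- tapply(cc$delta, cc$category, mean)
  so <- report_so(rep)
  rc <- if (light) NULL else report_rate_change(rep)
  tibble::tibble(
    seed = seed, condition = condition,
    so_hz = mean(so$so_hz), up_med = stats::median(so$median_up_ms,
                                                   na.rm = TRUE),
    ratio_inst = r("same_instance"), ratio_same = r("same_class"),
    ratio_cross = r("cross_class"),
    dcor_same = unname(agg["same_class"]),
    dcor_cross = unname(agg["cross_class"]),
    acc_pre = if (light) NA_real_ else report_accuracy(rep, "pre"),
    acc_post = if (light) NA_real_ else report_accuracy(rep, "post"),
    rate_trend = if (light) NA_real_ else rc$trend,
    dw = report_weight_change(rep))
}

battery <- function(condition) {
  seeds <- switch(condition,
    on = battery_seeds_on, off = battery_seeds_off,
    awake = battery_seeds_awake)
  cached(paste0("battery_", condition), {
    dplyr::bind_rows(lapply(seeds, battery_run, condition = condition))
  })
}

# slow-oscillation frequency per 100 s epoch over a 500 s sleep
battery_trend <- function() {
  cached("battery_trend", {
    dplyr::bind_rows(lapply(battery_seeds_trend, function(s) {
      rep <- battery_branch(s, "trend", sleep_s = 500)
      ep <- so_by_epoch(rep$net$log$sleep)
      tibble::tibble(seed = s, epoch = ep$epoch, so_hz = ep$so_hz)
    }))
  })
}
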
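# Shared fixtures for the test suite.  Simulation-backed objects are built
# once per test run and cached, so several test files can reuse the same
# trained network without repeating the (comparatively expensive) training.

.somnet_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .somnet_cache)) {
    assign(key, force(expr), envir = .somnet_cache)
  }
  get(key, envir = .somnet_cache)
}

# a small trained network (3 classes x 2 instances) used across test files
trained_fixture <- function() {
  cached("trained_small", {
    set.seed(101)
    cf <- somnet_config(n_instances = 2)
    set <- make_synth_set(synth_spec(3, 2, cf$within, cf$cross), n_holdout = 1)
    net <- build_network(length(set$features), set$labels, cf)
    net <- run_training(net, set$features)
    list(net = net, set = set)
  })
}

# deterministic step-edge image for feature tests
step_edge_image <- function(col = 14) {
  img <- matrix(0, 28, 28)
  img[, col:28] <- 1
  img
}

random_feature <- function() {
  levels_to_feature_test(sample.int(4L, 81L, replace = TRUE))
}

# high-resolution AdEx reference spike train, shared across test files
adex_step_reference <- function() {
  cached("adex_ref", {
    p <- adex_params()
    list(params = p,
         ref = simulate_adex_neuron(p, duration = 80, dt = 0.001,
                                    I_pA = 900),
         coarse = simulate_adex_neuron(p, duration = 80, dt = 0.1,
                                       I_pA = 900))
  })
}

levels_to_feature_test <- function(lev) {
  out <- integer(324)
  out[(seq_along(lev) - 1L) * 4L + lev] <- 1L
  out
}
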
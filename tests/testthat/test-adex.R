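test_that("parameter constructor enforces invariants and derives V_spike", {
  p <- adex_params()
  expect_equal(p$V_spike, p$theta + 5 * p$delta_V)
  expect_equal(p$V_spike, -40.4)
  expect_error(adex_params(tau_m = -1))
  expect_error(adex_params(E_inh = -60), "E_inh < E_l < E_exc")
})

test_that("near rest the membrane barely moves in one step", {
  p <- adex_params()
  st <- population_state(1, p)
  res <- adex_step(st, p, dt = 0.1)
  expect_lt(abs(res$state$V - p$E_l), 1e-3)
  expect_length(res$spiked, 0)
})

test_that("adaptation decays with its closed form when a = 0", {
  p <- adex_params(a = 0)
  st <- population_state(1, p)
  st$W <- 100
  # clamp V at rest by giving no input; V stays at E_l so only -W/tau_W acts
  for (k in 1:500) st <- adex_step(st, p, dt = 0.1)$state
  expect_equal(st$W, 100 * exp(-50 / p$tau_W), tolerance = 1e-3)
})

test_that("under clamped V the adaptation relaxes to a*(V - E_l)", {
  p <- adex_params(a = 4)
  V_hold <- -60
  W <- 0
  for (k in 1:20000) W <- W + 0.1 * (p$a * (V_hold - p$E_l) - W) / p$tau_W
  expect_equal(W, p$a * (V_hold - p$E_l), tolerance = 1e-3)
})

test_that("spike emission resets V, increments W by b, loads refractoriness", {
  p <- adex_params(b = 60, t_ref = 2)
  st <- population_state(3, p)
  st$V <- c(-40.0, -40.41, p$V_spike)    # first is above threshold already
  st$W <- c(10, 10, 10)
  spiked <- which(st$V >= p$V_spike)
  expect_equal(spiked, c(1, 3))           # -40.41 stays subthreshold
  st2 <- spike_and_reset(st, p, spiked)
  expect_equal(st2$V[spiked], rep(p$V_reset, 2))
  expect_equal(st2$W[spiked], c(70, 70))
  expect_equal(st2$refr[spiked], c(2, 2))
  expect_equal(st2$V[2], st$V[2])
})

test_that("dt refinement changes step-current spike times by less than the
           first-order bound, against a high-resolution reference", {
  x <- adex_step_reference()
  ref <- x$ref; coarse <- x$coarse
  expect_gt(min(length(ref), length(coarse)), 3)
  # onset latency converges; later spike times accumulate the per-interval
  # first-order error, so inter-spike intervals are bounded instead
  expect_lt(abs(ref[1] - coarse[1]), 0.2)
  n <- min(length(ref), length(coarse))
  expect_lt(max(abs(diff(ref[1:n]) - diff(coarse[1:n]))), 0.3)
})

test_that("Poisson delivery matches count statistics and respects windows", {
  set.seed(12)
  src <- poisson_source(1:5, rate = 2000, eff = 3, t_start = 10, t_stop = 20)
  tot <- 0
  for (t in seq(0, 29.9, by = 0.1)) {
    inc <- poisson_deliver(src, 5, t, 0.1)
    expect_true(all(inc$inc_exc >= 0))
    expect_equal(sum(inc$inc_inh), 0)
    if (t < 10 || t >= 20) expect_equal(sum(inc$inc_exc), 0)
    tot <- tot + sum(inc$inc_exc) / 3
  }
  # 5 targets x 2 kHz x 10 ms = 100 expected events
  expect_lt(abs(tot - 100), 4 * 10)
  expect_error(poisson_source(1, rate = -5, eff = 1))
})

test_that("a 30 kHz source delivers the Poisson-expected event count", {
  set.seed(3)
  src <- poisson_source(1, rate = 30000, eff = 1)
  tot <- 0
  for (t in seq(0, 999.9, by = 0.1))
    tot <- tot + sum(poisson_deliver(src, 1, t, 0.1)$inc_exc)
  expect_lt(abs(tot - 30000), 3 * sqrt(30000))
})

test_that("non-finite state is rejected with a diagnostic", {
  p <- adex_params()
  st <- population_state(2, p)
  st$V[2] <- NaN
  expect_error(adex_step(st, p), "neuron 2")
})
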
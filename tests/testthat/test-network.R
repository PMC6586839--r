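test_that("network sizes follow the 20-neurons-per-image rule", {
  net9 <- build_network(9, rep(1:3, each = 3))
  expect_equal(net9$pops$size, c(180, 200, 324, 200))
  net1 <- build_network(1)
  expect_equal(net1$pops$size[1], 20)
  expect_equal(build_network(30, rep(1:10, 3))$pops$size[1], 600)
  expect_error(build_network(0), "at least 1")
  expect_error(build_network(3, 1:2), "one label per image")
})

test_that("the fixed-weight table is installed exactly", {
  net <- build_network(9, rep(1:3, each = 3))
  expect_true(all(get_weights(net, "in_cx") == -4))
  expect_true(all(get_weights(net, "cx_in") == 60))
  expect_true(all(get_weights(net, "tc_re") == 10))
  expect_true(all(get_weights(net, "re_tc") == -10))
  win <- get_weights(net, "in_in")
  expect_true(all(diag(win) == 0) && all(win[row(win) != col(win)] == -1))
  wre <- get_weights(net, "re_re")
  expect_true(all(diag(wre) == 0) && all(wre[row(wre) != col(wre)] == -1))
  wcc <- get_weights(net, "cx_cx")
  expect_true(all(diag(wcc) == 0) && all(wcc[row(wcc) != col(wcc)] == 1))
  expect_true(all(get_weights(net, "cx_tc") == 1))
  expect_true(all(get_weights(net, "tc_cx") == 1))
  # absent projections stay empty
  expect_true(all(get_weights(net, "tc_tc") == 0))
  expect_true(all(get_weights(net, "re_cx") == 0))
})

test_that("group map is a disjoint cover of consecutive 20-neuron blocks", {
  net <- build_network(5, c(1, 1, 2, 2, 3))
  all_n <- unlist(net$groups$neurons)
  expect_equal(sort(all_n), 1:100)
  expect_equal(lengths(net$groups$neurons), rep(20L, 5))
})

test_that("phase schedules install and restore their constants exactly", {
  net <- build_network(2, c(1, 2))
  net <- apply_phase(net, "sleep")
  expect_true(all(get_weights(net, "in_cx") ==
                    somnet_config()$w_in_cx_sleep))
  expect_equal(net$params$cx$b, somnet_config()$b_sleep)
  expect_equal(net$plastic$active, c(TRUE, FALSE, FALSE))
  expect_equal(net$plastic$alpha[1], 3)
  net <- apply_phase(net, "training")
  expect_true(all(get_weights(net, "in_cx") == -4))
  expect_equal(net$params$cx$b, somnet_config()$b_wake)
  expect_true(all(net$plastic$active))
  net2 <- apply_phase(apply_phase(net, "retrieval"), "training")
  expect_identical(net2$W, net$W)
  expect_error(apply_phase(net, "rem"), "unknown phase")
})

test_that("awake control keeps wake constants with sleep plasticity", {
  net <- apply_phase(build_network(2, c(1, 2)), "awake_control")
  expect_true(all(get_weights(net, "in_cx") == -4))
  expect_equal(net$params$cx$b, somnet_config()$b_wake)
  expect_equal(net$plastic$active, c(TRUE, FALSE, FALSE))
  expect_equal(net$plastic$alpha[1], 3)
})

test_that("thalamic feedback toggling zeroes and restores cx->tc exactly", {
  fx <- trained_fixture()
  net <- fx$net
  w0 <- get_weights(net, "cx_tc")
  expect_gt(max(w0), 1)      # training strengthened the projection
  net <- set_thalamic_feedback(net, FALSE)
  expect_true(all(get_weights(net, "cx_tc") == 0))
  net <- set_thalamic_feedback(net, TRUE)
  expect_identical(get_weights(net, "cx_tc"), w0)
})

test_that("weight-sign segregation holds after training", {
  net <- trained_fixture()$net
  for (p in c("cx_cx", "cx_in", "cx_tc", "tc_cx", "tc_re"))
    expect_true(all(get_weights(net, p) >= 0), info = p)
  for (p in c("in_cx", "in_in", "re_tc", "re_re"))
    expect_true(all(get_weights(net, p) <= 0), info = p)
})

test_that("fixed projections are bit-identical across a trained phase", {
  fx <- trained_fixture()
  net0 <- build_network(fx$net$n_images, fx$net$groups$class,
                        fx$net$config)
  for (p in c("cx_in", "tc_re", "re_tc", "in_in", "re_re")) {
    expect_identical(get_weights(fx$net, p), get_weights(net0, p), info = p)
  }
})

test_that("frozen-seed protocol runs are bitwise reproducible", {
  cf <- somnet_config(n_instances = 1, n_holdout = 0, present_ms = 400,
                      gap_ms = 100, retrieve_ms = 200, retrieve_gap_ms = 100,
                      sleep_s = 2, epoch_s = 1, seed = 77)
  r1 <- run_full_protocol(cf)
  r2 <- run_full_protocol(cf)
  expect_identical(r1$net$W, r2$net$W)
  expect_identical(r1$net$log$sleep$raster, r2$net$log$sleep$raster)
  expect_identical(r1$net$state$V, r2$net$state$V)
})
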
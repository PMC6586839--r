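make_raster <- function(times, neurons, pop = "cx") {
  tibble::tibble(time_ms = times, neuron = as.integer(neurons), pop = pop)
}

test_that("up-state detection recovers constructed ground truth", {
  set.seed(2)
  # two 300 ms high-rate windows separated by 1 s of silence
  burst <- function(t0) make_raster(runif(600, t0, t0 + 300),
                                    sample(1:20, 600, TRUE))
  r <- dplyr::bind_rows(burst(100), burst(1400))
  # burst-scale detection parameters for a burst-scale ground truth
  seg <- detect_up_states(r, t_start = 0, t_stop = 2000, bin_ms = 5,
                          smooth_ms = 20, merge_ms = 50)
  expect_equal(nrow(seg), 2)
  expect_lte(abs(seg$onset_ms[1] - 100), 25)
  expect_lte(abs(seg$onset_ms[2] - 1400), 25)
  expect_true(all(seg$duration_ms > 250 & seg$duration_ms < 400))
})

test_that("empty or degenerate rasters give empty segmentations", {
  r <- make_raster(numeric(0), integer(0))
  expect_equal(nrow(detect_up_states(r)), 0)
  expect_equal(nrow(detect_up_states(make_raster(5, 1), t_start = 10,
                                     t_stop = 10)), 0)
})

test_that("so_frequency counts onsets per second", {
  seg <- tibble::tibble(onset_ms = seq(0, 9000, by = 1000),
                        offset_ms = seq(200, 9200, by = 1000),
                        duration_ms = 200)
  expect_equal(so_frequency(seg, 10), 1.0)
  expect_equal(so_frequency(seg[0, ], 10), 0)
})

test_that("block statistics match a hand-computed toy example", {
  groups <- tibble::tibble(image = 1:4, class = c(1, 1, 2, 2),
                           neurons = list(1:2, 3:4, 5:6, 7:8))
  W_pre <- matrix(1, 8, 8); diag(W_pre) <- 0
  W_pre[1, 2] <- W_pre[2, 1] <- 10       # same instance
  W_post <- W_pre
  W_post[1, 2] <- W_post[2, 1] <- 5       # halve one same-instance pair
  W_post[1, 3] <- 4                       # strengthen one same-class pair
  W_post[1, 5] <- 7                       # strengthen one cross-class pair
  bs <- weight_block_stats(W_pre, W_post, groups)
  expect_equal(bs$n, c(4 * 2, 2 * 2 * 4, 2 * 4 * 4))
  expect_equal(sum(bs$n), 8 * 7)
  i <- function(cat) which(bs$category == cat)
  # 8 ordered same-instance pairs: (1,2),(2,1) at 10 each, six more at 1
  expect_equal(bs$mean_pre[i("same_instance")], (10 + 10 + 6) / 8)
  expect_equal(bs$mean_post[i("same_instance")], (5 + 5 + 6) / 8)
  expect_equal(bs$ratio[i("same_class")], (16 + 3) / 16)
  expect_equal(bs$ratio[i("cross_class")], (32 + 6) / 32)
  expect_equal(weight_block_stats(W_pre, W_pre, groups)$ratio, rep(1, 3))
})

test_that("population correlations: self-correlation 1, independent groups
           near 0, symmetric and bounded", {
  set.seed(8)
  groups <- tibble::tibble(image = 1:4, class = c(1, 1, 2, 2),
                           neurons = list(1:5, 6:10, 11:15, 16:20))
  # independent Poisson groups over 10^4 bins of 10 ms
  r <- make_raster(runif(20000, 0, 1e5), sample(1:20, 20000, TRUE))
  cm <- population_correlations(r, groups, bin_ms = 10, t_start = 0,
                                t_stop = 1e5)
  expect_equal(diag(cm), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(cm - t(cm)) < 1e-12))
  expect_true(all(cm >= -1 & cm <= 1))
  off <- cm[row(cm) != col(cm)]
  expect_lt(mean(abs(off)), 0.05)
})

test_that("correlation change labels pairs by class", {
  groups <- tibble::tibble(image = 1:3, class = c(1, 1, 2),
                           neurons = list(1:2, 3:4, 5:6))
  cp <- diag(3); cq <- diag(3); cq[1, 2] <- cq[2, 1] <- 0.5
  cc <- correlation_change(cp, cq, groups)
  expect_equal(nrow(cc), 3)
  expect_equal(cc$category, c("same_class", "cross_class", "cross_class"))
  expect_equal(cc$delta, c(0.5, 0, 0))
})

test_that("rate-change analysis recovers known rates and flags the
           undefined trend", {
  win <- tibble::tibble(item = 1, t_start = 0, t_stop = 1000)
  r_pre <- make_raster(seq(0, 999, length.out = 50), rep(1, 50))
  r_post <- dplyr::bind_rows(r_pre,
                             make_raster(seq(0, 999, length.out = 20),
                                         rep(2, 20)))
  rc <- rate_change_analysis(r_pre, r_post, win, win, n_cx = 3)
  expect_equal(rc$rates$rate_pre, c(50, 0, 0))
  expect_equal(rc$rates$rate_post, c(50, 20, 0))
  expect_true(rc$trend_defined)
  expect_lt(rc$trend, 0)   # silent neuron rose, active one did not
  rc0 <- rate_change_analysis(r_pre, r_pre, win, win, n_cx = 3)
  expect_false(rc0$trend_defined)
  expect_equal(rc0$trend, 0)
  expect_equal(rc0$rates$delta, rep(0, 3))
})

test_that("accuracy counts abstentions as errors", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(accuracy(c(NA, NA), c(1, 2)), 0.0)
  expect_equal(accuracy(c(1, 2, 1, NA, 3, 3, 2, 1, 2, 3),
                        c(1, 2, 2, 1, 3, 3, 1, 1, 2, 3)), 0.7)
})

test_that("segmentation is idempotent on its own rasterisation", {
  set.seed(14)
  r <- dplyr::bind_rows(
    make_raster(runif(800, 500, 900), sample(1:20, 800, TRUE)),
    make_raster(runif(800, 2000, 2500), sample(1:20, 800, TRUE)))
  seg1 <- detect_up_states(r, t_start = 0, t_stop = 3000)
  # rebuild a raster that is active exactly inside the detected intervals
  r2 <- dplyr::bind_rows(lapply(seq_len(nrow(seg1)), function(k)
    make_raster(runif(800, seg1$onset_ms[k], seg1$offset_ms[k]),
                sample(1:20, 800, TRUE))))
  seg2 <- detect_up_states(r2, t_start = 0, t_stop = 3000)
  expect_equal(nrow(seg2), nrow(seg1))
  expect_lt(max(abs(seg2$onset_ms - seg1$onset_ms)), 50)
})
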
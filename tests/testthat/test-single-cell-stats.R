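test_that("elongation rate handles exact and degenerate inputs", {
  # constant length: zero rate
  expect_equal(elongation_rate(0:9, rep(3, 10))$rate_per_min, 0)
  # exact exponential input: slope and fit recovered exactly
  t <- 0:5
  est <- elongation_rate(t, 2 * exp(0.02 * t))
  expect_equal(est$rate_per_min, 0.02, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  expect_equal(est$n_frames, 6L)
  expect_error(elongation_rate(0:1, c(1, 2)), "3 frames")
  expect_error(elongation_rate(0:3, c(1, 2, -1, 2)), "> 0")
})

test_that("mean single-cell rate recovers the simulated control rate within 2%", {
  p <- sim_params(n_trenches = 6, t_total = 150, treat_start = 30,
                  treat_end = 150, inhibition = 0, obs_noise_sd = 0.02,
                  seed = 5)
  sim <- simulate_trenches(p)
  trk <- track_trenches(sim$observations)
  est <- elongation_rates(sim$observations, trk, breaks = NULL)
  m <- mean(est$rate_per_min[est$valid])
  expect_lt(abs(m - p$alpha0) / p$alpha0, 0.02)
})

test_that("rate estimator bias and RMSE shrink with track length", {
  alpha <- 0.028
  rmse <- vapply(c(5, 10, 20, 40), function(nf) {
    rates <- withr::with_seed(nf, vapply(1:300, function(i) {
      t <- seq_len(nf) - 1
      L <- 2 * exp(alpha * t) * exp(stats::rnorm(nf, 0, 0.03))
      elongation_rate(t, L)$rate_per_min
    }, numeric(1)))
    sqrt(mean((rates - alpha)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_lt(abs(mean(withr::with_seed(1, vapply(1:300, function(i) {
    t <- 0:39
    L <- 2 * exp(alpha * t) * exp(stats::rnorm(40, 0, 0.03))
    elongation_rate(t, L)$rate_per_min
  }, numeric(1)))) - alpha), 5e-4)
})

test_that("growth timeseries shows the treatment dip and recovers", {
  p <- sim_params(n_trenches = 5, t_total = 360, inhibition = 0.15,
                  obs_noise_sd = 0.02, seed = 8)
  sim <- simulate_trenches(p)
  trk <- track_trenches(sim$observations)
  est <- elongation_rates(sim$observations, trk, breaks = c(90, 270))
  ts <- growth_timeseries(est, window_width = 40)
  pre <- ts$mean_rate[ts$time_min < 80]
  mid <- ts$mean_rate[ts$time_min >= 130 & ts$time_min < 230]
  post <- ts$mean_rate[ts$time_min >= 300]
  drop <- 1 - mean(mid, na.rm = TRUE) / mean(pre, na.rm = TRUE)
  expect_gt(drop, 0.10)
  expect_lt(drop, 0.20)
  expect_lt(abs(mean(post, na.rm = TRUE) / mean(pre, na.rm = TRUE) - 1),
            0.05)
  # empty windows give NA, not zero
  ts2 <- growth_timeseries(est[est$t_mid < 100, ], window_width = 10,
                           t_range = c(0, 300))
  expect_true(anyNA(ts2$mean_rate))
  expect_false(any(ts2$mean_rate == 0, na.rm = TRUE))
  # per-window replicate summary
  expect_equal(window_mean_rate(est, c(0, 90)),
               mean(est$rate_per_min[est$valid & est$t_mid < 90]))
})

test_that("lysis frequency follows its defining arithmetic", {
  rec <- data.frame(cell_id = 1:100, trench_id = 1L, parent_id = NA,
                    birth_frame = 0L, last_frame = 179L,
                    fate = "censored")
  rec$fate[1:12] <- "lysed"
  rec$last_frame[1:12] <- 99L
  ls <- lysis_frequency(rec, window = c(0, 180))
  expect_equal(ls$n_lineages, 100L)
  expect_equal(ls$n_events, 12L)
  expect_equal(ls$frequency, 0.04)
  expect_error(lysis_frequency(rec, window = c(500, 600)), "no lineages")
})

test_that("lysis-free simulations yield zero frequency in the window", {
  p <- sim_params(n_trenches = 3, t_total = 150, treat_start = 50,
                  treat_end = 150, lambda0 = 0, lambda_treat = 0,
                  seed = 12)
  sim <- simulate_trenches(p)
  ob <- observable_forest(sim$truth, eviction_margin = 6)
  ls <- lysis_frequency(ob$records, window = c(50, 150))
  expect_equal(ls$n_events, 0L)
  expect_equal(ls$frequency, 0)
})

test_that("tracked lysis rate falls inside the exact Poisson interval of the truth", {
  p <- sim_params(n_trenches = 10, t_total = 240, treat_start = 10,
                  treat_end = 240, lambda0 = 0.2, lambda_treat = 0.2,
                  obs_noise_sd = 0.02, seed = 6)
  sim <- simulate_trenches(p)
  trk <- track_trenches(sim$observations)
  lr <- lysis_rate(trk$records, window = c(0, 240))
  expect_gt(0.2, lr$ci[1])
  expect_lt(0.2, lr$ci[2])
  # statistics from tracked output match those from ground truth
  ob <- observable_forest(sim$truth, eviction_margin = 6)
  lo <- lysis_rate(ob$records, window = c(0, 240))
  expect_lt(abs(lr$rate - lo$rate) / lo$rate, 0.15)
})

test_that("replicate comparison reproduces the Welch statistic", {
  a <- c(3.1, 2.9, 3.3, 3.0)
  b <- c(2.5, 2.7, 2.3)
  res <- compare_replicates(a, b)
  # hand-computed Welch t and Welch-Satterthwaite df
  se2a <- stats::var(a) / length(a)
  se2b <- stats::var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_hand <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * stats::pt(abs(t_hand), df_hand, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical groups: zero difference, p = 1
  same <- compare_replicates(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_error(compare_replicates(1, c(1, 2)), "2 replicate")
})

test_that("control vs inhibited replicates separate with good power", {
  p_vals <- vapply(1:5, function(s) {
    ctrl <- vapply(1:3, function(r) {
      p <- sim_params(n_trenches = 2, t_total = 120, treat_start = 30,
                      treat_end = 120, inhibition = 0,
                      obs_noise_sd = 0.02, seed = 100 * s + r)
      sim <- simulate_trenches(p)
      trk <- track_trenches(sim$observations)
      est <- elongation_rates(sim$observations, trk, breaks = c(30))
      window_mean_rate(est, c(30, 120))
    }, numeric(1))
    trt <- vapply(1:3, function(r) {
      p <- sim_params(n_trenches = 2, t_total = 120, treat_start = 30,
                      treat_end = 120, inhibition = 0.15,
                      obs_noise_sd = 0.02, seed = 7000 + 100 * s + r)
      sim <- simulate_trenches(p)
      trk <- track_trenches(sim$observations)
      est <- elongation_rates(sim$observations, trk, breaks = c(30))
      window_mean_rate(est, c(30, 120))
    }, numeric(1))
    compare_replicates(ctrl, trt)$p_value
  }, numeric(1))
  expect_gte(mean(p_vals <= 0.05), 0.8)
})
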
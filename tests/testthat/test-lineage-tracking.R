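test_that("a single constant cell tracks as one censored record", {
  obs <- make_obs(rep(list(4.0), 10))
  trk <- track_trench(obs)
  expect_equal(nrow(trk$records), 1L)
  expect_equal(trk$records$fate, "censored")
  expect_equal(trk$records$birth_frame, 0L)
  expect_equal(trk$records$last_frame, 9L)
  expect_true(all(trk$assignments$cell_id == trk$records$cell_id))
})

test_that("a clean split is recognised as a division with linked daughters", {
  obs <- make_obs(list(4.0, c(2.02, 1.98)))
  trk <- track_trench(obs)
  rec <- trk$records
  expect_equal(sum(rec$fate == "divided"), 1L)
  parent <- rec$cell_id[rec$fate == "divided"]
  kids <- rec[!is.na(rec$parent_id), ]
  expect_equal(nrow(kids), 2L)
  expect_true(all(kids$parent_id == parent))
  expect_true(all(kids$birth_frame ==
                    rec$last_frame[rec$cell_id == parent] + 1L))
  # exhaustive ordered-matching oracle agrees the division is minimal cost
  o <- oracle_match_cost(LA = 4.0, cA = 2.0, LB = c(2.02, 1.98),
                         cB = c(1.01, 3.01))
  d <- dp_assignment_cost(LA = 4.0, cA = 2.0, LB = c(2.02, 1.98),
                          cB = c(1.01, 3.01))
  expect_equal(d, o, tolerance = 1e-12)
  expect_lt(o, 4)  # cheaper than any history that terminates the parent
})

test_that("dynamic programme matches the exhaustive oracle on random frames", {
  withr::with_seed(42, {
    for (rep in 1:40) {
      n <- sample(1:4, 1)
      LA <- stats::runif(n, 2, 6)
      cA <- cumsum(LA) - LA / 2
      # build next frame by randomly growing/dividing/terminating
      LB <- numeric(0)
      for (i in seq_len(n)) {
        u <- stats::runif(1)
        if (u < 0.2) next
        if (u < 0.4) {
          f <- stats::runif(1, 0.4, 0.6)
          LB <- c(LB, f * LA[i] * 1.03, (1 - f) * LA[i] * 1.03)
        } else LB <- c(LB, LA[i] * 1.03)
      }
      if (!length(LB)) LB <- stats::runif(1, 2, 6)
      LB <- LB * exp(stats::rnorm(length(LB), 0, 0.02))
      cB <- cumsum(LB) - LB / 2
      o <- oracle_match_cost(LA, cA, LB, cB, ahat = 0.03, dt = 1)
      d <- dp_assignment_cost(LA, cA, LB, cB, ahat = 0.03, dt = 1)
      expect_equal(d, o, tolerance = 1e-9)
    }
  })
})

test_that("interior disappearance with shifted survivors is lysis", {
  obs <- make_obs(list(c(2.0, 3.0, 4.0), c(3.0, 4.0), c(3.0, 4.0)))
  trk <- track_trench(obs)
  rec <- trk$records
  expect_equal(sum(rec$fate == "lysed"), 1L)
  expect_equal(rec$last_frame[rec$fate == "lysed"], 0L)
  expect_equal(sum(rec$fate == "censored"), 2L)
})

test_that("disappearance at the open end is eviction", {
  obs <- make_obs(list(c(30, 40.9), 30, 30))
  trk <- track_trench(obs, trench_len = 75, eviction_margin = 6)
  rec <- trk$records
  expect_equal(sum(rec$fate == "evicted"), 1L)
  # the evicted cell is the distal one (its edge was at 70.9 >= 69)
  ev <- rec[rec$fate == "evicted", ]
  expect_equal(ev$last_frame, 0L)
  expect_equal(classify_fate(70.9, FALSE), "evicted")
  expect_equal(classify_fate(40, FALSE), "lysed")
  expect_equal(classify_fate(70.9, TRUE), "lysed")
})

test_that("missing frames split tracks with censoring at the gap", {
  obs <- make_obs(list(3, 3, 3), frames = c(0L, 1L, 2L))
  obs2 <- make_obs(list(3, 3), frames = c(5L, 6L))
  trk <- track_trench(rbind(obs, obs2))
  rec <- trk$records
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$fate, c("censored", "censored"))
  expect_equal(rec$last_frame[1], 2L)
  expect_equal(rec$birth_frame[2], 5L)
  expect_true(is.na(rec$parent_id[2]))
})

test_that("a trench that empties before the movie ends is terminated, not censored", {
  obs <- make_obs(list(3, 3, 3))
  trk <- track_trench(obs, t_final = 10)
  expect_equal(trk$records$fate, "lysed")  # interior disappearance
  obs2 <- make_obs(list(72))
  trk2 <- track_trench(obs2, t_final = 10)
  expect_equal(trk2$records$fate, "evicted")
})

test_that("tracking conserves rows and preserves rank order", {
  p <- sim_params(n_trenches = 3, t_total = 150, treat_start = 60,
                  treat_end = 150, obs_noise_sd = 0.02, seed = 17)
  sim <- simulate_trenches(p)
  trk <- track_trenches(sim$observations)
  rec <- trk$records
  expect_equal(nrow(sim$observations),
               sum(rec$last_frame - rec$birth_frame + 1L))
  # every observation row is assigned exactly once
  expect_equal(nrow(trk$assignments), nrow(sim$observations))
  expect_false(anyNA(trk$assignments$cell_id))
  # coexisting tracks never swap rank order
  asg <- trk$assignments
  for (tr in unique(asg$trench_id)) {
    sub <- asg[asg$trench_id == tr, ]
    by_fr <- split(sub, sub$frame)
    for (k in seq_len(length(by_fr) - 1L)) {
      a <- by_fr[[k]]; b <- by_fr[[k + 1L]]
      common <- intersect(a$cell_id, b$cell_id)
      if (length(common) < 2L) next
      ra <- a$rank[match(common, a$cell_id)]
      rb <- b$rank[match(common, b$cell_id)]
      expect_true(all(diff(rb[order(ra)]) > 0))
    }
  }
})

test_that("noise-free tracking reproduces the observable ground truth", {
  for (s in c(2, 9)) {
    p <- sim_params(n_trenches = 2, t_total = 150, treat_start = 60,
                    treat_end = 150, obs_noise_sd = 0, seed = s)
    sim <- simulate_trenches(p)
    ob <- observable_forest(sim$truth, eviction_margin = 6)
    trk <- track_trenches(sim$observations)
    expect_true(compare_forests(trk, ob)$identical)
    expect_equal(assignment_accuracy(trk, ob), 1)
    # per-fate confusion matrix is diagonal
    tab_t <- table(trk$records$fate)
    tab_o <- table(ob$records$fate)
    expect_equal(as.list(tab_t), as.list(tab_o))
  }
})

test_that("lineage tables round-trip through CSV", {
  rec <- data.frame(cell_id = 1:2, trench_id = 1L,
                    parent_id = c(NA_integer_, 1L),
                    birth_frame = c(0L, 3L), last_frame = c(2L, 9L),
                    fate = c("divided", "censored"))
  f <- tempfile(fileext = ".csv")
  write_lineage(rec, f)
  expect_equal(read_lineage(f), rec)
})
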
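# Read-outs and model-comparison statistics.

test_that("windowed mean weight handles flat, ramp and out-of-range cases", {
  traj <- data.frame(time_ms = 0:5000,
                     rho_a2v = 0.4,
                     rho_v2a = seq(0, 1, length.out = 5001))
  expect_equal(mean_weight_window(traj, c(4750, 5000)), 0.4)
  # linear ramp over a window averages to its midpoint value
  expect_equal(mean_weight_window(traj, c(1000, 2000), "v2a"),
               mean(traj$rho_v2a[1001:2001]))
  expect_equal(mean_weight_window(traj, c(0, 5000), "v2a"), 0.5,
               tolerance = 1e-3)
  expect_error(mean_weight_window(traj, c(4900, 5200)), "outside")
})

test_that("memory decision index thresholds at the pooled 10th percentile", {
  vals <- seq(0.05, 0.5, by = 0.05)
  rec <- memory_decision_index(vals)
  thr <- attr(rec, "threshold")
  # sort-and-count oracle
  expect_equal(thr, quantile(vals, 0.1, type = 7, names = FALSE))
  expect_equal(as.logical(rec), vals > thr)
  # all-equal pool: nothing is strictly above the threshold
  expect_false(any(memory_decision_index(rep(0.3, 20))))
  # nearest-rank alternative
  rec2 <- memory_decision_index(vals, method = "nearest_rank")
  expect_equal(attr(rec2, "threshold"),
               quantile(vals, 0.1, type = 1, names = FALSE))
  expect_error(memory_decision_index(1:5), "at least 10")
})

test_that("decision index is invariant to order and pool duplication, monotone", {
  set.seed(21)
  for (i in 1:20) {
    v <- runif(30)
    perm <- sample(30)
    expect_equal(as.logical(memory_decision_index(v))[perm],
                 as.logical(memory_decision_index(v[perm])))
    expect_equal(attr(memory_decision_index(c(v, v)), "threshold"),
                 attr(memory_decision_index(v), "threshold"))
    # raising one trial's value never unrecalls that trial, and the pooled
    # threshold responds monotonically
    j <- sample(30, 1)
    v2 <- v; v2[j] <- v2[j] + 0.5
    r1 <- memory_decision_index(v); r2 <- memory_decision_index(v2)
    expect_true(r2[j] >= r1[j])
    expect_gte(attr(r2, "threshold"), attr(r1, "threshold"))
  }
})

test_that("percentage baseline change is plain arithmetic with NA at zero", {
  expect_equal(percent_baseline_change(0.5, 0.5), 0)
  expect_equal(percent_baseline_change(0.5, 0.75), 50)
  expect_equal(percent_baseline_change(0.5, 0.25), -50)
  expect_warning(out <- percent_baseline_change(0, 0.3), "zero baseline")
  expect_true(is.na(out))
})

test_that("accuracy normalization centres the four conditions", {
  expect_equal(normalize_accuracy(rep(3, 4)), rep(0, 4))
  expect_equal(normalize_accuracy(c(4, 2, 2, 2)), c(1.5, -0.5, -0.5, -0.5))
  set.seed(2)
  for (i in 1:10) expect_equal(mean(normalize_accuracy(runif(4))), 0)
  expect_error(normalize_accuracy(c(1, 2, 3)), "four")
})

test_that("model comparison matches the normal-equations oracle", {
  sim <- c(0.9, 0.3, 0.2, 0.25)
  emp <- c(0.52, 0.38, 0.36, 0.40)
  X <- cbind(1, sim)
  beta <- solve(t(X) %*% X, t(X) %*% emp)
  rss_oracle <- sum((emp - X %*% beta)^2)
  cmp <- compare_models(sim, sim * 0.5 + 0.1, emp)
  expect_equal(cmp$rss_full, rss_oracle, tolerance = 1e-12)
  expect_equal(unname(cmp$coef_full), c(beta), tolerance = 1e-10)
  # affine rescaling of the simulated values is absorbed by the fit
  cmp2 <- compare_models(sim * 7 - 2, sim, emp)
  expect_equal(cmp2$rss_full, rss_oracle, tolerance = 1e-10)
  expect_equal(cmp2$f_statistic, 0, tolerance = 1e-8)
  # a perfect linear predictor beats an unrelated competitor decisively
  cmp3 <- compare_models(emp * 2 + 1, c(0.1, 0.8, 0.2, 0.6), emp)
  expect_lt(cmp3$rss_full, 1e-20)
  expect_gt(cmp3$f_statistic, 1e3)
  expect_gt(cmp3$bic_variant, cmp3$bic_full)
  # data-frame empirical input with offset matching
  df <- data.frame(offset = c(180, 0, 270, 90),
                   accuracy = emp[c(3, 1, 4, 2)])
  expect_equal(compare_models(sim, sim, df)$rss_full, rss_oracle,
               tolerance = 1e-12)
  expect_error(compare_models(sim, sim, data.frame(offset = c(0, 45, 90, 135),
                                                   accuracy = emp)),
               "offsets")
})

test_that("condition summaries report mean, SE and n per condition", {
  trials <- data.frame(condition = rep(1:2, each = 4),
                       rho_a2v = c(1, 2, 3, 4, 5, 5, 5, 5))
  s <- condition_summary(trials)
  expect_equal(s$mean, c(2.5, 5))
  expect_equal(s$se[1], sd(1:4) / 2)
  expect_equal(s$n, c(4L, 4L))
})
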
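# Theta-gated STDP rule: trace sums, thresholded updates, variants.

test_that("LTP trace sums phase-weighted exponentially decaying pairings", {
  pp <- plasticity_params()
  # single pairing at full inhibitory-phase weight stays below threshold
  h <- make_history(100, 0)
  expect_equal(potential_ltp(just_after(100), h, pp), 0.65, tolerance = 1e-6)
  expect_lt(potential_ltp(just_after(100), h, pp), pp$eps_ltp)
  # theta = 1 annihilates the LTP weighting entirely
  h <- make_history(c(50, 60, 70, 80), rep(1, 4))
  expect_equal(potential_ltp(just_after(80), h, pp), 0)
  # two pairings 10 ms apart cross the threshold
  h <- make_history(c(0, 10), c(0, 0))
  expect_equal(potential_ltp(just_after(10), h, pp),
               0.65 * (1 + exp(-0.5)), tolerance = 1e-6)
  expect_gt(potential_ltp(just_after(10), h, pp), pp$eps_ltp)
  # strictness: history at or after t is a contract violation
  expect_error(potential_ltp(10, make_history(10, 0), pp), "strictly before")
})

test_that("LTD trace mirrors LTP with theta in place of its complement", {
  pp <- plasticity_params()
  h <- make_history(c(10, 20, 30), rep(0, 3))
  expect_equal(potential_ltd(just_after(30), h, pp), 0)
  h <- make_history(60, 1)
  expect_equal(potential_ltd(just_after(60), h, pp), 0.65, tolerance = 1e-6)
  h <- make_history(c(0, 10, 20), rep(1, 3))
  expect_equal(potential_ltd(just_after(20), h, pp),
               0.65 * (1 + exp(-0.5) + exp(-1)), tolerance = 1e-6)
})

test_that("phase antisymmetry: theta <-> 1-theta maps LTP into LTD", {
  pp <- plasticity_params()
  set.seed(5)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    times <- sort(runif(n, 0, 150))
    th <- runif(n)
    t <- just_after(max(times))
    expect_equal(potential_ltp(t, make_history(times, th), pp),
                 potential_ltd(t, make_history(times, 1 - th), pp),
                 tolerance = 1e-12)
  }
})

test_that("thresholded update is graded above epsilon and zero at it", {
  pp <- plasticity_params()
  expect_equal(plasticity_delta(0.5, 1, pp, "ltp"), 0)   # F = eps exactly
  expect_equal(plasticity_delta(0, 1.5, pp, "ltp"), 0.75)
  expect_equal(plasticity_delta(1, 1.5, pp, "ltd"), -0.375)
  expect_equal(plasticity_delta(1, 2, pp, "ltp"), 0)     # soft bound at rho=1
  expect_equal(plasticity_delta(0, 2, pp, "ltd"), 0)     # soft bound at rho=0
})

test_that("no single spike pairing ever triggers plasticity (exhaustive scan)", {
  pp <- plasticity_params()
  for (d in seq(0, 100, by = 1)) for (th in c(0, 0.25, 0.5, 0.75, 1)) {
    fl <- potential_ltp(just_after(d), make_history(0, th), pp)
    fd <- potential_ltd(just_after(d), make_history(0, th), pp)
    expect_lt(fl, pp$eps_ltp)
    expect_lt(fd, pp$eps_ltd)
    expect_equal(plasticity_delta(0.5, fl, pp, "ltp"), 0)
    expect_equal(plasticity_delta(0.5, fd, pp, "ltd"), 0)
  }
})

test_that("burst grading: no change below 3 pairings, increasing from 3 to 4", {
  pp <- plasticity_params()
  deltas <- sapply(1:4, function(k) {
    times <- 10 * (0:(k - 1))
    h <- make_history(times, rep(0, k))
    # postsynaptic partner fires 1 ms after the presynaptic burst ends
    f <- potential_ltp(max(times) + 1, h, pp)
    plasticity_delta(0, f, pp, "ltp")
  })
  expect_equal(deltas[1], 0)
  expect_equal(deltas[2], 0)
  expect_gt(deltas[3], 0)
  expect_gt(deltas[4], deltas[3])
})

test_that("apply_plasticity_at_spike updates only plastic partners of the spiker", {
  net <- build_network(seed = 3)
  g <- neuron_groups()
  pp <- plasticity_params()
  hist <- spike_history(net$n)
  s <- g$hip_vis[1]
  partner <- g$hip_aud[which(net$plastic[g$hip_aud, s])][1]
  skip_if(is.na(partner))  # connectivity draw dependent (p = 1 - 0.5^5)
  # partner burst at the LTP phase, then s spikes
  for (tt in c(100, 110, 120))
    hist <- record_spike(hist, partner, tt, 0)
  rho0 <- net$rho
  net2 <- apply_plasticity_at_spike(s, 121, net, hist, pp)
  expect_gt(net2$rho[partner, s], rho0[partner, s])
  # non-plastic entries untouched
  expect_equal(net2$rho[net$plastic == FALSE], rho0[net$plastic == FALSE])
  # efficacies stay within bounds
  expect_true(all(net2$rho >= 0 & net2$rho <= 1))
})

test_that("rho stays in [0,1] for arbitrary random spike bombardment", {
  net <- build_network(seed = 8)
  pp <- plasticity_params()
  hist <- spike_history(net$n)
  hip <- 21:30
  set.seed(99)
  t <- 0
  for (i in 1:300) {
    t <- t + sample(1:5, 1)
    s <- sample(hip, 1)
    th <- runif(1)
    net <- apply_plasticity_at_spike(s, t, net, hist, pp, theta_now = th)
    hist <- record_spike(hist, s, t, th)
    expect_true(all(net$rho >= 0 & net$rho <= 1))
  }
})

test_that("record_spike appends, prunes, and rejects time regressions", {
  h <- spike_history(2)
  h <- record_spike(h, 1, 100, 0.2)
  expect_equal(h[[1]], list(t = 100, theta = 0.2))
  h <- record_spike(h, 1, 300, 0.9, trace_window = 200)
  expect_equal(h[[1]]$t, c(100, 300))
  h <- record_spike(h, 1, 301, 0.5, trace_window = 200)
  expect_equal(h[[1]]$t, c(300, 301))  # entry at 100 pruned
  expect_error(record_spike(h, 1, 200, 0.5), "regression")
  expect_error(record_spike(h, 2, 10, 1.5), "0, 1")
})

test_that("pruning error is bounded by the geometric tail", {
  pp <- plasticity_params()
  # spikes straddling the window edge: pruned contribution is tiny
  times <- c(0, 5, 250, 260)
  th <- rep(0, 4)
  full <- sum(0.65 * exp((times - 261) / 20))
  pruned <- potential_ltp(261, make_history(times, th), pp)  # window 200
  expect_lt(abs(full - pruned), 2 * 0.65 * exp(-pp$trace_window_ms / pp$tau_s))
})

test_that("incremental traces match brute-force re-summation on the grid", {
  pp <- plasticity_params()
  set.seed(31)
  for (i in 1:30) {
    n <- sample(1:12, 1)
    times <- sort(sample(0:180, n))
    th <- runif(n)
    t_eval <- 190
    h <- make_history(times, th)
    expect_equal(incremental_trace(h, t_eval, pp, "ltp"),
                 potential_ltp(t_eval, h, pp), tolerance = 1e-9)
    expect_equal(incremental_trace(h, t_eval, pp, "ltd"),
                 potential_ltd(t_eval, h, pp), tolerance = 1e-9)
  }
})

test_that("lesioned variants reweight the trace sums as defined", {
  # theta_only: no exponential, theta re-ranged to [-1, 1]
  pp <- plasticity_params(variant = "theta_only")
  h <- make_history(c(10, 40), c(0.25, 1))   # theta' = -0.5, +1
  expect_equal(potential_ltp(just_after(40), h, pp),
               0.65 * ((1 - (-0.5)) + (1 - 1)), tolerance = 1e-9)
  expect_equal(potential_ltd(just_after(40), h, pp),
               0.65 * (-0.5 + 1), tolerance = 1e-9)
  # half-cycle window: no decay inside, older spikes drop out entirely
  h2 <- make_history(c(150, 200), c(0, 0))
  expect_equal(potential_ltp(just_after(200), h2, pp), 2 * 0.65 * 2,
               tolerance = 1e-9)
  expect_equal(potential_ltp(251, h2, pp), 0.65 * 2)  # spike at 150 outside
  expect_equal(potential_ltp(320, h2, pp), 0)         # both outside
  # stdp_only: pure exponential pairing, no phase factors
  ps <- plasticity_params(variant = "stdp_only")
  h3 <- make_history(c(0, 10), c(0.1, 0.9))
  expect_equal(potential_ltp(just_after(10), h3, ps),
               0.65 * (1 + exp(-0.5)), tolerance = 1e-6)
  expect_equal(potential_ltd(just_after(10), h3, ps),
               0.65 * (1 + exp(-0.5)), tolerance = 1e-6)
})

test_that("heterosynaptic flag is rejected (not part of the model surface)", {
  expect_error(plasticity_params(heterosynaptic_enabled = TRUE),
               "heterosynaptic")
})
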
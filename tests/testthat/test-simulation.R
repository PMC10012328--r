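# Trial engine: determinism, discretization exactness, spike-train
# invariants, and a brute-force replay oracle for the in-loop plasticity.

test_that("identical seed and spec give bit-identical trial outputs", {
  a <- quick_trial(seed = 51, record_trajectory = TRUE, record_spikes = TRUE)
  b <- quick_trial(seed = 51, record_trajectory = TRUE, record_spikes = TRUE)
  expect_identical(a$summary, b$summary)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$spikes, b$spikes)
  c <- quick_trial(seed = 52)
  expect_false(identical(a$summary$rho_a2v, c$summary$rho_a2v))
})

test_that("the engine's two-state recursion reproduces the alpha kernel exactly", {
  np <- neuron_params()
  dt <- 1
  d <- exp(-dt / np$tau_s)
  c1 <- dt * exp(1) / np$tau_s
  y <- z <- 0
  A <- 0.65
  got <- numeric(300)
  for (m in 1:300) {           # impulse injected at step 0
    if (m == 1) z <- A
    y <- d * (y + c1 * z)
    z <- d * z
    got[m] <- y
  }
  expect_equal(got, epsp_kernel(1:300, 1, A, np$tau_s), tolerance = 1e-12)
})

test_that("no neuron ever violates the refractory period", {
  res <- quick_trial(seed = 61, record_spikes = TRUE)
  expect_gte(res$min_isi_ms, neuron_params()$refractory_ms)
  isis <- unlist(tapply(res$spikes$time_ms, res$spikes$neuron,
                        function(x) diff(sort(x))))
  expect_true(all(isis >= 2))
})

test_that("zero-amplitude stimulus leaves inter-subgroup weights near zero", {
  vals <- sapply(1:10, function(i) {
    net <- build_network(seed = 700 + i)
    spec <- stimulus_spec(4, 0, amplitude = 0)
    s <- run_trial(net, model_params(), spec, seed = 800 + i)$summary
    c(s$rho_a2v, s$rho_v2a)
  })
  expect_true(all(vals < 0.05))
})

test_that("trajectory read-out window matches the summary value", {
  res <- quick_trial(seed = 71, record_trajectory = TRUE)
  expect_equal(res$summary$rho_a2v,
               mean_weight_window(res$trajectory, c(4750, 5000), "a2v"))
  expect_equal(res$summary$baseline_a2v,
               mean_weight_window(res$trajectory, c(250, 2000), "a2v"))
  expect_true(all(res$trajectory$rho_a2v >= 0 & res$trajectory$rho_a2v <= 1))
})

test_that("burst pulses elicit the scheduled spikes at 100 Hz spacing", {
  net <- build_network(seed = 5)
  spec <- burst_spec(4, "trough", n_trials = 1)
  res <- run_trial(net, model_params(), spec, seed = 6, record_spikes = TRUE)
  stim <- 21:25
  for (s in stim) {
    burst <- sort(res$spikes$time_ms[res$spikes$neuron == s &
                                     res$spikes$time_ms > 800 &
                                     res$spikes$time_ms < 950])
    expect_length(burst, 4)
    expect_equal(diff(burst), rep(10, 3))
    # spikes sit at the theta trough (LTP-permissive phase)
    th <- theta_from_phase(2 * pi * 4 * burst / 1000)
    expect_true(all(th < 0.1))
  }
})

test_that("in-loop plasticity matches a brute-force replay of the spike record", {
  pp_exact <- plasticity_params(trace_window_ms = 1e9)  # no pruning
  net <- build_network(seed = 15)
  spec <- burst_spec(4, "trough", n_trials = 1)
  res <- run_trial(net, model_params(), spec, seed = 16,
                   record_spikes = TRUE, record_trajectory = TRUE)
  # reconstruct the burst-trial initial efficacies
  rho <- net$rho
  same <- outer(net$subgroup, net$subgroup, "==")
  rho[net$plastic & same] <- spec$rho_init_intra
  # replay every spike in time order, same-ms spikes excluded from each
  # other's histories and all same-ms updates computed from pre-update rho
  sp <- res$spikes[order(res$spikes$time_ms, res$spikes$neuron), ]
  hist <- lapply(1:net$n, function(i) list(t = numeric(), theta = numeric()))
  gp <- pp_exact$gamma_p; gd <- pp_exact$gamma_d
  for (tt in unique(sp$time_ms)) {
    th <- theta_from_phase(2 * pi * 4 * tt / 1000)
    spikers <- sp$neuron[sp$time_ms == tt]
    hip_spikers <- spikers[spikers >= 21]
    rho_new <- rho
    for (s in hip_spikers) {
      ip <- which(net$plastic[, s])
      if (length(ip)) {
        f <- vapply(ip, function(i) potential_ltp(tt, hist[[i]], pp_exact), 0)
        rho_new[cbind(ip, s)] <- rho_new[cbind(ip, s)] +
          gp * (1 - rho[cbind(ip, s)]) * pmax(0, f - 1)
      }
      jp <- which(net$plastic[s, ])
      if (length(jp)) {
        f <- vapply(jp, function(j) potential_ltd(tt, hist[[j]], pp_exact), 0)
        rho_new[cbind(s, jp)] <- rho_new[cbind(s, jp)] -
          gd * rho[cbind(s, jp)] * pmax(0, f - 1)
      }
    }
    rho <- pmin(pmax(rho_new, 0), 1)
    for (s in spikers)
      hist[[s]] <- list(t = c(hist[[s]]$t, tt),
                        theta = c(hist[[s]]$theta, th))
  }
  m <- matrix(FALSE, net$n, net$n); m[21:25, ] <- TRUE; m[, 21:25] <- TRUE
  idx <- which(net$plastic & m)
  expect_equal(mean(rho[idx]),
               tail(res$trajectory$rho_measured, 1), tolerance = 1e-9)
})
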
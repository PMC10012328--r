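# Trial simulation engine.
#
# Fixed-step forward Euler at dt = 1 ms (configurable).  Synaptic currents
# are the superposition of peak-normalized EPSP alpha kernels over all
# delivered spike events (synaptic and background), evaluated with an exact
# two-state recursion of the alpha kernel (the discrete update reproduces
# the closed-form kernel to machine precision on the step grid), scaled by
# the global synaptic gain; per-step cost is O(n).  Plasticity traces are
# kept incrementally (exponential decay plus an increment at each spike);
# the test suite holds them to within 1e-9 of the brute-force history
# re-summation in potential_ltp()/potential_ltd().

theta_only_sums <- function(partners, t, hist_t, hist_th, pp, ltp) {
  amp <- if (ltp) pp$A_plus else pp$A_minus
  win <- pp$theta_only_window_ms
  vapply(partners, function(i) {
    keep <- hist_t[[i]] >= t - win & hist_t[[i]] < t
    th <- hist_th[[i]][keep]
    if (!length(th)) return(0)
    if (ltp) sum(amp * (1 - th)) else sum(amp * th)
  }, 0)
}

#' Simulate one trial
#'
#' Runs the network for one trial of either the entrainment memory paradigm
#' (a [stimulus_spec()]: interstimulus interval, then cosine-modulated or
#' constant direct current into the two NC subgroups, with optional theta
#' reset at onset) or the burst-stimulation protocol (a [burst_spec()]:
#' suprathreshold current pulses into one hippocampal subgroup timed to a
#' theta extreme).  All stochastic elements (initial oscillator phases,
#' Poisson background, per-trial noise draws) are governed by `seed`.
#'
#' @param network a [build_network()] result
#' @param params a [model_params()] object
#' @param protocol a [stimulus_spec()] or [burst_spec()] object
#' @param seed integer seed for this trial
#' @param record_trajectory return the per-step mean-efficacy trajectory
#' @param record_spikes return the spike raster
#' @return a list of class `trial_result` with `summary` (a one-row data
#'   frame) and, if requested, `trajectory` (time series of inter-subgroup
#'   mean efficacies, auditory-to-visual and visual-to-auditory, plus the
#'   measured-set mean for burst trials) and `spikes`
#' @export
run_trial <- function(network, params = model_params(), protocol, seed,
                      record_trajectory = FALSE, record_spikes = FALSE) {
  stopifnot(inherits(network, "lif_network"), inherits(params, "model_params"))
  with_seed(seed, run_trial_impl(network, params, protocol, seed,
                                 record_trajectory, record_spikes))
}

run_trial_impl <- function(network, params, protocol, seed,
                           record_trajectory, record_spikes) {
  np <- params$neuron
  pp <- params$plasticity
  osc <- params$oscillators
  variant <- pp$variant
  dt <- params$sim$dt_ms
  n <- network$n
  grp <- neuron_groups()
  hip <- c(grp$hip_vis, grp$hip_aud)
  is_nc <- network$region == "NC"
  is_hip <- !is_nc

  is_burst <- inherits(protocol, "burst_spec")
  rho <- network$rho

  if (is_burst) {
    # burst timing: pulses end 6 ms before each spike target; spike targets
    # centred on the first theta extreme leaving room for the baseline window
    period <- 1000 / osc$hip_theta_hz
    earliest <- protocol$baseline_window_ms + 150
    t_ext <- if (protocol$target_phase == "trough") {
      k <- ceiling((earliest - period / 2) / period)
      period / 2 + k * period            # theta = 0 at phase pi
    } else {
      k <- ceiling(earliest / period)
      k * period                          # theta = 1 at phase 0 (mod 2 pi)
    }
    nsp <- protocol$n_spikes_per_burst
    spacing <- 1000 / protocol$intra_burst_hz
    targets <- t_ext + spacing * (seq_len(nsp) - 1 - (nsp - 1) / 2)
    pulse_on <- targets - protocol$pulse_width_ms
    onset <- NA_real_
    total_ms <- max(targets) + protocol$post_gap_ms +
      protocol$post_window_ms + 10
    n_steps <- as.integer(round(total_ms / dt))
    tv <- (seq_len(n_steps) - 1) * dt
    stim_idx <- grp$hip_vis
    # per-neuron response latency (integer ms) desynchronizes the
    # stimulated population slightly, as in a physical preparation
    lat <- sample(0:protocol$pulse_jitter_ms, length(stim_idx),
                  replace = TRUE)
    pulse <- matrix(0, n_steps, length(stim_idx))
    for (u in seq_along(stim_idx)) for (i in seq_len(nsp))
      pulse[tv >= pulse_on[i] + lat[u] & tv < targets[i] + lat[u], u] <-
        protocol$pulse_amplitude
    vis_in <- aud_in <- numeric(n_steps)
    # mid-range intra-subgroup efficacy so both LTP and LTD have headroom
    same <- outer(network$subgroup, network$subgroup, "==")
    intra <- network$plastic & same
    rho[intra] <- protocol$rho_init_intra
    phi_h0 <- 0                           # deterministic phase for targeting
    f_hip <- osc$hip_theta_hz
    ec_offset <- pi
    theta_reset <- FALSE
    phase_vis <- 0
  } else {
    stopifnot(inherits(protocol, "stimulus_spec"))
    onset <- protocol$isi_ms
    total_ms <- onset + max(3000, protocol$duration_ms)
    n_steps <- as.integer(round(total_ms / dt)) + 1L  # closed end time
    tv <- (seq_len(n_steps) - 1) * dt
    tn <- draw_trial_noise(protocol)
    stim <- make_modulated_input(protocol, n_steps, dt, onset, tn)
    vis_in <- stim$visual
    aud_in <- stim$auditory
    pulse <- NULL
    stim_idx <- integer()
    phi_h0 <- stats::runif(1, 0, 2 * pi)
    f_hip <- if (variant == "stdp_only") osc$hip_theta_hz else tn$hip_hz
    ec_offset <- tn$ec_offset_rad
    theta_reset <- isTRUE(protocol$theta_reset) && variant != "stdp_only"
    phase_vis <- tn$phase_vis_rad
  }

  # oscillators (precomputed over the whole trial)
  phi_alpha <- stats::runif(1, 0, 2 * pi) + 2 * pi * osc$nc_alpha_hz * tv / 1000
  w_h <- 2 * pi * f_hip / 1000
  phi_hip <- phi_h0 + w_h * tv
  if (theta_reset) {
    post <- tv >= onset
    lag <- if (is.null(protocol$reset_lag_ms)) 0 else protocol$reset_lag_ms
    phi_hip[post] <- phase_vis + w_h * (tv[post] - onset - lag)
  }
  theta_vec <- theta_from_phase(phi_hip)
  hip_amp <- if (variant == "stdp_only") 0 else osc$hip_theta_amp
  i_ac_hip <- hip_amp * cos(phi_hip)
  i_ac_nc <- osc$nc_alpha_amp * cos(phi_alpha)
  gate_vec <- if (variant == "stdp_only") rep(1, n_steps) else
    ec_gate((1 - cos(phi_hip + ec_offset)) / 2, params$ec$w_ec)

  # background
  lambda <- ifelse(is_nc, params$background$nc_rate,
                   params$background$hip_rate) * dt / 1000
  w_bg <- ifelse(is_nc, params$background$nc_wmax, params$background$hip_wmax)

  # synapse bookkeeping
  wm <- network$w_max
  pre_pl <- lapply(seq_len(n), function(s) which(network$plastic[, s]))
  post_pl <- lapply(seq_len(n), function(s) which(network$plastic[s, ]))
  delay_steps <- as.integer(round(np$delay_ms / dt))
  src_queue <- vector("list", n_steps + delay_steps + 1L)

  # measured index sets
  msk <- function(rows, cols) {
    m <- matrix(FALSE, n, n); m[rows, cols] <- TRUE
    which(network$plastic & m)
  }
  idx_a2v <- msk(grp$hip_aud, grp$hip_vis)
  idx_v2a <- msk(grp$hip_vis, grp$hip_aud)
  if (!length(idx_a2v) || !length(idx_v2a))
    warning("degenerate network draw: an inter-subgroup plastic synapse set ",
            "is empty; its mean efficacy is reported as 0")
  idx_meas <- if (is_burst) {
    m <- matrix(FALSE, n, n); m[stim_idx, ] <- TRUE; m[, stim_idx] <- TRUE
    which(network$plastic & m)
  } else integer()

  # state
  state <- list(v = rep(np$E_L, n), refractory_until = rep(-Inf, n),
                last_spike = rep(0, n))
  z <- y <- numeric(n)    # two-state alpha-kernel filter per target neuron
  decay_s <- exp(-dt / np$tau_s)
  c1 <- dt * exp(1) / np$tau_s
  decay_tr <- exp(-dt / pp$tau_s)
  L <- D <- numeric(n)
  hist_t <- hist_th <- if (variant == "theta_only")
    lapply(seq_len(n), function(i) numeric()) else NULL

  traj_a2v <- traj_v2a <- numeric(n_steps)
  traj_meas <- if (is_burst) numeric(n_steps) else NULL
  sp_t <- numeric(0); sp_id <- integer(0)

  min_isi <- Inf
  prev_spike_t <- rep(-Inf, n)

  for (k in seq_len(n_steps)) {
    t <- tv[k]
    L <- L * decay_tr
    D <- D * decay_tr
    # advance the alpha-kernel filter, then inject this step's deliveries
    y <- decay_s * (y + c1 * z)
    z <- decay_s * z
    srcs <- src_queue[[k]]
    if (length(srcs)) {
      g <- gate_vec[k]
      for (s in srcs) {
        w <- wm[s, ] * rho[s, ]
        if (is_nc[s]) w[hip] <- w[hip] * g
        z <- z + w
      }
    }
    # background shot noise: each event is a one-step current pulse of
    # height w_max (subthreshold depolarizing bias plus jitter)
    i_bg <- w_bg * stats::rpois(n, lambda)
    i_syn <- params$syn_gain * y + i_bg
    i_adp <- numeric(n)
    dts <- t - state$last_spike[hip]
    i_adp[hip] <- np$A_ADP * (dts / np$tau_ADP) * exp(1 - dts / np$tau_ADP)
    i_dc <- numeric(n)
    if (is_burst) {
      i_dc[stim_idx] <- pulse[k, ]
    } else {
      i_dc[grp$nc_vis] <- vis_in[k]
      i_dc[grp$nc_aud] <- aud_in[k]
    }
    i_ac <- numeric(n)
    i_ac[is_nc] <- i_ac_nc[k]
    i_ac[hip] <- i_ac_hip[k]

    res <- lif_step(state, np, i_syn + i_ac + i_dc + i_adp, t, dt)
    state <- res$state
    spiked <- res$spiked

    if (length(spiked)) {
      hs <- spiked[is_hip[spiked]]
      if (length(hs)) {
        # all updates from pre-update rho and pre-step traces (same-ms spikes
        # excluded); deltas accumulated so simultaneous LTP/LTD both apply
        rho_new <- rho
        thp_now <- 2 * theta_vec[k] - 1
        for (s in hs) {
          ip <- pre_pl[[s]]
          jp <- post_pl[[s]]
          if (variant == "theta_only") {
            # the eliciting spike's own phase selects the branch, applied
            # bidirectionally (nonspecific pure phase-dependent learning):
            # inhibitory phase -> potentiate all synapses with recently
            # active partners, excitatory phase -> depress them
            ltp <- thp_now <= 0
            fi <- theta_only_sums(ip, t, hist_t, hist_th, pp, ltp)
            fj <- theta_only_sums(jp, t, hist_t, hist_th, pp, ltp)
            if (ltp) {
              if (length(ip))
                rho_new[cbind(ip, s)] <- rho_new[cbind(ip, s)] +
                  pp$gamma_p * (1 - rho[cbind(ip, s)]) * pmax(0, fi - pp$eps_ltp)
              if (length(jp))
                rho_new[cbind(s, jp)] <- rho_new[cbind(s, jp)] +
                  pp$gamma_p * (1 - rho[cbind(s, jp)]) * pmax(0, fj - pp$eps_ltp)
            } else {
              if (length(ip))
                rho_new[cbind(ip, s)] <- rho_new[cbind(ip, s)] -
                  pp$gamma_d * rho[cbind(ip, s)] * pmax(0, fi - pp$eps_ltd)
              if (length(jp))
                rho_new[cbind(s, jp)] <- rho_new[cbind(s, jp)] -
                  pp$gamma_d * rho[cbind(s, jp)] * pmax(0, fj - pp$eps_ltd)
            }
          } else {
            if (length(ip))
              rho_new[cbind(ip, s)] <- rho_new[cbind(ip, s)] +
                pp$gamma_p * (1 - rho[cbind(ip, s)]) * pmax(0, L[ip] - pp$eps_ltp)
            if (length(jp))
              rho_new[cbind(s, jp)] <- rho_new[cbind(s, jp)] -
                pp$gamma_d * rho[cbind(s, jp)] * pmax(0, D[jp] - pp$eps_ltd)
          }
        }
        if (any(!is.finite(rho_new)))
          stop("non-finite efficacy at t = ", t, " ms (invariant breach)")
        rho <- pmin(pmax(rho_new, 0), 1)
      }
      th <- theta_vec[k]
      if (variant == "full") {
        L[spiked] <- L[spiked] + pp$A_plus * (1 - th)
        D[spiked] <- D[spiked] + pp$A_minus * th
      } else if (variant == "stdp_only") {
        L[spiked] <- L[spiked] + pp$A_plus
        D[spiked] <- D[spiked] + pp$A_minus
      } else {
        thp <- 2 * th - 1
        for (s in spiked[is_hip[spiked]]) {
          keep <- hist_t[[s]] >= t - pp$trace_window_ms
          hist_t[[s]] <- c(hist_t[[s]][keep], t)
          hist_th[[s]] <- c(hist_th[[s]][keep], thp)
        }
      }
      kk <- k + delay_steps
      src_queue[[kk]] <- c(src_queue[[kk]], spiked)
      min_isi <- min(min_isi, t - prev_spike_t[spiked])
      prev_spike_t[spiked] <- t
      if (record_spikes) {
        sp_t <- c(sp_t, rep(t, length(spiked)))
        sp_id <- c(sp_id, spiked)
      }
    }
    traj_a2v[k] <- if (length(idx_a2v)) sum(rho[idx_a2v]) / length(idx_a2v) else 0
    traj_v2a[k] <- if (length(idx_v2a)) sum(rho[idx_v2a]) / length(idx_v2a) else 0
    if (is_burst)
      traj_meas[k] <- if (length(idx_meas))
        sum(rho[idx_meas]) / length(idx_meas) else 0
  }

  win_mean <- function(x, from, to) mean(x[tv >= from & tv <= to])
  if (is_burst) {
    t_first_pulse <- min(pulse_on)
    baseline <- win_mean(traj_meas, t_first_pulse - protocol$baseline_window_ms,
                         t_first_pulse)
    post0 <- max(targets) + protocol$post_gap_ms
    post <- win_mean(traj_meas, post0, post0 + protocol$post_window_ms)
    summary <- data.frame(seed = seed,
                          n_spikes = protocol$n_spikes_per_burst,
                          target_phase = protocol$target_phase,
                          baseline_rho = baseline, post_rho = post,
                          pct_change = percent_baseline_change(baseline, post),
                          min_isi_ms = min_isi)
  } else {
    summary <- data.frame(seed = seed,
                          modulation_hz = protocol$modulation_hz,
                          phase_offset_deg = protocol$phase_offset_deg,
                          variant = variant,
                          rho_a2v = win_mean(traj_a2v, onset + 2750, onset + 3000),
                          rho_v2a = win_mean(traj_v2a, onset + 2750, onset + 3000),
                          baseline_a2v = win_mean(traj_a2v, onset - 1750, onset),
                          min_isi_ms = min_isi)
  }

  out <- list(summary = summary, min_isi_ms = min_isi, onset_ms = onset,
              dt_ms = dt)
  if (record_trajectory) {
    out$trajectory <- data.frame(time_ms = tv, rho_a2v = traj_a2v,
                                 rho_v2a = traj_v2a)
    if (is_burst) out$trajectory$rho_measured <- traj_meas
  }
  if (record_spikes)
    out$spikes <- data.frame(time_ms = sp_t, neuron = sp_id,
                             region = network$region[sp_id],
                             subgroup = network$subgroup[sp_id])
  class(out) <- "trial_result"
  out
}

#' Run one condition of the memory paradigm
#'
#' Simulates `n_trials` independent trials of a [stimulus_spec()] condition.
#' Each trial gets a fresh network draw and fresh Poisson/noise streams from
#' seeds derived deterministically from `master_seed` via
#' [derive_trial_seed()], so any single trial can be reproduced in isolation.
#'
#' @param spec a [stimulus_spec()] object
#' @param params a [model_params()] object
#' @param n_trials number of trials
#' @param master_seed master seed for the condition grid
#' @param condition_id integer condition index inside the grid (distinct per
#'   condition)
#' @return data frame with one row per trial (readout-window and baseline
#'   mean efficacies in both directions)
#' @export
run_memory_condition <- function(spec, params = model_params(), n_trials = 32,
                                 master_seed = 1, condition_id = 0) {
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    net_seed <- derive_trial_seed(master_seed, condition_id * 2L, i)
    trial_seed <- derive_trial_seed(master_seed, condition_id * 2L + 1L, i)
    net <- build_network(params$connectivity, seed = net_seed)
    res <- run_trial(net, params, spec, seed = trial_seed)
    res$summary$trial <- i
    rows[[i]] <- res$summary
  }
  do.call(rbind, rows)
}

#' Run the burst-stimulation protocol
#'
#' Simulates `n_trials` trials of a [burst_spec()] condition, each with a
#' fresh network draw, and reports the per-trial percentage synaptic change
#' relative to the baseline window.
#'
#' @param spec a [burst_spec()] object
#' @param params a [model_params()] object
#' @param master_seed master seed
#' @param condition_id integer condition index
#' @return data frame with one row per trial
#' @export
run_burst_protocol <- function(spec, params = model_params(),
                               master_seed = 1, condition_id = 0) {
  rows <- vector("list", spec$n_trials)
  for (i in seq_len(spec$n_trials)) {
    net_seed <- derive_trial_seed(master_seed, condition_id * 2L, i)
    trial_seed <- derive_trial_seed(master_seed, condition_id * 2L + 1L, i)
    net <- build_network(params$connectivity, seed = net_seed)
    res <- run_trial(net, params, spec, seed = trial_seed)
    res$summary$trial <- i
    rows[[i]] <- res$summary
  }
  do.call(rbind, rows)
}

#' Run a grid of memory-paradigm conditions
#'
#' Convenience runner over frequency x phase-offset conditions.  Conditions
#' are assigned consecutive integer ids in row order, making every trial
#' individually reproducible from the master seed.
#'
#' @param conditions data frame with columns `freq_hz` (NA for no-flicker)
#'   and `offset_deg`
#' @param params a [model_params()] object
#' @param n_trials trials per condition
#' @param master_seed master seed
#' @param noise a [noise_spec()] object applied to every condition
#' @return data frame of per-trial summaries with a `condition` column
#' @export
run_memory_grid <- function(conditions, params = model_params(), n_trials = 32,
                            master_seed = 1, noise = noise_spec()) {
  out <- vector("list", nrow(conditions))
  for (ci in seq_len(nrow(conditions))) {
    spec <- stimulus_spec(
      modulation_hz = conditions$freq_hz[ci],
      phase_offset_deg = conditions$offset_deg[ci],
      amplitude_range = if (params$plasticity$variant == "stdp_only")
        "bipolar" else "unipolar",
      amplitude = if (params$plasticity$variant == "stdp_only") 1.75 else NULL,
      noise = noise)
    df <- run_memory_condition(spec, params, n_trials, master_seed,
                               condition_id = ci)
    df$condition <- ci
    out[[ci]] <- df
  }
  do.call(rbind, out)
}
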
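# Theta-gated STDP: potential-plasticity traces for LTP and LTD weighted by
# opposing theta phases, and thresholded graded weight updates.
#
# These reference implementations re-sum the full spike history at every
# call.  The simulation engine keeps equivalent incremental exponential
# traces (one multiply-add per step); the two paths are held to agree to
# 1e-9 by the test suite.

#' Create an empty spike-history set
#'
#' Per-neuron ordered records of `(spike time, theta at spike time)`, the
#' substrate of the plasticity trace sums.
#'
#' @param n number of neurons
#' @return list of class `spike_history`; one `list(t, theta)` per neuron
#' @export
spike_history <- function(n) {
  structure(lapply(seq_len(n), function(i) list(t = numeric(), theta = numeric())),
            class = "spike_history")
}

#' Record a spike in a history set
#'
#' Appends `(t, theta_now)` to the neuron's history and prunes entries older
#' than `trace_window` relative to `t`.  Pruning changes any later trace
#' value by at most `A * n_pruned * exp(-window / tau_s)`.
#'
#' @param histories a [spike_history()] set
#' @param neuron neuron index
#' @param t spike time (ms); must not precede existing entries
#' @param theta_now normalized theta in `[0, 1]` at the spike time
#' @param trace_window retention window (ms)
#' @return the updated history set
#' @export
record_spike <- function(histories, neuron, t, theta_now, trace_window = 200) {
  h <- histories[[neuron]]
  if (length(h$t) && t < h$t[length(h$t)])
    stop("spike time regression for neuron ", neuron, ": t = ", t,
         " < last recorded ", h$t[length(h$t)])
  if (theta_now < 0 || theta_now > 1) stop("'theta_now' must lie in [0, 1]")
  keep <- h$t >= t - trace_window
  histories[[neuron]] <- list(t = c(h$t[keep], t),
                              theta = c(h$theta[keep], theta_now))
  histories
}

# shared guts of the two trace sums; sign selects the theta weighting
trace_sum <- function(t, times, thetas, amp, params, weight_fun) {
  if (length(times) == 0) return(0)
  if (any(times >= t)) stop("all history times must be strictly before t")
  win <- if (params$variant == "theta_only") params$theta_only_window_ms else
    params$trace_window_ms
  keep <- times >= t - win
  times <- times[keep]; thetas <- thetas[keep]
  if (!length(times)) return(0)
  w <- weight_fun(thetas)
  kern <- switch(params$variant,
                 full = exp((times - t) / params$tau_s),
                 stdp_only = exp((times - t) / params$tau_s),
                 theta_only = rep(1, length(times)))
  sum(amp * w * kern)
}

#' Potential LTP trace
#'
#' Potential potentiation at a postsynaptic connection evaluated at the time
#' `t` of an eliciting spike: the sum over the presynaptic partner's historic
#' spikes (strictly before `t`) of
#' `A_plus * (1 - theta(t_i)) * exp((t_i - t) / tau_s)`.
#' Under `variant = "theta_only"` the exponential is dropped and theta is
#' re-ranged to `[-1, 1]` (summand `A_plus * (1 - (2 theta - 1))`); under
#' `variant = "stdp_only"` the phase factor is replaced by 1.
#'
#' @param t evaluation time (ms)
#' @param presyn_history `list(t, theta)` of the presynaptic neuron's spikes,
#'   all strictly before `t`
#' @param params a [plasticity_params()] object
#' @return the trace value (non-negative)
#' @export
potential_ltp <- function(t, presyn_history, params = plasticity_params()) {
  weight_fun <- switch(params$variant,
                       full = function(th) 1 - th,
                       theta_only = function(th) 1 - (2 * th - 1),
                       stdp_only = function(th) rep(1, length(th)))
  trace_sum(t, presyn_history$t, presyn_history$theta, params$A_plus,
            params, weight_fun)
}

#' Potential LTD trace
#'
#' Potential depression at a presynaptic connection evaluated at the time `t`
#' of an eliciting spike: the sum over the postsynaptic partner's historic
#' spikes of `A_minus * theta(t_j) * exp((t_j - t) / tau_s)`.  Variant
#' handling mirrors [potential_ltp()] with `theta` in place of `1 - theta`
#' (re-ranged theta for `"theta_only"`, factor 1 for `"stdp_only"`).
#'
#' @inheritParams potential_ltp
#' @param postsyn_history `list(t, theta)` of the postsynaptic neuron's
#'   spikes, all strictly before `t`
#' @return the trace value (may be negative under `"theta_only"`)
#' @export
potential_ltd <- function(t, postsyn_history, params = plasticity_params()) {
  weight_fun <- switch(params$variant,
                       full = function(th) th,
                       theta_only = function(th) 2 * th - 1,
                       stdp_only = function(th) rep(1, length(th)))
  trace_sum(t, postsyn_history$t, postsyn_history$theta, params$A_minus,
            params, weight_fun)
}

#' Incremental trace evaluation on the simulation time grid
#'
#' The simulation engine keeps each neuron's potential-plasticity traces
#' incrementally: per timestep the trace decays by `exp(-dt / tau_s)` and at
#' each of the neuron's spikes it is incremented by the phase-weighted
#' amplitude (`A_plus * (1 - theta)` for the LTP trace, `A_minus * theta`
#' for the LTD trace).  This function reproduces that scheme for a given
#' history so it can be checked against the brute-force re-summation of
#' [potential_ltp()] / [potential_ltd()]; for spike times on the `dt` grid
#' the two agree to floating-point accuracy.
#'
#' @param history `list(t, theta)` spike history of one neuron (times on
#'   the `dt` grid, strictly below `t_eval`)
#' @param t_eval evaluation time (ms, on the grid)
#' @param params a [plasticity_params()] object (variant `"full"`)
#' @param kind `"ltp"` or `"ltd"`
#' @param dt timestep (ms)
#' @return the trace value at `t_eval`
#' @export
incremental_trace <- function(history, t_eval, params = plasticity_params(),
                              kind = c("ltp", "ltd"), dt = 1) {
  kind <- match.arg(kind)
  decay <- exp(-dt / params$tau_s)
  amp <- if (kind == "ltp") params$A_plus else params$A_minus
  w <- if (kind == "ltp") 1 - history$theta else history$theta
  tr <- 0
  tcur <- if (length(history$t)) min(history$t) else t_eval
  for (i in seq_along(history$t)) {
    steps <- round((history$t[i] - tcur) / dt)
    tr <- tr * decay^steps + amp * w[i]
    tcur <- history$t[i]
  }
  tr * decay^round((t_eval - tcur) / dt)
}

#' Thresholded graded weight update
#'
#' The efficacy increments applied when potential plasticity exceeds its
#' threshold: `gamma_p * (1 - rho) * max(0, F_ltp - eps_ltp)` for
#' potentiation and `-gamma_d * rho * max(0, F_ltd - eps_ltd)` for
#' depression.  The soft bounds `(1 - rho)` and `rho` keep efficacy inside
#' `[0, 1]` for any positive finite trace excess at millisecond-discrete
#' updates.
#'
#' @param rho current efficacy in `[0, 1]`, vectorised
#' @param trace potential-plasticity trace value, vectorised
#' @param params a [plasticity_params()] object
#' @param kind `"ltp"` or `"ltd"`
#' @return the efficacy increment (same sign convention as above)
#' @export
plasticity_delta <- function(rho, trace, params = plasticity_params(),
                             kind = c("ltp", "ltd")) {
  kind <- match.arg(kind)
  if (kind == "ltp") {
    params$gamma_p * (1 - rho) * pmax(0, trace - params$eps_ltp)
  } else {
    -params$gamma_d * rho * pmax(0, trace - params$eps_ltd)
  }
}

#' Apply plasticity for one spike event
#'
#' When a neuron spikes at time `t`, every plastic postsynaptic connection
#' onto it (presynaptic partner `i`) is potentiated by
#' `gamma_p (1 - rho_i) max(0, F_LTP(t, i) - eps_ltp)` and every plastic
#' presynaptic connection from it (postsynaptic partner `j`) is depressed by
#' `gamma_d rho_j max(0, F_LTD(t, j) - eps_ltd)`.  All updates are computed
#' from the pre-update efficacies (the two differentials are simultaneous)
#' and the spiking neuron's own same-millisecond spike must not yet be in the
#' partner histories.
#'
#' Under `variant = "theta_only"` the eliciting spike's own phase selects
#' the branch, applied bidirectionally and nonspecifically: a spike in the
#' inhibitory half of the theta cycle (`theta_now <= 0.5`) potentiates all
#' the neuron's plastic synapses whose partner was recently active, a spike
#' in the excitatory half depresses them.
#'
#' @param spiking_neuron index of the neuron that spiked at exactly time `t`
#' @param t spike time (ms)
#' @param network a [build_network()] result (its `rho` matrix is updated)
#' @param histories a [spike_history()] set with all spikes strictly before
#'   `t`
#' @param params a [plasticity_params()] object
#' @param theta_now normalized theta at the spike time (used only by the
#'   `"theta_only"` variant's branch selection)
#' @return the network with updated `rho`
#' @export
apply_plasticity_at_spike <- function(spiking_neuron, t, network, histories,
                                      params = plasticity_params(),
                                      theta_now = 0) {
  s <- spiking_neuron
  rho <- network$rho
  pre <- which(network$plastic[, s])   # synapses i -> s
  post <- which(network$plastic[s, ])  # synapses s -> j
  if (params$variant == "theta_only") {
    ltp <- theta_now <= 0.5
    pot <- function(h) if (ltp) potential_ltp(t, h, params) else
      potential_ltd(t, h, params)
    kind <- if (ltp) "ltp" else "ltd"
    if (length(pre)) {
      f <- vapply(pre, function(i) pot(histories[[i]]), 0)
      rho[cbind(pre, s)] <- rho[cbind(pre, s)] +
        plasticity_delta(rho[cbind(pre, s)], f, params, kind)
    }
    if (length(post)) {
      f <- vapply(post, function(j) pot(histories[[j]]), 0)
      rho[cbind(s, post)] <- rho[cbind(s, post)] +
        plasticity_delta(rho[cbind(s, post)], f, params, kind)
    }
  } else {
    if (length(pre)) {
      f <- vapply(pre, function(i) potential_ltp(t, histories[[i]], params), 0)
      rho[cbind(pre, s)] <- rho[cbind(pre, s)] +
        plasticity_delta(rho[cbind(pre, s)], f, params, "ltp")
    }
    if (length(post)) {
      f <- vapply(post, function(j) potential_ltd(t, histories[[j]], params), 0)
      rho[cbind(s, post)] <- rho[cbind(s, post)] +
        plasticity_delta(rho[cbind(s, post)], f, params, "ltd")
    }
  }
  if (any(!is.finite(rho)))
    stop("non-finite efficacy after update at t = ", t, " (invariant breach)")
  network$rho <- pmin(pmax(rho, 0), 1)
  network
}
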
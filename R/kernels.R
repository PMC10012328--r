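# Single-timestep neuron and current dynamics.

#' Advance leaky integrate-and-fire membranes by one timestep
#'
#' Forward-Euler update of the membrane equation
#' `C_m dV/dt = g_m (E_L - V) + I` for a vector of neurons.  Neurons inside
#' their refractory period are clamped to the resting potential.  Neurons at
#' or above threshold at the end of the step are reported as spiking, their
#' voltage is reset to `E_L`, the refractory clock is set to
#' `t + refractory_ms` and the last-spike time (which also resets the ADP
#' ramp) is set to `t`.
#'
#' @param state list with numeric vectors `v` (membrane potential, mV),
#'   `refractory_until` (ms) and `last_spike` (ms), one entry per neuron
#' @param params a [neuron_params()] object
#' @param I_total total input current per neuron at time `t` (sum of
#'   synaptic, oscillatory, direct, background and ADP currents)
#' @param t current time (ms)
#' @param dt timestep (ms), must be positive
#' @return list with the updated `state` and `spiked`, the integer indices of
#'   neurons that fired during this step
#' @export
lif_step <- function(state, params, I_total, t, dt) {
  if (!(dt > 0)) stop("'dt' must be positive")
  v <- state$v
  free <- t >= state$refractory_until
  v[free] <- v[free] + (dt / params$C_m) *
    (params$g_m * (params$E_L - v[free]) + I_total[free])
  v[!free] <- params$E_L
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v))[1]
    stop("non-finite membrane potential for neuron ", bad, " at t = ", t, " ms")
  }
  spiked <- which(free & v >= params$V_th)
  if (length(spiked)) {
    v[spiked] <- params$E_L
    state$refractory_until[spiked] <- t + params$refractory_ms
    state$last_spike[spiked] <- t
  }
  state$v <- v
  list(state = state, spiked = spiked)
}

#' EPSP alpha-function kernel
#'
#' Synaptic response elicited `delta_t` ms after a delivered spike event:
#' `W_max * rho * (e * delta_t / tau_s) * exp(-delta_t / tau_s)`.
#' The kernel is zero at the origin and attains its maximum, exactly
#' `W_max * rho`, at `delta_t = tau_s`.  A neuron's synaptic current is the
#' superposition of these kernels over all delivered events, scaled by the
#' global synaptic gain (see [model_params()]).
#'
#' @param delta_t time since event delivery (ms); non-negative, vectorised
#' @param rho synaptic efficacy in `[0, 1]`
#' @param w_max maximal synaptic weight
#' @param tau_s kernel time constant (ms)
#' @return current (model units), same length as `delta_t`
#' @export
epsp_kernel <- function(delta_t, rho, w_max, tau_s = 20) {
  if (any(delta_t < 0)) stop("'delta_t' must be non-negative")
  if (any(rho < 0 | rho > 1)) stop("'rho' must lie in [0, 1]")
  w_max * rho * (exp(1) * delta_t / tau_s) * exp(-delta_t / tau_s)
}

#' Afterdepolarization ramp current
#'
#' Slowly ramping depolarizing current
#' `A_ADP * (delta_t / tau_ADP) * exp(1 - delta_t / tau_ADP)` re-started by
#' every spike (the caller resets `delta_t` via the last-spike time).  It
#' peaks at exactly `A_ADP` when `delta_t = tau_ADP`, biasing hippocampal
#' neurons toward theta-periodic firing.
#'
#' @param delta_t time since the neuron's last spike (ms); non-negative,
#'   vectorised
#' @param a_adp ramp peak current
#' @param tau_adp ramp time constant (ms)
#' @return current (model units)
#' @export
adp_current <- function(delta_t, a_adp = 0.2, tau_adp = 250) {
  if (any(delta_t < 0)) stop("'delta_t' must be non-negative")
  a_adp * (delta_t / tau_adp) * exp(1 - delta_t / tau_adp)
}

#' Draw Poisson background event counts
#'
#' Background synaptic bombardment is modelled as an independent Poisson
#' spike train per neuron with the given rate; each step the number of events
#' is Poisson with mean `rate * dt / 1000`.  Background events carry no
#' presynaptic identity and take no part in plasticity; each event injects a
#' one-timestep current pulse of height `w_max` (charge `w_max * dt`),
#' providing a subthreshold depolarizing bias plus shot noise.
#'
#' @param rate_hz event rate per neuron (spikes/s), non-negative
#' @param dt timestep (ms)
#' @param n number of neurons (independent draws)
#' @return integer vector of event counts, length `n`
#' @export
poisson_background <- function(rate_hz, dt = 1, n = 1) {
  if (rate_hz < 0) stop("'rate_hz' must be non-negative")
  stats::rpois(n, rate_hz * dt / 1000)
}

#' Entorhinal gate on neocortex-to-hippocampus transmission
#'
#' Multiplicative gain applied to the EPSP amplitude of NC-to-hippocampus
#' spike events, representing an entorhinal relay whose theta is
#' phase-reversed relative to hippocampal theta:
#' `((1 - theta_hip) + (1 - w_ec)) / (1 + (1 - w_ec))`.
#' The gain is a strictly decreasing affine function of `theta_hip`, equal to
#' 1 at the hippocampal theta trough (`theta_hip = 0`, the LTP-permissive
#' phase) and minimal at the peak.
#'
#' @param theta_hip normalized hippocampal theta in `[0, 1]`, vectorised
#' @param w_ec gate weight in `[0, 1]`
#' @return gain in `(0, 1]`
#' @export
ec_gate <- function(theta_hip, w_ec = 0.3) {
  if (any(theta_hip < 0 | theta_hip > 1)) stop("'theta_hip' must lie in [0, 1]")
  if (w_ec < 0 || w_ec > 1) stop("'w_ec' must lie in [0, 1]")
  ((1 - theta_hip) + (1 - w_ec)) / (1 + (1 - w_ec))
}

#' Normalized theta from an oscillator phase
#'
#' The shared phase convention: with phase `phi`, the oscillatory current is
#' `amplitude * cos(phi)` and the normalized theta is
#' `theta = (1 + cos(phi)) / 2`, so `theta = 1` at the depolarizing
#' (excitatory, LTD-inducing) extreme and `theta = 0` at the hyperpolarizing
#' (inhibitory, LTP-inducing) extreme.
#'
#' @param phase oscillator phase (radians), vectorised
#' @return theta in `[0, 1]`
#' @export
theta_from_phase <- function(phase) (1 + cos(phase)) / 2
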
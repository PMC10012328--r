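# Parameter containers.  All currents are in dimensionless model units, all
# voltages in mV, all times in ms; every printed amplitude from the source
# experiments is used at its printed numeric value.

#' Neuron physiology parameters
#'
#' Leaky integrate-and-fire membrane constants shared by all neurons, plus the
#' afterdepolarization (ADP) constants used by hippocampal neurons.  The
#' defaults are the model's reference parameter set: resting potential
#' -70 mV, threshold -55 mV, leak conductance 0.03, 2 ms refractory period,
#' 2 ms synaptic delay, 20 ms EPSP time constant, and an ADP ramp of peak 0.2
#' with a 250 ms time constant.  Membrane capacitance is 1 model unit so that
#' currents and dV/dt are numerically interchangeable.
#'
#' @param E_L resting potential (mV)
#' @param V_th spike threshold (mV); must exceed `E_L`
#' @param g_m leak conductance (model units)
#' @param C_m membrane capacitance (model units)
#' @param refractory_ms absolute refractory period (ms)
#' @param delay_ms synaptic transmission delay applied to every spike event (ms)
#' @param tau_s EPSP alpha-function time constant (ms)
#' @param A_ADP ADP ramp peak current (model units)
#' @param tau_ADP ADP ramp time constant (ms)
#' @return a list of class `neuron_params`
#' @export
neuron_params <- function(E_L = -70, V_th = -55, g_m = 0.03, C_m = 1,
                          refractory_ms = 2, delay_ms = 2, tau_s = 20,
                          A_ADP = 0.2, tau_ADP = 250) {
  if (!(V_th > E_L)) stop("'V_th' must be greater than 'E_L'")
  stopifnot_scalar(g_m, "g_m", 0, strict_lower = TRUE)
  stopifnot_scalar(C_m, "C_m", 0, strict_lower = TRUE)
  stopifnot_scalar(refractory_ms, "refractory_ms", 0, strict_lower = TRUE)
  stopifnot_scalar(delay_ms, "delay_ms", 0, strict_lower = TRUE)
  stopifnot_scalar(tau_s, "tau_s", 0, strict_lower = TRUE)
  stopifnot_scalar(tau_ADP, "tau_ADP", 0, strict_lower = TRUE)
  structure(list(E_L = E_L, V_th = V_th, g_m = g_m, C_m = C_m,
                 refractory_ms = refractory_ms, delay_ms = delay_ms,
                 tau_s = tau_s, A_ADP = A_ADP, tau_ADP = tau_ADP),
            class = "neuron_params")
}

#' Plasticity rule parameters
#'
#' Parameters of the theta-gated STDP rule: potentiation/depression trace
#' weights `A_plus`/`A_minus`, trace decay constant `tau_s`, learning rates
#' `gamma_p` (potentiation, twice the depression rate `gamma_d` by default),
#' and plasticity thresholds `eps_ltp`/`eps_ltd` that nullify singlet and
#' doublet spike pairings.  `variant` selects the full rule or one of the two
#' lesioned variants: `"theta_only"` (phase-dependent learning without the
#' STDP exponential) and `"stdp_only"` (STDP without theta modulation).
#'
#' @param A_plus LTP trace weight per presynaptic spike
#' @param A_minus LTD trace weight per postsynaptic spike
#' @param tau_s trace decay time constant (ms)
#' @param gamma_p potentiation rate constant
#' @param gamma_d depression rate constant
#' @param eps_ltp potentiation threshold
#' @param eps_ltd depression threshold
#' @param variant one of `"full"`, `"theta_only"`, `"stdp_only"`
#' @param trace_window_ms spike-history retention window (ms); spikes older
#'   than this are pruned, bounding the trace error by `exp(-window/tau_s)`
#'   per spike
#' @param theta_only_window_ms partner-activity integration window of the
#'   `"theta_only"` variant (ms).  Without the STDP exponential, the variant
#'   integrates partner spikes over the current theta half-cycle
#'   (default 100 ms, just under half a 4 Hz cycle), so opposite-phase
#'   volleys fall outside the window
#' @param heterosynaptic_enabled reserved flag for heterosynaptic LTD on
#'   non-stimulated pathways; not part of the supported model surface and must
#'   remain `FALSE`
#' @return a list of class `plasticity_params`
#' @export
plasticity_params <- function(A_plus = 0.65, A_minus = 0.65, tau_s = 20,
                              gamma_p = 1.5, gamma_d = 0.75,
                              eps_ltp = 1, eps_ltd = 1,
                              variant = c("full", "theta_only", "stdp_only"),
                              trace_window_ms = 200,
                              theta_only_window_ms = 100,
                              heterosynaptic_enabled = FALSE) {
  variant <- match.arg(variant)
  stopifnot_scalar(A_plus, "A_plus", 0)
  stopifnot_scalar(A_minus, "A_minus", 0)
  stopifnot_scalar(tau_s, "tau_s", 0, strict_lower = TRUE)
  stopifnot_scalar(gamma_p, "gamma_p", 0)
  stopifnot_scalar(gamma_d, "gamma_d", 0)
  stopifnot_scalar(trace_window_ms, "trace_window_ms", 0, strict_lower = TRUE)
  if (isTRUE(heterosynaptic_enabled))
    stop("heterosynaptic LTD is not implemented; 'heterosynaptic_enabled' must be FALSE")
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_s = tau_s,
                 gamma_p = gamma_p, gamma_d = gamma_d,
                 eps_ltp = eps_ltp, eps_ltd = eps_ltd, variant = variant,
                 trace_window_ms = trace_window_ms,
                 theta_only_window_ms = theta_only_window_ms,
                 heterosynaptic_enabled = FALSE),
            class = "plasticity_params")
}

#' Network connectivity specification
#'
#' Connection probabilities and maximal weights of the two-region
#' architecture: 20 neocortical (NC) neurons in visual/auditory subgroups of
#' 10, and 10 hippocampal neurons in visual/auditory subgroups of 5.
#' NC neurons connect within subgroup with probability 0.25 (W_max 0.3,
#' fixed); NC and hippocampal subgroups of matching modality are fully
#' bipartitely connected (0.35 down, 0.08 up, fixed); hippocampal directed
#' pairs exist with probability 0.5 (W_max 0.65) and are the only plastic
#' synapses, starting at full efficacy within subgroup and zero efficacy
#' between subgroups.
#'
#' @param nc_intra_p probability of an NC intra-subgroup directed connection
#' @param nc_intra_wmax maximal weight of NC intra-subgroup synapses
#' @param nc_to_hip_wmax maximal weight of NC to hippocampus synapses
#' @param hip_to_nc_wmax maximal weight of hippocampus to NC synapses
#' @param hip_p probability of a hippocampal directed connection
#' @param hip_wmax maximal weight of hippocampal synapses
#' @return a list of class `connectivity_spec`
#' @export
connectivity_spec <- function(nc_intra_p = 0.25, nc_intra_wmax = 0.3,
                              nc_to_hip_wmax = 0.35, hip_to_nc_wmax = 0.08,
                              hip_p = 0.5, hip_wmax = 0.65) {
  stopifnot_scalar(nc_intra_p, "nc_intra_p", 0, 1)
  stopifnot_scalar(hip_p, "hip_p", 0, 1)
  for (w in c(nc_intra_wmax = nc_intra_wmax, nc_to_hip_wmax = nc_to_hip_wmax,
              hip_to_nc_wmax = hip_to_nc_wmax, hip_wmax = hip_wmax))
    stopifnot_scalar(w, "W_max", 0)
  structure(list(nc_intra_p = nc_intra_p, nc_intra_wmax = nc_intra_wmax,
                 nc_to_hip_wmax = nc_to_hip_wmax,
                 hip_to_nc_wmax = hip_to_nc_wmax,
                 hip_p = hip_p, hip_wmax = hip_wmax),
            class = "connectivity_spec")
}

#' Full model parameter set
#'
#' Bundles all tunable parameters of the model with their reference defaults:
#' neuron physiology, the plasticity rule, connectivity, Poisson background
#' drive (4000 spikes/s at weight 0.023 onto NC neurons, 1500 spikes/s at
#' 0.015 onto hippocampal neurons), oscillatory drive (10 Hz alpha at
#' amplitude 0.1 into NC, 4 Hz theta at amplitude 0.25 into the hippocampus)
#' and the entorhinal gate weight (0.3).
#'
#' @param neuron a [neuron_params()] object
#' @param plasticity a [plasticity_params()] object
#' @param connectivity a [connectivity_spec()] object
#' @param nc_rate,nc_wmax NC background Poisson rate (spikes/s) and per-event
#'   weight
#' @param hip_rate,hip_wmax hippocampal background Poisson rate and weight
#' @param nc_alpha_hz,nc_alpha_amp NC alpha oscillation frequency (Hz) and
#'   current amplitude
#' @param hip_theta_hz,hip_theta_amp hippocampal theta frequency and amplitude
#' @param w_ec entorhinal gate weight in `[0, 1]`
#' @param syn_gain dimensionless gain converting summed spike-event EPSP
#'   kernels into membrane current.  The default 0.08 places the drive of a
#'   full neocortical volley onto a hippocampal neuron at about twice
#'   rheobase, so that the entorhinal gate and the theta current decide
#'   firing phase (see the methods vignette)
#' @param dt_ms integration timestep (ms)
#' @return a list of class `model_params`
#' @export
model_params <- function(neuron = neuron_params(),
                         plasticity = plasticity_params(),
                         connectivity = connectivity_spec(),
                         nc_rate = 4000, nc_wmax = 0.023,
                         hip_rate = 1500, hip_wmax = 0.015,
                         nc_alpha_hz = 10, nc_alpha_amp = 0.1,
                         hip_theta_hz = 4, hip_theta_amp = 0.25,
                         w_ec = 0.3, syn_gain = 0.08, dt_ms = 1) {
  stopifnot(inherits(neuron, "neuron_params"),
            inherits(plasticity, "plasticity_params"),
            inherits(connectivity, "connectivity_spec"))
  stopifnot_scalar(nc_rate, "nc_rate", 0)
  stopifnot_scalar(hip_rate, "hip_rate", 0)
  stopifnot_scalar(w_ec, "w_ec", 0, 1)
  stopifnot_scalar(syn_gain, "syn_gain", 0, strict_lower = TRUE)
  stopifnot_scalar(dt_ms, "dt_ms", 0, strict_lower = TRUE)
  structure(list(neuron = neuron, plasticity = plasticity,
                 connectivity = connectivity,
                 background = list(nc_rate = nc_rate, nc_wmax = nc_wmax,
                                   hip_rate = hip_rate, hip_wmax = hip_wmax),
                 oscillators = list(nc_alpha_hz = nc_alpha_hz,
                                    nc_alpha_amp = nc_alpha_amp,
                                    hip_theta_hz = hip_theta_hz,
                                    hip_theta_amp = hip_theta_amp),
                 ec = list(w_ec = w_ec),
                 syn_gain = syn_gain,
                 sim = list(dt_ms = dt_ms)),
            class = "model_params")
}
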
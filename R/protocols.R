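# Trial protocols: entrainment stimuli, the no-flicker control and the
# burst-stimulation replication, plus the input-strength scaling rules.

#' Canonical stimulus modulation frequencies (Hz)
#'
#' The six modulation frequencies of the entrainment paradigm, chosen to
#' avoid harmonic relationships with the 4 Hz hippocampal theta.
#'
#' @return named numeric vector: delta, theta, alpha, beta, lowgamma,
#'   highgamma
#' @export
modulation_frequencies <- function() {
  c(delta = 1.652, theta = 4, alpha = 10.472,
    beta = 18.335, lowgamma = 41.236, highgamma = 71.771)
}

#' Stimulus input strength as a function of modulation frequency
#'
#' Faster modulation leaves less integration time per cycle, so the stimulus
#' amplitude is scaled up with frequency: an exponential rule
#' `1.75 * exp((f / 20)^3)` for the low frequencies (delta, theta, alpha) and
#' a logarithmic rule `2.2 * log10(f)` for the high frequencies (beta and
#' gamma).  With `rule = "auto"` the exponential rule is used below 14 Hz
#' (near the two curves' crossover at ~13.9 Hz) and the logarithmic rule
#' above, which reproduces the canonical assignment.
#'
#' @param f modulation frequency (Hz), positive; vectorised
#' @param rule `"auto"`, `"exponential_low"` or `"logarithmic_high"`
#' @return stimulus amplitude (model current units)
#' @export
input_strength_for_frequency <- function(f, rule = c("auto", "exponential_low",
                                                     "logarithmic_high")) {
  rule <- match.arg(rule)
  if (any(f <= 0)) stop("'f' must be positive")
  expo <- 1.75 * exp((f / 20)^3)
  loga <- 2.2 * log10(f)
  switch(rule,
         exponential_low = expo,
         logarithmic_high = loga,
         auto = ifelse(f <= 14, expo, loga))
}

#' Per-trial noise specification
#'
#' Independent per-trial normal draws that model trial-by-trial variability:
#' of the stimulus modulation frequency (SD a fraction of the nominal
#' frequency), of the hippocampal theta frequency, of the entorhinal phase
#' offset relative to hippocampal theta (nominally 180 degrees) and of the
#' stimulus phases (SD in degrees around each nominal offset).  Each source
#' is enabled independently.
#'
#' @param input_freq enable input-frequency noise
#' @param hip_dynamics enable hippocampal-frequency and EC-offset noise
#' @param input_phase enable stimulus-phase noise
#' @param input_freq_sd_frac SD of the input frequency as a fraction of its
#'   nominal value
#' @param hip_freq_sd SD of the hippocampal theta frequency (Hz)
#' @param ec_offset_mean_deg,ec_offset_sd_deg mean and SD of the EC phase
#'   offset (degrees)
#' @param input_phase_sd_deg SD of each stimulus phase (degrees)
#' @return a list of class `noise_spec`
#' @export
noise_spec <- function(input_freq = FALSE, hip_dynamics = FALSE,
                       input_phase = FALSE,
                       input_freq_sd_frac = 0.015, hip_freq_sd = 0.02,
                       ec_offset_mean_deg = 180, ec_offset_sd_deg = 0.167,
                       input_phase_sd_deg = 5) {
  for (s in c(input_freq_sd_frac, hip_freq_sd, ec_offset_sd_deg,
              input_phase_sd_deg))
    if (s < 0) stop("noise SDs must be non-negative")
  structure(list(input_freq = input_freq, hip_dynamics = hip_dynamics,
                 input_phase = input_phase,
                 input_freq_sd_frac = input_freq_sd_frac,
                 hip_freq_sd = hip_freq_sd,
                 ec_offset_mean_deg = ec_offset_mean_deg,
                 ec_offset_sd_deg = ec_offset_sd_deg,
                 input_phase_sd_deg = input_phase_sd_deg),
            class = "noise_spec")
}

#' Entrainment-paradigm stimulus specification
#'
#' One trial of the multisensory entrainment paradigm: after an
#' interstimulus interval, cosine-modulated direct currents are fed to the
#' visual and auditory NC subgroups for `duration_ms`, the auditory envelope
#' leading the visual one by `phase_offset_deg`.  `modulation_hz = NA`
#' selects the no-flicker control (constant input at amplitude 1.75 for half
#' the standard duration).  By default the amplitude follows
#' [input_strength_for_frequency()].
#'
#' @param modulation_hz modulation frequency (Hz), or `NA` for no-flicker
#' @param phase_offset_deg auditory phase offset relative to visual, in
#'   degrees (the auditory series leads by this much)
#' @param amplitude stimulus amplitude; `NULL` selects the frequency-scaled
#'   default (1.75 for no-flicker)
#' @param amplitude_range `"unipolar"` (envelope in `[0, A]`) or `"bipolar"`
#'   (envelope in `[-A, A]`, used by the STDP-only variant)
#' @param duration_ms stimulus duration (default 3000; halved automatically
#'   for no-flicker)
#' @param isi_ms interstimulus interval preceding the stimulus
#' @param theta_reset reset hippocampal theta at stimulus onset so that its
#'   LTP-permissive trough aligns with the hippocampal response to the
#'   visual stimulus peaks
#' @param reset_lag_ms alignment lag of the theta reset (ms): the trough is
#'   placed this long after each visual envelope peak, compensating the
#'   synaptic delay, EPSP rise time and membrane integration so that the
#'   stimulus-driven volleys (not the raw envelope) coincide with the
#'   LTP-permissive phase.  Default 45 ms (2 ms delay + 20 ms kernel peak +
#'   membrane charging)
#' @param noise a [noise_spec()] object
#' @return a list of class `stimulus_spec`
#' @export
stimulus_spec <- function(modulation_hz = 4, phase_offset_deg = 0,
                          amplitude = NULL,
                          amplitude_range = c("unipolar", "bipolar"),
                          duration_ms = 3000, isi_ms = 2000,
                          theta_reset = TRUE, reset_lag_ms = 45,
                          noise = noise_spec()) {
  amplitude_range <- match.arg(amplitude_range)
  no_flicker <- is.na(modulation_hz)
  if (no_flicker) duration_ms <- duration_ms / 2
  if (is.null(amplitude))
    amplitude <- if (no_flicker) 1.75 else
      input_strength_for_frequency(modulation_hz)
  structure(list(modulation_hz = modulation_hz,
                 phase_offset_deg = phase_offset_deg,
                 amplitude = amplitude, amplitude_range = amplitude_range,
                 duration_ms = duration_ms, isi_ms = isi_ms,
                 theta_reset = theta_reset, reset_lag_ms = reset_lag_ms,
                 noise = noise),
            class = "stimulus_spec")
}

#' Burst-stimulation protocol specification
#'
#' Replication of theta-phase burst stimulation in hippocampal cultures: a
#' single burst of 1-4 suprathreshold current pulses at 100 Hz (amplitude 3)
#' is injected into one hippocampal subgroup, timed so the elicited spikes
#' centre on the requested theta extreme (`"trough"`, theta = 0, the
#' LTP-permissive phase, or `"peak"`, theta = 1).  Plastic synapses onto or
#' from the stimulated neurons are the measured population; their
#' intra-subgroup efficacies are initialised mid-range (`rho_init_intra`) so
#' both potentiation and depression have headroom, and overall synaptic
#' change is reported as the percentage difference to a baseline period.
#'
#' @param n_spikes_per_burst number of pulses in the burst (1-4)
#' @param target_phase `"trough"` or `"peak"`
#' @param pulse_amplitude injected current per pulse
#' @param pulse_width_ms pulse width; 6 ms at amplitude 3 reaches threshold
#'   on the final integration step, so each pulse elicits exactly one spike
#' @param intra_burst_hz within-burst pulse rate (100 Hz = 10 ms spacing)
#' @param pulse_jitter_ms maximum per-neuron response latency (ms): each
#'   stimulated neuron's pulse train is shifted by an integer latency drawn
#'   uniformly from `0:pulse_jitter_ms`, modelling the latency
#'   heterogeneity of a stimulated population (perfectly synchronous spikes
#'   cannot pair under the strict before-the-spike history rule)
#' @param rho_init_intra initial efficacy of hippocampal intra-subgroup
#'   synapses for this protocol
#' @param baseline_window_ms length of the baseline window ending at the
#'   first pulse
#' @param post_gap_ms gap between the last burst spike target and the
#'   post window
#' @param post_window_ms length of the post window
#' @param n_trials number of trials per condition
#' @return a list of class `burst_spec`
#' @export
burst_spec <- function(n_spikes_per_burst = 4,
                       target_phase = c("trough", "peak"),
                       pulse_amplitude = 3, pulse_width_ms = 6,
                       intra_burst_hz = 100, pulse_jitter_ms = 2,
                       rho_init_intra = 0.5,
                       baseline_window_ms = 500, post_gap_ms = 250,
                       post_window_ms = 500, n_trials = 25) {
  target_phase <- match.arg(target_phase)
  if (!n_spikes_per_burst %in% 1:4)
    stop("'n_spikes_per_burst' must be 1, 2, 3 or 4")
  structure(list(n_spikes_per_burst = as.integer(n_spikes_per_burst),
                 target_phase = target_phase,
                 pulse_amplitude = pulse_amplitude,
                 pulse_width_ms = pulse_width_ms,
                 intra_burst_hz = intra_burst_hz,
                 pulse_jitter_ms = pulse_jitter_ms,
                 rho_init_intra = rho_init_intra,
                 baseline_window_ms = baseline_window_ms,
                 post_gap_ms = post_gap_ms,
                 post_window_ms = post_window_ms,
                 n_trials = as.integer(n_trials)),
            class = "burst_spec")
}

#' Resolve per-trial noise draws
#'
#' Draws the trial's realised input frequency, hippocampal theta frequency,
#' EC phase offset and stimulus phase jitters from the enabled noise sources
#' (nominal values otherwise).  Uses the current RNG state.
#'
#' @param spec a [stimulus_spec()] object
#' @return list with `input_hz`, `hip_hz`, `ec_offset_rad`, `phase_vis_rad`,
#'   `phase_aud_rad`
#' @export
draw_trial_noise <- function(spec) {
  noise <- spec$noise
  input_hz <- spec$modulation_hz
  if (isTRUE(noise$input_freq) && !is.na(input_hz))
    input_hz <- stats::rnorm(1, input_hz, noise$input_freq_sd_frac * input_hz)
  hip_hz <- 4
  ec_offset_deg <- 180
  if (isTRUE(noise$hip_dynamics)) {
    hip_hz <- stats::rnorm(1, 4, noise$hip_freq_sd)
    ec_offset_deg <- stats::rnorm(1, noise$ec_offset_mean_deg,
                                  noise$ec_offset_sd_deg)
  }
  phase_vis <- 0
  phase_aud <- spec$phase_offset_deg * pi / 180
  if (isTRUE(noise$input_phase)) {
    jit <- stats::rnorm(2, 0, noise$input_phase_sd_deg) * pi / 180
    phase_vis <- phase_vis + jit[1]
    phase_aud <- phase_aud + jit[2]
  }
  list(input_hz = input_hz, hip_hz = hip_hz,
       ec_offset_rad = ec_offset_deg * pi / 180,
       phase_vis_rad = phase_vis, phase_aud_rad = phase_aud)
}

#' Cosine-modulated stimulus current series
#'
#' Builds the visual and auditory direct-current series for one trial.  The
#' unipolar envelope is `A * (1 - cos(2 pi f t' + psi)) / 2` from stimulus
#' onset (`t' = t - onset`), starting at its trough so the onset is
#' discontinuity-free; the bipolar range maps the same cosine to `[-A, A]`.
#' The auditory series is the visual series phase-advanced (led) by the
#' phase offset; the two are exact time-translates of each other, and the
#' current is zero during the interstimulus interval.
#'
#' @param spec a [stimulus_spec()] object
#' @param n_steps total number of timesteps in the trial
#' @param dt timestep (ms)
#' @param onset_ms stimulus onset time (ms from trial start)
#' @param trial_noise resolved noise draws from [draw_trial_noise()];
#'   defaults to the noise-free nominal values
#' @return list of numeric vectors `visual` and `auditory` (length
#'   `n_steps`), plus the realised `input_hz` and phases
#' @export
make_modulated_input <- function(spec, n_steps, dt = 1, onset_ms = spec$isi_ms,
                                 trial_noise = NULL) {
  if (is.na(spec$modulation_hz))
    return(make_no_flicker_input(spec, n_steps, dt, onset_ms))
  if (is.null(trial_noise))
    trial_noise <- list(input_hz = spec$modulation_hz,
                        phase_vis_rad = 0,
                        phase_aud_rad = spec$phase_offset_deg * pi / 180)
  t <- (seq_len(n_steps) - 1) * dt
  tp <- t - onset_ms
  on <- tp >= 0 & tp < spec$duration_ms
  w <- 2 * pi * trial_noise$input_hz / 1000
  env <- function(psi) {
    x <- numeric(n_steps)
    if (spec$amplitude_range == "unipolar") {
      x[on] <- spec$amplitude * (1 - cos(w * tp[on] + psi)) / 2
    } else {
      x[on] <- -spec$amplitude * cos(w * tp[on] + psi)
    }
    x
  }
  list(visual = env(trial_noise$phase_vis_rad),
       auditory = env(trial_noise$phase_aud_rad),
       input_hz = trial_noise$input_hz,
       phase_vis_rad = trial_noise$phase_vis_rad,
       phase_aud_rad = trial_noise$phase_aud_rad)
}

#' Constant (no-flicker) stimulus current series
#'
#' Both subgroups receive a constant direct current of the given amplitude
#' for the (halved) stimulus duration; zero during the interstimulus
#' interval.
#'
#' @inheritParams make_modulated_input
#' @return list of numeric vectors `visual` and `auditory`
#' @export
make_no_flicker_input <- function(spec, n_steps, dt = 1,
                                  onset_ms = spec$isi_ms) {
  t <- (seq_len(n_steps) - 1) * dt
  on <- t - onset_ms >= 0 & t - onset_ms < spec$duration_ms
  x <- numeric(n_steps)
  x[on] <- spec$amplitude
  list(visual = x, auditory = x, input_hz = NA_real_,
       phase_vis_rad = 0, phase_aud_rad = 0)
}
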
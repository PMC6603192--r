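#' Parameters of a synthetic spiking cell
#'
#' Ground-truth parameter carrier for the leaky integrate-and-fire
#' simulator: a passive RC membrane (leak reversal = true RMP, membrane
#' resistance, capacitance with `tau_m = R * C`), spike generation at a
#' fixed voltage threshold with a stylized piecewise-linear spike template
#' (so amplitude, dv/dt extrema, half-width and AHP have analytic values),
#' spike-triggered adaptation, and a slow hyperpolarization-activated
#' inward current producing a voltage sag.
#'
#' @param e_leak_mV leak reversal = ground-truth resting potential (mV)
#' @param r_MOhm membrane resistance (MOhm)
#' @param c_pF membrane capacitance (pF); `tau_m_ms = r_MOhm * c_pF / 1000`
#' @param v_threshold_mV spike threshold (mV)
#' @param spike_amp_mV template amplitude above threshold (mV)
#' @param ahp_mV template afterhyperpolarization relative to threshold
#'   (mV, negative); doubles as the post-spike reset level
#' @param dvdt_max_mV_per_ms,dvdt_min_mV_per_ms template up-/downstroke
#'   slopes (mV/ms; min is negative)
#' @param adapt_increment_pA spike-triggered adaptation-current increment
#' @param adapt_tau_ms adaptation decay time constant
#' @param gh_nS H-like sag conductance (0 disables the sag)
#' @param sag_tau_ms activation time constant of the sag current
#' @param sag_vhalf_mV,sag_slope_mV activation-curve midpoint and slope
#' @param e_h_mV reversal of the sag current
#' @param noise_sd_mV SD of additive Gaussian recording noise (mV)
#' @param seed integer seed making the cell deterministic
#' @return list of class `synthetic_cell_params`
#' @export
synthetic_cell_params <- function(e_leak_mV = -77, r_MOhm = 150,
                                  c_pF = 150, v_threshold_mV = -40,
                                  spike_amp_mV = 58, ahp_mV = -8,
                                  dvdt_max_mV_per_ms = 430,
                                  dvdt_min_mV_per_ms = -60,
                                  adapt_increment_pA = 50,
                                  adapt_tau_ms = 120,
                                  gh_nS = 0, sag_tau_ms = 40,
                                  sag_vhalf_mV = -82, sag_slope_mV = 7,
                                  e_h_mV = -30,
                                  noise_sd_mV = 0.3, seed = 1L) {
  stopifnot(r_MOhm > 0, c_pF > 0, adapt_tau_ms > 0, sag_tau_ms > 0,
            noise_sd_mV >= 0, spike_amp_mV > 0, dvdt_max_mV_per_ms > 0,
            dvdt_min_mV_per_ms < 0)
  p <- as.list(environment())
  p$tau_m_ms <- r_MOhm * c_pF / 1000
  structure(p, class = "synthetic_cell_params")
}

#' Protocol set for simulation
#'
#' The standard protocols are a 60-s rest trace, the 50-ms family in 10-pA
#' increments, the 500-ms family from -100 to +500 pA in 20-pA increments,
#' and five repetitions of a 50-ms step at rheobase + 10 pA for waveform
#' averaging.  All fields are tunable so tests and large Monte-Carlo runs
#' can scale the data volume down (shorter rest trace, lower sampling
#' rate, narrower step range) without changing the analysis definitions.
#'
#' @param rate_kHz sampling rate (kHz)
#' @param rest_s rest-trace duration (s)
#' @param short_max_pA top amplitude of the 50-ms family
#' @param short_onset_ms,short_pad_ms onset and post-step padding, 50-ms family
#' @param long_range_pA amplitude range of the 500-ms family
#' @param long_onset_ms,long_pad_ms onset and post-step padding, 500-ms family
#' @param n_waveform_reps repetitions of the rheobase + 10 pA step
#' @return list of class `sim_protocols`
#' @export
sim_protocols <- function(rate_kHz = 20, rest_s = 60, short_max_pA = 400,
                          short_onset_ms = 10, short_pad_ms = 40,
                          long_range_pA = c(-100, 500), long_onset_ms = 100,
                          long_pad_ms = 100, n_waveform_reps = 5) {
  structure(as.list(environment()), class = "sim_protocols")
}

# integrate one sweep; returns a voltage_sweep (noise added here, on top of
# the deterministic integration, so ground truth stays exact)
simulate_sweep <- function(params, protocol, rate_kHz, noise = TRUE) {
  dt <- 1 / rate_kHz
  n <- round((protocol$onset_ms + protocol$duration_ms +
                attr(protocol, "pad_ms")) * rate_kHz)
  i_vec <- numeric(n)
  on <- round(protocol$onset_ms * rate_kHz) + 1L
  off <- round((protocol$onset_ms + protocol$duration_ms) * rate_kHz)
  i_vec[on:off] <- protocol$amplitude_pA
  s0 <- 1 / (1 + exp((params$e_leak_mV - params$sag_vhalf_mV) /
                       params$sag_slope_mV))
  out <- .lif_integrate(i_vec, dt, params$e_leak_mV, params$e_leak_mV,
                        params$r_MOhm, params$c_pF, params$v_threshold_mV,
                        params$spike_amp_mV, params$ahp_mV,
                        params$dvdt_max_mV_per_ms, params$dvdt_min_mV_per_ms,
                        params$adapt_increment_pA, params$adapt_tau_ms,
                        params$gh_nS, params$sag_tau_ms, params$sag_vhalf_mV,
                        params$sag_slope_mV, params$e_h_mV, 0, s0)
  v <- out$v_mV
  if (noise && params$noise_sd_mV > 0)
    v <- v + rnorm(length(v), 0, params$noise_sd_mV)
  voltage_sweep(v, rate_kHz, protocol)
}

#' Simulate a full current-clamp recording for one cell
#'
#' Produces a [trace_bundle()] containing the rest trace, the 50-ms and
#' 500-ms step families, and (when the cell spikes) repeated rheobase + 10
#' pA sweeps for waveform averaging.  Deterministic for a fixed
#' `params$seed`.  The ground-truth parameters travel with the bundle in
#' its `ground_truth` field.
#'
#' @param params a [synthetic_cell_params()]
#' @param protocols a [sim_protocols()]
#' @param cell_id identifier for the bundle
#' @param access_resistance_MOhm recording-quality metadatum for the bundle
#' @param meta optional [cell_meta()]
#' @return a [trace_bundle()]
#' @export
simulate_cell <- function(params, protocols = sim_protocols(),
                          cell_id = "synthetic-cell",
                          access_resistance_MOhm = 10, meta = NULL) {
  stopifnot(inherits(params, "synthetic_cell_params"),
            inherits(protocols, "sim_protocols"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(params$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  rate <- protocols$rate_kHz

  prot <- function(amp, onset, dur, pad, isi) {
    p <- step_protocol(amp, onset, dur, isi)
    attr(p, "pad_ms") <- pad
    p
  }
  rest <- simulate_sweep(params,
                         prot(0, 0, protocols$rest_s * 1000, 0, NA), rate)

  short_amps <- if (protocols$short_max_pA >= 10)
    seq(10, protocols$short_max_pA, by = 10) else numeric(0)
  short <- lapply(short_amps, function(a)
    simulate_sweep(params, prot(a, protocols$short_onset_ms, 50,
                                protocols$short_pad_ms, 3), rate))

  long_amps <- seq(protocols$long_range_pA[1], protocols$long_range_pA[2],
                   by = 20)
  long <- lapply(long_amps, function(a)
    simulate_sweep(params, prot(a, protocols$long_onset_ms, 500,
                                protocols$long_pad_ms, 5), rate))

  waveform <- NULL
  rheo <- tryCatch(current_threshold(short), error = function(e) NULL)
  if (!is.null(rheo) && protocols$n_waveform_reps > 0) {
    waveform <- lapply(seq_len(protocols$n_waveform_reps), function(i)
      simulate_sweep(params, prot(rheo + 10, protocols$short_onset_ms, 50,
                                  protocols$short_pad_ms, 3), rate))
  }
  trace_bundle(cell_id = cell_id, rest_trace = rest, short_steps = short,
               long_steps = long,
               access_resistance_MOhm = access_resistance_MOhm,
               waveform_steps = waveform, meta = meta,
               ground_truth = unclass(params))
}
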
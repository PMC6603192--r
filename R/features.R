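#' Analysis configuration
#'
#' Collects the tunable knobs of the extraction pipeline with their
#' defaults.  Values not overridden keep the defaults documented here.
#'
#' @param detect_level_mV spike-detection level (mV)
#' @param dvdt_criterion_mV_per_ms AP-threshold derivative criterion
#' @param rest_min_duration_s minimum rest-trace duration accepted for the
#'   RMP average (60 s by protocol; lowered for synthetic scale-downs)
#' @param steady_window_ms steady-state window for deflections and sag;
#'   `NULL` means the last 10% of the step
#' @param tau_sweep_pA amplitude of the hyperpolarizing sweep used for the
#'   membrane-time-constant fit (default -40 pA)
#' @param tau_refine polish the time-constant estimate with `nls`
#' @param sag_target_mV target steady-state hyperpolarization for the sag
#'   sweep selection (default -7.5 mV)
#' @param sag_smooth_ms running-mean window before the sag trough search
#' @param min_isi_spikes spike count qualifying a sweep for ISI statistics
#' @param n_waveform_spikes spikes averaged for the AP waveform
#' @return list of class `feature_config`
#' @export
feature_config <- function(detect_level_mV = 0,
                           dvdt_criterion_mV_per_ms = 10,
                           rest_min_duration_s = 60,
                           steady_window_ms = NULL,
                           tau_sweep_pA = -40,
                           tau_refine = TRUE,
                           sag_target_mV = -7.5,
                           sag_smooth_ms = 10,
                           min_isi_spikes = 10,
                           n_waveform_spikes = 5) {
  structure(as.list(environment()), class = "feature_config")
}

#' Extract the full intrinsic-excitability feature row for one cell
#'
#' Runs the complete extraction: passive properties (RMP, R_in, tau_m,
#' C_m, sag), rheobase from the 50-ms family, averaged-AP waveform
#' features, firing-rate curve and I-F slope, first-AP latency and ISI
#' statistics.  Waveform averaging uses the bundle's `waveform_steps`
#' repetitions when present, otherwise pools all short-family sweeps at
#' amplitudes >= rheobase + 10 pA.
#'
#' Features whose preconditions are not met on this cell (e.g. fewer than
#' five spikes for waveform averaging, no 10-spike sweep for ISI) are
#' returned as `NA` rather than failing the cell.
#'
#' @param bundle a [trace_bundle()]
#' @param config a [feature_config()]
#' @return one-row data frame with the feature set and `cell_id`
#' @export
extract_features <- function(bundle, config = feature_config()) {
  stopifnot(inherits(bundle, "trace_bundle"))
  pp <- passive_properties(bundle, config)

  na_or <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  i_ap <- na_or(current_threshold(bundle$short_steps, config$detect_level_mV))

  wf_feats <- list(v_threshold_mV = NA_real_, ap_amplitude_mV = NA_real_,
                   ahp_mV = NA_real_, t_ahp_ms = NA_real_,
                   half_width_ms = NA_real_, dvdt_max_mV_per_ms = NA_real_,
                   dvdt_min_mV_per_ms = NA_real_)
  if (!is.na(i_ap)) {
    wf_sweeps <- bundle$waveform_steps
    if (is.null(wf_sweeps)) {
      amps <- family_amplitudes(bundle$short_steps)
      wf_sweeps <- bundle$short_steps[amps >= i_ap + 10 - 1e-9]
    }
    wave <- tryCatch(
      average_ap_waveform(wf_sweeps, n_spikes = config$n_waveform_spikes,
                          detect_level_mV = config$detect_level_mV),
      error = function(e) NULL)
    if (!is.null(wave))
      wf_feats <- ap_features(wave, config$dvdt_criterion_mV_per_ms)
  }

  fi <- fi_curve(bundle$long_steps, config$detect_level_mV)
  slope <- na_or(as.numeric(if_slope(fi)))
  latency <- na_or(first_ap_latency(bundle$long_steps))
  isi <- isi_stats(bundle$long_steps, config$min_isi_spikes,
                   config$detect_level_mV)

  data.frame(cell_id = bundle$cell_id,
             rmp_mV = pp$rmp_mV, r_in_MOhm = pp$r_in_MOhm,
             tau_m_ms = pp$tau_m_ms, c_m_pF = pp$c_m_pF,
             sag_ratio_pct = pp$sag_ratio_pct,
             sag_sweep_amplitude_pA = pp$sag_sweep_amplitude_pA,
             i_ap_pA = i_ap,
             v_threshold_mV = wf_feats$v_threshold_mV,
             ap_amplitude_mV = wf_feats$ap_amplitude_mV,
             ahp_mV = wf_feats$ahp_mV, t_ahp_ms = wf_feats$t_ahp_ms,
             half_width_ms = wf_feats$half_width_ms,
             dvdt_max_mV_per_ms = wf_feats$dvdt_max_mV_per_ms,
             dvdt_min_mV_per_ms = wf_feats$dvdt_min_mV_per_ms,
             if_slope_Hz_per_100pA = slope,
             first_ap_latency_ms = latency,
             mean_isi_ms = isi$mean_isi_ms,
             adaptation_ratio = isi$adaptation_ratio,
             stringsAsFactors = FALSE)
}
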
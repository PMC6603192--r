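#' Detect action potentials in a sweep
#'
#' Upward crossings of a fixed detection level (default 0 mV), with events
#' closer than a refractory interval merged into the first.  Times are
#' reported at the crossing sample.
#'
#' @param sweep a [voltage_sweep()]
#' @param detect_level_mV detection level, default 0
#' @param refractory_ms merge interval, default 1
#' @return list of class `spike_train` with `spike_times_ms` (ms, strictly
#'   increasing) and `sweep_amplitude_pA`
#' @export
detect_spikes <- function(sweep, detect_level_mV = 0, refractory_ms = 1) {
  stopifnot(inherits(sweep, "voltage_sweep"))
  v <- sweep$samples_mV
  up <- which(v[-1] >= detect_level_mV & v[-length(v)] < detect_level_mV) + 1L
  t <- (up - 1) / sweep$sampling_rate_kHz
  if (length(t) > 1L) {
    # an event within refractory_ms of the last *kept* event is merged away
    kept <- t[1]
    sel <- logical(length(t)); sel[1] <- TRUE
    for (i in seq_along(t)[-1]) {
      if (t[i] - kept >= refractory_ms) { sel[i] <- TRUE; kept <- t[i] }
    }
    t <- t[sel]
  }
  structure(list(spike_times_ms = t,
                 sweep_amplitude_pA = sweep$protocol$amplitude_pA),
            class = "spike_train")
}

#' Current threshold (rheobase) from the 50-ms step family
#'
#' The minimum injected current needed to elicit the first action
#' potential: the amplitude of the first sweep of the ascending 10-pA
#' family containing at least one spike.
#'
#' @param short_steps list of 50-ms [voltage_sweep()]s, ascending amplitude
#' @param detect_level_mV spike-detection level
#' @return I_AP in pA
#' @export
current_threshold <- function(short_steps, detect_level_mV = 0) {
  validate_family(short_steps, label = "short_steps")
  for (s in short_steps) {
    if (length(detect_spikes(s, detect_level_mV)$spike_times_ms) >= 1L)
      return(s$protocol$amplitude_pA)
  }
  stop("no rheobase: no sweep of the short family elicited a spike",
       call. = FALSE)
}

#' Average action-potential waveform
#'
#' Peak-aligned mean of the first five spike-centered windows found in the
#' supplied sweep(s) at rheobase + 10 pA.  Because a single 50-ms step
#' rarely holds five spikes, repetitions of the same stimulus may be
#' supplied as a list and are concatenated into one event pool.
#'
#' @param sweeps a [voltage_sweep()] or list of sweeps at one amplitude
#' @param n_spikes number of spikes to average (default 5)
#' @param pre_ms,post_ms window before/after the spike peak (>= 2 and
#'   >= 10 ms respectively by contract)
#' @param detect_level_mV spike-detection level
#' @return list of class `ap_waveform` with `samples_mV`,
#'   `sampling_rate_kHz` and `peak_index`
#' @export
average_ap_waveform <- function(sweeps, n_spikes = 5, pre_ms = 2,
                                post_ms = 10, detect_level_mV = 0) {
  if (inherits(sweeps, "voltage_sweep")) sweeps <- list(sweeps)
  rate <- sweeps[[1]]$sampling_rate_kHz
  n_pre <- round(pre_ms * rate)
  n_post <- round(post_ms * rate)
  windows <- list()
  for (s in sweeps) {
    if (abs(s$sampling_rate_kHz - rate) > 1e-9)
      stop("all sweeps must share one sampling rate", call. = FALSE)
    st <- detect_spikes(s, detect_level_mV)
    for (t0 in st$spike_times_ms) {
      i_cross <- round(t0 * rate) + 1L
      # peak: maximum within 2 ms after the crossing
      i_hi <- min(length(s$samples_mV), i_cross + round(2 * rate))
      i_peak <- i_cross - 1L + which.max(s$samples_mV[i_cross:i_hi])
      if (i_peak - n_pre < 1L || i_peak + n_post > length(s$samples_mV))
        next
      windows[[length(windows) + 1L]] <-
        s$samples_mV[(i_peak - n_pre):(i_peak + n_post)]
    }
  }
  if (length(windows) < n_spikes)
    stop("insufficient spikes for waveform averaging: need ", n_spikes,
         ", found ", length(windows), call. = FALSE)
  m <- colMeans(do.call(rbind, windows[seq_len(n_spikes)]))
  structure(list(samples_mV = m, sampling_rate_kHz = rate,
                 peak_index = n_pre + 1L),
            class = "ap_waveform")
}

# centered first-difference derivative, mV/ms
wave_derivative <- function(samples_mV, rate_kHz) {
  n <- length(samples_mV)
  d <- numeric(n)
  d[2:(n - 1)] <- (samples_mV[3:n] - samples_mV[1:(n - 2)]) * rate_kHz / 2
  d[1] <- (samples_mV[2] - samples_mV[1]) * rate_kHz
  d[n] <- (samples_mV[n] - samples_mV[n - 1]) * rate_kHz
  d
}

#' Action-potential voltage threshold
#'
#' First sample of the upstroke where the centered first-difference
#' derivative exceeds 10 mV/ms.
#'
#' @param wave an [average_ap_waveform()] result (or compatible list)
#' @param dvdt_criterion_mV_per_ms derivative criterion, default 10
#' @return list with `v_threshold_mV` and `index`
#' @export
ap_threshold <- function(wave, dvdt_criterion_mV_per_ms = 10) {
  v <- wave$samples_mV
  d <- wave_derivative(v, wave$sampling_rate_kHz)
  i_peak <- if (!is.null(wave$peak_index)) wave$peak_index else which.max(v)
  idx <- which(d[seq_len(i_peak)] > dvdt_criterion_mV_per_ms)[1]
  if (is.na(idx))
    stop("no threshold: depolarization speed never exceeds ",
         dvdt_criterion_mV_per_ms, " mV/ms", call. = FALSE)
  list(v_threshold_mV = v[idx], index = idx)
}

#' Waveform features of an averaged action potential
#'
#' Amplitude (peak minus threshold), afterhyperpolarization (post-peak
#' minimum minus threshold, negative), AHP time to peak (threshold crossing
#' to that minimum), half-width (time between the two crossings of
#' threshold + amplitude/2, linearly interpolated), and the dv/dt extrema.
#' If the post-spike minimum falls on the window edge the AHP cannot be
#' confirmed and is reported as `NA`.
#'
#' @param wave an [average_ap_waveform()] result
#' @param dvdt_criterion_mV_per_ms threshold-detection criterion
#' @return list with `v_threshold_mV`, `ap_amplitude_mV`, `ahp_mV`,
#'   `t_ahp_ms`, `half_width_ms`, `dvdt_max_mV_per_ms`, `dvdt_min_mV_per_ms`
#' @export
ap_features <- function(wave, dvdt_criterion_mV_per_ms = 10) {
  v <- wave$samples_mV
  rate <- wave$sampling_rate_kHz
  thr <- ap_threshold(wave, dvdt_criterion_mV_per_ms)
  i_peak <- if (!is.null(wave$peak_index)) wave$peak_index else which.max(v)
  v_peak <- v[i_peak]
  amp <- v_peak - thr$v_threshold_mV
  d <- wave_derivative(v, rate)

  # post-spike trough: the first local minimum after the peak (a window-edge
  # minimum means the repolarization never turned around, so no AHP)
  ahp <- t_ahp <- NA_real_
  if (i_peak + 2L <= length(v)) {
    idx <- seq.int(i_peak + 1L, length(v) - 1L)
    loc <- idx[v[idx] <= v[idx - 1L] & v[idx] <= v[idx + 1L]]
    if (length(loc)) {
      i_min <- loc[1]
      ahp <- v[i_min] - thr$v_threshold_mV
      t_ahp <- (i_min - thr$index) / rate
    }
  }

  # half-width at threshold + amplitude/2, with linear interpolation
  half <- thr$v_threshold_mV + amp / 2
  up_i <- which(v[-1] >= half & v[-length(v)] < half)
  up_i <- up_i[up_i < i_peak][1]
  dn_i <- which(v[-1] < half & v[-length(v)] >= half)
  dn_i <- dn_i[dn_i >= i_peak][1]
  hw <- NA_real_
  if (!is.na(up_i) && !is.na(dn_i)) {
    f_up <- (half - v[up_i]) / (v[up_i + 1] - v[up_i])
    f_dn <- (v[dn_i] - half) / (v[dn_i] - v[dn_i + 1])
    hw <- ((dn_i + f_dn) - (up_i + f_up)) / rate
  }
  list(v_threshold_mV = thr$v_threshold_mV, ap_amplitude_mV = amp,
       ahp_mV = ahp, t_ahp_ms = t_ahp, half_width_ms = hw,
       dvdt_max_mV_per_ms = max(d), dvdt_min_mV_per_ms = min(d))
}

#' Firing-rate curve from the 500-ms family
#'
#' Spike count divided by the 0.5-s step duration, for every depolarizing
#' sweep.
#'
#' @param long_steps list of 500-ms [voltage_sweep()]s
#' @param detect_level_mV spike-detection level
#' @return data frame with `amplitude_pA` and `frequency_Hz`
#' @export
fi_curve <- function(long_steps, detect_level_mV = 0) {
  amps <- family_amplitudes(long_steps)
  dep <- which(amps > 0)
  n_sp <- vapply(long_steps[dep], function(s) {
    st <- detect_spikes(s, detect_level_mV)
    sum(st$spike_times_ms >= s$protocol$onset_ms &
          st$spike_times_ms <= s$protocol$onset_ms + s$protocol$duration_ms)
  }, numeric(1))
  dur_s <- vapply(long_steps[dep],
                  function(s) s$protocol$duration_ms / 1000, numeric(1))
  data.frame(amplitude_pA = amps[dep], frequency_Hz = n_sp / dur_s)
}

#' Input-frequency slope
#'
#' Linear coefficient of a second-order polynomial fit of firing frequency
#' versus injected current over the suprathreshold range (silent sweeps are
#' excluded; a polynomial over the flat subthreshold range would bias the
#' linear term).  Reported in Hz per 100 pA.
#'
#' @param fi data frame from [fi_curve()]
#' @return slope in Hz/100 pA; the full quadratic fit is attached as
#'   attribute `"fit"`
#' @export
if_slope <- function(fi) {
  supra <- fi[fi$frequency_Hz > 0, , drop = FALSE]
  if (nrow(supra) < 3L)
    stop("if_slope needs >= 3 suprathreshold points; got ", nrow(supra),
         call. = FALSE)
  fit <- poly2_fit(supra$amplitude_pA, supra$frequency_Hz)
  structure(unname(fit$coefficients["b"]) * 100, fit = fit)
}

#' Latency of the first action potential
#'
#' On the first suprathreshold sweep of the 500-ms family (lowest amplitude
#' with at least one spike inside the step window), the time from step
#' onset to the first upward crossing of 0 mV.  Events before onset
#' (spontaneous) are excluded from the search window.
#'
#' @param long_steps list of 500-ms [voltage_sweep()]s
#' @param detect_level_mV crossing level, fixed at 0 mV by definition
#' @return latency in ms
#' @export
first_ap_latency <- function(long_steps, detect_level_mV = 0) {
  amps <- family_amplitudes(long_steps)
  for (i in order(amps)) {
    if (amps[i] <= 0) next
    s <- long_steps[[i]]
    st <- detect_spikes(s, detect_level_mV)
    t_in <- st$spike_times_ms[st$spike_times_ms >= s$protocol$onset_ms &
                                st$spike_times_ms <= s$protocol$onset_ms +
                                s$protocol$duration_ms]
    if (length(t_in)) return(t_in[1] - s$protocol$onset_ms)
  }
  stop("no suprathreshold sweep in the 500-ms family", call. = FALSE)
}

#' Inter-spike-interval statistics
#'
#' From the lowest-amplitude 500-ms sweep with at least `min_spikes`
#' action potentials: the mean of all inter-spike intervals and the
#' adaptation ratio ISI_1 / ISI_last (with exactly 10 spikes the last ISI
#' is the 9th, so both common phrasings coincide).
#'
#' @param long_steps list of 500-ms [voltage_sweep()]s
#' @param min_spikes qualifying spike count, default 10
#' @param detect_level_mV spike-detection level
#' @return list with `mean_isi_ms`, `adaptation_ratio` and
#'   `sweep_amplitude_pA`; all `NA` when no sweep qualifies
#' @export
isi_stats <- function(long_steps, min_spikes = 10, detect_level_mV = 0) {
  amps <- family_amplitudes(long_steps)
  for (i in order(amps)) {
    st <- detect_spikes(long_steps[[i]], detect_level_mV)
    if (length(st$spike_times_ms) >= min_spikes) {
      isi <- diff(st$spike_times_ms)
      return(list(mean_isi_ms = mean(isi),
                  adaptation_ratio = isi[1] / isi[length(isi)],
                  sweep_amplitude_pA = amps[i]))
    }
  }
  list(mean_isi_ms = NA_real_, adaptation_ratio = NA_real_,
       sweep_amplitude_pA = NA_real_)
}
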
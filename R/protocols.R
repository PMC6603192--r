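#' Current-step protocol descriptor
#'
#' Describes a single square current step within a sweep.  The two protocol
#' families used throughout are the 50-ms family (10-pA increments, one step
#' every 3 s, used to find the current threshold) and the 500-ms family
#' (20-pA increments from -100 to +500 pA at 0.2 Hz, used for passive
#' properties, sag and firing-rate curves).
#'
#' @param amplitude_pA injected current amplitude (pA)
#' @param onset_ms stimulus onset within the sweep (ms, >= 0)
#' @param duration_ms step duration (ms, > 0); 50 or 500 in the standard
#'   protocols
#' @param inter_sweep_s pause between consecutive sweeps (s); 3 for the
#'   short family, 5 (0.2 Hz) for the long family
#' @return an object of class `step_protocol`
#' @export
step_protocol <- function(amplitude_pA, onset_ms, duration_ms,
                          inter_sweep_s = NA_real_) {
  stopifnot(is.numeric(amplitude_pA), length(amplitude_pA) == 1L)
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("step duration must be positive", call. = FALSE)
  if (!is.numeric(onset_ms) || onset_ms < 0)
    stop("step onset must be >= 0", call. = FALSE)
  structure(
    list(amplitude_pA = as.numeric(amplitude_pA),
         onset_ms = as.numeric(onset_ms),
         duration_ms = as.numeric(duration_ms),
         inter_sweep_s = as.numeric(inter_sweep_s)),
    class = "step_protocol")
}

#' A single voltage sweep
#'
#' One membrane-voltage trace recorded (or simulated) in response to a
#' current step, with its sampling metadata.  Internal unit system is
#' mV / pA / ms throughout.
#'
#' @param samples_mV numeric vector of voltage samples (mV)
#' @param sampling_rate_kHz samples per millisecond
#' @param protocol a [step_protocol()]
#' @param strict_rate if `TRUE`, enforce the acquisition-hardware range of
#'   20--50 kHz (applied when reading real recordings); synthetic data may
#'   legitimately use lower rates, so the default is `FALSE`
#' @return an object of class `voltage_sweep`
#' @export
voltage_sweep <- function(samples_mV, sampling_rate_kHz, protocol,
                          strict_rate = FALSE) {
  stopifnot(is.numeric(samples_mV), length(samples_mV) >= 2L,
            inherits(protocol, "step_protocol"))
  if (!is.numeric(sampling_rate_kHz) || sampling_rate_kHz <= 0)
    stop("sampling rate must be positive", call. = FALSE)
  if (strict_rate && (sampling_rate_kHz < 20 || sampling_rate_kHz > 50))
    stop("sampling rate ", sampling_rate_kHz,
         " kHz outside the acquisition range [20, 50] kHz", call. = FALSE)
  sweep_ms <- length(samples_mV) / sampling_rate_kHz
  if (protocol$onset_ms + protocol$duration_ms > sweep_ms + 1e-9)
    stop("step (onset ", protocol$onset_ms, " + duration ",
         protocol$duration_ms, " ms) exceeds sweep length ",
         signif(sweep_ms, 6), " ms", call. = FALSE)
  structure(
    list(samples_mV = as.numeric(samples_mV),
         sampling_rate_kHz = as.numeric(sampling_rate_kHz),
         protocol = protocol),
    class = "voltage_sweep")
}

#' @export
print.voltage_sweep <- function(x, ...) {
  cat(sprintf("<voltage_sweep> %d samples @ %g kHz, step %+g pA (%g ms)\n",
              length(x$samples_mV), x$sampling_rate_kHz,
              x$protocol$amplitude_pA, x$protocol$duration_ms))
  invisible(x)
}

# time axis (ms) of a sweep, first sample at t = 0
sweep_time_ms <- function(sweep) {
  (seq_along(sweep$samples_mV) - 1) / sweep$sampling_rate_kHz
}

sweep_duration_ms <- function(sweep) {
  length(sweep$samples_mV) / sweep$sampling_rate_kHz
}

family_amplitudes <- function(sweeps) {
  vapply(sweeps, function(s) s$protocol$amplitude_pA, numeric(1))
}

# Families must be sorted by ascending amplitude with uniform increments.
validate_family <- function(sweeps, increment_pA = NULL, label = "family") {
  if (length(sweeps) == 0L) return(invisible(sweeps))
  amps <- family_amplitudes(sweeps)
  if (is.unsorted(amps, strictly = TRUE))
    stop(label, " sweeps must be sorted by strictly ascending amplitude",
         call. = FALSE)
  if (!is.null(increment_pA) && length(amps) > 1L) {
    d <- diff(amps)
    if (any(abs(d - increment_pA) > 1e-9))
      stop(label, " amplitude increments are not uniform at ", increment_pA,
           " pA", call. = FALSE)
  }
  invisible(sweeps)
}

#' Per-cell trace bundle
#'
#' Container for one cell's current-clamp protocols: a resting trace at
#' 0 pA, the 50-ms depolarizing step family, and the 500-ms step family
#' covering -100...+500 pA.  The long family must reach down to -100 pA and
#' include 0 pA so the input-resistance I/V fit is possible.  An optional
#' `waveform_steps` family holds repeated 50-ms steps at rheobase + 10 pA
#' used to average action-potential waveforms (repetitions of the same
#' stimulus are pooled into one event pool).
#'
#' @param cell_id character identifier
#' @param rest_trace [voltage_sweep()] at 0 pA (nominally >= 60 s)
#' @param short_steps list of sweeps, ascending 10-pA increments
#' @param long_steps list of sweeps, ascending 20-pA increments, covering
#'   -100...0 pA
#' @param access_resistance_MOhm series resistance metadatum (MOhm)
#' @param waveform_steps optional list of repeated sweeps at one amplitude
#' @param meta optional [cell_meta()]
#' @param ground_truth optional list of simulator ground-truth parameters
#' @return an object of class `trace_bundle`
#' @export
trace_bundle <- function(cell_id, rest_trace, short_steps, long_steps,
                         access_resistance_MOhm,
                         waveform_steps = NULL, meta = NULL,
                         ground_truth = NULL) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L,
            inherits(rest_trace, "voltage_sweep"),
            is.list(short_steps), is.list(long_steps))
  if (abs(rest_trace$protocol$amplitude_pA) > 1e-9)
    stop("rest trace must be recorded at 0 pA", call. = FALSE)
  validate_family(short_steps, 10, "short_steps")
  validate_family(long_steps, 20, "long_steps")
  amps <- family_amplitudes(long_steps)
  if (length(amps) && (min(amps) > -100 + 1e-9 || !any(abs(amps) < 1e-9)))
    stop("incomplete bundle: long_steps must cover -100...0 pA ",
         "(input-resistance fit); found range [", min(amps), ", ",
         max(amps), "]", call. = FALSE)
  if (!is.null(waveform_steps)) {
    wamps <- family_amplitudes(waveform_steps)
    if (length(unique(round(wamps, 6))) != 1L)
      stop("waveform_steps must all share one amplitude", call. = FALSE)
  }
  if (!is.null(meta) && !inherits(meta, "cell_meta"))
    stop("meta must be a cell_meta object", call. = FALSE)
  structure(
    list(cell_id = cell_id, rest_trace = rest_trace,
         short_steps = short_steps, long_steps = long_steps,
         access_resistance_MOhm = as.numeric(access_resistance_MOhm),
         waveform_steps = waveform_steps, meta = meta,
         ground_truth = ground_truth),
    class = "trace_bundle")
}

#' @export
print.trace_bundle <- function(x, ...) {
  cat(sprintf(
    "<trace_bundle> cell %s: rest %.1f s, %d short + %d long sweeps, Rs %.1f MOhm\n",
    x$cell_id, sweep_duration_ms(x$rest_trace) / 1000,
    length(x$short_steps), length(x$long_steps),
    x$access_resistance_MOhm))
  invisible(x)
}

#' Cohort metadata for one cell
#'
#' @param group treatment group, `"sham"` or `"SNI"`
#' @param subregion prefrontal subregion, `"PrL"` or `"IL"`
#' @param layer cortical layer, `"L2/3"` or `"L5"`
#' @param x_um,y_um soma coordinates (micrometres) relative to the dorsal
#'   apex and the midline of the coronal slice; must be >= 0
#' @return an object of class `cell_meta`
#' @export
cell_meta <- function(group, subregion = "PrL", layer = "L2/3",
                      x_um = NA_real_, y_um = NA_real_) {
  group <- match.arg(group, c("sham", "SNI"))
  subregion <- match.arg(subregion, c("PrL", "IL"))
  layer <- match.arg(layer, c("L2/3", "L5"))
  for (v in c(x_um, y_um))
    if (!is.na(v) && v < 0)
      stop("coordinates must be >= 0", call. = FALSE)
  structure(list(group = group, subregion = subregion, layer = layer,
                 x_um = as.numeric(x_um), y_um = as.numeric(y_um)),
            class = "cell_meta")
}

#' Recording-quality inclusion filter
#'
#' Cells enter the analysis only when the resting membrane potential is
#' below -60 mV and the access resistance is below 20 MOhm (strict
#' inequalities).  Optionally the rest-trace drift criterion is applied:
#' the absolute difference between the mean of the first and the last
#' `drift_window_s` seconds of the rest trace must not exceed
#' `max_drift_mV` (a configurable operationalization of "stable RMP").
#'
#' @param bundle a [trace_bundle()]
#' @param rmp_mV resting membrane potential measured from the rest trace
#' @param rmp_cutoff_mV inclusion cutoff for RMP (default -60)
#' @param rs_cutoff_MOhm inclusion cutoff for access resistance (default 20)
#' @param max_drift_mV maximum allowed rest-trace drift (mV); `NULL` skips
#'   the stability check
#' @param drift_window_s window used at either end of the rest trace (s)
#' @return list with `accept` (logical) and `reason` (`"ok"`, `"RMP"`,
#'   `"Rs"`, or `"drift"`)
#' @export
inclusion_filter <- function(bundle, rmp_mV, rmp_cutoff_mV = -60,
                             rs_cutoff_MOhm = 20, max_drift_mV = NULL,
                             drift_window_s = 10) {
  stopifnot(inherits(bundle, "trace_bundle"), is.numeric(rmp_mV))
  if (!(rmp_mV < rmp_cutoff_mV))
    return(list(accept = FALSE, reason = "RMP"))
  if (!(bundle$access_resistance_MOhm < rs_cutoff_MOhm))
    return(list(accept = FALSE, reason = "Rs"))
  if (!is.null(max_drift_mV)) {
    v <- bundle$rest_trace$samples_mV
    k <- min(length(v) %/% 2,
             round(drift_window_s * 1000 * bundle$rest_trace$sampling_rate_kHz))
    drift <- abs(mean(v[seq_len(k)]) - mean(v[seq.int(length(v) - k + 1, length(v))]))
    if (drift > max_drift_mV)
      return(list(accept = FALSE, reason = "drift"))
  }
  list(accept = TRUE, reason = "ok")
}
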
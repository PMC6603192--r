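#' Resting membrane potential
#'
#' Arithmetic mean of the whole rest trace recorded at 0 pA.  The standard
#' protocol averages a full minute of rest recording; shorter traces raise
#' an error unless `min_duration_s` is lowered (synthetic scale-downs).
#'
#' @param rest a [voltage_sweep()] at 0 pA
#' @param min_duration_s minimum accepted trace duration (s)
#' @return RMP in mV
#' @export
resting_membrane_potential <- function(rest, min_duration_s = 60) {
  stopifnot(inherits(rest, "voltage_sweep"))
  dur_s <- sweep_duration_ms(rest) / 1000
  if (dur_s < min_duration_s - 1e-9)
    stop("insufficient data: rest trace is ", signif(dur_s, 4),
         " s, need >= ", min_duration_s,
         " s (lower min_duration_s to override)", call. = FALSE)
  mean(rest$samples_mV)
}

#' Steady-state voltage deflection of a step response
#'
#' Mean voltage over the final window of the current step minus the
#' baseline.  The default window is the last 10% of the step (50 ms of a
#' 500-ms step).
#'
#' @param sweep a [voltage_sweep()]
#' @param baseline_mV baseline voltage (typically the RMP)
#' @param window_ms averaging window ending at step offset; default
#'   `duration_ms / 10`
#' @return deflection in mV (negative for hyperpolarizations)
#' @export
steady_state_deflection <- function(sweep, baseline_mV, window_ms = NULL) {
  stopifnot(inherits(sweep, "voltage_sweep"))
  p <- sweep$protocol
  if (is.null(window_ms)) window_ms <- p$duration_ms / 10
  if (window_ms > p$duration_ms + 1e-9)
    stop("steady-state window (", window_ms, " ms) exceeds step duration (",
         p$duration_ms, " ms)", call. = FALSE)
  steady_state_voltage(sweep, window_ms) - baseline_mV
}

# centered running mean with shrinking windows at the edges (no NAs)
running_mean <- function(v, k) {
  half <- k %/% 2
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# mean voltage over the last window_ms of the step
steady_state_voltage <- function(sweep, window_ms = NULL) {
  p <- sweep$protocol
  if (is.null(window_ms)) window_ms <- p$duration_ms / 10
  rate <- sweep$sampling_rate_kHz
  i_end <- min(length(sweep$samples_mV), round((p$onset_ms + p$duration_ms) * rate))
  i_start <- max(1L, i_end - round(window_ms * rate) + 1L)
  mean(sweep$samples_mV[i_start:i_end])
}

#' Input resistance from the subthreshold I/V curve
#'
#' Ordinary-least-squares slope of steady-state voltage deflection versus
#' injected current over the 500-ms sweeps with amplitudes in
#' \[-100, 0\] pA.  With internal units mV/pA the raw slope is in GOhm and
#' is rescaled to MOhm.  Sweeps containing spikes are excluded with a
#' warning (the fit is defined on subthreshold responses only).
#'
#' @param long_steps list of 500-ms [voltage_sweep()]s
#' @param rmp_mV resting membrane potential (baseline for the deflections)
#' @param range_pA amplitude window entering the fit, default `c(-100, 0)`
#' @param window_ms steady-state window (see [steady_state_deflection()])
#' @return input resistance in MOhm; the underlying `lm` fit is attached as
#'   attribute `"fit"`
#' @export
input_resistance <- function(long_steps, rmp_mV, range_pA = c(-100, 0),
                             window_ms = NULL) {
  amps <- family_amplitudes(long_steps)
  keep <- amps >= range_pA[1] - 1e-9 & amps <= range_pA[2] + 1e-9
  sweeps <- long_steps[keep]
  has_spike <- vapply(sweeps, function(s)
    length(detect_spikes(s)$spike_times_ms) > 0, logical(1))
  if (any(has_spike)) {
    warning("excluding ", sum(has_spike),
            " sweep(s) with spikes from the I/V fit")
    sweeps <- sweeps[!has_spike]
  }
  if (length(sweeps) < 3L)
    stop("input_resistance needs >= 3 subthreshold sweeps in [",
         range_pA[1], ", ", range_pA[2], "] pA; got ", length(sweeps),
         call. = FALSE)
  i_pA <- family_amplitudes(sweeps)
  dv <- vapply(sweeps, steady_state_deflection, numeric(1),
               baseline_mV = rmp_mV, window_ms = window_ms)
  fit <- lm(dv ~ i_pA)
  r <- unname(coef(fit)[2]) * 1000  # mV/pA = GOhm -> MOhm
  if (!is.finite(r) || r <= 0)
    stop("input-resistance fit produced a non-positive slope", call. = FALSE)
  structure(r, fit = fit)
}

#' Membrane time constant and capacitance
#'
#' Mono-exponential fit `V(t) = V_ss + dV * exp(-t / tau_m)` to the onset
#' transient of the hyperpolarizing -40 pA step of the 500-ms family.  The
#' fit window runs from step onset to five times an initial tau estimate
#' (capped at step end).  Capacitance follows from the passive relation
#' `C_m = tau_m / R_in` (ms / MOhm = nF, reported in pF).
#'
#' @param sweep hyperpolarizing [voltage_sweep()] (at or nearest -40 pA)
#' @param r_in_MOhm input resistance in MOhm from [input_resistance()]
#' @param span multiple of the initial tau estimate defining the fit window
#' @param refine if `TRUE` (default) polish the fast log-linear estimate
#'   with a nonlinear least-squares fit
#' @return list with `tau_m_ms`, `c_m_pF`, `v_ss_mV` and `fit_window_ms`
#' @export
membrane_time_constant <- function(sweep, r_in_MOhm, span = 5,
                                   refine = TRUE) {
  stopifnot(inherits(sweep, "voltage_sweep"))
  p <- sweep$protocol
  if (p$amplitude_pA >= 0)
    stop("membrane_time_constant expects a hyperpolarizing sweep",
         call. = FALSE)
  rate <- sweep$sampling_rate_kHz
  v <- sweep$samples_mV
  i_on <- max(1L, round(p$onset_ms * rate) + 1L)
  i_off <- min(length(v), round((p$onset_ms + p$duration_ms) * rate))
  v0 <- mean(v[max(1L, i_on - round(5 * rate)):max(1L, i_on - 1L)])
  v_ss <- steady_state_voltage(sweep)
  dv_total <- v_ss - v0
  if (abs(dv_total) < 0.5)
    stop("degenerate input: voltage transient amplitude ",
         signif(abs(dv_total), 3), " mV is too small to fit", call. = FALSE)
  if (dv_total > 0)
    stop("polarity error: depolarizing response to hyperpolarizing current",
         call. = FALSE)

  # initial tau: first crossing of (1 - 1/e) of the total deflection
  seg <- v[i_on:i_off]
  t_seg <- (seq_along(seg) - 1) / rate
  target <- v0 + (1 - exp(-1)) * dv_total
  idx <- which(seg <= target)[1]
  tau0 <- if (is.na(idx)) p$duration_ms / 5 else max(t_seg[idx], 2 / rate)

  i_win <- which(t_seg <= min(span * tau0, p$duration_ms))
  tt <- t_seg[i_win]
  vv <- seg[i_win]

  # log-linear estimate on the (positive, decaying) distance to steady state
  pos <- vv - v_ss            # negative-going transient: starts above v_ss
  keep <- pos > max(pos) * 1e-4
  if (sum(keep) >= 3) {
    est <- lm(log(pos[keep]) ~ tt[keep])
    tau <- -1 / unname(coef(est)[2])
  } else tau <- tau0
  if (!is.finite(tau) || tau <= 0) tau <- tau0

  if (refine) {
    # profiled least squares: for fixed tau the model is linear in
    # (v_ss, dv), so minimize the profiled RSS over tau with optimize();
    # deterministic and immune to the convergence failures of full
    # nonlinear iteration on noisy traces
    prof <- function(tau_f) {
      x <- exp(-tt / tau_f)
      f <- lm.fit(cbind(1, x), vv)
      sum(f$residuals^2)
    }
    opt <- stats::optimize(prof, interval = c(1 / rate,
                                              2 * p$duration_ms),
                           tol = 1e-4)
    tau <- opt$minimum
    x <- exp(-tt / tau)
    cf <- lm.fit(cbind(1, x), vv)$coefficients
    v_ss <- unname(cf[1])
    rss <- opt$objective
    if (!is.finite(rss))
      stop("exponential fit failed on this sweep", call. = FALSE)
  }
  c_m <- tau / r_in_MOhm * 1000  # ms/MOhm = nF -> pF
  list(tau_m_ms = tau, c_m_pF = c_m, v_ss_mV = v_ss,
       fit_window_ms = max(tt))
}

#' Voltage sag ratio
#'
#' From the hyperpolarizing 500-ms sweep whose steady-state deflection is
#' closest to -7.5 mV (ties broken toward the smaller-magnitude current),
#' computes `(V_ss - V_min) / (V_min - V_rmp)` where `V_min` is the
#' minimum voltage after step onset and `V_ss` the steady-state voltage.
#' The literal ratio is negative for a rebounding hyperpolarization;
#' following the universal sign convention for sag percentages the
#' magnitude is reported, scaled to percent.
#'
#' Because the raw minimum of a noisy trace is an extreme-value statistic
#' (biased downward by the noise floor), the trace is smoothed with a
#' running mean of `smooth_ms` before the trough search; the sag trough is
#' broad (it develops on the H-current time scale), so light smoothing
#' does not distort it.  Set `smooth_ms = 0` for the literal sample
#' minimum.
#'
#' @param long_steps list of 500-ms [voltage_sweep()]s
#' @param rmp_mV resting membrane potential
#' @param target_deflection_mV selection target, default -7.5
#' @param window_ms steady-state window
#' @param smooth_ms running-mean window applied before the trough search
#' @return list with `sag_pct`, `amplitude_pA` (the chosen injection),
#'   `v_min_mV` and `v_ss_mV`
#' @export
sag_ratio <- function(long_steps, rmp_mV, target_deflection_mV = -7.5,
                      window_ms = NULL, smooth_ms = 10) {
  amps <- family_amplitudes(long_steps)
  hyp <- which(amps < 0)
  if (length(hyp) == 0L)
    stop("no hyperpolarizing sweep available for the sag computation",
         call. = FALSE)
  defl <- vapply(long_steps[hyp], steady_state_deflection, numeric(1),
                 baseline_mV = rmp_mV, window_ms = window_ms)
  score <- abs(defl - target_deflection_mV)
  # ties toward the smaller-magnitude current
  best <- hyp[order(score, abs(amps[hyp]))][1]
  sweep <- long_steps[[best]]
  rate <- sweep$sampling_rate_kHz
  p <- sweep$protocol
  i_on <- max(1L, round(p$onset_ms * rate) + 1L)
  i_off <- min(length(sweep$samples_mV), round((p$onset_ms + p$duration_ms) * rate))
  v <- sweep$samples_mV
  k <- round(smooth_ms * rate)
  if (k > 1) v <- running_mean(v, k)
  v_min <- min(v[i_on:i_off])
  v_ss <- steady_state_voltage(sweep, window_ms)
  denom <- v_min - rmp_mV
  if (abs(denom) < 1e-12)
    stop("degenerate sag computation: V_min equals RMP", call. = FALSE)
  list(sag_pct = 100 * abs((v_ss - v_min) / denom),
       amplitude_pA = p$amplitude_pA, v_min_mV = v_min, v_ss_mV = v_ss)
}

#' Passive-property summary for one cell
#'
#' Convenience driver computing RMP, input resistance, membrane time
#' constant, capacitance and sag ratio from a [trace_bundle()].
#'
#' @param bundle a [trace_bundle()]
#' @param config a [feature_config()]
#' @return list of class `passive_properties`
#' @export
passive_properties <- function(bundle, config = feature_config()) {
  rmp <- resting_membrane_potential(bundle$rest_trace,
                                    config$rest_min_duration_s)
  r_in <- input_resistance(bundle$long_steps, rmp,
                           window_ms = config$steady_window_ms)
  amps <- family_amplitudes(bundle$long_steps)
  i_tau <- which.min(abs(amps - config$tau_sweep_pA))
  tau <- membrane_time_constant(bundle$long_steps[[i_tau]], as.numeric(r_in),
                                refine = config$tau_refine)
  sag <- sag_ratio(bundle$long_steps, rmp,
                   target_deflection_mV = config$sag_target_mV,
                   window_ms = config$steady_window_ms,
                   smooth_ms = config$sag_smooth_ms)
  structure(list(rmp_mV = rmp, r_in_MOhm = as.numeric(r_in),
                 tau_m_ms = tau$tau_m_ms, c_m_pF = tau$c_m_pF,
                 sag_ratio_pct = sag$sag_pct,
                 sag_sweep_amplitude_pA = sag$amplitude_pA),
            class = "passive_properties")
}
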
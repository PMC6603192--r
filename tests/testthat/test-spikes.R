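test_that("spike detection: crossings, refractory merge, empty trains", {
  flat <- mk_sweep(rep(-70, 2000), 20, 100, 10, 50)
  expect_length(detect_spikes(flat)$spike_times_ms, 0)

  times <- c(120, 155, 190, 228, 270, 315, 365, 420, 480, 545)
  sw <- pulse_sweep(times, rate = 20)
  got <- detect_spikes(sw)$spike_times_ms
  expect_length(got, 10)
  expect_true(all(abs(got - times) <= 1 / 20 + 1e-9))

  # two crossings 0.3 ms apart merge into one event
  v <- rep(-70, 200)
  v[c(50, 56)] <- 20  # 0.3 ms apart at 20 kHz
  expect_length(detect_spikes(mk_sweep(v, 20, 100, 0, 5))$spike_times_ms, 1)
})

test_that("detect_spikes agrees with a brute-force oracle on random traces", {
  set.seed(99)
  for (i in 1:100) {
    n <- 400
    v <- -70 + cumsum(rnorm(n, 0, 8))  # random walk crossing 0 repeatedly
    sw <- mk_sweep(v, 20, 100, 0, n / 20)
    got <- detect_spikes(sw)$spike_times_ms
    # oracle: scan crossings then greedy refractory merge
    cross <- which(v[-1] >= 0 & v[-n] < 0) + 1L
    tt <- (cross - 1) / 20
    keep <- c()
    for (t0 in tt) if (!length(keep) || t0 - keep[length(keep)] >= 1)
      keep <- c(keep, t0)
    expect_identical(got, as.numeric(keep))
  }
})

test_that("current threshold is the first spiking amplitude", {
  fam <- lapply(seq(100, 200, 10), function(a) {
    sw <- if (a >= 180) pulse_sweep(30, rate = 20, total_ms = 100,
                                    onset = 10, dur = 50, amp = a)
      else mk_sweep(rep(-70, 2000), 20, a, 10, 50)
    sw
  })
  expect_equal(current_threshold(fam), 180)
  silent <- lapply(seq(100, 150, 10), function(a)
    mk_sweep(rep(-70, 2000), 20, a, 10, 50))
  expect_error(current_threshold(silent), "no rheobase")
})

# one stylized triangular spike at t0 (ms): flat -40, rise to +20 in 1 ms,
# fall at -60 mV/ms down to `floor_mV`, then flat
tri_trace <- function(t0, rate = 10, total = 60, floor_mV = -48) {
  n <- round(total * rate)
  t <- (seq_len(n) - 1) / rate
  v <- rep(-40, n)
  rise <- t >= t0 & t < t0 + 1
  v[rise] <- -40 + 60 * (t[rise] - t0)
  fall <- t >= t0 + 1
  v[fall] <- pmax(floor_mV, 20 - 60 * (t[fall] - t0 - 1))
  v
}

test_that("AP threshold sits at the dv/dt breakpoint", {
  # piecewise ramp: 2 mV/ms for 5 ms then 50 mV/ms
  rate <- 20
  t <- seq(0, 8, by = 1 / rate)
  v <- ifelse(t <= 5, -50 + 2 * t, -40 + 50 * (t - 5))
  wave <- list(samples_mV = v, sampling_rate_kHz = rate,
               peak_index = length(v))
  thr <- ap_threshold(wave)
  expect_equal(thr$index, which(t == 5))  # centered diff first exceeds here
  expect_equal(thr$v_threshold_mV, -40)
  flatw <- list(samples_mV = rep(-70, 100), sampling_rate_kHz = rate,
                peak_index = 100)
  expect_error(ap_threshold(flatw), "no threshold")
})

test_that("AP threshold is stable under resampling 20 -> 50 kHz", {
  shape <- function(t) -55 + 35 * plogis((t - 5) * 3) + 40 * plogis((t - 6) * 8)
  for (rate in c(20, 50)) {
    t <- seq(0, 8, by = 1 / rate)
    w <- list(samples_mV = shape(t), sampling_rate_kHz = rate,
              peak_index = length(t))
    assign(paste0("v", rate), ap_threshold(w)$v_threshold_mV)
  }
  expect_lt(abs(v20 - v50), 0.5)
})

test_that("waveform features on the hand-built triangular spike", {
  v <- tri_trace(10)
  wave <- list(samples_mV = v, sampling_rate_kHz = 10,
               peak_index = which.max(v))
  f <- ap_features(wave)
  expect_equal(f$v_threshold_mV, -40, tolerance = 0.6)  # corner sample
  expect_equal(f$ap_amplitude_mV, 60, tolerance = 0.6)
  expect_equal(f$half_width_ms, 1, tolerance = 0.02)
  expect_equal(f$dvdt_max_mV_per_ms, 60, tolerance = 1e-9)
  expect_equal(f$dvdt_min_mV_per_ms, -60, tolerance = 1e-9)
  # monotone decay to -48 below threshold -40 -> AHP = -8
  expect_equal(f$ahp_mV, -8, tolerance = 0.6)
  # post-spike minimum at the window edge -> AHP missing
  v2 <- tri_trace(10, floor_mV = -400)[1:150]  # still falling at cut
  wave2 <- list(samples_mV = v2, sampling_rate_kHz = 10,
                peak_index = which.max(v2))
  f2 <- ap_features(wave2)
  expect_true(is.na(f2$ahp_mV))
})

test_that("waveform averaging needs five spikes and preserves identity", {
  sw5 <- pulse_sweep(c(15, 25, 35, 45, 55), rate = 20, total_ms = 100,
                     onset = 10, dur = 50)
  w <- average_ap_waveform(sw5)
  one <- sw5$samples_mV[(round(15 * 20) + 1 + 20 - 40):(round(15 * 20) + 1 + 20 + 200)]
  # five identical pulses: the average equals any single aligned window
  expect_equal(max(w$samples_mV), 20)
  expect_equal(w$samples_mV[w$peak_index], 20)
  sw3 <- pulse_sweep(c(15, 30, 45), rate = 20, total_ms = 100, onset = 10,
                     dur = 50)
  expect_error(average_ap_waveform(sw3), "need 5, found 3")
  # pooling repetitions across sweeps
  reps <- list(pulse_sweep(c(15, 30), rate = 20, total_ms = 100, onset = 10,
                           dur = 50),
               pulse_sweep(c(15, 30, 45), rate = 20, total_ms = 100,
                           onset = 10, dur = 50))
  expect_silent(average_ap_waveform(reps))
})

test_that("peak-aligned averaging tolerates one-sample jitter", {
  rate <- 20
  base <- function(shift) {
    v <- rep(-70, 2000)
    i0 <- 300 + shift
    v[i0:(i0 + 10)] <- c(seq(-70, 25, length.out = 6),
                         seq(15, -60, length.out = 5))
    mk_sweep(v, rate, 200, 10, 50)
  }
  sweeps <- lapply(c(0, 1, -1, 1, 0), base)
  w <- average_ap_waveform(sweeps)
  expect_equal(max(w$samples_mV), 25, tolerance = 25 * 0.01)
})

test_that("firing-rate curve and I-F slope", {
  fam <- lapply(seq(20, 200, 20), function(a) {
    n_sp <- max(0, round(a / 10) - 4)  # 0,0,2,4,... spikes
    times <- if (n_sp > 0) seq(120, 580, length.out = n_sp) else numeric(0)
    pulse_sweep(times, rate = 5, amp = a)
  })
  fi <- fi_curve(fam)
  expect_equal(fi$frequency_Hz, pmax(0, round(fi$amplitude_pA / 10) - 4) / 0.5)
  # 10 spikes in 500 ms -> 20 Hz
  one <- fi_curve(list(pulse_sweep(seq(110, 560, 50), rate = 5, amp = 100)))
  expect_equal(one$frequency_Hz, 20)
  silent <- fi_curve(lapply(c(20, 40), function(a)
    mk_sweep(rep(-70, 3500), 5, a, 100, 500)))
  expect_equal(silent$frequency_Hz, c(0, 0))

  # slope of exact polynomial relations
  fi_lin <- data.frame(amplitude_pA = seq(100, 300, 20),
                       frequency_Hz = 0.14 * seq(100, 300, 20))
  expect_equal(as.numeric(if_slope(fi_lin)), 14, tolerance = 1e-9)
  x <- seq(100, 300, 20)
  fi_quad <- data.frame(amplitude_pA = x,
                        frequency_Hz = 0.001 * x^2 + 0.12 * x)
  expect_equal(as.numeric(if_slope(fi_quad)), 12, tolerance = 1e-6)
  expect_error(if_slope(data.frame(amplitude_pA = c(1, 2),
                                   frequency_Hz = c(1, 2))), ">= 3")
})

test_that("first-AP latency uses the first suprathreshold sweep, post onset", {
  fam <- list(mk_sweep(rep(-70, 3500), 5, 20, 100, 500),
              pulse_sweep(260, rate = 5, amp = 40),   # first supra: 160 ms
              pulse_sweep(150, rate = 5, amp = 60))
  expect_equal(first_ap_latency(fam), 160)
  # spontaneous event before onset is ignored
  spont <- pulse_sweep(c(50, 300), rate = 5, amp = 40)
  expect_equal(first_ap_latency(list(spont)), 200)
  expect_error(first_ap_latency(list(mk_sweep(rep(-70, 3500), 5, 20,
                                              100, 500))),
               "no suprathreshold")
})

test_that("ISI statistics from the first >= 10-spike sweep", {
  times <- 110 + 50 * 0:9  # 10 spikes, ISI 50
  sw <- pulse_sweep(times, rate = 20, amp = 200)
  quiet <- mk_sweep(rep(-70, 14000), 20, 100, 100, 500)
  r <- isi_stats(list(quiet, sw))
  expect_equal(r$mean_isi_ms, 50)
  expect_equal(r$adaptation_ratio, 1)
  expect_equal(r$sweep_amplitude_pA, 200)
  # geometric ISIs x1.25: ratio = 1.25^-8
  isis <- 20 * 1.25^(0:8)
  tg <- 110 + cumsum(c(0, isis))
  rg <- isi_stats(list(pulse_sweep(tg, rate = 20, amp = 220,
                                   total_ms = 900, dur = 700)))
  expect_equal(rg$adaptation_ratio, 1.25^-8, tolerance = 0.01)
  expect_equal(rg$adaptation_ratio, 20 / 119.2, tolerance = 0.01)
  none <- isi_stats(list(quiet))
  expect_true(is.na(none$mean_isi_ms) && is.na(none$adaptation_ratio))
})

test_that("waveform features are DC-invariant; latency shifts predictably", {
  v <- tri_trace(10)
  w1 <- list(samples_mV = v, sampling_rate_kHz = 10, peak_index = which.max(v))
  w2 <- list(samples_mV = v + 5, sampling_rate_kHz = 10,
             peak_index = which.max(v))
  f1 <- ap_features(w1); f2 <- ap_features(w2)
  expect_equal(f1$ap_amplitude_mV, f2$ap_amplitude_mV)
  expect_equal(f1$half_width_ms, f2$half_width_ms)
  expect_equal(f1$ahp_mV, f2$ahp_mV)
  expect_equal(f2$v_threshold_mV - f1$v_threshold_mV, 5)
})
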
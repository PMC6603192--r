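# scaled-down protocols for fast cell simulation in tests
fast_prot <- function(...) sim_protocols(rate_kHz = 5, rest_s = 2,
                                         short_max_pA = 300, ...)
fast_cfg <- feature_config(rest_min_duration_s = 2)

test_that("simulation is deterministic per seed and unstable dt errors", {
  p <- synthetic_cell_params(seed = 123)
  b1 <- simulate_cell(p, fast_prot())
  b2 <- simulate_cell(p, fast_prot())
  expect_identical(b1$rest_trace$samples_mV, b2$rest_trace$samples_mV)
  expect_identical(b1$long_steps[[5]]$samples_mV,
                   b2$long_steps[[5]]$samples_mV)
  b3 <- simulate_cell(synthetic_cell_params(seed = 124), fast_prot())
  expect_false(identical(b1$rest_trace$samples_mV,
                         b3$rest_trace$samples_mV))
  # tau_m = 4 ms at 0.5 kHz sampling -> dt = 2 ms too coarse
  expect_error(
    simulate_cell(synthetic_cell_params(r_MOhm = 40, c_pF = 100),
                  sim_protocols(rate_kHz = 0.5, rest_s = 1)),
    "unstable integration")
})

test_that("noiseless ground-truth recovery: RMP, R_in, tau_m", {
  p <- synthetic_cell_params(e_leak_mV = -77.1, r_MOhm = 150,
                             c_pF = 25 / 150 * 1000,  # tau = 25 ms
                             gh_nS = 0, noise_sd_mV = 0, seed = 5)
  f <- extract_features(simulate_cell(p, fast_prot()), fast_cfg)
  expect_equal(f$rmp_mV, -77.1, tolerance = 1e-6)
  expect_lt(abs(f$r_in_MOhm - 150) / 150, 0.01)
  expect_lt(abs(f$tau_m_ms - 25) / 25, 0.01)
  expect_equal(f$c_m_pF * f$r_in_MOhm / 1000, f$tau_m_ms)
})

test_that("RMP recovered within 0.1 mV from a noisy 1-min rest trace", {
  p <- synthetic_cell_params(e_leak_mV = -77.1, noise_sd_mV = 0.5, seed = 9)
  b <- simulate_cell(p, sim_protocols(rate_kHz = 20, rest_s = 60,
                                      short_max_pA = 0,
                                      long_range_pA = c(-100, 0),
                                      n_waveform_reps = 0))
  expect_lt(abs(resting_membrane_potential(b$rest_trace) + 77.1), 0.1)
})

test_that("sag: zero conductance gives < 0.5%, tuned conductance recovers", {
  p0 <- synthetic_cell_params(gh_nS = 0, noise_sd_mV = 0, seed = 2)
  f0 <- extract_features(simulate_cell(p0, fast_prot()), fast_cfg)
  expect_lt(f0$sag_ratio_pct, 0.5)

  ph <- synthetic_cell_params(gh_nS = 2.5, noise_sd_mV = 0, seed = 2)
  fh <- extract_features(simulate_cell(ph, fast_prot()), fast_cfg)
  expect_gt(fh$sag_ratio_pct, 5)
  # noisy pipeline within 2 percentage points of the clean value
  phn <- synthetic_cell_params(gh_nS = 2.5, noise_sd_mV = 0.3, seed = 21)
  fhn <- extract_features(simulate_cell(phn, fast_prot()), fast_cfg)
  expect_lt(abs(fhn$sag_ratio_pct - fh$sag_ratio_pct), 2)
})

test_that("rheobase matches the closed-form LIF prediction (grid quantized)", {
  for (r in c(150, 250, 290)) {
    p <- synthetic_cell_params(r_MOhm = r, c_pF = 100, gh_nS = 0,
                               noise_sd_mV = 0, adapt_increment_pA = 0,
                               seed = 3)
    tau <- r * 100 / 1000
    i_star <- (p$v_threshold_mV - p$e_leak_mV) /
      (r * (1 - exp(-50 / tau)) / 1000)
    b <- simulate_cell(p, sim_protocols(rate_kHz = 20, rest_s = 1,
                                        short_max_pA = 500,
                                        long_range_pA = c(-100, 0),
                                        n_waveform_reps = 0))
    expect_equal(current_threshold(b$short_steps),
                 10 * ceiling(i_star / 10 - 1e-9))
  }
})

test_that("adaptation: ratio 1 without adaptation, monotone decrease with it", {
  ratios <- vapply(c(0, 10, 20, 30, 40), function(bq) {
    p <- synthetic_cell_params(adapt_increment_pA = bq, gh_nS = 0,
                               noise_sd_mV = 0, seed = 8)
    f <- extract_features(simulate_cell(p, fast_prot()), fast_cfg)
    f$adaptation_ratio
  }, numeric(1))
  expect_equal(ratios[1], 1, tolerance = 0.05)
  expect_true(all(diff(ratios) < 0))
})

test_that("firing-rate curve is nondecreasing in current (adapting LIF)", {
  p <- synthetic_cell_params(noise_sd_mV = 0, seed = 4)
  fi <- fi_curve(simulate_cell(p, fast_prot())$long_steps)
  expect_true(all(diff(fi$frequency_Hz) >= 0))
})

test_that("tree generator: limits and bookkept ground truth", {
  expect_error(generate_tree(n_primary = 0), "empty arbor")
  unb <- generate_tree(n_primary = 3, branch_prob = 0, seed = 1)
  s <- arbor_summary(unb)
  expect_equal(s$n_nodes, 0)
  expect_equal(s$n_ends, 3)

  for (seed in 1:30) {
    tr <- generate_tree(n_primary = sample(2:5, 1), branch_prob = 0.45,
                        max_order = 4, seed = seed)
    gt <- attr(tr, "ground_truth")
    s <- arbor_summary(tr)
    expect_equal(s$total_length_um, gt$total_length_um, tolerance = 1e-9)
    expect_equal(s$n_nodes, gt$n_nodes)
    expect_equal(s$n_ends, gt$n_ends)
    expect_equal(sort(s$terminal_orders), sort(gt$terminal_orders))
    expect_true(all(s$terminal_orders <= 4))
    # strict bifurcation: ends - nodes = primaries
    expect_equal(s$n_ends - s$n_nodes, s$n_primary)
  }
})

test_that("two-arbor neuron carries per-arbor truth and a soma contour", {
  nr <- generate_neuron(seed = 31)
  gt <- attr(nr, "ground_truth")
  expect_equal(arbor_summary(nr, "basal")$total_length_um,
               gt$basal$total_length_um, tolerance = 1e-9)
  expect_equal(arbor_summary(nr, "apical")$total_length_um,
               gt$apical$total_length_um, tolerance = 1e-9)
  expect_gt(as.numeric(soma_area(nr)), 0)
  expect_identical(attr(soma_area(nr), "provenance"), "contour")
  # SWC round trip of a generated neuron
  f <- tempfile(fileext = ".swc")
  write_swc(nr, f)
  expect_equal(read_swc(f)$nodes$x, nr$nodes$x)
})

test_that("cohort generator hits its targets and exercises the pipeline", {
  spec <- cohort_spec_from_table("prl_l23")
  n_seed <- 10
  cohorts <- lapply(seq_len(n_seed), function(s)
    suppressMessages(generate_cohort(spec, simulate = TRUE, seed = s)))
  expect_equal(nrow(cohorts[[1]]$features), 28 + 31)
  tg <- spec$targets
  for (grp in c("sham", "SNI")) {
    for (feat in c("rmp_mV", "r_in_MOhm", "tau_m_ms")) {
      r <- tg[tg$group == grp & tg$feature == feat, ]
      means <- vapply(cohorts, function(co)
        mean(co$features[co$features$group == grp, feat]), numeric(1))
      # unbiased targeting: pooled mean within 3 SE of the target
      z <- (mean(means) - r$mean) / (r$sd / sqrt(r$n * n_seed))
      expect_lt(abs(z), 3)
    }
  }
  # minimal cohort runs end-to-end
  tiny <- cohort_spec(data.frame(
    feature = rep("rmp_mV", 2), group = c("sham", "SNI"),
    mean = c(-77, -74), sd = c(3, 3), n = 2))
  co2 <- generate_cohort(tiny, simulate = TRUE, seed = 1)
  expect_equal(nrow(co2$features), 4)
})

test_that("behavior generator: exact averages and detectable allodynia", {
  beh0 <- generate_behavior(trial_sd_g = 0, seed = 1)
  merged <- merge(beh0$trials, beh0$thresholds,
                  by = c("subject", "group", "paw", "timepoint"))
  expect_equal(merged$force_g, merged$threshold_g)

  hits <- 0; n_rep <- 25
  for (s in 1:n_rep) {
    beh <- generate_behavior(seed = s)
    ipsi <- beh$thresholds[beh$thresholds$paw == "ipsi", ]
    an <- anova_two_way(ipsi, "threshold_g", "group", "timepoint",
                        subject = "subject", repeated = TRUE)
    if (an$p[an$effect == "group:timepoint"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, round(0.9 * n_rep))
  # contralateral paw: null interaction most of the time
  fp <- 0
  for (s in 1:n_rep) {
    beh <- generate_behavior(seed = 100 + s)
    con <- beh$thresholds[beh$thresholds$paw == "contra", ]
    an <- anova_two_way(con, "threshold_g", "group", "timepoint",
                        subject = "subject", repeated = TRUE)
    if (an$p[an$effect == "group:timepoint"] < 0.05) fp <- fp + 1
  }
  expect_lte(fp, ceiling(0.2 * n_rep))
})
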
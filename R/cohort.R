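#' Cohort specification
#'
#' Per-group, per-feature target mean and SD for synthetic cohorts.  When
#' building a spec from a published table row, SDs are reconstructed as
#' `SEM * sqrt(n)` (only means, SEMs and n are printed).
#'
#' @param targets data frame with columns `feature`, `group`, `mean`,
#'   `sd`, `n`
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(targets) {
  req <- c("feature", "group", "mean", "sd", "n")
  stopifnot(is.data.frame(targets), all(req %in% names(targets)))
  if (any(targets$n < 2)) stop("group sizes must be >= 2", call. = FALSE)
  if (any(targets$sd <= 0)) stop("target SDs must be > 0", call. = FALSE)
  structure(list(targets = targets), class = "cohort_spec")
}

#' Cohort spec from a published table
#'
#' Builds a [cohort_spec()] targeting the printed group means of selected
#' features of one comparison table, with `SD = SEM * sqrt(n)`.
#'
#' @param table_id one of `"prl_l23"`, `"prl_l5"`, `"il_l23"`, `"il_l5"`
#' @param features feature names as in [published_tables()]; default the
#'   three latent passive properties the simulator can target directly
#' @param n override the per-group sample sizes (default: printed n)
#' @return a [cohort_spec()]
#' @export
cohort_spec_from_table <- function(table_id,
                                   features = c("rmp_mV", "r_in_MOhm",
                                                "tau_m_ms"),
                                   n = NULL) {
  tab <- published_tables(table_id)
  tab <- tab[tab$feature %in% features, ]
  if (nrow(tab) == 0) stop("no matching features in table ", table_id,
                           call. = FALSE)
  mk <- function(grp) {
    mean_col <- paste0(grp, "_mean"); sem_col <- paste0(grp, "_sem")
    n_col <- paste0(grp, "_n")
    nn <- if (is.null(n)) tab[[n_col]] else rep(n, nrow(tab))
    data.frame(feature = tab$feature, group = if (grp == "sham") "sham" else "SNI",
               mean = tab[[mean_col]], sd = tab[[sem_col]] * sqrt(tab[[n_col]]),
               n = nn)
  }
  cohort_spec(rbind(mk("sham"), mk("sni")))
}

# latent features the simulator can target directly
latent_features <- c("rmp_mV", "r_in_MOhm", "tau_m_ms")

#' Generate a synthetic sham/SNI cohort
#'
#' Draws per-cell latent parameters from the spec's normal targets and
#' either (a) simulates full current-clamp recordings per cell and runs
#' the real extraction pipeline over them (`simulate = TRUE`; targeting at
#' the latent-parameter level, verified by closed-loop recovery), or (b)
#' returns the latent draws directly as the feature table
#' (`simulate = FALSE`; used for large statistical calibration runs where
#' trace-level simulation adds nothing but cost).
#'
#' Latent targeting maps `rmp_mV` to the leak reversal, `r_in_MOhm` to the
#' membrane resistance (redrawn while <= 20 MOhm, with a message) and
#' `tau_m_ms` to the capacitance via `C = tau / R`.  Non-latent features in
#' the spec are drawn directly (they appear only in the feature table).
#'
#' @param spec a [cohort_spec()]
#' @param simulate run the trace-level pipeline (default `TRUE`)
#' @param protocols [sim_protocols()] for the simulated recordings; the
#'   default is a scaled-down protocol set (short rest trace, reduced
#'   sampling rate, subthreshold long family) adequate for the passive
#'   features
#' @param config [feature_config()] used by the extraction
#' @param noise_sd_mV recording noise handed to the simulator
#' @param seed integer seed
#' @return list with `features` (per-cell data frame with `cell_id`,
#'   `group` and one column per feature), `bundles` (list, when simulated)
#'   and `spec`
#' @export
generate_cohort <- function(spec, simulate = TRUE,
                            protocols = cohort_protocols(),
                            config = cohort_config(protocols),
                            noise_sd_mV = 0.3, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  tg <- spec$targets
  groups <- unique(tg$group)
  feats <- unique(tg$feature)
  draw <- function(feature, group, n) {
    r <- tg[tg$feature == feature & tg$group == group, ]
    if (nrow(r) != 1) return(rep(NA_real_, n))
    rnorm(n, r$mean, r$sd)
  }
  features <- list(); bundles <- list()
  for (grp in groups) {
    n <- unique(tg$n[tg$group == grp])[1]
    latent <- list(
      rmp = if ("rmp_mV" %in% feats) draw("rmp_mV", grp, n) else rep(-75, n),
      r_in = if ("r_in_MOhm" %in% feats) draw("r_in_MOhm", grp, n) else rep(150, n),
      tau = if ("tau_m_ms" %in% feats) draw("tau_m_ms", grp, n) else rep(25, n))
    # infeasible draws (non-physiological resistance/time constant) are
    # redrawn by truncation
    for (nm in c("r_in", "tau")) {
      r <- tg[tg$feature == c(r_in = "r_in_MOhm", tau = "tau_m_ms")[nm] &
                tg$group == grp, ]
      # feasibility floors: pyramidal cells below 20 MOhm or tau below 5 ms
      # are non-physiological (and too stiff for the scaled integrator)
      lo <- c(r_in = 20, tau = 5)[nm]
      bad <- which(latent[[nm]] <= lo)
      n_resampled <- 0L
      while (length(bad) && nrow(r) == 1) {
        n_resampled <- n_resampled + length(bad)
        latent[[nm]][bad] <- rnorm(length(bad), r$mean, r$sd)
        bad <- which(latent[[nm]] <= lo)
      }
      if (n_resampled > 0L)
        message(grp, "/", nm, ": ", n_resampled,
                " infeasible draw(s) resampled by truncation")
    }
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("%s-%03d", grp, i)
      if (simulate) {
        par <- synthetic_cell_params(
          e_leak_mV = latent$rmp[i], r_MOhm = latent$r_in[i],
          c_pF = latent$tau[i] / latent$r_in[i] * 1000,
          noise_sd_mV = noise_sd_mV,
          seed = sample.int(.Machine$integer.max, 1))
        b <- simulate_cell(par, protocols, cell_id = id,
                           meta = cell_meta(grp))
        bundles[[id]] <- b
        row <- extract_features(b, config)
      } else {
        row <- data.frame(cell_id = id, rmp_mV = latent$rmp[i],
                          r_in_MOhm = latent$r_in[i],
                          tau_m_ms = latent$tau[i])
      }
      # non-latent targeted features are painted directly onto the table
      for (f in setdiff(feats, latent_features))
        row[[f]] <- draw(f, grp, 1)
      row$group <- grp
      rows[[i]] <- row
    }
    features[[grp]] <- do.call(rbind, rows)
  }
  features <- do.call(rbind, features)
  rownames(features) <- NULL
  list(features = features, bundles = if (simulate) bundles, spec = spec)
}

#' Scaled-down protocol set for cohort simulation
#'
#' Passive-feature cohorts only need the rest trace and the subthreshold
#' long family, so Monte-Carlo runs use a 5-s rest trace at 2 kHz and the
#' -100...0 pA long family, omitting the 50-ms family entirely (spike
#' features come out `NA`).  The analysis definitions are unchanged; only
#' the data volume shrinks.
#'
#' @param rate_kHz sampling rate
#' @param rest_s rest duration
#' @param long_max_pA top of the long family
#' @return a [sim_protocols()]
#' @export
cohort_protocols <- function(rate_kHz = 2, rest_s = 5, long_max_pA = 0) {
  sim_protocols(rate_kHz = rate_kHz, rest_s = rest_s, short_max_pA = 0,
                long_range_pA = c(-100, long_max_pA), n_waveform_reps = 0)
}

# matching analysis config: accept the short rest trace
#' @rdname cohort_protocols
#' @param protocols the protocol set to accept
#' @export
cohort_config <- function(protocols = cohort_protocols()) {
  feature_config(rest_min_duration_s = protocols$rest_s)
}

#' Generate a mechanical withdrawal-threshold table
#'
#' Emulates the dynamic plantar test: three consecutive trials per paw per
#' timepoint, with the threshold defined as the average of the three
#' trials.  The injured-paw post-surgery mean drops for the SNI group
#' (mechanical allodynia); the contralateral paw is unaffected.
#'
#' @param n_per_group animals per group
#' @param baseline_g baseline withdrawal threshold (grams)
#' @param sni_post_g post-surgery mean of the SNI group's injured paw
#' @param sham_post_g post-surgery mean for sham (default: baseline)
#' @param between_sd_g between-animal SD
#' @param trial_sd_g within-animal trial SD
#' @param seed integer seed
#' @return list with `trials` (long table: subject, group, paw, timepoint,
#'   trial, force_g) and `thresholds` (averaged per the three-trial rule)
#' @export
generate_behavior <- function(n_per_group = 10, baseline_g = 7.5,
                              sni_post_g = 3.5, sham_post_g = baseline_g,
                              between_sd_g = 0.8, trial_sd_g = 0.5,
                              seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(subject = seq_len(2 * n_per_group),
                      paw = c("ipsi", "contra"),
                      timepoint = c("baseline", "post7d"),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$subject <= n_per_group, "sham", "SNI")
  subj_offset <- rnorm(2 * n_per_group, 0, between_sd_g)
  grid$mu <- baseline_g + subj_offset[grid$subject]
  drop <- grid$group == "SNI" & grid$paw == "ipsi" & grid$timepoint == "post7d"
  grid$mu[drop] <- grid$mu[drop] - (baseline_g - sni_post_g)
  sham_drop <- grid$group == "sham" & grid$paw == "ipsi" &
    grid$timepoint == "post7d"
  grid$mu[sham_drop] <- grid$mu[sham_drop] - (baseline_g - sham_post_g)
  trials <- grid[rep(seq_len(nrow(grid)), each = 3), ]
  trials$trial <- rep(1:3, nrow(grid))
  trials$force_g <- pmax(0, rnorm(nrow(trials), trials$mu, trial_sd_g))
  trials$mu <- NULL
  thr <- aggregate(force_g ~ subject + group + paw + timepoint, trials, mean)
  names(thr)[names(thr) == "force_g"] <- "threshold_g"
  list(trials = trials, thresholds = thr)
}
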
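#' Group summary (mean, SEM, n)
#'
#' @param x numeric vector, or leave `x` missing and pass `mean`, `sem`,
#'   `n` directly (e.g. values printed in a publication table)
#' @param mean,sem,n summary components when `x` is not given
#' @return list of class `group_summary`
#' @export
group_summary <- function(x = NULL, mean = NULL, sem = NULL, n = NULL) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    n <- length(x)
    mean <- base::mean(x)
    sem <- sd(x) / sqrt(n)
  }
  if (n < 2) stop("group_summary needs n >= 2", call. = FALSE)
  if (!is.null(sem) && !is.na(sem) && sem <= 0)
    stop("sem must be positive", call. = FALSE)
  structure(list(mean = mean, sem = sem, n = n), class = "group_summary")
}

new_stat_result <- function(statistic, df, p, label, adjusted_p = NULL) {
  stopifnot(p >= 0, p <= 1)
  structure(list(statistic = statistic, df = df, p_two_tailed = p,
                 label = label, adjusted_p = adjusted_p),
            class = "group_stat_result")
}

#' @export
print.group_stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$label,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_two_tailed))
  invisible(x)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical pooled-variance two-tailed Student's t-test,
#' `df = n_a + n_b - 2`.  A Welch option is available but is not the
#' default, matching the test battery used for the group tables.
#'
#' @param a,b numeric vectors (each n >= 2)
#' @param var_equal pooled variance (default `TRUE`); `FALSE` gives Welch
#' @return a `group_stat_result`
#' @export
ttest_two_sample <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 <= 0)
      stop("degenerate data: zero pooled variance", call. = FALSE)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    label <- "Student t (pooled)"
  } else {
    se2 <- va / na + vb / nb
    if (se2 <= 0) stop("degenerate data: zero variance", call. = FALSE)
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    label <- "Welch t"
  }
  new_stat_result(t, df, 2 * pt(-abs(t), df), label)
}

#' Student's t-test from printed summary statistics
#'
#' Reconstructs the pooled two-sample t-test from group means, SEMs and
#' sample sizes as printed in publication tables: `SD_i = SEM_i * sqrt(n_i)`,
#' pooled variance `((n_a-1) SD_a^2 + (n_b-1) SD_b^2) / (n_a+n_b-2)`,
#' `t = (mean_a - mean_b) / (s_p * sqrt(1/n_a + 1/n_b))`, two-tailed p at
#' `n_a + n_b - 2` degrees of freedom.  Applied to a summary computed from
#' raw data it reproduces [ttest_two_sample()] exactly.
#'
#' @param a,b [group_summary()] objects
#' @return a `group_stat_result`
#' @export
ttest_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sda <- a$sem * sqrt(a$n)
  sdb <- b$sem * sqrt(b$n)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * sda^2 + (b$n - 1) * sdb^2) / df
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  new_stat_result(t, df, 2 * pt(-abs(t), df), "Student t (from summary)")
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1.  Monotone in `p` and bounded
#' above by the Bonferroni adjustment `m * p`.
#'
#' @param p_values vector of raw p-values
#' @param m number of comparisons (default `length(p_values)`)
#' @return adjusted p-values
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(m >= 1, all(p_values >= 0 & p_values <= 1))
  pmin(1, 1 - (1 - p_values)^m)
}

#' Second-order polynomial least-squares fit
#'
#' Fits `y = a x^2 + b x + c` by ordinary least squares.  The linear
#' coefficient `b` is the quantity reported as the input-frequency slope.
#'
#' @param x,y numeric vectors (>= 3 points)
#' @return list with `coefficients` (named `a`, `b`, `c`), `se` (standard
#'   errors, `NA` with exactly 3 points) and the underlying `lm` fit
#' @export
poly2_fit <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x))
    stop("poly2_fit needs >= 3 (x, y) points", call. = FALSE)
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design: x values do not span a quadratic",
         call. = FALSE)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  se <- if (nrow(sm) == 3 && length(x) > 3) sm[, "Std. Error"] else rep(NA_real_, 3)
  list(coefficients = c(a = unname(cf[3]), b = unname(cf[2]),
                        c = unname(cf[1])),
       se = c(a = unname(se[3]), b = unname(se[2]), c = unname(se[1])),
       fit = fit)
}

#' Two-way ANOVA, plain or with repeated measures
#'
#' Partitioned-sums-of-squares two-factor ANOVA for the group-by-level
#' designs used with firing-rate and Sholl curves.  With
#' `repeated = FALSE` both factors are between-subject (sequential
#' partition via `aov`).  With `repeated = TRUE` the classical univariate
#' mixed partition is used: the between factor (`a`) is tested against the
#' subject-within-group stratum and the within factor (`b`) and the
#' interaction against the subject-by-level stratum.  No sphericity
#' correction is applied by default; `gg_correction = TRUE` applies the
#' Greenhouse-Geisser epsilon to the within-factor tests.
#'
#' @param data data frame in long format
#' @param response,a,b,subject column names: response value, between
#'   factor, second (within or between) factor, and subject id (required
#'   when `repeated = TRUE`)
#' @param repeated treat `b` as a within-subject factor
#' @param gg_correction Greenhouse-Geisser correction for within tests
#' @return data frame with one row per effect: `effect`, `df1`, `df2`,
#'   `ss`, `F`, `p`
#' @export
anova_two_way <- function(data, response, a, b, subject = NULL,
                          repeated = FALSE, gg_correction = FALSE) {
  d <- data.frame(y = data[[response]],
                  A = factor(data[[a]]), B = factor(data[[b]]))
  if (anyNA(d$y)) stop("missing response values", call. = FALSE)
  # constant response: every SS is zero (up to rounding), conventionally
  # all F = 0 and p = 1
  y_const <- var(d$y) < .Machine$double.eps * mean(d$y)^2 * 100 ||
    var(d$y) == 0
  fix_degenerate <- function(out) {
    if (y_const) {
      out$F[] <- 0; out$p[] <- 1; out$ss[] <- 0
    }
    out
  }
  maybe_quiet <- if (y_const) suppressWarnings else identity
  if (!repeated) {
    fit <- aov(y ~ A * B, data = d)
    tab <- maybe_quiet(anova(fit))
    eff <- rownames(tab)
    resid_row <- which(eff == "Residuals")
    out <- data.frame(
      effect = c(a, b, paste0(a, ":", b)),
      df1 = tab$Df[1:3], df2 = tab$Df[resid_row], ss = tab$`Sum Sq`[1:3],
      F = tab$`F value`[1:3], p = tab$`Pr(>F)`[1:3])
    attr(out, "ss_residual") <- tab$`Sum Sq`[resid_row]
    attr(out, "ss_total") <- sum(tab$`Sum Sq`)
    return(fix_degenerate(out))
  }
  if (is.null(subject))
    stop("repeated-measures ANOVA needs a subject column", call. = FALSE)
  d$S <- factor(data[[subject]])
  # every subject must be observed at every level of B
  tab_sb <- table(d$S, d$B)
  if (any(tab_sb == 0)) {
    idx <- which(tab_sb == 0, arr.ind = TRUE)[1, ]
    stop("missing cell in repeated design: subject ",
         rownames(tab_sb)[idx[1]], " has no observation at ", b, " = ",
         colnames(tab_sb)[idx[2]], call. = FALSE)
  }
  fit <- aov(y ~ A * B + Error(S/B), data = d)
  sm <- maybe_quiet(summary(fit))
  # between stratum: A against subjects-within-groups
  s_between <- sm[["Error: S"]][[1]]
  s_within <- sm[["Error: S:B"]][[1]]
  get_row <- function(strat, name) {
    i <- match(name, trimws(rownames(strat)))
    list(df = strat$Df[i], ss = strat$`Sum Sq`[i], F = strat$`F value`[i],
         p = strat$`Pr(>F)`[i])
  }
  rA <- get_row(s_between, "A")
  rB <- get_row(s_within, "B")
  rAB <- get_row(s_within, "A:B")
  df2_between <- s_between$Df[match("Residuals", trimws(rownames(s_between)))]
  df2_within <- s_within$Df[match("Residuals", trimws(rownames(s_within)))]
  pB <- rB$p; pAB <- rAB$p; dfB1 <- rB$df; dfAB1 <- rAB$df; df2w <- df2_within
  if (gg_correction) {
    eps <- gg_epsilon(d)
    pB <- pf(rB$F, eps * dfB1, eps * df2w, lower.tail = FALSE)
    pAB <- pf(rAB$F, eps * dfAB1, eps * df2w, lower.tail = FALSE)
  }
  out <- data.frame(
    effect = c(a, b, paste0(a, ":", b)),
    df1 = c(rA$df, dfB1, dfAB1),
    df2 = c(df2_between, df2w, df2w),
    ss = c(rA$ss, rB$ss, rAB$ss),
    F = c(rA$F, rB$F, rAB$F),
    p = c(rA$p, pB, pAB))
  attr(out, "ss_residual") <- c(between = s_between$`Sum Sq`[
    match("Residuals", trimws(rownames(s_between)))], within = s_within$`Sum Sq`[
      match("Residuals", trimws(rownames(s_within)))])
  attr(out, "gg_correction") <- gg_correction
  fix_degenerate(out)
}

# Greenhouse-Geisser epsilon from the subject x level matrix
gg_epsilon <- function(d) {
  m <- tapply(d$y, list(d$S, d$B), mean)
  S <- stats::cov(m, use = "complete.obs")
  k <- ncol(S)
  mean_diag <- mean(diag(S)); mean_all <- mean(S)
  num <- (k * (mean_diag - mean_all))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * mean(rowMeans(S)^2) + k^2 * mean_all^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Sidak-adjusted per-level post-hoc comparisons
#'
#' After a two-way ANOVA on a group-by-level layout, compares the two
#' groups at every level of `b` with pooled t-tests and applies the Sidak
#' adjustment across levels.
#'
#' @param data long-format data frame
#' @param response,a,b column names as in [anova_two_way()]
#' @return data frame with `level`, `t`, `df`, `p`, `p_adj`
#' @export
posthoc_sidak <- function(data, response, a, b) {
  d <- data.frame(y = data[[response]], A = factor(data[[a]]),
                  B = factor(data[[b]]))
  if (nlevels(d$A) != 2)
    stop("post-hoc comparisons expect exactly two groups", call. = FALSE)
  lv <- levels(d$B)
  res <- lapply(lv, function(l) {
    dd <- d[d$B == l, ]
    r <- ttest_two_sample(dd$y[dd$A == levels(d$A)[1]],
                          dd$y[dd$A == levels(d$A)[2]])
    data.frame(level = l, t = r$statistic, df = r$df, p = r$p_two_tailed)
  })
  out <- do.call(rbind, res)
  out$p_adj <- sidak_adjust(out$p, m = length(lv))
  out
}
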
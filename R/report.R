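#' Build a publication-style group-comparison table
#'
#' Summarizes a per-cell feature table into mean +/- SEM (n) per group per
#' feature, with a pooled two-tailed t-test per row and a significance
#' star at p < 0.05.  Rows where either group has fewer than two values
#' are marked not testable.
#'
#' @param features data frame with a `group` column and numeric feature
#'   columns (e.g. from [generate_cohort()] or [extract_features()] rows
#'   joined to metadata)
#' @param group_col name of the grouping column (two groups expected)
#' @param alpha star threshold, fixed at the conventional 0.05
#' @return data frame with one row per feature: per-group mean/SEM/n, `t`,
#'   `df`, `p`, `star`, `testable`
#' @export
build_group_table <- function(features, group_col = "group", alpha = 0.05) {
  stopifnot(group_col %in% names(features))
  g <- factor(features[[group_col]])
  if (nlevels(g) > 2)
    stop("build_group_table expects at most two groups", call. = FALSE)
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  rows <- lapply(num_cols, function(f) {
    x <- split(features[[f]], g)
    x <- lapply(x, function(v) v[!is.na(v)])
    s <- lapply(x, function(v)
      c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v)))
    out <- data.frame(feature = f,
                      g1 = levels(g)[1],
                      g1_mean = s[[1]]["mean"], g1_sem = s[[1]]["sem"],
                      g1_n = s[[1]]["n"])
    if (nlevels(g) == 2) {
      out$g2 <- levels(g)[2]
      out$g2_mean <- s[[2]]["mean"]; out$g2_sem <- s[[2]]["sem"]
      out$g2_n <- s[[2]]["n"]
      testable <- s[[1]]["n"] >= 2 && s[[2]]["n"] >= 2 &&
        (var(x[[1]]) + var(x[[2]])) > 0
      if (testable) {
        r <- ttest_two_sample(x[[1]], x[[2]])
        out$t <- r$statistic; out$df <- r$df; out$p <- r$p_two_tailed
      } else {
        out$t <- out$df <- out$p <- NA_real_
      }
      out$star <- !is.na(out$p) & out$p < alpha
      out$testable <- isTRUE(testable)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Morphometric summary row for one reconstruction
#'
#' @param tree a [neuron_tree()]
#' @param cell_id identifier carried into the row
#' @return one-row data frame with basal and apical arbor summaries,
#'   complexity indices and the soma area
#' @export
morphometry_row <- function(tree, cell_id = "cell") {
  one <- function(arbor) {
    s <- tryCatch(arbor_summary(tree, arbor), error = function(e) NULL)
    if (is.null(s))
      return(setNames(rep(NA_real_, 6),
                      paste0(arbor, "_", c("number", "nodes", "ends",
                                           "total_length_um",
                                           "mean_length_um", "complexity"))))
    setNames(c(s$n_primary, s$n_nodes, s$n_ends, s$total_length_um,
               s$mean_length_um,
               (sum(s$terminal_orders) + s$n_ends) *
                 (s$total_length_um / s$n_primary)),
             paste0(arbor, "_", c("number", "nodes", "ends",
                                  "total_length_um", "mean_length_um",
                                  "complexity")))
  }
  vals <- c(one("basal"), one("apical"),
            soma_area_um2 = as.numeric(soma_area(tree)))
  cbind(data.frame(cell_id = cell_id), as.data.frame(as.list(vals)))
}

#' Group Sholl curves and treatment-effect ANOVA
#'
#' Assembles per-cell Sholl profiles into a long table (cell, group,
#' radius, intersections, shell length) and runs the two-way
#' treatment-by-distance ANOVA on each measure, plain or with repeated
#' measures over distance.
#'
#' @param profiles named list of [sholl()] results, one per cell
#' @param groups character vector of group labels aligned with `profiles`
#' @param repeated treat distance as a within-cell factor
#' @param max_radius_um truncate profiles to a common radius (default: the
#'   largest radius present in every profile)
#' @return list with `long` (the assembled table) and `anova` (list with
#'   elements `intersections` and `length`)
#' @export
sholl_group_analysis <- function(profiles, groups, repeated = FALSE,
                                 max_radius_um = NULL) {
  stopifnot(length(profiles) == length(groups))
  if (is.null(max_radius_um))
    max_radius_um <- min(vapply(profiles, function(p)
      max(p$ring_radii_um), numeric(1)))
  long <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    keep <- p$ring_radii_um <= max_radius_um + 1e-9
    data.frame(cell = i, group = groups[i],
               radius_um = p$ring_radii_um[keep],
               intersections = p$intersections[keep],
               shell_length_um = p$length_per_shell_um[keep])
  }))
  an <- list(
    intersections = anova_two_way(long, "intersections", "group",
                                  "radius_um", subject = "cell",
                                  repeated = repeated),
    length = anova_two_way(long, "shell_length_um", "group", "radius_um",
                           subject = "cell", repeated = repeated))
  list(long = long, anova = an)
}
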
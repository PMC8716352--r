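# Targeting-error geometry and study-level statistics. Per needle the
# error has three components: the angular deviation D between planned
# trajectory AB and actual needle AC; the absolute deviation |BC|
# from planned target to actual tip; and the longitudinal deviation
# |CC'|, where C' is the planned-depth point on the ACTUAL trajectory
# (C' = A + |AB| * unit(AC)). The robot fixes the trajectory but the
# insertion depth is manual, so |CC'| isolates the depth error.

#' Per-needle targeting errors
#'
#' @param A planned (= actual) entry point, mm.
#' @param B planned target point, mm.
#' @param C actual needle tip, mm.
#' @return A `deviation_metrics` list: `angular_deg`, `absolute_mm`,
#'   `longitudinal_mm`.
#' @section Errors: `cbctnav_validation` when C coincides with A (the
#'   actual trajectory, hence the angle, is undefined) or A equals B.
#' @examples
#' targeting_errors(c(0, 0, 0), c(0, 0, 100), c(2, 0, 100))
#' @export
targeting_errors <- function(A, B, C) {
  a <- as_point3(A, "A"); b <- as_point3(B, "B"); cc <- as_point3(C, "C")
  ab <- b - a; ac <- cc - a
  nab <- sqrt(sum(ab^2)); nac <- sqrt(sum(ac^2))
  cbct_check(nab > 0, "cbctnav_validation", "A and B coincide: planned trajectory undefined")
  cbct_check(nac > 0, "cbctnav_validation", "C coincides with A: angular deviation undefined")
  cosang <- sum(ab * ac) / (nab * nac)
  angular <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  c_prime <- a + nab * ac / nac
  structure(list(angular_deg = angular,
                 absolute_mm = sqrt(sum((cc - b)^2)),
                 longitudinal_mm = sqrt(sum((cc - c_prime)^2))),
            class = "deviation_metrics")
}

#' Summary statistics for one metric in one group
#'
#' Sample statistics with the n-1 denominator for the standard
#' deviation, as in the usual study table. A single observation gets
#' `std = 0` with `degenerate = TRUE`.
#'
#' @param values numeric vector, n >= 1.
#' @return `list(n, mean, std, min, max, degenerate)`.
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  cbct_check(length(values) >= 1 && all(is.finite(values)),
             "cbctnav_validation", "values must be a nonempty finite numeric vector")
  n <- length(values)
  list(n = n, mean = mean(values),
       std = if (n > 1) sd(values) else 0,
       min = min(values), max = max(values),
       degenerate = n < 2)
}

#' One-way ANOVA for two groups, from sums of squares
#'
#' Classic single-factor analysis of variance computed from first
#' principles: between-group and within-group sums of squares, F as
#' the ratio of mean squares, p from the F survival function. With
#' zero within-group variance and unequal means the F statistic is
#' infinite (reported as `Inf`, p = 0); identical groups give F = 0,
#' p = 1.
#'
#' @param group_a_values,group_b_values numeric vectors, each n >= 2.
#' @return An `anova_result`: `f_stat`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
one_way_anova <- function(group_a_values, group_b_values) {
  a <- as.numeric(group_a_values); b <- as.numeric(group_b_values)
  cbct_check(length(a) >= 2 && length(b) >= 2, "cbctnav_validation",
             "each group needs at least 2 observations")
  groups <- list(a, b)
  ns <- lengths(groups)
  n <- sum(ns)
  grand <- sum(a) / n + sum(b) / n
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_between <- length(groups) - 1L
  df_within <- n - length(groups)
  if (ss_within == 0) {
    if (ss_between == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (ss_between / df_between) / (ss_within / df_within)
    p <- pf(f, df_between, df_within, lower.tail = FALSE)
  }
  structure(list(f_stat = f, df_between = df_between, df_within = df_within,
                 p_value = p),
            class = "anova_result")
}

#' Study-level report: per-group summaries, ANOVA, success rate
#'
#' Builds the study table from a list of simulated (or measured)
#' needle outcomes: for each of the three deviation metrics plus
#' procedural time and iteration count, the overall / in-plane /
#' out-of-plane summaries (`n`, mean, std, min, max) and the
#' between-group one-way ANOVA p-value; plus the technical success
#' rate, the fraction of needles whose tip lies inside the target
#' lesion sphere.
#'
#' @param outcomes list of `needle_outcome`s, e.g. from
#'   [simulate_study()].
#' @param lesion_radius success radius, mm; defaults to each
#'   outcome's own `lesion_radius` (5 mm if absent).
#' @return A `study_report`: `metrics` (per-metric list of `overall`,
#'   `in_plane`, `out_of_plane` summaries and `anova`),
#'   `success_rate` (fraction in `[0, 1]`), `n_outcomes`,
#'   `per_needle` (data.frame of raw per-needle values).
#' @export
study_summary <- function(outcomes, lesion_radius = NULL) {
  cbct_check(length(outcomes) >= 2, "cbctnav_validation",
             "need at least 2 outcomes to summarise")
  rows <- lapply(seq_along(outcomes), function(i) {
    o <- outcomes[[i]]
    dev <- targeting_errors(o$entry_A, o$target_B, o$tip_C)
    r <- lesion_radius %||% o$lesion_radius %||% 5
    data.frame(needle = i, group = o$group_label,
               angular_deg = dev$angular_deg,
               absolute_mm = dev$absolute_mm,
               longitudinal_mm = dev$longitudinal_mm,
               time_s = o$procedural_time_s,
               iterations = o$iterations,
               hit = dev$absolute_mm <= r)
  })
  per_needle <- do.call(rbind, rows)

  metric_cols <- c("angular_deg", "absolute_mm", "longitudinal_mm",
                   "time_s", "iterations")
  in_rows <- per_needle$group == "in_plane"
  metrics <- lapply(metric_cols, function(m) {
    va <- per_needle[[m]][in_rows]
    vb <- per_needle[[m]][!in_rows]
    list(overall = summarize_group(per_needle[[m]]),
         in_plane = if (length(va)) summarize_group(va) else NULL,
         out_of_plane = if (length(vb)) summarize_group(vb) else NULL,
         anova = if (length(va) >= 2 && length(vb) >= 2)
           one_way_anova(va, vb) else NULL)
  })
  names(metrics) <- metric_cols

  structure(list(metrics = metrics,
                 success_rate = mean(per_needle$hit),
                 n_outcomes = nrow(per_needle),
                 per_needle = per_needle),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(format_study_report(x), sep = "\n")
  invisible(x)
}

#' Format a study report as an aligned text table
#'
#' @param report a [study_summary()] result.
#' @return Character vector of lines.
#' @export
format_study_report <- function(report) {
  fmt_row <- function(label, s) {
    if (is.null(s)) return(NULL)
    sprintf("  %-13s n=%2d  mean %8.3f  std %8.3f  min %8.3f  max %8.3f",
            label, s$n, s$mean, s$std, s$min, s$max)
  }
  titles <- c(angular_deg = "Angular deviation D [deg]",
              absolute_mm = "Absolute deviation |BC| [mm]",
              longitudinal_mm = "Longitudinal deviation |CC'| [mm]",
              time_s = "Procedural time [s]",
              iterations = "Iterations [count]")
  lines <- c(sprintf("Study report: %d needle placements, technical success %.1f%%",
                     report$n_outcomes, 100 * report$success_rate))
  for (m in names(report$metrics)) {
    mm <- report$metrics[[m]]
    lines <- c(lines, titles[[m]],
               fmt_row("overall", mm$overall),
               fmt_row("in-plane", mm$in_plane),
               fmt_row("off-plane", mm$out_of_plane),
               if (!is.null(mm$anova))
                 sprintf("  p (in/off)    %.4f  (F=%.4g, df=%d,%d)",
                         mm$anova$p_value, mm$anova$f_stat,
                         mm$anova$df_between, mm$anova$df_within))
  }
  lines
}
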
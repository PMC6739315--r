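# Dynamics observables: activation-curve summaries (E_max, t-E_max, EC50,
# t-EC50), phase segmentation, mechanical-memory baseline metrics, matrix
# deposition rates, and replicate aggregation with the standard group
# tests.

#' Summarise an activation time series
#'
#' \code{E_max} is the series maximum, \code{t_E_max} the time of its first
#' attainment, \code{EC50} exactly \code{E_max/2}, and \code{t_EC50} the
#' first time the series reaches or exceeds \code{EC50}; ties resolve to
#' the earliest sample.
#'
#' @param time Sample times (s), strictly increasing.
#' @param values Non-negative counts at those times.
#' @return Object of class \code{dynamics_summary}.
#' @export
summarize_dynamics <- function(time, values) {
  if (length(time) < 2 || length(values) != length(time))
    stop("need at least 2 aligned samples", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  e_max <- max(values)
  t_e_max <- time[which(values == e_max)[1]]
  ec50 <- e_max / 2
  t_ec50 <- time[which(values >= ec50)[1]]
  out <- list(E_max = e_max, t_E_max = t_e_max, EC50 = ec50,
              t_EC50 = t_ec50, n = length(values))
  class(out) <- "dynamics_summary"
  out
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf(
    "E_max = %g at t = %g s; EC50 = %g first reached at t = %g s (%d samples)\n",
    x$E_max, x$t_E_max, x$EC50, x$t_EC50, x$n))
  invisible(x)
}

#' Segment an activation series into phases
#'
#' Labels contiguous sample runs as an \emph{activation/active} phase
#' (running-median level at or above \code{active_frac} of E_max), a
#' \emph{deactivation} phase (declining below it), and a terminal
#' \emph{stable} phase: the longest suffix, at least \code{min_dwell}
#' samples long, whose values stay within \code{stable_tol} of the suffix
#' median (absolute slack of 2.5\% of E_max for near-zero medians). Phases
#' are ordered, non-overlapping, and cover the series. All-zero series give
#' a single \code{null} phase; series shorter than \code{min_dwell} a
#' single \code{undetermined} phase.
#'
#' @param time,values The series.
#' @param e_max Reference maximum (default the series maximum).
#' @param active_frac Fraction of E_max defining the active level (0.5).
#' @param min_dwell Minimum stable-phase length in samples (30).
#' @param stable_tol Relative band around the stable median (0.5).
#' @param k Running-median window (odd, default 5).
#' @return Data.frame with \code{start}, \code{end} (s) and \code{label}.
#' @export
detect_phases <- function(time, values, e_max = max(values),
                          active_frac = 0.5, min_dwell = 30,
                          stable_tol = 0.5, k = 5) {
  n <- length(values)
  phase_df <- function(s, e, lab)
    data.frame(start = s, end = e, label = lab, stringsAsFactors = FALSE)
  if (all(values == 0))
    return(phase_df(time[1], time[n], "null"))
  if (n < min_dwell)
    return(phase_df(time[1], time[n], "undetermined"))
  sm <- if (n >= k) as.numeric(stats::runmed(values, k)) else values
  hi <- sm >= active_frac * e_max
  # end of the active region: last sample at or above the active level
  b1 <- max(which(hi))
  # stable suffix: longest tail (>= min_dwell) hugging its own median
  slack <- function(med) pmax(stable_tol * med, 0.025 * e_max)
  j_stable <- NA_integer_
  for (j in seq_len(n - min_dwell + 1)) {
    tail_v <- values[j:n]
    med <- stats::median(tail_v)
    if (all(abs(tail_v - med) <= slack(med))) { j_stable <- j; break }
  }
  ph <- NULL
  if (!is.na(j_stable) && j_stable <= b1) {
    # active level persists into the tail: active phase then stable remainder
    b1 <- min(b1, j_stable - 1)
  }
  if (b1 >= 1)
    ph <- rbind(ph, phase_df(time[1], time[b1], "active"))
  if (!is.na(j_stable)) {
    if (j_stable > b1 + 1)
      ph <- rbind(ph, phase_df(time[b1 + 1], time[j_stable - 1],
                               "deactivation"))
    ph <- rbind(ph, phase_df(time[max(j_stable, b1 + 1)], time[n], "stable"))
  } else if (b1 < n) {
    ph <- rbind(ph, phase_df(time[b1 + 1], time[n], "deactivation"))
  }
  if (is.null(ph)) ph <- phase_df(time[1], time[n], "undetermined")
  ph
}

#' Mechanical-memory baseline metrics
#'
#' The memory baseline is the median of the final \code{tail_window}
#' seconds of the series. Reported: the baseline level, its fold-change
#' over the pre-stimulus basal level (flagged infinite when basal is zero
#' but the baseline is not), the baseline as a percentage of E_max, and the
#' fraction of samples in the assessment window (by default the tail
#' window) lying below 5\% of E_max.
#'
#' @param time,values The series.
#' @param basal_level Pre-stimulus basal level (from the equilibration
#'   burn-in).
#' @param e_max Reference maximum (default series maximum).
#' @param tail_window Tail length in seconds (default 3600, i.e. the last
#'   60 min of samples).
#' @param below_window Optional \code{c(start, end)} (s) over which the
#'   below-5\% fraction is computed (defaults to the tail window).
#' @return Object of class \code{memory_metrics}.
#' @export
memory_metrics <- function(time, values, basal_level, e_max = max(values),
                           tail_window = 3600, below_window = NULL) {
  n <- length(values)
  span <- time[n] - time[1]
  if (tail_window > span)
    stop("tail window longer than the series", call. = FALSE)
  tail_idx <- time >= time[n] - tail_window
  baseline <- stats::median(values[tail_idx])
  infinite_fold <- (basal_level == 0 && baseline > 0)
  fold <- if (basal_level > 0) baseline / basal_level else NA_real_
  if (is.null(below_window)) below_window <- c(time[n] - tail_window, time[n])
  win <- time >= below_window[1] & time <= below_window[2]
  frac_below <- mean(values[win] < 0.05 * e_max)
  out <- list(baseline = baseline, basal_level = basal_level,
              fold_change = fold, infinite_fold = infinite_fold,
              pct_of_emax = 100 * baseline / e_max,
              frac_below_5pct = frac_below)
  class(out) <- "memory_metrics"
  out
}

#' @export
print.memory_metrics <- function(x, ...) {
  fold <- if (x$infinite_fold) "infinite (basal = 0)" else
    sprintf("%.1f-fold over basal %.3g", x$fold_change, x$basal_level)
  cat(sprintf(
    "memory baseline %.3g (%s; %.2f%% of E_max; %.0f%% of window samples < 5%% E_max)\n",
    x$baseline, fold, x$pct_of_emax, 100 * x$frac_below_5pct))
  invisible(x)
}

#' Matrix-protein deposition rate
#'
#' Least-squares slope of the cumulative deposited-ECMp count against time
#' over a window, in molecules per minute. Exact on noiseless
#' piecewise-linear input windows.
#'
#' @param time Sample times (s).
#' @param cumulative Cumulative deposited count (non-decreasing).
#' @param window Optional \code{c(start, end)} (s).
#' @return Rate (ECMp/min).
#' @export
ecmp_rate <- function(time, cumulative, window = range(time)) {
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 2) stop("window must contain at least 2 samples",
                          call. = FALSE)
  t <- time[keep]; y <- cumulative[keep]
  60 * sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Aggregate a replicate set
#'
#' Per-time-point median with interquartile range and mean with standard
#' deviation for one monitored column, across the replicates of a
#' \code{mech_abm_replicates} set (time grids must align).
#'
#' @param repset A \code{mech_abm_replicates}.
#' @param column Series column to aggregate (default \code{"pERK"}).
#' @return Data.frame: time, median, q25, q75, mean, sd, n.
#' @export
aggregate_replicates <- function(repset, column = "pERK") {
  stopifnot(inherits(repset, "mech_abm_replicates"))
  runs <- Filter(function(r) inherits(r, "mech_abm_sim"), repset$runs)
  if (length(runs) < 2)
    stop("need >= 2 successful replicates for dispersion", call. = FALSE)
  tgrid <- runs[[1]]$series$time
  for (r in runs)
    if (!identical(r$series$time, tgrid))
      stop("replicate time grids are misaligned", call. = FALSE)
  m <- vapply(runs, function(r) r$series[[column]], numeric(length(tgrid)))
  data.frame(time = tgrid,
             median = apply(m, 1, stats::median),
             q25 = apply(m, 1, stats::quantile, 0.25, names = FALSE),
             q75 = apply(m, 1, stats::quantile, 0.75, names = FALSE),
             mean = rowMeans(m),
             sd = apply(m, 1, stats::sd),
             n = length(runs))
}

#' Compare a scalar metric between two groups
#'
#' Normality of each group is checked (Shapiro-Wilk at \code{alpha}); if
#' both pass, Welch's t-test is used, otherwise the Mann-Whitney test. The
#' test actually applied is reported.
#'
#' @param x,y Numeric vectors of per-replicate metric values.
#' @param alpha Normality-test level (0.05).
#' @return List: \code{test} ("Welch t" or "Mann-Whitney"), \code{p_value},
#'   \code{normal} (logical pair), and the underlying \code{htest}.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha
  }
  nx <- normal(x); ny <- normal(y)
  if (identical(x, y) || (stats::var(x) == 0 && stats::var(y) == 0 &&
                          mean(x) == mean(y))) {
    return(list(test = "degenerate", p_value = 1, normal = c(nx, ny),
                htest = NULL))
  }
  if (nx && ny) {
    ht <- stats::t.test(x, y)
    list(test = "Welch t", p_value = ht$p.value, normal = c(nx, ny),
         htest = ht)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    list(test = "Mann-Whitney", p_value = ht$p.value, normal = c(nx, ny),
         htest = ht)
  }
}

#' Compare a scalar metric across model variants
#'
#' One-way ANOVA with Tukey HSD post hoc when every group passes the
#' Shapiro-Wilk normality check, otherwise Kruskal-Wallis. The test used is
#' reported.
#'
#' @param values Numeric vector of metric values.
#' @param group Factor of the same length (e.g. variant names).
#' @param alpha Normality-test level.
#' @return List: \code{test}, \code{p_value}, \code{posthoc} (Tukey table or
#'   NULL), and the fitted object.
#' @export
compare_variants <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  ok <- vapply(split(values, group), function(v)
    length(unique(v)) >= 3 && stats::shapiro.test(v)$p.value >= alpha,
    logical(1))
  if (all(ok)) {
    fit <- stats::aov(values ~ group)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    list(test = "one-way ANOVA", p_value = p,
         posthoc = stats::TukeyHSD(fit)$group, fit = fit)
  } else {
    ht <- stats::kruskal.test(values, group)
    list(test = "Kruskal-Wallis", p_value = ht$p.value, posthoc = NULL,
         fit = ht)
  }
}

#' Hill-type steepness of a normalised activation curve
#'
#' Fits \eqn{y(t) = t^h / (t_{50}^h + t^h)} to a rising activation curve
#' normalised to its maximum, returning the apparent Hill exponent h. Used
#' to verify that the ultrasensitive response sharpens down the kinase
#' cascade (Raf to MEK to ERK) under a step stimulus.
#'
#' @param time Sample times (> 0 for the fit; the t = 0 sample is dropped).
#' @param values Activation counts.
#' @return Fitted Hill exponent (numeric).
#' @export
hill_steepness <- function(time, values) {
  y <- values / max(values)
  keep <- time > 0
  t <- time[keep]; y <- y[keep]
  t50_0 <- t[which(y >= 0.5)[1]]
  if (is.na(t50_0)) t50_0 <- stats::median(t)
  fit <- try(stats::nls(y ~ t^h / (t50^h + t^h),
                        start = list(h = 1, t50 = t50_0),
                        control = stats::nls.control(maxiter = 200,
                                                     warnOnly = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NA_real_)
  unname(stats::coef(fit)[["h"]])
}
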
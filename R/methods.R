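# S3 methods for simulation objects.

#' @export
print.mech_abm_sim <- function(x, ...) {
  s <- x$series
  cat(sprintf("mechabm simulation: variant %s, %d s stimulated, seed %d\n",
              x$config$variant$name, x$config$duration, x$config$seed))
  cat(sprintf("  %d samples; basal pERK %.3g\n", nrow(s), x$basal_perk))
  cat(sprintf("  pERK peak %d at %.1f min; active integrins peak %d; %d ECMp deposited\n",
              max(s$pERK), s$time[which.max(s$pERK)] / 60,
              max(s$active_integrins), max(s$dep_total)))
  invisible(x)
}

#' @export
summary.mech_abm_sim <- function(object, species = "pERK", ...) {
  s <- object$series
  dyn <- summarize_dynamics(s$time, s[[species]])
  ph <- detect_phases(s$time, s[[species]])
  rate <- ecmp_rate(s$time, s$dep_total)
  out <- list(variant = object$config$variant$name, species = species,
              dynamics = dyn, phases = ph, ecmp_rate = rate,
              basal_perk = object$basal_perk,
              mu_ecm_final = s$mu_ecm[nrow(s)])
  class(out) <- "summary.mech_abm_sim"
  out
}

#' @export
print.summary.mech_abm_sim <- function(x, ...) {
  cat(sprintf("Variant %s, monitored species %s\n", x$variant, x$species))
  print(x$dynamics)
  cat(sprintf("overall ECMp rate %.2f /min; final ECM modulus %.3g Pa\n",
              x$ecmp_rate, x$mu_ecm_final))
  cat("phases:\n")
  print(x$phases)
  invisible(x)
}

#' Plot a simulation
#'
#' Three stacked panels: active integrins, pERK (cytoplasmic + nuclear),
#' and cumulative deposited matrix proteins by gene.
#'
#' @param x A \code{mech_abm_sim}.
#' @param ... Unused.
#' @export
plot.mech_abm_sim <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  tmin <- s$time / 60
  graphics::plot(tmin, s$active_integrins, type = "l", xlab = "time (min)",
                 ylab = "active integrins",
                 main = sprintf("variant %s", x$config$variant$name))
  graphics::plot(tmin, s$pERK, type = "l", xlab = "time (min)",
                 ylab = "pERK", col = "firebrick")
  graphics::lines(tmin, s$pERK_nuc, col = "steelblue", lty = 2)
  graphics::legend("topright", c("total", "nuclear"), lty = c(1, 2),
                   col = c("firebrick", "steelblue"), bty = "n")
  cols <- c("grey30", "goldenrod", "seagreen", "slateblue")
  graphics::matplot(tmin, s[, c("dep_ALP", "dep_OPN", "dep_OCN", "dep_BSP")],
                    type = "l", lty = 1, col = cols, xlab = "time (min)",
                    ylab = "cumulative ECMp")
  graphics::legend("topleft", c("ALP", "OPN", "OCN", "BSP"), lty = 1,
                   col = cols, bty = "n")
  invisible(x)
}

#' @export
print.mech_abm_replicates <- function(x, ...) {
  ok <- sum(vapply(x$runs, inherits, logical(1), "mech_abm_sim"))
  cat(sprintf("mechabm replicate set: variant %s, %d/%d replicates%s\n",
              x$config$variant$name, ok, length(x$runs),
              if (isTRUE(x$partial)) " (partial)" else ""))
  invisible(x)
}

#' @export
summary.mech_abm_replicates <- function(object, column = "pERK", ...) {
  agg <- aggregate_replicates(object, column)
  emax <- vapply(object$runs, function(r)
    if (inherits(r, "mech_abm_sim")) max(r$series[[column]]) else NA_real_,
    numeric(1))
  out <- list(column = column, aggregate = agg, e_max = emax,
              variant = object$config$variant$name)
  class(out) <- "summary.mech_abm_replicates"
  out
}

#' @export
print.summary.mech_abm_replicates <- function(x, ...) {
  cat(sprintf("Variant %s, %s across %d replicates\n", x$variant, x$column,
              sum(!is.na(x$e_max))))
  cat(sprintf("  E_max mean %.1f (sd %.1f)\n", mean(x$e_max, na.rm = TRUE),
              stats::sd(x$e_max, na.rm = TRUE)))
  utils::head(x$aggregate)
  invisible(x)
}

#' Plot a replicate set (median with interquartile band)
#'
#' @param x A \code{mech_abm_replicates}.
#' @param column Series column (default \code{"pERK"}).
#' @param ... Unused.
#' @export
plot.mech_abm_replicates <- function(x, column = "pERK", ...) {
  agg <- aggregate_replicates(x, column)
  tmin <- agg$time / 60
  graphics::plot(tmin, agg$median, type = "n", xlab = "time (min)",
                 ylab = sprintf("%s (median, IQR)", column),
                 ylim = range(c(agg$q25, agg$q75)),
                 main = sprintf("variant %s (n = %d)",
                                x$config$variant$name, agg$n[1]))
  graphics::polygon(c(tmin, rev(tmin)), c(agg$q25, rev(agg$q75)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(tmin, agg$median, col = "steelblue4")
  invisible(x)
}
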
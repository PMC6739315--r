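# The hybrid scheduler: per-second coupling between the closed-form
# mechanics and the agent world, the fixed step ordering, the run loop and
# replicate management. The inner loop lives in compiled code; this file
# owns orchestration, sampling layout and the R-visible contracts.

.sample_cols <- c("time", "active_integrins", "pFAK", "activeRas", "pRaf",
                  "pMEK", "pERK_cyt", "pERK_nuc", "activeRunx2",
                  "transcribing", "mrna_live", "dep_ALP", "dep_OPN",
                  "dep_OCN", "dep_BSP", "dep_total", "mu_ecm", "tx_total",
                  "tl_total")

# flatten mechanics for the compiled engine
mech_flat <- function(config, sigma_on = TRUE) {
  el <- config$elastic
  n_int <- as.integer(config$counts[["integrin"]])
  a <- patch_radius(el$cell_radius, n_int)
  beta_eff <- switch(config$stiffening, power = config$beta, linear = 1,
                     compound = 0)
  conv <- if (config$stiffening == "compound") 1 else 0
  c(eta0 = el$eta, k0 = el$k, fscale = pi * a^2 * el$sigma_far,
    increment = config$ecmp_increment, beta = beta_eff, conv = conv,
    sigma_on = as.numeric(sigma_on),
    rcell = el$cell_radius * 1e9, rnuc = config$nuclear_radius * 1e9,
    mu_base = el$mu_ecm_base)
}

kinetics_flat <- function(kinetics) {
  k <- as.numeric(kinetics)
  if (length(k) != kinetics_n_params())
    stop("kinetics vector does not match the engine layout", call. = FALSE)
  k
}

samples_to_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- .sample_cols
  df$pERK <- df$pERK_cyt + df$pERK_nuc
  df
}

#' Advance a world by discrete one-second steps
#'
#' Executes the fixed within-step phase order: (1) coupling exchange and
#' mechanical priming of integrins; (2) Brownian movement of all mobile
#' agents; (3) reaction resolution over eligible pairs (each agent
#' participates in at most one reaction per step; nearest eligible partner,
#' ties to the lower id); (4) transcription, translation and secretion
#' events whose delays elapse; (5) activation-cycle/lifetime ticks; (6)
#' sampling when the step index is a multiple of the sampling interval.
#'
#' @param world A \code{mech_abm_world}.
#' @param config The \code{\link{run_config}}.
#' @param n Number of steps to advance.
#' @param sample_every Sampling interval in steps (0 = no samples).
#' @param sigma_on Apply the far-field shear (FALSE during burn-in).
#' @param reverse_order Iterate catalysts in descending id order (used to
#'   verify order-invariance of the reaction resolution).
#' @return List with the advanced \code{world} and a \code{series}
#'   data.frame of samples (possibly empty).
#' @export
step_world <- function(world, config, n = 1, sample_every = 0,
                       sigma_on = TRUE, reverse_order = FALSE) {
  stopifnot(inherits(world, "mech_abm_world"))
  res <- abm_run_cpp(world, mech_flat(config, sigma_on),
                     kinetics_flat(config$kinetics), as.integer(n),
                     as.integer(sample_every), reverse_order)
  w <- res$world
  w$theta <- world$theta; w$phi <- world$phi
  w$sensitivity_class <- world$sensitivity_class
  class(w) <- "mech_abm_world"
  list(world = w, series = samples_to_df(res$samples))
}

#' Coupling exchange: the per-integrin force table
#'
#' Reads the integrin coordinates and the cumulative deposited-ECMp count
#' from the world, recomputes the current ECM modulus, and evaluates the
#' interface stress and the patch force at every integrin, together with
#' each integrin's activation flag. This is the quantity exchanged between
#' the mechanical model and the agent model every simulated second.
#'
#' @param world A \code{mech_abm_world}.
#' @param config The \code{\link{run_config}}.
#' @param sigma_on If \code{FALSE} the far-field stress is absent and all
#'   forces are zero.
#' @return Data.frame: \code{index}, \code{theta}, \code{phi},
#'   \code{sigma_rr}, \code{force_N}, \code{mt_N}, \code{active}.
#' @export
coupling_exchange <- function(world, config, sigma_on = TRUE) {
  stopifnot(inherits(world, "mech_abm_world"))
  el <- config$elastic
  ft <- force_table(world$theta, world$phi, world$mt, el,
                    n_deposited = world$n_dep,
                    N = world$n_integrin,
                    increment = config$ecmp_increment,
                    convention = if (config$stiffening == "compound")
                      "compound" else "power",
                    beta = switch(config$stiffening, power = config$beta,
                                  linear = 1, compound = 1))
  if (!sigma_on) {
    ft$sigma_rr <- 0; ft$force_N <- 0; ft$active <- FALSE
  }
  ft
}

#' Run one simulation
#'
#' An unstimulated equilibration burn-in (no applied stress; establishes the
#' basal pERK level) followed by the stimulated run of \code{duration}
#' one-second steps under constant far-field shear. Time series are sampled
#' every \code{sampling_interval} steps (t = 0, the state at stimulus
#' onset, included). Identical config and seed give identical output.
#'
#' @param config A \code{\link{run_config}}.
#' @param verbose Print progress.
#' @return Object of class \code{mech_abm_sim}: \code{series} (stimulated
#'   phase), \code{equil_series} (burn-in), \code{basal_perk} (mean pERK
#'   over the burn-in samples), \code{world} (final state), \code{config},
#'   \code{elapsed} (wall seconds).
#' @export
run_sim <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  world <- init_world(config)
  equil <- NULL
  if (config$equilibration > 0) {
    res <- step_world(world, config, n = config$equilibration,
                      sample_every = config$equil_sampling_interval,
                      sigma_on = FALSE)
    world <- res$world
    equil <- res$series
    equil$time <- equil$time - config$equilibration  # ends at t = 0
    if (verbose)
      message(sprintf("equilibration done (%d s), basal pERK %.3f",
                      config$equilibration, mean(equil$pERK)))
  }
  world$time_step <- 0
  res <- step_world(world, config, n = config$duration,
                    sample_every = config$sampling_interval,
                    sigma_on = TRUE)
  out <- list(series = res$series, equil_series = equil,
              basal_perk = if (is.null(equil)) NA_real_ else
                mean(equil$pERK),
              world = res$world, config = config,
              elapsed = proc.time()[["elapsed"]] - t0)
  class(out) <- "mech_abm_sim"
  if (verbose)
    message(sprintf("run %s finished: %d s simulated in %.1f s wall",
                    config$variant$name, config$duration, out$elapsed))
  out
}

#' Run a replicate set
#'
#' Runs \code{n} independent replicates with per-replicate seeds derived
#' deterministically from the base seed. Results are identical whether the
#' replicates are executed serially or concurrently, because each replicate
#' is a self-contained seeded run.
#'
#' @param config A \code{\link{run_config}} (its seed is the base seed).
#' @param n Number of replicates (default 16).
#' @param parallel Use \code{parallel::mclapply} when possible.
#' @param verbose Print per-replicate progress.
#' @return Object of class \code{mech_abm_replicates}: \code{runs} (list of
#'   \code{mech_abm_sim}), \code{seeds}, \code{config}, \code{partial}
#'   (TRUE if any replicate failed).
#' @export
run_replicates <- function(config, n = 16, parallel = FALSE,
                           verbose = FALSE) {
  stopifnot(n >= 1)
  seeds <- replicate_seeds(config$seed, n)
  one <- function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    tryCatch(run_sim(cfg, verbose = verbose),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "mechabm_failed_run"))
  }
  runs <- if (parallel && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n), one,
                       mc.cores = max(1L, parallel::detectCores() - 1L))
  } else lapply(seq_len(n), one)
  failed <- vapply(runs, inherits, logical(1), "mechabm_failed_run")
  if (any(failed))
    warning(sum(failed), " replicate(s) failed; set marked partial")
  out <- list(runs = runs, seeds = seeds, config = config,
              partial = any(failed))
  class(out) <- "mech_abm_replicates"
  out
}

#' Deterministic per-replicate seeds
#'
#' Distinct seeds for a replicate set, derived from the base seed; all below
#' 2^31.
#'
#' @param base_seed Integer base seed.
#' @param n Number of replicates.
#' @return Integer vector of length \code{n}.
#' @export
replicate_seeds <- function(base_seed, n) {
  s0 <- derive_seed(base_seed, "replicate")
  vapply(seq_len(n), function(i)
    as.integer((as.double(s0) + 7919 * i) %% 2147483647), integer(1))
}
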
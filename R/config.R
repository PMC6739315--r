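# Run configuration: agent counts, kinetic parameters, geometry, and the
# validated config object consumed by the engine.

#' Initial molecular-agent counts
#'
#' The default census of the osteoblast world at time zero: 500 integrins,
#' 1000 FAK, 1000 Ras, 32 Raf, 3400 MEK, 2300 ERK, 24 Runx2, 24
#' transcription-factor complexes, 600 ribosomes, 2 mRNA copies per
#' osteogenic gene (ALP, OPN, OCN, BSP) and 1 protein copy per gene,
#' 8892 agents in total.
#'
#' @return Named integer vector of per-species counts (mRNA and protein
#'   entries are per-gene).
#' @export
agent_counts <- function() {
  c(integrin = 500L, FAK = 1000L, Ras = 1000L, Raf = 32L, MEK = 3400L,
    ERK = 2300L, Runx2 = 24L, complex = 24L, ribosome = 600L,
    mRNA_per_gene = 2L, protein_per_gene = 1L)
}

#' Osteogenic gene panel
#' @return Character vector of the four matrix-protein genes.
#' @export
ecmp_genes <- function() c("ALP", "OPN", "OCN", "BSP")

#' Kinetic parameters of the signalling cascade
#'
#' All per-encounter interaction radii (nm), per-encounter success
#' probabilities, active-state lifetimes (s), post-reaction refractory
#' (activation-cycle-switch, ACS) durations (s), diffusion coefficients
#' (nm^2/s) and expression parameters, with calibrated defaults. None of
#' these constants is published; the defaults are the package's documented
#' calibration (see the methods vignette) against the printed sensitive /
#' ultrasensitive / heterogeneous dynamics.
#'
#' Override any subset via \code{...}; unknown names are an error.
#'
#' @param ... Named overrides of the defaults.
#' @return Named numeric vector of class \code{mechabm_kinetics}.
#' @export
kinetics_params <- function(...) {
  def <- c(
    # integrin mechanics-to-chemistry coupling
    prime_mean = 240,        # mean stochastic priming delay (s)
    off_delay = 60,          # deactivation delay once force < MT (s)
    # interaction radii (nm) / success probabilities / catalyst ACS (s)
    r_integrin_fak = 125, p_integrin_fak = 1, acs_integrin = 2,
    r_fak_ras = 232,     p_fak_ras = 1,     acs_fak = 5,
    r_ras_raf = 530,     p_ras_raf = 1,     acs_ras = 5,
    r_raf_mek = 432,     p_raf_mek = 1,     acs_raf = 2,
    r_mek_erk = 191,     p_mek_erk = 1,     acs_mek = 2,
    r_erk_runx2 = 120,   p_erk_runx2 = 1,   acs_erk = 2,
    r_runx2_complex = 240, p_runx2_complex = 1, acs_runx2 = 30,
    r_mrna_ribosome = 300, p_translation = 1,
    # active-state lifetimes (mean, s); drawn uniform +/- life_relwidth
    life_fak = 600, life_ras = 2000, life_raf = 300, life_mek = 150,
    life_erk = 240, life_erk_intermediate = 400,
    life_ras_intermediate = 4400, life_runx2 = 300,
    life_relwidth = 0.5,
    life_dist = 1,  # 0 = uniform +/- relwidth, 1 = truncated exponential
    life_cap = 5.6,   # truncation of exponential lifetimes, in multiples of the mean
    # post-active refractory before returning to the receptive state (s)
    post_fak = 60, post_ras = 60, post_raf = 10, post_mek = 60,
    post_erk = 60, post_runx2 = 60,
    # basal (stimulus-independent) short-lived ERK phosphorylation
    basal_rate = 0.15, basal_life_lo = 1, basal_life_hi = 4,
    # gene expression
    tx_delay_lo = 30, tx_delay_hi = 90, acs_complex = 240,
    yield_mean = 2.5, yield_sd = 0.5,
    acs_mrna = 120, acs_ribosome = 60,
    mrna_lifetime = 1800,
    secretion_delay = 60,
    # diffusion coefficients (nm^2/s)
    d_kinase = 1e6, d_mrna = 1e5, d_ribosome = 1e5, d_protein = 1e6,
    d_nuclear = 1e5,
    # relative promoter weights ALP, OPN, OCN, BSP
    gene_w_alp = 1, gene_w_opn = 1, gene_w_ocn = 1, gene_w_bsp = 1
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(def))
    if (length(bad))
      stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    def[names(ov)] <- unlist(ov)
  }
  if (any(!is.finite(def)) || any(def < 0))
    stop("kinetic parameters must be finite and non-negative", call. = FALSE)
  class(def) <- c("mechabm_kinetics", "numeric")
  def
}

#' Simulation run configuration
#'
#' Assembles and validates everything one run needs: the integrin variant,
#' stimulated duration, seed, sampling cadence, world geometry, elastic
#' parameters, ECM-stiffening convention, kinetic parameters and agent
#' counts. An unstimulated equilibration burn-in (no applied stress)
#' precedes the loaded phase and establishes the basal pERK level used by
#' the mechanical-memory metrics.
#'
#' @param variant Variant name (\code{"SM"}, \code{"USM"}, \code{"HM10"},
#'   \code{"HM1"}) or a \code{\link{variant_spec}}.
#' @param duration Stimulated duration (s; 1 step = 1 s).
#' @param seed Master seed (integer); all randomness derives from it.
#' @param sampling_interval Record every this-many steps (default 100).
#' @param equilibration Unstimulated burn-in (s, default 600).
#' @param equil_sampling_interval Sampling cadence during burn-in (s).
#' @param elastic An \code{\link{elastic_params}} object.
#' @param kinetics A \code{\link{kinetics_params}} vector.
#' @param counts Agent counts as from \code{\link{agent_counts}}.
#' @param ecmp_increment Per-deposit ECM elasticity increment (0.001).
#' @param stiffening Stiffening convention (\code{"power"},
#'   \code{"linear"}, \code{"compound"}), see
#'   \code{\link{update_ecm_modulus}}.
#' @param beta Stiffening exponent for the power convention
#'   (calibrated default 1.56).
#' @param layout Integrin placement, \code{"fibonacci"} or \code{"random"}.
#' @param ratio_convention Heterogeneous-mix reading, \code{"percent"} or
#'   \code{"odds"} (see \code{\link{variant_spec}}).
#' @param nuclear_radius Nuclear radius (m).
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(variant = "SM", duration = 21600, seed = 1L,
                       sampling_interval = 100L, equilibration = 600,
                       equil_sampling_interval = 10L,
                       elastic = elastic_params(),
                       kinetics = kinetics_params(),
                       counts = agent_counts(),
                       ecmp_increment = 0.001,
                       stiffening = c("power", "linear", "compound"),
                       beta = 1.56,
                       layout = c("fibonacci", "random"),
                       ratio_convention = c("percent", "odds"),
                       nuclear_radius = 4e-6) {
  stiffening <- match.arg(stiffening)
  layout <- match.arg(layout)
  ratio_convention <- match.arg(ratio_convention)
  if (is.character(variant))
    variant <- variant_spec(variant, ratio_convention = ratio_convention)
  stopifnot(inherits(variant, "variant_spec"))
  stopifnot(inherits(elastic, "elastic_params"))
  stopifnot(inherits(kinetics, "mechabm_kinetics"))
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (sampling_interval < 1) stop("sampling_interval must be >= 1",
                                  call. = FALSE)
  if (equilibration < 0) stop("equilibration must be >= 0", call. = FALSE)
  if (nuclear_radius >= elastic$cell_radius)
    stop("nuclear radius must be smaller than the cell radius",
         call. = FALSE)
  need <- names(agent_counts())
  if (!all(need %in% names(counts)))
    stop("counts must provide: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(counts < 0)) stop("agent counts must be non-negative",
                            call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  out <- list(variant = variant, duration = as.integer(duration),
              seed = seed,
              sampling_interval = as.integer(sampling_interval),
              equilibration = as.integer(equilibration),
              equil_sampling_interval = as.integer(equil_sampling_interval),
              elastic = elastic, kinetics = kinetics,
              counts = counts, ecmp_increment = ecmp_increment,
              stiffening = stiffening, beta = beta, layout = layout,
              ratio_convention = ratio_convention,
              nuclear_radius = nuclear_radius)
  class(out) <- "run_config"
  out
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("mechabm run config: variant %s, %d s stimulated (+%d s burn-in), seed %d\n",
              x$variant$name, x$duration, x$equilibration, x$seed))
  cat(sprintf("  %d integrins, sampling every %d steps, stiffening %s (beta %g, increment %g)\n",
              x$counts[["integrin"]], x$sampling_interval, x$stiffening,
              x$beta, x$ecmp_increment))
  invisible(x)
}

# deterministic sub-seeds so that e.g. threshold draws do not perturb
# placement draws (per-purpose stream separation at the R level)
derive_seed <- function(seed, purpose) {
  off <- c(placement = 104729L, thresholds = 224737L, replicate = 350377L)
  stopifnot(purpose %in% names(off))
  as.integer((as.double(seed) * 2654435761 + off[[purpose]]) %% 2147483647)
}
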
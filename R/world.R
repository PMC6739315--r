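# World construction: the molecular-agent census at time zero, with every
# species placed uniformly in its home compartment, and helpers to inspect
# a world.

# species codes shared with the compiled engine
species_codes <- function() {
  c(integrin = 0L, FAK = 1L, Ras = 2L, Raf = 3L, MEK = 4L, ERK = 5L,
    Runx2 = 6L, complex = 7L, ribosome = 8L, mRNA = 9L, ECMp = 10L)
}

# state codes shared with the compiled engine
state_codes <- function() {
  c(dead = -1L, basal = 0L, active = 1L, refractory = 2L,
    transcribing = 3L, intermediate = 4L, inert = 5L)
}

# uniform points in a spherical shell [r0, r1] (nm); consumes the R RNG
runif_shell <- function(n, r0, r1) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  r <- (r0^3 + stats::runif(n) * (r1^3 - r0^3))^(1 / 3)
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  v * r
}

#' Initialise the agent world
#'
#' Instantiates every molecular agent at its default count, in its basal
#' state, uniformly distributed in its home compartment: integrins static on
#' the membrane (deterministic equal-area layout by default), kinases and
#' ribosomes in the cytoplasm, Runx2 and transcription complexes in the
#' nucleus, the baseline mRNA pool in the nucleus and the baseline matrix
#' proteins in the cytoplasm. Thresholds are assigned from the variant using
#' a dedicated sub-seed so that changing variant does not perturb placement
#' draws. The world is bit-reproducible from the config seed.
#'
#' The baseline mRNA pool (2 copies per gene) is held static (neither
#' translated nor degraded): it stands for the basal transcript steady state
#' in which synthesis balances decay, so that with zero signalling the world
#' stays at its census baseline.
#'
#' @param config A \code{\link{run_config}}.
#' @return An object of class \code{mech_abm_world}: a list of parallel
#'   per-agent vectors (\code{species}, \code{state}, \code{x}, \code{y},
#'   \code{z}, \code{acs}, \code{life}, \code{aux}, \code{gene}), the
#'   integrin threshold table, counters and the RNG state.
#' @export
init_world <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cn <- config$counts
  n_int <- as.integer(cn[["integrin"]])
  rc <- config$elastic$cell_radius * 1e9   # nm
  rn <- config$nuclear_radius * 1e9

  # thresholds on their own sub-seed (stream separation)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(config$seed, "thresholds"))
  f_ref <- reference_force(config$elastic, n_int)
  thr <- assign_thresholds(config$variant, n_int, f_ref)

  set.seed(derive_seed(config$seed, "placement"))
  lay <- integrin_layout(n_int, config$layout)
  Xpat <- sin(lay$theta)^2 * sin(2 * lay$phi)

  sp <- species_codes()
  genes <- ecmp_genes()
  spec <- integer(0); gene <- integer(0); pos <- NULL
  add <- function(code, n, where, g = -1L) {
    spec <<- c(spec, rep(as.integer(code), n))
    gene <<- c(gene, rep(as.integer(g), n))
    pos <<- rbind(pos, where)
  }
  memb <- cbind(rc * sin(lay$theta) * cos(lay$phi),
                rc * sin(lay$theta) * sin(lay$phi),
                rc * cos(lay$theta))
  add(sp[["integrin"]], n_int, memb)
  add(sp[["FAK"]], cn[["FAK"]], runif_shell(cn[["FAK"]], rn, rc))
  add(sp[["Ras"]], cn[["Ras"]], runif_shell(cn[["Ras"]], rn, rc))
  add(sp[["Raf"]], cn[["Raf"]], runif_shell(cn[["Raf"]], rn, rc))
  add(sp[["MEK"]], cn[["MEK"]], runif_shell(cn[["MEK"]], rn, rc))
  add(sp[["ERK"]], cn[["ERK"]], runif_shell(cn[["ERK"]], rn, rc))
  add(sp[["Runx2"]], cn[["Runx2"]], runif_shell(cn[["Runx2"]], 0, rn))
  add(sp[["complex"]], cn[["complex"]], runif_shell(cn[["complex"]], 0, rn))
  add(sp[["ribosome"]], cn[["ribosome"]],
      runif_shell(cn[["ribosome"]], rn, rc))
  n_mrna <- as.integer(cn[["mRNA_per_gene"]])
  n_prot <- as.integer(cn[["protein_per_gene"]])
  for (g in seq_along(genes))
    add(sp[["mRNA"]], n_mrna, runif_shell(n_mrna, 0, rn), g - 1L)
  for (g in seq_along(genes))
    add(sp[["ECMp"]], n_prot, runif_shell(n_prot, rn, rc), g - 1L)

  n <- length(spec)
  state <- integer(n)
  state[spec == sp[["mRNA"]]] <- state_codes()[["inert"]]
  aux <- numeric(n)
  aux[spec == sp[["ECMp"]]] <- config$kinetics[["secretion_delay"]]

  w <- list(species = spec, state = state, gene = gene,
            x = pos[, 1], y = pos[, 2], z = pos[, 3],
            acs = numeric(n), life = numeric(n), aux = aux,
            freelist = integer(0),
            mt = thr$mt, Xpat = Xpat,
            n_integrin = n_int, time_step = 0, n_dep = 0,
            dep_gene = numeric(4), cum_tx = numeric(4),
            cum_tl = numeric(4),
            rng = rng_state_init(config$seed),
            theta = lay$theta, phi = lay$phi,
            sensitivity_class = thr$sensitivity_class)
  class(w) <- "mech_abm_world"
  w
}

#' @export
print.mech_abm_world <- function(x, ...) {
  alive <- x$state != state_codes()[["dead"]]
  cat(sprintf("mechabm world: %d agents (t = %d s, %d ECMp deposited)\n",
              sum(alive), as.integer(x$time_step), as.integer(x$n_dep)))
  tab <- table(factor(x$species[alive],
                      levels = species_codes(),
                      labels = names(species_codes())))
  print(tab)
  invisible(x)
}

#' Per-species state census of a world
#'
#' Counts agents by species and state; the backbone of the conservation
#' checks (for each kinase, basal + active + refractory + intermediate
#' equals the initial census at all times).
#'
#' @param world A \code{mech_abm_world}.
#' @return A table of species x state counts (live agents only).
#' @export
world_census <- function(world) {
  alive <- world$state != state_codes()[["dead"]]
  sc <- state_codes(); sc <- sc[names(sc) != "dead"]
  table(
    species = factor(world$species[alive], levels = species_codes(),
                     labels = names(species_codes())),
    state = factor(world$state[alive], levels = sc, labels = names(sc)))
}

#' Compartment classification
#'
#' Classifies positions into the nucleus (r < nuclear radius), membrane
#' (within \code{tol} of the cell surface) or cytoplasm; every agent belongs
#' to exactly one compartment (the ECM is implicitly outside).
#'
#' @param x,y,z Coordinates (nm).
#' @param cell_radius,nuclear_radius Radii (nm).
#' @param tol Membrane tolerance (nm, default 1).
#' @return Character vector: \code{"nucleus"}, \code{"cytoplasm"} or
#'   \code{"membrane"}.
#' @export
compartment_of <- function(x, y, z, cell_radius = 1e4,
                           nuclear_radius = 4e3, tol = 1) {
  r <- sqrt(x^2 + y^2 + z^2)
  out <- rep("cytoplasm", length(r))
  out[r < nuclear_radius] <- "nucleus"
  out[abs(r - cell_radius) <= tol] <- "membrane"
  out
}
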
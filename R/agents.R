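# Agent-level primitives exposed at the R surface: Brownian moves with
# reflecting spherical boundaries, activation-cycle-switch ticks, and the
# neighbour query (linear scan and spatial index, cross-checkable).

#' One Brownian step for a set of positions
#'
#' Displaces each position by an independent zero-mean Gaussian per axis
#' with variance \code{2 * D * dt}, then reflects radially at the spherical
#' compartment boundaries \code{[lower, upper]} (radii in nm; \code{lower =
#' 0} disables the inner boundary). With \code{D = 0} positions are
#' unchanged. Draws come from the engine's motion stream.
#'
#' @param pos Numeric matrix (n x 3) of positions (nm).
#' @param D Diffusion coefficient (nm^2/s).
#' @param dt Time step (s).
#' @param lower,upper Reflecting radial bounds (nm).
#' @param seed Integer seed for the motion stream, or an existing 32-int
#'   RNG state from a previous call.
#' @return List with \code{pos} (moved positions) and \code{rng} (advanced
#'   stream state, reusable for the next call).
#' @export
brownian_step <- function(pos, D, dt = 1, lower = 0, upper = 1e4,
                          seed = 1L) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, D >= 0, dt >= 0, upper > 0, lower >= 0)
  rng <- if (length(seed) == 32L) as.integer(seed) else
    rng_state_init(as.integer(seed))
  brownian_step_cpp(pos, D, dt, lower, upper, rng)
}

#' Activation-cycle-switch tick
#'
#' Advances every agent's dormancy timer by one second: positive timers
#' decrement; a refractory agent whose timer reaches zero returns to its
#' receptive basal state. Agents with a positive timer take part in no
#' reaction.
#'
#' @param world A \code{mech_abm_world}.
#' @return The world with timers advanced.
#' @export
acs_tick <- function(world) {
  sc <- state_codes()
  pos <- world$acs > 0
  world$acs[pos] <- world$acs[pos] - 1
  back <- world$state == sc[["refractory"]] & world$acs <= 0
  world$state[back] <- sc[["basal"]]
  world
}

#' Neighbours of an agent within a radius
#'
#' All other live agents within Euclidean distance \code{radius} of agent
#' \code{id}. Two independent implementations are provided: a linear scan
#' (\code{method = "brute"}) and the engine's uniform-grid spatial index
#' (\code{method = "grid"}); they return identical sets.
#'
#' @param world A \code{mech_abm_world}.
#' @param id Agent index (1-based).
#' @param radius Search radius (nm), > 0.
#' @param method \code{"grid"} (default) or \code{"brute"}.
#' @param cell_radius Domain radius for the grid (nm).
#' @return Sorted integer vector of agent indices.
#' @export
neighbours_within <- function(world, id, radius,
                              method = c("grid", "brute"),
                              cell_radius = 1e4) {
  method <- match.arg(method)
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be positive", call. = FALSE)
  if (method == "brute")
    sort(neighbours_within_cpp(world, as.integer(id), radius))
  else
    grid_neighbours_cpp(world, as.integer(id), radius, cell_radius)
}
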
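# Closed-form tissue/interface mechanics: normal stress at the cell-ECM
# interface of a spherical inclusion under far-field shear, per-integrin
# forces, ECM stiffening by deposited matrix proteins, and the
# mechanosensitivity-threshold machinery.

#' Elastic parameters of the cell-ECM system
#'
#' Bundles the elastic constants of the spherical-inclusion interface model:
#' a spherical cell of shear modulus \code{mu_cell} embedded in an ECM of
#' shear modulus \code{mu_ecm_base}, joined by a linear-spring interface of
#' stiffness \code{alpha} (identical in the normal and tangential
#' directions), loaded by a uniform far-field shear stress \code{sigma_far}.
#' Two non-dimensional groups govern the interface stress: the modulus ratio
#' \code{eta = mu_cell / mu_ecm} and the interface number
#' \code{k = alpha * R / mu_ecm}.
#'
#' @param mu_cell Shear modulus of the cell (Pa).
#' @param mu_ecm_base Initial shear modulus of the ECM (Pa).
#' @param alpha Interface spring constant (Pa/m).
#' @param cell_radius Cell radius R (m).
#' @param sigma_far Far-field shear stress \eqn{\sigma_{xy,\infty}} (Pa).
#'   The default is chosen so that with 500 integrins on a 10 um cell and
#'   \code{eta = k = 1} the peak per-integrin force at time zero is 10 pN,
#'   the top of the physiological 2-10 pN range integrins are reported to
#'   sense.
#' @return An object of class \code{elastic_params}.
#' @examples
#' ep <- elastic_params()
#' ep$eta  # 1
#' ep$k    # 1
#' @export
elastic_params <- function(mu_cell = 1000,
                           mu_ecm_base = 1000,
                           alpha = mu_ecm_base / cell_radius,
                           cell_radius = 10e-6,
                           sigma_far = 15.804852) {
  vals <- c(mu_cell = mu_cell, mu_ecm_base = mu_ecm_base, alpha = alpha,
            cell_radius = cell_radius, sigma_far = sigma_far)
  if (!all(is.finite(vals)))
    stop("elastic parameters must all be finite", call. = FALSE)
  if (any(vals <= 0))
    stop("elastic parameters must all be strictly positive", call. = FALSE)
  out <- list(mu_cell = mu_cell, mu_ecm_base = mu_ecm_base, alpha = alpha,
              cell_radius = cell_radius, sigma_far = sigma_far,
              eta = mu_cell / mu_ecm_base,
              k = alpha * cell_radius / mu_ecm_base)
  class(out) <- "elastic_params"
  out
}

#' @export
print.elastic_params <- function(x, ...) {
  cat("Elastic parameters (spherical inclusion under far-field shear)\n")
  cat(sprintf("  mu_cell  = %g Pa, mu_ecm(base) = %g Pa, alpha = %g Pa/m\n",
              x$mu_cell, x$mu_ecm_base, x$alpha))
  cat(sprintf("  R = %g um, sigma_xy_inf = %g Pa  (eta = %g, k = %g)\n",
              x$cell_radius * 1e6, x$sigma_far, x$eta, x$k))
  invisible(x)
}

# dimensionless stress concentration factor of the interface solution;
# sigma_rr = coef(eta, k) * sigma_far * sin^2(theta) * sin(2*phi)
sigma_rr_coef <- function(eta, k) {
  5 * eta * k /
    (6 * (2 * eta + k) + 4 * eta * k * (71 * eta + 16 * k) /
       (152 * eta + 19 * eta * k + 16 * k))
}

#' Normal interface stress at a point on the cell surface
#'
#' Evaluates the closed-form normal stress \eqn{\sigma_{rr}} at the cell-ECM
#' interface of a spherical cell under uniform far-field shear:
#' \deqn{\sigma_{rr} = \frac{5\eta k}{6(2\eta+k) +
#'   \frac{4\eta k(71\eta+16k)}{152\eta+19\eta k+16k}}\,
#'   \sigma_{xy,\infty}\,\sin^2\theta\,\sin 2\phi}
#' with \eqn{\eta} and \eqn{k} evaluated against the current (possibly
#' stiffened) ECM modulus. Positive values are tensile.
#'
#' @param theta,phi Spherical polar angles (rad); vectorised.
#' @param params An \code{\link{elastic_params}} object.
#' @param mu_ecm_current Current ECM shear modulus (Pa); defaults to the
#'   unstiffened base modulus.
#' @return Normal stress (Pa), same length as \code{theta}.
#' @export
compute_sigma_rr <- function(theta, phi, params = elastic_params(),
                             mu_ecm_current = params$mu_ecm_base) {
  stopifnot(inherits(params, "elastic_params"))
  if (!all(is.finite(mu_ecm_current)) || any(mu_ecm_current <= 0))
    stop("mu_ecm_current must be finite and positive", call. = FALSE)
  if (!all(is.finite(theta)) || !all(is.finite(phi)))
    stop("angles must be finite", call. = FALSE)
  eta <- params$mu_cell / mu_ecm_current
  k <- params$alpha * params$cell_radius / mu_ecm_current
  sigma_rr_coef(eta, k) * params$sigma_far * sin(theta)^2 * sin(2 * phi)
}

#' Equal-area integrin patch radius
#'
#' Each of N equal-sized integrins tiles an area \eqn{4\pi R^2/N} of the cell
#' surface; the circle of equal area has radius \eqn{a = 2R/\sqrt{N}}.
#'
#' @param R Cell radius (m).
#' @param N Number of integrins (>= 1).
#' @return Patch radius a (m).
#' @export
patch_radius <- function(R, N) {
  if (!is.finite(R) || R <= 0) stop("R must be positive", call. = FALSE)
  if (!all(is.finite(N)) || any(N < 1))
    stop("N must be a positive integer count", call. = FALSE)
  2 * R / sqrt(N)
}

#' Force on an integrin patch
#'
#' The force transmitted to one integrin is the interface normal stress
#' integrated over its patch, \eqn{F = \pi a^2 \sigma_{rr}}; the variation of
#' \eqn{\sigma_{rr}} within the small patch is neglected. The sign of the
#' stress is carried (positive = tension).
#'
#' @param a Patch radius (m).
#' @param sigma_rr Normal stress at the patch centre (Pa); vectorised.
#' @return Signed force (N).
#' @export
integrin_force <- function(a, sigma_rr) {
  if (!all(is.finite(a)) || any(a <= 0))
    stop("patch radius must be positive", call. = FALSE)
  pi * a^2 * sigma_rr
}

#' ECM modulus after matrix-protein deposition
#'
#' Every deposited matrix protein (ECMp) raises the ECM elasticity by a
#' per-protein increment of 0.001. The increment has no published units;
#' three conventions are provided, all config-exposed:
#' \describe{
#'   \item{\code{"power"} (default)}{\eqn{\mu_M = \mu_{base}(1 + i\,n)^\beta}
#'     with stiffening exponent \code{beta} (default 2). This is the
#'     calibrated convention: it silences an all-sensitive integrin
#'     population on the hours timescale while letting ultrasensitive
#'     integrins persist far longer.}
#'   \item{\code{"linear"}}{\eqn{\mu_M = \mu_{base}(1 + i\,n)}; equals
#'     \code{"power"} with \code{beta = 1}.}
#'   \item{\code{"compound"}}{\eqn{\mu_M = \mu_{base}(1 + i)^n}; each
#'     deposit multiplies the modulus by \code{1 + i}.}
#' }
#'
#' @param n_deposited Cumulative count of deposited ECMp (>= 0).
#' @param params An \code{\link{elastic_params}} object (supplies the base
#'   modulus).
#' @param increment Per-protein elasticity increment (default 0.001).
#' @param convention One of \code{"power"}, \code{"linear"},
#'   \code{"compound"}.
#' @param beta Stiffening exponent for the \code{"power"} convention.
#' @return Current ECM shear modulus (Pa); never below the base modulus.
#' @export
update_ecm_modulus <- function(n_deposited, params = elastic_params(),
                               increment = 0.001,
                               convention = c("power", "linear", "compound"),
                               beta = 2) {
  convention <- match.arg(convention)
  if (!all(is.finite(n_deposited)) || any(n_deposited < 0))
    stop("n_deposited must be a non-negative count", call. = FALSE)
  base <- params$mu_ecm_base
  switch(convention,
         power = base * (1 + increment * n_deposited)^beta,
         linear = base * (1 + increment * n_deposited),
         compound = base * (1 + increment)^n_deposited)
}

#' Integrin model variants
#'
#' The four integrin mechanosensitivity populations: homogeneous sensitive
#' (\code{SM}: every threshold at 10\% of the reference force), homogeneous
#' ultrasensitive (\code{USM}: 1\%), and heterogeneous mixtures with 10\%
#' (\code{HM10}) or 1\% (\code{HM1}) of the population ultrasensitive and the
#' remainder sensitive. For the heterogeneous variants the named percentage
#' of N (rounded to nearest) is used; an alternative reading of the mixing
#' ratios 1:10 / 1:100 as 1/11 and 1/101 of the population is available via
#' \code{ratio_convention = "odds"}.
#'
#' @param name One of \code{"SM"}, \code{"USM"}, \code{"HM10"}, \code{"HM1"}.
#' @param mt_sensitive,mt_ultrasensitive Threshold levels as fractions of the
#'   reference force (defaults 0.10 and 0.01).
#' @param ratio_convention \code{"percent"} (default) or \code{"odds"}.
#' @return An object of class \code{variant_spec} with the class fractions.
#' @export
variant_spec <- function(name = c("SM", "USM", "HM10", "HM1"),
                         mt_sensitive = 0.10, mt_ultrasensitive = 0.01,
                         ratio_convention = c("percent", "odds")) {
  name <- match.arg(name)
  ratio_convention <- match.arg(ratio_convention)
  uf <- switch(name,
               SM = 0,
               USM = 1,
               HM10 = if (ratio_convention == "percent") 0.10 else 1 / 11,
               HM1 = if (ratio_convention == "percent") 0.01 else 1 / 101)
  out <- list(name = name,
              sensitive_fraction = 1 - uf,
              ultrasensitive_fraction = uf,
              mt_sensitive = mt_sensitive,
              mt_ultrasensitive = mt_ultrasensitive)
  class(out) <- "variant_spec"
  out
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf(
    "Integrin variant %s: %.1f%% sensitive (MT = %g f_ref), %.1f%% ultrasensitive (MT = %g f_ref)\n",
    x$name, 100 * x$sensitive_fraction, x$mt_sensitive,
    100 * x$ultrasensitive_fraction, x$mt_ultrasensitive))
  invisible(x)
}

#' Assign mechanosensitivity thresholds to an integrin population
#'
#' Draws the per-integrin mechanosensitivity thresholds (MT) for a variant.
#' Thresholds are fractions of the reference force \code{f_ref}, defined as
#' the peak per-integrin force at time zero (patch at theta = pi/2,
#' phi = pi/4 with the unstiffened ECM). For heterogeneous variants, the
#' ultrasensitive members (rounded to the nearest integer count) are chosen
#' uniformly at random, reproducibly from the current RNG state.
#'
#' @param variant A \code{\link{variant_spec}} (or variant name).
#' @param N Number of integrins.
#' @param f_ref Reference force (N), > 0.
#' @return A data.frame with columns \code{mt} (N) and
#'   \code{sensitivity_class} (\code{"sensitive"}/\code{"ultrasensitive"}).
#' @export
assign_thresholds <- function(variant, N, f_ref) {
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(inherits(variant, "variant_spec"))
  if (!is.finite(f_ref) || f_ref <= 0)
    stop("f_ref must be positive", call. = FALSE)
  if (!is.finite(N) || N < 1) stop("N must be >= 1", call. = FALSE)
  n_ultra <- round(variant$ultrasensitive_fraction * N)
  cls <- rep("sensitive", N)
  if (n_ultra > 0) {
    idx <- if (n_ultra >= N) seq_len(N) else sample.int(N, n_ultra)
    cls[idx] <- "ultrasensitive"
  }
  mt <- ifelse(cls == "ultrasensitive",
               variant$mt_ultrasensitive, variant$mt_sensitive) * f_ref
  data.frame(mt = mt, sensitivity_class = cls, stringsAsFactors = FALSE)
}

#' Mechanical activation rule
#'
#' An integrin is mechanically activated when the (signed) force on it is at
#' or above its mechanosensitivity threshold. Only tensile (positive) forces
#' activate; compression never does.
#'
#' @param force Signed force (N); vectorised.
#' @param mt Mechanosensitivity threshold (N), > 0.
#' @return Logical activation flag.
#' @export
check_activation <- function(force, mt) {
  if (!all(is.finite(mt)) || any(mt <= 0))
    stop("mt must be positive", call. = FALSE)
  force >= mt
}

#' Near-uniform integrin layout on the sphere
#'
#' Deterministic equal-area (Fibonacci lattice) placement of N static
#' integrins on the cell surface, or a seeded uniform-random placement.
#'
#' @param N Number of integrins.
#' @param layout \code{"fibonacci"} (default, deterministic) or
#'   \code{"random"} (uses the current RNG state).
#' @return A data.frame with columns \code{theta}, \code{phi} (rad).
#' @export
integrin_layout <- function(N, layout = c("fibonacci", "random")) {
  layout <- match.arg(layout)
  if (layout == "fibonacci") {
    i <- seq_len(N) - 0.5
    z <- 1 - 2 * i / N
    theta <- acos(z)
    golden <- pi * (3 - sqrt(5))
    phi <- (i * golden) %% (2 * pi)
  } else {
    z <- stats::runif(N, -1, 1)
    theta <- acos(z)
    phi <- stats::runif(N, 0, 2 * pi)
  }
  data.frame(theta = theta, phi = phi)
}

#' Reference force for threshold assignment
#'
#' The peak per-integrin force at time zero: the patch-integrated interface
#' stress at its spatial maximum (theta = pi/2, phi = pi/4) with the
#' unstiffened ECM.
#'
#' @param params An \code{\link{elastic_params}} object.
#' @param N Number of integrins.
#' @return Force (N).
#' @export
reference_force <- function(params = elastic_params(), N = 500) {
  a <- patch_radius(params$cell_radius, N)
  integrin_force(a, compute_sigma_rr(pi / 2, pi / 4, params))
}

#' Per-integrin force table
#'
#' Evaluates the mechanical model at every integrin location: the interface
#' normal stress for the current ECM modulus, the patch force, and the
#' activation flag against each integrin's threshold.
#'
#' @param theta,phi Integrin angular positions (rad).
#' @param mt Per-integrin thresholds (N).
#' @param params An \code{\link{elastic_params}} object.
#' @param n_deposited Cumulative deposited ECMp count.
#' @param N Number of integrins (defaults to \code{length(theta)}).
#' @param ... Passed to \code{\link{update_ecm_modulus}} (convention, beta,
#'   increment).
#' @return A data.frame with columns \code{index}, \code{theta}, \code{phi},
#'   \code{sigma_rr}, \code{force_N}, \code{mt_N}, \code{active}.
#' @export
force_table <- function(theta, phi, mt, params = elastic_params(),
                        n_deposited = 0, N = length(theta), ...) {
  mu <- update_ecm_modulus(n_deposited, params, ...)
  s <- compute_sigma_rr(theta, phi, params, mu)
  a <- patch_radius(params$cell_radius, N)
  f <- integrin_force(a, s)
  data.frame(index = seq_along(theta), theta = theta, phi = phi,
             sigma_rr = s, force_N = f, mt_N = mt,
             active = check_activation(f, mt))
}

#' Within-patch variation of the interface stress pattern
#'
#' Quantifies how much the angular stress pattern
#' \eqn{X = \sin^2\theta \sin 2\phi} varies inside one equal-area integrin
#' patch: for each patch (a spherical cap of the equal-area angular radius
#' \eqn{2/\sqrt{N}}), the mean absolute deviation of X from its patch-centre
#' value is estimated by Monte Carlo over the cap, expressed as a fraction of
#' the global maximum |X| = 1, and averaged over all patches. For N = 500
#' this evaluates to under 7.5\%, justifying the constant-stress-per-patch
#' approximation.
#'
#' @param N Number of patches.
#' @param n_mc Monte Carlo points per patch.
#' @param seed RNG seed for the sweep.
#' @return Mean within-patch absolute deviation (fraction of max |X|).
#' @export
patch_variation <- function(N = 500, n_mc = 200, seed = 1) {
  lay <- integrin_layout(N)
  alpha_cap <- 2 / sqrt(N)  # equal-area cap angular radius
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  xpat <- function(th, ph) sin(th)^2 * sin(2 * ph)
  dev <- vapply(seq_len(N), function(i) {
    th0 <- lay$theta[i]; ph0 <- lay$phi[i]
    c0 <- c(sin(th0) * cos(ph0), sin(th0) * sin(ph0), cos(th0))
    # uniform points on the cap around c0
    cosa <- 1 - stats::runif(n_mc) * (1 - cos(alpha_cap))
    sina <- sqrt(pmax(0, 1 - cosa^2))
    psi <- stats::runif(n_mc, 0, 2 * pi)
    # orthonormal frame at c0
    ref <- if (abs(c0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * c0) * c0; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(c0[2] * e1[3] - c0[3] * e1[2],
            c0[3] * e1[1] - c0[1] * e1[3],
            c0[1] * e1[2] - c0[2] * e1[1])
    p <- outer(cosa, c0) + outer(sina * cos(psi), e1) + outer(sina * sin(psi), e2)
    th <- acos(pmin(1, pmax(-1, p[, 3])))
    ph <- atan2(p[, 2], p[, 1])
    mean(abs(xpat(th, ph) - xpat(th0, ph0)))
  }, numeric(1))
  mean(dev)
}

# save/restore .Random.seed without assuming it exists
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
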
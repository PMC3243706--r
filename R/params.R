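#' Model parameters for the coarse-grained microtubule lattice
#'
#' Collects every physical constant, equilibrium value and algorithm
#' tolerance of the model in one validated record. Defaults are the standard
#' parameterization of the coarse-grained 13-protofilament microtubule:
#' spring constants in nN/nm (stretch) and nN*nm per radian^2 (bend,
#' dihedral), rest lengths in nm, equilibrium angles in degrees, association
#' free energies in kBT per dimer.
#'
#' @param k_long_stretch,k_lat_stretch,k_diag_stretch stretch spring
#'   constants, nN/nm.
#' @param k_long_bend,k_lat_bend bending constants, nN*nm.
#' @param k_long_dihedral,k_lat_dihedral dihedral bending constants, nN*nm.
#' @param r0_long,r0_lat equilibrium longitudinal / lateral intervals, nm.
#' @param theta0_long_GTP,theta0_long_GDP equilibrium longitudinal bend
#'   angle between neighboring monomers, degrees; hydrolysis (GTP -> GDP)
#'   increases the intrinsic curvature.
#' @param theta0_lat equilibrium lateral bend angle, degrees (zero: flat
#'   sheets are the lateral ground state).
#' @param phi0_long,phi0_lat equilibrium dihedral angles, degrees.
#' @param dG_long,dG_lat,dG_S association free energies: longitudinal bond,
#'   lateral bond, and the entropic immobilization penalty, kBT per dimer.
#' @param n_protofilaments,pitch_monomers lattice architecture; the standard
#'   microtubule has 13 protofilaments and a helical pitch of 3 monomers.
#' @param monomer_mass mass of one coarse-grained monomer, kDa.
#' @param dt Verlet integration step, internal time units.
#' @param convergence_tol absolute tolerance on |RMS(last 10) - RMS(last 20)|
#'   of the total potential energy, nN*nm.
#' @param kinetic_energy_target initial thermostat target: average kinetic
#'   energy per monomer, nN*nm. Default 0.5 kBT.
#' @param thermostat \code{"cap"} (default): during \code{\link{relax}} the
#'   velocity rescaling only removes kinetic energy above the target, so a
#'   relaxation is purely dissipative and the transient energy peak is
#'   physical; \code{"constant"}: rescale to the exact target every step
#'   (which also pumps heat into soft modes).
#' @param anneal_patience,anneal_factor staged-quench schedule: when the
#'   potential energy has not improved for \code{anneal_patience} steps the
#'   kinetic target is multiplied by \code{anneal_factor}.
#' @param max_steps relaxation step budget.
#' @param polish_maxit iteration budget of the gradient polish that
#'   follows the Verlet phase of \code{\link{relax}}.
#' @param divergence_factor abort when the energy exceeds this multiple of
#'   the starting energy.
#' @param kBT_internal thermal energy in internal units, nN*nm per kBT
#'   (4.141e-3 at 300 K).
#' @param lateral_rest_convention \code{"euclidean"}: the stated 5.2 nm rest
#'   length applies to the Euclidean monomer distance; \code{"chord"}: the
#'   rest length is the planar chord 2R sin(pi/n) of the derived cylinder;
#'   \code{"tube"}: the rest length is the actual lateral neighbor distance
#'   on the derived cylinder, sqrt(chord^2 + rise^2), making the canonical
#'   tube lattice stretch-free (the same convention the printed diagonal
#'   rest lengths follow).
#' @param rng_seed integer seed recorded with runs.
#' @return An object of class \code{mt_params} (a validated list), with the
#'   derived geometry fields filled in by \code{\link{derive_geometry}}.
#' @export
mt_params <- function(k_long_stretch = 3.0,
                      k_lat_stretch = 14.0,
                      k_diag_stretch = 3.0,
                      k_long_bend = 2.0,
                      k_lat_bend = 8.5,
                      k_long_dihedral = 0.04,
                      k_lat_dihedral = 0.17,
                      r0_long = 4.0,
                      r0_lat = 5.2,
                      theta0_long_GTP = 5.0,
                      theta0_long_GDP = 18.0,
                      theta0_lat = 0.0,
                      phi0_long = 0.0,
                      phi0_lat = 0.0,
                      dG_long = -19,
                      dG_lat = -4,
                      dG_S = 11,
                      n_protofilaments = 13L,
                      pitch_monomers = 3L,
                      monomer_mass = 55,
                      dt = 0.1,
                      convergence_tol = 1e-4,
                      kinetic_energy_target = 0.5 * 4.141e-3,
                      thermostat = c("cap", "constant"),
                      anneal_patience = 50L,
                      anneal_factor = 0.5,
                      max_steps = 200000L,
                      polish_maxit = 25000L,
                      divergence_factor = 1e3,
                      kBT_internal = 4.141e-3,
                      lateral_rest_convention = c("euclidean", "chord",
                                                  "tube"),
                      rng_seed = 1L) {
  p <- list(
    k_long_stretch = k_long_stretch, k_lat_stretch = k_lat_stretch,
    k_diag_stretch = k_diag_stretch, k_long_bend = k_long_bend,
    k_lat_bend = k_lat_bend, k_long_dihedral = k_long_dihedral,
    k_lat_dihedral = k_lat_dihedral,
    r0_long = r0_long, r0_lat = r0_lat,
    theta0_long_GTP = theta0_long_GTP, theta0_long_GDP = theta0_long_GDP,
    theta0_lat = theta0_lat, phi0_long = phi0_long, phi0_lat = phi0_lat,
    dG_long = dG_long, dG_lat = dG_lat, dG_S = dG_S,
    n_protofilaments = as.integer(n_protofilaments),
    pitch_monomers = as.integer(pitch_monomers),
    monomer_mass = monomer_mass, dt = dt,
    convergence_tol = convergence_tol,
    kinetic_energy_target = kinetic_energy_target,
    thermostat = match.arg(thermostat),
    anneal_patience = as.integer(anneal_patience),
    anneal_factor = anneal_factor,
    max_steps = as.integer(max_steps),
    polish_maxit = as.integer(polish_maxit),
    divergence_factor = divergence_factor,
    kBT_internal = kBT_internal,
    lateral_rest_convention = match.arg(lateral_rest_convention),
    rng_seed = as.integer(rng_seed)
  )
  class(p) <- "mt_params"
  validate_params(p)
  derive_geometry(p)
}

validate_params <- function(p) {
  ks <- c("k_long_stretch", "k_lat_stretch", "k_diag_stretch", "k_long_bend",
          "k_lat_bend", "k_long_dihedral", "k_lat_dihedral")
  for (k in ks) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1 || p[[k]] <= 0)
      stop("parameter '", k, "' must be a single strictly positive number")
  }
  for (k in c("r0_long", "r0_lat", "monomer_mass", "dt", "convergence_tol",
              "kBT_internal")) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1 || p[[k]] <= 0)
      stop("parameter '", k, "' must be a single strictly positive number")
  }
  if (p$theta0_long_GDP <= p$theta0_long_GTP)
    stop("theta0_long_GDP must exceed theta0_long_GTP ",
         "(hydrolysis increases intrinsic curvature)")
  if (p$kinetic_energy_target < 0)
    stop("kinetic_energy_target must be >= 0")
  if (p$anneal_factor <= 0 || p$anneal_factor >= 1)
    stop("anneal_factor must lie in (0, 1)")
  if (p$n_protofilaments <= 2)
    stop("n_protofilaments must exceed 2")
  if (p$pitch_monomers < 0)
    stop("pitch_monomers must be >= 0")
  invisible(p)
}

#' Derive the cylinder geometry and diagonal rest lengths
#'
#' From the lattice architecture (n protofilaments, helical pitch in
#' monomers) and the two primary rest lengths, computes the cylinder radius
#' \eqn{R = n r_{lat} / 2\pi}, the per-subunit helical rise
#' \eqn{h = pitch \cdot r_{long} / n}, the lateral chord
#' \eqn{c = 2R\sin(\pi/n)}, and the two diagonal rest lengths
#' \eqn{\sqrt{c^2 + (r_{long} \mp h)^2}}. For the standard parameters these
#' are 5.9988 nm and 7.1242 nm.
#'
#' @param params an \code{mt_params} object (possibly without derived
#'   fields).
#' @return the same object with \code{radius}, \code{rise},
#'   \code{lat_chord}, \code{r0_diag_short} and \code{r0_diag_long} set.
#' @export
derive_geometry <- function(params) {
  n <- params$n_protofilaments
  if (is.null(n) || n <= 2) stop("need more than 2 protofilaments")
  if (params$r0_long <= 0 || params$r0_lat <= 0)
    stop("rest lengths must be positive")
  R <- n * params$r0_lat / (2 * pi)
  h <- params$pitch_monomers * params$r0_long / n
  ch <- 2 * R * sin(pi / n)
  params$radius <- R
  params$rise <- h
  params$lat_chord <- ch
  params$r0_diag_short <- sqrt(ch^2 + (params$r0_long - h)^2)
  params$r0_diag_long <- sqrt(ch^2 + (params$r0_long + h)^2)
  if (params$r0_diag_short > params$r0_diag_long)
    stop("internal geometry error: diagonal ordering violated")
  params
}

#' @export
print.mt_params <- function(x, ...) {
  cat("Coarse-grained microtubule model parameters\n")
  cat(sprintf("  %d protofilaments, pitch %d monomers\n",
              x$n_protofilaments, x$pitch_monomers))
  cat(sprintf("  r0 long/lat: %.3f / %.3f nm; diagonals: %.4f / %.4f nm\n",
              x$r0_long, x$r0_lat, x$r0_diag_short, x$r0_diag_long))
  cat(sprintf("  theta0 long GTP/GDP: %.1f / %.1f deg\n",
              x$theta0_long_GTP, x$theta0_long_GDP))
  cat(sprintf("  k stretch (long/lat/diag): %.2f / %.2f / %.2f nN/nm\n",
              x$k_long_stretch, x$k_lat_stretch, x$k_diag_stretch))
  cat(sprintf("  k bend (long/lat): %.2f / %.2f nN*nm; k dihedral: %.3f / %.3f\n",
              x$k_long_bend, x$k_lat_bend, x$k_long_dihedral, x$k_lat_dihedral))
  cat(sprintf("  dG long/lat/S: %g / %g / %g kBT per dimer\n",
              x$dG_long, x$dG_lat, x$dG_S))
  invisible(x)
}
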
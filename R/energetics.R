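# Term-array assembly: flatten the topology into the parallel vectors the
# C++ engine consumes (0-based indices, per-term stiffness / rest value /
# energy-component id). The longitudinal bend equilibrium follows the
# nucleotide state of the central monomer's dimer: 5 deg (GTP) or 18 deg
# (GDP) by default.
term_arrays <- function(lattice, params) {
  if (params$phi0_long != 0 || params$phi0_lat != 0)
    stop("nonzero equilibrium dihedral angles are not supported")
  tp <- lattice$topology
  m <- lattice$monomers
  deg <- pi / 180

  pr <- tp$pairs
  pk <- c(long = params$k_long_stretch, lat = params$k_lat_stretch,
          diag_short = params$k_diag_stretch,
          diag_long = params$k_diag_stretch)[pr$class]
  lat_rest <- switch(params$lateral_rest_convention,
                     chord = params$lat_chord,
                     tube = sqrt(params$lat_chord^2 + params$rise^2),
                     params$r0_lat)
  pr0 <- c(long = params$r0_long, lat = lat_rest,
           diag_short = params$r0_diag_short,
           diag_long = params$r0_diag_long)[pr$class]
  pcomp <- c(long = 0L, lat = 1L, diag_short = 2L, diag_long = 2L)[pr$class]

  tr <- tp$triples
  tk <- ifelse(tr$class == "long", params$k_long_bend, params$k_lat_bend)
  th0_long <- ifelse(m$nucleotide[tr$b] == "GDP",
                     params$theta0_long_GDP, params$theta0_long_GTP) * deg
  t0 <- ifelse(tr$class == "long", th0_long, params$theta0_lat * deg)
  tcomp <- ifelse(tr$class == "long", 3L, 4L)

  dh <- tp$dihedrals
  dk <- ifelse(dh$class == "long", params$k_long_dihedral,
               params$k_lat_dihedral)
  dcomp <- ifelse(dh$class == "long", 5L, 6L)

  list(pairs = cbind(pr$i, pr$j) - 1L, pk = as.numeric(pk),
       pr0 = as.numeric(pr0), pcomp = as.integer(pcomp),
       triples = cbind(tr$a, tr$b, tr$c) - 1L, tk = as.numeric(tk),
       tth0 = as.numeric(t0), tcomp = as.integer(tcomp),
       dihs = cbind(dh$a, dh$b, dh$c) - 1L, dk = as.numeric(dk),
       dcomp = as.integer(dcomp))
}

empty_imat <- function() matrix(integer(), 0, 3)

comp_names <- c("e_long_stretch", "e_lat_stretch", "e_diag_stretch",
                "e_long_bend", "e_lat_bend", "e_long_dihedral",
                "e_lat_dihedral")

#' Harmonic interaction energy
#'
#' All seven lattice interactions share the quadratic form
#' \eqn{E = k \, \delta^2 / 2} where \eqn{\delta} is the deviation of a
#' distance (nm) or angle (radians) from its equilibrium value.
#'
#' @param k stiffness (nN/nm for distances, nN*nm per radian^2 for angles).
#' @param deviation displacement from equilibrium.
#' @return energy in nN*nm.
#' @export
harmonic_energy <- function(k, deviation) {
  stopifnot(all(k >= 0))
  0.5 * k * deviation^2
}

#' Bending angle of a monomer triple
#'
#' Returns the supplementary angle of the interior angle A-B-C: zero for a
#' straight chain, growing as the chain kinks.
#'
#' @param A,B,C position 3-vectors.
#' @return angle in radians, in \code{[0, pi]}.
#' @export
bend_angle <- function(A, B, C) {
  u <- A - B
  v <- C - B
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9)
    stop("degenerate bend triple: coincident points")
  ci <- sum(u * v) / (nu * nv)
  ci <- max(-1, min(1, ci))
  pi - acos(ci)
}

#' Dihedral angle with a radial reference
#'
#' Longitudinal class: signed angle between plane(A, B, C) and the
#' reference plane (A', A, B), where A' - A is the radial direction of A
#' from the lab z axis. Lateral class: signed angle between plane
#' (A', A, B) and (B', B, C) with A, B, C three monomers along a helical
#' turn. Zero for an untwisted reference lattice; the sign follows the
#' right-hand rule about the A-to-B direction (a mirror reflection negates
#' it). The potential is quadratic about zero, so energies are
#' sign-independent.
#'
#' @param A,B,C position 3-vectors (for the lateral class these are the
#'   D, E, F monomers of the turn).
#' @param class \code{"long"} or \code{"lat"}.
#' @return signed angle in radians.
#' @export
dihedral_angle <- function(A, B, C, class = c("long", "lat")) {
  class <- match.arg(class)
  ur <- function(p) {
    rho <- sqrt(p[1]^2 + p[2]^2)
    if (rho < 1e-9) stop("monomer on the tube axis: radial reference undefined")
    c(p[1], p[2], 0) / rho
  }
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  if (class == "long") {
    n1 <- cross3(B - A, C - B)
    n2 <- cross3(ur(A), B - A)
  } else {
    n1 <- cross3(ur(A), B - A)
    n2 <- cross3(ur(B), C - B)
  }
  l1 <- sqrt(sum(n1^2)); l2 <- sqrt(sum(n2^2))
  if (l1 < 1e-9 || l2 < 1e-9)
    stop("degenerate dihedral: collinear triple")
  co <- max(-1, min(1, sum(n1 * n2) / (l1 * l2)))
  ang <- acos(co)
  axis <- B - A
  s <- sum(cross3(n2, n1) * axis)
  if (s < 0) ang <- -ang
  ang
}

#' Total potential energy of a conformation
#'
#' Sums the harmonic energy of every topology term with its
#' class-appropriate stiffness, rest value and (for longitudinal bends)
#' nucleotide-dependent equilibrium angle.
#'
#' @param lattice \code{mt_lattice}.
#' @param conf \code{mt_conformation}.
#' @param params \code{mt_params}.
#' @param per_monomer also return the per-monomer attribution (each term's
#'   energy split equally among its participants); a visualization
#'   convention only.
#' @return an \code{mt_energy}: the seven components (nN*nm), their sum
#'   \code{e_total}, and optionally \code{per_monomer}.
#' @export
total_energy <- function(lattice, conf, params, per_monomer = FALSE) {
  ta <- term_arrays(lattice, params)
  res <- cpp_eval(conf$pos, ta$pairs, ta$pk, ta$pr0, ta$pcomp, ta$triples,
                  ta$tk, ta$tth0, ta$tcomp, ta$dihs, ta$dk, ta$dcomp,
                  FALSE, per_monomer)
  out <- as.list(setNames(res$components, comp_names))
  out$e_total <- res$total
  if (per_monomer) out$per_monomer <- res$per_monomer
  class(out) <- "mt_energy"
  out
}

#' @export
print.mt_energy <- function(x, ...) {
  for (nm in comp_names)
    cat(sprintf("  %-16s %12.6g nN*nm\n", nm, x[[nm]]))
  cat(sprintf("  %-16s %12.6g nN*nm\n", "e_total", x$e_total))
  invisible(x)
}

#' Forces on every monomer
#'
#' Negative gradient of \code{\link{total_energy}} with respect to the
#' monomer coordinates; interactions are purely internal, so the net force
#' and net torque vanish.
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces, nN.
#' @export
forces <- function(lattice, conf, params) {
  ta <- term_arrays(lattice, params)
  res <- cpp_eval(conf$pos, ta$pairs, ta$pk, ta$pr0, ta$pcomp, ta$triples,
                  ta$tk, ta$tth0, ta$tcomp, ta$dihs, ta$dk, ta$dcomp,
                  TRUE, FALSE)
  res$forces
}

#' Convert internal energies to thermal units
#'
#' @param e energy in nN*nm.
#' @param params \code{mt_params} (uses \code{kBT_internal}).
#' @return energy in kBT.
#' @export
energy_to_kBT <- function(e, params) e / params$kBT_internal
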
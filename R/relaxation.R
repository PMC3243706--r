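#' One (or a few) velocity-Verlet integration steps
#'
#' Advances the conformation by plain velocity-Verlet steps of size
#' \code{params$dt}. With \code{rescale = TRUE} the velocities are rescaled
#' after each step by a single scalar so that the average kinetic energy per
#' monomer equals \code{params$kinetic_energy_target}; with
#' \code{rescale = FALSE} the integration is symplectic and total energy is
#' conserved to O(dt^2).
#'
#' @param lattice \code{mt_lattice}.
#' @param conf \code{mt_conformation}.
#' @param params \code{mt_params}.
#' @param n_steps number of steps.
#' @param rescale apply the kinetic-energy thermostat.
#' @return list: updated \code{conf}, vectors \code{e_pot} and \code{e_kin}
#'   (one entry per step, measured after the step).
#' @export
verlet_step <- function(lattice, conf, params, n_steps = 1, rescale = TRUE) {
  ta <- term_arrays(lattice, params)
  res <- cpp_verlet(conf$pos, conf$vel, conf$mass, ta$pairs, ta$pk, ta$pr0,
                    ta$pcomp, ta$triples, ta$tk, ta$tth0, ta$tcomp, ta$dihs,
                    ta$dk, ta$dcomp, params$dt, as.integer(n_steps),
                    params$kinetic_energy_target, rescale)
  list(conf = new_conformation(res$pos, conf$mass, res$vel),
       e_pot = res$e_pot, e_kin = res$e_kin)
}

#' Relax a conformation to its equilibrium
#'
#' Velocity-Verlet integration with single-scalar kinetic-energy rescaling,
#' terminated by the convergence rule: the difference between the root mean
#' square of the total potential energy over the last ten and the last
#' twenty steps must fall below \code{params$convergence_tol}. The kinetic
#' target follows a staged quench (see \code{\link{mt_params}}) so that the
#' criterion can fire once the structure has settled. Velocities are zeroed
#' on entry: a relaxation always starts from a conformational perturbation
#' at rest.
#'
#' @param lattice \code{mt_lattice}.
#' @param conf \code{mt_conformation}.
#' @param params \code{mt_params}.
#' @param max_steps step budget (default \code{params$max_steps}).
#' @param rescale apply the thermostat (default TRUE; without it a
#'   perturbed lattice oscillates forever and never converges).
#' @param trace_thin record every n-th energy in the returned trace (the
#'   peak and final energies are tracked at every step regardless).
#' @param polish after the Verlet phase, descend to the precise local
#'   minimum with L-BFGS on the analytic gradient (default TRUE). The
#'   thermostat quench alone leaves a small residual strain in soft
#'   collective modes; polishing removes it so equilibrium energies (and
#'   hence steppings) are well defined. The transient peak is still taken
#'   from the Verlet trace.
#' @return list: \code{conf} (relaxed), \code{trace} (an
#'   \code{mt_trace}: \code{e_total} series in nN*nm, \code{converged},
#'   \code{steps_taken}, \code{peak_energy}, \code{e_initial},
#'   \code{e_final}, \code{components}).
#' @export
relax <- function(lattice, conf, params, max_steps = params$max_steps,
                  rescale = TRUE, trace_thin = 1L, polish = TRUE) {
  if (max_steps < 20) stop("max_steps must be >= 20 for the RMS criterion")
  ta <- term_arrays(lattice, params)
  vel0 <- matrix(0, nrow(conf$pos), 3)
  cap_only <- !identical(params$thermostat, "constant")
  res <- cpp_relax(conf$pos, vel0, conf$mass, ta$pairs, ta$pk, ta$pr0,
                   ta$pcomp, ta$triples, ta$tk, ta$tth0, ta$tcomp, ta$dihs,
                   ta$dk, ta$dcomp, params$dt, params$kinetic_energy_target,
                   rescale, cap_only, params$anneal_patience,
                   params$anneal_factor, params$convergence_tol,
                   as.integer(max_steps), params$divergence_factor,
                   as.integer(trace_thin))
  if (res$diverged) {
    f <- forces(lattice, new_conformation(res$pos, conf$mass), params)
    worst <- which.max(rowSums(f^2))
    m <- lattice$monomers[worst, ]
    stop(sprintf(paste0("relaxation diverged after %d steps ",
                        "(largest force on monomer %d: protofilament %d, ",
                        "axial %d, |F| = %.3g nN)"),
                 res$steps, worst, m$pf, m$axial,
                 sqrt(max(rowSums(f^2)))))
  }
  pos <- res$pos
  vel <- res$vel
  e_final <- res$e_final
  e_trace <- res$trace
  components <- setNames(as.numeric(res$components), comp_names)
  if (polish) {
    n <- nrow(pos)
    fn <- function(x) cpp_eval(matrix(x, n, 3), ta$pairs, ta$pk, ta$pr0,
                               ta$pcomp, ta$triples, ta$tk, ta$tth0,
                               ta$tcomp, ta$dihs, ta$dk, ta$dcomp,
                               FALSE, FALSE)$total
    gr <- function(x) -as.vector(cpp_eval(matrix(x, n, 3), ta$pairs, ta$pk,
                                          ta$pr0, ta$pcomp, ta$triples,
                                          ta$tk, ta$tth0, ta$tcomp, ta$dihs,
                                          ta$dk, ta$dcomp, TRUE,
                                          FALSE)$forces)
    maxit <- params$polish_maxit
    if (is.null(maxit)) maxit <- 10000L
    opt <- stats::optim(as.vector(pos), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e5))
    if (opt$value <= e_final) {
      pos <- matrix(opt$par, n, 3)
      vel <- matrix(0, n, 3)
      e_final <- opt$value
      e_trace <- c(e_trace, e_final)
      cc <- cpp_eval(pos, ta$pairs, ta$pk, ta$pr0, ta$pcomp, ta$triples,
                     ta$tk, ta$tth0, ta$tcomp, ta$dihs, ta$dk, ta$dcomp,
                     FALSE, FALSE)
      components <- setNames(as.numeric(cc$components), comp_names)
    }
  }
  trace <- structure(
    list(e_total = e_trace, converged = res$converged,
         steps_taken = res$steps,
         peak_energy = max(res$peak_energy, res$e_initial),
         e_initial = res$e_initial, e_final = e_final,
         components = components),
    class = "mt_trace")
  list(conf = new_conformation(pos, conf$mass, vel), trace = trace)
}

#' @export
print.mt_trace <- function(x, ...) {
  cat(sprintf("mt_trace: %d steps, %s; E %.4f -> %.4f (peak %.4f) nN*nm\n",
              x$steps_taken,
              if (x$converged) "converged" else "NOT converged",
              x$e_initial, x$e_final, x$peak_energy))
  invisible(x)
}
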
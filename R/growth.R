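# Experiment presets: multi-closure sequences, curvature / nucleotide-state
# variants, the sheet-length sweep, parameter sensitivity, and the
# Tetris-like growth loop coupling assembly and closure.

#' Build and relax the standard sheet-ended starting state
#'
#' Constructs the lattice (GTP sheet over a hydrolyzed body by default) and
#' relaxes the initial-guess conformation to its equilibrium; the relaxed
#' state, not the guess, defines the reference energy E0.
#'
#' @param params \code{mt_params}.
#' @param n_closed_turns zipped seam pairs in the body (default 27, which
#'   with the default 10-monomer sheet gives 40 monomers per protofilament,
#'   520 in total).
#' @param sheet_length open-seam length in monomers (default 10).
#' @param scenario nucleotide scenario, see \code{\link{build_lattice}}.
#' @param curl_deg initial-guess curl, see \code{\link{build_lattice}}.
#' @param max_steps relaxation budget.
#' @return list: \code{lattice}, \code{conf}, \code{E0} (nN*nm),
#'   \code{trace}, \code{params}.
#' @export
standard_sheet_state <- function(params = mt_params(), n_closed_turns = 27,
                                 sheet_length = 10, scenario = "standard",
                                 curl_deg = NULL,
                                 max_steps = params$max_steps) {
  built <- build_lattice(params, n_closed_turns, sheet_length,
                         scenario = scenario, curl_deg = curl_deg)
  res <- relax(built$lattice, built$conf, params, max_steps = max_steps)
  list(lattice = built$lattice, conf = res$conf, E0 = res$trace$e_final,
       trace = res$trace, params = params, scenario = scenario)
}

#' Run a sequence of successive monomer-pair closures
#'
#' Each closure starts from an equilibrium conformation and is measured
#' against it. Two protocols are available. Under \code{"formfind"} (the
#' default) every closure starts from a freshly form-found equilibrium of
#' the partially zipped structure, i.e. the sequence walks quasi-statically
#' through the family of form-found sheet states; this reproduces the
#' steady, self-similar zipping regime in which successive barriers and
#' steppings agree. Under \code{"continue"} each closure starts from the
#' relaxed end state of the previous closure's own trajectory; in this
#' model that trajectory progressively escapes into more widely flared
#' sheet conformations, so barriers grow over the first closures (see the
#' methods vignette).
#'
#' @param state a relaxed state from \code{\link{standard_sheet_state}}.
#' @param n_closures number of closures (0 is a no-op).
#' @param mode closure protocol, \code{"formfind"} or \code{"continue"}.
#' @param hydrolysis,threshold,seam_diagonals passed to
#'   \code{\link{close_monomer_pair}}.
#' @param max_steps per-closure relaxation budget.
#' @param trace_thin trace thinning.
#' @return list: \code{result} (data.frame: closure, pair, barrier_kBT,
#'   stepping_kBT, E_before, E_after, converged, n_hydrolyzed),
#'   \code{traces} (list of \code{mt_trace}), \code{state} (final state).
#' @export
run_closure_sequence <- function(state, n_closures = 3,
                                 mode = c("formfind", "continue"),
                                 hydrolysis = "synchronous_turn",
                                 threshold = 0.5, seam_diagonals = FALSE,
                                 max_steps = state$params$max_steps,
                                 trace_thin = 1L) {
  mode <- match.arg(mode)
  params <- state$params
  lattice <- state$lattice
  conf <- state$conf
  E_before <- state$E0
  scn <- state$scenario
  if (is.null(scn)) scn <- "standard"
  rows <- list()
  traces <- list()
  if (n_closures > 0) for (i in seq_len(n_closures)) {
    cl <- close_monomer_pair(lattice, conf, params, hydrolysis = hydrolysis,
                             threshold = threshold, E_before = E_before,
                             seam_diagonals = seam_diagonals,
                             max_steps = max_steps, trace_thin = trace_thin)
    rows[[i]] <- data.frame(
      closure = i, pair = cl$pair, barrier_kBT = cl$barrier_kBT,
      stepping_kBT = cl$stepping_kBT, E_before = E_before,
      E_after = cl$trace$e_final, converged = cl$trace$converged,
      n_hydrolyzed = cl$n_hydrolyzed)
    traces[[i]] <- cl$trace
    if (mode == "continue" || i == n_closures) {
      lattice <- cl$lattice
      conf <- cl$conf
      E_before <- cl$trace$e_final
    } else {
      # form-find the next partially zipped structure from scratch
      nz <- nrow(cl$lattice$seam)
      s_left <- sheet_length(cl$lattice)
      nxt <- standard_sheet_state(params, n_closed_turns = nz,
                                  sheet_length = s_left, scenario = scn,
                                  max_steps = max_steps)
      lattice <- nxt$lattice
      conf <- nxt$conf
      E_before <- nxt$E0
    }
  }
  result <- if (length(rows)) do.call(rbind, rows) else
    data.frame(closure = integer(), pair = integer(),
               barrier_kBT = numeric(), stepping_kBT = numeric(),
               E_before = numeric(), E_after = numeric(),
               converged = logical(), n_hydrolyzed = integer())
  list(result = result, traces = traces,
       state = list(lattice = lattice, conf = conf, E0 = E_before,
                    params = params))
}

#' Build, relax and close a single monomer pair
#'
#' The elementary experiment behind the variant comparisons: form-find the
#' sheet-ended state under the given parameters and scenario, then measure
#' one closure. Variants are compared from a common initial-guess geometry
#' (\code{curl_deg = 5} by default) so that differences reflect the
#' potential, not the guess.
#'
#' @param params \code{mt_params}.
#' @param scenario nucleotide scenario (see \code{\link{build_lattice}}).
#' @param hydrolysis closure hydrolysis rule.
#' @param n_closed_turns,sheet_length model size.
#' @param curl_deg initial-guess curl, degrees per monomer.
#' @param threshold random-hydrolysis threshold.
#' @param max_steps relaxation budget.
#' @return data.frame row: barrier_kBT, stepping_kBT, E0, converged, plus
#'   the closure trace in \code{attr(, "trace")} and the final state in
#'   \code{attr(, "state")}.
#' @export
run_single_closure <- function(params = mt_params(), scenario = "standard",
                               hydrolysis = "synchronous_turn",
                               n_closed_turns = 27, sheet_length = 10,
                               curl_deg = 5, threshold = 0.5,
                               max_steps = params$max_steps) {
  st <- standard_sheet_state(params, n_closed_turns = n_closed_turns,
                             sheet_length = sheet_length,
                             scenario = scenario, curl_deg = curl_deg,
                             max_steps = max_steps)
  cl <- close_monomer_pair(st$lattice, st$conf, params,
                           hydrolysis = hydrolysis, threshold = threshold,
                           E_before = st$E0, max_steps = max_steps)
  out <- data.frame(barrier_kBT = cl$barrier_kBT,
                    stepping_kBT = cl$stepping_kBT, E0 = st$E0,
                    converged = cl$trace$converged)
  attr(out, "trace") <- cl$trace
  attr(out, "state") <- list(lattice = cl$lattice, conf = cl$conf,
                             E0 = cl$trace$e_final, params = params)
  out
}

#' Sweep the sheet length and close one monomer pair per condition
#'
#' Ten (by default) models of equal total protofilament length but different
#' open-sheet lengths are built and relaxed independently; one closure is
#' performed in each, giving barrier and stepping versus sheet length. The
#' derived statistic is the minimum sheet length (in dimer layers) whose
#' barrier stays on the long-sheet plateau.
#'
#' @param params \code{mt_params}.
#' @param lengths sheet lengths in monomers.
#' @param total_length total protofilament length, monomers (constant
#'   across conditions).
#' @param hydrolysis closure hydrolysis rule.
#' @param tolerance plateau tolerance for the cap estimate.
#' @param max_steps per-relaxation budget.
#' @return list: \code{result} (data.frame: sheet_length, barrier_kBT,
#'   stepping_kBT, converged), \code{min_stable_cap_dimer_layers},
#'   \code{traces}.
#' @export
run_sheet_length_sweep <- function(params = mt_params(), lengths = 1:10,
                                   total_length = 40,
                                   hydrolysis = "synchronous_turn",
                                   tolerance = 0.1,
                                   max_steps = params$max_steps) {
  rows <- list()
  traces <- list()
  for (i in seq_along(lengths)) {
    s <- lengths[i]
    b <- total_length - params$pitch_monomers - s
    if (b < 1) stop("total_length too short for sheet length ", s)
    st <- standard_sheet_state(params, n_closed_turns = b, sheet_length = s,
                               max_steps = max_steps)
    cl <- close_monomer_pair(st$lattice, st$conf, params,
                             hydrolysis = hydrolysis, E_before = st$E0,
                             max_steps = max_steps)
    rows[[i]] <- data.frame(sheet_length = s, barrier_kBT = cl$barrier_kBT,
                            stepping_kBT = cl$stepping_kBT,
                            converged = cl$trace$converged)
    traces[[i]] <- cl$trace
  }
  result <- do.call(rbind, rows)
  cap <- tryCatch(minimum_stable_cap(result, tolerance = tolerance),
                  error = function(e) NA_integer_)
  list(result = result, min_stable_cap_dimer_layers = cap, traces = traces)
}

#' Sensitivity of the closure energetics to the empirical constants
#'
#' Varies one interaction constant (diagonal stretch or either dihedral
#' constant) by the given factors, keeping the others at their defaults, and
#' measures one closure per condition.
#'
#' @param params \code{mt_params}.
#' @param constant \code{"k_diag"}, \code{"k_long_dihedral"} or
#'   \code{"k_lat_dihedral"}.
#' @param factors multiplicative factors to apply.
#' @param n_closed_turns,sheet_length model size.
#' @param max_steps per-relaxation budget.
#' @return data.frame: constant, factor, barrier_kBT, stepping_kBT,
#'   converged.
#' @export
run_sensitivity_sweep <- function(params = mt_params(),
                                  constant = c("k_diag", "k_long_dihedral",
                                               "k_lat_dihedral"),
                                  factors = c(0.1, 1, 10),
                                  n_closed_turns = 27, sheet_length = 10,
                                  max_steps = params$max_steps) {
  constant <- match.arg(constant)
  field <- c(k_diag = "k_diag_stretch",
             k_long_dihedral = "k_long_dihedral",
             k_lat_dihedral = "k_lat_dihedral")[constant]
  rows <- list()
  for (i in seq_along(factors)) {
    p <- params
    p[[field]] <- params[[field]] * factors[i]
    st <- standard_sheet_state(p, n_closed_turns = n_closed_turns,
                               sheet_length = sheet_length,
                               max_steps = max_steps)
    cl <- close_monomer_pair(st$lattice, st$conf, p, E_before = st$E0,
                             max_steps = max_steps)
    rows[[i]] <- data.frame(constant = constant, factor = factors[i],
                            barrier_kBT = cl$barrier_kBT,
                            stepping_kBT = cl$stepping_kBT,
                            converged = cl$trace$converged)
  }
  do.call(rbind, rows)
}

#' Tetris-like growth: stochastic assembly harmonized with seam closure
#'
#' Repeats the fill-in / close-up cycle: GTP dimers assemble stochastically
#' at candidate tips (one accepted event per growth step, regulated by the
#' combined association and strain energy) until the next dimer layer is
#' complete across all protofilaments, then the seam zips one dimer length
#' (two monomer pairs by default). The sheet length is tracked after every
#' event.
#'
#' @param params \code{mt_params}.
#' @param n_layers number of complete layer cycles to grow.
#' @param state optional starting state (default: a freshly relaxed
#'   standard sheet).
#' @param policy assembly selection policy.
#' @param hydrolysis closure hydrolysis rule.
#' @param closures_per_layer seam advance per completed layer (2 monomer
#'   pairs = one dimer length).
#' @param stall_limit terminate after this many consecutive growth steps
#'   without an acceptable site.
#' @param force_accept treat every valid site as acceptable with equal
#'   probability (bookkeeping mode for tests).
#' @param max_steps per-relaxation budget.
#' @param ... passed to \code{\link{standard_sheet_state}} when
#'   \code{state} is missing.
#' @return list: \code{events} (data.frame log: event, step, pf, pair,
#'   site_class, dE_total, prob, draws, E_before, E_after, barrier_kBT,
#'   stepping_kBT, sheet_length), \code{state}, \code{completed_layers},
#'   \code{stalled}.
#' @export
run_tetris <- function(params = mt_params(), n_layers = 1, state = NULL,
                       policy = "boltzmann", hydrolysis = "synchronous_turn",
                       closures_per_layer = 2L, stall_limit = 25L,
                       force_accept = FALSE,
                       max_steps = params$max_steps, ...) {
  if (is.null(state)) state <- standard_sheet_state(params, ...)
  lattice <- state$lattice
  conf <- state$conf
  E <- state$E0
  L0 <- max(lattice$monomers$axial) + 1L
  log <- list()
  step <- 0L
  stalled <- FALSE
  completed <- 0L
  add_row <- function(...) {
    log[[length(log) + 1L]] <<- data.frame(...)
  }
  for (layer in seq_len(n_layers)) {
    target <- L0 + 2L * layer
    repeat {
      pf_len <- tapply(lattice$monomers$axial,
                       lattice$monomers$pf, max) + 1L
      open_pfs <- as.integer(names(pf_len)[pf_len < target])
      if (length(open_pfs) == 0) break
      stall <- 0L
      repeat {
        step <- step + 1L
        if (force_accept) {
          # bookkeeping mode: accept a uniformly drawn open tip without
          # evaluating the 13-site thermodynamics
          pf <- open_pfs[sample.int(length(open_pfs), 1L)]
          added <- add_dimer(lattice, conf, params, pf)
          rl <- relax(added$lattice, added$conf, params,
                      max_steps = max_steps)
          att <- list(site = data.frame(pf = pf,
                                        site_class = added$site_class,
                                        dE_total = NA_real_),
                      lattice = added$lattice, conf = rl$conf,
                      E = rl$trace$e_final, prob = 1 / length(open_pfs),
                      draws = 1L)
        } else {
          sites <- candidate_assembly_energies(lattice, conf, params,
                                               E0 = E, pfs = open_pfs,
                                               max_steps = max_steps)
          att <- attempt_assembly(sites, params, policy = policy)
        }
        if (is.null(att$site)) {
          stall <- stall + 1L
          if (stall >= stall_limit) {
            stalled <- TRUE
            break
          }
        } else {
          lattice <- att$lattice
          conf <- att$conf
          add_row(event = "assembly", step = step, pf = att$site$pf,
                  pair = NA_integer_, site_class = att$site$site_class,
                  dE_total = att$site$dE_total, prob = att$prob,
                  draws = att$draws, E_before = E, E_after = att$E,
                  barrier_kBT = NA_real_, stepping_kBT = NA_real_,
                  sheet_length = sheet_length(lattice))
          E <- att$E
          break
        }
      }
      if (stalled) break
    }
    if (stalled) break
    for (k in seq_len(closures_per_layer)) {
      step <- step + 1L
      cl <- close_monomer_pair(lattice, conf, params,
                               hydrolysis = hydrolysis, E_before = E,
                               max_steps = max_steps)
      lattice <- cl$lattice
      conf <- cl$conf
      add_row(event = "closure", step = step, pf = NA_integer_,
              pair = cl$pair, site_class = NA_character_,
              dE_total = NA_real_, prob = NA_real_, draws = cl$draws,
              E_before = E, E_after = cl$trace$e_final,
              barrier_kBT = cl$barrier_kBT,
              stepping_kBT = cl$stepping_kBT,
              sheet_length = sheet_length(lattice))
      E <- cl$trace$e_final
    }
    completed <- layer
  }
  events <- if (length(log)) do.call(rbind, log) else data.frame()
  if (stalled)
    warning(sprintf("tetris run stalled after %d consecutive growth steps ",
                    stall_limit),
            "with no acceptable assembly site")
  list(events = events,
       state = list(lattice = lattice, conf = conf, E0 = E, params = params),
       completed_layers = completed, stalled = stalled)
}
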
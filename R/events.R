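# Discrete growth events: GTP-dimer assembly with association
# thermodynamics, monomer-pair seam closure (sheet-to-tube transition), and
# GTP-hydrolysis rules. Every event produces a new lattice/topology and is
# followed by a relaxation.

#' Free energy of association for an assembly site
#'
#' A dimer filling a gap forms two lateral bonds and one longitudinal bond;
#' a side site one lateral and one longitudinal; a crest site only the
#' longitudinal bond. Every association pays the entropic immobilization
#' penalty \code{dG_S}.
#'
#' @param site_class \code{"gap"}, \code{"side"} or \code{"crest"}.
#' @param params \code{mt_params}.
#' @return association free energy in kBT per dimer (negative favors
#'   assembly).
#' @export
association_energy <- function(site_class, params) {
  n_lat <- c(gap = 2, side = 1, crest = 0)[site_class]
  if (any(is.na(n_lat))) stop("unknown site class")
  unname(n_lat * params$dG_lat + params$dG_long + params$dG_S)
}

# dimer bookkeeping: one row per dimer with its top monomer's ideal z
dimer_table <- function(lattice, params) {
  m <- lattice$monomers
  d <- m$axial %/% 2
  beta <- m$kind == "beta"
  data.frame(pf = m$pf[beta], d = d[beta],
             nucleotide = m$nucleotide[beta],
             z_top = site_z(params, m$pf[beta], m$axial[beta]),
             row.names = NULL)
}

set_dimers_gdp <- function(lattice, pf, d) {
  if (length(pf) == 0) return(lattice)
  m <- lattice$monomers
  hit <- paste(m$pf, m$axial %/% 2) %in% paste(pf, d)
  lattice$monomers$nucleotide[hit] <- "GDP"   # irreversible: GTP -> GDP only
  lattice
}

# closed-tube surface height implied by the zipped seam
zipped_root_z <- function(lattice, params) {
  if (nrow(lattice$seam) == 0) return(-Inf)
  params$r0_long * (max(lattice$seam$pair) + lattice$pitch)
}

#' Apply a GTP-hydrolysis rule
#'
#' Rules: \code{synchronous_turn} hydrolyzes every dimer that now lies
#' entirely below the closed-tube surface implied by the zipped seam (so
#' each monomer-pair closure converts the helical turn at the sheet root);
#' \code{ordered_cap} leaves only the top \code{k_layers} dimer layers of
#' each protofilament as GTP; \code{random} draws one uniform number per
#' GTP dimer in the sheet and hydrolyzes when the draw exceeds
#' \code{threshold}. Hydrolysis is irreversible: no rule ever restores GTP.
#'
#' @param lattice \code{mt_lattice}.
#' @param params \code{mt_params}.
#' @param rule one of \code{"synchronous_turn"}, \code{"ordered_cap"},
#'   \code{"random"}.
#' @param k_layers for \code{ordered_cap}: GTP cap depth in dimer layers.
#' @param threshold for \code{random}: hydrolyze when draw > threshold.
#' @return list: updated \code{lattice}, \code{n_hydrolyzed}, \code{draws}
#'   (number of uniform draws consumed).
#' @export
apply_hydrolysis <- function(lattice, params,
                             rule = c("synchronous_turn", "ordered_cap",
                                      "random"),
                             k_layers = 2L, threshold = 0.5) {
  rule <- match.arg(rule)
  dt <- dimer_table(lattice, params)
  draws <- 0L
  if (rule == "synchronous_turn") {
    z_root <- zipped_root_z(lattice, params)
    hit <- dt$nucleotide == "GTP" & dt$z_top <= z_root + 1e-9
  } else if (rule == "ordered_cap") {
    if (k_layers < 0) stop("k_layers must be >= 0")
    top <- tapply(dt$d, dt$pf, max)
    hit <- dt$nucleotide == "GTP" & dt$d <= top[as.character(dt$pf)] - k_layers
  } else {
    if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
    z_root <- zipped_root_z(lattice, params)
    sheet <- dt$nucleotide == "GTP" & dt$z_top > z_root + 1e-9
    ord <- order(dt$pf, dt$d)                # deterministic draw order
    hit <- rep(FALSE, nrow(dt))
    idx <- ord[sheet[ord]]
    if (length(idx) > 0) {
      u <- runif(length(idx))
      draws <- length(idx)
      hit[idx] <- u > threshold
    }
  }
  lattice <- set_dimers_gdp(lattice, dt$pf[hit], dt$d[hit])
  list(lattice = lattice, n_hydrolyzed = sum(hit), draws = draws)
}

# Append one GTP dimer at the tip of protofilament pf; positions continue
# the tip's local direction at rest spacing. Returns the updated lattice,
# conformation and the site class (gap / side / crest) by the count of
# laterally adjacent pre-assembled dimers (seam-side neighbors never count:
# cross-seam bonds appear only through closure).
add_dimer <- function(lattice, conf, params, pf) {
  m <- lattice$monomers
  rows <- which(m$pf == pf)
  tip <- max(m$axial[rows])
  if (tip %% 2 == 0)
    stop("protofilament tip holds an incomplete dimer")
  a_new <- tip + c(1L, 2L)
  flanks <- c(pf - 1L, pf + 1L)
  flanks <- flanks[flanks >= 0 & flanks < lattice$npf]
  n_nb <- 0L
  for (q in flanks) {
    if (!is.na(monomer_id(lattice, q, a_new[1])) &&
        !is.na(monomer_id(lattice, q, a_new[2]))) n_nb <- n_nb + 1L
  }
  site_class <- c("crest", "side", "gap")[n_nb + 1L]

  tip_id <- monomer_id(lattice, pf, tip)
  prev_id <- monomer_id(lattice, pf, tip - 1L)
  xt <- conf$pos[tip_id, ]
  dir <- xt - conf$pos[prev_id, ]
  dir <- dir / sqrt(sum(dir^2))
  new_pos <- rbind(xt + params$r0_long * dir, xt + 2 * params$r0_long * dir)

  lattice$monomers <- rbind(m, data.frame(
    pf = pf, axial = a_new, kind = c("alpha", "beta"), nucleotide = "GTP"))
  lattice$topology <- rebuild_topology(lattice)
  lattice <- index_monomers(lattice)
  conf <- new_conformation(rbind(conf$pos, new_pos),
                           c(conf$mass, rep(params$monomer_mass, 2)))
  list(lattice = lattice, conf = conf, site_class = site_class)
}

#' Evaluate the assembly energetics of every candidate tip site
#'
#' For each candidate protofilament a GTP dimer is tentatively appended at
#' the tip, the structure is relaxed, and the total energy change
#' (mechanical strain relative to the pre-assembly equilibrium, plus the
#' site's association free energy) is recorded. All tentative additions are
#' fully rolled back; the relaxed candidate states are cached on the result
#' so that \code{\link{attempt_assembly}} need not recompute them.
#'
#' @param lattice,conf a relaxed state.
#' @param params \code{mt_params}.
#' @param E0 equilibrium energy of the input state, nN*nm (computed when
#'   missing).
#' @param pfs candidate protofilaments (default: all).
#' @param max_steps relaxation budget per candidate.
#' @return data.frame with one row per site: \code{pf}, \code{site_class},
#'   \code{dG_assoc} (kBT), \code{strain} (kBT), \code{dE_total} (kBT),
#'   \code{valid}; relaxed candidates cached in
#'   \code{attr(, "candidates")}.
#' @export
candidate_assembly_energies <- function(lattice, conf, params, E0 = NULL,
                                        pfs = 0:(lattice$npf - 1),
                                        max_steps = params$max_steps) {
  if (is.null(E0)) E0 <- total_energy(lattice, conf, params)$e_total
  out <- data.frame(pf = pfs, site_class = NA_character_,
                    dG_assoc = NA_real_, strain = NA_real_,
                    dE_total = NA_real_, valid = FALSE)
  cand <- vector("list", length(pfs))
  for (i in seq_along(pfs)) {
    added <- add_dimer(lattice, conf, params, pfs[i])
    res <- try(relax(added$lattice, added$conf, params,
                     max_steps = max_steps), silent = TRUE)
    out$site_class[i] <- added$site_class
    out$dG_assoc[i] <- association_energy(added$site_class, params)
    if (inherits(res, "try-error")) next
    strain <- energy_to_kBT(res$trace$e_final - E0, params)
    out$strain[i] <- strain
    out$dE_total[i] <- strain + out$dG_assoc[i]
    out$valid[i] <- TRUE
    cand[[i]] <- list(lattice = added$lattice, conf = res$conf,
                      E = res$trace$e_final)
  }
  attr(out, "candidates") <- cand
  attr(out, "E0") <- E0
  out
}

#' Attempt one stochastic assembly event
#'
#' Sites with non-negative total energy change are excluded (such an
#' assembly does not happen). Among the remaining sites one is selected:
#' under the \code{"boltzmann"} policy with probability proportional to
#' \code{exp(-dE_total)} (one assembly event per growth step); under
#' \code{"metropolis"} each negative site is accepted independently with
#' probability \code{min(1, exp(-dE_total))} and one accepted site is then
#' chosen uniformly. Uses the R random number stream.
#'
#' @param sites result of \code{\link{candidate_assembly_energies}}.
#' @param params \code{mt_params}.
#' @param policy selection policy.
#' @return list: \code{site} (chosen row of \code{sites}, or NULL),
#'   \code{lattice}, \code{conf}, \code{E} (of the accepted state, or NULL),
#'   \code{prob} (selection probability used), \code{draws} (RNG draws
#'   consumed).
#' @export
attempt_assembly <- function(sites, params,
                             policy = c("boltzmann", "metropolis")) {
  policy <- match.arg(policy)
  cand <- attr(sites, "candidates")
  neg <- which(sites$valid & sites$dE_total < 0)
  if (length(neg) == 0)
    return(list(site = NULL, lattice = NULL, conf = NULL, E = NULL,
                prob = NA_real_, draws = 0L))
  if (policy == "boltzmann") {
    # shift before exponentiating to avoid overflow for very negative dE
    w <- exp(-(sites$dE_total[neg] - min(sites$dE_total[neg])))
    w <- w / sum(w)
    pick <- if (length(neg) == 1) 1L else
      sample.int(length(neg), 1L, prob = w)
    draws <- 1L
    prob <- w[pick]
  } else {
    acc <- runif(length(neg)) < pmin(1, exp(-sites$dE_total[neg]))
    draws <- length(neg)
    if (!any(acc))
      return(list(site = NULL, lattice = NULL, conf = NULL, E = NULL,
                  prob = NA_real_, draws = draws))
    hits <- which(acc)
    pick <- if (length(hits) == 1) hits else {
      draws <- draws + 1L
      hits[sample.int(length(hits), 1L)]
    }
    prob <- mean(acc)
  }
  idx <- neg[pick]
  list(site = sites[idx, ], lattice = cand[[idx]]$lattice,
       conf = cand[[idx]]$conf, E = cand[[idx]]$E, prob = prob,
       draws = draws)
}

#' Close the next monomer pair at the sheet bottom
#'
#' The lowest existing unzipped cross-seam pair acquires lateral stretch,
#' lateral bending and lateral dihedral bending interactions (and, when
#' \code{seam_diagonals = TRUE}, the two diagonal stretch terms), the
#' hydrolysis rule is applied, and the whole structure is relaxed. The
#' transient energy barrier and the equilibrium energy stepping relative to
#' the pre-closure equilibrium are reported in kBT.
#'
#' @param lattice,conf a relaxed pre-closure state.
#' @param params \code{mt_params}.
#' @param hydrolysis \code{"synchronous_turn"}, \code{"random"} or
#'   \code{"none"}.
#' @param threshold threshold for the random rule.
#' @param E_before pre-closure equilibrium energy, nN*nm (computed when
#'   missing).
#' @param seam_diagonals also add cross-seam diagonal terms for the newly
#'   zipped pair (off by default: closure adds the lateral tension or
#'   compression, bending, and dihedral bending interactions).
#' @param max_steps relaxation budget.
#' @param trace_thin trace thinning for the returned relaxation trace.
#' @return list: \code{lattice}, \code{conf}, \code{trace},
#'   \code{pair} (zipped pair index), \code{E_before} (nN*nm),
#'   \code{barrier_kBT}, \code{stepping_kBT}, \code{n_hydrolyzed},
#'   \code{draws}.
#' @export
close_monomer_pair <- function(lattice, conf, params,
                               hydrolysis = c("synchronous_turn", "random",
                                              "none"),
                               threshold = 0.5, E_before = NULL,
                               seam_diagonals = FALSE,
                               max_steps = params$max_steps,
                               trace_thin = 1L) {
  hydrolysis <- match.arg(hydrolysis)
  j <- next_seam_pair(lattice)
  if (is.na(j))
    stop("seam fully zipped: blunt end, no monomer pair left to close")
  if (is.null(E_before)) E_before <- total_energy(lattice, conf, params)$e_total

  lattice$seam <- rbind(lattice$seam,
                        data.frame(pair = j, diagonals = seam_diagonals))
  draws <- 0L
  n_hyd <- 0L
  if (hydrolysis == "synchronous_turn") {
    h <- apply_hydrolysis(lattice, params, "synchronous_turn")
    lattice <- h$lattice; n_hyd <- h$n_hydrolyzed
  } else if (hydrolysis == "random") {
    h <- apply_hydrolysis(lattice, params, "random", threshold = threshold)
    lattice <- h$lattice; n_hyd <- h$n_hydrolyzed; draws <- h$draws
  }
  lattice$topology <- rebuild_topology(lattice)

  res <- relax(lattice, conf, params, max_steps = max_steps,
               trace_thin = trace_thin)
  list(lattice = lattice, conf = res$conf, trace = res$trace, pair = j,
       E_before = E_before,
       barrier_kBT = energy_to_kBT(res$trace$peak_energy - E_before, params),
       stepping_kBT = energy_to_kBT(res$trace$e_final - E_before, params),
       n_hydrolyzed = n_hyd, draws = draws)
}
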
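#' @useDynLib mtzip, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
#' @importFrom utils head tail write.csv
NULL

# Lattice conventions
# -------------------
# Protofilaments are numbered 0..n-1 counterclockwise round the tube from
# the right side of the seam (viewed from the plus end). Monomer (p, a) of
# the closed body sits at angle 2*pi*p/n on a cylinder of radius R, at
# z = a * r0_long + p * rise, so following lateral neighbors once around the
# tube gains n * rise = pitch * r0_long (3 monomers for the standard 13_3
# lattice). The seam lies between protofilament n-1 and protofilament 0;
# seam pair j links (n-1, j) to (0, j + pitch), an alpha-beta contact.
# The minus end is at z = 0; axial index a counts from it. alpha monomers
# occupy even a, the beta of the same dimer sits directly above.

new_lattice <- function(monomers, seam, sheet_base_axial, npf, pitch) {
  lat <- list(monomers = monomers, seam = seam,
              sheet_base_axial = sheet_base_axial,
              npf = as.integer(npf), pitch = as.integer(pitch),
              topology = NULL)
  class(lat) <- "mt_lattice"
  lat <- index_monomers(lat)
  lat$topology <- rebuild_topology(lat)
  lat
}

#' @export
print.mt_lattice <- function(x, ...) {
  cat(sprintf("mt_lattice: %d monomers on %d protofilaments (pitch %d)\n",
              nrow(x$monomers), x$npf, x$pitch))
  cat(sprintf("  zipped seam pairs: %d; sheet (open seam) length: %d monomers\n",
              nrow(x$seam), sheet_length(x)))
  cat(sprintf("  GTP dimers: %d / %d\n",
              sum(x$monomers$nucleotide == "GTP" & x$monomers$kind == "beta"),
              sum(x$monomers$kind == "beta")))
  tp <- x$topology
  cat(sprintf("  topology: %d stretch, %d bend, %d dihedral terms\n",
              nrow(tp$pairs), nrow(tp$triples), nrow(tp$dihedrals)))
  invisible(x)
}

# Row index of monomer (pf, axial), NA when absent. Vectorized.
monomer_id <- function(lattice, pf, axial) {
  key <- paste(pf, axial)
  unname(lattice$.index[key])
}

# (Re)build the monomer lookup index; stored as an environment-free named
# vector so that plain list copies keep working.
index_monomers <- function(lattice) {
  m <- lattice$monomers
  lattice$.index <- setNames(seq_len(nrow(m)), paste(m$pf, m$axial))
  lattice
}

#' Rebuild the full interaction topology from the monomer table and seam state
#'
#' Topology is always derived, never patched: every assembly, closure or
#' rollback reconstructs the term lists from the monomer table plus the
#' zipped-pair set, so terms can never dangle. Classes:
#' stretch \code{long}, \code{lat}, \code{diag_short}, \code{diag_long};
#' bend and dihedral \code{long}, \code{lat}. Cross-seam lateral terms exist
#' only for zipped pairs; cross-seam diagonals only for zipped pairs whose
#' \code{diagonals} flag is set (the initially built body, by default).
#'
#' @param lattice an \code{mt_lattice}.
#' @return list with data.frames \code{pairs(i, j, class)},
#'   \code{triples(a, b, c, class)} and \code{dihedrals(a, b, c, class)};
#'   indices are 1-based rows of \code{lattice$monomers}. Bend and dihedral
#'   terms share their defining monomer triples.
#' @export
rebuild_topology <- function(lattice) {
  lattice <- index_monomers(lattice)  # local refresh; callers re-index too
  m <- lattice$monomers
  npf <- lattice$npf
  pitch <- lattice$pitch
  id <- function(p, a) {
    ok <- !is.na(p) & !is.na(a) & p >= 0 & p < npf & a >= 0
    out <- rep(NA_integer_, length(ok))
    if (any(ok)) out[ok] <- monomer_id(lattice, p[ok], a[ok])
    out
  }
  p <- m$pf; a <- m$axial
  self <- seq_len(nrow(m))

  pair_rows <- function(i, j, class) {
    ok <- !is.na(i) & !is.na(j)
    data.frame(i = i[ok], j = j[ok], class = rep(class, sum(ok)),
               row.names = NULL)
  }

  # longitudinal stretch: (p, a) - (p, a+1)
  pr_long <- pair_rows(self, id(p, a + 1), "long")
  # lateral stretch within the wall: (p, a) - (p+1, a), p < npf-1
  up <- ifelse(p < npf - 1, p + 1, NA_integer_)
  pr_lat <- pair_rows(self, id(up, a), "lat")
  # diagonals within the wall
  pr_ds <- pair_rows(self, id(up, a - 1), "diag_short")
  pr_dl <- pair_rows(self, id(up, a + 1), "diag_long")

  # seam terms from the zipped-pair set
  seam <- lattice$seam
  if (nrow(seam) > 0) {
    j <- seam$pair
    pr_seam <- pair_rows(id(rep(npf - 1L, length(j)), j),
                         id(rep(0L, length(j)), j + pitch), "lat")
    dj <- seam$pair[seam$diagonals]
    pr_seam_ds <- pair_rows(id(rep(npf - 1L, length(dj)), dj),
                            id(rep(0L, length(dj)), dj + pitch - 1L),
                            "diag_short")
    pr_seam_dl <- pair_rows(id(rep(npf - 1L, length(dj)), dj),
                            id(rep(0L, length(dj)), dj + pitch + 1L),
                            "diag_long")
  } else {
    pr_seam <- pr_seam_ds <- pr_seam_dl <-
      data.frame(i = integer(), j = integer(), class = character())
  }
  pairs <- rbind(pr_long, pr_lat, pr_seam, pr_ds, pr_dl, pr_seam_ds,
                 pr_seam_dl)

  triple_rows <- function(A, B, C, class) {
    ok <- !is.na(A) & !is.na(B) & !is.na(C)
    data.frame(a = A[ok], b = B[ok], c = C[ok],
               class = rep(class, sum(ok)), row.names = NULL)
  }
  # longitudinal bend/dihedral triples: (p, a-1), (p, a), (p, a+1)
  tr_long <- triple_rows(id(p, a - 1), self, id(p, a + 1), "long")

  # lateral triples centered at (p, a); seam-adjacent centers use the zipped
  # cross-seam partner when (and only when) that pair is zipped.
  zipped <- seam$pair
  interior <- triple_rows(id(ifelse(p > 0 & p < npf - 1, p - 1, NA_integer_),
                             a),
                          self,
                          id(ifelse(p > 0 & p < npf - 1, p + 1, NA_integer_),
                             a), "lat")
  # center on pf 0: D = (npf-1, a - pitch) via pair j = a - pitch
  sel0 <- p == 0L & (a - pitch) %in% zipped
  tr_p0 <- triple_rows(id(rep(npf - 1L, sum(sel0)), a[sel0] - pitch),
                       self[sel0], id(rep(1L, sum(sel0)), a[sel0]), "lat")
  # center on pf npf-1: F = (0, a + pitch) via pair j = a
  selN <- p == npf - 1L & a %in% zipped
  tr_pN <- triple_rows(id(rep(npf - 2L, sum(selN)), a[selN]), self[selN],
                       id(rep(0L, sum(selN)), a[selN] + pitch), "lat")
  triples <- rbind(tr_long, interior, tr_p0, tr_pN)

  dihedrals <- triples
  names(dihedrals) <- c("a", "b", "c", "class")

  rownames(pairs) <- rownames(triples) <- rownames(dihedrals) <- NULL
  list(pairs = pairs, triples = triples, dihedrals = dihedrals)
}

# open-seam length: existing cross-seam pairs that are not zipped
sheet_length <- function(lattice) {
  m <- lattice$monomers
  npf <- lattice$npf
  len12 <- sum(m$pf == npf - 1)
  len0 <- sum(m$pf == 0)
  jmax <- min(len12 - 1, len0 - 1 - lattice$pitch)
  sum(!(seq(0, jmax) %in% lattice$seam$pair))
}

# next closable pair (lowest existing unzipped), or NA
next_seam_pair <- function(lattice) {
  m <- lattice$monomers
  npf <- lattice$npf
  len12 <- sum(m$pf == npf - 1)
  len0 <- sum(m$pf == 0)
  jmax <- min(len12 - 1, len0 - 1 - lattice$pitch)
  if (jmax < 0) return(NA_integer_)
  open <- setdiff(seq(0, jmax), lattice$seam$pair)
  if (length(open) == 0) NA_integer_ else min(open)
}

#' Build a sheet-ended (or blunt) microtubule lattice and conformation
#'
#' Places the closed body on the derived cylinder and the open sheet on an
#' outward-curled initial guess surface: above the closed boundary each
#' protofilament curls in its own radial plane with the GTP intrinsic
#' longitudinal angle per monomer and zero lateral bend. The guess is not an
#' equilibrium; relax it (see \code{\link{relax}}) before measuring energies.
#'
#' @param params \code{mt_params}.
#' @param n_closed_turns number of zipped seam pairs in the closed body
#'   (>= 1). The body then spans \code{n_closed_turns} axial levels on the
#'   seam's leading side plus the pitch offset on the lagging side.
#' @param sheet_length_monomers open-seam length: the number of
#'   existing-but-unzipped cross-seam monomer pairs (>= 0; 0 = blunt tube).
#' @param scenario nucleotide assignment: \code{"standard"} (sheet GTP, body
#'   GDP), \code{"all_GTP"}, \code{"all_GDP"}, \code{"half_sheet_GDP"} (the
#'   lower half of the sheet already hydrolyzed), or \code{"interlaced"}
#'   (the spiral pattern: in sheet-dimer coordinates the n-th dimer of the
#'   n-th protofilament is GDP for n = 1..10, the n-th and (n+1)-th for
#'   n = 11..13, the rest GTP; body GDP).
#' @param curl_deg initial-guess curl per monomer in the sheet, degrees;
#'   defaults to \code{params$theta0_long_GTP}.
#' @return list with elements \code{lattice} and \code{conf}.
#' @export
build_lattice <- function(params, n_closed_turns, sheet_length_monomers,
                          scenario = c("standard", "all_GTP", "all_GDP",
                                       "half_sheet_GDP", "interlaced"),
                          curl_deg = NULL) {
  scenario <- match.arg(scenario)
  npf <- params$n_protofilaments
  pitch <- params$pitch_monomers
  if (n_closed_turns < 1) stop("n_closed_turns must be >= 1")
  if (sheet_length_monomers < 0) stop("sheet_length_monomers must be >= 0")
  b <- as.integer(n_closed_turns)
  s <- as.integer(sheet_length_monomers)
  L <- b + s + pitch                     # per-protofilament monomer count
  if (L < 2) stop("protofilaments need at least one dimer")
  if (L %% 2 != 0)
    stop("protofilament length (n_closed_turns + sheet + pitch = ", L,
         ") must be even: tubulin assembles as whole dimers")
  if (is.null(curl_deg)) curl_deg <- params$theta0_long_GTP

  pf <- rep(0:(npf - 1), each = L)
  axial <- rep(0:(L - 1), times = npf)
  monomers <- data.frame(
    pf = pf, axial = axial,
    kind = ifelse(axial %% 2 == 0, "alpha", "beta"),
    nucleotide = "GTP", row.names = NULL
  )
  seam <- data.frame(pair = seq_len(b) - 1L, diagonals = TRUE)

  # nucleotide states
  z_root <- params$r0_long * (b - 1 + pitch)  # closed-tube surface height
  monomers <- assign_nucleotides(monomers, params, scenario, z_root, b, s)

  lattice <- new_lattice(monomers, seam, b, npf, pitch)
  conf <- initial_conformation(lattice, params, b, curl_deg)
  list(lattice = lattice, conf = conf)
}

# z coordinate of the ideal lattice site (cylinder placement)
site_z <- function(params, pf, axial) {
  axial * params$r0_long + pf * params$rise
}

assign_nucleotides <- function(monomers, params, scenario, z_root, b, s) {
  z_top <- site_z(params, monomers$pf, 2 * (monomers$axial %/% 2) + 1)
  below <- z_top <= z_root + 1e-9   # dimer entirely inside the closed tube
  nt <- rep("GTP", nrow(monomers))
  if (scenario == "standard") {
    nt[below] <- "GDP"
  } else if (scenario == "all_GDP") {
    nt[] <- "GDP"
  } else if (scenario == "all_GTP") {
    # nothing
  } else if (scenario == "half_sheet_GDP") {
    z_mid <- z_root + s * params$r0_long / 2
    nt[z_top <= z_mid + 1e-9] <- "GDP"
  } else if (scenario == "interlaced") {
    nt[below] <- "GDP"
    # sheet dimers, counted from the bottom of the sheet per protofilament
    sheet_dimer <- monomers$axial %/% 2 - (b %/% 2) + 1L  # 1-based from root
    pf1 <- monomers$pf + 1L                                # 1-based labels
    hit <- (pf1 <= 10 & sheet_dimer == pf1) |
      (pf1 >= 11 & (sheet_dimer == pf1 | sheet_dimer == pf1 + 1L))
    nt[hit & !below] <- "GDP"
  }
  # both monomers of a dimer report the dimer state (the alpha N-site is
  # non-exchangeable and mechanically inert)
  key <- paste(monomers$pf, monomers$axial %/% 2)
  beta_state <- tapply(nt, key, function(v) v[length(v)])
  monomers$nucleotide <- as.vector(beta_state[key])
  monomers
}

initial_conformation <- function(lattice, params, b, curl_deg) {
  m <- lattice$monomers
  R <- params$radius
  h <- params$rise
  r0 <- params$r0_long
  n <- nrow(m)
  pos <- matrix(0, n, 3)
  # monomers above the top of the zipped seam curl outward; a blunt tube
  # (no unzipped pair) stays entirely on the cylinder
  j_next <- next_seam_pair(lattice)
  z_root <- if (is.na(j_next)) Inf else r0 * (j_next - 1 + lattice$pitch)
  alpha <- curl_deg * pi / 180
  for (p in unique(m$pf)) {
    rows <- which(m$pf == p)
    rows <- rows[order(m$axial[rows])]
    a_base <- floor((z_root - p * h) / r0)  # last monomer on the cylinder
    ur <- c(cos(2 * pi * p / lattice$npf), sin(2 * pi * p / lattice$npf), 0)
    for (i in seq_along(rows)) {
      a <- m$axial[rows[i]]
      if (a <= a_base) {
        pos[rows[i], ] <- c(R * ur[1], R * ur[2], a * r0 + p * h)
      } else {
        k <- a - a_base
        # curl outward in the radial plane, plus a tiny radial bias so a
        # zero-curl guess still breaks the cylindrical symmetry
        ang <- pmin(k * alpha, pi / 2)
        rad <- R + r0 * sum(sin(pmin(seq_len(k) * alpha, pi / 2))) + 0.01 * k
        zz <- (a_base * r0 + p * h) + r0 * sum(cos(pmin(seq_len(k) * alpha,
                                                        pi / 2)))
        pos[rows[i], ] <- c(rad * ur[1], rad * ur[2], zz)
      }
    }
  }
  new_conformation(pos, params$monomer_mass)
}

#' Construct a conformation object
#'
#' @param pos N x 3 matrix of positions, nm.
#' @param mass monomer mass (scalar, kDa) or vector of length N.
#' @param vel optional N x 3 velocity matrix (default zero).
#' @return an \code{mt_conformation}: list of \code{pos}, \code{vel},
#'   \code{mass}.
#' @export
new_conformation <- function(pos, mass, vel = NULL) {
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (length(mass) == 1) mass <- rep(mass, n)
  stopifnot(nrow(vel) == n, length(mass) == n, all(is.finite(pos)))
  structure(list(pos = pos, vel = vel, mass = mass),
            class = "mt_conformation")
}

#' @export
print.mt_conformation <- function(x, ...) {
  cat(sprintf("mt_conformation: %d monomers, z range [%.2f, %.2f] nm\n",
              nrow(x$pos), min(x$pos[, 3]), max(x$pos[, 3])))
  invisible(x)
}
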
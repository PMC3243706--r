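# Configuration, fixtures, format writers and run manifests.

#' Load a model / experiment configuration
#'
#' The configuration is a YAML file with a \code{params} mapping (any subset
#' of \code{\link{mt_params}} arguments; unset fields take the standard
#' defaults) and an optional \code{experiment} mapping passed through
#' verbatim. Unknown parameter keys and invariant violations are rejected
#' with the offending key named.
#'
#' @param path YAML file.
#' @return list: \code{params} (validated \code{mt_params}),
#'   \code{experiment} (list or NULL).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  praw <- cfg$params
  if (is.null(praw)) praw <- list()
  known <- names(formals(mt_params))
  bad <- setdiff(names(praw), known)
  if (length(bad) > 0)
    stop("unknown parameter key(s) in config: ", paste(bad, collapse = ", "))
  params <- do.call(mt_params, praw)
  list(params = params, experiment = cfg$experiment)
}

#' Save a configuration
#'
#' @param params \code{mt_params}.
#' @param path output YAML file.
#' @param experiment optional experiment description list.
#' @export
save_config <- function(params, path, experiment = NULL) {
  keep <- intersect(names(params), names(formals(mt_params)))
  cfg <- list(params = params[keep])
  if (!is.null(experiment)) cfg$experiment <- experiment
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Small structures with hand-enumerable topology for brute-force energy and
#' force oracles. \code{planar_3x4} is a flat 3-protofilament, 4-monomer
#' sheet far from the tube axis, parameterized so the constructed grid is
#' its own energy minimum (zero intrinsic curvature, diagonal rest lengths
#' matching the unstaggered grid). \code{tube_13xN} is a blunt closed tube.
#' \code{sheet_standard} is the standard 10-monomer GTP sheet starting
#' structure (unrelaxed guess).
#'
#' @param kind fixture name.
#' @param N tube length in monomers per protofilament (for
#'   \code{tube_13xN}).
#' @return list: \code{lattice}, \code{conf}, \code{params}.
#' @export
make_fixture <- function(kind = c("planar_3x4", "tube_13xN",
                                  "sheet_standard"), N = 6) {
  kind <- match.arg(kind)
  if (kind == "planar_3x4") {
    params <- mt_params(n_protofilaments = 3, pitch_monomers = 0,
                        theta0_long_GTP = 0, theta0_long_GDP = 18)
    # unstaggered grid: both diagonals equal the grid diagonal
    params$r0_diag_short <- params$r0_diag_long <-
      sqrt(params$r0_lat^2 + params$r0_long^2)
    pf <- rep(0:2, each = 4)
    axial <- rep(0:3, times = 3)
    monomers <- data.frame(pf = pf, axial = axial,
                           kind = ifelse(axial %% 2 == 0, "alpha", "beta"),
                           nucleotide = "GTP")
    lattice <- new_lattice(monomers,
                           data.frame(pair = integer(),
                                      diagonals = logical()),
                           sheet_base_axial = 0L, npf = 3, pitch = 0)
    # a flat isolated sheet has no meaningful tube axis, so the planar
    # fixture carries no dihedral terms; with zero intrinsic curvature the
    # constructed grid is then exactly its own energy minimum
    lattice$topology$dihedrals <- lattice$topology$dihedrals[0, ]
    pos <- cbind(pf * params$r0_lat, 0, axial * params$r0_long)
    conf <- new_conformation(pos, params$monomer_mass)
    return(list(lattice = lattice, conf = conf, params = params))
  }
  if (kind == "tube_13xN") {
    if (N < 4 || N %% 2 != 0) stop("tube fixture needs an even N >= 4")
    params <- mt_params()
    built <- build_lattice(params, n_closed_turns = N - 3,
                           sheet_length_monomers = 0)
    return(list(lattice = built$lattice, conf = built$conf,
                params = params))
  }
  params <- mt_params()
  built <- build_lattice(params, n_closed_turns = 27,
                         sheet_length_monomers = 10)
  list(lattice = built$lattice, conf = built$conf, params = params)
}

element_tag <- function(kind, nucleotide) {
  paste0(ifelse(kind == "alpha", "A", "B"),
         ifelse(nucleotide == "GTP", "G", "D"))
}

#' Write a conformation as (extended) XYZ
#'
#' One frame per call; \code{append = TRUE} accumulates a multi-frame
#' trajectory. The element tag encodes the monomer kind and nucleotide
#' (AG/AD/BG/BD for alpha/beta x GTP/GDP); with a lattice the protofilament,
#' axial index, kind and nucleotide columns are added, and optionally a
#' per-monomer energy column.
#'
#' @param conf \code{mt_conformation}.
#' @param path output file.
#' @param lattice optional \code{mt_lattice} for the extra columns.
#' @param energies optional per-monomer energies (nN*nm).
#' @param comment frame comment string.
#' @param append append as an additional frame.
#' @export
write_xyz <- function(conf, path, lattice = NULL, energies = NULL,
                      comment = "mtzip frame", append = FALSE) {
  n <- nrow(conf$pos)
  lines <- character(n + 2)
  lines[1] <- as.character(n)
  lines[2] <- comment
  if (is.null(lattice)) {
    tag <- rep("BG", n)
    extra <- rep("", n)
  } else {
    m <- lattice$monomers
    tag <- element_tag(m$kind, m$nucleotide)
    extra <- sprintf(" %d %d %s %s", m$pf, m$axial, m$kind, m$nucleotide)
  }
  if (!is.null(energies)) extra <- sprintf("%s %.10g", extra, energies)
  lines[3:(n + 2)] <- sprintf("%s %.10f %.10f %.10f%s", tag,
                              conf$pos[, 1], conf$pos[, 2], conf$pos[, 3],
                              extra)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read the first frame of an XYZ file
#'
#' @param path XYZ file written by \code{\link{write_xyz}}.
#' @return list: \code{pos} (N x 3), \code{tag}, \code{comment}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  list(pos = pos, tag = vapply(rows, `[`, "", 1), comment = lines[2])
}

#' Write a conformation as PDB
#'
#' One atom per coarse-grained monomer, one chain per protofilament
#' (A, B, C, ...), residue number = axial index + 1. The per-monomer energy
#' (if given) goes to the B-factor column.
#'
#' @param lattice \code{mt_lattice}.
#' @param conf \code{mt_conformation}.
#' @param path output file.
#' @param energies optional per-monomer energies for the B-factor column.
#' @export
write_pdb <- function(lattice, conf, path, energies = NULL) {
  m <- lattice$monomers
  n <- nrow(m)
  if (is.null(energies)) energies <- rep(0, n)
  chain <- LETTERS[(m$pf %% 26) + 1]
  resname <- ifelse(m$kind == "alpha", "ALA", "BTB")
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n) %% 100000, resname, chain, (m$axial + 1) %% 10000,
    conf$pos[, 1], conf$pos[, 2], conf$pos[, 3], 1.0,
    pmin(999.99, pmax(-99.99, energies)))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Serialize lattice + conformation to a structured text file
#'
#' A restartable single-file snapshot: documented key-value header followed
#' by fixed-order whitespace-separated blocks (monomers, seam, positions,
#' velocities, masses) at full double precision.
#'
#' @param lattice \code{mt_lattice}.
#' @param conf \code{mt_conformation}.
#' @param path output file.
#' @export
write_state <- function(lattice, conf, path) {
  m <- lattice$monomers
  s <- lattice$seam
  out <- c(
    "# mtzip state v1",
    sprintf("npf %d", lattice$npf),
    sprintf("pitch %d", lattice$pitch),
    sprintf("sheet_base_axial %d", lattice$sheet_base_axial),
    sprintf("monomers %d", nrow(m)),
    sprintf("%d %d %s %s", m$pf, m$axial, m$kind, m$nucleotide),
    sprintf("seam %d", nrow(s)),
    if (nrow(s) > 0) sprintf("%d %d", s$pair, as.integer(s$diagonals)),
    sprintf("positions %d", nrow(conf$pos)),
    sprintf("%.17g %.17g %.17g", conf$pos[, 1], conf$pos[, 2],
            conf$pos[, 3]),
    sprintf("velocities %d", nrow(conf$vel)),
    sprintf("%.17g %.17g %.17g", conf$vel[, 1], conf$vel[, 2],
            conf$vel[, 3]),
    sprintf("masses %d", length(conf$mass)),
    sprintf("%.17g", conf$mass))
  writeLines(out, path)
  invisible(path)
}

#' Restore a lattice + conformation snapshot
#'
#' @param path file written by \code{\link{write_state}}.
#' @return list: \code{lattice}, \code{conf}.
#' @export
read_state <- function(path) {
  lines <- readLines(path)
  i <- 2  # skip header comment
  take_kv <- function() {
    parts <- strsplit(lines[i], " ")[[1]]
    i <<- i + 1
    as.integer(parts[2])
  }
  npf <- take_kv(); pitch <- take_kv(); sba <- take_kv()
  nm <- take_kv()
  mrows <- strsplit(lines[i:(i + nm - 1)], " ")
  i <- i + nm
  monomers <- data.frame(
    pf = as.integer(vapply(mrows, `[`, "", 1)),
    axial = as.integer(vapply(mrows, `[`, "", 2)),
    kind = vapply(mrows, `[`, "", 3),
    nucleotide = vapply(mrows, `[`, "", 4))
  ns <- take_kv()
  if (ns > 0) {
    srows <- strsplit(lines[i:(i + ns - 1)], " ")
    i <- i + ns
    seam <- data.frame(pair = as.integer(vapply(srows, `[`, "", 1)),
                       diagonals = as.logical(as.integer(
                         vapply(srows, `[`, "", 2))))
  } else {
    seam <- data.frame(pair = integer(), diagonals = logical())
  }
  read_block <- function(ncol) {
    n <- take_kv()
    rows <- strsplit(lines[i:(i + n - 1)], " ")
    i <<- i + n
    matrix(as.numeric(unlist(rows)), n, ncol, byrow = TRUE)
  }
  pos <- read_block(3)
  vel <- read_block(3)
  mass <- as.numeric(read_block(1))
  lattice <- new_lattice(monomers, seam, sba, npf, pitch)
  list(lattice = lattice, conf = new_conformation(pos, mass, vel))
}

#' Write / read an event log
#'
#' Line-delimited JSON, one event record per line, full numeric precision,
#' so that a replayed run can be compared bit-for-bit.
#'
#' @param events event data.frame (e.g. from \code{\link{run_tetris}}).
#' @param path output file.
#' @export
write_event_log <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[vapply(rec, is.null, TRUE)] <- NA
    as.data.frame(rec)
  })
  do.call(rbind, rows)
}

#' Write a run manifest
#'
#' Records the full configuration, seed and package version so that a run
#' can be reproduced bit-identically.
#'
#' @param path output JSON file.
#' @param params \code{mt_params}.
#' @param experiment experiment description list.
#' @param seed RNG seed used.
#' @export
write_manifest <- function(path, params, experiment = list(), seed = NULL) {
  keep <- intersect(names(params), names(formals(mt_params)))
  jsonlite::write_json(
    list(package = "mtzip",
         version = as.character(utils::packageVersion("mtzip")),
         seed = seed, params = params[keep], experiment = experiment),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Append a relaxation trace to a CSV energy series
#'
#' @param trace \code{mt_trace}.
#' @param path CSV file (created with header when absent).
#' @param run label column value.
#' @export
write_energy_csv <- function(trace, path, run = "run") {
  df <- data.frame(run = run, step = seq_along(trace$e_total) - 1,
                   e_total = trace$e_total)
  write.table(df, path, sep = ",", row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}

#' @importFrom utils write.table
NULL
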
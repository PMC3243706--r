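# Independent brute-force oracles for the lattice energetics, written
# directly from the model conventions: harmonic terms over the enumerated
# topology, supplementary bend angles, radial-reference dihedrals measured
# against the tube axis (parallel to z through the xy centroid) with the
# smooth degeneracy window.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
vnorm <- function(a) sqrt(sum(a^2))

# per-term stiffness / rest / equilibrium lookups, re-derived from params
oracle_energy <- function(lattice, conf, params) {
  tp <- lattice$topology
  m <- lattice$monomers
  pos <- conf$pos
  cxy <- colMeans(pos[, 1:2, drop = FALSE])
  ur <- function(p) {
    v <- c(p[1] - cxy[1], p[2] - cxy[2], 0)
    v / vnorm(v)
  }
  deg <- pi / 180
  comp <- setNames(numeric(7), c("e_long_stretch", "e_lat_stretch",
                                 "e_diag_stretch", "e_long_bend",
                                 "e_lat_bend", "e_long_dihedral",
                                 "e_lat_dihedral"))
  lat_rest <- switch(params$lateral_rest_convention,
                     chord = params$lat_chord,
                     tube = sqrt(params$lat_chord^2 + params$rise^2),
                     params$r0_lat)
  for (r in seq_len(nrow(tp$pairs))) {
    i <- tp$pairs$i[r]; j <- tp$pairs$j[r]; cl <- tp$pairs$class[r]
    d <- vnorm(pos[i, ] - pos[j, ])
    k <- switch(cl, long = params$k_long_stretch,
                lat = params$k_lat_stretch, params$k_diag_stretch)
    r0 <- switch(cl, long = params$r0_long, lat = lat_rest,
                 diag_short = params$r0_diag_short, params$r0_diag_long)
    slot <- switch(cl, long = 1L, lat = 2L, 3L)
    comp[slot] <- comp[slot] + 0.5 * k * (d - r0)^2
  }
  for (r in seq_len(nrow(tp$triples))) {
    A <- pos[tp$triples$a[r], ]; B <- pos[tp$triples$b[r], ]
    C <- pos[tp$triples$c[r], ]
    u <- A - B; v <- C - B
    th <- pi - acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v)))))
    if (tp$triples$class[r] == "long") {
      th0 <- if (m$nucleotide[tp$triples$b[r]] == "GDP")
        params$theta0_long_GDP else params$theta0_long_GTP
      comp[4] <- comp[4] + 0.5 * params$k_long_bend * (th - th0 * deg)^2
    } else {
      comp[5] <- comp[5] +
        0.5 * params$k_lat_bend * (th - params$theta0_lat * deg)^2
    }
  }
  for (r in seq_len(nrow(tp$dihedrals))) {
    A <- pos[tp$dihedrals$a[r], ]; B <- pos[tp$dihedrals$b[r], ]
    C <- pos[tp$dihedrals$c[r], ]
    if (tp$dihedrals$class[r] == "long") {
      a1 <- B - A; b1 <- C - B
      a2 <- ur(A); b2 <- B - A
      k <- params$k_long_dihedral; slot <- 6L
    } else {
      a1 <- ur(A); b1 <- B - A
      a2 <- ur(B); b2 <- C - B
      k <- params$k_lat_dihedral; slot <- 7L
    }
    n1 <- cross3(a1, b1); n2 <- cross3(a2, b2)
    u1 <- sum(n1^2) / (sum(a1^2) * sum(b1^2))
    u2 <- sum(n2^2) / (sum(a2^2) * sum(b2^2))
    if (u1 < 1e-12 || u2 < 1e-12) next
    w <- (u1 / (u1 + 1e-6)) * (u2 / (u2 + 1e-6))
    co <- max(-1, min(1, sum(n1 * n2) / (vnorm(n1) * vnorm(n2))))
    comp[slot] <- comp[slot] + 0.5 * k * acos(co)^2 * w
  }
  c(as.list(comp), list(e_total = sum(comp)))
}

# central finite-difference forces for a subset of monomers
fd_forces <- function(lattice, conf, params, rows, h = 1e-6) {
  out <- matrix(NA_real_, nrow(conf$pos), 3)
  for (i in rows) for (k in 1:3) {
    cp <- conf; cp$pos[i, k] <- cp$pos[i, k] + h
    cm <- conf; cm$pos[i, k] <- cm$pos[i, k] - h
    out[i, k] <- -(total_energy(lattice, cp, params)$e_total -
                   total_energy(lattice, cm, params)$e_total) / (2 * h)
  }
  out
}

# small jittered copy of a conformation (fixed seed supplied by caller)
jitter_conf <- function(conf, sd = 0.03) {
  conf$pos <- conf$pos + matrix(rnorm(length(conf$pos), 0, sd),
                                ncol = 3)
  conf
}

# cheap relaxation settings for unit tests
fast_params <- function(...) {
  mt_params(max_steps = 30000L, polish_maxit = 4000L, ...)
}
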
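# Independent reference implementations (oracles) used by the tests.
# These deliberately re-derive everything with plain R loops and their own
# geometry code; they never call the package's compiled kernels.

o_norm <- function(v) sqrt(sum(v * v))

o_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / (o_norm(u) * o_norm(v)))))
}

o_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

o_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- o_cross(b1, b2); n2 <- o_cross(b2, b3)
  m1 <- o_cross(n1, b2) / o_norm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Brute-force O(N^2) energy of a protein(+DNA) system, no cutoffs.
# pos: full coordinate matrix (protein beads first). Mirrors the documented
# interaction rules: bonded terms from the topology; nonbonded protein
# pairs excluded when closer than 4 in sequence on one chain; native-contact
# pairs get the 12-10 term only; everything else gets repulsion plus
# Debye-Huckel when both beads are charged; DNA-DNA pairs skipped;
# minimum-image along Z (period L) for protein-DNA pairs only.
oracle_energy <- function(protein, dna, pos, model, params,
                          zperiod = if (is.null(dna)) 0 else
                            dna$n_bp * dna$rise) {
  pb <- protein$beads
  np <- nrow(pb)
  ntot <- nrow(pos)
  charge <- c(pb$charge, if (!is.null(dna)) dna$beads$charge)
  radius <- c(pb$radius, if (!is.null(dna)) dna$beads$radius)
  chain <- c(as.character(pb$chain), rep(NA_character_, ntot - np))
  seqpos <- c(ave(seq_len(np), pb$chain, FUN = seq_along),
              rep(0, ntot - np))
  e <- list(bonds = 0, angles = 0, dihedrals = 0, contacts = 0,
            repulsion = 0, electrostatics = 0)
  for (r in seq_len(nrow(protein$bonds))) {
    b <- o_norm(pos[protein$bonds$i[r], ] - pos[protein$bonds$j[r], ])
    e$bonds <- e$bonds + params$K_bonds * (b - protein$bonds$b0[r])^2
  }
  for (r in seq_len(nrow(protein$angles))) {
    th <- o_angle(pos[protein$angles$i[r], ], pos[protein$angles$j[r], ],
                  pos[protein$angles$k[r], ])
    e$angles <- e$angles + params$K_angles * (th - protein$angles$theta0[r])^2
  }
  for (r in seq_len(nrow(protein$dihedrals))) {
    ph <- o_dihedral(pos[protein$dihedrals$i[r], ],
                     pos[protein$dihedrals$j[r], ],
                     pos[protein$dihedrals$k[r], ],
                     pos[protein$dihedrals$l[r], ])
    d <- ph - protein$dihedrals$phi0[r]
    e$dihedrals <- e$dihedrals +
      params$K_dihedrals * ((1 - cos(d)) + 0.5 * (1 - cos(3 * d)))
  }
  in_contact <- matrix(FALSE, np, np)
  for (r in seq_len(nrow(protein$contacts))) {
    i <- protein$contacts$i[r]; j <- protein$contacts$j[r]
    in_contact[i, j] <- in_contact[j, i] <- TRUE
    rr <- o_norm(pos[i, ] - pos[j, ])
    s <- protein$contacts$aij[r] / rr
    e$contacts <- e$contacts + params$K_contacts * (5 * s^12 - 6 * s^10)
  }
  for (i in seq_len(ntot - 1)) {
    if (i > np) break  # both-DNA pairs are static, skip
    for (j in (i + 1):ntot) {
      both_protein <- j <= np
      if (both_protein) {
        if (!is.na(chain[i]) && chain[i] == chain[j] &&
            abs(seqpos[i] - seqpos[j]) <= 3) next
        if (in_contact[i, j]) next
      }
      dv <- pos[i, ] - pos[j, ]
      if (!both_protein && zperiod > 0) {
        dv[3] <- dv[3] - zperiod * round(dv[3] / zperiod)
      }
      rr <- o_norm(dv)
      cij <- radius[i] + radius[j]
      e$repulsion <- e$repulsion + params$K_repulsion * (cij / rr)^12
      if (charge[i] != 0 && charge[j] != 0) {
        e$electrostatics <- e$electrostatics +
          params$K_electrostatics * model$B * charge[i] * charge[j] *
          exp(-model$kappa * rr) / (model$eps_r * rr)
      }
    }
  }
  e$total <- sum(unlist(e))
  e
}

# central-difference gradient of the package energy (used against
# analytic forces)
numeric_forces <- function(sys, pos, h = 1e-5, beads = seq_len(nrow(pos))) {
  F <- matrix(NA_real_, nrow(pos), 3)
  for (i in beads) {
    for (c in 1:3) {
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      F[i, c] <- -(cg_energy(sys, pp)$total - cg_energy(sys, pm)$total) /
        (2 * h)
    }
  }
  F
}

# naive sliding-origin MSD (double loop)
oracle_msd <- function(x, lags) {
  n <- length(x)
  vapply(lags, function(lag) {
    mean(vapply(seq_len(n - lag), function(t0)
      (x[t0 + lag] - x[t0])^2, numeric(1)))
  }, numeric(1))
}

# brute-force residue contact scan over ALL residue pairs of an atom set
oracle_contacts <- function(atoms, cutoff, min_seq_sep) {
  a <- atoms$atoms
  key <- paste(a$chain, a$resno)
  ukey <- unique(key)
  n <- length(ukey)
  chain_of <- sub(" .*$", "", ukey)
  within <- ave(seq_len(n), chain_of, FUN = seq_along)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (chain_of[i] == chain_of[j] &&
          abs(within[i] - within[j]) < min_seq_sep) next
      ai <- a[key == ukey[i], c("x", "y", "z"), drop = FALSE]
      aj <- a[key == ukey[j], c("x", "y", "z"), drop = FALSE]
      mind <- min(sqrt(outer(ai$x, aj$x, "-")^2 +
                       outer(ai$y, aj$y, "-")^2 +
                       outer(ai$z, aj$z, "-")^2))
      if (mind <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  out
}

# deterministic random toy system (protein + short DNA + perturbed
# positions) for force/energy cross-checks
random_system <- function(seed, n_min = 20, n_max = 50, with_dna = TRUE) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  nq <- sample(2:6, 1)
  charged <- sort(sample(n, nq))
  sign <- sample(c(-1, 1), 1)
  tp <- make_toy_protein(n, charged = charged, charge = sign)
  dna <- if (with_dna) build_bdna(sample(8:16, 1)) else NULL
  sys <- cg_system(tp$protein, dna, elec_cutoff = Inf,
                   rep_cutoff_factor = Inf)
  pos <- sys$positions
  np <- nrow(tp$protein$beads)
  com <- colMeans(pos[seq_len(np), , drop = FALSE])
  shift <- if (with_dna) c(14, 0, dna$n_bp * dna$rise / 2) else c(0, 0, 0)
  pos[seq_len(np), ] <- sweep(pos[seq_len(np), , drop = FALSE], 2,
                              com - shift)
  pos[seq_len(np), ] <- pos[seq_len(np), ] +
    matrix(rnorm(np * 3, 0, 0.25), np, 3)
  list(protein = tp$protein, dna = dna, sys = sys, pos = pos, np = np)
}
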
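# synthetic_data: download-free fixtures -- toy helical proteins with PDB
# text, stochastic trajectories with prescribed coupling/diffusion/noise,
# and the canonical fixture suite with ground-truth manifest.

toy_pdb_line <- function(serial, resname, chain, resno, x, y, z) {
  sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, resname, chain, resno, x, y, z)
}

#' Build a toy charged alpha-helical protein
#'
#' An ideal alpha-helical CA trace (default: radius 2.3 A, rise 1.5 A and
#' 100 degrees of twist per residue) with unit charges at the requested
#' positions, returned both as a `CGProtein` and as equivalent PDB text.
#' Charged positions are written as LYS (+1) or ASP (-1) so that the PDB
#' text round-trips through [read_pdb()] + [coarse_grain_protein()] to the
#' identical model. Native contacts use a CA-CA cutoff of `contact_cutoff`
#' (default 6.5 A -- the toy has no side-chain heavy atoms, so the helical
#' i,i+3 / i,i+4 contacts require a CA-level cutoff).
#'
#' @param n Number of residues (>= 4).
#' @param charged Integer positions carrying charge (default none).
#' @param charge +1 (default) or -1 for the charged positions.
#' @param helix_radius,rise,twist Helix geometry (A, A, degrees/residue).
#' @param chain Chain identifier for the PDB text.
#' @param contact_cutoff CA-CA native-contact cutoff (A).
#' @return List with `protein` (`CGProtein`) and `pdb` (character vector of
#'   PDB lines).
#' @export
make_toy_protein <- function(n = 20, charged = integer(0), charge = +1,
                             helix_radius = 2.3, rise = 1.5, twist = 100,
                             chain = "A", contact_cutoff = 6.5) {
  if (n < 4) stopf("need at least 4 residues, got %d", n)
  charged <- as.integer(charged)
  if (length(charged) && (min(charged) < 1 || max(charged) > n)) {
    stopf("charged positions must lie in 1..%d", n)
  }
  stopifnot(charge %in% c(-1, 1))
  i <- seq_len(n)
  phi <- (i - 1) * twist * pi / 180
  x <- helix_radius * cos(phi)
  y <- helix_radius * sin(phi)
  z <- (i - 1) * rise
  resname <- rep("ALA", n)
  resname[charged] <- if (charge > 0) "LYS" else "ASP"
  pdb <- vapply(i, function(k)
    toy_pdb_line(k, resname[k], chain, k, x[k], y[k], z[k]), character(1))
  protein <- coarse_grain_protein(read_pdb(paste(pdb, collapse = "\n")),
                                  contact_cutoff = contact_cutoff)
  protein$source <- sprintf("toy_helix_n%d_q%+d*%d", n, charge,
                            length(charged))
  list(protein = protein, pdb = pdb)
}

#' Build a toy three-chain ring (clamp stand-in)
#'
#' Three identical toy helices (chains A, B, C) arranged 120 degrees apart
#' around a ring, as a synthetic stand-in for a homotrimeric sliding clamp
#' in tests of the trimer charge designs. Charges alternate LYS/ASP at the
#' given per-chain positions.
#'
#' @param n Residues per chain.
#' @param positive,negative Per-chain residue positions carrying +1 / -1.
#' @param ring_radius Distance of each chain's helix axis from the ring
#'   centre (A).
#' @return List with `protein` and `pdb` as in [make_toy_protein()].
#' @export
make_toy_trimer <- function(n = 24, positive = c(5, 12, 20),
                            negative = c(8, 16), ring_radius = 16) {
  stopifnot(n >= 4)
  i <- seq_len(n)
  phi <- (i - 1) * 100 * pi / 180
  base <- cbind(2.3 * cos(phi), 2.3 * sin(phi), (i - 1) * 1.5)
  resname <- rep("ALA", n)
  resname[positive] <- "LYS"
  resname[negative] <- "ASP"
  pdb <- character(0)
  serial <- 0L
  for (ci in 1:3) {
    ang <- (ci - 1) * 2 * pi / 3
    centre <- c(ring_radius * cos(ang), ring_radius * sin(ang), 0)
    rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                  3, 3)
    xyz <- base %*% t(rot)
    xyz <- sweep(xyz, 2, -centre)
    for (k in i) {
      serial <- serial + 1L
      pdb <- c(pdb, toy_pdb_line(serial, resname[k], LETTERS[ci], k,
                                 xyz[k, 1], xyz[k, 2], xyz[k, 3]))
    }
  }
  protein <- coarse_grain_protein(read_pdb(paste(pdb, collapse = "\n")),
                                  contact_cutoff = 6.5)
  protein$source <- sprintf("toy_trimer_n%d", n)
  list(protein = protein, pdb = pdb)
}

#' Generate a stochastic trajectory with prescribed coupling and diffusion
#'
#' The axial coordinate Z performs a Gaussian random walk with the
#' prescribed 1D diffusion coefficient (step variance 2 D dt). For the
#' first `coupled_fraction` of the frames the azimuth tracks
#' `slope * Z` plus Gaussian angle noise of sd `theta_sd` (sliding); for
#' the remaining frames the azimuth performs an independent, mean-reverting
#' bounded walk (hopping: translation decoupled from rotation). The radial
#' distance fluctuates AR(1)-style about `radius_mean`. The single tracked
#' bead is placed at (r cos theta, r sin theta, Z), so [angular_trace()]
#' recovers theta exactly (up to unwrapping). Ground truth is stored in the
#' trajectory metadata.
#'
#' @param n_frames Number of frames.
#' @param slope Ground-truth coupling slope in rad/A (default -2*pi/34).
#' @param coupled_fraction Fraction of frames in the coupled mode, in
#'   [0, 1] (default 1).
#' @param D 1D diffusion coefficient along Z, A^2 per time unit.
#' @param theta_sd Angular noise sd in rad (coupled frames).
#' @param radius_mean,radius_sd Radial distance mean / sd (A).
#' @param dt Frame spacing in time units.
#' @param seed Integer seed (deterministic output).
#' @return A `Trajectory` with one bead and `metadata$ground_truth`.
#' @export
make_synthetic_trajectory <- function(n_frames = 5000, slope = -2 * pi / 34,
                                      coupled_fraction = 1, D = 0.5,
                                      theta_sd = 0, radius_mean = 15,
                                      radius_sd = 0.5, dt = 1,
                                      seed = NULL) {
  stopifnot(n_frames >= 2, coupled_fraction >= 0, coupled_fraction <= 1,
            D >= 0, theta_sd >= 0, radius_mean > 0, radius_sd >= 0, dt > 0)
  with_seed(seed, {
    z <- c(0, cumsum(rnorm(n_frames - 1, 0, sqrt(2 * D * dt))))
    n_coupled <- round(coupled_fraction * n_frames)
    theta <- numeric(n_frames)
    if (n_coupled > 0) {
      theta[seq_len(n_coupled)] <- slope * z[seq_len(n_coupled)] +
        rnorm(n_coupled, 0, theta_sd)
    }
    if (n_coupled < n_frames) {
      idx <- (n_coupled + 1):n_frames
      anchor <- if (n_coupled > 0) theta[n_coupled] else 0
      th <- anchor
      for (t in idx) {
        th <- anchor + 0.99 * (th - anchor) + rnorm(1, 0, 0.05)
        theta[t] <- th
      }
    }
    r <- numeric(n_frames)
    r[1] <- radius_mean
    if (n_frames > 1 && radius_sd > 0) {
      innov <- rnorm(n_frames - 1, 0, radius_sd * sqrt(1 - 0.9^2))
      for (t in 2:n_frames) r[t] <- radius_mean + 0.9 * (r[t - 1] -
                                                    radius_mean) + innov[t - 1]
    } else r[] <- radius_mean
    r <- pmax(r, 1)
    coords <- array(0, c(n_frames, 1, 3))
    coords[, 1, 1] <- r * cos(theta)
    coords[, 1, 2] <- r * sin(theta)
    coords[, 1, 3] <- z
    meta <- list(kind = "synthetic",
                 ground_truth = list(slope = slope,
                                     coupled_fraction = coupled_fraction,
                                     D = D, theta_sd = theta_sd,
                                     radius_mean = radius_mean,
                                     radius_sd = radius_sd, dt = dt,
                                     seed = seed %||% NA))
    beads <- data.frame(index = 1L, chain = "A", resno = 1L,
                        resname = "COM", x = coords[1, 1, 1],
                        y = coords[1, 1, 2], z = coords[1, 1, 3],
                        charge = 0, radius = 2)
    new_trajectory(times = (seq_len(n_frames) - 1) * dt, coords = coords,
                   beads = beads, metadata = meta)
  })
}

#' Write the canonical fixture suite
#'
#' Generates the fixtures used by tests and documentation -- toy helices
#' with 6, 5 and 4 charges (PDB + CG model files), 20-bp and 100-bp ideal
#' duplexes, and three synthetic trajectories spanning sliding,
#' intermediate and hopping -- together with `manifest.json` recording
#' every ground-truth value. Regeneration with the same seed is
#' byte-identical.
#'
#' @param dir Output directory (created if missing).
#' @param seed Master seed for the stochastic trajectories.
#' @return The manifest list, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  manifest <- list(seed = seed, proteins = list(), dna = list(),
                   trajectories = list())
  charge_sets <- list(q6 = toy_slider_charges(),
                      q5 = toy_slider_charges()[-3],
                      q4 = toy_slider_charges()[-c(3, 5)])
  for (nm in names(charge_sets)) {
    tp <- make_toy_protein(n = 20, charged = charge_sets[[nm]])
    writeLines(tp$pdb, p(sprintf("toy_helix_%s.pdb", nm)))
    write_cg_model(tp$protein, p(sprintf("toy_helix_%s.cg", nm)))
    manifest$proteins[[nm]] <- list(n = 20, charged = charge_sets[[nm]],
                                    net_charge = sum(tp$protein$beads$charge))
  }
  for (nbp in c(20, 100)) {
    dna <- build_bdna(nbp)
    write_cg_model(dna, p(sprintf("bdna_%dbp.cg", nbp)))
    manifest$dna[[sprintf("bdna_%dbp", nbp)]] <-
      list(n_bp = nbp, beads = nrow(dna$beads),
           charge = sum(dna$beads$charge),
           pitch = dna$rise * 360 / dna$twist)
  }
  specs <- list(
    sliding = list(slope = -2 * pi / 34, coupled_fraction = 1,
                   theta_sd = 0.1),
    intermediate = list(slope = -2 * pi / 34, coupled_fraction = 0.55,
                        theta_sd = 0.2),
    hopping = list(slope = 0, coupled_fraction = 0, theta_sd = 0))
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    sp <- specs[[i]]
    traj <- make_synthetic_trajectory(
      n_frames = 5000, slope = sp$slope,
      coupled_fraction = sp$coupled_fraction, D = 0.5,
      theta_sd = sp$theta_sd, seed = derive_seed(seed, i))
    write_trajectory(traj, p(sprintf("traj_%s.txt", nm)))
    manifest$trajectories[[nm]] <- traj$metadata$ground_truth
  }
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Default charged positions of the toy sliding helix
#'
#' Six positions on the DNA-facing face of a 20-residue ideal helix,
#' emulating a recognition helix whose basic residues contact the major
#' groove.
#'
#' @return Integer vector of six residue positions.
#' @export
toy_slider_charges <- function() c(3L, 6L, 10L, 13L, 17L, 20L)
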
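# forcefield: parameters, Debye-Huckel model, system assembly, and R-side
# wrappers around the compiled energy/force kernels.

#' Force-field parameters
#'
#' Constants of the structure-based coarse-grained potential. Defaults are
#' the published values: harmonic bonds 100 kcal/mol/A^2, harmonic angles
#' 20 kcal/mol, dihedral / native-contact / repulsion scales 1 kcal/mol,
#' Coulomb constant 332 kcal A/mol/e^2, dielectric constant 70, and a
#' 2.0 A excluded-volume radius for the backbone bead.
#'
#' @param K_bonds,K_angles,K_dihedrals,K_contacts,K_repulsion Energy scales
#'   (kcal/mol; bonds kcal/mol/A^2).
#' @param K_electrostatics Coulomb constant, kcal A/mol/e^2.
#' @param eps_r Relative dielectric constant (dimensionless).
#' @param backbone_radius Default bead repulsion radius in Angstrom.
#' @return A `ForceFieldParams` list.
#' @export
ff_params <- function(K_bonds = 100, K_angles = 20, K_dihedrals = 1,
                      K_contacts = 1, K_repulsion = 1,
                      K_electrostatics = 332, eps_r = 70,
                      backbone_radius = 2.0) {
  p <- list(K_bonds = K_bonds, K_angles = K_angles,
            K_dihedrals = K_dihedrals, K_contacts = K_contacts,
            K_repulsion = K_repulsion, K_electrostatics = K_electrostatics,
            eps_r = eps_r, backbone_radius = backbone_radius)
  if (any(unlist(p) < 0)) stopf("force-field constants must be >= 0")
  structure(p, class = "ForceFieldParams")
}

#' Debye screening parameter from salt concentration
#'
#' Inverse Debye length for a monovalent (1:1) salt in a continuum of
#' dielectric constant `eps_r` at temperature `temperature`:
#' kappa^2 = 8 pi l_B n, with l_B the Bjerrum length and n the number
#' density of each ion species. kappa is proportional to sqrt(C) and is 0
#' at zero salt.
#'
#' @param concentration Molar salt concentration (mol/L), >= 0.
#' @param temperature Temperature in Kelvin (default 300).
#' @param eps_r Dielectric constant (default 70, the simulation value).
#' @return kappa in 1/Angstrom.
#' @export
kappa_from_molar <- function(concentration, temperature = 300, eps_r = 70) {
  if (any(concentration < 0)) stopf("salt concentration must be >= 0")
  e <- 1.602176634e-19      # C
  eps0 <- 8.8541878128e-12  # F/m
  kB <- 1.380649e-23        # J/K
  NA_ <- 6.02214076e23
  lB <- e^2 / (4 * pi * eps0 * eps_r * kB * temperature) * 1e10  # Angstrom
  n <- concentration * NA_ * 1e-27  # ions per A^3 (each species)
  sqrt(8 * pi * lB * n)
}

#' Salt-dependent electrostatic model
#'
#' Bundles the screening parameter kappa, the salt-dependent coefficient
#' B(kappa) = exp(kappa a)/(1 + kappa a) (with ion-exclusion radius `a`;
#' B -> 1 as kappa -> 0), and the dielectric constant.
#'
#' @param salt Molar salt concentration.
#' @param temperature Kelvin (default 300).
#' @param eps_r Dielectric constant (default 70).
#' @param ion_radius Ion-exclusion radius `a` in Angstrom (default 4.2).
#' @return An `ElectrostaticModel` list with salt, kappa, B, eps_r.
#' @export
electrostatic_model <- function(salt = 0.01, temperature = 300, eps_r = 70,
                                ion_radius = 4.2) {
  kappa <- kappa_from_molar(salt, temperature, eps_r)
  structure(list(salt = salt, temperature = temperature, kappa = kappa,
                 B = exp(kappa * ion_radius) / (1 + kappa * ion_radius),
                 eps_r = eps_r, ion_radius = ion_radius),
            class = "ElectrostaticModel")
}

#' Debye-Huckel pair energy
#'
#' Screened Coulomb energy of one charge pair:
#' `K_electrostatics * B(kappa) * qi * qj * exp(-kappa r) / (eps_r * r)`.
#'
#' @param r Separation in Angstrom, > 0.
#' @param qi,qj Charges in units of e.
#' @param model An `ElectrostaticModel`.
#' @param params A `ForceFieldParams`.
#' @return Energy in kcal/mol.
#' @export
debye_huckel_pair <- function(r, qi, qj, model = electrostatic_model(),
                              params = ff_params()) {
  if (any(r <= 0)) stopf("overlapping charges: r must be > 0")
  params$K_electrostatics * model$B * qi * qj *
    exp(-model$kappa * r) / (model$eps_r * r)
}

#' Assemble a simulation system
#'
#' Packs a coarse-grained protein and (optionally) a static B-DNA duplex
#' into the flat representation used by the compiled energy/force/dynamics
#' kernels. Protein beads are the leading (mobile) block; DNA beads are
#' static. Nonbonded interactions within the protein exclude pairs closer
#' than 4 in sequence (covered by bonded terms); native-contact pairs get
#' the 12-10 attraction instead of generic repulsion; all remaining pairs
#' (including every protein-DNA pair) interact by excluded-volume repulsion
#' and, when both beads are charged, Debye-Huckel electrostatics. DNA-DNA
#' interactions are constant (static duplex) and skipped. When a duplex is
#' present, protein-DNA distances are minimum-imaged along Z with period
#' equal to the duplex length, emulating an infinite straight DNA.
#'
#' @param protein A `CGProtein`.
#' @param dna A `BDNADuplex`, or NULL for protein-only systems.
#' @param params `ForceFieldParams`.
#' @param model `ElectrostaticModel` (sets kappa, B, eps_r).
#' @param elec_cutoff Electrostatic cutoff in Angstrom; `Inf` (default)
#'   evaluates all pairs.
#' @param rep_cutoff_factor Repulsion evaluated for r < factor * C_ij;
#'   `Inf` (default) evaluates all pairs.
#' @param z_periodic Apply Z minimum-imaging (default TRUE when `dna` given).
#' @return A `CGSystem` list (positions, topology arrays, merged params).
#' @export
cg_system <- function(protein, dna = NULL, params = ff_params(),
                      model = electrostatic_model(),
                      elec_cutoff = Inf, rep_cutoff_factor = Inf,
                      z_periodic = !is.null(dna)) {
  pb <- protein$beads
  np <- nrow(pb)
  pos <- as.matrix(pb[, c("x", "y", "z")])
  charge <- pb$charge
  radius <- pb$radius
  group <- as.integer(factor(pb$chain, levels = unique(pb$chain))) - 1L
  seqpos <- as.integer(ave(seq_len(np), pb$chain, FUN = seq_along))
  zperiod <- 0
  if (!is.null(dna)) {
    db <- dna$beads
    pos <- rbind(pos, as.matrix(db[, c("x", "y", "z")]))
    charge <- c(charge, db$charge)
    radius <- c(radius, db$radius)
    group <- c(group, rep(-1L, nrow(db)))
    seqpos <- c(seqpos, rep(0L, nrow(db)))
    if (z_periodic) zperiod <- dna$n_bp * dna$rise
  }
  im <- function(df, cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "integer"
    m - 1L  # 0-based for C++
  }
  sys <- list(
    positions = unname(pos), n_mobile = np,
    charge = as.numeric(charge), radius = as.numeric(radius),
    group = group, seq = seqpos,
    bonds = im(protein$bonds, c("i", "j")), b0 = protein$bonds$b0,
    angles = im(protein$angles, c("i", "j", "k")),
    theta0 = protein$angles$theta0,
    dihedrals = im(protein$dihedrals, c("i", "j", "k", "l")),
    phi0 = protein$dihedrals$phi0,
    contacts = im(protein$contacts, c("i", "j")), aij = protein$contacts$aij,
    zperiod = zperiod,
    params = list(
      K_bonds = params$K_bonds, K_angles = params$K_angles,
      K_dihedrals = params$K_dihedrals, K_contacts = params$K_contacts,
      K_repulsion = params$K_repulsion,
      K_electrostatics = params$K_electrostatics,
      eps_r = model$eps_r, kappa = model$kappa, Bkappa = model$B,
      elec_cutoff = if (is.finite(elec_cutoff)) elec_cutoff else 0,
      rep_cutoff_factor =
        if (is.finite(rep_cutoff_factor)) rep_cutoff_factor else 0),
    protein = protein, dna = dna, model = model, ff = params
  )
  structure(sys, class = "CGSystem")
}

#' Potential energy with per-term breakdown
#'
#' @param sys A `CGSystem`.
#' @param positions Optional N x 3 coordinate matrix (default: the system's
#'   stored positions).
#' @return An `EnergyBreakdown`: named list of bonds, angles, dihedrals,
#'   contacts, repulsion, electrostatics, total (kcal/mol).
#' @export
cg_energy <- function(sys, positions = sys$positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) != nrow(sys$positions)) {
    stopf("positions must cover all %d beads", nrow(sys$positions))
  }
  e <- cpp_energy(unclass(sys), positions)
  structure(as.list(e), class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat("EnergyBreakdown (kcal/mol):\n")
  for (nm in names(x)) cat(sprintf("  %-15s %12.6f\n", nm, x[[nm]]))
  invisible(x)
}

#' Analytic forces
#'
#' Negative gradient of [cg_energy()] with respect to every bead position,
#' in kcal/mol/Angstrom. Forces on static DNA beads are reported too (they
#' are needed for the Newton's-third-law bookkeeping) but are never applied
#' by the integrator.
#'
#' @inheritParams cg_energy
#' @return N x 3 numeric matrix of forces.
#' @export
cg_forces <- function(sys, positions = sys$positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) != nrow(sys$positions)) {
    stopf("positions must cover all %d beads", nrow(sys$positions))
  }
  cpp_forces(unclass(sys), positions)
}
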
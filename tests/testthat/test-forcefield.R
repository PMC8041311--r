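test_that("Debye screening parameter follows the 1:1-salt closed form", {
  expect_identical(kappa_from_molar(0), 0)
  # square-root law
  expect_equal(kappa_from_molar(0.04) / kappa_from_molar(0.01), 2)
  # independent closed-form evaluation: kappa^2 = 8 pi lB NA C * 1e-27
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  lB <- e^2 / (4 * pi * eps0 * 70 * kB * 300) * 1e10
  kap <- sqrt(8 * pi * lB * 0.01 * 6.02214076e23 * 1e-27)
  expect_equal(kappa_from_molar(0.01, 300, 70), kap, tolerance = 1e-12)
  expect_error(kappa_from_molar(-0.1), ">= 0")
})

test_that("Debye-Huckel pair energy matches printed-constant arithmetic", {
  m0 <- electrostatic_model(0)
  expect_equal(m0$kappa, 0)
  expect_equal(m0$B, 1)
  # 332/(70*10) with zero screening
  expect_equal(debye_huckel_pair(10, 1, 1, m0), 332 / 700,
               tolerance = 1e-12)
  expect_identical(debye_huckel_pair(7.3, 0, 1, m0), 0)
  expect_error(debye_huckel_pair(0, 1, 1, m0), "overlapping")
  # screening monotonicity for an attractive pair: energy increases to 0
  salts <- c(0.005, 0.01, 0.02, 0.04, 0.08)
  es <- vapply(salts, function(s)
    debye_huckel_pair(12, 1, -1, electrostatic_model(s, ion_radius = 0)),
    numeric(1))
  expect_true(all(diff(es) > 0))
  expect_true(all(es < 0))
})

test_that("native configuration is the minimum of every bonded term", {
  tp <- make_toy_protein(15, charged = c(4, 9))
  sys <- cg_system(tp$protein, elec_cutoff = Inf, rep_cutoff_factor = Inf)
  e <- cg_energy(sys)
  expect_equal(e$bonds, 0, tolerance = 1e-16)
  expect_equal(e$angles, 0, tolerance = 1e-16)
  expect_equal(e$dihedrals, 0, tolerance = 1e-16)
  # contact term at the native distances: -K_contacts per contact
  expect_equal(e$contacts, -nrow(tp$protein$contacts), tolerance = 1e-9)
  # total equals the sum of components
  expect_equal(e$total,
               e$bonds + e$angles + e$dihedrals + e$contacts +
                 e$repulsion + e$electrostatics,
               tolerance = 1e-12)
})

test_that("repulsion is one K_repulsion unit at r = C_ij", {
  # two neutral chains, all inter-chain pairs far away except beads 1 and 5
  # held at exactly C_ij
  tt <- make_toy_trimer(4, positive = integer(0), negative = integer(0))
  p <- tt$protein
  sys <- cg_system(p, elec_cutoff = Inf, rep_cutoff_factor = Inf)
  cij <- p$beads$radius[1] + p$beads$radius[5]
  pos <- matrix(0, 12, 3)
  pos[1:4, 1] <- c(0, -500, -510, -520)        # chain A: bead 1 at origin
  pos[5:8, 1] <- c(cij, 500, 510, 520)         # chain B: bead 5 at C_ij
  pos[9:12, 1] <- c(5000, 5010, 5020, 5030)    # chain C: far away
  e <- cg_energy(sys, pos)
  expect_equal(e$repulsion, ff_params()$K_repulsion, tolerance = 1e-6)
})

test_that("energy matches the brute-force O(N^2) oracle", {
  params <- ff_params()
  for (seed in c(101, 202, 303)) {
    rs <- random_system(seed)
    model <- electrostatic_model(0.02)
    sys <- cg_system(rs$protein, rs$dna, params, model,
                     elec_cutoff = Inf, rep_cutoff_factor = Inf)
    got <- cg_energy(sys, rs$pos)
    want <- oracle_energy(rs$protein, rs$dna, rs$pos, model, params)
    for (term in c("bonds", "angles", "dihedrals", "contacts",
                   "repulsion", "electrostatics", "total")) {
      expect_equal(got[[term]], want[[term]], tolerance = 1e-9,
                   label = sprintf("seed %d term %s", seed, term))
    }
  }
})

test_that("analytic forces match central differences", {
  for (seed in c(7, 21)) {
    rs <- random_system(seed, n_min = 20, n_max = 30)
    model <- electrostatic_model(0.02)
    sys <- cg_system(rs$protein, rs$dna, ff_params(), model,
                     elec_cutoff = Inf, rep_cutoff_factor = Inf)
    F <- cg_forces(sys, rs$pos)
    beads <- unique(c(1, 2, rs$np %/% 2, rs$np - 1, rs$np))
    Fn <- numeric_forces(sys, rs$pos, h = 1e-5, beads = beads)
    expect_lt(max(abs(F[beads, ] - Fn[beads, ])), 1e-5)
  }
})

test_that("bonded forces vanish at the native structure", {
  tp <- make_toy_protein(12)  # no charges
  sys <- cg_system(tp$protein)
  F <- cg_forces(sys)
  # pure bonded + contact minimum; nonbonded repulsion is tiny but nonzero,
  # so isolate bonded terms
  p0 <- ff_params(K_contacts = 0, K_repulsion = 0, K_electrostatics = 0)
  sys0 <- cg_system(tp$protein, params = p0)
  expect_lt(max(abs(cg_forces(sys0))), 1e-8)
})

test_that("equal charges repel along the pair axis with equal magnitude", {
  tt <- make_toy_trimer(4, positive = 2, negative = integer(0))
  p <- tt$protein
  sys <- cg_system(p, elec_cutoff = Inf, rep_cutoff_factor = Inf)
  pos <- sys$positions
  F <- cg_forces(sys, pos)
  iq <- which(p$beads$charge == 1)
  expect_length(iq, 3)
  # Newton's third law over the whole isolated system
  expect_lt(max(abs(colSums(F))), 1e-9)
})

test_that("energy is invariant under rigid-body motion", {
  rs <- random_system(55, with_dna = FALSE)
  sys <- cg_system(rs$protein, model = electrostatic_model(0.02),
                   elec_cutoff = Inf, rep_cutoff_factor = Inf)
  e0 <- cg_energy(sys, rs$pos)
  # translation
  e1 <- cg_energy(sys, sweep(rs$pos, 2, c(13.7, -8.1, 5.5), "+"))
  # rotation about an arbitrary axis
  th <- 0.73
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  e2 <- cg_energy(sys, rs$pos %*% R)
  for (term in names(e0)) {
    denom <- max(abs(e0[[term]]), 1)
    expect_lt(abs(e1[[term]] - e0[[term]]) / denom, 1e-9)
    expect_lt(abs(e2[[term]] - e0[[term]]) / denom, 1e-9)
  }
})

test_that("electrostatic magnitude strictly decreases with kappa", {
  rs <- random_system(66)
  es <- vapply(c(0.005, 0.01, 0.03, 0.06), function(s) {
    sys <- cg_system(rs$protein, rs$dna,
                     model = electrostatic_model(s, ion_radius = 0),
                     elec_cutoff = Inf, rep_cutoff_factor = Inf)
    abs(cg_energy(sys, rs$pos)$electrostatics)
  }, numeric(1))
  expect_true(all(diff(es) < 0))
})
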
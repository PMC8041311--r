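test_that("PDB text round-trips through the parser", {
  tp <- make_toy_protein(3 + 1)  # minimal synthetic PDB
  atoms <- read_pdb(paste(tp$pdb, collapse = "\n"))
  expect_equal(nrow(atoms$atoms), 4)
  res <- unique(paste(atoms$atoms$chain, atoms$atoms$resno))
  expect_length(res, 4)
  # identity read-back of coordinates (PDB precision is 1e-3 A)
  expect_equal(atoms$atoms$x, tp$protein$beads$x, tolerance = 1e-9)
  expect_equal(atoms$atoms$z, tp$protein$beads$z, tolerance = 1e-9)
})

test_that("malformed and degenerate PDB inputs fail loudly", {
  tp <- make_toy_protein(5)
  bad <- tp$pdb
  substr(bad[3], 31, 38) <- "   xx.yy"
  expect_error(read_pdb(paste(bad, collapse = "\n")), "line 3")
  # residue whose CA is renamed: error names the residue
  noca <- tp$pdb
  substr(noca[2], 13, 16) <- "CB  "
  expect_error(read_pdb(paste(noca, collapse = "\n")), "residue 2")
  # a DNA-like file with no CA at all
  nca <- gsub(" CA ", " P  ", tp$pdb, fixed = TRUE)
  expect_error(read_pdb(paste(nca, collapse = "\n")), "not a protein chain")
})

test_that("coarse graining counts beads/bonds/angles/dihedrals and charges", {
  tp <- make_toy_protein(10)
  p <- tp$protein
  expect_equal(nrow(p$beads), 10)
  expect_equal(nrow(p$bonds), 9)
  expect_equal(nrow(p$angles), 8)
  expect_equal(nrow(p$dihedrals), 7)
  # charge scheme lookup: K at two positions
  tp2 <- make_toy_protein(10, charged = c(2, 5))
  expect_equal(sum(tp2$protein$beads$charge == 1), 2)
  expect_equal(sum(tp2$protein$beads$charge), 2)
  # reference values all come from the input conformation
  xyz <- as.matrix(tp$protein$beads[, c("x", "y", "z")])
  b <- tp$protein$bonds
  d <- sqrt(rowSums((xyz[b$j, ] - xyz[b$i, ])^2))
  expect_equal(b$b0, d, tolerance = 1e-12)
})

test_that("chain breaks are flagged and bonded terms stop at the gap", {
  tp <- make_toy_protein(8)
  pdb <- tp$pdb
  # displace the last three residues far away
  for (k in 6:8) {
    x <- as.numeric(substr(pdb[k], 31, 38)) + 50
    substr(pdb[k], 31, 38) <- sprintf("%8.3f", x)
  }
  atoms <- read_pdb(paste(pdb, collapse = "\n"))
  expect_warning(p <- coarse_grain_protein(atoms, contact_cutoff = 6.5),
                 "chain break")
  expect_equal(nrow(p$bonds), 6)  # bond 5-6 removed
  expect_error(coarse_grain_protein(atoms, contact_cutoff = 6.5,
                                    on_chain_break = "error"),
               "chain break")
})

test_that("native contacts respect cutoff, separation, and symmetry", {
  # two residues with heavy atoms 3 A apart at sequence separation 4
  mk <- function(cutoff) {
    lines <- c(
      sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              1:5, 1:5, c(0, 20, 40, 60, 3), c(0, 0, 0, 0, 0), rep(0, 5)))
    build_native_contacts(read_pdb(paste(lines, collapse = "\n")),
                          cutoff = cutoff, min_seq_sep = 3)
  }
  c1 <- mk(4.5)
  expect_equal(nrow(c1), 1)
  expect_equal(c(c1$i, c1$j), c(1, 5))
  expect_equal(c1$aij, 3)
  expect_equal(nrow(mk(2.0)), 0)
  # no self contacts, i < j canonical form
  tp <- make_toy_protein(20)
  cc <- tp$protein$contacts
  expect_true(all(cc$i < cc$j))
  # contact pairs never duplicate bond/angle pairs (min separation 3)
  expect_true(all(cc$j - cc$i >= 3))
})

test_that("contact list equals an exhaustive brute-force scan on a hairpin", {
  # synthetic two-strand hairpin: strand 1 at y=0, strand 2 at y=4.2,
  # running antiparallel, with CA+CB-like atoms
  lines <- character(0)
  serial <- 0
  for (i in 1:10) {
    serial <- serial + 1
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, i, i * 3.8, 0, 0))
  }
  for (i in 11:20) {
    serial <- serial + 1
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, i, (21 - i) * 3.8, 4.2, 0))
  }
  atoms <- read_pdb(paste(lines, collapse = "\n"))
  got <- build_native_contacts(atoms, cutoff = 4.5, min_seq_sep = 3)
  want <- oracle_contacts(atoms, cutoff = 4.5, min_seq_sep = 3)
  expect_equal(nrow(got), nrow(want))
  expect_equal(as.matrix(got[, c("i", "j")]), want, ignore_attr = TRUE)
})

test_that("ideal B-DNA geometry, counts and charges", {
  dna <- build_bdna(100)
  expect_equal(nrow(dna$beads), 600)
  expect_equal(sum(dna$beads$charge == -1), 200)
  expect_equal(sum(dna$beads$charge), -200)
  # 34 A per 10 bp (helical pitch)
  dna11 <- build_bdna(paste(rep("G", 11), collapse = ""))
  bA <- dna11$beads[dna11$beads$strand == "A" & dna11$beads$kind == "base", ]
  expect_equal(bA$z[11] - bA$z[1], 34.0)
  # smallest case
  dna1 <- build_bdna("A")
  expect_equal(nrow(dna1$beads), 6)
  expect_equal(sum(dna1$beads$charge == -1), 2)
  expect_error(build_bdna("ACGU"), "invalid base")
  expect_error(build_bdna(""), "empty|invalid")
})

test_that("B-DNA helical closure: azimuth(n+10) == azimuth(n) mod 2pi", {
  for (len in c(11, 25, 40)) {
    dna <- build_bdna(len)
    b <- dna$beads[dna$beads$strand == "A" & dna$beads$kind == "base", ]
    phi <- atan2(b$y, b$x)
    for (n in seq_len(len - 10)) {
      d <- (phi[n + 10] - phi[n]) %% (2 * pi)
      expect_lt(min(d, 2 * pi - d), 1e-9)
    }
  }
})

test_that("groove track advances one turn per pitch", {
  dna <- build_bdna(50)
  z <- seq(0, 34, by = 1)
  th <- groove_azimuth(dna, z)
  expect_equal(th[length(th)] - th[1], dna$handedness * 2 * pi)
  slope <- (th[2] - th[1]) / (z[2] - z[1])
  expect_equal(slope, -2 * pi / 34, tolerance = 1e-12)
})

test_that("CG model files round-trip bit-exactly", {
  tp <- make_toy_protein(15, charged = c(2, 9))
  f <- withr::local_tempfile()
  write_cg_model(tp$protein, f)
  back <- read_cg_model(f)
  for (sec in c("beads", "bonds", "angles", "dihedrals", "contacts")) {
    expect_identical(back[[sec]], tp$protein[[sec]], label = sec)
  }
  dna <- build_bdna(13)
  f2 <- withr::local_tempfile()
  write_cg_model(dna, f2)
  dback <- read_cg_model(f2)
  expect_identical(dback$beads, dna$beads)
  expect_identical(dback$sequence, dna$sequence)
  expect_identical(dback$rise, dna$rise)
})

test_that("reading a non-model file errors", {
  f <- withr::local_tempfile(lines = "hello")
  expect_error(read_cg_model(f), "not a slidescope CG model")
})

test_that("charge bookkeeping: net charges follow the scheme", {
  sch <- default_charge_scheme()
  expect_equal(sum(sch != 0), 5)
  expect_setequal(names(sch)[sch == 1], c("LYS", "ARG", "HIS"))
  expect_setequal(names(sch)[sch == -1], c("ASP", "GLU"))
  tp <- make_toy_protein(12, charged = c(1, 4, 8), charge = -1)
  expect_equal(sum(tp$protein$beads$charge), -3)
  for (len in c(5, 17, 31)) {
    dna <- build_bdna(len)
    expect_equal(sum(dna$beads$charge), -2 * len)
  }
})
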
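# structure_io: PDB input, one-bead-per-residue coarse graining, native
# contacts, and the ideal B-DNA builder.

#' Default residue charge scheme
#'
#' Integer charges (units of the elementary charge e) for the 20 standard
#' amino acids: Asp/Glu carry -1, Lys/Arg/His carry +1, all others 0.
#' Histidine is treated as positively charged, matching models in which the
#' sliding-clamp positive-patch residues include a histidine. The DNA
#' phosphate bead always carries -1 and is handled by [build_bdna()].
#'
#' @return Named numeric vector keyed by three-letter residue code.
#' @export
default_charge_scheme <- function() {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  q <- setNames(numeric(length(aa)), aa)
  q[c("ASP", "GLU")] <- -1
  q[c("LYS", "ARG", "HIS")] <- +1
  q
}

#' Read ATOM records from PDB-format text
#'
#' Parses the fixed-column ATOM records of a PDB file. HETATM records are
#' skipped; alternate locations other than blank or "A" are dropped. Every
#' residue must contain a CA atom (the coarse-graining anchor).
#'
#' @param x Path to a PDB file, or a character scalar/vector of PDB text.
#' @param chain Optional chain identifier(s) to keep; default all chains.
#' @return An `AtomRecordSet`: list with `atoms` (data.frame: chain, resno,
#'   resname, atom, element, x, y, z) and `source` label.
#' @export
read_pdb <- function(x, chain = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    src <- basename(x)
    lines <- readLines(x, warn = FALSE)
  } else {
    src <- "text"
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  is_atom <- startsWith(lines, "ATOM")
  idx <- which(is_atom)
  if (length(idx) == 0L) stopf("no ATOM records found in '%s'", src)
  recs <- lines[idx]
  sub_f <- function(s, a, b) substr(s, a, b)
  altloc <- trimws(sub_f(recs, 17, 17))
  keep <- altloc %in% c("", "A")
  recs <- recs[keep]; idx <- idx[keep]
  xs <- suppressWarnings(as.numeric(sub_f(recs, 31, 38)))
  ys <- suppressWarnings(as.numeric(sub_f(recs, 39, 46)))
  zs <- suppressWarnings(as.numeric(sub_f(recs, 47, 54)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs))
  if (length(bad)) {
    stopf("malformed ATOM record at line %d: cannot parse coordinates",
          idx[bad[1]])
  }
  atoms <- data.frame(
    chain   = sub_f(recs, 22, 22),
    resno   = suppressWarnings(as.integer(sub_f(recs, 23, 26))),
    resname = trimws(sub_f(recs, 18, 20)),
    atom    = trimws(sub_f(recs, 13, 16)),
    element = trimws(sub_f(recs, 77, 78)),
    x = xs, y = ys, z = zs,
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$resno)) {
    stopf("malformed ATOM record at line %d: cannot parse residue number",
          idx[which(is.na(atoms$resno))[1]])
  }
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stopf("no ATOM records left for chain '%s'", chain)
  # drop hydrogens (element H, or H* atom names when element column is empty)
  elem <- atoms$element
  guess <- substr(gsub("^[0-9]", "", atoms$atom), 1, 1)
  hyd <- elem == "H" | (elem == "" & guess == "H")
  atoms <- atoms[!hyd, , drop = FALSE]
  if (!any(atoms$atom == "CA")) stopf("not a protein chain: no CA atoms")
  key <- paste(atoms$chain, atoms$resno)
  has_ca <- tapply(atoms$atom == "CA", key, any)
  if (!all(has_ca)) {
    miss <- names(has_ca)[!has_ca][1]
    stopf("residue %s (chain %s) has no CA atom",
          sub("^\\S+ ", "", miss), sub(" .*$", "", miss))
  }
  structure(list(atoms = atoms, source = src), class = "AtomRecordSet")
}

#' @export
print.AtomRecordSet <- function(x, ...) {
  nres <- length(unique(paste(x$atoms$chain, x$atoms$resno)))
  cat(sprintf("AtomRecordSet '%s': %d atoms, %d residues, chains %s\n",
              x$source, nrow(x$atoms), nres,
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

# ordered residue table (one row per residue, CA coordinates), order of
# first appearance in the file
residue_table <- function(atoms) {
  a <- atoms$atoms
  key <- paste(a$chain, a$resno)
  first <- !duplicated(key)
  res <- a[first, c("chain", "resno", "resname")]
  ca <- a[a$atom == "CA", ]
  ca_key <- paste(ca$chain, ca$resno)
  m <- match(key[first], ca_key)
  res$x <- ca$x[m]; res$y <- ca$y[m]; res$z <- ca$z[m]
  rownames(res) <- NULL
  res
}

#' Build the native-contact list of a structure
#'
#' A residue pair (i, j) is a native contact when any heavy-atom pair between
#' the two residues lies within `cutoff` Angstrom and the residues are at
#' least `min_seq_sep` apart in sequence (pairs on different chains always
#' satisfy the separation requirement). The stored contact distance `aij` is
#' the CA-CA distance in the source structure, which the force field uses as
#' the minimum of the 12-10 contact potential.
#'
#' @param atoms An `AtomRecordSet`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param min_seq_sep Minimum intra-chain sequence separation (default 3).
#' @return data.frame with columns i, j (1-based bead indices, i < j), aij.
#' @export
build_native_contacts <- function(atoms, cutoff = 4.5, min_seq_sep = 3) {
  stopifnot(cutoff > 0, min_seq_sep >= 3)
  res <- residue_table(atoms)
  n <- nrow(res)
  a <- atoms$atoms
  akey <- paste(a$chain, a$resno)
  rkey <- paste(res$chain, res$resno)
  a$res_idx <- match(akey, rkey)
  # index within chain for sequence separation
  within <- ave(seq_len(n), res$chain, FUN = seq_along)
  ca <- as.matrix(res[, c("x", "y", "z")])
  # prefilter on CA-CA distance: heavy atoms lie within ~10 A of their CA
  pre <- cutoff + 20
  atom_by_res <- split(seq_len(nrow(a)), a$res_idx)
  out_i <- integer(0); out_j <- integer(0); out_a <- numeric(0)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    same <- res$chain[js] == res$chain[i]
    sep_ok <- !same | abs(within[js] - within[i]) >= min_seq_sep
    d2 <- (ca[js, 1] - ca[i, 1])^2 + (ca[js, 2] - ca[i, 2])^2 +
      (ca[js, 3] - ca[i, 3])^2
    js <- js[sep_ok & d2 <= pre^2]
    if (!length(js)) next
    ai <- a[atom_by_res[[as.character(i)]], c("x", "y", "z"), drop = FALSE]
    for (j in js) {
      aj <- a[atom_by_res[[as.character(j)]], c("x", "y", "z"), drop = FALSE]
      dx <- outer(ai$x, aj$x, "-"); dy <- outer(ai$y, aj$y, "-")
      dz <- outer(ai$z, aj$z, "-")
      if (min(dx * dx + dy * dy + dz * dz) <= cutoff^2) {
        out_i <- c(out_i, i); out_j <- c(out_j, j)
        out_a <- c(out_a, sqrt(sum((ca[j, ] - ca[i, ])^2)))
      }
    }
  }
  data.frame(i = out_i, j = out_j, aij = out_a)
}

#' Coarse-grain a protein to one bead per residue
#'
#' Each residue becomes a single bead at its CA position. Bond, angle and
#' dihedral reference values are taken from the input conformation (they are
#' the minima of the corresponding harmonic/cosine terms), charges are
#' assigned from the residue-type scheme, and native contacts are built with
#' [build_native_contacts()].
#'
#' @param atoms An `AtomRecordSet`.
#' @param scheme Named charge vector, see [default_charge_scheme()].
#' @param contact_cutoff Heavy-atom contact cutoff in Angstrom.
#' @param min_seq_sep Minimum sequence separation for contacts.
#' @param on_chain_break "warn" (default) or "error" when sequential CA-CA
#'   distance exceeds 4.5 A; bonded terms are never built across a break.
#' @param radius Excluded-volume radius per bead in Angstrom (default 2.0).
#' @return A `CGProtein` (beads, bonds, angles, dihedrals, contacts).
#' @export
coarse_grain_protein <- function(atoms, scheme = default_charge_scheme(),
                                 contact_cutoff = 4.5, min_seq_sep = 3,
                                 on_chain_break = c("warn", "error"),
                                 radius = 2.0) {
  on_chain_break <- match.arg(on_chain_break)
  res <- residue_table(atoms)
  n <- nrow(res)
  if (n < 4L) stopf("need at least 4 residues, got %d", n)
  q <- scheme[res$resname]
  if (anyNA(q)) {
    warnf("residue type(s) %s not in charge scheme; assigning charge 0",
          paste(unique(res$resname[is.na(q)]), collapse = ","))
    q[is.na(q)] <- 0
  }
  beads <- data.frame(
    index = seq_len(n), chain = res$chain, resno = res$resno,
    resname = res$resname, x = res$x, y = res$y, z = res$z,
    charge = as.numeric(q), radius = radius
  )
  pos <- as.matrix(beads[, c("x", "y", "z")])
  # sequential bonds within a chain, broken across gaps
  same_chain <- res$chain[-n] == res$chain[-1]
  d <- sqrt(rowSums((pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE])^2))
  gap <- same_chain & d > 4.5
  if (any(gap)) {
    msg <- sprintf("chain break after residue %s:%d (CA-CA %.2f A)",
                   res$chain[which(gap)[1]], res$resno[which(gap)[1]],
                   d[which(gap)[1]])
    if (on_chain_break == "error") stopf("%s", msg) else warnf("%s", msg)
  }
  bonded <- same_chain & !gap
  bi <- which(bonded)
  bonds <- data.frame(i = bi, j = bi + 1L, b0 = d[bi])
  ok2 <- bonded[-length(bonded)] & bonded[-1]
  ai <- which(ok2)
  angles <- data.frame(i = ai, j = ai + 1L, k = ai + 2L,
                       theta0 = vapply(ai, function(i)
                         bead_angle(pos[i, ], pos[i + 1, ], pos[i + 2, ]),
                         numeric(1)))
  ok3 <- ok2[-length(ok2)] & bonded[-(1:2)]
  di <- which(ok3)
  dihedrals <- data.frame(i = di, j = di + 1L, k = di + 2L, l = di + 3L,
                          phi0 = vapply(di, function(i)
                            bead_dihedral(pos[i, ], pos[i + 1, ],
                                          pos[i + 2, ], pos[i + 3, ]),
                            numeric(1)))
  contacts <- build_native_contacts(atoms, contact_cutoff, min_seq_sep)
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, contacts = contacts,
                 source = atoms$source),
            class = "CGProtein")
}

#' @export
print.CGProtein <- function(x, ...) {
  cat(sprintf(
    "CGProtein '%s': %d beads (net charge %+g), %d bonds, %d angles, %d dihedrals, %d contacts\n",
    x$source, nrow(x$beads), sum(x$beads$charge), nrow(x$bonds),
    nrow(x$angles), nrow(x$dihedrals), nrow(x$contacts)))
  invisible(x)
}

# idealized coarse-grained B-DNA geometry: cylindrical radius (A) and
# azimuthal offset (deg) of each bead kind relative to the base-pair
# reference azimuth. Only the relative geometry (groove shape, charge
# spacing) matters at this resolution. The two phosphate tracks are
# separated by 148 deg across the minor groove; the major-groove centre sits
# opposite the base-pair reference azimuth.
bdna_geometry <- function() {
  data.frame(
    kind   = c("phosphate", "sugar", "base"),
    r      = c(8.9, 6.9, 2.3),
    dphi   = c(74, 55, 18)   # strand A offset; strand B uses -dphi
  )
}

#' Build an ideal coarse-grained B-DNA duplex
#'
#' Generates a static, linear double-stranded B-DNA on the Z axis with three
#' beads per nucleotide (phosphate, sugar, base). With the default rise of
#' 3.4 A and twist of 36 deg the duplex advances 34 A per 10 bp (the helical
#' pitch) and the azimuth closes after 10 bp. Phosphate beads carry charge
#' -1 e, all other beads are neutral.
#'
#' The internal frame is chosen so that the major-groove track satisfies
#' theta = -(2*pi/34) * Z when theta is measured with `atan2(y, x)`; sliding
#' proteins tracking the groove therefore show the negative coupling slope
#' conventionally reported for canonical B-DNA (see `handedness`).
#'
#' @param sequence Base string (ACGT) of strand A, 5' to 3', or an integer
#'   length (a repeated ACGT sequence of that length is used).
#' @param rise Rise per base pair in Angstrom (default 3.4).
#' @param twist Twist per base pair in degrees (default 36).
#' @param handedness -1 (default) or +1: sign applied to the azimuthal
#'   advance per base pair in the internal frame.
#' @param first_phosphate Keep the 5'-terminal phosphate charged (default
#'   TRUE). FALSE neutralizes it without removing the bead.
#' @param radius Excluded-volume radius per DNA bead in Angstrom.
#' @return A `BDNADuplex`: beads data.frame (strand, nt, kind, x, y, z,
#'   charge, radius) plus sequence and geometry fields.
#' @export
build_bdna <- function(sequence, rise = 3.4, twist = 36, handedness = -1,
                       first_phosphate = TRUE, radius = 2.0) {
  if (is.numeric(sequence)) {
    if (!is_count(sequence)) stopf("length must be a positive integer")
    sequence <- paste(rep_len(strsplit("ACGT", "")[[1]], sequence),
                      collapse = "")
  }
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) == 0L) stopf("empty DNA sequence")
  bad <- setdiff(unique(bases), c("A", "C", "G", "T"))
  if (length(bad)) stopf("invalid base(s) in sequence: %s",
                         paste(bad, collapse = ","))
  stopifnot(handedness %in% c(-1, 1), rise > 0, twist > 0)
  n <- length(bases)
  comp <- c(A = "T", C = "G", G = "C", T = "A")[bases]
  geom <- bdna_geometry()
  nt <- rep(seq_len(n), each = 3L)
  kind <- rep(geom$kind, n)
  r <- rep(geom$r, n)
  dphi <- rep(geom$dphi, n) * pi / 180
  phi_ref <- handedness * (nt - 1L) * twist * pi / 180
  z <- (nt - 1L) * rise
  mk <- function(strand_sign, strand) {
    phi <- phi_ref + strand_sign * handedness * dphi
    data.frame(strand = strand, nt = nt, kind = kind,
               x = r * cos(phi), y = r * sin(phi), z = z,
               charge = ifelse(kind == "phosphate", -1, 0),
               radius = radius)
  }
  beads <- rbind(mk(+1, "A"), mk(-1, "B"))
  if (!first_phosphate) {
    beads$charge[beads$nt == 1L & beads$kind == "phosphate"] <- 0
  }
  rownames(beads) <- NULL
  structure(list(beads = beads, sequence = paste(bases, collapse = ""),
                 complement = paste(comp, collapse = ""),
                 n_bp = n, rise = rise, twist = twist,
                 handedness = handedness),
            class = "BDNADuplex")
}

#' @export
print.BDNADuplex <- function(x, ...) {
  cat(sprintf(
    "BDNADuplex: %d bp, %d beads, total charge %g e, rise %.2f A, twist %g deg, pitch %.1f A\n",
    x$n_bp, nrow(x$beads), sum(x$beads$charge), x$rise, x$twist,
    x$rise * 360 / x$twist))
  invisible(x)
}

#' Azimuth of a DNA groove at a given height
#'
#' Returns the azimuthal angle (radians, continuous, not wrapped) of the
#' centre of the major or minor groove of an ideal duplex at height `z`,
#' in the duplex's own frame. A point tracking the major groove while
#' translating along Z has `theta = groove_azimuth(dna, z)`, i.e. slope
#' `handedness * 2*pi / pitch` in rad/A.
#'
#' @param dna A `BDNADuplex`.
#' @param z Height(s) along the axis in Angstrom.
#' @param groove "major" (default) or "minor".
#' @return Numeric vector of angles in radians.
#' @export
groove_azimuth <- function(dna, z, groove = c("major", "minor")) {
  groove <- match.arg(groove)
  pitch <- dna$rise * 360 / dna$twist
  offset <- if (groove == "major") pi else 0
  dna$handedness * 2 * pi * z / pitch + offset
}

#' Write / read a coarse-grained model file
#'
#' Plain-text, full-precision (%.17g) serialization of a `CGProtein` or
#' `BDNADuplex`; numeric fields round-trip bit-exactly.
#'
#' @param x A `CGProtein` or `BDNADuplex`.
#' @param path Output file path.
#' @return `write_cg_model` returns `path` invisibly; `read_cg_model`
#'   returns the reconstructed object.
#' @export
write_cg_model <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num_block <- function(df) {
    apply(df, 1L, function(row) paste(vapply(row, function(v) {
      if (is.numeric(v)) fmt_num(v) else as.character(v)
    }, character(1)), collapse = "\t"))
  }
  w("#SLIDESCOPE-CG 1")
  if (inherits(x, "CGProtein")) {
    w("TYPE protein")
    w("SOURCE %s", x$source)
    for (sec in c("beads", "bonds", "angles", "dihedrals", "contacts")) {
      df <- x[[sec]]
      w("%s %d %s", toupper(sec), nrow(df), paste(names(df), collapse = " "))
      if (nrow(df)) {
        lines <- vapply(seq_len(nrow(df)), function(r) {
          paste(vapply(seq_along(df), function(c) {
            v <- df[[c]][r]
            if (is.numeric(v) && !is.integer(v)) fmt_num(v) else as.character(v)
          }, character(1)), collapse = "\t")
        }, character(1))
        writeLines(lines, con)
      }
    }
  } else if (inherits(x, "BDNADuplex")) {
    w("TYPE dna")
    w("SEQUENCE %s", x$sequence)
    w("GEOM %s %s %d", fmt_num(x$rise), fmt_num(x$twist), x$handedness)
    df <- x$beads
    w("BEADS %d %s", nrow(df), paste(names(df), collapse = " "))
    lines <- vapply(seq_len(nrow(df)), function(r) {
      paste(vapply(seq_along(df), function(c) {
        v <- df[[c]][r]
        if (is.numeric(v) && !is.integer(v)) fmt_num(v) else as.character(v)
      }, character(1)), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  } else stopf("cannot serialize object of class %s", class(x)[1])
  invisible(path)
}

#' @rdname write_cg_model
#' @export
read_cg_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "#SLIDESCOPE-CG 1") {
    stopf("'%s' is not a slidescope CG model file (version 1)", path)
  }
  type <- sub("^TYPE ", "", lines[2])
  cur <- 3L
  parse_block <- function() {
    hdr <- strsplit(lines[cur], " ")[[1]]
    nr <- as.integer(hdr[2]); cols <- hdr[-(1:2)]
    rows <- if (nr > 0) lines[(cur + 1L):(cur + nr)] else character(0)
    cur <<- cur + 1L + nr
    if (nr == 0L) {
      df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
      return(df)
    }
    mat <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cols
    for (cc in cols) {
      if (!cc %in% c("chain", "resname", "strand", "kind")) {
        v <- as.numeric(df[[cc]])
        if (cc %in% c("index", "resno", "i", "j", "k", "l", "nt")) {
          v <- as.integer(v)
        }
        df[[cc]] <- v
      }
    }
    df
  }
  if (type == "protein") {
    src <- sub("^SOURCE ", "", lines[cur]); cur <- cur + 1L
    out <- list()
    for (sec in c("beads", "bonds", "angles", "dihedrals", "contacts")) {
      out[[sec]] <- parse_block()
    }
    out$source <- src
    structure(out, class = "CGProtein")
  } else if (type == "dna") {
    seqn <- sub("^SEQUENCE ", "", lines[cur]); cur <- cur + 1L
    geom <- as.numeric(strsplit(lines[cur], " ")[[1]][-1]); cur <- cur + 1L
    beads <- parse_block()
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    bases <- strsplit(seqn, "")[[1]]
    structure(list(beads = beads, sequence = seqn,
                   complement = paste(comp[bases], collapse = ""),
                   n_bp = nchar(seqn), rise = geom[1], twist = geom[2],
                   handedness = as.integer(geom[3])),
              class = "BDNADuplex")
  } else stopf("unknown model TYPE '%s'", type)
}

#' Write the native-contact list as TSV
#'
#' @param protein A `CGProtein`.
#' @param path Output path.
#' @export
write_contacts_tsv <- function(protein, path) {
  df <- protein$contacts
  lines <- c("i\tj\taij",
             sprintf("%d\t%d\t%s", df$i, df$j, fmt_num(df$aij)))
  writeLines(lines, path)
  invisible(path)
}
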
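# variant_engine: charge-neutralization variants (recognition-helix scans,
# sliding-clamp subunit designs) and simulate-and-classify scans.

#' Enumerate recognition-helix charge-retention variants
#'
#' All C(n, k) ways of retaining `k_retained` of the listed charged residue
#' ids; every non-retained id is marked neutralized. When applied with
#' [apply_charge_variant()], all protein charges outside the retained set
#' are zeroed as well (the scan studies the listed charges in isolation).
#' Variants are emitted in deterministic lexicographic order.
#'
#' @param charged_ids Integer residue ids of the charged positions under
#'   study (e.g. the six charged residues of a recognition helix).
#' @param k_retained How many of them remain charged (0..length(charged_ids)).
#' @return List of `ChargeVariant`s: label, retained, neutralized.
#' @export
enumerate_variants <- function(charged_ids, k_retained) {
  n <- length(charged_ids)
  if (!is_count(k_retained + 1) || k_retained < 0 || k_retained > n) {
    stopf("k_retained must be in 0..%d", n)
  }
  charged_ids <- as.integer(charged_ids)
  sets <- if (k_retained == 0) {
    list(integer(0))
  } else {
    cmb <- combn(charged_ids, k_retained)
    lapply(seq_len(ncol(cmb)), function(c) cmb[, c])
  }
  lapply(sets, function(keep) {
    structure(list(
      label = sprintf("keep[%s]", paste(keep, collapse = ",")),
      retained = keep,
      neutralized = setdiff(charged_ids, keep)),
      class = "ChargeVariant")
  })
}

#' @export
print.ChargeVariant <- function(x, ...) {
  cat(sprintf("ChargeVariant %s: %d retained, %d neutralized\n",
              x$label, length(x$retained), length(x$neutralized)))
  invisible(x)
}

#' Apply a charge variant to a protein
#'
#' Returns the protein with every bead charge either kept at its original
#' value (residues in `retained`, optionally restricted to `chain`) or set
#' to exactly 0; no new charges are created.
#'
#' @param protein A `CGProtein`.
#' @param variant A `ChargeVariant`, or an integer vector of retained
#'   residue ids.
#' @param chain Restrict retention to one chain id (default: any chain).
#' @return The modified `CGProtein` with a `variant` field recording the
#'   per-bead charge vector.
#' @export
apply_charge_variant <- function(protein, variant, chain = NULL) {
  retained <- if (inherits(variant, "ChargeVariant")) variant$retained
              else as.integer(variant)
  keep <- protein$beads$resno %in% retained
  if (!is.null(chain)) keep <- keep & protein$beads$chain %in% chain
  out <- protein
  out$beads$charge <- ifelse(keep, protein$beads$charge, 0)
  out$variant <- list(
    label = if (inherits(variant, "ChargeVariant")) variant$label
            else sprintf("keep[%s]", paste(retained, collapse = ",")),
    retained = retained, charges = out$beads$charge)
  out$source <- paste0(protein$source, "|", out$variant$label)
  out
}

#' Sliding-clamp (PCNA-type) charge variants
#'
#' Builds the three published charge designs of a homotrimeric clamp:
#' \describe{
#'   \item{charged_monomer}{all charges neutralized on two of the three
#'     chains; one chain keeps its full charge complement.}
#'   \item{positive_monomer}{all negative charges neutralized everywhere
#'     and positive charges neutralized on two chains; one chain keeps its
#'     positive charges only.}
#'   \item{six_positive}{only the six listed positively charged residues
#'     (defaults K20, K77, K80, R149, H153, K217) remain charged, on one
#'     chain.}
#' }
#'
#' @param trimer A `CGProtein` with exactly 3 chains.
#' @param mode One of "charged_monomer", "positive_monomer", "six_positive".
#' @param chain Which chain retains charges (default the first).
#' @param six_ids Residue ids for the six_positive design.
#' @return The modified `CGProtein` (with a `variant` record).
#' @export
pcna_variant <- function(trimer,
                         mode = c("charged_monomer", "positive_monomer",
                                  "six_positive"),
                         chain = NULL,
                         six_ids = c(20, 77, 80, 149, 153, 217)) {
  mode <- match.arg(mode)
  chains <- unique(trimer$beads$chain)
  if (length(chains) != 3L) {
    stopf("expected a trimer with 3 chains, found %d (%s)",
          length(chains), paste(chains, collapse = ","))
  }
  chain <- chain %||% chains[1]
  b <- trimer$beads
  on_chain <- b$chain == chain
  q <- b$charge
  if (mode == "charged_monomer") {
    q[!on_chain] <- 0
  } else if (mode == "positive_monomer") {
    q[!(on_chain & b$charge > 0)] <- 0
  } else {
    present <- six_ids %in% b$resno[on_chain]
    if (!all(present)) {
      stopf("residue id(s) %s absent from chain %s",
            paste(six_ids[!present], collapse = ","), chain)
    }
    pos_ok <- vapply(six_ids, function(id)
      any(on_chain & b$resno == id & b$charge > 0), logical(1))
    if (!all(pos_ok)) {
      stopf("residue id(s) %s on chain %s are not positively charged",
            paste(six_ids[!pos_ok], collapse = ","), chain)
    }
    q[!(on_chain & b$resno %in% six_ids & b$charge > 0)] <- 0
  }
  out <- trimer
  out$beads$charge <- q
  out$variant <- list(label = mode, chain = chain, charges = q)
  out$source <- paste0(trimer$source, "|", mode)
  out
}

#' Simulate-and-classify scan over variants and salt concentrations
#'
#' Runs `replicates` Langevin simulations per (variant, salt) cell with
#' deterministic per-cell seeds derived from `master_seed`, fits the
#' theta/Z slope of each replicate, and aggregates with
#' [classify_mechanism()]. A failing replicate marks the cell failed; the
#' scan continues.
#'
#' @param protein Base `CGProtein` (already coarse-grained).
#' @param dna A `BDNADuplex`.
#' @param variants List of `ChargeVariant`s (or NULL for wild type only).
#' @param salts Numeric vector of molar salt concentrations.
#' @param config `SimulationConfig` template (its seed/salt are overridden).
#' @param replicates Replicates per cell (published scans use 10).
#' @param master_seed Master seed for the per-replicate seed stream.
#' @param selection Bead selection for [angular_trace()].
#' @param chain Chain restriction passed to [apply_charge_variant()].
#' @return A `VariantScanResult` data.frame: one row per cell with
#'   mean_slope, se, classification, n_ok, failed.
#' @export
scan_variants <- function(protein, dna, variants = NULL, salts,
                          config = sim_config(), replicates = 10,
                          master_seed = 1, selection = "protein",
                          chain = NULL) {
  if (is.null(variants)) {
    variants <- list(structure(list(label = "wild_type", retained = NULL),
                               class = "ChargeVariant"))
  }
  if (length(variants) < 1 || length(salts) < 1) {
    stopf("need at least one variant and one salt concentration")
  }
  rows <- list()
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    prot_v <- if (is.null(v$retained) && v$label == "wild_type") protein
              else apply_charge_variant(protein, v, chain = chain)
    for (si in seq_along(salts)) {
      fits <- list(); nfail <- 0L
      for (ri in seq_len(replicates)) {
        cfg <- config
        cfg$salt <- salts[si]
        cfg$seed <- derive_seed(master_seed, vi, si, ri)
        fit <- tryCatch({
          traj <- run_simulation(prot_v, dna, cfg)
          fit_theta_z(angular_trace(traj, selection))
        }, error = function(e) e)
        if (inherits(fit, "error")) nfail <- nfail + 1L
        else fits[[length(fits) + 1L]] <- fit
      }
      summ <- if (length(fits)) classify_mechanism(fits) else
        list(mean_slope = NA_real_, se = NA_real_, n = 0L,
             classification = "failed")
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v$label, salt = salts[si],
        mean_slope = summ$mean_slope, se = summ$se,
        classification = if (nfail == replicates) "failed"
                         else summ$classification,
        n_ok = length(fits), n_failed = nfail,
        failed = nfail == replicates)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("VariantScanResult", "data.frame")
  out
}

#' Write a scan result as TSV
#' @param scan A `VariantScanResult`.
#' @param path Output path.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
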
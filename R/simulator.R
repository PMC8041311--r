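# simulator: Langevin dynamics of the protein around the static duplex,
# trajectory container and plain-text trajectory IO.

#' Simulation configuration
#'
#' Reduced-unit Langevin settings. The published protocol uses reduced
#' temperature 0.4, a 300 A box and 1e7-step production runs; the
#' `n_steps` default here is one tenth of that (desk scale) and is meant to
#' be overridden. Time step and friction are in reduced units; energies are
#' kcal/mol with kB = 1, so temperature 0.4 means kB*T = 0.4 kcal/mol.
#'
#' @param temperature Reduced temperature (default 0.4).
#' @param friction Langevin friction gamma in reduced units (default 0.05).
#' @param dt Time step in reduced units (default 0.005).
#' @param n_steps Number of MD steps (default 1e6; published runs use 1e7).
#' @param stride Save a frame every `stride` steps (default 1000); must
#'   divide `n_steps`.
#' @param box_xy Edge of the confining box in X/Y (reflecting walls at
#'   +/- box_xy/2; default 300 A). The Z direction is periodic with period
#'   equal to the DNA length.
#' @param salt Molar salt concentration (default 0.01).
#' @param seed Integer random seed; recorded in the trajectory metadata.
#' @param offset Initial protein COM distance from the DNA axis (A).
#' @param z_offset Initial protein COM height relative to mid-DNA (A).
#' @param elec_cutoff Electrostatic cutoff used during dynamics (default
#'   30 A; energy drift from the neglected tail is < 1e-3 kcal/mol per
#'   charge pair at the default screening).
#' @param rep_cutoff_factor Repulsion cutoff in units of C_ij (default 3).
#' @param skin Neighbour-list skin in Angstrom.
#' @param max_disp Per-step displacement limit (A) that triggers the
#'   instability guard.
#' @param log_every Energy-breakdown logging interval in saved frames.
#' @param mass Bead mass in reduced units (uniform; default 1).
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(temperature = 0.4, friction = 0.05, dt = 0.005,
                       n_steps = 1e6, stride = 1000, box_xy = 300,
                       salt = 0.01, seed = NULL, offset = 25, z_offset = 0,
                       elec_cutoff = 30, rep_cutoff_factor = 3,
                       skin = 4, max_disp = 2, log_every = 10, mass = 1) {
  stopifnot(n_steps >= 1, stride >= 1, dt > 0, friction >= 0,
            temperature >= 0, mass > 0)
  if (n_steps %% stride != 0) {
    stopf("stride (%g) must divide n_steps (%g) evenly", stride, n_steps)
  }
  structure(list(temperature = temperature, friction = friction, dt = dt,
                 n_steps = n_steps, stride = stride, box_xy = box_xy,
                 salt = salt, seed = seed, offset = offset,
                 z_offset = z_offset, elec_cutoff = elec_cutoff,
                 rep_cutoff_factor = rep_cutoff_factor, skin = skin,
                 max_disp = max_disp, log_every = log_every, mass = mass),
            class = "SimulationConfig")
}

#' Initialize a simulation state
#'
#' Places the protein with its centre of mass at the configured distance
#' from the DNA axis, at mid-DNA height plus `z_offset`, and draws initial
#' velocities from the Maxwell distribution at the configured reduced
#' temperature (zero temperature gives zero velocities). The draw consumes
#' the R random stream; set `config$seed` for reproducibility.
#'
#' @param protein A `CGProtein`.
#' @param dna A `BDNADuplex` or NULL.
#' @param config A `SimulationConfig`.
#' @param params `ForceFieldParams`.
#' @return A `SimState` list: system, positions, velocities, time.
#' @export
init_state <- function(protein, dna = NULL, config = sim_config(),
                       params = ff_params()) {
  model <- electrostatic_model(config$salt)
  sys <- cg_system(protein, dna, params, model,
                   elec_cutoff = config$elec_cutoff,
                   rep_cutoff_factor = config$rep_cutoff_factor)
  np <- sys$n_mobile
  pos <- sys$positions
  com <- colMeans(pos[seq_len(np), , drop = FALSE])
  zmid <- if (!is.null(dna)) (dna$n_bp - 1) * dna$rise / 2 else 0
  target <- c(config$offset, 0, zmid + config$z_offset)
  pos[seq_len(np), ] <- sweep(pos[seq_len(np), , drop = FALSE], 2,
                              com - target)
  if (!is.null(dna)) {
    nd <- nrow(pos) - np
    pp <- pos[seq_len(np), , drop = FALSE]
    dp <- pos[np + seq_len(nd), , drop = FALSE]
    cij <- outer(sys$radius[seq_len(np)], sys$radius[np + seq_len(nd)], "+")
    d2 <- outer(pp[, 1], dp[, 1], "-")^2 + outer(pp[, 2], dp[, 2], "-")^2 +
      outer(pp[, 3], dp[, 3], "-")^2
    if (any(d2 < (0.5 * cij)^2)) {
      stopf(paste("initial protein-DNA bead overlap (closer than 0.5*C_ij);",
                  "increase the axis offset (currently %g A)"),
            config$offset)
    }
  }
  vel <- with_seed(config$seed, {
    if (config$temperature > 0) {
      matrix(rnorm(np * 3, 0, sqrt(config$temperature / config$mass)),
             np, 3)
    } else matrix(0, np, 3)
  })
  structure(list(system = sys, positions = pos, velocities = vel,
                 config = config, time = 0),
            class = "SimState")
}

run_conf <- function(config, n_steps, stride) {
  list(dt = config$dt, gamma = config$friction,
       temperature = config$temperature, mass = config$mass,
       n_steps = n_steps, stride = stride, box_xy = config$box_xy,
       max_disp = config$max_disp, skin = config$skin,
       log_every = config$log_every)
}

#' Advance a simulation state by discrete Langevin steps
#'
#' One (or `n`) BAOAB Langevin update(s) at the configured reduced
#' temperature and friction. DNA beads never move; protein beads are
#' confined by the reflecting X/Y walls. Uses the R random stream.
#'
#' @param state A `SimState` from [init_state()].
#' @param n Number of steps (default 1).
#' @return The updated `SimState`.
#' @export
langevin_step <- function(state, n = 1) {
  out <- cpp_run(unclass(state$system), state$positions, state$velocities,
                 run_conf(state$config, n, n))
  if (out$error_step >= 0) {
    stopf(paste("integration unstable at step %d (displacement > %g A per",
                "step); reduce dt (currently %g)"),
          out$error_step, state$config$max_disp, state$config$dt)
  }
  np <- state$system$n_mobile
  last <- out$frames[dim(out$frames)[1], , , drop = TRUE]
  state$positions[seq_len(np), ] <- matrix(last, np, 3)
  state$velocities <- out$velocities
  state$time <- state$time + n * state$config$dt
  state
}

#' Run a Langevin trajectory
#'
#' Simulates the protein diffusing around the static duplex and records
#' stride-spaced frames of the protein beads in the DNA frame (the duplex
#' axis is Z). Fully reproducible given `config$seed`.
#'
#' @inheritParams init_state
#' @return A `Trajectory`: times (reduced units), coords (frames x beads x
#'   3 array, Angstrom), bead table, energy log, metadata.
#' @export
run_simulation <- function(protein, dna = NULL, config = sim_config(),
                           params = ff_params()) {
  state <- init_state(protein, dna, config, params)
  out <- with_seed(config$seed,
                   cpp_run(unclass(state$system), state$positions,
                           state$velocities,
                           run_conf(config, config$n_steps, config$stride)))
  if (out$error_step >= 0) {
    stopf(paste("integration unstable at step %d (last stable frame %d);",
                "reduce dt (currently %g)"),
          out$error_step, out$last_frame, config$dt)
  }
  elog <- out$energy_log[seq_len(out$n_logged), , drop = FALSE]
  colnames(elog) <- c("time", "bonds", "angles", "dihedrals", "contacts",
                      "repulsion", "electrostatics", "kinetic_temperature")
  meta <- list(
    kind = "langevin",
    config = unclass(config),
    salt = config$salt, kappa = state$system$model$kappa,
    n_bp = if (!is.null(dna)) dna$n_bp else NA,
    zperiod = state$system$zperiod,
    handedness = if (!is.null(dna)) dna$handedness else NA,
    seed = config$seed %||% NA,
    topology = sprintf("%d beads, %d contacts, net charge %+g",
                       nrow(protein$beads), nrow(protein$contacts),
                       sum(protein$beads$charge))
  )
  new_trajectory(times = out$times, coords = out$frames,
                 beads = protein$beads, metadata = meta,
                 energy_log = as.data.frame(elog))
}

new_trajectory <- function(times, coords, beads, metadata,
                           energy_log = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[1] == length(times))
  structure(list(times = times, coords = coords, beads = beads,
                 metadata = metadata, energy_log = energy_log),
            class = "Trajectory")
}

#' Construct a trajectory from raw coordinates
#'
#' Wraps a frames x beads x 3 coordinate array (Angstrom, DNA frame with
#' the duplex axis on Z) as a `Trajectory`, e.g. for analysing externally
#' generated or hand-constructed paths.
#'
#' @param coords Numeric array of dimension (frames, beads, 3).
#' @param times Frame times (default 0, 1, 2, ...).
#' @param beads Optional bead table.
#' @param metadata Optional metadata list.
#' @return A `Trajectory`.
#' @export
trajectory_from_coords <- function(coords, times = NULL, beads = NULL,
                                   metadata = list(kind = "external")) {
  coords <- as.array(coords)
  times <- times %||% (seq_len(dim(coords)[1]) - 1)
  new_trajectory(times, coords, beads, metadata)
}

#' @export
print.Trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames x %d beads (%s), t = %g..%g\n",
              d[1], d[2], x$metadata$kind %||% "unknown",
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `Trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Write / read a trajectory file
#'
#' Plain-text, versioned trajectory format: a JSON metadata header followed
#' by full-precision coordinate frames. Numeric arrays round-trip
#' bit-exactly. Reading a truncated or version-mismatched file is an error.
#'
#' @param traj A `Trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   the reconstructed `Trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  d <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#SLIDESCOPE-TRAJ 1", con)
  hdr <- jsonlite::toJSON(list(nframes = d[1], nbeads = d[2],
                               metadata = traj$metadata),
                          auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(paste("META", hdr), con)
  writeLines(paste("TIMES", paste(fmt_num(traj$times), collapse = " ")), con)
  for (f in seq_len(d[1])) {
    writeLines(sprintf("FRAME %d", f), con)
    m <- matrix(traj$coords[f, , ], d[2], 3)
    writeLines(paste(fmt_num(m[, 1]), fmt_num(m[, 2]), fmt_num(m[, 3])), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "#SLIDESCOPE-TRAJ 1") {
    stopf("'%s' is not a slidescope trajectory file (version 1)", path)
  }
  meta_raw <- jsonlite::fromJSON(sub("^META ", "", lines[2]),
                                 simplifyVector = TRUE)
  nf <- meta_raw$nframes; nb <- meta_raw$nbeads
  times <- as.numeric(strsplit(sub("^TIMES ", "", lines[3]), " ")[[1]])
  expected <- 3L + nf * (nb + 1L)
  if (length(lines) < expected || length(times) != nf) {
    stopf("truncated trajectory file: expected %d frames of %d beads",
          nf, nb)
  }
  coords <- array(NA_real_, c(nf, nb, 3))
  cur <- 4L
  for (f in seq_len(nf)) {
    if (lines[cur] != sprintf("FRAME %d", f)) {
      stopf("corrupt trajectory file at line %d", cur)
    }
    block <- lines[(cur + 1L):(cur + nb)]
    m <- matrix(as.numeric(unlist(strsplit(block, " ", fixed = TRUE))),
                nb, 3, byrow = TRUE)
    coords[f, , ] <- m
    cur <- cur + nb + 1L
  }
  new_trajectory(times, coords, beads = NULL, metadata = meta_raw$metadata)
}

#' Export a trajectory to XYZ format
#'
#' @param traj A `Trajectory`.
#' @param path Output path.
#' @param element Element symbol used for every bead (default "C").
#' @export
export_xyz <- function(traj, path, element = "C") {
  d <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(d[1])) {
    writeLines(c(as.character(d[2]),
                 sprintf("frame %d t=%g", f, traj$times[f])), con)
    m <- matrix(traj$coords[f, , ], d[2], 3)
    writeLines(sprintf("%s %.3f %.3f %.3f", element, m[, 1], m[, 2],
                       m[, 3]), con)
  }
  invisible(path)
}
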
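#' Simulation control parameters
#'
#' Reduced units: energy unit `epsilon = 1`, unit bead mass, time unit
#' tau. The default temperature (0.5) sits well below the folding
#' temperature of the narrow native wells, so the monomers stay intact
#' while the chains reorient and bind.
#'
#' @param dt integration time step, tau (default 0.002: the stiffest
#'   term, the k_b = 200 bond, has period ~0.44 tau, so ~220 steps per
#'   oscillation).
#' @param gamma Langevin friction, 1/tau (`0` gives NVE dynamics). The
#'   default 0.05 is underdamped, as is usual for structure-based
#'   models: inertial motion lets the chains approach and reorient on
#'   annealing-stage timescales.
#' @param temperature reduced temperature.
#' @param stride steps between recorded frames.
#' @return named list.
#' @export
sim_control <- function(dt = 2e-3, gamma = 0.05, temperature = 0.5,
                        stride = 100L) {
  stopifnot(dt > 0, gamma >= 0, temperature >= 0, stride >= 1)
  list(dt = dt, gamma = gamma, temperature = temperature,
       stride = as.integer(stride))
}

#' Forces and energy decomposition of a configuration
#'
#' Analytic gradients of every term in the topology. The energy
#' decomposition (`bond`, `angle`, `dihedral`, `contact`, `dca`,
#' `excluded`) sums to `total` exactly.
#'
#' @param X n x 3 coordinate matrix (Angstrom).
#' @param topology a `coev_topology`.
#' @return list with `forces` (n x 3) and named `energy` vector.
#' @export
compute_forces <- function(X, topology) {
  cpp_forces(X, topology$bonds, topology$angles, topology$dihedrals,
             topology$intra_contacts, topology$dca_contacts,
             topology$exclusions, topology$params$sigma_ex,
             topology$params$epsilon)
}

#' Integrate Langevin dynamics for a fixed number of steps
#'
#' BAOAB splitting with unit masses; `gamma = 0` reduces to velocity
#' Verlet. Deterministic for a given seed.
#'
#' @param X,V n x 3 coordinates and velocities (`V = NULL` starts at
#'   rest).
#' @param topology a `coev_topology`.
#' @param nsteps number of steps.
#' @param control a [sim_control()] list.
#' @param seed integer RNG seed for the thermostat noise.
#' @return list with final `X`, `V`, recorded `frames`
#'   (n x 3 x n_frames array), per-frame `energies` matrix and final
#'   `kinetic` energy.
#' @export
langevin_run <- function(X, topology, nsteps, control = sim_control(),
                         V = NULL, seed = 1L) {
  if (is.null(V)) V <- matrix(0, nrow(X), 3)
  cpp_run_md(X, V, topology$bonds, topology$angles, topology$dihedrals,
             topology$intra_contacts, topology$dca_contacts,
             topology$exclusions, topology$params$sigma_ex,
             topology$params$epsilon, control$dt, control$gamma,
             control$temperature, as.integer(nsteps), control$stride,
             as.integer(seed))
}

#' Run one annealing stage to convergence
#'
#' Integrates with the stage's restraint parameters until the monitored
#' series stabilises: the sliding-window standard deviation over
#' `window` recorded frames drops below `tol` times the window mean in
#' magnitude (or below the absolute floor `min_sd`, whichever is
#' larger -- a purely relative criterion can never fire once an RMSD
#' series hovers near zero), or `max_steps` is reached
#' (`converged = FALSE`). The monitored series is the RMSD to a native
#' reference when one is given (validation mode); otherwise the total
#' restraint energy, which is the observable available in blind
#' prediction.
#'
#' @param X,V coordinates and velocities carried into the stage.
#' @param topology a `coev_topology` (will be re-parameterised).
#' @param stage stage number or schedule record.
#' @param control a [sim_control()] list.
#' @param seed stage RNG seed.
#' @param native optional reference `ca_structure` (two chains) for the
#'   RMSD monitor.
#' @param min_sd absolute convergence floor for the windowed standard
#'   deviation (0.3: Angstrom for the RMSD monitor, epsilon for the
#'   energy monitor, both well under thermal fluctuation scales).
#' @return list: `X`, `V`, `frames` (list of n x 3 matrices),
#'   `energies` (data frame), `monitor` (numeric series), `converged`,
#'   `steps`.
#' @export
run_stage <- function(X, topology, stage, control = sim_control(),
                      seed = 1L, V = NULL, native = NULL,
                      min_sd = 0.3) {
  rec <- if (is.numeric(stage) && length(stage) == 1L)
    topology$schedule[stage, ] else stage
  topology <- set_stage(topology, rec)
  if (is.null(V)) V <- matrix(0, nrow(X), 3)

  window <- rec$window
  tol <- rec$tol
  max_steps <- rec$max_steps
  chunk_frames <- max(25L, window %/% 4L)
  chunk_steps <- chunk_frames * control$stride

  frames <- list()
  energies <- list()
  monitor <- numeric(0)
  steps <- 0L
  converged <- FALSE
  sub <- 0L

  while (steps < max_steps) {
    nst <- min(chunk_steps, max_steps - steps)
    sub <- sub + 1L
    res <- langevin_run(X, topology, nst, control, V = V,
                        seed = seed + sub)
    X <- res$X; V <- res$V
    steps <- steps + nst
    nf <- res$n_frames
    if (nf > 0L) {
      for (f in seq_len(nf)) frames[[length(frames) + 1L]] <-
          res$frames[, , f]
      energies[[length(energies) + 1L]] <-
        res$energies[seq_len(nf), , drop = FALSE]
      mon_new <- if (!is.null(native)) {
        vapply(seq_len(nf), function(f)
          dimer_rmsd_coords(res$frames[, , f], ca_coords(native),
                            topology$n_chain_a), numeric(1))
      } else {
        res$energies[seq_len(nf), "dca"]
      }
      monitor <- c(monitor, mon_new)
    }
    if (length(monitor) >= window) {
      tail_m <- monitor[(length(monitor) - window + 1L):length(monitor)]
      if (sd(tail_m) < max(tol * abs(mean(tail_m)), min_sd)) {
        converged <- TRUE
        break
      }
    }
  }
  list(X = X, V = V, frames = frames,
       energies = as.data.frame(do.call(rbind, energies)),
       monitor = monitor, converged = converged, steps = steps,
       stage = rec$stage)
}

#' Run the full 7-stage annealing binding protocol
#'
#' Executes the stages of the schedule sequentially, carrying
#' coordinates and velocities across stage boundaries (no
#' re-thermalisation) and updating the restraint parameters `(r0, A,
#' w)` between stages. A stage that hits its step cap without
#' stabilising is recorded as non-converged (warning) and the protocol
#' continues, matching the fixed 7-step design.
#'
#' @param initial a two-chain `ca_structure` starting pose (from
#'   [build_initial_pose()]) or an n x 3 coordinate matrix.
#' @param topology a `coev_topology`.
#' @param control a [sim_control()] list.
#' @param seed run seed; per-stage seeds are derived from it.
#' @param native optional native dimer (`ca_structure`) enabling the
#'   RMSD convergence monitor (validation mode).
#' @return object of class `coev_trajectory`: list with `frames` (list
#'   of n x 3 matrices), `energies` (data frame incl. `stage`),
#'   `monitor`, `stage_converged` (logical, length 7), `final_X`,
#'   `final_V`, `n_chain_a`, `control`, `seed`.
#' @export
run_annealing <- function(initial, topology, control = sim_control(),
                          seed = 1L, native = NULL) {
  X <- if (inherits(initial, "ca_structure")) ca_coords(initial)
       else as.matrix(initial)
  stopifnot(nrow(X) == topology$n)
  V <- NULL
  frames <- list()
  energies <- list()
  monitor <- numeric(0)
  conv <- logical(0)
  for (s in seq_len(nrow(topology$schedule))) {
    st <- run_stage(X, topology, s, control,
                    seed = derive_seed(seed, 100L + s), V = V,
                    native = native)
    X <- st$X; V <- st$V
    if (!st$converged)
      warning("stage ", s, " reached its step cap without stabilising")
    conv <- c(conv, st$converged)
    if (length(st$frames) > 0L) {
      st$energies$stage <- s
      frames <- c(frames, st$frames)
      energies[[length(energies) + 1L]] <- st$energies
      monitor <- c(monitor, st$monitor)
    }
  }
  structure(list(frames = frames,
                 energies = do.call(rbind, energies),
                 monitor = monitor, stage_converged = conv,
                 final_X = X, final_V = V,
                 n_chain_a = topology$n_chain_a,
                 control = control, seed = seed),
            class = "coev_trajectory")
}

#' @export
print.coev_trajectory <- function(x, ...) {
  cat("coev_trajectory: ", length(x$frames), " frames, ",
      sum(x$stage_converged), "/", length(x$stage_converged),
      " stages converged\n", sep = "")
  invisible(x)
}

#' Expand one run seed into per-module seeds
#'
#' Deterministic counter scheme: `(seed * 7919 + k) mod (2^31 - 1)`,
#' kept strictly positive so it is always a valid 32-bit R seed.
#'
#' @param seed base integer seed.
#' @param k counter.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) * 7919 + as.numeric(k)) %% 2147483647
  as.integer(s) + 1L
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL per recorded frame (optionally thinned), C-alpha ATOM
#' records with chain labels A/B.
#'
#' @param traj a `coev_trajectory`.
#' @param path output path.
#' @param thin keep every `thin`-th frame (default 1 = all).
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, thin = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  nA <- traj$n_chain_a
  sel <- seq(1L, length(traj$frames), by = thin)
  for (m in seq_along(sel)) {
    X <- traj$frames[[sel[m]]]
    writeLines(sprintf("MODEL     %4d", m), con)
    ch <- c(rep("A", nA), rep("B", nrow(X) - nA))
    resno <- c(seq_len(nA), seq_len(nrow(X) - nA))
    lines <- sprintf(
      "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(X)), ch, resno, X[, 1], X[, 2], X[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
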
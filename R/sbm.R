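#' Gaussian contact potential with excluded-volume core
#'
#' `V(r) = eps (sigma_ex / r)^12 - A eps exp(-(r - r0)^2 / (2 w^2))`:
#' a single-basin attractive Gaussian well of amplitude `A` and width
#' `w` centred at the equilibrium distance `r0`, riding on an `r^-12`
#' repulsive core. For `r0` well above `sigma_ex` the minimum sits near
#' `r0` with depth close to `-A eps`.
#'
#' @param r distance(s), Angstrom.
#' @param r0 equilibrium distance, Angstrom.
#' @param A well amplitude (dimensionless multiple of `epsilon`).
#' @param w Gaussian width (standard deviation), Angstrom.
#' @param sigma_ex excluded-volume diameter, Angstrom.
#' @param epsilon energy unit.
#' @return energy value(s), same length as `r`.
#' @export
gaussian_contact_energy <- function(r, r0, A = 1, w = 0.5,
                                    sigma_ex = 4, epsilon = 1) {
  stopifnot(all(r > 0), w > 0)
  epsilon * (sigma_ex / r)^12 -
    A * epsilon * exp(-(r - r0)^2 / (2 * w^2))
}

#' Default 7-stage annealing schedule
#'
#' The binding protocol modulates the inter-chain Gaussian restraints
#' over seven stages: the equilibrium distance `r0` decreases from the
#' initial 50 Angstrom separation down to the typical native contact
#' distance of 8 Angstrom, the width `w` narrows to sharpen the target
#' basin, and the amplitude `A` ramps up during the last three stages to
#' lock the complex in. All values can be overridden.
#'
#' @param r0 per-stage equilibrium distances (7 values, strictly
#'   decreasing).
#' @param A per-stage amplitudes (non-decreasing; increases confined to
#'   the last three stages by default).
#' @param w per-stage Gaussian widths, Angstrom.
#' @param max_steps integration step cap per stage.
#' @param window convergence window, in recorded frames.
#' @param tol relative sliding-window standard-deviation tolerance.
#' @return object of class `coev_schedule`: data frame with one row per
#'   stage.
#' @export
default_schedule <- function(r0 = c(50, 38, 28, 20, 14, 10, 8),
                             A = c(1, 1, 1, 1, 2, 3, 4),
                             w = c(10, 8, 6, 5, 4, 3, 1.5),
                             max_steps = 100000L,
                             window = 200L,
                             tol = 0.02) {
  sched <- data.frame(stage = seq_along(r0), r0 = r0, A = A, w = w,
                      max_steps = as.integer(max_steps),
                      window = as.integer(window), tol = tol)
  validate_schedule(sched)
}

validate_schedule <- function(sched) {
  stopifnot(nrow(sched) == 7L,
            all(diff(sched$r0) < 0),
            all(sched$w > 0), all(sched$A > 0),
            all(diff(sched$A) >= 0))
  class(sched) <- c("coev_schedule", "data.frame")
  sched
}

#' Default force-field parameters for the C-alpha model
#'
#' Reduced units: the energy unit `epsilon` is 1, lengths in Angstrom.
#' `k_d` emitted into topologies is `kd_factor` times the base dihedral
#' constant: stiffened dihedrals keep each monomer near-rigid while the
#' chains reorient and bind.
#'
#' @return named list of parameters.
#' @export
sbm_params <- function() {
  list(k_b = 200,        # bond, eps/A^2
       k_a = 40,         # angle, eps/rad^2
       k_d_base = 1,     # dihedral base constant, eps
       kd_factor = 100,  # monomer-rigidity stiffening of dihedrals
       sigma_ex = 4,     # excluded-volume diameter, A
       epsilon = 1,
       contact_cutoff = 8,  # native contact definition, A
       contact_min_sep = 4, # |i-j| >= 4 for intra-chain contacts
       A_intra = 1,      # native-well amplitude
       w_intra = 0.5)    # native-well width, A (narrow: near-rigid)
}

#' Build the coarse-grained structure-based topology for docking
#'
#' One bead per residue. Bonded terms (bonds, angles, dihedrals) take
#' their equilibrium values from each monomer's native structure;
#' intra-chain native contacts (C-alpha map at 8 Angstrom, sequence
#' separation >= 4) become narrow Gaussian wells centred at their native
#' distances; the DCA-derived inter-chain restraints become Gaussian
#' wells whose `(r0, A, w)` follow the annealing schedule (initialised
#' from stage 1). The emitted dihedral constant is
#' `kd_factor * k_d_base`.
#'
#' @param monomerA,monomerB single-chain `ca_structure`s (for a
#'   homodimer, two copies of the same monomer).
#' @param restraints a `coev_restraints`; residue indices are 0-based
#'   within each monomer.
#' @param params list from [sbm_params()] (entries can be overridden).
#' @param schedule a `coev_schedule`; stage 1 initialises the restraint
#'   wells.
#' @return object of class `coev_topology`.
#' @export
build_topology <- function(monomerA, monomerB, restraints,
                           params = sbm_params(),
                           schedule = default_schedule()) {
  XA <- ca_coords(monomerA)
  XB <- ca_coords(monomerB)
  nA <- nrow(XA); nB <- nrow(XB)
  r <- restraints$interchain_restraints
  bad <- r$res_a < 0 | r$res_a >= nA | r$res_b < 0 | r$res_b >= nB
  if (any(bad))
    stop("restraints reference missing residues: ",
         paste(sprintf("(%d,%d)", r$res_a[bad], r$res_b[bad]),
               collapse = " "))

  chain_terms <- function(X, off) {
    n <- nrow(X)
    bonds <- angles <- dihedrals <- NULL
    if (n >= 2) {
      i <- seq_len(n - 1)
      bonds <- cbind(i - 1 + off, i + off,
                     sqrt(rowSums((X[i, , drop = FALSE] -
                                   X[i + 1, , drop = FALSE])^2)),
                     params$k_b)
    }
    if (n >= 3) {
      i <- seq_len(n - 2)
      th <- vapply(i, function(k) bead_angle(X[k, ], X[k + 1, ], X[k + 2, ]),
                   numeric(1))
      angles <- cbind(i - 1 + off, i + off, i + 1 + off, th, params$k_a)
    }
    if (n >= 4) {
      i <- seq_len(n - 3)
      ph <- vapply(i, function(k)
        bead_dihedral(X[k, ], X[k + 1, ], X[k + 2, ], X[k + 3, ]),
        numeric(1))
      dihedrals <- cbind(i - 1 + off, i + off, i + 1 + off, i + 2 + off,
                         ph, params$kd_factor * params$k_d_base)
    }
    list(bonds = bonds, angles = angles, dihedrals = dihedrals)
  }

  tA <- chain_terms(XA, 0L)
  tB <- chain_terms(XB, nA)

  intra_wells <- function(s, X, off) {
    cm <- contact_map(s, cutoff = params$contact_cutoff,
                      min_sep = params$contact_min_sep)
    if (nrow(cm$pairs) == 0L)
      return(matrix(numeric(0), 0, 5))
    cbind(cm$pairs[, 1] + off, cm$pairs[, 2] + off, cm$dist,
          params$A_intra, params$w_intra)
  }
  cnA <- intra_wells(monomerA, XA, 0L)
  cnB <- intra_wells(monomerB, XB, nA)
  cn <- rbind(cnA, cnB)

  st1 <- schedule[1, ]
  cd <- if (nrow(r) == 0L) matrix(numeric(0), 0, 5)
        else cbind(r$res_a, r$res_b + nA, st1$r0, st1$A, st1$w)

  n <- nA + nB
  excl <- rbind(
    # short-range same-chain neighbours are covered by bonded terms
    do.call(rbind, lapply(1:3, function(d) {
      iA <- seq_len(max(nA - d, 0)); iB <- seq_len(max(nB - d, 0))
      rbind(cbind(iA - 1L, iA - 1L + d),
            cbind(iB - 1L + nA, iB - 1L + d + nA))
    })),
    cn[, 1:2, drop = FALSE],
    cd[, 1:2, drop = FALSE])
  storage.mode(excl) <- "integer"
  excl <- unique(excl)

  or_empty <- function(m, k) if (is.null(m)) matrix(numeric(0), 0, k)
                             else unname(m)
  structure(list(n = n, n_chain_a = nA,
                 chain = rep(c("A", "B"), c(nA, nB)),
                 bonds = or_empty(tA$bonds %+rbind% tB$bonds, 4),
                 angles = or_empty(tA$angles %+rbind% tB$angles, 5),
                 dihedrals = or_empty(tA$dihedrals %+rbind% tB$dihedrals, 6),
                 intra_contacts = unname(cn),
                 dca_contacts = unname(cd),
                 exclusions = unname(excl),
                 params = params, schedule = schedule,
                 native = rbind(XA, XB)),
            class = "coev_topology")
}

`%+rbind%` <- function(a, b) {
  if (is.null(a)) b else if (is.null(b)) a else rbind(a, b)
}

bead_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, ct)))
}

bead_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Load one annealing stage into the restraint wells
#'
#' @param topology a `coev_topology`.
#' @param stage stage number (1..7) or a one-row schedule record.
#' @return the topology with `dca_contacts` re-parameterised.
#' @export
set_stage <- function(topology, stage) {
  rec <- if (is.numeric(stage) && length(stage) == 1L)
    topology$schedule[stage, ] else stage
  if (nrow(topology$dca_contacts) > 0L) {
    topology$dca_contacts[, 3] <- rec$r0
    topology$dca_contacts[, 4] <- rec$A
    topology$dca_contacts[, 5] <- rec$w
  }
  topology$stage <- rec$stage
  topology
}

#' @export
print.coev_topology <- function(x, ...) {
  cat("coev_topology: ", x$n, " beads (", x$n_chain_a, "+",
      x$n - x$n_chain_a, "), ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$dihedrals), " dihedrals, ",
      nrow(x$intra_contacts), " native wells, ",
      nrow(x$dca_contacts), " DCA restraints\n", sep = "")
  invisible(x)
}

#' Serialize a topology to JSON
#'
#' Documented schema: `particles` (count, chain labels), `bonds`,
#' `angles`, `dihedrals`, `intra_contacts`, `dca_contacts` (plain
#' arrays, 0-based indices), `exclusions`, `params`, `schedule`. Output
#' is deterministic: identical inputs produce byte-identical files.
#'
#' @param topology a `coev_topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(
    particles = list(n = topology$n, chain = topology$chain),
    bonds = topology$bonds, angles = topology$angles,
    dihedrals = topology$dihedrals,
    intra_contacts = topology$intra_contacts,
    dca_contacts = topology$dca_contacts,
    exclusions = topology$exclusions,
    params = topology$params,
    schedule = as.data.frame(topology$schedule))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
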
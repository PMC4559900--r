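#' Optimal least-squares superposition (Kabsch)
#'
#' Rigid-body superposition of `mobile` onto `reference`: proper
#' rotation (determinant +1) and translation minimising the
#' root-mean-square residual.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (3-vector),
#'   `rmsd`, and `transform(X)` applying the fit to new coordinates.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(nrow(mobile) == nrow(reference), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2L || qr(B)$rank < 2L)
    stop("degenerate (collinear) point set: superposition undefined")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  translation <- cr - as.vector(R %*% cm)
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = function(X) sweep(as.matrix(X) %*% t(R), 2,
                                     translation, "+"))
}

rmsd_after_fit <- function(mobile, reference) {
  superpose(mobile, reference)$rmsd
}

## RMSD between two dimer coordinate sets with chain-swap handling;
## nA beads of chain A first. Used per-frame, so kept lean.
dimer_rmsd_coords <- function(pred, native, nA) {
  n <- nrow(pred)
  r1 <- rmsd_after_fit(pred, native)
  nB <- n - nA
  if (nA == nB) {
    swap <- c((nA + 1):n, 1:nA)
    r2 <- rmsd_after_fit(pred[swap, , drop = FALSE], native)
    min(r1, r2)
  } else r1
}

#' Whole-complex dimer RMSD with chain-swap symmetry
#'
#' C-alpha RMSD after optimal superposition, computed for both chain
#' assignments (A to A, B to B) and (A to B, B to A) when the chains
#' have equal length -- the labelling of identical chains is arbitrary
#' for a homodimer -- and returning the minimum.
#'
#' @param pred,native two-chain `ca_structure`s with matching per-chain
#'   residue counts.
#' @return RMSD in Angstrom.
#' @export
dimer_rmsd <- function(pred, native) {
  np <- table(factor(pred$residues$chain, levels = pred$chains))
  nn <- table(factor(native$residues$chain, levels = native$chains))
  if (!all(as.integer(np) == as.integer(nn)))
    stop("chain length mismatch between prediction and reference")
  dimer_rmsd_coords(ca_coords(pred), ca_coords(native),
                    as.integer(np)[1])
}

#' Interface residues of a native dimer
#'
#' Residues having any cross-chain C-alpha neighbour within
#' `interface_cutoff`.
#'
#' @param native a two-chain `ca_structure`.
#' @param interface_cutoff Angstrom (default 10, CAPRI-style).
#' @return integer vector of 0-based residue indices (whole-complex
#'   numbering).
#' @export
interface_residues <- function(native, interface_cutoff = 10) {
  X <- ca_coords(native)
  ch <- native$residues$chain
  D <- as.matrix(stats::dist(X))
  cross <- outer(ch, ch, "!=")
  idx <- which(apply(D < interface_cutoff & cross, 1, any))
  sort(idx - 1L)
}

#' Interfacial RMSD (iRMSD)
#'
#' RMSD over the native interface residues only (cross-chain C-alpha
#' within `interface_cutoff`, 10 Angstrom by default), superposed on
#' those residues, minimised over the homodimer chain swap.
#'
#' @inheritParams dimer_rmsd
#' @param interface_cutoff interface definition cutoff, Angstrom.
#' @return iRMSD in Angstrom.
#' @export
interfacial_rmsd <- function(pred, native, interface_cutoff = 10) {
  irmsd_coords(ca_coords(pred), native, interface_cutoff)
}

irmsd_coords <- function(predX, native, interface_cutoff = 10) {
  iface <- interface_residues(native, interface_cutoff)
  if (length(iface) == 0L)
    stop("no inter-chain contacts within ", interface_cutoff,
         " Angstrom: empty interface")
  natX <- ca_coords(native)
  if (nrow(predX) != nrow(natX))
    stop("chain length mismatch between prediction and reference")
  ch <- native$residues$chain
  nA <- sum(ch == ch[1])
  n <- nrow(natX)
  sel <- iface + 1L
  r1 <- rmsd_after_fit(predX[sel, , drop = FALSE],
                       natX[sel, , drop = FALSE])
  if (nA == n - nA) {
    swap <- c((nA + 1):n, 1:nA)
    r2 <- rmsd_after_fit(predX[swap, , drop = FALSE][sel, , drop = FALSE],
                         natX[sel, , drop = FALSE])
    min(r1, r2)
  } else r1
}

#' Score an annealing trajectory against a native dimer
#'
#' Per-frame dimer RMSD and iRMSD; the best complex is the
#' minimum-RMSD frame over the whole trajectory, and the final-stage
#' mean is taken over the frames of the last stage. Contact recovery is
#' the fraction of native inter-chain contacts (8 Angstrom) reproduced
#' within 8 Angstrom in the best frame.
#'
#' @param traj a `coev_trajectory`.
#' @param native the native dimer (`ca_structure`), chain sizes
#'   matching the topology.
#' @param interface_cutoff iRMSD interface cutoff, Angstrom.
#' @param contact_cutoff native contact cutoff for recovery, Angstrom.
#' @return object of class `coev_report`: list with `rmsd_best`,
#'   `best_frame`, `rmsd_final_stage_mean`, `irmsd_best`,
#'   `irmsd_at_best`, `rmsd_series`, `irmsd_series`,
#'   `interface_residues`, `contact_recovery`.
#' @export
evaluate_trajectory <- function(traj, native, interface_cutoff = 10,
                                contact_cutoff = 8) {
  natX <- ca_coords(native)
  nA <- traj$n_chain_a
  rmsd_series <- vapply(traj$frames, dimer_rmsd_coords, numeric(1),
                        native = natX, nA = nA)
  irmsd_series <- vapply(traj$frames, irmsd_coords, numeric(1),
                         native = native,
                         interface_cutoff = interface_cutoff)
  best <- which.min(rmsd_series)
  last_stage <- max(traj$energies$stage)
  in_last <- traj$energies$stage == last_stage

  cmn <- contact_map(native, cutoff = contact_cutoff)
  inter <- split_contacts_by_chain(cmn)$inter
  bestX <- traj$frames[[best]]
  if (nrow(inter) > 0L) {
    rec_of <- function(X) {
      d <- sqrt(rowSums((X[inter[, 1] + 1L, , drop = FALSE] -
                         X[inter[, 2] + 1L, , drop = FALSE])^2))
      mean(d < contact_cutoff)
    }
    recovery <- rec_of(bestX)
    n <- nrow(bestX)
    if (nA == n - nA) { # identical chains: labels are arbitrary
      swap <- c((nA + 1):n, 1:nA)
      recovery <- max(recovery, rec_of(bestX[swap, , drop = FALSE]))
    }
  } else recovery <- NA_real_

  structure(list(
    rmsd_best = min(rmsd_series), best_frame = best,
    rmsd_final_stage_mean = mean(rmsd_series[in_last]),
    irmsd_best = min(irmsd_series),
    irmsd_at_best = irmsd_series[best],
    rmsd_series = rmsd_series, irmsd_series = irmsd_series,
    interface_residues = interface_residues(native, interface_cutoff),
    contact_recovery = recovery), class = "coev_report")
}

#' @export
print.coev_report <- function(x, ...) {
  cat("coev_report: RMSD_best = ", round(x$rmsd_best, 2),
      " A (frame ", x$best_frame, "), final-stage mean = ",
      round(x$rmsd_final_stage_mean, 2), " A, iRMSD_best = ",
      round(x$irmsd_best, 2), " A, contact recovery = ",
      round(x$contact_recovery, 2), "\n", sep = "")
  invisible(x)
}

#' Contact-map comparison table for a predicted complex
#'
#' Long-format table of native and predicted contact sets (monomeric =
#' intra-chain, dimeric = inter-chain, both at 8 Angstrom) plus the
#' restraint overlay, ready for plotting; also reports the restraint
#' true-positive fraction (restraints present among native dimeric
#' contacts).
#'
#' @param pred_best predicted complex (`ca_structure` or n x 3 matrix
#'   with `n_chain_a` attr taken from `native`).
#' @param native native dimer `ca_structure`.
#' @param restraints optional `coev_restraints` to overlay.
#' @param cutoff contact cutoff, Angstrom.
#' @return list with `table` (data frame `set`, `i`, `j`; indices
#'   0-based within a single chain for intra sets, chain-local for
#'   inter sets) and `restraint_tp_fraction`.
#' @export
contact_map_report <- function(pred_best, native, restraints = NULL,
                               cutoff = 8) {
  ch <- native$residues$chain
  nA <- sum(ch == ch[1])
  predX <- if (inherits(pred_best, "ca_structure")) ca_coords(pred_best)
           else as.matrix(pred_best)

  sets <- function(X, label) {
    D <- as.matrix(stats::dist(X))
    idx <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
    i <- idx[, 1] - 1L; j <- idx[, 2] - 1L
    intra <- (i < nA & j < nA) | (i >= nA & j >= nA)
    loc <- function(k) ifelse(k >= nA, k - nA, k)
    rbind(
      if (any(intra)) data.frame(set = paste0(label, "_monomeric"),
                                 i = loc(i[intra]), j = loc(j[intra])),
      if (any(!intra)) data.frame(set = paste0(label, "_dimeric"),
                                  i = loc(i[!intra]), j = loc(j[!intra])))
  }
  tab <- rbind(sets(ca_coords(native), "native"),
               sets(predX, "predicted"))

  tp <- NA_real_
  if (!is.null(restraints) && nrow(restraints$pairs) > 0L) {
    nat <- tab[tab$set == "native_dimeric", , drop = FALSE]
    natkey <- c(paste(nat$i, nat$j, sep = "|"),
                paste(nat$j, nat$i, sep = "|"))
    rkey <- paste(restraints$pairs$i, restraints$pairs$j, sep = "|")
    tp <- mean(rkey %in% natkey)
    tab <- rbind(tab, data.frame(set = "restraint",
                                 i = restraints$pairs$i,
                                 j = restraints$pairs$j))
  }
  list(table = tab, restraint_tp_fraction = tp)
}
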
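#' Construct a sparse-coupling Potts model
#'
#' A q-state Potts model over L positions with single-site fields
#' `h_i(a)` and couplings `J_ij(a,b)` on a sparse set of planted pairs.
#' Energy convention: `E(s) = -sum_i h_i(s_i) - sum_(ij) J_ij(s_i,
#' s_j)`, sampled at inverse temperature `beta`.
#'
#' @param L number of positions.
#' @param q number of states.
#' @param pairs K x 2 matrix of 0-based planted position pairs (i < j).
#' @param J list of K q x q coupling matrices (or a single matrix
#'   recycled for all pairs).
#' @param h L x q field matrix (default all zero).
#' @param beta inverse temperature (default 1).
#' @return object of class `coev_potts`.
#' @export
potts_model <- function(L, q, pairs = matrix(integer(0), 0, 2),
                        J = list(), h = matrix(0, L, q), beta = 1) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0L) {
    stopifnot(all(pairs[, 1] < pairs[, 2]),
              all(pairs >= 0L), all(pairs < L))
    if (is.matrix(J)) J <- replicate(nrow(pairs), J, simplify = FALSE)
    stopifnot(length(J) == nrow(pairs))
    for (Jk in J) stopifnot(all(dim(Jk) == c(q, q)))
  }
  stopifnot(all(dim(h) == c(L, q)), beta >= 0)
  structure(list(L = as.integer(L), q = as.integer(q), pairs = pairs,
                 J = J, h = h, beta = beta),
            class = "coev_potts")
}

#' @export
print.coev_potts <- function(x, ...) {
  cat("coev_potts: L = ", x$L, ", q = ", x$q, ", ",
      nrow(x$pairs), " planted pair(s), beta = ", x$beta, "\n", sep = "")
  invisible(x)
}

#' Sample an alignment from a Potts model
#'
#' Single-site Gibbs sampling of one long chain: `burn_in` full sweeps
#' of equilibration, then one sequence recorded every `thin` sweeps.
#' Deterministic for a given seed. The planted pair list travels with
#' the returned alignment as metadata.
#'
#' @param model a `coev_potts`.
#' @param M number of sequences to draw.
#' @param burn_in equilibration sweeps (default 200).
#' @param thin sweeps between recorded sequences (default 10).
#' @param seed integer RNG seed.
#' @return a `coev_msa` with `q = model$q` and
#'   `metadata$planted_pairs`.
#' @export
sample_potts <- function(model, M, burn_in = 200L, thin = 10L,
                         seed = 1L) {
  stopifnot(M >= 1)
  mat <- cpp_sample_potts(model$L, model$q, model$h, model$pairs,
                          model$J, model$beta, as.integer(M),
                          as.integer(burn_in), as.integer(thin),
                          as.integer(seed))
  rownames(mat) <- sprintf("sample_%04d", seq_len(M))
  new_msa(mat, q = model$q,
          metadata = list(planted_pairs = model$pairs, seed = seed))
}

#' Build an idealised two-chain toy dimer with a known interface
#'
#' Chain A is an idealised C-alpha helix (rise 1.5 Angstrom, radius 2.3
#' Angstrom, 100-degree twist per residue). Chain B is a copy rotated
#' 180 degrees about the helix axis and packed laterally so that
#' exactly `interface_size` cross-chain C-alpha pairs fall under 8
#' Angstrom; the seed picks the order in which candidate azimuthal
#' twists of chain B are tried. Every bead carries one dummy full-atom
#' sphere (radius 1.7 Angstrom) so the SASA machinery and the
#' 50-percent exposure filter can be exercised: mid-chain beads are
#' partially buried by their helical neighbours, termini and
#' protruding beads exposed, giving the exposure filter a nontrivial
#' bipartition.
#'
#' @param n beads per chain (>= 10).
#' @param interface_size exact number of cross-chain contacts at 8
#'   Angstrom.
#' @param seed integer seed (tie-break order of packings only).
#' @return object of class `coev_toy_dimer`: a two-chain
#'   `ca_structure` in `structure`, plus `interface` (matrix of 0-based
#'   chain-local pairs `i_a`, `j_b`), `n` and the packing parameters.
#' @export
build_toy_dimer <- function(n = 30L, interface_size = 8L, seed = 1L) {
  stopifnot(n >= 10L, interface_size >= 1L, interface_size <= n)
  rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
  t <- seq_len(n) - 1L
  XA <- cbind(radius * cos(t * twist), radius * sin(t * twist),
              rise * t)

  set.seed(seed)
  twists <- sample(seq(0, 350, by = 10)) * pi / 180
  found <- NULL
  for (tw in twists) {
    # anti-parallel packing: flipping about x reverses the helix
    # direction, so facing beads are sequence-distant (i + j ~ n) and
    # the mapped couplings are not monomeric contacts
    XB0 <- XA %*% t(rotation_matrix(c(1, 0, 0), pi))
    XB0 <- XB0 %*% t(rotation_matrix(c(0, 0, 1), tw))
    XB0 <- sweep(XB0, 2, c(0, 0, rise * (n - 1)), "+")
    for (d in seq(16, 5, by = -0.005)) {
      XB <- sweep(XB0, 2, c(d, 0, 0), "+")
      D <- sqrt(outer(rowSums(XA^2), rep(1, n)) +
                outer(rep(1, n), rowSums(XB^2)) -
                2 * XA %*% t(XB))
      cnt <- sum(D < 8)
      if (min(D) < 3.5) break # steric clash: stop approaching
      if (cnt == interface_size) { found <- list(XB = XB, D = D, d = d,
                                                 tw = tw); break }
      if (cnt > interface_size) break # overshot the requested count
    }
    if (!is.null(found)) break
  }
  if (is.null(found))
    stop("infeasible packing: no separation yields exactly ",
         interface_size, " cross-chain contacts")

  XB <- found$XB
  iface <- which(found$D < 8, arr.ind = TRUE) - 1L
  colnames(iface) <- c("i_a", "j_b")

  residues <- data.frame(
    chain = rep(c("A", "B"), each = n),
    resno = rep(seq_len(n), 2),
    resid = "UNK", aa = "X",
    x = c(XA[, 1], XB[, 1]), y = c(XA[, 2], XB[, 2]),
    z = c(XA[, 3], XB[, 3]), stringsAsFactors = FALSE)
  atoms <- data.frame(
    chain = residues$chain, resno = residues$resno, resid = "UNK",
    elety = "CA", element = "C",
    x = residues$x, y = residues$y, z = residues$z,
    radius = 1.7, stringsAsFactors = FALSE)
  s <- new_ca_structure(residues, atoms)
  structure(list(structure = s, interface = iface, n = as.integer(n),
                 separation = found$d, twist = found$tw, seed = seed),
            class = "coev_toy_dimer")
}

#' @export
print.coev_toy_dimer <- function(x, ...) {
  cat("coev_toy_dimer: 2 x ", x$n, " beads, ", nrow(x$interface),
      " interface contacts\n", sep = "")
  invisible(x)
}

#' Plant interface couplings of a toy dimer into a Potts model
#'
#' Maps the dimer's cross-chain contact pairs `(i_A, j_B)` to
#' single-chain position pairs `(min(i, j), max(i, j))` -- the
#' homodimer symmetry makes both chains share one sequence -- and puts
#' a diagonal-favouring coupling `J(a, a) = J0` on each distinct pair.
#' Mirrored self-pairs (`i = j`) carry no detectable covariation signal
#' and are skipped. Sampling from the resulting model and running the
#' coupling-inference pipeline should recover the interface.
#'
#' @param dimer a `coev_toy_dimer`.
#' @param q alphabet size (default 8).
#' @param beta inverse temperature (default 2: a strong, clearly
#'   detectable signal).
#' @param J0 diagonal coupling strength (default 1).
#' @return a `coev_potts` whose planted pairs are the mapped interface.
#' @export
plant_interface_couplings <- function(dimer, q = 8L, beta = 2, J0 = 1) {
  iface <- dimer$interface
  if (nrow(iface) == 0L) stop("toy dimer has an empty interface")
  i <- pmin(iface[, 1], iface[, 2])
  j <- pmax(iface[, 1], iface[, 2])
  keep <- i != j
  pr <- unique(cbind(i[keep], j[keep]))
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  J <- diag(J0, q)
  potts_model(L = dimer$n, q = q, pairs = pr, J = J, beta = beta)
}

#' Write a toy fixture set to disk in pipeline-ready formats
#'
#' Emits the sampled alignment as FASTA (states rendered as amino-acid
#' letters), both structures as PDB, and the interface truth table as
#' TSV, so tests exercise the same I/O paths as real data.
#'
#' @param dimer a `coev_toy_dimer`.
#' @param msa optional `coev_msa` to write alongside.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_toy_fixture <- function(dimer, msa = NULL, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$dimer_pdb <- file.path(dir, "toy_dimer.pdb")
  write_pose_pdb(dimer$structure, paths$dimer_pdb)
  paths$interface_tsv <- file.path(dir, "interface.tsv")
  write.table(as.data.frame(dimer$interface), paths$interface_tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(msa)) {
    paths$alignment <- file.path(dir, "alignment.fasta")
    letters20 <- AA_ALPHABET1[-1]
    lines <- character(0)
    for (s in seq_len(nrow(msa$sequences))) {
      lines <- c(lines, paste0(">", rownames(msa$sequences)[s]),
                 paste(letters20[msa$sequences[s, ] + 1L],
                       collapse = ""))
    }
    writeLines(lines, paths$alignment)
  }
  paths
}
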
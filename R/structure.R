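#' Read a protein structure as a C-alpha model
#'
#' Reads ATOM records from a PDB file via `bio3d`, keeping the first
#' model only. Alternate locations are resolved by highest occupancy,
#' then first occurrence; heteroatoms and waters are dropped. Residues
#' without a C-alpha atom are dropped with a warning. Full-atom
#' coordinates are retained for solvent-accessibility calculations.
#'
#' @param path path to a PDB file.
#' @param chain_selection optional character vector of chain identifiers;
#'   default all protein chains.
#' @return an object of class `ca_structure`; see [new_ca_structure()].
#' @export
read_pdb <- function(path, chain_selection = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain_selection)) {
    missing_ch <- setdiff(chain_selection, unique(at$chain))
    if (length(missing_ch) > 0L)
      stop("requested chain(s) not present: ",
           paste(missing_ch, collapse = ", "))
    at <- at[at$chain %in% chain_selection, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no protein atoms in ", path)

  # resolve altlocs: within (chain, resno, insert, atom name) keep the
  # highest-occupancy record, first on ties
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "|")), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno), ,
           drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  uk <- unique(rkey)
  has_ca <- vapply(uk, function(k)
    any(at$elety[rkey == k] == "CA"), logical(1))
  if (any(!has_ca)) {
    warning(sum(!has_ca), " residue(s) without a C-alpha dropped")
    keep <- rkey %in% uk[has_ca]
    at <- at[keep, , drop = FALSE]
    rkey <- rkey[keep]
  }
  if (nrow(at) == 0L) stop("no residues with C-alpha atoms in ", path)

  ca <- at[at$elety == "CA", , drop = FALSE]
  aa <- unname(AA_3TO1[ca$resid])
  aa[is.na(aa)] <- "X"
  residues <- data.frame(chain = ca$chain, resno = ca$resno,
                         resid = ca$resid, aa = aa,
                         x = ca$x, y = ca$y, z = ca$z,
                         stringsAsFactors = FALSE)
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resid = at$resid, elety = at$elety,
                      element = at$elesy, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  new_ca_structure(residues, atoms)
}

#' Construct a C-alpha structure object
#'
#' @param residues data frame with columns `chain`, `resno`, `resid`,
#'   `aa` (one-letter), `x`, `y`, `z` (C-alpha coordinates, Angstrom).
#' @param atoms optional full-atom data frame (`chain`, `resno`, `resid`,
#'   `elety`, `element`, `x`, `y`, `z`, optionally `radius`); needed for
#'   SASA.
#' @return object of class `ca_structure` with fields `residues`,
#'   `atoms`, `chains`.
#' @export
new_ca_structure <- function(residues, atoms = NULL) {
  stopifnot(nrow(residues) >= 2L,
            all(is.finite(as.matrix(residues[, c("x", "y", "z")]))))
  structure(list(residues = residues, atoms = atoms,
                 chains = unique(residues$chain)),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat("ca_structure: ", nrow(x$residues), " residues, chains ",
      paste(x$chains, collapse = ", "),
      if (!is.null(x$atoms)) paste0(" (", nrow(x$atoms), " atoms)"),
      "\n", sep = "")
  invisible(x)
}

#' C-alpha coordinate matrix of a structure
#'
#' @param s a `ca_structure`.
#' @param chain optional chain to subset.
#' @return n x 3 numeric matrix.
#' @export
ca_coords <- function(s, chain = NULL) {
  r <- s$residues
  if (!is.null(chain)) r <- r[r$chain %in% chain, , drop = FALSE]
  as.matrix(r[, c("x", "y", "z")])
}

#' One-letter sequence of a structure chain
#' @param s a `ca_structure`.
#' @param chain chain identifier; default the first chain.
#' @return single string.
#' @export
structure_sequence <- function(s, chain = s$chains[1]) {
  paste(s$residues$aa[s$residues$chain == chain], collapse = "")
}

#' C-alpha contact map
#'
#' Residue pairs `(i, j)`, `i < j`, whose C-alpha distance is strictly
#' below `cutoff` (strict inequality at the boundary, for
#' reproducibility). Indices are 0-based positions in the residue table
#' of `s` (both chains included if present).
#'
#' @param s a `ca_structure`.
#' @param cutoff distance cutoff in Angstrom (default 8).
#' @param min_sep minimum index separation (default 1 = exclude
#'   self-pairs only).
#' @return object of class `coev_contact_map`: list with `n`, `pairs`
#'   (two-column 0-based integer matrix), `dist`, `cutoff`, `chain`
#'   (per-residue chain labels).
#' @export
contact_map <- function(s, cutoff = 8, min_sep = 1L) {
  stopifnot(cutoff > 0)
  X <- ca_coords(s)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  idx <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    keep <- (idx[, 2] - idx[, 1]) >= min_sep
    idx <- idx[keep, , drop = FALSE]
  }
  structure(list(n = n,
                 pairs = cbind(i = idx[, 1] - 1L, j = idx[, 2] - 1L),
                 dist = D[idx],
                 cutoff = cutoff,
                 chain = s$residues$chain),
            class = "coev_contact_map")
}

#' @export
print.coev_contact_map <- function(x, ...) {
  cat("coev_contact_map: ", nrow(x$pairs), " pairs of ", x$n,
      " residues at < ", x$cutoff, " A\n", sep = "")
  invisible(x)
}

#' Split a contact map into intra- and inter-chain parts
#' @param cm a `coev_contact_map` built from a multi-chain structure.
#' @return list with `intra` and `inter` pair matrices (0-based).
#' @export
split_contacts_by_chain <- function(cm) {
  ch_i <- cm$chain[cm$pairs[, 1] + 1L]
  ch_j <- cm$chain[cm$pairs[, 2] + 1L]
  list(intra = cm$pairs[ch_i == ch_j, , drop = FALSE],
       inter = cm$pairs[ch_i != ch_j, , drop = FALSE])
}

#' Write a contact map as TSV
#' @param cm a `coev_contact_map`.
#' @param path output path; columns `i`, `j`, `distance` (0-based).
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  df <- data.frame(i = cm$pairs[, 1], j = cm$pairs[, 2],
                   distance = cm$dist)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (normalised internally).
#' @param angle rotation angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  c_ * diag(3) + s_ * ux + (1 - c_) * tcrossprod(u)
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

transform_structure <- function(s, R, t) {
  rot <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + t[1]; df$y <- xyz[, 2] + t[2]; df$z <- xyz[, 3] + t[3]
    df
  }
  s$residues <- rot(s$residues)
  if (!is.null(s$atoms)) s$atoms <- rot(s$atoms)
  s
}

#' Generate a symmetry mate of a monomer
#'
#' Appends a second chain whose coordinates are the monomer's
#' transformed by a proper rotation and a translation, e.g. a
#' crystallographic symmetry operation.
#'
#' @param s a single-chain `ca_structure`.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation 3-vector (Angstrom).
#' @param new_chain chain label for the mate; default the first unused
#'   letter.
#' @return two-chain `ca_structure`.
#' @export
make_symmetry_mate <- function(s, rotation, translation,
                               new_chain = NULL) {
  if (!is_rotation(rotation))
    stop("'rotation' must be a proper rotation matrix (orthonormal, det +1)")
  if (is.null(new_chain))
    new_chain <- setdiff(LETTERS, s$chains)[1]
  mate <- transform_structure(s, rotation, translation)
  mate$residues$chain <- new_chain
  if (!is.null(mate$atoms)) mate$atoms$chain <- new_chain
  residues <- rbind(s$residues, mate$residues)
  atoms <- if (!is.null(s$atoms)) rbind(s$atoms, mate$atoms) else NULL
  new_ca_structure(residues, atoms)
}

#' Build the separated, reoriented starting pose for docking
#'
#' Pulls the two chains of a dimer apart along the line joining their
#' centroids until the centroid distance has grown by `separation`
#' (default 50 Angstrom), then rotates the second chain about that axis
#' (180 degrees by default, or about a seeded random axis), destroying
#' the native relative orientation. With the default separation no
#' native inter-chain contact at 8 Angstrom survives.
#'
#' @param dimer a two-chain `ca_structure`.
#' @param separation added centroid-centroid distance in Angstrom.
#' @param angle rotation applied to the second chain, radians.
#' @param rotate_axis `"center"` (the inter-centroid axis) or
#'   `"random"` (seeded random axis).
#' @param seed RNG seed used when `rotate_axis = "random"`.
#' @return a `ca_structure` with the same chains in the new pose.
#' @export
build_initial_pose <- function(dimer, separation = 50, angle = pi,
                               rotate_axis = c("center", "random"),
                               seed = 1L) {
  rotate_axis <- match.arg(rotate_axis)
  if (length(dimer$chains) != 2L)
    stop("initial pose requires exactly two chains, got ",
         length(dimer$chains))
  chA <- dimer$chains[1]; chB <- dimer$chains[2]
  XA <- ca_coords(dimer, chA); XB <- ca_coords(dimer, chB)
  cA <- colMeans(XA); cB <- colMeans(XB)
  axis <- cB - cA
  if (sqrt(sum(axis^2)) < 1e-9) axis <- c(0, 0, 1)
  axis <- axis / sqrt(sum(axis^2))

  if (separation == 0 && angle == 0) return(dimer)

  selB_r <- dimer$residues$chain == chB
  shift <- axis * separation
  dimer$residues[selB_r, c("x", "y", "z")] <-
    sweep(dimer$residues[selB_r, c("x", "y", "z")], 2, shift, "+")
  if (!is.null(dimer$atoms)) {
    selB_a <- dimer$atoms$chain == chB
    dimer$atoms[selB_a, c("x", "y", "z")] <-
      sweep(dimer$atoms[selB_a, c("x", "y", "z")], 2, shift, "+")
  }

  if (angle != 0) {
    rot_axis <- axis
    if (rotate_axis == "random") {
      set.seed(seed)
      v <- stats::rnorm(3)
      rot_axis <- v / sqrt(sum(v^2))
    }
    R <- rotation_matrix(rot_axis, angle)
    cB2 <- cB + shift
    rot_about <- function(df, sel) {
      xyz <- as.matrix(df[sel, c("x", "y", "z")])
      xyz <- sweep(xyz, 2, cB2)
      xyz <- xyz %*% t(R)
      df[sel, c("x", "y", "z")] <- sweep(xyz, 2, cB2, "+")
      df
    }
    dimer$residues <- rot_about(dimer$residues, selB_r)
    if (!is.null(dimer$atoms))
      dimer$atoms <- rot_about(dimer$atoms, dimer$atoms$chain == chB)
  }
  dimer
}

#' Write a C-alpha structure (or pose) as PDB
#'
#' Writes the C-alpha trace as ATOM records via `bio3d::write.pdb`,
#' preserving chain identifiers and residue numbers.
#'
#' @param s a `ca_structure`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_pose_pdb <- function(s, path) {
  r <- s$residues
  n <- nrow(r)
  xyz <- as.vector(t(as.matrix(r[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = r$resno,
                   chain = r$chain, resid = r$resid,
                   elety = rep("CA", n), o = rep(1, n), b = rep(0, n))
  invisible(path)
}
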
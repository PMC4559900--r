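## van der Waals radii by element (Angstrom); default 1.7 for unknowns.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, SE = 1.90)

## Theoretical maximum accessible surface area per residue type
## (Gly-X-Gly extended tripeptide values, Tien et al. 2013), Angstrom^2.
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223,
             Q = 225, G = 104, H = 224, I = 197, L = 201, K = 236,
             M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
             Y = 263, V = 174)

## Deterministic quasi-uniform points on the unit sphere (Fibonacci
## lattice) so SASA values are reproducible for a given n_points.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per residue (Shrake-Rupley)
#'
#' Numerical SASA: each atom's sphere of radius (vdW + probe) is sampled
#' at `n_points` quasi-uniform points; a point is exposed if it lies
#' outside every neighbouring atom's expanded sphere. Residue SASA is the
#' sum over its atoms; relative SASA divides by a tabulated per-residue
#' maximum (for residue types without a tabulated maximum, e.g. synthetic
#' beads, the isolated-sphere area of the residue's atoms is used).
#'
#' @param s a `ca_structure` with full-atom coordinates (a `radius`
#'   column in `s$atoms` overrides the element-based vdW radii).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @param chain optional chain restriction; the filtering protocol
#'   computes SASA on a single monomer chain.
#' @return object of class `coev_sasa`: data frame with `chain`,
#'   `resno`, `aa`, `abs_sasa`, `rel_sasa` and `flagged` (residues
#'   missing side-chain atoms).
#' @export
sasa <- function(s, probe = 1.4, n_points = 960L, chain = NULL) {
  stopifnot(probe > 0, n_points >= 16L)
  if (is.null(s$atoms)) stop("full-atom coordinates required for SASA")
  at <- s$atoms
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  n <- nrow(at)
  if (n == 0L) stop("no atoms in selected chain(s)")

  radii <- if ("radius" %in% names(at)) at$radius
           else unname(VDW_RADII[toupper(at$element)])
  radii[is.na(radii)] <- 1.70
  R <- radii + probe
  X <- as.matrix(at[, c("x", "y", "z")])
  pts <- fibonacci_sphere(n_points)

  area <- numeric(n)
  D2 <- as.matrix(stats::dist(X))^2
  for (a in seq_len(n)) {
    nb <- which(D2[a, ] < (R[a] + R)^2 & seq_len(n) != a)
    sph <- sweep(pts * R[a], 2, X[a, ], "+")
    if (length(nb) == 0L) {
      exposed <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (b in nb) {
        d2 <- (sph[, 1] - X[b, 1])^2 + (sph[, 2] - X[b, 2])^2 +
              (sph[, 3] - X[b, 3])^2
        buried <- buried | (d2 < R[b]^2)
        if (all(buried)) break
      }
      exposed <- sum(!buried)
    }
    area[a] <- 4 * pi * R[a]^2 * exposed / n_points
  }

  key <- paste(at$chain, at$resno, sep = "|")
  uk <- unique(key)
  backbone <- c("N", "CA", "C", "O", "OXT")
  res_rows <- match(uk, key)
  aa1 <- unname(AA_3TO1[at$resid[res_rows]])
  aa1[is.na(aa1)] <- "X"
  abs_sasa <- vapply(uk, function(k) sum(area[key == k]), numeric(1))
  iso <- vapply(uk, function(k) sum(4 * pi * R[key == k]^2), numeric(1))
  denom <- unname(MAX_ASA[aa1])
  denom[is.na(denom)] <- iso[is.na(denom)]
  flagged <- vapply(uk, function(k) {
    rid <- at$resid[key == k][1]
    !identical(rid, "GLY") && all(at$elety[key == k] %in% backbone) &&
      rid %in% names(AA_3TO1)
  }, logical(1))
  if (any(flagged))
    warning(sum(flagged), " residue(s) lack side-chain atoms; SASA from ",
            "available atoms only")

  out <- data.frame(chain = at$chain[res_rows], resno = at$resno[res_rows],
                    aa = aa1, abs_sasa = unname(abs_sasa),
                    rel_sasa = unname(abs_sasa / denom),
                    flagged = unname(flagged), stringsAsFactors = FALSE)
  class(out) <- c("coev_sasa", "data.frame")
  out
}
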
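#' Map alignment columns to structure residues
#'
#' Produces a collinear (strictly increasing on both sides) mapping from
#' 0-based alignment columns to 0-based residue indices of a structure
#' chain. Two methods are supported:
#'
#' * `"pairwise"`: global alignment (match +1, mismatch -1, gap -2)
#'   between the alignment's per-column consensus sequence and the
#'   structure sequence; every aligned (non-gap on both sides) position
#'   is mapped, whether identical or substituted. This is a fallback for
#'   cases without a profile-HMM mapping.
#' * `"external_table"`: a user-supplied two-column table (e.g. derived
#'   from `hmmscan` output), validated for collinearity. Preferred for
#'   real protein families.
#'
#' A coverage below `min_coverage` raises a "mapping failed" error: it
#' almost always signals a wrong family/structure pairing.
#'
#' @param msa a `coev_msa`.
#' @param structure a `ca_structure`; its first chain's sequence is used
#'   unless `chain` says otherwise.
#' @param method `"pairwise"` or `"external_table"`.
#' @param table for `external_table`: path to a TSV with header
#'   `aln_col<TAB>res_index` (both 0-based), or an equivalent data frame.
#' @param chain chain of `structure` to map against.
#' @param min_coverage minimal fraction of alignment columns mapped.
#' @return object of class `coev_mapping`: list with `pairs` (data frame
#'   `aln_col`, `res_index`, 0-based) and `coverage`.
#' @export
map_alignment_to_structure <- function(msa, structure,
                                       method = c("pairwise",
                                                  "external_table"),
                                       table = NULL,
                                       chain = structure$chains[1],
                                       min_coverage = 0.3) {
  method <- match.arg(method)
  L <- ncol(msa$sequences)
  n_res <- sum(structure$residues$chain == chain)

  if (method == "external_table") {
    df <- if (is.data.frame(table)) table
          else read.delim(table, header = TRUE, sep = "\t")
    if (!all(c("aln_col", "res_index") %in% names(df)))
      stop("mapping table must have columns 'aln_col' and 'res_index'")
    pairs <- data.frame(aln_col = as.integer(df$aln_col),
                        res_index = as.integer(df$res_index))
  } else {
    cons <- msa_consensus(msa)
    cons_cols <- which(!is.na(cons)) # all-gap columns cannot be mapped
    cons_seq <- paste(cons[cons_cols], collapse = "")
    struct_seq <- structure_sequence(structure, chain)
    al <- global_align(cons_seq, struct_seq)
    pairs <- data.frame(aln_col = cons_cols[al$i] - 1L,
                        res_index = al$j - 1L)
  }

  validate_mapping(pairs, L, n_res)
  coverage <- nrow(pairs) / L
  if (coverage < min_coverage)
    stop("mapping failed: only ", round(100 * coverage, 1),
         "% of alignment columns mapped (need >= ",
         round(100 * min_coverage), "%); check that the family and ",
         "structure belong together")
  structure(list(pairs = pairs, coverage = coverage, chain = chain),
            class = "coev_mapping")
}

validate_mapping <- function(pairs, L, n_res) {
  if (anyDuplicated(pairs$aln_col) || anyDuplicated(pairs$res_index))
    stop("mapping has duplicate columns or residue indices")
  if (is.unsorted(pairs$aln_col, strictly = TRUE))
    stop("mapping alignment columns must be strictly increasing")
  if (is.unsorted(pairs$res_index, strictly = TRUE))
    stop("mapping residue indices must be strictly increasing ",
         "(collinear mapping required)")
  if (any(pairs$aln_col < 0L) || any(pairs$aln_col >= L))
    stop("alignment columns out of range [0, ", L, ")")
  if (any(pairs$res_index < 0L) || any(pairs$res_index >= n_res))
    stop("residue indices out of range [0, ", n_res, ")")
  invisible(pairs)
}

#' @export
print.coev_mapping <- function(x, ...) {
  cat("coev_mapping: ", nrow(x$pairs), " columns mapped (coverage ",
      round(100 * x$coverage, 1), "%)\n", sep = "")
  invisible(x)
}

## Global Needleman-Wunsch through Biostrings with the simple
## +1/-1/-2 scoring the mapping contract specifies (linear gaps).
global_align <- function(a, b) {
  letters_all <- unique(strsplit(paste0(a, b, "X"), "")[[1]])
  m <- matrix(-1, length(letters_all), length(letters_all),
              dimnames = list(letters_all, letters_all))
  diag(m) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = m, gapOpening = 0, gapExtension = 2,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ii <- jj <- integer(0)
  ai <- bi <- 0L
  for (k in seq_along(pat)) {
    pa_gap <- pat[k] == "-"
    su_gap <- sub[k] == "-"
    if (!pa_gap) ai <- ai + 1L
    if (!su_gap) bi <- bi + 1L
    if (!pa_gap && !su_gap) { ii <- c(ii, ai); jj <- c(jj, bi) }
  }
  list(i = ii, j = jj)
}

#' Translate a DI ranking from alignment columns to residue indices
#'
#' Couplings involving unmapped alignment columns cannot be placed on
#' the structure; they are dropped and reported via a message and the
#' `dropped` attribute.
#'
#' @param ranking a `coev_diranking` in alignment-column indices.
#' @param mapping a `coev_mapping`.
#' @return a `coev_diranking` in 0-based residue indices, with
#'   attributes `dropped` (rows lost) and `aln_cols` (original columns).
#' @export
map_ranking <- function(ranking, mapping) {
  lut <- rep(NA_integer_, max(ranking$i, ranking$j) + 1L)
  lut[mapping$pairs$aln_col + 1L] <- mapping$pairs$res_index
  ri <- lut[ranking$i + 1L]
  rj <- lut[ranking$j + 1L]
  keep <- !is.na(ri) & !is.na(rj)
  if (any(!keep))
    message(sum(!keep), " coupling(s) dropped: unmapped alignment columns")
  out <- data.frame(i = pmin(ri[keep], rj[keep]),
                    j = pmax(ri[keep], rj[keep]),
                    DI = ranking$DI[keep])
  res <- new_diranking(out)
  attr(res, "dropped") <- as.data.frame(ranking)[!keep, , drop = FALSE]
  res
}
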
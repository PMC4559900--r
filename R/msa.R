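#' Read a multiple sequence alignment
#'
#' Reads a gapped amino-acid alignment from FASTA or Stockholm and encodes
#' it over a 21-state alphabet: state 0 is the gap, states 1..20 are the
#' amino acids in alphabetical one-letter order. Gap characters (`-`, `.`),
#' ambiguity codes (`X`, `B`, `Z`, `J`, `U`, `O`) and lowercase insert
#' states are all encoded as the gap state.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return An object of class `coev_msa`: a list with `sequences` (M x L
#'   integer matrix of states in `0..20`), `labels` (M identifiers) and
#'   `q = 21`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC-", ">b", "AC-"), f)
#' msa <- read_alignment(f)
#' dim(msa$sequences)
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path) # BStringSet keeps case as-is
    labels <- names(set)
    seqs <- as.character(set)
  } else {
    parsed <- parse_stockholm(path)
    labels <- parsed$labels
    seqs <- parsed$seqs
  }
  if (length(seqs) == 0L) stop("empty alignment: ", path)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- labels[which(lens != lens[1])[1]]
    stop("ragged alignment: sequence '", bad, "' has length ",
         lens[lens != lens[1]][1], ", expected ", lens[1])
  }
  mat <- encode_sequences(seqs)
  rownames(mat) <- labels
  new_msa(mat, labels)
}

new_msa <- function(sequences, labels = rownames(sequences),
                    q = N_STATES, metadata = list()) {
  stopifnot(is.matrix(sequences), nrow(sequences) >= 2L,
            ncol(sequences) >= 2L,
            all(sequences >= 0L & sequences < q))
  structure(list(sequences = sequences, labels = labels, q = as.integer(q),
                 metadata = metadata),
            class = "coev_msa")
}

#' @export
print.coev_msa <- function(x, ...) {
  cat("coev_msa: ", nrow(x$sequences), " sequences x ",
      ncol(x$sequences), " columns (q = ", x$q, ")\n", sep = "")
  invisible(x)
}

## Stockholm is a line-oriented block format; the Biostrings reader
## normalises case, which would lose the lowercase insert-state marks we
## must encode as gaps, so the (trivial) block assembly is done here.
parse_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty alignment: ", path)
  seqs <- character()
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#") || startsWith(ln, "//"))
      next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2L) next
    nm <- parts[1]
    seqs[nm] <- paste0(if (nm %in% names(seqs)) seqs[[nm]] else "", parts[2])
  }
  if (length(seqs) == 0L) stop("no sequences found in Stockholm file: ", path)
  list(labels = names(seqs), seqs = unname(seqs))
}

encode_sequences <- function(seqs) {
  code <- rep(GAP_STATE, 256L)
  for (a in seq(2L, N_STATES)) {
    code[utf8ToInt(AA_ALPHABET1[a]) + 1L] <- a - 1L
  }
  L <- nchar(seqs[1])
  mat <- matrix(0L, nrow = length(seqs), ncol = L)
  for (s in seq_along(seqs)) {
    mat[s, ] <- code[utf8ToInt(seqs[s]) + 1L]
  }
  mat
}

#' Decode an encoded alignment back to character sequences
#'
#' Inverse of the encoding used by [read_alignment()]: state 0 becomes
#' `-`, states 1..20 the amino acids in alphabetical order.
#'
#' @param msa a `coev_msa`.
#' @return character vector of aligned sequences.
#' @export
decode_msa <- function(msa) {
  apply(msa$sequences, 1L, function(row)
    paste(AA_ALPHABET1[row + 1L], collapse = ""))
}

#' Per-column consensus sequence of an alignment
#'
#' Most frequent non-gap state per column; columns that are entirely gaps
#' yield `NA`.
#'
#' @param msa a `coev_msa`.
#' @return character vector of length L with one-letter codes (or `NA`).
#' @export
msa_consensus <- function(msa) {
  apply(msa$sequences, 2L, function(col) {
    col <- col[col != GAP_STATE]
    if (length(col) == 0L) return(NA_character_)
    tab <- tabulate(col, nbins = N_STATES - 1L)
    AA_ALPHABET1[which.max(tab) + 1L]
  })
}
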
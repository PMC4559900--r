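#' Surface-accessibility filter on a DI ranking
#'
#' Keeps a pair only if at least one of its residues is solvent exposed:
#' relative SASA strictly greater than `threshold` (50% by default, the
#' conventional minimum for a residue to count as accessible). Setting
#' `threshold = 0` disables the filter. Pairs referring to residues
#' without a SASA value are dropped and reported.
#'
#' @param ranking a `coev_diranking` whose `i`, `j` are 0-based residue
#'   indices of the chain `sasa_profile` was computed on (use
#'   [map_ranking()] first if the ranking is in alignment columns).
#' @param sasa_profile a `coev_sasa` for the monomer chain.
#' @param threshold relative-SASA threshold (fraction, default 0.5).
#' @return filtered `coev_diranking`, order preserved, with attribute
#'   `removed` (data frame of removed pairs and their SASA values).
#' @export
sasa_filter <- function(ranking, sasa_profile, threshold = 0.5) {
  rel <- sasa_profile$rel_sasa
  ri <- ranking$i + 1L
  rj <- ranking$j + 1L
  known <- ri <= length(rel) & rj <= length(rel)
  if (any(!known))
    message(sum(!known), " pair(s) dropped: no SASA value for residue")
  si <- rel[ifelse(known, ri, NA)]
  sj <- rel[ifelse(known, rj, NA)]
  keep <- known & (threshold <= 0 | pmax(si, sj) > threshold)
  removed <- data.frame(as.data.frame(ranking)[!keep, , drop = FALSE],
                        rel_sasa_i = si[!keep], rel_sasa_j = sj[!keep])
  out <- as.data.frame(ranking)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ranking)
  attr(out, "removed") <- removed
  attr(out, "rel_sasa_i") <- si[keep]
  attr(out, "rel_sasa_j") <- sj[keep]
  out
}

#' Truncate a DI ranking to its top entries
#'
#' @param ranking a `coev_diranking` (already sorted descending).
#' @param n_top number of top-DI pairs to keep (default 100).
#' @return the first `min(n_top, nrow)` entries.
#' @export
select_top <- function(ranking, n_top = 100L) {
  stopifnot(n_top >= 1)
  out <- as.data.frame(ranking)[seq_len(min(n_top, nrow(ranking))), ,
                                drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ranking)
  out
}

#' Remove monomeric contacts and symmetrize the survivors
#'
#' Discards every ranked pair that is a contact within the native
#' monomer (exact membership in the monomer's 8-Angstrom C-alpha contact
#' map by default; an optional dilation margin `delta` also removes
#' pairs whose monomer distance is below `cutoff + delta`). Each
#' surviving intra-sequence pair `(i, j)` is symmetrized into the two
#' inter-chain restraints `(i_A, j_B)` and `(j_A, i_B)` of the
#' homodimer.
#'
#' @param ranking a `coev_diranking` in 0-based residue indices.
#' @param monomer_map `coev_contact_map` of the native monomer at the
#'   configured cutoff (8 Angstrom in the reference protocol).
#' @param monomer optional `ca_structure` of the monomer, required when
#'   `delta > 0` (the dilated map is rebuilt at `cutoff + delta`).
#' @param delta dilation margin in Angstrom (default 0 = exact
#'   membership).
#' @return object of class `coev_restraints`; see
#'   [extract_dimer_restraints()] for the fields.
#' @export
remove_monomeric <- function(ranking, monomer_map, monomer = NULL,
                             delta = 0) {
  map <- monomer_map
  if (delta > 0) {
    if (is.null(monomer))
      stop("'monomer' structure needed to apply a dilation margin")
    map <- contact_map(monomer, cutoff = monomer_map$cutoff + delta)
  }
  keys <- paste(map$pairs[, 1], map$pairs[, 2], sep = "|")
  rk <- paste(pmin(ranking$i, ranking$j), pmax(ranking$i, ranking$j),
              sep = "|")
  in_map <- rk %in% keys
  kept <- as.data.frame(ranking)[!in_map, , drop = FALSE]
  rownames(kept) <- NULL
  new_restraints(kept, removed_monomeric =
                   as.data.frame(ranking)[in_map, , drop = FALSE])
}

new_restraints <- function(pairs, removed_monomeric = NULL,
                           provenance = NULL) {
  sym <- pairs[pairs$i != pairs$j, , drop = FALSE]
  interchain <- rbind(
    data.frame(res_a = sym$i, res_b = sym$j, DI = sym$DI),
    data.frame(res_a = sym$j, res_b = sym$i, DI = sym$DI))
  interchain <- interchain[order(-interchain$DI, interchain$res_a,
                                 interchain$res_b), , drop = FALSE]
  rownames(interchain) <- NULL
  structure(list(pairs = pairs, interchain_restraints = interchain,
                 removed_monomeric = removed_monomeric,
                 provenance = provenance),
            class = "coev_restraints")
}

#' @export
print.coev_restraints <- function(x, ...) {
  cat("coev_restraints: ", nrow(x$pairs), " pairs -> ",
      nrow(x$interchain_restraints), " inter-chain restraints\n",
      sep = "")
  invisible(x)
}

#' Full dimerization-coupling extraction pipeline
#'
#' Applies the filters in the reference order -- surface-accessibility
#' filter, top-N truncation, monomeric-contact removal -- and records,
#' for every input pair, which single filter (if any) removed it. On
#' real protein families the surviving count is typically a few tens;
#' a count outside `[10, 150]` triggers a warning since it usually
#' indicates a mis-mapped family or an uninformative alignment.
#'
#' @param ranking a `coev_diranking` in 0-based residue indices (after
#'   [map_ranking()] when coming from an alignment).
#' @param sasa_profile a `coev_sasa` of the monomer chain.
#' @param monomer_map `coev_contact_map` of the monomer (8 Angstrom).
#' @param sasa_threshold relative-SASA cutoff (default 0.5).
#' @param n_top DI pairs retained after the SASA filter (default 100).
#' @param monomer,delta see [remove_monomeric()].
#' @return a `coev_restraints` whose `provenance` data frame has one row
#'   per input pair: indices, DI, SASA values, verdict (`kept`,
#'   `removed_sasa`, `removed_top_n`, `removed_monomeric`).
#' @export
extract_dimer_restraints <- function(ranking, sasa_profile, monomer_map,
                                     sasa_threshold = 0.5, n_top = 100L,
                                     monomer = NULL, delta = 0) {
  prov <- data.frame(as.data.frame(ranking),
                     rel_sasa_i = sasa_profile$rel_sasa[ranking$i + 1L],
                     rel_sasa_j = sasa_profile$rel_sasa[ranking$j + 1L],
                     verdict = "kept", stringsAsFactors = FALSE)
  key <- function(d) paste(d$i, d$j, sep = "|")
  prov_key <- key(prov)

  s1 <- sasa_filter(ranking, sasa_profile, sasa_threshold)
  prov$verdict[!prov_key %in% key(s1)] <- "removed_sasa"

  s2 <- select_top(s1, n_top)
  prov$verdict[prov$verdict == "kept" & !prov_key %in% key(s2)] <-
    "removed_top_n"

  s3 <- remove_monomeric(s2, monomer_map, monomer = monomer,
                         delta = delta)
  prov$verdict[prov$verdict == "kept" &
                 prov_key %in% key(s3$removed_monomeric)] <-
    "removed_monomeric"

  n_surv <- nrow(s3$pairs)
  if (n_surv < 10 || n_surv > 150)
    warning("surviving coupling count (", n_surv, ") outside the ",
            "typical range [10, 150]; check the mapping and alignment")
  new_restraints(s3$pairs, removed_monomeric = s3$removed_monomeric,
                 provenance = prov)
}

#' Write restraints as TSV plus a JSON-lines provenance audit
#'
#' @param restraints a `coev_restraints`.
#' @param path output TSV path (`chainA_res`, `chainB_res`, `DI`); if
#'   provenance is present it is written next to it as
#'   `<path>.provenance.jsonl`, one JSON object per input pair.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  df <- restraints$interchain_restraints
  names(df) <- c("chainA_res", "chainB_res", "DI")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(restraints$provenance)) {
    lines <- vapply(seq_len(nrow(restraints$provenance)), function(r)
      as.character(jsonlite::toJSON(as.list(restraints$provenance[r, ]),
                                    auto_unbox = TRUE, digits = NA)),
      character(1))
    writeLines(lines, paste0(path, ".provenance.jsonl"))
  }
  invisible(path)
}
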
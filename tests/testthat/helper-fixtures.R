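# Shared fixture builders. Everything is generated in code at test time;
# file-based fixtures are written to tempdir().

write_fasta_fixture <- function(seqs, names = paste0("s", seq_along(seqs))) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names), seqs)), f)
  f
}

write_stockholm_fixture <- function(seqs,
                                    names = paste0("s", seq_along(seqs))) {
  f <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID test",
               paste(names, seqs), "//"), f)
  f
}

# minimal hand-written PDB: one CA per residue, optional altlocs
pdb_line <- function(serial, elety, resid, chain, resno, x, y, z,
                     alt = " ", occ = 1) {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           %s",
          serial, paste0(" ", elety), alt, resid, chain, resno, x, y, z,
          occ, substr(elety, 1, 1))
}

write_minimal_pdb <- function() {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(3, "CA", "VAL", "A", 3, 7.6, 0, 0),
    "TER", "END"), f)
  f
}

write_altloc_pdb <- function() {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, alt = "A", occ = 0.3),
    pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9, alt = "B", occ = 0.7),
    pdb_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(4, "CA", "VAL", "A", 3, 7.6, 0, 0),
    "HETATM    5  O   HOH A   4      20.000  20.000  20.000  1.00  0.00           O",
    "TER", "END"), f)
  f
}

# straight-chain structure: n beads spaced `spacing` Angstrom along x
straight_chain <- function(n, spacing = 3.8, chain = "A") {
  new_ca_structure(data.frame(
    chain = chain, resno = seq_len(n), resid = "GLY", aa = "G",
    x = spacing * (seq_len(n) - 1), y = 0.01 * (seq_len(n) - 1)^2,
    z = 0, stringsAsFactors = FALSE))
}

# toy dimer + restraints from its true interface (the planted couplings)
toy_restraints <- function(toy) {
  iface <- toy$interface
  df <- unique(data.frame(i = pmin(iface[, 1], iface[, 2]),
                          j = pmax(iface[, 1], iface[, 2]), DI = 1))
  df <- df[df$i != df$j, ]
  mono <- subset_chain(toy$structure, "A")
  remove_monomeric(coevdock:::new_diranking(df), contact_map(mono, 8))
}

random_rotation <- function(seed) {
  set.seed(seed)
  v <- stats::rnorm(3)
  rotation_matrix(v / sqrt(sum(v^2)), stats::runif(1, 0, 2 * pi))
}

make_ranking <- function(i, j, DI) {
  coevdock:::new_diranking(data.frame(i = i, j = j, DI = DI))
}
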
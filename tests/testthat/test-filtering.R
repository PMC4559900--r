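# A profile with known relative SASA per residue index (0-based)
fake_sasa <- function(rel) {
  out <- data.frame(chain = "A", resno = seq_along(rel), aa = "X",
                    abs_sasa = rel * 100, rel_sasa = rel,
                    flagged = FALSE)
  class(out) <- c("coev_sasa", "data.frame")
  out
}

test_that("the exposure filter keeps pairs with one exposed residue", {
  sp <- fake_sasa(c(0.8, 0.1, 0.4, 0.49))
  rk <- make_ranking(i = c(0L, 2L), j = c(1L, 3L), DI = c(2, 1))
  out <- sasa_filter(rk, sp, threshold = 0.5)
  expect_equal(nrow(out), 1L)                # (0.8, 0.1) kept
  expect_equal(c(out$i, out$j), c(0L, 1L))   # (0.4, 0.49) removed
  expect_equal(nrow(attr(out, "removed")), 1L)
  # threshold 0 disables the filter
  expect_equal(nrow(sasa_filter(rk, sp, threshold = 0)), 2L)
})

test_that("select_top truncates and preserves DI order", {
  rk <- make_ranking(i = 0:149, j = 151:300, DI = 150:1)
  expect_equal(nrow(select_top(rk, 100)), 100L)
  expect_equal(select_top(rk, 100)$DI[1], 150)
  expect_equal(nrow(select_top(make_ranking(0:29, 31:60, 30:1), 100)),
               30L)
  expect_equal(select_top(rk, 1)$DI, 150)
})

test_that("monomeric contacts are removed and survivors symmetrized", {
  mono <- straight_chain(40) # neighbours at 3.8 A are monomer contacts
  mm <- contact_map(mono, 8)
  rk <- make_ranking(i = c(0L, 5L, 2L), j = c(1L, 30L, 20L),
                     DI = c(3, 2, 1))
  rs <- remove_monomeric(rk, mm)
  # (0,1) is 3.8 A apart in the monomer -> removed; the others are far
  expect_equal(nrow(rs$pairs), 2L)
  expect_equal(nrow(rs$removed_monomeric), 1L)
  expect_equal(nrow(rs$interchain_restraints), 4L)
  # both (i_A, j_B) and (j_A, i_B) present per surviving pair
  key <- paste(rs$interchain_restraints$res_a,
               rs$interchain_restraints$res_b)
  expect_true(all(c("5 30", "30 5", "2 20", "20 2") %in% key))
})

test_that("counted removals match a direct distance scan of the fixture", {
  set.seed(42)
  toy <- build_toy_dimer(30, 6, seed = 5)
  mono <- subset_chain(toy$structure, "A")
  X <- ca_coords(mono)
  prs <- t(combn(0:29, 2))
  sel <- prs[sample(nrow(prs), 10), ]
  rk <- make_ranking(i = sel[, 1], j = sel[, 2], DI = 10:1)
  dists <- sqrt(rowSums((X[sel[, 1] + 1, ] - X[sel[, 2] + 1, ])^2))
  inside <- sum(dists < 8)
  rs <- remove_monomeric(rk, contact_map(mono, 8))
  expect_equal(nrow(rs$pairs), 10L - inside)
  expect_equal(nrow(rs$interchain_restraints), 2L * (10L - inside))
})

test_that("dilation widens the exclusion zone", {
  mono <- straight_chain(40)
  rk <- make_ranking(i = 0L, j = 2L, DI = 1) # 7.6 A: inside 8 A map
  rk2 <- make_ranking(i = 0L, j = 3L, DI = 1) # 11.4 A: outside
  expect_equal(nrow(remove_monomeric(rk2, contact_map(mono, 8))$pairs), 1L)
  expect_equal(nrow(remove_monomeric(rk2, contact_map(mono, 8),
                                     monomer = mono, delta = 4)$pairs), 0L)
  expect_error(remove_monomeric(rk, contact_map(mono, 8), delta = 2),
               "monomer")
})

test_that("full filter pipeline matches a hand-derived truth table", {
  # 20 ranked pairs over a 40-residue straight chain with known SASA.
  # Hand-derived below: verdicts depend on SASA of both members, the
  # top-N cut (n_top = 8, which the 6 SASA survivors all fit under) and
  # the monomer map (neighbours within 8 A: |i - j| <= 2 at 3.8 A).
  mono <- straight_chain(40)
  rel <- rep(0.2, 40)
  exposed <- c(0, 3, 6, 9, 12, 15, 18, 21, 24, 27, 30, 33, 36, 39)
  rel[exposed + 1] <- 0.9
  sp <- fake_sasa(rel)
  mm <- contact_map(mono, 8)

  i <- c(0L, 1L, 2L, 3L, 0L, 1L, 4L, 5L, 6L, 7L, 8L, 10L, 11L, 13L,
         14L, 16L, 17L, 19L, 20L, 22L)
  j <- c(30L, 2L, 4L, 33L, 1L, 35L, 5L, 36L, 8L, 10L, 11L, 39L, 14L,
         16L, 17L, 19L, 20L, 22L, 23L, 25L)
  di <- seq(20, 1)
  rk <- make_ranking(i, j, di)

  # truth table by hand:
  #  pair (i,j)   sasa_keep (max rel > .5)  in_map (|i-j|<=2)  final
  #  (0,30) T, (1,2) F, (2,4) F, (3,33) T, (0,1) T, (1,35) F,
  #  (4,5) F, (5,36) T, (6,8) T, (7,10) F, (8,11) F, (10,39) T,
  #  (11,14) F, (13,16) F, (14,17) F, (16,19) F, (17,20) F, (19,22) F,
  #  (20,23) F, (22,25) F
  # SASA survivors in DI order: (0,30),(3,33),(0,1),(5,36),(6,8),(10,39)
  # top 8 keeps all 6; monomer map removes (0,1) [3.8 A] and (6,8) [7.6 A]
  rs <- extract_dimer_restraints(rk, sp, mm, n_top = 8L) |>
    suppressWarnings()
  expect_equal(rs$pairs$i, c(0L, 3L, 5L, 10L))
  expect_equal(rs$pairs$j, c(30L, 33L, 36L, 39L))
  expect_equal(nrow(rs$interchain_restraints), 8L)

  prov <- rs$provenance
  expect_equal(nrow(prov), 20L)
  verdict_of <- function(pi, pj)
    prov$verdict[prov$i == pi & prov$j == pj]
  expect_equal(verdict_of(0, 1), "removed_monomeric")
  expect_equal(verdict_of(6, 8), "removed_monomeric")
  expect_equal(verdict_of(1, 2), "removed_sasa")
  expect_equal(verdict_of(22, 25), "removed_sasa")
  expect_equal(sum(prov$verdict == "kept"), 4L)
  # every removal attributed to exactly one filter
  expect_true(all(prov$verdict %in%
                    c("kept", "removed_sasa", "removed_top_n",
                      "removed_monomeric")))
})

test_that("filter order is the reference order: sasa, top-N, monomeric", {
  # constructed so that swapping top-N and SASA changes the output:
  # high-DI buried pairs crowd out exposed ones if top-N runs first
  mono <- straight_chain(30)
  rel <- rep(0.1, 30); rel[c(1, 20)] <- 0.9
  sp <- fake_sasa(rel)
  mm <- contact_map(mono, 8)
  rk <- make_ranking(i = c(2L, 3L, 0L), j = c(12L, 13L, 19L),
                     DI = c(3, 2, 1))
  rs <- suppressWarnings(
    extract_dimer_restraints(rk, sp, mm, n_top = 2L))
  # reference order: SASA first leaves only (0,19), then top-2, monomer
  expect_equal(rs$pairs$i, 0L)
  # the other order would have kept {(2,12),(3,13)} and dropped (0,19)
  wrong <- remove_monomeric(
    sasa_filter(select_top(rk, 2L), sp, 0.5), mm)
  expect_equal(nrow(wrong$pairs), 0L)
})

test_that("surviving counts outside [10, 150] trigger a warning", {
  mono <- straight_chain(30)
  sp <- fake_sasa(rep(0.9, 30))
  mm <- contact_map(mono, 8)
  rk <- make_ranking(i = c(0L, 1L), j = c(10L, 11L), DI = c(2, 1))
  expect_warning(extract_dimer_restraints(rk, sp, mm), "outside")
})

test_that("restraint writer emits TSV and provenance JSON-lines", {
  mono <- straight_chain(30)
  sp <- fake_sasa(rep(0.9, 30))
  rk <- make_ranking(i = 0:14, j = 15:29, DI = 15:1)
  rs <- suppressWarnings(
    extract_dimer_restraints(rk, sp, contact_map(mono, 8)))
  f <- tempfile(fileext = ".tsv")
  write_restraints(rs, f)
  back <- read.delim(f)
  expect_equal(names(back), c("chainA_res", "chainB_res", "DI"))
  expect_equal(nrow(back), nrow(rs$interchain_restraints))
  jl <- readLines(paste0(f, ".provenance.jsonl"))
  expect_equal(length(jl), 15L)
  expect_true(all(vapply(jl, jsonlite::validate, logical(1))))
})
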
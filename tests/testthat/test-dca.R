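msa_from_matrix <- function(mat, q) coevdock:::new_msa(mat, q = q)

test_that("reweighting matches brute-force identity counting", {
  # two identical sequences cluster together
  m <- msa_from_matrix(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)), q = 3)
  w <- compute_weights(m, 0.8)
  expect_equal(w$weights, c(0.5, 0.5))
  expect_equal(w$Meff, 1)

  # mutually dissimilar sequences keep weight 1
  m2 <- msa_from_matrix(rbind(c(0L, 1L, 2L), c(1L, 2L, 0L),
                              c(2L, 0L, 1L)), q = 3)
  expect_equal(compute_weights(m2, 0.8)$Meff, 3)

  # 5-sequence toy vs the O(M^2 L) oracle
  set.seed(5)
  mat <- matrix(sample(0:2, 5 * 4, replace = TRUE), 5, 4)
  m3 <- msa_from_matrix(mat, q = 3)
  for (theta in c(0.3, 0.5, 0.8))
    expect_equal(compute_weights(m3, theta)$weights,
                 oracle_weights(mat, theta))
})

test_that("frequencies obey pseudocount limits and match weighted counts", {
  set.seed(2)
  mat <- matrix(sample(0:2, 4 * 3, replace = TRUE), 4, 3)
  m <- msa_from_matrix(mat, q = 3)

  # lambda -> infinity: uniform
  fr <- compute_frequencies(m, lambda = 1e12)
  expect_true(max(abs(fr$f_i - 1 / 3)) < 1e-10)
  expect_true(abs(fr$f_ij[1, 5] - 1 / 9) < 1e-10)

  # lambda = 0, effectively single sequence: one-hot
  m1 <- msa_from_matrix(rbind(mat[1, ], mat[1, ]), q = 3)
  fr1 <- compute_frequencies(m1, weights = c(1, 1), lambda = 0)
  expect_equal(unname(fr1$f_i[1, mat[1, 1] + 1]), 1)
  expect_equal(sum(fr1$f_i == 0), 3 * 2)

  # toy alignment, lambda = Meff: equals direct weighted counting
  w <- compute_weights(m, 0.6)$weights
  fr2 <- compute_frequencies(m, weights = w, lambda = sum(w))
  oc <- oracle_freq(mat, w, sum(w), 3)
  expect_equal(fr2$f_i, oc$f_i, tolerance = 1e-12)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    blk <- fr2$f_ij[(i - 1) * 3 + 1:3, (j - 1) * 3 + 1:3]
    expect_equal(blk, oc$f_ij[i, j, , ], ignore_attr = TRUE)
  }
})

test_that("frequency invariants hold: normalisation and marginalisation", {
  set.seed(9)
  mat <- matrix(sample(0:3, 30 * 5, replace = TRUE), 30, 5)
  m <- msa_from_matrix(mat, q = 4)
  w <- compute_weights(m, 0.8)
  fr <- compute_frequencies(m, w$weights)
  expect_true(max(abs(rowSums(fr$f_i) - 1)) < 1e-9)
  for (i in 1:4) for (j in 1:5) {
    if (i == j) next
    blk <- fr$f_ij[(i - 1) * 4 + 1:4, (j - 1) * 4 + 1:4]
    expect_lt(abs(sum(blk) - 1), 1e-9)
    expect_lt(max(abs(rowSums(blk) - fr$f_i[i, ])), 1e-9)
  }
  expect_lte(fr$Meff, nrow(mat))
})

test_that("mean-field inversion: independent columns give near-zero couplings", {
  set.seed(4)
  mat <- matrix(sample(0:2, 50 * 4, replace = TRUE), 50, 4)
  m <- msa_from_matrix(mat, q = 3)
  fr <- compute_frequencies(m, lambda = 1e9)
  cp <- invert_mean_field(fr)
  offdiag <- cp$e_ij
  for (i in 1:4) offdiag[i, i, , ] <- 0
  expect_lt(max(abs(offdiag)), 1e-6)
})

test_that("mean-field inversion matches the closed-form 2x2 case", {
  # L = 2, q = 2: C is 2x2, e_12(1,1) = -C^-1[1,2] analytically
  set.seed(11)
  mat <- matrix(sample(0:1, 40 * 2, replace = TRUE, prob = c(0.4, 0.6)),
                40, 2)
  m <- msa_from_matrix(mat, q = 2)
  fr <- compute_frequencies(m, lambda = 2)
  cp <- invert_mean_field(fr)
  f1 <- fr$f_i[1, 2]; f2 <- fr$f_i[2, 2]
  f12 <- fr$f_ij[2, 4] # block (1,2), states (1,1)
  C <- matrix(c(f1 * (1 - f1), f12 - f1 * f2,
                f12 - f1 * f2, f2 * (1 - f2)), 2, 2)
  Cinv <- solve(C)
  expect_equal(cp$e_ij[1, 2, 2, 2], -Cinv[1, 2], tolerance = 1e-10)
  # gauge: gap-state rows and columns stay zero
  expect_true(all(cp$e_ij[1, 2, 1, ] == 0))
  expect_true(all(cp$e_ij[1, 2, , 1] == 0))
  # coupling symmetry e_ij(a,b) = e_ji(b,a)
  expect_equal(cp$e_ij[1, 2, , ], t(cp$e_ij[2, 1, , ]))
})

test_that("singular correlation matrix advises a positive pseudocount", {
  mat <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L))
  m <- msa_from_matrix(mat, q = 2)
  fr <- compute_frequencies(m, lambda = 0)
  expect_error(invert_mean_field(fr), "lambda > 0")
})

test_that("inversion is a true inverse of the correlation matrix", {
  set.seed(3)
  mat <- matrix(sample(0:2, 30 * 4, replace = TRUE), 30, 4)
  m <- msa_from_matrix(mat, q = 3)
  fr <- compute_frequencies(m)
  C <- fr$f_ij
  cp <- invert_mean_field(fr)
  expect_lt(max(abs(solve(cp$C) %*% cp$C - diag(nrow(cp$C)))), 1e-8)
})

test_that("DI is zero for zero couplings and nonnegative in general", {
  set.seed(6)
  mat <- matrix(sample(0:2, 25 * 3, replace = TRUE), 25, 3)
  m <- msa_from_matrix(mat, q = 3)
  fr <- compute_frequencies(m)
  cp <- invert_mean_field(fr)
  cp0 <- cp
  cp0$e_ij[] <- 0
  expect_equal(direct_information(cp0, fr, 1, 2), 0, tolerance = 1e-12)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_gte(direct_information(cp, fr, pr[1], pr[2]), 0)
})

test_that("DI agrees with the exhaustive two-state oracle", {
  set.seed(12)
  for (rep in 1:5) {
    M <- sample(5:30, 1)
    mat <- matrix(sample(0:1, M * 3, replace = TRUE), M, 3)
    m <- msa_from_matrix(mat, q = 2)
    d <- run_dca(m, min_separation = 0L)
    for (r in seq_len(nrow(d$ranking))) {
      i <- d$ranking$i[r] + 1L
      j <- d$ranking$j[r] + 1L
      W <- exp(d$coupling$e_ij[i, j, , ])
      expect_equal(d$ranking$DI[r],
                   oracle_di_q2(W, d$freq$f_i[i, ], d$freq$f_i[j, ]),
                   tolerance = 1e-6)
    }
  }
})

test_that("rank_pairs applies separation, ordering and the tie rule", {
  set.seed(8)
  mat <- matrix(sample(0:2, 20 * 3, replace = TRUE), 20, 3)
  m <- msa_from_matrix(mat, q = 3)
  d <- run_dca(m, min_separation = 2L)
  expect_equal(nrow(d$ranking), 1L)
  expect_equal(c(d$ranking$i, d$ranking$j), c(0L, 2L))

  # descending order with lexicographic ties
  rk <- coevdock:::new_diranking(
    data.frame(i = c(2L, 0L, 1L), j = c(4L, 3L, 2L), DI = c(1, 1, 1)))
  expect_equal(rk$i, c(0L, 1L, 2L))
})

test_that("DI ranking recovers a planted coupling and ignores sequence order", {
  model <- potts_model(6, 3, pairs = cbind(1L, 4L), J = diag(2, 3),
                       beta = 1)
  msa <- sample_potts(model, 400, seed = 21)
  d <- run_dca(msa)
  expect_equal(c(d$ranking$i[1], d$ranking$j[1]), c(1L, 4L))

  # permuting sequence order leaves weights multiset and DI unchanged
  perm <- sample(nrow(msa$sequences))
  msa2 <- coevdock:::new_msa(msa$sequences[perm, ], q = msa$q)
  d2 <- run_dca(msa2)
  expect_equal(sort(compute_weights(msa2, 0.8)$weights),
               sort(compute_weights(msa, 0.8)$weights))
  expect_equal(d2$ranking$DI, d$ranking$DI, tolerance = 1e-10)
})

test_that("relabeling non-gauge states leaves DI unchanged", {
  model <- potts_model(5, 4, pairs = cbind(0L, 3L), J = diag(1.5, 4),
                       beta = 1)
  msa <- sample_potts(model, 300, seed = 31)
  d <- run_dca(msa)
  # permute states 1..3, keeping the gauge state 0 fixed
  relab <- c(0L, 3L, 1L, 2L)
  msa2 <- coevdock:::new_msa(
    matrix(relab[msa$sequences + 1L], nrow(msa$sequences)), q = 4)
  d2 <- run_dca(msa2)
  expect_equal(d2$ranking$DI, d$ranking$DI, tolerance = 1e-8)
})

test_that("q=2 mean-field DI ranks pairs like exhaustive mutual information", {
  set.seed(14)
  for (rep in 1:3) {
    mat <- matrix(sample(0:1, 60 * 4, replace = TRUE), 60, 4)
    # inject correlation between columns 1 and 3
    mat[, 3] <- ifelse(stats::runif(60) < 0.85, mat[, 1], mat[, 3])
    m <- msa_from_matrix(mat, q = 2)
    d <- run_dca(m, min_separation = 0L)
    mi <- function(i, j) {
      tab <- table(factor(mat[, i], 0:1), factor(mat[, j], 0:1)) / 60
      pi_ <- rowSums(tab); pj_ <- colSums(tab)
      sum(tab * log(tab / outer(pi_, pj_)), na.rm = TRUE)
    }
    prs <- t(combn(1:4, 2))
    mis <- apply(prs, 1, function(r) mi(r[1], r[2]))
    top_mi <- prs[which.max(mis), ] - 1L
    expect_equal(c(d$ranking$i[1], d$ranking$j[1]), top_mi)
  }
})

test_that("DI tables round-trip through the TSV writer with sidecar", {
  set.seed(15)
  mat <- matrix(sample(0:2, 20 * 4, replace = TRUE), 20, 4)
  m <- msa_from_matrix(mat, q = 3)
  d <- run_dca(m)
  f <- tempfile(fileext = ".tsv")
  write_di_table(d$ranking, d$freq, f)
  back <- read.delim(f)
  expect_equal(back$DI, d$ranking$DI)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$theta, 0.8)
  expect_equal(side$Meff, d$Meff)
})
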
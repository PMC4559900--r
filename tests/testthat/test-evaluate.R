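test_that("superposition recovers rigid motions exactly", {
  set.seed(10)
  X <- matrix(rnorm(30, sd = 4), 10, 3)
  fit0 <- superpose(X, X)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  R <- rotation_matrix(c(0, 1, 0), pi / 2)
  Y <- sweep(X %*% t(R), 2, c(5, -2, 8), "+")
  fit <- superpose(X, Y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$transform(X), Y, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("superposition matches the quaternion-grid oracle", {
  set.seed(20)
  for (rep in 1:3) {
    A <- matrix(rnorm(30, sd = 3), 10, 3)
    B <- matrix(rnorm(30, sd = 3), 10, 3)
    expect_equal(superpose(A, B)$rmsd, oracle_superpose_rmsd(A, B),
                 tolerance = 1e-3)
  }
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate|collinear")
})

test_that("dimer RMSD handles the homodimer chain swap", {
  toy <- build_toy_dimer(20, 5, seed = 2)
  nat <- toy$structure
  expect_equal(dimer_rmsd(nat, nat), 0, tolerance = 1e-10)

  swapped <- nat
  n <- 20
  swapped$residues <- rbind(nat$residues[21:40, ], nat$residues[1:20, ])
  swapped$residues$chain <- rep(c("A", "B"), each = n)
  swapped <- new_ca_structure(swapped$residues, NULL)
  expect_equal(dimer_rmsd(swapped, nat), 0, tolerance = 1e-10)

  # arbitrary rigid motion of the prediction changes nothing
  moved <- coevdock:::transform_structure(nat, random_rotation(5),
                                          c(20, -7, 3))
  expect_equal(dimer_rmsd(moved, nat), 0, tolerance = 1e-9)
})

test_that("displaced chain B gives the RMSD the superposition oracle gives", {
  toy <- build_toy_dimer(15, 3, seed = 4)
  nat <- toy$structure
  pred <- nat
  selB <- pred$residues$chain == "B"
  pred$residues[selB, "x"] <- pred$residues[selB, "x"] + 3
  pred <- new_ca_structure(pred$residues, NULL)
  got <- dimer_rmsd(pred, nat)
  # independent route: optimal whole-complex superposition for both
  # chain assignments, via the quaternion-grid oracle
  P <- ca_coords(pred); N <- ca_coords(nat)
  o1 <- oracle_superpose_rmsd(P, N)
  o2 <- oracle_superpose_rmsd(P[c(16:30, 1:15), ], N)
  expect_equal(got, min(o1, o2), tolerance = 2e-3)
  expect_gt(got, 0)
})

test_that("chain length mismatches are refused", {
  a <- build_toy_dimer(12, 2, seed = 1)$structure
  b <- build_toy_dimer(14, 2, seed = 1)$structure
  expect_error(dimer_rmsd(a, b), "mismatch")
})

test_that("iRMSD is zero on the native and reduces to dimer RMSD when all residues are interfacial", {
  toy <- build_toy_dimer(12, 3, seed = 3)
  nat <- toy$structure
  expect_equal(interfacial_rmsd(nat, nat), 0, tolerance = 1e-12)
  pred <- nat
  selB <- pred$residues$chain == "B"
  pred$residues[selB, c("x", "y")] <- pred$residues[selB, c("x", "y")] + 1.5
  pred <- new_ca_structure(pred$residues, NULL)
  # a cutoff wider than the complex makes every residue interfacial
  expect_equal(interfacial_rmsd(pred, nat, interface_cutoff = 500),
               dimer_rmsd(pred, nat), tolerance = 1e-10)
})

test_that("iRMSD equals superposition on the hand-listed interface set", {
  toy <- build_toy_dimer(20, 5, seed = 2)
  nat <- toy$structure
  X <- ca_coords(nat)
  D <- as.matrix(dist(X))
  cross <- outer(nat$residues$chain, nat$residues$chain, "!=")
  manual <- sort(which(apply(D < 10 & cross, 1, any)))
  expect_equal(interface_residues(nat, 10), manual - 1L)

  pred <- nat
  selB <- pred$residues$chain == "B"
  set.seed(8)
  pred$residues[selB, c("x", "y", "z")] <-
    pred$residues[selB, c("x", "y", "z")] + matrix(rnorm(60, 0, 0.4), 20)
  pred <- new_ca_structure(pred$residues, NULL)
  got <- interfacial_rmsd(pred, nat)
  P <- ca_coords(pred)
  o1 <- oracle_superpose_rmsd(P[manual, , drop = FALSE],
                              X[manual, , drop = FALSE])
  swap <- c(21:40, 1:20)
  o2 <- oracle_superpose_rmsd(P[swap, ][manual, , drop = FALSE],
                              X[manual, , drop = FALSE])
  expect_equal(got, min(o1, o2), tolerance = 2e-3)
})

test_that("shrinking the interface cutoff never enlarges the interface", {
  toy <- build_toy_dimer(25, 6, seed = 6)
  nat <- toy$structure
  prev <- interface_residues(nat, 14)
  for (cut in c(12, 10, 9)) {
    cur <- interface_residues(nat, cut)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(interfacial_rmsd(nat, build_initial_pose(nat, 50)),
               "interface")
})

test_that("trajectory evaluation equals a frame-by-frame recomputation", {
  toy <- build_toy_dimer(20, 5, seed = 2)
  nat <- toy$structure
  natX <- ca_coords(nat)
  set.seed(31)
  frames <- lapply(1:12, function(k)
    natX + matrix(rnorm(120, 0, 0.1 * k), 40, 3))
  traj <- structure(list(
    frames = frames,
    energies = data.frame(stage = rep(c(6L, 7L), each = 6)),
    monitor = numeric(12), stage_converged = rep(TRUE, 7),
    final_X = frames[[12]], final_V = NULL, n_chain_a = 20L,
    control = sim_control(), seed = 1L), class = "coev_trajectory")
  rep_ <- evaluate_trajectory(traj, nat)

  manual_rmsd <- vapply(frames, function(F) {
    r1 <- superpose(F, natX)$rmsd
    r2 <- superpose(F[c(21:40, 1:20), ], natX)$rmsd
    min(r1, r2)
  }, numeric(1))
  expect_equal(rep_$rmsd_series, manual_rmsd, tolerance = 1e-10)
  expect_equal(rep_$rmsd_best, min(manual_rmsd))
  expect_equal(rep_$best_frame, which.min(manual_rmsd))
  expect_equal(rep_$rmsd_final_stage_mean, mean(manual_rmsd[7:12]))
  expect_true(all(rep_$rmsd_best <= rep_$rmsd_series))

  # single identical frame: zeros and full recovery
  traj1 <- traj
  traj1$frames <- list(natX)
  traj1$energies <- data.frame(stage = 7L)
  rep1 <- evaluate_trajectory(traj1, nat)
  expect_equal(rep1$rmsd_best, 0, tolerance = 1e-10)
  expect_equal(rep1$rmsd_final_stage_mean, 0, tolerance = 1e-10)
  expect_equal(rep1$contact_recovery, 1)
})

test_that("argmin frame selection picks the best frame", {
  toy <- build_toy_dimer(15, 3, seed = 9)
  nat <- toy$structure
  natX <- ca_coords(nat)
  shift <- function(a) {
    X <- natX; X[16:30, 1] <- X[16:30, 1] + a; X
  }
  traj <- structure(list(
    frames = list(shift(5), shift(2), shift(3)),
    energies = data.frame(stage = c(7L, 7L, 7L)),
    monitor = numeric(3), stage_converged = rep(TRUE, 7),
    final_X = shift(3), final_V = NULL, n_chain_a = 15L,
    control = sim_control(), seed = 1L), class = "coev_trajectory")
  rep_ <- evaluate_trajectory(traj, nat)
  expect_equal(rep_$best_frame, 2L)
  expect_equal(rep_$rmsd_series[2], min(rep_$rmsd_series))
})

test_that("contact-map report reproduces native sets and restraint TP", {
  toy <- build_toy_dimer(25, 10, seed = 3)
  nat <- toy$structure
  cm <- contact_map_report(nat, nat)
  tab <- cm$table
  nm <- tab[tab$set == "native_monomeric", c("i", "j")]
  pm <- tab[tab$set == "predicted_monomeric", c("i", "j")]
  expect_equal(nm[order(nm$i, nm$j), ], pm[order(pm$i, pm$j), ],
               ignore_attr = TRUE)
  nd <- tab[tab$set == "native_dimeric", c("i", "j")]
  pd <- tab[tab$set == "predicted_dimeric", c("i", "j")]
  expect_equal(nrow(nd), nrow(pd))

  # 10 restraints, 2 deliberately false -> TP fraction 0.8
  iface <- toy$interface
  df <- unique(data.frame(i = iface[, 1], j = iface[, 2], DI = 1))
  df <- df[df$i != df$j, ][1:8, ]
  truekey <- paste(nd$i, nd$j)
  all_pairs <- expand.grid(i = 0:24, j = 0:24)
  far <- all_pairs[!(paste(all_pairs$i, all_pairs$j) %in% truekey) &
                     !(paste(all_pairs$j, all_pairs$i) %in% truekey), ]
  fake <- far[c(10, 300), ]
  rs <- coevdock:::new_restraints(
    rbind(df, data.frame(i = fake$i, j = fake$j, DI = 0.5)))
  cm2 <- contact_map_report(nat, nat, rs)
  expect_equal(cm2$restraint_tp_fraction, 0.8)
})
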
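# ion hydration shells, coordination profiles, crossings, Boltzmann inversion

test_that("shell composition counts planted partners by category", {
  # exactly 6 water oxygens at 0.30 nm
  dirs <- edgepore:::sphere_dirs(6) * 0.30
  part <- data.frame(name = rep("OW", 6), resname = rep("SOL", 6),
                     residue = 2:7, x = dirs[, 1], y = dirs[, 2],
                     z = dirs[, 3])
  fx <- shell_fixture(part)
  sc <- shell_composition(fx$frame, fx$top, 1)
  expect_identical(unname(sc["water_O"]), 6L)
  expect_true(all(sc[names(sc) != "water_O"] == 0L))
  # add one Q15 side-chain O at 0.34 nm
  part2 <- rbind(part, data.frame(name = "OE1", resname = "GLN",
                                  residue = 15, x = 0.34, y = 0, z = 0))
  fx2 <- shell_fixture(part2)
  sc2 <- shell_composition(fx2$frame, fx2$top, 1)
  expect_identical(unname(sc2["Q15_sidechain"]), 1L)
  expect_identical(unname(sc2["protein_total"]), 1L)
  # partner at 0.36 nm is excluded at the 0.35 cutoff
  part3 <- rbind(part, data.frame(name = "OE1", resname = "GLN",
                                  residue = 15, x = 0.36, y = 0, z = 0))
  fx3 <- shell_fixture(part3)
  expect_identical(unname(shell_composition(fx3$frame, fx3$top, 1)["Q15_sidechain"]), 0L)
  expect_error(shell_composition(fx$frame, fx$top, 999), "out of range")
})

test_that("shell counts are invariant under atom permutation", {
  dirs <- edgepore:::sphere_dirs(5) * 0.3
  part <- data.frame(name = c(rep("OW", 4), "OE1"),
                     resname = c(rep("SOL", 4), "GLN"),
                     residue = c(2:5, 15L),
                     x = dirs[, 1], y = dirs[, 2], z = dirs[, 3])
  fx <- shell_fixture(part)
  sc <- shell_composition(fx$frame, fx$top, 1)
  perm <- c(1L, sample(2:6))
  top2 <- fx$top[perm, ]; class(top2) <- class(fx$top)
  top2$atom_index <- seq_len(6) - 1L
  f2 <- frame_snapshot(fx$frame$coords[perm, ], fx$frame$box)
  sc2 <- shell_composition(f2, top2, 1)
  expect_identical(as.integer(sc), as.integer(sc2))
})

test_that("coordination profile recovers planted shells with replicate SEM", {
  sys <- fix_system(seed = 7)
  plan <- list(list(x = 1, y = 1, z = rep(0, 10),
                    shell = c(water_O = 4, protein_total = 0)))
  # planted: 4 waters + 2 protein atoms at z = 0
  plan[[1]]$shell <- c(water_O = 4, backbone_carbonyl_O_res9_21 = 1,
                       Q15_sidechain = 1)
  ps <- make_permeation_series(sys, plan)
  cp <- coordination_profile(ps$traj, ps$ion_rows)
  at0 <- cp[!is.na(cp$value), ]   # single occupied bin (contains z = 0)
  expect_equal(at0$value[at0$category == "water_O"], 4)
  expect_equal(at0$value[at0$category == "protein_total"], 2)
  # replicate merge: shells of 4 and 6 waters -> mean 5, SEM 1
  mk <- function(nw) {
    p <- list(list(x = 1, y = 1, z = rep(0, 4), shell = c(water_O = nw)))
    make_permeation_series(sys, p)$traj$replicates[[1]]
  }
  r4 <- mk(4); r6 <- mk(6)
  # pad topologies: regenerate with 6 and park 2 waters out of shell for r4
  p6 <- list(list(x = 1, y = 1, z = rep(0, 4), shell = c(water_O = 6)))
  ps6 <- make_permeation_series(sys, p6)
  r4b <- lapply(ps6$traj$replicates[[1]], function(f) {
    # move the last two shell waters 2 nm away
    n <- nrow(f$coords)
    f$coords[(n - 1):n, 3] <- f$coords[(n - 1):n, 3] + 2
    f
  })
  traj2 <- trajectory_set(ps6$traj$topology, list(r4b, ps6$traj$replicates[[1]]),
                          100, 0)
  cp2 <- coordination_profile(traj2, ps6$ion_rows)
  w0 <- cp2[cp2$category == "water_O" & !is.na(cp2$value), ]
  expect_equal(w0$value, 5)
  expect_equal(w0$sem, 1)
  # bins without observations are missing
  expect_true(all(is.na(cp$value[cp$n_obs == 0])))
})

test_that("crossing detection follows the hysteresis state machine", {
  sys <- fix_system(seed = 8)
  mk_traj <- function(zpath) {
    plan <- list(list(x = 1.2, y = 4.3, z = zpath, shell = c(water_O = 0)))
    make_permeation_series(sys, plan)
  }
  # monotone traversal -> 1 down event
  ps <- mk_traj(seq(3, -3, length.out = 13))
  ev <- crossing_events(ps$traj, ps$ion_rows)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$direction, "down")
  expect_gt(ev$exit_time, ev$entry_time)
  # dip to the center and return -> 0 events
  ps2 <- mk_traj(c(3, 1, 0, 1, 3))
  expect_identical(nrow(crossing_events(ps2$traj, ps2$ion_rows)), 0L)
  # two full traversals -> 2 events
  ps3 <- mk_traj(c(3, 0, -3, 0, 3))
  ev3 <- crossing_events(ps3$traj, ps3$ion_rows)
  expect_identical(nrow(ev3), 2L)
  expect_identical(ev3$direction, c("down", "up"))
  # time reversal maps up <-> down 1:1
  ps4 <- mk_traj(rev(seq(3, -3, length.out = 13)))
  ev4 <- crossing_events(ps4$traj, ps4$ion_rows)
  expect_identical(nrow(ev4), 1L)
  expect_identical(ev4$direction, "up")
  # empty selection: zero events
  expect_identical(nrow(crossing_events(ps$traj, integer(0))), 0L)
})

test_that("Boltzmann inversion has the exact closed forms", {
  z <- seq(-3.95, 3.95, by = 0.1)
  mkprof <- function(rho) edgepore:::axial_profile(z, rho, 0,
                                                   "number_density", 0.1)
  # uniform density -> dG = 0 everywhere
  pf <- permeation_free_energy(mkprof(rep(2, length(z))))
  expect_true(all(abs(pf$value) < 1e-12))
  # bin at rho_bulk / 2 -> RT ln 2
  rho <- rep(1, length(z)); rho[abs(z) < 0.05] <- 0.5
  pf2 <- permeation_free_energy(mkprof(rho))
  expect_equal(pf2$value[abs(pf2$z) < 0.05],
               rep(0.0083145 * 300 * log(2), 2), tolerance = 1e-9)
  # empty interior bin -> NA flag, not Inf
  rho3 <- rep(1, length(z)); rho3[10] <- 0
  pf3 <- permeation_free_energy(mkprof(rho3))
  expect_true(is.na(pf3$value[10]))
  expect_false(any(is.infinite(pf3$value), na.rm = TRUE))
  # zero bulk density -> error
  expect_error(permeation_free_energy(mkprof(ifelse(abs(z) >= 2.5, 0, 1))),
               "bulk density|bulk window")
  # difference identity: dG(z1) - dG(z2) = RT ln(rho(z2)/rho(z1))
  set.seed(41)
  rho4 <- runif(length(z), 0.5, 2)
  pf4 <- permeation_free_energy(mkprof(rho4))
  i <- 5; j <- 60
  expect_equal(pf4$value[i] - pf4$value[j],
               0.0083145 * 300 * log(rho4[j] / rho4[i]), tolerance = 1e-9)
})
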
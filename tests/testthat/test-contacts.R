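# residue-resolved heavy-atom contact analysis (0.5 nm cutoff)

# minimal protein + partner fixture: one ALA residue and one movable P atom
contact_fixture <- function(dx) {
  top <- suppressWarnings(topology(
    name = c("N", "CA", "C", "O", "CB", "HA", "P"),
    residue_name = c(rep("ALA", 6), "POPC"),
    residue_number = c(rep(1L, 6), 2L),
    chain_id = c(rep("A", 6), "L")))
  xyz <- rbind(c(0, 0, 0), c(0.15, 0, 0), c(0.3, 0, 0), c(0.3, 0.12, 0),
               c(0.15, -0.15, 0), c(0.15, 1.0, 0),   # HA held far off
               c(0.3 + dx, 0, 0))            # partner along x from atom C
  list(top = top, frame = frame_snapshot(xyz + 3, c(10, 10, 10)))
}

test_that("contact threshold brackets at the 0.5 nm cutoff", {
  near <- contact_fixture(0.49)
  far <- contact_fixture(0.51)
  partner <- atom_select(near$top, subrole = "phosphate")
  expect_true(frame_contacts(near$frame, near$top, 1, partner)[["1"]])
  expect_false(frame_contacts(far$frame, far$top, 1, partner)[["1"]])
})

test_that("contact is boolean presence, not a pair count", {
  fx <- contact_fixture(0.3)
  # add a second qualifying partner
  add <- topology("P", "POPC", 3L, chain_id = "L", atom_index = 99L)
  top <- rbind(fx$top, add); class(top) <- class(fx$top)
  f <- frame_snapshot(rbind(fx$frame$coords, c(3.3, 3.4, 3)), fx$frame$box)
  partner <- atom_select(top, subrole = "phosphate")
  hits <- frame_contacts(f, top, 1, partner)
  expect_identical(sum(hits), 1L)
  expect_true(hits[["1"]])
})

test_that("hydrogens are excluded from both sides", {
  fx <- contact_fixture(0.3)
  # hydrogen partner selection yields no contact even when close
  h <- atom_select(fx$top, name = "HA")
  expect_false(any(frame_contacts(fx$frame, fx$top, 1, h)))
  # hydrogen-only approach at 0.2 nm: partner sits 0.2 nm from HA, with all
  # heavy atoms of the residue beyond the 0.5 nm cutoff
  f <- fx$frame
  f$coords[7, ] <- f$coords[6, ] + c(0, 0.2, 0)
  d_heavy <- min(edgepore:::mi_dist_point(
    f$coords[7, ], f$coords[1:5, , drop = FALSE], f$box))
  expect_gt(d_heavy, 0.5)   # fixture geometry holds heavies away
  expect_false(frame_contacts(f, fx$top, 1,
                              atom_select(fx$top, subrole = "phosphate"))[["1"]])
})

test_that("planted contact frequencies and replicate SEM are exact", {
  emb <- fix_embedded()
  traj <- make_contact_series(emb, 15, n_frames = 10,
                              contact_frames = c(2, 5, 9))
  partners <- list(phosphate = atom_select(traj$topology, subrole = "phosphate"))
  cm <- contact_frequency(traj, 13:16, partners)
  expect_equal(cm$frequency[cm$residue_number == 15], 0.3)
  # always-present partner -> frequency 1
  traj2 <- make_contact_series(emb, 15, n_frames = 5, contact_frames = 1:5)
  cm2 <- contact_frequency(traj2, 15, partners)
  expect_equal(cm2$frequency, 1)
  # two replicates at 0.2 and 0.4 -> mean 0.3, SEM 0.1
  f1 <- make_contact_series(emb, 15, 5, 1)$replicates[[1]]
  f2 <- make_contact_series(emb, 15, 5, 1:2)$replicates[[1]]
  traj3 <- trajectory_set(traj$topology, list(f1, f2), 100, 0)
  cm3 <- contact_frequency(traj3, 15, partners)
  expect_equal(cm3$frequency, 0.3)
  expect_equal(cm3$sem, 0.1)
})

test_that("frequencies are invariant to frame order and rigid transforms,
           and monotone in the cutoff", {
  emb <- fix_embedded(seed = 3)
  traj <- make_contact_series(emb, 14, n_frames = 6,
                              contact_frames = c(1, 4))
  partners <- list(phosphate = atom_select(traj$topology, subrole = "phosphate"))
  cm <- contact_frequency(traj, 13:16, partners)
  # frame order
  rev_traj <- traj
  rev_traj$replicates[[1]] <- rev(traj$replicates[[1]])
  for (i in seq_along(rev_traj$replicates[[1]]))
    rev_traj$replicates[[1]][[i]]$time <- (i - 1) * 100
  cm_rev <- contact_frequency(rev_traj, 13:16, partners)
  expect_equal(cm$frequency, cm_rev$frequency)
  # rigid translation of whole frames
  sh_traj <- traj
  sh_traj$replicates[[1]] <- lapply(traj$replicates[[1]], function(f) {
    f$coords <- sweep(f$coords, 2, c(1.3, -0.7, 0.4), `+`); f
  })
  cm_sh <- contact_frequency(sh_traj, 13:16, partners)
  expect_equal(cm$frequency, cm_sh$frequency)
  # enlarging the cutoff never decreases any frequency
  cm_big <- contact_frequency(traj, 13:16, partners, cutoff = 0.8)
  expect_true(all(cm_big$frequency >= cm$frequency))
})

test_that("cell-list search equals the O(N^2) oracle, with bracketing", {
  set.seed(31)
  box <- c(5, 5, 5)
  for (trial in 1:10) {
    na <- sample(20:60, 1); nb <- sample(100:400, 1)
    a <- cbind(runif(na, 0, 5), runif(na, 0, 5), runif(na, 0, 5))
    b <- cbind(runif(nb, 0, 5), runif(nb, 0, 5), runif(nb, 0, 5))
    # add threshold-bracketing partners at +/- 0.01 nm around both cutoffs
    for (cut in c(0.5, 0.35)) {
      b2 <- rbind(b, a[1, ] + c(cut - 0.01, 0, 0), a[1, ] + c(cut + 0.01, 0, 0))
      got <- count_within(a, b2, cut, box, method = "cell")
      want <- oracle_count_within(a, b2, cut, box)
      expect_identical(got, want)
    }
  }
})
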
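# trajectory model: readers/writers, role tagging, selections, stride/discard

test_that("PDB reading converts Angstrom to nm and tags roles", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   60.000   60.000   60.000  90.00  90.00  90.00 P 1           1",
    "HETATM    1  OW  HOH W   1      10.000   0.000   0.000  1.00  0.00           O",
    "END"), p)
  s <- read_structure(p, "pdb")
  expect_equal(s$frame$coords[1, 1], 1.0)
  expect_identical(s$topology$role, "water")
  expect_identical(s$topology$subrole, "water_O")
})

test_that("frame_table rows map directly onto atom records", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#FRAME t=0 box=6 6 9",
               "5\tP\tPOPC\t12\tL\tlipid\tphosphate\t1\t2\t3"), p)
  s <- read_structure(p, "frame_table")
  expect_identical(s$topology$role, "lipid")
  expect_identical(s$topology$subrole, "phosphate")
  expect_identical(s$topology$atom_index, 5L)
  expect_equal(unname(s$frame$coords[1, ]), c(1, 2, 3))
})

test_that("unknown atoms are tagged other with a warning, never dropped", {
  expect_warning(
    top <- topology("XX", "FOO", 1L),
    "tagged 'other'")
  expect_identical(top$role, "other")
  expect_equal(nrow(top), 1L)
})

test_that("incompatible role/subrole combinations are rejected", {
  expect_error(topology("OW", "SOL", 1L, role = "lipid", subrole = "water_O"),
               "incompatible")
  expect_error(topology(c("OW", "OW"), c("SOL", "SOL"), c(1L, 1L),
                        atom_index = c(0L, 0L)),
               "unique")
})

test_that("frame_table round trip is bit-exact in coordinates and tags", {
  sys <- fix_system()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_frame_table(sys$topology, sys$frame, p)
  back <- read_structure(p, "frame_table")
  expect_identical(unname(back$frame$coords), unname(sys$frame$coords))
  expect_identical(back$topology$role, sys$topology$role)
  expect_identical(back$topology$subrole, sys$topology$subrole)
  expect_identical(back$frame$box, sys$frame$box)
})

test_that("multi-MODEL PDB reads as a trajectory with one frame per MODEL", {
  sheet <- fix_sheet()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sheet$topology, list(sheet$frame, sheet$frame), p)
  tr <- read_trajectory(p, stride = 1, discard = 0, dialect = "pdb")
  expect_length(tr$replicates[[1]], 2L)
})

test_that("selections resolve roles, residue ranges, and compose", {
  emb <- fix_embedded()
  top <- emb$topology
  w <- atom_select(top, role = "water", subrole = "water_O")
  expect_true(all(top$subrole[w] == "water_O"))
  # HHQK domain: residues 13-16 of the protein
  hhqk <- atom_select(top, role = "protein", residue = 13:16)
  expect_true(length(hhqk) > 0)
  expect_true(all(top$residue_number[hhqk] %in% 13:16))
  # carbonyl O of the beta1 span
  co <- intersect(atom_select(top, role = "protein", residue = 9:21),
                  atom_select(top, subrole = "carbonyl_O"))
  expect_true(all(top$name[co] == "O"))
  # empty result is legal
  expect_length(atom_select(top, role = "ion", residue = 99999), 0L)
})

test_that("selection algebra: |A u B| + |A n B| = |A| + |B|", {
  top <- fix_embedded()$topology
  set.seed(42)
  for (i in 1:20) {
    a <- atom_select(top, role = sample(c("protein", "lipid", "water", "ion"), 2))
    b <- atom_select(top, residue = sample(nrow(top), 50))
    expect_identical(length(union(a, b)) + length(intersect(a, b)),
                     length(a) + length(b))
  }
})

test_that("stride and discard arithmetic matches floor((span-discard)/stride)+1", {
  sheet <- fix_sheet()
  frames <- lapply(0:9, function(i) {
    f <- sheet$frame; f$time <- i * 100; f
  })
  p <- withr::local_tempfile(fileext = ".tsv")
  write_frame_table(sheet$topology, frames, p)
  tr <- read_trajectory(p, stride = 100, discard = 500)
  expect_length(tr$replicates[[1]], 5L)       # 500..900 ps
  tr0 <- read_trajectory(p, stride = 100, discard = 0)
  expect_length(tr0$replicates[[1]], 10L)     # identity
  expect_error(read_trajectory(p, stride = 100, discard = 5000),
               "no frames remain")
  # property: regular spacing
  for (discard in c(0, 200, 300)) {
    tr <- read_trajectory(p, stride = 100, discard = discard)
    expect_length(tr$replicates[[1]],
                  floor((900 - discard) / 100) + 1)
  }
})

test_that("topology mismatch across replicates is a hard error naming an atom", {
  sheet <- fix_sheet()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_frame_table(sheet$topology, sheet$frame, p1)
  top2 <- sheet$topology
  top2$name[1] <- "CA"
  class(top2) <- class(sheet$topology)
  write_frame_table(top2, sheet$frame, p2)
  expect_error(read_trajectory(c(p1, p2), stride = 100, discard = 0),
               "topology mismatch")
})
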
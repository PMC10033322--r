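# polar transmembrane defect reaction coordinate

test_that("slice grid construction and commensurability", {
  expect_identical(build_slice_grid(2.8, 0.1)$n_slices, 28L)
  expect_identical(build_slice_grid(1.0, 0.5)$n_slices, 2L)
  expect_error(build_slice_grid(2.8, 0.3), "configuration error")
  expect_error(build_slice_grid(-1, 0.1), "> 0")
})

test_that("frame_xi endpoints and planted fractions are exact", {
  g <- build_slice_grid()
  sys <- fix_system()
  expect_identical(frame_xi(sys$frame, sys$topology, g), 0)
  full <- plant_edge_defect(sys, 1:28, g)
  expect_identical(frame_xi(full$frame, full$topology, g), 1)
  part <- plant_edge_defect(sys, 1:7, g)
  expect_identical(frame_xi(part$frame, part$topology, g), 0.25)
})

test_that("empty polar selection is an error distinct from xi = 0", {
  sys <- fix_system()
  expect_error(frame_xi(sys$frame, sys$topology, polar = integer(0)),
               "empty polar selection")
})

test_that("slice boundaries assign exact-boundary atoms to the lower slice", {
  g <- build_slice_grid()
  # z = 0 is the boundary between 0-based slices 13 and 14
  expect_identical(edgepore:::slice_index(0, g), 13L)
  expect_identical(edgepore:::slice_index(1e-12, g), 14L)
  expect_identical(edgepore:::slice_index(-1.4, g), NA_integer_)  # bottom face
  expect_identical(edgepore:::slice_index(1.4, g), 28L - 1L)      # top face
  expect_identical(edgepore:::slice_index(1.41, g), NA_integer_)
})

test_that("per-edge xi follows the lateral cutoff attribution", {
  g <- build_slice_grid()
  emb <- fix_embedded()
  edges <- attr(emb, "edges")
  planted <- plant_edge_defect(emb, 1:28, g, edge = edges$edgeA)
  expect_identical(edge_xi(planted$frame, planted$topology, g,
                           edges$edgeA), 1)
  expect_identical(edge_xi(planted$frame, planted$topology, g,
                           edges$edgeB), 0)
  expect_identical(frame_xi(planted$frame, planted$topology, g), 1)
  # shrinking the cutoff far enough excludes the column from both edges
  tiny_a <- edge_definition("a", edges$edgeA$atoms, lateral_cutoff = 0.01)
  expect_identical(edge_xi(planted$frame, planted$topology, g, tiny_a), 0)
  # a column within reach of both edges counts toward both
  both_a <- edge_definition("a", edges$edgeA$atoms, lateral_cutoff = 5)
  both_b <- edge_definition("b", edges$edgeB$atoms, lateral_cutoff = 5)
  expect_identical(edge_xi(planted$frame, planted$topology, g, both_a), 1)
  expect_identical(edge_xi(planted$frame, planted$topology, g, both_b), 1)
})

test_that("xi is invariant under in-plane translation and atom relabeling,
           and monotone under added polar atoms", {
  g <- build_slice_grid()
  set.seed(11)
  sys <- fix_system(seed = 5)
  for (trial in 1:10) {
    planted <- plant_edge_defect(sys, sample(28, sample(28, 1)), g)
    xi0 <- frame_xi(planted$frame, planted$topology, g)
    # rigid in-plane translation
    f2 <- planted$frame
    f2$coords[, 1] <- f2$coords[, 1] + runif(1, -3, 3)
    f2$coords[, 2] <- f2$coords[, 2] + runif(1, -3, 3)
    expect_identical(frame_xi(f2, planted$topology, g), xi0)
    # permutation of atom order
    perm <- sample(nrow(planted$topology))
    topp <- planted$topology[perm, ]
    class(topp) <- class(planted$topology)
    topp$atom_index <- seq_len(nrow(topp)) - 1L
    fp <- frame_snapshot(planted$frame$coords[perm, , drop = FALSE],
                         planted$frame$box, 0)
    expect_identical(frame_xi(fp, topp, g), xi0)
    # monotonicity: adding one more polar atom never decreases xi
    more <- plant_edge_defect(planted, sample(28, 1), g)
    expect_gte(frame_xi(more$frame, more$topology, g), xi0)
  }
})

test_that("slice implementation equals the brute-force z-scan oracle", {
  g <- build_slice_grid()
  set.seed(12)
  for (trial in 1:20) {
    n <- sample(30:200, 1)
    nm <- rep("OW", n); rn <- rep("SOL", n)
    top <- topology(nm, rn, seq_len(n))
    xyz <- cbind(runif(n, 0, 6), runif(n, 0, 6), runif(n, -4.5, 4.5))
    f <- frame_snapshot(xyz, c(6, 6, 9))
    polar <- seq_len(n)
    expect_identical(frame_xi(f, top, g, polar = polar, center = 0),
                     oracle_xi(f, top, g, polar, center = 0))
  }
})

test_that("per-edge xi never exceeds total xi", {
  g <- build_slice_grid()
  emb <- fix_embedded(seed = 6)
  edges <- attr(emb, "edges")
  set.seed(13)
  for (trial in 1:10) {
    planted <- plant_edge_defect(emb, sample(28, sample(28, 1)), g,
                                 edge = edges$edgeA)
    xi <- frame_xi(planted$frame, planted$topology, g)
    for (e in edges)
      expect_lte(edge_xi(planted$frame, planted$topology, g, e), xi)
  }
})

test_that("xi distribution is a direct count with per-replicate SEM", {
  d <- xi_distribution(c(1, 1, 0, 0), n_slices = 28)
  expect_equal(d$p[d$xi == 0], 0.5)
  expect_equal(d$p[d$xi == 1], 0.5)
  expect_equal(sum(d$p), 1)
  # degenerate single frame
  d1 <- xi_distribution(0.25, n_slices = 28)
  expect_equal(d1$p[abs(d1$xi - 0.25) < 1e-12], 1)
  # planted 3-point distribution recovered exactly by counting
  set.seed(14)
  vals <- sample(c(0, 7 / 28, 1), 1000, replace = TRUE,
                 prob = c(0.2, 0.5, 0.3))
  d3 <- xi_distribution(vals, n_slices = 28)
  expect_identical(d3$count[d3$xi == 0], sum(vals == 0))
  expect_identical(d3$count[abs(d3$xi - 0.25) < 1e-12], sum(vals == 7 / 28))
  expect_identical(d3$count[d3$xi == 1], sum(vals == 1))
  expect_equal(d3$p[d3$xi == 0], mean(vals == 0))
  # two identical replicates -> SEM 0; differing -> analytic two-point SEM
  d2 <- xi_distribution(list(c(0, 1), c(0, 1)), n_slices = 28)
  expect_true(all(d2$sem == 0))
  d4 <- xi_distribution(list(c(0, 0), c(1, 1)), n_slices = 28)
  expect_equal(d4$sem[d4$xi == 0], sd(c(1, 0)) / sqrt(2))
})

test_that("free-energy transform is -RT ln p with undefined zero bins", {
  expect_equal(xi_free_energy(1), 0)
  expect_equal(xi_free_energy(exp(-1)), 0.0083145 * 300, tolerance = 1e-12)
  expect_true(is.na(xi_free_energy(0)))
  expect_error(xi_free_energy(-0.1), "negative")
  # temperature scaling of differences: dG1 - dG2 = RT ln(p2/p1)
  set.seed(15)
  for (trial in 1:10) {
    p <- runif(2)
    temp <- runif(1, 200, 400)
    dg <- xi_free_energy(p, temperature = temp)
    expect_equal(dg[1] - dg[2], 0.0083145 * temp * log(p[2] / p[1]),
                 tolerance = 1e-9)
  }
})
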
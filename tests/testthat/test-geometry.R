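p5 <- sim_params(n_bonds = 25, r_sep = 5)   # L = 2, D = 1.2

test_that("points classify into the four regions correctly", {
  expect_identical(classify_region(c(0, 0, 1), p5), "cis")
  expect_identical(classify_region(c(0, 0, -1), p5), "pore")
  expect_identical(classify_region(c(0, 0, -(2 + 5 / 2)), p5), "trans")
  expect_identical(classify_region(c(2, 0, -1), p5), "membrane")
  expect_identical(classify_region(c(0, 0, -6.9), p5), "trans")
  expect_identical(classify_region(c(0, 0, -8), p5), "membrane")
  # matrix input vectorises
  m <- rbind(c(0, 0, 1), c(0.5, 0, -0.5), c(0, 3, -4))
  expect_identical(classify_region(m, p5), c("cis", "pore", "trans"))
})

test_that("wall gaps match hand-computed distances", {
  expect_equal(wall_gap(c(0, 0, -1), p5), 0.6)          # on-axis: D/2
  expect_equal(wall_gap(c(1, 0, -4), p5), 2.0)          # min of the faces
  expect_equal(wall_gap(c(0, 0, -4.5), p5), 2.5)        # slab midpoint
  # under the open pore the nearest material is the rim, not the face plane
  expect_equal(wall_gap(c(0, 0, -4), p5), sqrt(2^2 + 0.6^2))
  # cis point facing the mouth: true distance to the rim circle
  expect_equal(wall_gap(c(0, 0, 0.3), p5), sqrt(0.3^2 + 0.6^2))
  # cis point over membrane material: distance to the face
  expect_equal(wall_gap(c(3, 0, 0.7), p5), 0.7)
})

test_that("gap is zero exactly on solid surfaces and NA strictly inside", {
  on_surface <- rbind(
    c(5, 0, 0),       # cis face
    c(0.6, 0, -1),    # pore cylinder wall
    c(3, 0, -2),      # trans-side face of the left membrane
    c(1, 1, -7))      # right membrane face (L + R = 7)
  expect_equal(unname(wall_gap(on_surface, p5)), rep(0, 4))
  expect_true(is.na(wall_gap(c(2, 0, -1), p5)))     # inside left membrane
  expect_true(is.na(wall_gap(c(0, 0, -7.5), p5)))   # inside right membrane
})

test_that("classification and gap are consistent on random points", {
  set.seed(1)
  pts <- cbind(runif(500, -4, 4), runif(500, -4, 4), runif(500, -9, 3))
  reg <- classify_region(pts, p5)
  gap <- wall_gap(pts, p5)
  inside <- is.na(gap)
  # only membrane-labelled points can be inside material
  expect_true(all(reg[inside] == "membrane"))
  expect_true(all(gap[!inside] >= 0))
  # far points feel exactly zero wall repulsion
  far <- !inside & gap > p5$rmin_morse
  expect_true(all(wall_energy(gap[far], p5) == 0))
})

test_that("trans-slab gaps are invariant under lateral translation", {
  set.seed(2)
  base <- cbind(runif(100, 1, 5), runif(100, 1, 5), runif(100, -6.9, -2.1))
  shift <- base
  shift[, 1] <- shift[, 1] + 17.3
  shift[, 2] <- shift[, 2] - 42.1
  keep <- sqrt(shift[, 1]^2 + shift[, 2]^2) > p5$d_pore / 2
  expect_equal(wall_gap(shift[keep, ], p5), wall_gap(base[keep, ], p5))
})

test_that("the energy field is continuous across the pore mouth", {
  # walking along the axis through the mouth, gap (hence wall energy)
  # changes continuously: the rim is the nearest surface on both sides
  zs <- seq(0.2, -0.2, by = -0.01)
  g <- wall_gap(cbind(0.1, 0, zs), p5)
  expect_true(all(abs(diff(g)) < 0.02))
})

test_that("initial conformation is valid and straight", {
  p <- sim_params(n_bonds = 10)
  conf <- initial_conformation(p)
  expect_equal(nrow(conf), 11L)
  expect_equal(unname(conf[1, 3]), p$park_z)
  expect_equal(bond_lengths(conf), rep(p$l0, 10))
  expect_equal(interior_angles(conf), rep(pi, 9))
  expect_silent(validate_conformation(conf, p))
  bad <- conf
  bad[5, 3] <- bad[5, 3] + 1    # stretches a bond past lmax
  expect_error(validate_conformation(bad, p), "bond length")
})
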
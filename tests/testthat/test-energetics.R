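p <- sim_params(n_bonds = 25)

test_that("FENE bond energy matches the closed form and diverges at bounds", {
  expect_equal(fene_energy(0.7, p), 0)
  # -(20 * 0.09 / 2) * log(1 - 0.25), evaluated independently
  expect_equal(fene_energy(0.55, p), 0.258913865207, tolerance = 1e-9)
  expect_identical(fene_energy(0.4, p), Inf)
  expect_identical(fene_energy(1.0, p), Inf)
  expect_identical(fene_energy(1.05, p), Inf)
  # convex on (lmin, lmax), minimum at l0, symmetric about l0
  l <- seq(0.45, 0.95, by = 0.01)
  u <- fene_energy(l, p)
  expect_true(all(diff(u, differences = 2) > 0))
  expect_equal(which.min(u), which(l == 0.7))
  expect_equal(fene_energy(0.7 + 0.2, p), fene_energy(0.7 - 0.2, p))
})

test_that("Morse pair energy has its -eps minimum at rmin and a clean tail", {
  expect_equal(morse_energy(0.8, p), -1)
  expect_equal(morse_energy(0.9, p), -0.17320615953, tolerance = 1e-9)
  expect_equal(morse_energy(0.6, p), 14521.7607305, tolerance = 1e-6)
  r <- seq(0.81, 1.49, by = 0.01)
  expect_true(all(diff(morse_energy(r, p)) > 0))    # rises past the minimum
  expect_true(all(morse_energy(r, p) > -1))
  expect_identical(morse_energy(1.5, p), 0)          # truncated at cutoff
  expect_identical(morse_energy(3.0, p), 0)
})

test_that("bending energy vanishes for straight chains and peaks backfolded", {
  expect_equal(bend_energy(pi, 10), 0)
  expect_equal(bend_energy(0, 10), 20)
  expect_equal(bend_energy(pi / 2, 10), 10)
  expect_equal(bend_energy(pi, 70), 0)
})

test_that("wall repulsion is non-negative, continuous at rmin, zero beyond", {
  expect_equal(wall_energy(0.8, p), 0)
  expect_equal(wall_energy(2.0, p), 0)
  expect_equal(wall_energy(0.7, p), 100.464064757, tolerance = 1e-8)
  g <- seq(0.05, 1.4, by = 0.005)
  u <- wall_energy(g, p)
  expect_true(all(u >= 0))
  expect_true(all(diff(u) <= 0))                     # monotone repulsive
  expect_lt(wall_energy(0.8 - 1e-9, p), 1e-6)        # continuous join
  expect_identical(wall_energy(NA_real_, p), Inf)    # inside material
})

test_that("electric energy is piecewise linear with total drop q*E*L", {
  pE <- sim_params(e_field = 5)
  expect_equal(electric_energy(0, pE), 0)
  expect_equal(electric_energy(1.3, pE), 0)
  expect_equal(electric_energy(-1, pE), -5)
  expect_equal(electric_energy(-3, pE), -10)
  expect_equal(electric_energy(-50, pE), -pE$q_charge * pE$e_field * pE$l_pore)
  # continuity at both pore planes
  expect_equal(electric_energy(-1e-12, pE), 0, tolerance = 1e-9)
  expect_equal(electric_energy(-2 + 1e-12, pE), electric_energy(-2, pE),
               tolerance = 1e-9)
})

test_that("simple conformations have zero (or tail-level) total energy", {
  pc <- sim_params(n_bonds = 1, e_field = 3)
  dimer <- rbind(c(0, 0, 50), c(0, 0, 50.7))
  expect_equal(total_energy(dimer, pc)$u_total, 0)
  pt <- sim_params(n_bonds = 2, kappa = 10, e_field = 3)
  trimer <- rbind(c(0, 0, 50), c(0, 0, 50.7), c(0, 0, 51.4))
  u <- total_energy(trimer, pt)
  expect_equal(u$u_fene, 0)
  expect_equal(u$u_bend, 0)
  expect_equal(u$u_wall, 0)
  expect_equal(u$u_elec, 0)
  # the 1-4 pair at distance 1.4 only contributes the ~1e-6 Morse tail
  expect_lt(abs(u$u_total), 1e-5)
})

test_that("total energy equals an independent brute-force double loop", {
  sc <- sampled_conformation(n_bonds = 9, kappa = 2, seed = 11)
  conf <- sc$conf
  pp <- sim_params(n_bonds = 9, kappa = 2, e_field = 4)
  # place the coil on the cis side near the wall, clear of the pore shadow,
  # so the face distance is the wall gap and the wall term is active
  conf[, 3] <- conf[, 3] - min(conf[, 3]) + 0.15
  conf[, 1] <- conf[, 1] + 5
  # independent oracle: plain loops over the published formulas
  oracle <- 0
  n <- nrow(conf)
  for (i in 1:(n - 1)) {
    l <- sqrt(sum((conf[i + 1, ] - conf[i, ])^2))
    oracle <- oracle - (pp$k_spring * pp$r0^2 / 2) *
      log(1 - ((l - pp$l0) / pp$r0)^2)
  }
  for (i in 1:n) for (j in 1:n) {
    if (j - i > 1) {
      r <- sqrt(sum((conf[i, ] - conf[j, ])^2))
      if (r < pp$cutoff)
        oracle <- oracle + exp(-2 * 24 * (r - 0.8)) - 2 * exp(-24 * (r - 0.8))
    }
  }
  for (i in 2:(n - 1)) {
    b1 <- conf[i, ] - conf[i - 1, ]
    b2 <- conf[i + 1, ] - conf[i, ]
    cth <- -sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2))
    oracle <- oracle + pp$kappa * (1 + cth)
  }
  for (i in 1:n) {
    z <- conf[i, 3]
    g <- z + pp$wall_offset          # cis side above the face here
    if (g <= 0.8) oracle <- oracle + exp(-48 * (g - 0.8)) -
        2 * exp(-24 * (g - 0.8)) + 1
    oracle <- oracle + if (z >= 0) 0 else if (z >= -2) 4 * z else -8
  }
  expect_equal(total_energy(conf, pp)$u_total, oracle, tolerance = 1e-9)
  # the compiled kernel agrees with the R implementation term by term
  ck <- poretrans:::cpp_total_energy(conf, unclass(pp))
  expect_equal(unname(ck["u_total"]), oracle, tolerance = 1e-9)
  expect_equal(unname(ck["u_fene"]), total_energy(conf, pp)$u_fene)
  expect_equal(unname(ck["u_morse"]), total_energy(conf, pp)$u_morse)
})

test_that("breakdown components sum to the total", {
  sc <- sampled_conformation(n_bonds = 7, kappa = 3, seed = 4)
  u <- total_energy(sc$conf, sc$params, free_space = TRUE)
  expect_equal(u$u_total, u$u_fene + u$u_morse + u$u_bend + u$u_wall + u$u_elec)
  expect_s3_class(as.data.frame(u), "data.frame")
})

test_that("truncating the Morse tail at the cutoff is inconsequential", {
  sc <- sampled_conformation(n_bonds = 12, kappa = 1, seed = 9, mcs = 800)
  p1 <- sim_params(n_bonds = 12, kappa = 1, e_field = 0)
  p2 <- sim_params(n_bonds = 12, kappa = 1, e_field = 0, cutoff = 100)
  u1 <- total_energy(sc$conf, p1, free_space = TRUE)$u_total
  u2 <- total_energy(sc$conf, p2, free_space = TRUE)$u_total
  expect_lt(abs(u1 - u2), 1e-4)
})

test_that("delta_energy matches full recomputation and flags hard rejects", {
  pp <- sim_params(n_bonds = 9, kappa = 2, e_field = 4)
  sc <- sampled_conformation(n_bonds = 9, kappa = 2, seed = 21)
  conf <- sc$conf
  conf[, 3] <- conf[, 3] - min(conf[, 3]) + 0.3
  expect_equal(delta_energy(conf, 4, conf[4, ], pp), 0)
  set.seed(33)
  for (k in 1:40) {
    i <- sample(nrow(conf), 1)
    trial <- conf[i, ] + runif(3, -0.25, 0.25)
    du <- delta_energy(conf, i, trial, pp)
    after <- conf
    after[i, ] <- trial
    u0 <- total_energy(conf, pp)$u_total
    u1 <- total_energy(after, pp)$u_total
    if (is.finite(du)) {
      expect_equal(du, u1 - u0, tolerance = 1e-9)
    } else {
      expect_identical(u1, Inf)
    }
  }
  # a trial bond beyond lmax is an immediate infinite rejection
  stretch <- conf[5, ] + (conf[5, ] - conf[4, ]) * 2
  expect_identical(delta_energy(conf, 5, stretch, pp), Inf)
})
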
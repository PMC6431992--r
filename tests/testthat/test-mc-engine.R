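test_that("Metropolis rule accepts downhill moves and rejects infinities", {
  set.seed(1)
  expect_true(all(metropolis_accept(c(-5, -0.01, 0))))
  expect_false(any(metropolis_accept(rep(Inf, 100))))
})

test_that("acceptance frequency at delta U = ln 2 is one half", {
  set.seed(42)
  n <- 1e5
  acc <- mean(metropolis_accept(rep(log(2), n)))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))
})

test_that("trial moves are uniform in monomer and increment", {
  set.seed(7)
  n_draw <- 30000
  idx <- integer(n_draw)
  inc <- matrix(0, n_draw, 3)
  for (k in seq_len(n_draw)) {
    m <- trial_move(10, "translocating", step_max = 0.25)
    idx[k] <- m$index
    inc[k, ] <- m$delta
  }
  expect_true(all(abs(inc) < 0.25))
  se <- 0.25 / sqrt(3) / sqrt(n_draw)
  expect_true(all(abs(colMeans(inc)) < 3 * se))
  expect_gt(chisq.test(table(factor(idx, levels = 1:10)))$p.value, 1e-3)
  # the frozen first monomer is never proposed while relaxing
  relax_idx <- replicate(2000, trial_move(10, "relaxing")$index)
  expect_true(all(relax_idx >= 2))
  expect_gt(chisq.test(table(factor(relax_idx, levels = 2:10)))$p.value, 1e-3)
})

test_that("relaxation keeps the shut-pore constraints and converges", {
  p <- desk_params(n_bonds = 12, kappa = 5)
  eq <- relax(p, seed = 3)
  expect_equal(unname(eq[1, ]), c(0, 0, p$park_z))   # frozen at the mouth
  expect_true(all(eq[-1, 3] >= 0))                   # reflecting shut wall
  expect_true(attr(eq, "converged"))
  wm <- attr(eq, "window_means")
  nw <- length(wm)
  expect_gte(nw, 2)
  expect_lt(abs(wm[nw] - wm[nw - 1]) / max(abs(wm[nw - 1]), 1), p$relax_tol)
  expect_silent(validate_conformation(eq, p, closed_pore = TRUE))
  # same seed, same conformation
  expect_identical(unclass(relax(p, seed = 3)), unclass(eq))
})

test_that("a fully flexible chain equilibrates to a swollen coil", {
  ree2 <- function(N, nrep, minmcs) {
    p <- sim_params(n_bonds = N, kappa = 0, e_field = 0, r_sep = 5,
                    relax_mcs = minmcs, relax_window = 500)
    vapply(seq_len(nrep), function(i) {
      eq <- relax(p, seed = 500 + i)
      sum((eq[nrow(eq), ] - eq[1, ])^2)
    }, numeric(1))
  }
  a <- ree2(6, 40, 1500)
  b <- ree2(24, 40, 8000)
  # excluded volume swells the coil: R^2 grows faster than the chain length
  # (ratio 4 would be ideal random-walk; self-avoiding is ~ 4^1.18 = 5.1)
  expect_gt(mean(b) / mean(a), 4.2)
})

test_that("accumulated move energies match a full recomputation", {
  p <- sim_params(n_bonds = 19, kappa = 10, e_field = 5, r_sep = 5)
  set.seed(8)
  res <- poretrans:::cpp_evolve(
    poretrans:::unclass_matrix(initial_conformation(p)), unclass(p),
    n_mcs = 5000)   # 5000 x 20 = 1e5 trial moves in the full geometry
  expect_lt(abs(res$u_incr - res$u_final) / max(abs(res$u_final), 1), 1e-6)
  # and the R energy module agrees with the kernel on the final state
  expect_equal(total_energy(res$positions, p)$u_total, res$u_final,
               tolerance = 1e-9)
})

test_that("sampled bond lengths follow the l^2 exp(-U_FENE) marginal", {
  p <- sim_params(n_bonds = 1, kappa = 0, e_field = 0)
  s <- sample_free_chain(p, n_samples = 2e5, thin = 25, burn = 500, seed = 42)
  l <- as.numeric(s$bonds)
  dens <- function(x) x^2 * exp(-fene_energy(x, p))
  grid <- seq(p$lmin + 1e-9, p$lmax - 1e-9, length.out = 4001)
  cdf <- cumsum(dens(grid))
  cdf <- cdf / cdf[length(cdf)]
  edges <- c(p$lmin, grid[findInterval((1:19) / 20, cdf)], p$lmax)
  obs <- as.numeric(table(cut(l, edges)))
  expd <- rep(length(l) / 20, 20)
  chi2 <- sum((obs - expd)^2 / expd)
  expect_gt(pchisq(chi2, df = 19, lower.tail = FALSE), 0.01)
})

test_that("sampled bond angles reproduce the closed-form mean cosine", {
  # for the pure bending Boltzmann weight, E[cos theta] = 1/k - coth(k)
  pa <- sim_params(n_bonds = 2, kappa = 2, e_field = 0, eps_morse = 0)
  s <- sample_free_chain(pa, n_samples = 6e4, thin = 30, burn = 500, seed = 7)
  u <- as.numeric(s$cos_angles)
  bm <- colMeans(matrix(u, ncol = 60))     # batch means absorb correlation
  se <- sd(bm) / sqrt(60)
  expect_lt(abs(mean(u) - (-0.537314720728)), 3 * se)
})

test_that("a charged monomer in the pore drifts along -z", {
  p <- sim_params(n_bonds = 1, kappa = 0, e_field = 5, r_sep = 5)
  start <- rbind(c(0, 0, -1.2), c(0, 0, -0.5))
  set.seed(12)
  dz <- vapply(1:150, function(i) {
    res <- poretrans:::cpp_evolve(start, unclass(p), n_mcs = 15)
    mean(res$positions[, 3]) - mean(start[, 3])
  }, numeric(1))
  expect_lt(mean(dz) + 3 * sd(dz) / sqrt(length(dz)), 0)
})

test_that("acceptance statistics are logged and stable across seeds", {
  p <- desk_params(n_bonds = 15, kappa = 10)
  r1 <- run_translocation(p, seed = 5)
  r2 <- run_translocation(p, seed = 6)
  for (r in list(r1, r2)) {
    expect_gt(r$acceptance_rate, 0.05)
    expect_lt(r$acceptance_rate, 0.95)
  }
  expect_lt(abs(r1$acceptance_rate - r2$acceptance_rate), 0.1)
})
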
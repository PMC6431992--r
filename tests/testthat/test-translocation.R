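p <- desk_params(n_bonds = 15, kappa = 5, e_field = 5, r_sep = 5)

test_that("identical seed and parameters give bit-identical records", {
  r1 <- run_translocation(p, seed = 11)
  r2 <- run_translocation(p, seed = 11)
  expect_identical(r1, r2)
  r3 <- run_translocation(p, seed = 12)
  expect_false(r3$tau == r1$tau)
})

test_that("a completed record satisfies the protocol invariants", {
  rec <- run_translocation(p, seed = 21)
  expect_false(rec$failed)
  expect_gt(rec$tau, 0)
  expect_length(rec$waiting, p$n_bonds + 1L)
  expect_true(all(rec$waiting > 0))          # every monomer crosses the pore
  expect_gte(rec$attempts, 1)
  # the last pore exit is the completion time
  expect_equal(max(rec$last_exit, na.rm = TRUE), rec$tau)
  # at completion the whole chain is inside the trans slab
  z <- rec$final_conformation[, 3]
  expect_true(all(z < -p$l_pore))
  expect_true(all(z > -(p$l_pore + p$r_sep)))
  expect_silent(validate_conformation(rec$final_conformation, p))
})

test_that("the event log is consistent with the waiting times", {
  # pick a sample that succeeds on its first attempt so the log covers a
  # single uninterrupted clock
  rec <- NULL
  for (s in 31:60) {
    cand <- run_translocation(p, seed = s, record_events = TRUE)
    if (cand$attempts == 1L) { rec <- cand; break }
  }
  expect_false(is.null(rec))
  ev <- rec$events
  expect_s3_class(ev, "data.frame")
  expect_identical(names(ev), c("mcs", "monomer", "event"))
  expect_identical(ev$event[nrow(ev)], "done")
  expect_equal(ev$mcs[nrow(ev)], rec$tau)
  # every monomer finally exits into trans
  exits <- ev[ev$event == "exit_pore_trans", ]
  expect_setequal(unique(exits$monomer), 0:p$n_bonds)
  # pore residence reconstructed from enter/exit pairs equals W(s)
  for (s in c(0L, 7L, p$n_bonds)) {
    es <- ev[!is.na(ev$monomer) & ev$monomer == s, ]
    t_in <- es$mcs[es$event == "enter_pore"]
    t_out <- es$mcs[grepl("^exit_pore", es$event)]
    # monomer 0 starts inside the mouth: its first residence interval
    # begins at the first observation (t = 1), with no enter event
    if (s == 0L) t_in <- c(1, t_in)
    expect_length(t_out, length(t_in))
    expect_equal(sum(t_out - t_in), unname(rec$waiting[as.character(s)]))
  }
})

test_that("ensembles aggregate records and are order independent", {
  ens <- run_ensemble(p, n_samples = 6, base_seed = 300)
  expect_length(ens$records, 6)
  taus <- vapply(ens$records, `[[`, numeric(1), "tau")
  expect_equal(ens$tau_mean, mean(taus))
  expect_equal(ens$tau_se, sd(taus) / sqrt(6))
  expect_equal(unname(ens$w_mean),
               unname(colMeans(do.call(rbind,
                 lapply(ens$records, `[[`, "waiting")))))
  # reproducible from the same base seed
  ens2 <- run_ensemble(p, n_samples = 6, base_seed = 300)
  expect_identical(ens2$tau, ens$tau)
  # waiting profile ignores record order
  wp1 <- waiting_profile(ens$records)
  wp2 <- waiting_profile(rev(ens$records))
  expect_identical(wp1, wp2)
})

test_that("snapshots are exportable frames of the right shape", {
  rec <- run_translocation(p, seed = 77, snapshot_every = 500)
  expect_gt(length(rec$snapshots), 0)
  last <- rec$snapshots[[length(rec$snapshots)]]
  expect_equal(dim(last), c(p$n_bonds + 1L, 3L))
  expect_equal(last, unname(unclass(rec$final_conformation)[, ]),
               ignore_attr = TRUE)
})
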
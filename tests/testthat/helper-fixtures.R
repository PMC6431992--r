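# Small fast parameter sets and hand-built records used across tests.

desk_params <- function(n_bonds = 15, kappa = 5, e_field = 5, r_sep = 5, ...) {
  sim_params(n_bonds = n_bonds, kappa = kappa, e_field = e_field,
             r_sep = r_sep, relax_window = 500, max_mcs = 1e6, ...)
}

# a minimal translocation_record stand-in with prescribed fields
fake_record <- function(tau, waiting, failed = FALSE) {
  names(waiting) <- seq_along(waiting) - 1L
  structure(list(tau = tau, waiting = waiting, failed = failed,
                 attempts = 1L, acceptance_rate = 0.5, seed = 1L,
                 last_exit = rep(tau, length(waiting))),
            class = "translocation_record")
}

# an equilibrated dilute conformation for energy tests (deterministic)
sampled_conformation <- function(n_bonds = 9, kappa = 2, seed = 11,
                                 mcs = 400) {
  p <- sim_params(n_bonds = n_bonds, kappa = kappa, e_field = 0)
  set.seed(seed)
  res <- poretrans:::cpp_evolve(
    poretrans:::unclass_matrix(initial_conformation(p)),
    unclass(p), n_mcs = mcs, free_space = TRUE)
  list(conf = res$positions, params = p)
}
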
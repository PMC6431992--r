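#' Metropolis acceptance rule
#'
#' Accepts a trial move with probability `min(1, exp(-delta_u / kbt))`;
#' downhill and neutral moves (`delta_u <= 0`) are always accepted and an
#' infinite energy difference is always rejected. Draws from R's RNG, so
#' results are reproducible under [set.seed()].
#'
#' @param delta_u energy difference(s) of the trial move, in `k_B T`.
#' @param kbt thermal energy (default 1).
#' @return Logical vector of accept decisions.
#' @export
metropolis_accept <- function(delta_u, kbt = 1) {
  p <- exp(-delta_u / kbt)
  p[delta_u <= 0] <- 1
  p[is.na(p)] <- 0            # Inf - Inf guards
  runif(length(delta_u)) < p
}

#' Propose a single-monomer trial move
#'
#' Picks a monomer uniformly from the movable set and draws each coordinate
#' increment uniformly from `(-step_max, step_max)`. During the relaxation
#' phase monomer 0 is frozen at the shut pore mouth and is never proposed.
#'
#' @param n_monomers number of monomers (`n_bonds + 1`).
#' @param phase `"translocating"` (all monomers movable) or `"relaxing"`
#'   (monomer 0 excluded).
#' @param step_max half-width of the increment interval.
#' @return A list with `index` (1-based monomer row) and `delta`
#'   (length-3 displacement).
#' @export
trial_move <- function(n_monomers, phase = c("translocating", "relaxing"),
                       step_max = 0.25) {
  phase <- match.arg(phase)
  lo <- if (phase == "relaxing") 2L else 1L
  index <- lo + floor(runif(1) * (n_monomers - lo + 1L))
  index <- min(as.integer(index), n_monomers)
  list(index = index, delta = runif(3, -step_max, step_max))
}

#' Equilibrate the chain on the cis side with the pore shut
#'
#' Starting from the straight construction of [initial_conformation()],
#' runs Metropolis dynamics with monomer 0 frozen at the pore mouth and a
#' reflecting closed wall at z = 0 (trial z < 0 rejected for the mobile
#' monomers). Stops when the mean total energy of consecutive windows of
#' `relax_window` MCS agrees to relative tolerance `relax_tol`, after a
#' hard minimum of `max(relax_mcs, 50 * n_bonds^2)` MCS and at most
#' `relax_max_mcs` MCS. The quadratic floor is the slow conformational
#' (Rouse-like) relaxation time of the grafted coil under local-move
#' dynamics; the energy, which equilibrates much faster than the global
#' conformation, would otherwise satisfy the window criterion while the
#' chain is still far from its equilibrium extension.
#'
#' @param params a [sim_params] object.
#' @param seed optional integer; if given, `set.seed(seed)` is called first.
#' @return The equilibrated conformation matrix (class `conformation`) with
#'   attributes `relax_mcs`, `converged`, `acceptance_rate` and
#'   `window_means` (the per-window mean energies, in `k_B T`).
#' @export
relax <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  init <- initial_conformation(params)
  min_mcs <- min(max(params$relax_mcs, 50 * params$n_bonds^2),
                 params$relax_max_mcs)
  res <- cpp_relax(unclass_matrix(init), unclass(params),
                   as.integer(min_mcs),
                   as.integer(params$relax_window),
                   params$relax_tol,
                   as.integer(params$relax_max_mcs))
  conf <- res$positions
  colnames(conf) <- c("x", "y", "z")
  structure(conf,
            class = c("conformation", class(conf)),
            relax_mcs = res$mcs,
            converged = res$converged,
            acceptance_rate = res$accepts / res$trials,
            window_means = res$window_means)
}

#' Run one translocation sample
#'
#' The full protocol: equilibrate on the cis side ([relax()]), release
#' monomer 0 and open the pore at t = 0, advance Metropolis dynamics in MCS
#' units, restart from the stored equilibrated conformation whenever the
#' chain withdraws (all monomers back on cis, pore empty, after having
#' engaged the pore), and stop when the last monomer's z drops below -L.
#' A sample exceeding `params$max_mcs` MCS is flagged failed.
#'
#' @param params a [sim_params] object.
#' @param seed integer seed for this sample; the sample is a deterministic
#'   function of `(params, seed)`.
#' @param record_events keep a per-MCS event log (pore entries/exits,
#'   withdrawals, completion).
#' @param snapshot_every if > 0, keep a conformation snapshot every that
#'   many MCS (of the final attempt) plus the final frame.
#' @return A `translocation_record`: list with `tau` (MCS), `waiting`
#'   (per-monomer pore residence times W(s), s = 0..N, in MCS), `last_exit`
#'   (MCS of each monomer's final pore exit), `attempts`, `acceptance_rate`
#'   (accepted fraction during the successful attempt), `final_conformation`,
#'   `seed`, `failed`, and optionally `events` / `snapshots`.
#' @examples
#' \donttest{
#' p <- sim_params(n_bonds = 15, kappa = 5, e_field = 5, r_sep = 5,
#'                 relax_mcs = 500, relax_window = 250, max_mcs = 1e6)
#' rec <- run_translocation(p, seed = 1)
#' rec$tau
#' }
#' @export
run_translocation <- function(params, seed, record_events = FALSE,
                              snapshot_every = 0) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(as.integer(seed))
  eq <- relax(params)
  res <- cpp_translocate(unclass_matrix(eq), unclass(params),
                         params$max_mcs, record_events,
                         as.integer(snapshot_every))
  conf <- res$positions
  colnames(conf) <- c("x", "y", "z")
  waiting <- as.numeric(res$waiting)
  names(waiting) <- 0:params$n_bonds
  last_seen <- as.numeric(res$last_seen)
  last_exit <- ifelse(last_seen < 0, NA_real_, last_seen + 1)
  events <- NULL
  if (record_events && !is.null(res$events)) {
    em <- res$events[[1]]
    codes <- c("enter_pore", "exit_pore_trans", "exit_pore_cis",
               "withdrawal", "done")
    events <- data.frame(mcs = em[, 1],
                         monomer = ifelse(em[, 2] < 0, NA_integer_, em[, 2]),
                         event = codes[em[, 3]])
  }
  structure(
    list(tau = res$tau,
         waiting = waiting,
         last_exit = last_exit,
         attempts = res$attempts,
         acceptance_rate = res$accepts_attempt / res$trials_attempt,
         final_conformation = structure(conf, class = c("conformation",
                                                        class(conf))),
         failed = res$failed,
         seed = as.integer(seed),
         relax_mcs = attr(eq, "relax_mcs"),
         events = events,
         snapshots = if (snapshot_every > 0) res$snapshots else NULL),
    class = "translocation_record")
}

#' @export
print.translocation_record <- function(x, ...) {
  if (x$failed) {
    cat("Translocation sample (seed", x$seed, "): FAILED (max_mcs reached)\n")
  } else {
    cat(sprintf("Translocation sample (seed %d): tau = %g MCS, %d attempt(s), acceptance %.1f%%\n",
                x$seed, x$tau, x$attempts, 100 * x$acceptance_rate))
  }
  invisible(x)
}

#' Run an ensemble of independent translocation samples
#'
#' Samples use seeds `base_seed`, `base_seed + 1`, ... and are mutually
#' independent, so results do not depend on execution order. Failed samples
#' (those hitting `max_mcs`) are excluded from the time statistics and
#' reported in `n_failed`.
#'
#' @param params a [sim_params] object.
#' @param n_samples number of samples (default `params$n_samples`).
#' @param base_seed first seed (default `params$base_seed`).
#' @param record_events forwarded to [run_translocation()].
#' @param progress print a line every `progress` samples (0 = quiet).
#' @return A `translocation_ensemble`: list with `params`, `records`,
#'   `tau_mean`, `tau_se`, `tau` (per-sample times), `w_mean` (mean waiting
#'   profile), `n_failed` and `acceptance_mean`.
#' @export
run_ensemble <- function(params, n_samples = params$n_samples,
                         base_seed = params$base_seed,
                         record_events = FALSE, progress = 0) {
  stopifnot(inherits(params, "sim_params"), n_samples >= 1)
  records <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    records[[i]] <- run_translocation(params, seed = base_seed + i - 1,
                                      record_events = record_events)
    if (progress > 0 && i %% progress == 0)
      message("sample ", i, "/", n_samples, "  tau = ", records[[i]]$tau)
  }
  new_ensemble(params, records, base_seed)
}

new_ensemble <- function(params, records, base_seed) {
  ok <- !vapply(records, `[[`, logical(1), "failed")
  tau <- vapply(records[ok], `[[`, numeric(1), "tau")
  wmat <- do.call(rbind, lapply(records[ok], `[[`, "waiting"))
  acc <- vapply(records[ok], `[[`, numeric(1), "acceptance_rate")
  structure(
    list(params = params,
         records = records,
         base_seed = base_seed,
         tau = tau,
         tau_mean = mean(tau),
         tau_se = if (length(tau) > 1) sd(tau) / sqrt(length(tau)) else NA_real_,
         w_mean = colMeans(wmat),
         n_failed = sum(!ok),
         acceptance_mean = mean(acc)),
    class = "translocation_ensemble")
}

#' @export
print.translocation_ensemble <- function(x, ...) {
  p <- x$params
  cat(sprintf("Translocation ensemble: N = %d, kappa = %g, E = %g, R = %g\n",
              p$n_bonds, p$kappa, p$e_field, p$r_sep))
  cat(sprintf("  %d samples (%d failed), base seed %d\n",
              length(x$records), x$n_failed, as.integer(x$base_seed)))
  cat(sprintf("  mean tau = %.4g +/- %.3g MCS, mean acceptance %.1f%%\n",
              x$tau_mean, x$tau_se, 100 * x$acceptance_mean))
  invisible(x)
}

#' @export
summary.translocation_ensemble <- function(object, ...) {
  att <- vapply(object$records, `[[`, numeric(1), "attempts")
  out <- list(
    tau_mean = object$tau_mean, tau_se = object$tau_se,
    tau_median = stats::median(object$tau),
    tau_quartiles = quantile(object$tau, c(0.25, 0.75)),
    n_samples = length(object$records), n_failed = object$n_failed,
    attempts_mean = mean(att),
    acceptance_mean = object$acceptance_mean)
  class(out) <- "summary.translocation_ensemble"
  out
}

#' @export
print.summary.translocation_ensemble <- function(x, ...) {
  cat(sprintf("tau: mean %.4g (se %.3g), median %.4g, IQR [%.4g, %.4g] MCS\n",
              x$tau_mean, x$tau_se, x$tau_median,
              x$tau_quartiles[1], x$tau_quartiles[2]))
  cat(sprintf("%d samples, %d failed; mean attempts %.2f; mean acceptance %.1f%%\n",
              x$n_samples, x$n_failed, x$attempts_mean,
              100 * x$acceptance_mean))
  invisible(x)
}

#' @export
plot.translocation_ensemble <- function(x, ...) {
  wp <- waiting_profile(x)
  plot(wp$s, wp$mean, type = "l", xlab = "monomer s",
       ylab = "W(s) [MCS]", main = "Mean pore waiting time", ...)
  if (!all(is.na(wp$se)))
    arrows(wp$s, wp$mean - wp$se, wp$s, wp$mean + wp$se,
           angle = 90, code = 3, length = 0.02, col = grey(0.6))
  invisible(x)
}

#' Equilibrium sampler for an isolated (dilute) chain
#'
#' Runs the Metropolis kernel on a free chain with walls and field switched
#' off and records every bond length and interior-angle cosine at a fixed
#' thinning interval. Used to validate Boltzmann sampling against the
#' closed-form bond-length and angle marginals.
#'
#' @param params a [sim_params] object (only the chain constants matter).
#' @param n_samples number of recorded configurations.
#' @param thin MCS between recorded configurations.
#' @param burn MCS discarded before recording.
#' @param seed optional integer seed.
#' @return List with matrices `bonds` (`n_samples` x `n_bonds`) and
#'   `cos_angles` (`n_samples` x `n_bonds - 1`, cosines of the interior
#'   angles).
#' @export
sample_free_chain <- function(params, n_samples, thin = 10, burn = 200,
                              seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  init <- initial_conformation(params)
  res <- cpp_evolve(unclass_matrix(init), unclass(params),
                    n_mcs = as.integer(burn + n_samples * thin),
                    closed_pore = FALSE, fix_first = FALSE,
                    free_space = TRUE, record_every = as.integer(thin),
                    burn = as.integer(burn))
  list(bonds = res$bonds, cos_angles = res$cos_angles)
}

unclass_matrix <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}
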
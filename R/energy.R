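#' FENE bond energy
#'
#' Finitely extensible nonlinear elastic bond potential
#' `-(k r0^2 / 2) * log(1 - ((l - l0)/r0)^2)`, zero at the preferred length
#' `l0` and divergent at the extensibility bounds. Lengths at or beyond
#' `(lmin, lmax)` return `Inf` (the move proposing them is always rejected).
#'
#' @param l bond length(s).
#' @param params a [sim_params] object.
#' @return Energy in `k_B T`; vectorised over `l`.
#' @export
fene_energy <- function(l, params) {
  out <- rep(Inf, length(l))
  ok <- l > params$lmin & l < params$lmax
  x <- (l[ok] - params$l0) / params$r0
  out[ok] <- -0.5 * params$k_spring * params$r0^2 * log(1 - x^2)
  out
}

#' Morse excluded-volume pair energy
#'
#' `eps * (exp(-2 alpha (r - rmin)) - 2 exp(-alpha (r - rmin)))`, applied to
#' monomer pairs that are not bonded neighbours (|i - j| > 1) and truncated
#' to zero beyond `params$cutoff`. At the default decay `alpha = 24` the
#' neglected tail is below 1e-7 `k_B T`.
#'
#' @param r pair distance(s), positive.
#' @param params a [sim_params] object.
#' @return Energy in `k_B T`; vectorised over `r`.
#' @export
morse_energy <- function(r, params) {
  e1 <- exp(-params$alpha_morse * (r - params$rmin_morse))
  out <- params$eps_morse * (e1^2 - 2 * e1)
  out[r >= params$cutoff] <- 0
  out
}

#' Bending energy of an interior angle
#'
#' `kappa * (1 + cos(theta))` where `theta` is the interior angle between
#' consecutive bonds ([interior_angles()]): a straight chain has
#' `theta = pi` and zero energy, a full backfold `theta = 0` costs
#' `2 * kappa`.
#'
#' @param theta interior angle(s) in radians, in `[0, pi]`.
#' @param kappa bending stiffness in `k_B T`.
#' @return Energy in `k_B T`.
#' @export
bend_energy <- function(theta, kappa) {
  kappa * (1 + cos(theta))
}

#' Wall repulsion energy
#'
#' Purely repulsive truncated-shifted Morse wall:
#' `eps * (exp(-2 alpha (g - rmin)) - 2 exp(-alpha (g - rmin))) + eps` for a
#' gap `g <= rmin` and exactly 0 beyond, continuous at `g = rmin`. The gap
#' is the distance to the confining solid from [wall_gap()]; `NA` (inside
#' material) maps to `Inf`.
#'
#' @param gap distance(s) to the nearest confining surface.
#' @param params a [sim_params] object.
#' @return Energy in `k_B T`, `>= 0`; vectorised over `gap`.
#' @export
wall_energy <- function(gap, params) {
  out <- numeric(length(gap))
  out[is.na(gap)] <- Inf
  near <- !is.na(gap) & gap <= params$rmin_morse
  e1 <- exp(-params$alpha_morse * (gap[near] - params$rmin_morse))
  out[near] <- params$eps_morse * (e1^2 - 2 * e1) + params$eps_morse
  out
}

#' Electric potential energy of a monomer
#'
#' The uniform field E acts along -z only inside the pore column: the
#' energy is 0 for z >= 0, `q E z` across the pore (-L <= z < 0) and the
#' constant `-q E L` on the trans side, so the force `-dU/dz = -qE` acts
#' exactly across the pore and each monomer gains `q E L` in crossing it.
#'
#' @param z axial coordinate(s).
#' @param params a [sim_params] object.
#' @return Energy in `k_B T`; vectorised over `z`.
#' @export
electric_energy <- function(z, params) {
  qE <- params$q_charge * params$e_field
  out <- qE * pmax(z, -params$l_pore)
  out[z >= 0] <- 0
  out
}

#' Total energy of a conformation, term by term
#'
#' Sums FENE over the `n_bonds` bonds, Morse over all non-bonded pairs
#' within the cutoff, bending over the interior angles, and wall plus
#' electric terms over all monomers.
#'
#' @param conf an `(n_bonds + 1)`-by-3 position matrix.
#' @param params a [sim_params] object.
#' @param closed_pore use the shut-pore wall geometry of the equilibration
#'   phase (see [wall_gap()]).
#' @param free_space if `TRUE`, skip wall and electric terms (an isolated
#'   dilute chain).
#' @return An `energy_breakdown` object: list with `u_fene`, `u_morse`,
#'   `u_bend`, `u_wall`, `u_elec` and their sum `u_total`, in `k_B T`.
#' @examples
#' p <- sim_params(n_bonds = 2, kappa = 10)
#' conf <- initial_conformation(p)
#' total_energy(conf, p, free_space = TRUE)$u_total  # straight chain: 0
#' @export
total_energy <- function(conf, params, closed_pore = FALSE, free_space = FALSE) {
  conf <- as_point_matrix(conf)
  n <- nrow(conf)
  u_fene <- sum(fene_energy(bond_lengths(conf), params))
  u_bend <- if (n >= 3) sum(bend_energy(interior_angles(conf), params$kappa)) else 0
  u_morse <- 0
  if (n >= 3) {
    d <- as.matrix(stats::dist(conf))
    idx <- which(upper.tri(d) & abs(row(d) - col(d)) > 1 & d < params$cutoff,
                 arr.ind = TRUE)
    if (nrow(idx)) u_morse <- sum(morse_energy(d[idx], params))
  }
  if (free_space) {
    u_wall <- 0
    u_elec <- 0
  } else {
    # wall-particle centres sit wall_offset behind the material surface;
    # with the pore shut, monomer 0 is held by the relaxation constraint
    # inside the mouth and carries no wall/field terms
    rows <- if (closed_pore) seq_len(n)[-1] else seq_len(n)
    g <- wall_gap(conf[rows, , drop = FALSE], params, closed_pore) +
      params$wall_offset
    u_wall <- sum(wall_energy(g, params))
    u_elec <- sum(electric_energy(conf[rows, 3], params))
  }
  structure(
    list(u_fene = u_fene, u_morse = u_morse, u_bend = u_bend,
         u_wall = u_wall, u_elec = u_elec,
         u_total = u_fene + u_morse + u_bend + u_wall + u_elec),
    class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (k_B T):\n")
  for (f in c("u_fene", "u_morse", "u_bend", "u_wall", "u_elec", "u_total"))
    cat(sprintf("  %-8s %12.6g\n", f, x[[f]]))
  invisible(x)
}

#' @export
as.data.frame.energy_breakdown <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Energy change of a single-monomer trial move
#'
#' Evaluates `U(trial) - U(current)` touching only the terms that involve
#' the moved monomer: its one or two bonds, up to three interior angles, its
#' non-bonded pairs within the cutoff, and its wall and electric terms.
#' This is the quantity fed to the Metropolis criterion; a trial bond length
#' outside `(lmin, lmax)` or a trial position inside membrane material
#' returns `Inf` (certain rejection).
#'
#' @param conf current position matrix.
#' @param index monomer row index, 1-based (monomer s = index - 1).
#' @param trial_pos length-3 trial position.
#' @param params a [sim_params] object.
#' @param closed_pore,free_space geometry flags as in [total_energy()].
#' @return Scalar energy difference in `k_B T`.
#' @export
delta_energy <- function(conf, index, trial_pos, params,
                         closed_pore = FALSE, free_space = FALSE) {
  conf <- as_point_matrix(conf)
  n <- nrow(conf)
  if (index < 1L || index > n) stop("'index' out of range")
  site <- function(pos_i) {
    u <- 0
    for (j in c(index - 1L, index + 1L)) {
      if (j >= 1L && j <= n) {
        f <- fene_energy(sqrt(sum((pos_i - conf[j, ])^2)), params)
        if (!is.finite(f)) return(Inf)
        u <- u + f
      }
    }
    if (n >= 3) {
      tmp <- conf
      tmp[index, ] <- pos_i
      for (v in (index - 1L):(index + 1L)) {
        if (v >= 2L && v <= n - 1L) {
          th <- interior_angles(tmp[(v - 1L):(v + 1L), , drop = FALSE])
          u <- u + bend_energy(th, params$kappa)
        }
      }
    }
    others <- setdiff(seq_len(n), (index - 1L):(index + 1L))
    if (length(others)) {
      r <- sqrt(colSums((t(conf[others, , drop = FALSE]) - pos_i)^2))
      r <- r[r < params$cutoff]
      if (length(r)) u <- u + sum(morse_energy(r, params))
    }
    if (!free_space && !(closed_pore && index == 1L)) {
      g <- wall_gap(pos_i, params, closed_pore) + params$wall_offset
      w <- wall_energy(g, params)
      if (!is.finite(w)) return(Inf)
      u <- u + w + electric_energy(pos_i[3], params)
    }
    u
  }
  u_new <- site(as.numeric(trial_pos))
  if (!is.finite(u_new)) return(Inf)
  u_new - site(conf[index, ])
}
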
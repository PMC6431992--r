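#' Membrane and pore geometry
#'
#' The coordinate origin sits at the centre of the pore mouth on the cis
#' side; translocation proceeds along -z. The left membrane is the slab
#' `-L <= z <= 0` perforated by a cylindrical pore of radius `D/2` on the z
#' axis; the trans compartment is the laterally unbounded slab
#' `-(L + R) <= z <= -L`; the right membrane fills `z <= -(L + R)`. Both
#' membranes are infinite in x and y, and smooth: wall repulsion acts on the
#' true Euclidean distance to the confining solid, so the energy field is
#' continuous across the pore rim.
#'
#' @name geometry
NULL

#' Classify a point into cis / pore / trans / membrane
#'
#' @param pos a length-3 numeric `(x, y, z)` or an n-by-3 matrix of points.
#' @param params a [sim_params] object.
#' @return A character vector with values among `"cis"` (z >= 0), `"pore"`
#'   (inside the pore cylinder), `"trans"` (the slab between the membranes,
#'   -(L + R) <= z <= -L) and `"membrane"` (inside membrane material, either
#'   the perforated left slab or the right half-space). The labels are
#'   exhaustive and mutually exclusive.
#' @examples
#' p <- sim_params(n_bonds = 25, r_sep = 5)
#' classify_region(c(0, 0, 1), p)    # cis
#' classify_region(c(0, 0, -1), p)   # pore
#' @export
classify_region <- function(pos, params) {
  pos <- as_point_matrix(pos)
  L <- params$l_pore
  half <- params$d_pore / 2
  z <- pos[, 3]
  rho2 <- pos[, 1]^2 + pos[, 2]^2
  out <- character(nrow(pos))
  out[z >= 0] <- "cis"
  out[z <= -L] <- "trans"
  out[z < -(L + params$r_sep)] <- "membrane"   # inside the right membrane
  mid <- z > -L & z < 0
  out[mid] <- ifelse(rho2[mid] < half^2, "pore", "membrane")
  out
}

#' Distance from a point to the nearest confining surface
#'
#' Returns the shortest Euclidean distance from `pos` to the membrane
#' material (including the inner pore wall); this is the argument of the
#' wall repulsion. Corner cases (e.g. a point facing the pore mouth) take
#' the distance to the nearest surface point of the solid, here the pore rim
#' circle, so the resulting energy field is continuous.
#'
#' @inheritParams classify_region
#' @param closed_pore if `TRUE`, the left membrane is treated as an
#'   unperforated wall at z = 0 (the geometry used while the chain
#'   equilibrates on the cis side with the pore shut); the gap is then
#'   simply z.
#' @return Numeric vector of gaps; `NA` flags a point strictly inside
#'   membrane material (infinite wall energy). The gap is 0 exactly on a
#'   solid surface.
#' @examples
#' p <- sim_params(n_bonds = 25, r_sep = 5)
#' wall_gap(c(0, 0, -1), p)      # on the pore axis: D/2
#' wall_gap(c(0, 0, -4.5), p)    # mid-slab for R = 5
#' @export
wall_gap <- function(pos, params, closed_pore = FALSE) {
  pos <- as_point_matrix(pos)
  z <- pos[, 3]
  if (closed_pore) return(z)
  L <- params$l_pore
  half <- params$d_pore / 2
  rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  dz <- pmax(z - 0, -L - z, 0)          # axial distance to the slab [-L, 0]
  dr <- pmax(half - rho, 0)             # radial distance to rho >= D/2
  dleft <- sqrt(dz^2 + dr^2)
  inside_left <- dz == 0 & dr == 0 & z > -L & z < 0 & rho > half
  dleft[dz == 0 & dr == 0] <- 0         # on the slab surface
  dleft[inside_left] <- NA_real_
  dright <- z + L + params$r_sep
  dright[dright < 0] <- NA_real_
  pmin(dleft, dright)
}

as_point_matrix <- function(pos) {
  if (is.null(dim(pos))) {
    if (length(pos) != 3L) stop("a point must have 3 coordinates")
    pos <- matrix(pos, nrow = 1L)
  }
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L) stop("positions must be an n-by-3 matrix")
  storage.mode(pos) <- "double"
  pos
}

#' Build the straight pre-equilibration conformation
#'
#' Monomer 0 is parked at `(0, 0, park_z)` in the shut pore mouth and the
#' remaining monomers extend along +z at the preferred bond length.
#' The construction is trivially self-avoiding and satisfies every bond
#' constraint; [relax()] then equilibrates it.
#'
#' @param params a [sim_params] object.
#' @return An `(n_bonds + 1)`-by-3 matrix of positions (class
#'   `conformation`); row i holds monomer s = i - 1, with s = 0 the leading
#'   monomer.
#' @export
initial_conformation <- function(params) {
  n <- params$n_bonds + 1L
  conf <- cbind(x = numeric(n), y = numeric(n),
                z = params$park_z + params$l0 * (seq_len(n) - 1))
  structure(conf, class = c("conformation", class(conf)))
}

#' Validate a chain conformation
#'
#' Checks shape, finite coordinates, every bond length strictly inside
#' `(lmin, lmax)` and no monomer inside membrane material.
#'
#' @param conf an `(n_bonds + 1)`-by-3 position matrix.
#' @param params a [sim_params] object.
#' @param closed_pore geometry flag as in [wall_gap()].
#' @return `conf`, invisibly; errors describe the first violated constraint.
#' @export
validate_conformation <- function(conf, params, closed_pore = FALSE) {
  conf <- as_point_matrix(conf)
  if (nrow(conf) != params$n_bonds + 1L)
    stop("conformation must have n_bonds + 1 = ", params$n_bonds + 1L, " rows")
  if (!all(is.finite(conf))) stop("non-finite coordinates in conformation")
  b <- bond_lengths(conf)
  if (any(b <= params$lmin | b >= params$lmax))
    stop("bond length outside (lmin, lmax): ",
         paste(signif(b[b <= params$lmin | b >= params$lmax], 4), collapse = ", "))
  g <- wall_gap(conf, params, closed_pore = closed_pore)
  if (anyNA(g)) stop("monomer inside membrane material")
  invisible(conf)
}

#' Bond lengths of a conformation
#' @param conf position matrix.
#' @return Numeric vector of the `n - 1` bond lengths.
#' @export
bond_lengths <- function(conf) {
  d <- diff(as_point_matrix(conf))
  sqrt(rowSums(d^2))
}

#' Interior bond angles of a conformation
#'
#' The interior angle theta at vertex s is the angle between the reversed
#' incoming bond and the outgoing bond, so a straight (collinear) chain has
#' theta = pi and zero bending energy.
#'
#' @param conf position matrix with at least 3 rows.
#' @return Numeric vector of `n - 2` angles in radians, in `[0, pi]`.
#' @export
interior_angles <- function(conf) {
  conf <- as_point_matrix(conf)
  if (nrow(conf) < 3L) return(numeric(0))
  b <- diff(conf)
  n <- nrow(b)
  dots <- rowSums(b[-n, , drop = FALSE] * b[-1, , drop = FALSE])
  nrm <- sqrt(rowSums(b[-n, , drop = FALSE]^2) * rowSums(b[-1, , drop = FALSE]^2))
  acos(pmin(1, pmax(-1, -dots / nrm)))
}
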
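#' Simulation parameters for the translocation model
#'
#' Collects every model constant and run-control knob of the bead-spring
#' nanopore system. The defaults reproduce the reference parameterisation of
#' the model: FENE bonds with spring constant `k_spring = 20` (in units of
#' `k_B T`), preferred bond length `l0 = 0.7` and admissible range
#' `(lmin, lmax) = (0.4, 1.0)` (with `lmax` the unit of length), Morse
#' excluded volume with `alpha_morse = 24`, `rmin_morse = 0.8`,
#' `eps_morse = 1`, a pore of length `l_pore = 2` and diameter
#' `d_pore = 1.2`, one unit charge per monomer, and single-monomer trial
#' displacements drawn uniformly from `(-0.25, 0.25)` per coordinate.
#'
#' Lengths are in units of `lmax`, energies in units of `k_B T`, and times in
#' Monte Carlo steps (one MCS = `n_bonds + 1` trial moves).
#'
#' @param ... named overrides of any field listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{n_bonds}{chain length N; the chain has N + 1 monomers.}
#'   \item{kappa}{bending stiffness of the angle potential kappa*(1 + cos
#'     theta), in `k_B T`.}
#'   \item{e_field}{electric field strength E inside the pore; the driving
#'     force per unit charge along -z.}
#'   \item{r_sep}{separation R between the two confining membranes.}
#'   \item{l_pore, d_pore}{pore length L and diameter D.}
#'   \item{q_charge}{effective charge per monomer.}
#'   \item{k_spring, l0, lmin, lmax, r0}{FENE bond constants; `r0` is the
#'     finite extensibility range and must equal both `lmax - l0` and
#'     `l0 - lmin`.}
#'   \item{alpha_morse, rmin_morse, eps_morse}{Morse decay exponent, minimum
#'     location and depth, shared by excluded volume and wall repulsion.}
#'   \item{wall_offset}{depth of the outermost wall-particle centres behind
#'     the smooth membrane surface. The walls are built from immobile
#'     particles of diameter `rmin_morse`; the smooth-wall repulsion
#'     therefore acts on `wall_gap + wall_offset`, with default
#'     `rmin_morse / 2`. This leaves the pore axis force-free (distance
#'     `d_pore/2 + wall_offset = 1` at the defaults) while keeping the
#'     channel single-file.}
#'   \item{cutoff}{pair-interaction truncation radius; the Morse tail beyond
#'     it is below 1e-7 `k_B T` at the default `alpha_morse`.}
#'   \item{step_max}{half-width of the uniform trial-move increments.}
#'   \item{kbt}{thermal energy; fixed to 1 (energies are dimensionless).}
#'   \item{park_z}{z-coordinate at which monomer 0 is held during cis-side
#'     equilibration: half a preferred bond length inside the pore mouth by
#'     default, so the release at t = 0 starts with the chain threaded into
#'     the entrance while its bond partner remains on the cis side.}
#'   \item{n_samples, base_seed}{ensemble size and seed origin.}
#'   \item{relax_mcs, relax_window, relax_tol, relax_max_mcs}{equilibration
#'     control: configured minimum MCS (raised automatically to the
#'     conformational relaxation floor `50 * n_bonds^2`, see [relax()]),
#'     energy-averaging window, relative window-to-window tolerance, and
#'     hard cap.}
#'   \item{max_mcs}{guard on a single translocation sample; samples
#'     exceeding it are flagged failed.}
#' }
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(n_bonds = 25, kappa = 10, e_field = 5, r_sep = 5)
#' p$r0
#' @export
sim_params <- function(...) {
  p <- default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all arguments to sim_params() must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    # r0 is derived unless explicitly overridden
    if (!("r0" %in% names(dots)) &&
        any(c("l0", "lmin", "lmax") %in% names(dots))) {
      tmp <- modifyList(p, dots)
      dots$r0 <- tmp$lmax - tmp$l0
    }
    p <- modifyList(p, dots)
  }
  validate_params(p)
}

default_params <- function() {
  list(
    n_bonds = 150,
    kappa = 10,
    e_field = 5,
    r_sep = 5,
    l_pore = 2,
    d_pore = 1.2,
    q_charge = 1,
    k_spring = 20,
    l0 = 0.7,
    lmin = 0.4,
    lmax = 1.0,
    r0 = 0.3,
    alpha_morse = 24,
    rmin_morse = 0.8,
    eps_morse = 1,
    wall_offset = 0.4,
    cutoff = 1.5,
    step_max = 0.25,
    kbt = 1,
    park_z = -0.35,
    n_samples = 5000,
    base_seed = 1,
    relax_mcs = 2000,
    relax_window = 1000,
    relax_tol = 0.01,
    relax_max_mcs = 2e6,
    max_mcs = 1e8
  )
}

validate_params <- function(p) {
  num1 <- function(field, lower = -Inf, strict = TRUE) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", field, "' must be a finite numeric scalar")
    if (strict && v <= lower)
      stop("parameter '", field, "' must be > ", lower)
    if (!strict && v < lower)
      stop("parameter '", field, "' must be >= ", lower)
    invisible(v)
  }
  num1("n_bonds", 0)
  if (p$n_bonds != round(p$n_bonds)) stop("'n_bonds' must be an integer")
  for (f in c("kappa", "e_field")) num1(f, 0, strict = FALSE)
  for (f in c("r_sep", "l_pore", "d_pore", "k_spring", "l0", "lmin", "lmax",
              "alpha_morse", "rmin_morse", "step_max", "kbt",
              "cutoff")) num1(f, 0)
  num1("park_z", -Inf)
  if (p$park_z <= -p$l_pore || p$park_z >= p$l0)
    stop("'park_z' must place monomer 0 at the pore mouth (-l_pore < park_z < l0)")
  num1("eps_morse", 0, strict = FALSE)
  num1("q_charge", 0, strict = FALSE)
  num1("wall_offset", 0, strict = FALSE)
  if (p$wall_offset >= p$rmin_morse)
    stop("'wall_offset' must be smaller than rmin_morse")
  if (!(p$lmin < p$l0 && p$l0 < p$lmax))
    stop("bond lengths must satisfy lmin < l0 < lmax (got ",
         p$lmin, ", ", p$l0, ", ", p$lmax, ")")
  if (abs((p$lmax - p$l0) - (p$l0 - p$lmin)) > 1e-9)
    stop("l0 must be the midpoint of (lmin, lmax): lmax - l0 must equal l0 - lmin")
  if (abs(p$r0 - (p$lmax - p$l0)) > 1e-9)
    stop("r0 must equal lmax - l0 (= l0 - lmin)")
  if (p$cutoff < p$rmin_morse)
    stop("'cutoff' must not truncate the repulsive core (cutoff >= rmin_morse)")
  num1("n_samples", 0)
  if (p$n_samples != round(p$n_samples)) stop("'n_samples' must be an integer")
  for (f in c("relax_mcs", "relax_window", "relax_max_mcs", "max_mcs")) num1(f, 0)
  num1("relax_tol", 0)
  if (!is.numeric(p$base_seed) || length(p$base_seed) != 1L)
    stop("'base_seed' must be a numeric scalar")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Translocation model parameters\n")
  cat(sprintf("  chain:  N = %d bonds (%d monomers), kappa = %g kT\n",
              x$n_bonds, x$n_bonds + 1L, x$kappa))
  cat(sprintf("  drive:  E = %g (force qE = %g per monomer in the pore)\n",
              x$e_field, x$q_charge * x$e_field))
  cat(sprintf("  slab:   R = %g, pore L = %g, D = %g\n",
              x$r_sep, x$l_pore, x$d_pore))
  cat(sprintf("  bonds:  FENE k = %g, l0 = %g in (%g, %g)\n",
              x$k_spring, x$l0, x$lmin, x$lmax))
  cat(sprintf("  pairs:  Morse alpha = %g, rmin = %g, eps = %g, cutoff = %g\n",
              x$alpha_morse, x$rmin_morse, x$eps_morse, x$cutoff))
  cat(sprintf("  moves:  step (-%g, %g), kbt = %g\n",
              x$step_max, x$step_max, x$kbt))
  cat(sprintf("  run:    %d samples, base seed %d, max %g MCS/sample\n",
              x$n_samples, as.integer(x$base_seed), x$max_mcs))
  invisible(x)
}

#' Read simulation parameters from a YAML or JSON config file
#'
#' Missing keys take the model defaults (an empty file reproduces the
#' reference system exactly); unknown keys are an error so typos cannot
#' silently change a run.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file holding a flat
#'   mapping of `sim_params` fields.
#' @return A validated [sim_params] object.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '", ext, "' (use yaml or json): ", path)
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a flat mapping of parameter fields")
  do.call(sim_params, raw)
}

#' Write simulation parameters to a YAML or JSON config file
#'
#' @param params a [sim_params] object.
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    "yaml" = , "yml" = yaml::write_yaml(x, path),
    "json" = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE),
    stop("unsupported config format '", ext, "': ", path)
  )
  invisible(path)
}
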
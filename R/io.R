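#' Write conformations as an XYZ trajectory
#'
#' Standard XYZ text format: atom count line, comment line, then one
#' `sym x y z` row per monomer; multiple frames are concatenated.
#'
#' @param frames a position matrix or a list of position matrices.
#' @param path output file.
#' @param comment comment line (recycled over frames).
#' @param symbol element symbol used for every monomer.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, comment = "poretrans frame",
                      symbol = "C") {
  if (is.matrix(frames) || (is.numeric(frames) && !is.list(frames)))
    frames <- list(frames)
  comment <- rep_len(comment, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    m <- as_point_matrix(frames[[i]])
    writeLines(as.character(nrow(m)), con)
    writeLines(comment[i], con)
    writeLines(sprintf("%s %.8f %.8f %.8f", symbol, m[, 1], m[, 2], m[, 3]),
               con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path file written by [write_xyz()] or any plain XYZ file.
#' @return A list of n-by-3 position matrices, one per frame, with the
#'   comment lines attached as the `"comments"` attribute.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  comments <- character()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected an atom count at line ", i)
    comments <- c(comments, lines[i + 1L])
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    colnames(m) <- c("x", "y", "z")
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  attr(frames, "comments") <- comments
  frames
}

#' Write the per-sample event log as CSV
#'
#' Columns `mcs`, `monomer_index`, `event` with events among `enter_pore`,
#' `exit_pore_trans`, `exit_pore_cis`, `withdrawal`, `done`. Times are in
#' MCS from the release of the first monomer (clock resets on withdrawal).
#'
#' @param record a `translocation_record` produced with
#'   `record_events = TRUE`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(record, path) {
  if (is.null(record$events))
    stop("record has no event log; rerun with record_events = TRUE")
  ev <- record$events
  names(ev) <- c("mcs", "monomer_index", "event")
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Write ensemble or sweep results to a directory
#'
#' Persists a run reproducibly: a JSON manifest (resolved parameters,
#' package version, seeds, timestamp, file list) plus CSV tables. For an
#' ensemble: a one-row summary, the waiting-time profile W(s) and the
#' translocation-time histogram; units are stated in the headers (times in
#' MCS, energies in k_B T, lengths in units of lmax). For a sweep: the
#' sweep table and a JSON record of the power-law fit. Existing files are
#' never overwritten unless `force = TRUE`.
#'
#' @param x a `translocation_ensemble` or `tau_sweep`.
#' @param dir output directory (created if missing).
#' @param force overwrite existing files.
#' @param prefix filename prefix; default is derived from the parameter
#'   values so distinct runs get distinct names.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(x, dir, force = FALSE, prefix = NULL) {
  UseMethod("write_results")
}

#' @export
write_results.translocation_ensemble <- function(x, dir, force = FALSE,
                                                 prefix = NULL) {
  p <- x$params
  if (is.null(prefix))
    prefix <- sprintf("run_N%d_kappa%g_E%g_R%g", p$n_bonds, p$kappa,
                      p$e_field, p$r_sep)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_summary.csv", "_waiting.csv",
                                           "_histogram.csv",
                                           "_manifest.json")))
  check_overwrite(paths, force)

  summary_df <- data.frame(
    n_bonds = p$n_bonds, kappa = p$kappa, e_field = p$e_field,
    r_sep = p$r_sep, n_samples = length(x$records), n_failed = x$n_failed,
    tau_mean_mcs = x$tau_mean, tau_se_mcs = x$tau_se,
    acceptance_mean = x$acceptance_mean)
  write.csv(summary_df, paths[1], row.names = FALSE)

  wp <- waiting_profile(x)
  names(wp) <- c("s", "w_mean_mcs", "w_se_mcs")
  write.csv(wp, paths[2], row.names = FALSE)

  h <- tau_histogram(x)
  hist_df <- data.frame(bin_lo_mcs = h$bin_edges[-length(h$bin_edges)],
                        bin_hi_mcs = h$bin_edges[-1],
                        density = h$densities)
  write.csv(hist_df, paths[3], row.names = FALSE)

  manifest <- run_manifest(p, x$base_seed, length(x$records), paths[1:3])
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' @export
write_results.tau_sweep <- function(x, dir, force = FALSE, prefix = NULL) {
  if (is.null(prefix))
    prefix <- sprintf("sweep_%s", x$spec$vary)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_table.csv", "_fit.json",
                                           "_manifest.json")))
  check_overwrite(paths, force)
  tab <- x$table
  names(tab) <- c(x$spec$vary, "tau_mean_mcs", "tau_se_mcs", "n_failed")
  write.csv(tab, paths[1], row.names = FALSE)
  fit <- if (is.null(x$fit)) NULL else
    list(exponent = x$fit$exponent, exponent_se = x$fit$exponent_se,
         intercept_log10 = x$fit$intercept, r_squared = x$fit$r_squared,
         n_points = x$fit$n_points, fit_range = x$spec$fit_range)
  jsonlite::write_json(fit, paths[2], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- run_manifest(x$spec$params, x$spec$base_seed,
                           x$spec$n_samples, paths[1:2],
                           extra = list(vary = x$spec$vary,
                                        grid = x$spec$grid))
  jsonlite::write_json(manifest, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

check_overwrite <- function(paths, force) {
  hit <- paths[file.exists(paths)]
  if (length(hit) && !force)
    stop("refusing to overwrite existing output (use force = TRUE): ",
         paste(hit, collapse = ", "))
  invisible(TRUE)
}

run_manifest <- function(params, base_seed, n_samples, files,
                         extra = list()) {
  c(list(
      package = "poretrans",
      version = as.character(packageVersion("poretrans")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      params = unclass(params),
      base_seed = base_seed,
      sample_seeds = base_seed + seq_len(n_samples) - 1,
      rng = "R default (Mersenne-Twister via set.seed)",
      units = list(time = "MCS", energy = "k_B T", length = "lmax"),
      files = basename(files)),
    extra)
}
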
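#' Mean per-monomer waiting-time profile
#'
#' The waiting time W(s) of monomer s is the total time (in MCS) it spends
#' inside the pore during the successful attempt of one sample; the profile
#' averages W(s) elementwise over samples. Failed samples are excluded.
#' The result is invariant under reordering of the records.
#'
#' @param x a `translocation_ensemble` or a list of `translocation_record`s.
#' @return A data.frame with columns `s` (monomer index 0..N), `mean` and
#'   `se` (standard error; `NA` when only one record is available).
#' @export
waiting_profile <- function(x) {
  records <- if (inherits(x, "translocation_ensemble")) x$records else x
  if (inherits(records, "translocation_record")) records <- list(records)
  records <- Filter(function(r) !r$failed, records)
  if (!length(records)) stop("no successful records to average")
  w <- do.call(rbind, lapply(records, `[[`, "waiting"))
  n <- nrow(w)
  data.frame(
    s = as.integer(colnames(w)),
    mean = colMeans(w),
    se = if (n > 1) apply(w, 2, sd) / sqrt(n) else NA_real_,
    row.names = NULL)
}

#' Locate the early peak (or cusp) of a waiting-time profile
#'
#' Smooths the profile with a centred moving average and returns the first
#' strict interior local maximum inside the search window. When no strict
#' maximum exists but the profile has a kink, the cusp is located as the
#' point of largest discrete second-difference magnitude. A profile that is
#' monotone across the window has no peak and returns `NA`.
#'
#' The early peak marks the moment the translocated subchain first touches
#' the far membrane and must start spreading laterally.
#'
#' @param w numeric waiting-time profile indexed by monomer s = 0..N (e.g.
#'   the `mean` column of [waiting_profile()]), or that data.frame itself.
#' @param window integer range of s to search (default `c(2, 30)`).
#' @param smooth odd width of the moving-average filter (1 = none).
#' @return The monomer index s of the peak/cusp, or `NA_integer_` if the
#'   profile is monotone in the window. Attribute `"kind"` is `"peak"` or
#'   `"cusp"`.
#' @export
peak_position <- function(w, window = c(2, 30), smooth = 3) {
  if (is.data.frame(w)) w <- setNames(w$mean, w$s)
  s_idx <- if (!is.null(names(w))) as.integer(names(w)) else seq_along(w) - 1L
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    ws <- as.numeric(stats::filter(w, k, sides = 2))
    half <- (smooth - 1L) %/% 2L
    ws[seq_len(half)] <- w[seq_len(half)]               # keep edges raw
    ws[length(w) - seq_len(half) + 1L] <- w[length(w) - seq_len(half) + 1L]
  } else ws <- as.numeric(w)
  lo <- max(window[1], s_idx[2])
  hi <- min(window[2], s_idx[length(s_idx) - 1L])
  sel <- which(s_idx >= lo & s_idx <= hi)
  if (length(sel) < 1L) stop("search window outside the profile")
  is_max <- vapply(sel, function(i)
    ws[i] > ws[i - 1L] && ws[i] > ws[i + 1L], logical(1))
  if (any(is_max))
    return(structure(s_idx[sel[which(is_max)[1]]], kind = "peak"))
  # no strict maximum: look for a cusp, an interior point where the
  # curvature magnitude |second difference| peaks well above its
  # background level (a featureless monotone profile has none)
  d2 <- abs(ws[sel - 1L] - 2 * ws[sel] + ws[sel + 1L])
  cand <- which(d2 > pmax(2 * stats::median(d2), 1e-12))
  cand <- cand[vapply(cand, function(k)
    (k == 1L || d2[k] >= d2[k - 1L]) &&
    (k == length(d2) || d2[k] >= d2[k + 1L]), logical(1))]
  if (!length(cand))
    return(structure(NA_integer_, kind = "none"))
  structure(s_idx[sel[cand[which.max(d2[cand])]]], kind = "cusp")
}

#' Histogram and shape of the translocation-time distribution
#'
#' Normalised probability density of the per-sample translocation times,
#' plus the sample skewness g1 used to classify the distribution shape:
#' |g1| small for a near-Gaussian regime, g1 markedly positive for the
#' right-tailed regime seen for stiff chains under strong driving.
#'
#' @param x a `translocation_ensemble`, a list of records, or a numeric
#'   vector of translocation times.
#' @param breaks binning rule passed to [graphics::hist()] (default
#'   Freedman-Diaconis).
#' @return A `tau_histogram`: list with `bin_edges`, `densities` (integrate
#'   to 1), `counts`, `skewness`, `skewness_se` and `n`.
#' @export
tau_histogram <- function(x, breaks = "FD") {
  tau <- if (is.numeric(x)) x
         else if (inherits(x, "translocation_ensemble")) x$tau
         else vapply(Filter(function(r) !r$failed, x), `[[`, numeric(1), "tau")
  n <- length(tau)
  if (n < 1) stop("no translocation times to bin")
  if (diff(range(tau)) == 0) {       # degenerate sample: one occupied bin
    return(structure(
      list(bin_edges = tau[1] + c(-0.5, 0.5), densities = 1, counts = n,
           skewness = 0, skewness_se = skewness_se(n), n = n),
      class = "tau_histogram"))
  }
  h <- graphics::hist(tau, breaks = breaks, plot = FALSE)
  structure(
    list(bin_edges = h$breaks, densities = h$density, counts = h$counts,
         skewness = sample_skewness(tau), skewness_se = skewness_se(n), n = n),
    class = "tau_histogram")
}

# g1 = m3 / m2^(3/2); defined as 0 for a degenerate (constant) sample
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# large-sample standard error of g1 under normality
skewness_se <- function(n) {
  if (n < 4) return(NA_real_)
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

#' @export
print.tau_histogram <- function(x, ...) {
  cat(sprintf("Translocation-time histogram: %d samples, %d bins\n",
              x$n, length(x$counts)))
  cat(sprintf("  skewness g1 = %.3f (se %.3f under normality)\n",
              x$skewness, x$skewness_se))
  invisible(x)
}

#' @export
plot.tau_histogram <- function(x, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  plot(mids, x$densities, type = "h", xlab = "tau [MCS]",
       ylab = "probability density", ...)
  invisible(x)
}

#' Project a conformation onto the x-y plane
#'
#' Drops the axial coordinate; the pore centre maps to (0, 0). Used to
#' inspect post-translocation conformations (coils vs torus-like folds)
#' inside the slab.
#'
#' @param conf a position matrix (e.g. `final_conformation` of a record).
#' @return An n-by-2 matrix of (x, y) pairs in monomer order.
#' @export
xy_projection <- function(conf) {
  conf <- as_point_matrix(conf)
  out <- conf[, 1:2, drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Radius of gyration
#' @param m an n-by-d coordinate matrix.
#' @return Scalar root-mean-square distance from the centroid.
#' @export
radius_of_gyration <- function(m) {
  m <- as.matrix(m)
  sqrt(mean(rowSums(scale(m, scale = FALSE)^2)))
}
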
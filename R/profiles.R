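# Distance-binned trimmed statistics of interaction records, numerical
# integration of spring profiles into force profiles and of force profiles
# into pair potentials, and the hydrophilic-degree (separation-energy)
# statistic.

#' Distance-binned trimmed profile of a record component
#'
#' Bins record values on a regular distance grid (bin centered at `x` covers
#' `[x - w/2, x + w/2)`).  The per-bin mean and standard deviation are
#' computed from the values between the lower and upper trim percentiles
#' (outlier exclusion); the reported percentiles (10/25/75/90) are computed
#' on the untrimmed bin values.  Bins with fewer than `min_count` records are
#' masked (statistics set to NA).
#'
#' @param records data.frame of interaction records.
#' @param component name of the value column to profile (e.g. `"f_s_all"`).
#' @param bin_width bin width in A.
#' @param trim length-2 percentile interval (percent) kept for mean/std.
#' @param min_count minimum records per bin for the bin to be reported.
#' @param distance name of the distance column (`"r"`, or `"r_offset"` for
#'   surface-offset axes).
#' @return data.frame of class `profile_curve` with columns `x`, `mean`,
#'   `p10`, `p25`, `p75`, `p90`, `sd`, `n`, `masked`.
#' @export
bin_profile <- function(records, component, bin_width = 0.1,
                        trim = c(5, 95), min_count = 25L, distance = "r") {
  if (!nrow(records)) stop("empty record stream")
  stopifnot(component %in% names(records), distance %in% names(records))
  v <- records[[component]]
  x <- records[[distance]]
  ok <- is.finite(v) & is.finite(x)
  v <- v[ok]; x <- x[ok]
  # half-open bins [x - w/2, x + w/2); the tiny epsilon keeps exactly
  # representable boundary values on the upper side despite FP rounding
  bin <- floor(x / bin_width + 0.5 + 1e-9)
  centers <- sort(unique(bin))
  groups <- split(v, factor(bin, levels = centers))
  stat <- function(vals) {
    n <- length(vals)
    if (n < min_count)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, n, 1))
    q <- stats::quantile(vals, c(trim[1L], 10, 25, 75, 90, trim[2L]) / 100,
                         names = FALSE)
    inner <- vals[vals >= q[1L] & vals <= q[6L]]
    c(mean(inner), q[2L], q[3L], q[4L], q[5L],
      if (length(inner) > 1L) stats::sd(inner) else 0, n, 0)
  }
  S <- t(vapply(groups, stat, numeric(8L)))
  out <- data.frame(x = centers * bin_width,
                    mean = S[, 1L], p10 = S[, 2L], p25 = S[, 3L],
                    p75 = S[, 4L], p90 = S[, 5L], sd = S[, 6L],
                    n = as.integer(S[, 7L]), masked = S[, 8L] > 0)
  attr(out, "component") <- component
  attr(out, "bin_width") <- bin_width
  class(out) <- c("profile_curve", "data.frame")
  out
}

# contiguous unmasked run of a curve starting at its first unmasked bin
.unmasked_run <- function(curve) {
  w <- attr(curve, "bin_width")
  if (is.null(w)) w <- stats::median(diff(curve$x))
  msk <- if (is.null(curve$masked)) rep(FALSE, nrow(curve)) else curve$masked
  good <- !msk & is.finite(curve$mean)
  if (!any(good)) stop("profile has no unmasked bins")
  i0 <- which(good)[1L]
  run <- i0
  for (k in seq(i0 + 1L, length.out = nrow(curve) - i0)) {
    if (!good[k]) break
    if (abs(curve$x[k] - curve$x[k - 1L] - w) > 1e-9) break
    run <- c(run, k)
  }
  run
}

#' Integrate a spring-constant profile into an approximated force profile
#'
#' The spring constant is the derivative of the effective pairwise force
#' along the pair direction, so the force profile is recovered by cumulative
#' trapezoidal integration from the smallest unmasked bin, plus an offset
#' `g` chosen to make the mean of the approximated force zero over the
#' `zero_window` (where the true force has decayed).
#'
#' @param kcurve a [bin_profile()] curve of a spring component.
#' @param zero_window length-2 window (A) over which the approximated force
#'   averages to zero.
#' @return `profile_curve`-like data.frame with `x` and `mean` (the
#'   approximated force, kcal/mol/A), with attribute `g`.
#' @export
integrate_spring_to_force <- function(kcurve, zero_window = c(8, 12)) {
  run <- .unmasked_run(kcurve)
  if (any(kcurve$masked[seq(run[length(run)] + 1L,
                            length.out = nrow(kcurve) - run[length(run)])] == FALSE))
    stop("gap error: masked bins interrupt the spring profile")
  x <- kcurve$x[run]
  k <- kcurve$mean[run]
  fhat <- pracma::cumtrapz(x, k)[, 1L]
  zw <- x >= zero_window[1L] & x <= zero_window[2L]
  if (!any(zw)) stop("zero window contains no unmasked bins")
  g <- -mean(fhat[zw])
  out <- data.frame(x = x, mean = fhat + g)
  attr(out, "g") <- g
  attr(out, "bin_width") <- attr(kcurve, "bin_width")
  class(out) <- c("profile_curve", "data.frame")
  out
}

#' Integrate a force profile into a pair potential
#'
#' `U(x) = -int f dx` from the first unmasked bin; the additive constant is
#' arbitrary (set so U = 0 at the left edge).
#'
#' @param fcurve a force `profile_curve`.
#' @return data.frame with `x` and `U` (kcal/mol).
#' @export
integrate_force_to_potential <- function(fcurve) {
  run <- .unmasked_run(fcurve)
  x <- fcurve$x[run]
  f <- fcurve$mean[run]
  data.frame(x = x, U = -pracma::cumtrapz(x, f)[, 1L])
}

#' Hydrophilic degree (separation energy) of an interaction profile
#'
#' The degree is the averaged area of the negative regions of the mean
#' effective pairwise force and of its spring-integrated approximation,
#' interpreted as the maximum work required to bring the solvent particle to
#' `upper` A from the atom.  An everywhere-repulsive profile has degree zero
#' (hydrophobic).
#'
#' @param fcurve mean effective-force `profile_curve`.
#' @param fhatcurve approximated force curve from
#'   [integrate_spring_to_force()]; both on the same grid.
#' @param upper integration upper bound (A).
#' @param threshold classification threshold (kcal/mol).
#' @return list of class `hydrophilic_result` with `degree`, `area_f`,
#'   `area_fhat`, `g`, `classification`.
#' @export
hydrophilic_degree <- function(fcurve, fhatcurve, upper = 12,
                               threshold = 0.1) {
  neg_area <- function(curve) {
    run <- .unmasked_run(curve)
    x <- curve$x[run]
    f <- curve$mean[run]
    sel <- x <= upper
    if (sum(sel) < 2L) stop("profile does not span the integration range")
    -pracma::trapz(x[sel], pmin(f[sel], 0))
  }
  xs <- intersect(round(fcurve$x / 1e-6), round(fhatcurve$x / 1e-6))
  if (!length(xs)) stop("grid mismatch between force and spring profiles")
  a_f <- neg_area(fcurve)
  a_fhat <- neg_area(fhatcurve)
  degree <- (a_f + a_fhat) / 2
  structure(list(degree = degree, area_f = a_f, area_fhat = a_fhat,
                 g = attr(fhatcurve, "g"),
                 classification = if (degree > threshold) "hydrophilic"
                                  else "hydrophobic",
                 threshold = threshold),
            class = "hydrophilic_result")
}

#' @export
print.hydrophilic_result <- function(x, ...) {
  cat(sprintf("hydrophilic degree %.4g kcal/mol (%s; area_f = %.4g, area_fhat = %.4g)\n",
              x$degree, x$classification, x$area_f, x$area_fhat))
  invisible(x)
}
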
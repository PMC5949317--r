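#' Kubelka-Munk remission function
#'
#' Converts diffuse reflectance of an optically thick powder layer into the
#' absorption-to-scatter ratio \eqn{k/s} via the Kubelka-Munk remission
#' function \eqn{f(R_\infty) = (1 - R_\infty)^2 / (2 R_\infty)}.
#'
#' @param reflectance Numeric vector (or matrix) of diffuse reflectance values
#'   \eqn{R_\infty}, each in \eqn{(0, 1]}. Reflectance is measured against a
#'   non-absorbing reference (air), so 1 means a perfect reflector.
#' @return \eqn{k/s} values (dimensionless, \eqn{\ge 0}), same shape as the
#'   input. Strictly decreasing in reflectance; 0 at reflectance 1.
#' @seealso [invert_remission()], [absorbance_from_ratio()]
#' @examples
#' remission_function(c(1, 0.5, 0.2)) # 0, 0.25, 1.6
#' @export
remission_function <- function(reflectance) {
  check_numeric(reflectance, "reflectance")
  bad <- which(reflectance <= 0 | reflectance > 1)
  if (length(bad) > 0L) {
    stop(sprintf(
      "`reflectance` must lie in (0, 1]; value %.6g at position %d is outside the domain",
      reflectance[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  (1 - reflectance)^2 / (2 * reflectance)
}

#' Invert the Kubelka-Munk remission function
#'
#' Recovers diffuse reflectance from a \eqn{k/s} ratio. Of the two roots of
#' the quadratic \eqn{f(R) = x} the physical one lies in \eqn{(0, 1]}:
#' \eqn{R_\infty = 1 + x - \sqrt{x^2 + 2x}}. It is evaluated in the
#' algebraically identical form \eqn{1 / (1 + x + \sqrt{x^2 + 2x})}, which is
#' free of the catastrophic cancellation the subtractive form suffers at
#' large \eqn{x}.
#'
#' @param ratio Numeric vector (or matrix) of \eqn{k/s} values, \eqn{\ge 0}.
#' @return Reflectance \eqn{R_\infty \in (0, 1]}, same shape as the input.
#' @examples
#' invert_remission(c(0, 0.25, 1.6)) # 1, 0.5, 0.2
#' @export
invert_remission <- function(ratio) {
  check_numeric(ratio, "ratio")
  bad <- which(ratio < 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "`ratio` (k/s) must be >= 0; value %.6g at position %d is negative",
      ratio[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  1 / (1 + ratio + sqrt(ratio^2 + 2 * ratio))
}

#' Apparent absorbance from the k/s ratio
#'
#' The apparent absorbance of NIR diffuse reflectance,
#' \eqn{A = -\log_{10}\left[1 + k/s - \sqrt{(k/s)^2 + 2(k/s)}\right]},
#' i.e. \eqn{-\log_{10}} of the reflectance implied by the Kubelka-Munk
#' remission function.
#'
#' @inheritParams invert_remission
#' @return Absorbance \eqn{A \ge 0}, same shape as the input; 0 at ratio 0,
#'   strictly increasing, and approaching \eqn{\log_{10}(2 k/s)} for large
#'   ratios.
#' @examples
#' absorbance_from_ratio(4) # ~0.9956
#' @export
absorbance_from_ratio <- function(ratio) {
  -log10(invert_remission(ratio))
}

#' k/s ratio from apparent absorbance
#'
#' Inverse of [absorbance_from_ratio()]: composes \eqn{R_\infty = 10^{-A}}
#' with the remission function.
#'
#' @param absorbance Numeric vector (or matrix) of apparent absorbance values,
#'   \eqn{\ge 0}.
#' @return \eqn{k/s} values, same shape as the input.
#' @examples
#' ratio_from_absorbance(1) # (1 - 0.1)^2 / 0.2 = 4.05
#' @export
ratio_from_absorbance <- function(absorbance) {
  check_numeric(absorbance, "absorbance")
  bad <- which(absorbance < 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "`absorbance` must be >= 0; value %.6g at position %d is negative",
      absorbance[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  remission_function(10^(-absorbance))
}

#' Estimate the scatter coefficient from absorption and reflectance
#'
#' Given an absorption coefficient spectrum \eqn{k(\lambda)} and the measured
#' diffuse reflectance \eqn{R_\infty(\lambda)}, the Kubelka-Munk relation
#' \eqn{f(R_\infty) = k/s} yields \eqn{s = k / f(R_\infty)} per wavelength.
#' For real powders \eqn{k} is not observable, so this applies to situations
#' where \eqn{k} is known independently (e.g. simulated truth); see the
#' package vignette for the discussion of that gap.
#'
#' @param absorption_k Numeric vector, absorption coefficient per wavelength
#'   (inverse length, any consistent unit), \eqn{\ge 0}.
#' @param reflectance Numeric vector of the same length, \eqn{R_\infty \in
#'   (0, 1)} wherever \eqn{k > 0}.
#' @return Scatter coefficient spectrum \eqn{s}, same units as `absorption_k`.
#' @export
estimate_scatter <- function(absorption_k, reflectance) {
  check_numeric(absorption_k, "absorption_k")
  check_numeric(reflectance, "reflectance")
  if (length(absorption_k) != length(reflectance)) {
    stop(sprintf(
      "`absorption_k` (length %d) and `reflectance` (length %d) must be congruent",
      length(absorption_k), length(reflectance)
    ), call. = FALSE)
  }
  if (any(absorption_k < 0)) {
    stop("`absorption_k` must be >= 0", call. = FALSE)
  }
  f <- remission_function(reflectance)
  zero_div <- which(f == 0 & absorption_k > 0)
  if (length(zero_div) > 0L) {
    stop(sprintf(
      "reflectance is 1 (zero remission) where k > 0 at index %d: s is undefined",
      zero_div[1L]
    ), call. = FALSE)
  }
  s <- absorption_k / f
  s[absorption_k == 0] <- 0
  s
}

#' Scale a scatter coefficient by particle size
#'
#' The Kubelka-Munk scatter coefficient of a powder is inversely proportional
#' to its particle diameter, so \eqn{s(d) = s_0 \, d_{ref} / d}.
#'
#' @param diameter Particle diameter(s) in \eqn{\mu m}, \eqn{> 0}.
#' @param reference_scatter Scatter coefficient \eqn{s_0} at the reference
#'   diameter.
#' @param reference_diameter Reference diameter \eqn{d_{ref}} in \eqn{\mu m},
#'   \eqn{> 0}.
#' @return Scatter coefficient(s) at `diameter`, same units as
#'   `reference_scatter`.
#' @export
scatter_from_particle_size <- function(diameter, reference_scatter,
                                       reference_diameter) {
  check_numeric(diameter, "diameter")
  check_numeric(reference_scatter, "reference_scatter")
  check_numeric(reference_diameter, "reference_diameter")
  if (any(diameter <= 0) || any(reference_diameter <= 0) ||
      any(reference_scatter <= 0)) {
    stop("diameters and reference scatter must be > 0", call. = FALSE)
  }
  reference_scatter * reference_diameter / diameter
}

#' Tabulate the Kubelka-Munk curve
#'
#' Evaluates reflectance and apparent absorbance on a grid of \eqn{k/s}
#' values, the curve whose near-linear region underpins quantitative diffuse
#' reflectance modelling.
#'
#' @param ratio_lo,ratio_hi Bounds of the \eqn{k/s} grid, \eqn{0 \le lo < hi}.
#' @param step Grid increment, \eqn{> 0}.
#' @return A tibble with columns `ratio`, `remission` and `absorbance`.
#' @examples
#' km_curve(0, 10, step = 0.5)
#' @export
km_curve <- function(ratio_lo = 0, ratio_hi = 20, step = 0.01) {
  if (!(is.numeric(ratio_lo) && is.numeric(ratio_hi) && ratio_lo >= 0 &&
        ratio_lo < ratio_hi && is.numeric(step) && step > 0)) {
    stop("need 0 <= ratio_lo < ratio_hi and step > 0", call. = FALSE)
  }
  grid <- seq(ratio_lo, ratio_hi, by = step)
  remission <- invert_remission(grid)
  tibble::tibble(
    ratio = grid,
    remission = remission,
    absorbance = -log10(remission)
  )
}

#' Sliding-window linearity profile of absorbance versus k/s
#'
#' Quantifies where the curve \eqn{A(k/s)} is close enough to a straight line
#' for linear calibration: a window of fixed \eqn{k/s} span slides across the
#' configured range, a least-squares line of \eqn{A} against \eqn{k/s} is
#' fitted on each window, and the coefficient of determination plus the
#' largest absolute residual are reported. The curve flattens as
#' \eqn{A \approx \log_{10}(2x)} for large \eqn{x} (curvature
#' \eqn{\propto 1/x^2}), so late windows fit better than early ones.
#'
#' @param ratio_lo,ratio_hi Profiled \eqn{k/s} range (default 0 to 20).
#' @param window_width Span of each window in \eqn{k/s} units (default 4),
#'   must be smaller than the range.
#' @param step Grid increment and window stride (default 0.01).
#' @return A tibble of class `kmnir_linearity` with columns `window_start`,
#'   `window_end`, `fit_r2` and `max_abs_residual`; windows tile the range.
#' @seealso [linear_region_onset()], [autoplot.kmnir_linearity()]
#' @export
linearity_profile <- function(ratio_lo = 0, ratio_hi = 20, window_width = 4,
                              step = 0.01) {
  if (!(ratio_lo >= 0 && ratio_lo < ratio_hi)) {
    stop("need 0 <= ratio_lo < ratio_hi", call. = FALSE)
  }
  if (!(window_width > 0 && window_width < ratio_hi - ratio_lo)) {
    stop("`window_width` must be positive and smaller than the ratio range",
         call. = FALSE)
  }
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  x <- seq(ratio_lo, ratio_hi, by = step)
  npts <- round(window_width / step)
  if (npts < 2L) {
    stop("`step` too coarse: windows would contain fewer than 2 points",
         call. = FALSE)
  }
  y <- absorbance_from_ratio(x)
  n_win <- length(x) - npts
  if (n_win < 1L) {
    stop("configuration leaves no complete window", call. = FALSE)
  }
  # center globally before accumulating moments: the windowed sums then stay
  # well conditioned even when the profiled range sits far from the origin
  x0 <- x - mean(x); y0 <- y - mean(y)
  # running first/second moments over each window via cumulative sums
  m <- npts + 1L                       # points per window (inclusive ends)
  csx <- cumsum(x0); csy <- cumsum(y0)
  csxx <- cumsum(x0 * x0); csxy <- cumsum(x0 * y0); csyy <- cumsum(y0 * y0)
  idx_hi <- seq.int(m, length(x)); idx_lo <- seq_len(n_win)
  sx <- csx[idx_hi] - c(0, csx)[idx_lo]
  sy <- csy[idx_hi] - c(0, csy)[idx_lo]
  sxx <- csxx[idx_hi] - c(0, csxx)[idx_lo]
  sxy <- csxy[idx_hi] - c(0, csxy)[idx_lo]
  syy <- csyy[idx_hi] - c(0, csyy)[idx_lo]
  sxx_c <- sxx - sx^2 / m
  sxy_c <- sxy - sx * sy / m
  syy_c <- syy - sy^2 / m
  slope <- sxy_c / sxx_c
  intercept <- (sy - slope * sx) / m
  r2 <- pmin(1, pmax(0, sxy_c^2 / (sxx_c * syy_c)))
  max_res <- vapply(seq_len(n_win), function(i) {
    ii <- i:(i + npts)
    max(abs(y0[ii] - (intercept[i] + slope[i] * x0[ii])))
  }, numeric(1))
  out <- tibble::tibble(
    window_start = x[seq_len(n_win)],
    window_end = x[seq_len(n_win)] + window_width,
    fit_r2 = r2,
    max_abs_residual = max_res
  )
  class(out) <- c("kmnir_linearity", class(out))
  out
}

#' Onset of the linear region
#'
#' Smallest window start whose straight-line fit of \eqn{A} versus \eqn{k/s}
#' reaches the requested coefficient of determination — the package's
#' operational version of "the curve is linear beyond this k/s".
#'
#' @param profile A [linearity_profile()] tibble.
#' @param r2_threshold Minimum `fit_r2` for a window to count as linear
#'   (default 0.995).
#' @return The `window_start` value at onset, or `NA_real_` if no window
#'   reaches the threshold.
#' @export
linear_region_onset <- function(profile, r2_threshold = 0.995) {
  stopifnot(is.data.frame(profile), all(c("window_start", "fit_r2") %in%
                                          names(profile)))
  ok <- profile$fit_r2 >= r2_threshold
  if (!any(ok)) return(NA_real_)
  min(profile$window_start[ok])
}

#' @export
autoplot.kmnir_linearity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_start,
                                       y = .data$fit_r2)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "window start (k/s)", y = expression(R^2 ~ "of linear fit"),
      title = "Linearity of A vs k/s by sliding window"
    )
}

# shared argument check: numeric, finite, non-empty
check_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop(sprintf("`%s` must be a non-empty numeric vector", name),
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}
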
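#' Standard normal variate (SNV)
#'
#' Standardizes each spectrum to mean 0 and sample standard deviation 1
#' (n - 1 denominator), removing per-spectrum additive and multiplicative
#' scatter effects. Purely row-wise: no information flows between samples.
#'
#' @param spectra Spectra tibble, samples x wavelengths matrix, or a single
#'   spectrum vector.
#' @return Corrected spectra in the same container as the input.
#' @export
snv <- function(spectra) {
  with_spectra(spectra, function(m, wl) {
    if (ncol(m) < 2L) stop("SNV needs spectra with >= 2 points", call. = FALSE)
    mu <- rowMeans(m)
    sdev <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
    zero <- which(sdev == 0)
    if (length(zero) > 0L) {
      stop(sprintf("SNV undefined for constant spectrum in row %d (%s)",
                   zero[1L], rownames(m)[zero[1L]] %||% "unnamed"),
           call. = FALSE)
    }
    (m - mu) / sdev
  })
}

#' Multiplicative scatter correction (MSC)
#'
#' `msc_fit()` stores the mean calibration spectrum as the correction
#' reference; `msc_apply()` regresses every spectrum on that reference by
#' ordinary least squares, \eqn{x \approx a + b \cdot ref}, and returns
#' \eqn{(x - a)/b}. The reference is fitted on calibration data only and
#' reused unchanged for validation data, so no information leaks from
#' validation samples.
#'
#' @param calibration Calibration spectra (tibble or matrix), >= 2 rows.
#' @return `msc_fit()` a preprocessing state object; `msc_apply()` corrected
#'   spectra in the input's container.
#' @export
msc_fit <- function(calibration) {
  m <- if (is.data.frame(calibration)) spectra_matrix(calibration) else
    as.matrix(calibration)
  if (nrow(m) < 2L) stop("MSC needs >= 2 calibration spectra", call. = FALSE)
  new_preprocess_state("MSC", reference_spectrum = colMeans(m))
}

#' @rdname msc_fit
#' @param state A state from `msc_fit()`.
#' @param spectra Spectra to correct.
#' @export
msc_apply <- function(state, spectra) {
  stopifnot(inherits(state, "kmnir_preprocess"), state$method == "MSC")
  ref <- state$reference_spectrum
  with_spectra(spectra, function(m, wl) {
    if (ncol(m) != length(ref)) {
      stop("wavelength count differs from the fitted MSC reference",
           call. = FALSE)
    }
    msc_correct(m, ref)
  })
}

msc_correct <- function(m, ref) {
  ref_c <- ref - mean(ref)
  denom <- sum(ref_c^2)
  b <- as.vector((m - rowMeans(m)) %*% ref_c) / denom
  zero <- which(b == 0)
  if (length(zero) > 0L) {
    stop(sprintf("MSC slope is zero for row %d (%s): spectrum orthogonal to reference",
                 zero[1L], rownames(m)[zero[1L]] %||% "unnamed"),
         call. = FALSE)
  }
  a <- rowMeans(m) - b * mean(ref)
  (m - a) / b
}

#' Extended multiplicative scatter correction (EMSC)
#'
#' Like MSC but each spectrum is regressed on a wavelength polynomial plus
#' the reference spectrum: design \eqn{[1, \tilde\lambda, \ldots,
#' \tilde\lambda^p, ref]} with the wavelength axis scaled to \eqn{[-1, 1]}.
#' The fitted polynomial part is subtracted and the residual divided by the
#' reference coefficient. `polynomial_order = 0` reduces to MSC.
#'
#' @inheritParams msc_fit
#' @param polynomial_order Order of the wavelength polynomial (default 2).
#' @param wavelengths Wavelength grid; taken from the tibble when omitted.
#' @return `emsc_fit()` a state object; `emsc_apply()` corrected spectra.
#' @export
emsc_fit <- function(calibration, polynomial_order = 2, wavelengths = NULL) {
  m <- if (is.data.frame(calibration)) spectra_matrix(calibration) else
    as.matrix(calibration)
  if (nrow(m) < 2L) stop("EMSC needs >= 2 calibration spectra", call. = FALSE)
  if (polynomial_order < 0) stop("`polynomial_order` must be >= 0", call. = FALSE)
  if (is.null(wavelengths)) {
    wavelengths <- if (is.data.frame(calibration)) {
      spectra_wavelengths(calibration)
    } else {
      infer_wavelengths(m)
    }
  }
  if (ncol(m) <= polynomial_order + 2L) {
    stop("EMSC design singular: need more wavelengths than polynomial terms + 2",
         call. = FALSE)
  }
  new_preprocess_state("EMSC",
                       reference_spectrum = colMeans(m),
                       polynomial_order = polynomial_order,
                       wavelengths = wavelengths)
}

#' @rdname emsc_fit
#' @param state A state from `emsc_fit()`.
#' @param spectra Spectra to correct.
#' @export
emsc_apply <- function(state, spectra) {
  stopifnot(inherits(state, "kmnir_preprocess"), state$method == "EMSC")
  ref <- state$reference_spectrum
  p <- state$polynomial_order
  wl <- state$wavelengths
  with_spectra(spectra, function(m, wl_in) {
    if (ncol(m) != length(ref)) {
      stop("wavelength count differs from the fitted EMSC reference",
           call. = FALSE)
    }
    lam <- 2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1
    design <- cbind(outer(lam, 0:p, `^`), ref)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      stop("EMSC design matrix is singular", call. = FALSE)
    }
    coefs <- qr.coef(qrd, t(m))          # (p + 2) x n_samples
    b_ref <- coefs[nrow(coefs), ]
    zero <- which(b_ref == 0)
    if (length(zero) > 0L) {
      stop(sprintf("EMSC reference coefficient is zero for row %d", zero[1L]),
           call. = FALSE)
    }
    poly_part <- design[, -ncol(design), drop = FALSE] %*%
      coefs[-nrow(coefs), , drop = FALSE]
    t((t(m) - poly_part)) / b_ref
  })
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial convolution for smoothing (`deriv = 0`) or
#' smoothed derivatives, delegating to [signal::sgolayfilt()]. Edges are
#' handled by evaluating the first and last window's fitted polynomial, so
#' output length equals input length and stays aligned with the wavelength
#' grid. Derivatives are scaled by the grid spacing (units per nm).
#'
#' @inheritParams snv
#' @param window Odd number of points in the moving window (default 9, the
#'   classic nine-point filter).
#' @param polyorder Polynomial order, `< window` (default 2 for smoothing and
#'   first derivative; use 3 for second derivatives).
#' @param deriv Derivative order, `<= polyorder` (default 0 = smoothing).
#' @param spacing Wavelength spacing in nm; taken from the tibble when
#'   omitted, 1 otherwise.
#' @return Filtered spectra in the input's container.
#' @export
savitzky_golay <- function(spectra, window = 9, polyorder = 2, deriv = 0,
                           spacing = NULL) {
  if (window %% 2 != 1 || window <= polyorder || deriv > polyorder ||
      polyorder < 0 || deriv < 0) {
    stop("need odd `window` > `polyorder` >= `deriv` >= 0", call. = FALSE)
  }
  with_spectra(spectra, function(m, wl) {
    if (ncol(m) < window) {
      stop(sprintf("spectra have %d points, fewer than the %d-point window",
                   ncol(m), window), call. = FALSE)
    }
    ts <- spacing %||%
      (if (length(wl) > 1 && !all(wl == seq_along(wl))) wl[2] - wl[1] else 1)
    t(apply(m, 1L, signal::sgolayfilt, p = polyorder, n = window, m = deriv,
            ts = ts))
  })
}

#' Row-wise normalization
#'
#' @inheritParams snv
#' @param mode `"unit"` (default, Euclidean norm 1), `"max"` (maximum 1), or
#'   `"area"` (integral over wavelength equal to 1, using the grid spacing).
#' @param spacing Wavelength spacing in nm for area mode; inferred when
#'   possible.
#' @return Normalized spectra in the input's container.
#' @export
normalize_spectra <- function(spectra, mode = c("unit", "max", "area"),
                              spacing = NULL) {
  mode <- match.arg(mode)
  with_spectra(spectra, function(m, wl) {
    ts <- spacing %||%
      (if (length(wl) > 1 && !all(wl == seq_along(wl))) wl[2] - wl[1] else 1)
    norm <- switch(mode,
      unit = sqrt(rowSums(m^2)),
      max = apply(abs(m), 1L, max),
      area = rowSums(m) * ts
    )
    zero <- which(norm == 0)
    if (length(zero) > 0L) {
      stop(sprintf("zero-norm spectrum in row %d cannot be normalized",
                   zero[1L]), call. = FALSE)
    }
    m / norm
  })
}

#' Baseline subtraction
#'
#' @inheritParams snv
#' @param mode `"linear"` (default): subtract each spectrum's least-squares
#'   straight line in wavelength; `"offset"`: subtract each spectrum's
#'   minimum.
#' @return Corrected spectra in the input's container.
#' @export
baseline_subtract <- function(spectra, mode = c("linear", "offset")) {
  mode <- match.arg(mode)
  with_spectra(spectra, function(m, wl) {
    if (ncol(m) < 2L) stop("need >= 2 points per spectrum", call. = FALSE)
    if (mode == "offset") {
      m - apply(m, 1L, min)
    } else {
      lam <- wl - mean(wl)
      denom <- sum(lam^2)
      slope <- as.vector(m %*% lam) / denom
      m - rowMeans(m) - outer(slope, lam)
    }
  })
}

#' Named preprocessing pipelines
#'
#' One dispatcher over the preprocessing methods compared in the study, keyed
#' by the conventional labels: `RAW` (none), `MSC`, `SNV`, `EMSC`, `SG9`
#' (nine-point Savitzky-Golay smoothing), `1D+SG` / `2D+SG` (Savitzky-Golay
#' first/second derivative in a single pass), `NORM` (unit-vector
#' normalization) and `BASELINE` (linear detrend). `preprocess_fit()` learns
#' any state (the MSC/EMSC reference spectrum) from calibration data only;
#' `preprocess_apply()` applies a fitted state to new spectra without
#' modifying it.
#'
#' @param calibration Calibration spectra (tibble or matrix).
#' @param method One of the labels above.
#' @param ... Passed to the underlying operator (e.g. `polynomial_order`,
#'   `window`).
#' @return `preprocess_fit()` a `kmnir_preprocess` state; `preprocess_apply()`
#'   corrected spectra in the input's container.
#' @export
preprocess_fit <- function(calibration, method = "RAW", ...) {
  method <- toupper(method)
  if (!method %in% preprocess_methods()) {
    stop(sprintf("unknown preprocessing method '%s'; available: %s", method,
                 paste(preprocess_methods(), collapse = ", ")), call. = FALSE)
  }
  switch(method,
    "MSC" = msc_fit(calibration),
    "EMSC" = emsc_fit(calibration, ...),
    new_preprocess_state(method, ...)
  )
}

#' @rdname preprocess_fit
#' @param state A fitted `kmnir_preprocess` state.
#' @param spectra Spectra to transform.
#' @export
preprocess_apply <- function(state, spectra) {
  stopifnot(inherits(state, "kmnir_preprocess"))
  args <- state$args %||% list()
  switch(state$method,
    "RAW" = spectra,
    "MSC" = msc_apply(state, spectra),
    "EMSC" = emsc_apply(state, spectra),
    "SNV" = snv(spectra),
    "SG9" = do.call(savitzky_golay,
                    c(list(spectra, window = 9, polyorder = 2, deriv = 0),
                      args)),
    "1D+SG" = do.call(savitzky_golay,
                      c(list(spectra, window = 9, polyorder = 2, deriv = 1),
                        args)),
    "2D+SG" = do.call(savitzky_golay,
                      c(list(spectra, window = 9, polyorder = 3, deriv = 2),
                        args)),
    "NORM" = do.call(normalize_spectra, c(list(spectra), args)),
    "BASELINE" = do.call(baseline_subtract, c(list(spectra), args))
  )
}

#' @rdname preprocess_fit
#' @export
preprocess_methods <- function() {
  c("RAW", "MSC", "SNV", "EMSC", "SG9", "1D+SG", "2D+SG", "NORM", "BASELINE")
}

new_preprocess_state <- function(method, reference_spectrum = NULL,
                                 polynomial_order = NULL, wavelengths = NULL,
                                 ...) {
  structure(
    list(method = method, reference_spectrum = reference_spectrum,
         polynomial_order = polynomial_order, wavelengths = wavelengths,
         args = list(...)),
    class = "kmnir_preprocess"
  )
}

#' @export
print.kmnir_preprocess <- function(x, ...) {
  cat("<kmnir preprocessing state:", x$method, ">\n")
  if (!is.null(x$reference_spectrum)) {
    cat("  reference spectrum over", length(x$reference_spectrum),
        "wavelengths\n")
  }
  if (!is.null(x$polynomial_order)) {
    cat("  wavelength polynomial order", x$polynomial_order, "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
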
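#' Kennard-Stone calibration/validation split
#'
#' Deterministic maximin selection of a representative calibration subset:
#' the first two picks are the pair at maximal Euclidean distance; every
#' subsequent pick maximizes its minimum distance to the already-selected
#' samples. Ties are broken toward the smallest row index (and
#' lexicographically smallest pair for the seed pair), so the split is fully
#' reproducible. Remaining rows form the validation set.
#'
#' @param spectra Spectra tibble or samples x wavelengths matrix; distances
#'   are computed in this (usually raw absorbance) space.
#' @param n_calibration Number of calibration samples, `2 <= n_calibration <
#'   n_samples`.
#' @return A list with integer vectors `calibration` (in selection order) and
#'   `validation` (ascending).
#' @export
kennard_stone_split <- function(spectra, n_calibration) {
  m <- if (is.data.frame(spectra)) spectra_matrix(spectra) else
    as.matrix(spectra)
  n <- nrow(m)
  if (!(n_calibration >= 2 && n_calibration < n)) {
    stop(sprintf(
      "`n_calibration` must satisfy 2 <= n_calibration < n_samples (%d)", n),
      call. = FALSE)
  }
  d <- as.matrix(stats::dist(m))
  # seed pair: maximal distance, ties to the lexicographically smallest (i, j)
  best <- c(1L, 2L); best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    j <- which.max(d[i, (i + 1L):n]) + i
    if (d[i, j] > best_d) {
      best_d <- d[i, j]
      best <- c(i, j)
    }
  }
  selected <- best
  min_d <- pmin(d[, best[1L]], d[, best[2L]])
  while (length(selected) < n_calibration) {
    min_d[selected] <- -Inf
    nxt <- which.max(min_d)          # which.max takes the first maximum
    selected <- c(selected, nxt)
    min_d <- pmin(min_d, d[, nxt])
  }
  list(
    calibration = as.integer(selected),
    validation = setdiff(seq_len(n), selected)
  )
}

#' NIPALS partial least squares regression
#'
#' Fits a univariate-response PLS model by NIPALS deflation on the
#' mean-centered spectra and response (centering only, no variance scaling —
#' the usual convention for spectra). With a single response the NIPALS
#' weight for each component is available in closed form
#' (\eqn{w = X^\top y / \|X^\top y\|}), so no inner iteration is needed. The
#' regression vector collapses the sequential components into one set of
#' wavelength coefficients.
#'
#' @param x Calibration spectra tibble or matrix (samples x wavelengths).
#' @param y Numeric response vector (analyte content, mg/g).
#' @param n_latent Number of latent variables, between 1 and
#'   `min(n_samples - 1, n_wavelengths)`.
#' @return An object of class `kmnir_pls` with elements `n_latent`, `x_mean`,
#'   `y_mean`, `weights`, `x_loadings`, `y_loadings`, `scores`,
#'   `regression_vector` and `fitted`.
#' @param strict When `TRUE` (default) a degenerate component — the centered
#'   residuals carry no covariance with the response before `n_latent` is
#'   reached — is an error naming the component; when `FALSE` the model stops
#'   at the last well-defined component (used inside cross-validation where
#'   folds can be rank-deficient).
#' @seealso [predict.kmnir_pls()], [loocv_press()], [tidy.kmnir_pls()]
#' @export
pls_fit <- function(x, y, n_latent, strict = TRUE) {
  m <- if (is.data.frame(x)) spectra_matrix(x) else as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(m); p <- ncol(m)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (stats::sd(y) == 0) stop("response has zero variance", call. = FALSE)
  max_lv <- min(n - 1L, p)
  if (!(n_latent >= 1 && n_latent <= max_lv)) {
    stop(sprintf("`n_latent` must be in [1, %d]", max_lv), call. = FALSE)
  }
  x_mean <- colMeans(m)
  y_mean <- mean(y)
  e <- sweep(m, 2L, x_mean)
  f <- y - y_mean
  w_mat <- matrix(0, p, n_latent)
  p_mat <- matrix(0, p, n_latent)
  t_mat <- matrix(0, n, n_latent)
  q_vec <- numeric(n_latent)
  nw_first <- NA_real_
  achieved <- 0L
  for (a in seq_len(n_latent)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (a == 1L) nw_first <- nw
    degenerate <- nw == 0 || (a > 1L && nw < 1e-10 * nw_first)
    if (!degenerate) {
      w <- w / nw
      tt <- e %*% w
      tt2 <- sum(tt^2)
      degenerate <- tt2 == 0 || (a > 1L && tt2 < 1e-20 * sum(t_mat[, 1]^2))
    }
    if (degenerate) {
      if (strict) {
        stop(sprintf("NIPALS failed at component %d: residual X carries no covariance with y",
                     a), call. = FALSE)
      }
      break
    }
    pp <- crossprod(e, tt) / tt2
    qq <- sum(f * tt) / tt2
    e <- e - tcrossprod(tt, pp)
    f <- f - qq * tt
    w_mat[, a] <- w
    p_mat[, a] <- pp
    t_mat[, a] <- tt
    q_vec[a] <- qq
    achieved <- a
  }
  if (achieved == 0L) {
    stop("NIPALS failed at component 1: X carries no covariance with y",
         call. = FALSE)
  }
  if (achieved < n_latent) {
    n_latent <- achieved
    w_mat <- w_mat[, seq_len(achieved), drop = FALSE]
    p_mat <- p_mat[, seq_len(achieved), drop = FALSE]
    t_mat <- t_mat[, seq_len(achieved), drop = FALSE]
    q_vec <- q_vec[seq_len(achieved)]
  }
  # B = W (P'W)^{-1} q reproduces the sequential model as one linear map
  b <- w_mat %*% solve(crossprod(p_mat, w_mat), q_vec)
  fitted <- as.vector(y_mean + sweep(m, 2L, x_mean) %*% b)
  structure(
    list(
      n_latent = as.integer(n_latent), x_mean = x_mean, y_mean = y_mean,
      weights = w_mat, x_loadings = p_mat, y_loadings = q_vec,
      scores = t_mat, regression_vector = as.vector(b),
      fitted = fitted, wavelengths = infer_wavelengths(m)
    ),
    class = "kmnir_pls"
  )
}

#' Predict from a fitted PLS model
#'
#' @param object A `kmnir_pls` model.
#' @param newdata Spectra tibble, matrix, or single-spectrum vector with the
#'   model's wavelength count.
#' @param ... Unused.
#' @return Predicted responses (mg/g), one per spectrum:
#'   \eqn{\hat y = \bar y + (x - \bar x) \cdot b}.
#' @export
predict.kmnir_pls <- function(object, newdata, ...) {
  m <- if (is.data.frame(newdata)) spectra_matrix(newdata) else
    if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(m) != length(object$x_mean)) {
    stop(sprintf("newdata has %d wavelengths; model expects %d", ncol(m),
                 length(object$x_mean)), call. = FALSE)
  }
  as.vector(object$y_mean + sweep(m, 2L, object$x_mean) %*%
              object$regression_vector)
}

#' @rdname predict.kmnir_pls
#' @param model A `kmnir_pls` model.
#' @param x Spectra to predict.
#' @export
pls_predict <- function(model, x) predict(model, x)

#' @export
print.kmnir_pls <- function(x, ...) {
  cat("<kmnir PLS model>", x$n_latent, "latent variables over",
      length(x$x_mean), "wavelengths\n")
  invisible(x)
}

#' Tidy a PLS model
#'
#' @param x A `kmnir_pls` model.
#' @param ... Unused.
#' @return A tibble with one row per wavelength: `wavelength`, `coefficient`
#'   (the regression vector) and per-component loading columns.
#' @export
tidy.kmnir_pls <- function(x, ...) {
  load_tbl <- tibble::as_tibble(
    stats::setNames(as.data.frame(x$x_loadings),
                    paste0("loading_", seq_len(x$n_latent)))
  )
  dplyr::bind_cols(
    tibble::tibble(wavelength = x$wavelengths,
                   coefficient = x$regression_vector),
    load_tbl
  )
}

#' Glance at a PLS model
#'
#' @param x A `kmnir_pls` model.
#' @param ... Unused.
#' @return A one-row tibble: `n_latent`, `n_wavelengths`, `y_mean`.
#' @export
glance.kmnir_pls <- function(x, ...) {
  tibble::tibble(
    n_latent = x$n_latent,
    n_wavelengths = length(x$x_mean),
    y_mean = x$y_mean
  )
}

#' Leave-one-out PRESS curve for latent-variable selection
#'
#' For each candidate latent-variable count, every sample is held out in
#' turn, the model is refitted on the rest and the held-out sample predicted;
#' PRESS(a) is the sum of squared prediction errors. The selected count is
#' the PRESS minimum, ties broken toward fewer latent variables.
#'
#' @inheritParams pls_fit
#' @param max_latent Largest latent-variable count to try; capped at
#'   `n_samples - 2` and the wavelength count.
#' @return An object of class `kmnir_press`: a tibble with columns
#'   `lv_index` and `press_value`, plus attributes `selected_lv` and `rmsecv`
#'   (root of PRESS(selected)/n).
#' @export
loocv_press <- function(x, y, max_latent) {
  m <- if (is.data.frame(x)) spectra_matrix(x) else as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(m)
  if (n < 3L) stop("leave-one-out needs at least 3 samples", call. = FALSE)
  if (!(max_latent >= 1 && max_latent <= min(n - 2L, ncol(m)))) {
    stop(sprintf("`max_latent` must be in [1, %d]", min(n - 2L, ncol(m))),
         call. = FALSE)
  }
  press <- numeric(max_latent)
  for (i in seq_len(n)) {
    fit_full <- pls_fit(m[-i, , drop = FALSE], y[-i], max_latent,
                        strict = FALSE)
    preds <- predict_per_component(fit_full, m[i, , drop = FALSE])
    if (length(preds) < max_latent) {
      # fold exhausted its rank early; later counts inherit its last model
      preds <- c(preds, rep(preds[length(preds)],
                            max_latent - length(preds)))
    }
    press <- press + (preds - y[i])^2
  }
  selected <- which.min(press)         # which.min takes the first minimum
  out <- tibble::tibble(lv_index = seq_len(max_latent), press_value = press)
  attr(out, "selected_lv") <- as.integer(selected)
  attr(out, "rmsecv") <- sqrt(press[selected] / n)
  class(out) <- c("kmnir_press", class(out))
  out
}

# predictions of the sequential PLS model truncated at 1..n_latent components
predict_per_component <- function(model, newdata) {
  m <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  xc <- sweep(m, 2L, model$x_mean)
  a_max <- model$n_latent
  preds <- numeric(a_max)
  yhat <- model$y_mean
  for (a in seq_len(a_max)) {
    tt <- xc %*% model$weights[, a]
    yhat <- yhat + model$y_loadings[a] * as.vector(tt)
    xc <- xc - tcrossprod(as.vector(tt), model$x_loadings[, a])
    preds[a] <- yhat
  }
  preds
}

#' @export
print.kmnir_press <- function(x, ...) {
  cat("<kmnir PRESS curve> selected", attr(x, "selected_lv"),
      "latent variables; RMSECV", format(attr(x, "rmsecv"), digits = 4), "\n")
  NextMethod()
}

#' @export
autoplot.kmnir_press <- function(object, ...) {
  sel <- attr(object, "selected_lv")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lv_index,
                                       y = .data$press_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed") +
    ggplot2::labs(x = "latent variables", y = "PRESS",
                  title = "Leave-one-out PRESS")
}

#' Evaluate a calibrated PLS model
#'
#' Computes the standard calibration diagnostics: RMSEC and RMSEP (root mean
#' square error on the calibration and validation sets), the corresponding
#' \eqn{R^2} values (defined as \eqn{1 - SS_{res}/SS_{tot}} against each
#' set's own mean, not squared correlation), RMSECV from the PRESS curve, and
#' RPD — the ratio of the validation reference values' standard deviation
#' (n - 1 denominator) to RMSEP. A perfect validation fit yields an infinite
#' RPD, reported as `Inf` rather than dropped.
#'
#' @param model A fitted `kmnir_pls` model.
#' @param press_curve The `kmnir_press` curve used to select the model's
#'   latent variables (or `NULL` to omit RMSECV).
#' @param x_cal,y_cal Calibration spectra and references.
#' @param x_val,y_val Validation spectra and references (validation must be
#'   nonempty with non-constant references).
#' @param fraction_set,preprocess Labels recorded in the report.
#' @return A one-row tibble (a model report): `fraction_set`, `preprocess`,
#'   `n_latent`, `rmsec`, `r2_cal`, `rmsecv`, `r2_cv`, `rmsep`, `r2_pred`,
#'   `rpd`.
#' @export
evaluate_model <- function(model, press_curve, x_cal, y_cal, x_val, y_val,
                           fraction_set = NA_character_,
                           preprocess = NA_character_) {
  y_cal <- as.numeric(y_cal); y_val <- as.numeric(y_val)
  if (length(y_val) == 0L) stop("validation set is empty", call. = FALSE)
  sd_val <- stats::sd(y_val)
  if (!isTRUE(sd_val > 0)) {
    stop("validation references are constant: RPD is undefined", call. = FALSE)
  }
  pred_cal <- predict(model, x_cal)
  pred_val <- predict(model, x_val)
  rmsec <- sqrt(mean((pred_cal - y_cal)^2))
  rmsep <- sqrt(mean((pred_val - y_val)^2))
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  rmsecv <- if (is.null(press_curve)) NA_real_ else attr(press_curve, "rmsecv")
  r2_cv <- if (is.null(press_curve)) NA_real_ else {
    1 - press_curve$press_value[attr(press_curve, "selected_lv")] /
      sum((y_cal - mean(y_cal))^2)
  }
  tibble::tibble(
    fraction_set = fraction_set,
    preprocess = preprocess,
    n_latent = model$n_latent,
    rmsec = rmsec,
    r2_cal = r2(y_cal, pred_cal),
    rmsecv = rmsecv,
    r2_cv = r2_cv,
    rmsep = rmsep,
    r2_pred = r2(y_val, pred_val),
    rpd = if (rmsep == 0) Inf else sd_val / rmsep
  )
}
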
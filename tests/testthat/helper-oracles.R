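# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, no shared helpers.

# Greedy maximin (Kennard-Stone) selection written as naive nested loops with
# hand-computed Euclidean distances; ties to the smallest index.
naive_kennard_stone <- function(m, n_cal) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    }
  }
  # seed pair: lexicographically smallest pair attaining the max distance
  best_i <- 1L; best_j <- 2L; best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] > best_d) {
        best_d <- d[i, j]; best_i <- i; best_j <- j
      }
    }
  }
  sel <- c(best_i, best_j)
  while (length(sel) < n_cal) {
    best_k <- NA_integer_; best_min <- -Inf
    for (k in seq_len(n)) {
      if (k %in% sel) next
      mind <- Inf
      for (s in sel) mind <- min(mind, d[k, s])
      if (mind > best_min) {
        best_min <- mind; best_k <- k
      }
    }
    sel <- c(sel, best_k)
  }
  sel
}

# Least-squares predictions through the Moore-Penrose pseudoinverse.
pinv_predict <- function(x_cal, y_cal, x_new) {
  xc <- scale(x_cal, scale = FALSE)
  b <- MASS::ginv(xc) %*% (y_cal - mean(y_cal))
  mean(y_cal) + scale(x_new, center = attr(xc, "scaled:center"),
                      scale = FALSE) %*% b
}

# PRESS by the obvious double loop: one full PLS refit per (holdout, LV).
naive_loocv_press <- function(x, y, max_lv) {
  n <- nrow(x)
  press <- numeric(max_lv)
  for (a in seq_len(max_lv)) {
    for (i in seq_len(n)) {
      fit <- kmnir::pls_fit(x[-i, , drop = FALSE], y[-i], a, strict = FALSE)
      press[a] <- press[a] +
        (predict(fit, x[i, , drop = FALSE]) - y[i])^2
    }
  }
  press
}

# Small, fast simulation configuration for pipeline-level unit tests:
# coarse wavelength grid and fewer base samples, all other physics as the
# defaults.
small_config <- function(seed = 11, ...) {
  kmnir::sim_config(seed = seed, n_base_samples = 12L, wavelength_step = 20,
                    ...)
}

# The acceptance tests reuse one full-default study; compute it lazily once.
.study_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.study_cache$default)) {
    d <- kmnir::simulate_dataset(kmnir::sim_config(seed = 1))
    .study_cache$default <- list(
      data = d,
      result = kmnir::run_full_study(d$spectra, d$references)
    )
  }
  .study_cache$default
}

zero_noise_study <- function() {
  if (is.null(.study_cache$zero)) {
    cfg <- kmnir::sim_config(seed = 1, additive_noise_sd = 0,
                             multiplicative_noise_sd = 0, hplc_cv = 0)
    d <- kmnir::simulate_dataset(cfg)
    single <- kmnir::run_single_fraction_study(d$spectra, d$references)
    mixed <- kmnir::run_mixed_fraction_study(d$spectra, d$references)
    cross <- kmnir::cross_predict(mixed, d$spectra, d$references)
    .study_cache$zero <- list(data = d, single = single, mixed = mixed,
                              cross = cross)
  }
  .study_cache$zero
}
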
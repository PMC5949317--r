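test_that("Kennard-Stone picks the maximin sequence on the 1-D example", {
  m <- matrix(c(0, 1, 3, 10), ncol = 1)
  split <- kennard_stone_split(m, 3)
  # positions 0 and 10 seed the split; 3 maximizes the min distance
  expect_identical(split$calibration, c(1L, 4L, 3L))
  expect_identical(split$validation, 2L)
  split2 <- kennard_stone_split(m, 2)
  expect_identical(sort(split2$calibration), c(1L, 4L))
  expect_error(kennard_stone_split(m, 1), "n_calibration")
  expect_error(kennard_stone_split(m, 4), "n_calibration")
})

test_that("Kennard-Stone matches the exhaustive greedy oracle for n <= 8", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:8, 1)
    p <- sample(1:3, 1)
    m <- matrix(rnorm(n * p), n, p)
    for (n_cal in 2:(n - 1)) {
      expect_identical(kennard_stone_split(m, n_cal)$calibration,
                       as.integer(naive_kennard_stone(m, n_cal)),
                       info = sprintf("seed %d n %d n_cal %d", seed, n, n_cal))
    }
  }
  # duplicate rows resolved by the smallest-index tie rule, not an error
  md <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  split <- kennard_stone_split(md, 2)
  expect_identical(sort(split$calibration), c(1L, 3L))
})

test_that("PLS(1) on one wavelength equals ordinary least squares", {
  set.seed(10)
  x <- matrix(rnorm(12), ncol = 1)
  y <- 2 + 3 * x[, 1] + rnorm(12, 0, 0.1)
  fit <- pls_fit(x, y, 1)
  xx <- x[, 1]
  ols <- lm(y ~ xx)
  expect_equal(fit$fitted, unname(fitted(ols)), tolerance = 1e-10)
  expect_equal(predict(fit, matrix(0.5)),
               unname(predict(ols, data.frame(xx = 0.5))),
               tolerance = 1e-10)
})

test_that("full-rank NIPALS reproduces pseudoinverse least squares", {
  for (seed in 1:4) {
    set.seed(seed)
    x <- matrix(rnorm(24), 6, 4)
    y <- rnorm(6)
    fit <- pls_fit(x, y, 4)
    expect_equal(fit$fitted, drop(pinv_predict(x, y, x)), tolerance = 1e-8)
    x_new <- matrix(rnorm(8), 2, 4)
    expect_equal(predict(fit, x_new), drop(pinv_predict(x, y, x_new)),
                 tolerance = 1e-8)
  }
})

test_that("NIPALS internals satisfy the model invariants", {
  set.seed(5)
  x <- matrix(rnorm(80), 10, 8)
  y <- x %*% rnorm(8) + rnorm(10, 0, 0.05)
  fit <- pls_fit(x, y, 4)
  # successive scores mutually orthogonal
  g <- crossprod(fit$scores)
  offdiag <- g - diag(diag(g))
  expect_true(all(abs(offdiag) <= 1e-8 * sqrt(outer(diag(g), diag(g)))))
  # centered model: calibration predictions average to y_mean
  expect_equal(mean(fit$fitted), fit$y_mean, tolerance = 1e-10)
  # prediction is affine in the spectrum
  x1 <- rnorm(8); x2 <- rnorm(8); al <- 0.3
  expect_equal(predict(fit, al * x1 + (1 - al) * x2),
               al * predict(fit, x1) + (1 - al) * predict(fit, x2),
               tolerance = 1e-10)
  # exact linear response fits to machine precision at full rank
  y_exact <- drop(x %*% rnorm(8))
  fit_e <- pls_fit(x, y_exact, 8)
  expect_lt(sqrt(mean((fit_e$fitted - y_exact)^2)), 1e-9)
  expect_error(pls_fit(x, rep(1, 10), 2), "zero variance")
  expect_error(pls_fit(x, y, 50), "n_latent")
})

test_that("tidy and glance expose the fitted PLS state", {
  set.seed(5)
  x <- matrix(rnorm(40), 10, 4)
  colnames(x) <- c("800", "900", "1000", "1100")
  y <- x %*% rnorm(4) + rnorm(10, 0, 0.1)
  fit <- pls_fit(x, y, 2)
  td <- tidy(fit)
  expect_identical(names(td), c("wavelength", "coefficient", "loading_1",
                                "loading_2"))
  expect_equal(td$wavelength, c(800, 900, 1000, 1100))
  expect_equal(td$coefficient, fit$regression_vector)
  gl <- glance(fit)
  expect_identical(gl$n_latent, 2L)
  expect_equal(gl$y_mean, mean(y))
})

test_that("LOOCV PRESS matches the naive double-loop oracle", {
  set.seed(21)
  x <- matrix(rnorm(40), 8, 5)
  y <- x %*% rnorm(5) + rnorm(8, 0, 0.2)
  curve <- loocv_press(x, y, 4)
  expect_equal(curve$press_value, naive_loocv_press(x, y, 4),
               tolerance = 1e-9)
  expect_identical(attr(curve, "selected_lv"),
                   which.min(curve$press_value))
  expect_equal(attr(curve, "rmsecv"),
               sqrt(min(curve$press_value) / 8))
})

test_that("PRESS selects one LV for an exactly linear single-column response", {
  x <- matrix(seq(1, 9), ncol = 1)
  y <- 0.5 + 2 * x[, 1]
  curve <- loocv_press(x, y, 1)
  expect_identical(attr(curve, "selected_lv"), 1L)
  expect_lt(curve$press_value[1], 1e-18)
  # with extra pure-noise columns the first component still wins
  set.seed(8)
  x2 <- cbind(x, matrix(rnorm(27, 0, 1e-4), 9, 3))
  curve2 <- loocv_press(x2, y, 3)
  expect_identical(attr(curve2, "selected_lv"), 1L)
  expect_error(loocv_press(x, y, 5), "max_latent")
})

test_that("duplicating every sample leaves the selected LV unchanged", {
  set.seed(33)
  x <- matrix(rnorm(48), 8, 6)
  y <- x %*% rnorm(6) + rnorm(8, 0, 0.3)
  sel1 <- attr(loocv_press(x, y, 4), "selected_lv")
  xd <- rbind(x, x); yd <- c(y, y)
  sel2 <- attr(loocv_press(xd, yd, 4), "selected_lv")
  expect_identical(sel1, sel2)
})

test_that("model evaluation computes the report metrics by definition", {
  x_cal <- matrix(seq(0.1, 1, length.out = 10), ncol = 1)
  y_cal <- 1 + 2 * x_cal[, 1]
  fit <- pls_fit(x_cal, y_cal, 1)
  # validation with known errors: predictions off by +0.1 everywhere
  x_val <- matrix((c(1, 2, 3) - 1 + 0.1 * 0) / 2, ncol = 1)
  y_val <- c(1, 2, 3) - 0.1
  rep1 <- evaluate_model(fit, NULL, x_cal, y_cal, x_val, y_val,
                         fraction_set = "t", preprocess = "RAW")
  expect_equal(rep1$rmsep, 0.1, tolerance = 1e-9)
  expect_equal(rep1$rpd, sd(y_val) / 0.1, tolerance = 1e-9)
  expect_equal(rep1$rpd, 10, tolerance = 1e-9)
  # permutation invariance
  perm <- c(3, 1, 2)
  rep2 <- evaluate_model(fit, NULL, x_cal, y_cal,
                         x_val[perm, , drop = FALSE], y_val[perm])
  expect_equal(rep2$rmsep, rep1$rmsep)
  expect_equal(rep2$rpd, rep1$rpd)
  expect_equal(rep2$r2_pred, rep1$r2_pred)
  # perfect prediction reports the infinite-RPD sentinel
  rep3 <- evaluate_model(fit, NULL, x_cal, y_cal, x_val, y_val + 0.1)
  expect_equal(rep3$rmsep, 0, tolerance = 1e-12)
  expect_identical(rep3$rpd, Inf)
  expect_error(evaluate_model(fit, NULL, x_cal, y_cal, x_val, c(2, 2, 2)),
               "undefined")
  expect_error(evaluate_model(fit, NULL, x_cal, y_cal, x_val[0, , drop = FALSE],
                              numeric(0)), "empty")
})
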
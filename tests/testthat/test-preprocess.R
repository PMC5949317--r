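test_that("SNV standardizes rows and is idempotent and affine-invariant", {
  m <- rbind(c(1, 2, 3), c(10, 20, 60))
  out <- snv(m)
  expect_equal(out[1, ], c(-1, 0, 1))
  expect_equal(rowMeans(out), c(0, 0), tolerance = 1e-14)
  expect_equal(apply(out, 1, sd), c(1, 1), tolerance = 1e-14)
  expect_equal(snv(out), out, tolerance = 1e-10)
  # affine invariance: a + b*row maps to the same standardized row
  row0 <- c(0.2, 0.9, 0.4, 1.3, 0.8)
  expect_equal(drop(snv(3 + 2.5 * row0)), drop(snv(row0)), tolerance = 1e-12)
  expect_error(snv(rbind(c(1, 2, 3), c(5, 5, 5))), "row 2")
})

test_that("MSC removes additive and multiplicative scatter against the calibration mean", {
  wl <- seq(780, 2500, by = 20)
  ref_shape <- 0.3 + 0.2 * sin(wl / 300) + 0.1 * exp(-((wl - 1700) / 150)^2)
  cal <- rbind(ref_shape * 1.02, ref_shape * 0.98)
  st <- msc_fit(cal)
  expect_equal(st$reference_spectrum, ref_shape, tolerance = 1e-12)
  expect_equal(drop(msc_apply(st, rbind(0.5 + 2 * ref_shape))), ref_shape,
               tolerance = 1e-10)
  expect_equal(drop(msc_apply(st, rbind(ref_shape))), ref_shape,
               tolerance = 1e-12)
  expect_error(msc_fit(rbind(ref_shape)), ">= 2")
})

test_that("MSC collapses a purely additive+multiplicative fraction offset", {
  set.seed(42)
  wl <- seq(780, 2500, by = 20)
  base <- 0.2 + 0.3 * exp(-((wl - 1400) / 250)^2) + 0.1 * sin(wl / 500)
  f1 <- t(replicate(10, base + rnorm(1, 0, 0.002)))
  f2 <- t(replicate(10, 0.15 + 1.6 * base + rnorm(1, 0, 0.002)))
  dist_between <- function(m) {
    sqrt(sum((colMeans(m[1:10, ]) - colMeans(m[11:20, ]))^2))
  }
  raw <- rbind(f1, f2)
  st <- msc_fit(raw)
  corrected <- msc_apply(st, raw)
  expect_lt(dist_between(corrected), 0.01 * dist_between(raw))
})

test_that("EMSC removes the wavelength polynomial and reduces to MSC at order 0", {
  wl <- seq(780, 2500, by = 20)
  ref_shape <- 0.3 + 0.2 * sin(wl / 300) + 0.1 * exp(-((wl - 1700) / 150)^2)
  cal <- rbind(ref_shape * 1.01, ref_shape * 0.99)
  st <- emsc_fit(cal, polynomial_order = 2, wavelengths = wl)
  lam <- 2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1
  x <- ref_shape + (3 * lam^2 - lam + 0.2)
  expect_equal(drop(emsc_apply(st, rbind(x))), ref_shape, tolerance = 1e-9)
  expect_equal(drop(emsc_apply(st, rbind(2 * ref_shape))), ref_shape,
               tolerance = 1e-9)
  # order 0 is exactly MSC
  st0 <- emsc_fit(cal, polynomial_order = 0, wavelengths = wl)
  stm <- msc_fit(cal)
  set.seed(7)
  x2 <- rbind(0.4 + 1.7 * ref_shape + rnorm(length(wl), 0, 0.01))
  expect_equal(emsc_apply(st0, x2), msc_apply(stm, x2), tolerance = 1e-9)
  expect_error(emsc_fit(cal[, 1:3], polynomial_order = 2, wavelengths = wl[1:3]),
               "singular")
})

test_that("Savitzky-Golay reproduces polynomials and scales derivatives by spacing", {
  wl <- seq(1000, 1400, by = 2)
  quad <- 3e-6 * wl^2 - 4e-3 * wl + 2
  sm <- savitzky_golay(rbind(quad), window = 9, polyorder = 2, deriv = 0)
  expect_equal(drop(sm), quad, tolerance = 1e-9)
  ramp <- 0.01 * wl
  d1 <- savitzky_golay(rbind(ramp), window = 9, polyorder = 2, deriv = 1,
                       spacing = 2)
  expect_equal(drop(d1), rep(0.01, length(wl)), tolerance = 1e-10)
  d2 <- savitzky_golay(rbind(quad), window = 9, polyorder = 3, deriv = 2,
                       spacing = 2)
  expect_equal(drop(d2), rep(6e-6, length(wl)), tolerance = 1e-10)
  expect_error(savitzky_golay(rbind(quad), window = 8), "odd")
  expect_error(savitzky_golay(rbind(quad), window = 9, polyorder = 2,
                              deriv = 3), "odd `window`")
  expect_error(savitzky_golay(rbind(quad[1:5]), window = 9), "fewer")
})

test_that("normalization modes behave and reject zero rows", {
  expect_equal(drop(normalize_spectra(c(3, 4))), c(0.6, 0.8))
  r <- c(0.1, 0.5, 0.2, 0.7)
  expect_equal(drop(normalize_spectra(10 * r)), drop(normalize_spectra(r)),
               tolerance = 1e-12)
  mx <- normalize_spectra(rbind(r), mode = "max")
  expect_equal(max(mx), 1)
  ar <- normalize_spectra(rbind(r), mode = "area", spacing = 2)
  expect_equal(sum(ar) * 2, 1, tolerance = 1e-12)
  expect_error(normalize_spectra(rbind(c(0, 0, 0))), "zero-norm")
})

test_that("baseline subtraction removes lines and offsets additively", {
  wl <- seq(780, 900, by = 2)
  line <- 0.3 + 0.001 * wl
  out <- baseline_subtract(rbind(line))
  expect_equal(drop(out), rep(0, length(wl)), tolerance = 1e-12)
  out2 <- baseline_subtract(rbind(rep(4, 10)), mode = "offset")
  expect_equal(drop(out2), rep(0, 10))
  spec <- 0.2 + 0.4 * exp(-((wl - 840) / 20)^2)
  shifted <- spec + 0.7 + 0.001 * wl
  expect_equal(drop(baseline_subtract(rbind(shifted))),
               drop(baseline_subtract(rbind(spec))), tolerance = 1e-9)
})

test_that("operators preserve tibble shape and wavelength grid", {
  d <- pure_scatter_dataset(small_config())
  sp <- d$spectra
  for (method in preprocess_methods()) {
    st <- preprocess_fit(sp[1:10, ], method)
    out <- preprocess_apply(st, sp)
    expect_identical(dim(out), dim(sp))
    expect_identical(names(out), names(sp))
    expect_identical(out$sample_id, sp$sample_id)
    # applying a state does not modify the state
    st2 <- preprocess_fit(sp[1:10, ], method)
    expect_identical(st, st2)
  }
  expect_error(preprocess_fit(sp, "WAVELET"), "unknown")
})

test_that("MSC after SNV is an affine per-row map of MSC alone", {
  d <- pure_scatter_dataset(small_config())
  m <- spectra_matrix(d$spectra)
  st <- msc_fit(m)
  a <- msc_apply(st, m)
  b_ <- msc_apply(msc_fit(snv(m)), snv(m))
  cors <- vapply(seq_len(nrow(m)), function(i) cor(a[i, ], b_[i, ]),
                 numeric(1))
  expect_true(all(abs(cors) > 1 - 1e-9))
})

test_that("scatter correction collapses between-fraction variance on pure-scatter data", {
  d <- pure_scatter_dataset(small_config())
  sp <- d$spectra
  var_ratio <- function(m) {
    grand <- colMeans(m)
    frs <- unique(sp$fraction)
    between <- 0; within <- 0
    for (f in frs) {
      sub <- m[sp$fraction == f, , drop = FALSE]
      mu <- colMeans(sub)
      between <- between + nrow(sub) * sum((mu - grand)^2)
      within <- within + sum(sweep(sub, 2, mu)^2)
    }
    between / within
  }
  raw_ratio <- var_ratio(spectra_matrix(sp))
  for (method in c("MSC", "EMSC", "SNV")) {
    st <- preprocess_fit(sp, method)
    corrected <- spectra_matrix(preprocess_apply(st, sp))
    expect_lt(var_ratio(corrected), raw_ratio / 10)
  }
})
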
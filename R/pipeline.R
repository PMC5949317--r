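#' Study design
#'
#' Describes the comparative modelling study: which single sieve fractions
#' are modelled, which 3-fraction pooled ("mixed") ranges, which
#' preprocessing methods are compared, and which mixed model is used to
#' cross-predict its member fractions. Every mixed set is a union of
#' adjacent single fractions and every cross-prediction target is a member
#' of its mixed set.
#'
#' @param single_fractions Labels of the single-fraction models.
#' @param mixed_sets Named list: range label -> character vector of member
#'   fraction labels.
#' @param preprocess_methods Preprocessing labels to compare (see
#'   [preprocess_methods()]).
#' @param cross_prediction Named list: mixed-set label -> member fractions to
#'   cross-predict.
#' @param split_ratio Calibration share of the Kennard-Stone split (default
#'   2/3).
#' @param max_latent Upper bound on PLS latent variables before PRESS
#'   selection (default 12).
#' @return A `kmnir_design` list.
#' @export
study_design <- function(
    single_fractions = particle_fractions()$label,
    mixed_sets = list(
      "180-850" = c("355-850", "250-355", "180-250"),
      "150-355" = c("250-355", "180-250", "150-180"),
      "125-250" = c("180-250", "150-180", "125-150"),
      "90-180"  = c("150-180", "125-150", "90-125"),
      "0-150"   = c("125-150", "90-125", "<90")
    ),
    preprocess_methods = c("RAW", "MSC", "SNV", "EMSC", "SG9"),
    cross_prediction = list(
      "90-180" = c("150-180", "125-150", "90-125")
    ),
    split_ratio = 2 / 3,
    max_latent = 12L) {
  stopifnot(split_ratio > 0, split_ratio < 1, max_latent >= 1)
  for (set in names(cross_prediction)) {
    if (!set %in% names(mixed_sets)) {
      stop(sprintf("cross-prediction set '%s' is not a mixed set", set),
           call. = FALSE)
    }
    missing <- setdiff(cross_prediction[[set]], mixed_sets[[set]])
    if (length(missing) > 0L) {
      stop(sprintf("cross-prediction target(s) %s are not members of mixed set '%s'",
                   paste(missing, collapse = ", "), set), call. = FALSE)
    }
  }
  structure(
    list(single_fractions = single_fractions, mixed_sets = mixed_sets,
         preprocess_methods = preprocess_methods,
         cross_prediction = cross_prediction, split_ratio = split_ratio,
         max_latent = as.integer(max_latent)),
    class = "kmnir_design"
  )
}

# join spectra and references, erroring on any mismatch
align_references <- function(spectra, references) {
  stopifnot(is.data.frame(spectra), is.data.frame(references),
            "sample_id" %in% names(spectra),
            all(c("sample_id", "content") %in% names(references)))
  missing <- setdiff(spectra$sample_id, references$sample_id)
  if (length(missing) > 0L) {
    stop(sprintf("no reference value for sample id(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  extra <- setdiff(references$sample_id, spectra$sample_id)
  if (length(extra) > 0L) {
    stop(sprintf("reference table id(s) absent from spectra: %s",
                 paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  references$content[match(spectra$sample_id, references$sample_id)]
}

# split + per-method preprocess/PRESS/fit/evaluate for one sample subset.
# The Kennard-Stone split is computed once on the RAW absorbance spectra and
# shared by all methods so that method comparison is not confounded by split
# membership; preprocessing state is fitted on calibration rows only.
fit_fraction_set <- function(spectra, y, label, methods, split_ratio,
                             max_latent, verbose = FALSE) {
  n <- nrow(spectra)
  n_cal <- max(2L, round(n * split_ratio))
  if (n_cal >= n) n_cal <- n - 1L
  split <- kennard_stone_split(spectra, n_cal)
  m_raw <- spectra_matrix(spectra)
  reports <- list(); models <- list()
  for (method in methods) {
    state <- preprocess_fit(spectra[split$calibration, , drop = FALSE],
                            method)
    x_cal <- preprocess_apply(state, m_raw[split$calibration, , drop = FALSE])
    x_val <- preprocess_apply(state, m_raw[split$validation, , drop = FALSE])
    y_cal <- y[split$calibration]; y_val <- y[split$validation]
    lv_cap <- min(max_latent, length(y_cal) - 2L, ncol(x_cal))
    press <- loocv_press(x_cal, y_cal, lv_cap)
    model <- pls_fit(x_cal, y_cal, attr(press, "selected_lv"),
                     strict = FALSE)
    rep_row <- evaluate_model(model, press, x_cal, y_cal, x_val, y_val,
                              fraction_set = label, preprocess = method)
    if (verbose) {
      message(sprintf("  [%s | %-4s] n=%d lv=%d RMSEP=%.4f RPD=%.2f",
                      label, method, n, model$n_latent, rep_row$rmsep,
                      rep_row$rpd))
    }
    reports[[method]] <- rep_row
    models[[method]] <- list(
      state = state, model = model, press = press, split = split,
      sample_id = spectra$sample_id,
      cal_ids = spectra$sample_id[split$calibration],
      val_ids = spectra$sample_id[split$validation]
    )
  }
  list(report = dplyr::bind_rows(reports), models = models)
}

flag_best <- function(report) {
  # best = max RPD per fraction set; ties -> fewer latent variables, then
  # first in method order (row order within the set)
  report |>
    dplyr::group_by(.data$fraction_set) |>
    dplyr::mutate(
      best = dplyr::row_number() == order(-.data$rpd, .data$n_latent,
                                          seq_along(.data$rpd))[1L]
    ) |>
    dplyr::ungroup()
}

#' Single-fraction model comparison
#'
#' For every single sieve fraction in the design: Kennard-Stone split of that
#' fraction's samples, then for each preprocessing method a leave-one-out
#' PRESS curve, latent-variable selection, PLS fit and evaluation. Fractions
#' with fewer than 6 samples are skipped with a warning.
#'
#' @param spectra Spectra tibble with a `fraction` metadata column.
#' @param references Tibble with `sample_id` and `content` (mg/g).
#' @param design A [study_design()].
#' @param verbose Print per-model progress.
#' @return A `kmnir_study` object: element `report` (one row per fraction x
#'   method, with a `best` flag per fraction) and element `models` (fitted
#'   states for downstream prediction).
#' @export
run_single_fraction_study <- function(spectra, references,
                                      design = study_design(),
                                      verbose = FALSE) {
  y_all <- align_references(spectra, references)
  reports <- list(); models <- list()
  for (frac in design$single_fractions) {
    idx <- which(spectra$fraction == frac)
    if (length(idx) < 6L) {
      warning(sprintf("fraction '%s' has %d samples (< 6): skipped", frac,
                      length(idx)), call. = FALSE)
      next
    }
    res <- fit_fraction_set(spectra[idx, , drop = FALSE], y_all[idx], frac,
                            design$preprocess_methods, design$split_ratio,
                            design$max_latent, verbose)
    reports[[frac]] <- res$report
    models[[frac]] <- res$models
  }
  new_study(flag_best(dplyr::bind_rows(reports)), models, "single")
}

#' Mixed-fraction model comparison
#'
#' Pools the member fractions of each mixed particle-size range and runs the
#' same split/compare procedure as [run_single_fraction_study()].
#'
#' @inheritParams run_single_fraction_study
#' @return A `kmnir_study` object (see [run_single_fraction_study()]).
#' @export
run_mixed_fraction_study <- function(spectra, references,
                                     design = study_design(),
                                     verbose = FALSE) {
  y_all <- align_references(spectra, references)
  reports <- list(); models <- list()
  for (set in names(design$mixed_sets)) {
    idx <- which(spectra$fraction %in% design$mixed_sets[[set]])
    if (length(idx) < 6L) {
      warning(sprintf("mixed set '%s' has %d samples (< 6): skipped", set,
                      length(idx)), call. = FALSE)
      next
    }
    res <- fit_fraction_set(spectra[idx, , drop = FALSE], y_all[idx], set,
                            design$preprocess_methods, design$split_ratio,
                            design$max_latent, verbose)
    reports[[set]] <- res$report
    models[[set]] <- res$models
  }
  new_study(flag_best(dplyr::bind_rows(reports)), models, "mixed")
}

#' Cross-predict single fractions with a mixed-fraction model
#'
#' Applies each fitted mixed-range model (per preprocessing method) to the
#' member single fractions named in the design's cross-prediction map, using
#' only samples from the mixed model's own validation partition — samples
#' that entered the model's calibration (or its preprocessing reference) are
#' refused, so the reported errors are genuine out-of-calibration
#' predictions. Optionally pairs the results with the single-fraction
#' models' own validation metrics.
#'
#' @param mixed_study The `kmnir_study` from [run_mixed_fraction_study()].
#' @inheritParams run_single_fraction_study
#' @param single_study Optional `kmnir_study` from
#'   [run_single_fraction_study()]; when given, a `comparison` table pairing
#'   each target fraction's best single model with its best mixed-model
#'   cross-prediction is included.
#' @return A list with `report` (one row per mixed set x method x target
#'   fraction: `rmsep`, `r2_pred`, `rpd`, `n`) and, when `single_study` is
#'   supplied, `comparison` (one row per target fraction).
#' @export
cross_predict <- function(mixed_study, spectra, references,
                          design = study_design(), single_study = NULL) {
  stopifnot(inherits(mixed_study, "kmnir_study"))
  y_all <- align_references(spectra, references)
  rows <- list()
  for (set in names(design$cross_prediction)) {
    set_models <- mixed_study$models[[set]]
    if (is.null(set_models)) {
      stop(sprintf("mixed set '%s' was not fitted", set), call. = FALSE)
    }
    for (method in names(set_models)) {
      fitted <- set_models[[method]]
      for (target in design$cross_prediction[[set]]) {
        tgt_ids <- spectra$sample_id[spectra$fraction == target]
        if (length(tgt_ids) == 0L) {
          stop(sprintf("target fraction '%s' absent from the data", target),
               call. = FALSE)
        }
        use_ids <- intersect(tgt_ids, fitted$val_ids)
        leak <- intersect(use_ids, fitted$cal_ids)
        if (length(leak) > 0L) {
          stop(sprintf("sample(s) %s are in the mixed model's calibration: refusing to cross-predict them",
                       paste(utils::head(leak, 3), collapse = ", ")),
               call. = FALSE)
        }
        if (length(use_ids) < 2L) {
          stop(sprintf("target fraction '%s' has %d sample(s) in the validation partition of mixed set '%s': too few to evaluate",
                       target, length(use_ids), set), call. = FALSE)
        }
        idx <- match(use_ids, spectra$sample_id)
        x <- preprocess_apply(fitted$state,
                              spectra_matrix(spectra[idx, , drop = FALSE]))
        y <- y_all[idx]
        pred <- predict(fitted$model, x)
        rmsep <- sqrt(mean((pred - y)^2))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mixed_set = set, preprocess = method, target_fraction = target,
          n = length(y),
          rmsep = rmsep,
          r2_pred = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
          rpd = if (rmsep == 0) Inf else stats::sd(y) / rmsep
        )
      }
    }
  }
  report <- dplyr::bind_rows(rows)
  out <- list(report = report)
  if (!is.null(single_study)) {
    single_best <- dplyr::filter(single_study$report, .data$best)
    cmp <- report |>
      dplyr::group_by(.data$mixed_set, .data$target_fraction) |>
      dplyr::slice_max(.data$rpd, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::left_join(
        dplyr::select(single_best, fraction_set,
                      single_preprocess = "preprocess",
                      single_rmsep = "rmsep", single_r2 = "r2_pred",
                      single_rpd = "rpd"),
        by = c(target_fraction = "fraction_set")
      ) |>
      dplyr::select("target_fraction", "mixed_set",
                    mixed_preprocess = "preprocess", mixed_rmsep = "rmsep",
                    mixed_r2 = "r2_pred", mixed_rpd = "rpd",
                    "single_preprocess", "single_rmsep", "single_r2",
                    "single_rpd")
    out$comparison <- cmp
  }
  out
}

new_study <- function(report, models, kind) {
  structure(list(report = report, models = models, kind = kind),
            class = "kmnir_study")
}

#' @export
print.kmnir_study <- function(x, ...) {
  cat("<kmnir", x$kind, "fraction study>", nrow(x$report), "model reports\n")
  print(x$report, n = Inf)
  invisible(x)
}

#' @export
autoplot.kmnir_study <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$fraction_set, y = .data$rpd,
                               fill = .data$preprocess)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 3, linetype = "dashed") +
    ggplot2::labs(x = "fraction set", y = "RPD",
                  title = paste(object$kind, "fraction models"))
}

#' Kubelka-Munk linear-region report
#'
#' Tabulates the Kubelka-Munk curve and its sliding-window linearity profile,
#' writes both as tab-separated files, and reports the smallest window start
#' whose linear fit reaches the \eqn{R^2} threshold.
#'
#' @param out_dir Directory for `km_curve.tsv` and `linearity_profile.tsv`
#'   (created if needed); `NULL` to skip writing.
#' @inheritParams linearity_profile
#' @param r2_threshold Linearity criterion passed to
#'   [linear_region_onset()].
#' @param verbose Print the detected onset.
#' @return A list with `curve`, `profile` and `onset` (invisible).
#' @export
km_linear_region_report <- function(out_dir = NULL, ratio_lo = 0,
                                    ratio_hi = 20, window_width = 4,
                                    step = 0.01, r2_threshold = 0.995,
                                    verbose = FALSE) {
  curve <- km_curve(ratio_lo, ratio_hi, step)
  profile <- linearity_profile(ratio_lo, ratio_hi, window_width, step)
  onset <- linear_region_onset(profile, r2_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(curve, file.path(out_dir, "km_curve.tsv"))
    readr::write_tsv(profile, file.path(out_dir, "linearity_profile.tsv"))
  }
  if (verbose) {
    message(sprintf(
      "A vs k/s reaches window R^2 >= %.4g at window start k/s = %s",
      r2_threshold, format(onset)))
  }
  invisible(list(curve = curve, profile = profile, onset = onset))
}

#' Run the full comparative study
#'
#' Orchestrates the whole analysis on one dataset: single-fraction model
#' comparison, pooled (mixed) fraction model comparison, cross-prediction of
#' member fractions by the designated mixed model, and the Kubelka-Munk
#' linear-region report. Everything downstream of the data is deterministic,
#' so a fixed simulation seed gives byte-identical output files.
#'
#' @inheritParams run_single_fraction_study
#' @param out_dir Directory for the report files (`single_fraction_report.tsv`,
#'   `mixed_fraction_report.tsv`, `cross_prediction_report.tsv`,
#'   `comparison_report.tsv`, `km_curve.tsv`, `linearity_profile.tsv`);
#'   `NULL` to skip writing.
#' @param verbose Print progress.
#' @return A list: `single`, `mixed` (both `kmnir_study`), `cross` (from
#'   [cross_predict()]) and `km` (from [km_linear_region_report()]).
#' @export
run_full_study <- function(spectra, references, design = study_design(),
                           out_dir = NULL, verbose = FALSE) {
  if (verbose) message("single-fraction models:")
  single <- run_single_fraction_study(spectra, references, design, verbose)
  if (verbose) message("mixed-fraction models:")
  mixed <- run_mixed_fraction_study(spectra, references, design, verbose)
  cross <- cross_predict(mixed, spectra, references, design,
                         single_study = single)
  km <- km_linear_region_report(out_dir = NULL, verbose = verbose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(single$report, file.path(out_dir,
                                          "single_fraction_report.tsv"))
    write_report(mixed$report, file.path(out_dir,
                                         "mixed_fraction_report.tsv"))
    write_report(cross$report, file.path(out_dir,
                                         "cross_prediction_report.tsv"))
    if (!is.null(cross$comparison)) {
      write_report(cross$comparison, file.path(out_dir,
                                               "comparison_report.tsv"))
    }
    readr::write_tsv(km$curve, file.path(out_dir, "km_curve.tsv"))
    readr::write_tsv(km$profile, file.path(out_dir, "linearity_profile.tsv"))
  }
  list(single = single, mixed = mixed, cross = cross, km = km)
}

#' Spectra and report I/O
#'
#' Tab-separated text I/O for the package's tabular objects. Spectra files
#' are wide: metadata columns (`sample_id`, optionally `batch`, `fraction`)
#' followed by one column per wavelength named by its value in nm. Values
#' survive a write/read round trip to better than 12 significant digits.
#'
#' @param path File path.
#' @param spectra,references,report The object to write.
#' @return The read functions return tibbles; the write functions return the
#'   input invisibly.
#' @name kmnir-io
NULL

#' @rdname kmnir-io
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(out) == 0L) {
    stop(sprintf("spectra file %s is empty", path), call. = FALSE)
  }
  if (!"sample_id" %in% names(out)) {
    stop("spectra file lacks a `sample_id` column", call. = FALSE)
  }
  spectra_wavelengths(out)  # validates presence + strict monotonicity
  out
}

#' @rdname kmnir-io
#' @export
write_spectra <- function(spectra, path) {
  spectra_wavelengths(spectra)
  readr::write_tsv(spectra, path)
  invisible(spectra)
}

#' @rdname kmnir-io
#' @export
read_references <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(out) == 0L) {
    stop(sprintf("reference file %s is empty", path), call. = FALSE)
  }
  if (!all(c("sample_id", "content") %in% names(out))) {
    stop("reference file needs `sample_id` and `content` columns",
         call. = FALSE)
  }
  out
}

#' @rdname kmnir-io
#' @export
write_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(report)
}
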
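#' Spectra tibbles
#'
#' Throughout kmnir a spectra set is an ordinary tibble in wide form: metadata
#' columns first (`sample_id`, optionally `batch` and `fraction`), then one
#' numeric column per wavelength, named by its wavelength in nm (e.g. `"780"`,
#' `"782"`, ...). These helpers move between that tibble and the samples x
#' wavelengths matrix the numerical code operates on.
#'
#' @param spectra A spectra tibble.
#' @return `spectra_matrix()` a numeric matrix with `sample_id` rownames;
#'   `spectra_wavelengths()` the numeric wavelength grid in nm;
#'   `spectra_meta()` the metadata columns as a tibble.
#' @name spectra-tibble
NULL

meta_cols <- function(spectra) {
  names(spectra)[is.na(suppressWarnings(as.numeric(names(spectra))))]
}

#' @rdname spectra-tibble
#' @export
spectra_wavelengths <- function(spectra) {
  stopifnot(is.data.frame(spectra))
  wl <- suppressWarnings(as.numeric(names(spectra)))
  wl <- wl[!is.na(wl)]
  if (length(wl) == 0L) {
    stop("no wavelength columns (numeric names) found in spectra tibble",
         call. = FALSE)
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    stop("wavelength columns must be strictly increasing", call. = FALSE)
  }
  wl
}

#' @rdname spectra-tibble
#' @export
spectra_matrix <- function(spectra) {
  wl <- spectra_wavelengths(spectra)
  m <- as.matrix(spectra[as.character(wl)])
  storage.mode(m) <- "double"
  if ("sample_id" %in% names(spectra)) {
    rownames(m) <- spectra$sample_id
  }
  colnames(m) <- format_wl(wl)
  m
}

#' @rdname spectra-tibble
#' @export
spectra_meta <- function(spectra) {
  stopifnot(is.data.frame(spectra))
  tibble::as_tibble(spectra[meta_cols(spectra)])
}

#' Assemble a spectra tibble from a matrix and metadata
#'
#' @param mat Samples x wavelengths numeric matrix.
#' @param wavelengths Wavelength grid in nm (length `ncol(mat)`).
#' @param meta Optional metadata data frame with `nrow(mat)` rows.
#' @return A spectra tibble (see [spectra_matrix()]).
#' @export
as_spectra_tibble <- function(mat, wavelengths, meta = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) != length(wavelengths)) {
    stop(sprintf("matrix has %d columns but %d wavelengths given",
                 ncol(mat), length(wavelengths)), call. = FALSE)
  }
  colnames(mat) <- format_wl(wavelengths)
  out <- tibble::as_tibble(mat)
  if (!is.null(meta)) {
    stopifnot(nrow(meta) == nrow(mat))
    out <- dplyr::bind_cols(tibble::as_tibble(meta), out)
  }
  out
}

format_wl <- function(wl) {
  # drop trailing fractional zeros so 780 and 780.5 both round-trip
  out <- format(wl, trim = TRUE, scientific = FALSE, digits = 12)
  has_dot <- grepl(".", out, fixed = TRUE)
  out[has_dot] <- sub("\\.?0+$", "", out[has_dot])
  out
}

# Accept either a spectra tibble or a bare matrix; run f on the matrix and
# restore the original container. Used by every row-wise preprocessing op.
with_spectra <- function(spectra, f) {
  if (is.data.frame(spectra)) {
    wl <- spectra_wavelengths(spectra)
    m <- spectra_matrix(spectra)
    out <- f(m, wl)
    colnames(out) <- format_wl(wl)
    res <- spectra
    res[as.character(wl)] <- tibble::as_tibble(out)
    res
  } else {
    m <- if (is.matrix(spectra)) spectra else matrix(spectra, nrow = 1L)
    wl <- infer_wavelengths(m)
    out <- f(m, wl)
    if (is.matrix(spectra)) out else drop(out)
  }
}

infer_wavelengths <- function(m) {
  wl <- suppressWarnings(as.numeric(colnames(m)))
  if (length(wl) == ncol(m) && !anyNA(wl)) wl else seq_len(ncol(m))
}

#' Plot spectra coloured by a metadata column
#'
#' @param spectra A spectra tibble.
#' @param colour Name of the metadata column to colour by (default
#'   `"fraction"`).
#' @return A ggplot object: absorbance against wavelength, one line per
#'   sample.
#' @export
plot_spectra <- function(spectra, colour = "fraction") {
  wl <- spectra_wavelengths(spectra)
  long <- tidyr::pivot_longer(
    spectra, cols = dplyr::all_of(as.character(wl)),
    names_to = "wavelength", values_to = "absorbance"
  )
  long$wavelength <- as.numeric(long$wavelength)
  aes <- if (colour %in% names(spectra)) {
    ggplot2::aes(x = .data$wavelength, y = .data$absorbance,
                 group = .data$sample_id, colour = .data[[colour]])
  } else {
    ggplot2::aes(x = .data$wavelength, y = .data$absorbance,
                 group = .data$sample_id)
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "wavelength (nm)", y = "apparent absorbance")
}
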
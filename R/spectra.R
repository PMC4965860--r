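#' Spectra tables
#'
#' A spectra table is an ordinary tibble holding one spectrum per row:
#' a `dose` column (mg adulterant per g matrix), a `set` column
#' (`"calibration"` or `"prediction"`), and one numeric column per
#' wavenumber, named by the wavenumber in cm^-1. Because it is a plain
#' tibble it survives dplyr verbs; the helpers below move between the
#' tabular form and the samples-by-wavenumbers matrix the numerical
#' engines work on.
#'
#' @param grid numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @param absorbance numeric matrix, samples by wavenumbers.
#' @param dose numeric vector of dose labels (mg/g), one per sample.
#' @param set character vector, `"calibration"` or `"prediction"`.
#' @return `as_spectra()` returns a tibble with columns `dose`, `set`
#'   and one column per grid point.
#' @examples
#' sp <- as_spectra(c(1000, 1010), matrix(1:4, 2), dose = c(0, 1))
#' spectra_grid(sp)
#' spectra_matrix(sp)
#' @export
as_spectra <- function(grid, absorbance, dose, set = "calibration") {
  absorbance <- as.matrix(absorbance)
  if (length(grid) != ncol(absorbance)) {
    rlang::abort("`grid` length must equal the number of absorbance columns.")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    rlang::abort("`grid` must be strictly increasing.")
  }
  if (length(dose) != nrow(absorbance)) {
    rlang::abort("`dose` must have one value per spectrum.")
  }
  set <- rep_len(set, nrow(absorbance))
  colnames(absorbance) <- format_wavenumber(grid)
  dplyr::bind_cols(
    tibble::tibble(dose = as.numeric(dose), set = as.character(set)),
    tibble::as_tibble(absorbance)
  )
}

format_wavenumber <- function(grid) {
  # 15 significant digits so the grid survives the name round-trip
  vapply(grid, function(w) format(w, digits = 15, scientific = FALSE),
         character(1))
}

spectra_cols <- function(data) {
  setdiff(names(data), c("dose", "set"))
}

#' @rdname as_spectra
#' @param data a spectra tibble as produced by [as_spectra()] or
#'   [simulate_spectra()].
#' @export
spectra_grid <- function(data) {
  as.numeric(spectra_cols(data))
}

#' @rdname as_spectra
#' @export
spectra_matrix <- function(data) {
  m <- as.matrix(data[spectra_cols(data)])
  storage.mode(m) <- "double"
  m
}

check_spectra <- function(data) {
  if (!is.data.frame(data)) rlang::abort("`data` must be a data frame.")
  if (!all(c("dose", "set") %in% names(data))) {
    rlang::abort("A spectra table needs `dose` and `set` columns.")
  }
  wn <- suppressWarnings(spectra_grid(data))
  if (anyNA(wn)) {
    rlang::abort("All non-meta columns must be named by numeric wavenumbers.")
  }
  invisible(data)
}

#' Read and write the CSV spectra-matrix format
#'
#' Row 1 is `dose,set,<wavenumber_1>,...,<wavenumber_p>`; one row per
#' sample, absorbance in decimal AU, doses in mg/g.
#'
#' @param path file path.
#' @param data a spectra tibble.
#' @return `read_spectra()` returns a spectra tibble; `write_spectra()`
#'   returns `data` invisibly.
#' @export
read_spectra <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_spectra(data)
  data
}

#' @rdname read_spectra
#' @export
write_spectra <- function(data, path) {
  check_spectra(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Split a spectra table into calibration and prediction sets by dose level
#'
#' Membership is decided solely by the dose level, mirroring the level-wise
#' calibration/prediction design of the study: every sample whose dose is in
#' `design$calibration_levels` goes to the calibration set, every sample at a
#' `design$prediction_levels` dose to the prediction set.
#'
#' @param data a spectra tibble.
#' @param design a [dose_design()].
#' @return a named list with spectra tibbles `calibration` and `prediction`
#'   (their `set` columns rewritten accordingly); together they partition the
#'   input rows.
#' @export
split_by_level <- function(data, design) {
  check_spectra(data)
  known <- c(design$calibration_levels, design$prediction_levels)
  bad <- setdiff(unique(data$dose), known)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Dose level(s) not in the design: ",
      paste(format(bad), collapse = ", ")
    ))
  }
  is_cal <- data$dose %in% design$calibration_levels
  cal <- data[is_cal, , drop = FALSE]
  pred <- data[!is_cal, , drop = FALSE]
  if (nrow(cal)) cal$set <- "calibration"
  if (nrow(pred)) pred$set <- "prediction"
  list(calibration = cal, prediction = pred)
}

#' Plot spectra coloured by dose
#'
#' @param data a spectra tibble.
#' @param n_max at most this many spectra are drawn (evenly subsampled).
#' @return a ggplot object.
#' @export
plot_spectra <- function(data, n_max = 30) {
  check_spectra(data)
  if (nrow(data) > n_max) {
    data <- data[round(seq(1, nrow(data), length.out = n_max)), ]
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(data, .sample = dplyr::row_number()),
    cols = -c("dose", "set", ".sample"),
    names_to = "wavenumber", values_to = "absorbance",
    names_transform = list(wavenumber = as.numeric)
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavenumber, y = .data$absorbance,
    group = .data$.sample, colour = .data$dose
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(
      x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance (AU)",
      colour = "Dose (mg/g)"
    ) +
    ggplot2::theme_minimal()
}
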
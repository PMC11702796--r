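#' Construct a denaturation series of emission spectra
#'
#' A denaturation series holds one fluorescence emission spectrum per
#' condition (temperature in kelvin for thermal experiments, denaturant
#' concentration in molar for chemical ones), all on a common wavelength
#' grid. Spectra are stored column-wise and re-ordered so that condition
#' values are strictly ascending.
#'
#' @param wavelength_nm Numeric vector of emission wavelengths in nm,
#'   strictly increasing, length >= 3.
#' @param intensities Numeric matrix of intensities (arbitrary units),
#'   one row per wavelength, one column per condition. No missing values
#'   are allowed: fits downstream require complete curves.
#' @param condition_values Numeric vector of condition values (K or M),
#'   one per column of `intensities`, all distinct.
#' @param condition_kind `"temperature"` or `"denaturant"`.
#' @param direction `"unfolding"` or `"refolding"`.
#' @return An object of class `denaturation_series`.
#' @seealso [read_spectra_csv()], [simulate_spectra_series()],
#'   [build_signal_curve()]
#' @export
denaturation_series <- function(wavelength_nm, intensities, condition_values,
                                condition_kind = c("temperature", "denaturant"),
                                direction = c("unfolding", "refolding")) {
  condition_kind <- match.arg(condition_kind)
  direction <- match.arg(direction)
  wavelength_nm <- as.numeric(wavelength_nm)
  condition_values <- as.numeric(condition_values)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"

  if (length(wavelength_nm) < 3L)
    stop("wavelength grid must have at least 3 points", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("non-monotonic wavelength grid", call. = FALSE)
  if (nrow(intensities) != length(wavelength_nm))
    stop("intensity rows must match the wavelength grid", call. = FALSE)
  if (ncol(intensities) != length(condition_values))
    stop("one intensity column per condition is required", call. = FALSE)
  if (ncol(intensities) < 1L)
    stop("series must contain at least one spectrum", call. = FALSE)
  if (anyNA(intensities) || anyNA(wavelength_nm) || anyNA(condition_values))
    stop("missing values are not allowed in a denaturation series", call. = FALSE)
  if (anyDuplicated(condition_values))
    stop("condition values must be distinct", call. = FALSE)

  ord <- order(condition_values)
  structure(
    list(
      wavelength_nm = wavelength_nm,
      intensities = intensities[, ord, drop = FALSE],
      condition_values = condition_values[ord],
      condition_kind = condition_kind,
      direction = direction
    ),
    class = "denaturation_series"
  )
}

#' Number of conditions in a denaturation series
#' @param series A `denaturation_series`.
#' @return Integer count of spectra.
#' @export
n_conditions <- function(series) {
  stopifnot(inherits(series, "denaturation_series"))
  length(series$condition_values)
}

#' Extract one emission spectrum from a series
#'
#' @param series A `denaturation_series`.
#' @param i Condition index (1-based, in ascending condition order).
#' @return An `emission_spectrum`: list with `wavelength_nm`, `intensity`,
#'   `condition_value`, `direction`.
#' @export
get_spectrum <- function(series, i) {
  stopifnot(inherits(series, "denaturation_series"))
  i <- as.integer(i)
  if (i < 1L || i > n_conditions(series))
    stop("spectrum index out of range", call. = FALSE)
  structure(
    list(
      wavelength_nm = series$wavelength_nm,
      intensity = series$intensities[, i],
      condition_value = series$condition_values[i],
      direction = series$direction
    ),
    class = "emission_spectrum"
  )
}

#' @export
print.denaturation_series <- function(x, ...) {
  cat(sprintf(
    "<denaturation_series> %d spectra (%s, %s)\n  wavelengths: %g-%g nm (%d points)\n  conditions:  %g-%g %s\n",
    n_conditions(x), x$condition_kind, x$direction,
    min(x$wavelength_nm), max(x$wavelength_nm), length(x$wavelength_nm),
    min(x$condition_values), max(x$condition_values),
    if (x$condition_kind == "temperature") "K" else "M"
  ))
  invisible(x)
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(
    "<emission_spectrum> condition %g, %d wavelengths (%g-%g nm)\n",
    x$condition_value, length(x$wavelength_nm),
    min(x$wavelength_nm), max(x$wavelength_nm)
  ))
  invisible(x)
}
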
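#' Configuration for synthetic two-state denaturation spectra
#'
#' Builds the ground-truth description of a synthetic intrinsic-fluorescence
#' denaturation experiment. Each condition's spectrum is a mixture of a
#' native and an unfolded Gaussian emission band,
#' `(1 - fu) * G(lambda_native) + fu * G(lambda_unfolded)`, where the
#' unfolded fraction `fu` follows the two-state thermal or chemical model.
#' Unfolding red-shifts the peak (`lambda_unfolded > lambda_native`) and
#' lowers its intensity (`amp_unfolded < amp_native`), the signature seen
#' in tryptophan fluorescence.
#'
#' Defaults emulate the study conditions: thermal scans from 293 to 363 K
#' in 5 K steps with ground truth Tm = 333 K and an apparent van't Hoff
#' enthalpy of 50 kcal/mol; chemical titrations over 0-4 M denaturant at
#' 298.15 K with dG_app = 4 kcal/mol and m = 2 kcal/(mol M) (midpoint
#' D1/2 = 2 M); emission recorded 290-360 nm.
#'
#' @param mode `"thermal"` or `"chemical"`.
#' @param Tm_K,dH_app Thermal ground truth: melting temperature (K) and
#'   apparent enthalpy (kcal/mol).
#' @param dG_app,m_value,T_K Chemical ground truth: unfolding free energy
#'   (kcal/mol), m-value (kcal/(mol M)) and the fixed temperature (K).
#' @param conditions Condition grid (K or M). `NULL` picks the mode default.
#' @param wavelength_nm Emission wavelength grid (nm).
#' @param lambda_native,width_native,amp_native Native band centre (nm),
#'   Gaussian width (nm) and peak amplitude (a.u.).
#' @param lambda_unfolded,width_unfolded,amp_unfolded Unfolded band
#'   parameters; centre must exceed `lambda_native` and amplitude must be
#'   below `amp_native`.
#' @param noise_sd Gaussian noise standard deviation (a.u.) added to every
#'   intensity sample.
#' @param direction `"unfolding"` or `"refolding"` label for the output.
#' @param seed Non-negative integer seed.
#' @return A list of class `spectra_sim_config`.
#' @export
spectra_sim_config <- function(mode = c("thermal", "chemical"),
                               Tm_K = 333, dH_app = 50,
                               dG_app = 4, m_value = 2, T_K = 298.15,
                               conditions = NULL,
                               wavelength_nm = seq(290, 360, by = 1),
                               lambda_native = 330, width_native = 12,
                               amp_native = 100,
                               lambda_unfolded = 350, width_unfolded = 14,
                               amp_unfolded = 60,
                               noise_sd = 0.5,
                               direction = c("unfolding", "refolding"),
                               seed = 0L) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (is.null(conditions))
    conditions <- if (mode == "thermal") seq(293, 363, by = 5)
                  else seq(0, 4, by = 0.25)
  if (length(conditions) == 0L)
    stop("empty condition grid", call. = FALSE)
  if (lambda_unfolded <= lambda_native)
    stop("unfolding must red-shift the band: lambda_unfolded > lambda_native",
         call. = FALSE)
  if (amp_unfolded >= amp_native)
    stop("unfolded amplitude must be below the native amplitude", call. = FALSE)
  if (width_native <= 0 || width_unfolded <= 0)
    stop("band widths must be positive", call. = FALSE)
  if (mode == "thermal" && (Tm_K <= 0 || dH_app <= 0))
    stop("thermal ground truth requires Tm_K > 0 and dH_app > 0", call. = FALSE)
  if (mode == "chemical" && (m_value <= 0 || T_K <= 0))
    stop("chemical ground truth requires m_value > 0 and T_K > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L)
    stop("seed must be a non-negative integer", call. = FALSE)
  structure(
    list(mode = mode, Tm_K = Tm_K, dH_app = dH_app,
         dG_app = dG_app, m_value = m_value, T_K = T_K,
         conditions = sort(as.numeric(conditions)),
         wavelength_nm = as.numeric(wavelength_nm),
         lambda_native = lambda_native, width_native = width_native,
         amp_native = amp_native,
         lambda_unfolded = lambda_unfolded, width_unfolded = width_unfolded,
         amp_unfolded = amp_unfolded,
         noise_sd = noise_sd, direction = direction, seed = seed),
    class = "spectra_sim_config"
  )
}

#' Two-state unfolded fraction at given conditions
#'
#' Thermal mode: `fu = e^u / (1 + e^u)` with
#' `u = (dH_app / R) * (1/Tm - 1/x)`. Chemical mode:
#' `fu = e^v / (1 + e^v)` with `v = -(dG_app - m * x) / (R * T)`.
#'
#' @param config A [spectra_sim_config()].
#' @param x Condition values (K or M).
#' @return Unfolded fraction in (0, 1), same length as `x`.
#' @export
unfolded_fraction <- function(config, x) {
  stopifnot(inherits(config, "spectra_sim_config"))
  if (config$mode == "thermal") {
    u <- (config$dH_app / R_gas) * (1 / config$Tm_K - 1 / x)
  } else {
    u <- -(config$dG_app - config$m_value * x) / (R_gas * config$T_K)
  }
  stats::plogis(u)
}

#' Simulate a denaturation spectra series with known ground truth
#'
#' Deterministic given `config$seed`; the RNG state of the session is
#' left untouched.
#'
#' @param config A [spectra_sim_config()].
#' @return A [denaturation_series()].
#' @export
simulate_spectra_series <- function(config) {
  stopifnot(inherits(config, "spectra_sim_config"))
  wl <- config$wavelength_nm
  band <- function(center, width, amp) amp * exp(-0.5 * ((wl - center) / width)^2)
  native <- band(config$lambda_native, config$width_native, config$amp_native)
  unfolded <- band(config$lambda_unfolded, config$width_unfolded,
                   config$amp_unfolded)
  fu <- unfolded_fraction(config, config$conditions)
  clean <- outer(native, 1 - fu) + outer(unfolded, fu)
  intensities <- withr::with_seed(config$seed, {
    clean + matrix(stats::rnorm(length(clean), sd = config$noise_sd),
                   nrow = nrow(clean))
  })
  denaturation_series(
    wavelength_nm = wl,
    intensities = intensities,
    condition_values = config$conditions,
    condition_kind = if (config$mode == "thermal") "temperature" else "denaturant",
    direction = config$direction
  )
}
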
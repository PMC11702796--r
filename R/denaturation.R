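#' Peak emission wavelength of a spectrum
#'
#' Locates the wavelength of maximal intensity at sub-grid resolution by
#' fitting a parabola through the maximal sample and its two neighbours.
#' If the maximum sits on a boundary of the wavelength grid the boundary
#' wavelength is returned and the `"boundary"` attribute is set.
#'
#' @param spectrum An `emission_spectrum` (see [get_spectrum()]), or any
#'   list with `wavelength_nm` and `intensity`.
#' @return The peak wavelength (nm) with attributes `boundary` (logical)
#'   and `peak_intensity` (interpolated intensity at the peak).
#' @export
extract_lambda_max <- function(spectrum) {
  wl <- spectrum$wavelength_nm
  y <- spectrum$intensity
  if (length(wl) < 3L) stop("spectrum needs at least 3 points", call. = FALSE)
  if (diff(range(y)) == 0)
    stop("no unique maximum: all intensities equal", call. = FALSE)
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    out <- wl[i]
    attr(out, "boundary") <- TRUE
    attr(out, "peak_intensity") <- y[i]
    return(out)
  }
  # exact parabola through three (possibly non-uniformly spaced) points
  x0 <- wl[i - 1L]; x1 <- wl[i]; x2 <- wl[i + 1L]
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  d01 <- (y1 - y0) / (x1 - x0)
  d12 <- (y2 - y1) / (x2 - x1)
  curv <- (d12 - d01) / (x2 - x0)          # half the quadratic coefficient
  if (curv == 0) {
    out <- x1
    peak <- y1
  } else {
    out <- (x0 + x1) / 2 - d01 / (2 * curv)
    # Newton form of the interpolating quadratic, evaluated at the vertex
    peak <- y0 + d01 * (out - x0) + curv * (out - x0) * (out - x1)
  }
  attr(out, "boundary") <- FALSE
  attr(out, "peak_intensity") <- peak
  out
}

#' Construct a signal curve
#'
#' A signal curve is one unfolding observable per condition: the
#' independent variable of the two-state fits.
#'
#' @param x Condition values (K or M), strictly increasing.
#' @param y Observable values, same length.
#' @param channel `"lambda_max"`, `"peak_intensity"` or
#'   `"integrated_intensity"`.
#' @param condition_kind `"temperature"` or `"denaturant"`.
#' @param direction `"unfolding"` or `"refolding"`.
#' @return An object of class `signal_curve`.
#' @export
signal_curve <- function(x, y,
                         channel = c("lambda_max", "peak_intensity",
                                     "integrated_intensity"),
                         condition_kind = c("temperature", "denaturant"),
                         direction = c("unfolding", "refolding")) {
  channel <- match.arg(channel)
  condition_kind <- match.arg(condition_kind)
  direction <- match.arg(direction)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  structure(
    list(x = x, y = y, channel = channel, condition_kind = condition_kind,
         direction = direction, normalized = FALSE),
    class = "signal_curve"
  )
}

#' Reduce a spectra series to a signal curve
#'
#' @param series A [denaturation_series()] with at least 6 conditions
#'   (fewer under-determines the four-parameter fits downstream).
#' @param channel Observable: `"lambda_max"` (parabolically interpolated
#'   peak wavelength), `"peak_intensity"` (interpolated intensity at the
#'   peak) or `"integrated_intensity"` (trapezoidal integral over the
#'   emission window).
#' @return A [signal_curve()]. Boundary peaks trigger a warning.
#' @export
build_signal_curve <- function(series,
                               channel = c("lambda_max", "peak_intensity",
                                           "integrated_intensity")) {
  stopifnot(inherits(series, "denaturation_series"))
  channel <- match.arg(channel)
  n <- n_conditions(series)
  if (n < 6L)
    stop("at least 6 conditions are required for a fit-ready curve",
         call. = FALSE)
  vals <- vapply(seq_len(n), function(i) {
    sp <- get_spectrum(series, i)
    if (channel == "integrated_intensity") {
      wl <- sp$wavelength_nm
      return(sum(diff(wl) * (utils::head(sp$intensity, -1) +
                               utils::tail(sp$intensity, -1)) / 2))
    }
    lm <- extract_lambda_max(sp)
    if (isTRUE(attr(lm, "boundary")))
      warning("peak at wavelength-grid boundary for condition ",
              sp$condition_value, call. = FALSE)
    if (channel == "lambda_max") as.numeric(lm)
    else attr(lm, "peak_intensity")
  }, numeric(1))
  signal_curve(series$condition_values, vals, channel,
               series$condition_kind, series$direction)
}

#' Two-state thermal unfolding model
#'
#' Evaluates `Yn + Yd * e^u / (1 + e^u)` with
#' `u = (dH_app / R) (1/Tm - 1/x)`: a van't Hoff two-state sigmoid in
#' temperature. `Yn` is the pre-transition signal level and `Yd` the
#' transition amplitude, so the post-transition level is `Yn + Yd`
#' (the model value at `x = Tm` is exactly `Yn + Yd/2`).
#'
#' @param dH_app Apparent enthalpy, kcal/mol.
#' @param Tm_K Apparent melting temperature, K.
#' @param Yn,Yd Baseline level and transition amplitude (signal units).
#' @param x Temperatures (K).
#' @return Model signal, same length as `x`.
#' @export
eval_thermal_model <- function(dH_app, Tm_K, Yn, Yd, x) {
  stopifnot(all(x > 0), Tm_K > 0)
  u <- (dH_app / R_gas) * (1 / Tm_K - 1 / x)
  Yn + Yd * stats::plogis(u)
}

#' Two-state chemical unfolding model
#'
#' Evaluates `Yn + Yd * e^v / (1 + e^v)` with
#' `v = -(dG_app - m * x) / (R * T)`: the linear-extrapolation two-state
#' sigmoid in denaturant concentration. The midpoint `D1/2 = dG_app / m`
#' gives exactly `Yn + Yd/2`.
#'
#' @param dG_app Apparent unfolding free energy, kcal/mol.
#' @param m_value m-value (transition slope), kcal/(mol M).
#' @param Yn,Yd Baseline level and transition amplitude (signal units).
#' @param T_K Temperature (K) at which the titration was measured.
#' @param x Denaturant concentrations (M).
#' @return Model signal, same length as `x`.
#' @export
eval_chemical_model <- function(dG_app, m_value, Yn, Yd, T_K, x) {
  stopifnot(T_K > 0, all(x >= 0))
  v <- -(dG_app - m_value * x) / (R_gas * T_K)
  Yn + Yd * stats::plogis(v)
}

# Shared two-state fitting engine. Initialization: Yn = mean of the first
# 3 y, post level = mean of the last 3 y, midpoint = linear-interpolated
# crossing of (Yn + Ypost)/2; dH_app starts at 50 kcal/mol, m at
# 2 kcal/(mol M). Up to 5 deterministic multi-start restarts jitter the
# initials by +/-30% before the fit is flagged non-converged.
fit_two_state <- function(x, y, model = c("thermal", "chemical"),
                          T_K = 298.15) {
  model <- match.arg(model)
  n <- length(x)
  if (n < 6L) stop("at least 6 points are required", call. = FALSE)
  if (diff(range(y)) <= 5 * stats::median(abs(diff(y))))
    stop("degenerate transition: signal range does not exceed noise",
         call. = FALSE)

  yn0 <- mean(y[1:3])
  yp0 <- mean(y[(n - 2):n])
  yd0 <- yp0 - yn0
  mid_level <- (yn0 + yp0) / 2
  crossing <- which((y[-n] - mid_level) * (y[-1] - mid_level) <= 0)
  if (length(crossing)) {
    i <- crossing[1]
    frac <- (mid_level - y[i]) / (y[i + 1] - y[i])
    if (!is.finite(frac)) frac <- 0.5
    x_mid0 <- x[i] + frac * (x[i + 1] - x[i])
  } else {
    x_mid0 <- stats::median(x)
  }

  if (model == "thermal") {
    start0 <- c(p1 = 50, p2 = x_mid0, Yn = yn0, Yd = yd0)
    lower <- c(1e-3, min(x) - 20, -Inf, -Inf)
    upper <- c(Inf, max(x) + 20, Inf, Inf)
    predict_fun <- function(p, x) eval_thermal_model(p[1], p[2], p[3], p[4], x)
    formula <- y ~ eval_thermal_model(p1, p2, Yn, Yd, x)
  } else {
    m0 <- 2
    start0 <- c(p1 = m0 * x_mid0, p2 = m0, Yn = yn0, Yd = yd0)
    lower <- c(-Inf, 1e-6, -Inf, -Inf)
    upper <- c(Inf, Inf, Inf, Inf)
    predict_fun <- function(p, x) eval_chemical_model(p[1], p[2], p[3], p[4],
                                                      T_K, x)
    formula <- y ~ eval_chemical_model(p1, p2, Yn, Yd, T_K, x)
  }

  jitters <- withr::with_seed(7L, {
    lapply(seq_len(5L), function(i)
      stats::runif(length(start0), 0.7, 1.3))
  })
  starts <- c(list(rep(1, length(start0))), jitters)

  best <- NULL
  for (fac in starts) {
    start <- start0 * fac
    start[2] <- max(min(start[2], upper[2]), lower[2] + 1e-6)
    dat <- list(x = x, y = y, T_K = T_K)
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = dat,
                        start = as.list(start), lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    conv <- isTRUE(fit$convInfo$isConv)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss, converged = conv)
    if (conv) break
  }
  if (is.null(best))
    return(list(par = stats::setNames(start0, names(start0)),
                se = stats::setNames(rep(NA_real_, 4), names(start0)),
                rss = NA_real_, converged = FALSE, fitted = rep(NA_real_, n)))
  par <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) rep(NA_real_, length(par)))
  list(par = par, se = se, rss = best$rss, converged = best$converged,
       fitted = predict_fun(par, x))
}

#' Fit the two-state thermal model to a signal curve
#'
#' Nonlinear least squares of [eval_thermal_model()] against the curve,
#' with deterministic multi-start initialization and parameter standard
#' errors from the Jacobian. Thermal unfolding of this system is
#' irreversible, so `Tm_K` and `dH_app` are apparent quantities, not
#' equilibrium thermodynamic ones.
#'
#' @param curve A [signal_curve()] with at least 6 points spanning a
#'   transition.
#' @return A list of class `thermal_fit`: `dH_app`, `Tm_K`, `Yn`, `Yd`,
#'   `se` (named vector), `rss`, `converged`, `n`, plus the source
#'   `channel` and `direction`.
#' @export
fit_thermal <- function(curve) {
  stopifnot(inherits(curve, "signal_curve"))
  res <- fit_two_state(curve$x, curve$y, "thermal")
  structure(
    list(dH_app = unname(res$par[1]), Tm_K = unname(res$par[2]),
         Yn = unname(res$par[3]), Yd = unname(res$par[4]),
         se = stats::setNames(res$se, c("dH_app", "Tm_K", "Yn", "Yd")),
         rss = res$rss, converged = res$converged, n = length(curve$x),
         channel = curve$channel, direction = curve$direction),
    class = "thermal_fit"
  )
}

#' Fit the two-state chemical model to a signal curve
#'
#' @param curve A [signal_curve()] with at least 6 points spanning a
#'   transition. Unfolding and refolding limbs are fitted separately (one
#'   call each).
#' @param T_K Fixed measurement temperature, default 298.15 K.
#' @return A list of class `chemical_fit`: `dG_app`, `m_value`, `Yn`,
#'   `Yd`, `T_K`, `D_half` (= dG_app / m_value, M), `se`, `rss`,
#'   `converged`, `n`, `channel`, `direction`.
#' @export
fit_chemical <- function(curve, T_K = 298.15) {
  stopifnot(inherits(curve, "signal_curve"))
  res <- fit_two_state(curve$x, curve$y, "chemical", T_K = T_K)
  structure(
    list(dG_app = unname(res$par[1]), m_value = unname(res$par[2]),
         Yn = unname(res$par[3]), Yd = unname(res$par[4]), T_K = T_K,
         D_half = unname(res$par[1] / res$par[2]),
         se = stats::setNames(res$se, c("dG_app", "m_value", "Yn", "Yd")),
         rss = res$rss, converged = res$converged, n = length(curve$x),
         channel = curve$channel, direction = curve$direction),
    class = "chemical_fit"
  )
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf(
    "<thermal_fit> Tm = %.2f K, dH_app = %.2f kcal/mol (%s, %s)%s\n",
    x$Tm_K, x$dH_app, x$channel, x$direction,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
print.chemical_fit <- function(x, ...) {
  cat(sprintf(
    "<chemical_fit> dG_app = %.3f kcal/mol, m = %.3f, D1/2 = %.3f M (%s, %s)%s\n",
    x$dG_app, x$m_value, x$D_half, x$channel, x$direction,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Normalize a signal curve to fraction unfolded
#'
#' Uses a fitted baseline and amplitude: `fu = (y - Yn) / Yd`, clipped to
#' `[-0.1, 1.1]` for presentation.
#'
#' @param curve A [signal_curve()].
#' @param fit A `thermal_fit` or `chemical_fit` for the same curve.
#' @return The curve with `y` replaced by fraction unfolded and
#'   `normalized = TRUE`.
#' @export
normalize_signal_curve <- function(curve, fit) {
  stopifnot(inherits(curve, "signal_curve"))
  fu <- (curve$y - fit$Yn) / fit$Yd
  curve$y <- pmin(pmax(fu, -0.1), 1.1)
  curve$normalized <- TRUE
  curve
}

#' Stability deltas relative to wild type
#'
#' Computes the per-variant comparison metrics:
#' `dTm = Tm(WT) - Tm(variant)` from thermal fits;
#' `dD_half = D1/2(unfolding) - D1/2(refolding)` (hysteresis, per
#' variant); `ddD_half = dD_half(WT) - dD_half(variant)`; and
#' `dD_half_unf_vs_wt = D1/2,unf(WT) - D1/2,unf(variant)`, the
#' unfolding-midpoint shift used for the chemical free-energy component.
#' Positive values mean the variant is less stable than wild type.
#'
#' @param thermal Named list of `thermal_fit` objects (one per variant),
#'   or `NULL`.
#' @param chemical Named list (one per variant) of lists with elements
#'   `unfolding` and optionally `refolding`, each a `chemical_fit`; or
#'   `NULL`.
#' @param wt_label Name of the wild-type entry; must be present in every
#'   supplied list.
#' @return Data frame with one row per variant and columns `variant`,
#'   `Tm_K`, `delta_Tm`, `D_half_unf`, `D_half_ref`, `delta_D_half`,
#'   `delta_delta_D_half`, `delta_D_half_unf_vs_wt` (missing pieces NA).
#' @export
stability_deltas <- function(thermal = NULL, chemical = NULL,
                             wt_label = "WT") {
  variants <- union(names(thermal), names(chemical))
  if (length(variants) == 0L)
    stop("no fits supplied", call. = FALSE)
  if (!is.null(thermal) && !wt_label %in% names(thermal))
    stop("wild type '", wt_label, "' missing from thermal fits", call. = FALSE)
  if (!is.null(chemical) && !wt_label %in% names(chemical))
    stop("wild type '", wt_label, "' missing from chemical fits", call. = FALSE)
  variants <- c(wt_label, setdiff(variants, wt_label))

  tm <- function(v) if (!is.null(thermal[[v]])) thermal[[v]]$Tm_K else NA_real_
  dh_unf <- function(v) {
    f <- chemical[[v]]$unfolding
    if (!is.null(f)) f$D_half else NA_real_
  }
  dh_ref <- function(v) {
    f <- chemical[[v]]$refolding
    if (!is.null(f)) f$D_half else NA_real_
  }
  out <- data.frame(
    variant = variants,
    Tm_K = vapply(variants, tm, numeric(1)),
    D_half_unf = vapply(variants, dh_unf, numeric(1)),
    D_half_ref = vapply(variants, dh_ref, numeric(1)),
    row.names = NULL
  )
  out$delta_Tm <- out$Tm_K[out$variant == wt_label] - out$Tm_K
  out$delta_D_half <- out$D_half_unf - out$D_half_ref
  wt_dd <- out$delta_D_half[out$variant == wt_label]
  out$delta_delta_D_half <- wt_dd - out$delta_D_half
  wt_du <- out$D_half_unf[out$variant == wt_label]
  out$delta_D_half_unf_vs_wt <- wt_du - out$D_half_unf
  out
}
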
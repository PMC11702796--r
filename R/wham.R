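# Weighted histogram analysis over multi-temperature trajectories.
# Energies are binned once; the density of states Omega(E_b) and the
# per-temperature dimensionless free energies f_k are iterated to
# self-consistency in log space (log-sum-exp throughout):
#   Omega(E_b) = sum_k n_k(E_b) / sum_k N_k exp(f_k - E_b / (R T_k))
#   exp(-f_k)  = sum_b Omega(E_b) exp(-E_b / (R T_k)),   f_1 = 0.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Solve the WHAM self-consistency equations
#'
#' Combines energy histograms from every ladder temperature into one
#' relative density of states. No autocorrelation correction is applied:
#' every frame carries unit weight within its temperature (a documented
#' limitation; see the package vignette).
#'
#' @param data A [rex_dataset()].
#' @param bins Number of equal-width energy bins (default 200). Empty
#'   bins carry zero density and are never smoothed.
#' @param tol Convergence tolerance on `max |delta f_k|` (default 1e-7).
#' @param max_iter Iteration cap (default 10000). On hitting the cap the
#'   partial solution is returned with `converged = FALSE` and a warning.
#' @return A list of class `wham_solution`: `bin_centers` (representative
#'   energy per bin: the mean frame energy for occupied bins, which is
#'   exact for discrete energy levels; the geometric centre for empty
#'   ones), `bin_width`,
#'   `ln_omega` (anchored so the first occupied bin is 0; `-Inf` on empty
#'   bins), `temperatures`, `f_k` (dimensionless, `f_k[1] = 0`), `n_frames`
#'   per temperature, `iterations`, `residual`, `converged`.
#' @export
wham_solve <- function(data, bins = 200L, tol = 1e-7, max_iter = 10000L) {
  stopifnot(inherits(data, "rex_dataset"))
  E <- data$frames$energy_kcal_mol
  if (!all(is.finite(E))) stop("non-finite energies", call. = FALSE)
  temps <- data$ladder
  K <- length(temps)
  beta <- 1 / (R_gas * temps)

  rng <- range(E)
  if (rng[1] == rng[2]) {
    edges <- c(rng[1] - 0.5, rng[1] + 0.5)
    bins <- 1L
  } else {
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  width <- diff(edges)[1]
  bin_of <- pmin(pmax(findInterval(E, edges, rightmost.closed = TRUE), 1L),
                 bins)
  temp_of <- match(data$frames$temperature_K, temps)

  n_kb <- matrix(0, nrow = K, ncol = bins)
  tab <- table(factor(temp_of, levels = seq_len(K)),
               factor(bin_of, levels = seq_len(bins)))
  n_kb[] <- as.numeric(tab)
  N_k <- rowSums(n_kb)
  ln_total_b <- ifelse(colSums(n_kb) > 0, log(colSums(n_kb)), -Inf)
  ln_N <- log(N_k)
  # representative energy per bin: mean of the frames that fell in it
  # (exact for discrete energy levels, where the geometric bin centre
  # would introduce a reweighting bias); empty bins keep their centre
  e_rep <- centers
  occ <- sort(unique(bin_of))
  e_rep[occ] <- vapply(split(E, bin_of), mean, numeric(1))
  centers <- e_rep

  f <- numeric(K)
  iter <- 0L
  resid <- Inf
  # beta_k * E_b outer product, reused every iteration
  bE <- outer(beta, centers)
  repeat {
    iter <- iter + 1L
    # ln denominator per bin: logsumexp_k [ln N_k + f_k - beta_k E_b]
    denom <- apply(ln_N + f - bE, 2, logsumexp)
    ln_omega <- ln_total_b - denom
    f_new <- -apply(sweep(-bE, 2, ln_omega, "+"), 1, logsumexp)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid <= tol || iter >= max_iter) break
  }
  converged <- resid <= tol
  if (!converged)
    warning(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                    iter, resid), call. = FALSE)
  occupied <- which(is.finite(ln_omega))
  ln_omega_anchored <- ln_omega - ln_omega[occupied[1]]
  structure(
    list(bin_centers = centers, bin_width = width,
         ln_omega = ln_omega_anchored, temperatures = temps, f_k = f,
         n_frames = N_k, iterations = iter, residual = resid,
         converged = converged),
    class = "wham_solution"
  )
}

#' @export
print.wham_solution <- function(x, ...) {
  cat(sprintf(
    "<wham_solution> %d bins (width %.4g), %d temperatures, %d iterations, residual %.3g%s\n",
    length(x$bin_centers), x$bin_width, length(x$temperatures),
    x$iterations, x$residual, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Per-frame reweighting factors at a target temperature
#'
#' Standard WHAM frame weights
#' `w_i(T) = exp(-E_i/(R T)) / sum_k N_k exp(f_k - E_i/(R T_k))`,
#' normalized to sum to 1. These reweight any per-frame observable
#' (energy, Rg, helix fraction) to an arbitrary temperature.
#'
#' @param data The [rex_dataset()] the solution was computed from.
#' @param wham A [wham_solve()] result.
#' @param T_K Target temperature (K).
#' @param ln_den Optional precomputed per-frame log denominator from
#'   [wham_frame_ln_den()] (it does not depend on the target
#'   temperature, so callers evaluating many temperatures reuse it).
#' @return Numeric vector of normalized weights, one per frame.
#' @export
wham_frame_weights <- function(data, wham, T_K, ln_den = NULL) {
  stopifnot(inherits(data, "rex_dataset"), inherits(wham, "wham_solution"))
  E <- data$frames$energy_kcal_mol
  if (is.null(ln_den)) ln_den <- wham_frame_ln_den(data, wham)
  lw <- -E / (R_gas * T_K) - ln_den
  exp(lw - logsumexp(lw))
}

#' @rdname wham_frame_weights
#' @export
wham_frame_ln_den <- function(data, wham) {
  stopifnot(inherits(data, "rex_dataset"), inherits(wham, "wham_solution"))
  E <- data$frames$energy_kcal_mol
  beta_k <- 1 / (R_gas * wham$temperatures)
  # n x K matrix of ln N_k + f_k - beta_k E_i; row-wise log-sum-exp,
  # vectorized over frames
  M <- -outer(E, beta_k)
  M <- sweep(M, 2, log(wham$n_frames) + wham$f_k, "+")
  m <- do.call(pmax, as.data.frame(M))
  m + log(rowSums(exp(M - m)))
}

#' Reweighted canonical average of a per-frame observable
#'
#' @param data The [rex_dataset()].
#' @param wham A [wham_solve()] result.
#' @param observable Column name in `data$frames` (e.g. `"rg_angstrom"`)
#'   or a numeric vector with one value per frame.
#' @param T_K Target temperatures (K); vectorized.
#' @param se Also return a standard error estimated from 20 contiguous
#'   frame blocks (robust to autocorrelation).
#' @return Data frame with columns `T_K`, `mean` and (if requested) `se`.
#' @export
reweight_observable <- function(data, wham, observable, T_K, se = FALSE) {
  obs <- if (is.character(observable)) {
    if (!observable %in% names(data$frames))
      stop("unknown observable: ", observable, call. = FALSE)
    data$frames[[observable]]
  } else as.numeric(observable)
  ln_den <- wham_frame_ln_den(data, wham)
  out <- lapply(T_K, function(temp) {
    w <- wham_frame_weights(data, wham, temp, ln_den = ln_den)
    m <- sum(w * obs)
    if (!se) return(data.frame(T_K = temp, mean = m))
    blocks <- cut(seq_along(obs), breaks = 20L, labels = FALSE)
    bm <- vapply(split(seq_along(obs), blocks), function(idx) {
      sum(w[idx] * obs[idx]) / sum(w[idx])
    }, numeric(1))
    bm <- bm[is.finite(bm)]
    data.frame(T_K = temp, mean = m,
               se = stats::sd(bm) / sqrt(length(bm)))
  })
  do.call(rbind, out)
}

#' Heat capacity curve and melting temperature from a WHAM solution
#'
#' At each grid temperature the canonical mean and variance of the
#' binned energy are computed from the reweighted density of states;
#' `Cv(T) = (<E^2> - <E>^2) / (R T^2)` and the melting temperature is
#' the location of the Cv maximum, refined by a parabola through the
#' peak grid point and its neighbours.
#'
#' @param wham A [wham_solve()] result.
#' @param T_grid Temperatures (K); default: ladder range in 0.5 K steps.
#'   Values outside the ladder range by more than 25 K are refused
#'   (extrapolation error).
#' @return Data frame of class `thermo_curves` with columns `T_K`,
#'   `E_mean`, `Cv`, and attribute `Tm_K`.
#' @export
compute_cv <- function(wham, T_grid = NULL) {
  stopifnot(inherits(wham, "wham_solution"))
  if (is.null(T_grid))
    T_grid <- seq(min(wham$temperatures), max(wham$temperatures), by = 0.5)
  lo <- min(wham$temperatures) - 25
  hi <- max(wham$temperatures) + 25
  if (any(T_grid < lo | T_grid > hi))
    stop("extrapolation error: temperature grid outside ladder range +/- 25 K",
         call. = FALSE)
  keep <- is.finite(wham$ln_omega)
  lnw <- wham$ln_omega[keep]
  Eb <- wham$bin_centers[keep]
  res <- vapply(T_grid, function(temp) {
    lp <- lnw - Eb / (R_gas * temp)
    lp <- lp - logsumexp(lp)
    p <- exp(lp)
    e1 <- sum(p * Eb)
    e2 <- sum(p * Eb^2)
    c(e1, (e2 - e1^2) / (R_gas * temp^2))
  }, numeric(2))
  out <- data.frame(T_K = T_grid, E_mean = res[1, ], Cv = res[2, ])
  i <- which.max(out$Cv)
  tm <- out$T_K[i]
  if (i > 1L && i < nrow(out)) {
    y0 <- out$Cv[i - 1]; y1 <- out$Cv[i]; y2 <- out$Cv[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den < 0)
      tm <- out$T_K[i] + 0.5 * (y0 - y2) / den * (out$T_K[i + 1] - out$T_K[i])
  }
  attr(out, "Tm_K") <- tm
  class(out) <- c("thermo_curves", "data.frame")
  out
}

#' Melting temperature shifts relative to wild type
#'
#' `delta_Tm = Tm(WT) - Tm(variant)`; positive values are destabilizing.
#'
#' @param curves Named list of [compute_cv()] results, one per variant.
#' @param wt_label Wild-type entry name.
#' @return Named numeric vector of shifts (K), wild type included (0).
#' @export
delta_tm <- function(curves, wt_label = "WT") {
  if (!wt_label %in% names(curves))
    stop("wild type '", wt_label, "' missing", call. = FALSE)
  tms <- vapply(curves, function(cc) attr(cc, "Tm_K"), numeric(1))
  tms[wt_label] - tms
}

#' Potential of mean force over order parameters
#'
#' Histograms one or two per-frame coordinates with WHAM frame weights
#' reweighted to temperature `T_K`; `PMF = -R T ln P` per bin, shifted so
#' the minimum over occupied bins is 0. Empty bins are unreachable and
#' carry `Inf`.
#'
#' @param data A [rex_dataset()].
#' @param wham A [wham_solve()] result.
#' @param coords One or two frame column names, by default
#'   `c("rg_angstrom", "helix_fraction")` (the Rg-versus-helix-content
#'   landscape).
#' @param T_K Evaluation temperature (K).
#' @param bins Bins per coordinate (default 50).
#' @return A list of class `pmf_surface`: `coords`, `edges` (list per
#'   coordinate), `pmf` (vector or matrix, kcal/mol), `T_K`.
#' @export
compute_pmf <- function(data, wham, coords = c("rg_angstrom", "helix_fraction"),
                        T_K = 300, bins = 50L) {
  stopifnot(inherits(data, "rex_dataset"), inherits(wham, "wham_solution"))
  if (!length(coords) %in% 1:2)
    stop("coords must name 1 or 2 frame columns", call. = FALSE)
  miss <- setdiff(coords, names(data$frames))
  if (length(miss))
    stop("coordinates absent from frames: ", paste(miss, collapse = ", "),
         call. = FALSE)
  w <- wham_frame_weights(data, wham, T_K)
  edges <- lapply(coords, function(cn) {
    r <- range(data$frames[[cn]])
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1L)
  })
  names(edges) <- coords
  idx <- lapply(coords, function(cn) {
    pmin(pmax(findInterval(data$frames[[cn]], edges[[cn]],
                           rightmost.closed = TRUE), 1L), bins)
  })
  if (length(coords) == 1L) {
    p <- vapply(seq_len(bins), function(b) sum(w[idx[[1]] == b]), numeric(1))
  } else {
    p <- matrix(0, bins, bins)
    for (f in seq_along(w))
      p[idx[[1]][f], idx[[2]][f]] <- p[idx[[1]][f], idx[[2]][f]] + w[f]
  }
  if (sum(p > 0) <= 1L)
    warning("degenerate landscape: all frames fall in one bin", call. = FALSE)
  pmf <- -R_gas * T_K * log(p)
  pmf[!is.finite(pmf)] <- Inf
  pmf <- pmf - min(pmf)
  structure(list(coords = coords, edges = edges, pmf = pmf, T_K = T_K),
            class = "pmf_surface")
}

#' Sigmoidal melt of the reweighted mean radius of gyration
#'
#' Computes `<Rg>(T)` by WHAM reweighting on a temperature grid and fits
#' it with the two-state thermal sigmoid (signal = Rg). The midpoint is
#' an independent estimate of the melting temperature; the amplitude is
#' the coil-minus-helix Rg change.
#'
#' @param data A [rex_dataset()] with Rg present.
#' @param wham A [wham_solve()] result.
#' @param T_grid Temperatures (K); default ladder range in 2 K steps.
#' @return List with `midpoint_K`, `amplitude`, `curve` (data frame
#'   `T_K`, `rg_mean`) and `fit` (the underlying `thermal_fit`).
#' @export
rg_melting_fit <- function(data, wham, T_grid = NULL) {
  if (is.null(T_grid))
    T_grid <- seq(min(wham$temperatures), max(wham$temperatures), by = 2)
  rg <- reweight_observable(data, wham, "rg_angstrom", T_grid)
  res <- fit_two_state(rg$T_K, rg$mean, "thermal")
  fit <- structure(
    list(dH_app = unname(res$par[1]), Tm_K = unname(res$par[2]),
         Yn = unname(res$par[3]), Yd = unname(res$par[4]),
         se = stats::setNames(res$se, c("dH_app", "Tm_K", "Yn", "Yd")),
         rss = res$rss, converged = res$converged, n = length(T_grid),
         channel = "rg_mean", direction = "unfolding"),
    class = "thermal_fit")
  list(midpoint_K = fit$Tm_K, amplitude = fit$Yd,
       curve = data.frame(T_K = rg$T_K, rg_mean = rg$mean), fit = fit)
}

#' Exchange acceptance rates per adjacent temperature pair
#'
#' Attempts are attributed to the temperature pair the two replicas held
#' at the attempt step (looked up in the frames); when any attempt cannot
#' be matched to frames, attempts are grouped by replica pair instead.
#'
#' @param data A [rex_dataset()] with a non-empty exchange log.
#' @return Data frame with one row per pair: `pair`, `attempts`,
#'   `accepted`, `rate`; attributes `min_rate` and `max_rate`.
#' @export
exchange_rate_summary <- function(data) {
  stopifnot(inherits(data, "rex_dataset"))
  xl <- data$exchange_log
  if (is.null(xl) || nrow(xl) == 0L)
    stop("empty exchange log", call. = FALSE)
  fr <- data$frames
  key <- paste(fr$step, fr$replica_id)
  temp_a <- fr$temperature_K[match(paste(xl$step, xl$replica_a), key)]
  temp_b <- fr$temperature_K[match(paste(xl$step, xl$replica_b), key)]
  if (anyNA(temp_a) || anyNA(temp_b)) {
    pair <- paste0("replicas ", pmin(xl$replica_a, xl$replica_b), "-",
                   pmax(xl$replica_a, xl$replica_b))
  } else {
    pair <- sprintf("%g-%g K", pmin(temp_a, temp_b), pmax(temp_a, temp_b))
  }
  agg <- stats::aggregate(cbind(attempts = rep(1L, nrow(xl)),
                                accepted = as.integer(xl$accepted)) ~ pair,
                          FUN = sum)
  agg$rate <- agg$accepted / agg$attempts
  attr(agg, "min_rate") <- min(agg$rate)
  attr(agg, "max_rate") <- max(agg$rate)
  agg
}
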
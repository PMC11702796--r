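# Conversion of stability shifts to a common free-energy scale and the
# normalized per-mutation consensus score.

#' Free-energy change from a melting-temperature shift
#'
#' `ddG ~ dHm * dTm / Tm`: the first-order van't Hoff conversion of a
#' melting-point shift into a folding free-energy change. The same
#' formula serves the simulation route (with `dHm` from the heat-capacity
#' peak integral and `Tm` from the Cv maximum) and the thermal
#' denaturation route (with the fitted apparent enthalpy and melting
#' temperature); only the provenance of the inputs differs.
#'
#' @param dHm Transition enthalpy, kcal/mol (> 0).
#' @param dTm Melting-temperature shift `Tm(WT) - Tm(mutant)` (K);
#'   vectorized. Positive = destabilizing.
#' @param Tm_K Reference (wild-type) melting temperature (K, > 0).
#' @return ddG in kcal/mol, sign following `dTm`.
#' @export
ddg_from_tm_shift <- function(dHm, dTm, Tm_K) {
  if (!is.finite(dHm) || dHm <= 0) stop("dHm must be positive", call. = FALSE)
  if (!is.finite(Tm_K) || Tm_K <= 0) stop("Tm_K must be positive", call. = FALSE)
  dHm * dTm / Tm_K
}

#' Free-energy change from a chemical-denaturation midpoint shift
#'
#' `ddG ~ m * dD`: the linear-extrapolation conversion of a midpoint
#' concentration shift into a free-energy change.
#'
#' @param m_value m-value, kcal/(mol M) (> 0).
#' @param dD Midpoint shift (M); vectorized.
#' @return ddG in kcal/mol, sign following `dD`.
#' @export
ddg_from_chemical <- function(m_value, dD) {
  if (!is.finite(m_value) || m_value <= 0)
    stop("m_value must be positive", call. = FALSE)
  m_value * dD
}

#' Transition enthalpy from a heat-capacity peak
#'
#' Effective `dHm` as the integral of the Cv peak above its half-maximum
#' baseline, between the two temperatures at which Cv first falls to half
#' of the peak value on either side (linear interpolation at the
#' crossings; trapezoidal integration).
#'
#' @param curves A [compute_cv()] result.
#' @return Enthalpy (kcal/mol).
#' @export
cv_peak_enthalpy <- function(curves) {
  stopifnot(inherits(curves, "thermo_curves"))
  T_K <- curves$T_K
  cv <- curves$Cv
  i <- which.max(cv)
  half <- cv[i] / 2
  # linear-interpolated half-maximum crossing between grid points j, j+1
  cross_at <- function(j) {
    T_K[j] + (half - cv[j]) / (cv[j + 1] - cv[j]) * (T_K[j + 1] - T_K[j])
  }
  t_left <- T_K[1]
  if (i > 1) for (j in seq(i - 1, 1)) {
    if ((cv[j] - half) * (cv[j + 1] - half) <= 0) { t_left <- cross_at(j); break }
  }
  t_right <- T_K[length(T_K)]
  if (i < length(cv)) for (j in seq(i, length(cv) - 1)) {
    if ((cv[j] - half) * (cv[j + 1] - half) <= 0) { t_right <- cross_at(j); break }
  }
  keep <- T_K >= t_left & T_K <= t_right
  tt <- c(t_left, T_K[keep], t_right)
  yy <- c(half, cv[keep], half)
  ord <- order(tt)
  tt <- tt[ord]; yy <- yy[ord]
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2) -
    half * (t_right - t_left)
}

#' Aggregate per-tool predictor ddG values into one value per mutation
#'
#' @param table A [predictor_table()].
#' @param rule `"mean"` (default), `"median"`, or `"tool"` to select a
#'   single named predictor.
#' @param tool Tool name, required when `rule = "tool"`.
#' @return Named numeric vector: one signed ddG (kcal/mol) per mutation.
#' @export
aggregate_predictor_ddg <- function(table, rule = c("mean", "median", "tool"),
                                    tool = NULL) {
  stopifnot(inherits(table, "predictor_table"))
  rule <- match.arg(rule)
  if (nrow(table) == 0L) stop("empty predictor table", call. = FALSE)
  if (rule == "tool") {
    if (is.null(tool)) stop("rule 'tool' requires a tool name", call. = FALSE)
    sub <- table[table$tool == tool, , drop = FALSE]
    missing_mut <- setdiff(unique(table$mutation), sub$mutation)
    if (length(missing_mut))
      stop("tool '", tool, "' absent for mutation(s): ",
           paste(missing_mut, collapse = ", "), call. = FALSE)
    return(stats::setNames(sub$ddg_kcal_mol, sub$mutation))
  }
  fun <- if (rule == "mean") mean else stats::median
  vapply(split(table$ddg_kcal_mol, table$mutation), fun, numeric(1))
}

#' Normalized overall impact per mutation
#'
#' Sums the absolute values of the four per-mutation free-energy
#' components (predictor consensus, simulation, thermal denaturation,
#' chemical denaturation) and divides by the largest such sum across
#' mutations (the scaling factor), so the most affected mutation scores
#' exactly 1. Absolute values mean stabilizing and destabilizing shifts
#' both raise the score: the score measures magnitude of impact, not
#' direction.
#'
#' @param components Data frame with columns `mutation`, `ddg_pt`,
#'   `ddg_rex`, `ddg_td`, `ddg_cd` (signed, kcal/mol). `NA` components
#'   are rejected unless `allow_partial = TRUE`, in which case the row
#'   sum runs over the available components and `n_components` records
#'   how many entered.
#' @param allow_partial Permit missing components (default `FALSE`).
#' @return Data frame of class `impact_table` with the four absolute
#'   components, `sum_abs`, `overall_impact` and `n_components`;
#'   attribute `scaling_factor` (kcal/mol).
#' @export
overall_impact <- function(components, allow_partial = FALSE) {
  required <- c("mutation", "ddg_pt", "ddg_rex", "ddg_td", "ddg_cd")
  miss <- setdiff(required, names(components))
  if (length(miss))
    stop("missing component columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  components <- as.data.frame(components)[required]
  comp <- abs(as.matrix(components[, -1]))
  if (anyNA(comp) && !allow_partial)
    stop("missing components; set allow_partial = TRUE to opt in",
         call. = FALSE)
  s <- rowSums(comp, na.rm = TRUE)
  scaling <- max(s)
  if (scaling == 0)
    stop("zero scaling factor: all components are zero", call. = FALSE)
  out <- data.frame(
    mutation = components$mutation,
    abs_ddg_pt = comp[, "ddg_pt"], abs_ddg_rex = comp[, "ddg_rex"],
    abs_ddg_td = comp[, "ddg_td"], abs_ddg_cd = comp[, "ddg_cd"],
    sum_abs = s,
    overall_impact = s / scaling,
    n_components = rowSums(!is.na(comp)),
    row.names = NULL
  )
  attr(out, "scaling_factor") <- scaling
  class(out) <- c("impact_table", "data.frame")
  out
}

#' Pearson agreement between impact scores and reference scores
#'
#' @param impacts An `impact_table` or a named numeric vector of
#'   per-mutation scores.
#' @param reference Named numeric vector of reference pathogenicity
#'   scores (e.g. from [read_reference_scores()]).
#' @return List with `r` (sample Pearson correlation), `n_shared` and
#'   `mutations` (the shared set).
#' @export
correlate_with_reference <- function(impacts, reference) {
  if (inherits(impacts, "impact_table"))
    impacts <- stats::setNames(impacts$overall_impact, impacts$mutation)
  shared <- intersect(names(impacts), names(reference))
  if (length(shared) < 3L)
    stop("fewer than 3 shared mutations", call. = FALSE)
  a <- impacts[shared]
  b <- reference[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one of the score sets", call. = FALSE)
  list(r = stats::cor(a, b), n_shared = length(shared), mutations = shared)
}
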
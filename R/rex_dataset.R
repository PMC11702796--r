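#' Construct a replica-exchange dataset
#'
#' Holds per-frame observables from a multi-temperature replica-exchange
#' run, grouped by the temperature at which each frame was sampled, plus
#' an optional exchange-attempt log. Frames are labelled by their current
#' temperature (not by replica), which is the grouping the weighted
#' histogram analysis consumes.
#'
#' @param frames Data frame with columns `step`, `replica_id`,
#'   `temperature_K`, `energy_kcal_mol`, `rg_angstrom`, `helix_fraction`.
#' @param exchange_log Optional data frame with columns `step`,
#'   `replica_a`, `replica_b`, `accepted` (logical or 0/1).
#' @return An object of class `rex_dataset` with elements `frames`,
#'   `ladder` (sorted unique temperatures, K) and `exchange_log`.
#' @seealso [read_trajectory_table()], [simulate_rex_zimm_bragg()],
#'   [wham_solve()]
#' @export
rex_dataset <- function(frames, exchange_log = NULL) {
  required <- c("step", "replica_id", "temperature_K", "energy_kcal_mol",
                "rg_angstrom", "helix_fraction")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols))
    stop("missing trajectory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  frames <- as.data.frame(frames)[required]
  for (col in c("temperature_K", "energy_kcal_mol", "rg_angstrom", "helix_fraction"))
    frames[[col]] <- as.numeric(frames[[col]])
  if (nrow(frames) == 0L)
    stop("trajectory contains no frames", call. = FALSE)
  if (anyNA(frames))
    stop("missing values in trajectory frames", call. = FALSE)
  if (any(frames$helix_fraction < 0 | frames$helix_fraction > 1))
    stop("helix_fraction outside [0,1]", call. = FALSE)
  if (any(frames$temperature_K <= 0))
    stop("non-positive temperature in trajectory", call. = FALSE)
  if (!is.null(exchange_log)) {
    req_x <- c("step", "replica_a", "replica_b", "accepted")
    miss_x <- setdiff(req_x, names(exchange_log))
    if (length(miss_x))
      stop("missing exchange-log columns: ", paste(miss_x, collapse = ", "),
           call. = FALSE)
    exchange_log <- as.data.frame(exchange_log)[req_x]
    exchange_log$accepted <- as.logical(exchange_log$accepted)
    if (anyNA(exchange_log$accepted))
      stop("exchange-log 'accepted' must be logical or 0/1", call. = FALSE)
  }
  structure(
    list(
      frames = frames,
      ladder = sort(unique(frames$temperature_K)),
      exchange_log = exchange_log
    ),
    class = "rex_dataset"
  )
}

#' @export
print.rex_dataset <- function(x, ...) {
  cat(sprintf(
    "<rex_dataset> %d frames, ladder of %d temperatures (%g-%g K)%s\n",
    nrow(x$frames), length(x$ladder), min(x$ladder), max(x$ladder),
    if (is.null(x$exchange_log)) "" else
      sprintf(", %d exchange attempts", nrow(x$exchange_log))
  ))
  invisible(x)
}
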
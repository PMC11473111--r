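#' Convert a qPCR percent-of-control ratio into model units
#'
#' Applies the anchoring formula (KD / C) * M, where KD is the mean measured
#' value under knockdown, C the mean non-targeting-control value, and M the
#' calibration (microarray-anchored) value of the species in model units.
#' At the zero timepoint KD / C is fixed to 1 by convention, so every
#' condition shares the species' single initial condition.
#'
#' @param kd_mean Mean knockdown measurement (> 0 scale, same units as `c_mean`).
#' @param c_mean Mean control measurement; must be > 0.
#' @param m_mean Calibration value in model units; must be > 0.
#' @return `kd_mean / c_mean * m_mean`.
#' @examples
#' to_model_units(2, 4, 10)  # 5
#' @export
to_model_units <- function(kd_mean, c_mean, m_mean) {
  if (any(c_mean <= 0)) stop("c_mean must be positive")
  if (any(m_mean <= 0)) stop("m_mean must be positive")
  kd_mean / c_mean * m_mean
}

#' Express GAG measurements as percent of the day-7 control level
#'
#' The day-7 control GAG level is treated as 100% and every knockdown
#' measurement is expressed relative to it.
#'
#' @param gag_control_d7 Control GAG level at day 7 (> 0).
#' @param gag_kd_series Data frame with columns `day` and `value` (raw GAG
#'   under inhibition); may be empty.
#' @return The series with `value` replaced by `100 * value /
#'   gag_control_d7` and a `unit` column `"pct_control_d7"`.
#' @export
gag_percent_control <- function(gag_control_d7, gag_kd_series) {
  if (gag_control_d7 <= 0) stop("control day-7 GAG level must be positive")
  out <- gag_kd_series
  out$value <- 100 * gag_kd_series$value / gag_control_d7
  out$unit <- if (nrow(out)) "pct_control_d7" else character(0)
  out
}

#' Convert replicate qPCR tables into model-unit observation series
#'
#' Pools replicates (across donors) into per-day means, forms the knockdown
#' to control ratio per analyte and day, forces the day-0 ratio to 1 (shared
#' initial condition), and multiplies by the calibration value `M` of the
#' analyte at each day.
#'
#' @param qpcr Data frame with columns `condition`, `analyte`, `day`,
#'   `replicate`, `pct_control` (the schema written by
#'   [generate_qpcr_experiment()]).
#' @param calibration Data frame with columns `analyte`, `day`, `value`:
#'   the model-unit anchor M (typically the simulated or microarray control
#'   trajectory at the observation days).
#' @param control Label of the control condition in `qpcr`.
#' @return Data frame of observation series: `species`, `condition`, `day`,
#'   `value` (model units), `provenance = "qpcr"` -- the format consumed by
#'   [fit_kinetics()].
#' @export
qpcr_to_observations <- function(qpcr, calibration, control = "control") {
  need <- c("condition", "analyte", "day", "pct_control")
  if (length(setdiff(need, names(qpcr))))
    stop("qpcr table needs columns condition, analyte, day, pct_control")
  if (any(qpcr$pct_control <= 0)) stop("qPCR values must be positive")
  if (!control %in% qpcr$condition) stop("control condition not found")
  agg <- stats::aggregate(pct_control ~ condition + analyte + day,
                          data = qpcr, FUN = mean)
  ctrl <- agg[agg$condition == control, , drop = FALSE]
  out <- lapply(seq_len(nrow(agg)), function(i) {
    row <- agg[i, ]
    ci <- ctrl$pct_control[ctrl$analyte == row$analyte & ctrl$day == row$day]
    if (!length(ci)) stop("no control measurement for ", row$analyte,
                          " at day ", row$day)
    mi <- calibration$value[calibration$analyte == row$analyte &
                              calibration$day == row$day]
    if (!length(mi)) stop("no calibration value for ", row$analyte,
                          " at day ", row$day)
    ratio <- if (row$day == 0) 1 else row$pct_control / ci
    data.frame(species = row$analyte, condition = row$condition,
               day = row$day, value = to_model_units(ratio, 1, mi),
               provenance = "qpcr", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$species, out$condition, out$day), , drop = FALSE]
  rownames(out) <- NULL
  .check_observations(out)
  out
}

.check_observations <- function(obs) {
  need <- c("species", "condition", "day", "value")
  if (length(setdiff(need, names(obs))))
    stop("observations need columns species, condition, day, value")
  if (any(obs$day < 0)) stop("negative observation day")
  if (any(obs$value < 0)) stop("negative observation value")
  key <- split(obs$day, paste(obs$species, obs$condition, sep = "\r"))
  if (any(vapply(key, anyDuplicated, 1L) > 0))
    stop("duplicate day within an observation series")
  invisible(obs)
}
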
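# EP07-style paired interference screen.

#' Interference point estimate and decision
#'
#' Computes `d_obs = mean(test) - mean(control)` between samples with and
#' without the candidate interferent, expresses it as a percentage of the
#' control mean, and flags the substance when |percent interference| reaches
#' the decision threshold (default 10%; values at the threshold are flagged).
#'
#' @param test_values Measurements with interferent added (n >= 2).
#' @param control_values Matched control measurements (n >= 2).
#' @param interferent Interferent name (metadata).
#' @param interferent_concentration Tested interferent concentration, mg/dl.
#' @param analyte_level Analyte concentration of the sample pair, mg/dl.
#' @param threshold_pct Flagging threshold in percent (default 10).
#' @return An `interference_result` list: `d_obs`, `percent_interference`,
#'   `flagged`, sample sizes and metadata.
#' @export
interference_effect <- function(test_values, control_values,
                                interferent = NA_character_,
                                interferent_concentration = NA_real_,
                                analyte_level = NA_real_,
                                threshold_pct = 10) {
  if (length(test_values) < 2L || length(control_values) < 2L)
    stop("each arm needs at least 2 replicates")
  m_ctrl <- mean(control_values)
  if (m_ctrl == 0) stop("control mean is zero; percent interference undefined")
  d_obs <- mean(test_values) - m_ctrl
  pct <- 100 * d_obs / m_ctrl
  structure(list(interferent = interferent,
                 interferent_concentration = interferent_concentration,
                 analyte_level = analyte_level,
                 n_test = length(test_values),
                 n_control = length(control_values),
                 control_mean = m_ctrl,
                 d_obs = d_obs,
                 percent_interference = pct,
                 flagged = abs(pct) >= threshold_pct,
                 threshold_pct = threshold_pct),
            class = "interference_result")
}

#' Default interferent screening panel
#'
#' The recommended test concentrations for the six serum constituents
#' screened against the bilirubin assay, each tested at the low (0.4 mg/dl)
#' and high (2.0 mg/dl) analyte levels: 6 interferents x 2 levels = 12
#' planned runs.
#'
#' @return Data frame with columns `interferent`,
#'   `test_concentration_mg_dl`, `analyte_level_mg_dl`.
#' @export
default_interferent_panel <- function() {
  base <- data.frame(
    interferent = c("hemoglobin", "triglyceride", "ascorbic acid",
                    "acetaminophen", "acetylsalicylic acid", "ibuprofen"),
    test_concentration_mg_dl = c(1000, 1500, 1.75, 5.20, 3.00, 21.9))
  out <- merge(base, data.frame(analyte_level_mg_dl = c(0.4, 2.0)))
  out[order(match(out$interferent, base$interferent),
            out$analyte_level_mg_dl), c("interferent",
                                        "test_concentration_mg_dl",
                                        "analyte_level_mg_dl")]
}

#' Maximum non-interfering concentration by linear interpolation
#'
#' Extension helper (not part of the screening rule itself): given percent
#' interference observed at two tested interferent doses, linearly
#' interpolates the dose at which interference reaches the threshold.
#'
#' @param doses Two tested interferent concentrations.
#' @param pct_interference Percent interference observed at each dose.
#' @param threshold_pct Threshold (default 10).
#' @return Interpolated dose at the threshold, or `NA` if the threshold is
#'   not bracketed.
#' @export
interference_dose_threshold <- function(doses, pct_interference,
                                        threshold_pct = 10) {
  if (length(doses) != 2L || length(pct_interference) != 2L)
    stop("provide exactly two tested doses")
  p <- abs(pct_interference)
  if ((p[1] - threshold_pct) * (p[2] - threshold_pct) > 0) return(NA_real_)
  doses[1] + (threshold_pct - p[1]) * diff(doses) / diff(p)
}

#' Interference screen over a measurement table
#'
#' @param data Data frame with columns `interferent`, `analyte_level`,
#'   `arm` (`"test"` or `"control"`), `value`.
#' @param threshold_pct Flagging threshold (default 10).
#' @return List of `interference_result`, one per (interferent, level).
#' @export
interference_analysis <- function(data, threshold_pct = 10) {
  keys <- unique(data[, c("interferent", "analyte_level")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    d <- data[data$interferent == keys$interferent[i] &
                data$analyte_level == keys$analyte_level[i], ]
    out[[i]] <- interference_effect(
      d$value[d$arm == "test"], d$value[d$arm == "control"],
      interferent = keys$interferent[i],
      analyte_level = keys$analyte_level[i],
      threshold_pct = threshold_pct)
  }
  names(out) <- paste(keys$interferent, keys$analyte_level, sep = "@")
  out
}
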
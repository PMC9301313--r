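# EP17-style detection capability: nonparametric limit of blank per reagent
# lot, pooled low-level SD, the 95th-percentile multiplier with its
# small-sample correction, and the limit of detection.

#' Nonparametric limit of blank
#'
#' Ranks the blank measurements and reads off the `pctb` percentile at rank
#' position `r = 0.5 + B * pctb` (1-based ranks).  Fractional rank positions
#' are resolved by linear interpolation between the bracketing order
#' statistics; an integral rank position returns that order statistic
#' exactly.
#'
#' @param blanks Blank measurements, mg/dl (any order; `B = length(blanks)`).
#' @param pctb Percentile, default 0.95 (Type I error risk alpha = 0.05).
#' @param digits Rounding applied to the reported LoB (default 2 decimals,
#'   the assay's reporting convention); `NULL` for full precision.
#' @return LoB in mg/dl, with attribute `rank_position`.
#' @export
lob_nonparametric <- function(blanks, pctb = 0.95, digits = 2) {
  B <- length(blanks)
  if (B < 2L) stop("need at least 2 blank measurements")
  if (pctb <= 0 || pctb >= 1) stop("pctb must lie in (0, 1)")
  x <- sort(as.numeric(blanks))
  r <- 0.5 + B * pctb
  lo <- floor(r); hi <- ceiling(r)
  lo <- min(max(lo, 1L), B); hi <- min(max(hi, 1L), B)
  lob <- if (lo == hi) x[lo] else x[lo] + (r - lo) * (x[hi] - x[lo])
  if (!is.null(digits)) lob <- round(lob, digits)
  structure(lob, rank_position = r)
}

#' Pooled low-level standard deviation
#'
#' Degrees-of-freedom-weighted pooling across low-level samples:
#' `sqrt( sum((n_i - 1) sd_i^2) / sum(n_i - 1) )`.
#'
#' @param sds Per-sample SDs, mg/dl.
#' @param ns Per-sample measurement counts (each >= 2).
#' @return Pooled SD, mg/dl.
#' @export
pooled_sd <- function(sds, ns) {
  if (length(sds) != length(ns)) stop("sds and ns must have equal length")
  if (any(ns < 2)) stop("every sample needs n >= 2")
  df <- ns - 1
  sqrt(sum(df * sds^2) / sum(df))
}

#' EP17 percentile multiplier
#'
#' The 95th-percentile normal multiplier with the small-sample correction
#' `cp = z_0.95 / (1 - 1 / (4 df))`, where `df = N_total - K_samples` is the
#' degrees of freedom of the pooled low-level SD.
#'
#' @param n_total Total number of low-level measurements.
#' @param k_samples Number of distinct low-level samples.
#' @param percentile Normal percentile (default 0.95).
#' @return The multiplier `cp` (>= z).
#' @export
cp_multiplier <- function(n_total, k_samples, percentile = 0.95) {
  df <- n_total - k_samples
  if (df <= 0) stop("need n_total > k_samples")
  stats::qnorm(percentile) / (1 - 1 / (4 * df))
}

#' Limit of detection
#'
#' Parametric EP17 form `LoD = LoB + cp * SD_L` (default), combining the
#' limit of blank with the spread of low-level samples.  The bare variant
#' `LoD = cp * SD_L`, which ignores the blank distribution, is available via
#' `formula = "bare"`.
#'
#' @param lob Limit of blank, mg/dl.
#' @param cp Percentile multiplier, from [cp_multiplier()].
#' @param sd_l Pooled low-level SD, mg/dl (use the unrounded value).
#' @param formula `"lob_plus"` (default) or `"bare"`.
#' @param digits Rounding of the reported LoD (default 2 decimals); `NULL`
#'   for full precision.
#' @return LoD in mg/dl.
#' @export
lod <- function(lob, cp, sd_l, formula = c("lob_plus", "bare"), digits = 2) {
  formula <- match.arg(formula)
  if (any(c(lob, cp, sd_l) < 0)) stop("inputs must be >= 0")
  out <- switch(formula, lob_plus = lob + cp * sd_l, bare = cp * sd_l)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Detection-limit study from a measurement table
#'
#' Computes per-lot LoB from the blank measurements, takes the highest lot
#' LoB as the reported LoB, pools the low-level SDs per lot, and reports the
#' per-lot and overall LoD.
#'
#' @param blanks Data frame with columns `lot`, `value` (blank measurements);
#'   optionally `exclude` (logical) and `exclude_reason` for manually
#'   excluded readings.
#' @param low_levels Data frame with columns `lot`, `sample`, `value` of
#'   low-level measurements.
#' @param pctb Percentile for the LoB ranks.
#' @return A `detection_limits` list: per-lot LoB, reported LoB (max over
#'   lots), per-lot pooled SD, cp and LoD, and the overall LoD (max over
#'   lots).
#' @export
detection_limit_study <- function(blanks, low_levels, pctb = 0.95) {
  if (!is.null(blanks$exclude)) {
    excluded <- blanks[as.logical(blanks$exclude), , drop = FALSE]
    blanks <- blanks[!as.logical(blanks$exclude), , drop = FALSE]
  } else excluded <- blanks[0, , drop = FALSE]
  lob_by_lot <- vapply(split(blanks$value, blanks$lot), function(v)
    as.numeric(lob_nonparametric(v, pctb)), numeric(1))
  lob_rep <- max(lob_by_lot)

  per_lot <- lapply(split(low_levels, low_levels$lot), function(d) {
    agg <- tapply(d$value, d$sample, function(v) c(sd = stats::sd(v),
                                                   n = length(v)))
    sds <- vapply(agg, `[`, numeric(1), "sd")
    ns <- vapply(agg, `[`, numeric(1), "n")
    sd_l <- pooled_sd(sds, ns)
    cp <- cp_multiplier(sum(ns), length(ns))
    list(sd_l = sd_l, cp = cp, n_total = sum(ns), k_samples = length(ns),
         lod = lod(lob_rep, cp, sd_l))
  })
  structure(list(lob_by_lot = lob_by_lot, lob = lob_rep,
                 lots = per_lot,
                 lod = max(vapply(per_lot, `[[`, numeric(1), "lod")),
                 excluded_blanks = excluded),
            class = "detection_limits")
}
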
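# EP25-style shelf-life screening: each timepoint is compared against the
# baseline (week 0) with a Welch two-sample t-test, per concentration.

# Welch t-test p-value with the degenerate cases pinned down: identical
# constant arms compare exactly equal (p = 1); constant but different arms
# are an unambiguous difference (p = 0)
welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y)$p.value
}

#' Shelf-life stability analysis
#'
#' For every concentration, tests each later week against week 0 with a
#' Welch two-sample t-test of the replicate measurements.  A concentration is
#' "stable" when no week differs from baseline at level `alpha`.  No
#' multiplicity correction is applied by default (per-week reporting);
#' `bonferroni = TRUE` divides `alpha` by the number of comparisons.
#'
#' @param data Data frame with columns `concentration`, `week`, `replicate`,
#'   `value` (a `lot` column, if present, is pooled into the replicates).
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Apply a Bonferroni correction across weeks within each
#'   concentration (default `FALSE`).
#' @return A `stability_result` list, one element per concentration:
#'   `by_week` data frame (week, mean, SD, n, p-value vs week 0, flagged),
#'   `overall_mean`, `overall_se` (SE across weekly means), and `stable`.
#' @export
stability_analysis <- function(data, alpha = 0.05, bonferroni = FALSE) {
  need <- c("concentration", "week", "value")
  if (!all(need %in% names(data)))
    stop("missing column(s): ", paste(setdiff(need, names(data)), collapse = ", "))
  out <- lapply(split(data, data$concentration), function(d) {
    weeks <- sort(unique(d$week))
    if (!0 %in% weeks) stop("baseline week 0 missing")
    sizes <- table(d$week)
    if (any(sizes < 2)) stop("need at least 2 replicates per week")
    base <- d$value[d$week == 0]
    alpha_eff <- if (bonferroni) alpha / max(1, length(weeks) - 1) else alpha
    rows <- lapply(weeks, function(wk) {
      v <- d$value[d$week == wk]
      p <- if (wk == 0) NA_real_ else welch_p(v, base)
      data.frame(week = wk, mean = mean(v), sd = stats::sd(v),
                 n = length(v), p_value = p,
                 flagged = !is.na(p) & p < alpha_eff)
    })
    by_week <- do.call(rbind, rows)
    week_means <- by_week$mean
    list(by_week = by_week,
         overall_mean = mean(week_means),
         overall_se = stats::sd(week_means) / sqrt(length(week_means)),
         stable = !any(by_week$flagged),
         alpha = alpha_eff)
  })
  structure(out, class = "stability_result")
}
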
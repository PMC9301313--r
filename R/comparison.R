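# EP09-style comparison against a predicate analyzer: paired differences,
# median bias with a distribution-free signed-rank confidence interval, the
# equivalence criterion, and the CLIA total-error acceptability check.

#' Paired differences against the predicate method
#'
#' @param predicate Reference-method values, mg/dl.
#' @param test Candidate-device values, same length.
#' @return Data frame with `predicate`, `test`, `difference`
#'   (predicate - test) and `percent_error` (100 |difference| / predicate;
#'   `NA` where the predicate value is zero).
#' @export
paired_differences <- function(predicate, test) {
  if (length(predicate) != length(test)) stop("unequal lengths")
  if (length(predicate) < 1L) stop("need at least one pair")
  diff <- predicate - test
  pe <- ifelse(predicate == 0, NA_real_, 100 * abs(diff) / predicate)
  data.frame(predicate = predicate, test = test, difference = diff,
             percent_error = pe)
}

# signed-rank critical count: largest k with P(W <= k) <= alpha/2 under the
# null; exact from the signed-rank distribution for n <= exact_limit, normal
# approximation (with continuity correction) above
signrank_k <- function(n, conf_level, exact_limit = 25L) {
  alpha <- 1 - conf_level
  if (n <= exact_limit) {
    k <- stats::qsignrank(alpha / 2, n)
    # qsignrank returns smallest q with P(W <= q) >= alpha/2; step back if over
    if (stats::psignrank(k, n) > alpha / 2) k <- k - 1L
    k
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    floor(mu + stats::qnorm(alpha / 2) * sigma + 0.5)
  }
}

#' Median bias with distribution-free confidence interval
#'
#' The bias point estimate is the sample median of the paired differences.
#' The confidence interval is the Wilcoxon signed-rank interval: order the
#' Walsh averages (all pairwise midpoints `(d_i + d_j)/2`, `i <= j`) and take
#' the symmetric pair of order statistics determined by the signed-rank
#' critical value — exact for `n <= 25`, normal approximation above.  Zero
#' differences are dropped before ranking (standard signed-rank convention);
#' if all differences are equal the interval degenerates to that value with
#' a warning.
#'
#' @param differences Paired differences, mg/dl.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `median`, `ci_low`, `ci_high`, `conf_level`, `n_used`.
#' @export
median_bias_ci <- function(differences, conf_level = 0.95) {
  med <- stats::median(differences)
  d <- differences[differences != 0]
  n <- length(d)
  if (length(unique(differences)) == 1L) {
    warning("all differences identical; degenerate confidence interval")
    return(list(median = med, ci_low = med, ci_high = med,
                conf_level = conf_level, n_used = n))
  }
  if (n < 6L) stop("need at least 6 nonzero differences for a nondegenerate CI")
  w <- outer(d, d, `+`)[upper.tri(diag(n), diag = TRUE)] / 2
  w <- sort(w)
  M <- n * (n + 1) / 2
  k <- signrank_k(n, conf_level)
  lo <- if (k + 1 >= 1 && k + 1 <= M) w[k + 1] else min(w)
  hi <- if (M - k >= 1 && M - k <= M) w[M - k] else max(w)
  list(median = med, ci_low = lo, ci_high = hi,
       conf_level = conf_level, n_used = n)
}

#' Equivalence verdict from a bias confidence interval
#'
#' The methods are called equivalent when the whole confidence interval lies
#' within the predefined bias criterion (closed interval: endpoints exactly
#' at the criterion still pass).
#'
#' @param ci List with `ci_low` and `ci_high` (e.g. from
#'   [median_bias_ci()]).
#' @param criterion Bias criterion in mg/dl (default ±0.1).
#' @return Logical.
#' @export
equivalence_verdict <- function(ci, criterion = 0.1) {
  ci$ci_low >= -criterion && ci$ci_high <= criterion
}

#' CLIA total-error acceptability
#'
#' Per-sample check that the absolute difference from the predicate is within
#' the CLIA allowance for total bilirubin (±0.4 mg/dl; boundary inclusive).
#'
#' @param predicate,test Paired values, mg/dl.
#' @param limit Allowance in mg/dl (default 0.4).
#' @return List with logical vector `acceptable` and scalar `fraction`.
#' @export
clia_acceptability <- function(predicate, test, limit = 0.4) {
  if (length(predicate) != length(test)) stop("unequal lengths")
  ok <- abs(predicate - test) <= limit
  list(acceptable = ok, fraction = mean(ok))
}

#' Full predicate-comparison analysis
#'
#' @param data Data frame with columns `predicate_value` and `test_value`.
#' @param criterion Equivalence criterion, mg/dl.
#' @param clia_limit CLIA allowance, mg/dl.
#' @param conf_level Confidence level for the bias interval.
#' @return A `comparison_result` list: the difference table, median bias and
#'   CI, equivalence verdict, mean absolute percent error, and CLIA summary.
#' @export
comparison_analysis <- function(data, criterion = 0.1, clia_limit = 0.4,
                                conf_level = 0.95) {
  pd <- paired_differences(data$predicate_value, data$test_value)
  ci <- median_bias_ci(pd$difference, conf_level)
  clia <- clia_acceptability(data$predicate_value, data$test_value,
                             clia_limit)
  structure(list(differences = pd,
                 bias = ci,
                 equivalent = equivalence_verdict(ci, criterion),
                 criterion = criterion,
                 mean_abs_percent_error = mean(pd$percent_error, na.rm = TRUE),
                 clia = clia, clia_limit = clia_limit),
            class = "comparison_result")
}
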
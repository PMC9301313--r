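# EP06-style linearity assessment: polynomial fits of measured against
# assigned concentration, t-tests on the nonlinear coefficients, and the
# percent-difference rule between first- and second-order predictions.

#' Polynomial linearity fits
#'
#' Fits ordinary least squares polynomials of orders 1-3 of the measured
#' values on the assigned concentrations.  Replicates enter as individual
#' points, so with L levels and R replicates the residual degrees of freedom
#' are `L*R - (order+1)`.
#'
#' @param assigned Assigned (known) concentrations, one per measurement.
#' @param measured Measured values, same length.
#' @param orders Polynomial orders to fit (subset of 1-3).
#' @return A `linearity_fits` list, one element per order, each with
#'   `coefficients` (b0..b_order), `se`, `t` (coefficient / SE), `df`
#'   (residual degrees of freedom) and `sigma` (standard error of
#'   regression).
#' @export
fit_linearity <- function(assigned, measured, orders = 1:3) {
  if (length(assigned) != length(measured))
    stop("assigned and measured must have equal length")
  fits <- lapply(orders, function(ord) {
    if (length(unique(assigned)) < ord + 2L)
      stop("need at least order + 2 distinct assigned levels for order ", ord)
    fit <- stats::lm(measured ~ stats::poly(assigned, ord, raw = TRUE))
    sm <- summary(fit)
    co <- sm$coefficients
    list(order = ord,
         coefficients = stats::setNames(co[, 1], paste0("b", 0:ord)),
         se = stats::setNames(co[, 2], paste0("b", 0:ord)),
         t = stats::setNames(co[, 3], paste0("b", 0:ord)),
         df = fit$df.residual,
         sigma = sm$sigma,
         fit = fit)
  })
  structure(stats::setNames(fits, paste0("order", orders)),
            class = "linearity_fits")
}

#' Linearity verdict from polynomial fits
#'
#' Flags each nonlinear coefficient (b2 in the second-order fit; b2 and b3 in
#' the third-order fit) whose |t| exceeds the two-sided Student-t critical
#' value at its fit's residual degrees of freedom.  Additionally compares the
#' per-level first- and second-order predictions:
#' `%difference = 100 * (p2 - p1) / p2`.  The system is called linear when
#' the second-order nonlinear coefficient is not significant, or when every
#' |%difference| is below the laboratory criterion (default 20%).
#'
#' @param fits A `linearity_fits` object containing orders 1-3.
#' @param alpha Two-sided significance level (default 0.05).
#' @param pct_criterion Percent-difference criterion (default 20).
#' @param levels Assigned levels at which to compare predictions; defaults to
#'   the distinct assigned values of the fit data.
#' @return A `linearity_verdict` list: `critical_t` per order,
#'   `significant` flags per nonlinear coefficient, a `predictions` data
#'   frame (level, order-1 and order-2 predictions, difference,
#'   percent difference), and the `linear` verdict.
#' @export
nonlinearity_verdict <- function(fits, alpha = 0.05, pct_criterion = 20,
                                 levels = NULL) {
  need <- c("order1", "order2", "order3")
  if (!all(need %in% names(fits)))
    stop("fits must contain orders 1, 2 and 3")
  crit <- vapply(fits[need], function(f)
    stats::qt(1 - alpha / 2, f$df), numeric(1))
  sig <- list(
    order2 = abs(fits$order2$t["b2"]) > crit["order2"],
    order3 = abs(fits$order3$t[c("b2", "b3")]) > crit["order3"])

  if (is.null(levels)) {
    mf <- stats::model.frame(fits$order1$fit)
    levels <- sort(unique(mf[[2]][, 1]))
  }
  poly_eval <- function(coefs, x)
    as.vector(outer(x, seq_along(coefs) - 1, `^`) %*% coefs)
  p1 <- poly_eval(fits$order1$coefficients, levels)
  p2 <- poly_eval(fits$order2$coefficients, levels)
  pred <- data.frame(level = levels, order1 = p1, order2 = p2,
                     difference = p2 - p1,
                     pct_difference = 100 * (p2 - p1) / p2)
  linear <- !isTRUE(sig$order2[["b2"]]) ||
    all(abs(pred$pct_difference) < pct_criterion)
  structure(list(critical_t = crit, significant = sig, predictions = pred,
                 alpha = alpha, pct_criterion = pct_criterion,
                 linear = linear),
            class = "linearity_verdict")
}

#' Full linearity analysis of a measurement table
#'
#' @param data Data frame with columns `assigned` and `value` (one row per
#'   replicate measurement).
#' @inheritParams nonlinearity_verdict
#' @return List with `fits` and `verdict`.
#' @export
linearity_analysis <- function(data, alpha = 0.05, pct_criterion = 20) {
  fits <- fit_linearity(data$assigned, data$value)
  list(fits = fits,
       verdict = nonlinearity_verdict(fits, alpha, pct_criterion))
}
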
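# EP05-style precision analysis: balanced nested ANOVA, variance components,
# and the repeatability / within-laboratory / reproducibility estimates.
#
# Two balanced layouts are supported:
#   multisite:  site -> day(site) -> replicate        (reproducibility study)
#   singlesite: day -> run(day) -> replicate          (within-lab study)
#
# Variance components follow the standard method-of-moments identities for a
# balanced two-fold nested design,
#   V_error = MS_error
#   multisite:  V_day  = (MS_day  - MS_error) / n_rep
#               V_site = (MS_site - MS_day)   / (n_rep * n_day)
#   singlesite: V_run  = (MS_run  - MS_error) / n_rep
#               V_day  = (MS_day  - MS_run)   / (n_run * n_rep)
# with negative estimates truncated to zero (CLSI convention) and flagged.

#' Balanced nested ANOVA mean squares
#'
#' Computes the mean squares of a balanced two-fold nested design from a
#' precision dataset.  For the `multisite` layout the nesting is
#' site / day / replicate; for `singlesite` it is day / run / replicate.
#'
#' @param data Data frame with columns `value` and, depending on layout,
#'   `site`, `day` and (for singlesite) `run`.  One row per replicate.
#' @param layout `"multisite"` or `"singlesite"`.
#' @return List with the mean squares (`MS_site`/`MS_run`, `MS_day`,
#'   `MS_error`), their degrees of freedom, and the design counts
#'   (`n_top`, `n_mid`, `n_rep`).
#' @export
nested_anova <- function(data, layout = c("multisite", "singlesite")) {
  layout <- match.arg(layout)
  cols <- if (layout == "multisite") c("site", "day") else c("day", "run")
  missing <- setdiff(c(cols, "value"), names(data))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  top <- factor(data[[cols[1]]])
  mid <- interaction(top, factor(data[[cols[2]]]), drop = TRUE)
  y <- as.numeric(data$value)
  if (any(is.na(y))) stop("non-numeric or missing value entries")

  a <- nlevels(top)
  cell_counts <- table(top, factor(data[[cols[2]]]))
  if (a < 2L || ncol(cell_counts) < 2L)
    stop("need at least 2 levels in each nested factor")
  n_rep <- unique(as.vector(cell_counts))
  if (length(n_rep) != 1L || n_rep < 2L) {
    bad <- which(cell_counts != max(cell_counts), arr.ind = TRUE)[1, ]
    stop(sprintf("unbalanced design: %s '%s', %s '%s' has %d replicates",
                 cols[1], rownames(cell_counts)[bad[1]],
                 cols[2], colnames(cell_counts)[bad[2]],
                 cell_counts[bad[1], bad[2]]))
  }
  b <- ncol(cell_counts)

  grand <- mean(y)
  top_means <- tapply(y, top, mean)
  mid_means <- tapply(y, mid, mean)
  mid_top <- tapply(as.integer(top), mid, `[`, 1L)  # which top each cell is in

  ss_top <- b * n_rep * sum((top_means - grand)^2)
  ss_mid <- n_rep * sum((mid_means - top_means[mid_top])^2)
  ss_err <- sum((y - mid_means[mid])^2)

  df_top <- a - 1L
  df_mid <- a * (b - 1L)
  df_err <- a * b * (n_rep - 1L)
  ms <- list(MS_error = ss_err / df_err, MS_mid = ss_mid / df_mid,
             MS_top = ss_top / df_top,
             df = c(top = df_top, mid = df_mid, error = df_err),
             n_top = a, n_mid = b, n_rep = as.integer(n_rep),
             layout = layout, mean = grand)
  if (layout == "multisite") {
    ms$MS_site <- ms$MS_top; ms$MS_day <- ms$MS_mid
    ms$n_site <- a; ms$n_day <- b
  } else {
    ms$MS_day <- ms$MS_top; ms$MS_run <- ms$MS_mid
    ms$n_day <- a; ms$n_run <- b
  }
  ms
}

#' Variance components from nested mean squares
#'
#' Applies the balanced-design method-of-moments identities (see above) and
#' truncates negative estimates to zero, recording which components were
#' truncated.
#'
#' @param ms Mean squares from [nested_anova()], or a list with named entries
#'   `MS_error`, plus `MS_day`/`MS_site` (multisite) or `MS_run`/`MS_day`
#'   (singlesite).
#' @param n_rep,n_day,n_run Design counts; taken from `ms` when present.
#' @param layout `"multisite"` or `"singlesite"`; taken from `ms` when present.
#' @return A `variance_components` list: the components (`V_error`, `V_day`,
#'   and `V_site` or `V_run`), raw (untruncated) values, and truncation flags.
#' @export
variance_components <- function(ms, n_rep = ms$n_rep, n_day = ms$n_day,
                                n_run = ms$n_run,
                                layout = ms$layout %||% "multisite") {
  layout <- match.arg(layout, c("multisite", "singlesite"))
  if (is.null(n_rep) || n_rep <= 0) stop("n_rep must be positive")
  trunc0 <- function(x) pmax(x, 0)
  if (layout == "multisite") {
    if (is.null(n_day) || n_day <= 0) stop("n_day must be positive")
    raw <- c(V_error = ms$MS_error,
             V_day = (ms$MS_day - ms$MS_error) / n_rep,
             V_site = (ms$MS_site - ms$MS_day) / (n_rep * n_day))
  } else {
    if (is.null(n_run) || n_run <= 0) stop("n_run must be positive")
    raw <- c(V_error = ms$MS_error,
             V_run = (ms$MS_run - ms$MS_error) / n_rep,
             V_day = (ms$MS_day - ms$MS_run) / (n_run * n_rep))
  }
  structure(list(components = trunc0(raw), raw = raw,
                 truncated = raw < 0, layout = layout),
            class = "variance_components")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precision estimates from variance components
#'
#' Converts variance components to the CLSI precision tiers:
#' repeatability SD = sqrt(V_error); within-laboratory SD adds the
#' between-day (and, singlesite, between-run) components; reproducibility
#' (multisite only) adds the between-site component.  %CV = 100 * SD / mean,
#' computed from the unrounded SD.
#'
#' @param vc A `variance_components` object (or named list of components).
#' @param mean Mean measured concentration, mg/dl (> 0).
#' @return A `precision_estimates` data frame with columns `tier`, `SD`,
#'   `CV_pct`.
#' @export
precision_estimates <- function(vc, mean) {
  if (mean <= 0) stop("mean must be > 0")
  comp <- if (inherits(vc, "variance_components")) vc$components else unlist(vc)
  v_err <- comp[["V_error"]]
  v_day <- comp["V_day"]; v_day <- if (is.na(v_day)) 0 else v_day
  v_site <- comp["V_site"]; v_run <- comp["V_run"]
  multisite <- !is.na(v_site)
  sds <- c(repeatability = sqrt(v_err))
  if (multisite) {
    sds["within_laboratory"] <- sqrt(v_err + v_day)
    sds["reproducibility"] <- sqrt(v_err + v_day + v_site)
  } else {
    v_run <- if (is.na(v_run)) 0 else v_run
    sds["within_laboratory"] <- sqrt(v_err + v_run + v_day)
  }
  out <- data.frame(tier = names(sds), SD = unname(sds),
                    CV_pct = unname(100 * sds / mean))
  class(out) <- c("precision_estimates", "data.frame")
  attr(out, "mean") <- mean
  out
}

#' Full precision analysis of a measurement table
#'
#' Runs [nested_anova()], [variance_components()] and
#' [precision_estimates()] per sample.
#'
#' @param data Data frame with columns `sample`, `value`, and the layout's
#'   nesting columns (`site`,`day` or `day`,`run`) plus `replicate`.
#' @param layout `"multisite"` or `"singlesite"`.
#' @return Named list per sample: `mean`, `anova`, `variance_components`,
#'   `estimates`.
#' @export
precision_analysis <- function(data, layout = c("multisite", "singlesite")) {
  layout <- match.arg(layout)
  if (!"sample" %in% names(data)) data$sample <- "all"
  lapply(split(data, data$sample), function(d) {
    ms <- nested_anova(d, layout)
    vc <- variance_components(ms)
    list(mean = ms$mean, anova = ms, variance_components = vc,
         estimates = precision_estimates(vc, ms$mean))
  })
}

#' Simulate a balanced nested precision dataset
#'
#' Draws data from the hierarchical model
#' `y = mu + top_effect + mid_effect + error` with independent normal effects,
#' the generating model the nested ANOVA estimates components for.
#'
#' @param mu Grand mean, mg/dl.
#' @param v_top,v_mid,v_error True variance components, (mg/dl)^2: `v_top` is
#'   between-site (or between-day), `v_mid` the nested middle factor.
#' @param n_top,n_mid,n_rep Design counts.
#' @param layout `"multisite"` or `"singlesite"` (controls column names).
#' @param seed Seed.
#' @return Data frame in the layout's column convention.
#' @export
simulate_precision_dataset <- function(mu, v_top, v_mid, v_error,
                                       n_top = 3L, n_mid = 5L, n_rep = 5L,
                                       layout = c("multisite", "singlesite"),
                                       seed = 1L) {
  layout <- match.arg(layout)
  set.seed(as.integer(seed))
  top_eff <- stats::rnorm(n_top, 0, sqrt(v_top))
  mid_eff <- matrix(stats::rnorm(n_top * n_mid, 0, sqrt(v_mid)), n_top, n_mid)
  grid <- expand.grid(replicate = seq_len(n_rep), mid = seq_len(n_mid),
                      top = seq_len(n_top))
  grid$value <- mu + top_eff[grid$top] + mid_eff[cbind(grid$top, grid$mid)] +
    stats::rnorm(nrow(grid), 0, sqrt(v_error))
  if (layout == "multisite")
    data.frame(sample = "S", site = grid$top, day = grid$mid,
               replicate = grid$replicate, value = grid$value)
  else
    data.frame(sample = "S", day = grid$top, run = grid$mid,
               replicate = grid$replicate, value = grid$value)
}
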
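# Polynomial calibration of concentration on color features.
#
# The calibration family follows the constraints of a strip reader whose
# production model is a low-order (< 4) polynomial on features from a single
# color space: each candidate regresses concentration on one scalar feature,
# and model selection searches all 36 features x orders 1-3 on a held-out
# validation set.

.space_order <- c("RGB", "XYZ", "LAB", "HSV")

feature_space <- function(key) sub("_.*$", "", key)

features_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, lapply(features, unclass))
  as.matrix(features)
}

#' Fit a polynomial calibration model
#'
#' Ordinary least squares of concentration on the polynomial expansion (raw
#' powers 1..`order`) of the selected scalar feature(s), all drawn from one
#' color space.
#'
#' @param features List of `color_features` vectors, or a matrix/data.frame
#'   with the 36 named feature columns (one row per image).
#' @param concentrations Known concentrations, mg/dl, one per row.
#' @param feature_keys Feature name(s) to use, e.g. `"LAB_1_mean"`; all must
#'   belong to `space`.
#' @param space Color space id (`"RGB"`, `"XYZ"`, `"LAB"`, `"HSV"`); default
#'   taken from `feature_keys`.
#' @param order Polynomial order, 1-3.
#' @param quantifiable_range Assay range stored as model metadata; predictions
#'   outside it are flagged but not clipped.
#' @return A `calibration_model`: list with the space, keys, order,
#'   coefficients (named, intercept first) and training R-squared.
#' @export
fit_model <- function(features, concentrations, feature_keys,
                      space = feature_space(feature_keys[1]),
                      order = 1L, quantifiable_range = c(0.5, 7.0)) {
  if (!order %in% 1:3) stop("polynomial order must be 1, 2 or 3 (order < 4)")
  if (!space %in% .space_order) stop("unknown color space: ", space)
  if (any(feature_space(feature_keys) != space))
    stop("all selected features must come from the single space '", space, "'")
  X <- features_matrix(features)
  if (!all(feature_keys %in% colnames(X)))
    stop("feature key(s) not present: ",
         paste(setdiff(feature_keys, colnames(X)), collapse = ", "))
  y <- as.numeric(concentrations)
  if (nrow(X) != length(y)) stop("features and concentrations differ in length")
  p <- 1L + length(feature_keys) * order
  if (length(y) < p + 1L)
    stop("need at least order + 2 training points per feature")

  design <- do.call(cbind, lapply(feature_keys, function(k) {
    outer(X[, k], seq_len(order), `^`)
  }))
  colnames(design) <- unlist(lapply(feature_keys, function(k)
    paste0(k, "^", seq_len(order))))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, design), y)
  if (fit$rank < p) stop("rank-deficient design: features are collinear")
  coefs <- fit$coefficients
  fitted <- y - fit$residuals
  structure(
    list(space = space, feature_keys = feature_keys, order = as.integer(order),
         coefficients = coefs,
         training_r_squared = r_squared(y, fitted),
         validation_r_squared = NA_real_,
         quantifiable_range = quantifiable_range),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> order %d on %s [%s]\n", x$order, x$space,
              paste(x$feature_keys, collapse = ", ")))
  cat(sprintf("  training R^2 = %.4f", x$training_r_squared))
  if (!is.na(x$validation_r_squared))
    cat(sprintf(", validation R^2 = %.4f", x$validation_r_squared))
  cat("\n")
  invisible(x)
}

#' Predict concentration from color features
#'
#' Evaluates the calibration polynomial and floors the result at 0 mg/dl.
#' Values outside the model's quantifiable range are flagged via the
#' `outside_range` attribute.  Full precision is returned; rounding (the
#' device reports 2 decimals) is left to presentation.
#'
#' @param object A `calibration_model`.
#' @param features A `color_features` vector, or matrix/list of them.
#' @param digits Optional rounding of the reported value (e.g. 2 for the
#'   device's display convention); `NULL` keeps full precision.
#' @param ... Unused.
#' @return Numeric vector of predicted mg/dl, floored at 0, with logical
#'   attribute `outside_range`.
#' @export
predict.calibration_model <- function(object, features, digits = NULL, ...) {
  X <- features_matrix(if (is.null(dim(features)) && !is.list(features))
    t(as.matrix(unclass(features))) else features)
  if (!all(object$feature_keys %in% colnames(X)))
    stop("features are missing model key(s): ",
         paste(setdiff(object$feature_keys, colnames(X)), collapse = ", "))
  design <- do.call(cbind, lapply(object$feature_keys, function(k)
    outer(X[, k], seq_len(object$order), `^`)))
  raw <- as.vector(cbind(1, design) %*% object$coefficients)
  out <- pmax(raw, 0)
  if (!is.null(digits)) out <- round(out, digits)
  attr(out, "outside_range") <- out < object$quantifiable_range[1] |
    out > object$quantifiable_range[2]
  out
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of predictions against observations.
#'
#' @param observed,predicted Equal-length numeric vectors, `n >= 2`.
#' @return R-squared (can be negative for fits worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("need equal-length vectors with n >= 2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Select the best calibration model on a validation set
#'
#' Fits every candidate (by default each of the 36 features at orders 1-3),
#' scores each on the held-out validation set, and returns the candidate with
#' the highest validation R-squared.  Ties are broken by lower polynomial
#' order, then by color space in the fixed order RGB, XYZ, LAB, HSV.
#'
#' @param train_features,train_concentrations Training set.
#' @param val_features,val_concentrations Disjoint validation set.
#' @param feature_keys Candidate features (default: all columns).
#' @param orders Candidate polynomial orders (subset of 1-3).
#' @param quantifiable_range Passed to [fit_model()].
#' @return The winning `calibration_model` with `validation_r_squared` set.
#' @export
select_model <- function(train_features, train_concentrations,
                         val_features, val_concentrations,
                         feature_keys = NULL, orders = 1:3,
                         quantifiable_range = c(0.5, 7.0)) {
  Xt <- features_matrix(train_features)
  Xv <- features_matrix(val_features)
  if (is.null(feature_keys)) feature_keys <- colnames(Xt)
  if (length(feature_keys) == 0L || length(orders) == 0L)
    stop("empty candidate grid")
  # candidates are visited lower order first, then spaces in the fixed
  # enumeration order; replacing only on strict improvement makes the first
  # candidate seen win ties, implementing the tie-break rule
  feature_keys <- feature_keys[order(match(feature_space(feature_keys),
                                           .space_order))]
  best <- NULL; best_score <- -Inf
  for (ord in sort(orders)) {
    for (key in feature_keys) {
      model <- tryCatch(
        fit_model(Xt, train_concentrations, key, order = ord,
                  quantifiable_range = quantifiable_range),
        error = function(e) NULL)
      if (is.null(model)) next
      pred <- predict(model, Xv)
      score <- tryCatch(r_squared(val_concentrations, pred),
                        error = function(e) -Inf)
      # improvements below numerical noise count as ties (first seen wins)
      if (score > best_score + 1e-12) {
        model$validation_r_squared <- score
        best <- model; best_score <- score
      }
    }
  }
  if (is.null(best)) stop("no candidate model could be fit")
  best
}

#' Stratified train/validation split
#'
#' Splits image indices into train and validation sets, stratified by
#' concentration so every level appears in both sets where possible.
#'
#' @param concentrations Concentration label per image.
#' @param train_fraction Fraction assigned to training (default 0.6).
#' @param seed Seed for the within-stratum shuffle.
#' @return List with integer index vectors `train` and `validation`.
#' @export
stratified_split <- function(concentrations, train_fraction = 0.6, seed = 1L) {
  set.seed(as.integer(seed))
  train <- integer(0)
  for (lev in unique(concentrations)) {
    idx <- which(concentrations == lev)
    n_train <- max(1L, round(train_fraction * length(idx)))
    train <- c(train, sample(idx, n_train))
  }
  list(train = sort(train),
       validation = setdiff(seq_along(concentrations), train))
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(space = model$space, feature_keys = model$feature_keys,
         order = model$order,
         coefficients = as.list(model$coefficients),
         training_r_squared = model$training_r_squared,
         validation_r_squared = model$validation_r_squared,
         quantifiable_range = model$quantifiable_range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(space = x$space, feature_keys = x$feature_keys,
         order = as.integer(x$order), coefficients = unlist(x$coefficients),
         training_r_squared = x$training_r_squared,
         validation_r_squared = x$validation_r_squared,
         quantifiable_range = x$quantifiable_range),
    class = "calibration_model")
}
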
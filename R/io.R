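# Shared readers/writers and configuration defaults for the validation
# subcommands.

# required columns and their types, per input schema
.schemas <- list(
  precision = c(sample = "character", site = "numeric", day = "numeric",
                run = "numeric", replicate = "numeric", value = "numeric"),
  precision_multisite = c(sample = "character", site = "numeric",
                          day = "numeric", replicate = "numeric",
                          value = "numeric"),
  precision_singlesite = c(sample = "character", day = "numeric",
                           run = "numeric", replicate = "numeric",
                           value = "numeric"),
  lod_blanks = c(lot = "character", sample = "character",
                 replicate = "numeric", value = "numeric"),
  lod_low = c(lot = "character", sample = "character",
              replicate = "numeric", value = "numeric"),
  linearity = c(assigned = "numeric", replicate = "numeric",
                value = "numeric"),
  interference = c(interferent = "character", analyte_level = "numeric",
                   arm = "character", replicate = "numeric",
                   value = "numeric"),
  compare = c(sample_id = "character", predicate_value = "numeric",
              test_value = "numeric"),
  stability = c(concentration = "numeric", week = "numeric",
                lot = "character", replicate = "numeric",
                value = "numeric"),
  manifest = c(filename = "character", concentration_mg_dl = "numeric",
               seed = "numeric", panel_index = "numeric",
               pad_x0 = "numeric", pad_y0 = "numeric",
               pad_x1 = "numeric", pad_y1 = "numeric"))

#' Read and validate a measurement CSV
#'
#' Reads a CSV against one of the package's input schemas, checks for the
#' required columns, coerces types, and reports parse failures with the
#' offending row number.
#'
#' @param path CSV path.
#' @param schema One of `"precision_multisite"`, `"precision_singlesite"`,
#'   `"lod_blanks"`, `"lod_low"`, `"linearity"`, `"interference"`,
#'   `"compare"`, `"stability"`, `"manifest"`.
#' @return Data frame of validated records.
#' @export
read_measurements <- function(path, schema) {
  if (!schema %in% names(.schemas))
    stop("unknown schema '", schema, "'")
  spec <- .schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(names(spec), names(df))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  for (col in names(spec)) {
    if (spec[[col]] == "numeric") {
      parsed <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(parsed) & !is.na(df[[col]]) & nzchar(df[[col]]))
      if (length(bad) > 0)
        stop(sprintf("column '%s': non-numeric value '%s' on row %d",
                     col, df[[col]][bad[1]], bad[1]))
      if (anyNA(parsed))
        stop(sprintf("column '%s': missing value on row %d",
                     col, which(is.na(parsed))[1]))
      df[[col]] <- parsed
    }
  }
  df
}

#' Write an analysis report as JSON
#'
#' Reports carry a schema version, an echo of the run configuration (seed and
#' parameters), and the numeric results at full precision; display-rounded
#' fields, where present, are presentation-only.
#'
#' @param result Any serializable result object (lists/data frames).
#' @param path Output JSON path.
#' @param config Optional configuration list echoed into the report.
#' @return The path, invisibly.
#' @export
write_report <- function(result, path, config = list()) {
  payload <- list(schema_version = "1.0",
                  config = config,
                  results = strip_classes(result))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", force = TRUE)
  invisible(path)
}

# drop S3 classes so jsonlite serializes plain structures
strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  if (is.object(x)) {
    attrs <- attributes(x)
    x <- unclass(x)
    if (!is.null(attrs$names)) names(x) <- attrs$names
  }
  x
}

#' Display rounding conventions for report tables
#'
#' Rounds a precision-estimates table the way the validation reports print
#' it: SD at 3 decimals, %CV at 1 decimal.  Full-precision values remain
#' authoritative; this is presentation only.
#'
#' @param estimates A `precision_estimates` data frame.
#' @return Data frame with rounded display columns.
#' @export
format_precision_estimates <- function(estimates) {
  data.frame(tier = estimates$tier,
             SD = round(estimates$SD, 3),
             CV_pct = round(estimates$CV_pct, 1))
}

#' Default run configuration
#'
#' The package-wide defaults for the validation thresholds (10% interference
#' rule, ±0.1 mg/dl equivalence, ±0.4 mg/dl CLIA allowance, alpha = 0.05,
#' blank percentile 0.95) and the generator/detector parameter blocks.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       generator = unclass(generator_params()),
       geometry = unclass(assay_geometry()),
       roi = list(area_bounds = c(0.3, 3), aspect_bounds = c(1.0, 1.6),
                  frac = 0.6),
       model = list(orders = 1:3, quantifiable_range = c(0.5, 7.0),
                    train_fraction = 0.6),
       thresholds = list(interference_pct = 10, equivalence_mg_dl = 0.1,
                         clia_mg_dl = 0.4, alpha = 0.05, pctb = 0.95,
                         linearity_pct = 20))
}
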
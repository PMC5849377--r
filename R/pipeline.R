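#' Read / write a daily series CSV
#'
#' The on-disk schema is comma-delimited with dot decimals and columns
#' `date` (ISO-8601), `pm10`, `no2`, `temperature`, `wind` and,
#' optionally, `hospitalizations` (required for validation, optional for
#' pure prediction).  Dates must be strictly increasing; calendar gaps
#' are allowed but flagged with a warning.
#'
#' @param path CSV file path.
#' @param require_outcome Demand the `hospitalizations` column.
#' @return Data frame with `date` parsed as `Date` and numeric exposure
#'   columns.
#' @export
read_daily_series <- function(path, require_outcome = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "pm10", "no2", "temperature", "wind")
  if (require_outcome) need <- c(need, "hospitalizations")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop(sprintf("input CSV lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparseable dates in input CSV", call. = FALSE)
  if (any(diff(as.integer(d$date)) <= 0)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  if (any(diff(as.integer(d$date)) > 1)) {
    warning(sprintf("%d calendar gap(s) in the daily series",
                    sum(diff(as.integer(d$date)) > 1)), call. = FALSE)
  }
  if ("hospitalizations" %in% names(d)) {
    h <- d$hospitalizations
    if (any(h < 0, na.rm = TRUE) ||
        any(h != as.integer(h), na.rm = TRUE)) {
      stop("hospitalizations must be non-negative integer counts",
           call. = FALSE)
    }
  }
  d
}

#' @rdname read_daily_series
#' @param series Data frame to write.
#' @export
write_daily_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# md5 of a file, or of an object via its YAML rendering
.hash_file <- function(path) unname(tools::md5sum(path))
.hash_object <- function(obj) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(obj, tmp)
  .hash_file(tmp)
}

#' Run the full pipeline: simulate (optionally), predict, validate
#'
#' Executes the end-to-end analysis and writes three artifacts under
#' `output_dir`: `predictions.csv` (date, observed count, prediction to
#' 3 decimals), `validation.json` (the [validate_series()] report) and
#' `manifest.json` (a run manifest with input/config hashes, seed and
#' package version, so that identical manifests — timestamp aside —
#' imply identical outputs).
#'
#' @param input Optional path to a daily-series CSV.  When `NULL`, a
#'   synthetic series is generated with [generate_series()].
#' @param output_dir Directory for the artifacts (created if needed).
#' @param fis Model to use (default [respiratory_fis()]).
#' @param seed Seed for the synthetic generator (ignored when `input`
#'   is given).
#' @param n_days Length of the synthetic series.
#' @param lags,cutoff,ci_method Passed to [validate_series()].
#' @return Invisibly, a list with `series`, `predictions`, `report`,
#'   `manifest` and the artifact paths.
#' @export
run_pipeline <- function(input = NULL, output_dir = "results",
                         fis = respiratory_fis(), seed = 1L,
                         n_days = 730L, lags = 0:3, cutoff = 2L,
                         ci_method = "hanley") {
  if (is.null(input)) {
    config <- generator_config(n_days = n_days, seed = seed)
    series <- generate_series(config)
    input_hash <- .hash_object(unclass(config))
    source_desc <- "synthetic"
  } else {
    series <- read_daily_series(input, require_outcome = TRUE)
    input_hash <- .hash_file(input)
    source_desc <- input
  }
  report <- validate_series(series, fis = fis, lags = lags,
                            cutoff = cutoff, ci_method = ci_method)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  pred_path <- file.path(output_dir, "predictions.csv")
  pred_df <- data.frame(date = series$date,
                        observed = series$hospitalizations,
                        predicted = round(report$predictions, 3))
  utils::write.csv(pred_df, pred_path, row.names = FALSE, quote = FALSE)

  report_path <- file.path(output_dir, "validation.json")
  write_report_json(report, report_path)

  manifest <- list(
    subcommand = "run",
    input = source_desc,
    input_hash = input_hash,
    model_hash = .hash_object(fis_to_config(fis)),
    seed = as.integer(seed),
    n_days = if (is.null(input)) as.integer(n_days) else nrow(series),
    lags = as.integer(lags),
    cutoff = as.integer(cutoff),
    ci_method = ci_method,
    package_version = as.character(utils::packageVersion("fuzzyair")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)

  invisible(list(series = series, predictions = report$predictions,
                 report = report, manifest = manifest,
                 paths = c(predictions = pred_path, report = report_path,
                           manifest = manifest_path)))
}
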
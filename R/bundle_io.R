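# Disk layout for claims bundles: one file per table plus a JSON manifest.
# Integer day offsets are rendered as ISO-8601 dates in the files and
# converted back on read, so round-trips are lossless.

bundle_tables <- function() {
  c("person", "condition_occurrence", "drug_exposure", "visit_occurrence",
    "measurement", "observation_period", "truth")
}

date_columns <- list(
  person = character(),
  condition_occurrence = "date",
  drug_exposure = "start_date",
  visit_occurrence = "visit_date",
  measurement = "date",
  observation_period = c("enroll_start", "enroll_end"),
  truth = "index_date"
)

#' Write and read a claims bundle on disk
#'
#' `write_bundle()` writes one CSV or Parquet file per table plus a
#' `manifest.json` documenting the schema, the study window and the format.
#' The simulator's truth table is written only when present. `read_bundle()`
#' restores the bundle from such a directory.
#'
#' @param bundle a [claims_bundle][simulate_claims()].
#' @param directory output directory (created if needed).
#' @param format `"csv"` or `"parquet"` (Parquet needs the `arrow` package).
#' @return `write_bundle()` returns the manifest (a list) invisibly;
#'   `read_bundle()` returns a `claims_bundle`.
#' @export
write_bundle <- function(bundle, directory, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "claims_bundle"))
  if (format == "parquet" && !requireNamespace("arrow", quietly = TRUE)) {
    stop("parquet output requires the 'arrow' package")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  study_start <- bundle$meta$study_start
  ext <- if (format == "csv") ".csv" else ".parquet"

  tables <- intersect(bundle_tables(), names(bundle))
  if (is.null(bundle$truth)) tables <- setdiff(tables, "truth")
  manifest <- list(
    format = format,
    study_start = format(study_start),
    total_days = bundle$meta$total_days,
    simulated = isTRUE(bundle$meta$simulated),
    tables = list()
  )
  for (tab in tables) {
    dt <- copy(as.data.table(bundle[[tab]]))
    for (dc in date_columns[[tab]]) {
      if (dc %in% names(dt)) dt[[dc]] <- format(study_start + dt[[dc]])
    }
    file <- file.path(directory, paste0(tab, ext))
    if (format == "csv") {
      fwrite(dt, file)
    } else {
      arrow::write_parquet(dt, file)
    }
    manifest$tables[[tab]] <- list(
      file = basename(file), rows = nrow(dt),
      columns = as.list(vapply(dt, function(col) class(col)[1], ""))
    )
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(directory) {
  mf_path <- file.path(directory, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(mf_path)
  study_start <- as.Date(manifest$study_start)
  out <- list()
  for (tab in names(manifest$tables)) {
    file <- file.path(directory, manifest$tables[[tab]]$file)
    dt <- if (manifest$format == "csv") {
      fread(file)
    } else {
      as.data.table(arrow::read_parquet(file))
    }
    for (dc in date_columns[[tab]]) {
      if (dc %in% names(dt)) {
        dt[[dc]] <- as.integer(as.Date(dt[[dc]]) - study_start)
      }
    }
    out[[tab]] <- dt
  }
  out$meta <- list(
    study_start = study_start,
    total_days = as.integer(manifest$total_days),
    simulated = isTRUE(manifest$simulated)
  )
  structure(out, class = "claims_bundle")
}
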
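#' Sentinel compound id for no-compound (vehicle) wells
#'
#' Wells that receive serum and probe but no library compound carry this
#' string in their `compound_id` field. Their half-lifetimes provide the
#' per-sample baseline used by [normalize_half_life()].
#'
#' @format A length-one character vector, `"BASELINE"`.
#' @export
BASELINE_COMPOUND <- "BASELINE"

.plate_columns <- c("well_id", "sample_id", "compound_id",
                    "replicate", "time_min", "intensity")

new_well_record <- function(well_id, sample_id, compound_id, replicate,
                            times, intensities) {
  stopifnot(length(times) == length(intensities))
  structure(
    list(well_id = as.character(well_id),
         sample_id = as.character(sample_id),
         compound_id = as.character(compound_id),
         replicate = as.integer(replicate),
         times = as.numeric(times),
         intensities = as.numeric(intensities)),
    class = "well_record")
}

#' Read a plate time-series file
#'
#' Reads a long-format, comma-separated plate file (one row per well,
#' replicate and time point) into a collection of per-well records. Rows
#' belonging to the same `(well_id, replicate)` pair are gathered into one
#' record and sorted by time; duplicated time points within a well are a
#' format error (they cannot be ordered meaningfully).
#'
#' The expected columns are `well_id`, `sample_id`, `compound_id`,
#' `replicate`, `time_min`, `intensity`. Files with different headers can be
#' mapped via `schema`, a named character vector from the expected names to
#' the names actually present, e.g.
#' `c(time_min = "minutes", intensity = "counts")`. The decimal mark is the
#' dot and the separator the comma; other dialects are rejected, not guessed.
#'
#' @param path Path to a CSV file with a header line.
#' @param schema Optional named character vector renaming file columns to the
#'   expected ones (names are expected column names, values are the file's).
#' @return An object of class `well_records`: a list of per-well records,
#'   each holding `well_id`, `sample_id`, `compound_id`, `replicate` and the
#'   time-sorted `times` (minutes) and `intensities` (arbitrary units).
#' @seealso [write_plate()], [fit_plate()]
#' @export
read_plate <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("plate file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(!nzchar(names(schema))))
      stop("'schema' must be a named character vector")
    for (std in names(schema)) {
      src <- schema[[std]]
      if (!src %in% names(df))
        stop("schema error: column '", src, "' (mapped to '", std,
             "') not found in ", path)
      names(df)[names(df) == src] <- std
    }
  }
  missing <- setdiff(.plate_columns, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  df$time_min <- as.numeric(df$time_min)
  df$intensity <- as.numeric(df$intensity)
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$time_min) || anyNA(df$intensity) || anyNA(df$replicate))
    stop("format error: missing or non-numeric values in time_min/intensity/replicate")
  if (any(df$time_min < 0))
    stop("format error: negative time points")
  if (any(df$replicate < 1))
    stop("format error: replicate must be >= 1")

  key <- paste(df$well_id, df$replicate, sep = "\r")
  records <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, ]
    well <- sub$well_id[[1L]]
    if (length(unique(sub$sample_id)) != 1L ||
        length(unique(sub$compound_id)) != 1L)
      stop("format error: well '", well,
           "' maps to more than one sample or compound")
    o <- order(sub$time_min)
    times <- sub$time_min[o]
    if (anyDuplicated(times))
      stop("format error: duplicate time points in well '", well, "'")
    if (length(times) < 4L)
      stop("format error: well '", well, "' has fewer than 4 time points")
    new_well_record(well, sub$sample_id[[1L]], sub$compound_id[[1L]],
                    sub$replicate[[1L]], times, sub$intensity[o])
  })
  names(records) <- NULL
  structure(records, class = "well_records")
}

#' Write a plate file
#'
#' Serializes a collection of well records to the long-format CSV read by
#' [read_plate()]. Numeric fields are written with 17 significant digits so a
#' write/read round trip reproduces them exactly. Vehicle wells keep the
#' [BASELINE_COMPOUND] sentinel in `compound_id`.
#'
#' @param records A `well_records` collection (or list of well records).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(records, path) {
  if (length(records) == 0L) stop("cannot write an empty record set")
  df <- as.data.frame(records)
  df$time_min <- sprintf("%.17g", df$time_min)
  df$intensity <- sprintf("%.17g", df$intensity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.well_records <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(well_id = r$well_id, sample_id = r$sample_id,
               compound_id = r$compound_id, replicate = r$replicate,
               time_min = r$times, intensity = r$intensities)
  }))
}

#' @export
print.well_records <- function(x, ...) {
  n_base <- sum(vapply(x, function(r) r$compound_id == BASELINE_COMPOUND,
                       logical(1)))
  cat("Plate with", length(x), "well records",
      sprintf("(%d baseline)\n", n_base))
  cat("Samples:",
      length(unique(vapply(x, `[[`, character(1), "sample_id"))),
      " Compounds:",
      length(unique(vapply(x, `[[`, character(1), "compound_id"))), "\n")
  invisible(x)
}

#' @export
print.well_record <- function(x, ...) {
  cat(sprintf("Well %s  sample=%s  compound=%s  replicate=%d  (%d points, %g-%g min)\n",
              x$well_id, x$sample_id, x$compound_id, x$replicate,
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Read a sample metadata table
#'
#' Reads the sample annotation file linking each `sample_id` to a disease
#' group label (open set: e.g. AD, HC, MS, DB, RA, AD-MCI) and a batch id.
#' Both comma- and tab-separated files are accepted; the delimiter is sniffed
#' from the header line.
#'
#' @param path Path to a CSV/TSV file with columns `sample_id`, `group`,
#'   `batch_id` and a header line.
#' @return A `data.frame` of class `sample_metadata` with character columns
#'   `sample_id` (unique), `group` and `batch_id`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("sample_id", "group", "batch_id"), names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(is.na(df$group) | !nzchar(df$group)))
    stop("empty group label for sample(s): ",
         paste(df$sample_id[is.na(df$group) | !nzchar(df$group)],
               collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Sample ids belonging to a group
#'
#' Group-membership query over a metadata table: the index sets used by the
#' batch-baseline estimator (healthy controls and cases) are
#' `group_samples(meta, "HC")` and `group_samples(meta, "AD")`.
#'
#' @param metadata A `sample_metadata` table from [read_metadata()].
#' @param group A group label.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(metadata, group) {
  metadata$sample_id[metadata$group == group]
}

#' Write a sample metadata table
#'
#' @param metadata A `sample_metadata` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata[, c("sample_id", "group", "batch_id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
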
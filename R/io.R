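#' Read a dispensing table
#'
#' Reads the canonical dispensing CSV
#' (`patient_id,date,atc,strength_mg,units,days_supplied`), validates it and
#' returns the records sorted by (patient_id, date). Duplicate identical rows
#' are retained: two dispensings of the same drug on the same day are distinct
#' events in pharmacy data.
#'
#' @param path path to a CSV file with the canonical header.
#' @param required_cols columns that must be present.
#' @return a `data.frame` with `date` parsed as `Date`, sorted by
#'   (patient_id, date).
#' @export
read_dispensing_table <- function(path,
                                  required_cols = c("patient_id", "date", "atc",
                                                    "strength_mg", "units",
                                                    "days_supplied")) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("dispensing table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    df$date <- as.Date(df$date)
    return(df)
  }
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop("unparseable date(s) in dispensing table at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  df$date <- d
  validate_dispensing(df)
  df[order(df$patient_id, df$date), , drop = FALSE]
}

#' @rdname read_dispensing_table
#' @param records a dispensing `data.frame` (as returned by
#'   [read_dispensing_table()] or [generate_population()]).
#' @export
validate_dispensing <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  if (any(!nzchar(records$atc) | is.na(records$atc))) {
    stop("empty ATC code at row(s): ",
         paste(utils::head(which(!nzchar(records$atc) | is.na(records$atc)), 10),
               collapse = ", "))
  }
  bad <- which(is.na(records$days_supplied) | records$days_supplied < 1)
  if (length(bad)) {
    stop("days_supplied must be >= 1; violated at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  invisible(records)
}

#' Read a patient table
#'
#' Canonical patient CSV: `patient_id,birth_date,sex` with sex coded
#' `male`/`female`. Patient ids must be unique.
#'
#' @inheritParams read_dispensing_table
#' @return a `data.frame` with `birth_date` as `Date`.
#' @export
read_patient_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  missing <- setdiff(c("patient_id", "birth_date", "sex"), names(df))
  if (length(missing)) {
    stop("patient table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in patient table: ",
         paste(utils::head(unique(df$patient_id[duplicated(df$patient_id)]), 5),
               collapse = ", "))
  }
  if (nrow(df) && !all(df$sex %in% c("male", "female"))) {
    stop("sex must be coded male/female")
  }
  df$birth_date <- as.Date(df$birth_date)
  df
}

#' Write dispensing / patient tables in the canonical CSV dialect
#'
#' ISO-8601 dates, comma separated, header row, no quoting of numerics.
#' Round-trips losslessly through [read_dispensing_table()] /
#' [read_patient_table()].
#'
#' @param df table to write.
#' @param path destination path.
#' @export
write_canonical_csv <- function(df, path) {
  for (col in names(df)) {
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
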
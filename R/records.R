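#' Validate a table of individual fish records
#'
#' A fish-record table is the atomic input of the assessment pipeline: one row
#' per sampled fish with columns `group_id` (river or stock label), `sex`
#' (`"female"`, `"male"` or `"unknown"`), `age` (integer annulus count, years),
#' `length_mm` (body length, mm) and `weight_g` (body weight, g).
#'
#' @param records data.frame with the five schema columns.
#' @param groups optional character vector of admissible `group_id` values;
#'   when supplied, any other label is an error.
#' @return the validated data.frame, invisibly coerced (`age` to integer,
#'   `group_id`/`sex` to character).
#' @export
validate_fish_records <- function(records, groups = NULL) {
  required <- c("group_id", "sex", "age", "length_mm", "weight_g")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("fish records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records$group_id <- as.character(records$group_id)
  records$sex <- as.character(records$sex)

  bad_sex <- !records$sex %in% c("female", "male", "unknown")
  if (any(bad_sex)) {
    stop("invalid sex value(s) in row(s): ",
         paste(utils::head(which(bad_sex), 5L), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(records$age) | records$age < 0 |
          records$age != round(records$age))) {
    bad <- which(!is.finite(records$age) | records$age < 0 |
                   records$age != round(records$age))
    stop("age must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad_len <- which(!is.finite(records$length_mm) | records$length_mm <= 0)
  if (length(bad_len) > 0L) {
    stop("body length must be strictly positive; offending row(s): ",
         paste(utils::head(bad_len, 5L), collapse = ", "), call. = FALSE)
  }
  bad_wt <- which(!is.finite(records$weight_g) | records$weight_g <= 0)
  if (length(bad_wt) > 0L) {
    stop("body weight must be strictly positive; offending row(s): ",
         paste(utils::head(bad_wt, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(groups)) {
    alien <- setdiff(unique(records$group_id), groups)
    if (length(alien) > 0L) {
      stop("unknown group_id value(s): ", paste(alien, collapse = ", "),
           call. = FALSE)
    }
  }
  records$age <- as.integer(round(records$age))
  invisible(records)
}

#' Read fish records from a delimited text file
#'
#' Expects a UTF-8 CSV with header columns `group_id, sex, age, length_mm,
#' weight_g` and `.` as the decimal separator.
#'
#' @param path path to the CSV file.
#' @param groups optional admissible group labels (see
#'   [validate_fish_records()]).
#' @return validated data.frame of fish records.
#' @export
read_fish_records <- function(path, groups = NULL) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  validate_fish_records(records, groups = groups)
}

#' Write fish records to CSV
#'
#' Writes only the five schema columns so that simulated populations (which
#' carry extra bookkeeping columns such as the continuous age) round-trip
#' through the same reader the assessment uses.
#'
#' @param records data.frame of fish records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fish_records <- function(records, path) {
  cols <- c("group_id", "sex", "age", "length_mm", "weight_g")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
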
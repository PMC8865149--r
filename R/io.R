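# Delimited-text readers/writers for the study's canonical file layouts.
# All timestamps are UTC epoch milliseconds; files are comma-separated with a
# header row, UTF-8.

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

# Drop invalid rows with a logged count; record rejected line numbers
# (1-based data rows) in attributes rather than silently discarding.
reject_rows <- function(df, bad, what, path) {
  n_bad <- sum(bad)
  if (n_bad > 0) {
    lines <- which(bad)
    message(sprintf("%s: rejected %d malformed row(s) (%s) at line(s) %s",
                    basename(path), n_bad, what,
                    paste(utils::head(lines, 10), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  attr(df, "n_rejected") <- (attr(df, "n_rejected") %||% 0L) + n_bad
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sort_by_ts <- function(df) {
  nr <- attr(df, "n_rejected")
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- nr
  df
}

#' Read and write sensor and assessment tables
#'
#' Readers validate the documented schema (comma-separated, header row),
#' reject malformed rows with a logged count (recorded in the `n_rejected`
#' attribute), and return rows sorted by timestamp. Writers emit the same
#' layouts, so write-then-read is an identity on valid data.
#'
#' File layouts: `gps.csv` `timestamp,latitude,longitude,accuracy`;
#' `accel.csv` `timestamp,x,y,z`; `surveys.csv`
#' `subject,delivered,completed,instrument,q1..q8,total`; `visits.csv`
#' `subject,visit_index,date,madrs`; `calls.csv`
#' `subject,timestamp,direction,hashed_number`; `demographics.csv`
#' `subject,age,sex,diagnosis,timezone,os`.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return Readers: a validated, time-sorted data.frame with attribute
#'   `n_rejected`. Writers: `path`, invisibly.
#' @name sensor-io
NULL

#' @rdname sensor-io
#' @export
read_gps <- function(path) {
  df <- read_table_checked(path, c("timestamp", "latitude", "longitude",
                                   "accuracy"))
  for (cl in c("timestamp", "latitude", "longitude", "accuracy"))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  df <- reject_rows(df, !is.finite(df$timestamp), "unparseable timestamp", path)
  bad <- !is.finite(df$latitude) | !is.finite(df$longitude) |
    abs(df$latitude) > 90 | abs(df$longitude) > 180 |
    !is.finite(df$accuracy) | df$accuracy < 0
  df <- reject_rows(df, bad, "coordinate/accuracy out of range", path)
  sort_by_ts(df)
}

#' @rdname sensor-io
#' @export
read_accel <- function(path) {
  df <- read_table_checked(path, c("timestamp", "x", "y", "z"))
  for (cl in c("timestamp", "x", "y", "z"))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  df <- reject_rows(df, !is.finite(df$timestamp), "unparseable timestamp", path)
  df <- reject_rows(df, !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z),
                    "non-finite acceleration", path)
  sort_by_ts(df)
}

#' @rdname sensor-io
#' @export
read_surveys <- function(path) {
  qs <- paste0("q", 1:8)
  df <- read_table_checked(path, c("subject", "delivered", "completed",
                                   "instrument", qs, "total"))
  for (cl in c("delivered", "completed", qs, "total"))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  df <- reject_rows(df, !is.finite(df$delivered), "unparseable timestamp", path)
  item_sum <- rowSums(df[, qs, drop = FALSE])
  done <- is.finite(df$completed)
  bad <- (done & (df$completed < df$delivered)) |
    (done & (is.na(item_sum) | item_sum != df$total)) |
    (done & (df$total < 0 | df$total > 24)) |
    (done & apply(df[, qs, drop = FALSE], 1,
                  function(r) any(!is.na(r) & (r < 0 | r > 3))))
  df <- reject_rows(df, bad, "inconsistent survey record", path)
  df$timestamp <- df$delivered
  df <- sort_by_ts(df)
  df$timestamp <- NULL
  df
}

#' @rdname sensor-io
#' @export
read_visits <- function(path) {
  df <- read_table_checked(path, c("subject", "visit_index", "date", "madrs"))
  df$visit_index <- suppressWarnings(as.integer(df$visit_index))
  df$madrs <- suppressWarnings(as.numeric(df$madrs))
  date <- as.Date(df$date, format = "%Y-%m-%d")
  df <- reject_rows(df, is.na(date), "unparseable date", path)
  df$date <- as.Date(df$date)
  bad <- !is.finite(df$madrs) | df$madrs < 0 | df$madrs > 60 |
    is.na(df$visit_index)
  df <- reject_rows(df, bad, "MADRS/visit index out of range", path)
  nr <- attr(df, "n_rejected")
  df <- df[order(df$subject, df$visit_index), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- nr
  df
}

#' @rdname sensor-io
#' @export
read_calls <- function(path) {
  df <- read_table_checked(path, c("subject", "timestamp", "direction",
                                   "hashed_number"))
  df$timestamp <- suppressWarnings(as.numeric(df$timestamp))
  df <- reject_rows(df, !is.finite(df$timestamp), "unparseable timestamp", path)
  df <- reject_rows(df, !df$direction %in% c("incoming", "outgoing", "missed"),
                    "unknown call direction", path)
  sort_by_ts(df)
}

#' @rdname sensor-io
#' @export
read_demographics <- function(path) {
  df <- read_table_checked(path, c("subject", "age", "sex", "diagnosis",
                                   "timezone", "os"))
  df$age <- suppressWarnings(as.numeric(df$age))
  df <- reject_rows(df, !is.finite(df$age) | df$age < 0, "invalid age", path)
  df
}

write_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname sensor-io
#' @export
write_gps <- function(x, path) write_plain(x[, c("timestamp", "latitude",
                                                 "longitude", "accuracy")], path)

#' @rdname sensor-io
#' @export
write_accel <- function(x, path) write_plain(x[, c("timestamp", "x", "y", "z")],
                                             path)

#' @rdname sensor-io
#' @export
write_surveys <- function(x, path)
  write_plain(x[, c("subject", "delivered", "completed", "instrument",
                    paste0("q", 1:8), "total")], path)

#' @rdname sensor-io
#' @export
write_visits <- function(x, path) {
  x$date <- format(as.Date(x$date))
  write_plain(x[, c("subject", "visit_index", "date", "madrs")], path)
}

#' @rdname sensor-io
#' @export
write_calls <- function(x, path)
  write_plain(x[, c("subject", "timestamp", "direction", "hashed_number")], path)

#' @rdname sensor-io
#' @export
write_demographics <- function(x, path)
  write_plain(x[, c("subject", "age", "sex", "diagnosis", "timezone", "os")],
              path)

#' Write or read a whole cohort in the canonical layout
#'
#' `write_cohort()` writes `demographics.csv`, `visits.csv`, `surveys.csv`,
#' `calls.csv`, per-subject `subjects/<id>/gps.csv` and `accel.csv`, and a
#' `manifest.json` recording the generating configuration and seed.
#' `read_cohort()` reassembles the per-subject streams and tables.
#'
#' @param cohort a `"cohort"` object from [simulate_cohort()].
#' @param dir directory to write to / read from.
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a list with
#'   the tables and per-subject streams.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_demographics(cohort$demographics, file.path(dir, "demographics.csv"))
  write_visits(cohort$visits, file.path(dir, "visits.csv"))
  write_surveys(cohort$surveys, file.path(dir, "surveys.csv"))
  if (!is.null(cohort$calls))
    write_calls(cohort$calls, file.path(dir, "calls.csv"))
  for (sid in names(cohort$gps)) {
    sd <- file.path(dir, "subjects", sid)
    dir.create(sd, showWarnings = FALSE, recursive = TRUE)
    write_gps(cohort$gps[[sid]], file.path(sd, "gps.csv"))
    write_accel(cohort$accel[[sid]], file.path(sd, "accel.csv"))
  }
  manifest <- cohort$config
  manifest$start_date <- format(manifest$start_date)
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- list.dirs(file.path(dir, "subjects"), recursive = FALSE)
  gps <- lapply(subjects, function(s) read_gps(file.path(s, "gps.csv")))
  accel <- lapply(subjects, function(s) read_accel(file.path(s, "accel.csv")))
  names(gps) <- names(accel) <- basename(subjects)
  calls_path <- file.path(dir, "calls.csv")
  list(demographics = read_demographics(file.path(dir, "demographics.csv")),
       visits = read_visits(file.path(dir, "visits.csv")),
       surveys = read_surveys(file.path(dir, "surveys.csv")),
       calls = if (file.exists(calls_path)) read_calls(calls_path) else NULL,
       gps = gps, accel = accel,
       manifest = jsonlite::read_json(file.path(dir, "manifest.json")))
}
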
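#' @keywords internal
"_PACKAGE"

#' Derive a reproducible integer seed from a root seed and labels
#'
#' All randomness in the simulator flows from one root seed through named
#' substreams (per subject, per sensor, per day), so any component can be
#' regenerated in isolation. The derivation is a polynomial rolling hash of
#' the label path, reduced modulo a Mersenne prime so the result is a valid
#' 32-bit seed.
#'
#' @param root integer root seed.
#' @param ... labels (coerced to character) naming the substream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1)
  path <- paste(c(format(root, scientific = FALSE), ...), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(path)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Local-time helpers
#'
#' Timestamps are stored as UTC epoch milliseconds throughout; a per-subject
#' IANA timezone governs all day and hour binning (weekday/weekend contrasts
#' and hourly activity curves are local-time notions). A "day" is
#' `[00:00, 24:00)` local; weekend days are Saturday and Sunday.
#'
#' @param ts_ms numeric vector of UTC epoch milliseconds.
#' @param tz IANA timezone string.
#' @return `local_date()`: a `Date` vector; `local_seconds()`: seconds since
#'   local midnight; `day_type()`: `"weekday"` or `"weekend"`.
#' @name local-time
NULL

#' @rdname local-time
#' @export
local_date <- function(ts_ms, tz = "UTC") {
  if (tz == "UTC") # fast path: no offset, no DST
    return(as.Date(floor(ts_ms / MS_PER_DAY), origin = "1970-01-01"))
  as.Date(as.POSIXct(ts_ms / 1000, origin = "1970-01-01", tz = tz), tz = tz)
}

#' @rdname local-time
#' @export
local_seconds <- function(ts_ms, tz = "UTC") {
  if (tz == "UTC")
    return((ts_ms / 1000) %% SEC_PER_DAY)
  lt <- as.POSIXlt(ts_ms / 1000, origin = "1970-01-01", tz = tz)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

#' @rdname local-time
#' @param dates a `Date` vector.
#' @export
day_type <- function(dates) {
  wd <- as.POSIXlt(dates)$wday # 0 = Sunday, 6 = Saturday
  ifelse(wd == 0 | wd == 6, "weekend", "weekday")
}

# Epoch ms of local midnight for a Date in a timezone.
midnight_ms <- function(date, tz = "UTC") {
  if (tz == "UTC") return(as.numeric(date) * MS_PER_DAY)
  as.numeric(as.POSIXct(paste(format(date), "00:00:00"), tz = tz)) * 1000
}

# weighted mean that returns NA (not NaN) on empty input
wmean <- function(x, w) {
  if (length(x) == 0 || sum(w) == 0) return(NA_real_)
  sum(x * w) / sum(w)
}
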
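#' Parse FAERS date strings
#'
#' FAERS dates (`FDA_DT`, `EVENT_DT`, `START_DT`, ...) are digit strings of
#' length 8 (`YYYYMMDD`), 6 (`YYYYMM`) or 4 (`YYYY`); shorter, longer, or
#' calendar-invalid values occur in the raw files. This parser is total: it
#' never errors, and classifies every input by length and calendar validity.
#'
#' @param x character vector of raw date fields (may contain `NA` or `""`).
#'
#' @return A data.frame with one row per input and columns
#'   \describe{
#'     \item{raw}{the input string}
#'     \item{precision}{one of `"day"`, `"month"`, `"year"`, `"missing"`}
#'     \item{date}{a `Date`, non-`NA` only when `precision == "day"`}
#'     \item{year, month, day}{integer components, `NA` where not resolved}
#'   }
#'   Eight-digit strings are validated as real calendar days (e.g. `"20210230"`
#'   is missing); six-digit strings require month 01--12; four-digit strings are
#'   year-only partials. Everything else is missing.
#'
#' @examples
#' parse_faers_date(c("20221231", "202213", "2015", "", "7"))
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  raw <- x
  x[is.na(x)] <- ""
  x <- trimws(x)
  digits <- grepl("^[0-9]+$", x)
  len <- nchar(x)

  n <- length(x)
  precision <- rep("missing", n)
  year <- month <- day <- rep(NA_integer_, n)
  date <- rep(as.Date(NA), n)

  full <- digits & len == 8L
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    # as.Date() rolls nothing over with %Y%m%d: invalid days yield NA
    ok <- !is.na(d)
    idx <- which(full)[ok]
    precision[idx] <- "day"
    date[idx] <- d[ok]
    year[idx] <- as.integer(substr(x[idx], 1, 4))
    month[idx] <- as.integer(substr(x[idx], 5, 6))
    day[idx] <- as.integer(substr(x[idx], 7, 8))
  }

  ym <- digits & len == 6L
  if (any(ym)) {
    m <- as.integer(substr(x[ym], 5, 6))
    ok <- m >= 1L & m <= 12L
    idx <- which(ym)[ok]
    precision[idx] <- "month"
    year[idx] <- as.integer(substr(x[idx], 1, 4))
    month[idx] <- m[ok]
  }

  yo <- digits & len == 4L
  if (any(yo)) {
    idx <- which(yo)
    precision[idx] <- "year"
    year[idx] <- as.integer(x[idx])
  }

  data.frame(raw = raw, precision = precision, date = date,
             year = year, month = month, day = day,
             stringsAsFactors = FALSE)
}

# Numeric sort key for deduplication: full/partial digit strings padded to 8
# digits sort chronologically enough for the latest-FDA_DT rule; missing or
# non-digit values get NA so they order before any dated row.
faers_date_key <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  ok <- grepl("^[0-9]{4}$|^[0-9]{6}$|^[0-9]{8}$", x)
  key <- rep(NA_real_, length(x))
  pad <- vapply(x[ok], function(s) {
    as.numeric(paste0(s, strrep("0", 8L - nchar(s))))
  }, numeric(1), USE.NAMES = FALSE)
  key[ok] <- pad
  key
}

# Days between two 8-digit date strings; NA unless both are full valid dates.
faers_days_between <- function(start_raw, end_raw) {
  s <- parse_faers_date(start_raw)
  e <- parse_faers_date(end_raw)
  ok <- s$precision == "day" & e$precision == "day"
  out <- rep(NA_real_, length(ok))
  out[ok] <- as.numeric(e$date[ok] - s$date[ok])
  out
}
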
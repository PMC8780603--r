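#' Partial calendar dates in the FAERS dialect
#'
#' FAERS serialises dates as bare digit strings: `"YYYYMMDD"` (day precision),
#' `"YYYYMM"` (month precision) or `"YYYY"` (year precision). Reports routinely
#' carry only partial precision, so the cleaning rules must reason about the
#' *range* of calendar days a partial date could denote. These helpers keep the
#' canonical digit-string representation and expand it on demand.
#'
#' `pd_parse()` validates raw strings and returns the canonical form (`NA` for
#' anything unparseable, including impossible days such as `"20190431"`).
#' `pd_earliest()` / `pd_latest()` return the first and last [Date] consistent
#' with the stated precision. `pd_precision()` reports `"year"`, `"month"` or
#' `"day"`. `pd_format()` renders ISO-8601 truncated to the known precision
#' (e.g. `"2019-04"`), which doubles as the precision marker.
#'
#' @param x character vector of date strings.
#' @return `pd_parse()` and `pd_format()` character vectors; `pd_earliest()`
#'   and `pd_latest()` [Date] vectors; `pd_precision()` a character vector.
#' @examples
#' pd_parse(c("20190415", "201904", "2019", "20190431", "oops"))
#' pd_earliest("201904")
#' pd_latest("2019")
#' @export
pd_parse <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | !nzchar(x)] <- NA_character_
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
  if (!any(ok)) {
    return(out)
  }
  s <- x[ok]
  yr <- as.integer(substr(s, 1L, 4L))
  mo <- ifelse(nchar(s) >= 6L, as.integer(substr(s, 5L, 6L)), NA_integer_)
  dy <- ifelse(nchar(s) == 8L, as.integer(substr(s, 7L, 8L)), NA_integer_)
  valid <- yr >= 1000L & yr <= 2999L
  valid <- valid & (is.na(mo) | (mo >= 1L & mo <= 12L))
  has_day <- !is.na(dy) & valid
  if (any(has_day)) {
    iso <- sprintf("%04d-%02d-%02d", yr[has_day], mo[has_day], dy[has_day])
    # as.Date() with an explicit format rejects impossible days (Feb 30, Apr 31)
    valid[has_day] <- !is.na(as.Date(iso, format = "%Y-%m-%d"))
  }
  s[!valid] <- NA_character_
  out[ok] <- s
  out
}

#' @rdname pd_parse
#' @export
pd_precision <- function(x) {
  c("4" = "year", "6" = "month", "8" = "day")[as.character(nchar(x))]
}

#' @rdname pd_parse
#' @export
pd_earliest <- function(x) {
  n <- nchar(x)
  iso <- ifelse(is.na(x), NA_character_,
    ifelse(n == 4L, paste0(x, "0101"),
      ifelse(n == 6L, paste0(x, "01"), x)
    )
  )
  as.Date(iso, format = "%Y%m%d")
}

#' @rdname pd_parse
#' @export
pd_latest <- function(x) {
  out <- rep(as.Date(NA), length(x))
  if (!length(x)) {
    return(out)
  }
  n <- nchar(x)
  is_day <- !is.na(x) & n == 8L
  out[is_day] <- as.Date(x[is_day], format = "%Y%m%d")
  is_mon <- !is.na(x) & n == 6L
  if (any(is_mon)) {
    y <- as.integer(substr(x[is_mon], 1L, 4L))
    m <- as.integer(substr(x[is_mon], 5L, 6L))
    ny <- ifelse(m == 12L, y + 1L, y)
    nm <- ifelse(m == 12L, 1L, m + 1L)
    out[is_mon] <- as.Date(sprintf("%04d-%02d-01", ny, nm), format = "%Y-%m-%d") - 1L
  }
  is_yr <- !is.na(x) & n == 4L
  out[is_yr] <- as.Date(paste0(x[is_yr], "-12-31"), format = "%Y-%m-%d")
  out
}

#' @rdname pd_parse
#' @export
pd_format <- function(x) {
  n <- nchar(x)
  ifelse(is.na(x), NA_character_,
    ifelse(n == 4L, x,
      ifelse(n == 6L, paste0(substr(x, 1L, 4L), "-", substr(x, 5L, 6L)),
        paste0(
          substr(x, 1L, 4L), "-", substr(x, 5L, 6L), "-", substr(x, 7L, 8L)
        )
      )
    )
  )
}

# truncate canonical partial dates to coarser precision ("month" or "year")
pd_truncate <- function(x, to) {
  width <- if (to == "month") 6L else 4L
  ifelse(is.na(x), NA_character_, substr(x, 1L, pmin(nchar(x), width)))
}
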
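# Internal helpers shared across modules.

#' Convert clock times to angles on the diel circle
#'
#' Maps time of day to radians in `[0, 2*pi)`, with midnight at 0 and the
#' full circle equal to 24 h.  Accepts `POSIXct` timestamps (the date part is
#' ignored), `"HH:MM"` strings, or numeric hours.
#'
#' @param x `POSIXct`, character `"HH:MM"`, or numeric hours in `[0, 24)`.
#' @return Numeric vector of radians in `[0, 2*pi)`.
#' @examples
#' clock_to_radians(c("00:00", "06:00", "18:30"))
#' @export
clock_to_radians <- function(x) {
  if (inherits(x, "POSIXct")) {
    lt <- as.POSIXlt(x, tz = "UTC")
    h <- lt$hour + lt$min / 60 + lt$sec / 3600
  } else if (is.character(x)) {
    h <- parse_clock(x)
    if (anyNA(h) && !anyNA(x)) stop("unparseable clock time in input")
  } else {
    h <- as.numeric(x)
  }
  (h %% 24) / 24 * 2 * pi
}

#' @rdname clock_to_radians
#' @param theta numeric radians.
#' @return `radians_to_clock`: numeric hours in `[0, 24)`.
#' @export
radians_to_clock <- function(theta) (theta %% (2 * pi)) / (2 * pi) * 24

# "HH:MM" or "HH:MM:SS" -> fractional hours; NA if malformed/out of range
parse_clock <- function(x) {
  m <- regmatches(x, regexec("^\\s*([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?\\s*$", x))
  vapply(m, function(g) {
    if (length(g) < 3 || is.na(g[1])) return(NA_real_)
    hh <- as.numeric(g[2]); mm <- as.numeric(g[3])
    ss <- if (length(g) >= 4 && nzchar(g[4])) as.numeric(g[4]) else 0
    if (hh > 23 || mm > 59 || ss > 59) return(NA_real_)
    hh + mm / 60 + ss / 3600
  }, numeric(1))
}

# naive local civil timestamp stored as POSIXct in UTC
make_timestamp <- function(date, hours) {
  as.POSIXct(as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) +
               round(hours * 3600), origin = "1970-01-01", tz = "UTC")
}

# floor to whole minutes (detection records are minute-resolution)
floor_minute <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

# Deterministically derive k child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, k, salt = 0L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((as.integer(seed) + as.integer(salt)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
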
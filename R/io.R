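# Detection-record and site-table I/O, independence filtering, night index.
#
# Conventions: timestamps are naive local civil time stored as POSIXct in the
# "UTC" slot (single-timezone studies, no DST); deployments are closed date
# intervals; a night is labelled by the calendar date of the evening it
# begins on.

#' Read a camera-site table
#'
#' Expects a delimited text file with columns `site`, `lat`, `lon`, `block`,
#' `deploy_start`, `deploy_end` (ISO-8601 dates).  A site with several
#' deployment intervals repeats its row; intervals must not overlap.
#'
#' @param path CSV file path.
#' @return data.frame with columns `site_id`, `latitude`, `longitude`,
#'   `block_id`, `deploy_start`, `deploy_end` (one row per deployment).
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stopf("site file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "lat", "lon", "block", "deploy_start", "deploy_end")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("site table is missing column(s): %s", paste(miss, collapse = ", "))
  out <- data.frame(
    site_id = as.character(raw$site),
    latitude = as.numeric(raw$lat),
    longitude = as.numeric(raw$lon),
    block_id = as.character(raw$block),
    deploy_start = as.Date(raw$deploy_start),
    deploy_end = as.Date(raw$deploy_end),
    stringsAsFactors = FALSE
  )
  validate_sites(out)
  out
}

validate_sites <- function(sites) {
  if (any(is.na(sites$deploy_start)) || any(is.na(sites$deploy_end)))
    stopf("unparseable deployment date in site table")
  if (any(sites$deploy_end < sites$deploy_start))
    stopf("deployment interval ends before it starts")
  # NA coordinates are tolerated (the Mantel stage is skipped downstream);
  # out-of-range values are not
  bad <- sites$latitude < -90 | sites$latitude > 90 |
    sites$longitude < -180 | sites$longitude > 180
  if (any(bad, na.rm = TRUE))
    stopf("invalid coordinates for site(s): %s",
          paste(unique(sites$site_id[which(bad)]), collapse = ", "))
  nb <- tapply(sites$block_id, sites$site_id, function(b) length(unique(b)))
  if (any(nb > 1))
    stopf("site(s) mapped to more than one survey block: %s",
          paste(names(nb)[nb > 1], collapse = ", "))
  # overlapping deployments within a site
  for (s in unique(sites$site_id)) {
    d <- sites[sites$site_id == s, , drop = FALSE]
    d <- d[order(d$deploy_start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$deploy_start[-1] <= d$deploy_end[-nrow(d)]))
      stopf("overlapping deployment intervals at site %s", s)
  }
  invisible(sites)
}

#' Read detection records
#'
#' Expects columns `site`, `species`, `date` (ISO-8601) and `time`
#' (`"HH:MM"`, minute resolution).  Records are cross-referenced against the
#' site table; duplicate (site, species, minute) rows collapse to one
#' record.
#'
#' @param path CSV file path.
#' @param sites site table from [read_sites()].
#' @return data.frame `site_id, species, timestamp` sorted by
#'   (site, species, timestamp), with attribute `"outside_deployment"`
#'   listing rows whose timestamp falls outside every deployment of their
#'   site.
#' @export
read_detections <- function(path, sites) {
  if (!file.exists(path)) stopf("detection file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("site", "species", "date", "time")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("detection table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    out <- data.frame(site_id = character(), species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"))
    attr(out, "outside_deployment") <- out
    return(out)
  }
  d <- as.Date(raw$date, optional = TRUE)
  if (anyNA(d))
    stopf("unparseable date at data row(s): %s",
          paste(utils::head(which(is.na(d)), 5), collapse = ", "))
  h <- parse_clock(raw$time)
  if (anyNA(h))
    stopf("unparseable clock time at data row(s): %s",
          paste(utils::head(which(is.na(h)), 5), collapse = ", "))
  rec <- data.frame(
    site_id = as.character(raw$site),
    species = as.character(raw$species),
    timestamp = floor_minute(make_timestamp(d, h)),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(rec$site_id, sites$site_id)
  if (length(unknown))
    stopf("detection(s) reference unknown site id(s): %s", paste(unknown, collapse = ", "))
  rec <- rec[order(rec$site_id, rec$species, rec$timestamp), , drop = FALSE]
  rec <- rec[!duplicated(rec[, c("site_id", "species", "timestamp")]), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "outside_deployment") <- rec[!in_deployment(rec, sites), , drop = FALSE]
  rec
}

# logical: is each record's date inside one of its site's deployments?
in_deployment <- function(records, sites) {
  d <- as.Date(records$timestamp)
  ok <- logical(nrow(records))
  for (s in unique(records$site_id)) {
    i <- records$site_id == s
    dep <- sites[sites$site_id == s, , drop = FALSE]
    if (!nrow(dep)) next
    ok[i] <- vapply(d[i], function(x)
      any(x >= dep$deploy_start & x <= dep$deploy_end), logical(1))
  }
  ok
}

#' Read a solar override table
#'
#' Optional CSV `site, date, sunrise, sunset` with `"HH:MM"` times, taking
#' precedence over the internal solar computation in
#' [compute_solar_times()].
#'
#' @param path CSV file path.
#' @return data.frame `site_id, date, sunrise, sunset`.
#' @export
read_solar_overrides <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("site", "date", "sunrise", "sunset")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("solar override table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  data.frame(site_id = raw$site, date = as.Date(raw$date),
             sunrise = raw$sunrise, sunset = raw$sunset,
             stringsAsFactors = FALSE)
}

#' Collapse non-independent consecutive detections
#'
#' Within each (site, species) stream, consecutive detections closer than
#' `window_minutes` are treated as a single sample.  Under the default
#' chained rule a record is retained iff it falls at least `window_minutes`
#' after the most recently *retained* record of that stream; the first record
#' of a stream is always retained.  The `"sliding"` alternative compares each
#' record to its immediate predecessor (retained or not) and keeps it only
#' after a quiet gap.
#'
#' @param records detection data.frame (`site_id, species, timestamp`),
#'   sorted within (site, species).
#' @param window_minutes independence window; default 30.
#' @param rule `"chained"` (default) or `"sliding"`.
#' @return filtered detection data.frame.
#' @export
filter_independent <- function(records, window_minutes = 30, rule = c("chained", "sliding")) {
  rule <- match.arg(rule)
  if (window_minutes < 0) stopf("window_minutes must be non-negative")
  if (nrow(records) == 0) return(records)
  key <- paste(records$site_id, records$species, sep = "\r")
  t <- as.numeric(records$timestamp) / 60
  keep <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), key)) {
    ts <- t[idx]
    if (is.unsorted(ts)) stopf("records not sorted within (site, species)")
    if (rule == "chained") {
      k <- logical(length(ts))
      k[1] <- TRUE
      last <- ts[1]
      if (length(ts) > 1) for (j in 2:length(ts)) {
        if (ts[j] - last >= window_minutes) { k[j] <- TRUE; last <- ts[j] }
      }
    } else {
      k <- c(TRUE, diff(ts) >= window_minutes)
    }
    keep[idx] <- k
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the per-site night index
#'
#' One night runs from `buffer_before_sunset` minutes before sunset to
#' `buffer_after_sunrise` minutes after the next morning's sunrise, labelled
#' by the evening's calendar date; the interval is closed at the start and
#' open at the end.  Only nights fully covered by an active deployment are
#' kept (a deployment over dates `[a, b]` yields nights `a .. b-1`), so
#' partial nights at deployment edges are excluded rather than truncated.
#'
#' @param sites site table (with deployments).
#' @param solar output of [compute_solar_times()] covering every deployment
#'   date plus the following day.
#' @param buffer_before_sunset,buffer_after_sunrise minutes; defaults 60.
#' @return data.frame `site_id, block_id, night_date, start, end`.
#' @export
build_night_index <- function(sites, solar, buffer_before_sunset = 60,
                              buffer_after_sunrise = 60) {
  rows <- list()
  skey <- paste(solar$site_id, solar$date)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    nights <- seq(s$deploy_start, s$deploy_end - 1, by = "day")
    if (!length(nights)) next
    i_eve <- match(paste(s$site_id, nights), skey)
    i_mor <- match(paste(s$site_id, nights + 1), skey)
    if (anyNA(i_eve) || anyNA(i_mor)) {
      bad <- nights[is.na(i_eve) | is.na(i_mor)][1]
      stopf("missing solar times for site %s around %s", s$site_id, bad)
    }
    if (anyNA(solar$sunset[i_eve]) || anyNA(solar$sunrise[i_mor]))
      stopf("no sunrise/sunset available for site %s (no coordinates and no override)",
            s$site_id)
    if (any(solar$polar[i_eve]) || any(solar$polar[i_mor]))
      stopf("polar day/night at site %s: night construction refused", s$site_id)
    rows[[length(rows) + 1]] <- data.frame(
      site_id = s$site_id, block_id = s$block_id, night_date = nights,
      start = solar$sunset[i_eve] - buffer_before_sunset * 60,
      end = solar$sunrise[i_mor] + buffer_after_sunrise * 60,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    return(data.frame(site_id = character(), block_id = character(),
                      night_date = as.Date(character()),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC")))
  out <- do.call(rbind, rows)
  stopifnot(all(out$start < out$end))
  rownames(out) <- NULL
  out
}

#' Assign detections to nights
#'
#' @param records detection data.frame.
#' @param night_index output of [build_night_index()].
#' @return integer vector: for each record, the row of `night_index` whose
#'   interval (closed start, open end) contains its timestamp, or `NA` when
#'   the record falls outside every night.
#' @export
assign_nights <- function(records, night_index) {
  out <- rep(NA_integer_, nrow(records))
  for (s in unique(records$site_id)) {
    ri <- which(records$site_id == s)
    ni <- which(night_index$site_id == s)
    if (!length(ni)) next
    ni <- ni[order(night_index$start[ni])]
    starts <- as.numeric(night_index$start[ni])
    ends <- as.numeric(night_index$end[ni])
    pos <- findInterval(as.numeric(records$timestamp[ri]), starts)
    hit <- pos >= 1 & as.numeric(records$timestamp[ri]) < ends[pmax(pos, 1)]
    out[ri[hit]] <- ni[pos[hit]]
  }
  out
}
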
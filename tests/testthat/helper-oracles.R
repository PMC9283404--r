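# Independent oracles and fixture builders shared across the test files.

# --- Independent solar reference -------------------------------------------
# Astronomical Almanac low-precision solar position (~0.01 deg), evaluated
# iteratively at the event time; entirely separate constants and series from
# the package's Julian-century implementation.
oracle_solar <- function(latitude, longitude, date, tz_offset) {
  jd0 <- as.numeric(as.Date(date)) + 2440587.5
  comp <- function(hour_utc) {
    n <- jd0 + hour_utc / 24 - 2451545.0
    L <- (280.460 + 0.9856474 * n) %% 360
    g <- (357.528 + 0.9856003 * n) %% 360 * pi / 180
    lam <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
    eps <- (23.439 - 0.0000004 * n) * pi / 180
    decl <- asin(sin(eps) * sin(lam))
    ra <- atan2(cos(eps) * sin(lam), cos(lam)) * 180 / pi
    eot <- 4 * ((L - ra + 180) %% 360 - 180)   # minutes
    phi <- latitude * pi / 180
    cos_ha <- cos(90.833 * pi / 180) / (cos(phi) * cos(decl)) -
      tan(phi) * tan(decl)
    if (abs(cos_ha) > 1) return(NULL)
    ha <- acos(cos_ha) * 180 / pi
    c(sr = 720 - 4 * (longitude + ha) - eot,
      ss = 720 - 4 * (longitude - ha) - eot)
  }
  first <- comp(12 - longitude / 15)
  if (is.null(first)) return(list(polar = TRUE, sunrise = NA, sunset = NA))
  sr <- comp(first[["sr"]] / 60)
  ss <- comp(first[["ss"]] / 60)
  if (is.null(sr) || is.null(ss)) return(list(polar = TRUE, sunrise = NA, sunset = NA))
  list(polar = FALSE, sunrise = sr[["sr"]] / 60 + tz_offset,
       sunset = ss[["ss"]] / 60 + tz_offset)
}

# --- Exact co-occurrence oracle --------------------------------------------
# Enumerates every placement of N1 and N2 presence-nights among N nights and
# tabulates the co-occurrence count distribution.
oracle_cooccurrence <- function(N, N1, N2) {
  sets1 <- if (N1 == 0) list(integer(0)) else
    asplit(utils::combn(N, N1), 2)
  sets2 <- if (N2 == 0) list(integer(0)) else
    asplit(utils::combn(N, N2), 2)
  counts <- integer(min(N1, N2) + 1)
  tot_overlap <- 0
  for (s1 in sets1) for (s2 in sets2) {
    j <- length(intersect(s1, s2))
    counts[j + 1] <- counts[j + 1] + 1L
    tot_overlap <- tot_overlap + j
  }
  n_placements <- length(sets1) * length(sets2)
  list(pmf = counts / n_placements,
       expected = tot_overlap / n_placements,
       p_lt = function(obs) sum(counts[seq_len(obs + 1)]) / n_placements,
       p_gt = function(obs) sum(counts[(obs + 1):length(counts)]) / n_placements)
}

# --- Tiny record/site builders ---------------------------------------------
make_sites <- function(n = 1, block = "B1", start = "2019-05-01", end = "2019-05-31",
                       lat = 38.55, lon = 139.85) {
  data.frame(site_id = sprintf("S%02d", seq_len(n)),
             latitude = rep_len(lat, n), longitude = rep_len(lon, n),
             block_id = rep_len(block, n),
             deploy_start = as.Date(rep_len(start, n)),
             deploy_end = as.Date(rep_len(end, n)),
             stringsAsFactors = FALSE)
}

make_records <- function(site, species, when) {
  data.frame(site_id = site, species = species,
             timestamp = as.POSIXct(when, tz = "UTC"),
             stringsAsFactors = FALSE)
}

# Two-species synthetic scenario used by the co-occurrence/MRPP simulation
# checks: 12 sites in two equal blocks over one 90-day season.
two_species_config <- function(seed, theta = 0, a = 1, w = 0,
                               psi = 0.3, lambda = 1, n_sites = c(6L, 6L),
                               start = "2019-06-01", end = "2019-08-30") {
  h <- function(x) x / 24 * 2 * pi
  av <- if (a < 1 && w > 0)
    list(suppression_factor = a, window_hours = w) else NULL
  pr <- list(species_a = "A", species_b = "B", theta = theta)
  if (!is.null(av)) pr$avoidance <- av
  synthetic_config(
    species = list(
      list(name = "A", mixture = data.frame(weight = 1, mu = h(0), kappa = 1),
           psi = psi, lambda = lambda),
      list(name = "B", mixture = data.frame(weight = 1, mu = h(1), kappa = 1),
           psi = psi, lambda = lambda)),
    pairs = list(pr),
    design = list(
      blocks = data.frame(block_id = c("X", "Y"),
                          start = as.Date(rep(start, 2)),
                          end = as.Date(rep(end, 2)),
                          n_sites = n_sites),
      bbox = c(139.8, 139.9, 38.5, 38.6), tz_offset = 9),
    seed = seed)
}

# small matrix with prescribed row totals and co-occurrence count
incidence_fixture <- function(N, N1, N2, obs) {
  stopifnot(obs <= min(N1, N2), N1 + N2 - obs <= N)
  m <- matrix(0L, 2, N, dimnames = list(c("sp1", "sp2"), NULL))
  if (N1 > 0) m[1, seq_len(N1)] <- 1L
  cols2 <- c(seq_len(obs), if (N2 > obs) N1 + seq_len(N2 - obs))
  if (length(cols2)) m[2, cols2] <- 1L
  m
}
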
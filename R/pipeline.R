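# Pipeline orchestration: one configuration in, every stage's results plus
# a cross-method summary table and a reproducibility manifest out.

#' Assemble an analysis configuration
#'
#' @param species optional character vector fixing species order (defaults
#'   to sorted species found in the records); ordered pairs are formed in
#'   this order (dominant first).
#' @param filter_window_minutes independence window for overlap and
#'   spatial-autocorrelation stages (default 30).
#' @param night_buffers minutes before sunset / after sunrise defining a
#'   night (default `c(60, 60)`).
#' @param estimator overlap estimator (`"auto"`, `"Dhat1"`, `"Dhat4"`).
#' @param n_boot bootstrap replicates for the overlap CI.
#' @param n_sim null-model simulations for the C-score.
#' @param n_perm permutations for the MRPP.
#' @param mantel_n_perm permutations for the Mantel correlogram.
#' @param cutoff_hours nocturnal cutoff of the restricted MRPP
#'   (default [NOCTURNAL_CUTOFF_HOURS]).
#' @param alpha significance threshold (default 0.05).
#' @param aggregation_p MRPP p above which a pair is called aggregated
#'   (default 0.95).
#' @param overlap_high overlap class boundary used for the summary "+"
#'   (default 0.75).
#' @param tz_offset hours ahead of UTC of the study's civil time.
#' @param seed master seed propagated deterministically to every stage.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(species = NULL, filter_window_minutes = 30,
                            night_buffers = c(60, 60), estimator = "auto",
                            n_boot = 10000, n_sim = 1000, n_perm = 1000,
                            mantel_n_perm = 10000,
                            cutoff_hours = NOCTURNAL_CUTOFF_HOURS,
                            alpha = 0.05, aggregation_p = 0.95,
                            overlap_high = 0.75, tz_offset = 9, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, aggregation_p > 0, aggregation_p < 1,
            overlap_high > 0, overlap_high < 1)
  structure(list(species = species, filter_window_minutes = filter_window_minutes,
                 night_buffers = night_buffers, estimator = estimator,
                 n_boot = n_boot, n_sim = n_sim, n_perm = n_perm,
                 mantel_n_perm = mantel_n_perm, cutoff_hours = cutoff_hours,
                 alpha = alpha, aggregation_p = aggregation_p,
                 overlap_high = overlap_high, tz_offset = tz_offset,
                 seed = as.integer(seed)), class = "analysis_config")
}

#' Run the full niche-partitioning pipeline
#'
#' Stages, in order: independence filtering; Mantel-correlogram spatial QC
#' (skipped with a warning when coordinates are missing); night index and
#' detection-nondetection matrix; activity-overlap estimation with smoothed
#' bootstrap per unordered pair; probabilistic co-occurrence and C-score
#' null-model test per unordered pair; MRPP time-to-encounter test per
#' ordered pair, unrestricted and with the nocturnal cutoff.  Fully
#' deterministic under the configuration's master seed.
#'
#' @param records detection data.frame (see [read_detections()]).
#' @param sites site table (see [read_sites()]).
#' @param config `analysis_config`.
#' @param solar_overrides optional solar override table.
#' @return list of class `pipeline_result` with elements `overlap`,
#'   `cooccurrence`, `cscore`, `mrpp` (both variants, long format),
#'   `mantel`, `night_matrix`, `summary`, `manifest`.
#' @export
run_pipeline <- function(records, sites, config = analysis_config(),
                         solar_overrides = NULL) {
  validate_sites(sites)
  species <- config$species %||% sort(unique(records$species))
  if (length(species) < 2) stopf("pipeline stage 'overlap': need at least 2 species")
  seeds <- derive_seeds(config$seed, 4 + 4 * length(species)^2)
  filtered <- filter_independent(records, config$filter_window_minutes)

  # spatial QC
  warnings <- character(0)
  mantel <- NULL
  if (anyNA(sites$latitude) || anyNA(sites$longitude)) {
    warnings <- c(warnings, "site coordinates missing: Mantel correlogram skipped")
    warnf("site coordinates missing: Mantel correlogram skipped")
  } else {
    mantel <- mantel_correlogram(filtered, sites, n_perm = config$mantel_n_perm,
                                 seed = seeds[1])
  }

  # nights and incidence matrix
  dates <- sort(unique(do.call(c, lapply(seq_len(nrow(sites)), function(i)
    seq(sites$deploy_start[i], sites$deploy_end[i] + 1, by = "day")))))
  solar <- compute_solar_times(sites, dates, config$tz_offset, solar_overrides)
  nidx <- build_night_index(sites, solar,
                            buffer_before_sunset = config$night_buffers[1],
                            buffer_after_sunrise = config$night_buffers[2])
  nmat <- build_night_matrix(records, nidx, species = species)

  unordered <- utils::combn(species, 2, simplify = FALSE)
  ordered <- do.call(rbind, lapply(unordered, function(p)
    data.frame(before = c(p[1], p[2]), after = c(p[2], p[1]),
               stringsAsFactors = FALSE)))

  si <- 2
  overlap <- do.call(rbind, lapply(unordered, function(p) {
    a <- clock_to_radians(filtered$timestamp[filtered$species == p[1]])
    b <- clock_to_radians(filtered$timestamp[filtered$species == p[2]])
    res <- overlap_analysis(a, b, species_a = p[1], species_b = p[2],
                            estimator = config$estimator, n_boot = config$n_boot,
                            seed = seeds[si])
    si <<- si + 1
    res
  }))

  cooccurrence <- do.call(rbind, lapply(unordered, function(p)
    probabilistic_cooccurrence(nmat, p)))
  cscore <- do.call(rbind, lapply(unordered, function(p) {
    res <- c_score_test(nmat, p, n_sim = config$n_sim, seed = seeds[si])
    si <<- si + 1
    res
  }))

  mrpp <- do.call(rbind, lapply(seq_len(nrow(ordered)), function(i) {
    out <- lapply(c(Inf, config$cutoff_hours), function(co) {
      fit <- mrpp_test(records, ordered$before[i], ordered$after[i], sites,
                       n_perm = config$n_perm, cutoff_hours = co,
                       seed = seeds[si])
      si <<- si + 1
      data.frame(before = ordered$before[i], after = ordered$after[i],
                 cutoff_hours = co, n_encounters = fit$n_encounters,
                 observed_median_hours = fit$observed_median_hours,
                 p = fit$p, n_perm = fit$n_perm, n_skipped = fit$n_skipped,
                 degenerate = fit$degenerate, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }))

  bundle <- list(overlap = overlap, cooccurrence = cooccurrence, cscore = cscore,
                 mrpp = mrpp, mantel = mantel, night_matrix = nmat,
                 manifest = list(
                   package = "camtrapnp",
                   version = as.character(utils::packageVersion("camtrapnp")),
                   seed = config$seed,
                   parameters = unclass(config),
                   species = species,
                   n_records = nrow(records),
                   n_records_filtered = nrow(filtered),
                   n_site_nights = ncol(nmat),
                   warnings = warnings))
  bundle$summary <- summarize_results(bundle, alpha = config$alpha,
                                      aggregation_p = config$aggregation_p)
  structure(bundle, class = "pipeline_result")
}

symbol_or_blank <- function(plus, minus = FALSE) {
  ifelse(plus, "+", ifelse(minus, "-", ""))
}

#' Cross-method summary table
#'
#' One row per ordered species pair with a `+` / `-` / blank symbol per
#' method: `+` marks results on the overlapping/aggregation side of the
#' temporal niche, `-` the partitioning/segregation side.  Rules: overlap
#' `+` iff the class is high; probabilistic co-occurrence `+` iff
#' `p_gt < alpha`, `-` iff `p_lt < alpha`; C-score `+` iff `ses < 0` and
#' `p < alpha`, `-` iff `ses > 0` and `p < alpha`; MRPP (each cutoff) `+`
#' iff `p >= aggregation_p`, `-` iff `p <= alpha`.
#'
#' @param bundle `pipeline_result` (or a list with `overlap`,
#'   `cooccurrence`, `cscore`, `mrpp` components).
#' @param alpha significance threshold (default 0.05).
#' @param aggregation_p aggregation threshold on the MRPP p (default 0.95).
#' @return data.frame `before, after, overlap, prob_cooccurrence, c_score,
#'   mrpp, mrpp_cutoff`.
#' @export
summarize_results <- function(bundle, alpha = 0.05, aggregation_p = 0.95) {
  pairs_of <- function(b, a) {
    i <- (bundle$overlap$species_a == b & bundle$overlap$species_b == a) |
      (bundle$overlap$species_a == a & bundle$overlap$species_b == b)
    which(i)[1]
  }
  mr <- bundle$mrpp
  ordered <- unique(mr[, c("before", "after")])
  out <- lapply(seq_len(nrow(ordered)), function(i) {
    b <- ordered$before[i]; a <- ordered$after[i]
    io <- pairs_of(b, a)
    ov <- bundle$overlap[io, ]
    co <- bundle$cooccurrence[io, ]
    cs <- bundle$cscore[io, ]
    m_inf <- mr[mr$before == b & mr$after == a & is.infinite(mr$cutoff_hours), ]
    m_cut <- mr[mr$before == b & mr$after == a & !is.infinite(mr$cutoff_hours), ]
    data.frame(
      before = b, after = a,
      overlap = symbol_or_blank(ov$class == "high"),
      prob_cooccurrence = symbol_or_blank(co$p_gt < alpha, co$p_lt < alpha),
      c_score = symbol_or_blank(cs$ses < 0 & cs$p < alpha,
                                cs$ses > 0 & cs$p < alpha),
      mrpp = symbol_or_blank(m_inf$p >= aggregation_p, m_inf$p <= alpha),
      mrpp_cutoff = symbol_or_blank(m_cut$p >= aggregation_p, m_cut$p <= alpha),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write pipeline results to CSV files plus a JSON manifest
#'
#' Output is deterministic: the same configuration and seed produce
#' byte-identical files.
#'
#' @param bundle `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  put(bundle$overlap, "overlap.csv")
  put(bundle$cooccurrence, "cooccurrence_probabilistic.csv")
  put(bundle$cscore, "cooccurrence_cscore.csv")
  put(bundle$mrpp, "tte_mrpp.csv")
  if (!is.null(bundle$mantel) && !bundle$mantel$degenerate)
    put(bundle$mantel$classes, "mantel_correlogram.csv")
  put(bundle$summary, "summary.csv")
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mpath))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("camtrapnp pipeline result\n")
  cat(sprintf("  species: %s\n", paste(x$manifest$species, collapse = ", ")))
  cat(sprintf("  records: %d (%d after filtering), site-nights: %d\n",
              x$manifest$n_records, x$manifest$n_records_filtered,
              x$manifest$n_site_nights))
  cat("\nSummary table (+ overlap/aggregation side, - partitioning side):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
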
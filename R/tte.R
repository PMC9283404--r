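# Time-to-encounter analysis: ordered-pair minimum waiting times and the
# MRPP-style site-permutation test, with an optional nocturnal cutoff.
#
# p-value orientation: p is the proportion of permuted medians strictly
# greater than the observed median.  A small p means observed encounters
# take *longer* than expected under random site assignment (spatio-temporal
# segregation / avoidance); a large p means they happen *sooner* than
# expected (aggregation).

#' Default nocturnal cutoff for the restricted analysis (hours)
#'
#' The longest night of a temperate May-October survey (about 13 h) plus
#' the two 1-h buffers around sunset and sunrise.  Override via the
#' `cutoff_hours` arguments.
#' @export
NOCTURNAL_CUTOFF_HOURS <- 15

# per-site sorted detection times (numeric hours since epoch), keyed by the
# order sites appear in `sites` (keeps results invariant to site relabeling)
site_histories <- function(records, species, site_order) {
  t <- as.numeric(records$timestamp) / 3600
  keep <- records$species == species
  lapply(site_order, function(s) sort(t[keep & records$site_id == s]))
}

encounter_deltas <- function(before_hist, after_hist, cutoff_hours = NULL) {
  out <- vector("list", length(before_hist))
  for (i in seq_along(before_hist)) {
    bt <- before_hist[[i]]; at <- after_hist[[i]]
    if (!length(bt) || !length(at)) next
    pos <- findInterval(bt, at) + 1L        # first after-time strictly later
    ok <- pos <= length(at)
    d <- at[pos[ok]] - bt[ok]
    d <- d[d > 0]                           # same-minute joint triggers excluded
    if (!is.null(cutoff_hours)) d <- d[d <= cutoff_hours]
    out[[i]] <- d
  }
  out
}

#' Times-to-encounter for an ordered species pair
#'
#' For every detection of `before` at a site, the minimum time to the next
#' detection of `after` at the same site (strictly later; simultaneous
#' minutes are excluded as joint triggers).  Records with no subsequent
#' partner contribute nothing.  All detections are used (no independence
#' filtering) -- with a 1-min camera trigger delay every record is one pass.
#'
#' @param records detection data.frame (unfiltered).
#' @param before,after species identifiers (must differ).
#' @param sites site table mapping `site_id` to `block_id`.
#' @param cutoff_hours optional upper limit; deltas above it are dropped
#'   (see [NOCTURNAL_CUTOFF_HOURS]).
#' @return data.frame `site_id, block_id, anchor, delta_hours` of class
#'   `encounter_set` with attributes `before`, `after`, `cutoff_hours`.
#' @export
encounter_times <- function(records, before, after, sites, cutoff_hours = NULL) {
  if (identical(before, after)) stopf("before and after species must differ")
  if (!is.null(cutoff_hours) && !is.infinite(cutoff_hours) && cutoff_hours <= 0)
    stopf("cutoff_hours must be positive")
  if (!is.null(cutoff_hours) && is.infinite(cutoff_hours)) cutoff_hours <- NULL
  site_order <- unique(sites$site_id)
  blocks <- sites$block_id[match(site_order, sites$site_id)]
  bh <- site_histories(records, before, site_order)
  ah <- site_histories(records, after, site_order)
  rows <- list()
  for (i in seq_along(site_order)) {
    bt <- bh[[i]]; at <- ah[[i]]
    if (!length(bt) || !length(at)) next
    pos <- findInterval(bt, at) + 1L
    ok <- pos <= length(at)
    d <- at[pos[ok]] - bt[ok]
    keep <- d > 0
    if (!is.null(cutoff_hours)) keep <- keep & d <= cutoff_hours
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      site_id = site_order[i], block_id = blocks[i],
      anchor = as.POSIXct(bt[ok][keep] * 3600, origin = "1970-01-01", tz = "UTC"),
      delta_hours = d[keep], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), block_id = character(),
               anchor = as.POSIXct(character(), tz = "UTC"),
               delta_hours = numeric())
  rownames(out) <- NULL
  structure(out, before = before, after = after, cutoff_hours = cutoff_hours,
            class = c("encounter_set", "data.frame"))
}

#' Permute after-species site histories within survey blocks
#'
#' Applies, within each survey block, a uniform random permutation of site
#' labels to the whole per-site detection histories of the after species:
#' within-site temporal structure is preserved and records never cross
#' blocks.  This is the exchangeability move of the MRPP null model.  The
#' `"record"` mode instead reassigns each record independently to a uniform
#' random site of its block; it destroys within-site temporal clustering
#' and is provided only for comparison.
#'
#' @param records_after detection data.frame of the after species.
#' @param sites site table.
#' @param mode `"history"` (default) or `"record"`.
#' @return data.frame like `records_after` with permuted `site_id`.
#' @export
permute_site_histories <- function(records_after, sites,
                                   mode = c("history", "record")) {
  mode <- match.arg(mode)
  site_order <- unique(sites$site_id)
  blocks <- sites$block_id[match(site_order, sites$site_id)]
  out <- records_after
  if (mode == "history") {
    map <- site_order
    for (b in unique(blocks)) {
      i <- which(blocks == b)
      map[i] <- site_order[i][sample.int(length(i))]
    }
    out$site_id <- map[match(records_after$site_id, site_order)]
  } else {
    rec_block <- blocks[match(records_after$site_id, site_order)]
    for (b in unique(blocks)) {
      i <- which(rec_block == b)
      pool <- site_order[blocks == b]
      if (length(i)) out$site_id[i] <- pool[sample.int(length(pool), length(i),
                                                       replace = TRUE)]
    }
  }
  out
}

#' MRPP time-to-encounter permutation test for an ordered species pair
#'
#' Compares the observed median time-to-encounter with the medians obtained
#' after randomly permuting the after-species site histories within survey
#' blocks (`n_perm` times, same cutoff re-applied).  `p` is the proportion
#' of permuted medians strictly greater than the observed median: small p =
#' spatio-temporal segregation, large p = aggregation.  Replicates whose
#' permutation yields no encounters are skipped and counted in `n_skipped`;
#' the result is flagged degenerate when no block allows a non-trivial
#' permutation (every block has a single site).
#'
#' @inheritParams encounter_times
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @param mode permutation move, `"history"` (default; whole per-site
#'   histories exchanged within blocks) or `"record"` (independent
#'   per-record reassignment; see [permute_site_histories()]).
#' @return object of class `mrpp_result`: list with `before`, `after`,
#'   `observed_median_hours`, `permuted_medians`, `p`, `n_encounters`,
#'   `n_perm`, `n_skipped`, `cutoff_hours`, `degenerate`.
#' @export
mrpp_test <- function(records, before, after, sites, n_perm = 1000,
                      cutoff_hours = NULL, seed = NULL,
                      mode = c("history", "record")) {
  mode <- match.arg(mode)
  if (n_perm < 1) stopf("n_perm must be at least 1")
  if (!is.null(cutoff_hours) && is.infinite(cutoff_hours)) cutoff_hours <- NULL
  if (!is.null(seed)) set.seed(seed)
  site_order <- unique(sites$site_id)
  blocks <- sites$block_id[match(site_order, sites$site_id)]
  bh <- site_histories(records, before, site_order)
  ah <- site_histories(records, after, site_order)
  obs <- unlist(encounter_deltas(bh, ah, cutoff_hours))
  degenerate <- all(tabulate(factor(blocks)) <= 1)
  if (!length(obs)) {
    return(structure(list(before = before, after = after,
                          observed_median_hours = NA_real_,
                          permuted_medians = numeric(0), p = NA_real_,
                          n_encounters = 0L, n_perm = n_perm, n_skipped = n_perm,
                          cutoff_hours = cutoff_hours %||% Inf, degenerate = TRUE),
                     class = "mrpp_result"))
  }
  obs_med <- stats::median(obs)
  block_idx <- split(seq_along(site_order), blocks)
  perm_med <- rep(NA_real_, n_perm)
  for (k in seq_len(n_perm)) {
    if (mode == "history") {
      idx <- seq_along(site_order)
      for (g in block_idx) idx[g] <- g[sample.int(length(g))]
      ah_perm <- ah[idx]
    } else {
      ah_perm <- vector("list", length(site_order))
      for (g in block_idx) {
        tt <- unlist(ah[g])
        dest <- sample.int(length(g), length(tt), replace = TRUE)
        for (j in seq_along(g)) ah_perm[[g[j]]] <- sort(tt[dest == j])
      }
    }
    d <- unlist(encounter_deltas(bh, ah_perm, cutoff_hours))
    if (length(d)) perm_med[k] <- stats::median(d)
  }
  valid <- !is.na(perm_med)
  n_valid <- sum(valid)
  p <- if (n_valid) sum(perm_med[valid] > obs_med) / n_valid else NA_real_
  structure(list(before = before, after = after,
                 observed_median_hours = obs_med,
                 permuted_medians = perm_med[valid], p = p,
                 n_encounters = length(obs), n_perm = n_perm,
                 n_skipped = n_perm - n_valid,
                 cutoff_hours = cutoff_hours %||% Inf,
                 degenerate = degenerate), class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat(sprintf("MRPP time-to-encounter: %s -> %s\n", x$before, x$after))
  cat(sprintf("  observed median = %.2f h (n = %d, cutoff = %s h)\n",
              x$observed_median_hours, x$n_encounters,
              format(x$cutoff_hours)))
  cat(sprintf("  p = %.3f (%d permutations, %d skipped)%s\n", x$p,
              x$n_perm, x$n_skipped,
              if (x$degenerate) " [degenerate: no exchangeable sites]" else ""))
  invisible(x)
}
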
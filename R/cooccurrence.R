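# Nightly temporal co-occurrence: detection-nondetection night matrix,
# probabilistic (hypergeometric) co-occurrence, and the checkerboard C-score
# against a row-shuffle null model.

#' Build the species x site-night detection matrix
#'
#' Cell is 1 iff the species had at least one detection during that night
#' interval; detections outside every night are ignored here.
#'
#' @param records detection data.frame.
#' @param night_index output of [build_night_index()].
#' @param species optional character vector fixing row order (defaults to
#'   the sorted species present in `records`).
#' @return integer 0/1 matrix of class `night_matrix`; rows are species,
#'   columns site-nights named `"<site>|<night_date>"`, with attributes
#'   `site_id`, `block_id` and `night_date` describing the columns.
#' @export
build_night_matrix <- function(records, night_index, species = NULL) {
  if (nrow(night_index) == 0) stopf("empty night index")
  species <- species %||% sort(unique(records$species))
  m <- matrix(0L, nrow = length(species), ncol = nrow(night_index),
              dimnames = list(species, paste(night_index$site_id,
                                             night_index$night_date, sep = "|")))
  rec <- records[records$species %in% species, , drop = FALSE]
  nid <- assign_nights(rec, night_index)
  ok <- !is.na(nid)
  if (any(ok)) m[cbind(match(rec$species[ok], species), nid[ok])] <- 1L
  structure(m, site_id = night_index$site_id, block_id = night_index$block_id,
            night_date = night_index$night_date, class = c("night_matrix", "matrix"))
}

#' Probabilistic nightly co-occurrence of a species pair
#'
#' Under random, independent placement of each species' detection nights the
#' number of co-occurrence nights `j` is hypergeometric,
#' `P(j) = C(N1, j) C(N - N1, N2 - j) / C(N, N2)` with `N` site-nights and
#' row totals `N1`, `N2`.  The expected count is `N1 N2 / N` and the
#' reported tail probabilities are inclusive of the observed count, so
#' `p_lt + p_gt = 1 + P(obs)`.  A site-stratified expectation
#' (`sum_s n1s n2s / Ns`) is reported alongside; it has no exact tail law
#' and is given for comparison with per-site descriptions of the method.
#'
#' @param matrix `night_matrix` (or 0/1 matrix with species rownames and a
#'   `site_id` attribute for the stratified expectation).
#' @param pair character vector of two species (row names).
#' @return one-row data.frame `species_a, species_b, n_nights, n1, n2,
#'   observed, expected, expected_stratified, p_lt, p_gt`.
#' @export
probabilistic_cooccurrence <- function(matrix, pair) {
  stopifnot(length(pair) == 2)
  if (!all(pair %in% rownames(matrix)))
    stopf("species not in matrix: %s", paste(setdiff(pair, rownames(matrix)), collapse = ", "))
  r1 <- matrix[pair[1], ]; r2 <- matrix[pair[2], ]
  N <- length(r1); N1 <- sum(r1); N2 <- sum(r2)
  if (N1 > N || N2 > N) stopf("row total exceeds number of site-nights")
  if (N < 1) stopf("matrix has no site-nights")
  obs <- sum(r1 == 1 & r2 == 1)
  expected <- N1 * N2 / N
  p_lt <- stats::phyper(obs, N1, N - N1, N2)
  p_gt <- stats::phyper(obs - 1, N1, N - N1, N2, lower.tail = FALSE)
  site <- attr(matrix, "site_id")
  expected_strat <- if (!is.null(site)) {
    sum(tapply(seq_len(N), site, function(i) sum(r1[i]) * sum(r2[i]) / length(i)))
  } else NA_real_
  data.frame(species_a = pair[1], species_b = pair[2], n_nights = N,
             n1 = N1, n2 = N2, observed = obs, expected = expected,
             expected_stratified = expected_strat, p_lt = p_lt, p_gt = p_gt,
             stringsAsFactors = FALSE)
}

#' Checkerboard units / C-score of a species pair
#'
#' Checkerboard units are `CU = (r1 - S)(r2 - S)` with row totals `r1`,
#' `r2` and `S` shared site-nights.  Normalisations: `"raw"` (CU),
#' `"product"` (`CU / (r1 r2)`, the default) and `"pairs"`
#' (`CU / choose(N, 2)`).
#'
#' @inheritParams probabilistic_cooccurrence
#' @param normalization `"product"`, `"raw"` or `"pairs"`.
#' @return numeric C-score with attribute `normalization`.
#' @export
c_score <- function(matrix, pair, normalization = c("product", "raw", "pairs")) {
  normalization <- match.arg(normalization)
  r1 <- matrix[pair[1], ]; r2 <- matrix[pair[2], ]
  n1 <- sum(r1); n2 <- sum(r2); S <- sum(r1 == 1 & r2 == 1)
  cu <- (n1 - S) * (n2 - S)
  val <- switch(normalization,
    raw = cu,
    product = if (n1 == 0 || n2 == 0) { warnf("empty row: C-score defined as 0"); 0 }
              else cu / (n1 * n2),
    pairs = cu / choose(length(r1), 2)
  )
  structure(val, normalization = normalization)
}

#' Row-shuffle null model for an incidence matrix
#'
#' Each simulated matrix permutes every row's cells independently and
#' uniformly across all columns, preserving row totals (species detection
#' frequencies) while leaving column totals free.  With `stratify`, cells
#' are permuted only within column groups (e.g. survey blocks).
#'
#' @param matrix 0/1 incidence matrix.
#' @param n_sim number of simulated matrices.
#' @param seed optional integer seed.
#' @param stratify optional factor of length `ncol(matrix)`; permutation is
#'   restricted within its levels.
#' @return list of `n_sim` simulated matrices (attributes preserved).
#' @export
row_shuffle_null <- function(matrix, n_sim = 1000, seed = NULL, stratify = NULL) {
  if (n_sim < 1) stopf("n_sim must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(stratify)) stopifnot(length(stratify) == ncol(matrix))
  groups <- if (is.null(stratify)) list(seq_len(ncol(matrix)))
            else split(seq_len(ncol(matrix)), stratify)
  lapply(seq_len(n_sim), function(i) {
    out <- matrix
    for (g in groups)
      for (r in seq_len(nrow(matrix)))
        out[r, g] <- matrix[r, g][sample.int(length(g))]
    out
  })
}

#' Standardised effect size and rank p-value against a null distribution
#'
#' `ses = (obs - mean(sim)) / sd(sim)`; a negative SES means the species
#' pair co-occurs more than expected (fewer checkerboards).  The two-sided
#' rank p is `2 * min(#[sim <= obs] + 1, #[sim >= obs] + 1) / (n_sim + 1)`,
#' capped at 1.
#'
#' @param observed_c observed C-score.
#' @param simulated_cs numeric vector of null C-scores (length >= 2).
#' @return data.frame `observed_c, sim_mean, sim_ci_low, sim_ci_high, ses,
#'   p, n_sim, degenerate`.
#' @export
ses_p_value <- function(observed_c, simulated_cs) {
  if (length(simulated_cs) < 2) stopf("need at least 2 simulated values")
  observed_c <- as.numeric(observed_c)
  simulated_cs <- as.numeric(simulated_cs)
  n <- length(simulated_cs)
  mu <- mean(simulated_cs); sdv <- stats::sd(simulated_cs)
  degenerate <- !is.finite(sdv) || sdv == 0
  ses <- if (degenerate) 0 else (observed_c - mu) / sdv
  p <- if (degenerate) 1 else
    min(1, 2 * min(sum(simulated_cs <= observed_c) + 1,
                   sum(simulated_cs >= observed_c) + 1) / (n + 1))
  ci <- stats::quantile(simulated_cs, c(0.025, 0.975), names = FALSE)
  data.frame(observed_c = as.numeric(observed_c), sim_mean = mu,
             sim_ci_low = ci[1], sim_ci_high = ci[2], ses = ses, p = p,
             n_sim = n, degenerate = degenerate)
}

#' C-score null-model test for one species pair
#'
#' Runs [row_shuffle_null()], scores every simulated matrix with
#' [c_score()], and summarises with [ses_p_value()].  SES and p are
#' invariant to the normalisation choice (a constant factor cancels).
#'
#' @inheritParams c_score
#' @inheritParams row_shuffle_null
#' @return one-row data.frame (see [ses_p_value()]) plus `species_a,
#'   species_b, normalization`.
#' @export
c_score_test <- function(matrix, pair, n_sim = 1000, seed = NULL,
                         normalization = c("product", "raw", "pairs"),
                         stratify = NULL) {
  normalization <- match.arg(normalization)
  obs <- c_score(matrix, pair, normalization)
  sims <- row_shuffle_null(matrix[pair, , drop = FALSE], n_sim = n_sim,
                           seed = seed, stratify = stratify)
  sim_cs <- vapply(sims, function(m) as.numeric(c_score(m, pair, normalization)),
                   numeric(1))
  res <- ses_p_value(obs, sim_cs)
  cbind(data.frame(species_a = pair[1], species_b = pair[2],
                   normalization = normalization, stringsAsFactors = FALSE), res)
}
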
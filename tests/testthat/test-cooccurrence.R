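# Night matrix, probabilistic co-occurrence, C-score and its null model

night_fixture <- function() {
  sites <- make_sites(1, start = "2019-05-01", end = "2019-05-11")
  dates <- seq(as.Date("2019-05-01"), as.Date("2019-05-12"), by = "day")
  build_night_index(sites, compute_solar_times(sites, dates, 9))
}

test_that("night matrix counts detection nights and spans midnight", {
  nidx <- night_fixture()  # 10 nights
  rec <- make_records("S01", c("fox", "fox", "fox", "marten"),
                      c("2019-05-01 22:00", "2019-05-03 02:00",
                        "2019-05-05 23:30", "2019-05-02 12:00"))
  nm <- build_night_matrix(rec, nidx)
  expect_equal(sum(nm["fox", ]), 3)
  # the 02:00 detection is credited to the May 2 night
  expect_equal(nm["fox", paste("S01", "2019-05-02", sep = "|")], 1L)
  # daytime-only species has an all-zero row
  expect_equal(sum(nm["marten", ]), 0)
  expect_error(build_night_matrix(rec, nidx[0, ]), "empty night index")
})

test_that("hypergeometric co-occurrence matches exhaustive enumeration", {
  # N = 4, N1 = N2 = 2, obs = 2: all C(4,2)^2 placements
  or <- oracle_cooccurrence(4, 2, 2)
  expect_equal(or$pmf[3], 1 / 6, tolerance = 1e-12)
  m <- incidence_fixture(4, 2, 2, 2)
  res <- probabilistic_cooccurrence(m, c("sp1", "sp2"))
  expect_equal(res$observed, 2)
  expect_equal(res$expected, or$expected, tolerance = 1e-12)
  expect_equal(res$p_gt, or$p_gt(2), tolerance = 1e-12)
  expect_equal(res$p_lt, or$p_lt(2), tolerance = 1e-12)
})

test_that("a species present every night forces the boundary case", {
  m <- incidence_fixture(5, 5, 3, 3)
  res <- probabilistic_cooccurrence(m, c("sp1", "sp2"))
  expect_equal(res$expected, 3)
  expect_equal(res$p_gt, 1)
  expect_equal(res$p_lt, 1)
})

test_that("inclusive tails satisfy p_lt + p_gt = 1 + P(obs)", {
  set.seed(51)
  for (i in 1:50) {
    N <- sample(2:40, 1)
    N1 <- sample(0:N, 1); N2 <- sample(0:N, 1)
    lo <- max(0, N1 + N2 - N); hi <- min(N1, N2)
    obs <- if (lo == hi) lo else sample(lo:hi, 1)
    m <- incidence_fixture(N, N1, N2, obs)
    res <- probabilistic_cooccurrence(m, c("sp1", "sp2"))
    p_obs <- stats::dhyper(obs, N1, N - N1, N2)
    expect_lt(abs(res$p_lt + res$p_gt - 1 - p_obs), 1e-12)
  }
})

test_that("stratified expectation sums per-site products", {
  m <- cbind(incidence_fixture(4, 2, 2, 2), incidence_fixture(4, 3, 1, 0))
  attr(m, "site_id") <- rep(c("S1", "S2"), each = 4)
  res <- probabilistic_cooccurrence(m, c("sp1", "sp2"))
  expect_equal(res$expected_stratified, 2 * 2 / 4 + 3 * 1 / 4)
})

test_that("checkerboard units follow the hand-computed cases", {
  perfect <- rbind(sp1 = c(1, 0, 1, 0), sp2 = c(0, 1, 0, 1))
  expect_equal(as.numeric(c_score(perfect, c("sp1", "sp2"), "raw")), 4)
  partial <- rbind(sp1 = c(1, 1, 0, 0), sp2 = c(0, 1, 1, 0))
  expect_equal(as.numeric(c_score(partial, c("sp1", "sp2"), "raw")), 1)
  expect_equal(as.numeric(c_score(partial, c("sp1", "sp2"), "product")), 1 / 4)
  expect_equal(as.numeric(c_score(partial, c("sp1", "sp2"), "pairs")), 1 / 6)
  ident <- rbind(sp1 = c(1, 1, 0), sp2 = c(1, 1, 0))
  for (norm in c("raw", "product", "pairs"))
    expect_equal(as.numeric(c_score(ident, c("sp1", "sp2"), norm)), 0)
  empty <- rbind(sp1 = c(0, 0, 0), sp2 = c(1, 0, 1))
  expect_warning(v <- c_score(empty, c("sp1", "sp2"), "product"), "empty row")
  expect_equal(as.numeric(v), 0)
})

test_that("row shuffling preserves row totals and is seed-reproducible", {
  m <- incidence_fixture(12, 5, 7, 3)
  sims <- row_shuffle_null(m, n_sim = 30, seed = 9)
  expect_true(all(vapply(sims, function(s) all(rowSums(s) == rowSums(m)), logical(1))))
  expect_identical(row_shuffle_null(m, n_sim = 30, seed = 9), sims)

  strat <- rep(c("X", "Y"), each = 6)
  sims_s <- row_shuffle_null(m, n_sim = 20, seed = 10, stratify = strat)
  within_x <- vapply(sims_s, function(s) sum(s[1, strat == "X"]), numeric(1))
  expect_true(all(within_x == sum(m[1, strat == "X"])))
})

test_that("ses_p_value handles central, extreme, and degenerate nulls", {
  r <- ses_p_value(2, c(1, 2, 3))
  expect_equal(r$ses, 0)
  n <- 999
  lo <- ses_p_value(-5, stats::rnorm(n, 10))
  expect_lt(lo$ses, 0)
  expect_equal(lo$p, 2 / (n + 1))
  deg <- ses_p_value(4, rep(4, 100))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_equal(deg$ses, 0)
  expect_error(ses_p_value(1, 2), "at least 2")
})

test_that("SES and rank p are invariant to the C-score normalization", {
  sim <- simulate_detections(two_species_config(52, theta = 1))
  nm <- build_night_matrix(sim$records, sim$night_index)
  res <- lapply(c("raw", "product", "pairs"), function(norm)
    c_score_test(nm, c("A", "B"), n_sim = 200, seed = 5, normalization = norm))
  expect_equal(res[[1]]$ses, res[[2]]$ses, tolerance = 1e-9)
  expect_equal(res[[1]]$ses, res[[3]]$ses, tolerance = 1e-9)
  expect_identical(res[[1]]$p, res[[2]]$p)
  expect_identical(res[[1]]$p, res[[3]]$p)
})
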
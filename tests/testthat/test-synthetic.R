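# Synthetic camera-trap data generator

test_that("simulate_design mirrors the default survey layout and is reproducible", {
  cfg <- default_scenario(seed = 5)
  des <- simulate_design(cfg)
  expect_equal(nrow(des$sites), 18)
  expect_equal(length(unique(des$sites$block_id)), 4)
  expect_equal(tapply(des$sites$site_id, des$sites$block_id, length)[["B1"]], 7)
  # every site carries exactly one block label
  expect_equal(max(tapply(des$sites$block_id, des$sites$site_id,
                          function(b) length(unique(b)))), 1)
  expect_identical(simulate_design(cfg), des)

  one <- two_species_config(1, n_sites = c(1L, 0L))
  expect_equal(nrow(simulate_design(one)$sites), 1)
})

test_that("config validation rejects malformed scenarios", {
  cfg <- default_scenario()
  bad <- cfg$species
  bad[[1]]$mixture$weight <- c(0.6, 0.6)
  expect_error(synthetic_config(bad, cfg$pairs, cfg$design), "sum to 1")
  expect_error(synthetic_config(cfg$species,
                                list(list(species_a = "red_fox", species_b = "ghost",
                                          theta = 0)), cfg$design),
               "unknown species")
  empty_design <- cfg$design
  empty_design$blocks <- empty_design$blocks[0, ]
  expect_error(synthetic_config(cfg$species, cfg$pairs, empty_design), "block")
})

test_that("simulation is deterministic under the seed and respects lambda = 0", {
  cfg <- two_species_config(31)
  s1 <- simulate_detections(cfg)
  s2 <- simulate_detections(cfg)
  expect_identical(s1$records, s2$records)

  cfg0 <- two_species_config(31)
  cfg0$species[[2]]$lambda <- 0
  s0 <- simulate_detections(cfg0)
  expect_false("B" %in% s0$records$species)
  expect_gt(sum(s0$records$species == "A"), 0)
})

test_that("emitted records satisfy the io contract", {
  sim <- simulate_detections(two_species_config(32))
  rec <- sim$records
  expect_false(is.unsorted(order(rec$site_id, rec$species, rec$timestamp)))
  expect_true(all(as.POSIXlt(rec$timestamp, tz = "UTC")$sec == 0))
  expect_true(all(as.numeric(rec$timestamp) %% 60 == 0))   # minute resolution
  expect_equal(sum(duplicated(rec[, c("site_id", "species", "timestamp")])), 0)
  # inside deployments
  d <- as.Date(rec$timestamp)
  dep <- sim$sites[match(rec$site_id, sim$sites$site_id), ]
  expect_true(all(d >= dep$deploy_start & d <= dep$deploy_end + 1))
  # round trip through the CSV dialect io_model reads
  dir <- withr::local_tempdir()
  write_scenario(sim, dir)
  back <- read_detections(file.path(dir, "detections.csv"),
                          read_sites(file.path(dir, "sites.csv")))
  expect_equal(nrow(back), nrow(rec))
})

test_that("detection totals scale roughly linearly in lambda", {
  tot <- vapply(c(1, 2), function(lam) {
    sim <- simulate_detections(two_species_config(33, lambda = lam))
    sum(sim$records$species == "A")
  }, numeric(1))
  expect_gt(tot[2] / tot[1], 1.7)
  expect_lt(tot[2] / tot[1], 2.3)
})

test_that("nightly dependence follows the sign of theta", {
  counts <- function(theta, seed) {
    sim <- simulate_detections(two_species_config(seed, theta = theta))
    nm <- build_night_matrix(sim$records, sim$night_index)
    N <- ncol(nm)
    obs <- sum(nm["A", ] == 1 & nm["B", ] == 1)
    exp_ind <- sum(nm["A", ]) * sum(nm["B", ]) / N
    c(obs = obs, exp = exp_ind)
  }
  # ~1080 site-nights per replicate
  ind <- counts(0, 41)
  expect_lt(abs(ind["obs"] - ind["exp"]), 3.5 * sqrt(ind["exp"]))
  att <- counts(1.5, 42)
  expect_gt(att[["obs"]], att[["exp"]])
  rep_ <- counts(-1.5, 43)
  expect_lt(rep_[["obs"]], rep_[["exp"]])
})

test_that("total suppression leaves no subordinate detection inside the window", {
  sim <- simulate_detections(two_species_config(34, a = 0, w = 24))
  rec <- sim$records
  for (s in unique(rec$site_id)) {
    ta <- sort(as.numeric(rec$timestamp[rec$species == "A" & rec$site_id == s])) / 3600
    tb <- as.numeric(rec$timestamp[rec$species == "B" & rec$site_id == s]) / 3600
    if (!length(ta) || !length(tb)) next
    gap <- vapply(tb, function(t) {
      prev <- ta[ta < t]
      if (!length(prev)) Inf else t - max(prev)
    }, numeric(1))
    expect_true(all(gap > 24))
  }
})

test_that("true_overlap matches its closed-form limits", {
  mix <- data.frame(weight = c(0.4, 0.6), mu = c(1, 4), kappa = c(2, 3))
  expect_equal(true_overlap(mix, mix), 1, tolerance = 1e-9)
  sep1 <- data.frame(weight = 1, mu = 0, kappa = 20)
  sep2 <- data.frame(weight = 1, mu = pi, kappa = 20)
  expect_lt(true_overlap(sep1, sep2), 0.01)
  unif <- data.frame(weight = 1, mu = 0, kappa = 0)
  unif2 <- data.frame(weight = 1, mu = 3, kappa = 0)
  expect_equal(true_overlap(unif, unif2), 1, tolerance = 1e-9)
})

test_that("a daytime-only mixture cannot be forced into the night window", {
  cfg <- two_species_config(35)
  cfg$species[[1]]$mixture <- data.frame(weight = 1, mu = pi, kappa = 200)  # noon spike
  expect_error(simulate_detections(cfg), "rejection sampling failed")
})
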
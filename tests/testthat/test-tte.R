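# Time-to-encounter analysis and the MRPP permutation test

tte_sites <- function(n = 2, block = "B1") make_sites(n, block = block)

test_that("encounter times follow the subsequent-only, strictly-positive rule", {
  sites <- tte_sites(1)
  rec <- rbind(
    make_records("S01", "A", c("2019-05-02 20:00", "2019-05-03 20:00")),
    make_records("S01", "B", c("2019-05-02 21:30", "2019-05-02 19:00")))
  es <- encounter_times(rec, "A", "B", sites)
  expect_equal(nrow(es), 1)          # second A record has no subsequent B
  expect_equal(es$delta_hours, 1.5)

  # a prior-only partner yields nothing
  rec2 <- rbind(make_records("S01", "A", "2019-05-02 20:00"),
                make_records("S01", "B", "2019-05-02 19:00"))
  expect_equal(nrow(encounter_times(rec2, "A", "B", sites)), 0)

  # simultaneous minutes are joint triggers, not encounters
  rec3 <- rbind(make_records("S01", "A", "2019-05-02 20:00"),
                make_records("S01", "B", c("2019-05-02 20:00", "2019-05-02 22:00")))
  expect_equal(encounter_times(rec3, "A", "B", sites)$delta_hours, 2)

  expect_error(encounter_times(rec, "A", "A", sites), "must differ")
})

test_that("the nocturnal cutoff drops long encounters; Inf reproduces no cutoff", {
  sites <- tte_sites(1)
  rec <- rbind(make_records("S01", "A", "2019-05-02 20:00"),
               make_records("S01", "B", "2019-05-03 18:00"))   # 22 h later
  expect_equal(nrow(encounter_times(rec, "A", "B", sites, cutoff_hours = 15)), 0)
  expect_equal(encounter_times(rec, "A", "B", sites)$delta_hours, 22)
  expect_identical(encounter_times(rec, "A", "B", sites, cutoff_hours = Inf),
                   encounter_times(rec, "A", "B", sites))
})

test_that("ordered pairs are genuinely asymmetric", {
  sites <- tte_sites(1)
  rec <- rbind(
    make_records("S01", "A", c("2019-05-02 20:00", "2019-05-02 21:00")),
    make_records("S01", "B", "2019-05-02 23:00"))
  ab <- encounter_times(rec, "A", "B", sites)
  ba <- encounter_times(rec, "B", "A", sites)
  expect_equal(nrow(ab), 2)
  expect_equal(nrow(ba), 0)
})

test_that("site-history permutation preserves histories and block boundaries", {
  sites <- rbind(tte_sites(2, "B1"), make_sites(1, block = "B2"))
  sites$site_id <- c("S01", "S02", "S03")
  rec <- rbind(make_records("S01", "B", c("2019-05-02 20:00", "2019-05-02 20:30")),
               make_records("S02", "B", "2019-05-02 22:00"),
               make_records("S03", "B", "2019-05-02 23:00"))
  set.seed(1)
  swapped <- 0
  for (i in 1:400) {
    p <- permute_site_histories(rec, sites)
    # multiset of timestamps unchanged
    expect_identical(sort(p$timestamp), sort(rec$timestamp))
    # single-site block B2 is fixed
    expect_identical(p$site_id[4], "S03")
    if (p$site_id[1] == "S02") swapped <- swapped + 1
  }
  expect_gt(swapped / 400, 0.4)  # two-site block: identity or swap, each ~1/2
  expect_lt(swapped / 400, 0.6)
})

test_that("single-site blocks give a degenerate test with p = 0", {
  sites <- tte_sites(1)
  rec <- rbind(make_records("S01", "A", "2019-05-02 20:00"),
               make_records("S01", "B", "2019-05-02 21:00"))
  res <- mrpp_test(rec, "A", "B", sites, n_perm = 50, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$p, 0)
  expect_true(all(res$permuted_medians == res$observed_median_hours))
  expect_error(mrpp_test(rec, "A", "B", sites, n_perm = 0), "n_perm")
})

test_that("MRPP p is invariant to site relabeling", {
  sim <- simulate_detections(two_species_config(61, n_sites = c(3L, 3L)))
  r1 <- mrpp_test(sim$records, "A", "B", sim$sites, n_perm = 99, seed = 7)
  relab <- setNames(sprintf("Z%02d", 1:6), sort(unique(sim$sites$site_id)))
  rec2 <- sim$records; rec2$site_id <- unname(relab[rec2$site_id])
  sites2 <- sim$sites; sites2$site_id <- unname(relab[sites2$site_id])
  r2 <- mrpp_test(rec2, "A", "B", sites2, n_perm = 99, seed = 7)
  expect_identical(r2$p, r1$p)
  expect_identical(r2$permuted_medians, r1$permuted_medians)
})

test_that("an empty encounter set yields a flagged degenerate result", {
  sites <- tte_sites(2)
  rec <- make_records("S01", "A", "2019-05-02 20:00")  # no B at all
  res <- mrpp_test(rec, "A", "B", sites, n_perm = 20, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$n_encounters, 0L)
  expect_true(is.na(res$observed_median_hours))
})

test_that("the record-reassignment permutation preserves the time multiset", {
  sim <- simulate_detections(two_species_config(63, n_sites = c(3L, 3L)))
  recB <- sim$records[sim$records$species == "B", ]
  set.seed(2)
  p <- permute_site_histories(recB, sim$sites, mode = "record")
  expect_identical(sort(p$timestamp), sort(recB$timestamp))
  expect_true(all(p$site_id %in% sim$sites$site_id))
  # blocks are respected
  blk <- sim$sites$block_id[match(p$site_id, sim$sites$site_id)]
  blk0 <- sim$sites$block_id[match(recB$site_id, sim$sites$site_id)]
  expect_identical(blk, blk0)
  res <- mrpp_test(sim$records, "A", "B", sim$sites, n_perm = 30, seed = 4,
                   mode = "record")
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("permuted replicates re-apply the cutoff", {
  sim <- simulate_detections(two_species_config(62))
  res <- mrpp_test(sim$records, "A", "B", sim$sites, n_perm = 50,
                   cutoff_hours = 15, seed = 3)
  expect_true(all(res$permuted_medians <= 15))
  expect_lte(res$observed_median_hours, 15)
})
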
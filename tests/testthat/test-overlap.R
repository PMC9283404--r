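# Circular KDE and the coefficient of overlap

test_that("fitted density is a proper periodic density", {
  set.seed(21)
  for (kap in c(0.5, 2, 8)) {
    x <- rvonmises(300, pi / 3, kap)
    kde <- fit_circular_kde(x)
    grid <- seq(0, 2 * pi, length.out = 4097)
    f <- predict(kde, grid)
    expect_true(all(f >= 0))
    integral <- sum((f[-1] + f[-4097]) / 2) * (2 * pi / 4096)
    expect_lt(abs(integral - 1), 1e-6)
    expect_equal(f[1], f[4097], tolerance = 1e-12)  # periodicity
  }
})

test_that("density is equivariant under circular shifts of the sample", {
  set.seed(22)
  x <- rvonmises(200, 1, 2)
  shift <- 2.3
  kde1 <- fit_circular_kde(x)
  kde2 <- fit_circular_kde((x + shift) %% (2 * pi))
  grid <- seq(0, 2 * pi, length.out = 257)
  expect_equal(predict(kde2, (grid + shift) %% (2 * pi)), predict(kde1, grid),
               tolerance = 1e-10)
})

test_that("KDE recovers a known von Mises density in sup norm", {
  set.seed(23)
  x <- rvonmises(5000, pi, 2)
  kde <- fit_circular_kde(x)
  grid <- seq(0, 2 * pi, length.out = 512)
  expect_lt(max(abs(predict(kde, grid) - dvonmises(grid, pi, 2))), 0.05)
})

test_that("degenerate and undersized samples are handled explicitly", {
  expect_error(fit_circular_kde(1.5), "at least 2")
  expect_warning(fit_circular_kde(rep(1.2, 50)), "capped")
})

test_that("Dhat4 is exactly 1 for identical samples and symmetric in its arguments", {
  set.seed(24)
  x <- rvonmises(100, 2, 1.5)
  expect_identical(estimate_overlap(x, x, "Dhat4")$delta, 1)
  y <- rvonmises(120, 5, 1)
  for (est in c("Dhat1", "Dhat4")) {
    expect_equal(estimate_overlap(x, y, est)$delta,
                 estimate_overlap(y, x, est)$delta, tolerance = 1e-12)
  }
})

test_that("auto estimator selection follows the 75-sample rule", {
  set.seed(25)
  a <- rvonmises(50, 0, 1); b <- rvonmises(200, 1, 1)
  expect_equal(estimate_overlap(a, b, "auto")$estimator, "Dhat1")
  a2 <- rvonmises(80, 0, 1); b2 <- rvonmises(80, 1, 1)
  expect_equal(estimate_overlap(a2, b2, "auto")$estimator, "Dhat4")
})

test_that("overlap is invariant under a common circular shift", {
  set.seed(26)
  a <- rvonmises(150, 1, 2); b <- rvonmises(150, 4, 1.5)
  for (est in c("Dhat1", "Dhat4")) {
    d0 <- estimate_overlap(a, b, est)$delta
    d1 <- estimate_overlap((a + 1.7) %% (2 * pi), (b + 1.7) %% (2 * pi), est)$delta
    expect_equal(d1, d0, tolerance = 1e-6)
  }
})

test_that("overlap estimates recover the true overlap of known mixtures", {
  set.seed(27)
  mixa <- data.frame(weight = c(0.5, 0.5), mu = c(5.6, 0.8), kappa = c(5, 5))
  mixb <- data.frame(weight = 1, mu = 0.13, kappa = 2.2)
  dtrue <- true_overlap(mixa, mixb)
  a <- rmixvm(500, mixa); b <- rmixvm(500, mixb)
  d4 <- estimate_overlap(a, b, "Dhat4")$delta
  d1 <- estimate_overlap(a, b, "Dhat1")$delta
  expect_lt(abs(d4 - dtrue), 0.07)
  expect_lt(abs(d4 - d1), 0.05)
})

test_that("mean estimation error shrinks as samples grow", {
  set.seed(28)
  mixa <- data.frame(weight = 1, mu = 0, kappa = 1.5)
  mixb <- data.frame(weight = 1, mu = 2.5, kappa = 1.5)
  dtrue <- true_overlap(mixa, mixb)
  mean_err <- vapply(c(50, 200, 800), function(n) {
    mean(vapply(1:15, function(i)
      abs(estimate_overlap(rmixvm(n, mixa), rmixvm(n, mixb), "Dhat4")$delta - dtrue),
      numeric(1)))
  }, numeric(1))
  expect_true(mean_err[3] < mean_err[1])
  expect_lt(mean_err[3], mean_err[2] + 0.01)  # allow small Monte-Carlo wiggle
})

test_that("smoothed bootstrap is reproducible and brackets the point estimate", {
  set.seed(29)
  a <- rvonmises(120, 0.5, 1.5); b <- rvonmises(140, 1.5, 1.5)
  ci1 <- bootstrap_overlap_ci(a, b, n_boot = 200, seed = 77)
  ci2 <- bootstrap_overlap_ci(a, b, n_boot = 200, seed = 77)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  est <- attr(ci1, "estimate")
  expect_true(ci1[1] <= est && est <= ci1[2])
  expect_true(ci1[1] >= 0 && ci1[2] <= 1)
  expect_warning(bootstrap_overlap_ci(a, b, n_boot = 50, seed = 1), "unstable")
})

test_that("overlap classification uses the documented boundaries", {
  expect_equal(classify_overlap(c(0.5, 0.75, 0.76, 0.2)),
               c("low", "moderate", "high", "low"))
  expect_error(classify_overlap(1.2), "0, 1")
})

test_that("overlap_analysis returns a complete, consistent result row", {
  set.seed(30)
  a <- rvonmises(100, 0, 1); b <- rvonmises(100, 0.8, 1)
  row <- overlap_analysis(a, b, species_a = "fox", species_b = "marten",
                          n_boot = 150, seed = 3)
  expect_equal(row$n1, 100)
  expect_equal(row$class, classify_overlap(row$delta))
  expect_true(row$ci_low <= row$ci_high)
})
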
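test_that("response classification partitions every trial exactly once", {
  expect_identical(classify_response(300), "alert")
  expect_identical(classify_response(600), "lapse")
  expect_identical(classify_response(31000), "sleep_attack")
  expect_identical(classify_response(100), "false_start")
  expect_identical(classify_response(NA, pressed_pre_stimulus = TRUE), "false_start")
  expect_identical(classify_response(150), "alert")   # band edges inclusive
  expect_identical(classify_response(500), "alert")
  expect_identical(classify_response(500.1), "lapse")
  expect_error(classify_response(-5), "pre-stimulus")
  set.seed(41)
  rt <- exp(runif(500, log(60), log(40000)))
  cls <- classify_response(rt)
  expect_true(all(cls %in% c("false_start", "alert", "lapse", "sleep_attack")))
  expect_identical(sum(table(cls)), 500L)
})

test_that("time bins are right-open 120-s intervals with a closed final edge", {
  expect_identical(assign_time_bins(0), 1)
  expect_identical(assign_time_bins(300), 3)
  expect_identical(assign_time_bins(600), 5)
  expect_identical(assign_time_bins(119.999), 1)
  expect_identical(assign_time_bins(120), 2)
  expect_error(assign_time_bins(601), "outside")
})

test_that("inverse RT is 1000/RT", {
  expect_equal(inverse_rt(c(500, 1000, 250)), c(2, 1, 4))
  expect_error(inverse_rt(0), "> 0")
})

test_that("quintile table recovers a hand-constructed monotone pattern", {
  # 10 strictly increasing RTs, two per bin: a perfect diagonal
  d <- data.frame(subject = "s1",
                  onset_s = rep(c(60, 180, 300, 420, 540), each = 2) + c(0, 30),
                  rt_ms = seq(200, 470, by = 30))
  qt <- quintile_table(d)
  expect_equal(unclass(qt), diag(5) * 2L, ignore_attr = TRUE)
  expect_equal(rowSums(qt), rep(2, 5), ignore_attr = TRUE)

  # shuffled RTs at large n give near-uniform rows
  set.seed(42)
  n <- 5000
  d2 <- data.frame(subject = "s1", onset_s = runif(n, 0, 600),
                   rt_ms = sample(seq(151, 499, length.out = n)))
  qt2 <- quintile_table(d2)
  expect_equal(rowSums(qt2), as.vector(table(assign_time_bins(d2$onset_s))),
               ignore_attr = TRUE)
  expect_true(max(abs(qt2 / rowSums(qt2) - 0.2)) < 0.05)

  expect_warning(quintile_table(data.frame(subject = "s9", onset_s = 1:3 * 100,
                                           rt_ms = c(200, 300, 400))),
                 "fewer than 5")
})

test_that("chi-square of independence matches hand computation", {
  r <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 1)
  r2 <- chi_square_independence(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r2$statistic, 20 / 3, tolerance = 1e-12)
  set.seed(43)
  m <- matrix(rpois(25, 40), 5)
  r5 <- chi_square_independence(m)
  expect_equal(r5$df, 16)
  # invariant to row/column permutation; zero iff rows proportional
  perm <- m[sample(5), sample(5)]
  expect_equal(chi_square_independence(perm)$statistic, r5$statistic)
  prop <- outer(c(1, 2, 3, 1, 2), c(5, 10, 15, 20, 25))
  expect_equal(chi_square_independence(prop)$statistic, 0, tolerance = 1e-9)
  expect_error(chi_square_independence(matrix(c(1, 1, 0, 0), 2)), "margin")
})

test_that("lagged cross-correlation and its bootstrap CI behave at the null and identity", {
  # gamma at trial k-1 identical to RT at k: perfect correlation
  g <- c(runif(50, 1, 2), 0)
  rts <- c(0, g[1:50])
  r <- lagged_crosscorr_bootstrap(g, rts, n_boot = 200)
  expect_equal(r$r, 1)

  # independent white noise: small r, CI covering zero
  set.seed(44)
  n <- 2000
  g2 <- rnorm(n, 10, 1)
  rt2 <- rnorm(n, 300, 40)
  cc <- lagged_crosscorr_bootstrap(g2, rt2, n_boot = 500)
  expect_lt(abs(cc$r), 3 / sqrt(n))
  expect_true(cc$ci[1] < 0 && cc$ci[2] > 0)

  set.seed(45)
  c1 <- lagged_crosscorr_bootstrap(g2, rt2, n_boot = 300)
  set.seed(45)
  c2 <- lagged_crosscorr_bootstrap(g2, rt2, n_boot = 300)
  expect_identical(c1$ci, c2$ci)

  expect_error(lagged_crosscorr_bootstrap(rep(1, 10), rnorm(10)), "variance")
  expect_error(lagged_crosscorr_bootstrap(1:2, 1:3), "aligned")
})

test_that("fatigued simulator output shows the rising slow-quintile pattern", {
  coh <- simulate_cohort(8, param_sampler_default("cmf", point = list(
    upsilon = 3.5, lambda = 0.9, phi = 0.055, rho = -0.45, kappa = -0.1)),
    seed = 46)
  trials <- do.call(rbind, lapply(coh, `[[`, "trials"))
  qt <- quintile_table(trials)
  q5 <- qt[, 5] / rowSums(qt)
  expect_gt(q5[5], q5[1])
  expect_gt(cor(1:5, q5, method = "spearman"), 0.5)
  cs <- chi_square_independence(qt)
  expect_gt(cs$statistic, qchisq(0.95, 16))
})
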
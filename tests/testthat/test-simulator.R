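test_that("noise-free supra-threshold model responds in two cycles plus motor time", {
  p <- model_params(3, 1, 0.05, s = 0, t_motor = 0.1, variant = "gamma2")
  st <- fatigue_state()
  for (isi in c(2, 5, 10)) {
    tr <- simulate_trial(p, st, zeta = 1, isi = isi)
    expect_equal(tr$outcome$rt_ms, 200)
    expect_identical(tr$outcome$type, "alert")
    expect_identical(tr$outcome$n_ml_trial, 0L)
  }
  ses <- simulate_session(p, zeta = rep(1, 300), seed = 21)
  expect_true(all(ses$trials$rt_ms == 200))
  expect_identical(ses$final_state$n_ml, 0L)
})

test_that("noise-free sub-threshold model starves into a sleep attack", {
  p <- model_params(1, 1, 0.05, s = 0, variant = "gamma2")
  tr <- simulate_trial(p, fatigue_state(), zeta = 1, isi = 4)
  expect_identical(tr$outcome$type, "sleep_attack")
  expect_lte(abs(tr$outcome$n_ml_trial - floor(30 / (0.05 + 0.05))), 1)
  expect_identical(tr$state$n_ml, tr$outcome$n_ml_trial)
})

test_that("single-cycle false-start frequency matches the numeric-integration oracle", {
  # wait at 2.2, respond at 1.6 (mismatch 0.6), one pre-stimulus cycle
  p <- model_params(2.2, 1, 0.05, s = 0.25, mismatch = 0.6, variant = "gamma2")
  oracle <- integrate(function(x) dlogis(x, 1.6, 0.25) * plogis(x, 2.2, 0.25),
                      lower = 2.0, upper = Inf)$value
  set.seed(22)
  n <- 1e5
  st <- fatigue_state()
  fs <- vapply(seq_len(n), function(i) {
    simulate_trial(p, st, zeta = 1, isi = 0.05)$outcome$type == "false_start"
  }, logical(1))
  expect_lt(abs(mean(fs) - oracle), 3 * sqrt(oracle * (1 - oracle) / n))
})

test_that("session trial counts obey the renewal-process bounds", {
  p <- model_params(3, 1, 0.05, s = 0, variant = "gamma2")
  counts <- vapply(1:20, function(i) {
    nrow(simulate_session(p, zeta = 1, seed = i)$trials)
  }, numeric(1))
  expect_true(all(counts >= 600 / (10 + 30) & counts <= 600 / 2))
  # deterministic RT 0.2 s, mean ISI 6 s: renewal expectation ~ 600/6.2
  expect_lt(abs(mean(counts) - 600 / 6.2), 8)
})

test_that("sessions are reproducible under a fixed seed", {
  p <- cmf_printed()
  a <- simulate_session(p, seed = 42)
  b <- simulate_session(p, seed = 42)
  expect_identical(a$trials, b$trials)
  expect_identical(a$final_state, b$final_state)
})

test_that("session bookkeeping is conserved", {
  p <- cmf_refit()
  ses <- simulate_session(p, seed = 31)
  tr <- ses$trials
  expect_true(all(diff(tr$onset_s) > 0))
  expect_identical(ses$final_state$n_ml, as.integer(sum(tr$n_ml_trial)))
  # elapsed time stays within one trial's span of the stated duration
  expect_gte(ses$final_state$t_minutes * 60, tr$onset_s[nrow(tr)])
  expect_lte(ses$final_state$t_minutes * 60, 600 + 30 + 10)
  # each trial's span accounts for its ISI plus its response time
  resp <- tr$type %in% c("alert", "lapse")
  spans <- diff(c(0, tr$onset_s - tr$isi_s, ses$final_state$t_minutes * 60))[-1]
  expect_true(all(spans >= tr$isi_s - 1e-9))
})

test_that("gamma variants apply zeta by bin or by trial", {
  z5 <- c(1, 1.4, 0.7, 1.2, 0.9)
  p1 <- model_params(4, 0.95, 0.05, variant = "gamma1")
  s1 <- simulate_session(p1, zeta = z5, seed = 23)
  bins <- assign_time_bins(s1$trials$onset_s)
  expect_equal(s1$trials$zeta, z5[bins])
  expect_error(simulate_session(p1, zeta = rep(1, 3), seed = 1), "5 values")

  p2 <- model_params(4, 0.95, 0.05, variant = "gamma2")
  zt <- seq(0.8, 1.3, length.out = 40)  # deliberately too short
  expect_warning(s2 <- simulate_session(p2, zeta = zt, seed = 24),
                 "extended")
  n <- nrow(s2$trials)
  expect_equal(s2$trials$zeta, c(zt, rep(zt[40], n - 40)))
  expect_error(simulate_session(p2, seed = 1), "requires a zeta")
  expect_error(simulate_session(cmf_printed(), zeta = z5, seed = 1), "no zeta")
})

test_that("threshold decline compensates: kappa < 0 yields no more sleep attacks", {
  # weak utility so that microlapse cascades can reach the timeout
  base <- list(upsilon = 2.4, lambda = 0.9, phi = 0.05, rho = -0.3, s = 0.45)
  sa <- function(kappa) {
    p <- model_params(base$upsilon, base$lambda, base$phi, rho = base$rho,
                      kappa = kappa, s = base$s, variant = "cmf")
    sum(vapply(1:30, function(i) {
      sum(simulate_session(p, seed = i)$trials$type == "sleep_attack")
    }, numeric(1)))
  }
  expect_lte(sa(-0.15), sa(0))
})

test_that("a late motivation rise suppresses late lapses (end-spurt)", {
  p <- model_params(3.2, 0.95, 0.05, variant = "gamma2")
  rise <- seq(0.75, 1.25, length.out = 120)
  fall <- rev(rise)
  late <- function(z) {
    mean(vapply(1:40, function(i) {
      s <- simulate_session(p, zeta = z, seed = i)
      lapse_proportion(s$trials, 480, 600)
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(late(rise), late(fall))
})

test_that("cohorts are reproducible, order-independent and labelled", {
  sampler <- param_sampler_default("cmf")
  coh <- simulate_cohort(34, sampler, seed = 9)
  expect_length(coh, 34)
  expect_identical(vapply(coh, `[[`, "", "subject"), paste0("s", 1:34))
  coh2 <- simulate_cohort(34, sampler, seed = 9)
  expect_identical(coh[[17]]$trials, coh2[[17]]$trials)
  # point-mass sampler: all subjects share parameters
  pt <- param_sampler_default("cmf", point = list(upsilon = 3.82, lambda = 0.88,
                                                  phi = 0.057, rho = -0.2,
                                                  kappa = -0.15))
  coh3 <- simulate_cohort(3, pt, seed = 9)
  expect_identical(coh3[[1]]$params, coh3[[3]]$params)
})

test_that("mean lapse rate grows with the time-on-task penalty magnitude", {
  rate <- function(rho) {
    p <- model_params(3.2, 0.95, 0.055, rho = rho, kappa = -0.05, s = 0.45,
                      variant = "cmf")
    mean(vapply(1:25, function(i) {
      lapse_proportion(simulate_session(p, seed = i)$trials)
    }, numeric(1)))
  }
  r <- vapply(c(-0.02, -0.25, -0.5), rate, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("session CSV and sidecar round-trip", {
  p <- cmf_printed()
  ses <- simulate_session(p, seed = 77)
  path <- tempfile(fileext = ".csv")
  write_session_csv(ses, path, seed = 77)
  d <- read_session_csv(path)
  expect_equal(nrow(d), nrow(ses$trials))
  expect_equal(d$rt_ms, ses$trials$rt_ms)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$seed, 77)
  expect_equal(meta$sessions$upsilon, 3.8)
})
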
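test_that("moderated utility and threshold match direct exponentiation", {
  # printed-parameter spot checks
  expect_equal(cmf_utility(3.82, 0.88, 0, 0, -0.20), 3.82)
  expect_equal(cmf_utility(1.0, 0.5, 2, 0, -0.5), 0.25)
  expect_equal(cmf_utility(1.0, 0.98, 0, 10, -0.05), exp(-0.05 * log(11)),
               tolerance = 1e-12)
  expect_equal(cmf_threshold(2.0, 0, -0.15), 2.0)
  expect_equal(cmf_threshold(2.0, 10, -0.01), 2 * exp(-0.01 * log(11)),
               tolerance = 1e-12)
  expect_equal(cmf_threshold(2.0, 10, 0), 2.0)
  expect_equal(gamma_utility(4.15, 0.93, 0, 1.0), 4.15)
  expect_equal(gamma_utility(4.15, 0.93, 3, 1.2), 4.15 * 0.93^3 * 1.2,
               tolerance = 1e-12)
  expect_equal(gamma_utility(1.0, 0.9, 0, 0.0), 0.0)

  # random-point agreement with an independent log-scale evaluation
  set.seed(1)
  for (i in 1:120) {
    ups <- runif(1, 0.5, 8); lam <- runif(1, 0.2, 1); n <- sample(0:50, 1)
    t <- runif(1, 0, 30); rho <- -runif(1, 0, 0.9); kap <- -runif(1, 0, 0.9)
    tau <- runif(1, 0.5, 4); z <- runif(1, 0, 2.5)
    expect_equal(cmf_utility(ups, lam, n, t, rho),
                 exp(log(ups) + n * log(lam) + rho * log1p(t)),
                 tolerance = 1e-12)
    expect_equal(cmf_threshold(tau, t, kap),
                 exp(log(tau) + kap * log1p(t)), tolerance = 1e-12)
    expect_equal(gamma_utility(ups, lam, n, z),
                 z * exp(log(ups) + n * log(lam)), tolerance = 1e-12)
  }
})

test_that("utility moderators reject out-of-bound parameters by name", {
  expect_error(cmf_utility(-1, 0.9, 0, 0, -0.1), "upsilon")
  expect_error(cmf_utility(1, 1.2, 0, 0, -0.1), "lambda")
  expect_error(cmf_utility(1, 0.9, -2, 0, -0.1), "n_ml")
  expect_error(cmf_utility(1, 0.9, 0, -1, -0.1), "t_minutes")
  expect_error(cmf_threshold(0, 1, -0.1), "tau")
  expect_error(gamma_utility(1, 0.9, 0, -0.2), "zeta")
})

test_that("utility is strictly decreasing in microlapses and time-on-task", {
  set.seed(2)
  for (i in 1:40) {
    ups <- runif(1, 1, 6); lam <- runif(1, 0.5, 0.99); rho <- -runif(1, 0.01, 0.5)
    u_n <- cmf_utility(ups, lam, 0:20, 5, rho)
    expect_true(all(diff(u_n) < 0))
    u_t <- cmf_utility(ups, lam, 3, seq(0, 10, by = 0.5), rho)
    expect_true(all(diff(u_t) < 0))
  }
  # gamma utility at baseline motivation equals the CMF utility at task onset
  expect_equal(gamma_utility(3.1, 0.9, 4, 1), cmf_utility(3.1, 0.9, 4, 0, -0.3))
})

test_that("utility noise is logistic with variance pi^2/3 * s^2", {
  expect_identical(sample_utility_noise(0, 100), numeric(100))
  set.seed(3)
  x <- sample_utility_noise(1, 1e6)
  target <- pi^2 / 3
  se_var <- sqrt((4.2 - 1) * target^2 / 1e6)  # logistic excess kurtosis 1.2
  expect_lt(abs(var(x) - target), 3 * se_var)
  y <- sample_utility_noise(0.5, 1e6)
  expect_lt(abs(mean(y <= 0) - 0.5), 3 * sqrt(0.25 / 1e6))
  expect_error(sample_utility_noise(-0.1, 10), "s")
})

test_that("closed-form selection probabilities follow the soft-max over J", {
  ctx <- selection_context(c(wait = 1, respond = 1), threshold = 0.5, s = 0.3)
  expect_equal(unname(selection_probabilities(ctx)$p_select), c(0.5, 0.5))

  ctx1 <- selection_context(c(a = 3), threshold = 1, s = 0.4)
  expect_equal(unname(selection_probabilities(ctx1)$p_select), 1)

  ctx2 <- selection_context(c(a = 1, b = 2), threshold = 0, s = 0.5)  # 2s = 1
  p <- selection_probabilities(ctx2)$p_select
  expect_equal(unname(p), c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))),
               tolerance = 1e-12)

  # probabilities are non-negative and sum to one over J
  set.seed(4)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    ctx <- selection_context(runif(k, 0, 4), threshold = runif(1, 0, 3),
                             s = runif(1, 0.1, 1))
    pr <- selection_probabilities(ctx)
    if (pr$p_microlapse < 1) {
      expect_true(all(pr$p_select >= 0))
      expect_equal(sum(pr$p_select), 1, tolerance = 1e-12)
    }
  }

  # empty above-threshold set: microlapse with certainty
  ctx0 <- selection_context(c(a = 0.1, b = 0.2), threshold = 5, s = 0.3)
  expect_equal(selection_probabilities(ctx0)$p_microlapse, 1)

  # deterministic tie-break at s = 0 is flagged
  ctxt <- selection_context(c(a = 2, b = 2), threshold = 1, s = 0)
  pr <- selection_probabilities(ctxt)
  expect_true(pr$tie)
  expect_equal(unname(pr$p_select), c(1, 0))
})

test_that("noisy-max conflict resolution matches its closed forms", {
  # degenerate noise
  ctx <- selection_context(c(go = 3), threshold = 2, s = 0)
  expect_identical(resolve_conflict(ctx, 5), rep("go", 5))
  ctx0 <- selection_context(c(go = 1), threshold = 2, s = 0)
  expect_identical(resolve_conflict(ctx0, 5), rep("MICROLAPSE", 5))

  # microlapse frequency vs the logistic-CDF product
  set.seed(5)
  ctx <- selection_context(c(a = 1.8, b = 2.2), threshold = 2.0, s = 0.25)
  n <- 2e5
  fired <- resolve_conflict(ctx, n)
  p_ml <- plogis((2.0 - 1.8) / 0.25) * plogis((2.0 - 2.2) / 0.25)
  emp <- mean(fired == "MICROLAPSE")
  expect_lt(abs(emp - p_ml), 3 * sqrt(p_ml * (1 - p_ml) / n))

  # symmetric utilities: conditional selection is exactly 1/2
  set.seed(6)
  ctxs <- selection_context(c(a = 2.1, b = 2.1), threshold = 2.0, s = 0.3)
  f <- resolve_conflict(ctxs, n)
  sel <- f[f != "MICROLAPSE"]
  expect_lt(abs(mean(sel == "a") - 0.5), 3 * sqrt(0.25 / length(sel)))
})

test_that("conditional noisy-max frequencies match a numeric-integration oracle", {
  # P(b fires) = int f_b(x) F_a(x) dx over x >= UT, by quadrature
  u <- c(a = 1.9, b = 2.3); ut <- 2.0; s <- 0.3
  p_b <- integrate(function(x) dlogis(x, u["b"], s) * plogis(x, u["a"], s),
                   lower = ut, upper = Inf)$value
  p_a <- integrate(function(x) dlogis(x, u["a"], s) * plogis(x, u["b"], s),
                   lower = ut, upper = Inf)$value
  set.seed(7)
  n <- 2e5
  f <- resolve_conflict(selection_context(u, ut, s), n)
  expect_lt(abs(mean(f == "b") - p_b), 3 * sqrt(p_b * (1 - p_b) / n))
  expect_lt(abs(mean(f == "a") - p_a), 3 * sqrt(p_a * (1 - p_a) / n))
  # and the Luce soft-max is only an approximation of the conditional split
  pr <- selection_probabilities(selection_context(u, ut, s))
  expect_gt(abs(pr$p_select[["b"]] - p_b / (p_a + p_b)), 0.005)
})

test_that("model_params enforces the published bounds", {
  expect_error(model_params(0, 0.9, 0.05), "upsilon")
  expect_error(model_params(3, 1.1, 0.05), "lambda")
  expect_error(model_params(3, 0.9, 0.2), "phi")
  expect_error(model_params(3, 0.9, 0.05, rho = -1.5, variant = "cmf"), "rho")
  expect_error(model_params(3, 0.9, 0.05, kappa = 0.2, variant = "cmf"), "kappa")
  expect_error(model_params(3, 0.9, 0.05, rho = -0.1, variant = "gamma2"),
               "gamma-variant")
  p <- model_params(3, 0.9, 0.05, variant = "gamma1")
  expect_identical(c(p$rho, p$kappa), c(0, 0))
  expect_error(fatigue_state(-1), "n_ml")
})
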
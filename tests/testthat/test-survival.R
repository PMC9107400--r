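test_that("empirical survival curve follows its definition", {
  s <- residence_sample(2)
  cv <- empirical_ccdf(s)
  expect_equal(cv$time, c(0, 2))
  expect_equal(cv$ccdf, c(1, 0))
  set.seed(91)
  s2 <- residence_sample(rexp(200, 1 / 3))
  cv2 <- empirical_ccdf(s2)
  expect_equal(cv2$ccdf[1], 1)
  expect_true(all(diff(cv2$ccdf) <= 0))
  expect_true(all(cv2$ccdf >= 0 & cv2$ccdf <= 1))
})

test_that("empirical curve concentrates around the true survival (DKW)", {
  rs <- simulate_residence_events(1, 3, 3, 10000, seed = 97)
  cv <- empirical_ccdf(rs)
  expect_lt(max(abs(cv$ccdf - exp(-cv$time / 3))), 0.02)
})

test_that("censored events are excluded by default, poolable on request", {
  s <- residence_sample(c(1, 2, 3, 4), censored = c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(max(empirical_ccdf(s)$time), 3)
  expect_equal(max(empirical_ccdf(s, include_censored = TRUE)$time), 4)
  km <- empirical_ccdf(s, method = "km")
  expect_equal(km$ccdf[1], 1)
  expect_true(all(diff(km$ccdf) <= 0))
})

test_that("bleach profile fitting is exact on noiseless decay", {
  counts <- 1000 * exp(-(0:99) * 1 / 10)
  bp <- fit_bleach_profile(counts, frame_interval = 1)
  expect_equal(bp$k_b, 0.1, tolerance = 1e-7)
  expect_equal(bp$r_squared, 1, tolerance = 1e-9)
  bp0 <- fit_bleach_profile(rep(500, 50), 0.05)
  expect_equal(bp0$k_b, 0)
})

test_that("bleach rate is recovered from Poisson-noised counts", {
  counts <- simulate_bleach_counts(2000, 1 / 0.05, 0.05, 800,
                                   noise = "poisson", seed = 101)
  bp <- fit_bleach_profile(counts, 0.05)
  expect_lt(abs(bp$k_b - 0.05) / 0.05, 0.10)
})

test_that("photobleaching correction obeys the competing-exponential identity", {
  tau <- 3; kb <- 1 / 6
  t <- seq(0, 15, by = 0.01)
  raw <- sptkinetics:::new_survival_curve(t, exp(-t * (1 / tau + kb)))
  corr <- correct_ccdf(raw, kb)
  expect_lt(max(abs(corr$ccdf - exp(-t / tau))), 1e-9)
  # k_b = 0 is the identity
  ident <- correct_ccdf(raw, 0)
  expect_equal(ident$ccdf, raw$ccdf)
  # round trip: correcting then un-correcting recovers the raw curve
  back <- correct_ccdf(corr, -kb)
  expect_lt(max(abs(back$ccdf - raw$ccdf)), 1e-9)
})

test_that("over-correction beyond 1 raises a warning", {
  t <- seq(0, 10, by = 0.1)
  raw <- sptkinetics:::new_survival_curve(t, exp(-t / 20))
  expect_warning(correct_ccdf(raw, 0.5), "over-estimated")
})

test_that("corrected expected residence time recovers the censored mixture mean", {
  rs <- simulate_residence_events(0.75, 3, 8, 8000, bleach_mean = 20,
                                  frame_interval = 0.25, seed = 103)
  cv <- empirical_ccdf(rs, include_censored = TRUE)
  corr <- correct_ccdf(cv, 1 / 20)
  est <- expected_residence_time(corr)
  expect_lt(abs(est - 4.25) / 4.25, 0.10)
})

test_that("survival-curve integration matches closed forms", {
  t <- seq(0, 20, by = 0.002)
  cv <- sptkinetics:::new_survival_curve(t, exp(-t / 2))
  expect_lt(abs(expected_residence_time(cv) - 2) / 2, 0.01)
  step <- sptkinetics:::new_survival_curve(c(0, 1, 2), c(1, 0.5, 0))
  expect_equal(as.numeric(expected_residence_time(step, tail = FALSE)), 1.0)
  two <- sptkinetics:::new_survival_curve(
    seq(0, 80, by = 0.01),
    0.75 * exp(-seq(0, 80, by = 0.01) / 3) + 0.25 * exp(-seq(0, 80, by = 0.01) / 8))
  expect_lt(abs(expected_residence_time(two) - 4.25) / 4.25, 0.01)
})

test_that("a heavily truncated curve warns about the integral", {
  t <- seq(0, 1, by = 0.1)
  cv <- sptkinetics:::new_survival_curve(t, exp(-t / 10))
  expect_warning(expected_residence_time(cv), "truncated")
})

test_that("double-exponential parameters are recovered from clean samples", {
  rs <- simulate_residence_events(0.75, 3, 8, 5000, frame_interval = 0.25,
                                  seed = 1)
  fit <- fit_multi_exponential(empirical_ccdf(rs), n_components = 2)
  expect_lt(abs(fit$alpha[1] - 0.75), 0.1)
  expect_lt(abs(fit$tau[1] - 3) / 3, 0.15)
  expect_lt(abs(fit$tau[2] - 8) / 8, 0.20)
  expect_equal(sum(fit$alpha), 1, tolerance = 1e-9)
  # internal consistency: sum(alpha * tau) agrees with direct integration
  direct <- expected_residence_time(empirical_ccdf(rs))
  expect_lt(abs(fit$expected_residence - direct) / direct, 0.05)
})

test_that("BIC selects one component for single-exponential truth", {
  hits <- vapply(1:20, function(s) {
    rs <- simulate_residence_events(1, 3, 3, 2000, frame_interval = 0.25,
                                    seed = 200 + s)
    f <- fit_multi_exponential(empirical_ccdf(rs), n_components = 1:2)
    if (f$n_components == 1) return(TRUE)
    # a 2-component winner must collapse: alpha -> 1 or tau1 ~ tau2
    f$identifiability_flag || max(f$alpha) > 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the BIC-best model has the minimal BIC among fitted counts", {
  rs <- simulate_residence_events(0.75, 3, 8, 3000, frame_interval = 0.25,
                                  seed = 107)
  f <- fit_multi_exponential(empirical_ccdf(rs), n_components = 1:3)
  bics <- vapply(f$all_fits, `[[`, numeric(1), "bic")
  expect_equal(f$bic, min(bics))
})

test_that("fitted observed rate equals true rate plus bleach rate", {
  tau <- 4; kb <- 0.1
  t <- seq(0, 40, by = 0.05)
  raw <- sptkinetics:::new_survival_curve(t, exp(-t * (1 / tau + kb)))
  f <- fit_multi_exponential(raw, n_components = 1)
  expect_lt(abs(1 / f$tau[1] - (1 / tau + kb)) / (1 / tau + kb), 0.02)
})

test_that("nearly equal time constants are flagged", {
  t <- seq(0, 30, by = 0.05)
  raw <- sptkinetics:::new_survival_curve(t, exp(-t / 3))
  f2 <- fit_multi_exponential(raw, n_components = 2)
  expect_true(f2$identifiability_flag || max(f2$alpha) > 0.95)
})

test_that("residence bootstrap is deterministic under a fixed seed", {
  rs <- simulate_residence_events(0.75, 3, 8, 400, seed = 109)
  b1 <- bootstrap_residence(rs, n_resamples = 20, seed = 3)
  b2 <- bootstrap_residence(rs, n_resamples = 20, seed = 3)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci$lower[1] <= b1$ci$point[1] &&
                b1$ci$point[1] <= b1$ci$upper[1])
})

test_that("bootstrap intervals cover the true expected residence time", {
  covered <- vapply(1:100, function(s) {
    rs <- simulate_residence_events(1, 3, 3, 500, seed = 300 + s)
    b <- bootstrap_residence(rs, n_resamples = 200, seed = s)
    ci <- b$ci[b$ci$parameter == "expected_residence", ]
    ci$lower <= 3 && 3 <= ci$upper
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("bootstrap interval width shrinks with sample size", {
  width <- vapply(c(500, 5000), function(n) {
    rs <- simulate_residence_events(0.75, 3, 8, n, seed = 113)
    b <- bootstrap_residence(rs, n_resamples = 100, seed = 9)
    ci <- b$ci[b$ci$parameter == "expected_residence", ]
    ci$upper - ci$lower
  }, numeric(1))
  expect_lt(width[2], width[1])
})
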
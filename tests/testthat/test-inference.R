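test_that("feature reversal is an involution and shifts are reproducible", {
  fs <- 1000
  set.seed(8)
  feats <- stimulus_features(rnorm(500), rnorm(500), NULL, fs)
  twice <- reverse_features(reverse_features(feats))
  expect_identical(twice$fundamental, feats$fundamental)
  expect_identical(twice$envelope, feats$envelope)

  shifted <- reverse_features(feats, shift = 100)
  expect_equal(shifted$fundamental[1], rev(feats$fundamental)[101])
})

test_that("noise models stay below the genuine envelope where it peaks", {
  st <- synth_study_60s()
  axis <- lag_axis()
  truth <- ground_truth(axis, noise_sd = 0, seed = 5)
  rec <- gen_neural_response(st$features, truth)
  X <- build_design(st$features, axis)
  env <- trf_envelope(trf_magnitude(fit_ridge(X, rec, 1)), fs = 1000)

  nt <- noise_trf(st$features, rec, axis, lambda = 1, n_reversals = 10,
                  seed = 6)
  expect_equal(dim(nt$f), c(10L, 141L))
  # determinism
  nt2 <- noise_trf(st$features, rec, axis, lambda = 1, n_reversals = 10,
                   seed = 6)
  expect_identical(nt$f, nt2$f)

  peak <- which.max(env[, "f"])
  expect_lt(max(nt$f[, peak]), 0.3 * env[peak, "f"])

  # the bootstrap flags the genuine peak as significant at study settings
  sig <- bootstrap_significance(env[, "f"], nt$f, n_permutations = 10000,
                                seed = 7)
  expect_true(sig$significant[peak])
  expect_equal(sig$p[peak], 1 / 10001)
})

test_that("bootstrap p-values follow the empirical-p construction", {
  set.seed(10)
  noise <- matrix(rnorm(10 * 141), nrow = 10)

  obs_hi <- rep(max(noise) + 1, 141)
  hi <- bootstrap_significance(obs_hi, noise, n_permutations = 500, seed = 1)
  expect_true(all(hi$p == 1 / 501))

  # observed at the null median: p near 0.5
  noise_ranks <- matrix(rep(1:101, times = 3), nrow = 101)
  med <- bootstrap_significance(rep(51, 3), noise_ranks,
                                n_permutations = 4000, seed = 2)
  expect_true(all(abs(med$p - 0.5) < 0.05))

  # p in (0, 1]; Bonferroni never decreases a p-value
  some <- bootstrap_significance(rnorm(141), noise, n_permutations = 200,
                                 seed = 3)
  expect_true(all(some$p > 0 & some$p <= 1))
  expect_true(all(some$p_corrected >= some$p))
  expect_true(all(some$significant == (some$p_corrected < 0.05)))

  expect_error(bootstrap_significance(rnorm(141), noise[, 1:10]), "lag axis")
  expect_error(bootstrap_significance(rnorm(141), noise[0, , drop = FALSE]),
               "empty")
})

test_that("peak extraction respects the mask and breaks ties early", {
  lags <- seq(-20, 120)
  env <- exp(-(lags - 35)^2 / 50)
  pk <- find_peak(env, lags)
  expect_equal(pk$latency_ms, 35)
  expect_equal(pk$magnitude, 1)
  expect_true(pk$is_significant)

  none <- structure(list(significant = rep(FALSE, length(lags))),
                    class = "significance_profile")
  pk_none <- find_peak(env, lags, none)
  expect_false(pk_none$is_significant)
  expect_true(is.na(pk_none$latency_ms))

  twin <- numeric(length(lags))
  twin[lags == 30] <- 1
  twin[lags == 40] <- 1
  expect_equal(find_peak(twin, lags)$latency_ms, 30)
})

test_that("IQR screening matches hand-computed fences", {
  clean <- iqr_exclude(c(10, 11, 12, 13, 14))
  expect_equal(clean$excluded, numeric(0))

  # hand computation: Q1 = 11, Q3 = 13, IQR = 2, fences [8, 16]
  out <- iqr_exclude(c(10, 11, 12, 13, 100))
  expect_equal(out$fences, c(8, 16))
  expect_equal(out$excluded, 100)
  expect_equal(out$kept, c(10, 11, 12, 13))

  expect_warning(small <- iqr_exclude(c(1, 2, 3)), "fewer than 4")
  expect_equal(small$kept, c(1, 2, 3))

  same <- iqr_exclude(rep(7, 6))
  expect_equal(same$excluded, numeric(0))
})

test_that("attention scores implement the normalized difference", {
  expect_equal(attention_score(3, 1)$Q, 0.5)
  expect_equal(attention_score(2, 2)$Q, 0)
  expect_equal(attention_score(5, 0)$Q, 1)
  expect_equal(attention_score(1, 3)$Q, -attention_score(3, 1)$Q)
  expect_true(is.na(attention_score(0, 0)$Q))
  expect_error(attention_score(-1, 2), "nonnegative")
})

test_that("the normality gate routes to the right location test", {
  set.seed(33)
  x <- rnorm(30)
  y <- rnorm(30, 0.3)
  res <- compare_conditions(x, y)
  expect_equal(res$test, "t")
  expect_true(all(res$shapiro_p > 0.05))

  skew <- rexp(30)^2
  res2 <- compare_conditions(x, skew)
  expect_equal(res2$test, "mann-whitney")
  expect_lt(res2$shapiro_p["y"], 0.05)

  res3 <- compare_conditions(x, x)
  expect_gt(res3$p, 0.99)

  expect_error(compare_conditions(x[1:2], y), "n >= 3")
})

test_that("Brown-Forsythe agrees with the reference implementation", {
  set.seed(44)
  x <- rnorm(40, sd = 1)
  y <- rnorm(40, sd = 5)
  got <- compare_variances(x, y)
  ref <- car::leveneTest(c(x, y), factor(rep(1:2, each = 40)),
                         center = median)
  expect_equal(got$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(got$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  expect_lt(got$p, 0.01)

  self <- compare_variances(x, x)
  expect_equal(self$statistic, 0, tolerance = 1e-12)

  # type-I calibration: rejection rate near the nominal level
  set.seed(55)
  rej <- mean(replicate(400, compare_variances(rnorm(25), rnorm(25))$p < 0.05))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.1)

  # power against a 1 vs 25 variance ratio at n = 50
  set.seed(66)
  hits <- mean(replicate(40,
    compare_variances(rnorm(50, sd = 1), rnorm(50, sd = 5))$p < 0.01))
  expect_gt(hits, 0.95)
})
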
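profile_row <- function(age, years, current, hours = 0, instruments = 0) {
  data.frame(starting_age_years = age, total_training_years = years,
             currently_training = current, hours_per_week = hours,
             n_instruments_lifetime = instruments)
}

test_that("participants are classified by the three musician criteria", {
  expect_equal(classify_participant(profile_row(6, 12, TRUE, 5, 2)),
               "musician")
  expect_equal(classify_participant(profile_row(NA, 0, FALSE)),
               "non-musician")
  expect_equal(classify_participant(profile_row(9, 2, FALSE, 0, 1)),
               "non-musician")
  # meets neither column: early start but short, lapsed training
  expect_equal(classify_participant(profile_row(6, 5, FALSE, 0, 1)),
               "neutral")
  # boundary: age exactly 7 satisfies both columns' age rule
  expect_equal(classify_participant(profile_row(7, 10, TRUE, 2, 1)),
               "musician")
  expect_equal(classify_participant(profile_row(7, 3, FALSE, 0, 1)),
               "non-musician")

  expect_error(classify_participant(profile_row(6, 0, TRUE)),
               "currently training with zero")
  expect_error(classify_participant(profile_row(NA, 5, FALSE)),
               "without a starting age")
})

test_that("musical-training scores normalize to the cohort maximum", {
  coh <- rbind(profile_row(5, 12, TRUE, 10, 2),
               profile_row(8, 2, FALSE, 0, 1),
               profile_row(NA, 0, FALSE, 0, 0))
  sc <- compute_scores(coh)
  # hand computation: max age 8, max years 12, max hours 10, max instr 2
  expect_equal(sc$starting_age_score, c((8 - 5) / 8, 0, NA))
  expect_equal(sc$total_years_score, c(1, 2 / 12, 0))
  expect_equal(sc$current_hours_score, c(1, 0, 0))
  expect_equal(sc$n_instruments_score, c(1, 0.5, 0))
  expect_equal(sc$aggregate, c(3 + 3 / 8, 2 / 12 + 0.5, 0))

  # un-inverted age: the participant holding every cohort maximum scores 4
  coh2 <- rbind(profile_row(8, 12, TRUE, 10, 2),
                profile_row(5, 2, FALSE, 0, 1))
  sc2 <- compute_scores(coh2, invert_age = FALSE)
  expect_equal(sc2$aggregate[1], 4)

  # an all-zero component contributes zero for everyone, with a warning
  coh3 <- rbind(profile_row(5, 12, FALSE, 0, 2),
                profile_row(6, 10, FALSE, 0, 1))
  expect_warning(sc3 <- compute_scores(coh3), "current hours")
  expect_equal(sc3$current_hours_score, c(0, 0))

  expect_error(compute_scores(profile_row(5, 1, TRUE, 1, 1)[0, ]), "empty")
})

test_that("score correlations use Spearman with BH adjustment", {
  co <- gen_cohort(8, 8, 4, seed = 12)
  sc <- compute_scores(co)
  # monotone relation: rho = 1
  mono <- correlate_scores(rank(sc$aggregate), sc)
  expect_equal(mono$rho[mono$score == "aggregate"], 1, tolerance = 1e-12)

  set.seed(13)
  out <- correlate_scores(rnorm(nrow(co)), sc)
  expect_equal(nrow(out), 5L)
  # BH oracle: hand-computed step-up adjustment of the raw p-values
  bh_hand <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
  }
  expect_equal(out$p_adjusted, bh_hand(out$p), tolerance = 1e-12)
  # monotone: adjusted ordering follows raw ordering
  expect_true(all(diff(out$p_adjusted[order(out$p)]) >= -1e-12))

  expect_message(skip_out <- correlate_scores(c(1, 2, NA, rep(NA, nrow(co) - 3)),
                                              sc),
                 "fewer than")
  expect_true(is.na(skip_out$rho[1]))
  expect_error(correlate_scores(1:3, sc), "per participant")
})

test_that("behavioral statistics compare the three groups", {
  co <- gen_cohort(12, 12, 12, seed = 14)
  # identical behavioral distributions across groups
  co$percent_correct <- rep(c(60, 70, 80, 90, 75, 85), times = 6)
  same <- behavior_stats(co, cbind(f = rnorm(36), e = rnorm(36)))
  expect_equal(same$kruskal$p, 1, tolerance = 1e-12)
  expect_equal(nrow(same$spearman), 2L)

  # one group shifted far away
  co$percent_correct[co$group == "musician"] <-
    co$percent_correct[co$group == "musician"] + 50
  shifted <- behavior_stats(co, cbind(f = rnorm(36), e = rnorm(36)))
  expect_lt(shifted$kruskal$p, 0.001)

  co_bad <- co[co$group != "neutral", ]
  expect_error(behavior_stats(co_bad[0, ], cbind(f = 1, e = 1)[0, ]),
               "nonempty")
})

test_that("cohorts round-trip through CSV", {
  co <- gen_cohort(3, 4, 2, seed = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$starting_age_years, co$starting_age_years)
  expect_equal(back$currently_training, co$currently_training)
  expect_identical(classify_participant(back), co$group)
  suppressWarnings(
    expect_error(read_cohort(file.path(tempdir(), "no-such-cohort.csv"))))
})
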
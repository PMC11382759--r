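# Significance of individual speech-FFRs against time-reversed noise
# models, per-subject peak extraction, and the attention / group-level
# statistics.

#' Time-reverse the feature streams of a stimulus
#'
#' @param features a [stimulus_features] object.
#' @param shift optional circular shift (in samples) applied after
#'   reversal, used to obtain several distinct noise models from one
#'   stimulus.
#' @return a [stimulus_features] object with both streams reversed.
#' @export
reverse_features <- function(features, shift = 0L) {
  stopifnot(inherits(features, "stimulus_features"))
  rot <- function(x) {
    x <- rev(x)
    s <- shift %% length(x)
    if (s > 0) x <- c(x[(s + 1L):length(x)], x[1L:s])
    x
  }
  stimulus_features(rot(features$fundamental), rot(features$envelope),
                    NULL, features$fs)
}

#' Noise TRF envelopes from time-reversed features
#'
#' Runs the full TRF + magnitude + envelope pipeline with time-reversed
#' feature streams against the untouched neural response.  The first noise
#' model uses the plain reversal; further models add a seeded random
#' circular shift of the reversed streams so that each fit sees a distinct
#' misaligned stimulus.
#'
#' @param features a [stimulus_features] object (aligned with `response`).
#' @param response a [neural_recording] (or time x channels matrix).
#' @param axis a [lag_axis].
#' @param lambda ridge penalty (default 1).
#' @param n_reversals number of noise models (default 10).
#' @param seed integer seed for the circular shifts.
#' @param vector_components passed to [trf_magnitude()].
#' @return list with `f` and `e`: matrices of noise envelopes,
#'   n_reversals x n_lags.
#' @export
noise_trf <- function(features, response, axis = lag_axis(), lambda = 1,
                      n_reversals = 10L, seed = 1L, vector_components = 1) {
  shifts <- noise_shifts(features, n_reversals, seed)
  env_f <- matrix(NA_real_, n_reversals, axis$n_lags)
  env_e <- matrix(NA_real_, n_reversals, axis$n_lags)
  for (r in seq_len(n_reversals)) {
    design <- build_design(reverse_features(features, shifts[r]), axis)
    model <- fit_ridge(design, response, lambda)
    mag <- trf_magnitude(model, vector_components)
    env <- trf_envelope(mag, fs = feature_rate(features))
    env_f[r, ] <- env[, "f"]
    env_e[r, ] <- env[, "e"]
  }
  list(f = env_f, e = env_e, lags_ms = axis$lags_ms)
}

noise_shifts <- function(features, n_reversals, seed) {
  if (n_reversals < 1L) stop("need at least one noise model")
  n <- length(features$fundamental)
  c(0L, with_seed(seed,
                  sample.int(n - 1L, max(0L, n_reversals - 1L),
                             replace = n_reversals - 1L > n - 1L)))[
    seq_len(n_reversals)]
}

feature_rate <- function(features) features$fs

#' Bootstrap significance of a TRF envelope against noise models
#'
#' Resamples the subject's noise-model envelopes with replacement
#' `n_permutations` times to build a per-lag null distribution of noise
#' envelope values, computes an empirical p-value per lag as
#' `(1 + #\{null >= observed\}) / (n_permutations + 1)`, and applies the
#' Bonferroni correction across lags.
#'
#' @param genuine_envelope numeric vector, the observed envelope per lag.
#' @param noise_envelopes matrix of noise envelopes (models x lags), e.g.
#'   one component of [noise_trf()]'s result.
#' @param n_permutations bootstrap draws (default 10000).
#' @param alpha family-wise significance level for the mask (default 0.05).
#' @param seed integer seed for the resampling.
#' @return an object of class `significance_profile` with per-lag `p`,
#'   `p_corrected`, `significant` mask, and per-lag noise quantiles.
#' @export
bootstrap_significance <- function(genuine_envelope, noise_envelopes,
                                   n_permutations = 10000L, alpha = 0.05,
                                   seed = 1L) {
  if (is.null(dim(noise_envelopes)))
    noise_envelopes <- matrix(noise_envelopes, nrow = 1L)
  if (nrow(noise_envelopes) < 1L) stop("empty noise-model set")
  if (ncol(noise_envelopes) != length(genuine_envelope))
    stop("noise envelopes and genuine envelope must share the lag axis")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  m <- length(genuine_envelope)
  idx <- with_seed(seed,
                   sample.int(nrow(noise_envelopes), n_permutations,
                              replace = TRUE))
  null <- noise_envelopes[idx, , drop = FALSE]
  exceed <- colSums(null >= rep(genuine_envelope, each = n_permutations))
  p <- (1 + exceed) / (n_permutations + 1)
  p_corr <- pmin(1, p * m)
  structure(list(p = p, p_corrected = p_corr,
                 significant = p_corr < alpha,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 noise_quantiles = apply(noise_envelopes, 2L, stats::quantile,
                                         probs = c(0.05, 0.5, 0.95))),
            class = "significance_profile")
}

#' @export
print.significance_profile <- function(x, ...) {
  cat("<significance_profile> ", length(x$p), " lags, ",
      sum(x$significant), " significant after Bonferroni (alpha = ",
      x$alpha, ", ", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' Peak of a TRF envelope restricted to significant lags
#'
#' Finds the global maximum of the envelope over the lags flagged
#' significant.  Ties are broken toward the earliest lag.  With no
#' significant lag the peak is flagged absent rather than fabricated.
#'
#' @param envelope numeric vector of envelope values per lag.
#' @param lags_ms numeric vector of lag latencies in ms.
#' @param significance optional [bootstrap_significance()] profile; `NULL`
#'   treats every lag as eligible.
#' @return list with `latency_ms`, `magnitude`, `is_significant`,
#'   `excluded_as_outlier` (always `FALSE` here; set by cohort-level
#'   screening).
#' @export
find_peak <- function(envelope, lags_ms, significance = NULL) {
  eligible <- if (is.null(significance)) rep(TRUE, length(envelope))
  else significance$significant
  if (length(eligible) != length(envelope))
    stop("envelope and significance mask must share the lag axis")
  if (!any(eligible))
    return(list(latency_ms = NA_real_, magnitude = NA_real_,
                is_significant = FALSE, excluded_as_outlier = FALSE))
  idx <- which(eligible)
  best <- idx[which.max(envelope[idx])]   # which.max takes the first maximum
  list(latency_ms = lags_ms[best], magnitude = envelope[best],
       is_significant = TRUE, excluded_as_outlier = FALSE)
}

#' Interquartile-range outlier exclusion
#'
#' Excludes values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`.
#'
#' @param values numeric vector (NAs are dropped first).
#' @param k fence multiplier (default 1.5).
#' @return list with `kept`, `excluded`, `fences`, and the logical
#'   `is_outlier` aligned with the non-NA input.
#' @export
iqr_exclude <- function(values, k = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    warning("fewer than 4 values; no outlier exclusion performed")
    return(list(kept = values, excluded = numeric(),
                fences = c(-Inf, Inf),
                is_outlier = rep(FALSE, length(values))))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  fences <- c(q[1L] - k * iqr, q[2L] + k * iqr)
  out <- values < fences[1L] | values > fences[2L]
  list(kept = values[!out], excluded = values[out], fences = fences,
       is_outlier = out)
}

#' Attentional modulation score
#'
#' `Q = (a - i) / (a + i)`, the normalized difference between the envelope
#' TRF magnitude when the speaker is attended (`a`) and ignored (`i`).
#' Swapping the conditions flips the sign.
#'
#' @param a,i nonnegative envelope magnitudes at the peak latency.
#' @return list with `a`, `i`, and `Q` in `[-1, 1]`; `Q` is `NA` when
#'   `a + i = 0`.
#' @export
attention_score <- function(a, i) {
  if (is.na(a) || is.na(i)) return(list(a = a, i = i, Q = NA_real_))
  if (a < 0 || i < 0) stop("envelope magnitudes must be nonnegative")
  q <- if (a + i > 0) (a - i) / (a + i) else NA_real_
  list(a = a, i = i, Q = q)
}

#' Compare two samples with a normality-gated location test
#'
#' Shapiro-Wilk tests both samples at `gate_alpha`; if both pass, a
#' Student's t-test is used (unpaired with pooled variance by default),
#' otherwise a Mann-Whitney-U test (Wilcoxon signed-rank when `paired`).
#'
#' @param x,y numeric samples (each n >= 3).
#' @param paired logical (default `FALSE`).
#' @param gate_alpha level of the normality gate (default 0.05).
#' @return list with `test` (`"t"` or `"mann-whitney"`), `statistic`, `p`,
#'   `shapiro_p` (both gate p-values), and sample sizes.
#' @export
compare_conditions <- function(x, y, paired = FALSE, gate_alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) stop("each sample needs n >= 3")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && x[1L] == y[1L])
    return(list(test = "degenerate", statistic = NA_real_, p = 1,
                shapiro_p = c(x = NA_real_, y = NA_real_),
                n = c(length(x), length(y))))
  sw <- c(x = stats::shapiro.test(x)$p.value,
          y = stats::shapiro.test(y)$p.value)
  if (all(sw > gate_alpha)) {
    res <- stats::t.test(x, y, paired = paired, var.equal = TRUE)
    test <- "t"
  } else {
    res <- stats::wilcox.test(x, y, paired = paired, exact = FALSE,
                              correct = FALSE)
    test <- "mann-whitney"
  }
  list(test = test, statistic = unname(res$statistic), p = res$p.value,
       shapiro_p = sw, n = c(length(x), length(y)))
}

#' Brown-Forsythe test for equality of variances
#'
#' The median-centred Levene test: a one-way ANOVA F-test on the absolute
#' deviations of each observation from its group median, robust to
#' departures from normality.
#'
#' @param x,y numeric samples (each n >= 3).
#' @return list with `statistic` (F), `p`, and degrees of freedom.
#' @export
compare_variances <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) stop("each sample needs n >= 3")
  z <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  if (stats::sd(z) == 0)
    return(list(statistic = 0, p = 1, df = c(1L, length(z) - 2L)))
  res <- stats::oneway.test(z ~ g, var.equal = TRUE)
  list(statistic = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}
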
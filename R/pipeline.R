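# End-to-end orchestration: synthetic study -> features -> conditioning ->
# TRF estimation -> noise-model significance -> attention and cohort
# statistics, from a single validated config with seeded stages.

#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()].  All
#' arguments have study-scale defaults; pass only what should differ.
#' Configurations round-trip through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param seed master seed; stage seeds are derived as
#'   `seed * 100 + <stage offset>` so stages can be rerun in isolation.
#' @param n_musicians,n_nonmusicians,n_neutral synthetic cohort sizes
#'   (defaults 3, 4, 1; the study cohort corresponds to 18, 25, 9).
#' @param duration_s stimulus length per condition in seconds (default 60).
#' @param audio_fs audio sample rate in Hz (default 8000).
#' @param neural_fs neural/working sample rate in Hz (default 1000).
#' @param f0_range_hz speaker f0 range in Hz (default `c(70, 120)`).
#' @param wander_rate_hz f0 drift rate in Hz (default 0.5).
#' @param n_harmonics harmonics of the synthetic voice (default 5).
#' @param peak_latency_ms ground-truth kernel peak latency in ms
#'   (default 35).
#' @param attention_gain attended/ignored response gain ratio (default 1.5).
#' @param snr_db signal-to-noise ratio of the synthetic responses in dB
#'   (default 0).
#' @param noise_exponent noise spectral exponent, 0 = white, 1 = 1/f
#'   (default 0).
#' @param amplitude_sd,latency_sd_ms inter-subject TRF variability (see
#'   [gen_cohort()]).
#' @param tau_min_ms,tau_max_ms,step_ms TRF lag axis (defaults -20, 120, 1).
#' @param ridge_lambda ridge penalty (default 1).
#' @param n_noise_models time-reversed noise models per subject
#'   (default 10).
#' @param n_permutations bootstrap permutations (default 10000).
#' @param alpha significance level for the Bonferroni mask and the
#'   normality gates (default 0.05).
#' @param tube_delay_ms acoustic tube delay in ms applied when aligning
#'   real recordings (default 6; the synthetic generator produces aligned
#'   data, offset 0).
#' @param notch_hz power-line notch frequency (default 50; `NA` disables).
#' @param output_dir directory for persisted outputs (`NULL`: in-memory
#'   only).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_musicians = 3L, n_nonmusicians = 4L,
                            n_neutral = 1L, duration_s = 60, audio_fs = 8000,
                            neural_fs = 1000, f0_range_hz = c(70, 120),
                            wander_rate_hz = 0.5, n_harmonics = 5L,
                            peak_latency_ms = 35, attention_gain = 1.5,
                            snr_db = 0, noise_exponent = 0,
                            amplitude_sd = 0.2, latency_sd_ms = 1,
                            tau_min_ms = -20, tau_max_ms = 120, step_ms = 1,
                            ridge_lambda = 1, n_noise_models = 10L,
                            n_permutations = 10000L, alpha = 0.05,
                            tube_delay_ms = 6, notch_hz = 50,
                            output_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_musicians = as.integer(n_musicians),
              n_nonmusicians = as.integer(n_nonmusicians),
              n_neutral = as.integer(n_neutral), duration_s = duration_s,
              audio_fs = audio_fs, neural_fs = neural_fs,
              f0_range_hz = f0_range_hz, wander_rate_hz = wander_rate_hz,
              n_harmonics = as.integer(n_harmonics),
              peak_latency_ms = peak_latency_ms,
              attention_gain = attention_gain, snr_db = snr_db,
              noise_exponent = noise_exponent, amplitude_sd = amplitude_sd,
              latency_sd_ms = latency_sd_ms, tau_min_ms = tau_min_ms,
              tau_max_ms = tau_max_ms, step_ms = step_ms,
              ridge_lambda = ridge_lambda,
              n_noise_models = as.integer(n_noise_models),
              n_permutations = as.integer(n_permutations), alpha = alpha,
              tube_delay_ms = tube_delay_ms, notch_hz = notch_hz,
              output_dir = output_dir)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  check_scalar(cfg$duration_s, "duration_s", lower = 1)
  check_scalar(cfg$attention_gain, "attention_gain", lower = 1)
  check_scalar(cfg$ridge_lambda, "ridge_lambda", lower = 0)
  check_scalar(cfg$alpha, "alpha", lower = 0, upper = 1)
  if (cfg$n_musicians + cfg$n_nonmusicians + cfg$n_neutral < 2L)
    stop("the synthetic study needs at least 2 participants")
  if (cfg$n_noise_models < 1L) stop("n_noise_models must be >= 1")
  if (cfg$n_permutations < 1L) stop("n_permutations must be >= 1")
  if (cfg$f0_range_hz[2L] > cfg$neural_fs / 2)
    stop("f0 range must lie below the neural Nyquist frequency")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_seed <- function(cfg, offset) cfg$seed * 100L + offset

#' Run the speech-FFR analysis pipeline on synthetic data
#'
#' Executes the full analysis on a simulated study: generates a wandering
#' f0 voice and extracts the two speech features; simulates each
#' participant's attended and ignored neural responses from ground-truth
#' kernels with subject-specific amplitude and latency; conditions the
#' recordings (notch, FFR band-pass); fits TRFs by ridge regression for
#' every subject and condition; derives magnitude envelopes and tests them
#' against time-reversed noise models; extracts peaks, computes population
#' latencies with IQR outlier screening, attention scores Q, and the full
#' set of cohort statistics.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default `FALSE`).
#' @return a list with elements `config`, `truth` (per-subject ground
#'   truth summary), `features`, `envelopes`, `significance`, `peaks`
#'   (data.frame), `population_latency_ms`, `magnitude_table`, `qscores`,
#'   `stats`, `cohort`.  If `config$output_dir` is set, tables are also
#'   written there together with the config and a provenance record.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[speechFFR] ", ...)
  axis <- lag_axis(config$tau_min_ms, config$tau_max_ms, config$step_ms)
  n_sub <- config$n_musicians + config$n_nonmusicians + config$n_neutral

  say("simulate: ", config$duration_s, " s voice, ", n_sub, " subjects")
  f0 <- gen_f0_trajectory(config$duration_s, config$f0_range_hz,
                          config$wander_rate_hz,
                          seed = stage_seed(config, 1L), fs = config$audio_fs)
  voice <- gen_voice(f0, config$n_harmonics, seed = stage_seed(config, 2L))

  say("features: f0 track, fundamental waveform, envelope modulation")
  features <- extract_stimulus_features(voice, config$audio_fs,
                                        out_rate = config$neural_fs)
  feat_cor <- feature_correlation(features$fundamental, features$envelope)

  say("cohort: ", config$n_musicians, " musicians, ", config$n_nonmusicians,
      " non-musicians, ", config$n_neutral, " neutral")
  cohort <- gen_cohort(config$n_musicians, config$n_nonmusicians,
                       config$n_neutral, seed = stage_seed(config, 3L),
                       amplitude_sd = config$amplitude_sd,
                       latency_sd_ms = config$latency_sd_ms)
  cohort$group_observed <- classify_participant(cohort)

  say("simulate: neural responses (attended + ignored per subject)")
  design <- build_design(features, axis)
  truths <- lapply(seq_len(n_sub), function(s) {
    peak <- config$peak_latency_ms + cohort$latency_shift_ms[s]
    tr <- ground_truth(axis, peak_latency_ms = peak,
                       attention_gain = config$attention_gain,
                       snr_db = config$snr_db,
                       noise_exponent = config$noise_exponent,
                       seed = stage_seed(config, 4L) + s)
    tr$kernel_alpha <- tr$kernel_alpha * cohort$kernel_scale[s]
    tr$kernel_beta <- tr$kernel_beta * cohort$kernel_scale[s]
    tr
  })
  w_true <- vapply(truths, function(tr) c(tr$kernel_alpha, tr$kernel_beta),
                   numeric(2L * axis$n_lags))
  clean <- design %*% w_true                       # time x subjects
  n_t <- nrow(clean)
  y <- matrix(0, n_t, 2L * n_sub)
  cond <- rep(c("attended", "ignored"), n_sub)
  subj_of_col <- rep(seq_len(n_sub), each = 2L)
  for (s in seq_len(n_sub)) {
    noise_sd <- stats::sd(clean[, s]) * 10^(-config$snr_db / 20)
    y[, 2L * s - 1L] <- with_seed(truths[[s]]$seed, {
      config$attention_gain * clean[, s] +
        shaped_noise(n_t, noise_sd, config$noise_exponent)
    })
    y[, 2L * s] <- with_seed(truths[[s]]$seed + 7919L, {
      clean[, s] + shaped_noise(n_t, noise_sd, config$noise_exponent)
    })
  }

  say("neuralprep: notch + FFR band-pass")
  rec <- neural_recording(t(y), config$neural_fs, alignment_offset_ms = 0,
                          channel_roles = "source-point")
  if (!is.na(config$notch_hz)) rec <- notch(rec, config$notch_hz)
  rec <- ffr_bandpass(rec)

  say("fit: ridge TRFs (lambda = ", config$ridge_lambda, ", ",
      axis$n_lags, " lags)")
  model <- fit_ridge(design, rec, config$ridge_lambda)
  env_of_col <- function(w_col) {
    n_lags <- axis$n_lags
    mag <- cbind(f = abs(w_col[seq_len(n_lags)]),
                 e = abs(w_col[n_lags + seq_len(n_lags)]))
    trf_envelope(mag, fs = config$neural_fs)
  }
  w_all <- rbind(model$alpha, model$beta)
  envelopes <- lapply(seq_len(ncol(w_all)), function(j) env_of_col(w_all[, j]))

  say("test: ", config$n_noise_models, " noise models, ",
      config$n_permutations, " permutations")
  shifts <- noise_shifts(features, config$n_noise_models,
                         stage_seed(config, 5L))
  noise_env <- lapply(seq_len(ncol(w_all)), function(j)
    list(f = matrix(NA_real_, config$n_noise_models, axis$n_lags),
         e = matrix(NA_real_, config$n_noise_models, axis$n_lags)))
  for (r in seq_along(shifts)) {
    design_r <- build_design(reverse_features(features, shifts[r]), axis)
    model_r <- fit_ridge(design_r, rec, config$ridge_lambda)
    w_r <- rbind(model_r$alpha, model_r$beta)
    for (j in seq_len(ncol(w_r))) {
      env_r <- env_of_col(w_r[, j])
      noise_env[[j]]$f[r, ] <- env_r[, "f"]
      noise_env[[j]]$e[r, ] <- env_r[, "e"]
    }
  }
  significance <- lapply(seq_along(envelopes), function(j) {
    lapply(c(f = "f", e = "e"), function(feat)
      bootstrap_significance(envelopes[[j]][, feat], noise_env[[j]][[feat]],
                             config$n_permutations, config$alpha,
                             seed = stage_seed(config, 6L) + j))
  })

  say("stats: peaks, population latencies, attention scores, cohort tests")
  peaks <- do.call(rbind, lapply(seq_along(envelopes), function(j) {
    do.call(rbind, lapply(c("f", "e"), function(feat) {
      pk <- find_peak(envelopes[[j]][, feat], axis$lags_ms,
                      significance[[j]][[feat]])
      data.frame(subject = cohort$id[subj_of_col[j]],
                 condition = cond[j], feature = feat,
                 latency_ms = pk$latency_ms, magnitude = pk$magnitude,
                 is_significant = pk$is_significant)
    }))
  }))

  conditions <- expand.grid(condition = c("attended", "ignored"),
                            feature = c("f", "e"), stringsAsFactors = FALSE)
  pop_latency <- numeric(nrow(conditions))
  mag_rows <- list()
  for (k in seq_len(nrow(conditions))) {
    sel <- peaks$condition == conditions$condition[k] &
      peaks$feature == conditions$feature[k]
    lat <- peaks$latency_ms[sel & peaks$is_significant]
    scr <- if (length(lat) >= 4L) iqr_exclude(lat)
           else list(kept = lat)
    pop_latency[k] <- if (length(scr$kept)) mean(scr$kept) else NA_real_
    cols <- which(cond == conditions$condition[k])
    lag_idx <- if (is.na(pop_latency[k])) {
      # no significant individual peak anywhere: fall back to the maximum
      # of the population-average envelope for this condition/feature
      pop_env <- rowMeans(vapply(cols, function(j)
        envelopes[[j]][, conditions$feature[k]], numeric(axis$n_lags)))
      which.max(pop_env)
    } else {
      which.min(abs(axis$lags_ms - pop_latency[k]))
    }
    mag_rows[[k]] <- data.frame(
      subject = cohort$id[subj_of_col[cols]],
      condition = conditions$condition[k], feature = conditions$feature[k],
      population_latency_ms = pop_latency[k],
      magnitude = vapply(cols, function(j)
        envelopes[[j]][lag_idx, conditions$feature[k]], numeric(1)))
  }
  names(pop_latency) <- paste(conditions$feature, conditions$condition,
                              sep = "_")
  magnitude_table <- do.call(rbind, mag_rows)

  qscores <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    do.call(rbind, lapply(c("f", "e"), function(feat) {
      get_mag <- function(cnd) magnitude_table$magnitude[
        magnitude_table$subject == cohort$id[s] &
          magnitude_table$condition == cnd &
          magnitude_table$feature == feat]
      q <- attention_score(get_mag("attended"), get_mag("ignored"))
      data.frame(subject = cohort$id[s], feature = feat, a = q$a, i = q$i,
                 Q = q$Q, group = cohort$group_observed[s])
    }))
  }))

  stats_out <- cohort_statistics(magnitude_table, qscores, cohort,
                                 gate_alpha = config$alpha)
  stats_out$feature_correlation <- feat_cor
  stats_out$excluded_counts <- vapply(seq_len(nrow(conditions)), function(k) {
    sel <- peaks$condition == conditions$condition[k] &
      peaks$feature == conditions$feature[k]
    sum(!peaks$is_significant[sel])
  }, numeric(1))

  result <- list(config = config,
                 truth = data.frame(subject = cohort$id,
                                    peak_latency_ms = vapply(truths, `[[`,
                                      numeric(1), "peak_latency_ms"),
                                    kernel_scale = cohort$kernel_scale),
                 features = features, lag_axis = axis, model = model,
                 envelopes = envelopes, cond = cond,
                 subject_of_column = subj_of_col,
                 significance = significance, peaks = peaks,
                 population_latency_ms = pop_latency,
                 magnitude_table = magnitude_table, qscores = qscores,
                 stats = stats_out, cohort = cohort)
  if (!is.null(config$output_dir)) persist_outputs(result, config$output_dir)
  result
}

# Group and attention statistics on the per-subject magnitude and Q tables.
cohort_statistics <- function(magnitude_table, qscores, cohort,
                              gate_alpha = 0.05) {
  by_feat <- function(feat) {
    att <- magnitude_table$magnitude[magnitude_table$feature == feat &
                                       magnitude_table$condition == "attended"]
    ign <- magnitude_table$magnitude[magnitude_table$feature == feat &
                                       magnitude_table$condition == "ignored"]
    res <- list(attention = compare_conditions(att, ign,
                                               gate_alpha = gate_alpha))
    qs <- qscores[qscores$feature == feat, ]
    mus <- qs$Q[qs$group == "musician"]
    nonm <- qs$Q[qs$group == "non-musician"]
    if (sum(!is.na(mus)) >= 3L && sum(!is.na(nonm)) >= 3L) {
      res$q_group_mean <- compare_conditions(mus, nonm,
                                             gate_alpha = gate_alpha)
      res$q_group_variance <- compare_variances(mus, nonm)
    }
    res
  }
  out <- list(f = by_feat("f"), e = by_feat("e"))
  att_mag <- stats::reshape(
    magnitude_table[magnitude_table$condition == "attended",
                    c("subject", "feature", "magnitude")],
    direction = "wide", idvar = "subject", timevar = "feature")
  names(att_mag) <- sub("^magnitude[.]", "", names(att_mag))
  att_mag <- att_mag[match(cohort$id, att_mag$subject), ]
  scores <- compute_scores(cohort)
  out$score_correlations <- lapply(c(f = "f", e = "e"), function(feat)
    correlate_scores(att_mag[[feat]], scores))
  out$behavior <- behavior_stats(cohort, att_mag[, c("f", "e")])
  out
}

persist_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(result$config, file.path(dir, "config.yaml"))
  utils::write.csv(result$peaks, file.path(dir, "peaks.csv"),
                   row.names = FALSE)
  utils::write.csv(result$magnitude_table,
                   file.path(dir, "magnitudes.csv"), row.names = FALSE)
  utils::write.csv(result$qscores, file.path(dir, "qscores.csv"),
                   row.names = FALSE)
  write_cohort(result$cohort, file.path(dir, "cohort.csv"))
  env_tab <- data.frame(lag_ms = result$lag_axis$lags_ms)
  for (j in seq_along(result$envelopes)) {
    lbl <- paste0(result$cohort$id[result$subject_of_column[j]], "_",
                  result$cond[j])
    env_tab[[paste0(lbl, "_f")]] <- result$envelopes[[j]][, "f"]
    env_tab[[paste0(lbl, "_e")]] <- result$envelopes[[j]][, "e"]
  }
  utils::write.csv(env_tab, file.path(dir, "envelopes.csv"),
                   row.names = FALSE)
  report <- list(population_latency_ms = as.list(result$population_latency_ms),
                 stats = result$stats,
                 provenance = list(package = "speechFFR",
                                   version = as.character(utils::packageVersion("speechFFR")),
                                   seed = result$config$seed,
                                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
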
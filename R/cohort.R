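# Musician / non-musician classification, musical-training scores, and
# cohort-level correlation and group statistics.

validate_profiles <- function(cohort) {
  req <- c("starting_age_years", "total_training_years", "currently_training",
           "hours_per_week", "n_instruments_lifetime")
  missing <- setdiff(req, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  bad <- cohort$currently_training & cohort$total_training_years <= 0
  if (any(bad, na.rm = TRUE))
    stop("contradictory profile(s): currently training with zero total years")
  bad <- is.na(cohort$starting_age_years) & cohort$total_training_years > 0
  if (any(bad))
    stop("contradictory profile(s): training years without a starting age")
  invisible(cohort)
}

#' Classify participants as musicians, non-musicians, or neutral
#'
#' A participant is a *musician* if they started training at age 7 or
#' earlier, trained for 10 or more years in total, and are currently
#' training.  A participant is a *non-musician* if they never played an
#' instrument, or started at age 7 or later, trained at most 3 years in
#' total, and are not currently training.  Everyone else is *neutral*.
#'
#' @param cohort data.frame with columns `starting_age_years` (NA = never
#'   played), `total_training_years`, `currently_training`,
#'   `hours_per_week`, `n_instruments_lifetime`; e.g. from [gen_cohort()]
#'   or [read_cohort()].
#' @return character vector of group labels, one per row.
#' @export
classify_participant <- function(cohort) {
  validate_profiles(cohort)
  age <- cohort$starting_age_years
  years <- cohort$total_training_years
  current <- cohort$currently_training
  never <- is.na(age)
  musician <- !never & age <= 7 & years >= 10 & current
  nonmusician <- never | (!never & age >= 7 & years <= 3 & !current)
  ifelse(musician, "musician", ifelse(nonmusician, "non-musician", "neutral"))
}

#' Scores of musical training
#'
#' Four per-participant scores -- starting age (inverted, earlier = higher),
#' total training years, current weekly training hours, and lifetime
#' instrument count -- each normalized to [0, 1] by its cohort maximum,
#' plus their sum as an aggregate.  Participants who never played
#' contribute no value to the age component (it is absent, not zero-worst),
#' and their aggregate sums the remaining components.
#'
#' @param cohort data.frame as for [classify_participant()].
#' @param invert_age logical; `TRUE` (default) maps starting age `a` to
#'   `(max_age - a) / max_age` over participants who played, so that an
#'   earlier start scores higher.
#' @return data.frame with `starting_age_score`, `total_years_score`,
#'   `current_hours_score`, `n_instruments_score`, `aggregate`.
#' @export
compute_scores <- function(cohort, invert_age = TRUE) {
  validate_profiles(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort")
  norm_max <- function(x, label) {
    m <- max(x, na.rm = TRUE)
    if (!is.finite(m) || m == 0) {
      warning("all-zero ", label, " component; contributes 0 for everyone")
      return(ifelse(is.na(x), NA_real_, 0))
    }
    x / m
  }
  age <- cohort$starting_age_years
  age_score <- if (invert_age) {
    m <- max(age, na.rm = TRUE)
    if (!is.finite(m) || m == 0) rep(NA_real_, length(age))
    else (m - age) / m
  } else {
    norm_max(age, "starting age")
  }
  scores <- data.frame(
    starting_age_score = age_score,
    total_years_score = norm_max(cohort$total_training_years, "total years"),
    current_hours_score = norm_max(cohort$hours_per_week, "current hours"),
    n_instruments_score = norm_max(as.numeric(cohort$n_instruments_lifetime),
                                   "instrument count"))
  scores$aggregate <- rowSums(scores, na.rm = TRUE)
  scores
}

#' Correlate neural magnitudes with the musical-training scores
#'
#' Spearman correlation of the per-subject neural magnitude with each of
#' the four training scores and the aggregate, with Benjamini-Hochberg
#' false-discovery-rate adjustment across the five tests.  Scores with
#' fewer than `min_pairs` complete pairs are skipped with a notice.
#'
#' @param neural_magnitudes numeric vector, one value per participant.
#' @param scores data.frame from [compute_scores()].
#' @param min_pairs minimum complete pairs per score (default 4).
#' @return data.frame with `score`, `rho`, `p`, `p_adjusted`, `n`.
#' @export
correlate_scores <- function(neural_magnitudes, scores, min_pairs = 4L) {
  if (length(neural_magnitudes) != nrow(scores))
    stop("one neural magnitude per participant is required")
  out <- lapply(names(scores), function(sc) {
    ok <- stats::complete.cases(neural_magnitudes, scores[[sc]])
    if (sum(ok) < min_pairs) {
      message("skipping score '", sc, "': fewer than ", min_pairs,
              " complete pairs")
      return(data.frame(score = sc, rho = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- stats::cor.test(neural_magnitudes[ok], scores[[sc]][ok],
                          method = "spearman", exact = FALSE)
    data.frame(score = sc, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[, c("score", "rho", "p", "p_adjusted", "n")]
}

#' Behavioral statistics of the cohort
#'
#' Spearman correlation between the neural magnitudes and the percentage
#' of correctly answered comprehension questions (one test per feature),
#' and a Kruskal-Wallis comparison of the behavioral scores across the
#' three participant groups.
#'
#' @param cohort data.frame with `percent_correct` and a `group` column
#'   (or one derivable via [classify_participant()]).
#' @param neural_magnitudes numeric matrix or data.frame, participants x
#'   features (e.g. columns `f` and `e`).
#' @return list with `spearman` (data.frame per feature) and `kruskal`
#'   (statistic, df, p).
#' @export
behavior_stats <- function(cohort, neural_magnitudes) {
  if (is.null(cohort$group)) cohort$group <- classify_participant(cohort)
  if (is.vector(neural_magnitudes))
    neural_magnitudes <- matrix(neural_magnitudes,
                                dimnames = list(NULL, "neural"))
  neural_magnitudes <- as.data.frame(neural_magnitudes)
  if (nrow(neural_magnitudes) != nrow(cohort))
    stop("one neural magnitude row per participant is required")
  groups <- split(cohort$percent_correct, cohort$group)
  if (any(lengths(groups) == 0L) || length(groups) < 2L)
    stop("Kruskal comparison needs at least two nonempty groups")
  sp <- lapply(names(neural_magnitudes), function(feat) {
    ok <- stats::complete.cases(neural_magnitudes[[feat]],
                                cohort$percent_correct)
    ct <- stats::cor.test(neural_magnitudes[[feat]][ok],
                          cohort$percent_correct[ok], method = "spearman",
                          exact = FALSE)
    data.frame(feature = feat, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  kt <- stats::kruskal.test(cohort$percent_correct, factor(cohort$group))
  list(spearman = do.call(rbind, sp),
       kruskal = list(statistic = unname(kt$statistic),
                      df = unname(kt$parameter), p = kt$p.value))
}

#' Read / write a participant cohort as CSV
#'
#' Column dictionary: `id` (character), `group` (optional; recomputable via
#' [classify_participant()]), `starting_age_years` (NA = never played),
#' `total_training_years`, `currently_training` (logical),
#' `hours_per_week`, `n_instruments_lifetime`, `percent_correct`, plus any
#' extra columns, which are preserved.
#'
#' @param path CSV file path.
#' @return `read_cohort`: the cohort data.frame; `write_cohort`: `path`,
#'   invisibly.
#' @examples
#' path <- system.file("extdata", "synthetic_cohort.csv",
#'                     package = "speechFFR")
#' cohort <- read_cohort(path)
#' table(classify_participant(cohort))
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort$currently_training <- as.logical(cohort$currently_training)
  validate_profiles(cohort)
  cohort
}

#' @rdname read_cohort
#' @param cohort data.frame to write.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
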
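# Behavioral scoring and expertise-behavior correlations. Unanswered trials
# count as incorrect; chance is the trial-frequency-weighted accuracy of
# uniform guessing over the choices offered on each trial.

#' Behavioral performance as proportion correct
#'
#' Correct trials over all trials; unanswered trials stay in the denominator
#' as incorrect.
#' @param outcomes factor/character of per-trial outcomes (`correct`,
#'   `incorrect`, `unanswered`), e.g. from [simulate_behavior()].
#' @return proportion in \[0, 1\].
#' @export
performance <- function(outcomes) {
  if (length(outcomes) == 0L)
    stop("configuration error: empty behavioral record", call. = FALSE)
  mean(as.character(outcomes) == "correct")
}

#' Chance-level behavioral performance for a task structure
#'
#' Expected accuracy of uniform guessing over the choices offered per trial,
#' weighted by trial frequency: 25% for the 4-choice category task; 37.5% for
#' the subcategory session of the default design (54 of 72 trials with three
#' choices, 18 with two).
#'
#' @param n_trials trial count per trial type.
#' @param n_choices choices offered for that trial type.
#' @return expected accuracy.
#' @export
behavioral_chance <- function(n_trials, n_choices) {
  stopifnot(length(n_trials) == length(n_choices), all(n_choices >= 1))
  sum(n_trials / sum(n_trials) / n_choices)
}

#' Pearson correlation with exact t-based p-value
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`; two-tailed p from the t distribution
#' on `n - 2` df (the convention that reproduces the published behavioral
#' p-values, e.g. r = 0.593 at n = 20 -> p = 0.0059).
#'
#' @param x,y numeric vectors (n >= 4, nonconstant).
#' @return object of class `correlation_result`: `r`, `n`, `df`, `t`, `p`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("configuration error: need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("configuration error: constant input", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r_to_t(r, n)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  structure(list(r = r, n = n, df = n - 2L, t = tval, p = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, t(%d) = %.2f, p = %.4g, n = %d\n",
              x$r, x$df, x$t, x$p, x$n))
  invisible(x)
}

#' Summarize a cohort's behavior on one task
#'
#' Simulates (or recomputes) per-subject performance and its correlation with
#' expertise and rating. Non-rate-holders can be included as zero-rated
#' subjects, mirroring the reporting convention for novices without a
#' competition rating.
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param schedule a `stimulus_schedule`.
#' @param task `"category"` or `"subcategory"`.
#' @param scheme a [category_scheme()].
#' @param seed integer seed.
#' @param zero_rate_novices include novices at rating 0 (default FALSE: they
#'   are dropped from rating correlations).
#' @return list: `per_subject` data.frame (subject_id, group, expertise,
#'   rating, performance), `vs_expertise`, `vs_rating` ([correlate()] results).
#' @export
behavior_summary <- function(cohort, schedule, task = "category",
                             scheme = category_scheme(), seed = 1L,
                             zero_rate_novices = FALSE) {
  perf <- vapply(seq_len(nrow(cohort)), function(i) {
    resp <- simulate_behavior(cohort$expertise[i], schedule, task = task,
                              scheme = scheme,
                              seed = derive_seed(seed, "behavior", task, i))
    performance(resp$outcome)
  }, numeric(1))
  per_subject <- cbind(cohort, performance = perf)
  rating <- cohort$rating
  if (zero_rate_novices) rating[is.na(rating)] <- 0
  list(per_subject = per_subject,
       vs_expertise = correlate(cohort$expertise, perf),
       vs_rating = correlate(rating, perf))
}
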
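# Stimulus set and trial schedule for the program-categorization experiment:
# 72 code snippets in 4 functional categories of 18, subdivided into 11
# algorithm subcategories (ten of six snippets, one of twelve), presented over
# 6 runs x 36 trials with per-run category balance.

#' Category/subcategory scheme of the stimulus set
#'
#' Defines the two-level label hierarchy: four functional categories of 18
#' stimuli each, subdivided into eleven concrete-algorithm subcategories. Ten
#' subcategories hold six stimuli; one (by default `linear_search`) holds
#' twelve, which forces its parent category to have exactly two subcategories.
#'
#' @param categories four category labels.
#' @param subcategories named character vector mapping subcategory label ->
#'   parent category label; length 11.
#' @param sizes named integer vector of stimulus counts per subcategory.
#' @return an object of class `category_scheme`.
#' @examples
#' sc <- category_scheme()
#' sum(sc$sizes)  # 72
#' @export
category_scheme <- function(
    categories = c("math", "search", "sort", "string"),
    subcategories = c(
      arithmetic = "math", number_theory = "math", combinatorics = "math",
      linear_search = "search", binary_search = "search",
      bubble_sort = "sort", insertion_sort = "sort", selection_sort = "sort",
      string_match = "string", string_transform = "string", parsing = "string"
    ),
    sizes = c(
      arithmetic = 6L, number_theory = 6L, combinatorics = 6L,
      linear_search = 12L, binary_search = 6L,
      bubble_sort = 6L, insertion_sort = 6L, selection_sort = 6L,
      string_match = 6L, string_transform = 6L, parsing = 6L
    )) {
  obj <- structure(
    list(categories = as.character(categories),
         parent = subcategories,
         subcategories = names(subcategories),
         sizes = sizes),
    class = "category_scheme")
  validate_scheme(obj)
  obj
}

validate_scheme <- function(scheme) {
  if (length(scheme$categories) != 4L)
    stop("scheme invariant violated: need exactly 4 categories", call. = FALSE)
  if (length(scheme$subcategories) != 11L)
    stop("scheme invariant violated: need exactly 11 subcategories", call. = FALSE)
  if (!setequal(names(scheme$sizes), scheme$subcategories))
    stop("scheme invariant violated: sizes must be named by subcategory", call. = FALSE)
  if (!all(scheme$parent %in% scheme$categories))
    stop("scheme invariant violated: unknown parent category", call. = FALSE)
  per_cat <- tapply(scheme$sizes[scheme$subcategories],
                    scheme$parent[scheme$subcategories], sum)
  if (!all(per_cat[scheme$categories] == 18L))
    stop("scheme invariant violated: each category's subcategory sizes must sum to 18",
         call. = FALSE)
  if (sum(scheme$sizes) != 72L)
    stop("scheme invariant violated: total stimuli must be 72, got ",
         sum(scheme$sizes), call. = FALSE)
  if (sum(scheme$sizes == 12L) != 1L || !all(scheme$sizes %in% c(6L, 12L)))
    stop("scheme invariant violated: exactly one subcategory of size 12, rest size 6",
         call. = FALSE)
  big <- names(scheme$sizes)[scheme$sizes == 12L]
  if (sum(scheme$parent == scheme$parent[[big]]) != 2L)
    stop("scheme invariant violated: the size-12 subcategory's category must have ",
         "exactly 2 subcategories", call. = FALSE)
  invisible(scheme)
}

#' Build the stimulus set from a category scheme
#'
#' @param scheme a [category_scheme()].
#' @return data.frame with columns `stimulus_id`, `category`, `subcategory`
#'   (72 rows for the default scheme).
#' @export
build_stimulus_set <- function(scheme = category_scheme()) {
  validate_scheme(scheme)
  sub <- rep(scheme$subcategories, times = scheme$sizes[scheme$subcategories])
  data.frame(
    stimulus_id = sprintf("stim_%02d", seq_along(sub)),
    category = unname(scheme$parent[sub]),
    subcategory = sub,
    stringsAsFactors = FALSE)
}

# Random stimulus-by-run incidence matrix for one category: m stimuli, each
# appearing in `reps` distinct runs, every run holding exactly m*reps/n_runs of
# them. Starts from a feasible cyclic assignment and applies checkerboard swaps,
# which preserve row and column sums (and row-distinctness, the matrix being
# binary) while randomizing the design.
random_incidence <- function(m, n_runs, reps, n_swaps = 20L * m * n_runs) {
  stopifnot((m * reps) %% n_runs == 0)
  M <- matrix(0L, m, n_runs)
  pos <- 0L
  for (i in seq_len(m)) for (r in seq_len(reps)) {
    M[i, (pos %% n_runs) + 1L] <- 1L
    pos <- pos + 1L
  }
  for (s in seq_len(n_swaps)) {
    ab <- sample.int(m, 2L)
    cd <- sample.int(n_runs, 2L)
    block <- M[ab, cd]
    if (block[1, 1] == 1L && block[2, 2] == 1L && block[1, 2] == 0L && block[2, 1] == 0L)
      M[ab, cd] <- matrix(c(0L, 1L, 1L, 0L), 2L)
  }
  M
}

#' Generate a pseudo-randomized trial schedule
#'
#' Each stimulus appears exactly three times over the experiment, at most once
#' per run, and every run holds exactly `trials_per_run / 4` trials of each
#' category (9 for the default design). Each run is preceded by one unmodeled
#' dummy trial. Trials are 16 s: 2 s fixation, 10 s code presentation, 4 s
#' response window. Response-button order is randomized per trial and recorded.
#'
#' @param stimuli stimulus table from [build_stimulus_set()].
#' @param n_runs number of runs (default 6).
#' @param trials_per_run task trials per run (default 36).
#' @param seed integer seed; schedules are deterministic given the seed.
#' @param reps presentations per stimulus (default 3).
#' @return an object of class `stimulus_schedule` with an `entries` data.frame
#'   (run, trial, stimulus_id, category, subcategory, onset, durations, button
#'   order) and the design constants.
#' @export
make_schedule <- function(stimuli, n_runs = 6L, trials_per_run = 36L,
                          seed = 1L, reps = 3L) {
  n_stim <- nrow(stimuli)
  if (n_runs * trials_per_run != reps * n_stim)
    stop("scheduling error: n_runs * trials_per_run (", n_runs * trials_per_run,
         ") must equal ", reps, " * ", n_stim, " stimuli", call. = FALSE)
  cats <- sort(unique(stimuli$category))
  per_run_cat <- trials_per_run / length(cats)
  if (per_run_cat != round(per_run_cat))
    stop("scheduling error: trials_per_run not divisible by category count",
         call. = FALSE)
  trial_len <- 16; fix_s <- 2; code_s <- 10; resp_s <- 4
  dummy <- 1L

  with_seed(seed, {
    run_stim <- vector("list", n_runs)
    for (cat in cats) {
      idx <- which(stimuli$category == cat)
      M <- random_incidence(length(idx), n_runs, reps)
      for (r in seq_len(n_runs))
        run_stim[[r]] <- c(run_stim[[r]], idx[M[, r] == 1L])
    }
    entries <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
      ord <- sample(run_stim[[r]])
      data.frame(
        run = r,
        trial = seq_len(trials_per_run),
        stimulus_id = stimuli$stimulus_id[ord],
        category = stimuli$category[ord],
        subcategory = stimuli$subcategory[ord],
        onset = (dummy + seq_len(trials_per_run) - 1) * trial_len,
        fixation_s = fix_s, code_s = code_s, response_s = resp_s,
        button_order = vapply(seq_len(trials_per_run),
                              function(i) paste(sample.int(4L), collapse = ""),
                              character(1)),
        stringsAsFactors = FALSE)
    }))
  })
  structure(
    list(entries = entries, n_runs = as.integer(n_runs),
         trials_per_run = as.integer(trials_per_run),
         dummy_trials_per_run = dummy, trial_length_s = trial_len,
         seed = as.integer(seed)),
    class = "stimulus_schedule")
}

#' Total duration of one run in seconds
#'
#' `(trials_per_run + dummy_trials_per_run) * 16`; 592 s for the default
#' 36-trial design.
#' @param schedule a [make_schedule()] result.
#' @export
run_duration_seconds <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  (schedule$trials_per_run + schedule$dummy_trials_per_run) * schedule$trial_length_s
}

#' Check all schedule invariants, stopping at the first violation
#' @param schedule a `stimulus_schedule`.
#' @return the schedule, invisibly.
#' @export
validate_schedule <- function(schedule) {
  e <- schedule$entries
  reps <- table(e$stimulus_id)
  if (length(unique(reps)) != 1L)
    stop("schedule invariant violated: unequal stimulus repetition counts", call. = FALSE)
  per_run <- table(e$stimulus_id, e$run)
  if (any(per_run > 1L))
    stop("schedule invariant violated: stimulus repeated within a run", call. = FALSE)
  cat_run <- table(e$category, e$run)
  if (length(unique(as.vector(cat_run))) != 1L)
    stop("schedule invariant violated: per-run category counts not uniform", call. = FALSE)
  for (r in unique(e$run)) {
    on <- e$onset[e$run == r]
    if (any(diff(on) <= 0))
      stop("schedule invariant violated: onsets not strictly increasing in run ",
           r, call. = FALSE)
    if (max(on) + schedule$trial_length_s > run_duration_seconds(schedule))
      stop("schedule invariant violated: trial extends past run end", call. = FALSE)
  }
  invisible(schedule)
}

#' Write a schedule as a BIDS-events-like TSV
#'
#' One row per task trial, columns `onset` (s, run clock including the leading
#' dummy trial), `duration` (s), `run`, `trial`, `stimulus_id`, `category`,
#' `subcategory`.
#' @param schedule a `stimulus_schedule`.
#' @param path output file path.
#' @export
write_events_tsv <- function(schedule, path) {
  e <- schedule$entries
  out <- data.frame(onset = e$onset, duration = schedule$trial_length_s,
                    run = e$run, trial = e$trial, stimulus_id = e$stimulus_id,
                    category = e$category, subcategory = e$subcategory)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a schedule events TSV written by [write_events_tsv()]
#' @param path TSV path.
#' @return data.frame of events.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
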
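#!/usr/bin/env Rscript
# Step 1 — experimental design and behavioral calibration.
#
# Builds the 72-snippet stimulus set (4 categories x 18; 11 subcategories,
# ten of 6 and linear search with 12), generates a balanced 6-run x 36-trial
# schedule, simulates the 30-subject cohort's behavior on the category task
# (scanner session) and the subcategory task (post session), and reports the
# expertise-performance correlations. Writes results/design/.

suppressPackageStartupMessages(library(decodelight))
outdir <- "results/design"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260922L

scheme <- category_scheme()
stimuli <- build_stimulus_set(scheme)
schedule <- make_schedule(stimuli, seed = derive_seed(seed, "schedule"))
validate_schedule(schedule)
write_events_tsv(schedule, file.path(outdir, "events.tsv"))

cat(sprintf("Stimulus set: %d snippets, %d categories, %d subcategories\n",
            nrow(stimuli), length(scheme$categories), length(scheme$subcategories)))
cat(sprintf("Schedule: %d runs x %d trials (+1 dummy), run duration %d s\n",
            schedule$n_runs, schedule$trials_per_run,
            run_duration_seconds(schedule)))
cat("Per-run category counts (should all be 9):\n")
print(table(schedule$entries$category, schedule$entries$run))

cohort <- sample_cohort(seed = derive_seed(seed, "cohort"))
write_cohort_tsv(cohort, file.path(outdir, "cohort.tsv"))

cat("\n-- category task (scanner session), chance 25% --\n")
cat_sum <- behavior_summary(cohort, schedule, task = "category",
                            seed = derive_seed(seed, "cat"))
cat(sprintf("mean accuracy %.1f%% (SD %.1f)\n",
            100 * mean(cat_sum$per_subject$performance),
            100 * sd(cat_sum$per_subject$performance)))
cat("rating vs performance (rate-holders only): "); print(cat_sum$vs_rating)
cat("rating vs performance (novices zero-rated): ")
print(behavior_summary(cohort, schedule, task = "category",
                       seed = derive_seed(seed, "cat"),
                       zero_rate_novices = TRUE)$vs_rating)

cat(sprintf("\n-- subcategory task (post session), chance %.1f%% --\n",
            100 * behavioral_chance(c(54, 18), c(3, 2))))
sub_sum <- behavior_summary(cohort, schedule, task = "subcategory",
                            seed = derive_seed(seed, "sub"))
cat(sprintf("mean accuracy %.1f%% (SD %.1f)\n",
            100 * mean(sub_sum$per_subject$performance),
            100 * sd(sub_sum$per_subject$performance)))
cat("rating vs performance (rate-holders only): "); print(sub_sum$vs_rating)

perf <- data.frame(cat_sum$per_subject,
                   performance_subcategory = sub_sum$per_subject$performance)
write_cohort_tsv(perf, file.path(outdir, "behavior_summary.tsv"))
cat("\nWrote", outdir, "\n")
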
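#!/usr/bin/env Rscript
# Step 5 — figures and null-distribution export for the recovery run.
#
# Reads the snapshot written by step 4 and renders orthogonal-slice PNGs of
# the group t-map, r-map and the three significance masks, plus the
# permutation null distributions behind the thresholds (the same engines that
# set the voxel and cluster FWE cutoffs). Writes results/figures/.

suppressPackageStartupMessages(library(decodelight))
snapshot <- "scratch/recovery_group.rds"
if (!file.exists(snapshot))
  stop("run analysis/04_group_inference.R first (missing ", snapshot, ")")
res <- readRDS(snapshot)
grp <- res$group
outdir <- "results/figures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

report_slices(replace(grp$t_map, is.na(grp$t_map), 0),
              file.path(outdir, "group_t_map.png"), "group t (accuracy > chance)")
report_slices(replace(grp$r_map, is.na(grp$r_map), 0),
              file.path(outdir, "group_r_map.png"), "accuracy-behavior r")
report_slices(grp$accuracy_mask * 1, file.path(outdir, "accuracy_mask.png"),
              "voxel-FWE accuracy mask")
report_slices(grp$correlation_mask * 1, file.path(outdir, "correlation_mask.png"),
              "cluster-FWE correlation mask")
report_slices(grp$conjunction_mask * 1, file.path(outdir, "conjunction_mask.png"),
              "conjunction")

# permutation null distributions (scatter-margin style summary)
y <- decodelight:::stack_maps(lapply(res$acc_maps, smooth_map, fwhm_mm = 6,
                                     voxel_mm = c(2, 2, 2), mask = res$centers),
                              res$centers)
vox <- voxel_fwe(y, null = res$chance, alpha = 0.05, n_perm = 1000L,
                 seed = derive_seed(20260922L, "report"))
grDevices::png(file.path(outdir, "null_distributions.png"), 700, 350)
op <- graphics::par(mfrow = c(1, 2))
graphics::hist(vox$max_dist, breaks = 30, main = "null max t (sign flips)",
               xlab = "max t", col = "grey80")
graphics::abline(v = vox$threshold, col = 2, lwd = 2)
graphics::hist(grp$t_map[res$centers], breaks = 30,
               main = "observed t over centers", xlab = "t", col = "grey80")
graphics::abline(v = grp$accuracy_threshold, col = 2, lwd = 2)
graphics::par(op); grDevices::dev.off()
cat("Wrote", outdir, "\n")
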
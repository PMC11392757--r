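#!/usr/bin/env Rscript
# Fab-Fab angle flexibility: stiff non-covalent Fab dimers versus hinged
# covalent ones.
#
# Two groups of synthetic 105 ns trajectories (frames every 1 ns) are
# generated with known per-frame angle distributions: "bifab"-like models
# whose Fab-Fab angle fluctuates tightly (SD 3-5 degrees around 130-155),
# and "fab2"-like models with a flexible hinge (SD 12-18 degrees around
# 110-160, echoing the wide angle preferences of hinged dimers). The
# windowed 20-100 ns SD and range are computed per model and the group SDs
# compared with a two-tailed t-test.

suppressPackageStartupMessages(library(fabflex))

out_dir <- "results/flexibility"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

stiff_means <- c(130, 145, 150, 155, 140)
stiff_sds <- c(3, 4, 5, 3.5, 4.5)
hinged_means <- c(110, 160, 135, 120, 150)
hinged_sds <- c(15, 12, 18, 14, 16)

gen <- function(mean, sd, seed) {
  make_angle_trajectory(mean, sd, n_frames = 106, dt_ns = 1, seed = seed,
                        n_res_light = 31, n_res_heavy = 33)
}
stiff <- Map(gen, stiff_means, stiff_sds, 300 + seq_along(stiff_means))
hinged <- Map(gen, hinged_means, hinged_sds, 400 + seq_along(hinged_means))

trajs <- c(lapply(stiff, `[[`, "trajectory"),
           lapply(hinged, `[[`, "trajectory"))
names(trajs) <- c(paste0("bifab_", seq_along(stiff)),
                  paste0("fab2_", seq_along(hinged)))

report <- run_flexibility(list(
  trajectories = trajs,
  fab1 = stiff[[1]]$fab1, fab2 = stiff[[1]]$fab2,
  window_ns = c(20, 100),
  groups = list(bifab = names(trajs)[1:5], fab2 = names(trajs)[6:10]),
  output_dir = out_dir
))

cat("Windowed (20-100 ns) Fab-Fab angle statistics per model:\n")
print(report$summaries, digits = 3)
cat(sprintf("\nGroup comparison of angle SDs (two-tailed t-test):\n"))
cat(sprintf("  mean SD bifab  = %.2f deg\n", report$t_test$mean_a))
cat(sprintf("  mean SD f(ab)2 = %.2f deg\n", report$t_test$mean_b))
cat(sprintf("  t = %.3f, p = %.4f\n", report$t_test$t, report$t_test$p))
cat(sprintf("\nTables written under %s\n", out_dir))
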
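#!/usr/bin/env Rscript
# Interface persistence and LIE stability of a Fab-Fab interface.
#
# A scripted contact trajectory emulates an interface that is loose early
# and locks in after 4 ns (per-window occupancies rising from 0.2 to 0.95);
# contact persistence uses the 2 A / 1 ns / at-least-half rule. Energy
# fixtures emulate a stably bound interface (negative LIE plateau) and one
# that dissociates (LIE drifting through zero), classified by the
# positive-tail-mean rule.

suppressPackageStartupMessages(library(fabflex))

out_dir <- "results/interface"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

schedule <- c(0.2, 0.3, 0.4, 0.45, 0.7, 0.9, 0.95, 0.95, 0.9, 0.95)
ct <- make_contact_trajectory(schedule, frames_per_window = 10)

stable <- make_energy_series("stable", n_frames = 105, seed = 5)
dis <- make_energy_series("dissociating", n_frames = 105, seed = 5)

rep_stable <- run_interface(list(
  trajectory = ct$trajectory, group_a = "A", group_b = "B",
  energies = stable$series, output_dir = out_dir
))

cat("Per-window probe-pair occupancy (2 A cutoff, 1 ns windows):\n")
print(rep_stable$contacts, digits = 3)
cat(sprintf("\nPersistent windows: %d of %d (interface locks in after %d ns)\n",
            sum(rep_stable$contacts$persistent), length(schedule),
            min(rep_stable$contacts$window[rep_stable$contacts$persistent]) - 1))
cat(sprintf("\nStable fixture verdict:       %s (tail-mean LIE %.1f kcal/mol)\n",
            rep_stable$verdict, rep_stable$tail_mean))

rep_dis <- run_interface(list(energies = dis$series))
cat(sprintf("Dissociating fixture verdict: %s (tail-mean LIE %+.1f kcal/mol)\n",
            rep_dis$verdict, rep_dis$tail_mean))

# LIE coefficient variants give the same verdicts on these fixtures
for (vdw in c(0.18, 0.15)) {
  es <- energy_series(dis$series$time_ns, dis$series$e_elec, dis$series$e_vdw,
                      coeffs = c(elec = 0.5, vdw = vdw))
  cat(sprintf("  vdW coefficient %.2f: dissociating fixture -> %s\n",
              vdw, classify_association(es)))
}
cat(sprintf("\nTables written under %s\n", out_dir))
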
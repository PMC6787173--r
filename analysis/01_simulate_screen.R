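#!/usr/bin/env Rscript
# Simulate the event-level raw data of a small two-plate screen and persist
# the layouts, a sample of event tables, and the per-well gated summaries.
# Downstream scripts work from these tables.

suppressPackageStartupMessages(library(phagoscreen))
dir.create("results", showWarnings = FALSE)

seed <- 20260920L
planted <- list(
  `miR-sim-0007` = effect_profile("miR-sim-0007", phago_effect = 0.5,
                                  bead_effect = 0.6),
  `miR-sim-0021` = effect_profile("miR-sim-0021", phago_effect = 1.6)
)

sim <- simulate_screen(50, effects = planted, seed = seed, n_events = 5000)
utils::write.csv(sim$layout, "results/screen_layout.csv", row.names = FALSE)

# event-level excerpts (first 500 events) of one NT well and one planted-hit
# well; the full tables are regenerated on demand from the seed
layout <- sim$layout
nt_key <- paste(layout$plate_id, layout$well, sep = "_")[layout$role == "NT"][1]
hit_key <- paste(layout$plate_id, layout$well,
                 sep = "_")[layout$treatment_id == "miR-sim-0007"][1]
write_event_table(utils::head(sim$wells[[nt_key]], 500),
                  "results/example_events_NT.csv")
write_event_table(utils::head(sim$wells[[hit_key]], 500),
                  "results/example_events_hit.csv")

summaries <- gate_screen(sim, gate_config())
utils::write.csv(summaries, "results/well_summaries_stage1.csv",
                 row.names = FALSE)

nt_rows <- summaries[summaries$role == "NT", ]
cat(sprintf(
  "Simulated %d wells on %d plates (seed %d).\n",
  nrow(summaries), length(unique(summaries$plate_id)), seed
))
cat(sprintf(
  "NT controls: %.1f%% viable, %.1f%% transfected, %.1f%% FITC+ (mean MFI %.0f).\n",
  mean(nt_rows$pct_viable), mean(nt_rows$pct_transfected),
  mean(nt_rows$pct_fitc_pos), mean(nt_rows$mfi_fitc)
))
cat(sprintf(
  "CytoD functional controls: %.1f%% FITC+ (phagocytosis blocked).\n",
  mean(summaries$pct_fitc_pos[summaries$role == "CytoD"])
))
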
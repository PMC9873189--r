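#!/usr/bin/env Rscript
# Step 1: generate the simulated iron-resupply experiment.
#
# Emulates the study design: seven treatments (high-iron, low-iron,
# iron-recovery, actD, actD-Fe, DMSO, DMSO-Fe), a 6-h short-term grid
# densely sampled in the first hour, a 22-h long-term grid, duplicate
# transcription-arrest arms, a 24-probe panel with a positive-control
# ladder, one housekeeping probe and four attenuated high-abundance
# probes. Writes counts.csv / meta.csv / probes.csv / titration.csv /
# truth.json under results/simulation/.

library(ferrodecay)

seed <- 17L
dir <- "results/simulation"

sim <- simulate_experiment(seed = seed)
write_simulation(sim, dir)

cat("Simulated experiment (seed", seed, "):\n")
print(sim$counts)
cat("attenuated probes:",
    paste(sim$counts$probes$probe_id[sim$counts$probes$attenuated],
          collapse = ", "), "\n")
cat("wrote", dir, "\n")
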
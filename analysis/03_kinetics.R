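#!/usr/bin/env Rscript
# Stage 3: the desorption-kinetics analysis. Calibrates the effective
# Boltzmann constant on the strongest-binding row of the published relative
# rate table, regenerates the full table under both constants profiles,
# computes enhancement-factor curves for +10 K and +30 K warm-ups, and works
# through the isomer-resolved desorption partition examples.
# Outputs: results/kinetics/*.csv and a printed narrative.

suppressPackageStartupMessages(library(carbsorb))

out_dir <- "results/kinetics"
cfg <- run_config(seed = 1L, out_dir = out_dir)
rep <- replica_mode(cfg)

pe <- constants_profile("paper_effective")
co <- constants_profile("codata")
cat(sprintf("calibrated effective kB = %.4e kcal/(mol K) (standard: %.4e; %.1f%% lower)\n",
            pe$kB, co$kB, (1 - pe$kB / co$kB) * 100))

parts <- rep$kinetics$partitions
cat("\nisomer-resolved desorption (delta_eps = 2.4 kcal/mol, 1:1 adsorbed):\n")
print(parts, row.names = FALSE)
for (nm in names(rep$kinetics$isomer_EF)) {
  ef <- rep$kinetics$isomer_EF[[nm]]
  cat(sprintf("  %s: EF_total %.2f, EF_cis %.2f, EF_trans %.2f\n",
              nm, ef$EF_total, ef$EF_cis, ef$EF_trans))
}

for (ea in c(7.2, 11, 16)) {
  cat(sprintf("Ea = %4.1f kcal/mol: +10 K raises the total rate %.0f%%, +30 K gives %.1f-fold\n",
              ea,
              (enhancement_factor(ea, 273.15, 283.15, co) - 1) * 100,
              enhancement_factor(ea, 273.15, 303.15, co)))
}

dev <- read.csv(file.path(out_dir, "codata_deviation.csv"))
cat(sprintf("\nstandard-constant rates sit below the published table everywhere (%.0f%% to %.0f%%)\n",
            min(dev$rel_dev) * 100, max(dev$rel_dev) * 100))
cat("wrote", paste(list.files(out_dir), collapse = ", "), "to", out_dir, "\n")
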
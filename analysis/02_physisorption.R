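#!/usr/bin/env Rscript
# Stage 2: sample adsorption poses of each MCHM isomer over the central patch
# of the amorphous slab, minimize them rigid-body against the rigid surface,
# retain the conformer-poses within the 7 kcal/mol window, and extract the
# isomer binding difference delta_eps = mean(trans) - mean(cis). Carves the
# 12 A hydrogen-capped cluster at each retained minimum and reports the
# parity-screen retention, mirroring the cluster-model workflow.
#
# ~40 poses per isomer on the full 5 x 5 x 3 nm slab; takes a few minutes.
# Outputs: results/physisorption_poses.csv, results/physisorption_summary.csv

suppressPackageStartupMessages(library(carbsorb))
dir.create("results", showWarnings = FALSE)

slab <- build_amorphous_slab(slab_spec(seed = 20140109))
params <- vdw_params("lj126")
n_poses <- 40

ens <- list()
rows <- list()
for (iso in c("cis", "trans")) {
  confs <- enumerate_mchm_conformers(iso, dihedral_grid_step = 120)
  poses <- sample_poses(slab, confs, n_poses, patch_fraction = 0.6,
                        seed = if (iso == "cis") 101L else 202L)
  res <- lapply(poses, function(p)
    minimize_pose(p, slab, params, cutoff = 12, max_iters = 300))
  kept <- filter_conformers(res, window = 7.0)
  cl_kept <- vapply(kept, function(r)
    !carve_cluster(slab, r$pose, radius = 12)$discarded, logical(1))
  cat(sprintf("%s: %d poses, %d within window, %d/%d clusters pass the parity screen\n",
              iso, length(res), length(kept), sum(cl_kept), length(kept)))
  ens[[iso]] <- kept
  rows[[iso]] <- data.frame(
    isomer = iso, pose = seq_along(res),
    conformer = vapply(res, function(r) r$pose$conformer_index, integer(1)),
    E_int = vapply(res, function(r) r$E_int, numeric(1)),
    E_phys = vapply(res, function(r) r$E_phys, numeric(1)),
    converged = vapply(res, function(r) r$converged, logical(1)))
}

summ <- isomer_binding_summary(ens$cis, ens$trans)
print(summ)
cat(sprintf("the trans isomer binds %.2f kcal/mol more strongly on this surrogate surface\n",
            summ$delta_eps))

write.csv(do.call(rbind, rows), "results/physisorption_poses.csv",
          row.names = FALSE)
write.csv(data.frame(isomer = c("cis", "trans"),
                     mean_E_phys = c(summ$cis$mean, summ$trans$mean),
                     sd = c(summ$cis$sd, summ$trans$sd),
                     n = c(summ$cis$n, summ$trans$n),
                     delta_eps = summ$delta_eps),
          "results/physisorption_summary.csv", row.names = FALSE)
cat("wrote results/physisorption_poses.csv and results/physisorption_summary.csv\n")
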
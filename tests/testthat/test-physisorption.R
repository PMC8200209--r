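test_that("pair potentials hit their analytic landmarks", {
  lj <- vdw_params("lj126")
  s_cc <- lj$size[["C"]]
  expect_equal(pair_vdw_energy(s_cc, "C", "C", lj), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pair_vdw_energy(2^(1 / 6) * s_cc, "C", "C", lj),
               -lj$eps[["C"]], tolerance = 1e-12, ignore_attr = TRUE)
  buf <- vdw_params("buffered147")
  expect_equal(pair_vdw_energy(buf$size[["C"]], "C", "C", buf),
               -buf$eps[["C"]], tolerance = 1e-12, ignore_attr = TRUE)
  # cross parameters are symmetric
  expect_equal(pair_vdw_energy(3.2, "C", "H", lj),
               pair_vdw_energy(3.2, "H", "C", lj), ignore_attr = TRUE)
  expect_error(pair_vdw_energy(3, "C", "Xx", lj), "unparameterized")
})

test_that("interaction energy obeys cutoff, single-pair and periodic limits", {
  slab <- tiny_slab()
  pose_far <- adsorption_pose(build_mchm("cis"),
                              c(slab$cell_a[1] / 2, slab$cell_b[2] / 2,
                                max(slab$geometry$xyz[, 3]) + 100))
  expect_equal(as.numeric(interaction_energy(pose_far, slab, cutoff = 10)), 0)

  # one C above one C at the pair-minimum distance -> exactly -eps_CC
  lj <- vdw_params("lj126")
  rmin <- 2^(1 / 6) * lj$size[["C"]]
  e <- interaction_energy(single_atom_pose(rmin), single_atom_surface(),
                          cutoff = 10)
  expect_equal(as.numeric(e), -lj$eps[["C"]], tolerance = 1e-12)

  # shifting the adsorbate by one full lattice vector leaves E unchanged
  cs <- cis_conformers()
  p0 <- sample_poses(slab, cs, 1, seed = 3)[[1]]
  p1 <- adsorption_pose(p0$conformer, p0$translation + slab$cell_a,
                        p0$quaternion)
  e0 <- as.numeric(interaction_energy(p0, slab, cutoff = 9))
  e1 <- as.numeric(interaction_energy(p1, slab, cutoff = 9))
  expect_equal(e1, e0, tolerance = 1e-12)

  expect_error(interaction_energy(p0, slab, cutoff = 50), "half")
})

test_that("the optional Coulomb term follows the fixed-charge law", {
  lj <- vdw_params("lj126")
  r <- 4.0
  probe <- adsorption_pose(molgeom("O", matrix(0, 1, 3),
                                   partial_charges = -0.4), c(0, 0, r))
  surf <- surface_slab(molgeom("H", matrix(0, 1, 3), partial_charges = 0.4),
                       c(50, 0, 0), c(0, 50, 0), periodic = FALSE)
  e_vdw <- as.numeric(interaction_energy(probe, surf, cutoff = 10, lj))
  e_all <- as.numeric(interaction_energy(probe, surf, cutoff = 10, lj,
                                         electrostatics = TRUE))
  expect_equal(e_all - e_vdw, 332.06 * (-0.4) * 0.4 / r, tolerance = 1e-10)
  # vdW-only is the default; asking for charges that are absent errors
  expect_error(interaction_energy(single_atom_pose(4), surf, cutoff = 10, lj,
                                  electrostatics = TRUE), "charges")
})

test_that("interaction energy is invariant under joint rigid transformation", {
  surf <- as_cluster_surface(build_pah_flake(2, 2))
  pose <- adsorption_pose(build_mchm("trans"), c(0, 0, 4.5))
  e0 <- as.numeric(interaction_energy(pose, surf, cutoff = 12))
  set.seed(5)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  shift <- rnorm(3, sd = 10)
  rot_g <- function(g) adsorption_pose(g, center_of_mass(g), q)$geometry
  move <- function(g) molgeom(g$elements, sweep(rot_g(g)$xyz, 2, shift, `+`))
  # rotate both about their own centers consistently: rotate the combined
  # system about the origin instead
  R <- with(list(q = q), {
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
  xf <- function(g) molgeom(g$elements, sweep(g$xyz %*% t(R), 2, shift, `+`))
  e1 <- as.numeric(interaction_energy(xf(pose$geometry),
                                      as_cluster_surface(xf(surf$geometry)),
                                      cutoff = 12))
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("pose sampling is deterministic, patch-bounded and inclusive", {
  slab <- tiny_slab()
  cs <- cis_conformers()
  a <- sample_poses(slab, cs, 6, patch_fraction = 0.5, seed = 21)
  b <- sample_poses(slab, cs, 6, patch_fraction = 0.5, seed = 21)
  expect_identical(lapply(a, `[[`, "translation"),
                   lapply(b, `[[`, "translation"))
  ax <- slab$cell_a[1]; by <- slab$cell_b[2]
  for (p in a) {
    expect_gte(p$translation[1], 0.25 * ax); expect_lte(p$translation[1], 0.75 * ax)
    expect_gte(p$translation[2], 0.25 * by); expect_lte(p$translation[2], 0.75 * by)
    expect_gt(p$translation[3], max(slab$geometry$xyz[, 3]))
    expect_equal(sqrt(sum(p$quaternion^2)), 1, tolerance = 1e-9)
  }
  # the lowest-strain conformers are always in the sample
  n3 <- sample_poses(slab, cs, 3, seed = 1)
  expect_identical(sort(vapply(n3, `[[`, integer(1), "conformer_index")), 1:3)
})

test_that("rigid minimization descends to the analytic pair minimum", {
  lj <- vdw_params("lj126")
  rmin_analytic <- 2^(1 / 6) * lj$size[["C"]]
  # independent oracle: brute-force 1-D scan over height
  hs <- seq(3, 6, by = 1e-4)
  es <- pair_vdw_energy(hs, "C", "C", lj)
  h_oracle <- hs[which.min(es)]
  expect_equal(h_oracle, rmin_analytic, tolerance = 1e-3)

  r <- minimize_pose(single_atom_pose(5), single_atom_surface(),
                     step_tol = 1e-4)
  expect_true(r$converged)
  # the minimum manifold is the sphere at the pair-minimum separation
  expect_equal(sqrt(sum(r$pose$translation^2)), h_oracle, tolerance = 5e-3)
  expect_equal(r$E_int, -lj$eps[["C"]], tolerance = 1e-6)
  expect_identical(r$E_phys, -r$E_int)
})

test_that("minimization traces are non-increasing and idempotent at minima", {
  slab <- tiny_slab()
  poses <- sample_poses(slab, cis_conformers(), 2, seed = 13)
  for (p in poses) {
    r <- minimize_pose(p, slab, max_iters = 200)
    expect_true(all(diff(r$trace) <= 0))
    expect_lte(r$E_int, as.numeric(interaction_energy(p, slab)))
    r2 <- minimize_pose(r$pose, slab, max_iters = 200)
    expect_equal(r2$E_int, r$E_int, tolerance = 1e-4)
    expect_lt(sqrt(sum((r2$pose$translation - r$pose$translation)^2)), 0.1)
  }
})

test_that("conformer filtering keeps the in-window set independent of order", {
  e <- c(0, 3.0, 7.1)
  expect_identical(filter_conformers(e, 7.0), c(0, 3.0))
  expect_identical(filter_conformers(e, Inf), e)
  expect_identical(filter_conformers(c(2, 2, 2), 7.0), c(2, 2, 2))
  set.seed(8)
  e2 <- rnorm(20, sd = 5)
  perm <- sample(20)
  expect_identical(sort(filter_conformers(e2, 4)),
                   sort(filter_conformers(e2[perm], 4)))
})

test_that("conformer-referenced potential has the stated limits and gauge", {
  # rigid-adsorbate cancellation: reduces to -E_int
  expect_equal(conformer_referenced_potential(-6.2 + 10 + 3, 10, rep(3, 5)),
               6.2)
  expect_equal(conformer_referenced_potential(-6.2, 0, rep(0, 5)), 6.2)
  # gauge invariance: shifting all conformer energies and the complex energy
  # by the same constant leaves the result unchanged
  base <- conformer_referenced_potential(-4, 1, c(0, 0.5, 1, 2, 3, 9))
  expect_equal(conformer_referenced_potential(-4 + 7, 1, c(0, 0.5, 1, 2, 3, 9) + 7),
               base)
  # only the five lowest conformers enter the reference mean
  expect_equal(conformer_referenced_potential(0, 0, c(0, 0, 0, 0, 0, 100)), 0)
})

test_that("isomer binding summaries report the trans-minus-cis difference", {
  s <- isomer_binding_summary(c(7.0, 7.4), c(8.3, 8.7))
  expect_equal(s$delta_eps, 1.3, tolerance = 1e-12)
  expect_equal(isomer_binding_summary(c(1, 2, 3), c(1, 2, 3))$delta_eps, 0)
  s2 <- isomer_binding_summary(c(18.6 - 1, 18.6 + 1), c(23.2 - 1, 23.2 + 1))
  expect_equal(s2$delta_eps, 4.6, tolerance = 1e-12)
  expect_equal(s2$cis$n, 2L)
})

test_that("cluster carving caps, screens and converges to the slab energy", {
  slab <- tiny_slab()
  cs <- cis_conformers()
  pose <- sample_poses(slab, cs, 1, seed = 31)[[1]]

  # radius beyond the slab diagonal: everything retained, nothing to cap
  big <- carve_cluster(slab, pose, radius = 500)
  expect_equal(big$n_retained, n_atoms(slab$geometry))
  expect_equal(big$n_caps, 0L)

  # exact agreement with the full slab once the carve radius covers the
  # cutoff around a point adsorbate (caps then fall beyond the cutoff)
  cutoff <- 6
  p1 <- adsorption_pose(molgeom("C", matrix(0, 1, 3)),
                        c(slab$cell_a[1] / 2, slab$cell_b[2] / 2,
                          max(slab$geometry$xyz[, 3]) + 3.2))
  e_slab <- as.numeric(interaction_energy(p1, slab, cutoff = cutoff))
  cl <- carve_cluster(slab, p1, radius = cutoff + 2.5, screen = FALSE)
  e_cl <- as.numeric(interaction_energy(p1, as_cluster_surface(cl$geometry),
                                        cutoff = cutoff))
  expect_equal(e_cl, e_slab, tolerance = 1e-10)

  # monotone convergence of the absolute error as the radius grows (the
  # parity screen is switched off: it is orthogonal to convergence);
  # radii anchored at the closest surface atom so every cluster is nonempty
  d_near <- min(sqrt(rowSums(
    sweep(slab$geometry$xyz, 2, p1$translation)^2)))
  errs <- sapply(d_near + c(0.8, 2.5, 4.5, 6.5), function(rad) {
    ge <- carve_cluster(slab, p1, radius = rad, screen = FALSE)$geometry
    abs(as.numeric(interaction_energy(p1, as_cluster_surface(ge),
                                      cutoff = cutoff)) - e_slab)
  })
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("parity screening discards odd-electron clusters", {
  # a linear C3 chain "slab": carving the middle atom breaks two C-C bonds,
  # giving C1H2 (even); carving two atoms gives C2H1 with 13 electrons (odd)
  chain <- surface_slab(
    molgeom(c("C", "C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0))),
    cell_a = c(50, 0, 0), cell_b = c(0, 50, 0), periodic = FALSE)
  probe <- adsorption_pose(molgeom("C", matrix(0, 1, 3)), c(1.5, 0, 3))
  even_cl <- carve_cluster(chain, probe, radius = sqrt(1.5^2 + 3^2) - 0.2)
  expect_false(even_cl$discarded)
  expect_identical(electron_parity(even_cl$geometry), "even")
  probe2 <- adsorption_pose(molgeom("C", matrix(0, 1, 3)), c(0.75, 0, 2))
  odd_cl <- carve_cluster(chain, probe2,
                          radius = sqrt(2.25^2 + 2^2) - 0.2)
  expect_true(odd_cl$discarded)
  expect_identical(odd_cl$reason, "odd electron count")
})

test_that("default-scale carve retains on the order of hundreds of atoms", {
  slab <- paper_slab()
  pose <- sample_poses(slab, cis_conformers(), 1, seed = 5)[[1]]
  r <- minimize_pose(pose, slab, max_iters = 250)
  cl <- carve_cluster(slab, r$pose, radius = 12)
  expect_gte(cl$n_retained, 100)
  expect_lte(cl$n_retained, 1200)
})
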
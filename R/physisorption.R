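# Pairwise van-der-Waals physisorption engine: pose sampling above a surface,
# rigid-body minimization, conformational filtering/averaging, isomer
# binding-difference extraction, and hydrogen-capped cluster carving.
#
# Energies are vdW-only by design: the physisorption potential of interest is
# the intermolecular dispersion/repulsion well between the adsorbate and the
# carbon surface. E_phys = -E_int, positive = stronger binding (the reporting
# convention used throughout).

# UFF nonbonded parameters (Rappe et al. 1992): well depth (kcal/mol) and the
# position of the pair minimum x* (A) for like pairs.
.uff <- data.frame(
  element = c("H", "C", "N", "O"),
  eps     = c(0.044, 0.105, 0.069, 0.060),
  xstar   = c(2.886, 3.851, 3.660, 3.500),
  stringsAsFactors = FALSE
)

#' Van der Waals parameter set
#'
#' Element-wise UFF well depths and size parameters with two selectable
#' functional forms: the 12-6 Lennard-Jones potential (size parameter sigma,
#' the zero crossing) and the buffered-14-7 potential (size parameter r*, the
#' pair-minimum position). Cross parameters use a geometric mean on the well
#' depth and an arithmetic mean on the size (both symmetric).
#'
#' @param form `"lj126"` or `"buffered147"`.
#' @return An object of class `vdw_params`.
#' @export
vdw_params <- function(form = c("lj126", "buffered147")) {
  form <- match.arg(form)
  size <- if (form == "lj126") .uff$xstar / 2^(1 / 6) else .uff$xstar
  structure(list(form = form, elements = .uff$element,
                 eps = stats::setNames(.uff$eps, .uff$element),
                 size = stats::setNames(size, .uff$element),
                 combination = "geometric-eps/arithmetic-size"),
            class = "vdw_params")
}

#' Pairwise van der Waals energy
#'
#' @param r Distance(s), angstrom; must be positive.
#' @param element_i,element_j Element symbols (recycled against `r`).
#' @param params A [vdw_params()].
#' @return Energy in kcal/mol (negative = attractive).
#' @export
pair_vdw_energy <- function(r, element_i, element_j, params = vdw_params()) {
  stopifnot(inherits(params, "vdw_params"))
  if (any(r <= 0)) stop("pair distance must be positive")
  if (!all(c(element_i, element_j) %in% params$elements))
    stop("unparameterized element")
  eps <- sqrt(params$eps[element_i] * params$eps[element_j])
  s <- (params$size[element_i] + params$size[element_j]) / 2
  if (params$form == "lj126") {
    sr6 <- (s / r)^6
    4 * eps * (sr6^2 - sr6)
  } else {
    # buffered 14-7 (MMFF form); minimum of exactly -eps at r = r*
    rho <- r / s
    eps * (1.07 / (rho + 0.07))^7 * (1.12 / (rho^7 + 0.12) - 2)
  }
}

## ---- poses ---------------------------------------------------------------

.quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

.quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

.axis_angle_quat <- function(axis, angle) {
  c(cos(angle / 2), sin(angle / 2) * .unit(axis))
}

#' Construct an adsorption pose
#'
#' A rigid transform of an adsorbate conformer: rotate about the conformer's
#' center of mass by a unit quaternion, then translate the center of mass to
#' `translation`.
#'
#' @param conformer A `molgeom` (the adsorbate conformer, untransformed).
#' @param translation Length-3 target center-of-mass position (angstrom).
#' @param quaternion Length-4 unit quaternion (w, x, y, z).
#' @param conformer_index Optional bookkeeping index into a conformer set.
#' @return An object of class `adsorption_pose` with the posed geometry in
#'   `$geometry`.
#' @export
adsorption_pose <- function(conformer, translation, quaternion = c(1, 0, 0, 0),
                            conformer_index = NA_integer_) {
  stopifnot(inherits(conformer, "molgeom"), length(translation) == 3,
            length(quaternion) == 4)
  nq <- sqrt(sum(quaternion^2))
  if (abs(nq - 1) > 1e-9) quaternion <- quaternion / nq
  com <- center_of_mass(conformer)
  R <- .quat_to_mat(quaternion)
  xyz <- sweep(conformer$xyz, 2, com) %*% t(R)
  xyz <- sweep(xyz, 2, as.numeric(translation), `+`)
  structure(list(conformer = conformer, conformer_index = conformer_index,
                 translation = as.numeric(translation),
                 quaternion = quaternion,
                 geometry = molgeom(conformer$elements, xyz,
                                    bonds = conformer$bonds,
                                    partial_charges = conformer$partial_charges,
                                    name = conformer$name)),
            class = "adsorption_pose")
}

.pose_geom <- function(pose) {
  if (inherits(pose, "adsorption_pose")) pose$geometry
  else if (inherits(pose, "molgeom")) pose
  else stop("pose must be an adsorption_pose or molgeom")
}

# displacement components of surface atoms relative to a point, minimum-image
# in-plane when the slab is periodic
.surf_disp <- function(surface, point) {
  sx <- surface$geometry$xyz
  dx <- sx[, 1] - point[1]; dy <- sx[, 2] - point[2]; dz <- sx[, 3] - point[3]
  if (isTRUE(surface$periodic)) {
    a <- surface$cell_a; b <- surface$cell_b
    if (abs(a[2]) > 1e-9 || abs(b[1]) > 1e-9) {
      A <- cbind(a[1:2], b[1:2])
      f <- solve(A, rbind(dx, dy))
      f <- f - round(f)
      dxy <- A %*% f
      dx <- dxy[1, ]; dy <- dxy[2, ]
    } else {
      dx <- dx - a[1] * round(dx / a[1])
      dy <- dy - b[2] * round(dy / b[2])
    }
  }
  cbind(dx, dy, dz)
}

#' Adsorbate-surface interaction energy
#'
#' Sum of pairwise van der Waals energies over all adsorbate-surface atom
#' pairs within the cutoff, using the minimum-image convention in the two
#' periodic in-plane directions. Intramolecular pairs are excluded by
#' construction. Overlapping poses (any pair closer than 0.5 A) are flagged
#' via the `"overlap"` attribute but the energy is still returned.
#'
#' @param pose An `adsorption_pose` or a posed `molgeom`.
#' @param surface A `surface_slab`.
#' @param cutoff Pair cutoff, angstrom; for a periodic slab it must not
#'   exceed half the shortest in-plane cell length.
#' @param params A [vdw_params()].
#' @param electrostatics Add a fixed-charge Coulomb term from the
#'   geometries' `partial_charges` (default FALSE: the physisorption
#'   potential is vdW-only).
#' @return Energy in kcal/mol with attribute `overlap`.
#' @export
interaction_energy <- function(pose, surface, cutoff = 12,
                               params = vdw_params(),
                               electrostatics = FALSE) {
  g <- .pose_geom(pose)
  stopifnot(inherits(surface, "surface_slab"))
  if (isTRUE(surface$periodic)) {
    amin <- min(sqrt(sum(surface$cell_a^2)), sqrt(sum(surface$cell_b^2)))
    if (cutoff > amin / 2 + 1e-9)
      stop("cutoff exceeds half the shortest in-plane cell length")
  }
  sel <- surface$geometry$elements
  qa <- g$partial_charges
  qs <- surface$geometry$partial_charges
  if (electrostatics && (is.null(qa) || is.null(qs)))
    stop("electrostatics requested but partial charges are not set")
  e <- 0
  overlap <- FALSE
  for (k in seq_len(n_atoms(g))) {
    dsp <- .surf_disp(surface, g$xyz[k, ])
    dd <- sqrt(rowSums(dsp^2))
    inr <- which(dd <= cutoff)
    if (!length(inr)) next
    if (any(dd[inr] < 0.5)) overlap <- TRUE
    r <- pmax(dd[inr], 1e-3)
    e <- e + sum(pair_vdw_energy(r, g$elements[k], sel[inr], params))
    if (electrostatics)   # 332.06: Coulomb constant, kcal A / (mol e^2)
      e <- e + sum(332.06 * qa[k] * qs[inr] / r)
  }
  attr(e, "overlap") <- overlap
  e
}

#' Sample random adsorption poses above a surface
#'
#' Lateral positions are uniform over the central patch of the in-plane cell
#' (a `patch_fraction` of each lattice vector, centered), orientations are
#' uniform over rotations, and the initial height is uniform in
#' `height_range` above the highest surface atom. The lowest-strain
#' conformers (up to three) are guaranteed membership in the sample: pose
#' `k` uses conformer `k` for `k <= 3`, mirroring the deliberate inclusion
#' of the lowest-energy conformers in the sampled set.
#'
#' @param surface A `surface_slab`.
#' @param conformers A `conformer_set` (sorted by strain).
#' @param n_poses Number of poses, at least 1.
#' @param patch_fraction Fraction of each in-plane cell dimension sampled,
#'   in (0, 1]; the default 0.6 corresponds to the central ~3 x 3 nm patch
#'   of a 5 x 5 nm slab.
#' @param height_range Initial center-of-mass height window above the highest
#'   surface atom, angstrom.
#' @param seed Integer RNG seed.
#' @return List of `adsorption_pose` objects.
#' @export
sample_poses <- function(surface, conformers, n_poses, patch_fraction = 0.6,
                         height_range = c(2.5, 5), seed = 1L) {
  stopifnot(inherits(surface, "surface_slab"),
            inherits(conformers, "conformer_set"))
  if (length(conformers$geometries) == 0) stop("empty conformer set")
  if (n_poses < 1) stop("n_poses must be at least 1")
  if (patch_fraction <= 0 || patch_fraction > 1)
    stop("patch_fraction must be in (0, 1]")
  ncf <- length(conformers$geometries)
  zmax <- max(surface$geometry$xyz[, 3])
  .with_seed(seed, {
    idx <- c(seq_len(min(3, ncf, n_poses)),
             if (n_poses > min(3, ncf))
               sample.int(ncf, n_poses - min(3, ncf), replace = TRUE))
    lapply(seq_len(n_poses), function(k) {
      fa <- 0.5 + (stats::runif(1) - 0.5) * patch_fraction
      fb <- 0.5 + (stats::runif(1) - 0.5) * patch_fraction
      lat <- fa * surface$cell_a + fb * surface$cell_b
      h <- zmax + stats::runif(1, height_range[1], height_range[2])
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      adsorption_pose(conformers$geometries[[idx[k]]],
                      translation = c(lat[1], lat[2], h),
                      quaternion = q, conformer_index = idx[k])
    })
  })
}

## ---- rigid-body minimization ---------------------------------------------

#' Rigid-body minimization of a pose on a rigid surface
#'
#' Derivative-free pattern search over the six rigid degrees of freedom
#' (translation plus rotation about the adsorbate center of mass) with a
#' shrinking step. The energy trace is non-increasing by construction; the
#' result is flagged converged when both the step sizes and the energy change
#' fall below tolerance before `max_iters`.
#'
#' @param pose An `adsorption_pose`.
#' @param surface A `surface_slab`.
#' @param params A [vdw_params()].
#' @param cutoff Pair cutoff, angstrom.
#' @param step_tol Translation step tolerance, angstrom (the rotation
#'   tolerance is the same number in radians).
#' @param energy_tol Energy-change tolerance, kcal/mol.
#' @param max_iters Iteration cap.
#' @return An object of class `physisorption_result`: the minimized pose,
#'   `E_int`, `E_phys = -E_int`, `converged`, and the energy `trace`.
#' @export
minimize_pose <- function(pose, surface, params = vdw_params(), cutoff = 12,
                          step_tol = 1e-3, energy_tol = 1e-6,
                          max_iters = 2000) {
  stopifnot(inherits(pose, "adsorption_pose"), inherits(surface, "surface_slab"))
  # restrict the surface to atoms reachable from the starting position: the
  # pose moves at most a few angstroms during descent
  g0 <- pose$geometry
  com0 <- center_of_mass(g0)
  span <- max(sqrt(rowSums(sweep(g0$xyz, 2, com0)^2)))
  reach <- cutoff + span + 8
  dd <- sqrt(rowSums(.surf_disp(surface, com0)^2))
  keep <- which(dd <= reach)
  local_surface <- surface
  local_surface$geometry <- molgeom(surface$geometry$elements[keep],
                                    surface$geometry$xyz[keep, , drop = FALSE])
  # keep periodicity flags/cell: minimum image still applies to the subset
  tr <- pose$translation
  qq <- pose$quaternion
  conf <- pose$conformer
  energy_at <- function(tr, qq) {
    p <- adsorption_pose(conf, tr, qq, pose$conformer_index)
    as.numeric(interaction_energy(p, local_surface, cutoff, params))
  }
  e <- energy_at(tr, qq)
  if (!is.finite(e)) stop("non-finite interaction energy at starting pose")
  trace <- e
  step_t <- 0.4
  step_r <- 0.15
  axes <- diag(3)
  iters <- 0
  converged <- FALSE
  while (iters < max_iters) {
    iters <- iters + 1
    best_e <- e; best_tr <- tr; best_qq <- qq
    for (dim in 1:3) {
      for (sgn in c(-1, 1)) {
        cand <- tr; cand[dim] <- cand[dim] + sgn * step_t
        ec <- energy_at(cand, qq)
        if (is.finite(ec) && ec < best_e) {
          best_e <- ec; best_tr <- cand; best_qq <- qq
        }
        qc <- .quat_mult(.axis_angle_quat(axes[dim, ], sgn * step_r), qq)
        ec <- energy_at(tr, qc)
        if (is.finite(ec) && ec < best_e) {
          best_e <- ec; best_tr <- tr; best_qq <- qc
        }
      }
    }
    if (best_e < e - 1e-15) {
      de <- e - best_e
      e <- best_e; tr <- best_tr; qq <- best_qq
      trace <- c(trace, e)
      if (de < energy_tol && step_t < step_tol && step_r < step_tol) {
        converged <- TRUE
        break
      }
    } else {
      if (step_t < step_tol && step_r < step_tol) {
        converged <- TRUE
        break
      }
      step_t <- step_t / 2
      step_r <- step_r / 2
    }
  }
  final <- adsorption_pose(conf, tr, qq, pose$conformer_index)
  e_full <- as.numeric(interaction_energy(final, surface, cutoff, params))
  structure(list(pose = final, E_int = e_full, E_phys = -e_full,
                 converged = converged, iterations = iters, trace = trace),
            class = "physisorption_result")
}

#' @export
print.physisorption_result <- function(x, ...) {
  cat(sprintf("<physisorption_result> E_int = %.4f kcal/mol (E_phys = %.4f), %s after %d iterations\n",
              x$E_int, x$E_phys,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

## ---- filtering / referencing / summaries ----------------------------------

#' Retain results within an energy window of the minimum
#'
#' Keeps entries whose energy lies within `window` of the lowest energy in
#' the set (the conformer-retention rule; default window 7.0 kcal/mol). The
#' retained set is independent of input order.
#'
#' @param results A list of `physisorption_result` objects, or a numeric
#'   vector of energies.
#' @param window Retention window, kcal/mol.
#' @return The retained subset, same type as the input.
#' @export
filter_conformers <- function(results, window = 7.0) {
  if (length(results) == 0) stop("nonempty results required")
  e <- if (is.numeric(results)) results
       else vapply(results, function(r) r$E_int, numeric(1))
  keep <- e - min(e) <= window
  if (is.numeric(results)) results[keep] else results[keep]
}

#' Conformer-referenced apparent physisorption potential
#'
#' References the complex energy against the lone surface and the mean of the
#' five lowest adsorbate conformer energies:
#' `E_phys = -(E_complex - E_surface - mean(five lowest conformer energies))`.
#' With fewer than five conformer energies all of them are used.
#'
#' @param complex_energy Energy of the adsorbate-surface complex, kcal/mol.
#' @param surface_energy Energy of the lone surface, kcal/mol.
#' @param conformer_energies Energies of the lone adsorbate conformers.
#' @param n_lowest How many lowest conformer energies enter the reference
#'   mean (default 5); ties broken by stable sort on energy then index.
#' @return Apparent physisorption potential, kcal/mol (positive = bound).
#' @export
conformer_referenced_potential <- function(complex_energy, surface_energy,
                                           conformer_energies, n_lowest = 5) {
  stopifnot(length(conformer_energies) >= 1)
  ord <- order(conformer_energies, seq_along(conformer_energies))
  sel <- ord[seq_len(min(n_lowest, length(conformer_energies)))]
  -(complex_energy - surface_energy - mean(conformer_energies[sel]))
}

#' Summarize isomer binding ensembles
#'
#' Per-isomer mean, sample standard deviation and count of the physisorption
#' potentials, plus the isomer binding difference
#' `delta_eps = mean(trans) - mean(cis)` in kcal/mol.
#'
#' @param cis_results,trans_results Lists of `physisorption_result` objects
#'   or numeric vectors of `E_phys` values.
#' @return An object of class `isomer_binding_summary`.
#' @export
isomer_binding_summary <- function(cis_results, trans_results) {
  ext <- function(x) if (is.numeric(x)) x
    else vapply(x, function(r) r$E_phys, numeric(1))
  ec <- ext(cis_results); et <- ext(trans_results)
  if (!length(ec) || !length(et)) stop("both isomer ensembles must be nonempty")
  structure(list(
    cis = list(mean = mean(ec), sd = stats::sd(ec), n = length(ec)),
    trans = list(mean = mean(et), sd = stats::sd(et), n = length(et)),
    delta_eps = mean(et) - mean(ec)
  ), class = "isomer_binding_summary")
}

#' @export
print.isomer_binding_summary <- function(x, ...) {
  cat(sprintf("<isomer_binding_summary>\n  cis:   M = %.2f, SD = %.2f, n = %d\n  trans: M = %.2f, SD = %.2f, n = %d\n  delta_eps (trans - cis) = %.2f kcal/mol\n",
              x$cis$mean, x$cis$sd, x$cis$n,
              x$trans$mean, x$trans$sd, x$trans$n, x$delta_eps))
  invisible(x)
}

## ---- cluster carving -------------------------------------------------------

#' Carve a hydrogen-capped cluster around an adsorption site
#'
#' Retains all surface atoms within `radius` of the adsorbate center of mass
#' (minimum-image; retained atoms are unwrapped to the image nearest the
#' center). Every C-C bond broken by the cut is capped with hydrogen at
#' 1.09 A along the former bond direction. Clusters whose electron count is
#' odd (a non-singlet stand-in) or whose net formal charge is nonzero are
#' signalled as discarded rather than returned.
#'
#' @param surface A `surface_slab`.
#' @param pose An `adsorption_pose` (or posed `molgeom`) above the surface.
#' @param radius Carve radius, angstrom (default 12).
#' @param screen Apply the electron-parity/charge screen (default TRUE).
#'   With `screen = FALSE` the capped cluster is always returned, e.g. for
#'   convergence studies where the screen is irrelevant.
#' @return A list with `geometry` (the capped cluster as a non-periodic
#'   `molgeom`, or NULL), `discarded` flag, `reason`, `n_caps`, and
#'   `n_retained`.
#' @export
carve_cluster <- function(surface, pose, radius = 12, screen = TRUE) {
  stopifnot(inherits(surface, "surface_slab"), radius > 0)
  com <- center_of_mass(.pose_geom(pose))
  dsp <- .surf_disp(surface, com)
  dd <- sqrt(rowSums(dsp^2))
  inside <- which(dd <= radius)
  if (!length(inside))
    return(list(geometry = NULL, discarded = TRUE, reason = "empty cluster",
                n_caps = 0L, n_retained = 0L))
  cell <- if (isTRUE(surface$periodic))
    list(a = surface$cell_a, b = surface$cell_b) else NULL
  # the slab generator stores its connectivity; recompute only if absent
  bonds <- if (!is.null(surface$geometry$bonds)) surface$geometry$bonds
           else infer_bonds(surface$geometry, cell = cell)
  # unwrapped coordinates relative to the center of mass
  unwrapped <- sweep(dsp, 2, com, `+`)
  el <- surface$geometry$elements
  inset <- logical(length(el)); inset[inside] <- TRUE
  keep_xyz <- unwrapped[inside, , drop = FALSE]
  keep_el <- el[inside]
  newidx <- integer(length(el)); newidx[inside] <- seq_along(inside)
  kept_bonds <- bonds[inset[bonds[, 1]] & inset[bonds[, 2]], , drop = FALSE]
  caps <- list()
  broken <- bonds[xor(inset[bonds[, 1]], inset[bonds[, 2]]), , drop = FALSE]
  for (q in seq_len(nrow(broken))) {
    i <- broken[q, 1]; j <- broken[q, 2]
    if (!inset[i]) { tmp <- i; i <- j; j <- tmp }
    if (el[i] != "C" || el[j] != "C") next   # only C-C cuts are capped
    dv <- .surf_disp(surface, unwrapped[i, ])[j, ]
    caps[[length(caps) + 1]] <- list(pos = unwrapped[i, ] + 1.09 * .unit(dv),
                                     to = newidx[i])
  }
  nin <- length(inside); nh <- length(caps)
  all_el <- c(keep_el, rep("H", nh))
  all_xyz <- rbind(keep_xyz,
                   if (nh) do.call(rbind, lapply(caps, `[[`, "pos")))
  cb <- cbind(newidx[kept_bonds[, 1]], newidx[kept_bonds[, 2]])
  hb <- if (nh) cbind(vapply(caps, `[[`, integer(1), "to"), nin + seq_len(nh))
  g <- molgeom(all_el, all_xyz, bonds = rbind(cb, hb),
               net_charge = 0L, name = "carved_cluster")
  if (screen && electron_parity(g) == "odd")
    return(list(geometry = NULL, discarded = TRUE,
                reason = "odd electron count", n_caps = nh, n_retained = nin))
  list(geometry = g, discarded = FALSE, reason = NA_character_,
       n_caps = nh, n_retained = nin)
}

#' Treat a carved cluster (or any geometry) as a non-periodic surface
#'
#' Convenience wrapper so [interaction_energy()] can be evaluated against a
#' carved cluster with open boundaries.
#'
#' @param geometry A `molgeom`.
#' @return A non-periodic `surface_slab`.
#' @export
as_cluster_surface <- function(geometry) {
  surface_slab(geometry, cell_a = c(1, 0, 0), cell_b = c(0, 1, 0),
               periodic = FALSE)
}
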
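# Synthetic structure generators: planar PAH flakes, chair MCHM conformers,
# and a procedural hydrogen-capped amorphous-carbon slab. Everything is a pure
# function of its arguments (seed included) so the downstream physisorption
# and kinetics stages are testable without any external download.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.unit <- function(v) v / sqrt(sum(v^2))
.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

## ---- planar PAH flake ----------------------------------------------------

#' Build a planar fused-ring PAH flake
#'
#' Generates a hexagonally fused all-carbon flake in the z = 0 plane with
#' aromatic C-C bonds of 1.42 A and perimeter hydrogens at 1.09 A. The flake
#' is built from `rows` rows of fused hexagons whose lengths grow towards the
#' middle row (`cols`, `cols + 1`, ..., mirrored), so `build_pah_flake(1, 1)`
#' is benzene and `build_pah_flake(3, 3)` is the ovalene-like C32 flake
#' (rings arranged 3-4-3) used as the idealized planar carbon surface.
#' Printed hydrogen counts for ovalene vary in the literature (14 vs 16);
#' this generator guarantees the 32-carbon ring system with chemically
#' consistent perimeter capping, which yields 14 hydrogens.
#'
#' @param rows,cols Positive integers; number of hexagon rows and the length
#'   of the outermost row.
#' @return A `molgeom` with bonds set.
#' @export
build_pah_flake <- function(rows = 3, cols = 3) {
  stopifnot(rows >= 1, cols >= 1)
  d <- 1.42
  w <- sqrt(3) * d
  nrow_i <- cols + pmin(seq_len(rows) - 1, rows - seq_len(rows))
  # cumulative half-shift keeps equal-length adjacent rows edge-sharing
  shift <- numeric(rows)
  for (i in seq_len(rows)[-1])
    shift[i] <- shift[i - 1] + if (nrow_i[i] == nrow_i[i - 1]) w / 2 else 0
  centers <- do.call(rbind, lapply(seq_len(rows), function(i) {
    k <- seq_len(nrow_i[i]) - 1
    cbind((k - (nrow_i[i] - 1) / 2) * w + shift[i], (i - 1) * 1.5 * d)
  }))
  # hexagon vertices around each ring center, deduplicated on a fine grid
  ang <- (30 + 60 * (0:5)) * pi / 180
  vx <- as.vector(outer(centers[, 1], d * cos(ang), `+`))
  vy <- as.vector(outer(centers[, 2], d * sin(ang), `+`))
  key <- paste(round(vx / 1e-3), round(vy / 1e-3))
  keep <- !duplicated(key)
  cxy <- cbind(vx[keep], vy[keep])
  nc <- nrow(cxy)
  g <- molgeom(rep("C", nc), cbind(cxy, 0), name = "pah_flake")
  cb <- infer_bonds(g)
  deg <- tabulate(c(cb[, 1], cb[, 2]), nbins = nc)
  # perimeter carbons (2 C neighbours) get one H along the missing direction
  hx <- list()
  for (i in which(deg == 2)) {
    nb <- c(cb[cb[, 1] == i, 2], cb[cb[, 2] == i, 1])
    dir <- -(.unit(g$xyz[nb[1], ] - g$xyz[i, ]) +
             .unit(g$xyz[nb[2], ] - g$xyz[i, ]))
    hx[[length(hx) + 1]] <- g$xyz[i, ] + 1.09 * .unit(dir)
  }
  nh <- length(hx)
  all_el <- c(rep("C", nc), rep("H", nh))
  all_xyz <- rbind(g$xyz, do.call(rbind, hx))
  hb <- cbind(which(deg == 2), nc + seq_len(nh))
  molgeom(all_el, all_xyz, bonds = rbind(cb, hb),
          name = sprintf("pah_flake_%dx%d", rows, cols))
}

## ---- MCHM construction ---------------------------------------------------

# NeRF-style internal-coordinate placement: position a new atom bonded to p3
# with the given bond length, angle p2-p3-new and dihedral p1-p2-p3-new.
.place_atom <- function(p1, p2, p3, bond, angle_deg, dihedral_deg) {
  a <- angle_deg * pi / 180
  t <- dihedral_deg * pi / 180
  bc <- .unit(p3 - p2)
  n <- .unit(.cross3(p2 - p1, bc))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(a), bond * sin(a) * cos(t), bond * sin(a) * sin(t))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

# Two non-ring tetrahedral directions at ring carbon k (neighbours u, v),
# classified as axial (aligned with the chair z alternation) and equatorial.
.ring_slots <- function(xyz_ring, k) {
  nb1 <- xyz_ring[(k %% 6) + 1, ]
  nb2 <- xyz_ring[((k - 2) %% 6) + 1, ]
  p <- xyz_ring[k, ]
  b <- -.unit(.unit(nb1 - p) + .unit(nb2 - p))
  n <- .unit(.cross3(nb1 - p, nb2 - p))
  half <- 54.735 * pi / 180
  d1 <- cos(half) * b + sin(half) * n
  d2 <- cos(half) * b - sin(half) * n
  if (abs(d1[3]) >= abs(d2[3])) list(axial = d1, equatorial = d2)
  else list(axial = d2, equatorial = d1)
}

#' Build a cis- or trans-MCHM chair conformer
#'
#' Constructs 4-methylcyclohexane methanol (C8H16O, 25 atoms) on an ideal
#' chair cyclohexane ring with the hydroxymethyl group at C1 and the methyl
#' group at C4. The trans isomer places both substituents equatorial (the
#' 1,4-ring-face convention: their first atoms fall on opposite sides of the
#' mean ring plane); the cis isomer places the methyl axial so both first
#' atoms fall on the same side.
#'
#' @param isomer `"cis"` or `"trans"`.
#' @param ring_pucker Only `"chair"` is supported.
#' @param rotamer_angles Length-3 numeric, degrees: dihedral of the
#'   hydroxymethyl oxygen about C1-CH2, of the hydroxyl hydrogen about CH2-O,
#'   and of the methyl hydrogens about C4-CH3.
#' @return A `molgeom` with bonds set; `name` records the isomer.
#' @export
build_mchm <- function(isomer = c("cis", "trans"), ring_pucker = "chair",
                       rotamer_angles = c(180, 180, 60)) {
  isomer <- match.arg(isomer)
  if (!identical(ring_pucker, "chair"))
    stop("unsupported ring pucker: ", ring_pucker)
  stopifnot(length(rotamer_angles) == 3)
  d <- 0.25
  r <- sqrt(1.54^2 - 4 * d^2)
  k <- 0:5
  ring <- cbind(r * cos(k * pi / 3), r * sin(k * pi / 3), d * (-1)^k)
  el <- rep("C", 6)
  xyz <- ring
  bonds <- cbind(1:6, c(2:6, 1))
  add <- function(e, p, bond_to) {
    el <<- c(el, e)
    xyz <<- rbind(xyz, p)
    bonds <<- rbind(bonds, c(bond_to, length(el)))
    length(el)
  }
  s1 <- .ring_slots(ring, 1)          # C1 carries CH2OH
  s4 <- .ring_slots(ring, 4)          # C4 carries CH3
  sub1 <- "equatorial"
  sub4 <- if (isomer == "trans") "equatorial" else "axial"
  # hydroxymethyl at C1
  i_c7 <- add("C", ring[1, ] + 1.53 * s1[[sub1]], 1L)
  i_h1 <- add("H", ring[1, ] + 1.09 * s1[[setdiff(c("axial", "equatorial"), sub1)]], 1L)
  i_o <- add("O", .place_atom(ring[2, ], ring[1, ], xyz[i_c7, ],
                              1.43, 109.47, rotamer_angles[1]), i_c7)
  for (t in c(120, -120))
    add("H", .place_atom(ring[2, ], ring[1, ], xyz[i_c7, ],
                         1.09, 109.47, rotamer_angles[1] + t), i_c7)
  add("H", .place_atom(ring[1, ], xyz[i_c7, ], xyz[i_o, ],
                       0.96, 108, rotamer_angles[2]), i_o)
  # methyl at C4
  i_c8 <- add("C", ring[4, ] + 1.53 * s4[[sub4]], 4L)
  add("H", ring[4, ] + 1.09 * s4[[setdiff(c("axial", "equatorial"), sub4)]], 4L)
  for (t in c(0, 120, 240))
    add("H", .place_atom(ring[3, ], ring[4, ], xyz[i_c8, ],
                         1.09, 109.47, rotamer_angles[3] + t), i_c8)
  # remaining ring hydrogens (two per unsubstituted carbon)
  for (kk in c(2, 3, 5, 6)) {
    s <- .ring_slots(ring, kk)
    add("H", ring[kk, ] + 1.09 * s$axial, as.integer(kk))
    add("H", ring[kk, ] + 1.09 * s$equatorial, as.integer(kk))
  }
  molgeom(el, xyz, bonds = bonds, name = paste0(isomer, "-MCHM"))
}

#' Classify a 1,4-disubstituted cyclohexane as cis or trans
#'
#' Finds the six-membered carbon ring, fits its mean plane, and compares the
#' side on which each substituent's first carbon lies relative to the plane
#' at its attachment site. Same side is cis, opposite sides trans
#' (1,4-disubstitution convention). The test is invariant under mirror
#' inversion, as cis/trans isomerism must be.
#'
#' @param geometry A `molgeom` of a 4-substituted methyl/hydroxymethyl
#'   cyclohexane; bonds are inferred if absent.
#' @return `"cis"` or `"trans"`.
#' @export
classify_mchm_isomer <- function(geometry) {
  stopifnot(inherits(geometry, "molgeom"))
  bonds <- if (!is.null(geometry$bonds)) geometry$bonds else infer_bonds(geometry)
  gr <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n_atoms(geometry) - igraph::vcount(gr)))
  gi <- igraph::girth(gr)
  ring <- as.integer(gi$circle)
  if (length(ring) != 6 || !all(geometry$elements[ring] == "C"))
    stop("no six-membered carbon ring found")
  adj <- igraph::as_adj_list(gr)
  subs <- list()
  for (v in ring) {
    nb <- setdiff(as.integer(adj[[v]]), ring)
    nbC <- nb[geometry$elements[nb] == "C"]
    if (length(nbC)) subs[[length(subs) + 1]] <- c(attach = v, sub = nbC[1])
  }
  if (length(subs) != 2)
    stop("expected exactly two ring substituents, found ", length(subs))
  rc <- geometry$xyz[ring, , drop = FALSE]
  ctr <- colMeans(rc)
  normal <- svd(sweep(rc, 2, ctr))$v[, 3]
  side <- vapply(subs, function(s)
    sum(normal * (geometry$xyz[s["sub"], ] - geometry$xyz[s["attach"], ])),
    numeric(1))
  if (prod(side) > 0) "cis" else "trans"
}

## ---- conformer enumeration -----------------------------------------------

# Surrogate intramolecular strain: 3-fold torsional cosine terms on the two
# (or three) rotatable bonds plus a 1-4+ Lennard-Jones nonbonded sum.
.mchm_strain <- function(geometry, bonds) {
  gr <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  sep <- igraph::distances(gr)
  prs <- which(upper.tri(sep) & sep >= 3, arr.ind = TRUE)
  p <- vdw_params("lj126")
  rr <- sqrt(rowSums((geometry$xyz[prs[, 1], , drop = FALSE] -
                      geometry$xyz[prs[, 2], , drop = FALSE])^2))
  sum(pair_vdw_energy(rr, geometry$elements[prs[, 1]],
                      geometry$elements[prs[, 2]], p))
}

#' Surrogate intramolecular nonbonded strain of a geometry
#'
#' Lennard-Jones energy summed over atom pairs separated by three or more
#' bonds, used to rank rotamers. Invariant under atom reordering and rigid
#' motion.
#'
#' @param geometry A `molgeom`; bonds are inferred if absent.
#' @return Energy in kcal/mol.
#' @export
intramolecular_strain <- function(geometry) {
  stopifnot(inherits(geometry, "molgeom"))
  bonds <- if (!is.null(geometry$bonds)) geometry$bonds else infer_bonds(geometry)
  .mchm_strain(geometry, bonds)
}

#' Enumerate MCHM rotamers on a dihedral grid
#'
#' Scans the hydroxymethyl (C1-CH2) and hydroxyl (CH2-O) torsions -- and
#' optionally the methyl torsion -- on a regular grid, scores each rotamer
#' with a surrogate intramolecular energy (three-fold torsional cosine terms
#' on the scanned bonds plus nonbonded Lennard-Jones over pairs separated by
#' three or more bonds), removes duplicates (heavy-atom RMSD
#' below 0.05 A after optimal superposition), and returns the set sorted by
#' strain energy relative to the minimum.
#'
#' @param isomer `"cis"` or `"trans"`.
#' @param dihedral_grid_step Grid step in degrees; must divide 360.
#' @param include_methyl Also scan the methyl torsion (default FALSE; it is
#'   nearly strain-degenerate).
#' @return A `conformer_set`: list with `isomer`, `geometries` (list of
#'   `molgeom`), and `strain_energies` (kcal/mol, minimum exactly 0).
#' @export
enumerate_mchm_conformers <- function(isomer = c("cis", "trans"),
                                      dihedral_grid_step = 120,
                                      include_methyl = FALSE) {
  isomer <- match.arg(isomer)
  if (360 %% dihedral_grid_step != 0)
    stop("dihedral_grid_step must divide 360")
  grid <- seq(0, 359.999, by = dihedral_grid_step)
  mg <- if (include_methyl) grid else 60
  cases <- expand.grid(a1 = grid, a2 = grid, a3 = mg)
  geoms <- vector("list", nrow(cases))
  strain <- numeric(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    g <- build_mchm(isomer, rotamer_angles = as.numeric(cases[i, ]))
    geoms[[i]] <- g
    # barrier heights (kcal/mol): 1.4 for the C-C torsion, 0.5 for O-H
    strain[i] <- .mchm_strain(g, g$bonds) +
      0.7 * (1 + cos(3 * cases$a1[i] * pi / 180)) +
      0.25 * (1 + cos(3 * cases$a2[i] * pi / 180))
  }
  ord <- order(strain, seq_along(strain))
  geoms <- geoms[ord]; strain <- strain[ord]
  # duplicate removal by heavy-atom RMSD after optimal superposition
  heavy <- function(g) as.vector(t(g$xyz[g$elements != "H", , drop = FALSE]))
  keep <- logical(length(geoms))
  kept_xyz <- list()
  for (i in seq_along(geoms)) {
    hx <- heavy(geoms[[i]])
    dup <- any(vapply(kept_xyz, function(k)
      suppressWarnings(bio3d::rmsd(k, hx, fit = TRUE)) < 0.05, logical(1)))
    if (!dup) { keep[i] <- TRUE; kept_xyz[[length(kept_xyz) + 1]] <- hx }
  }
  geoms <- geoms[keep]; strain <- strain[keep]
  structure(list(isomer = isomer, geometries = geoms,
                 strain_energies = strain - strain[1]),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat("<conformer_set> ", x$isomer, "-MCHM: ", length(x$geometries),
      " conformers, strain range 0-",
      sprintf("%.2f", max(x$strain_energies)), " kcal/mol\n", sep = "")
  invisible(x)
}

## ---- amorphous carbon slab -----------------------------------------------

#' Specification of a synthetic amorphous-carbon slab
#'
#' @param lx,ly,lz Target extents in nm (defaults 5 x 5 x 3 nm, the slab
#'   dimensions of the activated-carbon surrogate used throughout).
#' @param target_density Target mass density, g/cm^3, in (1.0, 3.6). The
#'   default 1.6 matches a ~6000-carbon-atom slab at the default extents,
#'   the size of the reference amorphous-carbon model this generator
#'   stands in for.
#' @param sp3_bias Fraction in `[0, 1]` of sites displaced out-of-plane to
#'   emulate sp3 cross-linking roughness.
#' @param seed Integer RNG seed; the generator is a pure function of the spec.
#' @return An object of class `slab_spec`.
#' @export
slab_spec <- function(lx = 5, ly = 5, lz = 3, target_density = 1.6,
                      sp3_bias = 0.3, seed = 1L) {
  stopifnot(lx > 0, ly > 0, lz > 0, sp3_bias >= 0, sp3_bias <= 1)
  if (target_density <= 1.0 || target_density >= 3.6)
    stop("target_density must lie in (1.0, 3.6) g/cm^3")
  structure(list(lx = lx, ly = ly, lz = lz, target_density = target_density,
                 sp3_bias = sp3_bias, seed = as.integer(seed)),
            class = "slab_spec")
}

#' Build a hydrogen-capped amorphous carbon slab
#'
#' Procedural surrogate for an activated-carbon filter surface: (1) fill the
#' requested box with carbon on a perturbed layered-graphite template whose
#' interlayer spacing is set by the target density; (2) displace a random
#' `sp3_bias` fraction of sites out-of-plane; (3) relax with a short-range
#' pair repulsion until no C-C pair is closer than 1.2 A; (4) open vacuum
#' along the surface normal; (5) cap under-coordinated carbons with hydrogen
#' at 1.09 A along the mean missing-bond direction. The result contains only
#' C and H and reproduces the target density within 10%. This generator is an
#' explicit stand-in emulating the dimensions and density of equilibrated
#' amorphous-carbon models, not an electronic-structure construction.
#'
#' @param spec A [slab_spec()].
#' @return A `surface_slab`, with attributes `achieved_density` (g/cm^3) and
#'   `n_caps`.
#' @export
build_amorphous_slab <- function(spec) {
  stopifnot(inherits(spec, "slab_spec"))
  d <- 1.42
  ucx <- sqrt(3) * d          # rectangular honeycomb unit cell, 4 atoms
  ucy <- 3 * d
  lxA <- spec$lx * 10; lyA <- spec$ly * 10; lzA <- spec$lz * 10
  nx <- max(1L, round(lxA / ucx)); ny <- max(1L, round(lyA / ucy))
  ax <- nx * ucx; by <- ny * ucy
  area_per_atom <- ax * by / (4 * nx * ny)
  # interlayer spacing that realizes the target density (amu/A^3 -> g/cm^3
  # via 1.66054)
  h <- 12.011 * 1.66054 / (area_per_atom * spec$target_density)
  nlay <- max(2L, round(lzA / h))
  motif <- rbind(c(0, 0), c(ucx / 2, d / 2),        # honeycomb motif, 4 atoms
                 c(ucx / 2, 3 * d / 2), c(0, 2 * d))
  cellxy <- as.matrix(expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1)))
  layer_xy <- do.call(rbind, lapply(seq_len(nrow(motif)), function(m)
    cbind(motif[m, 1] + cellxy[, 1] * ucx, motif[m, 2] + cellxy[, 2] * ucy)))
  .with_seed(spec$seed, {
    xyz <- do.call(rbind, lapply(seq_len(nlay) - 1, function(l) {
      sh <- if (l %% 2 == 1) c(0, d) else c(0, 0)   # AB-like stacking
      cbind(layer_xy[, 1] + sh[1], layer_xy[, 2] + sh[2], l * h)
    }))
    n <- nrow(xyz)
    xyz <- xyz + matrix(stats::rnorm(3 * n, sd = 0.15), ncol = 3)
    nsp3 <- round(spec$sp3_bias * n)
    if (nsp3 > 0) {
      pick <- sample.int(n, nsp3)
      xyz[pick, 3] <- xyz[pick, 3] + sample(c(-0.55, 0.55), nsp3, replace = TRUE)
    }
    cell <- list(a = c(ax, 0, 0), b = c(0, by, 0))
    # short-range repulsion relax: push any pair closer than 1.2 A apart
    for (iter in 1:60) {
      pr <- .neighbor_pairs(xyz, 1.2, cell)
      if (!nrow(pr)) break
      for (q in seq_len(nrow(pr))) {
        i <- pr[q, "i"]; j <- pr[q, "j"]
        dv <- xyz[j, ] - xyz[i, ]
        dv[1] <- dv[1] - ax * round(dv[1] / ax)
        dv[2] <- dv[2] - by * round(dv[2] / by)
        dd <- sqrt(sum(dv^2))
        u <- if (dd > 1e-6) dv / dd else c(0, 0, 1)
        push <- (1.25 - dd) / 2
        xyz[i, ] <- xyz[i, ] - push * u
        xyz[j, ] <- xyz[j, ] + push * u
      }
    }
    slab_thickness <- (nlay - 1) * h + h   # one spacing per layer
    gC <- molgeom(rep("C", nrow(xyz)), xyz, name = "amorphous_carbon")
    bonds <- infer_bonds(gC, cell = cell)
    deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = nrow(xyz))
    # drop the (rare) fully detached atoms, then recompute connectivity
    if (any(deg == 0)) {
      keep <- which(deg > 0)
      xyz <- xyz[keep, , drop = FALSE]
      gC <- molgeom(rep("C", nrow(xyz)), xyz, name = "amorphous_carbon")
      bonds <- infer_bonds(gC, cell = cell)
      deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = nrow(xyz))
    }
    # hydrogen capping of under-coordinated carbons
    adj <- vector("list", nrow(xyz))
    for (q in seq_len(nrow(bonds))) {
      adj[[bonds[q, 1]]] <- c(adj[[bonds[q, 1]]], bonds[q, 2])
      adj[[bonds[q, 2]]] <- c(adj[[bonds[q, 2]]], bonds[q, 1])
    }
    caps <- list(); cap_to <- integer(0)
    minimg <- function(v) {
      v[1] <- v[1] - ax * round(v[1] / ax)
      v[2] <- v[2] - by * round(v[2] / by)
      v
    }
    dist_all <- function(p) {
      dx <- xyz[, 1] - p[1]; dy <- xyz[, 2] - p[2]; dz <- xyz[, 3] - p[3]
      dx <- dx - ax * round(dx / ax); dy <- dy - by * round(dy / by)
      sqrt(dx^2 + dy^2 + dz^2)
    }
    for (i in which(deg < 3)) {
      nb <- adj[[i]]
      dirsum <- -rowSums(vapply(nb, function(j)
        .unit(minimg(xyz[j, ] - xyz[i, ])), numeric(3)))
      if (sqrt(sum(dirsum^2)) < 1e-6) next
      hpos <- xyz[i, ] + 1.09 * .unit(dirsum)
      # skip caps that would collide with anything but their own carbon
      clash <- min(dist_all(hpos)[-i]) < 1.35
      if (!clash && length(caps))
        clash <- any(vapply(caps, function(c0)
          sqrt(sum(minimg(hpos - c0)^2)) < 0.9, logical(1)))
      if (clash) next
      caps[[length(caps) + 1]] <- hpos
      cap_to <- c(cap_to, i)
    }
    nC <- nrow(xyz); nH <- length(caps)
    all_xyz <- rbind(xyz, do.call(rbind, caps))
    gall <- molgeom(c(rep("C", nC), rep("H", nH)), all_xyz,
                    bonds = rbind(bonds, cbind(cap_to, nC + seq_len(nH))),
                    name = sprintf("amorphous_carbon_seed%d", spec$seed))
    # cleanup: a carbon whose cap was blocked can be left 1-coordinated;
    # such stragglers (and any orphaned hydrogens) are removed until every
    # C has coordination >= 2 and every H exactly 1
    for (pass in 1:5) {
      ab <- infer_bonds(gall, cell = cell)
      adeg <- tabulate(c(ab[, 1], ab[, 2]), nbins = n_atoms(gall))
      bad <- (gall$elements == "C" & adeg < 2) |
             (gall$elements == "H" & adeg != 1)
      if (!any(bad)) {
        gall$bonds <- ab
        break
      }
      keep2 <- which(!bad)
      gall <- molgeom(gall$elements[keep2],
                      gall$xyz[keep2, , drop = FALSE],
                      name = gall$name)
    }
    nH <- sum(gall$elements == "H")
    mass <- sum(.cs_lookup(gall$elements, "mass"))
    dens <- mass * 1.66054 / (ax * by * slab_thickness)
    slab <- surface_slab(gall, cell_a = c(ax, 0, 0), cell_b = c(0, by, 0))
    attr(slab, "achieved_density") <- dens
    attr(slab, "n_caps") <- nH
    attr(slab, "spec") <- spec
    slab
  })
}
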
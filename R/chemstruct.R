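# Molecular-geometry data model and file I/O shared by every other module.
# Coordinates are Cartesian angstroms throughout; atom order is authoritative
# and never silently changed.

# Element data: Cordero covalent radii (A), CODATA-consistent standard atomic
# masses (amu), atomic numbers. Only the elements the analysis needs.
.cs_elements <- data.frame(
  symbol = c("H", "C", "N", "O"),
  z      = c(1L, 6L, 7L, 8L),
  mass   = c(1.008, 12.011, 14.007, 15.999),
  covrad = c(0.31, 0.76, 0.71, 0.66),
  stringsAsFactors = FALSE
)

.cs_lookup <- function(symbols, what) {
  idx <- match(symbols, .cs_elements$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  .cs_elements[[what]][idx]
}

#' Construct a molecular geometry
#'
#' The universal structure carrier: an ordered set of atoms with Cartesian
#' coordinates in angstroms, an optional bond list, and a net formal charge.
#'
#' @param elements Character vector of chemical symbols (H, C, N, O).
#' @param xyz Numeric matrix with one row per atom and columns x, y, z (angstrom).
#' @param bonds Optional two-column integer matrix of 1-based atom index pairs.
#' @param net_charge Integer net charge in elementary charge units.
#' @param partial_charges Optional per-atom partial charges (elementary
#'   charge units); default zero for every atom.
#' @param name Free-text label.
#' @return An object of class `molgeom`.
#' @export
molgeom <- function(elements, xyz, bonds = NULL, net_charge = 0L,
                    partial_charges = NULL, name = "") {
  elements <- as.character(elements)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(nrow(xyz) == length(elements))
  if (length(elements) > 0 && !all(is.finite(xyz)))
    stop("atom positions must be finite")
  .cs_lookup(elements, "z")  # validates symbols
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) > 0) {
      if (any(bonds < 1L | bonds > length(elements)))
        stop("bond indices out of range")
      if (any(bonds[, 1] == bonds[, 2]))
        stop("self-bonds are not allowed")
      key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
      if (anyDuplicated(key))
        stop("duplicate bonds are not allowed")
    }
  }
  if (!is.null(partial_charges)) {
    partial_charges <- as.numeric(partial_charges)
    stopifnot(length(partial_charges) == length(elements))
  }
  structure(
    list(elements = elements, xyz = xyz, bonds = bonds,
         net_charge = as.integer(net_charge),
         partial_charges = partial_charges, name = name),
    class = "molgeom"
  )
}

#' @export
print.molgeom <- function(x, ...) {
  cat("<molgeom> ", if (nzchar(x$name)) x$name else "(unnamed)",
      ": ", length(x$elements), " atoms (", chemical_formula(x), "), charge ",
      x$net_charge, "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geometry A `molgeom`.
#' @return Integer atom count.
#' @export
n_atoms <- function(geometry) length(geometry$elements)

#' Hill-order chemical formula of a geometry
#' @param geometry A `molgeom`.
#' @return A string such as `"C8H16O"`.
#' @export
chemical_formula <- function(geometry) {
  tab <- table(geometry$elements)
  syms <- names(tab)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s) {
    n <- tab[[s]]
    if (n == 1) s else paste0(s, n)
  }, character(1)), collapse = "")
}

#' A periodic (in-plane) surface slab
#'
#' Wraps a geometry with two in-plane lattice vectors and an out-of-plane
#' vacuum axis, as used for planar PAH and amorphous-carbon surface models.
#'
#' @param geometry A `molgeom` holding the slab atoms.
#' @param cell_a,cell_b In-plane lattice vectors (length-3, angstrom).
#' @param vacuum_axis Out-of-plane direction, `"z"` only.
#' @param periodic Logical; whether minimum-image convention applies in-plane.
#' @return An object of class `surface_slab`.
#' @export
surface_slab <- function(geometry, cell_a, cell_b, vacuum_axis = "z",
                         periodic = TRUE) {
  stopifnot(inherits(geometry, "molgeom"), vacuum_axis == "z",
            length(cell_a) == 3, length(cell_b) == 3)
  cell_a <- as.numeric(cell_a); cell_b <- as.numeric(cell_b)
  cr <- c(cell_a[2] * cell_b[3] - cell_a[3] * cell_b[2],
          cell_a[3] * cell_b[1] - cell_a[1] * cell_b[3],
          cell_a[1] * cell_b[2] - cell_a[2] * cell_b[1])
  if (sqrt(sum(cr^2)) < 1e-8)
    stop("cell vectors must be nonzero and non-parallel")
  structure(list(geometry = geometry, cell_a = cell_a, cell_b = cell_b,
                 vacuum_axis = vacuum_axis, periodic = periodic),
            class = "surface_slab")
}

#' @export
print.surface_slab <- function(x, ...) {
  cat("<surface_slab> ", n_atoms(x$geometry), " atoms, cell ",
      sprintf("%.2f x %.2f", sqrt(sum(x$cell_a^2)), sqrt(sum(x$cell_b^2))),
      " A, periodic = ", x$periodic, "\n", sep = "")
  invisible(x)
}

## ---- XYZ I/O --------------------------------------------------------------

#' Read an XYZ file
#'
#' Plain XYZ: an atom-count header line, a comment line, then one
#' `element x y z` record per atom.
#'
#' @param path File path.
#' @return A `molgeom`; the comment line is kept in `name`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) stop("malformed XYZ atom-count line: ", lines[1])
  if (length(lines) < n + 2)
    stop("XYZ header declares ", n, " atoms but the file body has fewer records")
  body <- lines[seq_len(n) + 2]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(toks) < 4)) stop("malformed XYZ atom record")
  el <- vapply(toks, `[`, character(1), 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("unparsable coordinates in XYZ file")
  molgeom(el, xyz, name = if (length(lines) >= 2) lines[2] else "")
}

#' Write an XYZ file
#'
#' @param geometry A `molgeom`.
#' @param path Destination path.
#' @param comment Comment line; defaults to the geometry name.
#' @return The path, invisibly.
#' @export
write_xyz <- function(geometry, path, comment = geometry$name) {
  stopifnot(inherits(geometry, "molgeom"))
  comment <- gsub("[\r\n]", " ", comment)
  recs <- sprintf("%-2s %15.8f %15.8f %15.8f", geometry$elements,
                  geometry$xyz[, 1], geometry$xyz[, 2], geometry$xyz[, 3])
  writeLines(c(as.character(n_atoms(geometry)), comment, recs), path)
  invisible(path)
}

## ---- PDB I/O --------------------------------------------------------------

#' Read a PDB file
#'
#' Loads all ATOM and HETATM records through [bio3d::read.pdb()]. The element
#' is taken from columns 77-78 when populated, falling back to the leading
#' letters of the atom name. A CRYST1 record, if present, is kept as a
#' `"cryst1"` attribute.
#'
#' @param path File path.
#' @return A `molgeom`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file (", path,
                                           "): ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("PDB file contains no atom records: ", path)
  xyz <- cbind(at$x, at$y, at$z)
  if (anyNA(xyz)) stop("PDB records with unparsable coordinates in ", path)
  el <- trimws(at$elesy)
  blank <- is.na(el) | el == ""
  if (any(blank)) {
    # fall back to atom name: strip digits, keep leading element letters
    nm <- gsub("[0-9']", "", trimws(at$elety[blank]))
    el[blank] <- ifelse(toupper(substr(nm, 1, 1)) %in% .cs_elements$symbol,
                        toupper(substr(nm, 1, 1)), nm)
  }
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  g <- molgeom(el, xyz, name = basename(path))
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cl)) attr(g, "cryst1") <- cl[1]
  g
}

#' Write a PDB file
#'
#' Emits HETATM fixed-column records through [bio3d::write.pdb()] with the
#' element symbol in columns 77-78, occupancy 1.00 and B-factor 0.00. For a
#' [surface_slab()] a CRYST1 record with the in-plane cell is prepended.
#'
#' @param x A `molgeom` or `surface_slab`.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(x, path) {
  slab <- inherits(x, "surface_slab")
  g <- if (slab) x$geometry else x
  stopifnot(inherits(g, "molgeom"))
  n <- n_atoms(g)
  bio3d::write.pdb(file = path, xyz = as.vector(t(g$xyz)),
                   type = rep("HETATM", n),
                   resno = rep(1L, n), resid = rep("MOL", n),
                   eleno = seq_len(n),
                   elety = paste0(g$elements, seq_len(n) %% 100),
                   o = rep(1, n), b = rep(0, n),
                   elesy = g$elements)
  if (slab && x$periodic) {
    a <- sqrt(sum(x$cell_a^2)); b <- sqrt(sum(x$cell_b^2))
    gamma <- acos(sum(x$cell_a * x$cell_b) / (a * b)) * 180 / pi
    czmax <- max(g$xyz[, 3]) - min(g$xyz[, 3]) + 30
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     a, b, czmax, 90, 90, gamma)
    writeLines(c(cryst, readLines(path, warn = FALSE)), path)
  }
  invisible(path)
}

## ---- connectivity / valence ----------------------------------------------

# All pairs with separation <= cutoff. `cell` is NULL (open boundaries) or a
# list(a=, b=) of in-plane lattice vectors for the minimum-image convention.
# Grid binning keeps this usable for multi-thousand-atom slabs.
.neighbor_pairs <- function(xyz, cutoff, cell = NULL) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 3,
                           dimnames = list(NULL, c("i", "j", "d"))))
  ortho <- !is.null(cell) &&
    abs(cell$a[2]) < 1e-9 && abs(cell$a[3]) < 1e-9 &&
    abs(cell$b[1]) < 1e-9 && abs(cell$b[3]) < 1e-9
  if (!is.null(cell) && !ortho) {
    # oblique periodic cells only arise for small systems: dense minimum image
    A <- cbind(cell$a[1:2], cell$b[1:2])
    out <- list()
    for (i in seq_len(n - 1)) {
      d <- xyz[(i + 1):n, , drop = FALSE]
      d[, 1] <- d[, 1] - xyz[i, 1]; d[, 2] <- d[, 2] - xyz[i, 2]
      d[, 3] <- d[, 3] - xyz[i, 3]
      f <- t(solve(A, t(d[, 1:2, drop = FALSE])))
      f <- f - round(f)
      dxy <- t(A %*% t(f))
      dd <- sqrt(dxy[, 1]^2 + dxy[, 2]^2 + d[, 3]^2)
      k <- which(dd <= cutoff)
      if (length(k)) out[[length(out) + 1]] <- cbind(i, i + k, dd[k])
    }
    res <- if (length(out)) do.call(rbind, out) else
      matrix(numeric(0), ncol = 3)
    colnames(res) <- c("i", "j", "d")
    return(res)
  }
  ax <- if (ortho) cell$a[1] else NA_real_
  by <- if (ortho) cell$b[2] else NA_real_
  px <- xyz[, 1]; py <- xyz[, 2]; pz <- xyz[, 3]
  if (ortho) { px <- px %% ax; py <- py %% by }
  # bin atoms on a grid of spacing >= cutoff
  gx0 <- min(px); gy0 <- min(py); gz0 <- min(pz)
  nbx <- if (ortho) max(1L, floor(ax / cutoff)) else
    max(1L, floor((max(px) - gx0) / cutoff) + 1L)
  nby <- if (ortho) max(1L, floor(by / cutoff)) else
    max(1L, floor((max(py) - gy0) / cutoff) + 1L)
  nbz <- max(1L, floor((max(pz) - gz0) / cutoff) + 1L)
  hx <- if (ortho) ax / nbx else cutoff
  hy <- if (ortho) by / nby else cutoff
  bx <- pmin(nbx - 1L, floor((px - if (ortho) 0 else gx0) / hx))
  byi <- pmin(nby - 1L, floor((py - if (ortho) 0 else gy0) / hy))
  bz <- pmin(nbz - 1L, floor((pz - gz0) / cutoff))
  bid <- bx + nbx * (byi + nby * bz)
  byb <- split(seq_len(n), bid)
  keys <- as.integer(names(byb))
  kx <- keys %% nbx; ky <- (keys %/% nbx) %% nby; kz <- keys %/% (nbx * nby)
  keymap <- new.env(hash = TRUE)
  for (q in seq_along(keys)) assign(as.character(keys[q]), q, envir = keymap)
  out <- list()
  add_pairs <- function(ii, jj, same) {
    if (!length(ii) || !length(jj)) return()
    g <- expand.grid(i = ii, j = jj)
    if (same) g <- g[g$i < g$j, , drop = FALSE]
    if (!nrow(g)) return()
    dx <- px[g$i] - px[g$j]; dy <- py[g$i] - py[g$j]; dz <- pz[g$i] - pz[g$j]
    if (ortho) {
      dx <- dx - ax * round(dx / ax)
      dy <- dy - by * round(dy / by)
    }
    dd <- sqrt(dx^2 + dy^2 + dz^2)
    k <- which(dd <= cutoff)
    if (length(k))
      out[[length(out) + 1L]] <<- cbind(pmin(g$i[k], g$j[k]),
                                        pmax(g$i[k], g$j[k]), dd[k])
  }
  offs <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
  offs <- offs[with(offs, ox > 0 | (ox == 0 & (oy > 0 | (oy == 0 & oz >= 0)))), ]
  for (q in seq_along(keys)) {
    for (s in seq_len(nrow(offs))) {
      ox <- kx[q] + offs$ox[s]; oy <- ky[q] + offs$oy[s]; oz <- kz[q] + offs$oz[s]
      if (ortho) { ox <- ox %% nbx; oy <- oy %% nby } else {
        if (ox < 0 || ox >= nbx || oy < 0 || oy >= nby) next
      }
      if (oz < 0 || oz >= nbz) next
      key2 <- ox + nbx * (oy + nby * oz)
      q2 <- keymap[[as.character(key2)]]
      if (is.null(q2)) next
      same <- key2 == keys[q]
      if (!same && key2 < keys[q] && (ortho && (nbx <= 2 || nby <= 2))) {
        # tiny periodic grids revisit bins; allow and dedup later
      }
      if (same) add_pairs(byb[[q]], byb[[q]], TRUE)
      else add_pairs(byb[[q]], byb[[q2]], FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else matrix(numeric(0), ncol = 3)
  colnames(res) <- c("i", "j", "d")
  if (nrow(res) > 1) res <- res[!duplicated(res[, 1:2, drop = FALSE]), , drop = FALSE]
  res
}

#' Infer covalent bonds from interatomic distances
#'
#' A pair `(i, j)` is bonded iff its distance is at most
#' `tolerance_factor * (covalent radius i + covalent radius j)`.
#'
#' @param geometry A `molgeom`.
#' @param tolerance_factor Multiplier on the covalent-radius sum, in (1, 1.5].
#' @param cell Optional `list(a =, b =)` of in-plane lattice vectors; when
#'   given, distances use the minimum-image convention in-plane.
#' @return Two-column integer matrix of bonded index pairs (i < j).
#' @export
infer_bonds <- function(geometry, tolerance_factor = 1.15, cell = NULL) {
  stopifnot(inherits(geometry, "molgeom"))
  if (tolerance_factor <= 1.0 || tolerance_factor > 1.5)
    stop("tolerance_factor must be in (1.0, 1.5]")
  n <- n_atoms(geometry)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  rad <- .cs_lookup(geometry$elements, "covrad")
  maxcut <- tolerance_factor * 2 * max(rad)
  pr <- .neighbor_pairs(geometry$xyz, maxcut, cell)
  if (!nrow(pr)) return(matrix(integer(0), ncol = 2))
  thr <- tolerance_factor * (rad[pr[, "i"]] + rad[pr[, "j"]])
  keep <- pr[, "d"] <= thr & pr[, "d"] > 1e-9
  out <- cbind(as.integer(pr[keep, "i"]), as.integer(pr[keep, "j"]))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Electron-count parity of a geometry
#'
#' Parity of the total electron count, `sum(Z) - net_charge`. Odd parity
#' emulates a non-singlet (radical) species in the cluster-screening rule.
#'
#' @param geometry A `molgeom` with `net_charge` set.
#' @return `"even"` or `"odd"`.
#' @export
electron_parity <- function(geometry) {
  stopifnot(inherits(geometry, "molgeom"))
  ne <- sum(.cs_lookup(geometry$elements, "z")) - geometry$net_charge
  if (ne %% 2 == 0) "even" else "odd"
}

#' Mass-weighted center of mass
#'
#' @param geometry A nonempty `molgeom`.
#' @return Length-3 numeric vector (angstrom).
#' @export
center_of_mass <- function(geometry) {
  stopifnot(inherits(geometry, "molgeom"))
  if (n_atoms(geometry) == 0) stop("empty geometry has no center of mass")
  m <- .cs_lookup(geometry$elements, "mass")
  colSums(geometry$xyz * m) / sum(m)
}
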
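test_that("XYZ round-trip preserves elements and coordinates", {
  g <- molgeom(c("O", "H", "H"),
               rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                     c(0, -0.7572, -0.4692)), name = "water-like toy")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, path)
  g2 <- read_xyz(path)
  expect_identical(g2$elements, g$elements)
  expect_equal(g2$xyz, g$xyz, tolerance = 1e-8)
})

test_that("minimal and malformed XYZ inputs behave as specified", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "C 0 0 0"), path)
  g <- read_xyz(path)
  expect_identical(g$elements, "C")
  expect_equal(g$xyz, matrix(0, 1, 3))

  writeLines(c("5", "comment", "C 0 0 0", "C 1 0 0"), path)
  expect_error(read_xyz(path), "fewer")

  writeLines(c("1", "", "Xq 0 0 0"), path)
  expect_error(read_xyz(path), "unknown element")
})

test_that("PDB round-trip preserves coordinates to fixed-column precision", {
  set.seed(11)
  g <- molgeom(sample(c("C", "H", "O"), 10, replace = TRUE),
               matrix(round(rnorm(30, sd = 5), 3), ncol = 3))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(g, path)
  g2 <- read_pdb(path)
  expect_identical(g2$elements, g$elements)
  expect_equal(g2$xyz, g$xyz, tolerance = 1e-9)  # inputs already at 3 decimals
})

test_that("PDB reader unions ATOM and HETATM records and rejects empty models", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  MOL A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O1  MOL A   1       1.200   0.000   0.000  1.00  0.00           O",
    "END"), path)
  g <- read_pdb(path)
  expect_identical(g$elements, c("C", "O"))

  writeLines("END", path)
  expect_error(read_pdb(path))
})

test_that("slab PDB output carries a CRYST1 record", {
  slab <- tiny_slab()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(slab, path)
  lines <- readLines(path)
  expect_match(lines[1], "^CRYST1")
  expect_equal(as.numeric(substr(lines[1], 7, 15)), sqrt(sum(slab$cell_a^2)),
               tolerance = 1e-3)
})

test_that("bond inference matches a brute-force distance check", {
  two_c <- function(d) molgeom(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(nrow(infer_bonds(two_c(1.54), 1.2)), 1)
  expect_equal(nrow(infer_bonds(two_c(3.0), 1.2)), 0)

  # methane at standard geometry; oracle: all-pairs check against the radii
  ch <- 1.09 / sqrt(3)
  methane <- molgeom(c("C", "H", "H", "H", "H"),
                     rbind(c(0, 0, 0), c(ch, ch, ch), c(ch, -ch, -ch),
                           c(-ch, ch, -ch), c(-ch, -ch, ch)))
  rad <- c(C = 0.76, H = 0.31)
  oracle <- NULL
  for (i in 1:4) for (j in (i + 1):5) {
    d <- sqrt(sum((methane$xyz[i, ] - methane$xyz[j, ])^2))
    if (d <= 1.15 * (rad[methane$elements[i]] + rad[methane$elements[j]]))
      oracle <- rbind(oracle, c(i, j))
  }
  got <- infer_bonds(methane)
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE], oracle,
               ignore_attr = TRUE)
  expect_equal(nrow(got), 4)
})

test_that("bond inference is invariant under rigid motion", {
  g <- build_mchm("trans")
  b0 <- infer_bonds(g)
  set.seed(4)
  for (k in 1:5) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    rot <- adsorption_pose(g, translation = rnorm(3, sd = 20), quaternion = q)
    expect_identical(infer_bonds(rot$geometry), b0)
  }
})

test_that("electron parity follows the total electron count and flips with one H", {
  ch <- 1.09 / sqrt(3)
  methane <- molgeom(c("C", "H", "H", "H", "H"),
                     rbind(c(0, 0, 0), c(ch, ch, ch), c(ch, -ch, -ch),
                           c(-ch, ch, -ch), c(-ch, -ch, ch)))
  expect_identical(electron_parity(methane), "even")
  radical <- molgeom(methane$elements[1:4], methane$xyz[1:4, ])
  expect_identical(electron_parity(radical), "odd")
  expect_identical(electron_parity(build_mchm("cis")), "even")

  # property: removing one hydrogen flips the parity
  for (iso in c("cis", "trans")) {
    g <- build_mchm(iso)
    hidx <- which(g$elements == "H")[1]
    g1 <- molgeom(g$elements[-hidx], g$xyz[-hidx, ])
    expect_false(electron_parity(g1) == electron_parity(g))
  }
})

test_that("center of mass is the standard mass-weighted mean", {
  expect_equal(center_of_mass(molgeom("C", matrix(c(1, 2, 3), 1))), c(1, 2, 3))
  pair <- molgeom(c("O", "O"), rbind(c(-1.5, 0, 0), c(1.5, 0, 0)))
  expect_equal(center_of_mass(pair), c(0, 0, 0))
  # CO at the standard bond length: point divides the bond inversely to mass
  co <- molgeom(c("C", "O"), rbind(c(0, 0, 0), c(1.128, 0, 0)))
  expect_equal(center_of_mass(co)[1], 15.999 * 1.128 / (12.011 + 15.999),
               tolerance = 1e-12)
  expect_error(center_of_mass(molgeom(character(0), matrix(numeric(0), 0, 3))),
               "empty")
})
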
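# Shared fixtures, built once per session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small amorphous slab for fast physisorption tests
tiny_slab <- function() fixture("tiny_slab", function()
  build_amorphous_slab(slab_spec(2.5, 2.5, 1.2, 1.6, 0.2, seed = 7)))

# the default 5 x 5 x 3 nm matched-density slab
paper_slab <- function() fixture("paper_slab", function()
  build_amorphous_slab(slab_spec(seed = 7)))

cis_conformers <- function() fixture("cis_conformers", function()
  enumerate_mchm_conformers("cis", 120))

trans_conformers <- function() fixture("trans_conformers", function()
  enumerate_mchm_conformers("trans", 120))

# independent adaptive-quadrature oracle for the Maxwell-Boltzmann
# high-energy fraction: integral of the energy density above Ea
mb_fraction_quad <- function(Ea, T, kB = 1.987204e-3) {
  dens <- function(e) 2 / sqrt(pi) * (kB * T)^(-1.5) * sqrt(e) * exp(-e / (kB * T))
  stats::integrate(dens, Ea, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# a one-carbon "adsorbate" above a one-carbon "surface", used for analytic
# minimization and cluster checks
single_atom_pose <- function(height = 4) {
  adsorption_pose(molgeom("C", matrix(c(0, 0, 0), 1)), c(0, 0, height))
}

single_atom_surface <- function() {
  surface_slab(molgeom("C", matrix(c(0, 0, 0), 1)),
               cell_a = c(100, 0, 0), cell_b = c(0, 100, 0), periodic = FALSE)
}
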
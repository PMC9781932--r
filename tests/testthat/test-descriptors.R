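test_that("a solute in itself with a symmetric potential has zero affinities", {
  ps <- cosmo_params(c_hb = 0) # symmetric energies
  pot <- sigma_potential(symmetric_profile(), 298.15, ps)
  d <- affinity_descriptors(pot, pot)
  expect_equal(d$hba, 0, tolerance = 1e-6)
  expect_equal(d$hbd, 0, tolerance = 1e-6)
  expect_equal(d$hyd, 0, tolerance = 1e-6)
})

test_that("a constant shift of the solvent potential shifts all descriptors by -c", {
  solute <- sigma_potential(synth_profile_amide(), 298.15)
  solvent <- sigma_potential(synth_profile_water(), 298.15)
  base <- affinity_descriptors(solute, solvent)
  shifted <- solvent
  shifted$mu <- solvent$mu + 42
  d <- affinity_descriptors(solute, shifted)
  expect_equal(d$hba, base$hba - 42)
  expect_equal(d$hbd, base$hbd - 42)
  expect_equal(d$hyd, base$hyd - 42)
})

test_that("relative hydrophobicity orders water-like below alkane-like solvents", {
  solute <- sigma_potential(synth_profile_amide(), 298.15)
  in_water <- affinity_descriptors(solute, sigma_potential(synth_profile_water(), 298.15))
  in_alkane <- affinity_descriptors(solute, sigma_potential(synth_profile_alkane(), 298.15))
  # the ordering flips between the two solvent types (sign-level contrast)
  expect_false(isTRUE(all.equal(sign(in_water$hyd - in_alkane$hyd), 0)))
  expect_true(in_water$hyd != in_alkane$hyd)
})

test_that("grid and temperature mismatches are refused", {
  a <- sigma_potential(synth_profile_amide(), 298.15)
  b <- sigma_potential(synth_profile_water(), 308.15)
  expect_error(affinity_descriptors(a, b), "temperature")
})

test_that("relative energy contributions close to one wherever defined", {
  e <- tibble::tibble(e_misfit = 1, e_hb = 2, e_vdw = 1)
  d <- energy_descriptors(e)
  expect_equal(c(d$de_misfit, d$de_hb, d$de_vdw), c(0.25, 0.5, 0.25))
  set.seed(31)
  for (i in 1:20) {
    e <- tibble::tibble(e_misfit = rnorm(3), e_hb = rnorm(3), e_vdw = rnorm(3))
    x <- c(0.2, 0.5, 0.3)
    # per-component closure implies the mixture-weighted sums also close
    d <- energy_descriptors(e, x)
    expect_equal(d$de_misfit + d$de_hb + d$de_vdw, 1, tolerance = 1e-12)
  }
})

test_that("degenerate energy rows are flagged, and equal components mix trivially", {
  z <- tibble::tibble(e_misfit = 0, e_hb = 0, e_vdw = 0)
  expect_warning(d <- energy_descriptors(z), "zero total")
  expect_equal(d$de_misfit + d$de_hb + d$de_vdw, 0)
  e1 <- tibble::tibble(e_misfit = 2, e_hb = -1, e_vdw = 0.5)
  both <- dplyr::bind_rows(e1, e1)
  expect_equal(energy_descriptors(both, c(0.3, 0.7)), energy_descriptors(e1))
})

test_that("the descriptor vector has eight ordered columns and reacts to T", {
  am <- synth_profile_amide()
  solvents <- list(synth_profile_aprotic(), synth_profile_water())
  d1 <- descriptor_vector(am, solvents, c(0.5, 0.5), 298.15, log10x_cosmo = -1)
  expect_equal(names(d1), descriptor_names())
  expect_equal(ncol(d1), 8)
  d2 <- descriptor_vector(am, solvents, c(0.5, 0.5), 320, log10x_cosmo = -1)
  expect_false(isTRUE(all.equal(d1$hba, d2$hba)))
  # pure function: identical inputs give identical outputs
  d3 <- descriptor_vector(am, solvents, c(0.5, 0.5), 298.15, log10x_cosmo = -1)
  expect_identical(d1, d3)
})

test_that("min-max normalization maps each descriptor into [0, 1] and freezes", {
  tab <- make_descriptor_table(60, "linear", noise_sd = 0, seed = 2)
  tab$log10x_cosmo <- tab$log10x_cosmo * 50 - 10 # un-normalized scale
  nm <- normalize_descriptors(tab)
  for (cl in descriptor_names()) {
    expect_gte(min(nm[[cl]]), 0)
    expect_lte(max(nm[[cl]]), 1)
  }
  consts <- attr(nm, "normalization")
  again <- normalize_descriptors(tab[1:5, ], constants = consts)
  expect_equal(as.data.frame(again[, descriptor_names()]),
               as.data.frame(nm[1:5, descriptor_names()]))
})
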
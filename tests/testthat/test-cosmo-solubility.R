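test_that("the melting Gibbs energy is zero at Tm, positive below, linear in T", {
  fa <- fusion_constants("acetaminophen")
  expect_equal(fusion_gibbs(fa, fa$t_m), 0)
  expect_equal(fusion_gibbs(fa, 298.15), 26900 * (1 - 298.15 / 442.2))
  expect_equal(fusion_gibbs(fa, 298.15) / 1000, 8.76, tolerance = 1e-3)
  tt <- seq(250, 442.2, length.out = 10)
  expect_true(all(diff(fusion_gibbs(fa, tt)) < 0))
  d2 <- diff(diff(fusion_gibbs(fa, tt)))
  expect_equal(max(abs(d2)), 0, tolerance = 1e-9)
})

test_that("the iterative solver matches the ideal-solubility closed form", {
  fa <- fusion_constants("acetaminophen")
  am <- synth_profile_amide()
  # solvent identical to the solute: gamma = 1 exactly
  st <- solve_saturation(am, am, fa, 298.15, tol = 1e-12)
  ideal <- exp(-fusion_gibbs(fa, 298.15) / (8.31446 * 298.15))
  expect_lt(abs(log(st$x_sat) - log(ideal)), 1e-8)
  expect_equal(st$gamma_sat, 1, tolerance = 1e-6)
  expect_false(st$miscible_flag)
  # the converged state satisfies the equilibrium condition
  expect_lt(abs(st$ln_activity + fusion_gibbs(fa, 298.15) / (8.31446 * 298.15)),
            1e-6)
})

test_that("the ideal solubility of acetaminophen at 298.15 K is about 0.029", {
  fa <- fusion_constants("acetaminophen")
  am <- synth_profile_amide()
  st <- solve_saturation(am, am, fa, 298.15, tol = 1e-12)
  expect_equal(st$x_sat, 0.029, tolerance = 0.01)
})

test_that("approaching the melting point drives the ideal solubility to 1", {
  fa <- fusion_constants("acetaminophen")
  am <- synth_profile_amide()
  st <- solve_saturation(am, am, fa, fa$t_m - 1e-6, tol = 1e-10)
  expect_true(st$miscible_flag || st$x_sat > 0.999)
})

test_that("saturation solving is deterministic", {
  fa <- fusion_constants("phenacetin")
  am <- synth_profile_amide()
  w <- synth_profile_water()
  s1 <- solve_saturation(am, w, fa, 298.15)
  s2 <- solve_saturation(am, w, fa, 298.15)
  expect_identical(s1, s2)
})

test_that("miscibility patching extends the linear tail and touches nothing else", {
  # no flags: unchanged
  curve <- tibble::tibble(x2_star = seq(0, 1, 0.1),
                          ln_x = -3 + 2 * seq(0, 1, 0.1),
                          miscible = FALSE)
  out <- patch_miscibility(curve)
  expect_identical(out$ln_x, curve$ln_x)
  expect_true(all(!out$patched))

  # known linear tail, flags on the last three points
  truth <- function(x) -4 + 2.5 * x
  curve <- tibble::tibble(
    x2_star = seq(0, 1, 0.1),
    ln_x = c(-4 + 1.1 * seq(0, 0.2, 0.1), truth(seq(0.3, 0.7, 0.1)), 0, 0, 0),
    miscible = c(rep(FALSE, 8), TRUE, TRUE, TRUE)
  )
  out <- patch_miscibility(curve)
  expect_equal(out$ln_x[9:11], truth(seq(0.8, 1, 0.1)), tolerance = 1e-12)
  expect_identical(out$ln_x[1:8], curve$ln_x[1:8]) # bit-exact elsewhere
  expect_equal(out$patched, curve$miscible)

  # exactly collinear anchors reproduce the line exactly
  col <- tibble::tibble(x2_star = seq(0, 1, 0.1), ln_x = truth(seq(0, 1, 0.1)),
                        miscible = c(rep(FALSE, 9), TRUE, TRUE))
  outc <- patch_miscibility(col)
  expect_equal(outc$ln_x, truth(seq(0, 1, 0.1)), tolerance = 1e-12)
})

test_that("patching refuses curves with too short a valid run", {
  curve <- tibble::tibble(x2_star = seq(0, 1, 0.25),
                          ln_x = c(-3, -2, 0, 0, 0),
                          miscible = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(patch_miscibility(curve), ">= 5 valid points")
})
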
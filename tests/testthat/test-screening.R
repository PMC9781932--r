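test_that("the measured optimum composition is 0.8 for both co-solvents", {
  t1 <- table1_solubility()
  a_dmso <- dplyr::filter(t1, solute == "A", solvent1 == "DMSO")
  a_dmf <- dplyr::filter(t1, solute == "A", solvent1 == "DMF")
  expect_equal(optimal_composition(a_dmso), 0.8)
  expect_equal(optimal_composition(a_dmf), 0.8)
})

test_that("a monotone surface puts the optimum at the neat organic end", {
  d <- tibble::tibble(x2_star = seq(0, 1, 0.1), temperature = 298.15,
                      x_solute = exp(-3 + 2 * seq(0, 1, 0.1)))
  expect_equal(optimal_composition(d), 1.0)
})

test_that("re-fitting a surface generated from the model is an exact round trip", {
  grid <- seq(0, 1, 0.05)
  temps <- c(298.15, 308.15)
  gr <- tidyr::expand_grid(x2_star = grid, temperature = temps)
  ln_x <- jouyban_acree_predict(ja_truth, gr$x2_star, gr$temperature)
  fake <- structure(list(predictions = tibble::tibble(
    x2_star = gr$x2_star, temperature = gr$temperature,
    .pred = ln_x / log(10), in_domain = TRUE)), class = "screening_result")
  fit <- refit_ja(fake)
  expect_equal(fit$j, c(500, -200, 100), tolerance = 1e-6)
  # endpoints reproduced exactly by construction of the anchors
  expect_equal(jouyban_acree_predict(fit, 1, 298.15),
               ja_truth$ln_x2_sat(298.15), tolerance = 1e-9)
  expect_equal(jouyban_acree_predict(fit, 0, 308.15),
               ja_truth$ln_x3_sat(308.15), tolerance = 1e-9)
})

test_that("the environmental-index gate is a strict inequality", {
  res <- tibble::tibble(solute = "A",
                        solvent1 = c("DMSO", "DMSO_adj", "4FM", "DMF"),
                        log10x_opt = c(-0.5, -0.5, -0.78, -0.45),
                        x2_opt = c(0.8, 0.8, 1.0, 0.8))
  meta <- read_solvent_meta(system.file("extdata", "solvent_meta.csv",
                                        package = "cosolve"))
  ranked <- rank_solvents(res, meta)
  expect_false("DMSO" %in% ranked$solvent1)      # EI = 11.7
  expect_false("4FM" %in% ranked$solvent1)       # EI = 0.51 at a 0.5 cut
  expect_false("DMF" %in% ranked$solvent1)       # EI = 2.0
  expect_true("DMSO_adj" %in% ranked$solvent1)   # EI = 0.26
})

test_that("ranking sorts by predicted solubility, ties by lower EI, and logs losses", {
  res <- tibble::tibble(solvent1 = c("S1", "S2", "S3", "S4"),
                        log10x_opt = c(-1, -0.5, -0.5, -2))
  meta <- tibble::tibble(solvent_id = c("S1", "S2", "S3"),
                         ei = c(0.1, 0.3, 0.2))
  expect_warning(ranked <- rank_solvents(res, meta), "S4")
  expect_equal(ranked$solvent1, c("S3", "S2", "S1")) # tie -0.5 broken by EI
  expect_equal(ranked$rank, 1:3)
})

test_that("the full screening driver runs the pipeline and reports an optimum", {
  tab <- pipeline_descriptor_table()
  pool <- default_pool(hidden_units = c(8, 16), activations = "tanh",
                       losses = "squared", seeds = 1:2)
  ens <- build_ensemble(tab, pool, seed = 11)
  res <- screen_system(ens, synth_profile_amide(), synth_profile_aprotic(),
                       synth_profile_water(), fusion_constants("acetaminophen"),
                       grid = seq(0, 1, 0.1), solute_id = "A", solvent_id = "APR")
  expect_s3_class(res, "screening_result")
  expect_gt(res$in_domain_fraction, 0.5)
  expect_true(res$x2_opt %in% res$grid)
  # the reported optimum is the argmax over the in-domain grid
  ref <- dplyr::filter(res$predictions, in_domain)
  expect_equal(res$log10x_opt, max(ref$.pred))
  expect_equal(res$x2_opt, ref$x2_star[which.max(ref$.pred)])
  # the JA re-expression reproduces the predicted surface reasonably
  expect_false(is.null(res$ja))
  expect_lt(res$ja$mape, 50)
})

test_that("pipeline threshold defaults carry the canonical values", {
  def <- screening_defaults()
  expect_equal(def$curation_threshold, 10)
  expect_equal(def$rmsd_max, 0.06)
  expect_equal(def$outlier_max, 2)
  expect_equal(def$reliability_min, 99)
  expect_equal(def$ei_threshold, 0.5)
})
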
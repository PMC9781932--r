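test_that("profile construction enforces the basic invariants", {
  expect_error(sigma_profile(sigma_grid(), rep(-1, 71)), "non-negative")
  expect_error(sigma_profile(c(0, 0.1, 0.15), c(1, 1, 1)), "uniform")
  pr <- delta_profile(100)
  expect_equal(total_area(pr), 100)
})

test_that("file round trip preserves the profile", {
  pr <- symmetric_profile()
  tmp <- withr::local_tempfile(fileext = ".sigma")
  write_sigma_profile(pr, tmp)
  back <- read_sigma_profile(tmp)
  expect_equal(total_area(back), total_area(pr), tolerance = 1e-6)
  expect_equal(back$p, pr$p, tolerance = 1e-6)
})

test_that("a single-line file reads as a point mass", {
  tmp <- withr::local_tempfile(fileext = ".sigma")
  writeLines(c("# comment", "0.000 100"), tmp)
  pr <- read_sigma_profile(tmp)
  expect_equal(total_area(pr), 100)
  expect_equal(pr$p[pr$sigma == 0], 100)
})

test_that("rebinning from a finer grid conserves area and band integrals", {
  fine <- seq(-0.035, 0.035, 0.0005)
  dens <- exp(-((fine) / 0.01)^2) + 0.5 * exp(-((fine - 0.015) / 0.004)^2)
  p_fine <- dens / sum(dens) * 120
  tmp <- withr::local_tempfile(fileext = ".sigma")
  writeLines(sprintf("%.6f %.10g", fine, p_fine), tmp)
  pr <- read_sigma_profile(tmp)
  expect_equal(total_area(pr), 120, tolerance = 1e-3)
  band_mass <- function(s, p, lo, hi) sum(p[s >= lo - 1e-9 & s <= hi + 1e-9])
  expect_equal(band_mass(pr$sigma, pr$p, -0.01, 0.01),
               band_mass(fine, p_fine, -0.01, 0.01), tolerance = 0.02)
})

test_that("negative weights in a file are rejected", {
  tmp <- withr::local_tempfile(fileext = ".sigma")
  writeLines(c("-0.01 5", "0 -2", "0.01 5"), tmp)
  expect_error(read_sigma_profile(tmp), "negative")
})

test_that("mixing is linear, associative and respects composition checks", {
  a <- symmetric_profile()
  b <- synth_profile_alkane()
  expect_equal(mix_profiles(list(a), 1)$p, a$p)
  expect_equal(mix_profiles(list(a, a), c(0.5, 0.5))$p, a$p)
  m <- mix_profiles(list(delta_profile(100), delta_profile(200)), c(0.25, 0.75))
  expect_equal(total_area(m), 175)
  # associativity via flat three-way mix vs nested two-way mixes
  c3 <- synth_profile_water()
  flat <- mix_profiles(list(a, b, c3), c(0.2, 0.3, 0.5))
  nested <- mix_profiles(list(mix_profiles(list(a, b), c(0.4, 0.6)), c3),
                         c(0.5, 0.5))
  expect_equal(flat$p, nested$p, tolerance = 1e-12)
  expect_error(mix_profiles(list(a, b), c(0.6, 0.6)), "sum to 1")
})

test_that("generated profiles honour the total-area contract", {
  pr <- make_profile(data.frame(center = 0.005, width = 0.002, area = 1),
                     total_area = 150)
  expect_equal(total_area(pr), 150, tolerance = 1e-9)
  # a single peak at zero is symmetric: equal mass in both polar wings
  sym <- make_profile(data.frame(center = 0, width = 0.005, area = 1),
                      total_area = 80)
  wing <- function(pr, side) sum(pr$p[side * pr$sigma > 0.01])
  expect_equal(wing(sym, 1), wing(sym, -1), tolerance = 1e-12)
})

test_that("the water-like preset has substantial polar wings", {
  w <- synth_profile_water()
  wing_neg <- sum(w$p[w$sigma < -0.01]) / total_area(w)
  wing_pos <- sum(w$p[w$sigma > 0.01]) / total_area(w)
  expect_gt(wing_neg, 0.1)
  expect_gt(wing_pos, 0.1)
})
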
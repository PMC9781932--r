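test_that("splitting is a deterministic 70/15/15 partition with remainders to train", {
  d100 <- make_descriptor_table(100, "linear", seed = 1)
  s <- split_dataset(d100, seed = 5)
  expect_equal(vapply(s, nrow, integer(1)),
               c(train = 70L, test = 15L, validation = 15L))
  d101 <- make_descriptor_table(101, "linear", seed = 1)
  s2 <- split_dataset(d101, seed = 5)
  expect_equal(vapply(s2, nrow, integer(1)),
               c(train = 71L, test = 15L, validation = 15L))
  # disjoint and exhaustive
  all_targets <- sort(c(s$train$target, s$test$target, s$validation$target))
  expect_equal(all_targets, sort(d100$target))
  # same seed, same split
  s3 <- split_dataset(d100, seed = 5)
  expect_identical(s, s3)
  expect_error(split_dataset(d100[1:10, ], 1), "at least 20")
})

test_that("a constant target is learned to near-zero RMSD", {
  d <- make_descriptor_table(80, function(D) rep(-1.5, nrow(D)),
                             noise_sd = 0, seed = 3)
  s <- split_dataset(d, 1)
  net <- train_candidate(nn_config(hidden_units = 4, seed = 2), s$train, s$test)
  expect_lt(rmsd(s$validation$target, predict(net, s$validation)), 0.01)
})

test_that("a linear target is recovered below the noise floor", {
  d <- make_descriptor_table(300, "linear", noise_sd = 0.02, seed = 4)
  s <- split_dataset(d, 2)
  net <- train_candidate(nn_config(hidden_units = 8, seed = 1), s$train, s$test)
  expect_lt(rmsd(s$validation$target, predict(net, s$validation)), 0.04)
})

test_that("training is deterministic for a fixed config and seed", {
  d <- make_descriptor_table(60, "linear", seed = 6)
  s <- split_dataset(d, 3)
  n1 <- train_candidate(nn_config(seed = 9, max_epochs = 50), s$train, s$test)
  n2 <- train_candidate(nn_config(seed = 9, max_epochs = 50), s$train, s$test)
  expect_identical(n1$weights, n2$weights)
})

test_that("in-package networks match an independent shallow-net fit in quality", {
  skip_if_not_installed("nnet")
  d <- make_descriptor_table(300, "bumpy", noise_sd = 0.03, seed = 8)
  s <- split_dataset(d, 4)
  net <- train_candidate(nn_config(hidden_units = 12, seed = 1), s$train, s$test)
  ours <- rmsd(s$validation$target, predict(net, s$validation))
  ref <- nnet::nnet(target ~ ., data = s$train, size = 12, linout = TRUE,
                    decay = 1e-4, maxit = 500, trace = FALSE)
  theirs <- rmsd(s$validation$target,
                 as.numeric(predict(ref, s$validation)))
  # same problem, same architecture class: within a factor two of each other
  expect_lt(ours, 2 * theirs + 0.02)
})

test_that("the admission gate is the exact stated conjunction", {
  # each criterion violated on its own rejects the member
  expect_false(admit_member(0.07, 0, 100))   # accuracy
  expect_false(admit_member(0.05, 3, 100))   # precision
  expect_false(admit_member(0.05, 0, 98))    # reliability
  expect_true(admit_member(0.05, 1, 100))
  # boundary semantics: strict on RMSD, inclusive on the rates
  expect_false(admit_member(0.06, 0, 100))
  expect_true(admit_member(0.059, 2, 99))
  # property: random reports on either side of each threshold
  set.seed(41)
  for (i in 1:50) {
    r <- runif(1, 0, 0.12); o <- runif(1, 0, 4); rel <- runif(1, 95, 100)
    expect_equal(admit_member(r, o, rel),
                 (r < 0.06) && (o <= 2) && (rel >= 99))
  }
})

test_that("evaluate_member computes the three gate statistics", {
  d <- make_descriptor_table(200, "linear", noise_sd = 0.02, seed = 10)
  s <- split_dataset(d, 6)
  net <- train_candidate(nn_config(hidden_units = 8, seed = 3), s$train, s$test)
  rep <- evaluate_member(net, s$validation)
  expect_true(all(c("rmsd_val", "outlier_rate", "reliability_rate", "admitted")
                  %in% names(rep)))
  expect_equal(rep$rmsd_val,
               rmsd(s$validation$target, predict(net, s$validation)))
  expect_equal(rep$admitted,
               admit_member(rep$rmsd_val, rep$outlier_rate, rep$reliability_rate))
})

test_that("ensemble construction admits members and keeps predictions convex", {
  tab <- make_descriptor_table(400, "bumpy", noise_sd = 0.03, seed = 42)
  ens <- build_ensemble(tab, small_pool(), seed = 7)
  expect_gte(length(ens$members), 1)
  pr <- predict(ens, tab[1:40, ])
  expect_true(all(pr$.pred >= pr$.pred_min - 1e-12))
  expect_true(all(pr$.pred <= pr$.pred_max + 1e-12))
  # variance reduction: ensemble no worse than the median admitted member
  val <- split_dataset(tab, 7)$validation
  ens_rmsd <- rmsd(val$target, predict(ens, val)$.pred)
  member_rmsds <- ens$reports$rmsd_val[ens$reports$admitted]
  expect_lte(ens_rmsd, stats::median(member_rmsds) + 1e-9)
})

test_that("two builds with the same seeds are identical", {
  tab <- make_descriptor_table(200, "linear", noise_sd = 0.02, seed = 13)
  pool <- default_pool(hidden_units = 8, activations = "tanh",
                       losses = "squared", seeds = 1:2)
  # wide outlier gate: tiny validation sets quantize the outlier rate, and
  # this test is about determinism, not admission
  e1 <- build_ensemble(tab, pool, seed = 3, outlier_max = 10)
  e2 <- build_ensemble(tab, pool, seed = 3, outlier_max = 10)
  expect_identical(lapply(e1$members, `[[`, "weights"),
                   lapply(e2$members, `[[`, "weights"))
  expect_identical(e1$reports, e2$reports)
})

test_that("an impossible gate fails with an informative error", {
  tab <- make_descriptor_table(120, "bumpy", noise_sd = 0.2, seed = 14)
  pool <- default_pool(hidden_units = 4, activations = "tanh",
                       losses = "squared", seeds = 1)
  expect_error(build_ensemble(tab, pool, seed = 2, rmsd_max = 1e-6),
               "no candidate")
})

test_that("the applicability domain accepts training points and rejects outliers", {
  tab <- make_descriptor_table(200, "linear", noise_sd = 0.02, seed = 15)
  ens <- build_ensemble(tab, default_pool(8, "tanh", "squared", 1), seed = 4)
  tr <- split_dataset(tab, 4)$train
  ad_tr <- applicability_domain(ens, tr)
  expect_true(all(ad_tr$in_domain))
  # mean training leverage equals (p + 1) / n (hat-matrix identity)
  expect_equal(mean(ad_tr$leverage), (length(ens$features) + 1) / nrow(tr),
               tolerance = 1e-9)
  far <- tr[1, ]
  far$log10x_cosmo <- far$log10x_cosmo + 10
  expect_false(applicability_domain(ens, far)$in_domain)
})
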
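# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Split a descriptor table into training / test / validation subsets
#'
#' Deterministic 70/15/15 random partition: the test and validation
#' subsets get `floor(0.15 n)` rows each and the training subset the
#' remainder, so rounding leftovers always go to training.
#'
#' @param data A tibble with at least 20 rows.
#' @param seed Integer seed; the same seed always yields the same split.
#' @param props Proportions `c(train, test, validation)`.
#' @return A named list of tibbles `train`, `test`, `validation`.
#' @export
split_dataset <- function(data, seed, props = c(0.70, 0.15, 0.15)) {
  n <- nrow(data)
  if (n < 20) stop("need at least 20 rows to split.", call. = FALSE)
  stopifnot(length(props) == 3, abs(sum(props) - 1) < 1e-9)
  n_test <- floor(props[2] * n)
  n_val <- floor(props[3] * n)
  idx <- with_seed(seed, sample.int(n))
  test_i <- idx[seq_len(n_test)]
  val_i <- idx[n_test + seq_len(n_val)]
  train_i <- idx[-seq_len(n_test + n_val)]
  list(train = data[sort(train_i), , drop = FALSE],
       test = data[sort(test_i), , drop = FALSE],
       validation = data[sort(val_i), , drop = FALSE])
}

#' Configuration of one shallow-network candidate
#'
#' The architecture is fixed to a single hidden layer with a linear output
#' unit; the tunable dimensions are the hidden width, the activation, and
#' the error function, plus the optimization seed.
#'
#' @param hidden_units Number of hidden neurons (>= 1).
#' @param activation `"tanh"`, `"logistic"` or `"relu"`.
#' @param loss `"squared"` or `"absolute"`.
#' @param seed Integer seed for weight initialization.
#' @param max_epochs,patience Training length and early-stopping patience
#'   (epochs without test-set improvement).
#' @param learn_rate Adam step size.
#' @return A list of class `"nn_config"`.
#' @export
nn_config <- function(hidden_units = 8, activation = c("tanh", "logistic", "relu"),
                      loss = c("squared", "absolute"), seed = 1,
                      max_epochs = 2000, patience = 150, learn_rate = 0.02) {
  stopifnot(hidden_units >= 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 activation = match.arg(activation), loss = match.arg(loss),
                 seed = as.integer(seed), max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), learn_rate = learn_rate),
            class = "nn_config")
}

act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(a) 1 - a^2),
    logistic = list(f = function(z) 1 / (1 + exp(-z)), df = function(a) a * (1 - a)),
    relu = list(f = function(z) pmax(z, 0), df = function(a) (a > 0) * 1))
}

#' Train one shallow-network candidate
#'
#' Fits a single-hidden-layer network mapping (normalized) descriptors to
#' log10 solubility by full-batch Adam gradient descent, with early
#' stopping on the test subset: the weights with the lowest test RMSD seen
#' within the patience window are returned. Fully deterministic for a
#' fixed configuration (the seed drives weight initialization).
#'
#' @param config An [nn_config()].
#' @param train,test Tibbles holding normalized descriptor columns and the
#'   target column.
#' @param target Name of the target column.
#' @return An object of class `"shallow_net"` (weights, the feature order,
#'   the training curve). Supports [predict()][predict.shallow_net].
#' @export
train_candidate <- function(config, train, test, target = "target") {
  features <- setdiff(names(train), target)
  X <- as.matrix(train[, features]); y <- train[[target]]
  Xt <- as.matrix(test[, features]); yt <- test[[target]]
  p <- ncol(X); H <- config$hidden_units
  act <- act_fun(config$activation)

  w <- with_seed(config$seed, list(
    W1 = matrix(stats::rnorm(p * H, sd = sqrt(2 / (p + H))), p, H),
    b1 = stats::rnorm(H, sd = 0.1),
    w2 = matrix(stats::rnorm(H, sd = sqrt(1 / H)), H, 1),
    b2 = mean(y)
  ))
  forward <- function(w, X) {
    A <- act$f(sweep(X %*% w$W1, 2, w$b1, `+`))
    list(A = A, yhat = drop(A %*% w$w2) + w$b2)
  }
  m <- lapply(w, function(x) x * 0); v <- m
  b1t <- 1; b2t <- 1
  best <- list(rmsd = Inf, w = w, epoch = 0L)
  curve <- numeric(0)
  n <- nrow(X)
  for (epoch in seq_len(config$max_epochs)) {
    fw <- forward(w, X)
    err <- fw$yhat - y
    dl <- switch(config$loss, squared = err, absolute = sign(err)) / n
    dA <- (dl %*% t(w$w2)) * act$df(fw$A)
    grad <- list(W1 = crossprod(X, dA), b1 = colSums(dA),
                 w2 = crossprod(fw$A, matrix(dl)), b2 = sum(dl))
    b1t <- b1t * 0.9; b2t <- b2t * 0.999
    for (k in names(w)) {
      m[[k]] <- 0.9 * m[[k]] + 0.1 * grad[[k]]
      v[[k]] <- 0.999 * v[[k]] + 0.001 * grad[[k]]^2
      w[[k]] <- w[[k]] - config$learn_rate * (m[[k]] / (1 - b1t)) /
        (sqrt(v[[k]] / (1 - b2t)) + 1e-8)
    }
    test_rmsd <- rmsd(yt, forward(w, Xt)$yhat)
    curve <- c(curve, test_rmsd)
    if (!is.finite(test_rmsd)) stop("non-finite training loss.", call. = FALSE)
    if (test_rmsd < best$rmsd - 1e-12) {
      best <- list(rmsd = test_rmsd, w = w, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  structure(list(weights = best$w, features = features, target = target,
                 config = config, activation = config$activation,
                 test_rmsd = best$rmsd, training_curve = curve,
                 best_epoch = best$epoch),
            class = "shallow_net")
}

#' Predict from a shallow network
#'
#' @param object A `"shallow_net"`.
#' @param newdata Tibble with the (normalized) descriptor columns used in
#'   training.
#' @param ... Unused.
#' @return Numeric vector of predictions (log10 solubility scale).
#' @export
predict.shallow_net <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features])
  act <- act_fun(object$activation)
  A <- act$f(sweep(X %*% object$weights$W1, 2, object$weights$b1, `+`))
  drop(A %*% object$weights$w2) + object$weights$b2
}

#' The triple admission gate for ensemble membership
#'
#' A candidate network joins the ensemble only if it satisfies the exact
#' conjunction of accuracy, precision and reliability:
#' `rmsd_val < rmsd_max` AND `outlier_rate <= outlier_max` AND
#' `reliability_rate >= reliability_min`. Defaults: RMSD below 0.06 log10
#' units, at most 2 percent outliers, at least 99 percent reliable
#' predictions.
#'
#' @param rmsd_val Validation RMSD, log10 units.
#' @param outlier_rate Percentage of validation residuals beyond three
#'   (normalized) standard deviations.
#' @param reliability_rate Percentage of predictions corresponding to a
#'   physically admissible mole fraction (log10 x <= 0).
#' @param rmsd_max,outlier_max,reliability_min Gate thresholds.
#' @return Logical: admitted or not (vectorized).
#' @export
admit_member <- function(rmsd_val, outlier_rate, reliability_rate,
                         rmsd_max = 0.06, outlier_max = 2, reliability_min = 99) {
  (rmsd_val < rmsd_max) & (outlier_rate <= outlier_max) &
    (reliability_rate >= reliability_min)
}

#' Evaluate a candidate network on the validation subset
#'
#' Computes the three admission statistics: validation RMSD on the log10
#' scale; the outlier rate, i.e. the percentage of residuals whose
#' magnitude exceeds three standard deviations of the residual
#' distribution; and the reliability rate, the percentage of predictions
#' that map to a mole fraction in (0, 1] (log10 x <= 0). Admission is the
#' strict conjunction of [admit_member()].
#'
#' @param network A `"shallow_net"`.
#' @param validation Tibble with normalized descriptors and the target.
#' @param ... Gate thresholds passed to [admit_member()].
#' @return A one-row tibble (member report): configuration fields,
#'   `rmsd_val`, `outlier_rate`, `reliability_rate`, `admitted`.
#' @export
evaluate_member <- function(network, validation, ...) {
  y <- validation[[network$target]]
  pred <- predict(network, validation)
  res <- pred - y
  sd_res <- stats::sd(res)
  outlier_rate <- if (is.na(sd_res) || sd_res == 0) 0 else 100 * mean(abs(res) > 3 * sd_res)
  reliability_rate <- 100 * mean(pred <= 0)
  rv <- rmsd(y, pred)
  tibble::tibble(
    hidden_units = network$config$hidden_units,
    activation = network$config$activation,
    loss = network$config$loss,
    seed = network$config$seed,
    rmsd_val = rv, outlier_rate = outlier_rate,
    reliability_rate = reliability_rate,
    admitted = admit_member(rv, outlier_rate, reliability_rate, ...)
  )
}

#' Default hyperparameter pool for ensemble construction
#'
#' Cartesian grid over hidden width, activation and loss, replicated over
#' initialization seeds. The full default grid (6 widths x 3 activations x
#' 2 losses x 10 seeds = 360 candidates) mirrors a thorough search; tests
#' and examples use smaller pools.
#'
#' @param hidden_units,activations,losses Grid dimensions.
#' @param seeds Initialization seeds.
#' @return A tibble with one candidate configuration per row.
#' @export
default_pool <- function(hidden_units = c(4, 8, 12, 16, 24, 32),
                         activations = c("tanh", "logistic", "relu"),
                         losses = c("squared", "absolute"),
                         seeds = 1:10) {
  tidyr::expand_grid(hidden_units = hidden_units, activation = activations,
                     loss = losses, seed = seeds)
}

#' Build an admission-gated ensemble of shallow networks
#'
#' Splits the dataset 70/15/15, freezes min-max normalization constants
#' from the training subset, trains every candidate in the pool (early
#' stopping on the test subset), admits members through the triple
#' accuracy/precision/reliability gate evaluated on the validation subset,
#' and aggregates admitted members by an unweighted mean. An
#' applicability-domain model (descriptor-range box plus leverage with
#' threshold `h* = 3 (p + 1) / n`) is fitted on the training descriptors.
#'
#' @param data Descriptor table: eight descriptor columns plus `target`
#'   (log10 mole-fraction solubility).
#' @param pool Candidate grid, see [default_pool()].
#' @param seed Master seed controlling the split and (combined with each
#'   pool row's seed) weight initialization.
#' @param rmsd_max,outlier_max,reliability_min Admission thresholds.
#' @param target Target column name.
#' @param max_epochs,patience,learn_rate Training controls applied to all
#'   candidates.
#' @return An object of class `"ensemble_model"`: admitted `members`, the
#'   full pool `reports` tibble, frozen `normalization` constants, the
#'   applicability-domain model and the thresholds. Supports
#'   [predict()][predict.ensemble_model], [generics::tidy()],
#'   [generics::glance()].
#' @export
build_ensemble <- function(data, pool = default_pool(), seed = 1,
                           rmsd_max = 0.06, outlier_max = 2,
                           reliability_min = 99, target = "target",
                           max_epochs = 2000, patience = 150, learn_rate = 0.02) {
  stopifnot(nrow(pool) >= 1)
  features <- setdiff(names(data), target)
  splits <- split_dataset(data, seed)
  norm_train <- normalize_descriptors(splits$train, columns = features)
  constants <- attr(norm_train, "normalization")
  norm <- lapply(splits, normalize_descriptors, columns = features,
                 constants = constants)

  nets <- vector("list", nrow(pool))
  reports <- vector("list", nrow(pool))
  for (i in seq_len(nrow(pool))) {
    cfg <- nn_config(hidden_units = pool$hidden_units[i],
                     activation = pool$activation[i], loss = pool$loss[i],
                     seed = (seed * 1000L + pool$seed[i]) %% .Machine$integer.max,
                     max_epochs = max_epochs, patience = patience,
                     learn_rate = learn_rate)
    nets[[i]] <- train_candidate(cfg, norm$train, norm$test, target)
    reports[[i]] <- evaluate_member(nets[[i]], norm$validation,
                                    rmsd_max = rmsd_max,
                                    outlier_max = outlier_max,
                                    reliability_min = reliability_min)
  }
  reports <- dplyr::bind_rows(reports)
  admitted <- which(reports$admitted)
  if (length(admitted) == 0) {
    near <- dplyr::arrange(reports, .data$rmsd_val)
    stop("no candidate passed the admission gates; best validation RMSDs: ",
         paste(sprintf("%.4f", utils::head(near$rmsd_val, 5)), collapse = ", "),
         call. = FALSE)
  }

  Xtr <- cbind(1, as.matrix(norm$train[, features]))
  ad <- list(
    ranges = constants, margin = 0.05,
    n = nrow(Xtr), p = length(features),
    h_star = 3 * (length(features) + 1) / nrow(Xtr),
    # pseudo-inverse: rank-deficient designs (a constant descriptor, say)
    # keep a well-defined leverage on the informative directions
    xtx_inv = tryCatch({
      s <- svd(crossprod(Xtr))
      keep <- s$d > max(s$d) * 1e-10
      s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
    }, error = function(e) NULL)
  )
  if (is.null(ad$xtx_inv)) {
    warning("leverage model unavailable; applicability domain degraded to ",
            "the range check only.", call. = FALSE)
  }

  structure(list(
    members = nets[admitted], reports = reports, features = features,
    target = target, normalization = constants, ad = ad,
    thresholds = list(rmsd_max = rmsd_max, outlier_max = outlier_max,
                      reliability_min = reliability_min),
    seed = seed, splits_n = vapply(splits, nrow, integer(1))
  ), class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble of %d admitted shallow network(s) (pool of %d)\n",
              length(x$members), nrow(x$reports)))
  cat(sprintf("  gates: RMSD < %g, outliers <= %g%%, reliability >= %g%%\n",
              x$thresholds$rmsd_max, x$thresholds$outlier_max,
              x$thresholds$reliability_min))
  invisible(x)
}

#' Predict with an ensemble model
#'
#' Applies the frozen training normalization, averages the admitted
#' members' predictions, and attaches the member spread and the
#' applicability-domain verdict for each query.
#'
#' @param object An `"ensemble_model"`.
#' @param newdata Tibble with the raw (unnormalized) descriptor columns.
#' @param ... Unused.
#' @return A tibble with `.pred` (ensemble mean, log10 x), `.pred_min`,
#'   `.pred_max` (member extremes), `leverage`, `in_domain`.
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  norm <- normalize_descriptors(newdata, columns = object$features,
                                constants = object$normalization)
  preds <- vapply(object$members, predict, numeric(nrow(norm)), newdata = norm)
  preds <- matrix(preds, nrow = nrow(norm))
  ad <- applicability_domain(object, newdata)
  tibble::tibble(
    .pred = rowMeans(preds),
    .pred_min = apply(preds, 1, min),
    .pred_max = apply(preds, 1, max),
    leverage = ad$leverage,
    in_domain = ad$in_domain
  )
}

#' Applicability-domain check
#'
#' A query is in-domain when (a) every normalized descriptor lies within
#' `[-margin, 1 + margin]` of the training ranges and (b) its leverage
#' `h = x' (X'X)^-1 x` against the training design does not exceed the
#' Williams threshold `h* = 3 (p + 1) / n`. If the training matrix was
#' singular the check degrades to the range box alone.
#'
#' @param ensemble An `"ensemble_model"`.
#' @param newdata Tibble with raw descriptor columns.
#' @param margin Range slack on the normalized scale (default: the model's
#'   stored margin, 0.05).
#' @return A tibble `in_range`, `leverage`, `in_domain`.
#' @export
applicability_domain <- function(ensemble, newdata, margin = ensemble$ad$margin) {
  norm <- normalize_descriptors(newdata, columns = ensemble$features,
                                constants = ensemble$normalization)
  Z <- as.matrix(norm[, ensemble$features])
  in_range <- apply(Z >= -margin & Z <= 1 + margin, 1, all)
  if (!is.null(ensemble$ad$xtx_inv)) {
    Xq <- cbind(1, Z)
    leverage <- rowSums((Xq %*% ensemble$ad$xtx_inv) * Xq)
    ok_lev <- leverage <= ensemble$ad$h_star
  } else {
    leverage <- rep(NA_real_, nrow(Z))
    ok_lev <- TRUE
  }
  tibble::tibble(in_range = in_range, leverage = leverage,
                 in_domain = in_range & ok_lev)
}

#' @export
tidy.ensemble_model <- function(x, ...) x$reports

#' @export
glance.ensemble_model <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$members), n_pool = nrow(x$reports),
    admission_rate = length(x$members) / nrow(x$reports),
    best_rmsd_val = min(x$reports$rmsd_val),
    n_train = x$splits_n[["train"]], n_test = x$splits_n[["test"]],
    n_validation = x$splits_n[["validation"]]
  )
}

#' Parity plot of ensemble predictions against observed values
#'
#' @param object An `"ensemble_model"`.
#' @param data Descriptor table with the target column (e.g. the data the
#'   model was built from).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_model <- function(object, data, ...) {
  pr <- predict(object, data)
  d <- tibble::tibble(observed = data[[object$target]], predicted = pr$.pred,
                      in_domain = pr$in_domain)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                  colour = .data$in_domain)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = expression(log[10] ~ x ~ "(observed)"),
                  y = expression(log[10] ~ x ~ "(ensemble)")) +
    ggplot2::theme_minimal()
}
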
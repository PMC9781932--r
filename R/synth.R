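#' Generate a synthetic sigma-profile from Gaussian peaks
#'
#' Builds a smooth non-negative histogram on the standard grid as a sum of
#' Gaussian peaks (centre, width, area), then rescales so the total surface
#' area equals `total_area` exactly. Synthetic profiles emulate the shape
#' vocabulary of real screening-charge histograms (apolar bulk near
#' sigma = 0, hydrogen-bond donor mass at negative sigma, acceptor mass at
#' positive sigma) without claiming quantitative agreement with any
#' DFT-derived profile.
#'
#' @param peaks Data frame with columns `center` (e/A^2), `width` (e/A^2,
#'   > 0) and `area` (A^2, >= 0).
#' @param total_area Target total surface area, A^2.
#' @param grid Target grid, default [sigma_grid()].
#' @return A `"sigma_profile"`.
#' @export
make_profile <- function(peaks, total_area = sum(peaks$area), grid = sigma_grid()) {
  stopifnot(all(peaks$width > 0), all(peaks$area >= 0), total_area > 0)
  step <- grid[2] - grid[1]
  p <- Reduce(`+`, lapply(seq_len(nrow(peaks)), function(i) {
    peaks$area[i] * stats::dnorm(grid, peaks$center[i], peaks$width[i]) * step
  }))
  p <- p * total_area / sum(p)
  sigma_profile(grid, p)
}

#' Preset synthetic sigma-profiles
#'
#' Qualitative stand-ins for the main actor types of aqueous-organic
#' screening: `synth_profile_water()` has narrow polar wings at
#' sigma = -0.016 and +0.016 around a small neutral core;
#' `synth_profile_alkane()` is a single apolar hump;
#' `synth_profile_amide()` mimics an aromatic amide solute (large apolar
#' mass, an HB-donor shoulder at negative sigma, an HB-acceptor peak at
#' positive sigma); `synth_profile_aprotic()` mimics a dipolar aprotic
#' co-solvent (strong acceptor peak, no donor mass).
#'
#' @return A `"sigma_profile"`.
#' @name synth_profiles
NULL

#' @rdname synth_profiles
#' @export
synth_profile_water <- function() {
  make_profile(data.frame(center = c(-0.016, 0, 0.016),
                          width = c(0.0035, 0.004, 0.0035),
                          area = c(18, 7, 18)), total_area = 43)
}

#' @rdname synth_profiles
#' @export
synth_profile_alkane <- function() {
  make_profile(data.frame(center = 0, width = 0.004, area = 1), total_area = 200)
}

#' @rdname synth_profiles
#' @export
synth_profile_amide <- function() {
  make_profile(data.frame(center = c(-0.014, 0, 0.017),
                          width = c(0.003, 0.005, 0.003),
                          area = c(18, 110, 24)), total_area = 152)
}

#' @rdname synth_profiles
#' @export
synth_profile_aprotic <- function() {
  make_profile(data.frame(center = c(0, 0.015),
                          width = c(0.005, 0.003),
                          area = c(75, 28)), total_area = 103)
}

#' Generate a synthetic solubility dataset from known parameters
#'
#' Draws exact model solubilities from a lambda-h or Jouyban-Acree ground
#' truth, perturbs them with multiplicative log-normal noise of a given
#' coefficient of variation (solubility uncertainties scale roughly with
#' magnitude), and optionally plants gross outliers (a 50 percent
#' multiplicative error) at chosen record indices for curation tests. The
#' generator is a pure function of its arguments: the same spec and seed
#' reproduce the dataset bit-exactly.
#'
#' @param model `"lambda_h"` or `"jouyban_acree"`.
#' @param params For `"lambda_h"`: list with `lam`, `h`, `t_m`. For
#'   `"jouyban_acree"`: list with `j` (length 3) and anchor functions
#'   `ln_x2_sat(T)`, `ln_x3_sat(T)`.
#' @param temperatures Temperature grid, K.
#' @param compositions `x2_star` grid (Jouyban-Acree only; lambda-h
#'   records are neat, `x2_star = 1`).
#' @param noise_cv Relative multiplicative noise level (0 for exact model
#'   values).
#' @param seed Integer seed.
#' @param outliers Optional integer indices of records to corrupt.
#' @param solute,solvent1,solvent2 Identifier labels.
#' @return A list: `data` (standard solubility tibble), `truth` (the
#'   generating parameters) and `outliers` (the planted indices).
#' @export
make_solubility_dataset <- function(model = c("lambda_h", "jouyban_acree"),
                                    params, temperatures,
                                    compositions = NULL, noise_cv = 0, seed = 1,
                                    outliers = NULL, solute = "S",
                                    solvent1 = "ORG", solvent2 = "water") {
  model <- match.arg(model)
  if (model == "lambda_h") {
    x2 <- rep(1, length(temperatures))
    tt <- temperatures
    x <- lambda_h_solubility(params$lam, params$h, params$t_m, tt)
    s2 <- NA_character_
  } else {
    stopifnot(!is.null(compositions))
    gr <- tidyr::expand_grid(x2_star = compositions, temperature = temperatures)
    x2 <- gr$x2_star; tt <- gr$temperature
    x <- exp(jouyban_acree_predict(params, x2, tt))
    s2 <- ifelse(x2 == 1, NA_character_, solvent2)
  }
  n <- length(x)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    x <- x * with_seed(seed, exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)))
  }
  if (!is.null(outliers)) {
    stopifnot(all(outliers >= 1), all(outliers <= n))
    x[outliers] <- x[outliers] * 1.5
  }
  x <- pmin(x, 1)
  data <- tibble::tibble(
    solute = solute, solvent1 = solvent1, solvent2 = s2,
    x2_star = x2, temperature = tt, x_solute = x,
    u_x = NA_real_, source = "curated"
  )
  list(data = data, truth = params, outliers = outliers)
}

#' Generate a synthetic descriptor-to-solubility table
#'
#' Emits `n` eight-descriptor rows drawn uniformly from [0, 1] with a
#' target equal to a known smooth function of the descriptors plus
#' Gaussian noise in log10 units. The built-in target functions map into
#' the physically admissible range (log10 x <= 0) so reliability gates are
#' meaningful; with `noise_sd = 0.03` the best achievable validation RMSD
#' sits near 0.03, comfortably inside the 0.06 admission bar.
#'
#' @param n Number of rows (>= 50).
#' @param target_fn `"linear"`, `"bumpy"`, or a function taking the
#'   descriptor matrix and returning `n` target values.
#' @param noise_sd Gaussian noise standard deviation, log10 units.
#' @param seed Integer seed.
#' @return A tibble with the eight [descriptor_names()] columns and
#'   `target`.
#' @export
make_descriptor_table <- function(n, target_fn = c("linear", "bumpy"),
                                  noise_sd = 0.03, seed = 1) {
  if (n < 50) stop("need n >= 50.", call. = FALSE)
  if (is.character(target_fn)) {
    target_fn <- switch(match.arg(target_fn),
      linear = function(D) {
        w <- c(0.35, 0.2, 0.15, 0.1, 0.08, 0.06, 0.04, 0.02)
        -0.3 - 2.2 * drop(D %*% w)
      },
      bumpy = function(D) {
        -0.3 - 1.3 * D[, 1] - 0.5 * sin(pi * D[, 2]) * D[, 3] -
          0.4 * D[, 4]^2 - 0.3 * D[, 5] * D[, 6] - 0.2 * D[, 7] - 0.1 * D[, 8]
      })
  }
  with_seed(seed, {
    D <- matrix(stats::runif(n * 8), n, 8,
                dimnames = list(NULL, descriptor_names()))
    target <- target_fn(D) + stats::rnorm(n, 0, noise_sd)
    dplyr::bind_cols(tibble::as_tibble(D), tibble::tibble(target = target))
  })
}
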
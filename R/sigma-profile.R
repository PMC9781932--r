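#' The standard screening-charge-density grid
#'
#' All sigma-profiles and sigma-potentials in the package live on one
#' uniform grid of screening charge densities, sigma, in e/A^2. The default
#' span [-0.035, +0.035] with step 0.001 covers the descriptor bands
#' ([-0.03, -0.01], [-0.01, 0.01], [0.01, 0.03]) with margin and matches
#' the conventional COSMO histogram spacing.
#'
#' @param limit Half-width of the grid, e/A^2.
#' @param step Bin spacing, e/A^2.
#' @return Numeric vector of bin centres, symmetric about 0.
#' @export
sigma_grid <- function(limit = 0.035, step = 0.001) {
  n <- round(limit / step)
  seq(-n, n) * step
}

#' Construct a sigma-profile
#'
#' A sigma-profile is the histogram of a molecule's screening charge
#' density: for each sigma bin, the surface area (A^2) carrying that charge
#' density. It is the core COSMO-RS molecular fingerprint and the input to
#' the sigma-potential solver ([sigma_potential()]).
#'
#' @param sigma Bin centres, uniform and ascending, e/A^2.
#' @param p Non-negative surface-area weights, A^2 per bin.
#' @return A tibble of class `"sigma_profile"` with columns `sigma`, `p`.
#' @export
sigma_profile <- function(sigma, p) {
  stopifnot(length(sigma) == length(p))
  if (any(p < 0)) stop("profile weights `p` must be non-negative.", call. = FALSE)
  if (length(sigma) > 1) {
    d <- diff(sigma)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-9 * abs(d[1])) {
      stop("`sigma` must be a uniform ascending grid.", call. = FALSE)
    }
  }
  if (sum(p) <= 0) stop("profile must have positive total area.", call. = FALSE)
  out <- tibble::tibble(sigma = as.numeric(sigma), p = as.numeric(p))
  class(out) <- c("sigma_profile", class(out))
  out
}

#' Total surface area of a sigma-profile
#' @param profile A `"sigma_profile"`.
#' @return Total area, A^2 (sum of the bin weights).
#' @export
total_area <- function(profile) sum(profile$p)

#' Read a sigma-profile file
#'
#' Reads the common two-column text layout (sigma in e/A^2, area p(sigma)
#' in A^2 per bin; `#` comments and blank lines allowed) and rebins it onto
#' the standard internal grid by area-conserving reassignment: each source
#' bin is treated as a uniform density over its own width and integrated
#' over the target bins, so total area is preserved (to well below 0.1%)
#' and band integrals are respected.
#'
#' @param path Path to the profile file.
#' @param grid Target grid (default [sigma_grid()]); must cover the
#'   descriptor bands.
#' @return A `"sigma_profile"` on `grid`.
#' @export
read_sigma_profile <- function(path, grid = sigma_grid()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty sigma-profile file: ", path, call. = FALSE)
  mat <- do.call(rbind, lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "[,\t ]+")[[1]]))
    if (length(v) < 2 || any(is.na(v[1:2]))) {
      stop("malformed sigma-profile line: ", l, call. = FALSE)
    }
    v[1:2]
  }))
  s <- mat[, 1]; p <- mat[, 2]
  if (is.unsorted(s, strictly = TRUE)) stop("sigma column must be strictly increasing.", call. = FALSE)
  if (any(p < 0)) stop("negative p(sigma) in profile file.", call. = FALSE)
  if (length(s) > 1 && (min(s) > -0.03 || max(s) < 0.03)) {
    warning("profile grid narrower than the descriptor bands [-0.03, 0.03]; ",
            "outer bands will read as zero area.", call. = FALSE)
  }
  rebin_profile(s, p, grid)
}

# Area-conserving rebinning of a (sigma, p) histogram onto a uniform grid.
# A single input point is treated as a point mass assigned to its bin.
rebin_profile <- function(s, p, grid) {
  step <- if (length(grid) > 1) grid[2] - grid[1] else 1
  edges <- c(grid - step / 2, grid[length(grid)] + step / 2)
  out <- numeric(length(grid))
  if (length(s) == 1) {
    k <- which.min(abs(grid - s))
    out[k] <- p
  } else {
    w <- diff(s)
    src_edges <- c(s[1] - w[1] / 2, s[-length(s)] + w / 2, s[length(s)] + w[length(w)] / 2)
    for (i in seq_along(s)) {
      if (p[i] == 0) next
      lo <- src_edges[i]; hi <- src_edges[i + 1]
      dens <- p[i] / (hi - lo)
      # overlap of [lo, hi) with every target bin
      j0 <- max(1L, findInterval(lo, edges))
      j1 <- min(length(grid), max(1L, findInterval(hi, edges, rightmost.closed = TRUE)))
      for (j in j0:j1) {
        ov <- min(hi, edges[j + 1]) - max(lo, edges[j])
        if (ov > 0) out[j] <- out[j] + dens * ov
      }
    }
  }
  prof <- sigma_profile(grid, out)
  lost <- abs(sum(out) - sum(p)) / sum(p)
  if (lost > 1e-3) {
    warning(sprintf("rebinning lost %.3g%% of the surface area (grid truncation).",
                    100 * lost), call. = FALSE)
  }
  prof
}

#' Write a sigma-profile file
#'
#' Two-column text, readable by [read_sigma_profile()].
#'
#' @param profile A `"sigma_profile"`.
#' @param path Output path.
#' @return `profile`, invisibly.
#' @export
write_sigma_profile <- function(profile, path) {
  writeLines(c("# sigma [e/A^2]  p(sigma) [A^2]",
               sprintf("%.6f %.10g", profile$sigma, profile$p)), path)
  invisible(profile)
}

#' Mole-fraction-weighted mixture sigma-profile
#'
#' The sigma-profile of a mixture is the bin-wise mole-fraction-weighted sum
#' of the component profiles, so total areas mix linearly. All profiles must
#' share the same grid.
#'
#' @param profiles List of `"sigma_profile"` objects.
#' @param x Mole fractions, same length, non-negative, summing to 1
#'   (tolerance 1e-9).
#' @return A `"sigma_profile"`.
#' @export
mix_profiles <- function(profiles, x) {
  stopifnot(length(profiles) == length(x), length(profiles) >= 1)
  if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
    stop("mole fractions must be non-negative and sum to 1.", call. = FALSE)
  }
  g <- profiles[[1]]$sigma
  for (pr in profiles[-1]) {
    if (length(pr$sigma) != length(g) || max(abs(pr$sigma - g)) > 1e-12) {
      stop("all profiles must share the same sigma grid.", call. = FALSE)
    }
  }
  p <- Reduce(`+`, Map(function(pr, xi) xi * pr$p, profiles, x))
  sigma_profile(g, p)
}

#' @export
autoplot.sigma_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma, y = .data$p)) +
    ggplot2::geom_col(width = diff(object$sigma[1:2]) * 0.9, fill = "steelblue") +
    ggplot2::labs(x = expression(sigma ~ (e / ring(A)^2)),
                  y = expression(p(sigma) ~ (ring(A)^2)),
                  title = "sigma-profile") +
    ggplot2::theme_minimal()
}
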
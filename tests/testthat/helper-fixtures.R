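# Shared fixtures built in code.

# A noiseless lambda-h dataset at the acetaminophen melting point.
lh_truth <- list(lam = 0.4, h = 3000, t_m = 442.2)
lh_dataset <- function(noise_cv = 0, seed = 1, outliers = NULL,
                       temperatures = seq(288.15, 318.15, 6)) {
  make_solubility_dataset("lambda_h", lh_truth, temperatures,
                          noise_cv = noise_cv, seed = seed, outliers = outliers)
}

# A Jouyban-Acree ground truth with smooth van't Hoff-type anchors.
ja_truth <- list(
  j0 = 500, j1 = -200, j2 = 100,
  j = c(500, -200, 100),
  ln_x2_sat = function(tt) -1.2 - 600 / tt,
  ln_x3_sat = function(tt) -2.0 - 1200 / tt
)
ja_dataset <- function(noise_cv = 0, seed = 1, outliers = NULL,
                       compositions = seq(0.1, 0.9, 0.1),
                       temperatures = c(293.15, 298.15, 303.15, 308.15)) {
  make_solubility_dataset("jouyban_acree", ja_truth, temperatures,
                          compositions = compositions, noise_cv = noise_cv,
                          seed = seed, outliers = outliers)
}

# Uniform delta-like profile: all surface area in the sigma = 0 bin.
delta_profile <- function(area = 100) {
  g <- sigma_grid()
  p <- numeric(length(g))
  p[which(abs(g) < 1e-12)] <- area
  sigma_profile(g, p)
}

# A symmetric two-winged profile (used for symmetry checks).
symmetric_profile <- function() {
  make_profile(data.frame(center = c(-0.012, 0, 0.012),
                          width = c(0.003, 0.004, 0.003),
                          area = c(20, 60, 20)), total_area = 100)
}

# Small candidate pool so ensemble tests stay fast.
small_pool <- function() {
  default_pool(hidden_units = c(8, 16), activations = "tanh",
               losses = "squared", seeds = 1:3)
}

# Descriptor table computed through the real sigma pipeline for a pair of
# binary aqueous systems, with a smooth synthetic target tied to the
# computed-solubility descriptor. Cached per session: several tests share it.
pipeline_descriptor_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    am <- synth_profile_amide()
    fa <- fusion_constants("acetaminophen")
    systems <- list(aprotic = synth_profile_aprotic(),
                    alkane = synth_profile_alkane())
    grid <- seq(0, 1, 0.1)
    rows <- list()
    for (sv in names(systems)) {
      for (tt in c(298.15, 308.15)) {
        curve <- do.call(rbind, lapply(grid, function(x2) {
          mixp <- mix_profiles(list(systems[[sv]], synth_profile_water()),
                               c(x2, 1 - x2))
          st <- solve_saturation(am, mixp, fa, tt)
          data.frame(x2_star = x2,
                     ln_x = if (st$miscible_flag) 0 else log(st$x_sat),
                     miscible = st$miscible_flag)
        }))
        curve <- patch_miscibility(curve)
        for (i in seq_along(grid)) {
          dv <- descriptor_vector(am, list(systems[[sv]], synth_profile_water()),
                                  c(grid[i], 1 - grid[i]), tt,
                                  log10x_cosmo = curve$ln_x[i] / log(10))
          rows[[length(rows) + 1]] <- dv
        }
      }
    }
    tab <- dplyr::bind_rows(rows)
    # smooth, rank-preserving synthetic "experimental" solubility
    tab$target <- pmin(0, 0.8 * tab$log10x_cosmo - 0.1) +
      cosolve:::with_seed(99, stats::rnorm(nrow(tab), 0, 0.01))
    cache <<- tab
    cache
  }
})
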
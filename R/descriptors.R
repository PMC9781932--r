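#' Default charge-density bands of the affinity descriptors
#'
#' The electronegative region sigma in [-0.03, -0.01] quantifies affinity
#' for hydrogen-bond donors (HBA, acceptability); the electropositive
#' region [0.01, 0.03] quantifies affinity for acceptors (HBD, donicity);
#' the intermediate region [-0.01, 0.01] measures nonpolar character (HYD,
#' hydrophobicity).
#'
#' @return Named list of `c(lo, hi)` bands, e/A^2.
#' @export
descriptor_bands <- function() {
  list(hba = c(-0.03, -0.01), hbd = c(0.01, 0.03), hyd = c(-0.01, 0.01))
}

#' Relative solute-solvent affinity descriptors
#'
#' Contrasts the sigma-potential of the solute (as a pure liquid) with that
#' of the solute-free solvent environment. The solute potential is first
#' sigma-inverted (`mu_inv(sigma) = mu(-sigma)`) so that its donor band
#' faces the solvent's acceptor band and vice versa; each descriptor is the
#' difference of band means (the band-width-normalized area between the
#' inverted-solute and solvent curves):
#' \itemize{
#'   \item `hbd = band(mu_solute_inv, HBD) - band(mu_solvent, HBA)` -
#'     relative solute donicity with respect to solvent acceptability;
#'   \item `hba = band(mu_solute_inv, HBA) - band(mu_solvent, HBD)` -
#'     relative solute acceptability with respect to solvent donicity;
#'   \item `hyd = band(mu_solute_inv, HYD) - band(mu_solvent, HYD)` -
#'     relative hydrophobicity.
#' }
#'
#' @param solute_potential,solvent_potential `"sigma_potential"` objects on
#'   identical grids and temperature.
#' @param bands Band definition, see [descriptor_bands()].
#' @return A one-row tibble with columns `hba`, `hbd`, `hyd` (J/mol).
#' @export
affinity_descriptors <- function(solute_potential, solvent_potential,
                                 bands = descriptor_bands()) {
  if (length(solute_potential$sigma) != length(solvent_potential$sigma) ||
      max(abs(solute_potential$sigma - solvent_potential$sigma)) > 1e-12) {
    stop("potentials must share the same sigma grid.", call. = FALSE)
  }
  t1 <- attr(solute_potential, "temperature")
  t2 <- attr(solvent_potential, "temperature")
  if (!is.null(t1) && !is.null(t2) && abs(t1 - t2) > 1e-9) {
    stop("potentials were solved at different temperatures.", call. = FALSE)
  }
  inv <- solute_potential
  inv$mu <- rev(solute_potential$mu) # symmetric grid: mu(-sigma)
  tibble::tibble(
    hba = band_value(inv, bands$hba[1], bands$hba[2]) -
      band_value(solvent_potential, bands$hbd[1], bands$hbd[2]),
    hbd = band_value(inv, bands$hbd[1], bands$hbd[2]) -
      band_value(solvent_potential, bands$hba[1], bands$hba[2]),
    hyd = band_value(inv, bands$hyd[1], bands$hyd[2]) -
      band_value(solvent_potential, bands$hyd[1], bands$hyd[2])
  )
}

#' Profile-averaged contact energies between two species
#'
#' Ensemble-average misfit / hydrogen-bond / dispersion contact energies of
#' species `a` against species `b`, weighting every sigma pair by the
#' area-normalized profiles:
#' \eqn{E_j = \sum_{k,l} \hat{P}_a(\sigma_k) \hat{P}_b(\sigma_l)
#' e_j(\sigma_k, \sigma_l)}. Used to characterize the solute's interaction
#' energetics in each solvent component.
#'
#' @param profile_a,profile_b `"sigma_profile"` objects on the same grid.
#' @param params A [cosmo_params()] set.
#' @return A one-row tibble `e_misfit`, `e_hb`, `e_vdw` (J/mol).
#' @export
mean_contact_energies <- function(profile_a, profile_b, params = cosmo_params()) {
  pa <- profile_a$p / sum(profile_a$p)
  pb <- profile_b$p / sum(profile_b$p)
  g <- profile_a$sigma
  pair_w <- outer(pa, pb)
  comp <- function(which) {
    e <- outer(g, g, function(a, b) contact_energy(a, b, params)[[which]])
    sum(pair_w * e)
  }
  tibble::tibble(e_misfit = comp("e_misfit"), e_hb = comp("e_hb"),
                 e_vdw = comp("e_vdw"))
}

#' Relative interaction-energy descriptors
#'
#' For each component i, the relative contribution of interaction type j
#' (misfit, HB, vdW) is \eqn{\Delta E_j^i = E_j^i / \sum_j E_j^i}; the
#' three contributions sum to 1 wherever the denominator is nonzero. For a
#' multicomponent solvent the descriptors are mole-fraction-weighted sums
#' over the components, and `e_tot` is the weighted total interaction
#' energy.
#'
#' @param energies Tibble with one row per solvent component and columns
#'   `e_misfit`, `e_hb`, `e_vdw` (J/mol), e.g. rows of
#'   [mean_contact_energies()].
#' @param x Mole fractions of the components (sum to 1).
#' @return A one-row tibble `e_tot`, `de_misfit`, `de_hb`, `de_vdw`. When a
#'   component's total energy is zero its relative contributions are
#'   undefined and set to 0 with a warning.
#' @export
energy_descriptors <- function(energies, x = 1) {
  n <- nrow(energies)
  stopifnot(n >= 1, length(x) == n)
  if (abs(sum(x) - 1) > 1e-9) stop("mole fractions must sum to 1.", call. = FALSE)
  tot <- energies$e_misfit + energies$e_hb + energies$e_vdw
  rel <- matrix(0, n, 3)
  zero <- abs(tot) < .Machine$double.eps * 100
  if (any(zero)) {
    warning("zero total energy for ", sum(zero),
            " component(s); relative contributions set to 0.", call. = FALSE)
  }
  ok <- !zero
  rel[ok, 1] <- energies$e_misfit[ok] / tot[ok]
  rel[ok, 2] <- energies$e_hb[ok] / tot[ok]
  rel[ok, 3] <- energies$e_vdw[ok] / tot[ok]
  tibble::tibble(
    e_tot = sum(x * tot),
    de_misfit = sum(x * rel[, 1]),
    de_hb = sum(x * rel[, 2]),
    de_vdw = sum(x * rel[, 3])
  )
}

#' Names and order of the eight model descriptors
#' @return Character vector of the descriptor columns, in model order.
#' @export
descriptor_names <- function() {
  c("log10x_cosmo", "hba", "hbd", "hyd", "de_tot", "de_hb", "de_vdw", "de_misfit")
}

#' Build the eight-descriptor vector for one solute-solvent system
#'
#' Assembles the model input for one (solute, solvent composition,
#' temperature) system: the computed log10 saturation solubility
#' ([solve_saturation()], or a precomputed value), the three affinity
#' descriptors from sigma-potentials of the inverted solute versus the
#' solute-free solvent mixture ([affinity_descriptors()]), and the total
#' plus relative interaction energies ([energy_descriptors()]). `de_tot`
#' holds the total interaction energy; like every descriptor it is min-max
#' normalized per dataset before model training
#' ([normalize_descriptors()]).
#'
#' @param solute_profile `"sigma_profile"` of the solute.
#' @param solvent_profiles List of component `"sigma_profile"`s.
#' @param x Solute-free mole fractions of the components (sum to 1).
#' @param temperature Temperature, K.
#' @param fusion [fusion_props()] of the solute (used for the computed
#'   solubility descriptor; ignored when `log10x_cosmo` is supplied).
#' @param params A [cosmo_params()] set.
#' @param bands See [descriptor_bands()].
#' @param log10x_cosmo Optional precomputed log10 solubility (e.g. from a
#'   miscibility-patched grid, [patch_miscibility()]).
#' @return A one-row tibble with the eight columns of
#'   [descriptor_names()], in order.
#' @export
descriptor_vector <- function(solute_profile, solvent_profiles, x, temperature,
                              fusion = NULL, params = cosmo_params(),
                              bands = descriptor_bands(), log10x_cosmo = NULL) {
  if (!is.list(solvent_profiles) || inherits(solvent_profiles, "sigma_profile")) {
    solvent_profiles <- list(solvent_profiles)
  }
  mixture <- mix_profiles(solvent_profiles, x)
  solvent_pot <- sigma_potential(mixture, temperature, params)
  solute_pot <- sigma_potential(solute_profile, temperature, params)
  aff <- affinity_descriptors(solute_pot, solvent_pot, bands)
  en <- energy_descriptors(
    dplyr::bind_rows(lapply(solvent_profiles, function(pr) {
      mean_contact_energies(solute_profile, pr, params)
    })), x)
  if (is.null(log10x_cosmo)) {
    if (is.null(fusion)) {
      stop("supply either `fusion` properties or a precomputed `log10x_cosmo`.",
           call. = FALSE)
    }
    sat <- solve_saturation(solute_profile, mixture, fusion, temperature, params)
    log10x_cosmo <- log10(sat$x_sat)
  }
  tibble::tibble(
    log10x_cosmo = log10x_cosmo,
    hba = aff$hba, hbd = aff$hbd, hyd = aff$hyd,
    de_tot = en$e_tot, de_hb = en$de_hb, de_vdw = en$de_vdw,
    de_misfit = en$de_misfit
  )
}

#' Min-max normalize descriptor columns
#'
#' Maps each descriptor column to [0, 1] using per-column minima and maxima
#' (from `constants` when supplied, e.g. the training-split constants
#' frozen into an ensemble model; otherwise computed from `data`).
#' Constant columns map to 0.5.
#'
#' @param data Tibble containing descriptor columns.
#' @param columns Columns to normalize (default: the eight descriptors
#'   present in `data`).
#' @param constants Optional tibble `column, min, max` from a previous call
#'   (stored in attribute `"normalization"` of the result).
#' @return `data` with normalized columns and a `"normalization"`
#'   attribute.
#' @export
normalize_descriptors <- function(data, columns = intersect(descriptor_names(), names(data)),
                                  constants = NULL) {
  if (is.null(constants)) {
    constants <- tibble::tibble(
      column = columns,
      min = vapply(columns, function(cl) min(data[[cl]]), numeric(1)),
      max = vapply(columns, function(cl) max(data[[cl]]), numeric(1))
    )
  }
  for (i in seq_len(nrow(constants))) {
    cl <- constants$column[i]
    rng <- constants$max[i] - constants$min[i]
    data[[cl]] <- if (rng > 0) (data[[cl]] - constants$min[i]) / rng else 0.5
  }
  attr(data, "normalization") <- constants
  data
}
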
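#' COSMO-style surface-interaction parameter set
#'
#' Coefficients of the pairwise surface-contact energy decomposed into
#' electrostatic misfit, hydrogen bonding and dispersion (van der Waals)
#' contributions. These defaults are configuration, not claims about any
#' proprietary parametrization: magnitudes are chosen so that contacts
#' between strongly polar patches cost a few kJ/mol, the scale on which
#' published COSMO-RS misfit energies operate, and every value can be
#' overridden.
#'
#' Energies are in J/mol throughout the package.
#'
#' @param a_eff Effective contact area between two surface segments, A^2.
#' @param alpha_prime Misfit coefficient; `a_eff * alpha_prime / 2 *
#'   (sigma + sigma')^2` is the misfit energy, J/mol.
#' @param c_hb Hydrogen-bond coefficient (positive; the HB bracket is
#'   `<= 0`, making the HB energy `<= 0`).
#' @param sigma_hb Hydrogen-bond threshold charge density, e/A^2.
#' @param tau_vdw Single effective dispersion coefficient; the vdW energy is
#'   `a_eff * 2 * tau_vdw` independent of sigma (element-resolved values are
#'   collapsed to one effective coefficient).
#' @param hb_form `"cascade"` evaluates the min-cascade
#'   `min(0; min(0, sigma_don + sigma_hb); min(0, sigma_acc - sigma_hb))`
#'   with the acceptor-side min read as a gate: the term is zero whenever
#'   the acceptor patch is below the `+sigma_hb` threshold, and otherwise
#'   equals `min(0, sigma_don + sigma_hb)`; `"pair"` is the donor-acceptor
#'   product variant
#'   `min(0, sigma_don + sigma_hb) * max(0, sigma_acc - sigma_hb)` used by
#'   some published COSMO-RS flavours, which scales with both sides.
#' @return A list of class `"cosmo_params"`.
#' @export
cosmo_params <- function(a_eff = 6.25, alpha_prime = 1e6, c_hb = 2e4,
                         sigma_hb = 0.0085, tau_vdw = -200,
                         hb_form = c("cascade", "pair")) {
  stopifnot(a_eff > 0, sigma_hb >= 0, c_hb >= 0)
  structure(list(a_eff = a_eff, alpha_prime = alpha_prime, c_hb = c_hb,
                 sigma_hb = sigma_hb, tau_vdw = tau_vdw,
                 hb_form = match.arg(hb_form)),
            class = "cosmo_params")
}

GAS_CONSTANT <- 8.31446 # J/(mol K)

# Contact-energy matrices depend only on (grid, params); cache the most
# recent few so repeated potential solves on the same grid are cheap.
.energy_cache <- new.env(parent = emptyenv())

contact_energy_matrix <- function(g, params) {
  key <- paste(c(length(g), range(g), unlist(params[c("a_eff", "alpha_prime",
                                                     "c_hb", "sigma_hb",
                                                     "tau_vdw", "hb_form")])),
               collapse = "|")
  hit <- .energy_cache[[key]]
  if (!is.null(hit)) return(hit)
  e <- outer(g, g, function(a, b) contact_energy(a, b, params)$e_total)
  if (length(ls(.energy_cache)) > 8) rm(list = ls(.energy_cache), envir = .energy_cache)
  .energy_cache[[key]] <- e
  e
}

#' Pairwise surface-contact energy
#'
#' Decomposed interaction energy of two contacting surface patches with
#' screening charge densities `sigma` and `sigma_prime`:
#' misfit \eqn{E_{MF} = a_{eff} \frac{\alpha'}{2} (\sigma + \sigma')^2}
#' (always `>= 0`), hydrogen bonding
#' \eqn{E_{HB} = a_{eff} c_{HB} \min(0; \min(0, \sigma_{don} + \sigma_{HB});
#' \min(0, \sigma_{acc} - \sigma_{HB}))} with
#' \eqn{\sigma_{don} = \min(\sigma, \sigma')},
#' \eqn{\sigma_{acc} = \max(\sigma, \sigma')} (always `<= 0`), and a
#' sigma-independent dispersion term.
#'
#' @param sigma,sigma_prime Charge densities, e/A^2 (vectorized, recycled).
#' @param params A [cosmo_params()] set.
#' @return A tibble with columns `e_misfit`, `e_hb`, `e_vdw`, `e_total`
#'   (J/mol).
#' @export
contact_energy <- function(sigma, sigma_prime, params = cosmo_params()) {
  n <- max(length(sigma), length(sigma_prime))
  s <- rep_len(sigma, n); sp <- rep_len(sigma_prime, n)
  e_mf <- params$a_eff * params$alpha_prime / 2 * (s + sp)^2
  don <- pmin(s, sp); acc <- pmax(s, sp)
  # cascade: the donor min sets the strength, the acceptor min acts as a
  # gate -- no hydrogen bond unless the acceptor side crosses +sigma_hb
  # (a sub-threshold acceptor zeroes the term even for a strong donor).
  bracket <- switch(params$hb_form,
    cascade = pmin(0, don + params$sigma_hb) * (acc >= params$sigma_hb),
    pair = pmin(0, don + params$sigma_hb) * pmax(0, acc - params$sigma_hb))
  e_hb <- params$a_eff * params$c_hb * bracket
  e_vdw <- rep(params$a_eff * 2 * params$tau_vdw, n)
  tibble::tibble(e_misfit = e_mf, e_hb = e_hb, e_vdw = e_vdw,
                 e_total = e_mf + e_hb + e_vdw)
}

#' Solve the sigma-potential of a (mixture) environment
#'
#' The sigma-potential \eqn{\mu_s(\sigma)} is the chemical-potential cost
#' for placing a surface patch of charge density sigma into the environment
#' described by `profile`. It is the fixed point of
#' \deqn{\mu(\sigma) = -\frac{RT}{a_{eff}} \ln \sum_{\sigma'}
#'   \hat{P}(\sigma') \exp\left\{\frac{a_{eff}}{RT}
#'   [\mu(\sigma') - e(\sigma, \sigma')]\right\}}
#' with \eqn{\hat{P}} the area-normalized profile and
#' \eqn{e(\sigma, \sigma')} the total contact energy, solved by damped
#' successive substitution (log-sum-exp stabilized). By the package's unit
#' convention both mu and e carry the `a_eff` prefactor, i.e. they are
#' energies per contact segment in J/mol.
#'
#' @param profile A `"sigma_profile"` describing the environment (use
#'   [mix_profiles()] for mixtures).
#' @param temperature Temperature, K.
#' @param params A [cosmo_params()] set.
#' @param tol Convergence tolerance on `max |delta mu| / RT`.
#' @param max_iter Iteration cap.
#' @param damping Successive-substitution damping factor in (0, 1].
#' @param mu_init Optional starting potential (warm start, e.g. from a
#'   nearby composition).
#' @return A tibble of class `"sigma_potential"` with columns `sigma`,
#'   `mu` (J/mol) and attributes `temperature`, `iterations`, `converged`.
#' @export
sigma_potential <- function(profile, temperature, params = cosmo_params(),
                            tol = 1e-8, max_iter = 2000, damping = 0.5,
                            mu_init = NULL) {
  stopifnot(temperature > 0)
  g <- profile$sigma
  phat <- profile$p / sum(profile$p)
  rt <- GAS_CONSTANT * temperature
  beta <- params$a_eff / rt
  e_mat <- contact_energy_matrix(g, params)
  logp <- ifelse(phat > 0, log(phat), -Inf)
  mu <- if (is.null(mu_init)) numeric(length(g)) else mu_init
  converged <- FALSE
  iterations <- 0L
  neg_beta_e <- -beta * e_mat
  resid_prev <- Inf
  for (it in seq_len(max_iter)) {
    iterations <- it
    z <- neg_beta_e + rep(logp + beta * mu, each = length(g))
    m <- z[cbind(seq_along(g), max.col(z, ties.method = "first"))]
    mu_new <- -(1 / beta) * (m + log(rowSums(exp(z - m))))
    resid <- max(abs(mu_new - mu)) / rt
    mu <- (1 - damping) * mu + damping * mu_new
    # geometric-decay extrapolation: bound the remaining distance to the
    # fixed point, not just the last step size
    rho <- min(0.999, resid / resid_prev)
    err_est <- if (it > 2 && rho < 1) max(resid, resid * rho / (1 - rho)) else resid * 10
    resid_prev <- resid
    if (err_est < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("sigma-potential did not converge in %d iterations (last residual %.3g RT)",
                 max_iter, max(abs(mu_new - mu)) / rt), call. = FALSE)
  }
  out <- tibble::tibble(sigma = g, mu = mu)
  class(out) <- c("sigma_potential", class(out))
  attr(out, "temperature") <- temperature
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  out
}

#' Average sigma-potential over a charge-density band
#'
#' Arithmetic mean of mu over the grid points lying in the closed band
#' `[lo, hi]`; the data reduction behind the affinity descriptors.
#'
#' @param potential A `"sigma_potential"`.
#' @param lo,hi Band limits, e/A^2.
#' @return Mean mu over the band, J/mol.
#' @export
band_value <- function(potential, lo, hi) {
  keep <- potential$sigma >= lo - 1e-12 & potential$sigma <= hi + 1e-12
  if (!any(keep)) stop("band contains no grid points.", call. = FALSE)
  mean(potential$mu[keep])
}

#' @export
autoplot.sigma_potential <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma, y = .data$mu)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(-0.01, 0.01), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(sigma ~ (e / ring(A)^2)),
                  y = expression(mu[s](sigma) ~ (J / mol)),
                  title = sprintf("sigma-potential at %.2f K",
                                  attr(object, "temperature"))) +
    ggplot2::theme_minimal()
}
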
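#' Fusion properties of a solute
#'
#' Melting temperature and fusion enthalpy, which fix the ideal-solubility
#' reference state of a solid solute.
#'
#' @param t_m Melting temperature, K.
#' @param h_fus Fusion enthalpy, J/mol.
#' @return A list of class `"fusion_props"`.
#' @export
fusion_props <- function(t_m, h_fus) {
  stopifnot(t_m > 0, h_fus > 0)
  structure(list(t_m = t_m, h_fus = h_fus), class = "fusion_props")
}

#' Literature-averaged fusion constants for the two study solutes
#'
#' Acetaminophen: Tm = 442.2 K, Hfus = 26.90 kJ/mol. Phenacetin:
#' Tm = 408.1 K, Hfus = 30.70 kJ/mol.
#'
#' @param solute `"acetaminophen"` or `"phenacetin"`.
#' @return A [fusion_props()] object.
#' @export
fusion_constants <- function(solute = c("acetaminophen", "phenacetin")) {
  switch(match.arg(solute),
    acetaminophen = fusion_props(t_m = 442.2, h_fus = 26900),
    phenacetin = fusion_props(t_m = 408.1, h_fus = 30700))
}

#' Partial molar Gibbs free energy of melting
#'
#' The standard no-heat-capacity approximation
#' \eqn{\Delta_{fus}G(T) = \Delta H_{fus} (1 - T / T_m)}: zero at the
#' melting point, positive below it, linear in T.
#'
#' @param props A [fusion_props()] object.
#' @param temperature Temperature(s), K.
#' @return Gibbs energy of melting, J/mol.
#' @export
fusion_gibbs <- function(props, temperature) {
  stopifnot(all(temperature > 0))
  props$h_fus * (1 - temperature / props$t_m)
}

#' Iterative saturation solubility from sigma-profiles
#'
#' Computes the saturation mole fraction of a solid solute in a solvent
#' environment by iterating the solid-liquid equilibrium condition
#' \eqn{\ln(\gamma^{sat} x^{sat}) = -\Delta_{fus}G / RT}: starting from a
#' dilute guess, each cycle recomputes the saturated-mixture sigma-profile
#' (including the current solute mole fraction), solves its sigma-potential
#' and updates
#' \eqn{\ln x^{(i+1)} = -[\max(0, \Delta_{fus}G)/RT + \ln\gamma(x^{(i)})]}
#' with damping until successive `ln x` values agree to `tol`. The
#' activity coefficient is the profile-weighted sigma-potential difference
#' \eqn{\ln\gamma = \frac{a_{eff}}{RT} \sum_\sigma \hat{P}_{solute}(\sigma)
#' [\mu_{mix}(\sigma) - \mu_{solute}(\sigma)]}; the combinatorial
#' contribution is omitted (this estimate is consumed as a rank-informative
#' descriptor, not as a quantitative solubility). The `max(0, .)` guard
#' makes above-melting inputs degrade to liquid-liquid behaviour instead of
#' a negative melting penalty. When the update drives `ln x` to 0 or above,
#' the solver reports complete miscibility instead of a saturation point.
#'
#' In the ideal limit (solvent profile identical to the solute profile)
#' \eqn{\gamma = 1} and the result collapses to the closed form
#' \eqn{x = \exp(-\Delta_{fus}G / RT)}.
#'
#' @param solute_profile,solvent_profile `"sigma_profile"`s of the solute
#'   and the (possibly mixed, solute-free) solvent; same grid.
#' @param props [fusion_props()] of the solute.
#' @param temperature Temperature, K.
#' @param params A [cosmo_params()] set.
#' @param x0 Starting mole fraction.
#' @param damping Damping factor on the `ln x` update.
#' @param tol Convergence tolerance on `|ln x^(i+1) - ln x^(i)|`.
#' @param max_iter Iteration cap.
#' @return A list of class `"saturation_state"`: `x_sat`, `gamma_sat`,
#'   `ln_activity` (= ln(gamma x)), `converged`, `iterations`,
#'   `miscible_flag`.
#' @export
solve_saturation <- function(solute_profile, solvent_profile, props, temperature,
                             params = cosmo_params(), x0 = 1e-4, damping = 0.5,
                             tol = 1e-8, max_iter = 200) {
  rt <- GAS_CONSTANT * temperature
  dg <- max(0, fusion_gibbs(props, temperature))
  mu_solute <- sigma_potential(solute_profile, temperature, params)
  phat <- solute_profile$p / sum(solute_profile$p)
  mu_warm <- NULL # warm start: the mixture changes little between cycles
  ln_gamma_at <- function(x) {
    mixture <- mix_profiles(list(solute_profile, solvent_profile), c(x, 1 - x))
    mu_mix <- sigma_potential(mixture, temperature, params, mu_init = mu_warm)
    mu_warm <<- mu_mix$mu
    params$a_eff / rt * sum(phat * (mu_mix$mu - mu_solute$mu))
  }
  ln_x <- log(x0)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lg <- ln_gamma_at(exp(ln_x))
    target <- -(dg / rt + lg)
    if (target >= 0) {
      return(structure(list(x_sat = 1, gamma_sat = exp(lg), ln_activity = lg,
                            converged = TRUE, iterations = it,
                            miscible_flag = TRUE),
                       class = "saturation_state"))
    }
    ln_new <- (1 - damping) * ln_x + damping * target
    delta <- abs(ln_new - ln_x)
    ln_x <- ln_new
    trace <- c(trace, ln_x)
    if (delta < tol) {
      lg <- ln_gamma_at(exp(ln_x))
      return(structure(list(x_sat = exp(ln_x), gamma_sat = exp(lg),
                            ln_activity = lg + ln_x,
                            converged = TRUE, iterations = it,
                            miscible_flag = FALSE),
                       class = "saturation_state"))
    }
  }
  stop(sprintf("saturation iteration did not converge in %d cycles; last ln x: %s",
               max_iter,
               paste(sprintf("%.6f", utils::tail(trace, 5)), collapse = ", ")),
       call. = FALSE)
}

#' @export
print.saturation_state <- function(x, ...) {
  if (x$miscible_flag) {
    cat(sprintf("saturation state: complete miscibility flagged (%d iterations)\n",
                x$iterations))
  } else {
    cat(sprintf("saturation state: x_sat = %.6g, gamma_sat = %.4g (%d iterations)\n",
                x$x_sat, x$gamma_sat, x$iterations))
  }
  invisible(x)
}

#' Patch spurious complete-miscibility predictions on a composition grid
#'
#' Iterative COSMO-style solubility solvers can report complete
#' miscibility at high co-solvent fractions, which would inject nonphysical
#' values into the descriptor pipeline. Flagged grid points are replaced by
#' the straight-line extension (in `ln x` versus `x2_star`) fitted by least
#' squares through the last five valid points preceding the flagged run;
#' unflagged points are returned bit-exactly unchanged.
#'
#' @param curve Tibble with columns `x2_star`, `ln_x` and logical
#'   `miscible` (ordered or orderable by `x2_star`).
#' @return `curve` ordered by `x2_star`, with `ln_x` replaced on flagged
#'   rows and a logical `patched` column added.
#' @export
patch_miscibility <- function(curve) {
  stopifnot(all(c("x2_star", "ln_x", "miscible") %in% names(curve)))
  curve <- curve[order(curve$x2_star), , drop = FALSE]
  curve$patched <- FALSE
  if (!any(curve$miscible)) return(curve)
  flag <- curve$miscible
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    prev_valid <- which(!flag[seq_len(i0 - 1L)])
    if (length(prev_valid) < 5) {
      stop("need >= 5 valid points preceding a flagged region to extrapolate.",
           call. = FALSE)
    }
    anchor <- utils::tail(prev_valid, 5)
    fit <- stats::lm(ln_x ~ x2_star, data = curve[anchor, ])
    curve$ln_x[i0:i1] <- stats::predict(fit, newdata = curve[i0:i1, ])
    curve$patched[i0:i1] <- TRUE
  }
  curve
}
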
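#' Pipeline threshold defaults
#'
#' The thresholds driving every gate in the pipeline, at their canonical
#' values: 10 percent percentage-error cut for two-pass curation, the
#' RMSD < 0.06 / outliers <= 2 percent / reliability >= 99 percent ensemble
#' admission gates, and the strict EI < 0.5 green-solvent filter.
#'
#' @return Named list `curation_threshold`, `rmsd_max`, `outlier_max`,
#'   `reliability_min`, `ei_threshold`.
#' @export
screening_defaults <- function() {
  list(curation_threshold = 10, rmsd_max = 0.06, outlier_max = 2,
       reliability_min = 99, ei_threshold = 0.5)
}

#' Composition of maximum solubility at a reference temperature
#'
#' Returns the solute-free organic fraction `x2_star` at which the chosen
#' solubility column is largest among the records at the reference
#' temperature (the experimental or predicted optimum composition).
#'
#' @param data Tibble with columns `x2_star`, `temperature` and `value`.
#' @param reference_T Reference temperature, K (default 298.15).
#' @param value Name of the solubility column to maximize.
#' @param temp_tol Temperature matching tolerance, K.
#' @return The optimal `x2_star` (scalar).
#' @examples
#' t1 <- table1_solubility()
#' a_dmso <- dplyr::filter(t1, solute == "A", solvent1 == "DMSO")
#' optimal_composition(a_dmso) # 0.8
#' @export
optimal_composition <- function(data, reference_T = 298.15, value = "x_solute",
                                temp_tol = 0.01) {
  at_t <- data[abs(data$temperature - reference_T) <= temp_tol, , drop = FALSE]
  if (nrow(at_t) == 0) {
    stop("no records at the reference temperature.", call. = FALSE)
  }
  at_t$x2_star[which.max(at_t[[value]])]
}

#' Screen one candidate binary aqueous system with the ensemble
#'
#' Drives the full descriptor pipeline for one solute in
#' (organic solvent + water) across a composition grid: for every
#' temperature, iterative saturation solubilities are computed along the
#' grid, spurious complete-miscibility points are patched by linear
#' extension ([patch_miscibility()]), the eight descriptors are assembled,
#' and the ensemble predicts log10 solubility with an
#' applicability-domain verdict per point. The optimum composition is the
#' in-domain grid point with the highest prediction at the reference
#' temperature, and the whole predicted surface is re-expressed as
#' Jouyban-Acree parameters ([refit_ja()]) for portable use.
#'
#' @param ensemble A fitted [build_ensemble()] model.
#' @param solute_profile,solvent_profile,water_profile `"sigma_profile"`s
#'   of the solute, the organic component and water.
#' @param fusion [fusion_props()] of the solute.
#' @param grid Composition grid of `x2_star` values (default 0 to 1 by
#'   0.05).
#' @param temperatures Temperatures, K.
#' @param reference_T Reference temperature for the optimum (298.15 K).
#' @param params A [cosmo_params()] set.
#' @param bands See [descriptor_bands()].
#' @param solute_id,solvent_id Labels carried into the result.
#' @return An object of class `"screening_result"`: the per-point
#'   `predictions` tibble (descriptors, `.pred`, `in_domain`, `patched`),
#'   `x2_opt`, `log10x_opt`, `in_domain_fraction` and the refitted `ja`
#'   parameters. If every point is out of domain the optimum is `NA` and
#'   the result is flagged.
#' @export
screen_system <- function(ensemble, solute_profile, solvent_profile, water_profile,
                          fusion, grid = seq(0, 1, 0.05), temperatures = 298.15,
                          reference_T = 298.15, params = cosmo_params(),
                          bands = descriptor_bands(),
                          solute_id = "solute", solvent_id = "solvent") {
  rows <- list()
  for (tt in temperatures) {
    sat <- lapply(grid, function(x2) {
      mixture <- mix_profiles(list(solvent_profile, water_profile), c(x2, 1 - x2))
      solve_saturation(solute_profile, mixture, fusion, tt, params)
    })
    curve <- tibble::tibble(
      x2_star = grid,
      ln_x = vapply(sat, function(s) if (s$miscible_flag) 0 else log(s$x_sat),
                    numeric(1)),
      miscible = vapply(sat, `[[`, logical(1), "miscible_flag")
    )
    curve <- patch_miscibility(curve)
    desc <- purrr::map2_dfr(grid, curve$ln_x, function(x2, lnx) {
      descriptor_vector(solute_profile, list(solvent_profile, water_profile),
                        c(x2, 1 - x2), tt, params = params, bands = bands,
                        log10x_cosmo = lnx / log(10))
    })
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(x2_star = grid, temperature = tt, patched = curve$patched),
      desc)
  }
  predictions <- dplyr::bind_rows(rows)
  pr <- predict(ensemble, predictions)
  predictions <- dplyr::bind_cols(predictions, pr)

  ref <- predictions[abs(predictions$temperature - reference_T) < 1e-6 &
                       predictions$in_domain, , drop = FALSE]
  if (nrow(ref) == 0) {
    x2_opt <- NA_real_; log10x_opt <- NA_real_
    warning("no in-domain grid point at the reference temperature; ",
            "system flagged, not ranked.", call. = FALSE)
  } else {
    x2_opt <- optimal_composition(ref, reference_T, value = ".pred")
    log10x_opt <- max(ref$.pred)
  }

  result <- structure(list(
    solute_id = solute_id, solvent1_id = solvent_id,
    grid = grid, temperatures = temperatures, reference_T = reference_T,
    predictions = predictions,
    x2_opt = x2_opt, log10x_opt = log10x_opt,
    in_domain_fraction = mean(predictions$in_domain),
    ja = NULL
  ), class = "screening_result")
  result$ja <- tryCatch(refit_ja(result), error = function(e) NULL)
  result
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening result: %s in %s + water\n", x$solute_id, x$solvent1_id))
  cat(sprintf("  x2_opt = %s, log10x_opt = %s, in-domain fraction = %.2f\n",
              format(x$x2_opt), format(round(x$log10x_opt, 3)),
              x$in_domain_fraction))
  if (!is.null(x$ja)) {
    cat(sprintf("  JA re-fit: J0 = %.4g, J1 = %.4g, J2 = %.4g (back-fit MAPE %.2g%%)\n",
                x$ja$j[1], x$ja$j[2], x$ja$j[3], x$ja$mape))
  }
  invisible(x)
}

#' Re-express a predicted solubility surface as Jouyban-Acree parameters
#'
#' Fits the J0, J1, J2 coefficients to the ensemble's predicted surface so
#' the screening output can be used without the model itself: the
#' predicted neat-solvent endpoints anchor the model (interpolated against
#' 1/T across the screened temperatures) and the in-domain mixed
#' compositions supply the excess term.
#'
#' @param result A `"screening_result"`.
#' @return A `"jouyban_acree_fit"` whose back-fit MAPE quantifies how well
#'   the three parameters reproduce the ensemble surface.
#' @export
refit_ja <- function(result) {
  pred <- result$predictions
  as_records <- function(rows) {
    tibble::tibble(x2_star = rows$x2_star, temperature = rows$temperature,
                   x_solute = 10^rows$.pred)
  }
  end2 <- pred[pred$x2_star == 1, , drop = FALSE]
  end3 <- pred[pred$x2_star == 0, , drop = FALSE]
  if (nrow(end2) == 0 || nrow(end3) == 0) {
    stop("prediction grid must include both neat endpoints (x2* = 0 and 1).",
         call. = FALSE)
  }
  a2 <- ja_anchor(as_records(end2))
  a3 <- ja_anchor(as_records(end3))
  mixed <- pred[pred$x2_star > 0 & pred$x2_star < 1 & pred$in_domain, , drop = FALSE]
  if (nrow(mixed) < 4) stop("need >= 4 in-domain mixed compositions.", call. = FALSE)
  jouyban_acree_fit(as_records(mixed), a2, a3)
}

screening_summary <- function(result) {
  tibble::tibble(
    solute = result$solute_id, solvent1 = result$solvent1_id,
    x2_opt = result$x2_opt, log10x_opt = result$log10x_opt,
    in_domain_fraction = result$in_domain_fraction,
    j0 = if (!is.null(result$ja)) result$ja$j[1] else NA_real_,
    j1 = if (!is.null(result$ja)) result$ja$j[2] else NA_real_,
    j2 = if (!is.null(result$ja)) result$ja$j[3] else NA_real_,
    backfit_mape = if (!is.null(result$ja)) result$ja$mape else NA_real_
  )
}

#' Filter candidate solvents by environmental index and rank them
#'
#' Green screening: candidates whose environmental index is not strictly
#' below `ei_threshold` are excluded (EI = 0.51 fails a 0.5 cut; the gate
#' is a strict inequality), candidates with no EI entry are excluded with
#' a warning, and the survivors are ranked by their best in-domain
#' predicted log10 solubility (descending), ties broken by lower EI.
#'
#' @param results A list of `"screening_result"` objects, or a tibble with
#'   at least `solvent1` and `log10x_opt` columns.
#' @param meta Solvent metadata tibble (`solvent_id`, `ei`), see
#'   [read_solvent_meta()].
#' @param ei_threshold Strict EI cut (default 0.5).
#' @return The ranked tibble with `ei` and `rank` columns, one row per
#'   surviving candidate.
#' @export
rank_solvents <- function(results, meta, ei_threshold = 0.5) {
  tab <- if (inherits(results, "data.frame")) {
    tibble::as_tibble(results)
  } else {
    dplyr::bind_rows(lapply(results, screening_summary))
  }
  stopifnot(all(c("solvent1", "log10x_opt") %in% names(tab)))
  tab <- dplyr::left_join(tab, meta[, c("solvent_id", "ei")],
                          by = c(solvent1 = "solvent_id"))
  no_ei <- is.na(tab$ei)
  if (any(no_ei)) {
    warning("excluding candidate(s) with no EI entry: ",
            paste(unique(tab$solvent1[no_ei]), collapse = ", "), call. = FALSE)
  }
  kept <- tab[!no_ei & tab$ei < ei_threshold, , drop = FALSE]
  kept <- dplyr::arrange(kept, dplyr::desc(.data$log10x_opt), .data$ei)
  kept$rank <- seq_len(nrow(kept))
  kept
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.screening_result <- function(object, ...) {
  pred <- object$predictions
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$x2_star, y = .data$.pred,
                                     colour = factor(.data$temperature))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_domain)) +
    ggplot2::labs(x = expression(x[2]^"*"), y = expression(log[10] ~ x),
                  colour = "T (K)", shape = "in domain",
                  title = sprintf("%s in %s + water", object$solute_id,
                                  object$solvent1_id)) +
    ggplot2::theme_minimal()
}
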
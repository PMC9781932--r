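#' Two-pass outlier curation of solubility records
#'
#' Literature solubility collections mix methodologies and can disagree
#' badly for the same system. Before any data-driven modelling the records
#' for each system are curated in exactly two fitting passes: (1) fit the
#' chosen co-solvency model to all records; (2) exclude every record whose
#' percentage error against the pass-1 back-computed value is strictly
#' greater than `threshold` (default 10 percent), then refit on the
#' retained records. The procedure is deliberately not iterated to
#' convergence; if a third pass would still find exclusions the report's
#' `stable` flag is set to `FALSE` rather than looping.
#'
#' @param data Solubility tibble for one system (one solute in one neat
#'   solvent for `"lambda_h"`, one solute in one binary solvent for
#'   `"jouyban_acree"`).
#' @param model `"lambda_h"` or `"jouyban_acree"`.
#' @param threshold Exclusion threshold on percentage error (strict
#'   inequality: a record at exactly the threshold is retained). Default 10.
#' @param t_m Melting temperature (K), required for `"lambda_h"`.
#' @param ln_x2_sat,ln_x3_sat Anchor functions, required for
#'   `"jouyban_acree"` (see [ja_anchor()]).
#' @return An object of class `"curation_report"`: a list with `retained`
#'   and `excluded` record tibbles (a partition of the input, `excluded`
#'   carrying the pass-1 percentage error), `initial_fit`, `final_fit`,
#'   `initial_mape`, `final_mape`, `threshold` and `stable`.
#' @examples
#' syn <- make_solubility_dataset(
#'   model = "lambda_h", params = list(lam = 0.4, h = 3000, t_m = 442.2),
#'   temperatures = seq(278, 338, 3), noise_cv = 0, seed = 1,
#'   outliers = c(5, 15))
#' rep <- curate(syn$data, model = "lambda_h", t_m = 442.2)
#' nrow(rep$excluded) # the two planted outliers
#' @export
curate <- function(data, model = c("lambda_h", "jouyban_acree"), threshold = 10,
                   t_m = NULL, ln_x2_sat = NULL, ln_x3_sat = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(threshold), threshold >= 0 || is.infinite(threshold))
  fit_fn <- switch(model,
    lambda_h = function(d) {
      if (is.null(t_m)) stop("`t_m` is required for the lambda-h model.", call. = FALSE)
      lambda_h_fit(d, t_m)
    },
    jouyban_acree = function(d) {
      if (is.null(ln_x2_sat) || is.null(ln_x3_sat)) {
        stop("anchor functions are required for the Jouyban-Acree model.", call. = FALSE)
      }
      jouyban_acree_fit(d, ln_x2_sat, ln_x3_sat)
    })

  initial_fit <- fit_fn(data)
  pe1 <- initial_fit$data$pe
  drop <- pe1 > threshold
  if (all(drop)) stop("curation excluded every record.", call. = FALSE)

  retained <- data[!drop, , drop = FALSE]
  excluded <- data[drop, , drop = FALSE]
  excluded$pe_at_exclusion <- pe1[drop]

  final_fit <- if (any(drop)) fit_fn(retained) else initial_fit
  pe_final <- final_fit$data$pe
  structure(list(
    retained = retained, excluded = excluded,
    initial_fit = initial_fit, final_fit = final_fit,
    initial_mape = initial_fit$mape, final_mape = final_fit$mape,
    threshold = threshold,
    stable = !any(pe_final > threshold)
  ), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("curation report: %d retained, %d excluded (PE > %g%%)\n",
              nrow(x$retained), nrow(x$excluded), x$threshold))
  cat(sprintf("  MAPE %.3g%% -> %.3g%%%s\n", x$initial_mape, x$final_mape,
              if (x$stable) "" else "  [unstable: a third pass would still exclude]"))
  invisible(x)
}

#' @export
tidy.curation_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$retained, status = "retained", pe_at_exclusion = NA_real_),
    dplyr::mutate(x$excluded, status = "excluded")
  )
}

#' @export
glance.curation_report <- function(x, ...) {
  tibble::tibble(n_retained = nrow(x$retained), n_excluded = nrow(x$excluded),
                 initial_mape = x$initial_mape, final_mape = x$final_mape,
                 threshold = x$threshold, stable = x$stable)
}

#' @export
autoplot.curation_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature, y = .data$x_solute,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(retained = "grey30",
                                            excluded = "firebrick")) +
    ggplot2::labs(x = "T (K)", y = "mole-fraction solubility",
                  title = sprintf("two-pass curation (PE > %g%% excluded)",
                                  object$threshold)) +
    ggplot2::theme_minimal()
}
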
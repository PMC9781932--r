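#' Percentage error between observed and estimated solubility
#'
#' The unsigned relative deviation of an estimate from an experimental value,
#' expressed in percent: \eqn{PE = |x^{exp} - x^{est}| / x^{exp} \times 100}.
#' This is the statistic used both for reporting model accuracy and as the
#' exclusion criterion in two-pass data curation (see [curate()]).
#'
#' Note the asymmetry: the denominator is always the experimental value, so
#' `percentage_error(a, b)` is generally not `percentage_error(b, a)`.
#'
#' @param x_exp Numeric vector of experimental (reference) values; must be
#'   strictly positive.
#' @param x_est Numeric vector of estimated values, recycled against `x_exp`.
#' @return Numeric vector of percentage errors, `>= 0`.
#' @examples
#' percentage_error(0.20, 0.22) # 10
#' @export
percentage_error <- function(x_exp, x_est) {
  if (any(!is.finite(x_exp)) || any(x_exp <= 0)) {
    stop("`x_exp` must be finite and strictly positive.", call. = FALSE)
  }
  abs(x_exp - x_est) / x_exp * 100
}

#' Mean averaged percentage error (MAPE)
#'
#' Arithmetic mean of per-point percentage errors ([percentage_error()]).
#'
#' @inheritParams percentage_error
#' @return A single non-negative number, in percent.
#' @examples
#' mape(c(0.1, 0.2), c(0.11, 0.18)) # 10
#' @export
mape <- function(x_exp, x_est) {
  if (length(x_exp) != length(x_est)) {
    stop("`x_exp` and `x_est` must have the same length.", call. = FALSE)
  }
  if (length(x_exp) < 1L) stop("need at least one point.", call. = FALSE)
  mean(percentage_error(x_exp, x_est))
}

#' Root mean squared deviation (RMSD)
#'
#' \eqn{\sqrt{\frac{1}{N}\sum_i (x_i^{est} - x_i^{exp})^2}}, in the units of
#' the inputs. Zero exactly when the two vectors are identical.
#'
#' @inheritParams mape
#' @return A single non-negative number.
#' @export
rmsd <- function(x_exp, x_est) {
  if (length(x_exp) != length(x_est)) {
    stop("`x_exp` and `x_est` must have the same length.", call. = FALSE)
  }
  if (length(x_exp) < 1L) stop("need at least one point.", call. = FALSE)
  sqrt(mean((x_est - x_exp)^2))
}

#' Base-10 logarithm of a mole-fraction solubility
#'
#' Solubilities are modelled and reported on the log10 mole-fraction scale,
#' which is the conventional reporting scale for drug solubility spanning
#' several orders of magnitude. A mole fraction lies in (0, 1], so the result
#' is always `<= 0`.
#'
#' @param x_solute Mole-fraction solubility in (0, 1].
#' @return `log10(x_solute)`.
#' @examples
#' to_log10(0.3161) # about -0.50
#' @export
to_log10 <- function(x_solute) {
  if (any(!is.finite(x_solute)) || any(x_solute <= 0) || any(x_solute > 1)) {
    stop("`x_solute` must lie in (0, 1].", call. = FALSE)
  }
  log10(x_solute)
}
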
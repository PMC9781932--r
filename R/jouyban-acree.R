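#' Jouyban-Acree log-solubility in a binary solvent
#'
#' The co-solvency model
#' \deqn{\ln x_1 = x_2^* \ln x_{1,2}^{sat} + x_3^* \ln x_{1,3}^{sat} +
#'   \frac{x_2^* x_3^*}{T} \sum_{i=0}^{2} J_i (x_2^* - x_3^*)^i}
#' where \eqn{x_2^*} is the solute-free mole fraction of the organic
#' component, \eqn{x_3^* = 1 - x_2^*}, and the neat-solvent saturation
#' anchors \eqn{\ln x_{1,2}^{sat}(T)}, \eqn{\ln x_{1,3}^{sat}(T)} are
#' supplied per temperature. At the endpoints the prediction equals the
#' corresponding neat-solvent solubility exactly.
#'
#' @param params A `"jouyban_acree_fit"` or a list with numeric `j`
#'   (length 3: J0, J1, J2, in K) and functions `ln_x2_sat(T)`,
#'   `ln_x3_sat(T)`.
#' @param x2_star Solute-free organic mole fraction(s) in [0, 1].
#' @param temperature Temperature(s), K.
#' @return Natural-log mole-fraction solubility `ln x1`.
#' @seealso [jouyban_acree_fit()], [ja_anchor()]
#' @export
jouyban_acree_predict <- function(params, x2_star, temperature) {
  if (any(x2_star < 0 | x2_star > 1)) stop("`x2_star` must lie in [0, 1].", call. = FALSE)
  if (any(temperature <= 0)) stop("`temperature` must be positive.", call. = FALSE)
  j <- params$j
  x3 <- 1 - x2_star
  d <- x2_star - x3
  excess <- x2_star * x3 / temperature * (j[1] + j[2] * d + j[3] * d^2)
  x2_star * params$ln_x2_sat(temperature) + x3 * params$ln_x3_sat(temperature) + excess
}

#' Neat-solvent saturation anchor as a function of temperature
#'
#' The Jouyban-Acree model needs `ln x_sat(T)` of the solute in each neat
#' solvent at every requested temperature. When a fitted lambda-h model is
#' supplied the anchor is its prediction; otherwise `ln x` is interpolated
#' (and linearly extrapolated) against `1/T` through the neat-solvent
#' records, the conventional van't Hoff-type smoothing.
#'
#' @param data Solubility tibble of neat-solvent records (`temperature`,
#'   `x_solute`); ignored when `fit` is given.
#' @param fit Optional `"lambda_h_fit"` for the same solute + solvent.
#' @return A function `f(T) -> ln x_sat`.
#' @export
ja_anchor <- function(data = NULL, fit = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "lambda_h_fit"))
    return(function(temperature) log(predict(fit, temperature)))
  }
  stopifnot(!is.null(data), nrow(data) >= 1)
  if (nrow(data) == 1) {
    v <- log(data$x_solute)
    return(function(temperature) rep(v, length(temperature)))
  }
  cf <- stats::coef(stats::lm(log(x_solute) ~ I(1 / temperature), data = data))
  function(temperature) cf[[1]] + cf[[2]] / temperature
}

#' Fit Jouyban-Acree parameters to binary-solvent records
#'
#' The model is linear in (J0, J1, J2) once the neat anchors are fixed:
#' mixed-composition records are transformed to the excess response
#' \eqn{y = [\ln x_1 - x_2^* \ln x_2^{sat} - x_3^* \ln x_3^{sat}]
#'   \, T / (x_2^* x_3^*)}
#' and regressed on the basis \eqn{\{1, (x_2^*-x_3^*), (x_2^*-x_3^*)^2\}}
#' by ordinary least squares. A single pooled J set is fitted across
#' temperatures (T enters the model explicitly).
#'
#' @param data Solubility tibble for one solute + binary system; at least 4
#'   mixed-composition records (`0 < x2_star < 1`) at 2 or more distinct
#'   compositions are required.
#' @param ln_x2_sat,ln_x3_sat Anchor functions `f(T) -> ln x_sat` for the
#'   organic (solvent 2) and aqueous (solvent 3) endpoints; see
#'   [ja_anchor()].
#' @return An object of class `"jouyban_acree_fit"` with `j` (J0, J1, J2),
#'   the anchors, fitted values and fit statistics. Supports
#'   [predict()][predict.jouyban_acree_fit], [generics::tidy()] and
#'   [generics::glance()].
#' @export
jouyban_acree_fit <- function(data, ln_x2_sat, ln_x3_sat) {
  mixed <- data[data$x2_star > 0 & data$x2_star < 1, , drop = FALSE]
  if (nrow(mixed) < 4) stop("need >= 4 mixed-composition records.", call. = FALSE)
  if (length(unique(mixed$x2_star)) < 2) {
    stop("rank-deficient design: all records at a single composition.", call. = FALSE)
  }
  x2 <- mixed$x2_star; x3 <- 1 - x2; tt <- mixed$temperature
  y <- (log(mixed$x_solute) - x2 * ln_x2_sat(tt) - x3 * ln_x3_sat(tt)) * tt / (x2 * x3)
  d <- x2 - x3
  X <- cbind(1, d, d^2)
  qrX <- qr(X)
  if (qrX$rank < 3 && length(unique(d)) >= 3) {
    stop("rank-deficient Jouyban-Acree design.", call. = FALSE)
  }
  j <- qr.coef(qrX, y)
  j[is.na(j)] <- 0
  params <- list(j = unname(j), ln_x2_sat = ln_x2_sat, ln_x3_sat = ln_x3_sat)
  pred_ln <- jouyban_acree_predict(params, data$x2_star, data$temperature)
  structure(c(params, list(
    data = tibble::tibble(x2_star = data$x2_star,
                          temperature = data$temperature,
                          x_solute = data$x_solute,
                          fitted = exp(pred_ln),
                          pe = percentage_error(data$x_solute, exp(pred_ln))),
    mape = mape(data$x_solute, exp(pred_ln)),
    rmsd_log10 = rmsd(log10(data$x_solute), pred_ln / log(10)),
    n = nrow(data)
  )), class = "jouyban_acree_fit")
}

#' @export
print.jouyban_acree_fit <- function(x, ...) {
  cat(sprintf("Jouyban-Acree fit: J0 = %.6g, J1 = %.6g, J2 = %.6g (K)\n",
              x$j[1], x$j[2], x$j[3]))
  cat(sprintf("  n = %d, back-fit MAPE = %.3g%%\n", x$n, x$mape))
  invisible(x)
}

#' Predict from a fitted Jouyban-Acree model
#'
#' @param object A `"jouyban_acree_fit"`.
#' @param x2_star,temperature Composition and temperature grids (recycled
#'   together).
#' @param ... Unused.
#' @return Natural-log mole-fraction solubility.
#' @export
predict.jouyban_acree_fit <- function(object, x2_star = object$data$x2_star,
                                      temperature = object$data$temperature, ...) {
  jouyban_acree_predict(object, x2_star, temperature)
}

#' @export
tidy.jouyban_acree_fit <- function(x, ...) {
  tibble::tibble(term = c("j0", "j1", "j2"), estimate = x$j)
}

#' @export
glance.jouyban_acree_fit <- function(x, ...) {
  tibble::tibble(mape = x$mape, rmsd_log10 = x$rmsd_log10, n = x$n)
}
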
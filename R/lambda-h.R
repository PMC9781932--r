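#' Buchowski-Ksiazczak (lambda-h) solubility at a temperature
#'
#' Solves the two-parameter solid-liquid equilibrium equation
#' \deqn{\ln\left[1 + \frac{\lambda(1-x)}{x}\right] = \lambda h
#'   \left(\frac{1}{T} - \frac{1}{T_m}\right)}
#' for the saturation mole fraction \eqn{x \in (0, 1]}. `h` carries the
#' energetics of solubilization (lambda*h has units of K) and `lambda`
#' indexes solute association. The left-hand side is strictly decreasing in
#' `x`, so the root is found by bisection to a residual below 1e-12; at
#' `T = t_m` the model passes exactly through the pure-melt point `x = 1`.
#'
#' @param lam,h Model parameters; `lam > 0`, `h` in K (via `lam * h`).
#' @param t_m Melting temperature, K.
#' @param temperature Temperature(s), K, with `0 < T <= t_m`.
#' @return Mole-fraction solubility, same length as `temperature`.
#' @examples
#' # with lam = 1 the model collapses to x = exp(-h (1/T - 1/Tm))
#' lambda_h_solubility(1, 2000, t_m = 400, temperature = 300)
#' @export
lambda_h_solubility <- function(lam, h, t_m, temperature) {
  stopifnot(lam > 0, t_m > 0)
  if (any(temperature <= 0) || any(temperature > t_m + 1e-9)) {
    stop("`temperature` must satisfy 0 < T <= t_m.", call. = FALSE)
  }
  vapply(temperature, function(tt) {
    rhs <- lam * h * (1 / tt - 1 / t_m)
    f <- function(x) log1p(lam * (1 - x) / x) - rhs
    if (abs(rhs) < 1e-15) return(1)
    lo <- 1e-12; hi <- 1
    if (f(lo) < 0 || f(hi) > 1e-12) {
      stop(sprintf("no solubility root in (0,1] for T = %.6g K (bracket f: %.3g, %.3g)",
                   tt, f(lo), f(hi)), call. = FALSE)
    }
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-16 || abs(f((lo + hi) / 2)) < 1e-13) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Fit the lambda-h model to neat-solvent solubility records
#'
#' Least-squares fit of [lambda_h_solubility()] parameters to a set of
#' records for one solute in one neat solvent. Residuals are taken in
#' log10(x) because solubilities in a diverse solvent pool span several
#' orders of magnitude; accuracy is reported as MAPE on the linear scale.
#'
#' @param data Solubility tibble (columns `temperature`, `x_solute`) for a
#'   single solute + neat solvent; at least 3 records spanning at least 2
#'   distinct temperatures (2 records at 2 temperatures give a saturated,
#'   exactly interpolating fit).
#' @param t_m Melting temperature of the solute, K.
#' @param start Optional starting values `c(lam, h)`.
#' @return An object of class `"lambda_h_fit"`: a list with `lam`, `h`,
#'   `t_m`, the data, fitted values, and fit statistics. Supports
#'   [predict()][predict.lambda_h_fit], [generics::tidy()] and
#'   [generics::glance()].
#' @export
lambda_h_fit <- function(data, t_m, start = c(lam = 0.5, h = 2000)) {
  temperature <- data$temperature
  x <- data$x_solute
  if (length(unique(temperature)) < 2) {
    stop("need records at >= 2 distinct temperatures.", call. = FALSE)
  }
  if (length(x) < 2) stop("need >= 2 records.", call. = FALSE)
  obj <- function(par) {
    lam <- exp(par[1]); h <- par[2]
    pred <- tryCatch(lambda_h_solubility(lam, h, t_m, temperature),
                     error = function(e) rep(NA_real_, length(temperature)))
    if (any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
    sum((log10(pred) - log10(x))^2)
  }
  fit <- stats::optim(c(log(start[[1]]), start[[2]]), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  # polish from the simplex optimum
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  lam <- exp(fit$par[1]); h <- fit$par[2]
  fitted <- lambda_h_solubility(lam, h, t_m, temperature)
  structure(list(
    lam = lam, h = h, t_m = t_m,
    data = tibble::tibble(temperature = temperature, x_solute = x,
                          fitted = fitted,
                          pe = percentage_error(x, fitted)),
    sse_log10 = fit$value,
    mape = mape(x, fitted),
    rmsd_log10 = rmsd(log10(x), log10(fitted)),
    n = length(x)
  ), class = "lambda_h_fit")
}

#' @export
print.lambda_h_fit <- function(x, ...) {
  cat(sprintf("lambda-h fit: lambda = %.4g, h = %.6g K (t_m = %.6g K)\n",
              x$lam, x$h, x$t_m))
  cat(sprintf("  n = %d, MAPE = %.3g%%, RMSD(log10 x) = %.3g\n",
              x$n, x$mape, x$rmsd_log10))
  invisible(x)
}

#' Predict from a fitted lambda-h model
#'
#' @param object A `"lambda_h_fit"`.
#' @param temperature Temperatures, K.
#' @param ... Unused.
#' @return Mole-fraction solubilities.
#' @export
predict.lambda_h_fit <- function(object, temperature = object$data$temperature, ...) {
  lambda_h_solubility(object$lam, object$h, object$t_m, temperature)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.lambda_h_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda", "h"), estimate = c(x$lam, x$h))
}

#' @export
glance.lambda_h_fit <- function(x, ...) {
  tibble::tibble(mape = x$mape, rmsd_log10 = x$rmsd_log10, n = x$n,
                 sse_log10 = x$sse_log10)
}
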
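#' Fit a Boltzmann sigmoid to a detergent solubilization series
#'
#' Nonlinear least squares of
#' `y = Bottom + (Top - Bottom) / (1 + exp((x - V50)/slope))`
#' via Levenberg-Marquardt. Start values: `Top = max(y)`, `Bottom = min(y)`,
#' `V50 = x` at the point closest to midrange, `slope = (max(x) - min(x))/10`.
#' On failure the start is jittered for a bounded number of restarts.
#'
#' At the fitted `V50` the curve passes through `(Top + Bottom)/2` by
#' construction (the inflection point of the sigmoid).
#'
#' @param series A `solubilization_series` (see
#'   [new_solubilization_series()]).
#' @param max_restarts Restarts with jittered starts on non-convergence.
#' @return List of class `boltzmann_fit`: `top`, `bottom`, `v50`, `slope`,
#'   `rss`, `converged`, and `fitted` values.
#' @export
fit_boltzmann <- function(series, max_restarts = 5) {
  stopifnot(inherits(series, "solubilization_series"))
  x <- series$x; y <- series$y
  start <- list(top = max(y), bottom = min(y),
                v50 = x[which.min(abs(y - (max(y) + min(y)) / 2))],
                slope = (max(x) - min(x)) / 10)
  last_err <- NULL
  for (attempt in 0:max_restarts) {
    st <- start
    if (attempt > 0) {
      jit <- local_seed(attempt, stats::runif(4, 0.7, 1.3))
      st <- list(top = start$top * jit[1], bottom = start$bottom * jit[2],
                 v50 = start$v50 * jit[3], slope = start$slope * jit[4])
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + exp((x - v50) / slope)),
                        data = data.frame(x = x, y = y), start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      cf <- stats::coef(fit)
      return(structure(list(top = unname(cf["top"]),
                            bottom = unname(cf["bottom"]),
                            v50 = unname(cf["v50"]),
                            slope = unname(cf["slope"]),
                            rss = sum(stats::residuals(fit)^2),
                            converged = fit$convInfo$isConv,
                            fitted = stats::fitted(fit)),
                       class = "boltzmann_fit"))
    }
    last_err <- fit
  }
  stop_config("Boltzmann fit failed after %d restarts: %s", max_restarts,
              conditionMessage(last_err))
}

#' Predict scattering from a Boltzmann fit
#' @param object A `boltzmann_fit`.
#' @param newdata Optional data frame with column `x`.
#' @param ... Unused.
#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  boltzmann(newdata$x, object$top, object$bottom, object$v50, object$slope)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: Top %.4g, Bottom %.4g, V50 %.4g mM, slope %.4g mM (RSS %.3g)\n",
              x$top, x$bottom, x$v50, x$slope, x$rss))
  invisible(x)
}
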
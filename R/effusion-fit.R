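# Recovery of the characteristic effusion time from sampled concentration
# decays: least-squares fit of log-concentration against time.

#' Recover the effusion time from a sampled concentration decay
#'
#' Fits the exponential effusion model `c(t) = c0 * exp(-t / tau)` to
#' `(t, c)` samples by ordinary least squares on the log scale, and
#' returns the estimated e-folding time with its standard error (delta
#' method on the fitted slope). This is the parameter-recovery companion
#' of [solute_decay()] and [effusion_time()].
#'
#' @param time Sample times, s (at least 5, spanning at least one decay
#'   time for a trustworthy estimate).
#' @param conc Sampled concentrations; non-positive values (possible
#'   after noise) are dropped with a warning.
#' @return An object of class `effusion_fit`: list with `tau` (s),
#'   `se_tau`, `log_c0`, `fit` (the underlying `lm`), `n_used`.
#'   Supports `coef()`, `predict()`, `residuals()`, `summary()`.
#' @examples
#' t <- seq(0, 2, 0.05)
#' fit <- recover_effusion_time(t, 200 * exp(-t / 0.533))
#' coef(fit)["tau"]  # 0.533
#' @export
recover_effusion_time <- function(time, conc) {
  if (length(time) != length(conc)) {
    stop("recover_effusion_time: time and conc must have equal length")
  }
  keep <- is.finite(time) & is.finite(conc) & conc > 0
  if (any(!keep & is.finite(conc) & conc <= 0)) {
    warning("recover_effusion_time: dropped ", sum(conc <= 0, na.rm = TRUE),
            " non-positive concentration sample(s)")
  }
  time <- time[keep]; conc <- conc[keep]
  if (length(time) < 5L) {
    stop("recover_effusion_time: need at least 5 positive samples")
  }
  fit <- lm(log(conc) ~ time)
  slope <- coef(fit)[["time"]]
  if (slope >= 0) {
    stop("recover_effusion_time: samples do not decay ",
         "(fitted slope ", signif(slope, 3), " >= 0)")
  }
  se_slope <- suppressWarnings(
    summary(fit)$coefficients["time", "Std. Error"])
  out <- list(tau = -1 / slope,
              se_tau = se_slope / slope^2,
              log_c0 = coef(fit)[["(Intercept)"]],
              fit = fit,
              n_used = length(time))
  class(out) <- "effusion_fit"
  out
}

#' @export
coef.effusion_fit <- function(object, ...) {
  c(tau = object$tau, c0 = exp(object$log_c0))
}

#' @export
print.effusion_fit <- function(x, ...) {
  cat(sprintf("Effusion-time fit: tau = %.4g s (se %.2g), c0 = %.4g, n = %d\n",
              x$tau, x$se_tau, exp(x$log_c0), x$n_used))
  invisible(x)
}

#' @export
summary.effusion_fit <- function(object, ...) {
  print(object)
  cat("Underlying log-linear fit:\n")
  print(summary(object$fit)$coefficients)
  invisible(object)
}

#' Predicted concentrations from an effusion fit
#'
#' @param object An `effusion_fit`.
#' @param time Times at which to predict, s; defaults to the fitted
#'   times.
#' @param ... Unused.
#' @return Predicted concentrations on the original scale.
#' @export
predict.effusion_fit <- function(object, time = NULL, ...) {
  if (is.null(time)) {
    exp(predict(object$fit))
  } else {
    exp(object$log_c0 - time / object$tau)
  }
}

#' @export
residuals.effusion_fit <- function(object, ...) {
  residuals(object$fit)
}
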
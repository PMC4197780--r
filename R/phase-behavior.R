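# Tension-coupled membrane phase state: maps instantaneous tension to a
# binary uniform/domain-textured indicator synchronized with swell-burst
# cycles.

#' Phase-model parameters
#'
#' Parameters of the binary membrane phase-state indicator. Two modes are
#' provided. `"threshold"` (default) declares liquid-ordered /
#' liquid-disordered domains whenever the tension exceeds `sigma_phase`;
#' the default threshold sits inside the undulation-to-stretching
#' crossover band (0.1--1 mN/m), the tension scale at which the membrane
#' state changes qualitatively. `"temperature_shift"` instead shifts the
#' miscibility transition temperature linearly with tension at rate
#' `dT_dsigma` and declares domains when the working temperature falls at
#' or below the shifted transition; with the reported negative slope
#' (about -1 K per mN/m) tension alone *disfavours* domains, which is the
#' open mechanistic question this mode lets users explore.
#'
#' @param sigma_phase Tension threshold for domain appearance, N/m
#'   (threshold mode). Default `5e-4`.
#' @param dT_dsigma Miscibility-temperature shift per unit tension,
#'   K/(N/m). Default `-1000` (i.e. -1 K per mN/m).
#' @param T_mix0 Zero-tension miscibility transition temperature, K.
#'   Default `297` (just below room temperature, so an untensed membrane
#'   is uniform at 298.15 K).
#' @param mode `"threshold"` or `"temperature_shift"`.
#' @return An object of class `phase_model_params`.
#' @examples
#' phase_model_params()
#' @export
phase_model_params <- function(sigma_phase = 5e-4, dT_dsigma = -1000,
                               T_mix0 = 297,
                               mode = c("threshold", "temperature_shift")) {
  mode <- match.arg(mode)
  if (!is.numeric(sigma_phase) || length(sigma_phase) != 1L || sigma_phase <= 0) {
    stop("phase_model_params: sigma_phase must be a single positive number")
  }
  if (!is.numeric(dT_dsigma) || length(dT_dsigma) != 1L || !is.finite(dT_dsigma)) {
    stop("phase_model_params: dT_dsigma must be a single finite number")
  }
  if (!is.numeric(T_mix0) || length(T_mix0) != 1L || T_mix0 <= 0) {
    stop("phase_model_params: T_mix0 must be a single positive number")
  }
  p <- list(sigma_phase = sigma_phase, dT_dsigma = dT_dsigma,
            T_mix0 = T_mix0, mode = mode)
  class(p) <- "phase_model_params"
  p
}

#' @export
print.phase_model_params <- function(x, ...) {
  cat("Phase model (", x$mode, " mode):\n", sep = "")
  cat(sprintf("  sigma_phase  %.3g N/m\n", x$sigma_phase))
  cat(sprintf("  dT/dsigma    %.3g K/(N/m)\n", x$dT_dsigma))
  cat(sprintf("  T_mix0       %.2f K\n", x$T_mix0))
  invisible(x)
}

#' Membrane phase state at a given tension
#'
#' Deterministic, hysteresis-free binary classification of the membrane
#' as `"UNIFORM"` (optically homogeneous) or `"DOMAINS"`
#' (phase-separated). In threshold mode, domains appear at and above
#' `sigma_phase`; composed with a simulated trajectory this flips to
#' uniform once per cycle as the pore collapses the tension.
#'
#' @param sigma Membrane tension, N/m (non-negative; vectorised).
#' @param T Working temperature, K (used in temperature-shift mode).
#' @param params A [phase_model_params()] object.
#' @return Character vector of `"UNIFORM"` / `"DOMAINS"`.
#' @examples
#' phase_state(c(0, 5e-3))
#' @export
phase_state <- function(sigma, T = 298.15, params = phase_model_params()) {
  if (any(sigma < 0)) stop("phase_state: tension must be non-negative")
  domains <- switch(params$mode,
    threshold = sigma >= params$sigma_phase,
    temperature_shift = T <= params$T_mix0 + params$dT_dsigma * sigma
  )
  ifelse(domains, "DOMAINS", "UNIFORM")
}

#' Tension-induced shift of the miscibility transition temperature
#'
#' Linear shift `dT_dsigma * sigma` of the liquid-ordered /
#' liquid-disordered miscibility temperature with membrane tension.
#'
#' @param sigma Membrane tension, N/m (non-negative; vectorised).
#' @param params A [phase_model_params()] object.
#' @return Temperature shift, K (negative for the default slope).
#' @examples
#' miscibility_shift(1e-3)  # -1 K at 1 mN/m with the default slope
#' @export
miscibility_shift <- function(sigma, params = phase_model_params()) {
  if (any(sigma < 0)) stop("miscibility_shift: tension must be non-negative")
  params$dT_dsigma * sigma
}
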
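# Water and solute transport: van't Hoff pressure, trans-membrane water
# flux, diffusive effusion through an open pore, pressure-driven outflow.

#' Transport parameters
#'
#' Permeabilities and fluid constants for the osmotic transport laws.
#' Defaults describe sucrose-loaded phospholipid GUVs in water: water
#' permeability 1e-5 m/s (1e-3 cm/s), sucrose membrane permeability
#' 1e-10 m/s (effectively impermeant on experimental timescales, so the
#' background leak is off by default in the engine), sucrose diffusivity
#' in water 1e-9 m^2/s.
#'
#' @param P_w Osmotic water permeability of the membrane, m/s.
#' @param P_s Solute permeability of the intact membrane, m/s (used only
#'   when the engine's background leak is enabled).
#' @param D Solute diffusivity in water, m^2/s.
#' @param v_w Molar volume of water, m^3/mol.
#' @param eta Viscosity of the aqueous medium, Pa s.
#' @param preset Optional preset; `"fast_water"` sets `P_w = 1e-4` m/s
#'   (the upper end of reported water permeabilities).
#' @return An object of class `transport_params` (named list).
#' @examples
#' transport_params()
#' transport_params(preset = "fast_water")$P_w
#' @export
transport_params <- function(P_w = 1e-5, P_s = 1e-10, D = 1e-9,
                             v_w = 1.8e-5, eta = 1e-3, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("fast_water"))
    if (preset == "fast_water") P_w <- 1e-4
  }
  p <- list(P_w = P_w, P_s = P_s, D = D, v_w = v_w, eta = eta)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("transport_params: '", nm, "' must be a single positive number")
    }
  }
  class(p) <- "transport_params"
  p
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Transport parameters:\n")
  cat(sprintf("  water permeability P_w   %.3g m/s\n", x$P_w))
  cat(sprintf("  solute permeability P_s  %.3g m/s\n", x$P_s))
  cat(sprintf("  solute diffusivity D     %.3g m^2/s\n", x$D))
  cat(sprintf("  water molar volume       %.3g m^3/mol\n", x$v_w))
  cat(sprintf("  medium viscosity         %.3g Pa s\n", x$eta))
  invisible(x)
}

#' van't Hoff osmotic pressure
#'
#' Ideal osmotic pressure of a dilute solute concentration difference:
#' `delta_P = R_gas * T * delta_c`. Signed: negative differences
#' (hypertonic bath) give negative pressure.
#'
#' @param delta_c Osmolyte concentration difference (inside minus
#'   outside), mol/m^3. Note 1 mM = 1 mol/m^3.
#' @param T Absolute temperature, K.
#' @return Osmotic pressure, Pa.
#' @examples
#' vant_hoff_pressure(200, 298.15)  # ~0.5 MPa for a 200 mM differential
#' @export
vant_hoff_pressure <- function(delta_c, T = 298.15) {
  if (any(T <= 0)) stop("vant_hoff_pressure: temperature must be positive")
  .Rgas * T * delta_c
}

#' Osmotic water volume flux across the membrane
#'
#' Linear osmotic flux law: `Q = P_w * v_w * A * delta_c_eff`, with
#' `delta_c_eff` the effective driving concentration difference. Callers
#' fold the opposing Laplace pressure into `delta_c_eff` as
#' `delta_c - 2*sigma/(R * R_gas * T)`, so the flux vanishes at
#' osmotic/Laplace balance. Positive values mean influx (swelling).
#'
#' @param A Membrane area, m^2 (positive).
#' @param delta_c_eff Effective concentration difference, mol/m^3 (signed).
#' @param params A [transport_params()] object.
#' @return Volume rate, m^3/s.
#' @examples
#' water_volume_flux(4 * pi * (10e-6)^2, 200)  # ~4.5e-17 m^3/s
#' @export
water_volume_flux <- function(A, delta_c_eff, params = transport_params()) {
  if (any(A <= 0)) stop("water_volume_flux: area must be positive")
  params$P_w * params$v_w * A * delta_c_eff
}

#' Diffusive solute current through an open pore
#'
#' Effusion current through a pore of radius `r` in a vesicle of radius
#' `R` holding interior concentration `c`:
#' \deqn{j = \pi r^2 c D / R.}
#'
#' @param r Pore radius, m (non-negative; zero gives zero current).
#' @param c Intravesicular solute concentration, mol/m^3 (non-negative).
#' @param D Solute diffusivity, m^2/s.
#' @param R Vesicle radius, m (strictly positive).
#' @return Solute current out of the vesicle, mol/s.
#' @examples
#' pore_diffusive_current(5e-6, 200, 1e-9, 10e-6)  # ~1.57e-12 mol/s
#' @export
pore_diffusive_current <- function(r, c, D, R) {
  if (any(R <= 0)) stop("pore_diffusive_current: vesicle radius must be positive")
  if (any(r < 0)) stop("pore_diffusive_current: pore radius must be non-negative")
  if (any(c < 0)) stop("pore_diffusive_current: concentration must be non-negative")
  pi * r^2 * c * D / R
}

#' Characteristic effusion time of solute through an open pore
#'
#' e-folding time of the intravesicular concentration when the only loss
#' is the diffusive pore current: balancing `(4/3) pi R^3 dc/dt = -j`
#' with `j = pi r^2 c D / R` gives exponential decay with
#' \deqn{\tau = \frac{4 R^4}{3 r^2 D}.}
#' For a 10 um vesicle leaking through a 5 um pore with sucrose
#' diffusivity 1e-9 m^2/s this is ~0.5 s, the scale of observed pore
#' lifetimes.
#'
#' @param R Vesicle radius, m (positive).
#' @param r Pore radius, m; a closed pore (zero radius) returns `Inf`
#'   (it never effuses).
#' @param D Solute diffusivity, m^2/s (positive).
#' @return Effusion time, s.
#' @examples
#' effusion_time(10e-6, 5e-6, 1e-9)  # ~0.53 s
#' @export
effusion_time <- function(R, r, D) {
  if (any(R <= 0)) stop("effusion_time: vesicle radius must be positive")
  if (any(D <= 0)) stop("effusion_time: diffusivity must be positive")
  if (any(r < 0)) stop("effusion_time: pore radius must be non-negative")
  out <- 4 * R^4 / (3 * r^2 * D)
  out[r == 0] <- Inf
  out
}

#' Exponential solute concentration decay
#'
#' Interior concentration after time `t` of effusion with characteristic
#' time `tau`: `c = c0 * exp(-t / tau)`. After one effusion time the
#' fraction remaining is `1/e` (~0.368).
#'
#' @param c0 Initial concentration, mol/m^3 (non-negative).
#' @param t Elapsed time, s (non-negative).
#' @param tau Effusion time, s (strictly positive; `Inf` allowed and
#'   returns `c0`).
#' @return Concentration, mol/m^3.
#' @examples
#' solute_decay(200, 0.5333, 0.5333)  # 200/e
#' @export
solute_decay <- function(c0, t, tau) {
  if (any(c0 < 0)) stop("solute_decay: concentration must be non-negative")
  if (any(t < 0)) stop("solute_decay: time must be non-negative")
  if (any(tau <= 0)) stop("solute_decay: tau must be positive")
  c0 * exp(-t / tau)
}

#' Pressure-driven volume outflow through an open pore
#'
#' Low-Reynolds-number orifice conductance (Sampson flow) for the volume
#' ejected through the pore by the Laplace pressure excess:
#' `Q = r^3 * delta_P / (3 * eta)`; zero for a closed pore.
#'
#' @param delta_P Pressure difference driving the outflow, Pa.
#' @param r Pore radius, m (non-negative).
#' @param eta Medium viscosity, Pa s (positive).
#' @return Volume rate, m^3/s.
#' @examples
#' sampson_outflow(1e3, 5e-6, 1e-3)  # ~4.17e-11 m^3/s
#' @export
sampson_outflow <- function(delta_P, r, eta) {
  if (any(eta <= 0)) stop("sampson_outflow: viscosity must be positive")
  if (any(r < 0)) stop("sampson_outflow: pore radius must be non-negative")
  r^3 * delta_P / (3 * eta)
}
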
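# Static mechanics of the vesicle membrane: tension-pressure coupling,
# tension-area dilation, pore energetics, open-pore tension relaxation.
# All quantities SI.

#' Membrane material parameters
#'
#' Bundle of bilayer constants used throughout the mechanics and the
#' swell-burst engine. Defaults describe a typical phospholipid GUV
#' membrane: bending modulus ~1e-19 J, area-expansion modulus a few
#' hundred mN/m, pore edge (line) tension ~10 pN.
#'
#' Two conventions for the lytic threshold circulate for lipid bilayers:
#' slow osmotic loading ruptures membranes at a few mN/m, while fast
#' mechanical loading can sustain tens of mN/m. The default is the low,
#' osmotically relevant value; use `preset = "high_lysis"` for the
#' 30--40 mN/m figure.
#'
#' @param kappa Bending modulus, J. Default `1e-19`.
#' @param E_area Area-expansion modulus, N/m. Default `0.2`
#'   (within the typical 0.1--1 N/m band).
#' @param gamma Pore edge (line) tension, N. Default `1e-11`.
#' @param sigma_lys Lytic tension threshold at which a pore opens, N/m.
#'   Default `5e-3`.
#' @param sigma_close Tension below which an open pore reseals, N/m.
#'   Default `0.02 * sigma_lys` (near-complete relaxation).
#' @param c_undulation Dimensionless coefficient of the undulation term in
#'   the dilation law; `1/(24*pi)` for thermally fluctuating bilayers.
#' @param T Absolute temperature, K. Default `298.15`.
#' @param preset Optional preset name; `"high_lysis"` sets
#'   `sigma_lys = 0.035` N/m (with `sigma_close` rescaled).
#' @return An object of class `membrane_params` (named list).
#' @examples
#' p <- membrane_params()
#' p$sigma_lys
#' membrane_params(preset = "high_lysis")$sigma_lys
#' @export
membrane_params <- function(kappa = 1e-19, E_area = 0.2, gamma = 1e-11,
                            sigma_lys = 5e-3, sigma_close = 0.02 * sigma_lys,
                            c_undulation = 1 / (24 * pi), T = 298.15,
                            preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("high_lysis"))
    if (preset == "high_lysis") {
      sigma_lys <- 0.035
      sigma_close <- 0.02 * sigma_lys
    }
  }
  p <- list(kappa = kappa, E_area = E_area, gamma = gamma,
            sigma_lys = sigma_lys, sigma_close = sigma_close,
            c_undulation = c_undulation, T = T)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("membrane_params: '", nm, "' must be a single positive number")
    }
  }
  if (p$sigma_close >= p$sigma_lys) {
    stop("membrane_params: sigma_close (", p$sigma_close,
         ") must be below sigma_lys (", p$sigma_lys, ")")
  }
  class(p) <- "membrane_params"
  p
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("Membrane parameters:\n")
  cat(sprintf("  bending modulus kappa   %.3g J\n", x$kappa))
  cat(sprintf("  area modulus E_area     %.3g N/m\n", x$E_area))
  cat(sprintf("  edge tension gamma      %.3g N\n", x$gamma))
  cat(sprintf("  lytic tension           %.3g N/m\n", x$sigma_lys))
  cat(sprintf("  pore-closure tension    %.3g N/m\n", x$sigma_close))
  cat(sprintf("  undulation coefficient  %.5g\n", x$c_undulation))
  cat(sprintf("  temperature             %.2f K\n", x$T))
  invisible(x)
}

#' Laplace tension of a pressurised spherical membrane
#'
#' For a sphere of radius `R` sustaining an internal pressure excess
#' `delta_P`, the membrane tension is `sigma = delta_P * R / 2`.
#'
#' @param delta_P Pressure difference (inside minus outside), Pa. Must be
#'   non-negative.
#' @param R Vesicle radius, m. Must be positive.
#' @return Membrane tension, N/m.
#' @examples
#' laplace_tension(0.5e6, 10e-6)  # 2.5 N/m
#' @seealso [laplace_pressure()] for the inverse relation.
#' @export
laplace_tension <- function(delta_P, R) {
  if (any(R <= 0)) stop("laplace_tension: radius must be positive")
  if (any(delta_P < 0)) stop("laplace_tension: delta_P must be non-negative")
  delta_P * R / 2
}

#' Laplace pressure sustained by a tense spherical membrane
#'
#' Inverse of [laplace_tension()]: `delta_P = 2 * sigma / R`.
#'
#' @param sigma Membrane tension, N/m (non-negative).
#' @param R Vesicle radius, m (positive).
#' @return Pressure difference, Pa.
#' @examples
#' laplace_pressure(2.5, 10e-6)  # 0.5 MPa
#' @export
laplace_pressure <- function(sigma, R) {
  if (any(R <= 0)) stop("laplace_pressure: radius must be positive")
  if (any(sigma < 0)) stop("laplace_pressure: sigma must be non-negative")
  2 * sigma / R
}

#' Membrane area dilation at a given tension
#'
#' Fractional increase of projected membrane area under tension `sigma`,
#' as the superposition of undulation smoothing (logarithmic regime) and
#' molecular area stretching (linear regime):
#' \deqn{\alpha(\sigma) = \frac{k_B T}{8\pi\kappa}
#'   \ln\!\left(1 + \frac{c\,\sigma A_0}{\kappa}\right) + \frac{\sigma}{E}.}
#' The crossover between the two regimes lies at tensions of order
#' 0.1--1 mN/m for typical phospholipid membranes; above it the dilation
#' climbs essentially linearly with tension.
#'
#' @param sigma Membrane tension, N/m (non-negative; vectorised).
#' @param A0 Relaxed (reference) membrane area, m^2.
#' @param params A [membrane_params()] object.
#' @return Dimensionless area dilation (same length as `sigma`).
#' @examples
#' p <- membrane_params(T = 298)
#' area_dilation(1e-3, 4 * pi * (10e-6)^2, p)
#' @seealso [tension_from_dilation()] for the numerical inverse.
#' @export
area_dilation <- function(sigma, A0, params = membrane_params()) {
  if (any(sigma < 0)) stop("area_dilation: tension must be non-negative")
  if (A0 <= 0) stop("area_dilation: reference area must be positive")
  a <- .kB * params$T / (8 * pi * params$kappa)
  b <- params$c_undulation * A0 / params$kappa
  a * log1p(b * sigma) + sigma / params$E_area
}

# Scalar Newton inverse of the dilation law; a = kT/(8 pi kappa),
# b = c A0 / kappa, E = area modulus. Concave-increasing target, so Newton
# with a positivity safeguard converges quadratically from below.
.sigma_from_alpha <- function(alpha, a, b, E, tol = 1e-13, maxit = 100L) {
  if (alpha <= 0) return(0)
  f <- function(s) a * log1p(b * s) + s / E - alpha
  # start from whichever single-regime inverse is smaller (underestimate)
  s <- min(alpha * E, expm1(alpha / a) / b)
  if (!is.finite(s) || s <= 0) s <- alpha * E
  for (i in seq_len(maxit)) {
    fs <- f(s)
    dfs <- a * b / (1 + b * s) + 1 / E
    step <- fs / dfs
    s_new <- s - step
    if (s_new < 0) s_new <- s / 2
    if (abs(s_new - s) <= tol * max(s_new, 1e-300)) {
      return(s_new)
    }
    s <- s_new
  }
  # fall back to bracketing if Newton stalled (should not happen)
  upper <- max(alpha * E * 2, 1e-12)
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = tol * upper)$root
}

#' Tension producing a given area dilation
#'
#' Numerical inverse of [area_dilation()]: returns the tension `sigma`
#' such that `area_dilation(sigma, A0, params) == alpha`, to a relative
#' tolerance of about 1e-12. Round-trips with the forward relation.
#'
#' @param alpha Dimensionless area dilation (non-negative; vectorised).
#' @param A0 Relaxed membrane area, m^2.
#' @param params A [membrane_params()] object.
#' @return Membrane tension, N/m.
#' @examples
#' p <- membrane_params()
#' A0 <- 4 * pi * (10e-6)^2
#' tension_from_dilation(area_dilation(2e-3, A0, p), A0, p)  # 2e-3
#' @export
tension_from_dilation <- function(alpha, A0, params = membrane_params()) {
  if (any(alpha < 0)) stop("tension_from_dilation: dilation must be non-negative")
  if (A0 <= 0) stop("tension_from_dilation: reference area must be positive")
  a <- .kB * params$T / (8 * pi * params$kappa)
  b <- params$c_undulation * A0 / params$kappa
  out <- vapply(alpha, .sigma_from_alpha, numeric(1),
                a = a, b = b, E = params$E_area)
  bad <- alpha > 0 &
    abs(area_dilation(out, A0, params) - alpha) > 1e-10 * pmax(alpha, 1e-300)
  if (any(bad)) {
    stop("tension_from_dilation: inverse failed to converge for alpha = ",
         paste(signif(alpha[bad], 6), collapse = ", "))
  }
  out
}

#' Energy of a circular pore in a tense membrane
#'
#' Classical nucleation-theory competition between the tensional energy
#' released by the pore, `-pi r^2 sigma`, and the edge (line) tension
#' cost of its rim, `+2 pi r gamma`:
#' \deqn{E(r) = 2\pi r \gamma - \pi r^2 \sigma.}
#' The energy has a single interior maximum at `gamma / sigma` and is
#' negative for pores larger than `2 gamma / sigma`.
#'
#' @param r Pore radius, m (non-negative; vectorised).
#' @param sigma Membrane tension, N/m (non-negative).
#' @param gamma Pore edge tension, N (positive).
#' @return Pore energy, J.
#' @examples
#' pore_energy(2e-9, 5e-3, 1e-11)  # ~6.28e-20 J
#' @export
pore_energy <- function(r, sigma, gamma) {
  if (any(r < 0)) stop("pore_energy: pore radius must be non-negative")
  if (any(sigma < 0)) stop("pore_energy: tension must be non-negative")
  if (any(gamma <= 0)) stop("pore_energy: edge tension must be positive")
  2 * pi * r * gamma - pi * r^2 * sigma
}

#' Nucleation barrier for pore formation
#'
#' Critical radius and energy barrier of the pore-energy landscape of
#' [pore_energy()]: `r_star = gamma / sigma`, `barrier = pi gamma^2 /
#' sigma`. The barrier decreases monotonically with tension; pores whose
#' formation would cost more than a few tens of `k_B T` are thermally
#' inaccessible, which is why poration in this model is treated as a
#' deterministic threshold event and this operation serves as a
#' diagnostic.
#'
#' @param sigma Membrane tension, N/m. Must be strictly positive (at zero
#'   tension there is no finite barrier).
#' @param gamma Pore edge tension, N.
#' @param T Absolute temperature, K (for the `k_B T` scale).
#' @return An object of class `pore_energetics`: list with `r_star` (m),
#'   `barrier` (J), and `barrier_kT` (dimensionless).
#' @examples
#' pore_nucleation_barrier(5e-3, 1e-11, 298)
#' @export
pore_nucleation_barrier <- function(sigma, gamma, T = 298.15) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("pore_nucleation_barrier: no finite barrier at non-positive tension",
         " (r_star diverges as sigma -> 0)")
  }
  if (gamma <= 0) stop("pore_nucleation_barrier: edge tension must be positive")
  if (T <= 0) stop("pore_nucleation_barrier: temperature must be positive")
  out <- list(r_star = gamma / sigma,
              barrier = pi * gamma^2 / sigma,
              barrier_kT = pi * gamma^2 / sigma / (.kB * T))
  class(out) <- "pore_energetics"
  out
}

#' @export
print.pore_energetics <- function(x, ...) {
  cat(sprintf("Pore nucleation: r* = %.3g m, barrier = %.3g J (%.1f kT)\n",
              x$r_star, x$barrier, x$barrier_kT))
  invisible(x)
}

#' Critical pore radius for complete tension relaxation
#'
#' Radius to which a pore must grow so that, with the vesicle contents
#' unchanged, redistributing the lipids relaxes the membrane tension
#' completely: `r_c = 2 R0 sqrt(sigma0 / E)`.
#'
#' @param R0 Relaxed vesicle radius (zero-tension sphere), m.
#' @param sigma0 Membrane tension just before pore opening, N/m.
#' @param E_area Area-expansion modulus, N/m.
#' @return Critical pore radius, m.
#' @examples
#' critical_pore_radius(10e-6, 5e-3, 0.2)  # ~3.16 um
#' @export
critical_pore_radius <- function(R0, sigma0, E_area) {
  if (any(R0 <= 0)) stop("critical_pore_radius: R0 must be positive")
  if (any(sigma0 < 0)) stop("critical_pore_radius: sigma0 must be non-negative")
  if (any(E_area <= 0)) stop("critical_pore_radius: E_area must be positive")
  2 * R0 * sqrt(sigma0 / E_area)
}

#' Tension ratio after pore opening
#'
#' Residual-to-initial tension ratio of a porated vesicle, in terms of the
#' pore radius and the shrinkage of the vesicle since the pore opened:
#' \deqn{\sigma/\sigma_0 = 1 - r^2/r_c^2 - 4 (R_i^2 - R^2)/r_c^2,}
#' clamped below at zero (negative tension has no meaning here; the
#' returned value carries a `fully_relaxed` attribute when the clamp was
#' active). Both pore growth and content efflux (shrinking `R`) reduce
#' the ratio, the two routes to pore resealing.
#'
#' @param r Pore radius, m (non-negative).
#' @param r_c Critical pore radius from [critical_pore_radius()], m
#'   (strictly positive).
#' @param R_i Vesicle radius at the moment of pore opening, m.
#' @param R Current vesicle radius, m; must not exceed `R_i`.
#' @return Dimensionless ratio in `[0, 1]`, with logical attribute
#'   `fully_relaxed`.
#' @examples
#' open_pore_tension_ratio(0, 3.16e-6, 10e-6, 10e-6)        # 1
#' open_pore_tension_ratio(3.16e-6 / 2, 3.16e-6, 1e-5, 1e-5) # 0.75
#' @export
open_pore_tension_ratio <- function(r, r_c, R_i, R) {
  if (any(r_c <= 0)) stop("open_pore_tension_ratio: r_c must be positive")
  if (any(r < 0)) stop("open_pore_tension_ratio: pore radius must be non-negative")
  if (any(R > R_i)) {
    stop("open_pore_tension_ratio: current radius exceeds radius at opening")
  }
  ratio <- 1 - r^2 / r_c^2 - 4 * (R_i^2 - R^2) / r_c^2
  relaxed <- ratio < 0
  ratio[relaxed] <- 0
  attr(ratio, "fully_relaxed") <- relaxed
  ratio
}
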
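# Event-driven integration of the swell-burst cycle: swell-phase ODEs,
# root-located pore opening at the lytic tension, open-pore leakage,
# root-located resealing, repetition, and quiescence detection.

#' Simulation configuration
#'
#' Assembles and validates the full configuration of a swell-burst
#' simulation. Concentrations are in mol/m^3 (numerically equal to mM),
#' lengths in m, times in s. The default scenario is the canonical
#' experiment: a 10 um GUV encapsulating 200 mM sucrose, transferred into
#' deionised water.
#'
#' The vesicle starts flaccid: its relaxed membrane area `A0` is
#' `(1 + alpha_excess)` times the area of the initial sphere, so tension
#' stays zero until influx has filled the sphere of area `A0`.
#'
#' @param R_init Initial vesicle radius, m. Default `10e-6`.
#' @param c_in Initial intravesicular osmolyte concentration, mol/m^3.
#'   Default `200`.
#' @param c_out Bath osmolyte concentration, mol/m^3. Default `0`.
#' @param membrane A [membrane_params()] object.
#' @param transport A [transport_params()] object.
#' @param r_pore_open Pore radius at opening, m. Pores observed during
#'   swell-burst cycles are several microns across; default `5e-6`.
#' @param alpha_excess Initial excess membrane area fraction
#'   (dimensionless). Default `0.05`, the order of area expansion a
#'   bilayer tolerates before lysis.
#' @param t_max Simulated time horizon, s. Default `7200` (the 2 h
#'   observation window over which damped cycles play out).
#' @param dt_max Cap on the internal solver step, s. Default `5`.
#' @param seed Integer seed; the engine itself is deterministic, the seed
#'   is forwarded to synthetic-observable generation. Default `1`.
#' @param convective_solute Logical; carry solute out with the volume
#'   ejected through the open pore (at the interior concentration), in
#'   addition to the diffusive pore current. Default `TRUE`.
#' @param background_leak Logical; include the slow trans-membrane solute
#'   permeation (`P_s`) through the intact membrane. Default `FALSE`
#'   (sucrose is effectively impermeant on these timescales).
#' @param n_out Output resolution: number of stored state rows per
#'   simulation phase. Default `120`.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config()
#' cfg$c_in
#' @export
sim_config <- function(R_init = 10e-6, c_in = 200, c_out = 0,
                       membrane = membrane_params(),
                       transport = transport_params(),
                       r_pore_open = 5e-6, alpha_excess = 0.05,
                       t_max = 7200, dt_max = 5, seed = 1L,
                       convective_solute = TRUE, background_leak = FALSE,
                       n_out = 120L) {
  stopifnot(inherits(membrane, "membrane_params"),
            inherits(transport, "transport_params"))
  num1 <- function(x, nm, lo = 0, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (strict && x <= lo) || (!strict && x < lo)) {
      stop("sim_config: '", nm, "' must be a single number ",
           if (strict) "> " else ">= ", lo)
    }
  }
  num1(R_init, "R_init"); num1(c_in, "c_in", strict = FALSE)
  num1(c_out, "c_out", strict = FALSE); num1(r_pore_open, "r_pore_open")
  num1(alpha_excess, "alpha_excess", strict = FALSE)
  num1(t_max, "t_max"); num1(dt_max, "dt_max")
  if (!is.numeric(seed) || length(seed) != 1L) {
    stop("sim_config: 'seed' must be a single integer")
  }
  cfg <- list(R_init = R_init, c_in = c_in, c_out = c_out,
              membrane = membrane, transport = transport,
              r_pore_open = r_pore_open, alpha_excess = alpha_excess,
              t_max = t_max, dt_max = dt_max, seed = as.integer(seed),
              convective_solute = isTRUE(convective_solute),
              background_leak = isTRUE(background_leak),
              n_out = max(2L, as.integer(n_out)))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Swell-burst simulation configuration:\n")
  cat(sprintf("  R_init       %.3g um\n", x$R_init * 1e6))
  cat(sprintf("  c_in / c_out %.4g / %.4g mM\n", x$c_in, x$c_out))
  cat(sprintf("  pore radius  %.3g um\n", x$r_pore_open * 1e6))
  cat(sprintf("  excess area  %.1f %%\n", x$alpha_excess * 100))
  cat(sprintf("  t_max        %.5g s   dt_max %.3g s   seed %d\n",
              x$t_max, x$dt_max, x$seed))
  cat(sprintf("  convective solute %s, background leak %s\n",
              x$convective_solute, x$background_leak))
  invisible(x)
}

# geometry helpers
.V_of_R <- function(R) 4 / 3 * pi * R^3
.R_of_V <- function(V) (3 * V / (4 * pi))^(1 / 3)

# tension from current volume, relative to relaxed membrane area A0
.sigma_of_V <- function(V, A0, mem) {
  R <- .R_of_V(V)
  alpha <- 4 * pi * R^2 / A0 - 1
  if (alpha <= 0) return(0)
  a <- .kB * mem$T / (8 * pi * mem$kappa)
  b <- mem$c_undulation * A0 / mem$kappa
  .sigma_from_alpha(alpha, a, b, mem$E_area)
}

# ODE right-hand side; y = (V, n_s, leaked). parms$r_pore > 0 while open.
.sb_rhs <- function(t, y, parms) {
  V <- as.numeric(y[1]); n <- as.numeric(y[2])
  cfg <- parms$cfg
  mem <- cfg$membrane; tp <- cfg$transport
  R <- .R_of_V(V)
  Ap <- 4 * pi * R^2
  sigma <- .sigma_of_V(V, parms$A0, mem)
  c_in <- n / V
  dP_L <- 2 * sigma / R
  dce <- (c_in - cfg$c_out) - dP_L / (.Rgas * mem$T)
  Q_in <- tp$P_w * tp$v_w * Ap * dce
  r <- parms$r_pore
  if (r > 0) {
    j <- pi * r^2 * c_in * tp$D / R
    Q_out <- r^3 * dP_L / (3 * tp$eta)
    conv <- if (cfg$convective_solute) c_in * Q_out else 0
  } else {
    j <- 0; Q_out <- 0; conv <- 0
  }
  bg <- if (cfg$background_leak) tp$P_s * Ap * (c_in - cfg$c_out) else 0
  loss <- j + conv + bg
  list(c(Q_in - Q_out, -loss, loss),
       c(sigma = sigma, R = R, c_in = c_in))
}

# Equilibrium (osmotic pressure = Laplace pressure) for given solute load.
# Returns list(R, sigma, c_in). n_s in mol, A0 the relaxed membrane area.
.balance_state <- function(n_s, A0, cfg) {
  mem <- cfg$membrane
  R0s <- sqrt(A0 / (4 * pi))
  f <- function(R) {
    .Rgas * mem$T * (n_s / .V_of_R(R) - cfg$c_out) -
      2 * .sigma_of_V(.V_of_R(R), A0, mem) / R
  }
  if (f(R0s) <= 0) {
    # no tension develops: flaccid equilibrium at c_in = c_out
    if (cfg$c_out > 0) {
      V_eq <- n_s / cfg$c_out
      V_eq <- min(V_eq, .V_of_R(R0s))
      return(list(R = .R_of_V(V_eq), sigma = 0, c_in = n_s / V_eq))
    }
    return(list(R = R0s, sigma = 0, c_in = n_s / .V_of_R(R0s)))
  }
  hi <- R0s * 1.01
  while (f(hi) > 0) hi <- hi * 1.05
  R_eq <- uniroot(f, c(R0s, hi), tol = R0s * 1e-13)$root
  list(R = R_eq, sigma = .sigma_of_V(.V_of_R(R_eq), A0, mem),
       c_in = n_s / .V_of_R(R_eq))
}

#' Analytic osmotic/Laplace balance state
#'
#' Solves for the vesicle state at which the Laplace pressure of the
#' tense membrane exactly balances the residual van't Hoff pressure,
#' `2*sigma(R_eq)/R_eq = R_gas*T*(c_in - c_out)`, for a given solute
#' load. This is the fixed point a swell phase approaches; the simulation
#' is quiescent precisely when the balance tension is sub-lytic.
#'
#' @param config A [sim_config()] object.
#' @param n_s Intravesicular solute amount, mol. Defaults to the
#'   configuration's initial load.
#' @return An object of class `vesicle_state`: list with `R` (m), `n_s`
#'   (mol), `c_in` (mol/m^3), `sigma` (N/m), `r_pore = 0`, `sublytic`
#'   (logical). A warning of class `swellburst_lytic_equilibrium` is
#'   signalled when the balance tension reaches the lytic threshold
#'   (the configuration will burst, possibly repeatedly, before settling).
#' @examples
#' eq <- equilibrium_state(sim_config(c_in = 0.3))
#' eq$sigma
#' @export
equilibrium_state <- function(config, n_s = NULL) {
  stopifnot(inherits(config, "sim_config"))
  A0 <- (1 + config$alpha_excess) * 4 * pi * config$R_init^2
  if (is.null(n_s)) n_s <- config$c_in * .V_of_R(config$R_init)
  if (n_s < 0) stop("equilibrium_state: solute amount must be non-negative")
  bs <- .balance_state(n_s, A0, config)
  st <- list(t = NA_real_, R = bs$R, n_s = n_s, c_in = bs$c_in,
             c_out = config$c_out, sigma = bs$sigma, r_pore = 0,
             sublytic = bs$sigma < config$membrane$sigma_lys)
  class(st) <- "vesicle_state"
  if (!st$sublytic) {
    warning(structure(
      class = c("swellburst_lytic_equilibrium", "warning", "condition"),
      list(message = sprintf(
        paste0("equilibrium tension %.3g N/m is not sub-lytic ",
               "(sigma_lys = %.3g N/m): this solute load will burst"),
        bs$sigma, config$membrane$sigma_lys), call = sys.call(-1))))
  }
  st
}

#' @export
print.vesicle_state <- function(x, ...) {
  cat(sprintf(
    "Vesicle state: R = %.4g um, c_in = %.4g mM, sigma = %.3g mN/m%s\n",
    x$R * 1e6, x$c_in, x$sigma * 1e3,
    if (isTRUE(x$sublytic)) " (sub-lytic)" else ""))
  invisible(x)
}

# integrate one phase: two passes (root location, then dense output).
# Returns list(states = data.frame, t_end, y_end, root = TRUE/FALSE).
.integrate_phase <- function(t0, y0, t_hi, parms, rootfun, cfg) {
  ctl <- list(rtol = 1e-10, atol = 1e-24, hmax = cfg$dt_max, maxsteps = 5e5)
  run <- function(times, root = NULL) {
    out <- tryCatch(
      if (is.null(root)) {
        deSolve::lsoda(y0, times, .sb_rhs, parms, rtol = ctl$rtol,
                       atol = ctl$atol, hmax = ctl$hmax, maxsteps = ctl$maxsteps)
      } else {
        deSolve::lsodar(y0, times, .sb_rhs, parms, rtol = ctl$rtol,
                        atol = ctl$atol, hmax = ctl$hmax,
                        maxsteps = ctl$maxsteps, rootfunc = root)
      },
      warning = function(w) {
        stop("swell-burst solver failed near t = ", signif(t0, 8), " s (",
             conditionMessage(w), "); last state V = ", signif(y0[1], 8),
             ", n_s = ", signif(y0[2], 8), call. = FALSE)
      })
    out
  }
  pass1 <- run(c(t0, t_hi), root = rootfun)
  troot <- attr(pass1, "troot")
  has_root <- !is.null(troot) && length(troot) >= 1L
  t_end <- if (has_root) troot[1] else t_hi
  times <- seq(t0, t_end, length.out = max(2L, cfg$n_out))
  dense <- run(times)
  df <- data.frame(t = dense[, 1], V = dense[, 2], n_s = dense[, 3],
                   leaked = dense[, 4], sigma = dense[, "sigma"],
                   R = dense[, "R"], c_in = dense[, "c_in"],
                   r_pore = parms$r_pore)
  last <- dense[nrow(dense), ]
  list(states = df, t_end = t_end,
       y_end = setNames(as.numeric(last[2:4]), c("V", "n_s", "leaked")),
       root = has_root)
}

#' Simulate swell-burst cycles of an osmotically stressed vesicle
#'
#' Event-driven integration of the full cyclic mechanism. During a
#' *swell phase* the closed vesicle takes up water by osmosis
#' (`dV/dt = P_w v_w A (dc - dP_Laplace/(R_gas T))`) while membrane
#' tension follows the area dilation of [area_dilation()] relative to the
#' relaxed membrane area; when the tension reaches the lytic threshold a
#' pore of fixed radius `r_pore_open` opens instantaneously
#' (`PORE_OPEN`). During the *open phase* the Laplace pressure ejects
#' volume through the pore ([sampson_outflow()]) and solute leaves by
#' pore diffusion ([pore_diffusive_current()]) and, by default,
#' convection with the ejected volume; the falling tension reseals the
#' pore at `sigma_close` (`PORE_CLOSE`). Cycles repeat until the solute
#' load can no longer drive the tension to the lytic threshold -- the
#' osmotic/Laplace balance of [equilibrium_state()] turns sub-lytic --
#' whereupon a `QUIESCENT` event is recorded and the trajectory relaxes
#' towards the balance state. Both thresholds are located by root-finding
#' on `sigma(t)`, so event times are independent of the output grid and
#' of `dt_max`.
#'
#' The engine itself is deterministic; `config$seed` only affects
#' synthetic observables generated from the result.
#'
#' @param config A [sim_config()] object.
#' @param phase_params A [phase_model_params()] object used to annotate
#'   every stored state with its membrane phase.
#' @return An object of class `swell_burst` with components
#'   \describe{
#'     \item{states}{data frame: `t`, `R`, `V`, `n_s`, `leaked`, `c_in`,
#'       `sigma`, `r_pore`, `phase`.}
#'     \item{events}{data frame: `t`, `kind` (`PORE_OPEN`, `PORE_CLOSE`,
#'       `QUIESCENT`), `sigma`, `n_s`, `R`.}
#'     \item{cycles}{per-cycle summary from [detect_cycles()].}
#'     \item{quiescent, t_quiescent}{whether and when the no-further-burst
#'       condition was established.}
#'     \item{config, A0, R0_sphere}{inputs and derived reference geometry.}
#'   }
#' @examples
#' \donttest{
#' sim <- simulate_vesicle(sim_config(t_max = 60))
#' sim
#' head(sim$cycles)
#' }
#' @seealso [detect_cycles()], [synthesize_trace()], [plot.swell_burst()]
#' @export
simulate_vesicle <- function(config = sim_config(),
                             phase_params = phase_model_params()) {
  stopifnot(inherits(config, "sim_config"))
  mem <- config$membrane
  A0 <- (1 + config$alpha_excess) * 4 * pi * config$R_init^2
  R0s <- sqrt(A0 / (4 * pi))
  V0 <- .V_of_R(config$R_init)
  y <- c(V = V0, n_s = config$c_in * V0, leaked = 0)
  t <- 0
  seg <- list()
  ev <- list()
  quiescent <- FALSE
  t_quiescent <- NA_real_

  root_lys <- function(t, y, parms) {
    .sigma_of_V(y[1], parms$A0, parms$cfg$membrane) - parms$cfg$membrane$sigma_lys
  }
  root_close <- function(t, y, parms) {
    .sigma_of_V(y[1], parms$A0, parms$cfg$membrane) - parms$cfg$membrane$sigma_close
  }
  add_event <- function(t, kind, y) {
    list(t = t, kind = kind,
         sigma = .sigma_of_V(y[1], A0, mem), n_s = as.numeric(y[2]),
         R = .R_of_V(y[1]))
  }

  repeat {
    # closed membrane: can the remaining load still reach the lytic tension?
    bal <- .balance_state(as.numeric(y[2]), A0, config)
    if (bal$sigma < mem$sigma_lys) {
      quiescent <- TRUE
      t_quiescent <- t
      ev[[length(ev) + 1L]] <- add_event(t, "QUIESCENT", y)
      # relax towards the balance state (root: within 0.1% of R_eq)
      if (t < config$t_max && .R_of_V(y[1]) < 0.999 * bal$R) {
        root_eq <- function(t, y, parms) .R_of_V(y[1]) - 0.999 * bal$R
        ph <- .integrate_phase(t, y, config$t_max,
                               list(cfg = config, A0 = A0, r_pore = 0),
                               root_eq, config)
        seg[[length(seg) + 1L]] <- ph$states
        t <- ph$t_end; y <- ph$y_end
      } else if (length(seg) == 0L) {
        seg[[1L]] <- .integrate_phase(t, y, max(t, 1e-6),
                                      list(cfg = config, A0 = A0, r_pore = 0),
                                      NULL, config)$states
      }
      break
    }
    if (t >= config$t_max) break
    # swell phase up to lysis (or truncation at t_max)
    ph <- .integrate_phase(t, y, config$t_max,
                           list(cfg = config, A0 = A0, r_pore = 0),
                           root_lys, config)
    seg[[length(seg) + 1L]] <- ph$states
    t <- ph$t_end; y <- ph$y_end
    if (!ph$root) break                      # horizon reached mid-swell
    ev[[length(ev) + 1L]] <- add_event(t, "PORE_OPEN", y)
    # open-pore phase down to the resealing tension
    ph <- .integrate_phase(t, y, config$t_max,
                           list(cfg = config, A0 = A0,
                                r_pore = config$r_pore_open),
                           root_close, config)
    seg[[length(seg) + 1L]] <- ph$states
    t <- ph$t_end; y <- ph$y_end
    if (!ph$root) break                      # horizon reached mid-burst
    ev[[length(ev) + 1L]] <- add_event(t, "PORE_CLOSE", y)
  }

  states <- do.call(rbind, seg)
  keep <- c(TRUE, diff(states$t) > 0 | diff(states$r_pore) != 0)
  states <- states[keep, , drop = FALSE]
  rownames(states) <- NULL
  states$phase <- phase_state(states$sigma, mem$T, phase_params)

  events <- if (length(ev)) {
    data.frame(t = vapply(ev, `[[`, numeric(1), "t"),
               kind = vapply(ev, `[[`, character(1), "kind"),
               sigma = vapply(ev, `[[`, numeric(1), "sigma"),
               n_s = vapply(ev, `[[`, numeric(1), "n_s"),
               R = vapply(ev, `[[`, numeric(1), "R"))
  } else {
    data.frame(t = numeric(0), kind = character(0), sigma = numeric(0),
               n_s = numeric(0), R = numeric(0))
  }

  out <- list(states = states, events = events, cycles = NULL,
              quiescent = quiescent, t_quiescent = t_quiescent,
              config = config, phase_params = phase_params,
              A0 = A0, R0_sphere = R0s,
              final_state = list(t = t, R = .R_of_V(y[1]),
                                 V = as.numeric(y[1]),
                                 n_s = as.numeric(y[2]),
                                 leaked = as.numeric(y[3]),
                                 sigma = .sigma_of_V(y[1], A0, mem)))
  class(out) <- "swell_burst"
  out$cycles <- detect_cycles(out, quiet = TRUE)
  out
}

#' Per-cycle summaries of a swell-burst trajectory
#'
#' One record per completed cycle. A cycle period is the time elapsed
#' between two consecutive returns to the uniform (resealed, relaxed)
#' state, measured here between consecutive pore-opening events; the
#' final open/close pair, having no successor, is a truncated cycle and
#' is excluded.
#'
#' @param x A `swell_burst` object, or a data frame of events with
#'   columns `t` and `kind` (and optionally `sigma`, `n_s`).
#' @param quiet Suppress the message about an excluded truncated cycle.
#' @return Data frame with columns `index`, `t_start`, `t_end`, `period`
#'   (s), `sigma_peak` (N/m), `pore_lifetime` (s), `solute_lost_fraction`
#'   (fraction of the solute present at cycle start that left during the
#'   cycle).
#' @examples
#' ev <- data.frame(t = c(10, 11, 30, 31, 70, 71),
#'                  kind = rep(c("PORE_OPEN", "PORE_CLOSE"), 3))
#' detect_cycles(ev)$period  # 20, 40
#' @export
detect_cycles <- function(x, quiet = FALSE) {
  events <- if (inherits(x, "swell_burst")) x$events else as.data.frame(x)
  if (!all(c("t", "kind") %in% names(events))) {
    stop("detect_cycles: events need columns 't' and 'kind'")
  }
  events <- events[order(events$t), , drop = FALSE]
  opens <- events[events$kind == "PORE_OPEN", , drop = FALSE]
  closes <- events[events$kind == "PORE_CLOSE", , drop = FALSE]
  empty <- data.frame(index = integer(0), t_start = numeric(0),
                      t_end = numeric(0), period = numeric(0),
                      sigma_peak = numeric(0), pore_lifetime = numeric(0),
                      solute_lost_fraction = numeric(0))
  if (nrow(opens) == 0L) return(empty)
  if (nrow(closes) < nrow(opens) - 1L || nrow(closes) > nrow(opens)) {
    stop("detect_cycles: inconsistent event log (", nrow(opens), " open / ",
         nrow(closes), " close events)")
  }
  n_complete <- nrow(opens) - 1L
  if (n_complete < 1L) {
    if (!quiet) message("detect_cycles: only a truncated final cycle; excluded")
    return(empty)
  }
  if (!quiet && nrow(closes) >= nrow(opens)) {
    message("detect_cycles: final open/close pair has no successor; excluded")
  }
  idx <- seq_len(n_complete)
  has_num <- function(col) col %in% names(events) && is.numeric(events[[col]])
  sig <- if (has_num("sigma")) opens$sigma[idx] else rep(NA_real_, n_complete)
  lost <- if (has_num("n_s")) {
    (opens$n_s[idx] - closes$n_s[idx]) / opens$n_s[idx]
  } else {
    rep(NA_real_, n_complete)
  }
  data.frame(index = idx,
             t_start = opens$t[idx],
             t_end = opens$t[idx + 1L],
             period = diff(opens$t),
             sigma_peak = sig,
             pore_lifetime = closes$t[idx] - opens$t[idx],
             solute_lost_fraction = lost)
}

#' @export
print.swell_burst <- function(x, ...) {
  cat("Swell-burst trajectory\n")
  cat(sprintf("  scenario: R_init %.3g um, %.4g mM in / %.4g mM out\n",
              x$config$R_init * 1e6, x$config$c_in, x$config$c_out))
  n_open <- sum(x$events$kind == "PORE_OPEN")
  cat(sprintf("  simulated %.5g s; %d pore events, %d completed cycles\n",
              x$final_state$t, n_open, nrow(x$cycles)))
  if (x$quiescent) {
    cat(sprintf("  quiescent from t = %.5g s\n", x$t_quiescent))
  } else {
    cat("  horizon reached before quiescence\n")
  }
  if (nrow(x$cycles) >= 1L) {
    cat(sprintf("  periods %.3g -> %.3g s (%.2g-fold)\n",
                x$cycles$period[1], x$cycles$period[nrow(x$cycles)],
                x$cycles$period[nrow(x$cycles)] / x$cycles$period[1]))
  }
  invisible(x)
}

#' @export
summary.swell_burst <- function(object, ...) {
  cyc <- object$cycles
  out <- list(
    n_cycles = nrow(cyc),
    quiescent = object$quiescent,
    t_quiescent = object$t_quiescent,
    t_end = object$final_state$t,
    solute_remaining_fraction =
      object$final_state$n_s / (object$config$c_in * .V_of_R(object$config$R_init)),
    period_first = if (nrow(cyc)) cyc$period[1] else NA_real_,
    period_last = if (nrow(cyc)) cyc$period[nrow(cyc)] else NA_real_,
    mean_pore_lifetime = if (nrow(cyc)) mean(cyc$pore_lifetime) else NA_real_,
    cycles = cyc)
  class(out) <- "summary.swell_burst"
  out
}

#' @export
print.summary.swell_burst <- function(x, ...) {
  cat(sprintf("Swell-burst summary: %d completed cycles over %.5g s\n",
              x$n_cycles, x$t_end))
  cat(sprintf("  quiescent: %s%s\n", x$quiescent,
              if (x$quiescent) sprintf(" (from t = %.5g s)", x$t_quiescent) else ""))
  cat(sprintf("  solute remaining: %.1f %%\n",
              100 * x$solute_remaining_fraction))
  if (x$n_cycles > 0) {
    cat(sprintf("  periods: first %.3g s, last %.3g s (%.2g-fold increase)\n",
                x$period_first, x$period_last, x$period_last / x$period_first))
    cat(sprintf("  mean pore lifetime: %.3g s\n", x$mean_pore_lifetime))
  }
  invisible(x)
}

#' @export
as.data.frame.swell_burst <- function(x, ...) x$states

#' Plot a swell-burst trajectory
#'
#' Three stacked panels: membrane tension (with the lytic and resealing
#' thresholds), intravesicular osmolyte concentration, and vesicle
#' radius, with pore-opening events marked.
#'
#' @param x A `swell_burst` object.
#' @param ... Passed to the underlying [plot()] calls.
#' @return `x`, invisibly.
#' @export
plot.swell_burst <- function(x, ...) {
  s <- x$states
  op <- par(mfrow = c(3, 1), mar = c(2.5, 4.2, 1, 1), oma = c(2, 0, 1.5, 0))
  on.exit(par(op), add = TRUE)
  t_open <- x$events$t[x$events$kind == "PORE_OPEN"]
  plot(s$t, s$sigma * 1e3, type = "l", xlab = "", ylab = "tension (mN/m)", ...)
  abline(h = x$config$membrane$sigma_lys * 1e3, lty = 2)
  abline(h = x$config$membrane$sigma_close * 1e3, lty = 3)
  if (length(t_open)) abline(v = t_open, col = "grey70", lty = 1)
  plot(s$t, s$c_in, type = "l", xlab = "", ylab = "c_in (mM)", ...)
  plot(s$t, s$R * 1e6, type = "l", xlab = "", ylab = "radius (um)", ...)
  mtext("time (s)", side = 1, line = 0.5, outer = TRUE)
  mtext("swell-burst trajectory", side = 3, outer = TRUE)
  invisible(x)
}

#' Generate synthetic homogeneity traces from a simulated trajectory
#'
#' `simulate()` method for `swell_burst` objects: produces `nsim`
#' synthetic fluorescence-homogeneity traces (see [synthesize_trace()])
#' with consecutive seeds starting at `seed`.
#'
#' @param object A `swell_burst` object.
#' @param nsim Number of traces.
#' @param seed Base seed; defaults to the configuration seed.
#' @param ... Passed to [synthesize_trace()] (e.g. `sample_dt`,
#'   `noise_sd`).
#' @return A single `homogeneity_trace` if `nsim = 1`, else a list of
#'   them.
#' @export
simulate.swell_burst <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$config$seed
  traces <- lapply(seq_len(nsim) - 1L, function(k) {
    synthesize_trace(object, seed = seed + k, ...)
  })
  if (nsim == 1) traces[[1]] else traces
}
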
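# Synthetic fluorescence-homogeneity traces (the stand-in for time-lapse
# imaging of the vesicle surface) and the analysis stages that recover
# cycle periods and damping from them.

# run `expr` under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Synthesize a fluorescence-homogeneity trace
#'
#' Emulates the experimental readout of oscillatory phase separation: a
#' scalar homogeneity index in `[0, 1]` (1 = optically uniform membrane,
#' 0 = fully domain-textured), sampled from a simulated trajectory. The
#' binary phase signal is smoothed with a causal moving average over the
#' optical response time, sample times are optionally jittered
#' (irregular sampling), and truncated Gaussian noise is added and
#' clipped back to `[0, 1]`. Deterministic for a given seed.
#'
#' @param traj A `swell_burst` object from [simulate_vesicle()].
#' @param sample_dt Nominal sampling interval, s. Default `0.1`.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (dimensionless, non-negative). Default `0.05`.
#' @param seed Integer seed for jitter and noise. Defaults to the
#'   trajectory's configuration seed.
#' @param response_time Optical response time of the smoothing window, s.
#'   Default `0.2`.
#' @param jitter_frac Sampling irregularity: uniform jitter of up to this
#'   fraction of `sample_dt` on each sample time. Default `0.1`.
#' @param phase_params A [phase_model_params()] object; defaults to the
#'   one the trajectory was annotated with.
#' @return An object of class `homogeneity_trace`: data frame with
#'   columns `t` (s) and `h`, and attribute `meta` recording the
#'   generator settings.
#' @examples
#' \donttest{
#' sim <- simulate_vesicle(sim_config(t_max = 60))
#' tr <- synthesize_trace(sim, noise_sd = 0.1, seed = 1)
#' head(tr)
#' }
#' @export
synthesize_trace <- function(traj, sample_dt = 0.1, noise_sd = 0.05,
                             seed = NULL, response_time = 0.2,
                             jitter_frac = 0.1, phase_params = NULL) {
  stopifnot(inherits(traj, "swell_burst"))
  if (noise_sd < 0) stop("synthesize_trace: noise_sd must be non-negative")
  if (sample_dt <= 0) stop("synthesize_trace: sample_dt must be positive")
  if (is.null(seed)) seed <- traj$config$seed
  if (is.null(phase_params)) phase_params <- traj$phase_params
  s <- traj$states
  t_end <- s$t[nrow(s)]
  t_nom <- seq(0, t_end, by = sample_dt)
  .with_seed(seed, {
    if (jitter_frac > 0 && length(t_nom) > 2L) {
      jit <- runif(length(t_nom), -jitter_frac, jitter_frac) * sample_dt
      jit[c(1L, length(t_nom))] <- 0
      t_s <- pmin(pmax(t_nom + jit, 0), t_end)
      t_s <- sort(t_s)
    } else {
      t_s <- t_nom
    }
    # underlying binary signal at the sample times (tension interpolated
    # on the stored grid, then classified)
    sigma_s <- approx(s$t, s$sigma, xout = t_s, rule = 2,
                      ties = "ordered")$y
    h_raw <- as.numeric(phase_state(pmax(sigma_s, 0),
                                    traj$config$membrane$T,
                                    phase_params) == "UNIFORM")
    # causal moving-average over the optical response time
    k <- max(1L, round(response_time / sample_dt))
    if (k > 1L && length(h_raw) >= k) {
      cs <- cumsum(h_raw)
      i <- seq_along(h_raw)
      lo <- pmax(i - k + 1L, 1L)
      h_sm <- (cs - c(0, cs)[lo]) / (i - lo + 1L)
    } else {
      h_sm <- h_raw
    }
    h <- h_sm + if (noise_sd > 0) rnorm(length(h_sm), 0, noise_sd) else 0
    h <- pmin(pmax(h, 0), 1)
    out <- data.frame(t = t_s, h = h)
    attr(out, "meta") <- list(sample_dt = sample_dt, noise_sd = noise_sd,
                              seed = seed, response_time = response_time,
                              jitter_frac = jitter_frac,
                              phase_params = phase_params)
    class(out) <- c("homogeneity_trace", "data.frame")
    out
  })
}

#' @export
print.homogeneity_trace <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf(
    "Homogeneity trace: %d samples over %.4g s (dt ~ %.3g s, noise sd %.3g, seed %s)\n",
    nrow(x), x$t[nrow(x)], m$sample_dt, m$noise_sd, m$seed))
  invisible(x)
}

#' @export
plot.homogeneity_trace <- function(x, ...) {
  plot(x$t, x$h, type = "l", xlab = "time (s)", ylab = "homogeneity index",
       ylim = c(0, 1), ...)
  invisible(x)
}

#' Extract cycle periods from a homogeneity trace
#'
#' Detects upward crossings of the homogeneity index through `threshold`
#' -- each the appearance of uniform fluorescence that ends one
#' swell-burst cycle -- and returns the successive inter-crossing
#' intervals. Crossing times are linearly interpolated between samples;
#' crossings closer than `debounce` to the previous accepted one are
#' discarded (noise chatter near the threshold).
#'
#' @param trace A `homogeneity_trace`, or any data frame with columns
#'   `t` and `h`.
#' @param threshold Crossing level in (0, 1). Default `0.5`.
#' @param debounce Minimum spacing between accepted crossings, s.
#'   Default `1` (of the order of a pore lifetime, the fastest real
#'   transition in the signal).
#' @return Numeric vector of periods (s), with the accepted crossing
#'   times as attribute `crossings`. Fewer than two crossings give an
#'   empty vector with a warning.
#' @examples
#' tr <- data.frame(t = seq(0, 60, 0.1),
#'                  h = as.numeric(seq(0, 60, 0.1) %% 20 < 5))
#' extract_cycle_periods(tr)  # all 20
#' @export
extract_cycle_periods <- function(trace, threshold = 0.5, debounce = 1) {
  if (!all(c("t", "h") %in% names(trace))) {
    stop("extract_cycle_periods: trace needs columns 't' and 'h'")
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("extract_cycle_periods: threshold must lie in (0, 1)")
  }
  t <- trace$t; h <- trace$h
  up <- which(h[-1] >= threshold & h[-length(h)] < threshold)
  if (length(up)) {
    frac <- (threshold - h[up]) / (h[up + 1L] - h[up])
    t_cross <- t[up] + frac * (t[up + 1L] - t[up])
    acc <- t_cross[1]
    for (tc in t_cross[-1]) {
      if (tc - acc[length(acc)] >= debounce) acc <- c(acc, tc)
    }
  } else {
    acc <- numeric(0)
  }
  if (length(acc) < 2L) {
    warning("extract_cycle_periods: fewer than 2 threshold crossings; ",
            "no periods")
    periods <- numeric(0)
  } else {
    periods <- diff(acc)
  }
  attr(periods, "crossings") <- acc
  periods
}

#' Damping summary of an oscillatory trace
#'
#' Condenses a sequence of cycle periods into the quantities used to
#' characterise damped swell-burst oscillations: the number of cycles,
#' the fold-increase of the period, and (if the trace ends without
#' further crossings) the time at which the oscillation went quiescent.
#'
#' @param periods Numeric vector of periods from
#'   [extract_cycle_periods()] (its `crossings` attribute is used when
#'   present).
#' @param trace Optional `homogeneity_trace` the periods came from; used
#'   to decide whether the oscillation had stopped before the end of the
#'   record.
#' @param trailing_window Length of the trailing crossing-free window
#'   (s) required to declare quiescence. Defaults to twice the last
#'   period.
#' @return An object of class `damping_summary`: list with `n_cycles`,
#'   `periods`, `fold_increase` (last/first; 1 for a single period, `NA`
#'   if none), `t_quiescent` (s, or `NA`).
#' @examples
#' damping_summary(c(10, 20, 30))$fold_increase  # 3
#' @export
damping_summary <- function(periods, trace = NULL, trailing_window = NULL) {
  n <- length(periods)
  fold <- if (n == 0L) NA_real_ else periods[n] / periods[1]
  t_q <- NA_real_
  crossings <- attr(periods, "crossings")
  if (!is.null(trace) && !is.null(crossings) && length(crossings) >= 1L) {
    if (is.null(trailing_window)) {
      trailing_window <- if (n >= 1L) 2 * periods[n] else Inf
    }
    last_cross <- crossings[length(crossings)]
    if (trace$t[nrow(trace)] - last_cross >= trailing_window) {
      t_q <- last_cross
    }
  }
  out <- list(n_cycles = n, periods = as.numeric(periods),
              fold_increase = fold, t_quiescent = t_q)
  class(out) <- "damping_summary"
  out
}

#' @export
print.damping_summary <- function(x, ...) {
  cat(sprintf("Damping summary: %d cycles", x$n_cycles))
  if (x$n_cycles > 0) {
    cat(sprintf(", periods %.3g -> %.3g s (%.2g-fold)",
                x$periods[1], x$periods[x$n_cycles], x$fold_increase))
  }
  if (!is.na(x$t_quiescent)) {
    cat(sprintf(", quiescent from t = %.5g s", x$t_quiescent))
  }
  cat("\n")
  invisible(x)
}
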
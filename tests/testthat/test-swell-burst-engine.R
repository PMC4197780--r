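# Event-driven engine: cycles, conservation, event structure, quiescence,
# equilibrium self-consistency, solver-step invariance.

test_that("isotonic configuration produces no cycles and zero tension", {
  sim <- simulate_vesicle(sim_config(c_in = 200, c_out = 200, t_max = 60))
  expect_equal(sum(sim$events$kind == "PORE_OPEN"), 0)
  expect_equal(max(sim$states$sigma), 0)
  expect_equal(nrow(sim$cycles), 0)
  expect_true(sim$quiescent)
})

test_that("default hypotonic scenario produces damped cycles", {
  sim <- default_sim_short()
  cyc <- sim$cycles
  expect_gte(nrow(cyc), 2)
  # strictly increasing periods, strictly decreasing peak solute content
  expect_true(all(diff(cyc$period) > 0))
  n_open <- sim$events$n_s[sim$events$kind == "PORE_OPEN"]
  expect_true(all(diff(n_open) < 0))
  # cycle records are internally consistent
  expect_true(all(cyc$pore_lifetime > 0))
  expect_true(all(cyc$pore_lifetime < cyc$period))
  expect_true(all(cyc$solute_lost_fraction > 0 & cyc$solute_lost_fraction < 1))
  expect_equal(cyc$sigma_peak, rep(sim$config$membrane$sigma_lys, nrow(cyc)),
               tolerance = 1e-8)
})

test_that("solute is conserved to 1e-9 relative", {
  sim <- default_sim_short()
  n0 <- sim$config$c_in * 4 / 3 * pi * sim$config$R_init^3
  total <- sim$states$n_s + sim$states$leaked
  expect_true(all(abs(total - n0) <= 1e-9 * n0))
})

test_that("tension rises during swell phases and falls while the pore is open", {
  sim <- default_sim_short()
  s <- sim$states
  opens <- sim$events$t[sim$events$kind == "PORE_OPEN"]
  closes <- sim$events$t[sim$events$kind == "PORE_CLOSE"]
  for (i in 1:2) {
    swell <- s[s$t >= closes[i] & s$t <= opens[i + 1] & s$r_pore == 0, ]
    expect_true(all(diff(swell$sigma) >= 0))
    open <- s[s$t >= opens[i] & s$t <= closes[i] & s$r_pore > 0, ]
    expect_true(all(diff(open$sigma) <= 0))
  }
  # events alternate open/close
  kinds <- sim$events$kind[sim$events$kind != "QUIESCENT"]
  expect_equal(kinds, rep(c("PORE_OPEN", "PORE_CLOSE"), length(kinds) / 2))
})

test_that("cycle periods are independent of the solver step cap", {
  s1 <- simulate_vesicle(sim_config(t_max = 60, dt_max = 5))
  s2 <- simulate_vesicle(sim_config(t_max = 60, dt_max = 2.5))
  expect_equal(nrow(s1$cycles), nrow(s2$cycles))
  expect_true(all(abs(s1$cycles$period - s2$cycles$period) <
                    1e-3 * s1$cycles$period))
})

test_that("detect_cycles summarises a hand-constructed event log", {
  ev <- data.frame(t = c(10, 11, 30, 31, 70, 71),
                   kind = rep(c("PORE_OPEN", "PORE_CLOSE"), 3))
  cyc <- suppressMessages(detect_cycles(ev))
  expect_equal(cyc$period, c(20, 40))
  expect_equal(cyc$pore_lifetime, c(1, 1))
  expect_true(all(is.na(cyc$sigma_peak)))
  # no events -> empty summary
  expect_equal(nrow(detect_cycles(data.frame(t = numeric(0),
                                             kind = character(0)))), 0)
  # a lone open/close pair is a truncated cycle
  expect_message(
    out <- detect_cycles(data.frame(t = c(1, 2),
                                    kind = c("PORE_OPEN", "PORE_CLOSE"))),
    "truncated")
  expect_equal(nrow(out), 0)
})

test_that("equilibrium state solves the osmotic/Laplace balance", {
  cfg <- sim_config()
  # isotonic: zero tension, flaccid at the initial volume (c_in = c_out
  # already, so no water moves); matches where the dynamics actually sit
  eq_iso <- equilibrium_state(sim_config(c_in = 200, c_out = 200))
  expect_equal(eq_iso$sigma, 0)
  expect_equal(eq_iso$R, 10e-6)
  expect_equal(eq_iso$c_in, 200)
  # with a solute-free bath the flaccid balance is the relaxed sphere
  eq0 <- equilibrium_state(sim_config(c_in = 0, c_out = 0))
  expect_equal(eq0$R, sqrt(1.05 * 4 * pi * (10e-6)^2 / (4 * pi)))
  # small load: sub-lytic balance satisfying 2 sigma / R = RT dc
  eq <- equilibrium_state(sim_config(c_in = 0.3))
  expect_true(eq$sublytic)
  lhs <- 2 * eq$sigma / eq$R
  rhs <- vant_hoff_pressure(eq$c_in - 0, cfg$membrane$T)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # the full initial load cannot settle without bursting
  expect_warning(equilibrium_state(cfg), class = "swellburst_lytic_equilibrium")
})

test_that("the engine reaches quiescence and approaches the balance state", {
  sim <- default_sim_long()
  expect_true(sim$quiescent)
  expect_true("QUIESCENT" %in% sim$events$kind)
  expect_true(all(diff(sim$cycles$period) > 0))
  # residual load is sub-lytic by construction
  eq <- equilibrium_state(sim$config, n_s = sim$final_state$n_s)
  expect_true(eq$sublytic)
  expect_lt(eq$sigma, sim$config$membrane$sigma_lys)
  # long-time state within 1% of the analytic balance radius
  expect_lt(abs(sim$final_state$R - eq$R) / eq$R, 0.01)
})

test_that("sim_config validates its fields", {
  expect_error(sim_config(R_init = -1), "R_init")
  expect_error(sim_config(c_in = -5), "c_in")
  expect_error(sim_config(t_max = 0), "t_max")
  expect_error(sim_config(membrane = list()), "membrane_params")
})

test_that("print, summary and plot methods run", {
  sim <- default_sim_short()
  expect_output(print(sim), "Swell-burst trajectory")
  expect_output(print(summary(sim)), "completed cycles")
  expect_s3_class(as.data.frame(sim), "data.frame")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(sim))
})
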
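# Shared fixtures: simulations of the canonical scenario (10 um GUV,
# 200 mM sucrose inside, water outside), memoised so several test files
# can reuse them without re-integrating.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, t_max) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_vesicle(sim_config(t_max = t_max))
  }
  .sim_cache[[key]]
}

# a couple of minutes of simulated time: ~14 complete cycles
default_sim_short <- function() cached_sim("short", 120)

# long horizon: runs past quiescence and relaxes to the balance state
default_sim_long <- function() cached_sim("long", 2e5)

expect_rel_equal <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol * abs(expected),
              label = sprintf("|%.6g - %.6g| <= %g relative", object,
                              expected, tol))
}
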
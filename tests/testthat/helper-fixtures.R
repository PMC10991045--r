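# Shared fixtures, memoised so expensive ODE runs happen once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, expr, envir = .fixtures)
  }
  get(key, envir = .fixtures, inherits = FALSE)
}

fig8A_params <- function(pool = 1.5) preset_params("fig8A", pool = pool)
fig8B_params <- function(pool = 2) preset_params("fig8B", pool = pool)

sim_fig8A_pool0 <- function() {
  memo("fig8A_pool0", simulate_to_saturation(fig8A_params(pool = 0)))
}

sim_fig8B_pool2 <- function() {
  memo("fig8B_pool2", simulate_rc(fig8B_params(), light_on_duration = 0.05))
}

# Analytic single-exponential rise sampled on a uniform grid.
exp_rise_trace <- function(k, a = 1, b = 3, t_end = 6 / k, n = 300) {
  tm <- seq(0, t_end, length.out = n)
  as_trace(data.frame(time_s = tm, value = a + b * (1 - exp(-k * tm))),
           "raw_fluorescence")
}

# Raw fluorescence trace synthesized from a model run (noise-free).
raw_trace_from_sim <- function(sim, F0 = 1, Fmax = 4) {
  tr <- sim$trajectory
  as_trace(data.frame(time_s = tr$time_s,
                      value = F0 + (Fmax - F0) * tr$phi),
           "raw_fluorescence")
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
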
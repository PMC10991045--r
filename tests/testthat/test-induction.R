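test_that("normalization recovers the offset and plateau of an exponential rise", {
  raw <- exp_rise_trace(k = 1e3, a = 2, b = 5)
  norm <- normalize_induction(raw)
  expect_rel_error(norm$F0, 2, 0.01)
  expect_rel_error(norm$Fmax, 7, 0.01)
  expect_true(all(norm$phi$value >= 0 & norm$phi$value <= 1.05))

  flat <- as_trace(data.frame(time_s = 1:10, value = rep(2, 10)),
                   "raw_fluorescence")
  expect_error(normalize_induction(flat), class = "rcfluor_error_trace")
  falling <- as_trace(data.frame(time_s = 1:20, value = 20:1),
                      "raw_fluorescence")
  expect_error(normalize_induction(falling), class = "rcfluor_error_trace")
})

test_that("supplementary area matches analytic and hand-computed integrals", {
  k <- 1e3
  tm <- seq(0, 12 / k, length.out = 3000)
  phi <- as_trace(data.frame(tm, 1 - exp(-k * tm)), "phi")
  expect_rel_error(supplementary_area(phi), 1 / k, 0.005)

  expect_equal(
    supplementary_area(as_trace(data.frame(0:1, c(1, 1)), "phi")), 0)

  toy <- as_trace(data.frame(time_s = c(0, 1, 2),
                             value = c(0, 0.5, 1)), "phi")
  expect_equal(supplementary_area(toy), 1.0)
})

test_that("unsaturated traces are rejected with the maximum reached", {
  tm <- seq(0, 1e-3, length.out = 100)
  low <- as_trace(data.frame(tm, 0.8 * (1 - exp(-5e3 * tm))), "phi")
  err <- tryCatch(supplementary_area(low), error = function(e) e)
  expect_s3_class(err, "rcfluor_error_unsaturated")
  expect_match(conditionMessage(err), "0.79")
})

test_that("initial slope recovers tangent slopes of known rises", {
  k <- 1e3
  tm <- seq(0, 6 / k, length.out = 2000)
  phi <- as_trace(data.frame(tm, 1 - exp(-k * tm)), "phi")
  expect_rel_error(initial_slope(phi), k, 0.03)

  lin <- as_trace(data.frame(time_s = tm, value = pmin(50 * tm, 1)), "phi")
  expect_equal(initial_slope(lin), 50, tolerance = 1e-8)

  sparse <- as_trace(data.frame(time_s = c(0, 1, 2, 3),
                                value = c(0.2, 0.5, 0.8, 1)), "phi")
  expect_error(initial_slope(sparse), class = "rcfluor_error_trace")
})

test_that("connectivity and photochemical rate follow the area-slope identities", {
  # published cycA row: area 1.9e-4 s, slope 4.1e3 /s
  expect_equal(derive_connectivity(1.9e-4, 4.1e3), 0.221,
               tolerance = 1e-10)
  expect_equal(derive_connectivity(2e-4, 4e3), 0.2, tolerance = 1e-12)
  expect_equal(derive_connectivity(3e-4, 1 / 3e-4), 0, tolerance = 1e-9)
  expect_warning(p <- derive_connectivity(2e-4, 5.1e3))
  expect_identical(p, 0)
  expect_error(derive_connectivity(2e-4, 6e3),
               class = "rcfluor_error_domain")

  expect_equal(derive_photochemical_rate(1.9e-4), 1 / 1.9e-4)
  expect_equal(derive_photochemical_rate(1e-3), 1e3)
  expect_error(derive_photochemical_rate(0), class = "rcfluor_error_domain")
})

test_that("electron counts are area ratios", {
  expect_equal(electron_count(0.51, 0.11), 0.51 / 0.11, tolerance = 1e-12)
  expect_equal(electron_count(0.25, 0.25), 1)
  expect_warning(electron_count(0.1, 0.2))
  expect_error(electron_count(0, 0.1), class = "rcfluor_error_domain")
})

test_that("the full pipeline recovers generator k_I and p from noise-free traces", {
  for (k_I in c(5e3, 1e4)) {
    for (p in c(0, 0.1, 0.2, 0.3)) {
      prm <- rate_params(k_I = k_I, k2 = 1e10, rc_conc = 8e-6, A1 = 0,
                         A2 = 2e3, E = 1e2, p = p, pool = 0)
      sim <- simulate_to_saturation(prm, n_out = 900)
      feats <- analyze_induction(raw_trace_from_sim(sim))
      expect_rel_error(feats$k_I_per_s, k_I, 0.03)
      expect_lt(abs(feats$p - p), 0.02)
      expect_rel_error(feats$slope_per_s, (1 - p) * k_I, 0.03)
    }
  }
})

test_that("electron count grows monotonically with the donor pool from one", {
  pools <- c(0, 1, 2.5)
  areas <- vapply(pools, function(pl) {
    sim <- simulate_to_saturation(fig8A_params(pool = pl), n_out = 900)
    supplementary_area(
      as_trace(sim$trajectory[c("time_s", "phi")], "phi"))
  }, numeric(1))
  n <- areas / areas[1]
  expect_equal(n[1], 1)
  expect_true(all(diff(n) > 0))
  expect_equal(n, 1 + pools, tolerance = 0.02)
})

test_that("replicate averaging aligns grids by interpolation", {
  t1 <- seq(0, 1, length.out = 101)
  t2 <- seq(0.05, 1.05, length.out = 90)
  tr1 <- as_trace(data.frame(time_s = t1, value = t1), "phi")
  tr2 <- as_trace(data.frame(time_s = t2, value = t2), "phi")
  avg <- average_traces(list(tr1, tr2))
  expect_true(all(avg$time_s >= 0.05 & avg$time_s <= 1))
  expect_equal(avg$value, avg$time_s, tolerance = 1e-10)
})

test_that("induction objects expose tidy, glance and a JSON report", {
  sim <- sim_fig8A_pool0()
  feats <- analyze_induction(raw_trace_from_sim(sim))
  td <- tidy(feats)
  expect_named(td, c("term", "estimate"))
  expect_true("k_I_per_s" %in% td$term)
  g <- glance(feats)
  expect_equal(nrow(g), 1)
  expect_true(is.na(g$N))
  path <- withr::local_tempfile(fileext = ".json")
  write_induction_report(feats, path)
  rep <- jsonlite::read_json(path)
  expect_null(rep$N)
  expect_equal(rep$k_I_per_s, feats$k_I_per_s, tolerance = 1e-9)
})
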
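test_that("the vector field obeys simple limiting cases", {
  frozen <- rate_params(k_I = 0, k2 = 0, rc_conc = 8e-6, A1 = 0, A2 = 0,
                        E = 0, p = 0.3, pool = 1)
  st <- default_initial_state(frozen)
  d <- rc_ode_rhs(st, frozen)
  expect_equal(unname(d$fractions), rep(0, 12))
  expect_equal(d$donor_conc, 0)

  # fully open, no donors: the only flux is closure of P.QA.QB at k_I
  lit <- rate_params(k_I = 8e3, k2 = 0, rc_conc = 8e-6, A1 = 0, A2 = 0,
                     E = 0, p = 0.3, pool = 0)
  d <- rc_ode_rhs(default_initial_state(lit), lit)
  expect_equal(d$fractions[["P.QA.QB"]], -8e3)
  expect_equal(d$fractions[["P+.QA-.QB"]], 8e3)
  expect_equal(sum(d$fractions), 0, tolerance = 1e-9)
  expect_equal(d$separation_flux, 8e3)

  # lone P+.QA.QB with donors: first-order mass action bookkeeping
  don <- rate_params(k_I = 0, k2 = 1e9, rc_conc = 8e-6, A1 = 0, A2 = 0,
                     E = 0, p = 0.3, pool = 2)
  st <- default_initial_state(don)
  st$fractions[] <- 0
  st$fractions["P+.QA.QB"] <- 1
  d0 <- st$donor_conc
  d <- rc_ode_rhs(st, don)
  expect_equal(d$fractions[["P+.QA.QB"]], -1e9 * d0)
  expect_equal(d$fractions[["P.QA.QB"]], 1e9 * d0)
  expect_equal(d$donor_conc, -1e9 * d0 * 8e-6)
})

test_that("fraction derivatives always sum to zero", {
  prm <- fig8B_params()
  withr::with_seed(7, {
    for (i in 1:20) {
      fr <- stats::runif(12)
      fr <- fr / sum(fr)
      st <- list(fractions = setNames(fr, names(default_initial_state(prm)$fractions)),
                 donor_conc = stats::runif(1, 0, 2e-5))
      d <- rc_ode_rhs(st, prm)
      expect_equal(sum(d$fractions), 0, tolerance = 1e-10)
    }
  })
})

test_that("with no donor pool every RC closes exactly once and stays oxidized", {
  sim <- sim_fig8A_pool0()
  g <- glance(sim)
  expect_equal(g$n_electrons, 1, tolerance = 1e-4)
  expect_equal(g$final_p_plus, 1, tolerance = 1e-4)
  expect_equal(g$final_phi, 1, tolerance = 1e-3)
})

test_that("terbutryn block with donors present ends in the reduced-acceptor open-donor state", {
  prm <- rate_params(k_I = 8e3, k2 = 1e10, rc_conc = 8e-6, A1 = 0,
                     A2 = 2e3, E = 1e2, p = 0.3, pool = 1.5)
  sim <- simulate_rc(prm, light_on_duration = 5e-3)
  g <- glance(sim)
  expect_equal(g$n_electrons, 1, tolerance = 1e-4)
  final_states <- sim$states[nrow(sim$states), ]
  expect_equal(final_states[["P.QA-.QB"]], 1, tolerance = 1e-3)
})

test_that("state-vector mass is conserved and the donor pool never grows", {
  for (sim in list(sim_fig8A_pool0(), sim_fig8B_pool2())) {
    mass <- rowSums(as.matrix(sim$states[, -1]))
    expect_lt(max(abs(mass - 1)), 1e-8)
    tr <- sim$trajectory
    expect_true(all(diff(tr$donor_per_rc) <= 1e-10))
    expect_true(all(tr$donor_per_rc >= -1e-12))
    expect_true(all(diff(tr$cum_separations) >= -1e-10))
    expect_true(all(tr$phi >= 0 & tr$phi <= 1))
    expect_true(all(tr$p_plus >= -1e-10 & tr$p_plus <= 1 + 1e-10))
  }
})

test_that("reduced primary quinone rises to a single maximum then decays", {
  tr <- sim_fig8B_pool2()$trajectory
  pk <- which.max(tr$pqa_minus)
  expect_gt(tr$pqa_minus[pk], 0.5)
  expect_true(all(diff(tr$pqa_minus[pk:nrow(tr)]) <= 1e-6))
  expect_gt(pk, 5)  # a genuine interior maximum, not an endpoint
})

test_that("switching the light off stops charge separation", {
  prm <- fig8A_params(pool = 2)
  sim <- simulate_rc(prm, light_on_duration = 2e-4, total_time = 2e-3)
  tr <- sim$trajectory
  after <- tr[tr$time_s > 2e-4, ]
  expect_lt(diff(range(after$cum_separations)), 1e-6)
  # RCs re-open in the dark: phi decays after the pulse
  expect_lt(after$phi[nrow(after)], max(tr$phi) / 2)
})

test_that("integrator errors echo the parameters", {
  bad <- rate_params(k_I = 1e30, k2 = 1e10, rc_conc = 8e-6, A1 = 1e30,
                     A2 = 2e3, E = 1e2, p = 0.3, pool = 1)
  err <- tryCatch(simulate_rc(bad, light_on_duration = 1e3),
                  error = function(e) e)
  # either the solver copes (fine) or the error names the inputs
  if (inherits(err, "rcfluor_error_integrator")) {
    expect_match(conditionMessage(err), "k_I=")
  } else {
    succeed()
  }
})

test_that("trajectory CSV export uses the documented dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(sim_fig8A_pool0(), path)
  header <- readLines(path, n = 1)
  expect_identical(
    header, "time_s,phi,p_plus,x,pqa_minus,donor_per_rc,cum_separations")
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(sim_fig8A_pool0()$trajectory))
  expect_equal(back$phi, sim_fig8A_pool0()$trajectory$phi,
               tolerance = 1e-10)
})
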
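make_trace <- function(t, v, ch) as_trace(data.frame(time_s = t, value = v), ch)

test_that("pointwise reconstruction matches hand arithmetic", {
  t <- seq(0, 1, length.out = 12)
  # p = 0 and phi == P+: no RC is closed on the acceptor side alone
  phi <- make_trace(t, seq(0, 1, length.out = 12), "phi")
  pp <- make_trace(t, seq(0, 1, length.out = 12), "p_plus")
  qa <- reconstruct_qa_reduced(phi, pp, p = 0)
  expect_true(all(abs(qa$value) < 1e-12))

  # single value phi = 0.8, P+ = 0.4, p = 0.2 -> 0.8/0.96 - 0.4
  phi1 <- make_trace(t, rep(0.8, 12), "phi")
  pp1 <- make_trace(t, rep(0.4, 12), "p_plus")
  qa1 <- reconstruct_qa_reduced(phi1, pp1, p = 0.2)
  expect_equal(qa1$value[1], 0.8 / 0.96 - 0.4, tolerance = 1e-12)

  # open fraction: phi = 1 -> 0; phi = 0.5, p = 0.22 -> 0.78*0.5/0.89
  op <- reconstruct_open(make_trace(t, rep(1, 12), "phi"), p = 0.35)
  expect_true(all(op$value == 0))
  op2 <- reconstruct_open(make_trace(t, rep(0.5, 12), "phi"), p = 0.22)
  expect_equal(op2$value[1], 0.78 * 0.5 / 0.89, tolerance = 1e-12)
  op3 <- reconstruct_open(make_trace(t, rep(0.5, 12), "phi"), p = 0)
  expect_equal(op3$value[1], 0.5)
})

test_that("reconstruction from simulator output is a round-trip identity", {
  sim <- sim_fig8B_pool2()
  tr <- sim$trajectory
  phi <- make_trace(tr$time_s, tr$phi, "phi")
  pp <- make_trace(tr$time_s, pmin(tr$p_plus, 1), "p_plus")
  # the simulator's forward map is the cluster polynomial, so the matching
  # inverse must be used for the identity to hold
  qa <- reconstruct_qa_reduced(phi, pp, p = sim$params$p,
                               yield_map = "cluster")
  expect_lt(max(abs(qa$value - tr$pqa_minus)), 1e-6)
  # four-state closure: open + PQA- + P+ sums to 1
  open <- reconstruct_open(phi, p = sim$params$p, yield_map = "cluster")
  total <- open$value + qa$value + pmin(tr$p_plus, 1)
  expect_lt(max(abs(total - 1)), 1e-6)
})

test_that("non-overlapping grids are rejected", {
  a <- make_trace(seq(0, 1, length.out = 12), rep(0.5, 12), "phi")
  b <- make_trace(seq(2, 3, length.out = 12), rep(0.5, 12), "p_plus")
  expect_error(reconstruct_qa_reduced(a, b, p = 0.1),
               class = "rcfluor_error_trace")
})

test_that("curvature score classifies bisectrix, concave and convex curves", {
  pp <- seq(0, 1, length.out = 101)
  lin <- curvature_score(data.frame(p_plus = pp, phi = pp))
  expect_equal(lin$score, 0, tolerance = 1e-12)
  expect_identical(lin$label, "linear")

  # quadratic curve under the diagonal: integral of (x^2 - x) is -1/6;
  # the curve lies below the bisectrix, the exhausted-donor signature
  sq <- curvature_score(data.frame(p_plus = pp, phi = pp^2))
  expect_equal(sq$score, -1 / 6, tolerance = 1e-3)
  expect_identical(sq$label, "convex")

  rt <- curvature_score(data.frame(p_plus = pp, phi = sqrt(pp)))
  expect_identical(rt$label, "concave")

  expect_error(curvature_score(data.frame(p_plus = pp / 2, phi = pp / 2)),
               class = "rcfluor_error_span")
  expect_error(curvature_score(data.frame(p_plus = c(0, 1),
                                          phi = c(0, 1))),
               class = "rcfluor_error_trace")
})

test_that("curvature score is antisymmetric under reflection across the diagonal", {
  pp <- seq(0, 1, length.out = 201)
  curves <- list(pp^2, pp^0.5, fluorescence_yield(pp, 0.3))
  for (phi in curves) {
    fwd <- curvature_score(data.frame(p_plus = pp, phi = phi))$score
    rev <- curvature_score(data.frame(p_plus = phi, phi = pp))$score
    expect_equal(fwd, -rev, tolerance = 1e-10)
  }
})

test_that("simulated exhausted-pool correlation is convex and scores rise with pool", {
  tr0 <- sim_fig8A_pool0()$trajectory
  cs0 <- curvature_score(data.frame(p_plus = tr0$p_plus, phi = tr0$phi))
  expect_identical(cs0$label, "convex")
  expect_lt(cs0$score, -0.01)

  scores <- vapply(c(0, 0.75, 1.5), function(pl) {
    sim <- simulate_to_saturation(fig8A_params(pool = pl), n_out = 900,
                                  sat_tol = 1e-4)
    tr <- sim$trajectory
    curvature_score(data.frame(p_plus = tr$p_plus, phi = tr$phi))$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))  # fewer donors -> more convex
})

test_that("fully disconnected units with no donors give the bisectrix and no transition", {
  prm <- rate_params(k_I = 8e3, k2 = 1e10, rc_conc = 8e-6, A1 = 3e4,
                     A2 = 2e3, E = 1e2, p = 0, pool = 0)
  sim <- simulate_to_saturation(prm, n_out = 900, sat_tol = 1e-4)
  tr <- sim$trajectory
  cs <- curvature_score(data.frame(p_plus = tr$p_plus, phi = tr$phi))
  expect_identical(cs$label, "linear")
  expect_lt(abs(cs$score), 0.01)

  # p = 0 panel: every closed RC carries P+, phi tracks P+ at all pools,
  # so the score never flips sign
  res <- find_curvature_transition(prm, pool_grid = c(0, 0.5, 1),
                                   n_out = 600)
  expect_true(is.na(res$transition_pool))
})

test_that("correlate_traces aligns and scores a trace pair", {
  sim <- sim_fig8A_pool0()
  tr <- sim$trajectory
  cs <- correlate_traces(make_trace(tr$time_s, tr$phi, "phi"),
                         make_trace(tr$time_s, pmin(tr$p_plus, 1), "p_plus"))
  expect_s3_class(cs, "rc_curvature")
  expect_identical(cs$label, "convex")
  g <- glance(cs)
  expect_named(g, c("score", "label", "n"))
})
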
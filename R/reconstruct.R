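# Redox-state reconstruction from paired phi(t) and P+(t) measurements.
#
# The four coarse redox states P.QA, P+.QA, P.QA-, P+.QA- partition the RC
# population. Fluorescence reports the closed fraction x (through a yield
# map), absorption reports total P+; their difference isolates the
# open-donor reduced-acceptor state P.QA-.

align_pair <- function(phi, p_plus) {
  phi <- as_trace(phi, "phi")
  p_plus <- as_trace(p_plus, "p_plus")
  lo <- max(min(phi$time_s), min(p_plus$time_s))
  hi <- min(max(phi$time_s), max(p_plus$time_s))
  if (lo >= hi) {
    rcf_abort("phi and P+ traces do not overlap in time.",
              "rcfluor_error_trace")
  }
  keep <- phi$time_s >= lo & phi$time_s <= hi
  t_out <- phi$time_s[keep]
  pp_interp <- approx(p_plus$time_s, p_plus$value, xout = t_out)$y
  tibble(time_s = t_out, phi = phi$value[keep], p_plus = pp_interp)
}

#' Reconstruct the reduced-acceptor open-donor state P.QA-
#'
#' Computes `PQ_A^-(t) = phi / (1 - p (1 - phi)) - P+(t)` pointwise: the
#' closed fraction inferred from fluorescence minus the fraction closed on
#' the donor side. The P+ trace is linearly interpolated onto the phi time
#' grid over their overlapping window. Values below zero (possible with
#' noise) are clipped at 0; excursions beyond `-clip_tol` trigger a
#' warning, since they indicate an inconsistent `p` or mismatched
#' normalizations.
#'
#' @param phi Normalized variable-fluorescence trace (channel `"phi"`).
#' @param p_plus Fractional oxidized-dimer trace (channel `"p_plus"`).
#' @param p Exciton hopping probability in `[0, 1)`.
#' @param yield_map `"hyperbolic"` (the printed reconstruction formula,
#'   default) or `"cluster"`; see [closed_fraction_from_yield()]. Use
#'   `"cluster"` when the phi trace originates from the simulator, whose
#'   forward map is the cluster mean-field polynomial, to make the
#'   round trip exact.
#' @param clip_tol Tolerated negative excursion before warning (default
#'   0.02).
#' @return An `rc_trace`-like tibble (`time_s`, `value`) of the P.QA-
#'   fraction.
#' @examples
#' # single-point check: phi = 0.8, P+ = 0.4, p = 0.2 -> 0.43333
#' @export
reconstruct_qa_reduced <- function(phi, p_plus, p,
                                   yield_map = c("hyperbolic", "cluster"),
                                   clip_tol = 0.02) {
  yield_map <- match.arg(yield_map)
  check_unit_interval(p, "p", upper_open = TRUE)
  pair <- align_pair(phi, p_plus)
  x <- closed_fraction_from_yield(pmin(pmax(pair$phi, 0), 1), p,
                                  map = yield_map)
  val <- x - pair$p_plus
  if (min(val) < -clip_tol) {
    rcf_warn(sprintf(
      "Reconstructed PQ_A- reaches %.3f < -%g; clipping at 0. Check p and trace normalizations.",
      min(val), clip_tol))
  }
  out <- tibble(time_s = pair$time_s, value = pmax(val, 0))
  attr(out, "channel") <- "pqa_minus"
  out
}

#' Reconstruct the fully open state P.QA
#'
#' `PQ_A(t) = (1 - p)(1 - phi) / (1 - p (1 - phi))` under the hyperbolic
#' yield map (equivalently `1 - x`); monotone non-increasing for a monotone
#' induction.
#'
#' @inheritParams reconstruct_qa_reduced
#' @return A tibble (`time_s`, `value`) of the open fraction.
#' @export
reconstruct_open <- function(phi, p,
                             yield_map = c("hyperbolic", "cluster")) {
  yield_map <- match.arg(yield_map)
  check_unit_interval(p, "p", upper_open = TRUE)
  phi <- as_trace(phi, "phi")
  ph <- pmin(pmax(phi$value, 0), 1)
  val <- 1 - closed_fraction_from_yield(ph, p, map = yield_map)
  out <- tibble(time_s = phi$time_s, value = val)
  attr(out, "channel") <- "pqa_open"
  out
}

#' Curvature of the phi versus P+ correlation
#'
#' The parametric curve (P+(t), phi(t)) runs from (0, 0) to (1, 1). Its
#' position relative to the diagonal classifies the closure mechanism: fast
#' donor re-reduction keeps P+ low while reduced quinones accumulate, so
#' phi > P+ and the curve is concave (from below, lying above the
#' bisectrix); with an exhausted donor pool but connected photosynthetic
#' units phi < P+ and the curve is convex. The signed score is the
#' trapezoidal integral of `phi - P+` over P+ after sorting by P+ and
#' averaging duplicates: positive = concave, negative = convex,
#' `|score| <= linear_band` = linear (the bisectrix case).
#'
#' @param curve A data frame with columns `p_plus` and `phi`; at least 10
#'   pairs spanning P+ from <= 0.05 to >= 0.95 (see [correlate_traces()]
#'   to build one from a pair of traces).
#' @param linear_band Half-width of the linear class (default 0.01).
#' @return An object of class `rc_curvature`: list with `score`, `label`
#'   (`"concave"`, `"linear"` or `"convex"`) and the sorted `curve`.
#' @examples
#' pp <- seq(0, 1, length.out = 50)
#' curvature_score(data.frame(p_plus = pp, phi = pp^2))$label  # convex
#' @export
curvature_score <- function(curve, linear_band = 0.01) {
  curve <- as.data.frame(curve)
  if (!all(c("p_plus", "phi") %in% names(curve))) {
    rcf_abort("`curve` needs columns p_plus and phi.", "rcfluor_error_trace")
  }
  if (nrow(curve) < 10L) {
    rcf_abort("Need at least 10 (P+, phi) pairs.", "rcfluor_error_trace")
  }
  if (min(curve$p_plus) > 0.05 || max(curve$p_plus) < 0.95) {
    rcf_abort(sprintf(
      "P+ must span from <= 0.05 to >= 0.95; observed [%.3f, %.3f]. The score over a partial span is not comparable.",
      min(curve$p_plus), max(curve$p_plus)), "rcfluor_error_span")
  }
  srt <- curve |>
    dplyr::group_by(p_plus = .data$p_plus) |>
    dplyr::summarise(phi = mean(.data$phi), .groups = "drop") |>
    dplyr::arrange(.data$p_plus)
  ends_off <- max(abs(c(srt$p_plus[1], srt$phi[1],
                        srt$p_plus[nrow(srt)] - 1, srt$phi[nrow(srt)] - 1)))
  if (ends_off > 0.02) {
    rcf_warn(sprintf(
      "Curve endpoints deviate from (0,0)/(1,1) by %.3f; normalize traces to their saturation values.", ends_off))
  }
  score <- pracma::trapz(srt$p_plus, srt$phi - srt$p_plus)
  label <- if (score > linear_band) "concave"
           else if (score < -linear_band) "convex"
           else "linear"
  structure(list(score = score, label = label, curve = as_tibble(srt)),
            class = "rc_curvature")
}

#' @export
print.rc_curvature <- function(x, ...) {
  cat(sprintf("<rc_curvature> score %+.4f (%s), %d points\n",
              x$score, x$label, nrow(x$curve)))
  invisible(x)
}

#' @rdname curvature_score
#' @param x,object An `rc_curvature` object.
#' @param ... Unused.
#' @export
tidy.rc_curvature <- function(x, ...) x$curve

#' @rdname curvature_score
#' @export
glance.rc_curvature <- function(x, ...) {
  tibble(score = x$score, label = x$label, n = nrow(x$curve))
}

#' @rdname curvature_score
#' @export
autoplot.rc_curvature <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$p_plus, y = .data$phi)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(P^"+"), y = expression(varphi),
                  subtitle = sprintf("score %+.4f (%s)", object$score,
                                     object$label)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Correlate a phi trace with a P+ trace
#'
#' Aligns the two traces in time (interpolating P+ onto the phi grid) and
#' scores the resulting phi(P+) curve with [curvature_score()].
#'
#' @inheritParams reconstruct_qa_reduced
#' @inheritParams curvature_score
#' @return An `rc_curvature` object.
#' @export
correlate_traces <- function(phi, p_plus, linear_band = 0.01) {
  pair <- align_pair(phi, p_plus)
  curvature_score(pair[c("p_plus", "phi")], linear_band = linear_band)
}

#' Donor-pool size at which the phi(P+) curvature changes sign
#'
#' Simulates the kinetic model over a grid of donor-pool sizes, scores each
#' run's phi(P+) correlation, and locates the pool size where the signed
#' score crosses zero (linear interpolation between the bracketing grid
#' values). Shrinking the pool drives the curve from concave (abundant
#' donors) through linear to convex (exhausted pool with connected units),
#' so the transition marks the donor capacity at which donor-side closure
#' stops dominating.
#'
#' @param params A [rate_params()] object; its `pool` field is overridden
#'   by the grid values.
#' @param pool_grid Increasing pool sizes (donors per RC), at least 3
#'   values, including 0.
#' @param n_out Time points per simulation (default 1200).
#' @return An object of class `rc_transition`: `transition_pool` (NA if the
#'   score never changes sign -- a distinguished "no transition" result,
#'   not an error) and a `scores` tibble (pool, score, label).
#' @examples
#' \donttest{
#' find_curvature_transition(preset_params("fig8A"),
#'                           pool_grid = seq(0, 1.5, by = 0.5))
#' }
#' @export
find_curvature_transition <- function(params, pool_grid, n_out = 1200L) {
  if (length(pool_grid) < 3L || any(diff(pool_grid) <= 0) ||
      pool_grid[1] != 0) {
    rcf_abort("`pool_grid` must be increasing, >= 3 values, and include 0.",
              "rcfluor_error_domain")
  }
  scores <- purrr::map_dbl(pool_grid, function(pl) {
    prm <- do.call(rate_params, modifyList(unclass(params),
                                           list(pool = pl)))
    # tight saturation so the curve endpoint reaches (1, 1)
    sim <- simulate_to_saturation(prm, n_out = n_out, sat_tol = 1e-4)
    tr <- sim$trajectory
    # saturate P+ span: normalize P+ by its final value (== 1 by then)
    curvature_score(tibble(p_plus = tr$p_plus, phi = tr$phi))$score
  })
  labels <- ifelse(scores > 0.01, "concave",
                   ifelse(scores < -0.01, "convex", "linear"))
  # a genuine flip needs scores of opposite sign; near-zero scores (the
  # p = 0 bisectrix panel sits at numerical zero for every pool) carry no
  # sign information and are skipped when bracketing the crossing
  nz <- which(abs(scores) > 1e-6)
  flip_at <- which(diff(sign(scores[nz])) != 0)
  transition <- if (length(flip_at)) {
    i <- nz[flip_at[1]]; j <- nz[flip_at[1] + 1L]
    s1 <- scores[i]; s2 <- scores[j]
    pool_grid[i] + (0 - s1) / (s2 - s1) * (pool_grid[j] - pool_grid[i])
  } else NA_real_
  structure(list(transition_pool = transition,
                 scores = tibble(pool = pool_grid, score = scores,
                                 label = labels)),
            class = "rc_transition")
}

#' @export
print.rc_transition <- function(x, ...) {
  if (is.na(x$transition_pool)) {
    cat("<rc_transition> no curvature sign change on the grid\n")
  } else {
    cat(sprintf("<rc_transition> curvature flips at pool = %.3f donors/RC\n",
                x$transition_pool))
  }
  print(x$scores)
  invisible(x)
}

#' @rdname find_curvature_transition
#' @param x,object An `rc_transition` object.
#' @param ... Unused.
#' @export
tidy.rc_transition <- function(x, ...) x$scores

#' @rdname find_curvature_transition
#' @export
autoplot.rc_transition <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$pool, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label)) +
    ggplot2::labs(x = "donor pool (donors/RC)",
                  y = "curvature score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a two-state reconstruction to CSV
#'
#' Columns `time_s, pqa_minus, pqa_open` on the shared grid.
#'
#' @param qa_reduced Output of [reconstruct_qa_reduced()].
#' @param open Output of [reconstruct_open()] (interpolated onto the
#'   `qa_reduced` grid if needed).
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_reconstruction <- function(qa_reduced, open, path) {
  op <- approx(open$time_s, open$value, xout = qa_reduced$time_s)$y
  lines <- c("time_s,pqa_minus,pqa_open",
             sprintf("%.12g,%.12g,%.12g", qa_reduced$time_s,
                     qa_reduced$value, op))
  writeLines(lines, path)
  invisible(path)
}
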
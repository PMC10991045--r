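#' Extract the RC re-opening (relaxation) time from a fluorescence decay
#'
#' After the exciting pulse ends, the normalized variable fluorescence
#' decays as closed RCs re-open: the oxidized dimer is re-reduced by pool
#' donors and the reduced primary quinone is re-oxidized by the quinone
#' gate; the slower side sets the timescale. Two operational definitions
#' are provided, since a published "relaxation time" may be either: the
#' half-time (interpolated first crossing of 0.5) or the time constant of a
#' single-exponential fit `a * exp(-t / tau)` (from which the half-time is
#' `tau * log(2)`).
#'
#' @param decay A normalized decay trace (channel `"phi"`): first value
#'   near 1, tail decayed below 0.2 on average (last quarter), at least 6
#'   points. Sparse flash-probe data are treated as ordinary samples.
#' @param model `"half_time"` (default) or `"single_exponential"`.
#' @return An object of class `rc_relaxation`: `relaxation_time_s`, the
#'   `model` used, `half_time_s` (equal to the relaxation time in half-time
#'   mode, `tau * log(2)` in exponential mode) and `fit_quality` (R^2 of
#'   the exponential fit; NA in half-time mode).
#' @examples
#' tm <- seq(0, 3e-3, length.out = 60)
#' tr <- as_trace(data.frame(tm, exp(-tm * log(2) / 3e-4)), "phi")
#' extract_relaxation(tr)$relaxation_time_s  # 3e-4
#' @export
extract_relaxation <- function(decay,
                               model = c("half_time",
                                         "single_exponential")) {
  model <- match.arg(model)
  decay <- as_trace(decay, "phi", min_points = 6L)
  tm <- decay$time_s; v <- decay$value
  if (abs(v[1] - 1) > 0.15) {
    rcf_warn(sprintf(
      "First point is %.3f, not ~1; normalize the decay to its initial value.", v[1]))
  }
  tail_mean <- mean(v[tm >= tm[1] + 0.75 * (max(tm) - tm[1])])
  if (!is.finite(tail_mean) || tail_mean >= 0.2) {
    rcf_abort(sprintf(
      "Decay tail has not relaxed (tail mean %.3f >= 0.2); record longer or check the trace.", tail_mean),
      "rcfluor_error_relaxation")
  }
  if (model == "half_time") {
    below <- which(v <= 0.5)
    if (!length(below)) {
      rcf_abort("Signal never crosses 0.5; cannot take a half-time.",
                "rcfluor_error_relaxation")
    }
    i <- below[1]
    t_half <- if (i == 1L) tm[1] else {
      tm[i - 1] + (0.5 - v[i - 1]) * (tm[i] - tm[i - 1]) / (v[i] - v[i - 1])
    }
    structure(list(relaxation_time_s = t_half, model = model,
                   half_time_s = t_half, fit_quality = NA_real_),
              class = "rc_relaxation")
  } else {
    pos <- v > 0.02
    if (sum(pos) < 3L) {
      rcf_abort("Too few points above noise floor for an exponential fit.",
                "rcfluor_error_relaxation")
    }
    init <- lm(log(v[pos]) ~ tm[pos])
    tau0 <- -1 / unname(coef(init)[2])
    if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(tm)) / 3
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ a * exp(-time_s / tau), data = decay,
                        start = list(a = v[1], tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        rcf_abort(sprintf(
          "Exponential fit failed to converge: %s (initial tau %.3g s).",
          conditionMessage(e), tau0), "rcfluor_error_relaxation")
      })
    tau <- unname(coef(fit)["tau"])
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((v - mean(v))^2)
    structure(list(relaxation_time_s = tau, model = model,
                   half_time_s = tau * log(2), fit_quality = r2),
              class = "rc_relaxation")
  }
}

#' @export
print.rc_relaxation <- function(x, ...) {
  cat(sprintf("<rc_relaxation> %s: %.4g s (half-time %.4g s)%s\n",
              x$model, x$relaxation_time_s, x$half_time_s,
              if (is.na(x$fit_quality)) ""
              else sprintf(", R^2 = %.4f", x$fit_quality)))
  invisible(x)
}

#' @rdname extract_relaxation
#' @param x An `rc_relaxation` object.
#' @param ... Unused.
#' @export
tidy.rc_relaxation <- function(x, ...) {
  tibble(term = c("relaxation_time_s", "half_time_s"),
         estimate = c(x$relaxation_time_s, x$half_time_s))
}

#' @rdname extract_relaxation
#' @export
glance.rc_relaxation <- function(x, ...) {
  tibble(relaxation_time_s = x$relaxation_time_s, model = x$model,
         half_time_s = x$half_time_s, fit_quality = x$fit_quality)
}

#' Simulate the post-pulse relaxation of variable fluorescence
#'
#' Runs the kinetic model with illumination limited to a short pulse (50 us
#' by default, matching laser-diode excitation experiments) and returns the
#' dark decay of the normalized variable fluorescence, rescaled to start at
#' 1 at the end of the pulse. The dark window is extended automatically
#' until the decay completes (tail below 2% of the initial value), up to a
#' cap; frozen systems (all dark rates zero) return the flat trace
#' unchanged.
#'
#' @param params A [rate_params()] object.
#' @param pulse_duration Excitation pulse length (s), default 5e-5.
#' @param n_out Number of points in the returned decay (default 400).
#' @return An `rc_trace` (channel `"phi"`) with `time_s` measured from the
#'   end of the pulse. A warning is issued when the pulse closes almost no
#'   RCs (max phi < 0.05).
#' @export
simulate_relaxation <- function(params, pulse_duration = 5e-5,
                                n_out = 400L) {
  stopifnot(inherits(params, "rate_params"))
  d0 <- params$k2 * params$pool * params$rc_conc
  bottlenecks <- c(if (params$A1 > 0) 1 / params$A1,
                   if (d0 > 0) 1 / d0)
  t_slow <- if (length(bottlenecks)) max(bottlenecks) else 10 * pulse_duration
  t_dark <- 15 * t_slow
  for (i in 1:6) {
    sim <- simulate_rc(params, light_on_duration = pulse_duration,
                       total_time = pulse_duration + t_dark,
                       n_out = max(n_out * 2L, 800L))
    tr <- sim$trajectory
    phi0 <- tr$phi[which.min(abs(tr$time_s - pulse_duration))]
    if (max(tr$phi) < 0.05) {
      rcf_warn(sprintf(
        "Pulse of %.3g s closed almost no RCs (max phi %.3f); lengthen the pulse or raise k_I.",
        pulse_duration, max(tr$phi)))
    }
    dark <- tr[tr$time_s >= pulse_duration, ]
    frozen <- params$A1 == 0 && params$A2 == 0 && params$E == 0 && d0 == 0
    if (frozen || phi0 <= 0 ||
        dark$phi[nrow(dark)] <= 0.02 * max(phi0, .Machine$double.eps)) {
      break
    }
    t_dark <- t_dark * 4
  }
  val <- if (phi0 > 0) dark$phi / phi0 else dark$phi
  out <- tibble(time_s = dark$time_s - pulse_duration,
                value = pmin(pmax(val, 0), 1))
  # drop duplicate t = 0 rounding artefacts, keep strict monotonicity
  keep <- c(TRUE, diff(out$time_s) > 0)
  as_trace(out[keep, ], "phi")
}
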
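#' Normalize a raw fluorescence induction trace
#'
#' Determines the constant (instant) fluorescence level `F0` as the
#' intercept at `t = 0` of a least-squares line through the first
#' `n_initial` points, the maximum level `Fmax` as the mean over the
#' trailing `plateau_fraction` of the samples (the saturated plateau), and
#' returns the normalized variable fluorescence
#' `phi(t) = (F(t) - F0) / (Fmax - F0)`, clipped below at 0 and above at
#' 1.05. Averaging the plateau in time rather than taking the highest
#' values keeps `Fmax` unbiased under noise, and the loose upper clip lets
#' plateau noise cancel in the supplementary-area integral instead of
#' accumulating one-sidedly.
#'
#' @param raw A raw-fluorescence trace ([as_trace()] channel
#'   `"raw_fluorescence"`), at least 8 samples.
#' @param n_initial Number of leading points for the F0 line (default 5).
#' @param plateau_fraction Trailing fraction of the samples averaged into
#'   Fmax (default 0.05).
#' @return A list with `phi` (an `rc_trace`, channel `"phi"`), `F0` and
#'   `Fmax` (arbitrary units).
#' @examples
#' tm <- seq(0, 2e-3, length.out = 200)
#' raw <- as_trace(data.frame(tm, 1 + 3 * (1 - exp(-4e3 * tm))),
#'                 "raw_fluorescence")
#' normalize_induction(raw)$F0
#' @export
normalize_induction <- function(raw, n_initial = 5L,
                                plateau_fraction = 0.05) {
  raw <- as_trace(raw, trace_channel(raw) %||% "raw_fluorescence",
                  min_points = 8L)
  v <- raw$value; tm <- raw$time_s
  if (max(v) - min(v) <= 0) {
    rcf_abort("Trace has no rise (max == min); cannot normalize.",
              "rcfluor_error_trace")
  }
  if (cor(tm, v, method = "spearman") < 0) {
    rcf_abort("Trace is decreasing on average; not an induction rise.",
              "rcfluor_error_trace")
  }
  head_fit <- lm(value ~ time_s, data = raw[seq_len(min(n_initial,
                                                        nrow(raw))), ])
  f0 <- unname(coef(head_fit)[1])
  n_top <- max(1L, ceiling(plateau_fraction * length(v)))
  fmax <- mean(v[seq.int(length(v) - n_top + 1L, length(v))])
  if (fmax <= f0) {
    rcf_abort("Fmax <= F0 after fitting; trace too noisy or not rising.",
              "rcfluor_error_trace")
  }
  phi <- pmin(pmax((v - f0) / (fmax - f0), 0), 1.05)
  list(phi = as_trace(tibble(time_s = tm, value = phi), "phi"),
       F0 = f0, Fmax = fmax)
}

#' Supplementary area above a normalized induction curve
#'
#' The integral of `1 - phi` over the trace (trapezoidal rule), the work
#' integral measuring the cumulated photon demand to close all RCs. For a
#' single-turnover trace it equals `1 / k_I`; its ratio against a
#' single-turnover area counts electrons ([electron_count()]). The trace
#' must be saturated, i.e. reach `1 - saturation_tol`, for the truncated
#' integral to stand in for the infinite-horizon one.
#'
#' @param phi A normalized induction trace (channel `"phi"`).
#' @param saturation_tol How close to 1 the trace must get (default 0.01).
#' @return Area in seconds.
#' @export
supplementary_area <- function(phi, saturation_tol = 0.01) {
  phi <- as_trace(phi, "phi", min_points = 2L)
  mx <- max(phi$value)
  if (mx < 1 - saturation_tol) {
    rcf_abort(sprintf(
      "Induction does not saturate: max phi = %.4f < %.4f. The area of an unsaturated trace underestimates the electron count.",
      mx, 1 - saturation_tol), "rcfluor_error_unsaturated")
  }
  pracma::trapz(phi$time_s, 1 - phi$value)
}

#' Initial slope of a normalized induction curve
#'
#' Tangent slope of the rise at `t = 0`, which equals `(1 - p) * k_I`.
#' Estimated by a least-squares fit of `phi = s t + c t^2` through the
#' origin to the leading points with `phi` below `fit_upper_phi`: the
#' quadratic term absorbs the leading curvature of the rise inside the
#' window, so the reported `s` is an unbiased tangent slope rather than a
#' window-averaged chord (a straight-line fit over the same window biases
#' the slope low by several percent).
#'
#' @inheritParams supplementary_area
#' @param fit_upper_phi Upper phi bound of the fit window (default 0.15).
#' @return Slope in 1/s.
#' @export
initial_slope <- function(phi, fit_upper_phi = 0.15) {
  phi <- as_trace(phi, "phi", min_points = 4L)
  first_above <- which(phi$value >= fit_upper_phi)
  keep <- if (length(first_above)) seq_len(first_above[1] - 1L)
          else seq_len(nrow(phi))
  if (length(keep) < 4L) {
    rcf_abort(sprintf(
      "Only %d points below phi = %g; sample the early rise more densely.",
      length(keep), fit_upper_phi), "rcfluor_error_trace")
  }
  tm <- phi$time_s[keep]; v <- phi$value[keep]
  fit <- lm(v ~ 0 + tm + I(tm^2))
  unname(coef(fit)["tm"])
}

#' Exciton connectivity from area and slope
#'
#' `p = 1 - Area * Slope`: combining the supplementary area (`1/k_I`) with
#' the initial slope (`(1 - p) k_I`) of a single-turnover induction cancels
#' `k_I` and isolates the hopping probability.
#'
#' @param area Supplementary area (s) of a single-turnover induction.
#' @param slope Initial slope (1/s).
#' @return Hopping probability `p` in `[0, 1)`. If `area * slope` slightly
#'   exceeds 1 (up to 1.05, as noise allows), 0 is returned with a warning;
#'   beyond that the inputs are rejected as inconsistent.
#' @examples
#' derive_connectivity(1.9e-4, 4.1e3)  # 0.221
#' @export
derive_connectivity <- function(area, slope) {
  if (area <= 0 || slope <= 0) {
    rcf_abort("`area` and `slope` must be > 0.", "rcfluor_error_domain")
  }
  prod <- area * slope
  if (prod > 1.05) {
    rcf_abort(sprintf(
      "area * slope = %.3f > 1.05: inconsistent inputs.", prod),
      "rcfluor_error_domain")
  }
  if (prod > 1) {
    rcf_warn(sprintf("area * slope = %.3f > 1; clamping p to 0.", prod))
    return(0)
  }
  1 - prod
}

#' Photochemical rate constant from the single-turnover area
#'
#' `k_I = 1 / Area`. Valid only for a single-turnover induction (terbutryn
#' block or an exhausted donor pool), where the supplementary area equals
#' `1 / k_I` exactly.
#'
#' @param area Supplementary area (s), > 0.
#' @return `k_I` in 1/s.
#' @examples
#' derive_photochemical_rate(1.9e-4)  # 5263
#' @export
derive_photochemical_rate <- function(area) {
  if (area <= 0) rcf_abort("`area` must be > 0.", "rcfluor_error_domain")
  1 / area
}

#' Number of electrons transferred per RC
#'
#' Ratio of the multiple-turnover supplementary area to the single-turnover
#' (terbutryn) one: since the area scales with the cumulated photon demand,
#' and one electron passes per closure, `N = A_m / A_s`.
#'
#' @param area_multiple Supplementary area without inhibitor (s).
#' @param area_single Single-turnover supplementary area (s).
#' @return N, electrons per RC (>= 1 for consistent inputs; a warning is
#'   issued when `area_multiple < area_single`).
#' @examples
#' electron_count(0.51, 0.11)  # 4.64, about 5 electrons
#' @export
electron_count <- function(area_multiple, area_single) {
  if (area_multiple <= 0 || area_single <= 0) {
    rcf_abort("Areas must be > 0.", "rcfluor_error_domain")
  }
  if (area_multiple < area_single) {
    rcf_warn("area_multiple < area_single: N < 1 is unphysical; check that the single-turnover trace really is single turnover.")
  }
  area_multiple / area_single
}

#' Full induction-trace analysis
#'
#' Convenience pipeline: normalize a raw trace, integrate the supplementary
#' area, fit the initial slope, and derive `k_I` and `p`. Without a paired
#' area the trace is taken to be single turnover, so its own area gives
#' `k_I = 1/Area` and `p = 1 - Area * Slope`. When `single_turnover_area`
#' is supplied the analysed trace is a multiple-turnover one: the electron
#' count `N` is the ratio of the areas, `k_I` comes from the paired
#' single-turnover area, and `p = 1 - A_s * Slope` still holds because the
#' initial slope `(1 - p) k_I` is independent of the donor pool at `t = 0`.
#'
#' @inheritParams normalize_induction
#' @inheritParams initial_slope
#' @inheritParams supplementary_area
#' @param single_turnover_area Optional paired single-turnover area (s) for
#'   the electron count.
#' @return An object of class `rc_induction` with fields `F0`, `Fmax`,
#'   `slope_per_s`, `area_s`, `k_I_per_s`, `p`, `N` (NA unless paired), and
#'   the normalized `phi` trace. [tidy()] returns a term/estimate tibble;
#'   [glance()] a one-row tibble.
#' @export
analyze_induction <- function(raw, n_initial = 5L, plateau_fraction = 0.05,
                              fit_upper_phi = 0.15, saturation_tol = 0.01,
                              single_turnover_area = NULL) {
  norm <- normalize_induction(raw, n_initial, plateau_fraction)
  area <- supplementary_area(norm$phi, saturation_tol)
  slope <- initial_slope(norm$phi, fit_upper_phi)
  if (!is.null(single_turnover_area)) {
    n_elec <- electron_count(area, single_turnover_area)
    area_single <- single_turnover_area
  } else {
    n_elec <- NA_real_
    area_single <- area
  }
  structure(list(
    F0 = norm$F0, Fmax = norm$Fmax,
    slope_per_s = slope, area_s = area,
    k_I_per_s = derive_photochemical_rate(area_single),
    p = derive_connectivity(area_single, slope),
    N = n_elec, phi = norm$phi
  ), class = "rc_induction")
}

#' @export
print.rc_induction <- function(x, ...) {
  cat("<rc_induction>\n")
  cat(sprintf("  F0 = %.4g, Fmax = %.4g (a.u.)\n", x$F0, x$Fmax))
  cat(sprintf("  slope = %.4g /s, area = %.4g s\n", x$slope_per_s, x$area_s))
  cat(sprintf("  k_I = %.4g /s, p = %.3f%s\n", x$k_I_per_s, x$p,
              if (is.na(x$N)) "" else sprintf(", N = %.2f electrons", x$N)))
  invisible(x)
}

#' @rdname analyze_induction
#' @param x,object An `rc_induction` object.
#' @param ... Unused.
#' @export
tidy.rc_induction <- function(x, ...) {
  tibble(
    term = c("F0", "Fmax", "slope_per_s", "area_s", "k_I_per_s", "p", "N"),
    estimate = c(x$F0, x$Fmax, x$slope_per_s, x$area_s, x$k_I_per_s,
                 x$p, x$N)
  )
}

#' @rdname analyze_induction
#' @export
glance.rc_induction <- function(x, ...) {
  tibble(F0 = x$F0, Fmax = x$Fmax, slope_per_s = x$slope_per_s,
         area_s = x$area_s, k_I_per_s = x$k_I_per_s, p = x$p, N = x$N)
}

#' @rdname analyze_induction
#' @export
autoplot.rc_induction <- function(object, ...) {
  tr <- object$phi
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value, ymax = 1),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$value)) +
    ggplot2::labs(x = "time (s)", y = expression(varphi),
                  subtitle = sprintf("supplementary area %.3g s, k_I %.3g /s, p %.2f",
                                     object$area_s, object$k_I_per_s,
                                     object$p)) +
    ggplot2::theme_minimal()
}

#' Write an induction feature report as JSON
#'
#' Keys `F0, Fmax, slope_per_s, area_s, k_I_per_s, p, N` (`N` null unless a
#' paired single-turnover area was supplied), 12 significant digits.
#'
#' @param features An `rc_induction` object.
#' @param path Destination JSON file.
#' @return `path`, invisibly.
#' @export
write_induction_report <- function(features, path) {
  stopifnot(inherits(features, "rc_induction"))
  vals <- features[c("F0", "Fmax", "slope_per_s", "area_s", "k_I_per_s",
                     "p", "N")]
  if (is.na(vals$N)) vals["N"] <- list(NULL)
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = I(12),
                       null = "null")
  invisible(path)
}
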
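# Synthetic strain-panel data generation.
#
# Raw traces from the original induction/relaxation experiments are not
# publicly deposited, so validation runs on data generated from the kinetic
# model itself, with per-strain parameters assembled from the published
# derived quantities: k_I and p from the induction tables, acceptor-side
# rates from the measured re-opening times, and donor pools calibrated so
# the simulated electron counts match the reported N values (absolute pool
# sizes are never printed; N is the only constraint).

strain_table <- list(
  sphaeroides_241 = list(
    k_I = 8.0e3, p = 0.20, k2 = 1e10, rc_conc = 8e-6,
    A1 = 770.2, A2 = 385, E = 1e2, pool = 1.386),
  cycA = list(
    k_I = 5.2e3, p = 0.22, k2 = 1.733e5, rc_conc = 8e-6,
    A1 = 770.2, A2 = 385, E = 1e2, pool = 0.8),
  gelatinosus_wt = list(
    k_I = 9.3e3, p = 0.10, k2 = 1e10, rc_conc = 8e-6,
    A1 = 2310.5, A2 = 1155, E = 1e2, pool = 3.788),
  pufC = list(
    k_I = 8.7e3, p = 0.13, k2 = 1e10, rc_conc = 8e-6,
    A1 = 1732.9, A2 = 866, E = 1e2, pool = 1.181)
)

# Ferricyanide slowly oxidizes the reduced donors; modeled as an
# exponential shrinkage of the initial pool with a 1 h time constant, which
# brings the electron count to ~1 after about 4 h of treatment.
ferricyanide_tau_h <- 1.0

#' Bacterial strain presets for synthetic data generation
#'
#' Assembles a [rate_params()] set for one of the study strains:
#' `"sphaeroides_241"` (wild-type Rba. sphaeroides), `"cycA"` (its soluble
#' cytochrome c2 deletion, donor-side limited), `"gelatinosus_wt"`
#' (Rvx. gelatinosus with the RC-bound tetraheme subunit, largest donor
#' pool) and `"pufC"` (tetraheme-deletion mutant of Rvx. gelatinosus).
#' Condition flags modify the set: `terbutryn` blocks the first
#' inter-quinone transfer (`A1 = 0`, enforcing single turnover), and
#' `ferricyanide_hours` shrinks the pufC donor pool exponentially with the
#' treatment duration (only meaningful for `"pufC"`); oxidation during the
#' (millisecond) measurement itself is neglected.
#'
#' @param name Strain name.
#' @param terbutryn If `TRUE`, set `A1 = 0`.
#' @param ferricyanide_hours Hours of slow donor oxidation (default 0).
#' @return An object of class `strain_preset`: `name`, `label` (name plus
#'   condition suffixes), `params`, and the condition flags.
#' @examples
#' strain_preset("pufC", ferricyanide_hours = 4)$params$pool
#' @export
strain_preset <- function(name = c("sphaeroides_241", "cycA",
                                   "gelatinosus_wt", "pufC"),
                          terbutryn = FALSE, ferricyanide_hours = 0) {
  name <- match.arg(name)
  if (ferricyanide_hours < 0) {
    rcf_abort("`ferricyanide_hours` must be >= 0.", "rcfluor_error_domain")
  }
  base <- strain_table[[name]]
  label <- name
  if (ferricyanide_hours > 0) {
    base$pool <- base$pool * exp(-ferricyanide_hours / ferricyanide_tau_h)
    label <- sprintf("%s_fecn%gh", label, ferricyanide_hours)
  }
  if (terbutryn) {
    base$A1 <- 0
    label <- paste0(label, "_terb")
  }
  structure(list(name = name, label = label,
                 params = do.call(rate_params, base),
                 terbutryn = terbutryn,
                 ferricyanide_hours = ferricyanide_hours),
            class = "strain_preset")
}

#' @export
print.strain_preset <- function(x, ...) {
  cat(sprintf("<strain_preset> %s%s%s\n", x$name,
              if (x$terbutryn) " + terbutryn" else "",
              if (x$ferricyanide_hours > 0)
                sprintf(" + ferricyanide %g h", x$ferricyanide_hours)
              else ""))
  print(x$params)
  invisible(x)
}

json_truth <- function(vals, path) {
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = I(12))
  invisible(path)
}

#' Generate a synthetic fluorescence induction dataset
#'
#' Simulates the preset to saturation, maps the yield to raw fluorescence
#' via `F = F0 + (Fmax - F0) * phi`, adds multiplicative Gaussian noise
#' (`F * (1 + sigma * eps)`), and writes a two-column CSV plus a
#' machine-readable ground-truth sidecar (`<label>.truth.json` with the
#' generator's `k_I`, `p`, `pool`, `N`, `F0`, `Fmax`, `noise_sigma`,
#' `seed`). Identical seeds give byte-identical files.
#'
#' @param preset A [strain_preset()].
#' @param noise_sigma Relative noise standard deviation (default 0.01).
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @param F0_true,Fmax_true Raw-fluorescence levels (a.u.).
#' @param n_out Simulation output points.
#' @return Invisibly, a list with `trace_path`, `truth_path`, the noisy
#'   `trace` tibble and the `truth` list.
#' @export
generate_induction_dataset <- function(preset, noise_sigma = 0.01,
                                       seed = 1L, dir = tempdir(),
                                       F0_true = 1, Fmax_true = 4,
                                       n_out = 1500L) {
  stopifnot(inherits(preset, "strain_preset"))
  if (noise_sigma < 0) {
    rcf_abort("`noise_sigma` must be >= 0.", "rcfluor_error_domain")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_to_saturation(preset$params, n_out = n_out)
  tr <- sim$trajectory
  f_clean <- F0_true + (Fmax_true - F0_true) * tr$phi
  noisy <- withr::with_seed(seed, {
    f_clean * (1 + noise_sigma * stats::rnorm(length(f_clean)))
  })
  trace <- tibble(time_s = tr$time_s, value = noisy)
  trace_path <- file.path(dir, paste0(preset$label, ".csv"))
  truth_path <- file.path(dir, paste0(preset$label, ".truth.json"))
  write_trace(trace, trace_path)
  truth <- list(
    strain = preset$name, label = preset$label,
    k_I = preset$params$k_I, p = preset$params$p,
    pool = preset$params$pool,
    N = tr$cum_separations[nrow(tr)],
    F0 = F0_true, Fmax = Fmax_true,
    noise_sigma = noise_sigma, seed = seed
  )
  json_truth(truth, truth_path)
  invisible(list(trace_path = trace_path, truth_path = truth_path,
                 trace = trace, truth = truth))
}

#' Generate a synthetic flash-probe relaxation dataset
#'
#' Simulates the post-pulse fluorescence decay of the preset, samples it at
#' `n_flashes` log-spaced probe times spanning the decay (from the 95% to
#' the 2% level), adds multiplicative Gaussian noise, and writes a CSV plus
#' ground-truth sidecar (`half_time_s` measured on the dense noise-free
#' decay, pool, rates, seed). The probe flashes are assumed non-exciting.
#'
#' @inheritParams generate_induction_dataset
#' @param n_flashes Number of probe flashes (>= 4, default 15).
#' @param pulse_duration Excitation pulse length (s), default 5e-5.
#' @return Invisibly, a list with `trace_path`, `truth_path`, `trace`,
#'   `truth`.
#' @export
generate_relaxation_dataset <- function(preset, n_flashes = 15L,
                                        noise_sigma = 0.01, seed = 1L,
                                        dir = tempdir(),
                                        pulse_duration = 5e-5) {
  stopifnot(inherits(preset, "strain_preset"))
  if (n_flashes < 4L) {
    rcf_abort("`n_flashes` must be >= 4.", "rcfluor_error_domain")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dense <- simulate_relaxation(preset$params,
                               pulse_duration = pulse_duration)
  truth_fit <- extract_relaxation(dense, model = "half_time")
  cross <- function(level) {
    i <- which(dense$value <= level)[1]
    if (is.na(i) || i == 1L) return(dense$time_s[2])
    approx(dense$value[c(i - 1L, i)], dense$time_s[c(i - 1L, i)],
           xout = level)$y
  }
  t_lo <- max(cross(0.95), dense$time_s[2])
  t_hi <- max(cross(0.02), t_lo * 10)
  probes <- 10^seq(log10(t_lo), log10(t_hi), length.out = n_flashes)
  v_clean <- approx(dense$time_s, dense$value, xout = probes)$y
  noisy <- withr::with_seed(seed, {
    v_clean * (1 + noise_sigma * stats::rnorm(length(v_clean)))
  })
  trace <- tibble(time_s = probes, value = pmin(pmax(noisy, 0), 1.04))
  trace_path <- file.path(dir, paste0(preset$label, "_relax.csv"))
  truth_path <- file.path(dir, paste0(preset$label, "_relax.truth.json"))
  write_trace(trace, trace_path)
  truth <- list(
    strain = preset$name, label = preset$label,
    half_time_s = truth_fit$half_time_s,
    pool = preset$params$pool, k2 = preset$params$k2,
    A1 = preset$params$A1, pulse_duration_s = pulse_duration,
    n_flashes = n_flashes, noise_sigma = noise_sigma, seed = seed
  )
  json_truth(truth, truth_path)
  invisible(list(trace_path = trace_path, truth_path = truth_path,
                 trace = trace, truth = truth))
}
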
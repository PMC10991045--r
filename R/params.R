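#' Kinetic and optical rate parameters of the RC turnover model
#'
#' Bundles all constants of the multi-turnover reaction scheme: light-driven
#' charge separation, donor-side re-reduction of the oxidized dimer P+, the
#' two inter-quinone electron transfers of the two-electron gate, and the
#' quinol/quinone exchange with the (unlimited) membrane pool.
#'
#' @param k_I Photochemical rate constant (1/s), proportional to the light
#'   intensity; drives closure of open RCs.
#' @param k2 Bimolecular rate constant of P+ re-reduction by a reduced pool
#'   donor (1/M/s). Values above the diffusion limit of 1e10 are allowed but
#'   flagged with a warning.
#' @param rc_conc RC concentration (M).
#' @param A1 First inter-quinone electron transfer rate Q_A- Q_B -> Q_A Q_B-
#'   (1/s). Terbutryn poisoning corresponds to `A1 = 0`.
#' @param A2 Second inter-quinone transfer rate Q_A- Q_B- -> Q_A Q_BH2 (1/s).
#' @param E Quinol/quinone exchange rate Q_BH2 -> Q_B (1/s); the membrane
#'   quinone pool is treated as inexhaustible.
#' @param p Inter-unit exciton hopping (connectivity) probability,
#'   dimensionless, in `[0, 1)`.
#' @param pool Initial reduced-donor pool size, in donors per RC.
#'
#' @return An object of class `rate_params` (a validated named list).
#' @examples
#' rate_params(k_I = 8e3, k2 = 1e10, rc_conc = 8e-6,
#'             A1 = 3e4, A2 = 2e3, E = 1e2, p = 0.3, pool = 1.5)
#' @seealso [preset_params()] for published parameter sets,
#'   [read_rate_params()] for YAML/JSON files.
#' @export
rate_params <- function(k_I, k2, rc_conc, A1, A2, E, p, pool) {
  prm <- list(k_I = k_I, k2 = k2, rc_conc = rc_conc, A1 = A1, A2 = A2,
              E = E, p = p, pool = pool)
  validate_rate_params(prm)
  structure(prm, class = "rate_params")
}

validate_rate_params <- function(prm) {
  for (nm in names(prm)) {
    v <- prm[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      rcf_abort(sprintf("`%s` must be a single finite number.", nm),
                "rcfluor_error_domain")
    }
  }
  rates <- c("k_I", "k2", "A1", "A2", "E")
  bad <- rates[vapply(prm[rates], function(v) v < 0, logical(1))]
  if (length(bad)) {
    rcf_abort(sprintf("Rate constants must be >= 0; offending: %s.",
                      paste(bad, collapse = ", ")), "rcfluor_error_domain")
  }
  if (prm$p < 0 || prm$p >= 1) {
    rcf_abort("`p` must satisfy 0 <= p < 1.", "rcfluor_error_domain")
  }
  if (prm$pool < 0) {
    rcf_abort("`pool` must be >= 0 donors per RC.", "rcfluor_error_domain")
  }
  if (prm$rc_conc <= 0) {
    rcf_abort("`rc_conc` must be > 0 M.", "rcfluor_error_domain")
  }
  if (prm$k2 > 1e10) {
    rcf_warn(sprintf(
      "k2 = %.3g /M/s exceeds the diffusion limit of 1e10 /M/s.", prm$k2),
      "rcfluor_warning_diffusion_limit")
  }
  invisible(prm)
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  cat(sprintf("  k_I  = %.4g /s   (photochemical closure)\n", x$k_I))
  cat(sprintf("  k2   = %.4g /M/s (donor -> P+)\n", x$k2))
  cat(sprintf("  [RC] = %.4g M,  pool = %.4g donors/RC\n", x$rc_conc, x$pool))
  cat(sprintf("  A1   = %.4g /s, A2 = %.4g /s, E = %.4g /s\n",
              x$A1, x$A2, x$E))
  cat(sprintf("  p    = %.3f (exciton hopping probability)\n", x$p))
  invisible(x)
}

#' Published simulation parameter sets
#'
#' `"fig8A"` is the continuous-illumination set used to map the phi(P+)
#' curvature transition of a tetraheme-deficient mutant under progressive
#' donor oxidation (k_I = 8e3/s, k2 = 1e10/M/s, RC 8 uM, A1 = 3e4/s,
#' A2 = 2e3/s, E = 1e2/s, p = 0.3). `"fig8B"` is the set used for the rise
#' and decay of the reduced primary quinone (k_I = 2e4/s, k2 = 6e9/M/s,
#' RC 3 uM, A1 = 3e3/s, A2 = 1e3/s, E = 1e2/s, p = 0.3).
#'
#' @param name One of `"fig8A"`, `"fig8B"`.
#' @param pool Donor pool size (donors per RC). Defaults to 1.5 for
#'   `"fig8A"` (the top of its published scan range) and 2 for `"fig8B"`.
#' @return A [rate_params()] object.
#' @examples
#' preset_params("fig8A", pool = 0)
#' @export
preset_params <- function(name = c("fig8A", "fig8B"), pool = NULL) {
  name <- match.arg(name)
  base <- switch(name,
    fig8A = list(k_I = 8e3, k2 = 1e10, rc_conc = 8e-6,
                 A1 = 3e4, A2 = 2e3, E = 1e2, p = 0.3, pool = 1.5),
    fig8B = list(k_I = 2e4, k2 = 6e9, rc_conc = 3e-6,
                 A1 = 3e3, A2 = 1e3, E = 1e2, p = 0.3, pool = 2)
  )
  if (!is.null(pool)) base$pool <- pool
  do.call(rate_params, base)
}

#' Read rate parameters from a YAML or JSON file
#'
#' The file must contain exactly the keys `k_I`, `k2`, `rc_conc`, `A1`,
#' `A2`, `E`, `p`, `pool` in SI units (see [rate_params()]). The format is
#' chosen by extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path File path.
#' @return A [rate_params()] object.
#' @export
read_rate_params <- function(path) {
  if (!file.exists(path)) {
    rcf_abort(sprintf("Parameter file not found: %s", path),
              "rcfluor_error_io")
  }
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  needed <- c("k_I", "k2", "rc_conc", "A1", "A2", "E", "p", "pool")
  missing <- setdiff(needed, names(vals))
  if (length(missing)) {
    rcf_abort(sprintf("Parameter file lacks keys: %s.",
                      paste(missing, collapse = ", ")), "rcfluor_error_io")
  }
  do.call(rate_params, lapply(vals[needed], as.numeric))
}

#' Write rate parameters to YAML or JSON
#'
#' @param params A [rate_params()] object.
#' @param path Destination; format chosen by extension as in
#'   [read_rate_params()].
#' @return `path`, invisibly.
#' @export
write_rate_params <- function(params, path) {
  stopifnot(inherits(params, "rate_params"))
  vals <- unclass(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
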
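#' Kinetic parameters for the three-state actin model
#'
#' Constructs and validates the parameter set of the minimal actin model with
#' monomer (Ga), filament (Fa) and bundle (Bu) pools. All concentrations are
#' non-dimensional and time is in arbitrary units; the whole-cell reference
#' volume is normalised to 1, so `total_actin` is a concentration-equivalent
#' scalar.
#'
#' @param alpha_f positive-feedback (filament-templated) polymerization rate;
#'   surrogate for Rac1/nephrin signalling strength. Non-zero only in foot
#'   processes in the spatial model.
#' @param gamma_f basal polymerization rate lumping elongation (`gamma_f*Ga*Fa`)
#'   and nucleation (`2*gamma_f*Ga*Ga`; the factor 2 keeps mass balance for
#'   dimer formation).
#' @param beta_f filament turnover (depolymerization) rate.
#' @param k half-saturation constant of the feedback Hill function; the
#'   feedback only engages once Fa is of order k.
#' @param alpha_b bundling rate (filament merging and addition of filaments to
#'   bundles); surrogate for RhoA/crosslinker activity.
#' @param gamma_b rate of direct monomer addition to bundles.
#' @param beta_b bundle turnover rate; raised by mechanical stress.
#' @param hill_h Hill exponent of the feedback term (default 2).
#' @param nucleation_n optional separate nucleation coefficient; when `NULL`
#'   (default) nucleation is tied to `gamma_f`.
#' @param total_actin conserved total actin concentration (whole-cell scale).
#' @param phi_fp volume fraction of the cell occupied by foot processes
#'   (default 0.20, the measured share).
#'
#' @return An object of class `kinetic_params` (a named list).
#' @seealso [actin_params()] for the shipped scenario-keyed sets.
#' @export
kinetic_params <- function(alpha_f = 0.32, gamma_f = 0.002, beta_f = 0.06,
                           k = 0.22, alpha_b = 0.03, gamma_b = 0.0035,
                           beta_b = 0.01, hill_h = 2, nucleation_n = NULL,
                           total_actin = 0.4666, phi_fp = 0.2) {
  p <- list(alpha_f = alpha_f, gamma_f = gamma_f, beta_f = beta_f, k = k,
            alpha_b = alpha_b, gamma_b = gamma_b, beta_b = beta_b,
            hill_h = hill_h, nucleation_n = nucleation_n,
            total_actin = total_actin, phi_fp = phi_fp)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  rates <- c("alpha_f", "gamma_f", "beta_f", "alpha_b", "gamma_b", "beta_b")
  for (r in rates) {
    if (!is.numeric(p[[r]]) || length(p[[r]]) != 1L || p[[r]] < 0)
      stop("kinetic parameter '", r, "' must be a single non-negative number")
  }
  if (p$k <= 0) stop("'k' must be positive")
  if (p$phi_fp <= 0 || p$phi_fp >= 1) stop("'phi_fp' must be in (0, 1)")
  if (p$hill_h < 1) stop("'hill_h' must be >= 1")
  if (p$total_actin <= 0) stop("'total_actin' must be positive")
  if (!is.null(p$nucleation_n) && p$nucleation_n < 0)
    stop("'nucleation_n' must be non-negative")
  invisible(p)
}

#' Load a shipped kinetic parameter set by scenario name
#'
#' Parameter sets are stored in `inst/extdata/kinetic_params.json`, keyed by
#' the scenario they drive (`"baseline"`, `"fig2C"` ... `"fig2F"`, `"fig3E"`,
#' `"fig3F"`, `"S3"`, `"S4"`). Entries inherit from `"baseline"` and override
#' individual rates; `total_actin_scale` rescales the conserved pool.
#'
#' @param name scenario key.
#' @return A [kinetic_params()] object.
#' @export
actin_params <- function(name = "baseline") {
  path <- system.file("extdata", "kinetic_params.json", package = "podoactin")
  sets <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sets[["_comment"]] <- NULL
  if (!name %in% names(sets))
    stop("unknown parameter set '", name, "'; available: ",
         paste(names(sets), collapse = ", "))
  entry <- sets[[name]]
  base <- if (!is.null(entry$inherit)) sets[[entry$inherit]] else list()
  entry$inherit <- NULL
  scale <- entry$total_actin_scale
  entry$total_actin_scale <- NULL
  merged <- utils::modifyList(base, entry)
  p <- do.call(kinetic_params, merged)
  if (!is.null(scale)) p$total_actin <- p$total_actin * scale
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Three-state actin model parameters:\n")
  cat(sprintf("  polymerization: alpha_f=%g (Hill h=%g, k=%g), gamma_f=%g\n",
              x$alpha_f, x$hill_h, x$k, x$gamma_f))
  cat(sprintf("  bundling:       alpha_b=%g, gamma_b=%g\n", x$alpha_b, x$gamma_b))
  cat(sprintf("  turnover:       beta_f=%g, beta_b=%g\n", x$beta_f, x$beta_b))
  cat(sprintf("  pool:           total_actin=%g, phi_fp=%g\n",
              x$total_actin, x$phi_fp))
  invisible(x)
}
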
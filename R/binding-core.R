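#' Equilibrium concentration of the detection-Fab/drug complex
#'
#' Solves the 1:1 mass-action equilibrium `K_D = [A][B]/[AB]` for the bound
#' complex when total concentrations (rather than free concentrations) are
#' known -- the tight-binding ("quadratic") regime where ligand depletion
#' cannot be neglected. The physical root of the quadratic is
#' \deqn{[AB] = s - \sqrt{s^2 - a x}, \quad s = (a + x + K_D)/2,}
#' evaluated in the algebraically equivalent form
#' \eqn{[AB] = a x / (s + \sqrt{s^2 - a x})}, which avoids catastrophic
#' cancellation when \eqn{K_D \ll a, x} (very tight binding).
#'
#' All concentrations are nM; unit conversions belong at the boundary (see
#' [mass_to_molar()]). Arguments are vectorised and recycled.
#'
#' @param a_total Total concentration of the detection Fab (nM).
#' @param x_total Total concentration of drug binding sites (nM). For a drug
#'   with two Fab epitopes pass the site-adjusted concentration, see
#'   [effective_site_concentration()].
#' @param kd Equilibrium dissociation constant (nM).
#' @return Concentration of the bound complex (nM), bounded by
#'   `min(a_total, x_total)`.
#' @examples
#' solve_bound_complex(678, 20, 22.5)   # ~19.34 nM
#' solve_bound_complex(678, 20, 0)      # 20: infinitely tight binding
#' @export
solve_bound_complex <- function(a_total, x_total, kd) {
  .check_nonneg(a_total, "a_total")
  .check_nonneg(x_total, "x_total")
  .check_nonneg(kd, "kd")
  s <- (a_total + x_total + kd) / 2
  disc <- pmax(s^2 - a_total * x_total, 0)
  denom <- s + sqrt(disc)
  ab <- ifelse(denom > 0, a_total * x_total / denom, 0)
  pmin(ab, pmin(a_total, x_total))
}

#' Fraction of drug sites occupied at equilibrium
#'
#' `solve_bound_complex(a, x, kd) / x`: the bound fraction of the limiting
#' titrated species. In the trace-ligand limit (`x_total -> 0`) this tends to
#' the familiar hyperbola `a/(a + kd)`.
#'
#' @inheritParams solve_bound_complex
#' @return Fraction in `[0, 1]`.
#' @export
fraction_bound <- function(a_total, x_total, kd) {
  .check_nonneg(x_total, "x_total")
  if (any(x_total == 0))
    stop("fraction_bound is undefined at x_total = 0", call. = FALSE)
  solve_bound_complex(a_total, x_total, kd) / x_total
}

#' Parameters of the one-site specific binding curve
#'
#' Container for the three parameters of the saturation signal model fitted
#' to SEC titrations: the baseline signal `f_min`, the saturating signal
#' `f_max` (both in percent of total fluorescence), and the dissociation
#' constant `kd` (nM).
#'
#' @param f_min Baseline signal (value of the curve at zero drug).
#' @param f_max Saturating signal.
#' @param kd Equilibrium dissociation constant (nM).
#' @return An object of class `binding_curve_params`.
#' @export
binding_curve_params <- function(f_min, f_max, kd) {
  if (!is.finite(f_min) || !is.finite(f_max) || !is.finite(kd))
    stop("parameters must be finite", call. = FALSE)
  if (f_max < f_min) stop("f_max must be >= f_min", call. = FALSE)
  .check_nonneg(kd, "kd")
  structure(list(f_min = f_min, f_max = f_max, kd = kd),
            class = "binding_curve_params")
}

#' @export
print.binding_curve_params <- function(x, ...) {
  cat(sprintf("binding curve: f_min = %.4g, f_max = %.4g, K_D = %.4g nM\n",
              x$f_min, x$f_max, x$kd))
  invisible(x)
}

#' One-site specific binding signal model
#'
#' The saturation curve fitted to SEC titration data:
#' \deqn{Y = F + (F_{max} - F)\,[AB]/a,}
#' where \eqn{[AB]} is the quadratic tight-binding solution at total Fab
#' concentration `a_total` and total site concentration `x_total`. The term
#' \eqn{[AB]/a} is the fraction of the detection Fab driven into the complex,
#' i.e. the complex peak expressed as a share of total fluorescence.
#'
#' @param x_total Total drug site concentration(s), nM.
#' @param params A [binding_curve_params()] object.
#' @param a_total Total detection-Fab concentration (nM), must be positive.
#' @return Predicted signal, same length as `x_total`.
#' @export
signal_model <- function(x_total, params, a_total) {
  stopifnot(inherits(params, "binding_curve_params"))
  .check_nonneg(a_total, "a_total")
  if (any(a_total == 0))
    stop("signal_model requires a_total > 0", call. = FALSE)
  ab <- solve_bound_complex(a_total, x_total, params$kd)
  params$f_min + (params$f_max - params$f_min) * ab / a_total
}

#' Site-adjusted drug concentration for independent-epitope binding
#'
#' The drug carries `n_sites` identical, independent epitopes for the
#' monovalent detection Fab (two for the dual-variable-domain construct), so
#' a 1:1 equilibrium in *sites* describes the binding once the drug
#' concentration is multiplied by `n_sites`. The adjustment is always applied
#' explicitly by the caller, never hidden inside a fitting routine.
#'
#' @param drug_total Total drug concentration (nM).
#' @param n_sites Integer number of Fab epitopes per drug molecule (>= 1).
#' @return `drug_total * n_sites` (nM).
#' @examples
#' effective_site_concentration(10, 2) # 20
#' @export
effective_site_concentration <- function(drug_total, n_sites = 2L) {
  .check_nonneg(drug_total, "drug_total")
  if (any(n_sites < 1) || any(n_sites != round(n_sites)))
    stop("n_sites must be a positive integer", call. = FALSE)
  drug_total * n_sites
}

#' Convert between mass and molar concentration
#'
#' `mass_to_molar()` converts a mass concentration in micrograms per
#' millilitre to nanomolar at a given molecular mass (Da);
#' `molar_to_mass()` is the exact inverse. 2 ug/mL of a 200 kDa protein is
#' 10 nM.
#'
#' @param conc_ug_ml Mass concentration (ug/mL).
#' @param conc_nM Molar concentration (nM).
#' @param mass_da Molecular mass (Da), must be positive.
#' @return Concentration in the target unit.
#' @export
mass_to_molar <- function(conc_ug_ml, mass_da) {
  .check_nonneg(conc_ug_ml, "conc_ug_ml")
  if (any(!is.finite(mass_da)) || any(mass_da <= 0))
    stop("mass_da must be > 0", call. = FALSE)
  conc_ug_ml * 1e6 / mass_da
}

#' @rdname mass_to_molar
#' @export
molar_to_mass <- function(conc_nM, mass_da) {
  .check_nonneg(conc_nM, "conc_nM")
  if (any(!is.finite(mass_da)) || any(mass_da <= 0))
    stop("mass_da must be > 0", call. = FALSE)
  conc_nM * mass_da / 1e6
}

#' Back-convert an in-assay concentration to 100% serum
#'
#' Serum samples are diluted (1:5 by default) before the detection Fab is
#' added, so an in-assay concentration corresponds to `dilution_factor` times
#' that concentration in undiluted serum: the 2 ug/mL in-assay detection
#' limit is 10 ug/mL in 100% serum.
#'
#' @param conc_assay Concentration in the assay (any unit).
#' @param dilution_factor Fold-dilution of serum into the assay (>= 1).
#' @return Concentration in undiluted serum, same unit as the input.
#' @export
assay_to_serum <- function(conc_assay, dilution_factor = 5) {
  if (any(dilution_factor < 1))
    stop("dilution_factor must be >= 1", call. = FALSE)
  conc_assay * dilution_factor
}

#' Default molecular masses of the assay species
#'
#' The drug (a dual-variable-domain IgG construct) and the Fab detection
#' reagent masses are those used for the stoichiometry arithmetic; the free
#' dye mass is that of the fluorophore. The ADA mass defaults to 150 kDa, the
#' standard mass of an IgG, and is configurable because polyclonal ADA
#' preparations are heterogeneous.
#'
#' @return Named numeric vector of masses in Da.
#' @export
default_masses <- function() {
  c(huDVD = 200000, Fab488 = 47150, free_dye = 1011, ADA = 150000)
}

#' Read a molecular-mass table from YAML or JSON
#'
#' The file holds a flat mapping of species name to mass in Da. Entries
#' override [default_masses()]; species not mentioned keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named numeric vector of masses in Da.
#' @export
read_masses <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported mass-table format: ", ext, call. = FALSE))
  tab <- unlist(tab)
  if (any(tab <= 0)) stop("all masses must be > 0", call. = FALSE)
  out <- default_masses()
  out[names(tab)] <- tab
  out
}
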
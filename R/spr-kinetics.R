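#' Kinetic parameters of a 1:1 Langmuir interaction
#'
#' @param kon Association rate constant, 1/(M s), positive.
#' @param koff Dissociation rate constant, 1/s, non-negative.
#' @param rmax Saturating analyte response, RU, positive.
#' @return Object of class `kinetic_params`; `kd_nM()` gives `koff/kon` in nM.
#' @export
kinetic_params <- function(kon, koff, rmax) {
  if (!is.finite(kon) || kon <= 0) stop("kon must be > 0", call. = FALSE)
  if (!is.finite(koff) || koff < 0) stop("koff must be >= 0", call. = FALSE)
  if (!is.finite(rmax) || rmax <= 0) stop("rmax must be > 0", call. = FALSE)
  structure(list(kon = kon, koff = koff, rmax = rmax),
            class = "kinetic_params")
}

#' @rdname kinetic_params
#' @param params A `kinetic_params` object.
#' @export
kd_nM <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$koff / params$kon * 1e9
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "1:1 Langmuir: kon = %.4g /(M s), koff = %.4g /s, Rmax = %.4g RU, K_D = %.4g nM\n",
    x$kon, x$koff, x$rmax, kd_nM(x)))
  invisible(x)
}

# Closed-form 1:1 Langmuir response. Exact solution of
# dR/dt = kon*C*(Rmax - R) - koff*R with R(0) = 0, analyte removed at
# t_assoc. conc in nM, time in s.
langmuir_response <- function(time_s, conc_nM, t_assoc, kon, koff, rmax) {
  c_M <- conc_nM * 1e-9
  kobs <- kon * c_M + koff
  req <- ifelse(kobs > 0, rmax * kon * c_M / kobs, 0)
  r_assoc <- req * (1 - exp(-kobs * pmin(time_s, t_assoc)))
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(time_s <= t_assoc,
         r_assoc,
         r_end * exp(-koff * (time_s - t_assoc)))
}

#' Simulate a 1:1 Langmuir SPR sensorgram
#'
#' Generates the exact closed-form association/dissociation curve
#' \deqn{R(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t}), \quad
#'       R_{eq} = R_{max} \frac{C}{C + K_D},}
#' followed by exponential dissociation
#' \eqn{R(t) = R(t_{assoc}) e^{-k_{off}(t - t_{assoc})}}, with optional
#' additive Gaussian noise. Closed forms are exact for the 1:1 model, so no
#' ODE integration is needed. Mass-transport limitation, drift and bulk
#' refractive-index jumps are deliberately not modelled.
#'
#' @param params A [kinetic_params()] object.
#' @param conc Analyte concentration (nM), >= 0.
#' @param t_assoc Association duration (s), default 300 (5 minutes).
#' @param t_dissoc Dissociation duration (s), default 600 (10 minutes).
#' @param dt Sampling interval (s).
#' @param noise_sd Additive Gaussian noise standard deviation (RU), >= 0.
#' @param seed Optional seed; when given, the draw is made in a local RNG
#'   scope and is reproducible without touching the caller's RNG state.
#' @return A `sensorgram`: data frame with columns `time_s`, `response_RU`
#'   and attributes `conc_nM`, `t_assoc_end`.
#' @export
simulate_sensorgram <- function(params, conc, t_assoc = 300, t_dissoc = 600,
                                dt = 1, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_nonneg(conc, "conc")
  if (t_assoc <= 0 || t_dissoc <= 0)
    stop("phase durations must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  time_s <- seq(0, t_assoc + t_dissoc, by = dt)
  resp <- langmuir_response(time_s, conc, t_assoc,
                            params$kon, params$koff, params$rmax)
  if (noise_sd > 0) {
    draw <- function() rnorm(length(resp), 0, noise_sd)
    eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    resp <- resp + eps
  }
  structure(data.frame(time_s = time_s, response_RU = resp),
            conc_nM = conc, t_assoc_end = t_assoc,
            class = c("sensorgram", "data.frame"))
}

#' Global 1:1 Langmuir fit of a sensorgram series
#'
#' Fits a single set of (`kon`, `koff`, `rmax`) shared across all analyte
#' concentrations by Levenberg-Marquardt least squares on the closed-form
#' 1:1 model. Rate constants are fitted on a log10 scale, which enforces
#' positivity and conditions the problem despite the ~8 orders of magnitude
#' between `kon` and `koff`.
#'
#' Starting values are data-driven: `koff` from a log-linear regression on
#' the dissociation tail of the highest-concentration curve, `rmax` slightly
#' above the largest observed plateau, and `kon` from `koff` divided by the
#' concentration at half-maximal plateau.
#'
#' @param sensorgrams List of [simulate_sensorgram()]-style `sensorgram`
#'   objects (or data frames with `time_s`, `response_RU` plus `conc_nM` and
#'   `t_assoc_end` attributes) at >= 3 distinct concentrations.
#' @param per_curve_rmax Reserved; only the global (shared `rmax`) model is
#'   implemented and `TRUE` is rejected.
#' @return Object of class `langmuir_fit`: list with `kon`, `koff`, `rmax`,
#'   `kd` (nM), `se` (standard errors for `kon`, `koff`, `rmax`, `kd`, delta
#'   method for the rates), `rss`, `converged`, `n`. Non-convergence is
#'   flagged, not thrown.
#' @export
global_fit_langmuir <- function(sensorgrams, per_curve_rmax = FALSE) {
  if (isTRUE(per_curve_rmax))
    stop("per-curve rmax is not implemented; the model is global",
         call. = FALSE)
  stopifnot(is.list(sensorgrams), length(sensorgrams) >= 3)
  concs <- vapply(sensorgrams, function(s) attr(s, "conc_nM"), numeric(1))
  if (length(unique(concs)) < 3)
    stop("need sensorgrams at >= 3 distinct concentrations", call. = FALSE)
  t_assoc <- attr(sensorgrams[[1]], "t_assoc_end")

  dat <- do.call(rbind, lapply(sensorgrams, function(s) {
    data.frame(time_s = s$time_s, response_RU = s$response_RU,
               conc_nM = attr(s, "conc_nM"))
  }))

  # init: koff from the dissociation tail of the top curve
  top <- sensorgrams[[which.max(concs)]]
  dis <- top[top$time_s > t_assoc & top$response_RU > 0, ]
  koff0 <- if (nrow(dis) > 5) {
    sl <- coef(lm(log(response_RU) ~ time_s, data = dis))[2]
    max(-unname(sl), 1e-6)
  } else 1e-3
  plateau <- vapply(sensorgrams, function(s) {
    a <- s[s$time_s <= t_assoc, ]
    mean(tail(a$response_RU, max(3, nrow(a) %/% 20)))
  }, numeric(1))
  rmax0 <- max(plateau) * 1.05
  kd0_nM <- concs[which.min(abs(plateau - rmax0 / 2))]
  kd0_nM <- max(kd0_nM, 1e-3)
  kon0 <- koff0 / (kd0_nM * 1e-9)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      response_RU ~ langmuir_response(time_s, conc_nM, t_assoc,
                                      10^lkon, 10^lkoff, rmax),
      data = dat,
      start = list(lkon = log10(kon0), lkoff = log10(koff0), rmax = rmax0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    out <- list(kon = NA_real_, koff = NA_real_, rmax = NA_real_,
                kd = NA_real_,
                se = c(kon = NA_real_, koff = NA_real_, rmax = NA_real_,
                       kd = NA_real_),
                rss = NA_real_, converged = FALSE, n = nrow(dat),
                message = conditionMessage(fit))
    class(out) <- "langmuir_fit"
    return(out)
  }

  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  kon <- 10^cf[["lkon"]]; koff <- 10^cf[["lkoff"]]; rmax <- cf[["rmax"]]
  ln10 <- log(10)
  se_kon <- kon * ln10 * sqrt(vc[1, 1])
  se_koff <- koff * ln10 * sqrt(vc[2, 2])
  se_rmax <- sqrt(vc[3, 3])
  # kd = 10^(lkoff - lkon) * 1e9 nM
  var_lkd <- vc[2, 2] + vc[1, 1] - 2 * vc[1, 2]
  kd <- koff / kon * 1e9
  se_kd <- kd * ln10 * sqrt(max(var_lkd, 0))
  out <- list(kon = kon, koff = koff, rmax = rmax, kd = kd,
              se = c(kon = se_kon, koff = se_koff, rmax = se_rmax,
                     kd = se_kd),
              rss = sum(stats::residuals(fit)^2),
              converged = TRUE, n = nrow(dat))
  class(out) <- "langmuir_fit"
  out
}

#' @export
print.langmuir_fit <- function(x, ...) {
  if (!x$converged) {
    cat("global Langmuir fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("global 1:1 Langmuir fit (n = %d points)\n", x$n))
  cat(sprintf("  kon  = %.4g /(M s) (se %.3g)\n", x$kon, x$se["kon"]))
  cat(sprintf("  koff = %.4g /s (se %.3g)\n", x$koff, x$se["koff"]))
  cat(sprintf("  Rmax = %.4g RU (se %.3g)\n", x$rmax, x$se["rmax"]))
  cat(sprintf("  K_D  = %.4g nM (se %.3g)\n", x$kd, x$se["kd"]))
  invisible(x)
}

#' Expected saturating analyte response from ligand response units
#'
#' SPR response is proportional to bound mass, so a ligand captured at
#' `ru_ligand` response units binding `n_sites` analyte molecules per ligand
#' gives an expected analyte saturation response of
#' `ru_ligand * n_sites * mass_analyte / mass_ligand`. Comparing this
#' expectation with the measured analyte response tests the assumed
#' stoichiometry: 78 RU of a 200 kDa drug binding two 47.15 kDa Fabs predicts
#' 36.8 RU, i.e. 37 RU to instrument precision.
#'
#' @param ru_ligand Captured ligand response (RU).
#' @param mass_ligand Ligand molecular mass (Da).
#' @param mass_analyte Analyte molecular mass (Da).
#' @param n_sites Analyte binding sites per ligand molecule.
#' @return Expected analyte response (RU).
#' @export
expected_rmax <- function(ru_ligand, mass_ligand, mass_analyte, n_sites) {
  vals <- c(ru_ligand, mass_ligand, mass_analyte, n_sites)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all arguments must be positive", call. = FALSE)
  ru_ligand * n_sites * mass_analyte / mass_ligand
}

#' Read or write a sensorgram series as CSV
#'
#' Long format with columns `conc_nM`, `time_s`, `response_RU`; the
#' association end time is stored per file via the `t_assoc_end` argument /
#' attribute (the CSV itself is data-only).
#'
#' @param path File path.
#' @param sensorgrams List of `sensorgram` objects.
#' @param t_assoc_end Association end time (s) to attach on read.
#' @return `read_sensorgram_csv()` returns a list of `sensorgram` objects.
#' @export
read_sensorgram_csv <- function(path, t_assoc_end) {
  df <- utils::read.csv(path)
  need <- c("conc_nM", "time_s", "response_RU")
  if (!all(need %in% names(df)))
    stop("sensorgram CSV needs columns conc_nM, time_s, response_RU",
         call. = FALSE)
  lapply(split(df, df$conc_nM), function(d) {
    structure(data.frame(time_s = d$time_s, response_RU = d$response_RU),
              conc_nM = d$conc_nM[1], t_assoc_end = t_assoc_end,
              class = c("sensorgram", "data.frame"))
  })
}

#' @rdname read_sensorgram_csv
#' @export
write_sensorgram_csv <- function(sensorgrams, path) {
  df <- do.call(rbind, lapply(sensorgrams, function(s) {
    data.frame(conc_nM = attr(s, "conc_nM"), time_s = s$time_s,
               response_RU = s$response_RU)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
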
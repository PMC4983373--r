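#' Fit the equilibrium dissociation constant to a SEC titration
#'
#' Nonlinear least-squares fit of the one-site specific (quadratic
#' tight-binding) curve [signal_model()] to percent-bound observations from a
#' drug titration at fixed detection-Fab concentration. The free parameters
#' are the baseline `f_min`, the plateau `f_max` and `kd`; the Fab
#' concentration `a_total` is a known experimental constant.
#'
#' Starting values are derived from the data unless supplied: `f_min` and
#' `f_max` from the extreme observations, and `kd` from the half-maximal
#' concentration corrected for ligand depletion (in the tight-binding regime
#' the half-max sits near `a/2 + kd`, not at `kd`). Levenberg-Marquardt
#' iterations (via \pkg{minpack.lm}) with a positivity bound on `kd` do the
#' rest.
#'
#' Site stoichiometry is the caller's responsibility: pass concentrations
#' already adjusted with [effective_site_concentration()].
#'
#' When the Fab concentration greatly exceeds the fitted `kd`
#' (`a_total > 50 * kd`) the titration is stoichiometric rather than
#' affinity-limited and `kd` is weakly identified; the result carries a
#' `weak_identifiability` flag in that case. Detection sensitivity forces the
#' Fab concentration well above the low-nanomolar affinity in practice, so
#' the flag is a real failure mode of this assay format, not a corner case.
#'
#' @param points Data frame with columns `x_total_nM` (site-adjusted drug
#'   concentration, nM) and `percent_bound` (observed signal). At least 4
#'   points spanning a >= 10-fold concentration range are required.
#' @param a_total Total detection-Fab concentration (nM), positive.
#' @param init Optional [binding_curve_params()] with starting values.
#' @param relative_weights If `TRUE`, weight residuals by `1/y^2`
#'   (relative least squares); default `FALSE` (unweighted).
#' @return Object of class `kd_fit`: a list with `params`
#'   ([binding_curve_params()]), `se` (named standard errors), `rss`,
#'   `converged`, `weak_identifiability`, `n`, `a_total`, and the model
#'   `data`. On non-convergence `converged` is `FALSE` and the parameters are
#'   `NA`; no exception is thrown.
#' @export
fit_kd <- function(points, a_total, init = NULL, relative_weights = FALSE) {
  stopifnot(is.data.frame(points))
  if (!all(c("x_total_nM", "percent_bound") %in% names(points)))
    stop("`points` needs columns x_total_nM and percent_bound", call. = FALSE)
  x <- points$x_total_nM
  y <- points$percent_bound
  .check_nonneg(x, "x_total_nM")
  if (any(!is.finite(y))) stop("percent_bound must be finite", call. = FALSE)
  if (length(x) < 4)
    stop("at least 4 titration points are required", call. = FALSE)
  xp <- x[x > 0]
  if (length(xp) < 2 || max(xp) / min(xp) < 10)
    stop("titration must span at least a 10-fold concentration range",
         call. = FALSE)
  .check_nonneg(a_total, "a_total")
  if (a_total == 0) stop("a_total must be > 0", call. = FALSE)

  if (is.null(init)) {
    f0 <- min(y)
    fmax0 <- max(y)
    half <- (f0 + fmax0) / 2
    # In the tight-binding regime the half-maximal signal sits near
    # x = a/2 + kd, so the excess of the half-max concentration over a/2 is
    # a direct kd estimate; the floor guards against noise pushing it to 0.
    x_half <- tryCatch(
      exp(stats::approx(y, log(x), xout = half, ties = mean)$y),
      error = function(e) NA_real_)
    if (!is.finite(x_half)) x_half <- x[which.min(abs(y - half))]
    if (!is.finite(x_half) || x_half <= 0) x_half <- stats::median(xp)
    kd0 <- max(x_half - a_total / 2, x_half / 20)
    init <- binding_curve_params(f0, fmax0, kd0)
  }
  stopifnot(inherits(init, "binding_curve_params"))

  w <- if (relative_weights) 1 / pmax(y, 1e-6)^2 else rep(1, length(y))
  dat <- data.frame(x = x, y = y)
  sw <- sqrt(w)
  resid_fn <- function(p)
    sw * (y - (p[1] + (p[2] - p[1]) *
                 solve_bound_complex(a_total, x, p[3]) / a_total))

  # nls.lm rather than nls/nlsLM: a near-stoichiometric titration has an
  # almost-singular Jacobian in kd, which must yield a flagged result, not
  # an exception from model construction.
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(f = init$f_min, fmax = init$f_max, kd = max(init$kd, 1e-6)),
      fn = resid_fn,
      lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)

  failed <- inherits(fit, "error")
  converged <- !failed && fit$info %in% 1:4
  if (failed || !converged) {
    out <- list(params = NULL,
                se = c(f_min = NA_real_, f_max = NA_real_, kd = NA_real_),
                rss = if (failed) NA_real_ else fit$deviance,
                converged = FALSE, weak_identifiability = NA,
                n = length(y), a_total = a_total, data = dat,
                message = if (failed) conditionMessage(fit) else fit$message)
    class(out) <- "kd_fit"
    return(out)
  }

  cf <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  params <- binding_curve_params(unname(cf["f"]),
                                 unname(max(cf["fmax"], cf["f"])),
                                 unname(cf["kd"]))
  out <- list(
    params = params,
    se = c(f_min = unname(se[1]), f_max = unname(se[2]), kd = unname(se[3])),
    rss = fit$deviance,
    converged = TRUE,
    weak_identifiability = a_total > 50 * params$kd,
    n = length(y),
    a_total = a_total,
    data = dat)
  class(out) <- "kd_fit"
  out
}

#' @export
print.kd_fit <- function(x, ...) {
  if (!x$converged) {
    cat("K_D fit: did not converge\n")
    if (!is.null(x$message)) cat("  ", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("K_D fit (n = %d, a_total = %.4g nM)\n", x$n, x$a_total))
  cat(sprintf("  K_D   = %.4g nM (se %.3g)\n", x$params$kd, x$se["kd"]))
  cat(sprintf("  f_min = %.4g (se %.3g), f_max = %.4g (se %.3g)\n",
              x$params$f_min, x$se["f_min"], x$params$f_max, x$se["f_max"]))
  cat(sprintf("  RSS   = %.4g\n", x$rss))
  if (isTRUE(x$weak_identifiability))
    cat("  warning: a_total > 50 * K_D -- titration is stoichiometric,",
        "K_D weakly identified\n")
  invisible(x)
}

#' Read or write a titration table as CSV
#'
#' The on-disk format has columns `x_total_nM` and `percent_bound`.
#'
#' @param path File path.
#' @param points Data frame as accepted by [fit_kd()].
#' @return `read_titration_csv()` returns the data frame.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_total_nM", "percent_bound") %in% names(df)))
    stop("titration CSV needs columns x_total_nM, percent_bound",
         call. = FALSE)
  df
}

#' @rdname read_titration_csv
#' @export
write_titration_csv <- function(points, path) {
  utils::write.csv(points[, c("x_total_nM", "percent_bound")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Serialize a fit report to JSON
#'
#' Works for both [fit_kd()] and [global_fit_langmuir()] results.
#'
#' @param fit A `kd_fit` or `langmuir_fit` object.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  rep <- if (inherits(fit, "kd_fit")) {
    list(model = "one_site_quadratic",
         converged = fit$converged,
         kd_nM = if (fit$converged) fit$params$kd else NA,
         f_min = if (fit$converged) fit$params$f_min else NA,
         f_max = if (fit$converged) fit$params$f_max else NA,
         se = as.list(fit$se), rss = fit$rss,
         weak_identifiability = fit$weak_identifiability,
         n = fit$n, a_total_nM = fit$a_total)
  } else if (inherits(fit, "langmuir_fit")) {
    list(model = "langmuir_1to1_global",
         converged = fit$converged,
         kon_per_M_s = fit$kon, koff_per_s = fit$koff,
         rmax_RU = fit$rmax, kd_nM = fit$kd,
         se = as.list(fit$se), rss = fit$rss, n = fit$n)
  } else stop("unsupported fit object", call. = FALSE)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
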
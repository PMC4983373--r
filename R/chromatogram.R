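#' SEC fluorescence chromatogram
#'
#' A chromatogram is a fluorescence trace on a strictly increasing time grid
#' (minutes), with the column flow rate and a sample label carried as
#' metadata.
#'
#' @param time_min Elution time grid (minutes), strictly increasing.
#' @param signal Fluorescence signal (arbitrary units), same length.
#' @param flow_rate Column flow rate (mL/min); the default calibration
#'   assumes 0.3 mL/min.
#' @param label Sample identifier.
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(time_min, signal, flow_rate = 0.3, label = "") {
  if (length(time_min) != length(signal))
    stop("time and signal must have the same length", call. = FALSE)
  if (length(time_min) < 2 || any(diff(time_min) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(signal)))
    stop("signal must be finite", call. = FALSE)
  structure(list(time_min = as.numeric(time_min),
                 signal = as.numeric(signal),
                 flow_rate = flow_rate, label = as.character(label)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "chromatogram '%s': %d points, %.2f-%.2f min, flow %.2g mL/min\n",
    x$label, length(x$time_min), min(x$time_min), max(x$time_min),
    x$flow_rate))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ...) {
  plot(x$time_min, x$signal, type = "l", xlab = "time (min)",
       ylab = "fluorescence (AU)", main = x$label, ...)
}

#' Species classes resolved by the assay
#'
#' `ada_species()` lists the size classes that contain ADA (the complex
#' classes summed by [percent_complex()]); `drug_linked_species()`
#' additionally includes the binary drug-Fab complex, i.e. everything whose
#' fluorescence reports drug. The unspecific serum peak, free detection Fab
#' and free dye are never drug-linked.
#'
#' @return Character vector of species class names.
#' @export
ada_species <- function() {
  c("ADA1_DRUG1", "ADA1_DRUG2", "LARGE_COMPLEX")
}

#' @rdname ada_species
#' @export
drug_linked_species <- function() {
  c("DRUG_FAB", ada_species())
}

#' Default retention-window calibration
#'
#' Retention windows per species class at 0.3 mL/min. Free dye (19.5 min),
#' free Fab (18 min) and the drug-Fab complex (15 min) are anchored to
#' observed elution times; the ADA-complex windows are figure-informed
#' defaults (larger species elute earlier) and should be recalibrated per
#' column. Windows of distinct classes must not overlap. The free dye elutes
#' later than its 1 kDa mass predicts, so calibration is always by species,
#' never by a mass-to-time relation.
#'
#' @return Data frame with columns `species`, `t_start_min`, `t_end_min`.
#' @export
default_calibration <- function() {
  data.frame(
    species = c("LARGE_COMPLEX", "ADA1_DRUG2", "ADA1_DRUG1", "DRUG_FAB",
                "UNSPECIFIC", "FAB488", "FREE_DYE"),
    t_start_min = c(9.5, 12.0, 13.0, 14.5, 16.3, 17.5, 19.0),
    t_end_min   = c(11.9, 13.0, 14.0, 15.5, 17.1, 18.5, 20.0))
}

.check_calibration <- function(calibration) {
  need <- c("species", "t_start_min", "t_end_min")
  if (!is.data.frame(calibration) || !all(need %in% names(calibration)))
    stop("calibration needs columns species, t_start_min, t_end_min",
         call. = FALSE)
  if (any(calibration$t_start_min >= calibration$t_end_min))
    stop("each window needs t_start_min < t_end_min", call. = FALSE)
  o <- order(calibration$t_start_min)
  s <- calibration[o, ]
  if (nrow(s) > 1 &&
      any(s$t_start_min[-1] < s$t_end_min[-nrow(s)] - 1e-12))
    stop("calibration windows may not overlap", call. = FALSE)
  invisible(calibration)
}

.window_for <- function(calibration, species) {
  i <- match(species, calibration$species)
  if (is.na(i)) stop("species not in calibration: ", species, call. = FALSE)
  calibration[i, , drop = FALSE]
}

#' Render a chromatogram from a species table (forward model)
#'
#' Each species contributes a Gaussian peak centred in its calibration
#' window, with area proportional to its fluorescence weight: concentration
#' times the number of detection-Fab molecules carried
#' (`conc_nM * n_fab`). Free dye and the unspecific serum peak are
#' intrinsically fluorescent and weigh by concentration alone. An optional
#' broad Gaussian models the serum matrix background, and baseline noise is
#' additive Gaussian. One fluorescence-weight unit contributes one AU min of
#' area.
#'
#' @param species Data frame with columns `species_class`, `conc_nM` and,
#'   for complex classes, `n_fab` (defaults to 1 where missing).
#' @param calibration Retention calibration, see [default_calibration()].
#' @param peak_width Gaussian peak sigma (minutes); one shared width.
#' @param noise_sd Additive baseline noise standard deviation (AU).
#' @param seed Optional seed for a local, reproducible noise draw.
#' @param background_area Total area (AU min) of the broad serum background
#'   component; 0 disables it.
#' @param background_center,background_sd Centre and sigma (minutes) of the
#'   serum background Gaussian.
#' @param time_range,dt Time grid span and spacing (minutes).
#' @param flow_rate,label Metadata for the returned chromatogram.
#' @return A [chromatogram()].
#' @export
render_chromatogram <- function(species, calibration = default_calibration(),
                                peak_width = 0.2, noise_sd = 0, seed = NULL,
                                background_area = 0,
                                background_center = 14.5, background_sd = 2.5,
                                time_range = c(8, 21), dt = 0.01,
                                flow_rate = 0.3, label = "") {
  .check_calibration(calibration)
  stopifnot(is.data.frame(species),
            all(c("species_class", "conc_nM") %in% names(species)))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  .check_nonneg(species$conc_nM, "conc_nM")
  unknown <- setdiff(species$species_class, calibration$species)
  if (length(unknown))
    stop("uncalibrated species: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  t <- seq(time_range[1], time_range[2], by = dt)
  sig <- numeric(length(t))
  self_fluor <- c("FREE_DYE", "UNSPECIFIC")
  n_fab <- if ("n_fab" %in% names(species)) species$n_fab else
    rep(1, nrow(species))
  n_fab[is.na(n_fab)] <- 1
  for (i in seq_len(nrow(species))) {
    cls <- species$species_class[i]
    w <- .window_for(calibration, cls)
    center <- (w$t_start_min + w$t_end_min) / 2
    weight <- if (cls %in% self_fluor) species$conc_nM[i] else
      species$conc_nM[i] * n_fab[i]
    sig <- sig + weight * dnorm(t, center, peak_width)
  }
  if (background_area > 0)
    sig <- sig + background_area * dnorm(t, background_center, background_sd)
  if (noise_sd > 0) {
    draw <- function() rnorm(length(t), 0, noise_sd)
    eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    sig <- sig + eps
  }
  chromatogram(t, sig, flow_rate = flow_rate, label = label)
}

# Constant baseline: median signal over the first and last 5% of the trace.
.baseline <- function(chrom, edge_fraction = 0.05) {
  n <- length(chrom$time_min)
  k <- max(1L, floor(n * edge_fraction))
  median(c(head(chrom$signal, k), tail(chrom$signal, k)))
}

.trace_area <- function(chrom, baseline) {
  max(pracma::trapz(chrom$time_min, chrom$signal - baseline), 0)
}

#' Integrate a retention window
#'
#' Trapezoidal area of the baseline-corrected signal inside the window, and
#' that area as a fraction of the total baseline-corrected trace area. The
#' baseline is a constant estimated as the median of the first and last 5%
#' of the trace. Areas are floored at zero (noise can drive the corrected
#' integral slightly negative).
#'
#' @param chrom A [chromatogram()].
#' @param window One calibration row (or list) with `species`, `t_start_min`,
#'   `t_end_min`, contained in the chromatogram's time range.
#' @return One-row data frame: `species`, `t_start_min`, `t_end_min`, `area`
#'   (AU min), `percent_of_total` (fraction in `[0, 1]`).
#' @export
integrate_window <- function(chrom, window) {
  stopifnot(inherits(chrom, "chromatogram"))
  t0 <- window$t_start_min; t1 <- window$t_end_min
  if (is.null(t0) || is.null(t1) || t0 >= t1)
    stop("window needs t_start_min < t_end_min", call. = FALSE)
  if (t0 < min(chrom$time_min) || t1 > max(chrom$time_min))
    stop("window outside chromatogram time range", call. = FALSE)
  idx <- chrom$time_min >= t0 & chrom$time_min <= t1
  if (sum(idx) < 2) stop("empty window: no sampled points", call. = FALSE)
  b <- .baseline(chrom)
  area <- max(pracma::trapz(chrom$time_min[idx], chrom$signal[idx] - b), 0)
  total <- .trace_area(chrom, b)
  pct <- if (total > 0) min(area / total, 1) else 0
  data.frame(species = if (is.null(window$species)) NA_character_ else
               as.character(window$species),
             t_start_min = t0, t_end_min = t1,
             area = area, percent_of_total = pct)
}

#' Quantify every calibrated window of a chromatogram
#'
#' Applies [integrate_window()] to each calibration row; the standard
#' per-sample quantification report.
#'
#' @inheritParams integrate_window
#' @param calibration Retention calibration data frame.
#' @return Data frame, one row per window, with a `label` column.
#' @export
quantify_windows <- function(chrom, calibration = default_calibration()) {
  .check_calibration(calibration)
  out <- do.call(rbind, lapply(seq_len(nrow(calibration)), function(i)
    integrate_window(chrom, calibration[i, ])))
  out$label <- chrom$label
  out
}

#' Percentage-area signal-to-noise ratio
#'
#' The detection statistic of the assay: the percent of total trace area in
#' the complex window of a sample, divided by the percent of area in the same
#' retention window of a drug-free control run. Because both terms are
#' area *fractions*, the statistic is invariant to overall scaling of either
#' trace.
#'
#' @param sample,blank Chromatograms sharing the same time grid.
#' @param window Retention window (calibration row).
#' @return The ratio. A blank percentage of exactly zero yields `Inf` with a
#'   warning (infinite-SNR sentinel).
#' @export
snr <- function(sample, blank, window) {
  stopifnot(inherits(sample, "chromatogram"), inherits(blank, "chromatogram"))
  if (length(sample$time_min) != length(blank$time_min) ||
      any(abs(sample$time_min - blank$time_min) > 1e-9))
    stop("sample and blank must share the same time grid", call. = FALSE)
  ps <- integrate_window(sample, window)$percent_of_total
  pb <- integrate_window(blank, window)$percent_of_total
  if (pb == 0) {
    warning("blank percentage is zero; returning Inf", call. = FALSE)
    return(Inf)
  }
  ps / pb
}

#' Limit of detection from a titration of chromatograms
#'
#' Scans an ascending titration for the lowest concentration whose
#' signal-to-noise ratio against the drug-free blank reaches the threshold
#' (1.5 by default).
#'
#' @param titration List of elements each holding `conc_nM` and
#'   `chromatogram`, sorted by ascending concentration.
#' @param blank Drug-free control chromatogram on the same grid.
#' @param window Complex-peak retention window.
#' @param threshold S/N threshold, default 1.5.
#' @return The limit-of-detection concentration (nM), with the per-level S/N
#'   values attached as attribute `snr`. `NA` (with attribute
#'   `not_detected = TRUE`) if no level qualifies.
#' @export
detect_lod <- function(titration, blank, window, threshold = 1.5) {
  stopifnot(is.list(titration), length(titration) >= 2)
  conc <- vapply(titration, function(s) s$conc_nM, numeric(1))
  if (is.unsorted(conc, strictly = TRUE))
    stop("titration must be sorted by strictly ascending concentration",
         call. = FALSE)
  ratios <- vapply(titration, function(s) snr(s$chromatogram, blank, window),
                   numeric(1))
  hit <- which(ratios >= threshold)
  if (!length(hit)) {
    out <- structure(NA_real_, not_detected = TRUE,
                     snr = setNames(ratios, conc))
    message("no concentration reached S/N >= ", threshold)
    return(out)
  }
  structure(conc[min(hit)], snr = setNames(ratios, conc))
}

#' Fraction of fluorescence in ADA-containing complex windows
#'
#' Summed baseline-corrected areas of the ADA-containing size-class windows
#' (1 ADA : 1 drug, 1 ADA : 2 drug, and larger unresolved complexes) divided
#' by the total trace area: the "% complex" statistic.
#'
#' @inheritParams quantify_windows
#' @return Fraction in `[0, 1]`.
#' @export
percent_complex <- function(chrom, calibration = default_calibration()) {
  .check_calibration(calibration)
  cal <- calibration[calibration$species %in% ada_species(), , drop = FALSE]
  if (!nrow(cal))
    stop("calibration defines no ADA-containing windows", call. = FALSE)
  b <- .baseline(chrom)
  total <- .trace_area(chrom, b)
  if (total <= 0) stop("zero total trace area", call. = FALSE)
  areas <- vapply(seq_len(nrow(cal)), function(i)
    integrate_window(chrom, cal[i, ])$area, numeric(1))
  min(sum(areas) / total, 1)
}

#' Read or write a chromatogram as CSV
#'
#' Two columns: `time_min`, `fluorescence`.
#'
#' @param path File path.
#' @param chrom A [chromatogram()].
#' @param flow_rate,label Metadata attached on read.
#' @return `read_chromatogram_csv()` returns a [chromatogram()].
#' @export
read_chromatogram_csv <- function(path, flow_rate = 0.3, label = "") {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "fluorescence") %in% names(df)))
    stop("chromatogram CSV needs columns time_min, fluorescence",
         call. = FALSE)
  chromatogram(df$time_min, df$fluorescence, flow_rate = flow_rate,
               label = label)
}

#' @rdname read_chromatogram_csv
#' @export
write_chromatogram_csv <- function(chrom, path) {
  utils::write.csv(data.frame(time_min = chrom$time_min,
                              fluorescence = chrom$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read or write a retention calibration as YAML
#'
#' The YAML file is a list of mappings with keys `species`, `t_start_min`,
#' `t_end_min`.
#'
#' @param path File path.
#' @param calibration Calibration data frame.
#' @return `read_calibration_yaml()` returns the calibration data frame.
#' @export
read_calibration_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cal <- do.call(rbind, lapply(lst, function(w)
    data.frame(species = w$species, t_start_min = w$t_start_min,
               t_end_min = w$t_end_min)))
  .check_calibration(cal)
  cal
}

#' @rdname read_calibration_yaml
#' @export
write_calibration_yaml <- function(calibration, path) {
  .check_calibration(calibration)
  lst <- lapply(seq_len(nrow(calibration)), function(i)
    list(species = calibration$species[i],
         t_start_min = calibration$t_start_min[i],
         t_end_min = calibration$t_end_min[i]))
  yaml::write_yaml(lst, path)
  invisible(path)
}
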
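#' Immune-complex species composition
#'
#' A complex is described by its composition: `n_drug` drug molecules,
#' `n_ada` ADA molecules, and `n_fab` detection-Fab molecules bound. Each
#' drug molecule carries two Fab epitopes, so `n_fab <= 2 * n_drug`.
#'
#' @param n_drug,n_ada,n_fab Non-negative integer counts.
#' @param conc_nM Concentration of the species (nM).
#' @return One-row data frame with a `species_class` column assigned by
#'   [classify_complex()].
#' @export
complex_species <- function(n_drug, n_ada, n_fab = 2 * n_drug, conc_nM = 0) {
  counts <- c(n_drug, n_ada, n_fab)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (n_fab > 2 * n_drug)
    stop("n_fab may not exceed 2 * n_drug (two Fab epitopes per drug)",
         call. = FALSE)
  .check_nonneg(conc_nM, "conc_nM")
  data.frame(species_class = classify_complex(n_drug, n_ada),
             n_drug = n_drug, n_ada = n_ada, n_fab = n_fab,
             conc_nM = conc_nM)
}

#' Map a complex composition to its SEC size class
#'
#' Resolved classes: free drug-Fab (no ADA), one drug bound to one ADA, two
#' drugs bound to one ADA; anything larger falls into the unresolved
#' large-complex class.
#'
#' @param n_drug,n_ada Molecule counts (vectorised).
#' @return Character vector of species class names.
#' @export
classify_complex <- function(n_drug, n_ada) {
  mapply(function(nd, na) {
    if (nd < 1) stop("a complex must contain at least one drug molecule",
                     call. = FALSE)
    if (na == 0) "DRUG_FAB"
    else if (nd == 1 && na == 1) "ADA1_DRUG1"
    else if (nd == 2 && na == 1) "ADA1_DRUG2"
    else "LARGE_COMPLEX"
  }, n_drug, n_ada, USE.NAMES = FALSE)
}

#' Densitometry of a supernatant/pellet fractionation
#'
#' Band intensities per protein for the pellet and supernatant lanes of a
#' centrifuged reaction, together with the volume split of the two lanes:
#' the pellet lane carries the bottom 20% of the reaction volume (and hence
#' also 20% of the *soluble* protein), the supernatant lane the top 80%.
#'
#' @param pellet,supernatant Named numeric vectors of band intensities (same
#'   protein names, all >= 0).
#' @param pellet_volume_fraction,supernatant_volume_fraction Volume shares of
#'   the two lanes; must sum to 1.
#' @return Object of class `pellet_quant`.
#' @export
pellet_quant <- function(pellet, supernatant,
                         pellet_volume_fraction = 0.2,
                         supernatant_volume_fraction = 0.8) {
  if (is.null(names(pellet)) || is.null(names(supernatant)) ||
      !setequal(names(pellet), names(supernatant)))
    stop("pellet and supernatant must be named vectors over the same proteins",
         call. = FALSE)
  supernatant <- supernatant[names(pellet)]
  .check_nonneg(pellet, "pellet")
  .check_nonneg(supernatant, "supernatant")
  if (abs(pellet_volume_fraction + supernatant_volume_fraction - 1) > 1e-9)
    stop("volume fractions must sum to 1", call. = FALSE)
  structure(list(pellet = pellet, supernatant = supernatant,
                 pellet_volume_fraction = pellet_volume_fraction,
                 supernatant_volume_fraction = supernatant_volume_fraction),
            class = "pellet_quant")
}

#' @export
print.pellet_quant <- function(x, ...) {
  cat(sprintf("pellet quant (%d%%/%d%% volume split)\n",
              round(100 * x$pellet_volume_fraction),
              round(100 * x$supernatant_volume_fraction)))
  print(rbind(pellet = x$pellet, supernatant = x$supernatant))
  invisible(x)
}

#' Precipitated fraction per protein from a supernatant/pellet experiment
#'
#' The pellet lane holds all precipitated protein plus the soluble protein
#' dissolved in its share of the reaction volume, so the naive pellet lane
#' intensity overstates precipitation. Correcting for the volume split
#' (fractions `v_p`/`v_s`):
#' soluble total = S / v_s; precipitated = P - v_p * soluble;
#' fraction = precipitated / (precipitated + soluble). A soluble-only protein
#' therefore shows `v_p` (20%) of its intensity in the pellet lane and maps
#' to a precipitated fraction of zero.
#'
#' Densitometry noise can push the precipitated estimate slightly negative
#' (or above one); such values are clipped into `[0, 1]` and flagged via the
#' `clipped` attribute rather than silently accepted.
#'
#' @param q A [pellet_quant()].
#' @return Named vector of precipitated fractions in `[0, 1]`, with logical
#'   attribute `clipped` per protein.
#' @export
pellet_mass_balance <- function(q) {
  stopifnot(inherits(q, "pellet_quant"))
  P <- q$pellet; S <- q$supernatant
  if (any(P + S <= 0))
    stop("each protein needs pellet + supernatant intensity > 0",
         call. = FALSE)
  soluble <- S / q$supernatant_volume_fraction
  precipitated <- P - q$pellet_volume_fraction * soluble
  frac <- precipitated / (precipitated + soluble)
  clipped <- frac < 0 | frac > 1
  frac <- pmin(pmax(frac, 0), 1)
  structure(frac, clipped = clipped)
}

#' Complex profiling across an ADA titration
#'
#' Applies [percent_complex()] and per-window quantification to each sample
#' of an ADA titration at fixed drug and detection-Fab concentrations, and
#' summarises where complex detection peaks and how much it declines at the
#' highest ADA level (the signature of complex precipitation).
#'
#' @param series List of elements each holding `ada_conc_nM` and
#'   `chromatogram`; at least 2 concentrations.
#' @param calibration Retention calibration.
#' @return Object of class `ada_series_analysis`: list with `table` (one row
#'   per sample: `ada_conc_nM`, `percent_complex`, one percent column per
#'   calibrated window), `argmax_conc_nM` (ADA concentration of maximal
#'   percent complex) and `decline` (1 - last/max percent complex).
#' @export
ada_series_analysis <- function(series, calibration = default_calibration()) {
  stopifnot(is.list(series), length(series) >= 2)
  .check_calibration(calibration)
  rows <- lapply(series, function(s) {
    qw <- quantify_windows(s$chromatogram, calibration)
    pc <- percent_complex(s$chromatogram, calibration)
    pcts <- setNames(as.list(qw$percent_of_total),
                     paste0("pct_", qw$species))
    cbind(data.frame(ada_conc_nM = s$ada_conc_nM, percent_complex = pc),
          as.data.frame(pcts))
  })
  tab <- do.call(rbind, rows)
  imax <- which.max(tab$percent_complex)
  decline <- 1 - tab$percent_complex[nrow(tab)] / tab$percent_complex[imax]
  structure(list(table = tab,
                 argmax_conc_nM = tab$ada_conc_nM[imax],
                 decline = decline),
            class = "ada_series_analysis")
}

#' @export
print.ada_series_analysis <- function(x, ...) {
  cat("ADA titration complex profile\n")
  print(x$table[, c("ada_conc_nM", "percent_complex")], row.names = FALSE)
  cat(sprintf("max %% complex at %.4g nM ADA; decline to highest ADA: %.1f%%\n",
              x$argmax_conc_nM, 100 * x$decline))
  invisible(x)
}

#' One serum sample of a multi-dose timecourse
#'
#' @param dose_index Dose number (>= 1).
#' @param time_offset Sampling time relative to the dose; one of
#'   `timecourse_offsets()`.
#' @param chromatogram The sample's SEC trace, or `NULL` if missing.
#' @param lba_conc Free-drug concentration from the ligand-binding assay
#'   (ug/mL in 100% serum), or `NA`.
#' @param lba_bql `TRUE` if the LBA value was below the lower limit of
#'   quantitation; the value is then carried as the limit itself
#'   (`lba_lloq`), never as zero.
#' @param western_intensity Total-drug western band intensity (AU), or `NA`.
#' @param lba_lloq LBA lower limit of quantitation (ug/mL in serum).
#' @return Object of class `timecourse_point`.
#' @export
timecourse_point <- function(dose_index, time_offset, chromatogram = NULL,
                             lba_conc = NA_real_, lba_bql = FALSE,
                             western_intensity = NA_real_,
                             lba_lloq = 0.136) {
  if (dose_index < 1 || dose_index != round(dose_index))
    stop("dose_index must be a positive integer", call. = FALSE)
  time_offset <- match.arg(time_offset, timecourse_offsets())
  if (isTRUE(lba_bql)) lba_conc <- lba_lloq
  structure(list(dose_index = as.integer(dose_index),
                 time_offset = time_offset,
                 chromatogram = chromatogram,
                 lba_conc = lba_conc, lba_bql = isTRUE(lba_bql),
                 western_intensity = western_intensity,
                 lba_lloq = lba_lloq),
            class = "timecourse_point")
}

#' @rdname timecourse_point
#' @export
timecourse_offsets <- function() {
  c("pre", "15 min", "4 h", "24 h", "48 h", "96 h", "168 h")
}

#' Quantify free drug and complex classes over a dosing timecourse
#'
#' For every sample: the percent of trace area in the free drug-Fab window,
#' in each ADA-complex class window, and their sum (total drug-linked
#' fluorescence; the unspecific serum peak, free Fab and free dye are
#' excluded). Per dose and species class, the sampling time with the maximal
#' percent area is reported, which exposes the enrichment/clearance pattern
#' (free drug peaking right after the dose; complexes appearing transiently
#' once ADA titres are high).
#'
#' @param points List of [timecourse_point()]s sharing one calibration.
#'   Points with a missing chromatogram are skipped with a warning.
#' @param calibration Retention calibration.
#' @return Object of class `timecourse_analysis`: list with `table` (one row
#'   per sample: dose, time, per-class percents, `drug_linked_pct`, LBA and
#'   western values) and `peaks` (per dose and class, the `time_offset` of
#'   the maximal percent).
#' @export
timecourse_analysis <- function(points, calibration = default_calibration()) {
  stopifnot(is.list(points), length(points) >= 1)
  .check_calibration(calibration)
  rows <- list()
  for (p in points) {
    stopifnot(inherits(p, "timecourse_point"))
    if (is.null(p$chromatogram)) {
      warning(sprintf("dose %d %s: missing chromatogram, skipped",
                      p$dose_index, p$time_offset), call. = FALSE)
      next
    }
    qw <- quantify_windows(p$chromatogram, calibration)
    pct <- setNames(qw$percent_of_total, qw$species)
    classes <- intersect(drug_linked_species(), names(pct))
    rows[[length(rows) + 1]] <- cbind(
      data.frame(dose_index = p$dose_index, time_offset = p$time_offset,
                 free_drug_pct = unname(pct["DRUG_FAB"])),
      as.data.frame(setNames(as.list(unname(pct[ada_species()])),
                             paste0("pct_", ada_species()))),
      data.frame(drug_linked_pct = sum(pct[classes]),
                 lba_conc = p$lba_conc, lba_bql = p$lba_bql,
                 western_intensity = p$western_intensity))
  }
  if (!length(rows)) stop("no points with chromatograms", call. = FALSE)
  tab <- do.call(rbind, rows)
  tab$time_offset <- factor(tab$time_offset, levels = timecourse_offsets())
  tab <- tab[order(tab$dose_index, tab$time_offset), ]
  tab$time_offset <- as.character(tab$time_offset)
  rownames(tab) <- NULL

  cls_cols <- c(free_drug = "free_drug_pct",
                setNames(paste0("pct_", ada_species()), ada_species()))
  peaks <- do.call(rbind, lapply(split(tab, tab$dose_index), function(d) {
    do.call(rbind, lapply(names(cls_cols), function(cl) {
      v <- d[[cls_cols[[cl]]]]
      data.frame(dose_index = d$dose_index[1], class = cl,
                 peak_time = d$time_offset[which.max(v)],
                 peak_pct = max(v))
    }))
  }))
  rownames(peaks) <- NULL
  structure(list(table = tab, peaks = peaks),
            class = "timecourse_analysis")
}

#' @export
print.timecourse_analysis <- function(x, ...) {
  cat("timecourse quantification\n")
  print(x$table[, c("dose_index", "time_offset", "free_drug_pct",
                    "drug_linked_pct")], row.names = FALSE, digits = 3)
  cat("\npeak time per class:\n")
  print(x$peaks, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Concordance between ligand-binding assay and SEC detection
#'
#' Every sample with an LBA free-drug concentration above the SEC
#' sensitivity bound (10 ug/mL in 100% serum) should also show drug-linked
#' SEC signal; samples that do not are discordant. SEC signal is assessed
#' against the predose sample of the same dose when available (drug-linked
#' percent at least `snr_threshold` times the predose value), and otherwise
#' against an absolute floor of 1% of trace area. A missing or empty
#' chromatogram counts as no signal.
#'
#' @param points List of [timecourse_point()]s.
#' @param calibration Retention calibration.
#' @param sec_bound_ug_ml SEC sensitivity bound in 100% serum (ug/mL).
#' @param snr_threshold Ratio over predose required to call signal.
#' @return List with `n_discordant` and a per-sample `table`
#'   (`dose_index`, `time_offset`, `lba_conc`, `sec_signal`, `discordant`).
#' @export
concordance_check <- function(points, calibration = default_calibration(),
                              sec_bound_ug_ml = 10, snr_threshold = 1.5) {
  stopifnot(is.list(points))
  .check_calibration(calibration)
  drug_pct <- function(chrom) {
    if (is.null(chrom)) return(NA_real_)
    qw <- quantify_windows(chrom, calibration)
    sum(qw$percent_of_total[qw$species %in% drug_linked_species()])
  }
  doses <- vapply(points, function(p) p$dose_index, integer(1))
  offsets <- vapply(points, function(p) p$time_offset, character(1))
  pcts <- vapply(points, function(p) drug_pct(p$chromatogram), numeric(1))

  rows <- lapply(seq_along(points), function(i) {
    p <- points[[i]]
    pre <- which(doses == p$dose_index & offsets == "pre")
    signal <- if (is.na(pcts[i])) {
      FALSE
    } else if (length(pre) && !is.na(pcts[pre[1]]) && pcts[pre[1]] > 0) {
      pcts[i] / pcts[pre[1]] >= snr_threshold
    } else {
      pcts[i] > 0.01
    }
    measurable <- !is.na(p$lba_conc) && !p$lba_bql &&
      p$lba_conc > sec_bound_ug_ml
    data.frame(dose_index = p$dose_index, time_offset = p$time_offset,
               lba_conc = p$lba_conc, lba_bql = p$lba_bql,
               sec_signal = signal,
               discordant = measurable && !signal)
  })
  tab <- do.call(rbind, rows)
  list(n_discordant = sum(tab$discordant), table = tab)
}
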
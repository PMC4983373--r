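#' Configuration for the synthetic-data generators
#'
#' One object holds every knob of the seeded generators: the binding truths
#' that downstream fits must recover, the assay design constants, and the
#' noise levels. Each generator exposes its pre-noise truth alongside the
#' data so recovery can be asserted against it.
#'
#' Noise levels: `chromatogram_noise_sd` is additive baseline noise (AU) on
#' rendered traces; `sensorgram_noise_sd` is additive RU noise;
#' `titration_cv` and `lba_cv` are multiplicative (relative) errors on
#' percent-bound points and ligand-binding-assay values;
#' `densitometry_cv` is the relative error on gel band intensities.
#'
#' The serum background (a broad Gaussian of total area
#' `serum_background_area` centred mid-elution) models serum matrix
#' autofluorescence. Its magnitude is a deliberate calibration, not a
#' measurement: it is set so that, under the default titration design, the
#' complex-peak S/N crosses the 1.5 detection threshold between 5 and
#' 10 nM drug, i.e. the generator's detection limit is 10 nM in the assay.
#'
#' @param seed Integer seed; every generator draws in a local RNG scope
#'   derived from it, so identical configs give bit-identical output.
#' @param kd_nM True Fab-drug dissociation constant (nM).
#' @param fab_titration_nM Detection-Fab concentration in the LOD titration
#'   and complex experiments (nM).
#' @param fab_kd_fit_nM Detection-Fab concentration in the K_D titration
#'   design (nM).
#' @param free_dye_nM Residual free dye per sample (nM equivalents).
#' @param serum_background_area Total serum background area (AU min) at the
#'   standard 20% serum load.
#' @param unspecific_area Area (AU min) of the constant unspecific serum
#'   peak present in study samples.
#' @param spr_kon,spr_kd_nM,spr_rmax SPR truth: association rate (1/(M s)),
#'   dissociation constant (nM; `koff = kon * kd`), saturating response (RU).
#' @param chromatogram_noise_sd,sensorgram_noise_sd,densitometry_cv,titration_cv,lba_cv
#'   Noise levels, all >= 0.
#' @param large_complex_detection Detection-efficiency multiplier in `(0, 1]`
#'   on the large-complex class (steric hindrance of the Fab epitope in big
#'   complexes); default 1 (no hindrance).
#' @param calibration Retention calibration used for rendering.
#' @param scenario Free-text scenario label.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             kd_nM = 22.5,
                             fab_titration_nM = 678,
                             fab_kd_fit_nM = 585,
                             free_dye_nM = 30,
                             serum_background_area = 220,
                             unspecific_area = 15,
                             spr_kon = 1e5,
                             spr_kd_nM = 18.2,
                             spr_rmax = 37,
                             chromatogram_noise_sd = 0.05,
                             sensorgram_noise_sd = 0.5,
                             densitometry_cv = 0.05,
                             titration_cv = 0.02,
                             lba_cv = 0.05,
                             large_complex_detection = 1,
                             calibration = default_calibration(),
                             scenario = "default") {
  noise <- c(chromatogram_noise_sd, sensorgram_noise_sd, densitometry_cv,
             titration_cv, lba_cv)
  if (any(noise < 0)) stop("noise levels must be >= 0", call. = FALSE)
  if (large_complex_detection <= 0 || large_complex_detection > 1)
    stop("large_complex_detection must be in (0, 1]", call. = FALSE)
  .check_calibration(calibration)
  structure(list(seed = as.integer(seed), kd_nM = kd_nM,
                 fab_titration_nM = fab_titration_nM,
                 fab_kd_fit_nM = fab_kd_fit_nM,
                 free_dye_nM = free_dye_nM,
                 serum_background_area = serum_background_area,
                 unspecific_area = unspecific_area,
                 spr_kon = spr_kon, spr_kd_nM = spr_kd_nM,
                 spr_rmax = spr_rmax,
                 chromatogram_noise_sd = chromatogram_noise_sd,
                 sensorgram_noise_sd = sensorgram_noise_sd,
                 densitometry_cv = densitometry_cv,
                 titration_cv = titration_cv, lba_cv = lba_cv,
                 large_complex_detection = large_complex_detection,
                 calibration = calibration, scenario = scenario),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "generator config '%s' (seed %d): K_D %.3g nM, SPR K_D %.3g nM\n",
    x$scenario, x$seed, x$kd_nM, x$spr_kd_nM))
  invisible(x)
}

# Distinct RNG substream per generator, derived from the config seed and
# kept below 2^31.
.sub_seed <- function(config, k) {
  (config$seed * 7L + k * 1009L) %% .Machine$integer.max
}

#' Synthetic drug titration with chromatograms (LOD design)
#'
#' Emulates the detection-limit titration: drug at a ladder of in-assay
#' concentrations with the detection Fab in large excess, in 20% serum. At
#' each level the drug sites are partitioned into free and Fab-bound via the
#' exact equilibrium at the configured true K_D, and the sample is rendered
#' as a chromatogram (free dye, free Fab, drug-Fab complex, serum
#' background). A drug-free blank accompanies the series.
#'
#' @param config A [generator_config()].
#' @param conc_nM Drug concentration ladder (nM, ascending).
#' @return List with `samples` (list of `conc_nM` + `chromatogram`), `blank`
#'   (chromatogram), and `truth` (data frame of pre-noise per-level species
#'   concentrations).
#' @export
gen_titration <- function(config = generator_config(),
                          conc_nM = c(1, 2.5, 5, 10, 25, 62, 155, 390,
                                      830, 1600, 2500)) {
  stopifnot(inherits(config, "generator_config"))
  a <- config$fab_titration_nM
  withr::with_seed(.sub_seed(config, 1L), {
    truth <- data.frame(conc_nM = conc_nM,
                        sites_nM = effective_site_concentration(conc_nM, 2L))
    truth$bound_fab_nM <- solve_bound_complex(a, truth$sites_nM, config$kd_nM)
    truth$free_fab_nM <- a - truth$bound_fab_nM
    samples <- lapply(seq_along(conc_nM), function(i) {
      sp <- rbind(
        data.frame(species_class = "FREE_DYE", conc_nM = config$free_dye_nM,
                   n_fab = 1),
        data.frame(species_class = "FAB488", conc_nM = truth$free_fab_nM[i],
                   n_fab = 1),
        data.frame(species_class = "DRUG_FAB",
                   conc_nM = truth$bound_fab_nM[i] / 2, n_fab = 2))
      list(conc_nM = conc_nM[i],
           chromatogram = render_chromatogram(
             sp, config$calibration,
             noise_sd = config$chromatogram_noise_sd,
             background_area = config$serum_background_area,
             label = sprintf("drug_%gnM", conc_nM[i])))
    })
    blank_sp <- rbind(
      data.frame(species_class = "FREE_DYE", conc_nM = config$free_dye_nM,
                 n_fab = 1),
      data.frame(species_class = "FAB488", conc_nM = a, n_fab = 1))
    blank <- render_chromatogram(
      blank_sp, config$calibration,
      noise_sd = config$chromatogram_noise_sd,
      background_area = config$serum_background_area, label = "blank")
    list(samples = samples, blank = blank, truth = truth)
  })
}

#' Synthetic percent-bound points for the K_D titration design
#'
#' 22 log-spaced, site-doubled drug concentrations spanning the affinity
#' design (drug 0.32-20560.8 nM before site doubling) at the K_D-fit Fab
#' concentration. The response is the percent of total fluorescence in the
#' complex, `100 * [AB]/a`, with multiplicative Gaussian noise of relative
#' size `titration_cv`.
#'
#' @param config A [generator_config()].
#' @param n_points Number of titration points.
#' @param drug_range_nM Drug concentration range before site doubling (nM).
#' @return Data frame with `x_total_nM`, `percent_bound`, and attribute
#'   `truth` (list: `kd_nM`, `f_min`, `f_max`, `a_total_nM`, the noiseless
#'   `percent_true`).
#' @export
gen_kd_points <- function(config = generator_config(), n_points = 22,
                          drug_range_nM = c(0.32, 20560.8)) {
  stopifnot(inherits(config, "generator_config"))
  a <- config$fab_kd_fit_nM
  x <- effective_site_concentration(
    exp(seq(log(drug_range_nM[1]), log(drug_range_nM[2]),
            length.out = n_points)), 2L)
  y_true <- 100 * solve_bound_complex(a, x, config$kd_nM) / a
  y <- withr::with_seed(.sub_seed(config, 2L),
    y_true * (1 + rnorm(length(x), 0, config$titration_cv)))
  structure(data.frame(x_total_nM = x, percent_bound = y),
            truth = list(kd_nM = config$kd_nM, f_min = 0, f_max = 100,
                         a_total_nM = a, percent_true = y_true))
}

#' Synthetic SPR sensorgram series
#'
#' Twofold analyte dilution series (0.49 nM doubling up, topped by
#' 2000 nM) through the exact 1:1 Langmuir forward model at the configured
#' kinetic truth, 5 minutes association and 10 minutes dissociation, with
#' additive Gaussian RU noise.
#'
#' @param config A [generator_config()].
#' @param conc_nM Analyte concentration series (nM).
#' @param t_assoc,t_dissoc,dt Phase durations and sampling interval (s).
#' @return List of `sensorgram` objects with attribute `truth`
#'   (the generating [kinetic_params()]).
#' @export
gen_sensorgrams <- function(config = generator_config(),
                            conc_nM = c(0.49 * 2^(0:10), 2000),
                            t_assoc = 300, t_dissoc = 600, dt = 1) {
  stopifnot(inherits(config, "generator_config"))
  params <- kinetic_params(kon = config$spr_kon,
                           koff = config$spr_kon * config$spr_kd_nM * 1e-9,
                           rmax = config$spr_rmax)
  out <- withr::with_seed(.sub_seed(config, 4L),
    lapply(conc_nM, function(cc)
      simulate_sensorgram(params, cc, t_assoc, t_dissoc, dt,
                          noise_sd = config$sensorgram_noise_sd)))
  structure(out, truth = params)
}

# Scenario rule for partitioning drug across complex size classes as a
# function of the ADA:drug molar ratio r. Not a measured mechanism: a
# minimal documented scenario producing the qualitative titration pattern
# (complexed fraction saturating fast, mass shifting into large unresolved
# complexes with ADA excess, precipitation of the largest species).
.ada_partition <- function(r, r_max) {
  if (r <= 0)
    return(list(f_complex = 0, f_large = 0, p_drug = 0, p_ada = 0,
                p_fab = 0))
  f_complex <- 1 - exp(-4 * r)
  f_large <- f_complex * (1 - exp(-r / 1.2))
  s <- (r / r_max)^1.5
  list(f_complex = f_complex, f_large = f_large,
       p_drug = 0.40 * s, p_ada = 0.20 * s, p_fab = 0.20 * s)
}

#' Synthetic ADA titration with chromatograms and pellet densitometry
#'
#' Emulates the complex-formation titration: fixed drug (830 nM) and
#' detection Fab (678 nM) with increasing ADA. Drug partitions across size
#' classes by a documented scenario rule (see Details); a precipitation rule
#' removes a growing share of the large-complex class so that at the highest
#' ADA level the pellet holds 40% of drug, 20% of ADA and 20% of Fab.
#' Precipitated material is excluded from the chromatogram and routed into
#' the accompanying densitometry tables.
#'
#' Details: with `r` the ADA:drug molar ratio, the complexed drug fraction
#' is `1 - exp(-4 r)` (rabbit polyclonal ADA binds the drug much tighter
#' than the detection Fab); of the complexed drug, a share `1 - exp(-r/1.2)`
#' sits in the large unresolved class, the remainder split evenly between
#' the 1:1 and 1:2 ADA:drug classes; the pellet fractions grow as
#' `(r/r_max)^1.5` scaled to the 40/20/20% endpoint. Fab occupancy per drug
#' follows the Fab equilibrium (Fab is sub-stoichiometric at 830 nM drug);
#' the pellet carries proportionally less Fab than drug, reflecting hindered
#' Fab binding in precipitating complexes.
#'
#' @param config A [generator_config()].
#' @param ada_conc_nM ADA concentrations (nM), ascending, including 0.
#' @param drug_nM Total drug concentration (nM).
#' @return List with `samples` (list of `ada_conc_nM` + `chromatogram`),
#'   `pellets` (named list of [pellet_quant()] per ADA level), and `truth`
#'   (per-level data frame: class drug fractions, pellet fractions, soluble
#'   and pellet drug in nM).
#' @export
gen_ada_series <- function(config = generator_config(),
                           ada_conc_nM = c(0, 750, 1500, 2000, 3500),
                           drug_nM = 830) {
  stopifnot(inherits(config, "generator_config"))
  a <- config$fab_titration_nM
  sites <- effective_site_concentration(drug_nM, 2L)
  bound_fab <- solve_bound_complex(a, sites, config$kd_nM)
  free_fab <- a - bound_fab
  r_max <- max(ada_conc_nM) / drug_nM

  withr::with_seed(.sub_seed(config, 3L), {
    truth <- NULL
    samples <- vector("list", length(ada_conc_nM))
    pellets <- vector("list", length(ada_conc_nM))
    for (i in seq_along(ada_conc_nM)) {
      ada <- ada_conc_nM[i]
      part <- .ada_partition(ada / drug_nM, r_max)
      f_small <- part$f_complex - part$f_large
      # drug fractions per class; precipitation drawn from the large class
      fr <- c(DRUG_FAB = 1 - part$f_complex,
              ADA1_DRUG1 = f_small / 2,
              ADA1_DRUG2 = f_small / 2,
              LARGE_COMPLEX = part$f_large - part$p_drug)
      stopifnot(all(fr > -1e-12))
      fr <- pmax(fr, 0)
      # fluorescence weights: drug-bound Fab distributes with the drug;
      # Fab lost to the pellet comes out of the large-complex window
      wts <- c(fr[c("DRUG_FAB", "ADA1_DRUG1", "ADA1_DRUG2")] * bound_fab,
               LARGE_COMPLEX = max(
                 (part$f_large * bound_fab - part$p_fab * a) *
                   config$large_complex_detection, 0))
      sp <- rbind(
        data.frame(species_class = "FREE_DYE", conc_nM = config$free_dye_nM,
                   n_fab = 1),
        data.frame(species_class = "FAB488", conc_nM = free_fab, n_fab = 1),
        data.frame(species_class = names(wts), conc_nM = unname(wts),
                   n_fab = 1))
      samples[[i]] <- list(
        ada_conc_nM = ada,
        chromatogram = render_chromatogram(
          sp, config$calibration,
          noise_sd = config$chromatogram_noise_sd,
          background_area = config$serum_background_area,
          label = sprintf("ada_%gnM", ada)))

      amounts <- c(huDVD = drug_nM, ADA = ada, Fab488 = a)
      pfrac <- c(huDVD = part$p_drug, ADA = part$p_ada, Fab488 = part$p_fab)
      keep <- amounts > 0
      ncv <- function(n) 1 + rnorm(n, 0, config$densitometry_cv)
      p_lane <- (pfrac + 0.2 * (1 - pfrac)) * amounts * ncv(3)
      s_lane <- 0.8 * (1 - pfrac) * amounts * ncv(3)
      pellets[[i]] <- pellet_quant(pmax(p_lane[keep], 0),
                                   pmax(s_lane[keep], 0))

      truth <- rbind(truth, data.frame(
        ada_conc_nM = ada, f_drug_fab = unname(fr["DRUG_FAB"]),
        f_ada1_drug1 = unname(fr["ADA1_DRUG1"]),
        f_ada1_drug2 = unname(fr["ADA1_DRUG2"]),
        f_large_soluble = unname(fr["LARGE_COMPLEX"]),
        p_drug = part$p_drug, p_ada = part$p_ada, p_fab = part$p_fab,
        soluble_drug_nM = sum(fr) * drug_nM,
        pellet_drug_nM = part$p_drug * drug_nM))
    }
    names(pellets) <- paste0("ada_", ada_conc_nM, "nM")
    list(samples = samples, pellets = pellets, truth = truth)
  })
}

# per-dose free-drug serum concentrations (ug/mL) and complex loads
# (in-assay nM) for the study scenario
.study_design <- function() {
  offs <- timecourse_offsets()
  free1 <- c(0, 400, 350, 250, 180, 110, 60)
  free_late <- c(0, 5, 3, 0.05, 0.05, 0.05, 0.05)
  cx <- function(a11, a21, lg) c(ADA1_DRUG1 = a11, ADA1_DRUG2 = a21,
                                 LARGE_COMPLEX = lg)
  zero <- cx(0, 0, 0)
  list(
    `1` = list(free = setNames(free1, offs),
               complexes = setNames(rep(list(zero), 7), offs)),
    `6` = list(free = setNames(free_late, offs),
               complexes = setNames(list(zero, cx(40, 30, 0), cx(20, 15, 0),
                                         zero, zero, zero, zero), offs)),
    `13` = list(free = setNames(free_late, offs),
                complexes = setNames(list(zero, cx(35, 30, 25),
                                          cx(18, 15, 20),
                                          zero, zero, zero, zero), offs)))
}

#' Synthetic multi-dose study timecourse
#'
#' Emulates serum samples from a repeat-dose study with ADA-mediated
#' clearance: after the first dose only free drug circulates, maximal at
#' 15 minutes and declining monotonically to 168 h; after doses 6 and 13
#' (high ADA titres) free drug is cleared quickly and ADA complexes appear
#' transiently at 15 minutes and 4 hours, with a larger large-complex share
#' after dose 13. Every sample carries the constant unspecific serum peak.
#' Ligand-binding-assay values track free drug with multiplicative noise and
#' are floored at the 0.136 ug/mL lower limit of quantitation (carried as a
#' below-quantitation flag); western intensities track total drug.
#'
#' In-assay drug nM and serum ug/mL are numerically equal for a 200 kDa drug
#' at the 1:5 serum dilution, which keeps the two bookkeeping scales easy to
#' cross-check.
#'
#' @param config A [generator_config()].
#' @return List with `points` (list of [timecourse_point()]) and `truth`
#'   (per-sample data frame of free/complex drug and assay values, pre-noise).
#' @export
gen_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  design <- .study_design()
  a <- config$fab_titration_nM
  masses <- default_masses()
  withr::with_seed(.sub_seed(config, 5L), {
    points <- list()
    truth <- NULL
    for (dose in names(design)) {
      d <- design[[dose]]
      for (off in timecourse_offsets()) {
        free_serum <- d$free[[off]]
        cxs <- d$complexes[[off]]
        free_assay_nM <- mass_to_molar(free_serum / 5, masses[["huDVD"]])
        cx_drug_nM <- sum(c(1, 2, 3) * cxs)
        cx_fab_nM <- sum(2 * c(1, 2, 3) * cxs)
        fab_avail <- a - cx_fab_nM
        stopifnot(fab_avail > 0)
        sites <- effective_site_concentration(free_assay_nM, 2L)
        bound <- solve_bound_complex(fab_avail, sites, config$kd_nM)
        sp <- rbind(
          data.frame(species_class = "FREE_DYE",
                     conc_nM = config$free_dye_nM, n_fab = 1),
          data.frame(species_class = "FAB488", conc_nM = fab_avail - bound,
                     n_fab = 1),
          data.frame(species_class = "UNSPECIFIC",
                     conc_nM = config$unspecific_area, n_fab = 1),
          data.frame(species_class = "DRUG_FAB", conc_nM = bound / 2,
                     n_fab = 2),
          data.frame(species_class = names(cxs), conc_nM = unname(cxs),
                     n_fab = 2 * c(1, 2, 3)))
        chrom <- render_chromatogram(
          sp, config$calibration,
          noise_sd = config$chromatogram_noise_sd,
          background_area = config$serum_background_area,
          label = sprintf("dose%s_%s", dose, gsub(" ", "", off)))
        lba <- free_serum * (1 + rnorm(1, 0, config$lba_cv))
        bql <- lba < 0.136
        total_drug_serum <- free_serum +
          molar_to_mass(cx_drug_nM, masses[["huDVD"]]) * 5
        western <- total_drug_serum * (1 + rnorm(1, 0, config$lba_cv))
        points[[length(points) + 1]] <- timecourse_point(
          dose_index = as.integer(dose), time_offset = off,
          chromatogram = chrom,
          lba_conc = if (bql) NA_real_ else lba, lba_bql = bql,
          western_intensity = max(western, 0))
        truth <- rbind(truth, data.frame(
          dose_index = as.integer(dose), time_offset = off,
          free_serum_ug_ml = free_serum, free_assay_nM = free_assay_nM,
          complex_drug_assay_nM = cx_drug_nM,
          total_drug_serum_ug_ml = total_drug_serum))
      }
    }
    list(points = points, truth = truth)
  })
}
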
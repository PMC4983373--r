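test_that("rendering conserves fluorescence-weighted area", {
  sp <- data.frame(
    species_class = c("FREE_DYE", "FAB488", "DRUG_FAB", "ADA1_DRUG2"),
    conc_nM = c(30, 600, 40, 10),
    n_fab = c(1, 1, 2, 4))
  chrom <- render_chromatogram(sp)
  total <- pracma::trapz(chrom$time_min, chrom$signal)
  weights <- c(30, 600, 40 * 2, 10 * 4)
  expect_equal(total, sum(weights), tolerance = 1e-6)
})

test_that("equal fluorescence weights give equal peak areas", {
  cal <- default_calibration()
  sp <- data.frame(species_class = c("DRUG_FAB", "ADA1_DRUG1"),
                   conc_nM = c(5, 10), n_fab = c(2, 1))
  chrom <- render_chromatogram(sp)
  a1 <- integrate_window(chrom, cal[cal$species == "DRUG_FAB", ])$area
  a2 <- integrate_window(chrom, cal[cal$species == "ADA1_DRUG1", ])$area
  expect_equal(a1, a2, tolerance = 1e-9)

  # Fab-count weighting: a 4-Fab complex at 1 nM equals a 2-Fab one at 2 nM
  sp2 <- data.frame(species_class = c("ADA1_DRUG2", "DRUG_FAB"),
                    conc_nM = c(1, 2), n_fab = c(4, 2))
  ch2 <- render_chromatogram(sp2)
  b1 <- integrate_window(ch2, cal[cal$species == "ADA1_DRUG2", ])$area
  b2 <- integrate_window(ch2, cal[cal$species == "DRUG_FAB", ])$area
  expect_equal(b1, b2, tolerance = 1e-6)
})

test_that("rendering rejects uncalibrated species and bad noise", {
  sp <- data.frame(species_class = "MYSTERY", conc_nM = 1, n_fab = 1)
  expect_error(render_chromatogram(sp), "uncalibrated")
  ok <- data.frame(species_class = "FAB488", conc_nM = 1, n_fab = 1)
  expect_error(render_chromatogram(ok, noise_sd = -0.1), ">= 0")
})

test_that("window integration recovers analytic areas", {
  t <- seq(8, 21, by = 0.01)
  flat <- chromatogram(t, rep(0, length(t)))
  w <- list(species = "DRUG_FAB", t_start_min = 14.5, t_end_min = 15.5)
  expect_equal(integrate_window(flat, w)$area, 0)

  g <- gaussian_trace(center = 15, sigma = 0.1)
  q <- integrate_window(g, list(species = "x", t_start_min = 14,
                                t_end_min = 16))
  expect_equal(q$area, 1, tolerance = 1e-3)

  whole <- integrate_window(g, list(species = "all", t_start_min = 8,
                                    t_end_min = 21))
  expect_equal(whole$percent_of_total, 1)

  expect_error(integrate_window(g, list(species = "x", t_start_min = 5,
                                        t_end_min = 9)), "outside")
  expect_error(integrate_window(g, list(species = "x", t_start_min = 15,
                                        t_end_min = 14)), "t_start")
})

test_that("signal-to-noise is a ratio of area percentages", {
  w <- list(species = "DRUG_FAB", t_start_min = 14.5, t_end_min = 15.5)
  sample <- gaussian_trace(15, 0.2, area = 3) # plus a reference peak below
  ref <- gaussian_trace(18, 0.2, area = 97)
  sample$signal <- sample$signal + ref$signal
  blank <- gaussian_trace(15, 0.2, area = 1.5)
  blank$signal <- blank$signal + gaussian_trace(18, 0.2, area = 98.5)$signal

  expect_equal(snr(sample, sample, w), 1)
  expect_equal(snr(sample, blank, w), 2, tolerance = 1e-3)

  # scale invariance
  s10 <- chromatogram(sample$time_min, sample$signal * 10)
  b03 <- chromatogram(blank$time_min, blank$signal * 0.3)
  expect_equal(snr(s10, b03, w), snr(sample, blank, w), tolerance = 1e-12)

  empty <- chromatogram(blank$time_min, rep(0, length(blank$time_min)))
  expect_warning(r <- snr(sample, empty, w), "zero")
  expect_identical(r, Inf)
})

test_that("LOD search returns the first S/N threshold crossing", {
  w <- list(species = "DRUG_FAB", t_start_min = 14.5, t_end_min = 15.5)
  mk <- function(area_in_window) {
    ch <- gaussian_trace(15, 0.2, area = area_in_window)
    ch$signal <- ch$signal + gaussian_trace(18, 0.2, area = 100)$signal +
      gaussian_trace(15, 0.2, area = 2)$signal
    ch
  }
  blank <- mk(0)
  # window areas tuned to S/N approx (1.1, 1.6, 4.0) at (5, 10, 50) nM
  titr <- list(list(conc_nM = 5, chromatogram = mk(0.2)),
               list(conc_nM = 10, chromatogram = mk(1.25)),
               list(conc_nM = 50, chromatogram = mk(6.5)))
  lod <- detect_lod(titr, blank, w, threshold = 1.5)
  expect_equal(as.numeric(lod), 10)
  rat <- attr(lod, "snr")
  expect_lt(rat[["5"]], 1.5)
  expect_gte(rat[["10"]], 1.5)

  none <- titr[1]
  none[[2]] <- list(conc_nM = 7, chromatogram = mk(0.1))
  expect_message(miss <- detect_lod(none, blank, w), "no concentration")
  expect_true(is.na(miss))
  expect_true(attr(miss, "not_detected"))

  unsorted <- rev(titr)
  expect_error(detect_lod(unsorted, blank, w), "ascending")
})

test_that("percent complex sums the ADA-containing windows", {
  cal <- default_calibration()
  no_ada <- render_chromatogram(
    data.frame(species_class = c("FAB488", "DRUG_FAB"),
               conc_nM = c(600, 30), n_fab = c(1, 2)))
  expect_equal(percent_complex(no_ada, cal), 0, tolerance = 1e-6)

  all_large <- render_chromatogram(
    data.frame(species_class = "LARGE_COMPLEX", conc_nM = 10, n_fab = 6))
  expect_equal(percent_complex(all_large, cal), 1, tolerance = 1e-3)

  # 30% of Fab-weighted signal in ADA classes
  mix <- data.frame(
    species_class = c("FAB488", "DRUG_FAB", "ADA1_DRUG1", "LARGE_COMPLEX"),
    conc_nM = c(40, 15, 10, 5), n_fab = c(1, 2, 2, 2))
  chrom <- render_chromatogram(mix, noise_sd = 0.05, seed = 99)
  expect_equal(percent_complex(chrom, cal), 0.30, tolerance = 0.02)

  t <- seq(8, 21, by = 0.01)
  expect_error(percent_complex(chromatogram(t, rep(0, length(t))), cal),
               "zero total")
})

test_that("render then quantify recovers relative abundances", {
  cal <- default_calibration()
  sp <- data.frame(
    species_class = c("FREE_DYE", "FAB488", "DRUG_FAB", "ADA1_DRUG1",
                      "ADA1_DRUG2", "LARGE_COMPLEX"),
    conc_nM = c(30, 500, 40, 15, 10, 8),
    n_fab = c(1, 1, 2, 2, 4, 6))
  weights <- ifelse(sp$species_class %in% c("FREE_DYE", "UNSPECIFIC"),
                    sp$conc_nM, sp$conc_nM * sp$n_fab)
  target <- weights / sum(weights)
  for (seed in 1:5) {
    chrom <- render_chromatogram(sp, noise_sd = 0.05, seed = seed)
    qw <- quantify_windows(chrom, cal)
    got <- qw$percent_of_total[match(sp$species_class, qw$species)]
    expect_equal(got, target, tolerance = 0.02)
  }
})

test_that("chromatograms and calibrations round-trip through disk", {
  chrom <- render_chromatogram(
    data.frame(species_class = "FAB488", conc_nM = 10, n_fab = 1),
    noise_sd = 0.02, seed = 4, label = "rt")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram_csv(chrom, csv)
  back <- read_chromatogram_csv(csv, label = "rt")
  expect_equal(back$signal, chrom$signal, tolerance = 1e-9)
  expect_equal(back$time_min, chrom$time_min, tolerance = 1e-9)

  cal <- default_calibration()
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_calibration_yaml(cal, yml)
  cal2 <- read_calibration_yaml(yml)
  expect_equal(cal2$species, cal$species)
  expect_equal(cal2$t_start_min, cal$t_start_min, tolerance = 1e-9)

  bad <- cal
  bad$t_end_min[1] <- bad$t_start_min[2] + 0.5 # overlap
  expect_error(write_calibration_yaml(bad, yml), "overlap")
})
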
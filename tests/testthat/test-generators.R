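test_that("identical seeds reproduce every generator bit for bit", {
  cfg <- generator_config(seed = 123)
  t1 <- gen_titration(cfg)
  t2 <- gen_titration(generator_config(seed = 123))
  expect_identical(t1$samples[[3]]$chromatogram$signal,
                   t2$samples[[3]]$chromatogram$signal)
  expect_identical(t1$blank$signal, t2$blank$signal)

  expect_identical(gen_kd_points(cfg), gen_kd_points(cfg))
  s1 <- gen_sensorgrams(cfg)
  s2 <- gen_sensorgrams(cfg)
  expect_identical(s1[[5]]$response_RU, s2[[5]]$response_RU)
  a1 <- gen_ada_series(cfg)
  a2 <- gen_ada_series(cfg)
  expect_identical(a1$samples[[4]]$chromatogram$signal,
                   a2$samples[[4]]$chromatogram$signal)
  expect_identical(a1$pellets, a2$pellets)
  g1 <- gen_study(cfg)
  g2 <- gen_study(cfg)
  expect_identical(g1$points[[9]]$chromatogram$signal,
                   g2$points[[9]]$chromatogram$signal)
  expect_identical(g1$truth, g2$truth)

  # a different seed changes the noise
  t3 <- gen_titration(generator_config(seed = 124))
  expect_false(identical(t1$blank$signal, t3$blank$signal))
})

test_that("titration partitions drug by the exact equilibrium", {
  # background-free render: this test is about the equilibrium bookkeeping
  cfg <- quiet_config(seed = 1, serum_background_area = 0)
  tit <- gen_titration(cfg)
  with(tit$truth, {
    expect_equal(bound_fab_nM,
                 solve_bound_complex(678, sites_nM, 22.5),
                 tolerance = 1e-6)
    expect_equal(bound_fab_nM + free_fab_nM, rep(678, length(conc_nM)))
  })
  # zero drug reproduces the blank exactly when noiseless
  z <- gen_titration(cfg, conc_nM = c(0, 10))
  expect_equal(z$samples[[1]]$chromatogram$signal, z$blank$signal,
               tolerance = 1e-12)
  # at 2500 nM drug the Fab is saturated: free-Fab peak below 1% of trace
  cal <- default_calibration()
  top <- tit$samples[[length(tit$samples)]]
  expect_equal(top$conc_nM, 2500)
  q <- integrate_window(top$chromatogram, cal[cal$species == "FAB488", ])
  expect_lt(q$percent_of_total, 0.01)
})

test_that("kd titration points sample the stated design", {
  cfg <- quiet_config(seed = 1)
  pts <- gen_kd_points(cfg)
  expect_equal(nrow(pts), 22)
  expect_equal(range(pts$x_total_nM), c(0.64, 41121.6), tolerance = 1e-9)
  truth <- attr(pts, "truth")
  expect_equal(pts$percent_bound, truth$percent_true, tolerance = 1e-12)
  expect_equal(truth$a_total_nM, 585)
  # noisy replicates stay centred on the model (CLT bound at 3 sd)
  reps <- sapply(1:200, function(i)
    gen_kd_points(generator_config(seed = 5000L + i))$percent_bound)
  band <- 3 * 0.02 * truth$percent_true / sqrt(200)
  expect_true(all(abs(rowMeans(reps) - truth$percent_true) <= band + 1e-9))
})

test_that("sensorgram series obeys the equilibrium relation", {
  sg <- gen_sensorgrams(quiet_config(seed = 2))
  truth <- attr(sg, "truth")
  expect_equal(kd_nM(truth), 18.2)
  concs <- vapply(sg, function(s) attr(s, "conc_nM"), numeric(1))
  expect_equal(length(concs), 12)
  expect_equal(max(concs), 2000)
  plateau_top <- {
    s <- sg[[which.max(concs)]]
    s$response_RU[s$time_s == 300]
  }
  expect_lt(abs(plateau_top - 37 * 2000 / (2000 + 18.2)), 0.1)
  expect_lt(37 - plateau_top, 1)  # near rmax at the top concentration
})

test_that("ADA series conserves drug and hits the pellet scenario", {
  cfg <- quiet_config(seed = 3)
  ada <- gen_ada_series(cfg)
  # soluble + pellet drug equals the input at every ADA level
  expect_equal(ada$truth$soluble_drug_nM + ada$truth$pellet_drug_nM,
               rep(830, nrow(ada$truth)), tolerance = 1e-9)
  # scenario endpoint: 40/20/20% of drug/ADA/Fab in the pellet at 3.5 uM
  top <- ada$truth[ada$truth$ada_conc_nM == 3500, ]
  expect_equal(top$p_drug, 0.40, tolerance = 1e-12)
  expect_equal(top$p_ada, 0.20, tolerance = 1e-12)
  expect_equal(top$p_fab, 0.20, tolerance = 1e-12)
  # noiseless densitometry inverts exactly to the scenario truth
  inv <- pellet_mass_balance(ada$pellets[["ada_3500nM"]])
  expect_equal(unname(inv["huDVD"]), 0.40, tolerance = 1e-9)
  expect_equal(unname(inv["ADA"]), 0.20, tolerance = 1e-9)
  # without ADA only free dye, free Fab and the drug-Fab complex elute
  cal <- default_calibration()
  cfg0 <- quiet_config(seed = 3, serum_background_area = 0)
  ada0 <- gen_ada_series(cfg0)
  first <- ada0$samples[[1]]
  expect_equal(first$ada_conc_nM, 0)
  expect_lt(percent_complex(first$chromatogram, cal), 1e-6)
  q <- quantify_windows(first$chromatogram, cal)
  expect_gt(q$area[q$species == "DRUG_FAB"], 0)
})

test_that("study scenario encodes dosing, clearance and concordance", {
  cfg <- generator_config(seed = 11)
  st <- gen_study(cfg)
  expect_equal(length(st$points), 21)
  tr <- st$truth
  # predose samples contain no drug species
  pre <- tr[tr$time_offset == "pre", ]
  expect_true(all(pre$free_serum_ug_ml == 0))
  expect_true(all(pre$complex_drug_assay_nM == 0))
  # dose 1: free drug maximal at 15 min, monotone decay afterwards
  d1 <- tr[tr$dose_index == 1 & tr$time_offset != "pre", ]
  expect_true(all(diff(d1$free_serum_ug_ml) < 0))
  # dose 6: complexes exactly at 15 min and 4 h
  d6 <- tr[tr$dose_index == 6, ]
  expect_true(all((d6$complex_drug_assay_nM > 0) ==
                    (d6$time_offset %in% c("15 min", "4 h"))))
  # dose 13 carries a larger large-complex share than dose 6
  ta <- timecourse_analysis(st$points)
  p13 <- ta$peaks[ta$peaks$dose_index == 13 &
                    ta$peaks$class == "LARGE_COMPLEX", ]
  p6 <- ta$peaks[ta$peaks$dose_index == 6 &
                   ta$peaks$class == "LARGE_COMPLEX", ]
  expect_gt(p13$peak_pct, p6$peak_pct)
  # LBA below-quantitation values are flagged and floored
  bql <- vapply(st$points, function(p) p$lba_bql, logical(1))
  expect_true(any(bql))
  expect_true(all(vapply(st$points[bql], function(p) p$lba_conc == 0.136,
                         logical(1))))
  # LBA/SEC concordance holds on the default scenario
  expect_equal(concordance_check(st$points)$n_discordant, 0)
})

test_that("dose-6 complex signal vanishes at late time points", {
  cfg <- generator_config(seed = 21)
  st <- gen_study(cfg)
  ta <- timecourse_analysis(st$points)
  tab <- ta$table
  cx <- tab$pct_ADA1_DRUG1 + tab$pct_ADA1_DRUG2
  d6 <- tab$dose_index == 6
  base <- cx[d6 & tab$time_offset == "pre"]
  late <- cx[d6 & tab$time_offset %in% c("24 h", "96 h", "168 h")]
  early <- cx[d6 & tab$time_offset %in% c("15 min", "4 h")]
  # late samples fall back to the predose background level
  expect_true(all(abs(late - base) < 0.02))
  expect_true(all(early > 1.5 * base))
})
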
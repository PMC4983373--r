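test_that("bound-complex solution matches the worked equilibrium", {
  # oracle-checked by bisection in helper: bisect_bound(678, 20, 22.5)
  expect_equal(solve_bound_complex(678, 20, 22.5), 19.33936,
               tolerance = 1e-6)
  expect_equal(fraction_bound(678, 20, 22.5), 0.9669681, tolerance = 1e-6)
  # degenerate limits
  expect_equal(solve_bound_complex(678, 0, 22.5), 0)
  expect_equal(solve_bound_complex(678, 20, 0), 20)
  expect_equal(solve_bound_complex(0, 0, 0), 0)
})

test_that("closed form agrees with bisection root-finding across the domain", {
  set.seed(42)
  a <- runif(1000, 0, 1e4)
  x <- runif(1000, 0, 1e4)
  kd <- runif(1000, 0, 1e4)
  ab <- solve_bound_complex(a, x, kd)
  oracle <- mapply(bisect_bound, a, x, kd)
  expect_lt(max(abs(ab - oracle) / pmax(oracle, 1e-12)), 1e-9)
})

test_that("mass conservation and symmetry hold for random systems", {
  set.seed(7)
  a <- runif(300, 0, 1e4)
  x <- runif(300, 0, 1e4)
  kd <- runif(300, 0, 1e4)
  ab <- solve_bound_complex(a, x, kd)
  expect_true(all(a - ab >= -1e-9))
  expect_true(all(x - ab >= -1e-9))
  expect_true(all(ab >= 0))
  expect_equal(ab, solve_bound_complex(x, a, kd), tolerance = 1e-12)
})

test_that("fraction bound approaches the trace-ligand hyperbola", {
  expect_equal(fraction_bound(678, 1e-6, 22.5), 678 / 700.5,
               tolerance = 1e-6)
  set.seed(11)
  a <- runif(50, 100, 5000)
  kd <- runif(50, 1, 100)
  x <- a / runif(50, 100, 1000)   # a >= 100 * x
  err <- abs(fraction_bound(a, x, kd) - a / (a + kd))
  expect_true(all(err < 0.01))
  # saturation at large Fab excess
  expect_equal(fraction_bound(1e9, 20, 22.5), 1, tolerance = 1e-6)
  # monotone in a_total
  fr <- fraction_bound(c(10, 100, 1000, 1e4), 20, 22.5)
  expect_true(all(diff(fr) > 0))
})

test_that("binding inputs are validated", {
  expect_error(solve_bound_complex(-1, 20, 22.5), ">= 0")
  expect_error(fraction_bound(678, 0, 22.5), "undefined")
  expect_error(signal_model(20, binding_curve_params(0, 100, 22.5), 0),
               "a_total > 0")
  expect_error(binding_curve_params(10, 5, 22.5), "f_max")
})

test_that("signal model reproduces its limiting cases", {
  p <- binding_curve_params(3, 100, 22.5)
  expect_equal(signal_model(0, p, 678), 3)
  p0 <- binding_curve_params(0, 100, 22.5)
  expect_equal(signal_model(20, p0, 678), 100 * 19.33936 / 678,
               tolerance = 1e-6)
  # kd = 0: stoichiometric saturation, Y -> F + (Fmax - F) * min(a, x)/a
  ptight <- binding_curve_params(0, 100, 0)
  expect_equal(signal_model(678, ptight, 678), 100)
  expect_equal(signal_model(339, ptight, 678), 50)
})

test_that("unit conversions follow the assay bookkeeping", {
  expect_identical(mass_to_molar(2, 200000), 10)
  expect_identical(mass_to_molar(500, 200000), 2500)
  expect_identical(mass_to_molar(0, 47150), 0)
  set.seed(3)
  cc <- runif(20, 0.01, 1000)
  mm <- runif(20, 1000, 3e5)
  expect_equal(molar_to_mass(mass_to_molar(cc, mm), mm), cc,
               tolerance = 1e-12)
  expect_identical(assay_to_serum(2, 5), 10)
  expect_identical(assay_to_serum(0.5, 5), 2.5)
  expect_identical(assay_to_serum(7, 1), 7)
  expect_error(assay_to_serum(1, 0.5), ">= 1")
  expect_error(mass_to_molar(2, 0), "> 0")
})

test_that("site-concentration adjustment is explicit multiplication", {
  expect_identical(effective_site_concentration(10, 2L), 20)
  expect_identical(effective_site_concentration(0.32, 2L), 0.64)
  expect_identical(effective_site_concentration(7, 1L), 7)
  expect_error(effective_site_concentration(10, 0L), "positive integer")
  expect_error(effective_site_concentration(10, 1.5), "positive integer")
})

test_that("mass tables read from YAML and JSON override defaults", {
  expect_equal(unname(default_masses()["huDVD"]), 200000)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ADA: 160000", "myProtein: 52000"), yml)
  m <- read_masses(yml)
  expect_equal(unname(m["ADA"]), 160000)
  expect_equal(unname(m["myProtein"]), 52000)
  expect_equal(unname(m["Fab488"]), 47150)
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"free_dye": 1200}', js)
  expect_equal(unname(read_masses(js)["free_dye"]), 1200)
})
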
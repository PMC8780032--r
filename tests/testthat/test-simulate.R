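test_that("band profile: zero case, peak location, linearity", {
  g <- spectral_grid()
  expect_equal(make_band_profile(rep(0, 12), g)$values,
               rep(0, length(wavelengths(g))))

  # unit amplitude on C5 only: maximum at the grid point nearest 948.5 nm
  a <- rep(0, 12); a[5] <- 1
  p <- make_band_profile(a, g)
  peak_wl <- wavelengths(g)[which.max(p$values)]
  expect_lte(abs(peak_wl - 948.5), g$step_nm / 2)

  # profile is the elementwise sum of single-band profiles
  set.seed(8)
  amps <- stats::runif(12)
  total <- make_band_profile(amps, g)$values
  parts <- vapply(1:12, function(b) {
    ab <- rep(0, 12); ab[b] <- amps[b]
    make_band_profile(ab, g)$values
  }, numeric(length(wavelengths(g))))
  expect_equal(total, rowSums(parts), tolerance = 1e-12)
  expect_true(all(total >= 0))

  expect_error(make_band_profile(rep(0.1, 12), c(800, 803, 807)),
               "not uniform")
  expect_error(make_band_profile(c(-0.1, rep(0.1, 11)), g), "non-negative")
})

test_that("reference values: DMC ratio and two-end SSC mean", {
  f <- phantom_fruit("x", 10, 10, wet_weight = 10, dry_weight = 10,
                     band_amplitudes = rep(0.1, 12))
  expect_equal(reference_values(f)$dmc_pct, 100)
  f2 <- phantom_fruit("y", 10, 12, wet_weight = 12.50, dry_weight = 2.05,
                      band_amplitudes = rep(0.1, 12))
  rv <- reference_values(f2)
  expect_equal(rv$ssc, 11)
  expect_equal(rv$dmc_pct, 16.4)
  expect_error(phantom_fruit("z", 10, 10, wet_weight = 0, dry_weight = 0,
                             band_amplitudes = rep(0.1, 12)), "wet_weight")
  expect_error(phantom_fruit("z", 10, 10, wet_weight = 5, dry_weight = 6,
                             band_amplitudes = rep(0.1, 12)), "exceed")
})

test_that("no-effect design makes all configurations identical", {
  d <- tiny_design(effect_matrix = matrix(1, 4, 12),
                   depol_surface_weight = 0)
  f <- toy_fruit(skin = 0)
  specs <- lapply(configurations(), function(cfg) {
    m <- simulate_measurement(f, cfg, d)
    to_absorbance(m$scans[[1]], m$reference)$values
  })
  for (k in 2:4) expect_equal(specs[[k]], specs[[1]], tolerance = 1e-14)
})

test_that("default design orders mean absorbance: peeled > unpeeled, polarized > unpolarized", {
  d <- tiny_design()
  f <- toy_fruit(amps = default_base_amplitudes())
  mean_abs <- vapply(configurations(), function(cfg) {
    m <- simulate_measurement(f, cfg, d)
    mean(to_absorbance(m$scans[[1]], m$reference)$values)
  }, numeric(1))
  expect_gt(mean_abs["UP"], mean_abs["UU"])
  expect_gt(mean_abs["PP"], mean_abs["PU"])
  expect_gt(mean_abs["PU"], mean_abs["UU"])
  expect_gt(mean_abs["PP"], mean_abs["UP"])
})

test_that("same seed gives bit-identical scans; unknown configuration rejected", {
  d <- tiny_design(noise_sd = 0.01)
  f <- toy_fruit()
  m1 <- simulate_measurement(f, "UP", d, seed = 99L)
  m2 <- simulate_measurement(f, "UP", d, seed = 99L)
  expect_identical(lapply(m1$scans, `[[`, "values"),
                   lapply(m2$scans, `[[`, "values"))
  expect_error(simulate_measurement(f, "QQ", d), "unknown configuration")
})

test_that("co-polarized detection conserves the two components", {
  d <- tiny_design(noise_sd = 0)
  f <- toy_fruit()
  for (cfg in c("UP", "PP")) {
    m <- simulate_measurement(f, cfg, d)
    cmp <- m$components
    expect_equal(cmp$detected, cmp$i_parallel + 0.5 * cmp$i_perp,
                 tolerance = 1e-12)
    expect_true(all(cmp$detected >= 0))
  }
  expect_error(copolarized_detection(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("population has the right size, SSC range and determinism", {
  d <- simulation_design(n_fruit = 10, seed = 123L)
  pop <- simulate_population(d)
  expect_equal(nrow(pop$spectra$matrix), 40L)  # 10 fruit x 4 configurations
  expect_equal(nrow(pop$truth), 10L)
  expect_gte(min(pop$truth$ssc), 7)
  expect_lte(max(pop$truth$ssc), 20.5)
  expect_true(all(pop$spectra$sample_table$ssc_group %in%
                    c("Low", "Medium", "High")))

  # byte-wise determinism of the serialized spectra
  pop2 <- simulate_population(d)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(pop$spectra, p1)
  write_spectra_csv(pop2$spectra, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("raising an effect-matrix entry raises absorbance at that band centre", {
  centers <- wamacs_midpoints()
  f <- toy_fruit()
  for (b in c(2L, 5L, 9L)) {
    absorb_at_center <- function(bump) {
      em <- default_effect_matrix()
      em["UP", b] <- em["UP", b] + bump
      d <- tiny_design(effect_matrix = em)
      m <- simulate_measurement(f, "UP", d)
      a <- to_absorbance(m$scans[[1]], m$reference)$values
      a[nearest_index(d$grid, centers[b])]
    }
    expect_gt(absorb_at_center(0.5), absorb_at_center(0))
  }
})

test_that("SSC shift drains free bands and fills bound bands monotonically", {
  d <- tiny_design(ssc_shift_rate = 0.02)
  sscs <- c(8, 11, 14, 17, 20)
  shifted <- vapply(sscs, function(s)
    aquapolar:::ssc_shift_amplitudes(default_base_amplitudes(), s, d),
    numeric(12))
  free_tot <- colSums(shifted[1:5, ])
  bound_tot <- colSums(shifted[6:10, ])
  expect_true(all(diff(free_tot) < 0))
  expect_true(all(diff(bound_tot) > 0))
  expect_equal(shifted[11:12, 1], shifted[11:12, 5])  # C11/C12 untouched
})

test_that("zero surface weight collapses the polarization contrast exactly", {
  d <- tiny_design(depol_surface_weight = 0)
  f <- toy_fruit(amps = default_base_amplitudes())
  absorb <- function(cfg) {
    m <- simulate_measurement(f, cfg, d)
    to_absorbance(m$scans[[1]], m$reference)$values
  }
  expect_lt(max(abs(absorb("UP") - absorb("UU"))), 1e-12)
  expect_lt(max(abs(absorb("PP") - absorb("PU"))), 1e-12)
})
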
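test_that("the WAMACS table carries the twelve second-overtone bands", {
  tb <- wamacs_table()
  expect_equal(nrow(tb), 12L)
  expect_equal(tb$band_id, paste0("C", 1:12))
  expect_true(all(tb$lo_nm < tb$hi_nm))
  expect_true(!is.unsorted(tb$lo_nm))
  expect_equal(unname(unlist(tb[tb$band_id == "C5", c("lo_nm", "hi_nm")])),
               c(942, 955))
  expect_match(tb$assignment[tb$band_id == "C5"], "free water")
  expect_equal(unname(unlist(tb[tb$band_id == "C7", c("lo_nm", "hi_nm")])),
               c(965, 973))
  expect_match(tb$assignment[tb$band_id == "C7"], "one hydrogen bond")
  expect_equal(tb$species_class, c(rep("free", 5), rep("bound", 7)))
})

test_that("band assignment covers the bands and resolves the shared endpoint", {
  expect_equal(assign_band(946), "C5")
  expect_equal(assign_band(998), "C11")   # C10/C11 shared endpoint -> upper
  expect_equal(assign_band(899), NA_character_)
  expect_equal(assign_band(940), NA_character_)  # gap between C4 and C5
  expect_equal(assign_band(1007), "C11")
  expect_equal(assign_band(1021), "C12")
  expect_equal(assign_band(1021.5), NA_character_)
})

test_that("every published activated wavelength maps to its own band", {
  act <- published_activated_wavelengths()
  expect_equal(assign_band(act$wavelength_nm), act$band_id)
})

test_that("SSC grouping closes the printed gaps", {
  expect_equal(ssc_group(c(10.4, 12, 14.9, 15, 16.9, 11.95)),
               c("Low", "Medium", "Medium", "High", "High", "Low"))
  expect_error(ssc_group(-1), "negative")
})

test_that("published SSC summary is internally consistent", {
  tb <- kiwifruit_ssc_summary()
  grp <- tb[tb$group != "All", ]
  all_row <- tb[tb$group == "All", ]
  expect_equal(sum(grp$n), all_row$n)
  wmean <- sum(grp$n * grp$mean_brix) / sum(grp$n)
  expect_equal(wmean, all_row$mean_brix, tolerance = 0.05 / all_row$mean_brix)
})

test_that("SSC difference spectra subtract group means from the Low mean", {
  g <- spectral_grid(900, 912, 3)
  n <- 5L
  st <- data.frame(fruit_id = paste0("f", 1:6),
                   configuration = "UU",
                   ssc = c(10, 10, 13, 13, 16, 16))
  base <- matrix(stats::rnorm(6 * n), 6, n)
  base[3:4, ] <- base[1:2, ] + 1   # Medium = Low + 1
  base[5:6, ] <- base[1:2, ] + 2.5 # High = Low + 2.5
  s <- spectra_set(base, st, g, "snv2d")
  d <- ssc_difference_spectra(s)
  expect_equal(d$Low$values, rep(0, n))
  expect_equal(d$Medium$values, rep(-1, n), tolerance = 1e-12)
  expect_equal(d$High$values, rep(-2.5, n), tolerance = 1e-12)

  s_two <- spectra_set(base[1:4, ], st[1:4, ], g, "snv2d")
  expect_error(ssc_difference_spectra(s_two), "High")
  st_mix <- st; st_mix$configuration[1] <- "PP"
  expect_error(ssc_difference_spectra(spectra_set(base, st_mix, g, "snv2d")),
               "single configuration")
})

test_that("difference spectra of the simulator show the free/bound SSC migration", {
  sim <- simulated_snv2d(n_fruit = 60, seed = 19L)
  s2 <- sim$snv2d
  uu <- subset_samples(s2, s2$sample_table$configuration == "UU")
  d <- ssc_difference_spectra(uu)
  act <- published_activated_wavelengths()
  idx <- nearest_index(s2$grid, act$wavelength_nm)
  dh <- d$High$values[idx]
  # Low minus High of SNV+2D values: negative at free-band features (Low has
  # the deeper minima there), positive at bound-band features
  expect_true(all(dh[1:5] < 0))
  expect_true(all(dh[6:10] > 0))
})

test_that("activated-wavelength selection picks the strongest in-band extremum", {
  g <- spectral_grid()
  wl <- wavelengths(g)
  st <- data.frame(fruit_id = c("a", "b", "c"), configuration = "UU")
  bump_at <- function(center, sd = 5) exp(-(wl - center)^2 / (2 * sd^2))

  # every source a single bump at 946 nm: only C5 selected
  b946 <- bump_at(946)
  m <- fit_pca(spectra_set(outer(c(1, 2, 4), b946), st, g, "snv"), 2L)
  expect_warning(
    act <- select_activated(m, list(UU = b946), list(b946)),
    "no candidate"
  )
  expect_equal(act$band_id, "C5")
  expect_equal(act$wavelength_nm, wl[which.min(abs(wl - 946))])

  # equal-magnitude candidates in one band: lower wavelength wins
  two <- 0.6 * bump_at(944, 2) + 0.6 * bump_at(953, 2)
  suppressWarnings(
    act2 <- select_activated(m, list(UU = two), list(rep(0, length(wl))))
  )
  in_c5 <- act2[act2$band_id == "C5", ]
  peaks <- local_extrema_wl(two, wl)
  expect_equal(in_c5$wavelength_nm, min(peaks))
})

test_that("selection is invariant to source order and positive rescaling", {
  sim <- simulated_snv2d(n_fruit = 20, seed = 23L)
  s2 <- sim$snv2d
  m <- fit_pca(s2, 3L)
  mean_cfg <- lapply(configurations(), function(cfg)
    colMeans(s2$matrix[s2$sample_table$configuration == cfg, , drop = FALSE]))
  names(mean_cfg) <- configurations()
  diffs <- unlist(lapply(configurations(), function(cfg) {
    d <- ssc_difference_spectra(
      subset_samples(s2, s2$sample_table$configuration == cfg))
    d[c("Medium", "High")]
  }), recursive = FALSE)

  a1 <- suppressWarnings(select_activated(m, mean_cfg, diffs))
  a2 <- suppressWarnings(select_activated(m, rev(mean_cfg), rev(diffs)))
  expect_equal(a1[, c("band_id", "wavelength_nm")],
               a2[, c("band_id", "wavelength_nm")])

  scaled <- lapply(mean_cfg, function(v) 37.5 * v)
  a3 <- suppressWarnings(select_activated(m, scaled, diffs))
  expect_equal(a1[, c("band_id", "wavelength_nm", "source")],
               a3[, c("band_id", "wavelength_nm", "source")])

  # closure: each selected wavelength maps back to its band
  expect_equal(assign_band(a1$wavelength_nm), a1$band_id)

  flat <- rep(0, length(wavelengths(s2$grid)))
  expect_error(select_activated(m, list(UU = flat), list(flat),
                                n_pcs = 0L),
               "degenerate")
})
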
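make_input <- function(m, st, bands = paste0("C", seq_len(ncol(m)))) {
  act <- published_activated_wavelengths()[seq_len(ncol(m)), ]
  g <- spectral_grid()
  idx <- nearest_index(g, act$wavelength_nm)
  full <- matrix(0, nrow(m), length(wavelengths(g)))
  full[, idx] <- m
  aquagram_input(spectra_set(full, st, g, "snv2d"), act)
}

test_that("relative SNV standardizes each column over the pooled samples", {
  st <- data.frame(fruit_id = c("a", "b"), configuration = c("UU", "UP"))
  inp <- make_input(matrix(c(1, -1), 2, 1), st)
  out <- relative_snv(inp)
  expect_equal(unname(out[, 1]), c(1, -1) / sqrt(2), tolerance = 1e-12)

  # degenerate constant column names the wavelength
  inp2 <- make_input(matrix(c(2, 2), 2, 1), st)
  expect_error(relative_snv(inp2), "zero variance.*902")

  # location invariance: adding a constant to a column changes nothing
  set.seed(51)
  m <- matrix(stats::rnorm(40), 10, 4)
  st10 <- data.frame(fruit_id = letters[1:10],
                     configuration = rep(configurations(), length.out = 10))
  a <- relative_snv(make_input(m, st10))
  m2 <- m; m2[, 3] <- m2[, 3] + 5.5
  b <- relative_snv(make_input(m2, st10))
  expect_equal(unname(a), unname(b), tolerance = 1e-12)
})

test_that("standardized columns have pooled mean 0 and sd 1", {
  sim <- simulated_snv2d(n_fruit = 15, seed = 33L, noise_sd = 0.005)
  std <- relative_snv(aquagram_input(sim$snv2d,
                                     published_activated_wavelengths()))
  expect_lt(max(abs(colMeans(std))), 1e-10)
  expect_lt(max(abs(apply(std, 2, stats::sd) - 1)), 1e-10)
})

test_that("configuration profiles mirror and pool to zero for equal groups", {
  # two columns; configurations in equal numbers with values +a / -a
  st <- data.frame(fruit_id = paste0("f", 1:8),
                   configuration = rep(configurations(), each = 2))
  a <- 0.8
  m <- cbind(rep(c(a, -a), each = 4))  # UU, UP positive; PU, PP negative
  m <- cbind(m, -m)
  inp <- make_input(m, st)
  std <- relative_snv(inp)
  prof <- aquagram_by_configuration(std, negate_2d = FALSE)
  w <- profiles_wide(prof)
  expect_equal(w$UU, -w$PU, tolerance = 1e-12)  # mirror images
  expect_equal(w$UU, w$UP, tolerance = 1e-12)

  # equal group sizes: band-wise mean of the four profiles is 0
  sim <- simulated_snv2d(n_fruit = 12, seed = 9L, noise_sd = 0.005)
  std2 <- relative_snv(aquagram_input(sim$snv2d,
                                      published_activated_wavelengths()))
  w2 <- profiles_wide(aquagram_by_configuration(std2))
  pooled <- rowMeans(as.matrix(w2[, configurations()]))
  expect_lt(max(abs(pooled)), 1e-10)

  keep <- sim$snv2d$sample_table$configuration != "PP"
  expect_error(aquagram_by_configuration(std2[keep, ],
                                         sim$snv2d$sample_table[keep, ]),
               "missing configuration")
})

test_that("negate_2d flips displayed values and is recorded", {
  sim <- simulated_snv2d(n_fruit = 8, seed = 13L)
  std <- relative_snv(aquagram_input(sim$snv2d,
                                     published_activated_wavelengths()))
  up <- aquagram_by_configuration(std, negate_2d = TRUE)
  dn <- aquagram_by_configuration(std, negate_2d = FALSE)
  expect_equal(up$value, -dn$value)
  expect_true(attr(up, "negate_2d"))
  expect_false(attr(dn, "negate_2d"))
})

test_that("SSC-group profiles degenerate correctly at one fruit per group", {
  st <- data.frame(fruit_id = paste0("f", 1:12),
                   configuration = rep(configurations(), 3),
                   ssc = rep(c(9, 13, 17), each = 4))
  set.seed(60)
  m <- matrix(stats::rnorm(12 * 3), 12, 3)
  std <- relative_snv(make_input(m, st))
  p <- aquagram_by_ssc_group(std, configuration = "UU", negate_2d = FALSE)
  w <- profiles_wide(p)
  is_uu <- st$configuration == "UU"
  expect_equal(unname(as.matrix(w[, c("Low", "Medium", "High")])),
               unname(t(std[is_uu, ])), tolerance = 1e-12)

  st2 <- st[st$ssc < 15, ]
  std2 <- relative_snv(make_input(m[st$ssc < 15, ], st2))
  expect_error(aquagram_by_ssc_group(std2, configuration = "UU"),
               "empty SSC group")
  expect_error(aquagram_by_ssc_group(std, configuration = "ZZ"),
               "unknown configuration")
})

test_that("radar rendering is validated and byte-deterministic", {
  sim <- simulated_snv2d(n_fruit = 8, seed = 13L)
  std <- relative_snv(aquagram_input(sim$snv2d,
                                     published_activated_wavelengths()))
  prof <- aquagram_by_configuration(std)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_aquagram(prof, p1)
  render_aquagram(prof, p2)
  expect_true(file.exists(p1))
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  two_axes <- prof[prof$band_id %in% c("C1", "C2"), ]
  expect_error(render_aquagram(two_axes, withr::local_tempfile()),
               "at least 3")
})
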
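test_that("scan averaging is the elementwise mean", {
  g <- spectral_grid(800, 830, 3)
  n <- length(wavelengths(g))
  one <- spectrum(g, stats::rnorm(n), meta = list(scan = 1))
  expect_equal(average_scans(list(one))$values, one$values)

  v <- stats::rnorm(n); c0 <- 2.5
  s1 <- spectrum(g, v); s2 <- spectrum(g, -v + 2 * c0)
  expect_equal(average_scans(list(s1, s2))$values, rep(c0, n))

  scans <- lapply(1:5, function(k) spectrum(g, stats::rnorm(n)))
  oracle <- colMeans(do.call(rbind, lapply(scans, `[[`, "values")))
  expect_equal(average_scans(scans)$values, oracle, tolerance = 1e-14)

  g2 <- spectral_grid(800, 833, 3)
  expect_error(average_scans(list(one, spectrum(g2, rnorm(12)))),
               "mismatched")
})

test_that("SNV standardizes each spectrum with the n-1 convention", {
  g3 <- spectral_grid(800, 806, 3)
  expect_equal(snv(spectrum(g3, c(1, 2, 3), kind = "absorbance"))$values,
               c(-1, 0, 1))

  g <- spectral_grid()
  set.seed(21)
  v <- stats::rnorm(84)
  out <- snv(spectrum(g, v, kind = "absorbance"))$values
  expect_lt(abs(mean(out)), 1e-12)
  expect_lt(abs(stats::sd(out) - 1), 1e-12)
  expect_identical(snv(spectrum(g, v, kind = "absorbance"))$kind, "snv")

  expect_error(snv(spectrum(g, rep(1, 84), kind = "absorbance")), "sd = 0")
})

test_that("SNV is invariant under positive affine maps and flips under negative scale", {
  g <- spectral_grid()
  set.seed(22)
  for (i in 1:5) {
    v <- stats::rnorm(84)
    a <- stats::runif(1, 0.1, 10); b <- stats::rnorm(1, 0, 5)
    base <- snv(spectrum(g, v, kind = "absorbance"))$values
    aff <- snv(spectrum(g, a * v + b, kind = "absorbance"))$values
    neg <- snv(spectrum(g, -a * v + b, kind = "absorbance"))$values
    expect_equal(aff, base, tolerance = 1e-10)
    expect_equal(neg, -base, tolerance = 1e-10)
  }
})

test_that("Savitzky-Golay second derivative reproduces polynomials exactly", {
  g <- spectral_grid()
  x <- seq_along(wavelengths(g)) - 1  # abscissa in grid-step units
  quad <- spectrum(g, x^2, kind = "snv")
  expect_equal(savgol2d(quad)$values, rep(2, length(x)), tolerance = 1e-10)
  line <- spectrum(g, 3.7 * x - 2, kind = "snv")
  expect_equal(savgol2d(line)$values, rep(0, length(x)), tolerance = 1e-10)
  # per-nm scaling divides by the squared step
  expect_equal(savgol2d(quad, per_nm = TRUE)$values,
               rep(2 / g$step_nm^2, length(x)), tolerance = 1e-10)
})

test_that("Savitzky-Golay matches a central finite difference on a sine", {
  g <- spectral_grid()
  x <- seq_along(wavelengths(g)) - 1
  y <- sin(2 * pi * x / 30)
  sg <- savgol2d(spectrum(g, y, kind = "snv"))$values
  fd <- c(NA, y[1:(length(y) - 2)] - 2 * y[2:(length(y) - 1)] +
            y[3:length(y)], NA)  # centred difference, step = 1
  interior <- 10:(length(y) - 10)
  expect_lt(max(abs(sg[interior] - fd[interior])) / max(abs(fd[interior])),
            0.05)
})

test_that("savgol2d validates window arguments", {
  g <- spectral_grid(800, 830, 3)
  s <- spectrum(g, stats::rnorm(11), kind = "snv")
  expect_error(savgol2d(s, window_points = 6L), "odd")
  expect_error(savgol2d(s, window_points = 13L), "shorter")
  expect_error(savgol2d(s, window_points = 3L, polyorder = 2L),
               "polyorder")
})

test_that("mean centering zeroes column means and is idempotent", {
  g <- spectral_grid(800, 812, 3)
  st <- data.frame(fruit_id = c("a", "b"), configuration = c("UU", "UU"))
  v <- stats::rnorm(5)
  s <- spectra_set(rbind(v, v), st, g, "absorbance")
  expect_equal(unname(mean_center(s)$matrix), matrix(0, 2, 5))

  set.seed(30)
  m <- matrix(stats::rnorm(10), 2, 5)
  cent <- mean_center(spectra_set(m, st, g, "absorbance"))
  expect_lt(max(abs(colMeans(cent$matrix))), 1e-12)
  expect_equal(mean_center(cent)$matrix, cent$matrix, tolerance = 1e-14)
})

test_that("run_plan applies steps in order and enforces kind legality", {
  sim <- simulated_snv2d(n_fruit = 4)
  ab <- sim$absorbance

  snv_only <- run_plan(ab, preprocess_plan(steps = "snv"))
  expect_lt(max(abs(rowMeans(snv_only$matrix))), 1e-12)
  sds <- apply(snv_only$matrix, 1, stats::sd)
  expect_lt(max(abs(sds - 1)), 1e-12)

  # SNV + 2D of Gaussian bands: local minimum at each strong band centre
  s2 <- run_plan(ab, preprocess_plan())
  expect_identical(s2$kind, "snv2d")
  expect_identical(attr(s2, "provenance"), c("snv", "savgol2d"))
  wl <- wavelengths(s2$grid)
  i5 <- nearest_index(s2$grid, wamacs_midpoints()["C5"])
  row <- s2$matrix[1, ]
  expect_lt(row[i5], row[i5 - 2])
  expect_lt(row[i5], row[i5 + 2])

  # empty plan is the identity
  same <- run_plan(ab, preprocess_plan(steps = character(0)))
  expect_identical(same$matrix, ab$matrix)

  # savgol2d straight on absorbance is an illegal order
  expect_error(run_plan(ab, preprocess_plan(steps = c("savgol2d", "snv"))),
               "cannot be applied")
  expect_error(preprocess_plan(savgol_window_points = 8L), "odd")
})
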
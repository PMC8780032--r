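#' The WAMACS band table (second overtone of water)
#'
#' The twelve water matrix coordinates (WAMACS) C1-C12 for the 800-1100 nm
#' second-overtone region, as tabulated in the aquaphotomics literature from
#' the anharmonic oscillator model. C1-C5 relate to free water species, C6-C12
#' to bound water species (S0-S4 denote 0-4 hydrogen bonds).
#'
#' @return A data.frame with columns `band_id`, `lo_nm`, `hi_nm`,
#'   `assignment`, `species_class` (free/bound), ordered C1 to C12.
#' @export
#' @examples
#' wamacs_table()[5, ]  # C5, S0 free water, 942-955 nm
wamacs_table <- function() {
  data.frame(
    band_id = paste0("C", 1:12),
    lo_nm = c(900, 916, 923, 930, 942, 957, 965, 975, 982, 992, 998, 1014),
    hi_nm = c(908, 920, 927, 935, 955, 963, 973, 979, 989, 998, 1007, 1021),
    assignment = c(
      "v3 asymmetric stretching vibration",
      "OH stretch (water solvation shell)",
      "v1+v3 symmetric and asymmetric stretching vibration",
      "OH stretch (water solvation shell)",
      "S0 (free water)",
      "Water hydration, H5O2+",
      "S1 - water molecules with one hydrogen bond",
      "v2+v3 bending and asymmetric stretching vibration",
      "S2 - water molecules with 2 hydrogen bonds",
      "S3 - water molecules with 3 hydrogen bonds",
      "S4 - water molecules with 4 hydrogen bonds",
      "Strongly bonded water (v1, v2)"
    ),
    species_class = c(rep("free", 5), rep("bound", 7)),
    stringsAsFactors = FALSE
  )
}

#' Band midpoints (nm), used as Gaussian centres by the simulator
#' @return Named numeric vector, C1-C12.
#' @export
wamacs_midpoints <- function() {
  tb <- wamacs_table()
  stats::setNames((tb$lo_nm + tb$hi_nm) / 2, tb$band_id)
}

#' Published activated wavelengths, one per band
#'
#' The reference activated-wavelength set for this region (903, 916, 926,
#' 933, 946, 962, 965, 975, 988, 994, 1007, 1014 nm for C1-C12), usable as a
#' fixed [select_activated()] alternative when the analysis should be anchored
#' to the literature positions.
#'
#' @return A data.frame with columns `band_id`, `wavelength_nm`, `source`
#'   (`"published"`).
#' @export
published_activated_wavelengths <- function() {
  data.frame(
    band_id = paste0("C", 1:12),
    wavelength_nm = c(903, 916, 926, 933, 946, 962, 965, 975, 988, 994,
                      1007, 1014),
    source = "published",
    stringsAsFactors = FALSE
  )
}

#' Assign a wavelength to its WAMACS band
#'
#' Band intervals are closed, `[lo, hi]`; the single endpoint shared by two
#' bands (998 nm, C10/C11) is resolved deterministically to the upper band,
#' C11 — equivalently, each band is half-open `[lo, hi)` wherever the next
#' band starts at its upper limit.
#'
#' @param wavelength_nm wavelength(s) in nm.
#' @return Character vector of band ids (`"C1"`..`"C12"`), `NA` where the
#'   wavelength falls in none of the bands (e.g. 940 nm).
#' @export
#' @examples
#' assign_band(c(946, 998, 899))  # "C5", "C11", NA
assign_band <- function(wavelength_nm) {
  tb <- wamacs_table()
  vapply(wavelength_nm, function(w) {
    hit <- which(w >= tb$lo_nm & w <= tb$hi_nm)
    if (!length(hit)) return(NA_character_)
    tb$band_id[hit[length(hit)]]  # shared endpoint goes to the upper band
  }, character(1L))
}

#' Soluble solids content grouping
#'
#' Fruit are grouped by SSC into Low (< 12 degrees Brix), Medium (12 to < 15)
#' and High (>= 15); the boundaries close the gaps left by the printed group
#' ranges (7-11.9 / 12.1-14.9 / 15-20.5) so every real SSC is assigned.
#'
#' @param ssc SSC value(s) in degrees Brix, must be non-negative.
#' @return Character vector in `c("Low", "Medium", "High")`.
#' @export
#' @examples
#' ssc_group(c(10.4, 12, 16.9))
ssc_group <- function(ssc) {
  if (any(ssc < 0)) stop("negative SSC", call. = FALSE)
  out <- ifelse(ssc < 12, "Low", ifelse(ssc < 15, "Medium", "High"))
  as.character(out)
}

#' Published SSC population summary
#'
#' The reference SSC grouping of the 200-fruit study population: group sizes,
#' ranges and averages, plus the overall row. Shipped as published constants
#' for consistency checks (the weighted mean of the group averages reproduces
#' the overall average; the group sizes sum to the fruit count).
#'
#' @return A data.frame with columns `group`, `n`, `lo_brix`, `hi_brix`,
#'   `mean_brix`.
#' @export
kiwifruit_ssc_summary <- function() {
  data.frame(
    group = c("Low", "Medium", "High", "All"),
    n = c(61, 69, 70, 200),
    lo_brix = c(7, 12.1, 15, 7),
    hi_brix = c(11.9, 14.9, 20.5, 20.5),
    mean_brix = c(10.4, 13.5, 16.9, 13.7),
    stringsAsFactors = FALSE
  )
}

#' SSC difference spectra
#'
#' For one measurement configuration, the difference between the Low-SSC
#' group's mean spectrum and each group's mean spectrum:
#' `diff_g(lambda) = mean_Low(lambda) - mean_g(lambda)`. Computed on SNV+2D
#' spectra this highlights the free-to-bound water migration with sugar
#' content.
#'
#' @param set a [spectra_set()] restricted to one configuration, with an
#'   `ssc_group` column in its sample table (or an `ssc` column from which
#'   groups are derived).
#' @return Named list of `spectrum` objects of kind `difference`, one per
#'   group present (`Low` entry is identically zero).
#' @export
ssc_difference_spectra <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  st <- set$sample_table
  if (length(unique(st$configuration)) != 1L)
    stop("set must be restricted to a single configuration", call. = FALSE)
  grp <- if ("ssc_group" %in% names(st)) st$ssc_group else ssc_group(st$ssc)
  for (g in c("Low", "Medium", "High"))
    if (!any(grp == g))
      stop("empty SSC group: ", g, call. = FALSE)
  mean_of <- function(g) colMeans(set$matrix[grp == g, , drop = FALSE])
  m_low <- mean_of("Low")
  out <- lapply(c("Low", "Medium", "High"), function(g) {
    spectrum(set$grid, m_low - mean_of(g), kind = "difference",
             meta = list(configuration = st$configuration[1L], group = g))
  })
  stats::setNames(out, c("Low", "Medium", "High"))
}
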
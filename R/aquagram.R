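#' Assemble the aquagram input matrix
#'
#' Extracts the preprocessed absorbance values at the activated wavelengths,
#' ordered C1 to C12. Requested wavelengths are snapped to the nearest grid
#' column; both the requested and the grid wavelength actually used are
#' recorded.
#'
#' @param set a preprocessed `spectra_set` (kind `snv2d` by default in this
#'   pipeline, `snv` also accepted).
#' @param activated data.frame with `band_id` and `wavelength_nm` columns,
#'   e.g. from [select_activated()] or
#'   [published_activated_wavelengths()].
#' @return An object of class `aquagram_input`: `matrix`
#'   (samples x bands, columns named by band), `sample_table`, `bands`,
#'   `wavelength_requested`, `wavelength_used`, `kind`.
#' @export
aquagram_input <- function(set, activated) {
  stopifnot(inherits(set, "spectra_set"))
  if (!all(c("band_id", "wavelength_nm") %in% names(activated)))
    stop("activated needs band_id and wavelength_nm columns", call. = FALSE)
  ord <- order(match(activated$band_id, paste0("C", 1:12)))
  activated <- activated[ord, , drop = FALSE]
  idx <- nearest_index(set$grid, activated$wavelength_nm)
  m <- set$matrix[, idx, drop = FALSE]
  colnames(m) <- activated$band_id
  structure(list(matrix = m,
                 sample_table = set$sample_table,
                 bands = activated$band_id,
                 wavelength_requested = activated$wavelength_nm,
                 wavelength_used = set$grid$wavelengths[idx],
                 kind = set$kind),
            class = "aquagram_input")
}

#' Relative SNV standardization across the pooled sample set
#'
#' The aquagram transform: at each activated wavelength, standardize the
#' preprocessed absorbance over ALL samples of ALL configurations,
#' `A'(lambda) = (A(lambda) - mu_lambda) / sigma_lambda`, with the sample
#' (n-1) standard deviation. Every column of the result has pooled mean 0
#' and sd 1.
#'
#' @param input an [aquagram_input()].
#' @return samples x bands standardized matrix carrying the input's sample
#'   table as attribute `"sample_table"`.
#' @export
relative_snv <- function(input) {
  stopifnot(inherits(input, "aquagram_input"))
  m <- input$matrix
  if (nrow(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  mu <- colMeans(m)
  sg <- apply(m, 2L, stats::sd)
  if (any(sg == 0)) {
    bad <- which(sg == 0)[1L]
    stop("zero variance at activated wavelength ",
         input$wavelength_used[bad], " nm (band ", input$bands[bad], ")",
         call. = FALSE)
  }
  out <- sweep(sweep(m, 2L, mu), 2L, sg, `/`)
  attr(out, "sample_table") <- input$sample_table
  attr(out, "kind") <- input$kind
  out
}

.profile_frame <- function(groups, std_matrix, labels, negate_2d) {
  sgn <- if (negate_2d) -1 else 1
  rows <- lapply(labels, function(g) {
    data.frame(group = g,
               band_id = colnames(std_matrix),
               value = sgn * colMeans(std_matrix[groups == g, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "negate_2d") <- negate_2d
  class(out) <- c("aquagram_profiles", class(out))
  out
}

#' Aquagram profiles by measurement configuration
#'
#' Per configuration and band, the mean of the pooled-standardized values
#' ([relative_snv()]). With second-derivative input the standardized values
#' are sign-flipped by default (`negate_2d`) so that greater absorbance
#' plots outward (a stronger absorption band makes the second derivative
#' more negative at its centre); the flag's state travels with the result.
#'
#' @param std_matrix output of [relative_snv()].
#' @param sample_table data.frame aligned with the matrix rows (taken from
#'   the matrix attribute when omitted); must contain all four
#'   configurations.
#' @param negate_2d flip the sign of the standardized values (default TRUE,
#'   intended for `snv2d` input).
#' @return data.frame of class `aquagram_profiles` (`group`, `band_id`,
#'   `value`), groups ordered UU, UP, PU, PP.
#' @export
aquagram_by_configuration <- function(std_matrix, sample_table = NULL,
                                      negate_2d = TRUE) {
  if (is.null(sample_table)) sample_table <- attr(std_matrix, "sample_table")
  stopifnot(nrow(std_matrix) == nrow(sample_table))
  missing <- setdiff(configurations(), unique(sample_table$configuration))
  if (length(missing))
    stop("missing configuration(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  .profile_frame(sample_table$configuration, std_matrix, configurations(),
                 negate_2d)
}

#' Aquagram profiles by SSC group within one configuration
#'
#' The standardization population stays the full pooled set (all
#' configurations), so panels are comparable across configurations; only
#' the averaging is restricted to the chosen configuration's Low, Medium
#' and High SSC groups.
#'
#' @param std_matrix output of [relative_snv()].
#' @param configuration one of UU, UP, PU, PP.
#' @inheritParams aquagram_by_configuration
#' @return data.frame of class `aquagram_profiles`, groups Low/Medium/High.
#' @export
aquagram_by_ssc_group <- function(std_matrix, sample_table = NULL,
                                  configuration, negate_2d = TRUE) {
  if (is.null(sample_table)) sample_table <- attr(std_matrix, "sample_table")
  stopifnot(nrow(std_matrix) == nrow(sample_table))
  check_configuration(configuration)
  sel <- sample_table$configuration == configuration
  if (!any(sel)) stop("no samples for configuration ", configuration,
                      call. = FALSE)
  sub <- std_matrix[sel, , drop = FALSE]
  st <- sample_table[sel, , drop = FALSE]
  grp <- if ("ssc_group" %in% names(st)) st$ssc_group else ssc_group(st$ssc)
  for (g in c("Low", "Medium", "High"))
    if (!any(grp == g)) stop("empty SSC group: ", g, call. = FALSE)
  .profile_frame(grp, sub, c("Low", "Medium", "High"), negate_2d)
}

#' Render aquagram profiles as a radar chart
#'
#' Draws one closed polygon per group over band axes C1..C12 arranged
#' clockwise from the top, with concentric guide rings, and writes a PNG
#' (cairo device, fixed settings, byte-deterministic for fixed input).
#'
#' @param profiles an `aquagram_profiles` data.frame (>= 3 bands).
#' @param path output PNG path.
#' @param title plot title (default none).
#' @param width,height device size in pixels.
#' @return Invisibly, `path`.
#' @export
render_aquagram <- function(profiles, path, title = NULL,
                            width = 800L, height = 800L) {
  bands <- unique(profiles$band_id)
  groups <- unique(profiles$group)
  nb <- length(bands)
  if (nb < 3L) stop("need at least 3 band axes for a radar chart",
                    call. = FALSE)
  wide <- matrix(NA_real_, length(groups), nb,
                 dimnames = list(groups, bands))
  for (i in seq_len(nrow(profiles)))
    wide[profiles$group[i], profiles$band_id[i]] <- profiles$value[i]
  if (anyNA(wide)) stop("profiles are not complete over groups x bands",
                        call. = FALSE)

  lo <- min(wide); hi <- max(wide)
  span <- if (hi > lo) hi - lo else 1
  radial <- function(v) 0.25 + 0.75 * (v - lo) / span
  theta <- pi / 2 - 2 * pi * (seq_len(nb) - 1L) / nb  # clockwise from top

  cols <- c("#1f77b4", "#d62728", "#17becf", "#e377c2", "#2ca02c",
            "#ff7f0e")[seq_along(groups)]
  grDevices::png(path, width = width, height = height, type = "cairo")
  op <- graphics::par(mar = c(1, 1, if (is.null(title)) 1 else 3, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::plot.window(c(-1.3, 1.3), c(-1.3, 1.3), asp = 1)
  if (!is.null(title)) graphics::title(main = title)
  for (r in c(0.25, 0.5, 0.75, 1)) {
    a <- seq(0, 2 * pi, length.out = 241L)
    graphics::lines(r * cos(a), r * sin(a), col = "grey80")
  }
  for (j in seq_len(nb)) {
    graphics::lines(c(0, cos(theta[j])), c(0, sin(theta[j])), col = "grey85")
    graphics::text(1.15 * cos(theta[j]), 1.15 * sin(theta[j]), bands[j],
                   cex = 1.1)
  }
  for (gi in seq_along(groups)) {
    r <- radial(wide[gi, ])
    graphics::polygon(r * cos(theta), r * sin(theta), border = cols[gi],
                      lwd = 2)
  }
  graphics::legend("bottomright", legend = groups, col = cols, lwd = 2,
                   bty = "n", cex = 1.0)
  invisible(path)
}
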
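#' Average repeated scans of one measurement
#'
#' Elementwise arithmetic mean of replicate scans, mirroring the instrument's
#' five-scan averaging. All scans must share grid and kind.
#'
#' @param scans non-empty list of `spectrum` objects.
#' @return A `spectrum`; metadata is taken from the first scan with the scan
#'   index dropped.
#' @export
average_scans <- function(scans) {
  if (!length(scans)) stop("need at least one scan", call. = FALSE)
  stopifnot(all(vapply(scans, inherits, logical(1L), "spectrum")))
  g <- scans[[1L]]$grid
  k <- scans[[1L]]$kind
  for (s in scans[-1L]) {
    if (!same_grid(s$grid, g)) stop("mismatched scan grids", call. = FALSE)
    if (s$kind != k) stop("mismatched scan kinds", call. = FALSE)
  }
  v <- Reduce(`+`, lapply(scans, `[[`, "values")) / length(scans)
  meta <- scans[[1L]]$meta
  meta$scan <- NULL
  spectrum(g, v, kind = k, meta = meta)
}

#' Standard normal variate transform
#'
#' Per-spectrum standardization: subtract the spectrum's mean and divide by
#' its standard deviation (sample, n-1 denominator). Removes multiplicative
#' scatter and additive offset differences between spectra; the output has
#' mean 0 and sd 1 by construction.
#'
#' @param x a `spectrum` of kind `absorbance`, or a `spectra_set` (applied
#'   row-wise).
#' @param ... unused.
#' @return Same class as the input, kind `snv`.
#' @export
snv <- function(x, ...) UseMethod("snv")

.snv_values <- function(v) {
  if (length(v) < 2L) stop("need at least 2 points for SNV", call. = FALSE)
  s <- stats::sd(v)
  if (s == 0)
    stop("constant spectrum (sd = 0): flat or clipped input", call. = FALSE)
  (v - mean(v)) / s
}

#' @export
snv.spectrum <- function(x, ...) {
  spectrum(x$grid, .snv_values(x$values), kind = "snv", meta = x$meta)
}

#' @export
snv.spectra_set <- function(x, ...) {
  out <- t(apply(x$matrix, 1L, .snv_values))
  spectra_set(out, x$sample_table, x$grid, "snv")
}

#' Savitzky-Golay second derivative
#'
#' Per-point second derivative of the local least-squares polynomial fit
#' (default: 7-point window, second-order polynomial). The derivative is in
#' units of value per (grid step)^2, which makes polynomial reproduction
#' exact (`y = x^2` in step units gives exactly 2); set `per_nm = TRUE` to
#' divide by the step squared and obtain value per nm^2. Edge points are
#' computed from the one-sided polynomial fit of the boundary window, so the
#' output has the input's length.
#'
#' @param x a `spectrum` (kind `snv` yields kind `snv2d`) or `spectra_set`.
#' @param window_points odd window length in grid points, at least
#'   `polyorder + 2`.
#' @param polyorder polynomial order of the local fit.
#' @param per_nm report the derivative per nm^2 instead of per step^2.
#' @param ... unused.
#' @return Same class as the input.
#' @export
savgol2d <- function(x, window_points = 7L, polyorder = 2L, per_nm = FALSE,
                     ...) {
  UseMethod("savgol2d")
}

.check_savgol <- function(n_points, window_points, polyorder) {
  if (window_points %% 2L != 1L)
    stop("window_points must be odd", call. = FALSE)
  if (window_points < polyorder + 2L)
    stop("window_points must be at least polyorder + 2", call. = FALSE)
  if (window_points >= n_points)
    stop("window (", window_points, ") must be shorter than the spectrum (",
         n_points, ")", call. = FALSE)
}

.savgol2d_values <- function(v, window_points, polyorder, scale) {
  signal::sgolayfilt(v, p = polyorder, n = window_points, m = 2L, ts = 1) /
    scale
}

#' @export
savgol2d.spectrum <- function(x, window_points = 7L, polyorder = 2L,
                              per_nm = FALSE, ...) {
  .check_savgol(length(x$values), window_points, polyorder)
  scale <- if (per_nm) x$grid$step_nm^2 else 1
  kind <- if (x$kind == "snv") "snv2d" else x$kind
  spectrum(x$grid,
           .savgol2d_values(x$values, window_points, polyorder, scale),
           kind = kind, meta = x$meta)
}

#' @export
savgol2d.spectra_set <- function(x, window_points = 7L, polyorder = 2L,
                                 per_nm = FALSE, ...) {
  .check_savgol(ncol(x$matrix), window_points, polyorder)
  scale <- if (per_nm) x$grid$step_nm^2 else 1
  out <- t(apply(x$matrix, 1L, .savgol2d_values,
                 window_points = window_points, polyorder = polyorder,
                 scale = scale))
  kind <- if (x$kind == "snv") "snv2d" else x$kind
  spectra_set(out, x$sample_table, x$grid, kind)
}

#' Column-wise mean centering of a spectra set
#'
#' @param set a `spectra_set` with at least two samples.
#' @return The set with zero column means; the kind tag is unchanged.
#' @export
mean_center <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  if (nrow(set$matrix) < 2L) stop("need at least 2 samples", call. = FALSE)
  out <- sweep(set$matrix, 2L, colMeans(set$matrix))
  spectra_set(out, set$sample_table, set$grid, set$kind)
}

#' Preprocessing plan
#'
#' An ordered list of preprocessing steps with the Savitzky-Golay settings.
#' Valid steps: `average_scans`, `to_absorbance`, `snv`, `savgol2d`,
#' `mean_center`. The canonical chain for this pipeline is
#' `c("snv", "savgol2d")` applied to absorbance spectra (SNV + 2D).
#'
#' @param steps character vector of step names, applied in order.
#' @param savgol_window_points odd integer window (points).
#' @param savgol_polyorder polynomial order.
#' @return An object of class `preprocess_plan`.
#' @export
preprocess_plan <- function(steps = c("snv", "savgol2d"),
                            savgol_window_points = 7L,
                            savgol_polyorder = 2L) {
  bad <- setdiff(steps, c("average_scans", "to_absorbance", "snv",
                          "savgol2d", "mean_center"))
  if (length(bad))
    stop("unknown preprocessing step(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (savgol_window_points %% 2L != 1L ||
      savgol_window_points < savgol_polyorder + 2L)
    stop("savgol_window_points must be odd and >= polyorder + 2",
         call. = FALSE)
  structure(list(steps = as.character(steps),
                 savgol_window_points = as.integer(savgol_window_points),
                 savgol_polyorder = as.integer(savgol_polyorder)),
            class = "preprocess_plan")
}

# kind(s) each step accepts as input
.step_input_kinds <- function(step) {
  switch(step,
         average_scans = "intensity",
         to_absorbance = "intensity",
         snv = "absorbance",
         savgol2d = "snv",
         mean_center = .spectrum_kinds)
}

#' Run a preprocessing plan on a spectra set
#'
#' Applies the plan's steps in order, updating the processing-stage tag and
#' recording provenance. Steps are checked against the current kind, so an
#' illegal order (e.g. `savgol2d` before absorbance conversion) is rejected
#' up front.
#'
#' @param set a `spectra_set`.
#' @param plan a [preprocess_plan()].
#' @param references per-configuration reference spectra, required when the
#'   plan contains `to_absorbance` (see [to_absorbance_set()]).
#' @return The processed `spectra_set`; applied steps are recorded in the
#'   `"provenance"` attribute.
#' @export
run_plan <- function(set, plan, references = NULL) {
  stopifnot(inherits(set, "spectra_set"), inherits(plan, "preprocess_plan"))
  prov <- attr(set, "provenance")
  for (step in plan$steps) {
    ok <- .step_input_kinds(step)
    if (!set$kind %in% ok)
      stop("step '", step, "' cannot be applied to kind '", set$kind,
           "' (expects ", paste(ok, collapse = "/"), ")", call. = FALSE)
    set <- switch(step,
      average_scans = average_scan_rows(set),
      to_absorbance = {
        if (is.null(references))
          stop("to_absorbance step needs reference spectra", call. = FALSE)
        to_absorbance_set(set, references)
      },
      snv = snv(set),
      savgol2d = savgol2d(set, plan$savgol_window_points,
                          plan$savgol_polyorder),
      mean_center = mean_center(set)
    )
    prov <- c(prov, step)
  }
  attr(set, "provenance") <- prov
  set
}

#' Average scan rows of a spectra set
#'
#' Collapses replicate-scan rows to one row per (fruit, configuration); the
#' `scan` column is dropped from the sample table.
#'
#' @param set a `spectra_set` whose sample table has a `scan` column.
#' @return A `spectra_set` with one row per (fruit, configuration).
#' @export
average_scan_rows <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  st <- set$sample_table
  if (!"scan" %in% names(st)) return(set)  # already averaged
  key <- paste(st$fruit_id, st$configuration, sep = "\r")
  ukey <- unique(key)
  idx <- match(ukey, key)
  mat <- matrix(0, length(ukey), ncol(set$matrix))
  for (j in seq_along(ukey)) {
    mat[j, ] <- colMeans(set$matrix[key == ukey[j], , drop = FALSE])
  }
  meta <- st[idx, setdiff(names(st), "scan"), drop = FALSE]
  spectra_set(mat, meta, set$grid, set$kind)
}
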
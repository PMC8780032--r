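#' Spectrum and spectra-set containers
#'
#' A `spectrum` is one wavelength-indexed vector tagged with a processing
#' stage (`kind`) and sample metadata. A `spectra_set` is a samples x
#' wavelengths matrix joined to a sample table (fruit, measurement
#' configuration, soluble solids content, dry matter content, SSC group).
#'
#' Recognised kinds: `intensity` (raw counts), `absorbance`
#' (log10(reference/sample)), `snv` (standard normal variate), `snv2d`
#' (SNV followed by a Savitzky-Golay second derivative), `difference`
#' (between-group difference spectra).
#'
#' @param grid a [spectral_grid()].
#' @param values numeric vector, one value per grid point.
#' @param kind processing-stage tag.
#' @param meta named list of sample metadata (fruit_id, configuration, scan).
#' @return A `spectrum` object.
#' @export
spectrum <- function(grid, values, kind = "intensity", meta = list()) {
  stopifnot(inherits(grid, "spectral_grid"))
  kind <- match.arg(kind, .spectrum_kinds)
  if (length(values) != length(grid$wavelengths))
    stop("values length (", length(values), ") does not match grid length (",
         length(grid$wavelengths), ")", call. = FALSE)
  structure(list(grid = grid, values = as.numeric(values), kind = kind,
                 meta = meta),
            class = "spectrum")
}

.spectrum_kinds <- c("intensity", "absorbance", "snv", "snv2d", "difference")

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum:%s> %d points, %g-%g nm", x$kind,
              length(x$values), x$grid$start_nm, x$grid$stop_nm))
  if (length(x$meta)) {
    cat(" |", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' The four measurement configurations
#'
#' Unpeeled/Peeled crossed with Unpolarized/Polarized detection.
#' @export
configurations <- function() c("UU", "UP", "PU", "PP")

is_polarized <- function(configuration) {
  substr(configuration, 2L, 2L) == "P"
}
is_peeled <- function(configuration) {
  substr(configuration, 1L, 1L) == "P"
}

check_configuration <- function(configuration) {
  if (length(configuration) != 1L || !configuration %in% configurations())
    stop("unknown configuration '", paste(configuration, collapse = ","),
         "'; expected one of ", paste(configurations(), collapse = ", "),
         call. = FALSE)
  configuration
}

#' @param matrix samples x wavelengths numeric matrix.
#' @param sample_table data.frame with one row per matrix row; must contain at
#'   least `fruit_id` and `configuration` columns.
#' @rdname spectrum
#' @export
spectra_set <- function(matrix, sample_table, grid, kind = "intensity") {
  stopifnot(inherits(grid, "spectral_grid"))
  kind <- match.arg(kind, .spectrum_kinds)
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != length(grid$wavelengths))
    stop("matrix has ", ncol(matrix), " columns but grid has ",
         length(grid$wavelengths), " wavelengths", call. = FALSE)
  if (nrow(matrix) != nrow(sample_table))
    stop("matrix rows (", nrow(matrix), ") != sample_table rows (",
         nrow(sample_table), ")", call. = FALSE)
  if (!all(c("fruit_id", "configuration") %in% names(sample_table)))
    stop("sample_table must contain fruit_id and configuration columns",
         call. = FALSE)
  bad <- !sample_table$configuration %in% configurations()
  if (any(bad))
    stop("invalid configuration label in sample_table row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  colnames(matrix) <- wavelength_colnames(grid$wavelengths)
  rownames(sample_table) <- NULL
  structure(list(matrix = matrix, sample_table = sample_table, grid = grid,
                 kind = kind),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set:%s> %d samples x %d wavelengths (%g-%g nm)\n",
              x$kind, nrow(x$matrix), ncol(x$matrix),
              x$grid$start_nm, x$grid$stop_nm))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$matrix)

#' Subset a spectra set by sample
#'
#' @param set a `spectra_set`.
#' @param i logical or integer row selector.
#' @return A `spectra_set` with the selected samples.
#' @export
subset_samples <- function(set, i) {
  stopifnot(inherits(set, "spectra_set"))
  spectra_set(set$matrix[i, , drop = FALSE],
              set$sample_table[i, , drop = FALSE],
              set$grid, set$kind)
}

#' Extract one row of a spectra set as a spectrum
#' @param set a `spectra_set`.
#' @param i row index.
#' @export
set_spectrum <- function(set, i) {
  meta <- as.list(set$sample_table[i, , drop = FALSE])
  spectrum(set$grid, set$matrix[i, ], set$kind, meta)
}
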
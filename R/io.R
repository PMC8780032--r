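#' Wide-CSV spectra input/output
#'
#' Spectra travel as wide CSV: metadata columns first, then one column per
#' wavelength named `wl_` + zero-padded nm with one decimal (`wl_0800.0`,
#' `wl_0803.0`, ...). Numeric values are written with 17 significant digits so
#' a write/read round trip reproduces the matrix bit-exactly.
#'
#' @name spectra_csv
NULL

wavelength_colnames <- function(wl) sprintf("wl_%06.1f", wl)

parse_wavelength_colnames <- function(nms) {
  as.numeric(sub("^wl_", "", nms))
}

#' @param set a [spectra_set()].
#' @param path output file.
#' @return `write_spectra_csv` invisibly returns `path`.
#' @rdname spectra_csv
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  meta <- set$sample_table
  for (j in seq_along(meta)) {
    if (is.numeric(meta[[j]])) meta[[j]] <- sprintf("%.17g", meta[[j]])
  }
  vals <- apply(set$matrix, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)  # single sample
  colnames(vals) <- colnames(set$matrix)
  out <- cbind(meta, as.data.frame(vals, optional = TRUE),
               stringsAsFactors = FALSE)
  out$kind <- set$kind
  out <- out[, c("kind", setdiff(names(out), "kind"))]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param path CSV file written by `write_spectra_csv` (or following the same
#'   schema).
#' @return `read_spectra_csv` returns a [spectra_set()].
#' @rdname spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  is_wl <- grepl("^wl_", names(df))
  if (!any(is_wl)) stop("no wavelength (wl_*) columns found in ", path,
                        call. = FALSE)
  wl <- parse_wavelength_colnames(names(df)[is_wl])
  if (any(diff(wl) <= 0))
    stop("wavelength columns are not in increasing order", call. = FALSE)
  grid <- grid_from_wavelengths(wl)
  meta <- df[, !is_wl, drop = FALSE]
  kind <- "intensity"
  if ("kind" %in% names(meta)) {
    kind <- unique(meta$kind)
    if (length(kind) != 1L) stop("mixed kind tags in one file", call. = FALSE)
    meta$kind <- NULL
  }
  key_cols <- intersect(c("fruit_id", "configuration", "scan"), names(meta))
  if (length(key_cols)) {
    key <- do.call(paste, c(meta[key_cols], sep = "\r"))
    if (anyDuplicated(key))
      stop("duplicate (", paste(key_cols, collapse = ", "), ") rows: ",
           paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  if ("configuration" %in% names(meta)) {
    bad <- is.na(meta$configuration) | !meta$configuration %in% configurations()
    if (any(bad))
      stop("missing or invalid configuration label in row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(df[, is_wl, drop = FALSE])
  storage.mode(mat) <- "double"
  spectra_set(mat, meta, grid, kind)
}

#' Convert raw interactance intensity to absorbance
#'
#' Absorbance is defined as `A(lambda) = log10(reference / sample)`, i.e. the
#' base-10 logarithm of the reference-normalised intensity, so that water
#' absorption bands appear as positive peaks.
#'
#' @param sample a `spectrum` of kind `intensity`.
#' @param reference a reference `spectrum` of kind `intensity` on the same
#'   grid, values strictly positive.
#' @return A `spectrum` of kind `absorbance`.
#' @export
#' @examples
#' g <- spectral_grid(800, 830, 10)
#' s <- spectrum(g, rep(10, 4)); r <- spectrum(g, rep(100, 4))
#' to_absorbance(s, r)$values  # all 1
to_absorbance <- function(sample, reference) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference, "spectrum"))
  if (sample$kind != "intensity" || reference$kind != "intensity")
    stop("to_absorbance expects intensity spectra", call. = FALSE)
  if (!same_grid(sample$grid, reference$grid))
    stop("sample and reference grids differ", call. = FALSE)
  if (any(sample$values <= 0) || any(reference$values <= 0))
    stop("nonpositive intensity value (saturated or dark pixel?)",
         call. = FALSE)
  spectrum(sample$grid, log10(reference$values / sample$values),
           kind = "absorbance", meta = sample$meta)
}

#' @param set a `spectra_set` of kind `intensity`.
#' @param references either one reference `spectrum` for all rows, or a named
#'   list of reference spectra keyed by configuration (per-configuration
#'   reference scans).
#' @rdname to_absorbance
#' @export
to_absorbance_set <- function(set, references) {
  stopifnot(inherits(set, "spectra_set"), set$kind == "intensity")
  get_ref <- function(cfg) {
    if (inherits(references, "spectrum")) return(references)
    r <- references[[cfg]]
    if (is.null(r)) stop("no reference spectrum for configuration ", cfg,
                         call. = FALSE)
    r
  }
  out <- set$matrix
  for (i in seq_len(nrow(out))) {
    r <- get_ref(set$sample_table$configuration[i])
    if (!same_grid(set$grid, r$grid))
      stop("reference grid differs from set grid", call. = FALSE)
    if (any(out[i, ] <= 0) || any(r$values <= 0))
      stop("nonpositive intensity in row ", i, call. = FALSE)
    out[i, ] <- log10(r$values / out[i, ])
  }
  spectra_set(out, set$sample_table, set$grid, "absorbance")
}
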
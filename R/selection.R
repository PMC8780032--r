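#' Activated-wavelength selection from three evidence sources
#'
#' For each WAMACS band, pools candidate wavelengths from (a) local extrema
#' of the first PCA loadings within the selection window, (b) extrema of the
#' mean SNV+2D spectrum of each configuration, and (c) extrema of the SSC
#' difference spectra, then keeps the candidate of largest absolute
#' magnitude. Each source curve is standardized to unit maximum absolute
#' value before magnitudes are compared, so the choice is invariant to
#' positive rescaling of any one source and to the order sources are given.
#' Ties break toward the lower wavelength, then by source name.
#'
#' @param pca_model a [fit_pca()] result on the grid of the other sources.
#' @param mean_snv2d named list of `spectrum` objects (or numeric vectors),
#'   one mean SNV+2D spectrum per configuration.
#' @param diff_spectra list of difference `spectrum` objects (e.g. the
#'   Medium/High entries of [ssc_difference_spectra()] for each
#'   configuration); identically-zero curves are skipped.
#' @param n_pcs how many leading components contribute extrema (default 3).
#' @param window_nm window for the PCA-loading extrema (default 900-1020 nm).
#' @param bands band table, by default [wamacs_table()].
#' @return data.frame of class `activated_set` with columns `band_id`,
#'   `wavelength_nm`, `source` (`pca`, `snv2d` or `ssc_diff`) and
#'   `magnitude`; bands with no candidate are omitted with a warning.
#' @export
select_activated <- function(pca_model, mean_snv2d, diff_spectra,
                             n_pcs = 3L, window_nm = c(900, 1020),
                             bands = wamacs_table()) {
  stopifnot(inherits(pca_model, "pca_model"))
  grid <- pca_model$grid
  if (is.null(grid)) stop("pca_model carries no grid", call. = FALSE)
  wl <- grid$wavelengths

  curve_values <- function(x) {
    if (inherits(x, "spectrum")) {
      if (!same_grid(x$grid, grid))
        stop("all sources must share the PCA grid", call. = FALSE)
      x$values
    } else as.numeric(x)
  }

  candidates <- list()
  add_candidates <- function(v, src, window = NULL) {
    m <- max(abs(v))
    if (m == 0) return()                      # degenerate flat curve
    v <- v / m                                # unit max |value|
    use_wl <- wl; use_v <- v
    if (!is.null(window)) {
      sel <- wl >= window[1L] & wl <= window[2L]
      use_wl <- wl[sel]; use_v <- v[sel]
    }
    ex <- local_extrema(use_wl, use_v)
    if (nrow(ex)) {
      ex$source <- src
      candidates[[length(candidates) + 1L]] <<- ex
    }
  }

  for (j in seq_len(min(n_pcs, pca_model$n_components))) {
    # components explaining essentially no variance carry no signal, only
    # numerical noise in their loadings
    if (pca_model$explained_variance_pct[j] < 1e-6) next
    add_candidates(as.numeric(pca_model$loadings[j, ]), "pca", window_nm)
  }
  for (v in mean_snv2d) add_candidates(curve_values(v), "snv2d")
  for (v in diff_spectra) add_candidates(curve_values(v), "ssc_diff")

  if (!length(candidates))
    stop("no extremum candidates in any source: degenerate input",
         call. = FALSE)
  pool <- do.call(rbind, candidates)
  pool$band_id <- assign_band(pool$wavelength_nm)
  pool <- pool[!is.na(pool$band_id), , drop = FALSE]
  if (!nrow(pool))
    stop("no extremum candidate falls inside any WAMACS band", call. = FALSE)

  picks <- lapply(bands$band_id, function(b) {
    cand <- pool[pool$band_id == b, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand <- cand[order(-abs(cand$value), cand$wavelength_nm, cand$source), ,
                 drop = FALSE]
    data.frame(band_id = b,
               wavelength_nm = cand$wavelength_nm[1L],
               source = cand$source[1L],
               magnitude = abs(cand$value[1L]),
               stringsAsFactors = FALSE)
  })
  missing <- bands$band_id[vapply(picks, is.null, logical(1L))]
  if (length(missing))
    warning("no candidate wavelength for band(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  class(out) <- c("activated_set", class(out))
  out
}
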
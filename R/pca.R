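#' Principal components analysis of a spectra set
#'
#' Singular-value decomposition of the column-centered sample x wavelength
#' matrix. Loadings are the unit-norm right singular vectors; scores are the
#' centered data projected onto them; explained variance percentages come
#' from the squared singular values over all possible components. The sign
#' of each component is fixed deterministically: the loading element of
#' largest absolute value is made positive (ties to the lower wavelength),
#' removing the inherent sign ambiguity of the SVD.
#'
#' @param set a `spectra_set` (typically SNV+2D spectra) or a plain numeric
#'   matrix.
#' @param n_components number of components to retain (default 3).
#' @param center center columns before decomposition (default TRUE; pass
#'   FALSE only for pre-centered matrices).
#' @return An object of class `pca_model` with `loadings`
#'   (components x wavelengths), `scores` (samples x components),
#'   `explained_variance_pct` (all components), `n_components`, `center`
#'   (column means) and, when available, the `grid`.
#' @export
fit_pca <- function(set, n_components = 3L, center = TRUE) {
  grid <- NULL
  if (inherits(set, "spectra_set")) {
    grid <- set$grid
    x <- set$matrix
  } else {
    x <- as.matrix(set)
  }
  n <- nrow(x); p <- ncol(x)
  kmax <- min(n - 1L, p)
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be between 1 and min(samples - 1, wavelengths) = ",
         kmax, call. = FALSE)
  mu <- if (center) colMeans(x) else rep(0, p)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  d2 <- sv$d^2
  expl <- 100 * d2 / sum(d2)

  k <- n_components
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i <- which(abs(loadings[j, ]) == max(abs(loadings[j, ])))[1L]
    if (loadings[j, i] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- paste0("PC", seq_len(k))
  colnames(scores) <- paste0("PC", seq_len(k))
  if (!is.null(grid)) colnames(loadings) <- wavelength_colnames(grid$wavelengths)

  structure(list(loadings = loadings, scores = scores,
                 explained_variance_pct = expl,
                 n_components = k, center = mu, grid = grid),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components, explained variance: %s\n",
              x$n_components,
              paste(sprintf("%.2f%%",
                            x$explained_variance_pct[seq_len(x$n_components)]),
                    collapse = ", ")))
  invisible(x)
}

# Strict local extrema of v over wl; plateaus take the leftmost point.
local_extrema <- function(wl, v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_wl <- numeric(0); out_val <- numeric(0); out_sign <- integer(0)
  if (length(r$values) >= 3L) {
    for (j in 2:(length(r$values) - 1L)) {
      val <- r$values[j]
      if (val > r$values[j - 1L] && val > r$values[j + 1L]) {
        out_wl <- c(out_wl, wl[starts[j]]); out_val <- c(out_val, val)
        out_sign <- c(out_sign, 1L)
      } else if (val < r$values[j - 1L] && val < r$values[j + 1L]) {
        out_wl <- c(out_wl, wl[starts[j]]); out_val <- c(out_val, val)
        out_sign <- c(out_sign, -1L)
      }
    }
  }
  data.frame(wavelength_nm = out_wl, value = out_val, sign = out_sign)
}

#' Local extrema of a PCA loading within a wavelength window
#'
#' All strict local maxima and minima of the chosen component's loading
#' restricted to the window (default 900-1020 nm, the water-band region used
#' for wavelength identification), sorted by absolute value, descending;
#' ties resolve to the lower wavelength. Plateau extrema report their
#' leftmost point.
#'
#' @param model a [fit_pca()] result fitted on a `spectra_set`.
#' @param component component index (1-based, at most `n_components`).
#' @param window_nm length-2 numeric window; must intersect the grid.
#' @return data.frame with columns `wavelength_nm`, `value`, `sign`
#'   (+1 maximum, -1 minimum); zero rows if the loading is monotone there.
#' @export
loading_extrema <- function(model, component, window_nm = c(900, 1020)) {
  stopifnot(inherits(model, "pca_model"))
  if (component < 1L || component > model$n_components)
    stop("component must be between 1 and ", model$n_components,
         call. = FALSE)
  if (is.null(model$grid))
    stop("model was fitted without a grid; extrema need wavelengths",
         call. = FALSE)
  wl <- model$grid$wavelengths
  sel <- wl >= window_nm[1L] & wl <= window_nm[2L]
  if (!any(sel))
    stop("window [", window_nm[1L], ", ", window_nm[2L],
         "] nm lies outside the grid", call. = FALSE)
  ex <- local_extrema(wl[sel], as.numeric(model$loadings[component, sel]))
  ex[order(-abs(ex$value), ex$wavelength_nm), , drop = FALSE]
}
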
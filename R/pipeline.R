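#' Run configuration for the full analysis pipeline
#'
#' A single structured configuration driving simulate/load -> absorbance ->
#' SNV -> SNV+2D -> PCA -> activated-wavelength selection -> aquagrams.
#'
#' @param design a [simulation_design()] (the usual input; set `input_csv`
#'   instead to load measured intensity spectra plus references).
#' @param input_csv optional path to a wide intensity CSV (see
#'   [read_spectra_csv()]); `reference_csv` must then also be given.
#' @param reference_csv optional path to a wide CSV of per-configuration
#'   reference scans.
#' @param plan a [preprocess_plan()]; the default SNV + 2D chain.
#' @param n_components PCA components to fit and use for selection.
#' @param selection_window_nm window for PCA-loading extrema.
#' @param selection how activated wavelengths are chosen: `"data"` (three
#'   evidence sources, [select_activated()]) or `"published"` (the
#'   literature wavelengths, [published_activated_wavelengths()]).
#' @param negate_2d aquagram display sign flip (see
#'   [aquagram_by_configuration()]).
#' @param out_dir output directory for the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(design = simulation_design(),
                       input_csv = NULL, reference_csv = NULL,
                       plan = preprocess_plan(),
                       n_components = 3L,
                       selection_window_nm = c(900, 1020),
                       selection = c("data", "published"),
                       negate_2d = TRUE,
                       out_dir = tempfile("aquapolar_run_")) {
  selection <- match.arg(selection)
  if (is.null(design) && is.null(input_csv))
    stop("config needs either a simulation design or an input_csv",
         call. = FALSE)
  if (!is.null(input_csv) && is.null(reference_csv))
    stop("input_csv requires reference_csv", call. = FALSE)
  if (!is.null(design)) stopifnot(inherits(design, "simulation_design"))
  stopifnot(inherits(plan, "preprocess_plan"))
  structure(list(design = design, input_csv = input_csv,
                 reference_csv = reference_csv, plan = plan,
                 n_components = as.integer(n_components),
                 selection_window_nm = selection_window_nm,
                 selection = selection, negate_2d = isTRUE(negate_2d),
                 out_dir = out_dir),
            class = "run_config")
}

.write_table <- function(df, path, digits = 12) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- sprintf(paste0("%.", digits, "g"),
                                                df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Execute a configured pipeline run
#'
#' Runs every stage in order, writing spectra at each processing stage, PCA
#' outputs, the activated-wavelength table, aquagram profile CSVs and radar
#' PNGs, and a machine-readable manifest into the configured output
#' directory. Identical configuration and seed give identical numeric
#' outputs (byte-identical CSVs). Stage failures abort with the stage name.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`sim`,
#'   `absorbance`, `snv2d`, `pca`, `activated`, `std`, `profiles_config`,
#'   `profiles_ssc`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  sim <- NULL
  if (!is.null(config$input_csv)) {
    spectra <- .stage("load", read_spectra_csv(config$input_csv))
    refset <- .stage("load", read_spectra_csv(config$reference_csv))
    references <- stats::setNames(
      lapply(seq_len(nrow(refset$matrix)), set_spectrum, set = refset),
      refset$sample_table$configuration)
  } else {
    sim <- .stage("simulate", simulate_population(config$design))
    spectra <- sim$spectra
    references <- sim$references
    .stage("simulate", {
      write_spectra_csv(spectra, file.path(out, "spectra_intensity.csv"))
      .write_table(sim$truth, file.path(out, "ground_truth.csv"), 17)
    })
  }

  absorbance <- .stage("absorbance",
                       to_absorbance_set(spectra, references))
  snv2d <- .stage("preprocess", run_plan(absorbance, config$plan))
  .stage("preprocess", {
    write_spectra_csv(absorbance, file.path(out, "spectra_absorbance.csv"))
    write_spectra_csv(snv2d, file.path(out, "spectra_snv2d.csv"))
  })

  pca <- .stage("pca", fit_pca(snv2d, config$n_components))
  .stage("pca", {
    .write_table(data.frame(component = paste0("PC",
                              seq_along(pca$explained_variance_pct)),
                            explained_variance_pct =
                              pca$explained_variance_pct),
                 file.path(out, "pca_variance.csv"))
    lo <- as.data.frame(t(pca$loadings))
    lo <- cbind(wavelength_nm = snv2d$grid$wavelengths, lo)
    .write_table(lo, file.path(out, "pca_loadings.csv"))
    sc <- cbind(snv2d$sample_table, as.data.frame(pca$scores))
    .write_table(sc, file.path(out, "pca_scores.csv"))
    plot_scores(pca, snv2d$sample_table, file.path(out, "pca_scores.png"))
    plot_loadings(pca, file.path(out, "pca_loadings.png"))
  })

  activated <- .stage("selection", {
    if (config$selection == "published") {
      published_activated_wavelengths()
    } else {
      mean_snv2d <- lapply(configurations(), function(cfg) {
        colMeans(snv2d$matrix[snv2d$sample_table$configuration == cfg, ,
                              drop = FALSE])
      })
      names(mean_snv2d) <- configurations()
      diffs <- unlist(lapply(configurations(), function(cfg) {
        d <- ssc_difference_spectra(
          subset_samples(snv2d, snv2d$sample_table$configuration == cfg))
        d[c("Medium", "High")]
      }), recursive = FALSE)
      select_activated(pca, mean_snv2d, diffs,
                       n_pcs = config$n_components,
                       window_nm = config$selection_window_nm)
    }
  })
  .stage("selection",
         .write_table(as.data.frame(activated),
                      file.path(out, "activated_wavelengths.csv")))

  std <- .stage("aquagram", relative_snv(aquagram_input(snv2d, activated)))
  prof_cfg <- .stage("aquagram",
                     aquagram_by_configuration(std,
                                               negate_2d = config$negate_2d))
  prof_ssc <- .stage("aquagram", {
    res <- lapply(configurations(), function(cfg) {
      p <- aquagram_by_ssc_group(std, configuration = cfg,
                                 negate_2d = config$negate_2d)
      p$configuration <- cfg
      p
    })
    do.call(rbind, res)
  })
  .stage("aquagram", {
    out_cfg <- as.data.frame(prof_cfg)
    out_cfg$negate_2d <- attr(prof_cfg, "negate_2d")
    .write_table(out_cfg, file.path(out, "aquagram_by_configuration.csv"))
    out_ssc <- as.data.frame(prof_ssc)
    out_ssc$negate_2d <- config$negate_2d
    .write_table(out_ssc, file.path(out, "aquagram_by_ssc_group.csv"))
    render_aquagram(prof_cfg, file.path(out, "aquagram_configurations.png"),
                    title = "Aquagram by configuration")
    for (cfg in configurations()) {
      p <- prof_ssc[prof_ssc$configuration == cfg,
                    c("group", "band_id", "value")]
      class(p) <- c("aquagram_profiles", "data.frame")
      render_aquagram(p, file.path(out, sprintf("aquagram_ssc_%s.png", cfg)),
                      title = sprintf("Aquagram by SSC group (%s)", cfg))
    }
  })

  .stage("manifest", {
    cfg_yaml <- file.path(out, "run_config.yaml")
    yaml::write_yaml(config_to_list(config), cfg_yaml)
    manifest <- list(
      package = "aquapolar",
      version = as.character(utils::packageVersion("aquapolar")),
      seed = if (!is.null(config$design)) config$design$seed else NA,
      n_samples = nrow(spectra$matrix),
      config_md5 = unname(tools::md5sum(cfg_yaml)),
      selection = config$selection,
      negate_2d = config$negate_2d,
      files = sort(list.files(out))
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(sim = sim, absorbance = absorbance, snv2d = snv2d,
                 pca = pca, activated = activated, std = std,
                 profiles_config = prof_cfg, profiles_ssc = prof_ssc,
                 out_dir = out))
}

config_to_list <- function(config) {
  d <- config$design
  list(
    design = if (is.null(d)) NULL else list(
      n_fruit = d$n_fruit, grid = c(d$grid$start_nm, d$grid$stop_nm,
                                    d$grid$step_nm),
      ssc_low = d$ssc_low, ssc_high = d$ssc_high, noise_sd = d$noise_sd,
      n_scans = d$n_scans, depol_surface_weight = d$depol_surface_weight,
      copol_fraction = d$copol_fraction,
      effect_matrix = as.vector(d$effect_matrix),
      ssc_shift_rate = d$ssc_shift_rate,
      skin_scatter_mean = d$skin_scatter_mean, seed = d$seed),
    input_csv = config$input_csv,
    plan = unclass(config$plan),
    n_components = config$n_components,
    selection_window_nm = config$selection_window_nm,
    selection = config$selection,
    negate_2d = config$negate_2d
  )
}

#' Summarise a completed run directory
#'
#' Reads the manifest and the run's CSV outputs and writes `summary.csv`
#' (per-configuration mean aquagram value by band, wide) and `summary.txt`
#' (PCA variance percentages and selection provenance). Regenerating the
#' summary from the same directory is byte-identical.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return Invisibly, the summary data.frame.
#' @export
pipeline_report <- function(run_dir) {
  need <- c("manifest.json", "aquagram_by_configuration.csv",
            "pca_variance.csv", "activated_wavelengths.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run directory; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  aq <- utils::read.csv(file.path(run_dir, "aquagram_by_configuration.csv"))
  pv <- utils::read.csv(file.path(run_dir, "pca_variance.csv"))
  act <- utils::read.csv(file.path(run_dir, "activated_wavelengths.csv"))

  wide <- stats::reshape(aq[, c("group", "band_id", "value")],
                         direction = "wide", idvar = "band_id",
                         timevar = "group")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(match(wide$band_id, paste0("C", 1:12))), , drop = FALSE]
  rownames(wide) <- NULL
  .write_table(wide, file.path(run_dir, "summary.csv"))

  txt <- c(
    sprintf("aquapolar run summary (seed %s, %s samples)",
            manifest$seed, manifest$n_samples),
    "",
    "PCA explained variance (%):",
    sprintf("  %s: %.2f", pv$component[seq_len(min(5L, nrow(pv)))],
            pv$explained_variance_pct[seq_len(min(5L, nrow(pv)))]),
    "",
    "Activated wavelengths:",
    sprintf("  %s: %g nm (%s)", act$band_id, act$wavelength_nm, act$source)
  )
  writeLines(txt, file.path(run_dir, "summary.txt"))
  invisible(wide)
}

# Score / loading diagnostic plots (cairo PNG, deterministic).
plot_scores <- function(pca, sample_table, path) {
  cfg <- factor(sample_table$configuration, levels = configurations())
  cols <- c("#d62728", "#1f77b4", "#e377c2", "#17becf")
  grDevices::png(path, width = 800, height = 700, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(pca$scores[, 1L], pca$scores[, 2L],
                 col = cols[as.integer(cfg)], pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", pca$explained_variance_pct[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", pca$explained_variance_pct[2L]),
                 main = "PCA scores by configuration")
  graphics::legend("topright", legend = levels(cfg), col = cols, pch = 16,
                   bty = "n")
}

plot_loadings <- function(pca, path) {
  wl <- pca$grid$wavelengths
  grDevices::png(path, width = 900, height = 600, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  k <- pca$n_components
  graphics::matplot(wl, t(pca$loadings), type = "l", lty = 1,
                    col = seq_len(k) + 1L,
                    xlab = "wavelength (nm)", ylab = "loading",
                    main = "PCA loadings")
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topleft", legend = rownames(pca$loadings),
                   col = seq_len(k) + 1L, lty = 1, bty = "n")
}
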
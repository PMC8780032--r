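#!/usr/bin/env Rscript
# Activated-wavelength selection: pool extrema from (a) the PCA loadings,
# (b) the mean SNV+2D spectrum of each configuration and (c) the SSC
# difference spectra, keep the strongest candidate inside each WAMACS band,
# and compare the data-driven picks with the published positions.

library(aquapolar)

out <- "results/analysis"
snv2d <- read_spectra_csv(file.path(out, "spectra_snv2d.csv"))
pca <- fit_pca(snv2d, n_components = 3L)

mean_snv2d <- lapply(configurations(), function(cfg)
  colMeans(snv2d$matrix[snv2d$sample_table$configuration == cfg, ,
                        drop = FALSE]))
names(mean_snv2d) <- configurations()

diffs <- unlist(lapply(configurations(), function(cfg) {
  d <- ssc_difference_spectra(
    subset_samples(snv2d, snv2d$sample_table$configuration == cfg))
  d[c("Medium", "High")]
}), recursive = FALSE)

activated <- select_activated(pca, mean_snv2d, diffs)
utils::write.csv(as.data.frame(activated),
                 file.path(out, "activated_wavelengths.csv"),
                 row.names = FALSE)

pub <- published_activated_wavelengths()
cmp <- merge(as.data.frame(activated)[, c("band_id", "wavelength_nm",
                                          "source")],
             pub[, c("band_id", "wavelength_nm")],
             by = "band_id", suffixes = c("_selected", "_published"))
cmp <- cmp[order(match(cmp$band_id, paste0("C", 1:12))), ]
cat("Activated wavelengths (data-driven vs published):\n")
print(cmp, row.names = FALSE)
cat(sprintf("%d of %d selected wavelengths fall within %g nm of the published position.\n",
            sum(abs(cmp$wavelength_nm_selected -
                      cmp$wavelength_nm_published) <= 6),
            nrow(cmp), 6))
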
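#!/usr/bin/env Rscript
# Principal components analysis of the SNV+2D spectra: explained variance,
# score separation of the polarized vs unpolarized configurations, and
# loading extrema in the 900-1020 nm water-band window.

library(aquapolar)

out <- "results/analysis"
snv2d <- read_spectra_csv(file.path(out, "spectra_snv2d.csv"))

pca <- fit_pca(snv2d, n_components = 3L)
utils::write.csv(data.frame(component = paste0("PC", 1:3),
                            explained_variance_pct =
                              pca$explained_variance_pct[1:3]),
                 file.path(out, "pca_variance.csv"), row.names = FALSE)
utils::write.csv(cbind(snv2d$sample_table, as.data.frame(pca$scores)),
                 file.path(out, "pca_scores.csv"), row.names = FALSE)
lo <- cbind(wavelength_nm = wavelengths(snv2d$grid),
            as.data.frame(t(pca$loadings)))
utils::write.csv(lo, file.path(out, "pca_loadings.csv"), row.names = FALSE)

cat(sprintf("Explained variance: PC1 %.2f%%, PC2 %.2f%%, PC3 %.2f%% (cumulative %.1f%%).\n",
            pca$explained_variance_pct[1], pca$explained_variance_pct[2],
            pca$explained_variance_pct[3],
            sum(pca$explained_variance_pct[1:3])))

pol <- substr(snv2d$sample_table$configuration, 2, 2) == "P"
s1 <- pca$scores[, 1]
thr <- (mean(s1[pol]) + mean(s1[!pol])) / 2
mis <- min(mean((s1 > thr) != pol), mean((s1 > thr) == pol))
cat(sprintf("PC1 separates polarized from unpolarized configurations (%.1f%% overlap at the midpoint threshold).\n",
            100 * mis))

for (j in 1:3) {
  ex <- loading_extrema(pca, j)
  top <- utils::head(ex, 4)
  cat(sprintf("PC%d extrema (900-1020 nm, strongest first): %s\n", j,
              paste(sprintf("%g nm (%s)", top$wavelength_nm,
                            ifelse(top$sign > 0, "max", "min")),
                    collapse = ", ")))
}
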
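#!/usr/bin/env Rscript
# Phenotypic variation among the taxa: traditional descriptors (log
# length, log width, cell count) with Kruskal-Wallis and pairwise
# Wilcoxon tests; shape space via landmark-anchored Procrustes
# normalization, elliptic Fourier coefficients with the 95% harmonic
# power retention rule, PCA with the unknowns reprojected as
# supplementary individuals, permutational MANOVA, per-taxon mean
# shapes, and the UPGMA tree. Requires analysis/01_simulate.R output.

library(seedmorph)

read_pop <- function(dir) {
  masks <- list.files(file.path(dir, "masks"), pattern = "\\.png$",
                      full.names = TRUE)
  ids <- tools::file_path_sans_ext(basename(masks))
  list(records = read_descriptors(file.path(dir, "records.csv")),
       landmarks = read_landmarks(file.path(dir, "landmarks.csv")),
       masks = setNames(masks, ids))
}
modern <- read_pop("results/data/modern")
arch <- read_pop("results/data/archaeological")

records <- rbind(modern$records, arch$records)
landmarks <- c(modern$landmarks, arch$landmarks)
masks <- c(modern$masks, arch$masks)

message("tracing and normalising ", nrow(records), " outlines ...")
outs <- lapply(masks[records$id], extract_outline, scale = 0.01)
sizes <- t(vapply(outs, bounding_box_size, numeric(2)))
records$log_length <- log(sizes[records$id, 1])
records$log_width <- log(sizes[records$id, 2])

res <- mapply(function(o, l) resample_outline(o, 360, start = unclass(l)[2, ],
                                              check = FALSE),
              outs, landmarks[records$id], SIMPLIFY = FALSE)
ali <- gpa_align(res, landmarks[records$id])
cfs <- lapply(ali$outlines, efourier, H = 8)
sel <- choose_harmonics(cfs, 0.95)
cat(sprintf("retained H* = %d harmonics (mean cumulative power %.3f)\n",
            sel$H_star, sel$mean_cumulative[sel$H_star]))
coeffs <- coeff_matrix(cfs, H = sel$H_star)
write_coefficients(coeffs, "results/coefficients.csv")

modern_idx <- records$taxon != "unknown"
grp <- interaction(records$taxon[modern_idx], records$accession[modern_idx],
                   drop = TRUE)

# univariate descriptors
for (v in c("log_length", "log_width", "cells")) {
  kw <- kruskal_wallis(records[[v]][modern_idx], grp)
  cat(sprintf("Kruskal-Wallis %-10s chi2 = %7.2f, df = %d, p = %.3g\n",
              v, kw$chi2, kw$df, kw$p))
  W <- pairwise_wilcoxon(records[[v]][modern_idx], grp)
  write.csv(W, sprintf("results/wilcoxon_%s.csv", v))
}

# shape ordination with supplementary unknowns
pca <- pca_fit(coeffs[records$id[modern_idx], ])
supp <- pca_project(pca, coeffs[records$id[!modern_idx], ])
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% (together %.1f%%)\n",
            100 * pca$explained[1], 100 * pca$explained[2],
            100 * sum(pca$explained[1:2])))
scores <- rbind(
  data.frame(id = records$id[modern_idx], taxon = records$taxon[modern_idx],
             is_supplementary = FALSE, pca$scores[, 1:2]),
  data.frame(id = records$id[!modern_idx], taxon = "unknown",
             is_supplementary = TRUE, supp[, 1:2]))
write.csv(scores, "results/pca_scores.csv", row.names = FALSE)

pm <- permutational_manova(coeffs[records$id[modern_idx], ],
                           records$taxon[modern_idx], n_perm = 999, seed = 99)
cat(sprintf("perMANOVA: df = %d, F = %.3f, adj r2 = %.3f, p = %.3g\n",
            pm$df_between, pm$F, pm$adj_r2, pm$p))

# mean shapes and UPGMA tree
ms <- mean_shapes(coeffs[records$id[modern_idx], ], records$taxon[modern_idx])
tree <- upgma_tree(ms$coeffs, newick_file = "results/upgma.nwk")
cat("UPGMA tree written to results/upgma.nwk:\n")
cat(ape::write.tree(tree), "\n")

pdf("results/morphospace.pdf", width = 9, height = 4.5)
par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
taxa <- sort(unique(records$taxon[modern_idx]))
cols <- setNames(grDevices::hcl.colors(length(taxa), "Dark 3"), taxa)
plot(scores$PC1, scores$PC2, col = ifelse(scores$is_supplementary, "red",
     cols[scores$taxon]), pch = ifelse(scores$is_supplementary, 4, 16),
     cex = 0.6, xlab = sprintf("PC1 (%.0f%%)", 100 * pca$explained[1]),
     ylab = sprintf("PC2 (%.0f%%)", 100 * pca$explained[2]),
     main = "Shape space (red x = unknowns)")
plot(ape::as.phylo(tree), type = "unrooted", main = "UPGMA on mean shapes",
     cex = 0.8)
dev.off()
cat("figures written to results/morphospace.pdf\n")
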
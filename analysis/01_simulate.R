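#!/usr/bin/env Rscript
# Generate the synthetic study material: the modern reference collection
# (seven Papaver-like taxa x 30 seeds, plus a second 30-seed accession of
# setigerum and of somniferum), and 33 "archaeological" unknowns drawn
# half and half from the setigerum and somniferum models. Seeds are
# rendered to binary masks at 100 px/mm and auto-landmarked; everything
# is written under results/data/ as PNG + CSV for the later steps.

library(seedmorph)

out <- "results/data"
seed <- 42

models <- default_taxon_models(separation = 1)
modern_models <- c(models,
                   list(setigerum_b = accession_variant(models$setigerum),
                        somniferum_b = accession_variant(models$somniferum)))
noise <- function(s) noise_spec(rotation_sd = 0.08, outline_jitter_sd = 0.004,
                                landmark_jitter_sd = 0.008, seed = s)

message("simulating the modern reference collection ...")
modern <- simulate_population(modern_models, noise(seed),
                              out_dir = file.path(out, "modern"))

message("simulating the archaeological-style unknowns ...")
unk_models <- list(u1 = models$setigerum, u2 = models$somniferum)
unk_models$u1$n_seeds <- 17L; unk_models$u2$n_seeds <- 16L
unk_models$u1$accession <- unk_models$u2$accession <- "arch"
unknown <- simulate_population(unk_models, noise(seed + 1),
                               taxon_label = "unknown",
                               out_dir = file.path(out, "archaeological"))

cat(sprintf("modern: %d seeds in %d taxa (%d accessions)\n",
            nrow(modern$records), length(unique(modern$records$taxon)),
            nrow(unique(modern$records[c("taxon", "accession")]))))
cat(sprintf("unknown: %d seeds (truth: %s)\n", nrow(unknown$records),
            paste(table(unknown$records$true_taxon), collapse = "/")))
cat("masks, landmarks.csv and records.csv written under", out, "\n")
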
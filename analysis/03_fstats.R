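#!/usr/bin/env Rscript
# Stage 3: f-statistics.
#
# Population allele frequencies, the pairwise f2 matrix with block-
# jackknife errors, the three-population admixture scan (which should
# flag only the simulated hybrid), the f4 backcrossing table with the
# outgroup in first position, the f4-ratio admixture proportion, and a
# PCA summary.

library(introkit)

gm <- read_vcf("scratch/data/filtered.vcf")
gm <- assign_pseudochromosomes(gm, 10)
popmap <- read_population_map("scratch/data/popmap.tsv")
aft <- allele_frequencies(gm, popmap)
blocks <- make_blocks(gm, 50)

f2m <- f2_matrix(aft, blocks, corrected = TRUE)
write.table(round(f2m$estimate, 8), "results/f2_matrix.tsv", sep = "\t",
            quote = FALSE)

scan <- three_pop_scan(aft, blocks, z_threshold = 3)
write.table(scan, "results/f3_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
flagged <- unique(scan$target[scan$admixed])
message("f3 scan flags: ", paste(flagged, collapse = ", "))

rows <- list()
for (hyb in flagged) {
  sources <- setdiff(aft$pops, c("Outgroup", hyb))
  prs <- combn(sources, 2)
  for (k in seq_len(ncol(prs))) {
    est <- f4(aft, "Outgroup", hyb, prs[1, k], prs[2, k], blocks)
    rows[[length(rows) + 1]] <- data.frame(
      W = "Outgroup", X = hyb, Y = prs[1, k], Z = prs[2, k],
      f4 = est$estimate, stderr = est$stderr, z = est$z)
  }
}
f4_tab <- do.call(rbind, rows)
write.table(f4_tab, "results/f4_statistics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fr <- f4_ratio_alpha(aft, "Outgroup", "NPC", "East", "Hybrid", "Beringia",
                     blocks)
message(sprintf("f4-ratio alpha (East share of Hybrid): %.3f +/- %.3f",
                fr$alpha, fr$stderr))
write.table(data.frame(alpha = fr$alpha, stderr = fr$stderr, z = fr$z,
                       n_sites = fr$n_sites),
            "results/f4_ratio_alpha.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pc <- pca_genotypes(gm, n_components = 4)
coords <- data.frame(sample = rownames(pc$coords),
                     population = popmap[rownames(pc$coords)],
                     pc$coords)
write.table(coords, "results/pca_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * pc$explained[1], 100 * pc$explained[2]))
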
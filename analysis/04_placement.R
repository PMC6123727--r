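#!/usr/bin/env Rscript
# Stage 4: admixture-graph placement of the flagged hybrid.
#
# Builds a neighbour-joining backbone from the corrected f2 distances of
# the non-admixed populations, enumerates every pair of backbone edges
# as candidate attachment points for the hybrid, fits drifts and the
# admixture proportion for each, and bootstraps the best placement's
# mixed drift over SNP blocks.

library(introkit)

gm <- read_vcf("scratch/data/filtered.vcf")
gm <- assign_pseudochromosomes(gm, 10)
popmap <- read_population_map("scratch/data/popmap.tsv")
aft <- allele_frequencies(gm, popmap)
blocks <- make_blocks(gm, 50)
f2m <- f2_matrix(aft, blocks, corrected = TRUE)

backbone_pops <- c("Outgroup", "West", "East", "Beringia", "NPC")
d <- as.dist(f2m$estimate[backbone_pops, backbone_pops])
phy <- ape::root(ape::nj(d), "Outgroup", resolve.root = TRUE)
backbone <- free_graph_params(phylo_to_graph(phy))

pl <- enumerate_hybrid_placements(backbone, "Hybrid", f2m$estimate,
                                  f2m$stderr)
write.table(pl, "results/placements.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf(
  "best placement: (%s | %s), alpha %.3f (fraction from the first edge), score %.1f",
  pl$edge1[1], pl$edge2[1], pl$alpha[1], pl$score[1]))

bs <- block_f2_sums(aft, blocks, corrected = TRUE)
bo <- bootstrap_mixed_drift(bs, attr(pl, "fits")[[1]]$topology, "Hybrid",
                            n_boot = 1000, seed = 1, f2_se = f2m$stderr)
out <- rbind(mixed_drift_f2 = bo$mixed_drift, alpha = bo$alpha)
write.table(data.frame(quantity = rownames(out), out),
            "results/mixed_drift.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("mixed drift (f2 units): %.5f [%.5f, %.5f]",
                bo$mixed_drift["estimate"], bo$mixed_drift["lower"],
                bo$mixed_drift["upper"]))
message(sprintf("alpha: %.3f [%.3f, %.3f]", bo$alpha["estimate"],
                bo$alpha["lower"], bo$alpha["upper"]))

# heterozygosity of the hybrid, needed by stage 5 to move the f2-unit
# drift onto the dimensionless scale of the dating formula
p <- aft$p[, "Hybrid"]; nn <- aft$n[, "Hybrid"]
ok <- !is.na(p) & nn >= 2
h <- mean(p[ok] * (1 - p[ok]) * nn[ok] / (nn[ok] - 1))
write.table(data.frame(population = "Hybrid", het = h),
            "results/hybrid_het.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
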
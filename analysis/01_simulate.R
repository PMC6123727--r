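#!/usr/bin/env Rscript
# Stage 1: simulate the study dataset.
#
# The default refugial scenario: an outgroup, four refugial lineages
# (West deeply divergent; Beringia and NPC sisters, NPC bottlenecked;
# East), and one hybrid population drawing 60% of its ancestry from the
# East lineage and 40% from Beringia, with a small post-admixture
# (mixed) drift of F = 0.02. Emits a VCF + population map (large, under
# scratch/) and the ground truth (under results/).

library(introkit)

seed <- 1
n_sites <- 1e5
dir.create("scratch/data", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

mod <- make_refugial_scenario()
st <- simulate_study(mod, n_sites = n_sites, seed = seed)

write_vcf(st$gm, "scratch/data/study.vcf")
write_population_map(st$popmap, "scratch/data/popmap.tsv")
write_graph(mod$graph, "results/truth_graph.tsv")
jsonlite::write_json(
  list(seed = seed, n_sites = n_sites, alpha = 0.6, hybrid_drift_F = 0.02,
       sample_sizes = as.list(mod$sample_sizes),
       true_mixed_drift_f2 = st$truth$f2_graph$edges$drift[
         st$truth$f2_graph$edges$child == "Hybrid"]),
  "results/truth.json", auto_unbox = TRUE, digits = NA)

message(sprintf("simulated %d sites x %d samples (seed %d)",
                n_sites(st$gm), length(st$gm$samples), seed))
message("wrote scratch/data/study.vcf, scratch/data/popmap.tsv, results/truth_graph.tsv")
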
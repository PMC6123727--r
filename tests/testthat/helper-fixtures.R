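# Shared fixtures built in code at test time.

# tiny 3-sample, 4-record VCF with DP/GQ; GT strings chosen to exercise
# hom/het/missing/half-missing parsing
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Quality">',
    "##contig=<ID=scafA,length=2000000>",
    "##contig=<ID=scafB,length=500000>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "scafA\t100\t.\tA\tT\t50\tPASS\t.\tGT:DP:GQ\t0/0:10:60\t0/1:12:55\t1/1:9:70",
    "scafA\t250\t.\tG\tC\t50\tPASS\t.\tGT:DP:GQ\t0|1:8:40\t./.:.:.\t0/0:11:80",
    "scafA\t400\t.\tT\tA\t50\tPASS\t.\tGT:DP:GQ\t1/.:7:33\t1/1:13:90\t0/1:6:45",
    "scafB\t120\t.\tC\tG\t50\tPASS\t.\tGT:DP:GQ\t0/1:9:50\t0/0:10:66\t0/0:12:71")
  writeLines(lines, path)
  path
}

# dosages a hand-reading of the toy VCF GT fields must produce
toy_vcf_dosages <- function() {
  matrix(c(0, 1, 2,
           1, NA, 0,
           NA, 2, 1,
           1, 0, 0),
         nrow = 4, byrow = TRUE, dimnames = list(NULL, c("S1", "S2", "S3")))
}

# genotype matrix straight from a dosage matrix, sites every 100 bp
gm_from_dosage <- function(dosage, chrom = "chr1", pos = NULL,
                           scaffold_lengths = NULL) {
  n <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(n) * 100 - 99
  samples <- colnames(dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(dosage)))
  sites <- data.frame(chrom = rep(chrom, length.out = n), pos = pos,
                      ref = "A", alt = "T", is_indel = FALSE,
                      is_multi = FALSE)
  genotype_matrix(dosage, sites, samples,
                  scaffold_lengths = scaffold_lengths)
}

# the study-condition simulations are reused by several expensive tests;
# cache them per (seed, n_sites) within one test run
.study_cache <- new.env(parent = emptyenv())
cached_study <- function(seed, n_sites = 1e5) {
  key <- sprintf("s%d_n%d", seed, n_sites)
  if (is.null(.study_cache[[key]])) {
    mod <- make_refugial_scenario()
    st <- simulate_study(mod, n_sites = n_sites, seed = seed)
    st$aft <- allele_frequencies(st$gm, st$popmap)
    st$blocks <- make_blocks(st$gm, 50)
    st$model <- mod
    .study_cache[[key]] <- st
  }
  .study_cache[[key]]
}

# the true (admixture-free) backbone of the refugial scenario, free drifts
refugial_backbone <- function() {
  admixture_graph(data.frame(
    child  = c("Outgroup", "anc0", "West", "anc1", "East", "anc2",
               "Beringia", "NPC"),
    parent = c("root", "root", "anc0", "anc0", "anc1", "anc1",
               "anc2", "anc2"),
    drift  = NA_real_))
}
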
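#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT into alternate-allele dosages (half-missing calls such as
#' `1/.` become missing; any allele other than 0/1 marks the record
#' multiallelic, to be removed by [apply_site_filters()]). DP and GQ FORMAT
#' fields are carried along when present so per-call depth/quality masking
#' can be applied later.
#'
#' @param path VCF file, plain or bgzipped.
#' @param sample_subset optional character vector; restrict to these samples
#'   (error if any is absent).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  n_rec <- nrow(v@gt)
  all_samples <- colnames(v@gt)[-1]
  if (is.null(sample_subset)) sample_subset <- all_samples
  absent <- setdiff(sample_subset, all_samples)
  if (length(absent))
    stop("sample(s) not in VCF: ", paste(absent, collapse = ", "))

  if (is.null(n_rec) || n_rec == 0) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        is_indel = logical(0), is_multi = logical(0))
    return(genotype_matrix(matrix(NA_integer_, 0, length(sample_subset)),
                           sites, sample_subset))
  }

  fix <- matrix(fix, nrow = n_rec, dimnames = dimnames(fix))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  is_multi <- grepl(",", alt, fixed = TRUE)
  alt_lens <- vapply(strsplit(alt, ",", fixed = TRUE),
                     function(a) max(nchar(a)), integer(1))
  is_indel <- nchar(ref) != 1L | (alt != "." & alt_lens != 1L)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(gt, nrow = n_rec, dimnames = dimnames(gt))
  gt <- gt[, sample_subset, drop = FALSE]
  parsed <- parse_gt(gt)
  dosage <- parsed$dosage
  # non 0/1 alleles: dosage undefined, record flagged multiallelic
  is_multi <- is_multi | parsed$nonbiallelic_row

  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  dp <- gq <- NULL
  if ("DP" %in% fmt) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    dp <- matrix(dp, nrow = n_rec,
                 dimnames = list(NULL, all_samples))[, sample_subset,
                                                     drop = FALSE]
  }
  if ("GQ" %in% fmt) {
    gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
    gq <- matrix(gq, nrow = n_rec,
                 dimnames = list(NULL, all_samples))[, sample_subset,
                                                     drop = FALSE]
  }

  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      is_indel = is_indel, is_multi = is_multi)
  ord <- order(match(chrom, unique(chrom)), pos)
  if (any(ord != seq_along(ord))) {
    sites <- sites[ord, , drop = FALSE]; rownames(sites) <- NULL
    dosage <- dosage[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
    if (!is.null(gq)) gq <- gq[ord, , drop = FALSE]
  }
  genotype_matrix(dosage, sites, sample_subset, dp = dp, gq = gq)
}

# GT strings -> dosage; returns per-site flag for non-0/1 alleles
parse_gt <- function(gt) {
  u <- unique(as.vector(gt))
  u_clean <- gsub("|", "/", u, fixed = TRUE)
  dos <- rep(NA_integer_, length(u))
  nonbi <- rep(FALSE, length(u))
  for (i in seq_along(u)) {
    g <- u_clean[i]
    if (is.na(g) || g == "." || g == "./.") next
    al <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (!length(al) || !all(grepl("^(\\.|[0-9]+)$", al)))
      stop("malformed GT field: '", u[i], "'")
    if (any(al == ".")) next             # half-missing -> missing
    al <- as.integer(al)
    if (any(al > 1L)) { nonbi[i] <- TRUE; next }
    if (length(al) != 2L) stop("non-diploid GT field: '", u[i], "'")
    dos[i] <- sum(al)
  }
  m <- match(as.vector(gt), u)
  dosage <- matrix(dos[m], nrow = nrow(gt), dimnames = dimnames(gt))
  flag <- matrix(nonbi[m], nrow = nrow(gt))
  list(dosage = dosage, nonbiallelic_row = rowSums(flag, na.rm = TRUE) > 0)
}

#' Write a genotype matrix as a VCF
#'
#' Emits a minimal VCFv4.2 with GT (and DP/GQ when present). Dosage 0/1/2
#' maps to `0/0`, `0/1`, `1/1`; missing to `./.`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=introkit",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  has_dp <- !is.null(gm$dp); has_gq <- !is.null(gm$gq)
  if (has_dp) writeLines('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">', con)
  if (has_gq) writeLines('##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">', con)
  if (!is.null(gm$scaffold_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(gm$scaffold_lengths),
                       as.integer(gm$scaffold_lengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (n_sites(gm) > 0) {
    gt_map <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", n_sites(gm), length(gm$samples))
    ok <- !is.na(gm$dosage)
    gt[ok] <- gt_map[gm$dosage[ok] + 1L]
    fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
    cells <- gt
    if (has_dp) cells <- matrix(paste(cells, ifelse(is.na(gm$dp), ".", gm$dp), sep = ":"),
                                nrow = nrow(gt))
    if (has_gq) cells <- matrix(paste(cells, ifelse(is.na(gm$gq), ".", gm$gq), sep = ":"),
                                nrow = nrow(gt))
    lines <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                   gm$sites$alt, ".", "PASS", ".", fmt, sep = "\t")
    lines <- paste(lines, apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column TSV (sample, population), no header by default.
#'
#' @param path TSV file.
#' @param header does the file carry a header line?
#' @return named character vector: population label per sample.
#' @export
read_population_map <- function(path, header = FALSE) {
  tab <- utils::read.table(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  if (anyDuplicated(tab$sample))
    stop("duplicate sample(s) in population map")
  stats::setNames(tab$population, tab$sample)
}

#' Write a sample-to-population map
#' @param popmap named character vector (names are samples).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(popmap, path) {
  utils::write.table(data.frame(sample = names(popmap), population = popmap),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Site-filter configuration
#'
#' Defaults follow common resequencing practice for low-coverage genomes:
#' per-call masking at DP >= 2 and GQ >= 30, site-level minor allele
#' frequency >= 0.1 (removes singleton noise), scaffolds >= 1 Mb, indels
#' and private variants dropped, 1 SNP retained per 50 bp window, and 46
#' pseudo-chromosome groups.
#'
#' @param min_dp minimum per-call read depth; calls below are masked.
#' @param min_gq minimum per-call genotype quality; calls below are masked.
#' @param maf_min minimum minor allele frequency across all non-missing
#'   calls, pooled over samples; must be < 0.5.
#' @param max_missing_fraction maximum fraction of missing calls per site
#'   (after DP/GQ masking).
#' @param min_scaffold_length drop sites on scaffolds shorter than this (bp).
#' @param thin_window_bp window size for LD thinning (see [thin_by_window()]).
#' @param n_pseudochromosomes number of pseudo-chromosome groups (see
#'   [assign_pseudochromosomes()]).
#' @param drop_indels remove indel records?
#' @param drop_private_alleles remove sites whose minor allele is carried by
#'   a single sample?
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_dp = 2, min_gq = 30, maf_min = 0.1,
                          max_missing_fraction = 0.5,
                          min_scaffold_length = 1e6, thin_window_bp = 50,
                          n_pseudochromosomes = 46, drop_indels = TRUE,
                          drop_private_alleles = TRUE) {
  cfg <- list(min_dp = min_dp, min_gq = min_gq, maf_min = maf_min,
              max_missing_fraction = max_missing_fraction,
              min_scaffold_length = min_scaffold_length,
              thin_window_bp = thin_window_bp,
              n_pseudochromosomes = n_pseudochromosomes,
              drop_indels = drop_indels,
              drop_private_alleles = drop_private_alleles)
  with(cfg, stopifnot(min_dp >= 0, min_gq >= 0, maf_min >= 0, maf_min < 0.5,
                      max_missing_fraction >= 0, min_scaffold_length >= 0,
                      thin_window_bp >= 0, n_pseudochromosomes >= 1))
  structure(cfg, class = "filter_config")
}

#' Apply site filters
#'
#' In order: per-call DP/GQ masking; removal of multiallelic records and
#' (optionally) indels; per-site missingness; pooled minor allele
#' frequency; minimum scaffold length; (optionally) private alleles,
#' i.e. sites whose minor allele is observed in exactly one sample. Site
#' order is preserved and the operation is idempotent. A per-rule removal
#' count is attached as attribute `filter_report`.
#'
#' @param gm a `genotype_matrix`.
#' @param cfg a [filter_config()].
#' @return the filtered `genotype_matrix`; warns (does not error) when no
#'   site survives.
#' @export
apply_site_filters <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (n_sites(gm) == 0) return(gm)
  # per-call masking, VCFtools-style: drop the call, keep the site
  if (!is.null(gm$dp) && cfg$min_dp > 0)
    gm$dosage[!is.na(gm$dp) & gm$dp < cfg$min_dp] <- NA_integer_
  if (!is.null(gm$gq) && cfg$min_gq > 0)
    gm$dosage[!is.na(gm$gq) & gm$gq < cfg$min_gq] <- NA_integer_
  report <- c()
  keep <- rep(TRUE, n_sites(gm))

  drop_rule <- function(bad, rule) {
    newly <- keep & bad
    report[rule] <<- sum(newly)
    keep <<- keep & !bad
  }

  drop_rule(gm$sites$is_multi, "multiallelic")
  if (cfg$drop_indels) drop_rule(gm$sites$is_indel, "indel")

  n_samp <- length(gm$samples)
  n_called <- rowSums(!is.na(gm$dosage))
  drop_rule(1 - n_called / n_samp > cfg$max_missing_fraction, "missingness")

  alt_count <- rowSums(gm$dosage, na.rm = TRUE)
  n_copies <- 2 * n_called
  p <- ifelse(n_copies > 0, alt_count / n_copies, NA_real_)
  maf <- pmin(p, 1 - p)
  drop_rule(is.na(maf) | maf < cfg$maf_min, "maf")

  len <- scaffold_length_table(gm)
  drop_rule(len[gm$sites$chrom] < cfg$min_scaffold_length, "scaffold_length")

  if (cfg$drop_private_alleles) {
    minor_is_alt <- !is.na(p) & p <= 0.5
    alt_carriers <- rowSums(gm$dosage > 0, na.rm = TRUE)
    ref_carriers <- rowSums(gm$dosage < 2, na.rm = TRUE)
    carriers <- ifelse(minor_is_alt, alt_carriers, ref_carriers)
    drop_rule(carriers == 1, "private")
  }

  out <- subset_sites(gm, keep)
  attr(out, "filter_report") <-
    data.frame(rule = names(report), removed = as.integer(report),
               row.names = NULL)
  if (n_sites(out) == 0) warning("all sites removed by filters")
  out
}

#' Thin sites to one per window
#'
#' Keeps the first site in each non-overlapping `window_bp` window per
#' scaffold (windows anchored at coordinate 1), a cheap guard against
#' linkage disequilibrium between neighbouring SNPs.
#'
#' @param gm a `genotype_matrix` (sites position-sorted within scaffold).
#' @param window_bp window width in bp; 1 keeps everything.
#' @return the thinned `genotype_matrix`.
#' @export
thin_by_window <- function(gm, window_bp = 50) {
  if (window_bp < 1) stop("window_bp must be >= 1")
  if (n_sites(gm) <= 1 || window_bp == 1) return(gm)
  win <- (gm$sites$pos - 1) %/% window_bp
  key <- paste(gm$sites$chrom, win)
  subset_sites(gm, !duplicated(key))
}

#' Group scaffolds into pseudo-chromosomes
#'
#' Greedy largest-first bin packing of scaffolds (by length) into `n`
#' groups of near-equal total length. All sites of a scaffold share one
#' label; labels are the contiguous integers 1..n, stored in
#' `gm$sites$pseudochrom`. Fragmented assemblies gain chromosome-scale
#' units this way, e.g. for block construction.
#'
#' @param gm a `genotype_matrix`.
#' @param n number of groups; if it exceeds the scaffold count each
#'   scaffold gets its own group (with a warning).
#' @return `gm` with a `pseudochrom` site column; the scaffold-to-group
#'   map is attached as attribute `pseudochrom_map`.
#' @export
assign_pseudochromosomes <- function(gm, n = 46) {
  stopifnot(n >= 1)
  len <- scaffold_length_table(gm)
  if (n > length(len)) {
    warning("more pseudo-chromosomes than scaffolds; one scaffold per group")
    n <- length(len)
  }
  ord <- order(-len, names(len))          # largest first, name-stable ties
  group <- integer(length(len)); names(group) <- names(len)[ord]
  totals <- numeric(n)
  for (s in seq_along(ord)) {
    g <- which.min(totals)
    group[s] <- g
    totals[g] <- totals[g] + len[ord[s]]
  }
  gm$sites$pseudochrom <- unname(group[gm$sites$chrom])
  attr(gm, "pseudochrom_map") <- group
  gm
}

#' Write the dosage table as TSV
#' @param gm a `genotype_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(gm, path) {
  tab <- cbind(gm$sites[, c("chrom", "pos")], as.data.frame(gm$dosage))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
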
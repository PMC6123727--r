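test_that("read_vcf parses GT, DP, GQ and missing-data conventions", {
  path <- write_toy_vcf()
  gm <- read_vcf(path)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(unname(gm$dosage), unname(toy_vcf_dosages()))
  expect_equal(gm$samples, c("S1", "S2", "S3"))
  expect_equal(gm$sites$chrom, c("scafA", "scafA", "scafA", "scafB"))
  expect_equal(gm$sites$pos, c(100L, 250L, 400L, 120L))
  # half-missing 1/. and ./. both land as NA
  expect_true(is.na(gm$dosage[3, "S1"]))
  expect_true(is.na(gm$dosage[2, "S2"]))
  expect_equal(gm$dp[1, ], c(S1 = 10, S2 = 12, S3 = 9))
  expect_equal(gm$gq[3, ], c(S1 = 33, S2 = 90, S3 = 45))
})

test_that("read_vcf handles subsetting, empty files and bad input", {
  path <- write_toy_vcf()
  gm <- read_vcf(path, sample_subset = c("S3", "S1"))
  expect_equal(gm$samples, c("S3", "S1"))
  expect_equal(unname(gm$dosage[, "S3"]), unname(toy_vcf_dosages()[, "S3"]))
  expect_error(read_vcf(path, sample_subset = "S9"), "S9")

  empty <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "S1", "S2"),
                     collapse = "\t")), empty)
  gm0 <- read_vcf(empty)
  expect_equal(n_sites(gm0), 0L)
  expect_equal(gm0$samples, c("S1", "S2"))

  expect_error(read_vcf(tempfile()), "cannot read")
})

test_that("write_vcf -> read_vcf roundtrip is exact", {
  set.seed(42)
  dosage <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 20, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  gm <- gm_from_dosage(dosage, chrom = rep(c("s1", "s2"), each = 10),
                       scaffold_lengths = c(s1 = 5e6, s2 = 3e6))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(unname(back$dosage), unname(gm$dosage))
  expect_equal(back$sites$chrom, gm$sites$chrom)
  expect_equal(back$sites$pos, gm$sites$pos)
  expect_equal(back$sites$ref, gm$sites$ref)
  expect_equal(back$sites$alt, gm$sites$alt)
})

test_that("site filters enforce each rule and report removals", {
  # 6 sites: indel, private singleton, MAF 0.05, and 3 clean at MAF >= 0.1
  dosage <- matrix(c(
    0, 1, 1, 2, 0,    # clean, p = 0.4
    0, 0, 1, 0, 0,    # private: minor allele only in sample 3
    1, 1, 0, 1, 1,    # clean, p = 0.4
    0, 0, 0, 1, 0,    # private again (kept singleton-free check distinct)
    2, 2, 2, 1, 1,    # clean, p = 0.8, minor (ref) in two samples
    1, 1, 1, 1, 1),   # het everywhere, p = 0.5
    nrow = 6, byrow = TRUE)
  # rows: 1 clean, 2 indel, 3 clean, 4 private singleton, 5 clean, 6 clean
  gm <- gm_from_dosage(dosage, scaffold_lengths = c(chr1 = 2e6))
  gm$sites$is_indel[2] <- TRUE          # row 2: indel AND private
  cfg <- filter_config(min_scaffold_length = 0)
  out <- apply_site_filters(gm, cfg)
  expect_equal(out$sites$pos, gm$sites$pos[c(1, 3, 5, 6)])
  rep_tab <- attr(out, "filter_report")
  expect_equal(rep_tab$removed[rep_tab$rule == "indel"], 1L)
  expect_equal(rep_tab$removed[rep_tab$rule == "private"], 1L)

  # a site below the MAF threshold is removed
  gm2 <- gm_from_dosage(matrix(c(0, 0, 0, 0, 1,
                                 0, 2, 1, 1, 2), 2, byrow = TRUE),
                        scaffold_lengths = c(chr1 = 2e6))
  out2 <- apply_site_filters(gm2, filter_config(maf_min = 0.15,
                                                min_scaffold_length = 0,
                                                drop_private_alleles = FALSE))
  expect_equal(n_sites(out2), 1L)       # maf 0.1 < 0.15 dropped, 0.4 kept
})

test_that("null filter settings return input unchanged; short scaffolds drop", {
  set.seed(7)
  dosage <- matrix(sample(0:2, 40, replace = TRUE, prob = c(.3, .4, .3)),
                   10, 4)
  gm <- gm_from_dosage(dosage, chrom = rep(c("big", "small"), each = 5),
                       scaffold_lengths = c(big = 2e6, small = 5e5))
  null_cfg <- filter_config(min_dp = 0, min_gq = 0, maf_min = 0,
                            max_missing_fraction = 1,
                            min_scaffold_length = 0, drop_indels = FALSE,
                            drop_private_alleles = FALSE)
  out <- apply_site_filters(gm, null_cfg)
  expect_equal(out$dosage, gm$dosage)
  expect_equal(out$sites[names(gm$sites)], gm$sites)

  strict <- apply_site_filters(gm, filter_config(maf_min = 0,
                                                 drop_private_alleles = FALSE))
  expect_true(all(strict$sites$chrom == "big"))
})

test_that("DP/GQ masking works per call and filtering is idempotent", {
  path <- write_toy_vcf()
  gm <- read_vcf(path)
  cfg <- filter_config(min_dp = 8, min_gq = 45, maf_min = 0,
                       min_scaffold_length = 0,
                       drop_private_alleles = FALSE,
                       max_missing_fraction = 1)
  out <- apply_site_filters(gm, cfg)
  # site 3: S1 already half-missing, S3 GQ 45 passes, DP 6 fails -> masked
  i3 <- which(out$sites$pos == 400)
  expect_true(is.na(out$dosage[i3, "S3"]))
  # site 2: S1 GQ 40 < 45 -> masked
  i2 <- which(out$sites$pos == 250)
  expect_true(is.na(out$dosage[i2, "S1"]))
  # site 1 untouched
  expect_equal(unname(out$dosage[out$sites$pos == 100, ]), c(0, 1, 2))

  twice <- apply_site_filters(out, cfg)
  expect_equal(twice$dosage, out$dosage)
  expect_equal(twice$sites[names(out$sites)], out$sites)

  # idempotency under the default config on simulated data
  st <- cached_study(11, n_sites = 5000)
  cfgd <- filter_config(min_scaffold_length = 0)
  once <- apply_site_filters(st$gm, cfgd)
  again <- apply_site_filters(once, cfgd)
  expect_equal(again$dosage, once$dosage)
})

test_that("thin_by_window keeps the first site per tiled window", {
  gm <- gm_from_dosage(matrix(1, 4, 2), pos = c(10, 40, 60, 120))
  out <- thin_by_window(gm, 50)
  expect_equal(out$sites$pos, c(10, 60, 120))

  one <- gm_from_dosage(matrix(1, 1, 2), pos = 7)
  expect_equal(thin_by_window(one, 50)$sites$pos, 7)
  expect_equal(thin_by_window(gm, 1)$sites$pos, gm$sites$pos)
  expect_error(thin_by_window(gm, 0), "window_bp")

  # property: no two retained sites share a window, per scaffold
  set.seed(1)
  pos <- sort(sample.int(5000, 300))
  gm2 <- gm_from_dosage(matrix(1, 300, 2), pos = pos)
  th <- thin_by_window(gm2, 50)
  win <- (th$sites$pos - 1) %/% 50
  expect_false(any(duplicated(win)))
})

test_that("pseudo-chromosome assignment packs scaffolds largest-first", {
  dosage <- matrix(1, 8, 2)
  gm <- gm_from_dosage(dosage, chrom = rep(c("a", "b", "c", "d"), each = 2),
                       pos = rep(c(1, 50), 4),
                       scaffold_lengths = c(a = 8, b = 6, c = 5, d = 5))
  out <- assign_pseudochromosomes(gm, 2)
  map <- attr(out, "pseudochrom_map")
  totals <- tapply(c(a = 8, b = 6, c = 5, d = 5)[names(map)], map, sum)
  expect_equal(sort(as.vector(totals)), c(11, 13))
  expect_equal(unname(map[c("a", "b")]), c(1, 2))   # largest two split apart
  # all sites of one scaffold share a label; labels are 1..n
  expect_equal(as.vector(tapply(out$sites$pseudochrom, out$sites$chrom,
                                function(x) length(unique(x)))),
               rep(1L, 4))
  expect_setequal(unique(out$sites$pseudochrom), 1:2)

  expect_equal(unique(assign_pseudochromosomes(gm, 1)$sites$pseudochrom), 1L)
  eq <- assign_pseudochromosomes(gm, 4)
  expect_equal(length(unique(eq$sites$pseudochrom)), 4L)
  expect_warning(assign_pseudochromosomes(gm, 9), "more pseudo")

  # partition property: every scaffold in exactly one group
  expect_equal(sort(names(attr(out, "pseudochrom_map"))),
               sort(unique(gm$sites$chrom)))
})
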
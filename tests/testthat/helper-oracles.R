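# Independent brute-force oracles: plain per-site loops, no shared code
# with the package's vectorised estimators.

naive_f2 <- function(pA, pB) {
  tot <- 0; n <- 0
  for (i in seq_along(pA)) {
    if (is.na(pA[i]) || is.na(pB[i])) next
    tot <- tot + (pA[i] - pB[i])^2
    n <- n + 1
  }
  as.numeric(tot / n)
}

naive_f3 <- function(pC, pA, pB) {
  tot <- 0; n <- 0
  for (i in seq_along(pC)) {
    if (is.na(pC[i]) || is.na(pA[i]) || is.na(pB[i])) next
    tot <- tot + (pC[i] - pA[i]) * (pC[i] - pB[i])
    n <- n + 1
  }
  as.numeric(tot / n)
}

naive_f4 <- function(pA, pB, pC, pD) {
  tot <- 0; n <- 0
  for (i in seq_along(pA)) {
    if (is.na(pA[i]) || is.na(pB[i]) || is.na(pC[i]) || is.na(pD[i])) next
    tot <- tot + (pA[i] - pB[i]) * (pC[i] - pD[i])
    n <- n + 1
  }
  as.numeric(tot / n)
}

# frequency table straight from p (and optional n) matrices
aft_from_p <- function(p, n = NULL) {
  if (is.null(n)) n <- matrix(1000, nrow(p), ncol(p), dimnames = dimnames(p))
  sites <- data.frame(chrom = "chr1", pos = seq_len(nrow(p)) * 100 - 99,
                      ref = "A", alt = "T", is_indel = FALSE,
                      is_multi = FALSE)
  structure(list(p = p, n = n, pops = colnames(p), sites = sites),
            class = "allele_freq_table")
}

# complete random genotype matrix (no missing data) plus its frequencies
random_aft <- function(n_sites, pops, n_diploid = 3) {
  p <- matrix(NA_real_, n_sites, length(pops),
              dimnames = list(NULL, pops))
  n <- matrix(2 * n_diploid, n_sites, length(pops),
              dimnames = list(NULL, pops))
  for (k in seq_along(pops))
    p[, k] <- rbinom(n_sites, 2 * n_diploid, runif(n_sites, 0.1, 0.9)) /
      (2 * n_diploid)
  aft_from_p(p, n)
}
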
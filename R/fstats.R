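#' Per-population allele frequencies
#'
#' Derived (alternate) allele frequency and allele-copy count per
#' population per site: `p = sum(dosage) / (2 * called diploids)`,
#' `n = 2 * called diploids`. `p` is `NA` exactly where `n = 0`.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap named character vector mapping every sample of `gm` to a
#'   population label (see [read_population_map()]).
#' @param pops optional subset of population labels to compute.
#' @return an `allele_freq_table`: list with `p` and `n` (sites x
#'   populations matrices), `pops`, and the site table (with any
#'   pseudo-chromosome labels) for block construction.
#' @export
allele_frequencies <- function(gm, popmap, pops = NULL) {
  unmapped <- setdiff(gm$samples, names(popmap))
  if (length(unmapped))
    stop("samples missing from population map: ",
         paste(unmapped, collapse = ", "))
  labels <- unname(popmap[gm$samples])
  if (is.null(pops)) pops <- unique(labels)
  absent <- setdiff(pops, labels)
  if (length(absent))
    stop("population(s) with zero samples: ", paste(absent, collapse = ", "))
  p <- n <- matrix(NA_real_, n_sites(gm), length(pops),
                   dimnames = list(NULL, pops))
  for (pop in pops) {
    d <- gm$dosage[, labels == pop, drop = FALSE]
    called <- rowSums(!is.na(d))
    n[, pop] <- 2 * called
    p[, pop] <- ifelse(called > 0, rowSums(d, na.rm = TRUE) / (2 * called),
                       NA_real_)
  }
  structure(list(p = p, n = n, pops = pops, sites = gm$sites),
            class = "allele_freq_table")
}

#' Contiguous SNP blocks for jackknife/bootstrap resampling
#'
#' Splits sites into runs of `block_size` consecutive SNPs within each
#' pseudo-chromosome (or scaffold when no pseudo-chromosome labels exist);
#' the trailing block of each unit may be shorter. Resampling whole blocks
#' absorbs the residual linkage between neighbouring sites.
#'
#' @param sites site table of a `genotype_matrix` or `allele_freq_table`
#'   (the objects themselves are also accepted).
#' @param block_size sites per block (default 50).
#' @return integer vector of block indices (1-based, contiguous), one per site.
#' @export
make_blocks <- function(sites, block_size = 50) {
  if (inherits(sites, "genotype_matrix") ||
      inherits(sites, "allele_freq_table")) sites <- sites$sites
  stopifnot(block_size >= 1)
  unit <- if (!is.null(sites$pseudochrom)) sites$pseudochrom else sites$chrom
  unit <- match(unit, unique(unit))
  within <- stats::ave(seq_along(unit), unit, FUN = seq_along)
  key <- paste(unit, (within - 1) %/% block_size)
  match(key, unique(key))
}

#' Weighted delete-one-block jackknife
#'
#' For a ratio-of-sums estimator theta = sum(s_j) / sum(m_j) over blocks
#' j = 1..g, computes the full-data estimate and the weighted jackknife
#' standard error that accommodates unequal block sizes (Busing's
#' delete-m formulas). With equal blocks this reduces to the textbook
#' stderr^2 = ((g-1)/g) * sum((theta_(-j) - mean)^2).
#'
#' @param block_sums per-block sums of the per-site statistic.
#' @param block_counts per-block site counts m_j.
#' @return list with `estimate`, `stderr` (`NA` with fewer than 2 usable
#'   blocks), and `n_blocks`.
#' @export
block_jackknife <- function(block_sums, block_counts) {
  use <- block_counts > 0
  s <- block_sums[use]; m <- block_counts[use]
  g <- length(s)
  n <- sum(m); S <- sum(s)
  est <- S / n
  if (g < 2) return(list(estimate = est, stderr = NA_real_, n_blocks = g))
  loo <- (S - s) / (n - m)              # delete-one-block estimates
  h <- n / m
  theta_J <- g * est - sum((1 - m / n) * loo)
  tau <- h * est - (h - 1) * loo
  var_J <- sum((tau - theta_J)^2 / (h - 1)) / g
  list(estimate = est, stderr = sqrt(var_J), n_blocks = g)
}

fstat_estimate <- function(stat, pops, estimate, stderr, n_sites, n_blocks) {
  z <- if (!is.na(stderr) && stderr > 0) estimate / stderr else NA_real_
  structure(list(stat = stat, pops = pops, estimate = estimate,
                 stderr = stderr, z = z, n_sites = n_sites,
                 n_blocks = n_blocks),
            class = "fstat_estimate")
}

#' @export
print.fstat_estimate <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  stderr %.3g  Z %.2f  (%d sites, %d blocks)\n",
              x$stat, paste(x$pops, collapse = ", "), x$estimate,
              x$stderr, x$z, x$n_sites, x$n_blocks))
  invisible(x)
}

# shared driver: per-site terms -> block sums -> jackknife -> estimate
fstat_from_terms <- function(stat, pops, terms, usable, blocks) {
  if (!any(usable)) stop("no usable sites for ", stat)
  terms <- terms[usable]
  if (is.null(blocks)) {
    return(fstat_estimate(stat, pops, mean(terms), NA_real_,
                          length(terms), 1L))
  }
  b <- blocks[usable]
  sums <- rowsum(terms, b)[, 1]
  counts <- as.vector(table(factor(b, levels = unique(b))))
  jk <- block_jackknife(sums, counts)
  fstat_estimate(stat, pops, jk$estimate, jk$stderr, length(terms),
                 jk$n_blocks)
}

aft_cols <- function(aft, pops) {
  absent <- setdiff(pops, aft$pops)
  if (length(absent))
    stop("population(s) not in frequency table: ",
         paste(absent, collapse = ", "))
  pops
}

#' f2 statistic: squared allele-frequency difference
#'
#' `f2(A, B)` is the average over sites of `(pA - pB)^2`, an additive
#' measure of the drift separating two populations. The `corrected`
#' estimator subtracts the sampling contribution
#' `pA(1-pA)/(nA-1) + pB(1-pB)/(nB-1)` per site (unbiased for finite
#' samples; sites with fewer than 2 allele copies in either population are
#' skipped). The uncorrected moment estimator is the default so that the
#' exact algebraic identities linking f2, f3 and f4 hold on any input.
#'
#' @param aft an [allele_frequencies()] table.
#' @param A,B population labels.
#' @param blocks block index vector from [make_blocks()] (`NULL` for a
#'   point estimate without a standard error).
#' @param corrected apply the finite-sample bias correction?
#' @return an `fstat_estimate` (estimate, block-jackknife stderr, Z-score).
#' @export
f2 <- function(aft, A, B, blocks = NULL, corrected = FALSE) {
  aft_cols(aft, c(A, B))
  if (corrected && A == B) stop("f2(A, A) is undefined under correction")
  pA <- aft$p[, A]; pB <- aft$p[, B]
  nA <- aft$n[, A]; nB <- aft$n[, B]
  usable <- !is.na(pA) & !is.na(pB)
  terms <- (pA - pB)^2
  if (corrected) {
    usable <- usable & nA >= 2 & nB >= 2
    terms <- terms - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  }
  fstat_from_terms("f2", c(A, B), terms, usable, blocks)
}

#' f3 statistic: three-population admixture test
#'
#' `f3(C; A, B)` averages `(pC - pA)(pC - pB)` over sites. A significantly
#' negative value is proof that target C is admixed between populations
#' related to A and B; positive values do not rule admixture out. The
#' `corrected` form subtracts the target's sampling term
#' `pC(1-pC)/(nC-1)`, the standard three-population-test estimator.
#'
#' @inheritParams f2
#' @param C target population label; `C`, `A`, `B` must be distinct.
#' @return an `fstat_estimate`.
#' @export
f3 <- function(aft, C, A, B, blocks = NULL, corrected = FALSE) {
  aft_cols(aft, c(C, A, B))
  if (C %in% c(A, B)) stop("target must differ from both sources")
  pC <- aft$p[, C]; pA <- aft$p[, A]; pB <- aft$p[, B]
  nC <- aft$n[, C]
  usable <- !is.na(pC) & !is.na(pA) & !is.na(pB)
  terms <- (pC - pA) * (pC - pB)
  if (corrected) {
    usable <- usable & nC >= 2
    terms <- terms - pC * (1 - pC) / (nC - 1)
  }
  fstat_from_terms("f3", c(C, A, B), terms, usable, blocks)
}

#' f4 statistic: four-population introgression test
#'
#' `f4(A, B; C, D)` averages `(pA - pB)(pC - pD)` over sites. It is zero
#' in expectation when (A,B) and (C,D) are concordant sister pairs on a
#' tree; excess allele sharing across the pairs drives it away from zero.
#' Swapping the members of one pair flips the sign. No finite-sample
#' correction is needed: with four distinct populations the moment
#' estimator is unbiased.
#'
#' @inheritParams f2
#' @param A,B,C,D four distinct population labels.
#' @return an `fstat_estimate`.
#' @export
f4 <- function(aft, A, B, C, D, blocks = NULL) {
  aft_cols(aft, c(A, B, C, D))
  if (anyDuplicated(c(A, B, C, D))) stop("populations must be distinct")
  pA <- aft$p[, A]; pB <- aft$p[, B]; pC <- aft$p[, C]; pD <- aft$p[, D]
  usable <- !is.na(pA) & !is.na(pB) & !is.na(pC) & !is.na(pD)
  terms <- (pA - pB) * (pC - pD)
  fstat_from_terms("f4", c(A, B, C, D), terms, usable, blocks)
}

#' Three-population admixture scan
#'
#' Runs [f3()] for every (target; unordered source pair) combination of
#' distinct populations and flags targets whose Z-score falls at or below
#' `-z_threshold` as admixed. The corrected f3 estimator is the default
#' here: without the target's sampling-bias term, true admixture signals
#' in small samples can be masked by a positive offset.
#'
#' @param aft an [allele_frequencies()] table (3 or more populations).
#' @param blocks block index vector from [make_blocks()].
#' @param z_threshold flag threshold on the Z-score (default 3, the
#'   conventional three-population-test cutoff).
#' @param corrected use the corrected f3 estimator (default `TRUE`).
#' @param pops optional subset of populations to scan.
#' @return data.frame (one row per combination, sorted by Z ascending)
#'   with columns `target`, `source1`, `source2`, `estimate`, `stderr`,
#'   `z`, `n_sites`, `n_blocks`, `admixed`.
#' @export
three_pop_scan <- function(aft, blocks, z_threshold = 3, corrected = TRUE,
                           pops = NULL) {
  if (is.null(pops)) pops <- aft$pops
  if (length(pops) < 3) stop("need at least 3 populations")
  rows <- list()
  for (target in pops) {
    sources <- setdiff(pops, target)
    pairs <- utils::combn(sources, 2)
    for (k in seq_len(ncol(pairs))) {
      est <- f3(aft, target, pairs[1, k], pairs[2, k], blocks,
                corrected = corrected)
      rows[[length(rows) + 1L]] <-
        data.frame(target = target, source1 = pairs[1, k],
                   source2 = pairs[2, k], estimate = est$estimate,
                   stderr = est$stderr, z = est$z, n_sites = est$n_sites,
                   n_blocks = est$n_blocks)
    }
  }
  out <- do.call(rbind, rows)
  out$admixed <- !is.na(out$z) & out$z <= -z_threshold
  out[order(out$z), , drop = FALSE]
}

#' Admixture proportion by f4-ratio
#'
#' Estimates the proportion `alpha` of population X's ancestry drawn from
#' the B-side lineage (the remainder coming from the C-side lineage) as
#' `f4(A, O; X, C) / f4(A, O; B, C)`, where O is an outgroup and A is a
#' non-admixed population that branches off on B's side of the B/C split
#' below the point where X's B-ancestor attaches. Both f4 values are
#' computed over the same usable sites; the standard error of the ratio
#' comes from a weighted block jackknife of the ratio itself.
#'
#' @param aft an [allele_frequencies()] table.
#' @param O,A,B,X,C population labels (see Description for roles).
#' @param blocks block index vector from [make_blocks()].
#' @param tol denominators smaller than this (absolute value) raise an
#'   undefined-ratio error.
#' @return list with `alpha` (clamped to \code{[0, 1]}), `alpha_raw`,
#'   `stderr`, `z`, `n_sites`, `n_blocks`, and the two component f4 sums.
#' @export
f4_ratio_alpha <- function(aft, O, A, B, X, C, blocks, tol = 1e-9) {
  aft_cols(aft, c(O, A, B, X, C))
  if (anyDuplicated(c(O, A, B, X, C))) stop("populations must be distinct")
  p <- aft$p
  usable <- stats::complete.cases(p[, c(O, A, B, X, C)])
  num <- (p[, A] - p[, O]) * (p[, X] - p[, C])
  den <- (p[, A] - p[, O]) * (p[, B] - p[, C])
  num <- num[usable]; den <- den[usable]; b <- blocks[usable]
  S_num <- rowsum(num, b)[, 1]; S_den <- rowsum(den, b)[, 1]
  m <- as.vector(table(factor(b, levels = unique(b))))
  if (abs(sum(S_den)) / length(den) < tol)
    stop("f4-ratio denominator indistinguishable from zero")
  est <- sum(S_num) / sum(S_den)
  g <- length(S_num)
  loo <- (sum(S_num) - S_num) / (sum(S_den) - S_den)
  n <- sum(m); h <- n / m
  theta_J <- g * est - sum((1 - m / n) * loo)
  tau <- h * est - (h - 1) * loo
  se <- sqrt(sum((tau - theta_J)^2 / (h - 1)) / g)
  list(alpha = min(1, max(0, est)), alpha_raw = est, stderr = se,
       z = if (se > 0) est / se else NA_real_,
       n_sites = length(num), n_blocks = g,
       f4_num = sum(S_num) / n, f4_den = sum(S_den) / n)
}

#' Pairwise f2 matrix with jackknife standard errors
#'
#' Convenience wrapper: [f2()] for every unordered pair of populations.
#'
#' @inheritParams three_pop_scan
#' @param corrected apply the finite-sample bias correction to each f2?
#' @return list with symmetric matrices `estimate` and `stderr`
#'   (dimnames = populations; diagonal 0 and NA respectively).
#' @export
f2_matrix <- function(aft, blocks, pops = NULL, corrected = FALSE) {
  if (is.null(pops)) pops <- aft$pops
  k <- length(pops)
  est <- matrix(0, k, k, dimnames = list(pops, pops))
  se <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fij <- f2(aft, pops[i], pops[j], blocks, corrected = corrected)
    est[i, j] <- est[j, i] <- fij$estimate
    se[i, j] <- se[j, i] <- fij$stderr
  }
  list(estimate = est, stderr = se)
}

#' Per-block f2 accumulations for resampling
#'
#' Per-block sums of `(p_i - p_j)^2` and usable-site counts for every
#' unordered population pair, the sufficient statistics from which the f2
#' matrix can be rebuilt under any block resampling (jackknife or
#' bootstrap) without touching the per-site data again.
#'
#' @inheritParams f2_matrix
#' @return list with `sums` and `counts` (pairs x blocks matrices), the
#'   `pairs` (2 x n_pairs character matrix) and `pops`.
#' @export
block_f2_sums <- function(aft, blocks, pops = NULL, corrected = FALSE) {
  if (is.null(pops)) pops <- aft$pops
  pairs <- utils::combn(pops, 2)
  g <- length(unique(blocks))
  bfac <- factor(blocks, levels = unique(blocks))
  sums <- counts <- matrix(0, ncol(pairs), g)
  for (k in seq_len(ncol(pairs))) {
    pi <- aft$p[, pairs[1, k]]; pj <- aft$p[, pairs[2, k]]
    ni <- aft$n[, pairs[1, k]]; nj <- aft$n[, pairs[2, k]]
    usable <- !is.na(pi) & !is.na(pj)
    t2 <- (pi - pj)^2
    if (corrected) {
      usable <- usable & ni >= 2 & nj >= 2
      t2 <- t2 - pi * (1 - pi) / (ni - 1) - pj * (1 - pj) / (nj - 1)
    }
    sums[k, ] <- rowsum(ifelse(usable, t2, 0), bfac)[, 1]
    counts[k, ] <- rowsum(as.numeric(usable), bfac)[, 1]
  }
  list(sums = sums, counts = counts, pairs = pairs, pops = pops)
}

#' Rebuild an f2 matrix from block accumulations
#'
#' @param bs output of [block_f2_sums()].
#' @param block_idx block indices to include (with repetition allowed, as
#'   in a bootstrap draw); default all blocks once.
#' @return symmetric f2 matrix over `bs$pops`.
#' @export
f2_matrix_from_blocks <- function(bs, block_idx = NULL) {
  if (is.null(block_idx)) block_idx <- seq_len(ncol(bs$sums))
  s <- rowSums(bs$sums[, block_idx, drop = FALSE])
  m <- rowSums(bs$counts[, block_idx, drop = FALSE])
  k <- length(bs$pops)
  est <- matrix(0, k, k, dimnames = list(bs$pops, bs$pops))
  for (j in seq_len(ncol(bs$pairs))) {
    a <- bs$pairs[1, j]; b <- bs$pairs[2, j]
    est[a, b] <- est[b, a] <- s[j] / m[j]
  }
  est
}

#' Block bootstrap of an f-statistic
#'
#' Resamples blocks with replacement and recomputes the ratio-of-sums
#' estimate, giving a percentile confidence interval to complement the
#' jackknife standard error.
#'
#' @param block_sums,block_counts per-block sums and site counts.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param probs interval probabilities (default 2.5% and 97.5%).
#' @return list with `estimate`, `ci` (named quantiles) and the bootstrap
#'   `replicates`.
#' @export
fstat_bootstrap <- function(block_sums, block_counts, n_boot = 1000,
                            seed = 0, probs = c(0.025, 0.975)) {
  g <- length(block_sums)
  if (g < 2) stop("need at least 2 blocks to bootstrap")
  set.seed(seed)
  idx <- matrix(sample.int(g, g * n_boot, replace = TRUE), nrow = n_boot)
  reps <- apply(idx, 1, function(i) sum(block_sums[i]) / sum(block_counts[i]))
  list(estimate = sum(block_sums) / sum(block_counts),
       ci = stats::quantile(reps, probs, names = TRUE),
       replicates = reps)
}

#' Principal component analysis of genotypes
#'
#' Standard genotype PCA: per-site mean-centred dosages scaled by
#' `sqrt(p(1-p))` with missing calls mean-imputed and monomorphic sites
#' dropped, then an eigendecomposition of the sample covariance.
#'
#' @param gm a `genotype_matrix` with 2 or more samples.
#' @param n_components number of components to return.
#' @return list with `coords` (samples x components), `explained`
#'   (variance fractions, non-increasing, summing to at most 1) and
#'   `n_sites_used`.
#' @export
pca_genotypes <- function(gm, n_components = 10) {
  if (length(gm$samples) < 2) stop("need at least 2 samples")
  d <- gm$dosage
  p <- rowMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all sites monomorphic")
  d <- d[poly, , drop = FALSE]; p <- p[poly]
  x <- (d - 2 * p) / sqrt(p * (1 - p))   # mean-impute: NA -> 0 after centring
  x[is.na(x)] <- 0
  pc <- stats::prcomp(t(x), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rownames(coords) <- gm$samples
  list(coords = coords,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       n_sites_used = sum(poly))
}
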
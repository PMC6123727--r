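#' Construct a genotype matrix
#'
#' The central data container of the package: a sites-by-samples matrix of
#' diploid genotype dosages (count of alternate alleles, 0/1/2, `NA` for
#' missing calls) together with per-site metadata and optional per-call
#' depth (DP) and genotype-quality (GQ) matrices.
#'
#' @param dosage integer matrix, sites x samples; entries in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `is_indel`, `is_multi`; one row per row of `dosage`.
#' @param samples character vector of sample identifiers (columns of `dosage`).
#' @param dp,gq optional numeric matrices of the same shape as `dosage`.
#' @param scaffold_lengths optional named numeric vector of scaffold lengths
#'   in bp; scaffolds absent from it are approximated by their maximum
#'   observed position when a length is needed.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, samples, dp = NULL, gq = NULL,
                            scaffold_lengths = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(sites), nrow(sites) == nrow(dosage),
            length(samples) == ncol(dosage))
  needed <- c("chrom", "pos", "ref", "alt", "is_indel", "is_multi")
  missing_cols <- setdiff(needed, names(sites))
  if ("is_multi" %in% missing_cols) sites$is_multi <- FALSE
  if ("is_indel" %in% missing_cols) sites$is_indel <- FALSE
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols))
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  dimnames(dosage) <- list(NULL, samples)
  gm <- structure(
    list(dosage = dosage, sites = sites, samples = as.character(samples),
         dp = dp, gq = gq, scaffold_lengths = scaffold_lengths),
    class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d scaffolds)\n",
              n_sites(x), length(x$samples),
              length(unique(x$sites$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%", 100 * miss))
  if (!is.null(x$sites$pseudochrom))
    cat(sprintf("; %d pseudo-chromosomes", length(unique(x$sites$pseudochrom))))
  cat("\n")
  invisible(x)
}

validate_genotype_matrix <- function(gm) {
  d <- gm$dosage
  ok <- is.na(d) | d %in% 0:2
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (any(gm$sites$pos < 1)) stop("positions must be >= 1")
  # positions strictly increasing within each scaffold
  by_chrom <- split(gm$sites$pos, gm$sites$chrom)
  bad <- vapply(by_chrom, function(p) any(diff(p) <= 0), logical(1))
  if (any(bad))
    stop("positions must be strictly increasing within scaffold(s): ",
         paste(names(by_chrom)[bad], collapse = ", "))
  invisible(gm)
}

#' Number of sites in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer site count.
#' @export
n_sites <- function(gm) nrow(gm$dosage)

#' Subset a genotype matrix by site index
#'
#' Keeps all per-site metadata, DP/GQ matrices and any filter report in
#' sync; used by every filtering and thinning step.
#'
#' @param gm a `genotype_matrix`.
#' @param idx logical or integer index over sites.
#' @return the subset `genotype_matrix`.
#' @export
subset_sites <- function(gm, idx) {
  gm$dosage <- gm$dosage[idx, , drop = FALSE]
  gm$sites <- gm$sites[idx, , drop = FALSE]
  rownames(gm$sites) <- NULL
  if (!is.null(gm$dp)) gm$dp <- gm$dp[idx, , drop = FALSE]
  if (!is.null(gm$gq)) gm$gq <- gm$gq[idx, , drop = FALSE]
  gm
}

# length of each scaffold: recorded table where available, else max position
scaffold_length_table <- function(gm) {
  obs <- tapply(gm$sites$pos, gm$sites$chrom, max)
  out <- as.numeric(obs)
  names(out) <- names(obs)
  if (!is.null(gm$scaffold_lengths)) {
    known <- intersect(names(out), names(gm$scaffold_lengths))
    out[known] <- gm$scaffold_lengths[known]
  }
  out
}
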
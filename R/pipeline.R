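#' Analysis configuration
#'
#' Bundles every knob of the full introgression workflow. Input can be a
#' VCF path or an in-memory `genotype_matrix`; the population map a TSV
#' path or a named vector.
#'
#' @param vcf path to a multi-sample VCF (alternative to `gm`).
#' @param gm a `genotype_matrix` (alternative to `vcf`).
#' @param popmap population map: TSV path or named character vector.
#' @param outgroup outgroup population label (must be in the map).
#' @param filter a [filter_config()].
#' @param block_size SNP block size for jackknife/bootstrap (default 50).
#' @param f3_z flag threshold for the three-population scan (default 3).
#' @param f4_z significance threshold for f4 Z-scores (default 5).
#' @param backbone optional fixed backbone topology (an
#'   [admixture_graph()] or an edge-list TSV path); by default the
#'   backbone is a neighbour-joining tree on the f2 distances of the
#'   non-admixed populations, rooted at the outgroup.
#' @param Ne diploid effective size used to date mixed drift (> 0);
#'   combine the sizes of the contributing source populations.
#' @param generation_time years per generation (default 2).
#' @param n_boot bootstrap replicates for mixed-drift intervals.
#' @param seed master seed; every random stage derives from it.
#' @param output_dir optional directory for persisted artifacts.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(vcf = NULL, gm = NULL, popmap, outgroup,
                            filter = filter_config(), block_size = 50,
                            f3_z = 3, f4_z = 5, backbone = NULL,
                            Ne = 375000, generation_time = 2,
                            n_boot = 1000, seed = 0, output_dir = NULL) {
  if (is.null(vcf) && is.null(gm)) stop("need vcf or gm")
  stopifnot(Ne > 0, f3_z > 0, f4_z > 0, block_size >= 1, n_boot >= 2)
  structure(list(vcf = vcf, gm = gm, popmap = popmap, outgroup = outgroup,
                 filter = filter, block_size = block_size, f3_z = f3_z,
                 f4_z = f4_z, backbone = backbone, Ne = Ne,
                 generation_time = generation_time, n_boot = n_boot,
                 seed = seed, output_dir = output_dir),
            class = "analysis_config")
}

# unbiased per-population heterozygosity E[p(1-p)], used to move fitted
# f2-unit drift onto the dimensionless drift scale of the dating formula
population_het <- function(aft, pop) {
  p <- aft$p[, pop]; n <- aft$n[, pop]
  ok <- !is.na(p) & n >= 2
  mean(p[ok] * (1 - p[ok]) * n[ok] / (n[ok] - 1))
}

# f2-unit pendant drift -> dimensionless drift: d = F h_anc and
# h_leaf = (1 - F) h_anc  =>  F = d / (h_leaf + d)
f2_drift_to_F <- function(d, h_leaf) {
  d <- pmax(d, 0)
  d / (h_leaf + d)
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[introkit] ", fmt), ...))
}

#' Run the full introgression analysis
#'
#' Filter -> allele frequencies -> three-population scan -> f4
#' backcrossing tables -> graph placement of each flagged hybrid ->
#' block-bootstrap mixed-drift interval -> calendar dates. Every random
#' stage is seeded from the config, so repeated runs are identical.
#'
#' @param config an [analysis_config()].
#' @param quiet suppress per-stage log lines?
#' @return an `analysis_report` list with elements `filter_summary`,
#'   `scan`, `hybrids`, `backbone_edges`, `f4_tables`, `placements`,
#'   `alpha`, `mixed_drift`, `dates`, `pca`, `config_echo`, `seed` and
#'   `version`.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  gm <- if (!is.null(config$gm)) config$gm else read_vcf(config$vcf)
  popmap <- if (is.character(config$popmap) && length(config$popmap) == 1 &&
                file.exists(config$popmap))
    read_population_map(config$popmap) else config$popmap
  if (!config$outgroup %in% popmap)
    stop("outgroup '", config$outgroup, "' not in population map")

  gm <- apply_site_filters(gm, config$filter)
  filter_summary <- attr(gm, "filter_report")
  gm <- thin_by_window(gm, config$filter$thin_window_bp)
  gm <- assign_pseudochromosomes(gm, config$filter$n_pseudochromosomes)
  stage_log(quiet, "filtered: %d sites, %d samples", n_sites(gm),
            length(gm$samples))

  aft <- allele_frequencies(gm, popmap)
  blocks <- make_blocks(gm, config$block_size)
  pops <- aft$pops

  scan <- three_pop_scan(aft, blocks, z_threshold = config$f3_z)
  hybrids <- unique(scan$target[scan$admixed])
  stage_log(quiet, "f3 scan: %d combinations, flagged hybrid(s): %s",
            nrow(scan),
            if (length(hybrids)) paste(hybrids, collapse = ", ") else "none")

  backbone_pops <- setdiff(pops, hybrids)
  # bias-corrected f2 for everything that feeds the graph fits: the
  # uncorrected moment inflates every pendant drift by h/n, which would
  # leak straight into the mixed drift and hence the dates
  f2m <- f2_matrix(aft, blocks, corrected = TRUE)
  backbone <- resolve_backbone(config, f2m$estimate, backbone_pops)
  bs <- block_f2_sums(aft, blocks, corrected = TRUE)

  f4_tables <- list(); placements <- list()
  alpha_tab <- list(); drift_tab <- list(); dates <- list()
  for (i in seq_along(hybrids)) {
    hyb <- hybrids[i]
    f4_tables[[hyb]] <- hybrid_f4_table(aft, blocks, config$outgroup, hyb,
                                        setdiff(backbone_pops,
                                                config$outgroup),
                                        config$f4_z)
    pl <- enumerate_hybrid_placements(backbone, hyb, f2m$estimate,
                                      f2_se = f2m$stderr)
    placements[[hyb]] <- pl
    best_topology <- attr(pl, "fits")[[1]]$topology
    boot <- bootstrap_mixed_drift(bs, best_topology, hyb,
                                  n_boot = config$n_boot,
                                  seed = config$seed + 1000L + i,
                                  f2_se = f2m$stderr)
    # percentile endpoints can miss the point estimate by optimizer
    # granularity; widen minimally so the interval always contains it
    md <- boot$mixed_drift
    md["lower"] <- min(md["lower"], md["estimate"])
    md["upper"] <- max(md["upper"], md["estimate"])
    al <- boot$alpha
    al["lower"] <- min(al["lower"], al["estimate"])
    al["upper"] <- max(al["upper"], al["estimate"])
    alpha_tab[[hyb]] <- al
    h_leaf <- population_het(aft, hyb)
    F_est <- f2_drift_to_F(md, h_leaf)
    drift_tab[[hyb]] <- c(md, F = unname(F_est["estimate"]))
    dates[[hyb]] <- date_interval(F_est[["estimate"]], config$Ne,
                                  config$generation_time,
                                  D_low = F_est[["lower"]],
                                  D_high = F_est[["upper"]])
    stage_log(quiet,
              "%s: placement (%s | %s), alpha %.2f [%.2f, %.2f], %.0f yr [%.0f, %.0f]",
              hyb, pl$edge1[1], pl$edge2[1], al["estimate"], al["lower"],
              al["upper"], dates[[hyb]]$t_years, dates[[hyb]]$t_years_low,
              dates[[hyb]]$t_years_high)
  }

  pca <- tryCatch(pca_genotypes(gm, n_components = 4),
                  error = function(e) NULL)

  report <- structure(list(
    filter_summary = filter_summary,
    n_sites = n_sites(gm), n_samples = length(gm$samples),
    scan = scan, hybrids = hybrids,
    backbone_edges = backbone$edges[, c("child", "parent")],
    f4_tables = f4_tables, placements = placements,
    alpha = alpha_tab, mixed_drift = drift_tab, dates = dates,
    pca = pca,
    config_echo = config_echo(config), seed = config$seed,
    version = as.character(utils::packageVersion("introkit"))),
    class = "analysis_report")
  if (!is.null(config$output_dir)) persist_report(report, config)
  report
}

resolve_backbone <- function(config, f2_est, backbone_pops) {
  if (!is.null(config$backbone)) {
    bb <- if (inherits(config$backbone, "admixture_graph")) config$backbone
    else read_graph(config$backbone)
    return(free_graph_params(bb))
  }
  if (length(backbone_pops) < 3)
    stop("need at least 3 non-admixed populations to build a backbone")
  d <- stats::as.dist(f2_est[backbone_pops, backbone_pops])
  phy <- ape::root(ape::nj(d), config$outgroup, resolve.root = TRUE)
  free_graph_params(phylo_to_graph(phy))
}

# Table-2-style block: f4(W = outgroup, X = hybrid; Y, Z) for all source
# pairs; rotating the members of one pair flips the sign
hybrid_f4_table <- function(aft, blocks, outgroup, hybrid, sources, f4_z) {
  prs <- utils::combn(sources, 2)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    est <- f4(aft, outgroup, hybrid, prs[1, k], prs[2, k], blocks)
    data.frame(W = outgroup, X = hybrid, Y = prs[1, k], Z = prs[2, k],
               f4 = est$estimate, stderr = est$stderr, z = est$z,
               significant = !is.na(est$z) && abs(est$z) >= f4_z)
  })
  do.call(rbind, rows)
}

config_echo <- function(config) {
  list(outgroup = config$outgroup, block_size = config$block_size,
       f3_z = config$f3_z, f4_z = config$f4_z, Ne = config$Ne,
       generation_time = config$generation_time, n_boot = config$n_boot,
       seed = config$seed,
       filter = unclass(config$filter))
}

persist_report <- function(report, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(report, file.path(config$output_dir, "report.json"))
  tabs <- render_tables(report)
  utils::write.table(tabs$table1,
                     file.path(config$output_dir, "admixture_dates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tabs$table2,
                     file.path(config$output_dir, "f4_statistics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$scan,
                     file.path(config$output_dir, "f3_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Render report tables
#'
#' Builds the two headline tables of a hybrid-zone analysis: one row per
#' hybrid with its best source pair, f3 evidence, admixture proportion,
#' mixed drift and calendar dates; and the f4 backcrossing table
#' (outgroup, hybrid, source pair, f4, Z).
#'
#' @param report an `analysis_report` from [run_full_analysis()].
#' @return list with data.frames `table1` and `table2` (headers only
#'   when no hybrid was flagged).
#' @export
render_tables <- function(report) {
  empty1 <- data.frame(target = character(0), source1 = character(0),
                       source2 = character(0), f3 = numeric(0),
                       stderr = numeric(0), z = numeric(0),
                       alpha = numeric(0), alpha_low = numeric(0),
                       alpha_high = numeric(0), mixed_drift = numeric(0),
                       years = numeric(0), years_low = numeric(0),
                       years_high = numeric(0))
  empty2 <- data.frame(W = character(0), X = character(0),
                       Y = character(0), Z = character(0), f4 = numeric(0),
                       stderr = numeric(0), z = numeric(0),
                       significant = logical(0))
  if (!length(report$hybrids))
    return(list(table1 = empty1, table2 = empty2))
  rows1 <- lapply(report$hybrids, function(hyb) {
    best_f3 <- report$scan[report$scan$target == hyb, ][1, ]
    al <- report$alpha[[hyb]]; md <- report$mixed_drift[[hyb]]
    dt <- report$dates[[hyb]]
    data.frame(target = hyb, source1 = best_f3$source1,
               source2 = best_f3$source2, f3 = best_f3$estimate,
               stderr = best_f3$stderr, z = best_f3$z,
               alpha = al[["estimate"]], alpha_low = al[["lower"]],
               alpha_high = al[["upper"]],
               mixed_drift = md[["F"]],
               years = dt$t_years, years_low = dt$t_years_low,
               years_high = dt$t_years_high)
  })
  list(table1 = do.call(rbind, rows1),
       table2 = do.call(rbind, c(report$f4_tables,
                                 list(make.row.names = FALSE))))
}

#' Write / read an analysis report as JSON
#'
#' Numbers are serialised at full precision; `read_report` restores the
#' plain-list form (tables come back as data.frames).
#'
#' @param report an `analysis_report`.
#' @param path JSON file path.
#' @return `write_report`: `path` invisibly; `read_report`: the report
#'   list.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$dates <- lapply(out$dates, unclass)
  out$placements <- lapply(out$placements, function(p) {
    attr(p, "fits") <- NULL; p
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
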
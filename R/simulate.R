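#' Demographic model for the graph simulator
#'
#' Couples an [admixture_graph()] whose edges carry drift in
#' Balding-Nichols units (`F in [0, 1)`: the fraction of ancestral
#' heterozygosity lost along the edge) with an ancestral-frequency law
#' (uniform on `p_range`) and per-leaf diploid sample sizes.
#'
#' @param graph an `admixture_graph`; `drift` entries are F values.
#' @param sample_sizes named integer vector of diploids per leaf.
#' @param p_range ancestral derived-allele frequency range (uniform law).
#' @return a `demographic_model`.
#' @export
demographic_model <- function(graph, sample_sizes, p_range = c(0.05, 0.95)) {
  stopifnot(inherits(graph, "admixture_graph"))
  f <- graph$edges$drift
  if (anyNA(f) || any(f < 0 | f >= 1))
    stop("edge drifts must be F values in [0, 1)")
  missing_ss <- setdiff(graph$leaves, names(sample_sizes))
  if (length(missing_ss))
    stop("sample sizes missing for: ", paste(missing_ss, collapse = ", "))
  if (any(sample_sizes < 1)) stop("sample sizes must be >= 1")
  stopifnot(length(p_range) == 2, p_range[1] > 0, p_range[2] < 1,
            p_range[1] <= p_range[2])
  structure(list(graph = graph, sample_sizes = sample_sizes,
                 p_range = p_range),
            class = "demographic_model")
}

#' Simulate allele frequencies down an admixture graph
#'
#' Per site: the root frequency is uniform on the model's `p_range`; a
#' child along an edge with drift F is drawn from the Balding-Nichols
#' distribution `Beta(p (1-F)/F, (1-p) (1-F)/F)` (mean `p`, variance
#' `F p (1-p)`; F = 0 copies the parent, frequencies already fixed at 0
#' or 1 stay fixed); an admixture node mixes its parents as
#' `alpha p1 + (1-alpha) p2`. Fully determined by `seed`.
#'
#' @param model a [demographic_model()].
#' @param n_sites number of independent sites.
#' @param seed RNG seed.
#' @return matrix `n_sites` x nodes of frequencies (all graph nodes;
#'   subset columns to `model$graph$leaves` for population frequencies).
#' @export
simulate_frequencies <- function(model, n_sites, seed = 0) {
  stopifnot(n_sites >= 1)
  g <- model$graph
  set.seed(seed)
  P <- matrix(NA_real_, n_sites, length(g$nodes),
              dimnames = list(NULL, g$nodes))
  P[, g$root] <- stats::runif(n_sites, model$p_range[1], model$p_range[2])
  e <- g$edges
  for (v in g$topo) {
    if (v == g$root) next
    up <- which(e$child == v)
    if (length(up) == 2) {
      # drift down each parent edge, then instantaneous pulse mixing
      a <- e$alpha[up[1]]
      q1 <- drift_transition(P[, e$parent[up[1]]], e$drift[up[1]])
      q2 <- drift_transition(P[, e$parent[up[2]]], e$drift[up[2]])
      P[, v] <- a * q1 + (1 - a) * q2
    } else {
      P[, v] <- drift_transition(P[, e$parent[up]], e$drift[up])
    }
  }
  P
}

# Balding-Nichols one-edge transition, vectorised over sites
drift_transition <- function(p, F) {
  if (F == 0) return(p)
  out <- p
  interior <- p > 0 & p < 1
  if (any(interior)) {
    s <- (1 - F) / F
    out[interior] <- stats::rbeta(sum(interior),
                                  p[interior] * s, (1 - p[interior]) * s)
  }
  out
}

#' Simulate diploid genotypes from population frequencies
#'
#' Each diploid's dosage is Binomial(2, p) at its population's frequency;
#' missingness is applied independently per call. Sites are laid out at
#' fixed spacing along synthetic pseudo-chromosome scaffolds so that
#' positional operations (thinning, blocking) are exercised.
#'
#' @param freqs matrix sites x populations of frequencies in \code{[0, 1]}.
#' @param sample_sizes named integer vector of diploids per population
#'   (names must match `colnames(freqs)`).
#' @param missing_prob per-call missingness probability in \code{[0, 1)}.
#' @param sites_per_chrom sites per synthetic scaffold.
#' @param spacing_bp distance between consecutive sites (default 100 bp,
#'   i.e. already spaced more than one per 50 bp window).
#' @param seed RNG seed.
#' @return a [genotype_matrix()]; sample names are `<pop>_<k>`, the
#'   matching population map is attached as attribute `popmap`.
#' @export
simulate_genotypes <- function(freqs, sample_sizes, missing_prob = 0,
                               sites_per_chrom = 5000, spacing_bp = 100,
                               seed = 0) {
  stopifnot(all(freqs >= 0 & freqs <= 1), missing_prob >= 0,
            missing_prob < 1)
  pops <- colnames(freqs)
  stopifnot(!is.null(pops), all(pops %in% names(sample_sizes)))
  set.seed(seed)
  n_sites <- nrow(freqs)
  cols <- list(); popmap <- character(0)
  for (pop in pops) {
    for (k in seq_len(sample_sizes[[pop]])) {
      nm <- sprintf("%s_%d", pop, k)
      cols[[nm]] <- stats::rbinom(n_sites, 2, freqs[, pop])
      popmap[nm] <- pop
    }
  }
  dosage <- do.call(cbind, cols)
  if (missing_prob > 0)
    dosage[stats::runif(length(dosage)) < missing_prob] <- NA_integer_
  chrom_idx <- (seq_len(n_sites) - 1) %/% sites_per_chrom + 1
  within <- (seq_len(n_sites) - 1) %% sites_per_chrom
  sites <- data.frame(
    chrom = sprintf("pchr%02d", chrom_idx),
    pos = within * spacing_bp + 1L,
    ref = "A", alt = "T", is_indel = FALSE, is_multi = FALSE)
  scaff <- tapply(sites$pos, sites$chrom, max) + spacing_bp
  lens <- as.numeric(scaff); names(lens) <- names(scaff)
  gm <- genotype_matrix(dosage, sites, names(cols), scaffold_lengths = lens)
  attr(gm, "popmap") <- popmap
  gm
}

#' Forward Wright-Fisher drift oracle
#'
#' Brute-force check of the drift model: `n_loci` unlinked loci start at
#' frequency `p0` in a diploid population of constant size `N` and evolve
#' by binomial resampling of `2N` allele copies per generation. The
#' realised drift is summarised as `F_hat = Var(p_t) / (p0 (1 - p0))`,
#' with expectation `1 - (1 - 1/(2N))^t`.
#'
#' @param N diploid population size (>= 2).
#' @param t_generations generations to evolve (>= 0).
#' @param p0 starting frequency in (0, 1).
#' @param n_loci number of replicate loci.
#' @param seed RNG seed.
#' @return list with `F_hat`, the final frequencies `p_t`, and the
#'   closed-form `expected` value.
#' @export
wright_fisher_oracle <- function(N, t_generations, p0 = 0.5, n_loci = 5000,
                                 seed = 0) {
  stopifnot(N >= 2, t_generations >= 0, p0 > 0, p0 < 1, n_loci >= 2)
  set.seed(seed)
  p <- rep(p0, n_loci)
  for (g in seq_len(t_generations))
    p <- stats::rbinom(n_loci, 2 * N, p) / (2 * N)
  F_hat <- stats::var(p) / (p0 * (1 - p0))
  list(F_hat = F_hat, p_t = p,
       expected = 1 - (1 - 1 / (2 * N))^t_generations)
}

#' Exact moments of the simulated frequency process
#'
#' Propagates first and second moments of the Balding-Nichols process
#' through the graph: for every pair of nodes the cross-moment
#' `S[u, v] = E[p_u p_v]` follows from the martingale property
#' (`E[p_child | p_parent] = p_parent`), the one-edge variance
#' `F p (1-p)`, and linear mixing at admixture nodes. From `S` come the
#' exact expected heterozygosities `h_v = E[p_v (1 - p_v)]` and expected
#' f2 values between any two nodes -- the closed form that Monte-Carlo
#' simulations are tested against.
#'
#' @param model a [demographic_model()] (edge drifts in F units).
#' @return list with `S` (nodes x nodes), `het` (named vector), and
#'   `f2` (nodes x nodes expected f2 matrix).
#' @export
graph_moments <- function(model) {
  g <- model$graph
  a_ <- model$p_range[1]; b_ <- model$p_range[2]
  m0 <- (a_ + b_) / 2
  m2 <- (b_ - a_)^2 / 12 + m0^2           # E[p0^2] for uniform law
  nodes <- g$nodes
  S <- matrix(NA_real_, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  S[g$root, g$root] <- m2
  e <- g$edges
  done <- g$root
  for (v in g$topo) {
    if (v == g$root) next
    up <- which(e$child == v)
    if (length(up) == 2) {
      a <- e$alpha[up[1]]
      p1 <- e$parent[up[1]]; p2 <- e$parent[up[2]]
      F1 <- e$drift[up[1]]; F2 <- e$drift[up[2]]
      for (u in done)
        S[v, u] <- S[u, v] <- a * S[p1, u] + (1 - a) * S[p2, u]
      # parent-edge drift inflates each source's own second moment only
      S11 <- S[p1, p1] + F1 * (m0 - S[p1, p1])
      S22 <- S[p2, p2] + F2 * (m0 - S[p2, p2])
      S[v, v] <- a^2 * S11 + 2 * a * (1 - a) * S[p1, p2] + (1 - a)^2 * S22
    } else {
      par <- e$parent[up]; F <- e$drift[up]
      for (u in done) S[v, u] <- S[u, v] <- S[par, u]
      h_par <- m0 - S[par, par]
      S[v, v] <- S[par, par] + F * h_par
    }
    done <- c(done, v)
  }
  het <- m0 - diag(S)
  names(het) <- nodes
  f2m <- outer(diag(S), diag(S), "+") - 2 * S
  dimnames(f2m) <- list(nodes, nodes)
  list(S = S, het = het, f2 = f2m)
}

#' Express a Balding-Nichols model in f2 drift units
#'
#' Rescales each edge's F by the expected heterozygosity of its parent
#' node (`d_e = F_e * h_parent`), giving the graph whose
#' [expected_f2()] values equal the exact expectations of the simulated
#' frequency process.
#'
#' @param model a [demographic_model()].
#' @return an [admixture_graph()] with drifts in f2 units.
#' @export
as_f2_graph <- function(model) {
  mom <- graph_moments(model)
  g <- model$graph
  g$edges$drift <- g$edges$drift * mom$het[g$edges$parent]
  g
}

#' The default refugial study scenario
#'
#' A five-population design emulating a refugial phylogeographic study:
#' an outgroup; a deeply divergent "West" lineage; an "East" lineage;
#' sister "Beringia" and "NPC" lineages with NPC carrying the largest
#' pendant drift (an island-bottleneck analogue); and one hybrid
#' population drawing a fraction `alpha` of its ancestry from the East
#' lineage and `1 - alpha` from the Beringia lineage, with a small
#' post-admixture (mixed) pendant drift. All parameters can be
#' overridden.
#'
#' @param alpha admixture proportion from the East-side source
#'   (default 0.6).
#' @param hybrid_drift pendant (mixed) drift of the hybrid, F units
#'   (default 0.02).
#' @param sample_sizes named diploid counts per leaf.
#' @param drifts optional named overrides of edge F values (names are
#'   edge ids `parent->child`).
#' @param p_range ancestral frequency law range.
#' @return a [demographic_model()].
#' @export
make_refugial_scenario <- function(alpha = 0.6, hybrid_drift = 0.02,
                                   sample_sizes = c(Outgroup = 2, West = 4,
                                                    East = 4, Beringia = 4,
                                                    NPC = 2, Hybrid = 2),
                                   drifts = NULL,
                                   p_range = c(0.05, 0.95)) {
  stopifnot(alpha >= 0, alpha <= 1)
  edges <- data.frame(
    child  = c("Outgroup", "anc0", "West", "anc1", "EastAnc", "East",
               "anc2", "BerAnc", "Beringia", "NPC", "HybAnc", "HybAnc",
               "Hybrid"),
    parent = c("root", "root", "anc0", "anc0", "anc1", "EastAnc",
               "anc1", "anc2", "BerAnc", "anc2", "EastAnc", "BerAnc",
               "HybAnc"),
    drift  = c(0.30, 0.10, 0.20, 0.08, 0.06, 0.06,
               0.08, 0.04, 0.04, 0.30, 0, 0,
               hybrid_drift),
    alpha  = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, alpha, 1 - alpha,
               NA))
  if (!is.null(drifts)) {
    ids <- paste(edges$parent, edges$child, sep = "->")
    idx <- match(names(drifts), ids)
    if (anyNA(idx)) stop("unknown edge id in drift overrides")
    edges$drift[idx] <- unname(drifts)
  }
  demographic_model(admixture_graph(edges), sample_sizes, p_range)
}

#' Simulate a full study dataset
#'
#' Frequencies, genotypes, population map and ground truth for a
#' demographic model in one call; the bundle every downstream stage can
#' be exercised on.
#'
#' @param model a [demographic_model()].
#' @param n_sites number of sites (default 100000).
#' @param missing_prob per-call missingness probability.
#' @param sites_per_chrom sites per synthetic scaffold.
#' @param seed RNG seed; genotype sampling uses `seed + 1`.
#' @return list with `gm` (genotype matrix), `popmap`, `freqs` (leaf
#'   frequency matrix), and `truth` (model, seed, f2-unit graph).
#' @export
simulate_study <- function(model, n_sites = 1e5, missing_prob = 0.02,
                           sites_per_chrom = 5000, seed = 0) {
  P <- simulate_frequencies(model, n_sites, seed = seed)
  leafP <- P[, model$graph$leaves, drop = FALSE]
  gm <- simulate_genotypes(leafP, model$sample_sizes,
                           missing_prob = missing_prob,
                           sites_per_chrom = sites_per_chrom,
                           seed = seed + 1)
  list(gm = gm, popmap = attr(gm, "popmap"), freqs = leafP,
       truth = list(model = model, seed = seed,
                    f2_graph = as_f2_graph(model)))
}
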
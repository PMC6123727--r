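#' Fit an admixture graph to an observed f2 matrix
#'
#' Minimises the weighted sum of squared residuals
#' `sum_pairs ((obs_f2 - expected_f2) / se)^2` over non-negative edge
#' drifts and admixture proportions in \code{[0, 1]}, for a fixed
#' topology. For fixed admixture proportions the expected f2 values are
#' linear in the drifts, so drifts are profiled out exactly by
#' non-negative least squares; the remaining low-dimensional search over
#' proportions uses a dense grid of starts followed by bounded local
#' refinement. Note that some drift combinations are inherently
#' confounded (e.g. the two edges meeting at the root enter every leaf
#' pair identically, so only their sum is identified); fitted values for
#' such edges are one representative of an equivalence class with
#' identical expected statistics.
#'
#' @param f2_obs symmetric matrix of observed f2 values (dimnames are
#'   leaf names; must cover all leaves of `topology`).
#' @param topology an [admixture_graph()]; edges with `NA` drift are
#'   fitted and edges with a numeric drift are held fixed (use
#'   [free_graph_params()] to release a fully specified graph), likewise
#'   `NA` admixture proportions are fitted and numeric ones kept.
#' @param f2_se optional symmetric matrix of standard errors for
#'   weighting (`NULL` for unweighted least squares).
#' @param n_starts number of starting values per free admixture
#'   proportion (default 11, a grid over \code{[0, 1]}).
#' @param seed seed for the extra random starts used when more than one
#'   proportion is free.
#' @return a `graph_fit`: list with the fitted `graph`, named `drifts`
#'   and `alphas`, `objective`, `residuals`, `fitted` f2 matrix,
#'   `converged` and `n_starts`.
#' @export
fit_graph <- function(f2_obs, topology, f2_se = NULL, n_starts = 11,
                      seed = 0) {
  leaves <- topology$leaves
  miss <- setdiff(leaves, rownames(f2_obs))
  if (length(miss))
    stop("f2 observations missing for leaf/leaves: ",
         paste(miss, collapse = ", "))
  pairs <- utils::combn(leaves, 2)
  b <- apply(pairs, 2, function(pr) f2_obs[pr[1], pr[2]])
  wt <- if (is.null(f2_se)) rep(1, ncol(pairs)) else
    1 / apply(pairs, 2, function(pr) f2_se[pr[1], pr[2]])
  if (any(!is.finite(wt))) stop("non-finite weights (zero stderr?)")

  e <- topology$edges
  free_admix <- topology$admix_nodes[
    vapply(topology$admix_nodes,
           function(a) anyNA(e$alpha[e$child == a]), logical(1))]
  k_free <- length(free_admix)
  free_d <- is.na(e$drift)
  d_fixed <- ifelse(free_d, 0, e$drift)

  solve_at <- function(alphas) {
    g <- topology
    if (k_free)
      g <- set_graph_params(g, alphas = as.list(stats::setNames(alphas,
                                                                free_admix)))
    W <- path_weights(g)
    A <- t(apply(pairs, 2, function(pr) (W[pr[1], ] - W[pr[2], ])^2))
    b_adj <- b - as.vector(A %*% d_fixed)
    d <- d_fixed
    if (any(free_d))
      d[free_d] <- nnls_solve(A[, free_d, drop = FALSE] * wt, b_adj * wt)
    resid <- as.vector(A %*% d) - b
    list(graph = g, d = d, obj = sum((resid * wt)^2), resid = resid)
  }

  if (k_free == 0) {
    best <- solve_at(numeric(0)); best_alpha <- numeric(0); conv <- TRUE
  } else if (k_free == 1) {
    grid <- seq(0, 1, length.out = max(n_starts, 3))
    objs <- vapply(grid, function(a) solve_at(a)$obj, numeric(1))
    a0 <- grid[which.min(objs)]
    opt <- stats::optimize(function(a) solve_at(a)$obj,
                           lower = max(0, a0 - 0.15),
                           upper = min(1, a0 + 0.15), tol = 1e-6)
    best_alpha <- if (opt$objective < min(objs)) opt$minimum else a0
    best <- solve_at(best_alpha)
    conv <- TRUE
  } else {
    set.seed(seed)
    starts <- matrix(stats::runif(n_starts * k_free), n_starts, k_free)
    starts[1, ] <- 0.5
    best <- NULL; best_alpha <- NULL; conv <- FALSE
    for (s in seq_len(n_starts)) {
      opt <- stats::optim(starts[s, ], function(a) solve_at(a)$obj,
                          method = "L-BFGS-B", lower = 0, upper = 1)
      if (is.null(best) || opt$value < best$obj - 1e-12) {
        best <- solve_at(opt$par); best_alpha <- opt$par
        conv <- opt$convergence == 0
      }
    }
  }

  g <- set_graph_params(best$graph,
                        drifts = stats::setNames(best$d, e$id))
  pair_id <- apply(pairs, 2, paste, collapse = ":")
  fitted <- f2_obs[leaves, leaves, drop = FALSE]
  fitted[] <- 0
  for (j in seq_len(ncol(pairs)))
    fitted[pairs[1, j], pairs[2, j]] <- fitted[pairs[2, j], pairs[1, j]] <-
      b[j] + best$resid[j]
  structure(list(graph = g,
                 drifts = stats::setNames(best$d, e$id),
                 alphas = stats::setNames(best_alpha, free_admix),
                 objective = best$obj,
                 residuals = stats::setNames(best$resid, pair_id),
                 fitted = fitted, converged = conv, n_starts = n_starts,
                 topology = topology),
            class = "graph_fit")
}

# non-negative least squares, robust to collinear columns: exactly
# duplicated columns (confounded edges, e.g. the two halves of a split
# edge when alpha hits 0 or 1) are collapsed before the active-set solve,
# with a bounded quasi-Newton fallback for the remaining ill-conditioned
# cases -- the objective is a convex quadratic either way
nnls_solve <- function(A, b) {
  p <- ncol(A)
  if (p == 0) return(numeric(0))
  key <- apply(round(A, 12), 2, paste, collapse = ",")
  rep_idx <- match(key, key)            # first column of each duplicate set
  uniq <- which(rep_idx == seq_len(p))
  Au <- A[, uniq, drop = FALSE]
  xu <- tryCatch(pracma::lsqnonneg(Au, b)$x, error = function(e) NULL)
  if (is.null(xu)) {
    obj <- function(x) { r <- as.vector(Au %*% x) - b; sum(r * r) }
    grad <- function(x) 2 * as.vector(crossprod(Au, as.vector(Au %*% x) - b))
    opt <- stats::optim(rep(0, length(uniq)), obj, grad,
                        method = "L-BFGS-B", lower = 0,
                        control = list(factr = 1e4, maxit = 500))
    xu <- opt$par
  }
  x <- numeric(p)
  x[uniq] <- xu
  x[rep_idx != seq_len(p)] <- 0
  x
}

#' Release graph parameters for fitting
#'
#' Sets drift lengths (and optionally admixture proportions) to `NA` so
#' that [fit_graph()] treats them as free parameters.
#'
#' @param graph an [admixture_graph()].
#' @param free_alphas also free the admixture proportions?
#' @return the graph with parameters released.
#' @export
free_graph_params <- function(graph, free_alphas = TRUE) {
  graph$edges$drift <- NA_real_
  if (free_alphas) graph$edges$alpha[!is.na(graph$edges$alpha)] <- NA_real_
  graph
}

#' @export
print.graph_fit <- function(x, ...) {
  cat(sprintf("graph_fit: objective %.4g, %d edges%s\n", x$objective,
              length(x$drifts),
              if (length(x$alphas))
                paste0(", alpha = ",
                       paste(sprintf("%s: %.3f", names(x$alphas), x$alphas),
                             collapse = ", "))
              else ""))
  invisible(x)
}

#' Graft a hybrid onto two backbone edges
#'
#' Builds the placement topology for one candidate attachment pair: each
#' attachment edge is split at a new node (both halves free, so the
#' attachment position along the edge is implicit), an admixture node
#' with a free proportion joins the two attachment points through
#' zero-length source edges, and a free pendant edge (the mixed drift)
#' leads to the hybrid leaf.
#'
#' @param backbone an admixture-free [admixture_graph()].
#' @param edge1,edge2 edge ids (`"parent->child"`) of the two attachment
#'   edges; `alpha` is the fraction inherited via `edge1`.
#' @param hybrid name for the new hybrid leaf.
#' @return an [admixture_graph()] ready for [fit_graph()].
#' @export
build_attachment_graph <- function(backbone, edge1, edge2, hybrid) {
  e <- backbone$edges[, c("child", "parent", "drift", "alpha")]
  e$drift <- NA_real_
  split_edge <- function(tab, id, att) {
    k <- which(paste(tab$parent, tab$child, sep = "->") == id)
    row <- tab[k, ]
    tab <- tab[-k, ]
    rbind(tab,
          data.frame(child = att, parent = row$parent, drift = NA_real_,
                     alpha = NA_real_),
          data.frame(child = row$child, parent = att, drift = NA_real_,
                     alpha = NA_real_))
  }
  e <- split_edge(e, edge1, ".att1")
  e <- split_edge(e, edge2, ".att2")
  anc <- paste0(hybrid, "_anc")
  e <- rbind(e,
             data.frame(child = anc, parent = ".att1", drift = 0,
                        alpha = NA_real_),
             data.frame(child = anc, parent = ".att2", drift = 0,
                        alpha = NA_real_),
             data.frame(child = hybrid, parent = anc, drift = NA_real_,
                        alpha = NA_real_))
  admixture_graph(e)
}

# eligible attachment edges: all backbone edges, with the two edges
# meeting at the root collapsed to one candidate (attachment to either
# is the same unrooted placement)
candidate_edges <- function(backbone) {
  ids <- backbone$edges$id
  root_edges <- ids[backbone$edges$parent == backbone$root]
  if (length(root_edges) == 2) ids <- setdiff(ids, root_edges[2])
  ids
}

#' Enumerate hybrid placements on a backbone tree
#'
#' For every unordered pair of distinct backbone edges, grafts the hybrid
#' as a two-way admixture between attachment points on those edges and
#' fits all drifts plus the admixture proportion by [fit_graph()];
#' attachment positions along each edge need no extra parameters because
#' splitting an edge leaves both halves free. Placements are ranked by
#' fit score (weighted residual sum of squares), best first. The two
#' edges meeting at the root count as a single candidate (same unrooted
#' placement).
#'
#' @param backbone an [admixture_graph()] tree (no admixture nodes) over
#'   the non-admixed populations; drift values are ignored.
#' @param hybrid name of the hybrid population.
#' @param f2_obs observed f2 matrix covering the backbone leaves and the
#'   hybrid.
#' @param f2_se optional stderr matrix for weighting.
#' @return data.frame ranked by `score` with columns `edge1`, `edge2`,
#'   `alpha` (fraction from the `edge1` attachment), `mixed_drift` (the
#'   hybrid's fitted pendant drift, f2 units), `score`, `converged`; the
#'   per-placement `graph_fit` objects are attached as attribute `fits`.
#' @export
enumerate_hybrid_placements <- function(backbone, hybrid, f2_obs,
                                        f2_se = NULL) {
  if (length(backbone$admix_nodes))
    stop("backbone must be admixture-free")
  if (length(backbone$leaves) < 3) stop("backbone too small")
  cand <- candidate_edges(backbone)
  if (length(cand) < 2) stop("fewer than 2 eligible attachment edges")
  prs <- utils::combn(cand, 2)
  rows <- vector("list", ncol(prs)); fits <- vector("list", ncol(prs))
  for (k in seq_len(ncol(prs))) {
    g <- build_attachment_graph(backbone, prs[1, k], prs[2, k], hybrid)
    fit <- fit_graph(f2_obs, g, f2_se = f2_se)
    pend <- paste0(hybrid, "_anc->", hybrid)
    rows[[k]] <- data.frame(
      edge1 = prs[1, k], edge2 = prs[2, k],
      alpha = unname(fit$alphas[1]),
      mixed_drift = unname(fit$drifts[pend]),
      score = fit$objective, converged = fit$converged)
    fits[[k]] <- fit
  }
  out <- do.call(rbind, rows)
  ord <- order(out$score)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  out
}

#' Block-bootstrap interval for mixed drift and admixture proportion
#'
#' Resamples SNP blocks with replacement, rebuilds the observed f2 matrix
#' from the per-block accumulations, refits the chosen placement graph,
#' and returns percentile intervals for the hybrid's pendant (mixed)
#' drift and the admixture proportion. Seeded and reproducible.
#'
#' @param bs per-block f2 accumulations from [block_f2_sums()]; must
#'   cover all leaves of `placement_graph`.
#' @param placement_graph the augmented graph of the chosen placement
#'   (`attr(placements, "fits")[[1]]$topology`, or rebuilt with
#'   [build_attachment_graph()]).
#' @param hybrid name of the hybrid leaf.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param f2_se optional stderr matrix used as fixed weights in every
#'   refit.
#' @param probs percentile probabilities (default 2.5% / 97.5%).
#' @return list with `mixed_drift` and `alpha`, each `c(estimate, lower,
#'   upper)`, plus the bootstrap `replicates` data.frame.
#' @export
bootstrap_mixed_drift <- function(bs, placement_graph, hybrid,
                                  n_boot = 1000, seed = 0, f2_se = NULL,
                                  probs = c(0.025, 0.975)) {
  g_blocks <- ncol(bs$sums)
  if (g_blocks < 2) stop("need at least 2 blocks")
  stopifnot(n_boot >= 1)
  pend <- paste0(hybrid, "_anc->", hybrid)
  refit <- function(f2m) {
    fit <- fit_graph(f2m, placement_graph, f2_se = f2_se)
    c(mixed_drift = unname(fit$drifts[pend]),
      alpha = unname(fit$alphas[1]))
  }
  point <- refit(f2_matrix_from_blocks(bs))
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 2,
                 dimnames = list(NULL, c("mixed_drift", "alpha")))
  for (r in seq_len(n_boot)) {
    idx <- sample.int(g_blocks, g_blocks, replace = TRUE)
    reps[r, ] <- refit(f2_matrix_from_blocks(bs, idx))
  }
  ci <- apply(reps, 2, stats::quantile, probs = probs)
  list(mixed_drift = c(estimate = unname(point["mixed_drift"]),
                       lower = ci[1, "mixed_drift"],
                       upper = ci[2, "mixed_drift"]),
       alpha = c(estimate = unname(point["alpha"]),
                 lower = ci[1, "alpha"], upper = ci[2, "alpha"]),
       replicates = as.data.frame(reps))
}
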
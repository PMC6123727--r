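#' Construct an admixture graph
#'
#' A rooted directed acyclic graph of populations. Every edge carries a
#' non-negative drift length; a node with two parents is an admixture
#' node that inherits a fraction `alpha` of its ancestry from the
#' first-listed parent edge and `1 - alpha` from the second. Drift lengths
#' are in f2 units (expected squared allele-frequency change) unless a
#' simulation model states otherwise.
#'
#' @param edges data.frame with columns `child`, `parent`, `drift`
#'   (non-negative; `NA` allowed for to-be-fitted graphs) and optionally
#'   `alpha` (admixture weight of the edge, `NA` on ordinary edges; the
#'   two parent edges of an admixture node must carry `a` and `1 - a`, or
#'   both `NA` for a free parameter).
#' @return an `admixture_graph`: list with the edge table (stable edge
#'   `id`s), `nodes`, `root`, `leaves`, `admix_nodes` and a topological
#'   order.
#' @export
admixture_graph <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  if (is.null(edges$drift)) edges$drift <- NA_real_
  if (is.null(edges$alpha)) edges$alpha <- NA_real_
  edges$id <- paste(edges$parent, edges$child, sep = "->")
  if (anyDuplicated(edges$id)) stop("duplicate edge")
  nodes <- unique(c(edges$parent, edges$child))
  n_parents <- table(factor(edges$child, levels = nodes))
  root <- nodes[n_parents[nodes] == 0]
  if (length(root) != 1)
    stop("graph must have exactly one root, found: ",
         paste(root, collapse = ", "))
  if (any(n_parents > 2)) stop("nodes may have at most two parents")
  admix_nodes <- names(n_parents)[n_parents == 2]
  leaves <- setdiff(nodes, edges$parent)
  bad_d <- !is.na(edges$drift) & edges$drift < 0
  if (any(bad_d)) stop("negative drift on edge(s): ",
                       paste(edges$id[bad_d], collapse = ", "))
  bad_a <- !is.na(edges$alpha) & (edges$alpha < 0 | edges$alpha > 1)
  if (any(bad_a)) stop("alpha outside [0, 1]")
  for (a in admix_nodes) {
    al <- edges$alpha[edges$child == a]
    if (all(!is.na(al)) && abs(sum(al) - 1) > 1e-8)
      stop("admixture weights at '", a, "' must sum to 1")
  }
  topo <- topo_order(edges, nodes, root)
  g <- structure(list(edges = edges, nodes = nodes, root = root,
                      leaves = leaves, admix_nodes = admix_nodes,
                      topo = topo),
                 class = "admixture_graph")
  g
}

# Kahn's algorithm; errors on cycles, checks reachability from the root
topo_order <- function(edges, nodes, root) {
  indeg <- table(factor(edges$child, levels = nodes))
  order <- character(0)
  queue <- nodes[indeg == 0]
  indeg <- as.vector(indeg); names(indeg) <- nodes
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    kids <- edges$child[edges$parent == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) != length(nodes)) stop("graph contains a cycle")
  # reachability from root
  seen <- root
  repeat {
    new <- setdiff(edges$child[edges$parent %in% seen], seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  if (length(seen) != length(nodes))
    stop("node(s) unreachable from root: ",
         paste(setdiff(nodes, seen), collapse = ", "))
  order
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat(sprintf("admixture_graph: %d nodes, %d edges, %d leaves, %d admixture node(s)\n",
              length(x$nodes), nrow(x$edges), length(x$leaves),
              length(x$admix_nodes)))
  cat("  root:", x$root, "\n  leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write an admixture graph as an edge-list TSV
#'
#' Columns: child, parent, drift, alpha (empty on ordinary edges).
#'
#' @param path TSV file.
#' @return `read_graph`: an [admixture_graph()]; `write_graph`: `path`.
#' @export
read_graph <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  admixture_graph(tab)
}

#' @rdname read_graph
#' @param graph an `admixture_graph`.
#' @export
write_graph <- function(graph, path) {
  utils::write.table(graph$edges[, c("child", "parent", "drift", "alpha")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Leaf-to-edge path weights
#'
#' For each leaf, propagates mass 1 upward toward the root, splitting
#' `alpha : (1 - alpha)` across the two parent edges at admixture nodes.
#' The weight on an edge is the fraction of the leaf's ancestry that
#' drifted along it; weights over any cut separating the leaf from the
#' root sum to 1. This is the bookkeeping behind all expected
#' f-statistics on the graph.
#'
#' @param graph an [admixture_graph()] with all `alpha` values set.
#' @return matrix leaves x edges of weights in \code{[0, 1]}
#'   (dimnames: leaf names, edge ids).
#' @export
path_weights <- function(graph) {
  e <- graph$edges
  if (any(is.na(e$alpha[e$child %in% graph$admix_nodes])))
    stop("path weights need all admixture proportions set")
  W <- matrix(0, length(graph$leaves), nrow(e),
              dimnames = list(graph$leaves, e$id))
  # mass per (leaf, node), propagated rootward for all leaves at once
  M <- matrix(0, length(graph$leaves), length(graph$nodes),
              dimnames = list(graph$leaves, graph$nodes))
  M[cbind(seq_along(graph$leaves), match(graph$leaves, graph$nodes))] <- 1
  for (v in rev(graph$topo)) {
    up <- which(e$child == v)
    if (!length(up)) next
    for (k in up) {
      w <- if (length(up) == 2) e$alpha[k] else 1
      W[, k] <- M[, v] * w
      M[, e$parent[k]] <- M[, e$parent[k]] + M[, v] * w
    }
  }
  W
}

#' Expected f-statistics under a graph
#'
#' `expected_f2(i, j) = sum_e d_e (w_i(e) - w_j(e))^2` with `w` the
#' [path_weights()]; f3 and f4 follow through the exact identities
#' `f3(c; a, b) = (f2(c,a) + f2(c,b) - f2(a,b)) / 2` and
#' `f4(a, b; c, d) = (f2(a,d) + f2(b,c) - f2(a,c) - f2(b,d)) / 2`.
#' Under the Gaussian drift model these are the exact expectations of the
#' sample statistics; an admixed leaf can yield negative expected f3.
#'
#' @param graph an [admixture_graph()] with drifts and alphas set.
#' @param i,j,a,b,c,d leaf names.
#' @param W optional precomputed [path_weights()] matrix.
#' @return numeric expectation.
#' @export
expected_f2 <- function(graph, i, j, W = NULL) {
  if (is.null(W)) W <- path_weights(graph)
  if (!all(c(i, j) %in% rownames(W))) stop("unknown leaf")
  d <- graph$edges$drift
  if (anyNA(d)) stop("graph has unset drift lengths")
  sum(d * (W[i, ] - W[j, ])^2)
}

#' @rdname expected_f2
#' @export
expected_f2_matrix <- function(graph, W = NULL) {
  if (is.null(W)) W <- path_weights(graph)
  leaves <- rownames(W)
  d <- graph$edges$drift
  k <- length(leaves)
  out <- matrix(0, k, k, dimnames = list(leaves, leaves))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    out[i, j] <- out[j, i] <- sum(d * (W[i, ] - W[j, ])^2)
  out
}

#' @rdname expected_f2
#' @export
expected_f3 <- function(graph, c, a, b, W = NULL) {
  if (is.null(W)) W <- path_weights(graph)
  (expected_f2(graph, c, a, W) + expected_f2(graph, c, b, W) -
     expected_f2(graph, a, b, W)) / 2
}

#' @rdname expected_f2
#' @export
expected_f4 <- function(graph, a, b, c, d, W = NULL) {
  if (is.null(W)) W <- path_weights(graph)
  (expected_f2(graph, a, d, W) + expected_f2(graph, b, c, W) -
     expected_f2(graph, a, c, W) - expected_f2(graph, b, d, W)) / 2
}

#' Replace graph parameters
#'
#' Returns a copy of the graph with drift lengths and/or admixture
#' proportions substituted; used by the fitting routines.
#'
#' @param graph an [admixture_graph()].
#' @param drifts numeric vector over edges (length `nrow(graph$edges)`),
#'   or named by edge id.
#' @param alphas named vector: admixture node -> proportion on its
#'   first-listed parent edge.
#' @return the updated `admixture_graph`.
#' @export
set_graph_params <- function(graph, drifts = NULL, alphas = NULL) {
  if (!is.null(drifts)) {
    if (!is.null(names(drifts))) {
      idx <- match(names(drifts), graph$edges$id)
      if (anyNA(idx)) stop("unknown edge id in drifts")
      graph$edges$drift[idx] <- unname(drifts)
    } else {
      stopifnot(length(drifts) == nrow(graph$edges))
      graph$edges$drift <- drifts
    }
  }
  if (!is.null(alphas)) {
    for (a in names(alphas)) {
      k <- which(graph$edges$child == a)
      if (length(k) != 2) stop("'", a, "' is not an admixture node")
      graph$edges$alpha[k] <- c(alphas[[a]], 1 - alphas[[a]])
    }
  }
  graph
}

#' Convert an ape phylogeny to an admixture graph
#'
#' Turns a rooted `phylo` tree into the package's graph representation;
#' branch lengths become drift lengths (or `NA` when absent, for a
#' topology to be fitted).
#'
#' @param phy an [ape::phylo] object, rooted.
#' @return an [admixture_graph()].
#' @export
phylo_to_graph <- function(phy) {
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  n_tip <- length(phy$tip.label)
  lab <- function(v) if (v <= n_tip) phy$tip.label[v] else paste0("n", v)
  edges <- data.frame(
    child = vapply(phy$edge[, 2], lab, character(1)),
    parent = vapply(phy$edge[, 1], lab, character(1)),
    drift = if (is.null(phy$edge.length)) NA_real_ else phy$edge.length,
    alpha = NA_real_)
  admixture_graph(edges)
}
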
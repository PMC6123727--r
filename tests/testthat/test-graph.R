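# worked 7-edge admixture graph used across several tests:
# B and C sister-ish lineages, X a 60/40 hybrid of their ancestors
worked_graph <- function(alpha = 0.6, d_e5 = 0.01, d_e6 = 0.02,
                         d_pend = 0.005) {
  admixture_graph(data.frame(
    child  = c("sB", "sC", "B", "C", "xan", "xan", "X"),
    parent = c("root", "root", "sB", "sC", "sB", "sC", "xan"),
    drift  = c(0.05, 0.08, 0.03, 0.04, d_e5, d_e6, d_pend),
    alpha  = c(NA, NA, NA, NA, alpha, 1 - alpha, NA)))
}

test_that("graph construction validates structure", {
  g <- worked_graph()
  expect_equal(g$root, "root")
  expect_setequal(g$leaves, c("B", "C", "X"))
  expect_equal(g$admix_nodes, "xan")

  two_roots <- data.frame(child = c("A", "B"), parent = c("r1", "r2"),
                          drift = 0.1)
  expect_error(admixture_graph(two_roots), "exactly one root")
  cyc <- data.frame(child = c("A", "B", "r", "A"),
                    parent = c("r", "A", "B", "q"), drift = 0.1)
  expect_error(admixture_graph(cyc), "cycle|root")
  bad_a <- worked_graph()
  ed <- bad_a$edges[, c("child", "parent", "drift", "alpha")]
  ed$alpha[5:6] <- c(0.6, 0.6)
  expect_error(admixture_graph(ed), "sum to 1")
  ed2 <- worked_graph()$edges
  ed2$drift[1] <- -0.1
  expect_error(admixture_graph(ed2[, 1:4]), "negative drift")
})

test_that("path weights propagate mass with admixture splitting", {
  # two-leaf tree: everything on the pendant edges
  tr <- admixture_graph(data.frame(child = c("A", "B"),
                                   parent = c("root", "root"),
                                   drift = c(0.1, 0.2)))
  W <- path_weights(tr)
  expect_equal(W["A", "root->A"], 1)
  expect_equal(W["A", "root->B"], 0)

  # hand-propagated weights for the worked hybrid graph
  W <- path_weights(worked_graph(0.5))
  expect_equal(W["X", "xan->X"], 1)
  expect_equal(W["X", "sB->xan"], 0.5)
  expect_equal(W["X", "sC->xan"], 0.5)
  expect_equal(W["X", "root->sB"], 0.5)
  expect_equal(W["X", "root->sC"], 0.5)
  expect_equal(W["X", "sB->B"], 0)
  expect_equal(W["B", "root->sB"], 1)
  # mass crossing the root cut sums to 1 for every leaf
  root_edges <- c("root->sB", "root->sC")
  expect_equal(unname(rowSums(W[, root_edges])), c(1, 1, 1))

  # degenerate admixture alpha = 1 follows parent 1 only
  W1 <- path_weights(worked_graph(1))
  expect_equal(W1["X", "sC->xan"], 0)
  expect_equal(W1["X", "root->sC"], 0)
  expect_equal(W1["X", "root->sB"], 1)
})

test_that("expected f2 matches a per-edge hand evaluation", {
  tr <- admixture_graph(data.frame(child = c("A", "B"),
                                   parent = c("root", "root"),
                                   drift = c(0.1, 0.2)))
  expect_equal(expected_f2(tr, "A", "B"), 0.3)
  expect_equal(expected_f2(tr, "A", "A"), 0)

  # worked graph, alpha = 0.6: sum over the seven edges written out
  g <- worked_graph()
  hand <- 0.05 * (0.6 - 1)^2 + 0.08 * 0.4^2 + 0.03 * 1 + 0.04 * 0 +
    0.01 * 0.6^2 + 0.02 * 0.4^2 + 0.005 * 1
  expect_equal(expected_f2(g, "X", "B"), hand, tolerance = 1e-14)
  expect_error(expected_f2(g, "X", "nope"), "unknown leaf")
})

test_that("tree expectations: f3 non-negative, concordant f4 zero", {
  tree <- admixture_graph(data.frame(
    child  = c("n1", "n2", "A", "B", "C", "D"),
    parent = c("root", "root", "n1", "n1", "n2", "n2"),
    drift  = c(0.07, 0.02, 0.05, 0.11, 0.04, 0.09)))
  leaves <- tree$leaves
  for (cc in leaves) {
    rest <- setdiff(leaves, cc)
    prs <- combn(rest, 2)
    for (k in seq_len(ncol(prs)))
      expect_gte(expected_f3(tree, cc, prs[1, k], prs[2, k]), 0)
  }
  expect_equal(expected_f4(tree, "A", "B", "C", "D"), 0, tolerance = 1e-14)
  # discordant arrangements pick up the shared internal drift, with sign
  # set by the direction the two paths traverse it (here: both A->C and
  # B->D cross from the (A,B) side to the (C,D) side)
  expect_equal(expected_f4(tree, "A", "C", "B", "D"),
               0.07 + 0.02, tolerance = 1e-14)

  # admixed leaf with small pendant drift: negative f3 between sources
  g <- worked_graph(d_e5 = 0, d_e6 = 0, d_pend = 0.001)
  expect_lt(expected_f3(g, "X", "B", "C"), 0)
})

test_that("alpha = 1 admixture collapses to the corresponding tree", {
  g1 <- worked_graph(alpha = 1, d_e5 = 0.01, d_e6 = 0.02, d_pend = 0.005)
  tr <- admixture_graph(data.frame(
    child  = c("sB", "sC", "B", "C", "xan", "X"),
    parent = c("root", "root", "sB", "sC", "sB", "xan"),
    drift  = c(0.05, 0.08, 0.03, 0.04, 0.01, 0.005)))
  expect_equal(expected_f2_matrix(g1)[tr$leaves, tr$leaves],
               expected_f2_matrix(tr), tolerance = 1e-14)
})

test_that("root placement does not affect expected f2", {
  # same unrooted tree, root shifted along the central edge
  t1 <- admixture_graph(data.frame(
    child  = c("n1", "n2", "A", "B", "C", "D"),
    parent = c("root", "root", "n1", "n1", "n2", "n2"),
    drift  = c(0.06, 0.03, 0.05, 0.11, 0.04, 0.09)))
  t2 <- admixture_graph(data.frame(
    child  = c("n1", "n2", "A", "B", "C", "D"),
    parent = c("root", "root", "n1", "n1", "n2", "n2"),
    drift  = c(0.01, 0.08, 0.05, 0.11, 0.04, 0.09)))
  expect_equal(expected_f2_matrix(t1), expected_f2_matrix(t2),
               tolerance = 1e-14)
})

test_that("post-admixture source drift is confounded with mixed drift", {
  a <- 0.6
  g_sources <- worked_graph(a, d_e5 = 0.01, d_e6 = 0.02, d_pend = 0.005)
  g_pendant <- worked_graph(a, d_e5 = 0, d_e6 = 0,
                            d_pend = 0.005 + a^2 * 0.01 + (1 - a)^2 * 0.02)
  expect_equal(expected_f2_matrix(g_sources), expected_f2_matrix(g_pendant),
               tolerance = 1e-14)
})

test_that("expected f2 agrees with Monte-Carlo simulation", {
  mod <- demographic_model(worked_graph(), c(B = 2, C = 2, X = 2))
  P <- simulate_frequencies(mod, 5e4, seed = 99)
  g2 <- as_f2_graph(mod)
  for (pr in list(c("X", "B"), c("X", "C"), c("B", "C"))) {
    d2 <- (P[, pr[1]] - P[, pr[2]])^2
    mc <- mean(d2); se <- sd(d2) / sqrt(length(d2))
    expect_lt(abs(mc - expected_f2(g2, pr[1], pr[2])), 3 * se)
  }
})

test_that("graph TSV roundtrip and phylo conversion work", {
  g <- worked_graph()
  path <- tempfile(fileext = ".tsv")
  write_graph(g, path)
  back <- read_graph(path)
  expect_equal(back$edges[, c("child", "parent", "drift", "alpha")],
               g$edges[, c("child", "parent", "drift", "alpha")])
  expect_equal(expected_f2_matrix(back), expected_f2_matrix(g))

  phy <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.3):0;")
  gt <- phylo_to_graph(phy)
  expect_setequal(gt$leaves, c("A", "B", "C"))
  expect_equal(expected_f2(gt, "A", "B"), 0.3, tolerance = 1e-14)
  expect_equal(expected_f2(gt, "A", "C"), 0.45, tolerance = 1e-14)
})
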
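test_that("allele frequencies follow the dosage arithmetic", {
  dosage <- matrix(c(1, NA,
                     2, 1,
                     NA, NA), nrow = 3, byrow = TRUE,
                   dimnames = list(NULL, c("x1", "y1")))
  dosage <- cbind(dosage, y2 = c(NA, 2, NA))
  gm <- gm_from_dosage(dosage)
  aft <- allele_frequencies(gm, c(x1 = "X", y1 = "Y", y2 = "Y"))
  expect_equal(unname(aft$p[1, "X"]), 0.5)            # one het diploid
  expect_equal(unname(aft$p[2, "Y"]), 0.75)           # dosages {1, 2}
  expect_equal(unname(aft$n[2, "Y"]), 4)
  expect_true(is.na(aft$p[3, "X"]))           # all calls missing
  expect_equal(unname(aft$n[3, "X"]), 0)
  expect_error(allele_frequencies(gm, c(x1 = "X", y1 = "Y")), "missing")
  expect_error(allele_frequencies(gm, c(x1 = "X", y1 = "Y", y2 = "Y"),
                                  pops = c("X", "Z")), "zero samples")
})

test_that("f2, f3, f4 reproduce hand-computed toy values", {
  p <- cbind(A = c(1, 0.5, 0), B = c(0.5, 0.5, 0.5))
  aft <- aft_from_p(p)
  expect_equal(f2(aft, "A", "B")$estimate, 1 / 6, tolerance = 1e-12)
  expect_equal(f2(aft, "A", "A")$estimate, 0)

  p3 <- cbind(C = c(0.5, 0.5), A = c(1, 0), B = c(0, 1))
  aft3 <- aft_from_p(p3)
  expect_equal(f3(aft3, "C", "A", "B")$estimate, -0.25)

  p4 <- cbind(A = c(1, 0.5), B = c(0, 0.5), C = c(1, 1), D = c(0, 0))
  aft4 <- aft_from_p(p4)
  expect_equal(f4(aft4, "A", "B", "C", "D")$estimate, 0.5)
})

test_that("f-statistics equal the naive per-site oracle on small tables", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    p <- matrix(runif(4 * n), n, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
    if (rep == 3) p[1, "B"] <- NA     # pairwise deletion honoured
    aft <- aft_from_p(p)
    expect_equal(f2(aft, "A", "B")$estimate, naive_f2(p[, "A"], p[, "B"]),
                 tolerance = 1e-15)
    expect_equal(f3(aft, "C", "A", "B")$estimate,
                 naive_f3(p[, "C"], p[, "A"], p[, "B"]), tolerance = 1e-15)
    expect_equal(f4(aft, "A", "B", "C", "D")$estimate,
                 naive_f4(p[, "A"], p[, "B"], p[, "C"], p[, "D"]),
                 tolerance = 1e-15)
  }
})

test_that("algebraic identities among f2, f3, f4 hold to machine precision", {
  set.seed(202)
  for (rep in 1:25) {
    aft <- random_aft(50, c("A", "B", "C", "D"))
    f3_direct <- f3(aft, "C", "A", "B")$estimate
    f3_from_f2 <- (f2(aft, "C", "A")$estimate + f2(aft, "C", "B")$estimate -
                     f2(aft, "A", "B")$estimate) / 2
    expect_equal(f3_direct, f3_from_f2, tolerance = 1e-13)

    f4_direct <- f4(aft, "A", "B", "C", "D")$estimate
    f4_from_f2 <- (f2(aft, "A", "D")$estimate + f2(aft, "B", "C")$estimate -
                     f2(aft, "A", "C")$estimate -
                     f2(aft, "B", "D")$estimate) / 2
    expect_equal(f4_direct, f4_from_f2, tolerance = 1e-13)

    arr_sum <- f4_direct + f4(aft, "A", "C", "D", "B")$estimate +
      f4(aft, "A", "D", "B", "C")$estimate
    expect_equal(arr_sum, 0, tolerance = 1e-13)
  }
})

test_that("symmetries and degenerate arguments behave", {
  set.seed(33)
  aft <- random_aft(40, c("A", "B", "C", "D"))
  expect_equal(f2(aft, "A", "B")$estimate, f2(aft, "B", "A")$estimate)
  expect_true(f2(aft, "A", "B")$estimate >= 0)
  # f3(C; A, A) collapses to f2(C, A)
  p <- aft$p; p <- cbind(p, A2 = p[, "A"])
  aft2 <- aft_from_p(p, cbind(aft$n, A2 = aft$n[, "A"]))
  expect_equal(f3(aft2, "C", "A", "A2")$estimate,
               f2(aft2, "C", "A")$estimate, tolerance = 1e-13)
  # f4 with an identical pair is exactly zero
  expect_equal(f4(aft2, "B", "C", "A", "A2")$estimate, 0)
  # swapping one pair flips the sign
  expect_equal(f4(aft, "B", "A", "C", "D")$estimate,
               -f4(aft, "A", "B", "C", "D")$estimate)
  expect_error(f3(aft, "A", "A", "B"), "differ")
  expect_error(f4(aft, "A", "A", "C", "D"), "distinct")
  expect_error(f2(aft, "A", "Z"), "not in")
})

test_that("point estimates are invariant to site permutation", {
  set.seed(44)
  aft <- random_aft(200, c("A", "B", "C"))
  perm <- sample(200)
  aft_p <- aft_from_p(aft$p[perm, ], aft$n[perm, ])
  expect_equal(f3(aft, "C", "A", "B")$estimate,
               f3(aft_p, "C", "A", "B")$estimate, tolerance = 1e-13)
})

test_that("corrected estimators remove finite-sample bias", {
  # two independent samples of the SAME population: true f2 = 0, the
  # uncorrected moment is biased up by ~2 h/n, the corrected one is not
  set.seed(55)
  n_sites <- 20000; n_dip <- 3
  p_true <- runif(n_sites, 0.2, 0.8)
  pA <- rbinom(n_sites, 2 * n_dip, p_true) / (2 * n_dip)
  pB <- rbinom(n_sites, 2 * n_dip, p_true) / (2 * n_dip)
  aft <- aft_from_p(cbind(A = pA, B = pB),
                    matrix(2 * n_dip, n_sites, 2,
                           dimnames = list(NULL, c("A", "B"))))
  blocks <- rep(seq_len(n_sites / 50), each = 50)
  raw <- f2(aft, "A", "B", blocks)
  cor <- f2(aft, "A", "B", blocks, corrected = TRUE)
  expect_gt(raw$estimate, 10 * raw$stderr)       # clearly biased
  expect_lt(abs(cor$estimate), 4 * cor$stderr)   # unbiased within noise
  expect_error(f2(aft, "A", "A", corrected = TRUE), "undefined")

  # corrected f3 matches its defining subtraction
  aft3 <- random_aft(30, c("C", "A", "B"), n_diploid = 4)
  manual <- mean((aft3$p[, "C"] - aft3$p[, "A"]) *
                   (aft3$p[, "C"] - aft3$p[, "B"]) -
                   aft3$p[, "C"] * (1 - aft3$p[, "C"]) / (8 - 1))
  expect_equal(f3(aft3, "C", "A", "B", corrected = TRUE)$estimate, manual,
               tolerance = 1e-13)
})

test_that("three-population scan enumerates targets and flags admixture", {
  set.seed(66)
  aft3 <- random_aft(100, c("A", "B", "C"))
  blocks <- rep(1:4, each = 25)
  sc3 <- three_pop_scan(aft3, blocks)
  expect_equal(nrow(sc3), 3L)

  aft5 <- random_aft(100, c("A", "B", "C", "D", "E"))
  sc5 <- three_pop_scan(aft5, blocks)
  expect_equal(nrow(sc5), 30L)          # 5 targets x C(4,2) pairs
  expect_false(is.unsorted(sc5$z, na.rm = TRUE))
  expect_error(three_pop_scan(aft3, blocks, pops = c("A", "B")), "at least 3")

  # an exactly intermediate target is flagged
  n <- 5000
  pA <- runif(n); pB <- runif(n)
  pC <- 0.5 * pA + 0.5 * pB
  aftm <- aft_from_p(cbind(A = pA, B = pB, C = pC))
  scm <- three_pop_scan(aftm, rep(1:100, each = 50), corrected = FALSE)
  expect_true(all(scm$admixed[scm$target == "C" & scm$source1 == "A"]))
})

test_that("f4-ratio recovers degenerate mixtures exactly", {
  set.seed(77)
  n <- 2000
  O <- runif(n); A <- runif(n); B <- runif(n); C <- runif(n)
  blocks <- rep(1:40, each = 50)
  # X an exact copy of B: numerator == denominator
  aft <- aft_from_p(cbind(O = O, A = A, B = B, X = B, C = C))
  r1 <- f4_ratio_alpha(aft, "O", "A", "B", "X", "C", blocks)
  expect_equal(r1$alpha, 1, tolerance = 1e-12)
  expect_equal(r1$stderr, 0, tolerance = 1e-10)
  # X an exact copy of C: numerator vanishes identically
  aft0 <- aft_from_p(cbind(O = O, A = A, B = B, X = C, C = C))
  r0 <- f4_ratio_alpha(aft0, "O", "A", "B", "X", "C", blocks)
  expect_equal(r0$alpha, 0, tolerance = 1e-12)
  # zero denominator errors
  aftz <- aft_from_p(cbind(O = O, A = A, B = A, X = B, C = A))
  expect_error(f4_ratio_alpha(aftz, "O", "A", "B", "X", "C", blocks),
               "denominator")
})

test_that("PCA separates populations and orders components", {
  set.seed(88)
  # two duplicated samples -> identical coordinates
  d <- matrix(sample(0:2, 200, replace = TRUE), 50, 4)
  d[, 2] <- d[, 1]
  gm <- gm_from_dosage(d)
  pc <- pca_genotypes(gm)
  expect_equal(pc$coords[1, ], pc$coords[2, ], tolerance = 1e-10)
  expect_false(is.unsorted(rev(pc$explained)))
  expect_lte(sum(pc$explained), 1 + 1e-12)

  # strong 3-population structure: within < between distance on PC1-2
  st <- cached_study(11, n_sites = 5000)
  pc2 <- pca_genotypes(st$gm)
  lab <- st$popmap[rownames(pc2$coords)]
  xy <- pc2$coords[, 1:2]
  dd <- as.matrix(dist(xy))
  same <- outer(lab, lab, "==") & upper.tri(dd)
  diff <- outer(lab, lab, "!=") & upper.tri(dd)
  expect_lt(mean(dd[same]), mean(dd[diff]))

  mono <- gm_from_dosage(matrix(2, 10, 3))
  expect_error(pca_genotypes(mono), "monomorphic")
})
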
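test_that("pairwise FST matches hand arithmetic and its limits", {
  expect_identical(pairwise_fst(0.3, 0.3), 0)
  expect_identical(pairwise_fst(0, 1), 1)
  # hT = 0.5, hS = 0.32 -> 0.36
  expect_equal(pairwise_fst(0.2, 0.8), 0.36)
  expect_equal(pairwise_fst(c(0.2, 0), c(0.8, 0)), c(0.36, 0))
})

test_that("mean cross-group FST equals the brute-force double loop", {
  withr::with_seed(55, {
    freqs <- matrix(runif(4 * 30), 4, 30,
                    dimnames = list(c("f1", "f2", "w1", "w2"), NULL))
    design <- toy_design(rownames(freqs), c("farmed", "farmed",
                                            "wild", "wild"))
    got <- mean_cross_group_fst(freqs, design)
    brute <- (pairwise_fst(freqs["f1", ], freqs["w1", ]) +
                pairwise_fst(freqs["f1", ], freqs["w2", ]) +
                pairwise_fst(freqs["f2", ], freqs["w1", ]) +
                pairwise_fst(freqs["f2", ], freqs["w2", ])) / 4
    expect_equal(got, brute)
    # one pool per side reduces to the single pairwise value
    d2 <- toy_design(c("f1", "w1"), c("farmed", "wild"))
    expect_equal(mean_cross_group_fst(freqs[c("f1", "w1"), ], d2),
                 pairwise_fst(freqs["f1", ], freqs["w1", ]))
    # identical populations: zero everywhere
    same <- freqs[c(1, 1, 1, 1), ]
    rownames(same) <- rownames(freqs)
    expect_equal(mean_cross_group_fst(same, design), rep(0, 30))
  })
})

test_that("group Fisher test follows the point-probability rule", {
  # identical group tables -> p = 1
  snps <- make_snp_table(matrix(c(10L, 10L), 1, 2),
                         matrix(c(5L, 5L), 1, 2), c("p1", "p2"))
  design <- toy_design(c("p1", "p2"), c("farmed", "wild"))
  expect_equal(fisher_group_test(snps, design), 1)
  # [[3,0],[0,3]]: full enumeration gives 2 * (1/20) = 0.1
  snps2 <- make_snp_table(matrix(c(3L, 0L), 1, 2),
                          matrix(c(0L, 3L), 1, 2), c("p1", "p2"))
  expect_equal(fisher_group_test(snps2, design), 0.1)
  # empty margin -> p = 1 with a warning
  snps3 <- make_snp_table(matrix(c(4L, 6L), 1, 2),
                          matrix(c(0L, 0L), 1, 2), c("p1", "p2"))
  expect_warning(p3 <- fisher_group_test(snps3, design), "empty margin")
  expect_equal(p3, 1)
})

test_that("group Fisher p matches stats::fisher.test on random tables", {
  design <- toy_design(c("p1", "p2"), c("farmed", "wild"))
  withr::with_seed(202, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, sample(3:40, 1)), 2, 2)
      snps <- make_snp_table(matrix(as.integer(tab[1, ]), 1, 2),
                             matrix(as.integer(tab[2, ]), 1, 2),
                             c("p1", "p2"))
      skip_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
      if (skip_margin) next
      expect_equal(fisher_group_test(snps, design),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-10)
    }
  })
})

test_that("Omega estimation: identical populations give a near-zero ridge matrix", {
  freqs <- matrix(rep(c(0.2, 0.5, 0.8), each = 4), 4, 3,
                  dimnames = list(paste0("p", 1:4), NULL))
  om <- estimate_omega(freqs)
  expect_true(isSymmetric(om))
  expect_lt(max(abs(om)), 1e-10)
  expect_true(all(eigen(om, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("Omega recovers block structure from hierarchically drifting groups", {
  withr::with_seed(66, {
    L <- 4000
    p0 <- runif(L, 0.2, 0.8)
    bn <- function(p, c_) rbeta(L, p * (1 - c_) / c_, (1 - p) * (1 - c_) / c_)
    gA <- bn(p0, 0.08)
    gB <- bn(p0, 0.08)
    freqs <- rbind(a1 = bn(gA, 0.01), a2 = bn(gA, 0.01), a3 = bn(gA, 0.01),
                   b1 = bn(gB, 0.01), b2 = bn(gB, 0.01), b3 = bn(gB, 0.01))
    om <- estimate_omega(freqs)
    within <- c(om["a1", "a2"], om["a1", "a3"], om["a2", "a3"],
                om["b1", "b2"], om["b1", "b3"], om["b2", "b3"])
    between <- om[1:3, 4:6]
    expect_gt(mean(within), mean(between))
    expect_true(all(eigen(om, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  })
})

test_that("XtX equals the quadratic form and is zero for balanced sites", {
  withr::with_seed(77, {
    freqs <- matrix(runif(5 * 40, 0.1, 0.9), 5, 40,
                    dimnames = list(paste0("p", 1:5), NULL))
    om <- estimate_omega(freqs)
    got <- xtx_stat(freqs, om)
    # oracle: recompute z from its definition and apply z' Omega^-1 z per site
    pi_ <- colMeans(freqs)
    z <- sweep(sweep(freqs, 2, pi_), 2, sqrt(pi_ * (1 - pi_)), "/")
    oracle <- vapply(seq_len(ncol(z)), function(l)
      drop(t(z[, l]) %*% solve(om) %*% z[, l]), 1)
    expect_equal(got$xtx, oracle, tolerance = 1e-10)
    expect_equal(got$p, pchisq(oracle, df = 5, lower.tail = FALSE))
    # all populations equal at a site -> z = 0 -> xtx = 0, p = 1
    freqs0 <- cbind(freqs, rep(0.4, 5))
    om0 <- estimate_omega(freqs0)
    g0 <- xtx_stat(freqs0, om0)
    expect_equal(g0$xtx[41], 0)
    expect_equal(g0$p[41], 1)
  })
})

test_that("BH adjustment reproduces the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.05)), c(0.01, 0.05))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  # oracle: independent step-up implementation on random vectors
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- runif(sample(2:5, 1))
      n <- length(p)
      o <- order(p)
      q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
      oracle <- pmin(1, q_sorted[order(o)])
      expect_equal(bh_adjust(p), oracle)
    }
  })
})

test_that("consensus classification follows the two-threshold rule and is monotone", {
  expect_identical(as.character(classify_consensus(1e-6, 1e-6)),
                   "highly_suggestive")
  expect_identical(as.character(classify_consensus(1e-6, 1e-4)),
                   "suggestive")
  expect_identical(as.character(classify_consensus(1e-4, 1e-6)),
                   "suggestive")
  expect_identical(as.character(classify_consensus(1e-4, 1e-4)), "none")
  withr::with_seed(12, {
    q1 <- 10^runif(300, -8, 0)
    q2 <- 10^runif(300, -8, 0)
    lev <- as.integer(classify_consensus(q1, q2))
    expect_true(all(as.integer(classify_consensus(q1 / 10, q2)) >= lev))
    expect_true(all(as.integer(classify_consensus(q1, q2 / 10)) >= lev))
  })
})

test_that("population PCA matches an independent eigendecomposition", {
  withr::with_seed(30, {
    freqs <- matrix(runif(6 * 100), 6, 100,
                    dimnames = list(paste0("p", 1:6), NULL))
    pca <- population_pca(freqs)
    # oracle: eigenvalues of the sample covariance of the centered matrix
    x <- scale(freqs, center = TRUE, scale = FALSE)
    ev <- eigen(x %*% t(x), symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > 1e-9]
    expect_equal(pca$explained[seq_along(ev)], ev / sum(ev),
                 tolerance = 1e-8)
    expect_equal(sum(pca$explained), 1)
    # two populations: PC1 carries all the nonzero variance
    p2 <- population_pca(freqs[1:2, ])
    expect_equal(p2$explained[1], 1)
    # duplicated population rows land on identical coordinates
    dup <- freqs[c(1, 1, 2, 3), ]
    rownames(dup) <- paste0("p", 1:4)
    pd <- population_pca(dup)
    expect_equal(pd$coordinates[1, ], pd$coordinates[2, ])
  })
  expect_warning(population_pca(matrix(0.5, 3, 10)), "zero total variance")
})

test_that("scan statistics are invariant to population ordering", {
  cfg <- sim_config(n_sites = 400, n_selected = 5, n_farmed = 3, n_wild = 3,
                    pool_sizes = 25, seed = 23)
  sim <- simulate_counts(cfg)
  snps <- call_biallelic(filter_depth(merge_replicates(sim$counts), 25))
  scan1 <- genome_scan(snps, sim$design)
  perm <- c(4, 2, 6, 1, 3, 5)
  snps2 <- snps
  snps2$ref_count <- snps$ref_count[, perm]
  snps2$alt_count <- snps$alt_count[, perm]
  snps2$pools <- snps$pools[perm]
  scan2 <- genome_scan(snps2, sim$design)
  expect_equal(scan1$fisher_p, scan2$fisher_p)
  expect_equal(scan1$xtx, scan2$xtx, tolerance = 1e-9)
  expect_equal(scan1$mean_fst, scan2$mean_fst)
})

test_that("genome_scan output respects its row contract", {
  cfg <- sim_config(n_sites = 400, n_selected = 5, seed = 29)
  sim <- simulate_counts(cfg)
  snps <- call_biallelic(filter_depth(merge_replicates(sim$counts), 25))
  scan <- genome_scan(snps, sim$design)
  expect_identical(nrow(scan), nrow(snps$sites))
  expect_true(all(scan$fisher_q >= scan$fisher_p))
  expect_true(all(scan$xtx_q >= scan$xtx_p))
  expect_true(all(scan$mean_fst >= 0 & scan$mean_fst <= 1))
  expect_true(all(scan$xtx >= 0))
  om <- attr(scan, "omega")
  expect_true(isSymmetric(om))
  expect_true(all(eigen(om, symmetric = TRUE, only.values = TRUE)$values > 0))
})
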
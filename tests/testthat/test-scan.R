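test_that("fisher_exact matches hand-computable tables", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  # perfectly separating 10v10: the two extreme tables of the
  # hypergeometric with margins (10,10;10,10)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_warning(p <- fisher_exact(matrix(c(0, 0, 3, 4), 2)),
                 "zero row/column margin")
  expect_equal(p, 1)
  expect_error(fisher_exact(matrix(0, 2, 2)), "zero grand total")
  expect_error(fisher_exact(matrix(1, 3, 3)), "2 x 2 or 2 x 3")
})

test_that("fisher_exact equals full fixed-margin enumeration", {
  set.seed(11)
  for (rep in 1:60) {
    g <- sample(2:3, 1)
    tab <- random_table(g = g, max_total = 30)
    expect_equal(fisher_exact(tab), fisher_brute_force(tab),
                 tolerance = 1e-7, label = paste(tab, collapse = ","))
  }
})

test_that("fisher_exact is invariant to row and column permutation", {
  set.seed(3)
  for (rep in 1:20) {
    tab <- random_table(g = 3)
    p <- fisher_exact(tab)
    expect_equal(fisher_exact(tab[2:1, ]), p, tolerance = 1e-9)
    expect_equal(fisher_exact(tab[, c(2, 3, 1)]), p, tolerance = 1e-9)
  }
})

test_that("genome_scan ranks a perfectly separating variant first", {
  d <- separable_data(n_noise = 30, seed = 4, sep_col = 7L)
  K <- matrix(0.1, 10, 10, dimnames = list(paste0("s", 1:10),
                                           paste0("s", 11:20)))
  smp <- matched_sample(hungarian_select(K), d$G)
  scan <- genome_scan(smp)
  expect_equal(scan$variant[scan$rank == 1], d$sep)
  expect_equal(scan$p[scan$variant == d$sep], 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_true(all(scan$bh >= scan$p))
  expect_true(all(sort(scan$rank) == seq_len(nrow(scan))))
})

test_that("monomorphic variants are flagged with p = 1 and empty scans fail", {
  d <- separable_data(n_noise = 10)
  d$G[, 3] <- 1L
  K <- matrix(0.1, 10, 10, dimnames = list(paste0("s", 1:10),
                                           paste0("s", 11:20)))
  smp <- matched_sample(hungarian_select(K), d$G)
  scan <- genome_scan(smp)
  expect_true(scan$flagged[3])
  expect_equal(scan$p[3], 1)
  smp$genotypes <- smp$genotypes[, 0, drop = FALSE]
  expect_error(genome_scan(smp), "no variants")
})

test_that("missing genotypes are dropped per variant", {
  d <- separable_data(n_noise = 5, sep_col = 1L)
  G <- d$G
  G[1:2, 1] <- NA  # two cases missing at the separating SNP
  K <- matrix(0.1, 10, 10, dimnames = list(paste0("s", 1:10),
                                           paste0("s", 11:20)))
  smp <- matched_sample(hungarian_select(K), G)
  scan <- genome_scan(smp)
  # 8 cases vs 10 controls remain: still the extreme table
  expect_equal(scan$p[1], fisher_brute_force(matrix(c(10, 0, 0, 8), 2)),
               tolerance = 1e-9)
})

test_that("the p-value ECDF counts proportions of all tests", {
  e <- pvalue_ecdf(c(0.005, 0.5, 0.9), grid_max = 0.01, n_grid = 1)
  expect_equal(e$proportion, 1 / 3)
  e2 <- pvalue_ecdf(rep(1, 8), grid_max = 0.01)
  expect_true(all(e2$proportion == 0))
  expect_error(pvalue_ecdf(numeric(0)), "empty")
  set.seed(1)
  p <- runif(1e4)
  e3 <- pvalue_ecdf(p, grid_max = 0.05, n_grid = 5)
  se <- sqrt(e3$threshold * (1 - e3$threshold) / 1e4)
  expect_true(all(abs(e3$proportion - e3$threshold) <= 3 * se))
})

test_that("bh_adjust matches the independent step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(21)
  for (rep in 1:200) {
    p <- runif(sample(2:80, 1))
    expect_equal(bh_adjust(p), bh_brute_force(p), tolerance = 1e-12)
  }
})

test_that("q-values reduce to BH at pi0 = 1 and react to signal", {
  set.seed(5)
  p <- runif(60)
  expect_equal(storey_qvalues(p, pi0 = 1), bh_adjust(p), tolerance = 1e-12)
  # strong signal below lambda: pi0 < 1 so q_(1) < BH value; the q-value
  # recomputed by hand from the stated formula
  p2 <- c(0.001, 0.2, 0.3, 0.45)
  q2 <- storey_qvalues(p2)
  pi0 <- max(mean(p2 > 0.5) / 0.5, 1 / 4)
  expect_lt(pi0, 1)
  expect_equal(q2[1], pi0 * 4 * 0.001 / 1, tolerance = 1e-12)
  expect_lt(q2[1], bh_adjust(p2)[1])
  # uniform null: smoothed pi0 estimate is near 1
  set.seed(8)
  pu <- runif(1e4)
  expect_gt(kinforest:::estimate_pi0(pu), 0.9)
  expect_lte(kinforest:::estimate_pi0(pu), 1.0)
  expect_warning(storey_qvalues(rep(0.2, 5)), "identical")
})

test_that("local fdr is high under the null and low for real signal", {
  set.seed(9)
  pu <- runif(1e4)
  l <- local_fdr(pu)
  expect_true(all(l >= 0 & l <= 1))
  expect_gte(median(l), 0.8)
  # 5% of tests with very small p among uniform noise
  pm <- c(runif(475) * 1e-6, runif(9500 + 25))
  lm <- local_fdr(pm)
  expect_lt(lm[which.min(pm)], 0.5)
  expect_warning(lc <- local_fdr(rep(0.5, 100)), "constant")
  expect_true(all(lc == 1))
  expect_warning(local_fdr(c(0, runif(99))), "clipped")
})

test_that("all three adjustments preserve the raw p-value ranking", {
  set.seed(13)
  for (rep in 1:20) {
    p <- runif(200)
    ord <- order(p)
    for (adj in list(bh_adjust(p), storey_qvalues(p), local_fdr(p))) {
      expect_true(all(diff(adj[ord]) >= -1e-12))
    }
  }
})
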
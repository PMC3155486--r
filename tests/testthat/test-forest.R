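test_that("a separable variant drives the error to near zero and tops the importance", {
  for (s in 1:10) {
    d <- separable_data(n_noise = 50, seed = s)
    f <- kin_forest(d$G, d$y, ntree = 200, mtry = 51, seed = s + 1000,
                    keep_trees = FALSE)
    expect_lte(f$oob_error, 0.15)
    expect_equal(names(which.max(f$importance)), d$sep)
  }
})

test_that("pure-noise data sits at the chance error of a balanced sample", {
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    G <- matrix(sample(0:2, 20 * 40, replace = TRUE), 20,
                dimnames = list(NULL, paste0("v", 1:40)))
    y <- rep(1:0, each = 10)
    kin_forest(G, y, ntree = 200, seed = s, keep_trees = FALSE)$oob_error
  }, numeric(1))
  # individual OOB errors on 20 subjects are noisy; the seed average must
  # sit at chance and no seed may show spurious learning
  expect_lte(abs(mean(errs) - 0.5), 0.12)
  expect_gt(min(errs), 0.2)
})

test_that("a constant variable can never be a split variable", {
  d <- separable_data(n_noise = 20, seed = 2)
  d$G[, 4] <- 1L
  f <- kin_forest(d$G, d$y, ntree = 300, mtry = 21, seed = 9,
                  keep_trees = FALSE)
  expect_identical(unname(f$importance[4]), 0)
  expect_true(all(f$importance >= 0))
})

test_that("prediction is the mean tree vote and OOB votes cover the training sample", {
  d <- separable_data(n_noise = 10, seed = 3)
  f <- kin_forest(d$G, d$y, ntree = 100, mtry = 11, seed = 4)
  pr <- predict(f, d$G)
  # separable training data: every tree votes the training class
  expect_true(all(pr[d$y == 1] > 0.5))
  expect_true(all(pr[d$y == 0] < 0.5))
  oob <- predict(f)
  expect_length(oob, 20)
  expect_gte(mean(oob[d$y == 1] > 0.5), 0.9)
  # two-tree forests average votes in halves
  f2 <- kin_forest(d$G, d$y, ntree = 2, seed = 5)
  expect_true(all(predict(f2, d$G) %in% c(0, 0.5, 1)))
})

test_that("unseen category levels are routed like missing values", {
  d <- separable_data(n_noise = 10, seed = 6)
  f <- kin_forest(d$G, d$y, ntree = 100, mtry = 11, seed = 7)
  nd <- d$G[1:2, , drop = FALSE]
  nd[1, ] <- 9L  # a level never seen in training
  expect_silent(pr <- predict(f, nd))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("classification follows the strict-threshold Bayes rule", {
  expect_identical(classify(0.7, 0.5), 1L)
  expect_identical(classify(0.5, 0.5), 0L)  # tie goes to class 0
  expect_identical(classify(0.4, 0.3), 1L)
  expect_error(classify(0.5, 1.2), "threshold")
  expect_error(classify(0.5, 0), "threshold")
  # monotone non-increasing positive calls along a threshold sweep
  votes <- seq(0, 1, by = 0.05)
  calls <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                  function(t) sum(classify(votes, t)), integer(1))
  expect_true(all(diff(calls) <= 0))
})

test_that("the OOB error never uses in-bag subjects (bookkeeping audit)", {
  d <- separable_data(n_noise = 15, seed = 8)
  f <- kin_forest(d$G, d$y, ntree = 50, seed = 11, keep_inbag = TRUE)
  # every tree holds exactly inbag_per_class subjects of each class
  ipc <- f$config$inbag_per_class
  for (m in 1:50) {
    expect_equal(sum(f$inbag[m, d$y == 1]), ipc)
    expect_equal(sum(f$inbag[m, d$y == 0]), ipc)
  }
  # each subject's OOB vote count equals the trees that left it out
  expect_equal(f$oob_n, colSums(1 - f$inbag))
})

test_that("forests are reproducible and stable as M grows", {
  d <- separable_data(n_noise = 20, seed = 9)
  f1 <- kin_forest(d$G, d$y, ntree = 150, seed = 42, keep_trees = FALSE)
  f2 <- kin_forest(d$G, d$y, ntree = 150, seed = 42, keep_trees = FALSE)
  expect_identical(f1$importance, f2$importance)
  expect_identical(f1$oob_error, f2$oob_error)
  # doubling M changes the OOB error only by Monte-Carlo noise
  f4 <- kin_forest(d$G, d$y, ntree = 300, seed = 42, keep_trees = FALSE)
  expect_lte(abs(f4$oob_error - f1$oob_error), 0.1)
})

test_that("degenerate configurations are rejected", {
  d <- separable_data(n_noise = 5)
  expect_error(kin_forest(d$G, d$y, mtry = 99), "mtry")
  expect_error(kin_forest(d$G, d$y, inbag_per_class = 10),
               "configuration error")
  expect_error(kin_forest(d$G[1:3, ], d$y[1:3]), "at least 4 subjects")
  expect_error(kin_forest(d$G, rep(1, 20)), "at least 2 subjects")
})
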
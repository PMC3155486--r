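test_that("identity-structure kinship matrices are matched on the diagonal", {
  K <- matrix(c(1, 0, 0, 1), 2, 2)
  a <- hungarian_select(K)
  expect_equal(a$pairs$control_index, c(1, 2))
  expect_equal(a$total_kinship, 2)
  for (c_scale in c(0.1, 0.5, 3)) {
    a <- hungarian_select(c_scale * diag(4))
    expect_equal(a$pairs$control_index, 1:4)
    expect_equal(a$total_kinship, c_scale * 4)
  }
})

test_that("the assignment equals the brute-force optimum on random matrices", {
  set.seed(42)
  for (rep in 1:40) {
    I <- sample(1:5, 1)
    J <- sample(I:7, 1)
    K <- matrix(runif(I * J), I, J)
    a <- hungarian_select(K)
    expect_equal(a$total_kinship, lap_brute_force(K), tolerance = 1e-12)
    expect_false(anyDuplicated(a$pairs$control_index) > 0)
  }
})

test_that("more cases than potential controls is an infeasible design", {
  expect_error(hungarian_select(matrix(runif(6), 3, 2)),
               "fewer potential controls")
  expect_error(random_select(c("a", "b", "c"), c("x", "y")),
               "fewer potential controls")
})

test_that("permuting control columns permutes the matching but not its total", {
  set.seed(7)
  K <- matrix(runif(20), 4, 5,
              dimnames = list(paste0("c", 1:4), paste0("u", 1:5)))
  a <- hungarian_select(K)
  perm <- c(3, 5, 1, 2, 4)
  b <- hungarian_select(K[, perm])
  expect_equal(b$total_kinship, a$total_kinship, tolerance = 1e-12)
  expect_setequal(b$pairs$control_id, a$pairs$control_id)
})

test_that("a strictly dominant entry per row is always selected", {
  K <- matrix(0.01, 3, 5)
  K[1, 4] <- 0.9
  K[2, 1] <- 0.8
  K[3, 5] <- 0.85
  a <- hungarian_select(K)
  expect_equal(a$pairs$control_index, c(4, 1, 5))
})

test_that("random selection is seeded, exhaustive when forced, and uniform", {
  # pool of exactly I controls: everything selected regardless of seed
  a <- random_select(c("c1", "c2"), c("u1", "u2"), seed = 5)
  expect_setequal(a$pairs$control_id, c("u1", "u2"))
  # determinism
  b1 <- random_select(paste0("c", 1:3), paste0("u", 1:8), seed = 99)
  b2 <- random_select(paste0("c", 1:3), paste0("u", 1:8), seed = 99)
  expect_identical(b1$pairs, b2$pairs)
  # uniformity: choosing 2 of 5, each control appears with frequency 2/5
  n_draws <- 2000
  hits <- integer(5)
  names(hits) <- paste0("u", 1:5)
  for (s in seq_len(n_draws)) {
    d <- random_select(c("c1", "c2"), paste0("u", 1:5), seed = s)
    hits[d$pairs$control_id] <- hits[d$pairs$control_id] + 1L
  }
  se <- sqrt(0.4 * 0.6 / n_draws)
  expect_true(all(abs(hits / n_draws - 0.4) <= 3 * se))
})

test_that("the matched design always beats random selection in total kinship", {
  ped <- fixture_pedigree20()
  cases <- c("E1", "E2", "D2")
  pool <- setdiff(ped$id, c(cases, "D1", "D3"))
  K <- kinship_matrix(ped, cases, pool)
  h <- hungarian_select(K)
  for (s in 1:100) {
    r <- random_select(cases, pool, seed = s, kinship = K)
    expect_gte(h$total_kinship, r$total_kinship)
  }
})

test_that("matched samples are balanced, labelled and validated", {
  d <- separable_data(n_noise = 5)
  K <- matrix(runif(4 * 10), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("s", 11:20)))
  a <- hungarian_select(K)
  smp <- matched_sample(a, d$G)
  expect_s3_class(smp, "matched_sample")
  expect_equal(sum(smp$status == 1), 4)
  expect_equal(sum(smp$status == 0), 4)
  expect_identical(smp$subject_id[1:4], paste0("s", 1:4))
  expect_false(any(duplicated(smp$subject_id)))
  expect_identical(rownames(smp$genotypes), smp$subject_id)
  # controls carry their matched case
  expect_identical(smp$matched_case[5:8], a$pairs$case_id)

  # missing genotype row
  a_bad <- a
  a_bad$pairs$control_id[1] <- "ghost"
  expect_error(matched_sample(a_bad, d$G), "no genotype row")
  # duplicated control
  a_dup <- a
  a_dup$pairs$control_id[2] <- a_dup$pairs$control_id[1]
  expect_error(matched_sample(a_dup, d$G), "duplicated control")
})

test_that("matched-sample tables round-trip through TSV", {
  d <- separable_data(n_noise = 3)
  K <- matrix(runif(9), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 4:6)))
  smp <- matched_sample(hungarian_select(K), d$G)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matched_sample(smp, path)
  back <- matched_sample_from_table(read_matched_sample(path), d$G)
  expect_identical(back$subject_id, smp$subject_id)
  expect_identical(back$status, smp$status)
  expect_identical(back$genotypes, smp$genotypes)
  expect_identical(back$design, smp$design)
})
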
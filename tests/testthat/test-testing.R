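test_that("Bonferroni per-gene level divides the family-wise level by M", {
  expect_equal(per_gene_alpha(0.05, 20000), 2.5e-6)
  expect_equal(per_gene_alpha(0.05, 17000), 0.05 / 17000)
  expect_equal(per_gene_alpha(1, 1), 1)
  expect_error(per_gene_alpha(0, 10), "\\(0, 1\\]")
})

test_that("exact cutoff is the smallest t with tail at or below alpha", {
  null <- null_dist(2, 300, 20000, "Tr")
  cut <- significance_cutoff(null, 2.5e-6)
  expect_equal(cut$cutoff, 2L)
  expect_gt(dist_tail(null, 1), 2.5e-6)
  expect_lte(cut$achieved_size, 2.5e-6)

  cut <- significance_cutoff(dist_binomial(10, 0.3), 1)
  expect_equal(cut$cutoff, 0L)
  expect_equal(cut$achieved_size, 1)

  # smallest non-zero tail of Bin(3, 0.5) is 0.125: rejection impossible
  cut <- significance_cutoff(dist_binomial(3, 0.5), 1e-9)
  expect_equal(cut$cutoff, 4L)
  expect_equal(cut$achieved_size, 0)
})

test_that("achieved size never exceeds alpha and cutoffs are monotone", {
  withr::local_seed(7)
  alphas <- sort(c(1e-8, 2.5e-6, 1e-4, 0.01, 0.5), decreasing = FALSE)
  for (i in 1:20) {
    n <- sample(1:500, 1)
    q <- runif(1, 0, 0.2)
    cuts <- vapply(
      alphas,
      function(a) significance_cutoff(dist_binomial(n, q), a)$cutoff,
      integer(1)
    )
    sizes <- vapply(
      alphas,
      function(a) significance_cutoff(dist_binomial(n, q), a)$achieved_size,
      numeric(1)
    )
    expect_true(all(sizes <= alphas))
    # larger alpha -> smaller (or equal) cutoff
    expect_true(all(diff(cuts) <= 0))
  }
  # larger null success probability -> larger (or equal) cutoff
  probs <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.1)
  cuts <- vapply(
    probs,
    function(q) significance_cutoff(dist_binomial(100, q), 2.5e-6)$cutoff,
    integer(1)
  )
  expect_true(all(diff(cuts) >= 0))
})

test_that("tail probabilities are exact survival functions", {
  expect_equal(dist_tail(dist_binomial(2, 0.5), 1), 0.75)
  expect_equal(dist_tail(dist_binomial(5, 0.2), 6), 0)
  expect_equal(dist_tail(dist_binomial(5, 0.2), 0), 1)
  expect_equal(dist_tail(dist_binomial(5, 0.2), -3), 1)

  # recessive null with strict filtering (m = 50): tail at 2 is ~1.9e-7
  q2 <- prob_ge2(50, 5e-5)
  expect_equal(
    dist_tail(dist_binomial(200, q2), 2),
    oracle_binom_tail(2, 200, q2),
    tolerance = 1e-10
  )
  expect_lt(dist_tail(dist_binomial(200, q2), 2), 2.5e-6)
})

test_that("gene p-values are exact tails with capped Bonferroni adjustment", {
  null <- null_dist(2, 300, 20000, "Tr")
  pv <- gene_pvalue(0, null, 20000)
  expect_equal(pv$p_value, 1)
  expect_equal(pv$p_adjusted, 1)

  pv <- gene_pvalue(2, null, 20000)
  expect_equal(pv$p_value, null$prob^2, tolerance = 1e-10)
  expect_equal(pv$p_adjusted, 20000 * null$prob^2, tolerance = 1e-10)

  # seven of ten patients hit a ten-times-average gene at m = 694
  null10 <- null_dist(10, 694, 20000, "Td", w = 10)
  pv <- gene_pvalue(7, null10, 20000)
  expect_equal(pv$p_value, oracle_binom_tail(7, 10, null10$prob), tolerance = 1e-10)
  expect_equal(round(pv$p_value, 4), 0.0092)
})

test_that("p-value at the cutoff is always at or below the per-gene level", {
  withr::local_seed(13)
  for (i in 1:20) {
    n <- sample(1:300, 1)
    q <- runif(1, 0, 0.1)
    alpha <- 10^runif(1, -7, -1)
    null <- dist_binomial(n, q)
    cut <- significance_cutoff(null, alpha)
    if (cut$cutoff <= n) {
      expect_lte(gene_pvalue(cut$cutoff, null, 1)$p_value, alpha)
    }
  }
})

test_that("burden statistics collapse the count matrix per definition", {
  counts <- counts_from_matrix(rbind(c(2, 0), c(1, 1)))
  s <- burden_statistics(counts)
  expect_equal(s$Ta, c(3, 1))
  expect_equal(s$Tr, c(1, 0))
  expect_equal(s$Td, c(2, 1))

  s0 <- burden_statistics(counts_from_matrix(matrix(0, 3, 2)))
  expect_true(all(s0$Ta == 0) && all(s0$Tr == 0) && all(s0$Td == 0))

  s1 <- burden_statistics(counts_from_matrix(matrix(5, 1, 1)))
  expect_equal(c(s1$Ta, s1$Tr, s1$Td), c(5, 1, 1))
})

test_that("Poisson-binomial null matches enumeration for varying m", {
  withr::local_seed(5)
  for (i in 1:10) {
    q <- runif(sample(1:6, 1), 0, 0.6)
    for (t in 0:(length(q) + 1)) {
      expect_equal(
        mendelpower:::poisson_binomial_tail(q, t),
        oracle_poisbin_tail(q, t),
        tolerance = 1e-12
      )
    }
  }
  # collapses to pbinom when all q equal
  expect_equal(
    mendelpower:::poisson_binomial_tail(rep(0.1, 8), 3),
    oracle_binom_tail(3, 8, 0.1),
    tolerance = 1e-12
  )
})

test_that("a short gene hit in fewer patients can out-rank a long gene hit in all", {
  # 10 patients; gene A (average length) mutated in 7, gene B (27x average,
  # think of a giant mucin) mutated in all 10
  mat <- cbind(A = c(rep(1, 7), rep(0, 3)), B = rep(1, 10))
  counts <- counts_from_matrix(mat, gene_ids = c("A", "B"))
  genes <- tibble::tibble(gene_id = c("A", "B"), w = c(1, 27))
  fit <- burden_test(counts, genes, M = 20000, stat = "Td", common_m = 694)
  res <- tidy(fit)
  expect_equal(res$gene_id[res$rank == 1], "A")
  expect_lt(res$p_value[res$gene_id == "A"], res$p_value[res$gene_id == "B"])
  expect_gt(res$statistic[res$gene_id == "B"], res$statistic[res$gene_id == "A"])
})

test_that("burden test handles degenerate inputs", {
  empty <- tibble::tibble(
    patient_id = character(), gene_id = character(), count = integer()
  )
  fit <- burden_test(empty, M = 100)
  expect_equal(nrow(tidy(fit)), 0)

  one <- tibble::tibble(patient_id = "P1", gene_id = "G1", count = 0L)
  fit <- burden_test(one, M = 100, stat = "Td")
  res <- tidy(fit)
  expect_equal(res$p_value, 1)
  expect_equal(res$rank, 1L)

  counts <- tibble::tibble(patient_id = "P1", gene_id = "GX", count = 2L)
  genes <- tibble::tibble(gene_id = "GY", w = 1)
  expect_error(burden_test(counts, genes, M = 100), "GX")
})

test_that("per-patient m defaults to row totals; common_m restores constant m", {
  # patient 1 carries many background mutations, patient 2 few
  counts <- tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    gene_id = c("G1", "G2", "G1"),
    count = c(1L, 99L, 1L)
  )
  fit_row <- burden_test(counts, M = 1000, stat = "Td")
  fit_com <- burden_test(counts, M = 1000, stat = "Td", common_m = 100)
  p_row <- tidy(fit_row)$p_value[tidy(fit_row)$gene_id == "G1"]
  p_com <- tidy(fit_com)$p_value[tidy(fit_com)$gene_id == "G1"]
  # row totals (100 and 1) differ from common m = 100 for patient 2
  q_a <- prob_ge1(100, 1e-3)
  q_b <- prob_ge1(1, 1e-3)
  expect_equal(p_row, q_a * q_b, tolerance = 1e-12)
  expect_equal(p_com, oracle_binom_tail(2, 2, q_a), tolerance = 1e-12)
})

test_that("randomized decoys never displace a strongly hit short gene", {
  withr::local_seed(23)
  n <- 12
  for (rep in 1:5) {
    n_decoys <- sample(3:8, 1)
    mat <- cbind(
      sig = rep(2L, n),
      matrix(rbinom(n * n_decoys, 2, 0.15), n, n_decoys)
    )
    gene_ids <- c("sig", paste0("decoy", seq_len(n_decoys)))
    counts <- counts_from_matrix(mat, gene_ids = gene_ids)
    genes <- tibble::tibble(gene_id = gene_ids, w = c(0.5, runif(n_decoys, 5, 30)))
    res <- tidy(burden_test(counts, genes, M = 20000, stat = "Tr", common_m = 300))
    expect_equal(res$gene_id[res$rank == 1], "sig")
  }
})

test_that("tidy, glance and autoplot expose the burden test results", {
  counts <- counts_from_matrix(rbind(c(2, 1), c(2, 0), c(0, 1)))
  fit <- burden_test(counts, M = 50, stat = "Tr")
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$n_patients, 3L)
  expect_equal(g$n_genes_tested, 2L)
  expect_equal(g$per_gene_alpha, 0.001)
  expect_s3_class(autoplot(fit), "ggplot")
})
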
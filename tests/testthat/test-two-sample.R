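test_that("proportion-difference score matches the printed formulas", {
  s <- pd_score(18, 20, 10, 20, p_null = 0.7)
  expect_equal(s$z, 0.4)
  expect_equal(s$variance, 0.21 / 20 + 0.21 / 20)
  expect_equal(pd_score(10, 20, 10, 20, p_null = 0.3)$z, 0)
  expect_equal(pd_score(20, 20, 0, 20, p_null = 0.5)$z, 1)
  # overdispersion inflates each sample's term
  s2 <- pd_score(18, 20, 10, 20, p_null = 0.7, rho = 0.004)
  expect_equal(s2$variance, 0.21 * (0.004 * 19 + 1) * (1 / 20 + 1 / 20))
  expect_error(pd_score(5, 0, 1, 10, 0.5), ">= 1")
  expect_error(pd_score(5, 10, 1, 10, 1.2), "p_null")
})

test_that("pooled null frequency estimate is counts over totals, clipped", {
  expect_equal(estimate_null_p(18, 20, 10, 20), 0.7)
  expect_equal(estimate_null_p(10, 20, 10, 20), 0.5)
  p <- estimate_null_p(c(20, 20), c(20, 20), c(20, 20), c(20, 20))
  expect_lt(p, 1)
  expect_equal(p, 1 - 1 / 82)
})

test_that("swapping sample roles negates the combined difference", {
  x_t <- c(18, 15); n_t <- c(20, 20); x_n <- c(9, 12); n_n <- c(20, 22)
  a <- aseMeta:::two_sample_statistic(x_t, n_t, x_n, n_n, 0.6)
  b <- aseMeta:::two_sample_statistic(x_n, n_n, x_t, n_t, 0.6)
  expect_equal(a$t_pd, -b$t_pd)
  expect_equal(a$q_stat, b$q_stat)
})

test_that("two-sample run detects designed signal and is calibrated at zero", {
  strong <- data.frame(ase_id = "g", ref_count1 = c(20, 20),
                       alt_count1 = c(0, 0), ref_count2 = c(10, 10),
                       alt_count2 = c(10, 10))
  r <- run_two_sample(strong, n_sim = 5000, seed = 3)
  expect_gt(r$maf_difference, 0.4)
  expect_lt(r$p_ase, 0.01)
  same <- data.frame(ase_id = "g", ref_count1 = c(14, 13),
                     alt_count1 = c(6, 7), ref_count2 = c(14, 13),
                     alt_count2 = c(6, 7))
  r <- run_two_sample(same, n_sim = 5000, seed = 3)
  expect_equal(r$maf_difference, 0)
  expect_gt(r$p_ase, 0.5)
})

test_that("two-sample null p-values are uniform-or-conservative", {
  set.seed(31)
  n_genes <- 800
  counts <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    k <- sample(1:3, 1)
    n1 <- sample(20:40, k, replace = TRUE)
    n2 <- sample(20:40, k, replace = TRUE)
    r1 <- rbetabinom(k, n1, 0.5, 0.004)
    r2 <- rbetabinom(k, n2, 0.5, 0.004)
    data.frame(ase_id = sprintf("g%03d", i), ref_count1 = r1,
               alt_count1 = n1 - r1, ref_count2 = r2, alt_count2 = n2 - r2)
  }))
  r <- run_two_sample(counts, rho = 0.004, n_sim = 2000, seed = 13)
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(r$p_ase <= t),
               t + 2.5 * sqrt(t * (1 - t) / n_genes) + 1 / 2000)
  }
})

test_that("two-sample power stays below one-sample power at matched settings", {
  strata <- data.frame(snv_bin = "2", coverage_bin = "30-40",
                       n_genes = 60L)
  cache <- new_null_cache()
  one <- run_sim_study(maf_levels = 0.8, strata = strata,
                       n_replicates = 3, n_sim = 2000, seed = 21,
                       significance_only = TRUE, cache = cache)
  two <- run_sim_study(maf_levels = 0.8, strata = strata,
                       n_replicates = 3, n_sim = 2000, seed = 21,
                       significance_only = TRUE, two_sample = TRUE,
                       cache = cache)
  t1 <- one$tpr[one$stratum == "overall"]
  t2 <- two$tpr[two$stratum == "overall"]
  slack <- 2 * sqrt(one$tpr_se[one$stratum == "overall"]^2 +
                      two$tpr_se[two$stratum == "overall"]^2)
  expect_lte(t2, t1 + slack)
})
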
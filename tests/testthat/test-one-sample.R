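test_that("gene statistic reduces to the expected values", {
  # single SNV: FT round trip of 15/20, inside the natural bracket
  pg <- pseudo_phase(data.frame(ref_count = 15, alt_count = 5))
  st <- gene_statistic(pg)
  expect_equal(st$t_ft,
               ft_backtransform(ft_transform(15, 20)$z))
  expect_gte(st$t_ft, 15 / 21)
  expect_lte(st$t_ft, 16 / 21)
  expect_equal(st$q_stat, 0)
  # two identical balanced SNVs: exactly 0.5, no heterogeneity
  pg <- pseudo_phase(data.frame(ref_count = c(10, 10),
                                alt_count = c(10, 10)))
  st <- gene_statistic(pg)
  expect_equal(st$t_ft, 0.5)
  expect_equal(st$q_stat, 0)
  # discordant SNVs produce heterogeneity
  pg <- pseudo_phase(data.frame(ref_count = c(20, 10),
                                alt_count = c(0, 10)))
  expect_gt(gene_statistic(pg)$q_stat, 0)
})

test_that("bias correction recenters the statistic and is exact at the mean", {
  # a gene observed exactly at the bias level is balanced on the
  # transcript scale
  pg <- pseudo_phase(data.frame(ref_count = 60, alt_count = 40))
  st <- gene_statistic(pg, f_ref = 0.6)
  expect_lt(abs(st$t_ft - 0.5), 0.01)
  # no bias: correction is the identity
  st0 <- gene_statistic(pg, f_ref = 0.5)
  expect_equal(st0$t_ft, ft_backtransform(ft_transform(60, 100)$z))
})

test_that("single-SNV null matches exhaustive enumeration", {
  n <- 12
  null <- simulate_null(n, n_sim = 2e4, seed = 5)
  exact <- enumerate_single_snv_null(n)
  # every simulated value lies on an enumerated support point
  emp_support <- unique(null$t)
  expect_true(all(vapply(emp_support, function(t)
    any(abs(exact$t - t) < 1e-12), logical(1))))
  for (i in seq_len(nrow(exact))) {
    p_emp <- mean(abs(null$t - exact$t[i]) < 1e-12)
    se <- sqrt(exact$prob[i] * (1 - exact$prob[i]) / 2e4)
    expect_lt(abs(p_emp - exact$prob[i]), 4 * se + 1e-4)
  }
})

test_that("null simulation is deterministic and pseudo-phasing inflates it", {
  a <- simulate_null(c(20, 30), rho = 0.004, n_sim = 500, seed = 9)
  b <- simulate_null(c(20, 30), rho = 0.004, n_sim = 500, seed = 9)
  expect_identical(a, b)
  # pseudo-phasing pushes the null MAF statistic above 0.5
  null <- simulate_null(rep(50, 3), n_sim = 2000, seed = 2)
  expect_gt(median(null$t), 0.5)
  expect_warning(simulate_null(20, n_sim = 50, seed = 1), "100")
})

test_that("empirical p-values follow the right-tail rule with a floor", {
  null <- list(t = c(0.5, 0.6, 0.7, 0.8, 0.9), q = c(0, 1, 2, 3, 4))
  pv <- empirical_pvalues(list(t_ft = 0.75, q_stat = 2.5), null, k = 2)
  expect_equal(pv$p_ase, 2 / 5)
  expect_equal(pv$p_het, 2 / 5)
  # larger than all draws: floored, never zero
  pv <- empirical_pvalues(list(t_ft = 0.99, q_stat = 10), null, k = 2)
  expect_equal(pv$p_ase, 1 / 6)
  # k = 1: heterogeneity undefined
  pv <- empirical_pvalues(list(t_ft = 0.7, q_stat = 0), null, k = 1)
  expect_true(is.na(pv$p_het))
  # observed at the minimum: every draw is as extreme
  pv <- empirical_pvalues(list(t_ft = 0.5, q_stat = 0), null, k = 2)
  expect_equal(pv$p_ase, 1)
})

test_that("run_one_sample is reproducible and order-invariant", {
  counts <- rbind(
    make_gene_counts(c(18, 17), c(2, 3), "gA"),
    make_gene_counts(c(12, 9), c(8, 11), "gB"),
    make_gene_counts(c(18, 17), c(2, 3), "gC")  # identical data to gA
  )
  r1 <- run_one_sample(counts, n_sim = 2000, seed = 4)
  r2 <- run_one_sample(counts, n_sim = 2000, seed = 4)
  expect_identical(r1, r2)
  # identical count data gives identical results under one seed
  expect_equal(r1[r1$ase_id == "gA", -1], r1[r1$ase_id == "gC", -1],
               ignore_attr = TRUE)
  # gene order does not matter
  r3 <- run_one_sample(counts[c(3, 4, 1, 2, 5, 6), ], n_sim = 2000,
                       seed = 4)
  expect_equal(r3[r3$ase_id == "gB", -1], r1[r1$ase_id == "gB", -1],
               ignore_attr = TRUE)
  # shared cache gives the same numbers as no cache
  r4 <- run_one_sample(counts, n_sim = 2000, seed = 4,
                       cache = new_null_cache())
  expect_identical(r4, r1)
})

test_that("monoallelic genes get extreme estimates and minimal p-values", {
  counts <- make_gene_counts(c(25, 30), c(0, 0), "mono")
  r <- run_one_sample(counts, n_sim = 5000, seed = 8)
  expect_gt(r$maf, 0.95)
  expect_equal(r$p_ase, 1 / 5001)
})

test_that("a failing gene is flagged, not fatal", {
  counts <- rbind(
    data.frame(ase_id = "ok", ref_count = 15, alt_count = 5,
               hap1_is_ref = TRUE),
    data.frame(ase_id = "bad", ref_count = c(9, 9), alt_count = c(11, 11),
               hap1_is_ref = c(TRUE, NA))
  )
  r <- run_one_sample(counts, n_sim = 500, seed = 1)
  expect_true(is.na(r$note[r$ase_id == "ok"]))
  expect_match(r$note[r$ase_id == "bad"], "mixed")
  expect_true(is.na(r$maf[r$ase_id == "bad"]))
})

test_that("labels are used when present and pseudo ignores them", {
  counts <- data.frame(ase_id = "g", ref_count = c(3, 17),
                       alt_count = c(17, 3),
                       hap1_is_ref = c(FALSE, TRUE))
  r_auto <- run_one_sample(counts, n_sim = 2000, seed = 2)
  expect_identical(r_auto$phase_source, "known")
  r_pseudo <- run_one_sample(counts, n_sim = 2000, seed = 2,
                             phase = "pseudo")
  expect_identical(r_pseudo$phase_source, "pseudo")
  # here labels agree with the vote, so the estimates coincide
  expect_equal(r_auto$maf, r_pseudo$maf)
})
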
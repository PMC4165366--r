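test_that("the stratum grid is the full 5 x 5 design", {
  g <- ase_strata(40L)
  expect_equal(nrow(g), 25L)
  expect_equal(length(unique(g$snv_bin)), 5L)
  expect_equal(length(unique(g$coverage_bin)), 5L)
  expect_true(all(g$n_genes == 40L))
})

test_that("generated data respect strata, truth labels and the seed", {
  strata <- data.frame(snv_bin = c("2", "5+"),
                       coverage_bin = c("20-30", "50+"),
                       n_genes = c(20L, 20L))
  ds <- generate_dataset(strata, tp_fraction = 0.25, maf = 0.8,
                         rho = 0.004, seed = 33)
  expect_equal(nrow(ds$truth), 40L)
  expect_equal(sum(ds$truth$is_tp), 10L)
  k <- table(ds$counts$ase_id)
  two <- ds$truth$ase_id[ds$truth$snv_bin == "2"]
  expect_true(all(k[two] == 2L))
  five <- ds$truth$ase_id[ds$truth$snv_bin == "5+"]
  expect_true(all(k[five] >= 5L & k[five] <= 8L))
  n <- ds$counts$ref_count + ds$counts$alt_count
  in_two <- ds$counts$ase_id %in% two
  expect_true(all(n[in_two] >= 20L & n[in_two] <= 30L))
  expect_true(all(n[!in_two] >= 50L & n[!in_two] <= 100L))
  # bit-identical regeneration under the same seed
  ds2 <- generate_dataset(strata, tp_fraction = 0.25, maf = 0.8,
                          rho = 0.004, seed = 33)
  expect_identical(ds, ds2)
  # no true positives when the fraction is zero
  ds0 <- generate_dataset(strata, tp_fraction = 0, maf = 0.8, seed = 1)
  expect_false(any(ds0$truth$is_tp))
})

test_that("true-positive genes carry the designed imbalance", {
  strata <- data.frame(snv_bin = "5+", coverage_bin = "50+",
                       n_genes = 60L)
  ds <- generate_dataset(strata, tp_fraction = 0.5, maf = 0.9,
                         rho = 0.004, seed = 7)
  cnt <- ds$counts
  maj <- pmax(cnt$ref_count, cnt$alt_count)
  pooled <- tapply(maj, cnt$ase_id, sum) /
    tapply(cnt$ref_count + cnt$alt_count, cnt$ase_id, sum)
  tp <- ds$truth$ase_id[ds$truth$is_tp]
  expect_gt(mean(pooled[tp] > 0.8), 0.95)
  # truth labels point at the major haplotype for true positives
  hap1 <- ifelse(cnt$hap1_is_ref, cnt$ref_count, cnt$alt_count)
  in_tp <- cnt$ase_id %in% tp
  expect_gt(mean((hap1 >= (cnt$ref_count + cnt$alt_count) / 2)[in_tp]),
            0.95)
})

test_that("two-sample data sets carry a balanced second sample", {
  strata <- data.frame(snv_bin = "3", coverage_bin = "40-50",
                       n_genes = 40L)
  ds <- generate_dataset(strata, tp_fraction = 0.5, maf = 0.9,
                         two_sample = TRUE, seed = 5)
  expect_true(all(c("ref_count1", "alt_count1", "ref_count2",
                    "alt_count2") %in% names(ds$counts)))
  f2 <- sum(ds$counts$ref_count2) /
    sum(ds$counts$ref_count2 + ds$counts$alt_count2)
  expect_lt(abs(f2 - 0.5), 0.03)
})

test_that("scoring matches hand computation and handles edge cases", {
  truth <- data.frame(ase_id = c("a", "b", "c", "d"),
                      stratum = c("s1", "s1", "s2", "s2"),
                      is_tp = c(TRUE, FALSE, TRUE, TRUE))
  calls <- data.frame(ase_id = c("a", "b", "c", "d"),
                      ase_called = c(TRUE, TRUE, FALSE, TRUE))
  sc <- score_calls(calls, truth)
  s1 <- sc[sc$stratum == "s1", ]
  expect_equal(s1$tpr, 1)
  expect_equal(s1$fdr, 0.5)
  s2 <- sc[sc$stratum == "s2", ]
  expect_equal(s2$tpr, 0.5)
  expect_equal(s2$fdr, 0)
  ov <- sc[sc$stratum == "overall", ]
  expect_equal(ov$tpr, 0.5 * 1 + 0.5 * 0.5)
  expect_equal(ov$fdr, 0.25)
  # perfect caller and silent caller
  calls$ase_called <- truth$is_tp
  sc <- score_calls(calls, truth)
  expect_true(all(sc$tpr == 1) && all(sc$fdr == 0))
  calls$ase_called <- FALSE
  sc <- score_calls(calls, truth)
  expect_true(all(sc$tpr == 0) && all(sc$fdr == 0))
  expect_error(score_calls(calls[1:3, ], truth), "every gene")
})

test_that("a small benchmark run has the expected layout", {
  strata <- data.frame(snv_bin = "3", coverage_bin = "30-40",
                       n_genes = 30L)
  res <- run_sim_study(maf_levels = c(0.8, 0.9), strata = strata,
                       n_replicates = 2, n_sim = 1000, seed = 2,
                       significance_only = TRUE)
  expect_equal(nrow(res), 4L)  # (stratum + overall) x 2 MAF levels
  expect_true(all(res$tpr >= 0 & res$tpr <= 1))
  # TPR non-decreasing in the signal, within Monte-Carlo slack
  t8 <- res[res$maf == 0.8 & res$stratum == "overall", ]
  t9 <- res[res$maf == 0.9 & res$stratum == "overall", ]
  expect_gte(t9$tpr, t8$tpr - 2 * sqrt(t8$tpr_se^2 + t9$tpr_se^2))
})
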
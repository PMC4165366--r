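#' Stratum grid for the power/FDR benchmark
#'
#' The 5 x 5 grid of simulation strata: number of SNVs per gene (1, 2, 3, 4
#' or 5+) crossed with average per-SNV read coverage (10-20, 20-30, 30-40,
#' 40-50 or 50+ reads). "5+" SNVs are drawn uniformly from 5-8 and "50+"
#' coverage uniformly from 50-100; other bins are uniform over their
#' integer range.
#'
#' @param n_genes Genes per stratum (recycled over the 25 strata).
#' @return Data frame with columns \code{snv_bin}, \code{coverage_bin} and
#'   \code{n_genes}.
#' @export
ase_strata <- function(n_genes = 40L) {
  grid <- expand.grid(
    snv_bin = c("1", "2", "3", "4", "5+"),
    coverage_bin = c("10-20", "20-30", "30-40", "40-50", "50+"),
    stringsAsFactors = FALSE
  )
  grid$n_genes <- as.integer(rep_len(n_genes, nrow(grid)))
  grid
}

snv_bin_range <- function(bin) {
  switch(bin, "1" = c(1L, 1L), "2" = c(2L, 2L), "3" = c(3L, 3L),
         "4" = c(4L, 4L), "5+" = c(5L, 8L),
         stop("unknown SNV bin: ", bin))
}

coverage_bin_range <- function(bin) {
  switch(bin, "10-20" = c(10L, 20L), "20-30" = c(20L, 30L),
         "30-40" = c(30L, 40L), "40-50" = c(40L, 50L),
         "50+" = c(50L, 100L), stop("unknown coverage bin: ", bin))
}

runifint <- function(n, lo, hi) {
  if (lo == hi) rep.int(lo, n) else
    as.integer(sample(seq.int(lo, hi), n, replace = TRUE))
}

#' Generate a stratified synthetic ASE data set with truth labels
#'
#' Emulates the statistical structure assumed by the method: within each
#' stratum a fraction \code{tp_fraction} of genes are ASE true positives. At
#' each SNV of a true-positive gene one allele (allele A) is assigned to the
#' major haplotype at random and its counts are drawn from
#' Beta-Binomial(n, mu_A, rho) where \code{mu_A} maps the signal MAF to the
#' read scale under bias \code{f_ref} (see [bias_adjusted_mu()]); true
#' negatives draw reference counts at \code{mu = f_ref}. The signal MAF is
#' constant across SNVs within a run. In two-sample mode a balanced "other"
#' sample is generated for every gene at \code{mu = f_ref}, so true
#' positives carry sample-of-interest-specific ASE.
#'
#' @param strata Data frame as returned by [ase_strata()].
#' @param tp_fraction Fraction of genes per stratum that carry ASE.
#' @param maf Signal major haplotype frequency for true positives, in
#'   (0.5, 1).
#' @param rho Beta-binomial overdispersion (study default 0.004).
#' @param f_ref Global reference-allele observation probability at balanced
#'   expression (0.5 = no bias; 0.6 in the reference-bias variant).
#' @param two_sample Also generate a balanced second sample.
#' @param seed Optional integer seed (caller RNG preserved if supplied).
#' @return List with \code{counts} (a data frame accepted by
#'   [run_one_sample()], or with the paired \code{*1}/\code{*2} columns of
#'   [run_two_sample()] in two-sample mode; includes \code{hap1_is_ref}
#'   truth labels with haplotype 1 the major haplotype of true positives)
#'   and \code{truth} (per-gene \code{ase_id}, \code{snv_bin},
#'   \code{coverage_bin}, \code{stratum}, \code{is_tp}).
#' @export
generate_dataset <- function(strata = ase_strata(), tp_fraction = 0.25,
                             maf = 0.8, rho = 0.004, f_ref = 0.5,
                             two_sample = FALSE, seed = NULL) {
  stopifnot(is.data.frame(strata),
            all(c("snv_bin", "coverage_bin", "n_genes") %in% names(strata)))
  if (tp_fraction < 0 || tp_fraction > 1) {
    stop("'tp_fraction' must be in [0, 1]")
  }
  if (maf <= 0.5 || maf >= 1) stop("'maf' must be in (0.5, 1)")
  gen <- function() {
    counts <- vector("list", nrow(strata))
    truth <- vector("list", nrow(strata))
    gene_no <- 0L
    for (s in seq_len(nrow(strata))) {
      ng <- strata$n_genes[s]
      if (ng == 0L) next
      srange <- snv_bin_range(strata$snv_bin[s])
      crange <- coverage_bin_range(strata$coverage_bin[s])
      n_tp <- round(ng * tp_fraction)
      is_tp <- sample(rep(c(TRUE, FALSE), c(n_tp, ng - n_tp)))
      k <- runifint(ng, srange[1], srange[2])
      ids <- sprintf("gene_%05d", gene_no + seq_len(ng))
      gene_no <- gene_no + ng
      n <- runifint(sum(k), crange[1], crange[2])
      gid <- rep(seq_len(ng), k)
      tp <- rep(is_tp, k)
      # haplotype 1 is the major haplotype; its allele is ref or alt at
      # random per SNV
      h1_ref <- stats::runif(sum(k)) < 0.5
      f_h1 <- ifelse(h1_ref, f_ref, 1 - f_ref)
      mu_h1 <- ifelse(tp, bias_adjusted_mu(maf, f_h1), f_h1)
      x_h1 <- rbetabinom(sum(k), size = n, mu = mu_h1, rho = rho)
      ref <- ifelse(h1_ref, x_h1, n - x_h1)
      df <- data.frame(
        ase_id = ids[gid],
        locus = paste0(ids[gid], "_snv", stats::ave(gid, gid,
                                                    FUN = seq_along)),
        ref_count = as.integer(ref),
        alt_count = as.integer(n - ref),
        hap1_is_ref = h1_ref,
        stringsAsFactors = FALSE
      )
      if (two_sample) {
        names(df)[names(df) == "ref_count"] <- "ref_count1"
        names(df)[names(df) == "alt_count"] <- "alt_count1"
        n2 <- runifint(sum(k), crange[1], crange[2])
        # the other sample is allelically balanced for every gene
        ref2 <- rbetabinom(sum(k), n2, f_ref, rho)
        df$ref_count2 <- as.integer(ref2)
        df$alt_count2 <- as.integer(n2 - ref2)
      }
      counts[[s]] <- df
      truth[[s]] <- data.frame(
        ase_id = ids,
        snv_bin = strata$snv_bin[s],
        coverage_bin = strata$coverage_bin[s],
        stratum = paste(strata$snv_bin[s], strata$coverage_bin[s],
                        sep = "/"),
        is_tp = is_tp,
        stringsAsFactors = FALSE
      )
    }
    list(counts = do.call(rbind, counts), truth = do.call(rbind, truth))
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  rownames(out$counts) <- NULL
  rownames(out$truth) <- NULL
  out
}

#' Score truth-labeled ASE calls per stratum
#'
#' True positive rate is called TPs over all TPs; FDR is false calls over
#' all calls (0 when nothing is called). Overall rows are gene-count
#' weighted averages of the stratum values.
#'
#' @param calls Data frame with \code{ase_id} and logical
#'   \code{ase_called}.
#' @param truth Truth table from [generate_dataset()].
#' @return Data frame with one row per stratum plus an \code{"overall"}
#'   row: \code{stratum}, \code{n_genes}, \code{tpr}, \code{fdr}.
#' @export
score_calls <- function(calls, truth) {
  stopifnot(all(c("ase_id", "ase_called") %in% names(calls)),
            all(c("ase_id", "stratum", "is_tp") %in% names(truth)))
  m <- match(truth$ase_id, calls$ase_id)
  if (anyNA(m)) stop("every gene in 'truth' must appear in 'calls'")
  truth$called <- calls$ase_called[m] %in% TRUE
  per <- lapply(split(truth, truth$stratum), function(d) {
    n_tp <- sum(d$is_tp)
    n_called <- sum(d$called)
    data.frame(
      stratum = d$stratum[1],
      n_genes = nrow(d),
      tpr = if (n_tp > 0) sum(d$called & d$is_tp) / n_tp else NA_real_,
      fdr = if (n_called > 0) sum(d$called & !d$is_tp) / n_called else 0,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  w <- per$n_genes / sum(per$n_genes)
  overall <- data.frame(
    stratum = "overall", n_genes = sum(per$n_genes),
    tpr = sum(w * per$tpr, na.rm = TRUE) /
      sum(w[!is.na(per$tpr)]),
    fdr = sum(w * per$fdr), stringsAsFactors = FALSE
  )
  out <- rbind(per, overall)
  rownames(out) <- NULL
  out
}

#' Run the stratified power/FDR simulation benchmark
#'
#' For each signal level in \code{maf_levels} and each replicate: generate a
#' stratified data set ([generate_dataset()]), analyze it with matching
#' \code{rho} and \code{f_ref} ([run_one_sample()] or [run_two_sample()]),
#' call ASE at BH-adjusted p <= \code{fdr_level} (optionally with the
#' effect-size gate), and score against truth. Null simulations are shared
#' across replicates through one cache, since strata fix the set of per-SNV
#' total shapes.
#'
#' @param maf_levels Signal MAF levels, e.g. \code{c(0.7, 0.8, 0.9)}.
#' @param strata Stratum grid, see [ase_strata()].
#' @param tp_fraction Fraction of true-positive genes per stratum.
#' @param rho,f_ref Generating and analysis parameters (matched).
#' @param n_replicates Replicates per MAF level.
#' @param n_sim Null replicates per gene shape.
#' @param seed Master seed; replicate r of MAF level m uses a seed derived
#'   from it.
#' @param significance_only Call on the BH gate alone, without the
#'   effect-size cutoff.
#' @param two_sample Run the two-sample benchmark (balanced second sample;
#'   the one-sample-support gate uses the sample of interest's counts).
#' @param cache Optional shared null cache, see [new_null_cache()].
#' @return Data frame with one row per (maf, stratum): \code{maf},
#'   \code{stratum}, \code{n_genes}, \code{tpr}, \code{tpr_se}, \code{fdr},
#'   \code{fdr_se}, \code{n_replicates}; stratum \code{"overall"} rows carry
#'   the gene-count-weighted averages.
#' @export
run_sim_study <- function(maf_levels = c(0.7, 0.8, 0.9),
                          strata = ase_strata(), tp_fraction = 0.25,
                          rho = 0.004, f_ref = 0.5, n_replicates = 10,
                          n_sim = 1e4, seed = 1,
                          significance_only = FALSE, two_sample = FALSE,
                          cache = new_null_cache()) {
  out <- list()
  for (maf in maf_levels) {
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      rep_seed <- derive_seed(seed, sprintf("simrep|%g|%d", maf, r))
      ds <- generate_dataset(strata, tp_fraction = tp_fraction, maf = maf,
                             rho = rho, f_ref = f_ref,
                             two_sample = two_sample, seed = rep_seed)
      calls <- simulate_and_call(ds$counts, rho, f_ref, n_sim, seed, cache,
                                 significance_only, two_sample)
      reps[[r]] <- score_calls(calls, ds$truth)
    }
    tab <- do.call(rbind, reps)
    agg <- lapply(split(tab, tab$stratum), function(d) {
      data.frame(maf = maf, stratum = d$stratum[1],
                 n_genes = d$n_genes[1],
                 tpr = mean(d$tpr, na.rm = TRUE),
                 tpr_se = stats::sd(d$tpr, na.rm = TRUE) /
                   sqrt(sum(!is.na(d$tpr))),
                 fdr = mean(d$fdr),
                 fdr_se = stats::sd(d$fdr) / sqrt(nrow(d)),
                 n_replicates = nrow(d), stringsAsFactors = FALSE)
    })
    out[[length(out) + 1L]] <- do.call(rbind, agg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

simulate_and_call <- function(counts, rho, f_ref, n_sim, seed, cache,
                              significance_only, two_sample) {
  if (two_sample) {
    res2 <- run_two_sample(counts, rho = rho, f_ref = f_ref, n_sim = n_sim,
                           seed = seed, cache = cache)
    counts1 <- data.frame(ase_id = counts$ase_id, locus = counts$locus,
                          ref_count = counts$ref_count1,
                          alt_count = counts$alt_count1)
    res1 <- run_one_sample(counts1, rho = rho, f_ref = f_ref,
                           n_sim = n_sim, seed = seed, cache = cache,
                           phase = "pseudo")
    calls1 <- call_ase(res1,
                       maf_cutoff = if (significance_only) 0.5 else 0.7)
    call_ase(res2,
             maf_diff_cutoff = if (significance_only) 0 else 0.2,
             one_sample_calls = calls1)
  } else {
    res <- run_one_sample(counts, rho = rho, f_ref = f_ref, n_sim = n_sim,
                          seed = seed, cache = cache, phase = "pseudo")
    call_ase(res, maf_cutoff = if (significance_only) 0.5 else 0.7)
  }
}
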
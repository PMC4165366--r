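#' Per-SNV proportion-difference score for two-sample ASE
#'
#' The two-sample analogue of the per-SNV transformed score: the difference
#' of anchored-haplotype read frequencies between the sample of interest and
#' the other sample,
#' \eqn{z = x_t/n_t - x_n/n_n}, with null-hypothesis variance
#' \eqn{p(1-p)/n_t + p(1-p)/n_n} evaluated at the common haplotype frequency
#' \code{p_null}, each term inflated by \eqn{\rho(n-1)+1} when \code{rho} is
#' positive. No variance-stabilizing transform is applied on this scale, so
#' the combined estimate is sensitive to outlying SNVs (see vignette).
#'
#' @param x_t,n_t Anchored count and total in the sample of interest.
#' @param x_n,n_n Anchored count and total in the other sample.
#' @param p_null Common anchored-haplotype frequency under the null,
#'   strictly in (0, 1).
#' @param rho Overdispersion in \code{[0, 1)}.
#' @return A list with vectors \code{z} and \code{variance}.
#' @examples
#' pd_score(18, 20, 10, 20, p_null = 0.7) # z = 0.4, variance = 0.021
#' @export
pd_score <- function(x_t, n_t, x_n, n_n, p_null, rho = 0) {
  if (any(n_t < 1) || any(n_n < 1)) stop("totals must be >= 1")
  if (any(x_t < 0) || any(x_t > n_t) || any(x_n < 0) || any(x_n > n_n)) {
    stop("counts must lie within totals")
  }
  check_open_unit(p_null, "p_null")
  if (any(rho < 0) || any(rho >= 1)) stop("'rho' must be in [0, 1)")
  z <- x_t / n_t - x_n / n_n
  v <- p_null * (1 - p_null) *
    ((rho * (n_t - 1) + 1) / n_t + (rho * (n_n - 1) + 1) / n_n)
  list(z = z, variance = v)
}

#' Pooled estimate of the common haplotype frequency under the null
#'
#' Method-of-moments estimate of the anchored-haplotype frequency shared by
#' both samples under the null of no sample-specific ASE: anchored counts
#' pooled over both samples and all SNVs, divided by pooled totals, clipped
#' away from 0 and 1 (to \code{[1/(N+2), 1 - 1/(N+2)]}, \code{N} = pooled
#' total) so the null simulation never degenerates.
#'
#' @param x_t,n_t Anchored counts and totals in the sample of interest.
#' @param x_n,n_n Anchored counts and totals in the other sample.
#' @return A single frequency strictly in (0, 1).
#' @export
estimate_null_p <- function(x_t, n_t, x_n, n_n) {
  total <- sum(n_t) + sum(n_n)
  if (total < 1) stop("no reads")
  p <- (sum(x_t) + sum(x_n)) / total
  lo <- 1 / (total + 2)
  min(max(p, lo), 1 - lo)
}

# Expected pooled anchored count under a common haplotype frequency p when
# the phasing is re-derived by voting on the sample of interest: the folded
# count in that sample plus the other sample's count anchored by it.
# Binomial folding expectations, computed exactly per SNV.
expected_anchored_total <- function(p, n_t, n_n) {
  tot <- 0
  for (j in seq_along(n_t)) {
    n <- n_t[j]
    x <- 0:n
    pm <- stats::dbinom(x, n, p)
    e_t <- sum(pm * pmax(x, n - x))
    q <- sum(pm[x >= n - x])
    tot <- tot + e_t + n_n[j] * (q * p + (1 - q) * (1 - p))
  }
  tot
}

# Folding-corrected estimate of the common haplotype frequency: the p whose
# expected pooled anchored count matches the observed one. The raw pooled
# ratio overestimates p under balance (voting always anchors the larger
# count), which would make the simulated null anti-conservative; matching
# the folded moment removes that bias.
estimate_null_p_anchored <- function(x_t, n_t, x_n, n_n) {
  s <- sum(x_t) + sum(x_n)
  tot <- sum(n_t) + sum(n_n)
  hi <- 1 - 1 / (tot + 2)
  if (s <= expected_anchored_total(0.5, n_t, n_n)) return(0.5)
  if (s >= expected_anchored_total(hi, n_t, n_n)) return(hi)
  stats::uniroot(function(p) expected_anchored_total(p, n_t, n_n) - s,
                 c(0.5, hi), tol = 1e-6)$root
}

# Gene-level two-sample statistic from anchored counts. The inverse-variance
# weights share the common factor p0(1-p0), which cancels in the combined
# point estimate but not in Q.
two_sample_statistic <- function(x_t, n_t, x_n, n_n, p_null, rho = 0) {
  sc <- pd_score(x_t, n_t, x_n, n_n, p_null, rho)
  cmb <- meta_combine(sc$z, sc$variance)
  list(t_pd = cmb$combined_z, q_stat = cmb$q_stat, k = cmb$k,
       combined_variance = cmb$combined_variance)
}

#' Simulate the two-sample null distribution for one gene shape
#'
#' Under the null both samples share the anchored-haplotype frequency
#' \code{p_null}. Holding per-SNV totals fixed, haplotype-1 counts are drawn
#' for both samples from Beta-Binomial(n, mu = \code{bias_adjusted_mu(
#' p_null, f)}, rho) with the haplotype-to-allele assignment randomized per
#' SNV, the voting phasing is re-derived from the simulated sample of
#' interest and imposed on the other sample, the common frequency is
#' re-estimated from the simulated counts, and the gene-level
#' proportion-difference statistic and Q are recomputed.
#'
#' @param n_t,n_n Integer vectors of per-SNV totals (same loci, same order).
#' @param p_null Common anchored-haplotype frequency under the null.
#' @param rho Overdispersion in \code{[0, 1)}.
#' @param f_ref Reference-allele observation probability at balanced
#'   expression.
#' @param n_sim Number of replicates.
#' @param seed Integer seed; caller RNG state is preserved.
#' @return A list with vectors \code{t} and \code{q}.
#' @export
simulate_null_two_sample <- function(n_t, n_n, p_null, rho = 0,
                                     f_ref = 0.5, n_sim = 1e5, seed = 1) {
  n_t <- as.integer(n_t); n_n <- as.integer(n_n)
  if (length(n_t) != length(n_n) || length(n_t) == 0L) {
    stop("'n_t' and 'n_n' must be non-empty and of equal length")
  }
  if (any(n_t < 1) || any(n_n < 1)) stop("totals must be >= 1")
  check_open_unit(p_null, "p_null")
  if (n_sim < 100) {
    warning("fewer than 100 null replicates gives unusable p-values")
  }
  k <- length(n_t)
  with_seed(seed, {
    nt <- matrix(rep(n_t, each = n_sim), nrow = n_sim)
    nn <- matrix(rep(n_n, each = n_sim), nrow = n_sim)
    # haplotype 1 is the reference allele at random per SNV and replicate;
    # the assignment is a property of the locus, shared by both samples
    h1_ref <- matrix(stats::runif(n_sim * k) < 0.5, nrow = n_sim)
    f_h1 <- ifelse(h1_ref, f_ref, 1 - f_ref)
    mu_h1 <- bias_adjusted_mu(p_null, f_h1)
    x1_t <- matrix(
      rbetabinom(n_sim * k, size = as.vector(nt), mu = as.vector(mu_h1),
                 rho = rho), nrow = n_sim)
    x1_n <- matrix(
      rbetabinom(n_sim * k, size = as.vector(nn), mu = as.vector(mu_h1),
                 rho = rho), nrow = n_sim)
    ref_t <- ifelse(h1_ref, x1_t, nt - x1_t)
    ref_n <- ifelse(h1_ref, x1_n, nn - x1_n)
    # voting phasing on the simulated sample of interest, imposed on both
    anchor_ref <- ref_t >= nt - ref_t
    xa_t <- pmax(ref_t, nt - ref_t)
    xa_n <- ifelse(anchor_ref, ref_n, nn - ref_n)
    # re-estimate the pooled common frequency per replicate
    tot <- sum(n_t) + sum(n_n)
    p0 <- (rowSums(xa_t) + rowSums(xa_n)) / tot
    p0 <- pmin(pmax(p0, 1 / (tot + 2)), 1 - 1 / (tot + 2))
    z <- xa_t / nt - xa_n / nn
    cfac <- (rho * (n_t - 1) + 1) / n_t + (rho * (n_n - 1) + 1) / n_n
    wc <- 1 / cfac                    # p0(1-p0) cancels in the estimate
    zg <- as.vector(z %*% wc) / sum(wc)
    q <- as.vector((z - zg)^2 %*% wc) / (p0 * (1 - p0))
    list(t = zg, q = q)
  })
}

#' Two-sample differential ASE analysis
#'
#' Tests each gene for sample-of-interest-specific allelic imbalance (e.g.
#' tumor-specific ASE in a tumor/normal pair). Only loci present in both
#' samples are usable; phasing is anchored exclusively on the sample of
#' interest (voting pseudo-phasing), the per-SNV proportion differences are
#' combined by inverse-variance meta-analysis into an estimate of the
#' haplotype-frequency difference D, and significance comes from simulating
#' the pipeline under the null of a common haplotype frequency. That
#' frequency is estimated by pooling anchored counts across samples and
#' SNVs and then correcting for the upward bias that voting phasing imposes
#' on pooled counts (moment matching against the exact binomial folding
#' expectation), so the simulated null reproduces the phasing-induced
#' inflation of the observed statistic. To detect ASE specific to the other
#' sample, swap the samples so it becomes the sample of interest.
#'
#' @param counts Data frame with columns \code{ase_id}, \code{ref_count1},
#'   \code{alt_count1} (sample of interest), \code{ref_count2},
#'   \code{alt_count2} (other sample), optionally \code{locus}.
#' @param rho,f_ref,n_sim,seed,cache As in [run_one_sample()].
#' @return Data frame with one row per gene: \code{ase_id}, \code{n_snvs},
#'   \code{maf_difference} (estimate of D, interest minus other),
#'   \code{null_p_hap1} (folding-corrected common frequency used in the
#'   null simulation), \code{p_ase},
#'   \code{q_stat}, \code{p_het}, \code{n_sim}, \code{note}.
#' @export
run_two_sample <- function(counts, rho = 0, f_ref = 0.5, n_sim = 1e5,
                           seed = 1, cache = NULL) {
  if (!is.data.frame(counts) || nrow(counts) == 0L) {
    stop("'counts' must be a non-empty data frame")
  }
  need <- c("ase_id", "ref_count1", "alt_count1", "ref_count2",
            "alt_count2")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  ids <- unique(counts$ase_id)
  rows <- lapply(ids, function(id) {
    snvs <- counts[counts$ase_id == id, , drop = FALSE]
    tryCatch(
      analyze_gene_2s(id, snvs, rho, f_ref, n_sim, seed, cache),
      error = function(e) {
        data.frame(ase_id = id, n_snvs = nrow(snvs),
                   maf_difference = NA_real_, null_p_hap1 = NA_real_,
                   p_ase = NA_real_, q_stat = NA_real_, p_het = NA_real_,
                   n_sim = NA_real_, note = conditionMessage(e),
                   stringsAsFactors = FALSE)
      }
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

analyze_gene_2s <- function(id, snvs, rho, f_ref, n_sim, seed, cache) {
  locus <- if (is.null(snvs$locus)) paste0("snv", seq_len(nrow(snvs))) else
    snvs$locus
  interest <- data.frame(locus = locus, ref_count = snvs$ref_count1,
                         alt_count = snvs$alt_count1)
  other <- data.frame(locus = locus, ref_count = snvs$ref_count2,
                      alt_count = snvs$alt_count2)
  ph <- phase_by_other_sample(interest, other)
  x_t <- ph$interest$anchor_count; n_t <- ph$interest$n
  x_n <- ph$other$anchor_count;    n_n <- ph$other$n
  # raw pooled frequency normalizes Q identically in the observed and
  # simulated pipelines; the folding-corrected frequency parametrizes the
  # null generation
  p0 <- estimate_null_p(x_t, n_t, x_n, n_n)
  p0_gen <- estimate_null_p_anchored(x_t, n_t, x_n, n_n)
  stat <- two_sample_statistic(x_t, n_t, x_n, n_n, p0, rho)
  ord <- order(n_t, n_n)
  key <- null_key("2s", FALSE, 0L, rho, f_ref, n_sim, seed,
                  extra = paste(paste(n_t[ord], n_n[ord], sep = ":"),
                                format(p0_gen, digits = 12),
                                collapse = ","))
  null <- cache_fetch(cache, key, function() {
    simulate_null_two_sample(n_t[ord], n_n[ord], p0_gen, rho = rho,
                             f_ref = f_ref, n_sim = n_sim,
                             seed = derive_seed(seed, key))
  })
  pv <- empirical_pvalues(list(t_pd = stat$t_pd, q_stat = stat$q_stat),
                          null, k = stat$k)
  data.frame(ase_id = id, n_snvs = stat$k, maf_difference = stat$t_pd,
             null_p_hap1 = p0_gen, p_ase = pv$p_ase, q_stat = stat$q_stat,
             p_het = pv$p_het, n_sim = n_sim, note = NA_character_,
             stringsAsFactors = FALSE)
}
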
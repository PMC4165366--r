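#' Gene-level ASE statistic from a phased gene
#'
#' Freeman-Tukey transforms the anchored per-SNV counts, corrects each score
#' for pre-existing allelic bias (exact inversion of the mean map on the
#' transformed scale, using the anchored allele's own null observation
#' probability: \code{f_ref} for reference-anchored SNVs, \code{1 - f_ref}
#' otherwise), combines the scores by inverse-variance meta-analysis with
#' per-SNV variance \code{(rho (n - 1) + 1) / (n + 0.5)}, and backtransforms
#' the combined score to a transcript-scale major haplotype frequency (MAF)
#' estimate. For a single SNV this reduces to the natural estimate
#' \code{x/n} up to the transform round trip.
#'
#' @param phased A \code{phased_gene} (see [pseudo_phase()],
#'   [phase_from_labels()]).
#' @param rho Beta-binomial overdispersion in \code{[0, 1)}.
#' @param f_ref Probability of observing the reference allele at balanced
#'   expression (0.5 = no bias).
#' @return A list: \code{t_ft} (MAF estimate, always \code{>= 0.5}),
#'   \code{q_stat} (Cochran heterogeneity statistic), \code{combined_z},
#'   \code{combined_variance}, \code{k}, and \code{major_is_anchor}
#'   (whether the anchored haplotype is the major one).
#' @export
gene_statistic <- function(phased, rho = 0, f_ref = 0.5) {
  if (!inherits(phased, "phased_gene")) {
    stop("'phased' must be a phased_gene")
  }
  if (length(phased$n) == 0L) stop("empty gene")
  z <- ft_corrected_z(phased$anchor_count, phased$n, phased$anchor_is_ref,
                      f_ref)
  cmb <- meta_combine(z, ft_variance(phased$n, rho))
  p_anchor <- ft_backtransform(cmb$combined_z)
  list(t_ft = max(p_anchor, 1 - p_anchor),
       q_stat = cmb$q_stat,
       combined_z = cmb$combined_z,
       combined_variance = cmb$combined_variance,
       k = cmb$k,
       major_is_anchor = p_anchor >= 0.5)
}

# Bias-corrected FT score: transform counts, invert the read-scale ->
# transcript-scale map at the anchored allele's null observation
# probability, return on the 2*asin(sqrt(p)) scale. Identity when
# f_ref = 0.5. Works elementwise on vectors or matrices.
ft_corrected_z <- function(x, n, anchor_is_ref, f_ref) {
  z <- asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))
  if (f_ref == 0.5) return(z)
  check_open_unit(f_ref, "f_ref")
  f_anchor <- ifelse(anchor_is_ref, f_ref, 1 - f_ref)
  mu <- sin(z / 2)^2
  p <- mu * (1 - f_anchor) / (mu * (1 - f_anchor) + f_anchor * (1 - mu))
  2 * asin(sqrt(p))
}

#' Simulate the null distribution of the gene-level statistics
#'
#' Holding the per-SNV read totals fixed, draws reference-allele counts from
#' Beta-Binomial(n, mu = \code{f_ref}, rho = \code{rho}) under the null of
#' balanced expression, re-applies the identical phasing rule (voting
#' pseudo-phasing, or haplotype-1 anchoring with a gene-level major fold
#' when phase is known) and statistic computation as the observed pipeline,
#' and returns the empirical null samples of the MAF statistic and the
#' heterogeneity statistic Q.
#'
#' @param n Integer vector of per-SNV read totals.
#' @param rho Overdispersion in \code{[0, 1)}.
#' @param f_ref Reference-allele observation probability under the null.
#' @param n_sim Number of replicates (values below 100 trigger a warning).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param phase_known Logical; \code{TRUE} reproduces the known-phase
#'   pipeline instead of pseudo-phasing.
#' @return A list with numeric vectors \code{t} and \code{q} of length
#'   \code{n_sim}.
#' @export
simulate_null <- function(n, rho = 0, f_ref = 0.5, n_sim = 1e5,
                          seed = 1, phase_known = FALSE) {
  n <- as.integer(n)
  if (length(n) == 0L || any(n < 1)) stop("'n' must be positive integers")
  if (n_sim < 100) {
    warning("fewer than 100 null replicates gives unusable p-values")
  }
  k <- length(n)
  with_seed(seed, {
    nmat <- matrix(rep(n, each = n_sim), nrow = n_sim)
    x_ref <- matrix(
      rbetabinom(n_sim * k, size = as.vector(nmat), mu = f_ref, rho = rho),
      nrow = n_sim
    )
    if (phase_known) {
      xa <- x_ref
      anchor_ref <- TRUE
    } else {
      xa <- pmax(x_ref, nmat - x_ref)
      anchor_ref <- x_ref >= nmat - x_ref
    }
    z <- ft_corrected_z(xa, nmat, anchor_ref, f_ref)
    w <- 1 / ft_variance(n, rho)
    zg <- as.vector(z %*% w) / sum(w)
    q <- as.vector((z - zg)^2 %*% w)
    p_anchor <- ft_backtransform(zg)
    list(t = pmax(p_anchor, 1 - p_anchor), q = q)
  })
}

#' Empirical right-tail p-values against a simulated null
#'
#' \code{p_ase} is the fraction of null MAF statistics at least as large as
#' the observed one; \code{p_het} the analogous fraction for the
#' heterogeneity statistic Q (reported only for multi-SNV genes). Both are
#' floored at \code{1/(n_sim + 1)} so no p-value is exactly zero.
#'
#' @param observed List with \code{t_ft} (or \code{t_pd}) and \code{q_stat},
#'   as returned by [gene_statistic()].
#' @param null List with vectors \code{t} and \code{q}, as returned by
#'   [simulate_null()].
#' @param k Number of SNVs in the gene (heterogeneity is undefined at 1).
#' @return A list with \code{p_ase} and \code{p_het} (NA when \code{k = 1}).
#' @export
empirical_pvalues <- function(observed, null, k = observed$k) {
  t_obs <- if (!is.null(observed$t_ft)) observed$t_ft else observed$t_pd
  if (is.null(t_obs) || length(null$t) == 0L) {
    stop("need an observed statistic and a non-empty null sample")
  }
  n_sim <- length(null$t)
  floor_p <- 1 / (n_sim + 1)
  p_ase <- max(mean(null$t >= t_obs), floor_p)
  p_het <- if (!is.null(k) && k > 1) {
    max(mean(null$q >= observed$q_stat), floor_p)
  } else {
    NA_real_
  }
  list(p_ase = p_ase, p_het = p_het)
}

#' Create a cache for shared null distributions
#'
#' The simulated null depends on a gene only through the multiset of its
#' per-SNV read totals (plus \code{rho}, \code{f_ref}, phasing mode and
#' seed), so genes sharing that shape can share one simulation. The cache
#' stops admitting new entries after \code{max_entries} to bound memory;
#' lookups always remain correct because misses are simply recomputed.
#'
#' @param max_entries Maximum number of distinct null distributions to keep.
#' @return An environment usable as the \code{cache} argument of
#'   [run_one_sample()] and [run_two_sample()].
#' @export
new_null_cache <- function(max_entries = 2048L) {
  cache <- new.env(parent = emptyenv())
  assign("..max_entries", as.integer(max_entries), envir = cache)
  assign("..n_entries", 0L, envir = cache)
  cache
}

cache_fetch <- function(cache, key, compute) {
  if (is.null(cache)) return(compute())
  if (exists(key, envir = cache, inherits = FALSE)) {
    return(get(key, envir = cache, inherits = FALSE))
  }
  val <- compute()
  if (get("..n_entries", envir = cache) <
      get("..max_entries", envir = cache)) {
    assign(key, val, envir = cache)
    assign("..n_entries", get("..n_entries", envir = cache) + 1L,
           envir = cache)
  }
  val
}

#' One-sample gene-level ASE analysis
#'
#' For each gene (ASE unit): phase its SNVs (known haplotype labels when
#' present, voting pseudo-phasing otherwise), compute the meta-analytic MAF
#' statistic and heterogeneity statistic Q, simulate their joint null
#' distribution holding per-SNV totals fixed, and report empirical
#' p-values. No multiple-testing adjustment is applied here; see
#' [call_ase()].
#'
#' The null simulation for a gene depends only on the multiset of its
#' per-SNV totals (and \code{rho}, \code{f_ref}, phasing mode), and its RNG
#' stream is derived from \code{seed} and that shape, so results are
#' independent of gene order and genes with identical count data get
#' identical results. Pass a shared \code{cache} (see [new_null_cache()]) to
#' reuse simulations across calls.
#'
#' @param counts Data frame with columns \code{ase_id}, \code{ref_count},
#'   \code{alt_count}, optionally \code{locus} and logical
#'   \code{hap1_is_ref} labels.
#' @param rho Beta-binomial overdispersion in \code{[0, 1)}.
#' @param f_ref Global reference-allele observation probability at balanced
#'   expression (see [estimate_global_bias()]).
#' @param n_sim Null replicates per distinct gene shape (default 1e5; use
#'   1e6 for final analyses where runtime permits).
#' @param seed Integer seed for all null simulations.
#' @param cache Optional environment from [new_null_cache()].
#' @param phase \code{"auto"} uses labels when a gene has complete
#'   \code{hap1_is_ref}; \code{"pseudo"} ignores labels; \code{"known"}
#'   requires them. A gene with partial labels yields a flagged record.
#' @return Data frame with one row per gene: \code{ase_id}, \code{n_snvs},
#'   \code{maf} (transcript-scale MAF estimate), \code{p_ase},
#'   \code{q_stat}, \code{p_het} (NA for single-SNV genes),
#'   \code{phase_source}, \code{major_alleles} (comma-separated
#'   ref/alt per SNV), \code{n_sim} and \code{note} (non-NA when a gene
#'   failed and was skipped).
#' @examples
#' counts <- data.frame(ase_id = "g1", ref_count = c(18, 16),
#'                      alt_count = c(3, 5))
#' run_one_sample(counts, n_sim = 1000, seed = 7)
#' @export
run_one_sample <- function(counts, rho = 0, f_ref = 0.5, n_sim = 1e5,
                           seed = 1, cache = NULL,
                           phase = c("auto", "pseudo", "known")) {
  phase <- match.arg(phase)
  counts <- check_counts_table(counts)
  ids <- unique(counts$ase_id)
  rows <- lapply(ids, function(id) {
    snvs <- counts[counts$ase_id == id, , drop = FALSE]
    tryCatch(
      analyze_gene_1s(id, snvs, rho, f_ref, n_sim, seed, cache, phase),
      error = function(e) failed_row_1s(id, nrow(snvs), conditionMessage(e))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

analyze_gene_1s <- function(id, snvs, rho, f_ref, n_sim, seed, cache,
                            phase) {
  labels <- snvs$hap1_is_ref
  has_any <- !is.null(labels) && any(!is.na(labels))
  has_all <- !is.null(labels) && !anyNA(labels)
  if (has_any && !has_all) {
    stop("mixed labeled and unlabeled SNVs within a gene")
  }
  use_known <- switch(phase,
    auto = has_all && has_any,
    pseudo = FALSE,
    known = TRUE
  )
  phased <- if (use_known) phase_from_labels(snvs) else pseudo_phase(snvs)
  stat <- gene_statistic(phased, rho = rho, f_ref = f_ref)
  key <- null_key("1s", phased$phase_source == "known", phased$n, rho,
                  f_ref, n_sim, seed)
  null <- cache_fetch(cache, key, function() {
    simulate_null(sort(phased$n), rho = rho, f_ref = f_ref, n_sim = n_sim,
                  seed = derive_seed(seed, key),
                  phase_known = phased$phase_source == "known")
  })
  pv <- empirical_pvalues(stat, null)
  major_is_ref <- if (stat$major_is_anchor) {
    phased$anchor_is_ref
  } else {
    !phased$anchor_is_ref
  }
  data.frame(
    ase_id = id,
    n_snvs = length(phased$n),
    maf = stat$t_ft,
    p_ase = pv$p_ase,
    q_stat = stat$q_stat,
    p_het = pv$p_het,
    phase_source = phased$phase_source,
    major_alleles = paste(ifelse(major_is_ref, "ref", "alt"),
                          collapse = ","),
    n_sim = n_sim,
    note = NA_character_,
    stringsAsFactors = FALSE
  )
}

failed_row_1s <- function(id, k, msg) {
  data.frame(ase_id = id, n_snvs = k, maf = NA_real_, p_ase = NA_real_,
             q_stat = NA_real_, p_het = NA_real_,
             phase_source = NA_character_, major_alleles = NA_character_,
             n_sim = NA_real_, note = msg, stringsAsFactors = FALSE)
}

null_key <- function(mode, known, n, rho, f_ref, n_sim, seed, extra = "") {
  paste(mode, if (known) "known" else "pseudo",
        paste(sort(as.integer(n)), collapse = ","),
        format(rho, digits = 12), format(f_ref, digits = 12),
        n_sim, seed, extra, sep = "|")
}

check_counts_table <- function(counts) {
  if (!is.data.frame(counts) || nrow(counts) == 0L) {
    stop("'counts' must be a non-empty data frame")
  }
  need <- c("ase_id", "ref_count", "alt_count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  counts
}
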
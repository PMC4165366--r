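#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1). Thin wrapper around
#' \code{stats::p.adjust(method = "BH")} with input validation.
#'
#' @param p_values Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Assign ASE status to genes
#'
#' Applies the calling rules to the output of [run_one_sample()] or
#' [run_two_sample()] for one sample (or one sample pair): a gene is called
#' ASE when its BH-adjusted ASE p-value is at most \code{fdr_level} and its
#' effect size passes the cutoff -- estimated MAF at least \code{maf_cutoff}
#' in one-sample mode, MAF difference (interest minus other) at least
#' \code{maf_diff_cutoff} in two-sample mode. In two-sample mode, genes are
#' additionally required to show ASE in the one-sample analysis of the
#' sample of interest (\code{require_one_sample_support}). Multi-SNV genes
#' whose BH-adjusted heterogeneity p-value is at most \code{het_fdr_level}
#' are flagged as possibly isoform-specific; that adjustment is performed
#' over multi-SNV genes only, since single-SNV genes have no heterogeneity
#' test.
#'
#' The multiple-testing family is the batch passed in, which should be all
#' tested genes of one sample.
#'
#' @param results Data frame from [run_one_sample()] (column \code{maf}) or
#'   [run_two_sample()] (column \code{maf_difference}); mixing modes is an
#'   error.
#' @param fdr_level FDR level for the ASE call (default 0.05).
#' @param maf_cutoff One-sample effect-size cutoff on estimated MAF
#'   (default 0.7). Set to 0.5 to disable (significance-only calling).
#' @param maf_diff_cutoff Two-sample cutoff on estimated MAF difference
#'   (default 0.2). Set to 0 to disable.
#' @param het_fdr_level FDR level for the isoform-specific flag.
#' @param require_one_sample_support Two-sample mode only: require a
#'   positive one-sample call for the sample of interest.
#' @param one_sample_calls Two-sample mode with support gate: data frame
#'   with columns \code{ase_id} and \code{ase_called} from calling the
#'   sample of interest's one-sample results on the same counts. Genes
#'   absent from it are treated as unsupported.
#' @return \code{results} with added columns \code{p_ase_adj},
#'   \code{p_het_adj}, \code{ase_called} and \code{isoform_flag}.
#' @export
call_ase <- function(results, fdr_level = 0.05, maf_cutoff = 0.7,
                     maf_diff_cutoff = 0.2, het_fdr_level = 0.05,
                     require_one_sample_support = TRUE,
                     one_sample_calls = NULL) {
  stopifnot(is.data.frame(results))
  has_1s <- "maf" %in% names(results)
  has_2s <- "maf_difference" %in% names(results)
  if (has_1s && has_2s) stop("mixed one- and two-sample results")
  if (!has_1s && !has_2s) {
    stop("'results' must carry a 'maf' or 'maf_difference' column")
  }
  for (x in c(fdr_level, het_fdr_level)) {
    if (!is.finite(x) || x <= 0 || x >= 1) {
      stop("FDR levels must be strictly inside (0, 1)")
    }
  }
  results$p_ase_adj <- bh_adjust(results$p_ase)
  results$p_het_adj <- NA_real_
  multi <- !is.na(results$p_het)
  if (any(multi)) {
    results$p_het_adj[multi] <- bh_adjust(results$p_het[multi])
  }
  effect_ok <- if (has_1s) {
    !is.na(results$maf) & results$maf >= maf_cutoff
  } else {
    !is.na(results$maf_difference) &
      results$maf_difference >= maf_diff_cutoff
  }
  called <- !is.na(results$p_ase_adj) & results$p_ase_adj <= fdr_level &
    effect_ok
  if (has_2s && require_one_sample_support) {
    if (is.null(one_sample_calls)) {
      stop("two-sample calling with 'require_one_sample_support' needs ",
           "'one_sample_calls' (or set the gate to FALSE)")
    }
    supported <- results$ase_id %in%
      one_sample_calls$ase_id[one_sample_calls$ase_called %in% TRUE]
    called <- called & supported
  }
  results$ase_called <- called
  results$isoform_flag <- !is.na(results$p_het_adj) &
    results$p_het_adj <= het_fdr_level
  results
}
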
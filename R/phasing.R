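#' @title Haplotype assignment of SNV alleles within a gene
#' @description
#' A "phased gene" records, for each heterozygous SNV of a gene, which
#' allele is anchored to the haplotype used for gene-level inference and how
#' many reads support it. Three routes produce one: voting pseudo-phasing
#' when true phase is unknown ([pseudo_phase()]), pass-through of known
#' haplotype labels ([phase_from_labels()]), and anchoring a second sample
#' on the phasing of the sample of interest ([phase_by_other_sample()]).
#' @name phasing
NULL

new_phased_gene <- function(locus, n, anchor_count, anchor_is_ref,
                            phase_source) {
  structure(
    list(locus = as.character(locus),
         n = as.integer(n),
         anchor_count = as.integer(anchor_count),
         anchor_is_ref = as.logical(anchor_is_ref),
         phase_source = phase_source),
    class = "phased_gene"
  )
}

#' @export
print.phased_gene <- function(x, ...) {
  cat(sprintf("Phased gene (%s), %d SNV(s)\n", x$phase_source,
              length(x$n)))
  print(data.frame(locus = x$locus, n = x$n,
                   anchor_count = x$anchor_count,
                   anchor_allele = ifelse(x$anchor_is_ref, "ref", "alt")))
  invisible(x)
}

check_snv_counts <- function(snvs) {
  if (!is.data.frame(snvs) || nrow(snvs) == 0L) {
    stop("'snvs' must be a non-empty data frame")
  }
  need <- c("ref_count", "alt_count")
  miss <- setdiff(need, names(snvs))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(snvs$ref_count < 0) || any(snvs$alt_count < 0)) {
    stop("allele counts must be non-negative")
  }
  if (any(snvs$ref_count + snvs$alt_count < 1)) {
    stop("each SNV must have at least one read")
  }
  if (is.null(snvs$locus)) snvs$locus <- paste0("snv", seq_len(nrow(snvs)))
  snvs
}

#' Voting pseudo-phasing of SNVs within a gene
#'
#' At each SNV the allele with the larger read count is assigned to a
#' putative "major" haplotype. Ties are broken deterministically in favor of
#' the reference allele; the simulated null applies the identical rule, so
#' p-value calibration absorbs the choice.
#'
#' @param snvs Data frame with one row per SNV and columns \code{ref_count}
#'   and \code{alt_count} (optionally \code{locus}).
#' @return A \code{phased_gene} with \code{phase_source = "pseudo"}: the
#'   anchored haplotype is the major one, so
#'   \code{anchor_count >= n - anchor_count} at every SNV.
#' @examples
#' pseudo_phase(data.frame(ref_count = c(8, 3), alt_count = c(2, 7)))
#' @export
pseudo_phase <- function(snvs) {
  snvs <- check_snv_counts(snvs)
  major_is_ref <- snvs$ref_count >= snvs$alt_count
  new_phased_gene(
    locus = snvs$locus,
    n = snvs$ref_count + snvs$alt_count,
    anchor_count = ifelse(major_is_ref, snvs$ref_count, snvs$alt_count),
    anchor_is_ref = major_is_ref,
    phase_source = "pseudo"
  )
}

#' Phase a gene from known haplotype labels
#'
#' When the true phase of every SNV is known, no pseudo-phasing is done:
#' counts are anchored on haplotype 1 as labelled, and downstream inference
#' reports the major haplotype as whichever haplotype has the larger
#' meta-analytic frequency.
#'
#' @param snvs Data frame with columns \code{ref_count}, \code{alt_count}
#'   and a logical \code{hap1_is_ref} present (non-NA) at every SNV.
#' @return A \code{phased_gene} with \code{phase_source = "known"}, anchored
#'   on haplotype 1.
#' @export
phase_from_labels <- function(snvs) {
  snvs <- check_snv_counts(snvs)
  if (is.null(snvs$hap1_is_ref) || anyNA(snvs$hap1_is_ref)) {
    stop("every SNV must carry a non-missing 'hap1_is_ref' label")
  }
  h1 <- as.logical(snvs$hap1_is_ref)
  new_phased_gene(
    locus = snvs$locus,
    n = snvs$ref_count + snvs$alt_count,
    anchor_count = ifelse(h1, snvs$ref_count, snvs$alt_count),
    anchor_is_ref = h1,
    phase_source = "known"
  )
}

#' Anchor a second sample on the phasing of the sample of interest
#'
#' Pseudo-phases the sample of interest (e.g. tumor) by voting, then imposes
#' the resulting per-SNV major-allele identity on the other sample's counts.
#' The other sample's counts never influence the phasing.
#'
#' @param snvs_interest,snvs_other Data frames with columns
#'   \code{ref_count}, \code{alt_count} and matching \code{locus} in the
#'   same order.
#' @return A list with elements \code{interest} (a \code{phased_gene} with
#'   \code{phase_source = "pseudo"}) and \code{other}
#'   (\code{phase_source = "pseudo_from_other_sample"}).
#' @export
phase_by_other_sample <- function(snvs_interest, snvs_other) {
  snvs_interest <- check_snv_counts(snvs_interest)
  snvs_other <- check_snv_counts(snvs_other)
  if (nrow(snvs_interest) != nrow(snvs_other) ||
      !identical(as.character(snvs_interest$locus),
                 as.character(snvs_other$locus))) {
    stop("the two samples must cover the identical ordered loci")
  }
  anchor <- pseudo_phase(snvs_interest)
  other <- new_phased_gene(
    locus = snvs_other$locus,
    n = snvs_other$ref_count + snvs_other$alt_count,
    anchor_count = ifelse(anchor$anchor_is_ref, snvs_other$ref_count,
                          snvs_other$alt_count),
    anchor_is_ref = anchor$anchor_is_ref,
    phase_source = "pseudo_from_other_sample"
  )
  list(interest = anchor, other = other)
}
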
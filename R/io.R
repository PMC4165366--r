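#' Read a tab-separated SNV count table
#'
#' Expected columns: \code{ase_id}, \code{chrom}, \code{pos} (1-based),
#' \code{ref}, \code{alt}, \code{rna_ref_count}, \code{rna_alt_count};
#' optional \code{sample_id}, \code{dna_ref_count}, \code{dna_alt_count},
#' \code{hap1_is_ref}, and \code{rna_ref_count2}/\code{rna_alt_count2} for a
#' paired second sample. Rows with missing or negative counts are dropped
#' with a warning; more than 1\% malformed rows is an error. Duplicate
#' (chrom, pos) within a sample is an error.
#'
#' @param path Path to the TSV file (with header).
#' @return A validated SNV table (data frame).
#' @export
read_snv_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_snv_table(tab, where = path)
}

validate_snv_table <- function(tab, where = "snv table") {
  need <- c("ase_id", "chrom", "pos", "ref", "alt", "rna_ref_count",
            "rna_alt_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(where, ": missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(tab$sample_id)) tab$sample_id <- "sample1"
  count_cols <- intersect(
    c("rna_ref_count", "rna_alt_count", "dna_ref_count", "dna_alt_count",
      "rna_ref_count2", "rna_alt_count2"), names(tab))
  bad <- rep(FALSE, nrow(tab))
  for (cc in count_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- bad | is.na(v) | v < 0 | v != round(v)
    tab[[cc]] <- as.integer(round(v))
  }
  tab$pos <- suppressWarnings(as.integer(tab$pos))
  bad <- bad | is.na(tab$pos) | is.na(tab$ase_id)
  if (any(bad)) {
    if (mean(bad) > 0.01) {
      stop(where, ": ", sum(bad), " malformed rows (>1%)")
    }
    warning(where, ": dropping ", sum(bad), " malformed row(s)")
    tab <- tab[!bad, , drop = FALSE]
  }
  key <- paste(tab$sample_id, tab$chrom, tab$pos)
  if (anyDuplicated(key)) {
    stop(where, ": duplicate (chrom, pos) within a sample")
  }
  rownames(tab) <- NULL
  tab
}

#' Read allelic depths from a VCF plus a gene map
#'
#' Extracts per-sample AD-style allelic depths (reference, alternative) from
#' a VCF and assigns each SNV to a gene via an interval map. Positions stay
#' 1-based (VCF convention). Multi-allelic records are rejected with a
#' logged count; SNVs overlapping zero or more than one gene are dropped.
#'
#' @param vcf_path Path to a VCF file.
#' @param gene_map_path Interval-to-gene map: either a BED file (extension
#'   \code{.bed}, 0-based half-open, fourth column the gene id) or a TSV
#'   with header columns \code{chrom}, \code{start}, \code{end},
#'   \code{ase_id} (1-based inclusive).
#' @param sample Sample name or index in the VCF (default: first sample).
#' @return An SNV table as from [read_snv_table()].
#' @export
read_snv_vcf <- function(vcf_path, gene_map_path, sample = 1L) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message("dropping ", sum(multi), " multi-allelic VCF record(s)")
  }
  adm <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(adm)) stop("VCF has no AD (allelic depth) FORMAT field")
  sample_name <- if (is.character(sample)) sample else colnames(adm)[sample]
  ad <- adm[, sample]
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_ct <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  alt_ct <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2L) p[2L] else NA_character_, "")))
  keep <- !multi & !is.na(ref_ct) & !is.na(alt_ct)
  tab <- data.frame(
    sample_id = sample_name,
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    rna_ref_count = ref_ct[keep],
    rna_alt_count = alt_ct[keep],
    stringsAsFactors = FALSE
  )
  map <- read_gene_map(gene_map_path)
  tab$ase_id <- assign_genes(tab$chrom, tab$pos, map)
  n0 <- nrow(tab)
  tab <- tab[!is.na(tab$ase_id), , drop = FALSE]
  if (nrow(tab) < n0) {
    message("dropping ", n0 - nrow(tab),
            " SNV(s) mapping to zero or multiple genes")
  }
  validate_snv_table(tab, where = vcf_path)
}

read_gene_map <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    map <- utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE)[, 1:4]
    names(map) <- c("chrom", "start", "end", "ase_id")
    map$start <- map$start + 1L   # BED is 0-based half-open
  } else {
    map <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "ase_id")
    if (!all(need %in% names(map))) {
      stop("gene map must have columns ", paste(need, collapse = ", "))
    }
  }
  map
}

assign_genes <- function(chrom, pos, map) {
  vapply(seq_along(pos), function(i) {
    hit <- map$ase_id[map$chrom == chrom[i] & map$start <= pos[i] &
                        map$end >= pos[i]]
    if (length(hit) == 1L) hit else NA_character_
  }, "")
}

#' Filter an SNV table to reliable heterozygous loci
#'
#' Applies, per sample, the standard filters for ASE input: genomic (DNA)
#' heterozygosity support (both alleles covered by at least
#' \code{min_dna_reads} reads and at least \code{min_dna_frac} of the DNA
#' reads; applied only when DNA count columns are present), removal of
#' variants within \code{proximity_bp} of another variant (both are
#' removed), minimum RNA coverage of \code{min_rna_reads}, and a
#' read-sharing guard: of any two surviving SNVs closer than
#' \code{merge_bp} (a read length), only the one with higher RNA coverage is
#' kept, so that per-locus counts can be treated as independent. The
#' operation is idempotent.
#'
#' @param tab SNV table (see [read_snv_table()]).
#' @param min_dna_reads,min_dna_frac DNA heterozygosity support thresholds.
#' @param min_rna_reads Minimum total RNA reads per SNV.
#' @param proximity_bp Window for the nearby-variant exclusion.
#' @param merge_bp Minimum spacing between retained SNVs.
#' @return The filtered table, with an attribute \code{filter_log}: a named
#'   integer vector of rows removed by each rule.
#' @export
filter_heterozygous <- function(tab, min_dna_reads = 5,
                                min_dna_frac = 0.10, min_rna_reads = 10,
                                proximity_bp = 10, merge_bp = 76) {
  tab <- validate_snv_table(tab)
  log <- c(proximity = 0L, dna_support = 0L, rna_coverage = 0L,
           read_sharing = 0L)
  # nearby-variant exclusion, against all input variants
  drop <- rep(FALSE, nrow(tab))
  for (idx in split(seq_len(nrow(tab)),
                    paste(tab$sample_id, tab$chrom))) {
    pos <- tab$pos[idx]
    o <- order(pos)
    d <- diff(pos[o])
    close_pair <- d <= proximity_bp
    hit <- logical(length(pos))
    hit[o][c(close_pair, FALSE)] <- TRUE
    hit[o][c(FALSE, close_pair)] <- TRUE
    drop[idx] <- hit
  }
  log["proximity"] <- sum(drop)
  tab <- tab[!drop, , drop = FALSE]
  if (all(c("dna_ref_count", "dna_alt_count") %in% names(tab))) {
    dn <- tab$dna_ref_count + tab$dna_alt_count
    ok <- tab$dna_ref_count >= min_dna_reads &
      tab$dna_alt_count >= min_dna_reads &
      tab$dna_ref_count >= min_dna_frac * dn &
      tab$dna_alt_count >= min_dna_frac * dn
    log["dna_support"] <- sum(!ok)
    tab <- tab[ok, , drop = FALSE]
  }
  rna <- tab$rna_ref_count + tab$rna_alt_count
  ok <- rna >= min_rna_reads
  log["rna_coverage"] <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]
  # read-sharing guard: keep the higher-coverage SNV of any close pair
  repeat {
    rna <- tab$rna_ref_count + tab$rna_alt_count
    drop <- rep(FALSE, nrow(tab))
    for (idx in split(seq_len(nrow(tab)),
                      paste(tab$sample_id, tab$chrom))) {
      o <- idx[order(tab$pos[idx])]
      if (length(o) < 2L) next
      d <- diff(tab$pos[o])
      for (j in which(d < merge_bp)) {
        a <- o[j]; b <- o[j + 1L]
        loser <- if (rna[a] >= rna[b]) b else a
        drop[loser] <- TRUE
      }
    }
    if (!any(drop)) break
    log["read_sharing"] <- log["read_sharing"] + sum(drop)
    tab <- tab[!drop, , drop = FALSE]
  }
  rownames(tab) <- NULL
  attr(tab, "filter_log") <- log
  tab
}

#' Estimate global reference-allele bias
#'
#' Count-weighted mean reference-allele fraction across heterozygous SNVs:
#' a method-of-moments estimate of the probability of observing the
#' reference allele at balanced expression, assuming most loci are not
#' allelically imbalanced. 0.5 means no pre-existing bias.
#'
#' @param tab Filtered SNV table.
#' @return Object of class \code{bias_spec}: list with \code{f_ref_null},
#'   \code{scope = "global"} and \code{n_snvs}.
#' @export
estimate_global_bias <- function(tab) {
  tab <- validate_snv_table(tab)
  if (nrow(tab) == 0L) stop("empty table")
  if (nrow(tab) < 100) {
    warning("fewer than 100 SNVs; global bias estimate will be noisy")
  }
  f <- sum(tab$rna_ref_count) /
    sum(tab$rna_ref_count + tab$rna_alt_count)
  structure(list(f_ref_null = f, scope = "global", n_snvs = nrow(tab)),
            class = "bias_spec")
}

#' @export
print.bias_spec <- function(x, ...) {
  cat(sprintf("Global reference-allele bias f(0.5) = %.4f (%d SNVs)\n",
              x$f_ref_null, x$n_snvs))
  invisible(x)
}

#' Estimate beta-binomial overdispersion from allelic fractions
#'
#' Method-of-moments estimate of the overdispersion rho from the excess
#' variance of per-SNV reference fractions around the global bias
#' \code{f}: for each SNV with \code{n} reads,
#' \eqn{(\hat p - f)^2 n / (f(1-f))} estimates \eqn{\rho(n-1) + 1}; the
#' per-SNV solutions are averaged and floored at 0. Assumes the bulk of loci
#' are allelically balanced, so it should be applied to the filtered table
#' of a sample, not to genes pre-selected for ASE.
#'
#' @param tab Filtered SNV table.
#' @param f_ref Known bias; estimated from \code{tab} when NULL.
#' @return Estimated rho (non-negative scalar).
#' @export
estimate_overdispersion <- function(tab, f_ref = NULL) {
  tab <- validate_snv_table(tab)
  if (is.null(f_ref)) {
    f_ref <- suppressWarnings(estimate_global_bias(tab))$f_ref_null
  }
  check_open_unit(f_ref, "f_ref")
  n <- tab$rna_ref_count + tab$rna_alt_count
  keep <- n >= 2
  n <- n[keep]
  p <- tab$rna_ref_count[keep] / n
  if (length(n) == 0L) return(0)
  infl <- (p - f_ref)^2 * n / (f_ref * (1 - f_ref))
  max(0, mean((infl - 1) / (n - 1)))
}

RESULT_COLUMNS <- c("ase_id", "n_snvs", "maf", "maf_difference", "p_ase",
                    "p_ase_adj", "p_het", "p_het_adj", "ase_called",
                    "isoform_flag", "q_stat", "phase_source",
                    "major_alleles", "n_sim", "note")

#' Write gene-level ASE results to a TSV
#'
#' One row per gene in a fixed column order (missing fields are written as
#' NA); the file round-trips through [read_results()].
#'
#' @param results Data frame from [run_one_sample()], [run_two_sample()] or
#'   [call_ase()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  for (cc in setdiff(RESULT_COLUMNS, names(results))) {
    results[[cc]] <- rep(NA, nrow(results))
  }
  utils::write.table(results[, RESULT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path Path to the file.
#' @return Data frame with the canonical result columns.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(ase_id = "character",
                                   note = "character"))
}

#' Convert an SNV table to the count layout of the analysis functions
#'
#' @param tab SNV table (see [read_snv_table()]).
#' @param two_sample Use the paired \code{rna_*_count2} columns as the
#'   second sample.
#' @return Data frame suitable for [run_one_sample()] or
#'   [run_two_sample()].
#' @export
as_analysis_counts <- function(tab, two_sample = FALSE) {
  tab <- validate_snv_table(tab)
  locus <- paste0(tab$chrom, ":", tab$pos)
  if (two_sample) {
    need <- c("rna_ref_count2", "rna_alt_count2")
    if (!all(need %in% names(tab))) {
      stop("two-sample layout needs columns ",
           paste(need, collapse = ", "))
    }
    data.frame(ase_id = tab$ase_id, locus = locus,
               ref_count1 = tab$rna_ref_count,
               alt_count1 = tab$rna_alt_count,
               ref_count2 = tab$rna_ref_count2,
               alt_count2 = tab$rna_alt_count2,
               stringsAsFactors = FALSE)
  } else {
    out <- data.frame(ase_id = tab$ase_id, locus = locus,
                      ref_count = tab$rna_ref_count,
                      alt_count = tab$rna_alt_count,
                      stringsAsFactors = FALSE)
    if (!is.null(tab$hap1_is_ref)) out$hap1_is_ref <- tab$hap1_is_ref
    out
  }
}

#' Write synthetic fixture files (counts plus truth sidecar)
#'
#' Wraps [generate_dataset()] and writes a full SNV table (with synthetic
#' chromosome coordinates spaced so no distance filter triggers) and the
#' truth labels to \code{dir}. Regenerating with the same seed is
#' bit-identical.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Passed to [generate_dataset()] (strata, tp_fraction, maf,
#'   rho, f_ref, two_sample).
#' @return Named character vector with paths \code{counts} and
#'   \code{truth}, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(seed = seed, ...)
  counts <- ds$counts
  bases <- c("A", "C", "G", "T")
  nsnv <- nrow(counts)
  ref <- with_seed(derive_seed(seed, "fixture-alleles"), {
    r <- sample(bases, nsnv, replace = TRUE)
    a <- vapply(r, function(b) sample(setdiff(bases, b), 1L), "")
    list(r = r, a = a)
  })
  tab <- data.frame(
    sample_id = "synthetic1",
    ase_id = counts$ase_id,
    chrom = "chrS",
    pos = seq_len(nsnv) * 1000L,
    ref = ref$r,
    alt = ref$a,
    stringsAsFactors = FALSE
  )
  if ("ref_count1" %in% names(counts)) {
    tab$rna_ref_count <- counts$ref_count1
    tab$rna_alt_count <- counts$alt_count1
    tab$rna_ref_count2 <- counts$ref_count2
    tab$rna_alt_count2 <- counts$alt_count2
  } else {
    tab$rna_ref_count <- counts$ref_count
    tab$rna_alt_count <- counts$alt_count
  }
  tab$hap1_is_ref <- counts$hap1_is_ref
  paths <- c(counts = file.path(dir, "snv_counts.tsv"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(tab, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
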
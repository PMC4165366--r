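# Shared fixture builders; everything is generated in code.

# Minimal SNV table in the on-disk schema, n loci on one chromosome.
make_snv_table <- function(ref_counts, alt_counts, pos = NULL,
                           ase_id = "geneA", with_dna = FALSE) {
  n <- length(ref_counts)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  tab <- data.frame(
    sample_id = "s1", ase_id = rep_len(ase_id, n), chrom = "chr1",
    pos = pos, ref = "A", alt = "G",
    rna_ref_count = ref_counts, rna_alt_count = alt_counts,
    stringsAsFactors = FALSE
  )
  if (with_dna) {
    tab$dna_ref_count <- 20L
    tab$dna_alt_count <- 20L
  }
  tab
}

# Counts for run_one_sample: one gene per row-group.
make_gene_counts <- function(ref, alt, id = "g1") {
  data.frame(ase_id = id, ref_count = ref, alt_count = alt,
             stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg step-up, independent of stats::p.adjust.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive single-SNV null of the folded MAF statistic: support points and
# probabilities from Binomial(n, p_null) folded at n/2.
enumerate_single_snv_null <- function(n, p_null = 0.5) {
  x <- 0:n
  xa <- pmax(x, n - x)
  z <- asin(sqrt(xa / (n + 1))) + asin(sqrt((xa + 1) / (n + 1)))
  t_val <- sin(z / 2)^2
  agg <- tapply(stats::dbinom(x, n, p_null), t_val, sum)
  data.frame(t = as.numeric(names(agg)), prob = as.numeric(agg))
}
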
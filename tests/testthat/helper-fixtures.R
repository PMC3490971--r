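# Small in-code fixtures shared across test files.

# A seven-sample cohort at hand-chosen sites.
make_tiny_cohort <- function() {
  sites <- variant_sites(chrom = c("1", "2", "3"),
                         pos = c(100L, 200L, 300L),
                         ref = c("A", "C", "G"),
                         alt = c("G", "T", "A"),
                         rsid = c("rs1", "rs2", NA))
  geno <- rbind(c(2L, 1L, 0L),
                c(1L, 0L, NA),
                c(1L, 0L, 0L),
                c(1L, 1L, 1L),
                c(1L, 0L, 0L),
                c(1L, 0L, 0L),
                c(1L, 0L, 2L))
  cohort_genotypes(paste0("S", 1:7), sites, geno)
}

# Write a minimal VCF text file from raw GT strings (one record per row).
write_raw_vcf <- function(path, records, samples = paste0("S", 1:7)) {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# A small panel-frequency table written to disk.
write_tiny_panel <- function(path,
                             eur = c(0.20, 0.50, NA),
                             asn = c(0.15, 0.40, 0.30)) {
  df <- data.frame(chrom = c("1", "2", "3"), pos = c(100L, 200L, 300L),
                   ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                   rsid = c("rs1", "rs2", NA),
                   EUR_af = eur, EUR_n = c(758L, 758L, NA),
                   ASN_af = asn, ASN_n = c(592L, 592L, 592L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent brute-force binomial tail oracle: explicit term-by-term
# summation of choose(n, k) p^k (1-p)^(n-k), never calling pbinom.
brute_tail <- function(x, n, p, direction) {
  ks <- if (direction == "higher") x:n else 0:x
  sum(vapply(ks, function(k) choose(n, k) * p^k * (1 - p)^(n - k), numeric(1)))
}

# Independent transcription of the two-population Weir-Cockerham theta via
# the a/b variance-component arrangement (r = 2 demes, haploid allele
# samples): theta = a / (a + b) with among- and within-population
# components built from nbar, n_c, pbar and s^2.
wc_theta_oracle <- function(x1, n1, x2, n2) {
  r <- 2
  p1 <- x1 / n1; p2 <- x2 / n2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  pq <- pbar * (1 - pbar)
  a <- (nbar / nc) * (s2 - (pq - s2 * (r - 1) / r) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pq - s2 * (r - 1) / r)
  a / (a + b)
}
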
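# Accessors for the packaged example tables: potentially deleterious
# missense SNPs from a seven-exome study of the Qatari population,
# validated in larger cohorts, with continental reference-panel
# frequencies. Frequencies and labels are as printed in the published
# tables; they serve as worked examples for the correlation and
# classification machinery.

freqscan_extdata <- function(name) {
  system.file("extdata", name, package = "freqscan", mustWork = TRUE)
}

#' Ten enriched deleterious SNPs with TaqMan validation frequencies
#'
#' Missense SNPs in health-linked genes found at elevated frequency in a
#' seven-individual exome cohort (14 alleles, column `qe7_af`), with
#' validation frequencies from TaqMan genotyping of 86 individuals
#' (172 alleles, `qt86_af`) and continental panel frequencies
#' (`EUR_af`/`ASN_af`/`AFR_af`/`AMR_af`; panels of 379/296/185/242
#' individuals). The worked example for [pearson_with_inference].
#'
#' @return a data.frame of 10 SNPs.
#' @export
taqman_validation_snps <- function() {
  read_tsv_table(freqscan_extdata("deleterious_snps_taqman.tsv"),
                 na.strings = "NA")
}

#' Ten deleterious SNPs previously health-linked at the SNP level
#'
#' Tier-3 examples (SNP and gene both previously linked to human health)
#' with the small-cohort exome frequency (`qe7_af`, 14 alleles) and the
#' array-validation frequency in 149 individuals (`qa149_af`,
#' 298 alleles).
#'
#' @return a data.frame of 10 SNPs.
#' @export
affymetrix_snp_linked_snps <- function() {
  read_tsv_table(freqscan_extdata("deleterious_snps_affymetrix_snp_linked.tsv"))
}

#' Ten deleterious SNPs in health-linked genes (different SNP reported)
#'
#' Tier-2 examples (gene previously health-linked, but via a different
#' SNP), with small-cohort and array-validation frequencies.
#'
#' @return a data.frame of 10 SNPs.
#' @export
affymetrix_gene_linked_snps <- function() {
  read_tsv_table(freqscan_extdata("deleterious_snps_affymetrix_gene_linked.tsv"))
}

#' Continental panel sizes of the reference frequency panels
#'
#' Number of individuals behind the packaged continental allele-frequency
#' columns (Europe 379, Asia 296, Africa 185, Americas 242; allele counts
#' are twice these).
#'
#' @return named integer vector.
#' @export
reference_panel_sizes <- function() {
  c(EUR = 379L, ASN = 296L, AFR = 185L, AMR = 242L)
}
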
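test_that("VCF genotypes map to dosages, with half-calls treated as missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf(path, c(
    vcf_record("1", 100, "rs1", "A", "G", rep("0/1", 7)),
    vcf_record("2", 200, ".", "C", "T",
               c("./.", "0/.", "1|1", "0/0", "0/1", "1/0", "0/0"))))
  g <- read_cohort_vcf(path)
  expect_equal(unname(g$geno[, 1]), rep(1L, 7))
  expect_equal(unname(g$geno[, 2]), c(NA, NA, 2L, 0L, 1L, 1L, 0L))
  expect_true(is.na(g$sites$rsid[2]))
})

test_that("malformed VCFs fail with a line-numbered parse error", {
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "1\t2\t3"), bad)
  expect_error(read_cohort_vcf(bad), "line 1")
  bad2 <- withr::local_tempfile(fileext = ".vcf")
  lines <- readLines(write_raw_vcf(withr::local_tempfile(fileext = ".vcf"),
                                   vcf_record("1", 100, ".", "A", "G",
                                              rep("0/0", 7))))
  writeLines(c(lines, "1\t200\tbroken"), bad2)
  expect_error(read_cohort_vcf(bad2), "line 5")
})

test_that("multi-allelic and non-SNP records are rejected with counts, or split", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf(path, c(
    vcf_record("1", 100, ".", "A", "G", rep("0/1", 7)),
    vcf_record("1", 200, ".", "A", "G,T",
               c("1/2", "0/1", "0/2", "0/0", "2/2", "0/0", "0/0")),
    vcf_record("1", 300, ".", "AT", "A", rep("0/1", 7)),
    vcf_record("X", 400, ".", "A", "C", rep("0/1", 7))))
  g <- read_cohort_vcf(path)
  expect_equal(nrow(g$sites), 1L)
  expect_equal(attr(g, "filtered"),
               c(multiallelic = 1L, non_snp = 1L, non_autosomal = 1L))

  gs <- read_cohort_vcf(path, multiallelic = "split")
  expect_equal(nrow(gs$sites), 3L)
  split_sites <- gs$sites[gs$sites$pos == 200L, ]
  expect_setequal(split_sites$alt, c("G", "T"))
  # allele-1 dosage at the split record: 1/2 has one G, 2/2 has none
  g_alt <- gs$geno[, site_key(gs$sites) == "1:200:A:G"]
  expect_equal(unname(g_alt), c(1L, 1L, 0L, 0L, 0L, 0L, 0L))
  t_alt <- gs$geno[, site_key(gs$sites) == "1:200:A:T"]
  expect_equal(unname(t_alt), c(1L, 0L, 1L, 0L, 2L, 0L, 0L))
})

test_that("a generated cohort round-trips through VCF writing and reading", {
  cfg <- simulation_config(n_sites = 20, seed = 7)
  ds <- simulate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(ds$cohort, path)
  back <- read_cohort_vcf(path)
  expect_equal(back$samples, ds$cohort$samples)
  expect_equal(as.data.frame(back$sites), as.data.frame(ds$sites))
  expect_equal(back$geno, ds$cohort$geno)
  # write -> read -> write is byte-stable
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("allele statistics account for failed genotypes in the frequency", {
  sites <- variant_sites("1", 1:3 * 100L, c("A", "C", "G"), c("G", "T", "A"))
  # site 1: 1 alt/alt + 6 het; site 2: 1 het + 6 ref/ref;
  # site 3: 1 missing, 2 het among the remaining 6
  geno <- cbind(c(2L, rep(1L, 6)),
                c(1L, rep(0L, 6)),
                c(NA, 1L, 1L, 0L, 0L, 0L, 0L))
  g <- cohort_genotypes(paste0("S", 1:7), sites, geno)
  st <- cohort_allele_stats(g)
  expect_equal(st$x, c(8L, 1L, 2L))
  expect_equal(st$n_called, c(14L, 14L, 12L))
  expect_equal(st$freq, c(8 / 14, 1 / 14, 2 / 12))
  expect_equal(format_freq(st$freq), c("0.57", "0.07", "0.17"))
})

test_that("an all-missing site signals an undefined frequency, not zero", {
  sites <- variant_sites("1", 100L, "A", "G")
  g <- cohort_genotypes(c("a", "b"), sites, matrix(NA_integer_, 2, 1))
  st <- cohort_allele_stats(g)
  expect_true(is.nan(st$freq))
  expect_equal(st$n_called, 0L)
})

test_that("frequency identity holds on random genotype matrices", {
  set.seed(11)
  for (i in 1:20) {
    ns <- sample(3:30, 1)
    nsamp <- sample(2:10, 1)
    geno <- matrix(sample(c(0L, 1L, 2L, NA), nsamp * ns, replace = TRUE),
                   nsamp, ns)
    sites <- variant_sites("1", seq_len(ns) * 10L, "A", "G")
    g <- cohort_genotypes(paste0("s", seq_len(nsamp)), sites, geno)
    st <- cohort_allele_stats(g)
    hets <- colSums(geno == 1L, na.rm = TRUE)
    homalt <- colSums(geno == 2L, na.rm = TRUE)
    called <- colSums(!is.na(geno))
    expect_equal(st$freq, ifelse(called > 0,
                                 (hets + 2 * homalt) / (2 * called), NaN))
  }
})

test_that("concordance handles identity, total disagreement and 2/400", {
  g <- make_tiny_cohort()
  expect_equal(genotype_concordance(g, g)$discordance, 0)

  flipped <- g
  flipped$geno <- ifelse(is.na(g$geno), NA_integer_, 2L - g$geno)
  flipped$geno[which(g$geno == 1L)] <- 0L  # ensure every compared cell differs
  flipped <- cohort_genotypes(g$samples, g$sites, flipped$geno)
  expect_equal(genotype_concordance(g, flipped)$discordance, 1)

  set.seed(3)
  sites <- variant_sites("1", seq_len(40) * 10L, "A", "G")
  geno <- matrix(sample(0:2, 10 * 40, replace = TRUE), 10, 40)
  a <- cohort_genotypes(paste0("s", 1:10), sites, geno)
  geno2 <- geno
  geno2[1, 1] <- (geno[1, 1] + 1L) %% 3L
  geno2[5, 20] <- (geno[5, 20] + 1L) %% 3L
  b <- cohort_genotypes(paste0("s", 1:10), sites, geno2)
  rep <- genotype_concordance(a, b)
  expect_equal(rep$n_compared, 400L)
  expect_equal(rep$discordance, 0.005)
})

test_that("concordance is symmetric and matches on partial overlap only", {
  set.seed(5)
  cfg <- simulation_config(n_sites = 30, seed = 5)
  ds <- simulate_dataset(cfg)
  a <- ds$cohort
  perturbed <- a$geno
  flip <- which(!is.na(perturbed))[1:10]
  perturbed[flip] <- (perturbed[flip] + 1L) %% 3L
  b <- cohort_genotypes(a$samples, a$sites, perturbed)
  expect_equal(genotype_concordance(a, b)$discordance,
               genotype_concordance(b, a)$discordance)

  other <- cohort_genotypes("Z1", variant_sites("9", 999L, "A", "C"),
                            matrix(1L, 1, 1))
  expect_error(genotype_concordance(a, other), "share no samples")
})

test_that("panel frequency tables read continents, absences and bounds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_panel(path)
  panel <- read_panel_frequencies(path)
  expect_equal(attr(panel, "continents"), c("EUR", "ASN"))
  expect_true(is.na(panel$EUR_af[3]))  # absent, not zero
  expect_equal(panel$EUR_af[1], 0.20)

  bad <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_panel(bad, eur = c(1.2, 0.5, NA))
  expect_error(read_panel_frequencies(bad), "outside \\[0,1\\].*1:100:A:G")
})

test_that("a four-continent panel row yields four continent entries", {
  sites <- variant_sites("3", 41877414L, "T", "C", "rs3774372")
  panel <- panel_frequencies(
    sites,
    af = list(EUR = 0.20, ASN = 0.15, AFR = 0.23, AMR = 0.15),
    n = list(EUR = 758L, ASN = 592L, AFR = 370L, AMR = 484L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel_frequencies(panel, path)
  back <- read_panel_frequencies(path)
  expect_equal(attr(back, "continents"), c("EUR", "ASN", "AFR", "AMR"))
  expect_equal(back$AFR_af, 0.23)
})
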
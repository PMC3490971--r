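BASES <- c("A", "C", "G", "T")
AUTOSOMES <- c(as.character(1:22), paste0("chr", 1:22))

#' Construct a table of biallelic SNP sites
#'
#' A variant site is identified by chromosome, 1-based position, reference
#' allele and alternate allele (its "site key"); an optional dbSNP rsID can
#' be attached. Only single-base substitutions are admitted.
#'
#' @param chrom chromosome labels.
#' @param pos 1-based positions (integers >= 1).
#' @param ref,alt single reference/alternate bases, each one of A/C/G/T and
#'   different from one another.
#' @param rsid optional dbSNP identifiers (`NA` where unknown).
#' @return a `data.frame` of class `variant_sites` with columns
#'   `chrom`, `pos`, `ref`, `alt`, `rsid`.
#' @export
variant_sites <- function(chrom, pos, ref, alt, rsid = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   rsid = rep_len(as.character(rsid), length(chrom)),
                   stringsAsFactors = FALSE)
  if (any(df$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  if (!all(df$ref %in% BASES) || !all(df$alt %in% BASES)) {
    stop("ref and alt must each be one of A, C, G, T", call. = FALSE)
  }
  if (any(df$ref == df$alt)) stop("ref and alt must differ", call. = FALSE)
  class(df) <- c("variant_sites", "data.frame")
  df
}

#' Site keys ("chrom:pos:ref:alt") for a site table
#' @param sites a `variant_sites` table.
#' @return character vector of keys.
#' @export
site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Construct a cohort genotype set
#'
#' Diploid genotype calls for a cohort at biallelic SNP sites, stored as
#' alternate-allele dosages: 0 = ref/ref, 1 = ref/alt, 2 = alt/alt,
#' `NA` = missing. Half-called diploid genotypes are treated as fully
#' missing, since downstream allele counts are in whole alleles.
#'
#' @param samples ordered sample identifiers (at least one).
#' @param sites a `variant_sites` table.
#' @param geno integer matrix, samples x sites, values in \{0, 1, 2, NA\}.
#' @return an object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(samples, sites, geno) {
  samples <- as.character(samples)
  if (length(samples) < 1L) stop("at least one sample required", call. = FALSE)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(samples) || ncol(geno) != nrow(sites)) {
    stop("geno must be |samples| x |sites|", call. = FALSE)
  }
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  dimnames(geno) <- list(samples, site_key(sites))
  structure(list(samples = samples, sites = sites, geno = geno),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf("<cohort_genotypes> %d samples x %d sites (%.1f%% missing)\n",
              length(x$samples), nrow(x$sites),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.cohort_genotypes <- function(x) dim(x$geno)

# --- VCF input -------------------------------------------------------------

# Cheap structural validation so malformed files fail with a line number
# before being handed to the parser.
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "##fileformat=VCF")) {
    stop(sprintf("malformed VCF '%s': line 1 lacks ##fileformat header", path),
         call. = FALSE)
  }
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L) {
    stop(sprintf("malformed VCF '%s': missing #CHROM header line", path),
         call. = FALSE)
  }
  nfield <- length(strsplit(lines[[hdr]], "\t", fixed = TRUE)[[1L]])
  body <- seq_along(lines) > hdr
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(nf != nfield & nzchar(lines[body]))
  if (length(bad) > 0L) {
    stop(sprintf("malformed VCF '%s': line %d has %d fields, expected %d",
                 path, hdr + bad[[1L]], nf[bad[[1L]]], nfield), call. = FALSE)
  }
  invisible(TRUE)
}

gt_to_dosage <- function(gt) {
  # GT strings -> alt dosage; any genotype containing "." is fully missing.
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  known <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  alleles <- strsplit(gt[known], "[/|]")
  out[known] <- vapply(alleles, function(a) sum(a != "0"), integer(1))
  out[out > 2L] <- NA_integer_
  out
}

#' Read cohort genotypes from a VCF file
#'
#' Retains biallelic autosomal SNP records and maps GT fields to
#' alternate-allele dosages. Half-missing diploid calls (e.g. `0/.`) become
#' fully missing. Multi-allelic records are either rejected (default, with a
#' reported count) or split into one biallelic record per alternate allele;
#' non-SNP (indel or symbolic) records are always dropped with a count.
#'
#' @param path path to a VCF 4.x file with GT fields.
#' @param multiallelic `"reject"` (default) or `"split"`.
#' @param autosomes_only drop records on non-autosomal chromosomes
#'   (default `TRUE`).
#' @return a [cohort_genotypes] object. Attribute `filtered` records the
#'   numbers of multi-allelic, non-SNP and non-autosomal records removed.
#' @export
read_cohort_vcf <- function(path, multiallelic = c("reject", "split"),
                            autosomes_only = TRUE) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT fields", call. = FALSE)
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = 1, dimnames = list(NULL, names(gt_raw)))
  }
  samples <- colnames(gt_raw)

  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"]); alt <- toupper(fix[, "ALT"])
  rsid <- fix[, "ID"]; rsid[rsid %in% c(".", "")] <- NA_character_

  multi <- grepl(",", alt, fixed = TRUE)
  n_multi <- sum(multi)
  keep_rows <- list(); keep_meta <- list()

  add_record <- function(i, this_alt, dosage) {
    keep_meta[[length(keep_meta) + 1L]] <<- data.frame(
      chrom = chrom[i], pos = pos[i], ref = ref[i], alt = this_alt,
      rsid = rsid[i], stringsAsFactors = FALSE)
    keep_rows[[length(keep_rows) + 1L]] <<- dosage
  }

  n_nonsnp <- 0L; n_nonauto <- 0L
  for (i in seq_along(chrom)) {
    if (autosomes_only && !(chrom[i] %in% AUTOSOMES)) {
      n_nonauto <- n_nonauto + 1L
      next
    }
    if (multi[i]) {
      if (multiallelic == "reject") next
      alts <- strsplit(alt[i], ",", fixed = TRUE)[[1L]]
      gt <- sub(":.*$", "", gt_raw[i, ])
      for (k in seq_along(alts)) {
        if (!(nchar(ref[i]) == 1L && alts[k] %in% BASES)) next
        dos <- rep(NA_integer_, length(gt))
        ok <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
        al <- strsplit(gt[ok], "[/|]")
        dos[ok] <- vapply(al, function(a) sum(a == as.character(k)), integer(1))
        add_record(i, alts[k], dos)
      }
      next
    }
    if (!(ref[i] %in% BASES && alt[i] %in% BASES)) {
      n_nonsnp <- n_nonsnp + 1L
      next
    }
    add_record(i, alt[i], gt_to_dosage(gt_raw[i, ]))
  }

  if (length(keep_rows) == 0L) {
    stop("no biallelic SNP records retained from VCF", call. = FALSE)
  }
  meta <- do.call(rbind, keep_meta)
  sites <- variant_sites(meta$chrom, meta$pos, meta$ref, meta$alt, meta$rsid)
  geno <- t(do.call(rbind, keep_rows))
  rownames(geno) <- samples
  out <- cohort_genotypes(samples, sites, geno)
  attr(out, "filtered") <- c(
    multiallelic = if (multiallelic == "reject") n_multi else 0L,
    non_snp = n_nonsnp, non_autosomal = n_nonauto)
  out
}

#' Write cohort genotypes to a plain-text VCF file
#'
#' Minimal VCF 4.2 writer (GT-only) used for fixtures and round-trip
#' checking; dosage 1 is written as `0/1` and missing as `./.`.
#'
#' @param g a [cohort_genotypes] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(g, path) {
  stopifnot(inherits(g, "cohort_genotypes"))
  gt_strings <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(g$sites)), function(j) {
    dos <- g$geno[, j]
    gt <- ifelse(is.na(dos), "./.", gt_strings[dos + 1L])
    s <- g$sites[j, ]
    paste(c(s$chrom, s$pos, ifelse(is.na(s$rsid), ".", s$rsid),
            s$ref, s$alt, ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$samples), collapse = "\t"),
             body)
  writeLines(lines, path)
  invisible(path)
}

# --- Allele statistics -----------------------------------------------------

#' Cohort allele counts and frequencies with missing-genotype handling
#'
#' For each site, `x` is the number of alternate alleles among successfully
#' genotyped samples and `n_called` is twice the number of non-missing
#' calls, so failed genotypes are accounted for in the allele frequency.
#' When every call at a site is missing, the frequency is `NaN` — an
#' explicit undefined-frequency signal, distinct from a frequency of 0.
#'
#' @param g a [cohort_genotypes] object.
#' @param sites optional site indices (default: all sites).
#' @return a `data.frame` with one row per requested site: `x`, `n_called`,
#'   `freq`, plus the site key.
#' @export
cohort_allele_stats <- function(g, sites = NULL) {
  stopifnot(inherits(g, "cohort_genotypes"))
  idx <- sites %||% seq_len(nrow(g$sites))
  if (any(idx < 1L | idx > nrow(g$sites))) {
    stop("site index out of range", call. = FALSE)
  }
  geno <- g$geno[, idx, drop = FALSE]
  x <- colSums(geno, na.rm = TRUE)
  n_called <- 2L * colSums(!is.na(geno))
  freq <- ifelse(n_called > 0L, x / n_called, NaN)
  data.frame(key = site_key(g$sites[idx, , drop = FALSE]),
             x = as.integer(x), n_called = as.integer(n_called),
             freq = freq, row.names = NULL, stringsAsFactors = FALSE)
}

#' Genotype concordance between two call sets
#'
#' Compares calls over the intersection of samples (by identifier) and
#' sites (by site key), counting only cells called in both sets. Dosage
#' comparison is insensitive to allele order within a genotype.
#'
#' @param a,b [cohort_genotypes] objects sharing at least one sample and
#'   one site.
#' @return a list of class `concordance_report`: `n_compared`,
#'   `n_discordant`, `discordance`.
#' @export
genotype_concordance <- function(a, b) {
  stopifnot(inherits(a, "cohort_genotypes"), inherits(b, "cohort_genotypes"))
  samples <- intersect(a$samples, b$samples)
  keys <- intersect(site_key(a$sites), site_key(b$sites))
  if (length(samples) == 0L || length(keys) == 0L) {
    stop("call sets share no samples or no sites", call. = FALSE)
  }
  ga <- a$geno[samples, keys, drop = FALSE]
  gb <- b$geno[samples, keys, drop = FALSE]
  both <- !is.na(ga) & !is.na(gb)
  n_compared <- sum(both)
  if (n_compared == 0L) stop("no cells called in both sets", call. = FALSE)
  n_discordant <- sum(ga[both] != gb[both])
  structure(list(n_compared = n_compared, n_discordant = n_discordant,
                 discordance = n_discordant / n_compared),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d/%d discordant (rate %.4f)\n",
              x$n_discordant, x$n_compared, x$discordance))
  invisible(x)
}

# --- Panel frequency table -------------------------------------------------

#' Read a reference-panel allele-frequency table
#'
#' Tab-separated with columns `chrom`, `pos`, `ref`, `alt`, optionally
#' `rsid`, then one `<POP>_af` / `<POP>_n` pair per continental panel
#' (frequency of the alternate allele and the number of panel alleles).
#' Empty cells mean the panel has no data at that site — recorded as `NA`
#' ("absent"), never as 0.
#'
#' @param path path to the table.
#' @return a `data.frame` of class `panel_freq` with attribute `continents`.
#' @export
read_panel_frequencies <- function(path) {
  df <- read_tsv_table(path)
  af_cols <- grep("_af$", names(df), value = TRUE)
  if (length(af_cols) == 0L) {
    stop("panel table has no <POP>_af columns", call. = FALSE)
  }
  continents <- sub("_af$", "", af_cols)
  missing_n <- setdiff(paste0(continents, "_n"), names(df))
  if (length(missing_n) > 0L) {
    stop(sprintf("panel table lacks allele-count column(s): %s",
                 paste(missing_n, collapse = ", ")), call. = FALSE)
  }
  if (!"rsid" %in% names(df)) df$rsid <- NA_character_
  keys <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  for (cont in continents) {
    af <- df[[paste0(cont, "_af")]]
    n <- df[[paste0(cont, "_n")]]
    bad <- which(!is.na(af) & (af < 0 | af > 1))
    if (length(bad) > 0L) {
      stop(sprintf("panel frequency outside [0,1] for %s at site %s",
                   cont, keys[bad[[1L]]]), call. = FALSE)
    }
    bad_n <- which(!is.na(af) & (is.na(n) | n <= 0))
    if (length(bad_n) > 0L) {
      stop(sprintf("panel allele count must be > 0 for %s at site %s",
                   cont, keys[bad_n[[1L]]]), call. = FALSE)
    }
    off <- which(!is.na(af) & abs(af * n - round(af * n)) > 0.5)
    if (length(off) > 0L) {
      stop(sprintf("frequency x allele count not near-integer for %s at site %s",
                   cont, keys[off[[1L]]]), call. = FALSE)
    }
  }
  df$key <- keys
  attr(df, "continents") <- continents
  class(df) <- c("panel_freq", "data.frame")
  df
}

#' Build a panel-frequency table in memory
#'
#' @param sites a `variant_sites` table.
#' @param af named list (one entry per panel) of alternate-allele
#'   frequencies, `NA` where the panel lacks the site.
#' @param n named list of panel allele counts, same shape as `af`.
#' @return a `panel_freq` data frame (see [read_panel_frequencies]).
#' @export
panel_frequencies <- function(sites, af, n) {
  stopifnot(identical(names(af), names(n)))
  df <- as.data.frame(sites)
  for (cont in names(af)) {
    df[[paste0(cont, "_af")]] <- af[[cont]]
    df[[paste0(cont, "_n")]] <- n[[cont]]
  }
  df$key <- site_key(sites)
  attr(df, "continents") <- names(af)
  class(df) <- c("panel_freq", "data.frame")
  df
}

#' Write a panel-frequency table
#' @param panel a `panel_freq` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_frequencies <- function(panel, path) {
  df <- as.data.frame(panel)
  df$key <- NULL
  write_tsv_with_meta(df, path)
}
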
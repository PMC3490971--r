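# Functional impact, deleteriousness union rule and health-linkage tiers.

FUNCTIONAL_CATEGORIES <- c("noncoding", "silent", "missense", "splice", "nonsense")
SIFT_LABELS <- c("deleterious", "tolerated", "absent")
POLYPHEN_LABELS <- c("probably_damaging", "possibly_damaging", "benign", "absent")

#' Most severe functional category across transcripts
#'
#' A site can overlap several transcripts with different consequences; the
#' site-level category is the most severe under the fixed order
#' nonsense > splice > missense > silent > noncoding.
#'
#' @param categories character vector of per-transcript categories (at
#'   least one), each from the closed vocabulary.
#' @return the single most severe category.
#' @export
assign_functional_category <- function(categories) {
  if (length(categories) < 1L) stop("at least one annotation required", call. = FALSE)
  bad <- setdiff(categories, FUNCTIONAL_CATEGORIES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown functional category: %s", bad[[1L]]), call. = FALSE)
  }
  FUNCTIONAL_CATEGORIES[max(match(categories, FUNCTIONAL_CATEGORIES))]
}

#' Potentially-deleterious flag (predictor union rule)
#'
#' A missense variant is flagged potentially deleterious when EITHER
#' predictor fires: SIFT "deleterious", or PolyPhen "probably_damaging" or
#' "possibly_damaging". This liberal union deliberately casts a wider net
#' than consensus scores. Non-missense variants are never flagged unless
#' `include_splice = TRUE` extends eligibility to splice variants.
#'
#' @param category site-level functional category (vectorised).
#' @param sift_label one of `deleterious`, `tolerated`, `absent`.
#' @param polyphen_label one of `probably_damaging`, `possibly_damaging`,
#'   `benign`, `absent`.
#' @param include_splice also allow splice variants to carry the flag.
#' @return logical vector.
#' @export
is_potentially_deleterious <- function(category, sift_label, polyphen_label,
                                       include_splice = FALSE) {
  bad <- setdiff(sift_label, SIFT_LABELS)
  if (length(bad) > 0L) stop(sprintf("unknown SIFT label: %s", bad[[1L]]), call. = FALSE)
  bad <- setdiff(polyphen_label, POLYPHEN_LABELS)
  if (length(bad) > 0L) stop(sprintf("unknown PolyPhen label: %s", bad[[1L]]), call. = FALSE)
  eligible <- category == "missense" |
    (include_splice & category == "splice")
  fires <- sift_label == "deleterious" |
    polyphen_label %in% c("probably_damaging", "possibly_damaging")
  eligible & fires
}

#' Construct a health-linkage database
#'
#' Three record types mirroring how curated disease/pharmacogenomic
#' databases are queried: by dbSNP rsID, by gene + amino-acid substitution
#' (for records not linked to an rsID), and by gene symbol alone.
#'
#' @param snp_records data.frame with columns `rsid`, `source`, `phenotype`.
#' @param substitution_records data.frame with columns `gene`,
#'   `substitution`, `source`, `phenotype`.
#' @param gene_records data.frame with columns `gene`, `source`, `phenotype`.
#' @return an object of class `health_db`.
#' @export
health_db <- function(snp_records = NULL, substitution_records = NULL,
                      gene_records = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    df
  }
  snp_records <- snp_records %||% empty(c("rsid", "source", "phenotype"))
  substitution_records <- substitution_records %||%
    empty(c("gene", "substitution", "source", "phenotype"))
  gene_records <- gene_records %||% empty(c("gene", "source", "phenotype"))
  if (anyDuplicated(snp_records$rsid)) {
    stop("duplicate rsID keys in snp_records", call. = FALSE)
  }
  sub_keys <- toupper(paste(substitution_records$gene,
                            substitution_records$substitution, sep = "|"))
  if (anyDuplicated(sub_keys)) {
    stop("duplicate (gene, substitution) keys in substitution_records",
         call. = FALSE)
  }
  if (anyDuplicated(gene_records$gene)) {
    stop("duplicate gene keys in gene_records", call. = FALSE)
  }
  structure(list(snp_records = snp_records,
                 substitution_records = substitution_records,
                 gene_records = gene_records),
            class = "health_db")
}

#' Read a health-linkage database from three tab-separated tables
#'
#' @param snp_path,substitution_path,gene_path paths to the three record
#'   tables (see [health_db] for required columns).
#' @return a `health_db` object.
#' @export
read_health_db <- function(snp_path, substitution_path, gene_path) {
  health_db(read_tsv_table(snp_path),
            read_tsv_table(substitution_path),
            read_tsv_table(gene_path))
}

#' Health-linkage tier for deleterious missense variants
#'
#' Tier 3: the specific SNP is already health-linked — its rsID matches an
#' SNP record, or its gene + amino-acid substitution matches a substitution
#' record. Tier 2: the gene (but not this SNP) is health-linked. Tier 1:
#' neither. Tier 3 takes precedence over tier 2; substitution matching is
#' case-insensitive. A missing rsID simply skips the rsID query.
#'
#' @param rsid dbSNP identifiers (`NA` allowed), vectorised.
#' @param gene gene symbols.
#' @param substitution amino-acid substitution labels (e.g. "Pro12Ala"),
#'   `NA` allowed.
#' @param db a [health_db] object.
#' @return integer vector of tiers in \{1, 2, 3\}.
#' @export
assign_health_tier <- function(rsid, gene, substitution, db) {
  stopifnot(inherits(db, "health_db"))
  n <- max(length(rsid), length(gene), length(substitution))
  rsid <- rep_len(as.character(rsid), n)
  gene <- rep_len(as.character(gene), n)
  substitution <- rep_len(as.character(substitution), n)
  sub_keys <- toupper(paste(db$substitution_records$gene,
                            db$substitution_records$substitution, sep = "|"))
  query_keys <- toupper(paste(gene, substitution, sep = "|"))
  snp_hit <- !is.na(rsid) & rsid %in% db$snp_records$rsid
  sub_hit <- !is.na(substitution) & query_keys %in% sub_keys
  gene_hit <- !is.na(gene) & toupper(gene) %in% toupper(db$gene_records$gene)
  ifelse(snp_hit | sub_hit, 3L, ifelse(gene_hit, 2L, 1L))
}

#' Read a per-transcript annotation table
#'
#' One row per (site, transcript): columns `chrom`, `pos`, `ref`, `alt`,
#' `gene`, `category`, `substitution`, `sift`, `polyphen`.
#'
#' @param path path to the tab-separated table.
#' @return a data.frame with a `key` column added.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_table(path)
  need <- c("chrom", "pos", "ref", "alt", "gene", "category",
            "substitution", "sift", "polyphen")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("annotation table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df
}

#' Classify variants: category, deleteriousness, health tier
#'
#' Site-level classification from a per-transcript annotation table. The
#' site category is the most severe across its transcripts; gene,
#' substitution and predictor labels are taken from the transcript carrying
#' that most severe category. Health tiers are assigned only to potentially
#' deleterious missense variants (`NA` otherwise).
#'
#' @param stats per-site allele statistics from [cohort_allele_stats]
#'   (must carry a `key` column).
#' @param annotations per-(site, transcript) table from
#'   [read_annotation_table].
#' @param db a [health_db] object.
#' @param include_splice passed to [is_potentially_deleterious].
#' @return a `data.frame` of class `classified_variants`: one row per site
#'   with `key`, `gene`, `category`, `substitution`, `deleterious`, `tier`,
#'   `x`, `n_called`, `freq`.
#' @export
classify_variants <- function(stats, annotations, db,
                              include_splice = FALSE) {
  ann_split <- split(annotations, annotations$key)
  rows <- lapply(stats$key, function(k) {
    ann <- ann_split[[k]]
    if (is.null(ann)) {
      return(data.frame(key = k, gene = NA_character_,
                        category = NA_character_,
                        substitution = NA_character_,
                        sift = "absent", polyphen = "absent",
                        stringsAsFactors = FALSE))
    }
    cat <- assign_functional_category(ann$category)
    pick <- ann[ann$category == cat, , drop = FALSE][1L, ]
    data.frame(key = k, gene = pick$gene, category = cat,
               substitution = as.character(pick$substitution),
               sift = as.character(pick$sift),
               polyphen = as.character(pick$polyphen),
               stringsAsFactors = FALSE)
  })
  cls <- do.call(rbind, rows)
  cls$sift[is.na(cls$sift) | cls$sift == ""] <- "absent"
  cls$polyphen[is.na(cls$polyphen) | cls$polyphen == ""] <- "absent"
  cls$substitution[cls$substitution == ""] <- NA_character_
  has_cat <- !is.na(cls$category)
  cls$deleterious <- FALSE
  cls$deleterious[has_cat] <- is_potentially_deleterious(
    cls$category[has_cat], cls$sift[has_cat], cls$polyphen[has_cat],
    include_splice = include_splice)
  cls$tier <- NA_integer_
  eligible <- cls$deleterious & cls$category == "missense"
  eligible[is.na(eligible)] <- FALSE
  if (any(eligible)) {
    rsid <- stats$rsid %||% rep(NA_character_, nrow(stats))
    cls$tier[eligible] <- assign_health_tier(
      rsid[eligible], cls$gene[eligible], cls$substitution[eligible], db)
  }
  out <- cbind(cls[c("key", "gene", "category", "substitution",
                     "deleterious", "tier")],
               stats[c("x", "n_called", "freq")])
  class(out) <- c("classified_variants", "data.frame")
  out
}

#' Summarise deleterious variants by allele-count cutoff and tier
#'
#' For each allele-count cutoff `t`, counts potentially deleterious
#' variants observed in at least `t` cohort alleles, split by health tier,
#' with each tier's percentage of the cutoff total (displayed half-up to
#' whole percent; full-precision shares kept in `share`).
#'
#' @param variants a `classified_variants` table.
#' @param count_thresholds integer allele-count cutoffs (default `c(1, 6)`,
#'   i.e. >=1 and >=6 of the cohort's alleles).
#' @return a `data.frame` of class `classification_summary`: one row per
#'   (threshold, tier) plus a `total` row per threshold.
#' @export
summarize_classification <- function(variants, count_thresholds = c(1L, 6L)) {
  if (any(count_thresholds < 1L | count_thresholds != round(count_thresholds))) {
    stop("count_thresholds must be integers >= 1", call. = FALSE)
  }
  rows <- list()
  for (t in count_thresholds) {
    sel <- variants[!is.na(variants$deleterious) & variants$deleterious &
                      variants$x >= t, , drop = FALSE]
    total <- nrow(sel)
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = t, tier = "total", n = total, share = 1,
      pct_display = if (total > 0) "100%" else "0%",
      stringsAsFactors = FALSE)
    for (tier in 1:3) {
      n_tier <- sum(sel$tier == tier, na.rm = TRUE)
      share <- if (total > 0) n_tier / total else 0
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = t, tier = as.character(tier), n = n_tier, share = share,
        pct_display = format_percent(share), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("classification_summary", "data.frame")
  out
}
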
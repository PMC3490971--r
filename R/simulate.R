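# Balding-Nichols simulation of continental panels and a tiny structured
# cohort, with spike-in of differentiated sites and matching annotation /
# health-database fixtures, so every pipeline stage can be tested against
# known truth.

DEFAULT_PANELS <- list(
  EUR = list(n = 379, F = 0.10),
  ASN = list(n = 296, F = 0.10),
  AFR = list(n = 185, F = 0.10),
  AMR = list(n = 242, F = 0.10))

DEFAULT_CATEGORY_PROPS <- c(noncoding = 0.45, silent = 0.22, missense = 0.30,
                            splice = 0.02, nonsense = 0.01)

#' Simulation configuration
#'
#' Defines the study conditions for the generator: continental panel sizes
#' (default 379/296/185/242 individuals), a cohort of 7 split 3/2/2 across
#' three ancestry subgroups each drawing from one continental panel's
#' allele frequencies, Balding-Nichols divergence F per panel, ancestral
#' frequency bounds, the deleterious fraction of missense sites, the
#' health-tier proportions, and the missing-genotype rate.
#'
#' @param n_sites number of biallelic SNP sites.
#' @param panels named list; each element a list with `n` (individuals)
#'   and `F` (Balding-Nichols divergence in (0, 1)).
#' @param cohort_subgroups named integer vector of subgroup sizes
#'   (default `c(Q1 = 3, Q2 = 2, Q3 = 2)`).
#' @param cohort_sources named character vector mapping each subgroup to
#'   the panel whose frequencies it draws from
#'   (default Q1 -> EUR, Q2 -> ASN, Q3 -> AFR).
#' @param p0_bounds ancestral-frequency sampling bounds (default
#'   `c(0.05, 0.95)`, avoiding degenerate Beta parameters).
#' @param category_props functional-category proportions for the
#'   annotation fixture.
#' @param deleterious_fraction fraction of missense sites flagged
#'   potentially deleterious (default 0.52).
#' @param tier_props proportions of deleterious missense sites in health
#'   tiers 1/2/3 (default `c(0.72, 0.24, 0.04)`).
#' @param missing_rate per-call missing-genotype probability in the cohort
#'   (default 0.02).
#' @param seed master seed.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_sites = 10000,
                              panels = DEFAULT_PANELS,
                              cohort_subgroups = c(Q1 = 3, Q2 = 2, Q3 = 2),
                              cohort_sources = c(Q1 = "EUR", Q2 = "ASN",
                                                 Q3 = "AFR"),
                              p0_bounds = c(0.05, 0.95),
                              category_props = DEFAULT_CATEGORY_PROPS,
                              deleterious_fraction = 0.52,
                              tier_props = c(0.72, 0.24, 0.04),
                              missing_rate = 0.02,
                              seed = 1L) {
  stopifnot_scalar_number(n_sites, "n_sites", lo = 1)
  for (nm in names(panels)) {
    p <- panels[[nm]]
    stopifnot_scalar_number(p$n, paste0("panels$", nm, "$n"), lo = 1)
    stopifnot_scalar_number(p$F, paste0("panels$", nm, "$F"), lo = 1e-6, hi = 1 - 1e-6)
  }
  if (any(cohort_subgroups < 1)) stop("subgroup sizes must be >= 1", call. = FALSE)
  if (!all(names(cohort_subgroups) %in% names(cohort_sources))) {
    stop("every subgroup needs an ancestry source", call. = FALSE)
  }
  if (!all(cohort_sources %in% names(panels))) {
    stop("cohort sources must name panels", call. = FALSE)
  }
  stopifnot_scalar_number(deleterious_fraction, "deleterious_fraction", 0, 1)
  stopifnot_scalar_number(missing_rate, "missing_rate", 0, 1)
  if (sum(tier_props) > 1 + 1e-9 || any(tier_props < 0)) {
    stop("tier proportions must be >= 0 and sum to <= 1", call. = FALSE)
  }
  structure(list(n_sites = as.integer(n_sites), panels = panels,
                 cohort_subgroups = cohort_subgroups,
                 cohort_sources = cohort_sources,
                 p0_bounds = p0_bounds,
                 category_props = category_props,
                 deleterious_fraction = deleterious_fraction,
                 tier_props = tier_props,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

rbeta_bn <- function(n, p0, F) {
  # Balding-Nichols: population frequency ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F)
  stats::rbeta(n, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
}

sim_sites <- function(n_sites) {
  chrom <- as.character(rep_len(1:22, n_sites))
  pos <- seq_len(n_sites) * 1000L
  ref <- sample(BASES, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
  variant_sites(chrom, pos, ref, alt, paste0("rs", 900000L + seq_len(n_sites)))
}

#' Simulate a structured-population dataset with known truth
#'
#' Per site, an ancestral frequency p0 is drawn uniformly on the
#' configured bounds; each panel population's frequency is a
#' Balding-Nichols Beta draw around p0 with its divergence F; panel
#' diploid genotypes are Binomial(2, population frequency); each cohort
#' individual draws from its subgroup's source-population frequencies;
#' missing calls are injected into the cohort at the configured rate.
#' Fully reproducible from the config seed.
#'
#' @param cfg a [simulation_config].
#' @return a list of class `synthetic_dataset`: `config`, `sites`,
#'   `panel_geno` (list of individuals x sites dosage matrices),
#'   `panel_freq` (a `panel_freq` table computed from the panel
#'   genotypes), `cohort` (a [cohort_genotypes]), and `truth` (per-site
#'   p0, per-panel and per-subgroup frequencies, spike labels).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  ns <- cfg$n_sites

  p0 <- stats::runif(ns, cfg$p0_bounds[1], cfg$p0_bounds[2])
  sites <- sim_sites(ns)

  panel_geno <- list(); pop_freq <- list()
  for (pop in names(cfg$panels)) {
    pp <- cfg$panels[[pop]]
    f <- rbeta_bn(ns, p0, pp$F)
    # numerically degenerate draws would make downstream Binomials trivial
    f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
    g <- matrix(stats::rbinom(pp$n * ns, 2L, rep(f, each = pp$n)),
                nrow = pp$n, ncol = ns)
    rownames(g) <- paste0(pop, "_", seq_len(pp$n))
    panel_geno[[pop]] <- g
    pop_freq[[pop]] <- f
  }
  af <- lapply(panel_geno, function(g) colMeans(g) / 2)
  nn <- lapply(panel_geno, function(g) rep(2L * nrow(g), ns))
  pfreq <- panel_frequencies(sites, af, nn)

  subgroup_of <- rep(names(cfg$cohort_subgroups), cfg$cohort_subgroups)
  cohort_samples <- paste0(subgroup_of, "_",
                           unlist(lapply(cfg$cohort_subgroups, seq_len)))
  src_freq <- do.call(rbind, lapply(subgroup_of, function(sg) {
    pop_freq[[cfg$cohort_sources[[sg]]]]
  }))
  geno <- matrix(stats::rbinom(length(src_freq), 2L, src_freq),
                 nrow = length(cohort_samples), ncol = ns)
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(geno)) < cfg$missing_rate
    geno[miss] <- NA_integer_
  }
  cohort <- cohort_genotypes(cohort_samples, sites, geno)

  truth <- list(p0 = p0, pop_freq = pop_freq,
                subgroup_source = cfg$cohort_sources,
                spiked = rep(FALSE, ns),
                spike_freq = rep(NA_real_, ns))
  structure(list(config = cfg, sites = sites, panel_geno = panel_geno,
                 panel_freq = pfreq, cohort = cohort, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d sites, %d panels (%s), cohort of %d (%d spiked)\n",
    x$config$n_sites, length(x$panel_geno),
    paste(names(x$panel_geno), collapse = ", "),
    length(x$cohort$samples), sum(x$truth$spiked)))
  invisible(x)
}

#' Spike differentiated sites into a synthetic dataset
#'
#' Selects sites and displaces the cohort-source allele frequency away
#' from the across-panel mean frequency by `displacement` (positive for
#' higher in the cohort), clipping to \[0.02, 0.98\] with a warning when
#' clipping occurs. Cohort genotypes at the spiked sites are redrawn from
#' the displaced frequency (the existing missing-call mask is kept).
#' Truth labels are updated; with `displacement = 0` the genotypes are
#' redrawn from the unchanged frequency, so only labels change
#' distributionally.
#'
#' @param ds a `synthetic_dataset`.
#' @param n_spike number of sites to spike.
#' @param displacement signed frequency displacement.
#' @param seed seed for site selection and the redraw (default: derived
#'   from the dataset's config seed).
#' @return the modified `synthetic_dataset`.
#' @export
spike_differentiated_sites <- function(ds, n_spike, displacement,
                                       seed = NULL) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  ns <- ds$config$n_sites
  if (n_spike > ns) stop("spike count exceeds number of sites", call. = FALSE)
  seed <- seed %||% derive_seed(ds$config$seed, 104729L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  panel_mean <- Reduce(`+`, ds$truth$pop_freq) / length(ds$truth$pop_freq)
  # prefer sites where the full displacement fits inside [0.02, 0.98], so
  # the spiked truth actually realises the requested effect size; fall
  # back to clipped targets only when there are too few such sites
  feasible <- which(panel_mean + displacement >= 0.02 &
                      panel_mean + displacement <= 0.98)
  if (length(feasible) >= n_spike) {
    idx <- sort(sample(feasible, n_spike))
  } else {
    rest <- sample(setdiff(seq_len(ns), feasible), n_spike - length(feasible))
    idx <- sort(c(feasible, rest))
  }
  target <- panel_mean[idx] + displacement
  clipped <- target < 0.02 | target > 0.98
  if (any(clipped)) {
    warning(sprintf("%d spike target frequencies clipped to [0.02, 0.98]",
                    sum(clipped)))
  }
  target <- pmin(pmax(target, 0.02), 0.98)

  if (displacement == 0) {
    # labels only; the genotypes already realise the undisplaced frequencies
    ds$truth$spiked[idx] <- TRUE
    ds$truth$spike_freq[idx] <- target
    return(ds)
  }

  geno <- ds$cohort$geno
  miss_mask <- is.na(geno[, idx, drop = FALSE])
  redraw <- matrix(stats::rbinom(nrow(geno) * length(idx), 2L,
                                 rep(target, each = nrow(geno))),
                   nrow = nrow(geno))
  redraw[miss_mask] <- NA_integer_
  geno[, idx] <- redraw
  ds$cohort <- cohort_genotypes(ds$cohort$samples, ds$sites, geno)
  ds$truth$spiked[idx] <- TRUE
  ds$truth$spike_freq[idx] <- target
  ds
}

random_substitution <- function(n) {
  aa <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")
  from <- sample(aa, n, replace = TRUE)
  to <- vapply(from, function(a) sample(setdiff(aa, a), 1L), character(1))
  paste0(from, sample(500L, n, replace = TRUE), to)
}

#' Simulate annotation and health-database fixtures with known truth
#'
#' Assigns each site a functional category at the configured proportions;
#' missense sites get a unique synthetic gene symbol and an amino-acid
#' substitution; the configured fraction of missense sites is made
#' potentially deleterious with predictor labels consistent with the union
#' rule (a random choice of which predictor fires); deleterious missense
#' sites are assigned health tiers at the configured proportions, and the
#' health-database records are constructed so those tiers are true by
#' construction (tier 3 via an rsID or gene+substitution record, tier 2
#' via a gene record only). A fraction of sites receives a second, milder
#' transcript annotation to exercise the severity rule.
#'
#' @param ds a `synthetic_dataset`.
#' @param multi_transcript_rate fraction of sites with a second transcript
#'   row (default 0.1).
#' @param seed seed (default derived from the config seed).
#' @return a list: `annotations` (per-transcript table), `db` (a
#'   [health_db]), `truth` (per-site category, deleterious flag, tier).
#' @export
simulate_annotation_and_healthdb <- function(ds, multi_transcript_rate = 0.1,
                                             seed = NULL) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  cfg <- ds$config
  ns <- cfg$n_sites
  seed <- seed %||% derive_seed(cfg$seed, 224737L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  category <- sample(names(cfg$category_props), ns, replace = TRUE,
                     prob = cfg$category_props)
  gene <- paste0("GENE", formatC(seq_len(ns), width = 5, flag = "0"))
  substitution <- rep(NA_character_, ns)
  is_mis <- category == "missense"
  substitution[is_mis] <- random_substitution(sum(is_mis))

  deleterious <- rep(FALSE, ns)
  deleterious[is_mis] <- stats::runif(sum(is_mis)) < cfg$deleterious_fraction
  sift <- rep("absent", ns); polyphen <- rep("absent", ns)
  sift[is_mis] <- "tolerated"; polyphen[is_mis] <- "benign"
  which_pred <- sample(c("sift", "polyphen", "both"), sum(deleterious),
                       replace = TRUE)
  del_idx <- which(deleterious)
  sift[del_idx[which_pred != "polyphen"]] <- "deleterious"
  polyphen[del_idx[which_pred != "sift"]] <-
    sample(c("probably_damaging", "possibly_damaging"),
           sum(which_pred != "sift"), replace = TRUE)

  tier <- rep(NA_integer_, ns)
  pt <- cfg$tier_props / sum(cfg$tier_props)
  tier[del_idx] <- sample(1:3, length(del_idx), replace = TRUE, prob = pt)

  rsid <- ds$sites$rsid
  snp_rec <- sub_rec <- gene_rec <- NULL
  t3 <- which(tier == 3L)
  if (length(t3) > 0L) {
    # half linked by rsID, half by gene + substitution
    by_rs <- t3[seq_along(t3) %% 2L == 0L]
    by_sub <- setdiff(t3, by_rs)
    if (length(by_rs) > 0L) {
      snp_rec <- data.frame(rsid = rsid[by_rs], source = "OMIM",
                            phenotype = "synthetic phenotype",
                            stringsAsFactors = FALSE)
    }
    if (length(by_sub) > 0L) {
      sub_rec <- data.frame(gene = gene[by_sub],
                            substitution = substitution[by_sub],
                            source = "HGMD",
                            phenotype = "synthetic phenotype",
                            stringsAsFactors = FALSE)
    }
  }
  t2 <- which(tier == 2L)
  gene_linked <- unique(gene[c(t2, t3)])
  if (length(gene_linked) > 0L) {
    gene_rec <- data.frame(gene = gene_linked, source = "HUGE",
                           phenotype = "synthetic phenotype",
                           stringsAsFactors = FALSE)
  }
  db <- health_db(snp_rec, sub_rec, gene_rec)

  key <- site_key(ds$sites)
  ann <- data.frame(chrom = ds$sites$chrom, pos = ds$sites$pos,
                    ref = ds$sites$ref, alt = ds$sites$alt,
                    gene = gene, category = category,
                    substitution = substitution,
                    sift = sift, polyphen = polyphen, key = key,
                    stringsAsFactors = FALSE)
  extra <- which(stats::runif(ns) < multi_transcript_rate)
  if (length(extra) > 0L) {
    milder <- ifelse(category[extra] == "noncoding", "noncoding",
                     ifelse(category[extra] == "silent", "noncoding", "silent"))
    ann2 <- ann[extra, ]
    ann2$category <- milder
    ann2$substitution <- NA_character_
    ann2$sift <- "absent"; ann2$polyphen <- "absent"
    ann <- rbind(ann, ann2)
  }
  ann <- ann[order(match(ann$key, key)), ]
  rownames(ann) <- NULL

  list(annotations = ann, db = db,
       truth = data.frame(key = key, category = category,
                          deleterious = deleterious, tier = tier,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the cohort VCF, the panel-frequency table and a JSON truth file
#' (plus annotation and health-database tables when supplied) into a
#' directory.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @param ann optional result of [simulate_annotation_and_healthdb].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, ann = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_vcf(ds$cohort, file.path(dir, "cohort.vcf"))
  write_panel_frequencies(ds$panel_freq, file.path(dir, "panel_freq.tsv"))
  truth <- list(seed = ds$config$seed, n_sites = ds$config$n_sites,
                spiked = which(ds$truth$spiked),
                spike_freq = ds$truth$spike_freq[ds$truth$spiked])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(ann)) {
    write_tsv_with_meta(ann$annotations, file.path(dir, "annotations.tsv"))
    write_tsv_with_meta(ann$db$snp_records, file.path(dir, "healthdb_snp.tsv"))
    write_tsv_with_meta(ann$db$substitution_records,
                        file.path(dir, "healthdb_substitution.tsv"))
    write_tsv_with_meta(ann$db$gene_records, file.path(dir, "healthdb_gene.tsv"))
  }
  invisible(dir)
}
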
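# How representative is a tiny cohort's allele-frequency spectrum of its
# source population? Pearson correlation with Fisher-z intervals, and
# subsampling experiments on panel genotypes.

#' Fisher-z confidence interval for a Pearson correlation
#'
#' tanh(atanh(r) +/- z / sqrt(n - 3)). The normal quantile is fixed at
#' 1.96 for the conventional 95% interval.
#'
#' @param r correlation estimate.
#' @param n number of pairs (> 3).
#' @param z normal quantile (default 1.96).
#' @return numeric vector `c(low, high)`.
#' @export
fisher_z_ci <- function(r, n, z = 1.96) {
  if (n <= 3) stop("Fisher-z interval requires n > 3", call. = FALSE)
  tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
}

#' Pearson correlation of paired allele frequencies, with inference
#'
#' Product-moment correlation of small-sample versus large-sample allele
#' frequencies, a 95% Fisher-z confidence interval, the two-sided t-test
#' p-value (t = r sqrt(n-2) / sqrt(1-r^2), df = n - 2), and the ordinary
#' least-squares fit of the large-sample on the small-sample frequencies.
#'
#' @param f_small,f_large paired frequency vectors in \[0, 1\], length >= 3,
#'   neither constant.
#' @return a list of class `correlation_result`: `r`, `n`, `ci_low`,
#'   `ci_high`, `p`, `slope`, `intercept`.
#' @export
pearson_with_inference <- function(f_small, f_large) {
  if (length(f_small) != length(f_large)) {
    stop("frequency vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(f_small) & !is.na(f_large)
  f_small <- f_small[keep]; f_large <- f_large[keep]
  n <- length(f_small)
  if (n < 3) stop("at least 3 frequency pairs required", call. = FALSE)
  if (stats::sd(f_small) == 0 || stats::sd(f_large) == 0) {
    stop("degenerate input: zero variance in a frequency column", call. = FALSE)
  }
  r <- stats::cor(f_small, f_large)
  ci <- if (n > 3) fisher_z_ci(r, n) else c(NA_real_, NA_real_)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fit <- stats::lm(f_large ~ f_small)
  structure(list(r = r, n = n, ci_low = ci[1], ci_high = ci[2], p = p,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> r = %.2f (n = %d), 95%% CI (%.2f, %.2f), p = %.3g\n",
    x$r, x$n, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  least squares: large = %.3f + %.3f * small\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Draw a mixed small sample from population panels
#'
#' Uniform draw without replacement within each named population,
#' deterministic given the seed — e.g. a "world mix" of 3 + 2 + 2
#' individuals from three continental panels, mirroring a cohort of three
#' ancestry subgroups.
#'
#' @param pop_sizes named integer vector: individuals available per
#'   population.
#' @param composition named integer vector: individuals requested per
#'   population (names must appear in `pop_sizes`).
#' @param seed integer seed.
#' @return a data.frame with columns `population` and `index` (index of
#'   the individual within its population).
#' @export
compose_mixture_sample <- function(pop_sizes, composition, seed) {
  if (any(composition < 0)) stop("requested counts must be >= 0", call. = FALSE)
  unknown <- setdiff(names(composition), names(pop_sizes))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown population: %s", unknown[[1L]]), call. = FALSE)
  }
  over <- composition > pop_sizes[names(composition)]
  if (any(over)) {
    stop(sprintf("requested %d from population %s of size %d",
                 composition[over][[1L]], names(composition)[over][[1L]],
                 pop_sizes[names(composition)[over][[1L]]]), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  picks <- lapply(names(composition), function(pop) {
    k <- composition[[pop]]
    if (k == 0L) return(NULL)
    data.frame(population = pop,
               index = sort(sample.int(pop_sizes[[pop]], k)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, picks)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

geno_freqs <- function(geno_rows) {
  # allele frequencies from a (individuals x sites) dosage matrix
  colSums(geno_rows, na.rm = TRUE) / (2 * colSums(!is.na(geno_rows)))
}

#' Subsampling study of small-sample allele-frequency representativeness
#'
#' Repeatedly draws a small sample of `k` individuals (optionally as a
#' fixed mixture across populations) and a disjoint large comparison
#' sample of `m` individuals, computes per-site allele frequencies in
#' both, and the Pearson correlation between them. Sites monomorphic in a
#' replicate's small or large sample are dropped from that replicate
#' (correlation is undefined there). Replicate seeds are derived from the
#' master seed via a counter and recorded in the output.
#'
#' @param geno list of (individuals x sites) dosage matrices, one per
#'   population, or a single matrix (one panmictic population).
#' @param k small-sample size.
#' @param m large-sample size (drawn from the pooled remaining
#'   individuals).
#' @param reps number of replicates.
#' @param seed master seed.
#' @param mixture optional named integer vector giving the small sample's
#'   composition across populations (must sum to `k`); default: uniform
#'   draw from the pool.
#' @param allow_overlap let the large sample include small-sample
#'   individuals (default `FALSE`; the disjoint design is the honest one).
#' @param sites optional site indices to restrict to (e.g. a deleterious
#'   subset).
#' @return a list of class `subsample_correlation`: `replicates`
#'   (data.frame with `rep`, `seed`, `n_sites`, `r`), `mean_r`, `sd_r`.
#' @export
subsample_frequency_correlation <- function(geno, k, m, reps = 50, seed = 1,
                                            mixture = NULL,
                                            allow_overlap = FALSE,
                                            sites = NULL) {
  if (is.matrix(geno)) geno <- list(pop = geno)
  if (!is.null(sites)) geno <- lapply(geno, function(g) g[, sites, drop = FALSE])
  pop_sizes <- vapply(geno, nrow, integer(1))
  total <- sum(pop_sizes)
  if (k >= total && !allow_overlap) {
    stop("k must be smaller than the pooled population size", call. = FALSE)
  }
  if (!is.null(mixture) && sum(mixture) != k) {
    stop("mixture composition must sum to k", call. = FALSE)
  }
  pooled <- do.call(rbind, geno)
  pop_of <- rep(names(geno), pop_sizes)
  offset <- c(0L, cumsum(pop_sizes))[seq_along(geno)]
  names(offset) <- names(geno)

  res <- vector("list", reps)
  for (i in seq_len(reps)) {
    rep_seed <- derive_seed(seed, i)
    if (is.null(mixture)) {
      old <- .Random.seed_save()
      set.seed(rep_seed)
      small_idx <- sample.int(total, k)
      .Random.seed_restore(old)
    } else {
      mix <- compose_mixture_sample(pop_sizes, mixture, rep_seed)
      small_idx <- offset[mix$population] + mix$index
    }
    pool_large <- if (allow_overlap) seq_len(total) else setdiff(seq_len(total), small_idx)
    if (m > length(pool_large)) {
      stop("large-sample size exceeds remaining individuals", call. = FALSE)
    }
    old <- .Random.seed_save()
    set.seed(derive_seed(rep_seed, 7L))
    large_idx <- if (m == length(pool_large)) pool_large else sample(pool_large, m)
    .Random.seed_restore(old)

    f_small <- geno_freqs(pooled[small_idx, , drop = FALSE])
    f_large <- geno_freqs(pooled[large_idx, , drop = FALSE])
    # drop sites with no defined frequency and sites monomorphic in both
    # samples (they carry no information about frequency agreement)
    poly <- (f_small > 0 & f_small < 1) | (f_large > 0 & f_large < 1)
    keep <- !is.na(f_small) & !is.na(f_large) & poly
    f_s <- f_small[keep]; f_l <- f_large[keep]
    r <- if (sum(keep) >= 3 && stats::sd(f_s) > 0 && stats::sd(f_l) > 0) {
      stats::cor(f_s, f_l)
    } else NA_real_
    res[[i]] <- data.frame(rep = i, seed = rep_seed,
                           n_sites = sum(keep), r = r)
  }
  replicates <- do.call(rbind, res)
  structure(list(replicates = replicates,
                 mean_r = mean(replicates$r, na.rm = TRUE),
                 sd_r = stats::sd(replicates$r, na.rm = TRUE)),
            class = "subsample_correlation")
}

#' @export
print.subsample_correlation <- function(x, ...) {
  cat(sprintf("<subsample_correlation> %d replicates, mean r = %.3f (sd %.3f)\n",
              nrow(x$replicates), x$mean_r, x$sd_r))
  invisible(x)
}
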
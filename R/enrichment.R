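# The core scan: exact one-tailed binomial tests of cohort allele counts
# against reference-panel frequencies, Weir-Cockerham Fst, Storey q-values,
# and the combined enrichment call.

#' Exact one-tailed binomial tail probability
#'
#' Probability, under X ~ Binomial(n, p), of an allele count at least
#' (`direction = "higher"`) or at most (`direction = "lower"`) as extreme
#' as the observed count. The observed count is included in the tail by
#' default; tails are exact (no normal approximation). Degenerate panel
#' frequencies (p = 0 or 1) are handled exactly, so p-values of 0 are
#' legal and propagate.
#'
#' @param x observed alternate-allele count(s), 0 <= x <= n.
#' @param n number of cohort alleles.
#' @param p null success probability (panel frequency), in \[0, 1\].
#' @param direction `"higher"` for P(X >= x), `"lower"` for P(X <= x).
#' @param inclusive include the observed count in the tail (default);
#'   `FALSE` gives P(X > x) / P(X < x).
#' @return numeric vector of tail probabilities.
#' @export
binomial_tail_p <- function(x, n, p, direction = c("higher", "lower"),
                            inclusive = TRUE) {
  direction <- match.arg(direction)
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (direction == "higher") {
    q <- if (inclusive) x - 1 else x
    stats::pbinom(q, n, p, lower.tail = FALSE)
  } else {
    q <- if (inclusive) x else x - 1
    stats::pbinom(q, n, p)
  }
}

# Haploid-allele (ANOVA) mean squares for the two-population
# Weir-Cockerham estimator. Operates on allele counts: x alt alleles out
# of n sampled alleles per population.
wc_components <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  nt <- n1 + n2
  pbar <- (x1 + x2) / nt
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
  nc <- nt - (n1^2 + n2^2) / nt                            # /(r - 1) = 1
  list(msp = msp, msg = msg, nc = nc)
}

#' Two-population Weir-Cockerham Fst
#'
#' Moment-based theta estimator for two populations from allele counts
#' (haploid-allele parameterisation): with among- and within-population
#' mean squares MSP and MSG and sample-size correction n_c,
#' theta = (MSP - MSG) / (MSP + (n_c - 1) MSG). The raw estimate can be
#' negative; a zero-floored copy is returned for thresholding. When both
#' samples are monomorphic for the same allele the estimator is 0/0:
#' the value returned is 0 with `undefined = TRUE`.
#'
#' @param x1,n1 alternate-allele count and total allele count, population 1.
#' @param x2,n2 same for population 2. All vectorised; n1, n2 >= 2.
#' @return a `data.frame` with columns `theta_raw`, `theta` (floored at 0)
#'   and `undefined`.
#' @export
fst_two_populations <- function(x1, n1, x2, n2) {
  if (any(n1 < 2 | n2 < 2)) stop("n1 and n2 must be >= 2", call. = FALSE)
  if (any(x1 < 0 | x1 > n1 | x2 < 0 | x2 > n2)) {
    stop("allele counts must satisfy 0 <= x <= n", call. = FALSE)
  }
  comp <- wc_components(x1, n1, x2, n2)
  num <- comp$msp - comp$msg
  den <- comp$msp + (comp$nc - 1) * comp$msg
  undefined <- den == 0
  theta_raw <- ifelse(undefined, 0, num / den)
  data.frame(theta_raw = theta_raw, theta = pmax(theta_raw, 0),
             undefined = undefined)
}

#' Multilocus Weir-Cockerham Fst (ratio of sums)
#'
#' Combines per-site variance components as the ratio of summed numerators
#' to summed denominators — the standard way to estimate a genome-wide
#' theta, far less biased than averaging per-site ratios.
#'
#' @inheritParams fst_two_populations
#' @return a single theta estimate.
#' @export
fst_multilocus <- function(x1, n1, x2, n2) {
  comp <- wc_components(x1, n1, x2, n2)
  sum(comp$msp - comp$msg) / sum(comp$msp + (comp$nc - 1) * comp$msg)
}

#' Hudson-style Fst for two populations
#'
#' Unweighted Hudson estimator from sample frequencies with the usual
#' finite-sample correction; provided as an independent cross-check on the
#' Weir-Cockerham estimator, not as the scan default.
#'
#' @inheritParams fst_two_populations
#' @return numeric vector of per-site estimates.
#' @export
fst_hudson <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, 0, num / den)
}

#' Storey q-values
#'
#' q_i = min over ranks j >= rank(i) of (pi0 * m * p_(j) / j), capped at 1.
#' With `pi0_mode = "fixed_1"` (pi0 = 1) this reproduces Benjamini-Hochberg
#' adjusted p-values exactly. With `"smoother"`, pi0 is estimated as the
#' smoothed limit of #\{p > lambda\} / (m (1 - lambda)) over a lambda grid
#' (natural cubic smoothing spline, evaluated at the largest lambda),
#' capped into (0, 1].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (at least one).
#' @param pi0_mode `"fixed_1"` or `"smoother"`.
#' @param lambda grid for the smoother (default `seq(0.05, 0.95, 0.05)`).
#' @return a list of class `qvalue_result`: `qvalues` (aligned to the
#'   input), `pi0`, `method`.
#' @export
storey_qvalues <- function(pvalues, pi0_mode = c("fixed_1", "smoother"),
                           lambda = seq(0.05, 0.95, by = 0.05)) {
  pi0_mode <- match.arg(pi0_mode)
  if (length(pvalues) < 1L) stop("at least one p-value required", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  if (pi0_mode == "fixed_1" || m < 2L) {
    pi0 <- 1
  } else {
    pi0_lambda <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l),
                         numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(pvalues)
  q_sorted <- pi0 * m * pvalues[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  qvalues <- numeric(m)
  qvalues[o] <- q_sorted
  structure(list(qvalues = qvalues, pi0 = pi0, method = pi0_mode),
            class = "qvalue_result")
}

#' Combined enrichment call for one cohort-vs-panel comparison
#'
#' A site is called enriched in a direction only when BOTH thresholds pass
#' with strict inequalities: Fst above `fst_threshold` and the q-value for
#' that direction below `q_threshold`. If both directions somehow pass
#' (possible only with degenerate nulls), "higher" wins with a warning.
#'
#' @param fst zero-floored Fst values.
#' @param q_higher,q_lower q-values for the two one-tailed tests.
#' @param fst_threshold Fst cutoff (default 0.25).
#' @param q_threshold FDR cutoff (default 0.05).
#' @return character vector with values `enriched_higher`,
#'   `enriched_lower`, `not_enriched`.
#' @export
classify_enrichment <- function(fst, q_higher, q_lower,
                                fst_threshold = 0.25, q_threshold = 0.05) {
  hi <- fst > fst_threshold & q_higher < q_threshold
  lo <- fst > fst_threshold & q_lower < q_threshold
  if (any(hi & lo, na.rm = TRUE)) {
    warning("both directions pass thresholds at some site(s); calling 'higher'")
  }
  out <- rep("not_enriched", length(fst))
  out[lo] <- "enriched_lower"
  out[hi] <- "enriched_higher"
  out[is.na(fst) | is.na(q_higher) | is.na(q_lower)] <- NA_character_
  out
}

#' Scan cohort allele counts against panel frequencies
#'
#' For every site with panel data and every continental panel: the exact
#' one-tailed binomial p-values of the cohort's alternate-allele count
#' against the panel frequency (both directions), the two-population
#' Weir-Cockerham Fst between cohort and panel allele counts, q-values
#' computed within each continent (and, by default, within each direction
#' separately), and the combined threshold call. Sites with no panel data
#' in any continent form the "novel" stratum, excluded from testing and
#' reported via the `novel` attribute.
#'
#' @param stats per-site cohort allele statistics ([cohort_allele_stats]
#'   output; needs `key`, `x`, `n_called`).
#' @param panel a `panel_freq` table.
#' @param fst_threshold,q_threshold combined-call cutoffs
#'   (defaults 0.25 and 0.05).
#' @param pi0_mode passed to [storey_qvalues].
#' @param inclusive passed to [binomial_tail_p].
#' @param q_family `"by_direction"` (default): a separate q-value family
#'   per continent and direction; `"pooled"`: both directions of a
#'   continent share one family.
#' @return a `data.frame` of class `enrichment_scan`: one row per
#'   site x continent with `key`, `continent`, `x`, `n`, `p_cont`,
#'   `n_cont`, `theta_raw`, `theta`, `p_higher`, `p_lower`, `q_higher`,
#'   `q_lower`, `call`. Attributes: `novel` (keys without any panel data),
#'   `pi0` (per family), `thresholds`.
#' @export
enrichment_scan <- function(stats, panel, fst_threshold = 0.25,
                            q_threshold = 0.05,
                            pi0_mode = c("fixed_1", "smoother"),
                            inclusive = TRUE,
                            q_family = c("by_direction", "pooled")) {
  pi0_mode <- match.arg(pi0_mode)
  q_family <- match.arg(q_family)
  continents <- attr(panel, "continents")
  idx <- match(stats$key, panel$key)
  has_any <- rep(FALSE, nrow(stats))
  rows <- list()
  for (cont in continents) {
    af <- panel[[paste0(cont, "_af")]][idx]
    nc <- panel[[paste0(cont, "_n")]][idx]
    ok <- which(!is.na(idx) & !is.na(af) & stats$n_called > 0)
    has_any[ok] <- TRUE
    if (length(ok) == 0L) next
    x <- stats$x[ok]; n <- stats$n_called[ok]
    p_cont <- af[ok]; n_cont <- nc[ok]
    x_cont <- round(p_cont * n_cont)
    fst <- fst_two_populations(x, n, x_cont, n_cont)
    p_hi <- binomial_tail_p(x, n, p_cont, "higher", inclusive = inclusive)
    p_lo <- binomial_tail_p(x, n, p_cont, "lower", inclusive = inclusive)
    rows[[cont]] <- data.frame(
      key = stats$key[ok], continent = cont, x = x, n = n,
      p_cont = p_cont, n_cont = n_cont,
      theta_raw = fst$theta_raw, theta = fst$theta,
      p_higher = p_hi, p_lower = p_lo, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no site has panel data in any continent", call. = FALSE)
  }
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL

  pi0_used <- list()
  scan$q_higher <- NA_real_
  scan$q_lower <- NA_real_
  for (cont in unique(scan$continent)) {
    sel <- scan$continent == cont
    if (q_family == "by_direction") {
      qh <- storey_qvalues(scan$p_higher[sel], pi0_mode)
      ql <- storey_qvalues(scan$p_lower[sel], pi0_mode)
      scan$q_higher[sel] <- qh$qvalues
      scan$q_lower[sel] <- ql$qvalues
      pi0_used[[cont]] <- c(higher = qh$pi0, lower = ql$pi0)
    } else {
      pooled <- storey_qvalues(c(scan$p_higher[sel], scan$p_lower[sel]),
                               pi0_mode)
      k <- sum(sel)
      scan$q_higher[sel] <- pooled$qvalues[seq_len(k)]
      scan$q_lower[sel] <- pooled$qvalues[k + seq_len(k)]
      pi0_used[[cont]] <- c(pooled = pooled$pi0)
    }
  }
  scan$call <- classify_enrichment(scan$theta, scan$q_higher, scan$q_lower,
                                   fst_threshold, q_threshold)
  attr(scan, "novel") <- stats$key[!has_any]
  attr(scan, "pi0") <- pi0_used
  attr(scan, "thresholds") <- c(fst = fst_threshold, fdr = q_threshold)
  class(scan) <- c("enrichment_scan", "data.frame")
  scan
}

#' Summarise an enrichment scan
#'
#' Counts of enriched sites per continent, the union across continents,
#' counts by how many continents a site is enriched against (1-4), counts
#' of sites enriched higher (or lower) versus every tested continent, and
#' optionally a cross-tabulation with deleteriousness and health tier.
#'
#' @param scan an `enrichment_scan` table.
#' @param classified optional `classified_variants` table for the
#'   deleterious/tier cross-tab.
#' @return a list of class `enrichment_summary`: `per_continent`,
#'   `union_enriched`, `by_n_continents`, `higher_vs_all`, `lower_vs_all`,
#'   and (if `classified` given) `by_tier`.
#' @export
summarize_enrichment <- function(scan, classified = NULL) {
  enr <- scan[!is.na(scan$call) & scan$call != "not_enriched", , drop = FALSE]
  continents <- unique(scan$continent)
  per_continent <- vapply(continents,
                          function(cc) sum(enr$continent == cc), integer(1))
  keys_enriched <- unique(enr$key)
  n_cont_per_key <- if (nrow(enr) > 0) table(enr$key) else table(character(0))
  by_n <- vapply(seq_along(continents),
                 function(k) sum(n_cont_per_key == k), integer(1))
  if (length(continents) > 0L) {
    names(by_n) <- paste0("vs_", seq_along(continents), "_continents")
  }

  n_tested_per_key <- table(scan$key)
  dir_vs_all <- function(dir) {
    if (nrow(enr) == 0) return(0L)
    tab <- table(enr$key[enr$call == dir])
    sum(tab == n_tested_per_key[names(tab)])
  }
  out <- list(per_continent = per_continent,
              union_enriched = length(keys_enriched),
              by_n_continents = by_n,
              higher_vs_all = dir_vs_all("enriched_higher"),
              lower_vs_all = dir_vs_all("enriched_lower"))
  if (!is.null(classified)) {
    cls <- classified[match(unique(scan$key), classified$key), , drop = FALSE]
    cls$enriched <- cls$key %in% keys_enriched
    out$by_tier <- as.data.frame(table(
      enriched = cls$enriched,
      deleterious = cls$deleterious,
      tier = addNA(factor(cls$tier, levels = 1:3))))
  }
  class(out) <- c("enrichment_summary", "list")
  out
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat("<enrichment_summary>\n")
  cat("  union enriched:", x$union_enriched, "\n")
  cat("  per continent: ",
      paste(names(x$per_continent), x$per_continent, sep = "=", collapse = " "),
      "\n")
  cat("  by #continents:",
      paste(x$by_n_continents, collapse = " / "), "\n")
  cat("  higher vs all:", x$higher_vs_all,
      " lower vs all:", x$lower_vs_all, "\n")
  invisible(x)
}
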
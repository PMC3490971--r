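test_that("binomial tails match closed forms and the summation oracle", {
  expect_equal(binomial_tail_p(14, 14, 0.5, "higher"), 0.5^14)
  expect_equal(binomial_tail_p(0, 14, 0, "lower"), 1)
  expect_equal(binomial_tail_p(0, 14, 0, "higher"), 1)
  expect_equal(binomial_tail_p(14, 14, 1, "higher"), 1)
  expect_equal(binomial_tail_p(8, 14, 0.20, "higher"),
               brute_tail(8, 14, 0.20, "higher"), tolerance = 1e-12)
  expect_equal(binomial_tail_p(8, 14, 0.20, "higher"), 0.002397209,
               tolerance = 1e-6)
  # exclusive tails drop the observed count
  expect_equal(binomial_tail_p(8, 14, 0.2, "higher", inclusive = FALSE),
               brute_tail(9, 14, 0.2, "higher"), tolerance = 1e-12)
  expect_error(binomial_tail_p(15, 14, 0.2), "0 <= x <= n")
  expect_error(binomial_tail_p(3, 14, 1.2), "in \\[0, 1\\]")
})

test_that("binomial tails equal brute-force enumeration over a grid", {
  for (n in c(1, 5, 14, 20)) {
    for (p in seq(0, 1, by = 0.1)) {
      for (x in 0:n) {
        expect_equal(binomial_tail_p(x, n, p, "higher"),
                     brute_tail(x, n, p, "higher"), tolerance = 1e-12)
        expect_equal(binomial_tail_p(x, n, p, "lower"),
                     brute_tail(x, n, p, "lower"), tolerance = 1e-12)
      }
    }
  }
})

test_that("upper and complementary lower tails partition exactly", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    x <- sample(1:n, 1)
    p <- runif(1)
    expect_equal(binomial_tail_p(x, n, p, "higher") +
                   binomial_tail_p(x - 1, n, p, "lower"), 1)
  }
})

test_that("Weir-Cockerham theta matches the variance-component oracle", {
  cases <- rbind(c(8, 14, 152, 758), c(3, 10, 40, 100),
                 c(1, 14, 600, 758), c(5, 20, 5, 20), c(2, 4, 7, 8))
  for (i in seq_len(nrow(cases))) {
    v <- cases[i, ]
    got <- fst_two_populations(v[1], v[2], v[3], v[4])
    expect_equal(got$theta_raw, wc_theta_oracle(v[1], v[2], v[3], v[4]),
                 tolerance = 1e-12)
  }
  # Hudson estimator agrees in sign and ordering on differentiated cases
  wc <- fst_two_populations(c(8, 1), c(14, 14), c(152, 600), c(758, 758))
  hd <- fst_hudson(c(8, 1), c(14, 14), c(152, 600), c(758, 758))
  expect_equal(sign(wc$theta_raw), sign(hd))
  expect_equal(order(wc$theta_raw), order(hd))
})

test_that("theta limit and degeneracy behaviour", {
  # equal polymorphic frequencies, equal n: raw theta <= 0, clamped to 0
  eq <- fst_two_populations(10, 100, 10, 100)
  expect_true(eq$theta_raw <= 0)
  expect_equal(eq$theta, 0)
  # fixed difference at large n approaches 1
  fix <- fst_two_populations(1000, 1000, 0, 1000)
  expect_equal(fix$theta, 1, tolerance = 1e-2)
  # monomorphic for the same allele in both samples: undefined, returned 0
  mono <- fst_two_populations(0, 100, 0, 200)
  expect_true(mono$undefined)
  expect_equal(mono$theta, 0)
  expect_error(fst_two_populations(1, 1, 0, 10), ">= 2")
})

test_that("theta is invariant to swapping populations and allele relabels", {
  set.seed(43)
  for (i in 1:25) {
    n1 <- sample(10:500, 1); n2 <- sample(10:500, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    a <- fst_two_populations(x1, n1, x2, n2)$theta_raw
    expect_equal(a, fst_two_populations(x2, n2, x1, n1)$theta_raw)
    expect_equal(a, fst_two_populations(n1 - x1, n1, n2 - x2, n2)$theta_raw)
  }
})

test_that("q-values with pi0 = 1 equal Benjamini-Hochberg exactly", {
  expect_equal(storey_qvalues(0.03)$qvalues, 0.03)
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.03, 0.5))$qvalues,
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(storey_qvalues(rep(0.2, 5))$qvalues, rep(0.2, 5))
  set.seed(47)
  for (i in 1:10) {
    p <- runif(sample(c(3, 50, 500), 1))^sample(1:3, 1)
    q <- storey_qvalues(p, pi0_mode = "fixed_1")$qvalues
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
  }
  expect_error(storey_qvalues(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(storey_qvalues(numeric(0)), "at least one")
})

test_that("q-values are monotone in rank, capped at 1, scaled by pi0", {
  set.seed(53)
  p <- c(runif(300), runif(700, 0.2, 1))  # mixture with many near-null
  res <- storey_qvalues(p, pi0_mode = "smoother")
  expect_true(res$pi0 > 0 && res$pi0 <= 1)
  o <- order(p)
  expect_true(all(diff(res$qvalues[o]) >= -1e-15))
  expect_true(all(res$qvalues <= 1))
  # smoother q-values are the BH values shrunk by pi0
  bh <- storey_qvalues(p, pi0_mode = "fixed_1")$qvalues
  expect_equal(res$qvalues, pmin(bh * res$pi0, 1), tolerance = 1e-12)
})

test_that("combined enrichment calls need both thresholds strictly", {
  expect_equal(classify_enrichment(0.30, 0.01, 0.9), "enriched_higher")
  expect_equal(classify_enrichment(0.30, 0.10, 0.9), "not_enriched")
  expect_equal(classify_enrichment(0.10, 0.001, 0.9), "not_enriched")
  expect_equal(classify_enrichment(0.30, 0.9, 0.01), "enriched_lower")
  # boundary values fail the strict comparisons
  expect_equal(classify_enrichment(0.25, 0.01, 0.9), "not_enriched")
  expect_equal(classify_enrichment(0.30, 0.05, 0.9), "not_enriched")
  expect_warning(out <- classify_enrichment(0.9, 0.001, 0.001),
                 "both directions")
  expect_equal(out, "enriched_higher")
})

test_that("the scan joins cohort and panel, strata and q-families correctly", {
  sites <- variant_sites("1", c(100L, 200L, 300L), c("A", "C", "G"),
                         c("G", "T", "A"), c("rs1", "rs2", "rs3"))
  stats <- data.frame(key = site_key(sites), x = c(12L, 1L, 5L),
                      n_called = c(14L, 14L, 14L))
  panel <- panel_frequencies(
    sites,
    af = list(EUR = c(0.10, 0.12, NA), ASN = c(0.50, NA, NA)),
    n = list(EUR = c(758L, 758L, NA), ASN = c(592L, NA, NA)))
  scan <- enrichment_scan(stats, panel)
  expect_s3_class(scan, "enrichment_scan")
  expect_equal(nrow(scan), 3L)  # 2 EUR rows + 1 ASN row
  expect_equal(attr(scan, "novel"), site_key(sites)[3])
  row1 <- scan[scan$key == site_key(sites)[1] & scan$continent == "EUR", ]
  expect_equal(row1$p_higher, binomial_tail_p(12, 14, 0.10, "higher"))
  expect_equal(row1$theta_raw,
               fst_two_populations(12, 14, round(0.10 * 758), 758)$theta_raw)
  expect_equal(row1$call, "enriched_higher")
})

test_that("enrichment summaries count unions, directions and continents", {
  empty <- data.frame(key = character(0), continent = character(0),
                      call = character(0))
  class(empty) <- c("enrichment_scan", "data.frame")
  s0 <- summarize_enrichment(empty)
  expect_equal(s0$union_enriched, 0L)
  expect_equal(s0$higher_vs_all, 0L)

  scan <- data.frame(
    key = rep(c("a", "b", "c"), each = 2),
    continent = rep(c("EUR", "ASN"), 3),
    call = c("enriched_higher", "not_enriched",     # a: EUR only
             "enriched_higher", "enriched_higher",  # b: both
             "not_enriched", "not_enriched"))       # c: none
  class(scan) <- c("enrichment_scan", "data.frame")
  s <- summarize_enrichment(scan)
  expect_equal(s$union_enriched, 2L)
  expect_equal(unname(s$per_continent[c("EUR", "ASN")]), c(2L, 1L))
  expect_equal(unname(s$by_n_continents), c(1L, 1L))
  expect_equal(s$higher_vs_all, 1L)  # only b is enriched vs every continent
  expect_equal(s$lower_vs_all, 0L)
})
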
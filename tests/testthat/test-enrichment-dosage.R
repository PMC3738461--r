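test_that("the X-linkage baseline uses assigned, supported genes", {
  asn <- tibble::tibble(chromosome = rep(c("X", "A"), c(390, 2930)))
  expect_equal(expected_fx(asn), 390 / 3320)
  expect_equal(round(expected_fx(asn), 2), 0.12)
  asn2 <- tibble::tibble(chromosome = rep(c("X", "A"), c(497, 3215)))
  expect_equal(round(expected_fx(asn2), 2), 0.13)
  expect_equal(expected_fx(tibble::tibble(chromosome = c("X", "X"))), 1)
  # low-support genes drop out of the baseline
  asn3 <- tibble::tibble(chromosome = c("X", "X", "A", "ambiguous"))
  expect_equal(expected_fx(asn3, low_support = c(TRUE, FALSE, FALSE, FALSE)),
               0.5)
  expect_error(expected_fx(tibble::tibble(chromosome = "ambiguous")),
               "baseline")
})

test_that("chi-square enrichment matches its closed form", {
  p0 <- 390 / 3320
  # observation exactly at expectation: no signal
  n <- 1000
  at <- chisq_enrichment(round(n * p0), n - round(n * p0), p0)
  expect_lt(at$statistic, 0.01)
  expect_equal(at$pct_deviation, 100 * (at$f_X / p0 - 1))
  # hand-computed goodness of fit for the strongly enriched male-biased set
  obs <- c(63, 205)
  expd <- sum(obs) * c(p0, 1 - p0)
  stat_hand <- sum((obs - expd)^2 / expd)
  res <- chisq_enrichment(63, 205, p0)
  expect_equal(res$statistic, stat_hand)
  expect_equal(res$f_X, 63 / 268)
  expect_equal(round(res$f_X, 2), 0.24)
  expect_equal(round(res$pct_deviation), 100)
  expect_lt(res$p_value, 1e-8)
  # the small balanced cell: frequency 0.50, deviation ~ +326%
  res2 <- chisq_enrichment(6, 6, p0)
  expect_equal(res2$f_X, 0.5)
  expect_equal(round(res2$pct_deviation), 326)
})

test_that("the chi-square equals the squared one-proportion z statistic", {
  set.seed(90)
  for (i in 1:50) {
    n <- sample(20:500, 1)
    x <- rbinom(1, n, 0.3)
    if (x == 0 || x == n) next
    p0 <- runif(1, 0.05, 0.95)
    z <- (x / n - p0) / sqrt(p0 * (1 - p0) / n)
    expect_equal(chisq_enrichment(x, n - x, p0)$statistic, z^2,
                 tolerance = 1e-10)
  }
  # percent deviation is scale-invariant
  a <- chisq_enrichment(20, 60, 0.2)
  b <- chisq_enrichment(200, 600, 0.2)
  expect_equal(a$pct_deviation, b$pct_deviation)
})

test_that("RPKM follows its closed form", {
  expect_equal(unname(rpkm(rbind(g1 = 100), lengths = 1000,
                           totals = 1e7)[1, 1]), 10)
  expect_equal(unname(rpkm(rbind(g1 = 0), lengths = 1000,
                           totals = 1e7)[1, 1]), 0)
  m <- rbind(g1 = c(100, 100), g2 = c(50, 50))
  r1 <- rpkm(m, c(g1 = 2000, g2 = 500), totals = c(1e7, 2e7))
  expect_equal(r1[, 1], 2 * r1[, 2])  # doubling the total halves RPKM
  expect_equal(unname(r1["g2", 1]), 50 / (0.5 * 10))
  expect_error(rpkm(m, c(0, 100), totals = c(1e7, 1e7)), "lengths")
})

test_that("the Wilcoxon machinery behaves on degenerate and shifted input", {
  # identical samples: no rank signal
  asn <- tibble::tibble(gene = paste0("g", 1:40),
                        chromosome = rep(c("X", "A"), each = 20))
  me <- tibble::tibble(gene = paste0("g", 1:40),
                       total_rpkm = rep(10, 40),
                       rpkm_M = rep(c(1, 2, 3, 4), 10))
  me$log2_M <- log2(me$rpkm_M + 1)
  res <- dosage_tests(me, asn, thresholds = 0, double_x_males = FALSE)
  expect_gt(res$p_value, 0.9)
  # doubling X in males shifts log2 values by ~1 for well-expressed genes
  x <- c(50, 100, 400)
  expect_equal(log2(2 * x + 1) - log2(x + 1), rep(1, 3), tolerance = 0.02)
})

test_that("rank-sum p-values match an exact enumeration oracle", {
  # brute-force null distribution of the rank-sum statistic for n <= 8
  exact_p <- function(x, y) {
    ranks <- rank(c(x, y))
    w_obs <- sum(ranks[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    combs <- utils::combn(length(x) + length(y), length(x))
    ws <- apply(combs, 2, function(idx) {
      sum(rank(c(x, y))[idx]) - length(x) * (length(x) + 1) / 2
    })
    mean(abs(ws - mean(ws)) >= abs(w_obs - mean(ws)) - 1e-9)
  }
  set.seed(91)
  for (i in 1:20) {
    x <- runif(sample(3:5, 1), 0, 20)
    y <- runif(sample(3:5, 1), 5, 25)
    ours <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, exact_p(x, y), tolerance = 1e-9,
                 info = paste("case", i))
  }
})

test_that("dosage comparisons recover planted compensation regimes", {
  # X genes expressed at half the autosomal rate in males only: the raw
  # male X-vs-A comparison rejects, the doubled-X variant does not
  reject_raw <- reject_doubled <- logical(10)
  for (r in 1:10) {
    # well-expressed regime: at low counts computational doubling cannot
    # restore the sampling distribution (a halved-mean count has more
    # zeros and a higher CV), so the exact-null check needs counting
    # noise to be negligible
    # and no planted morph bias: the default proportions put a genuine
    # male-biased excess on the X, which is exactly what this comparison
    # must not be contaminated by
    cfg <- synth_config(n_genes = 1600, n_markers = 400, n_scaffolds = 40,
                        n_chimeric = 0, depth_range = c(1e7, 1e7),
                        baseline_sdlog = 1, male_x_factor = 0.5,
                        bias_props = tibble::tibble(
                          category = bias_categories(),
                          prop_A = rep(0, 6), prop_X = rep(0, 6)))
    ds <- synth_dataset(cfg, seed = 92 + r)
    rp <- rpkm(ds$counts, setNames(ds$genes$length, ds$genes$gene))
    me <- morph_rpkm(rp, ds$design)
    asn <- ds$genes[, c("gene", "scaffold", "chromosome")]
    # no expression filter: thresholding on total RPKM (which the halved
    # male X depresses) would select the X genes asymmetrically and break
    # the exactness of the doubled-X null
    res <- dosage_tests(me, asn, thresholds = 0)
    reject_raw[r] <- res$p_value[res$morph == "M" & !res$doubled_X] < 0.01
    reject_doubled[r] <- res$p_value[res$morph == "M" & res$doubled_X] < 0.01
  }
  expect_gte(mean(reject_raw), 0.9)
  expect_lte(mean(reject_doubled), 0.1)
})

test_that("low-expression enrichment uses the configured cutoff", {
  set.seed(93)
  n <- 600
  asn <- tibble::tibble(gene = paste0("g", 1:n),
                        chromosome = rep(c("X", "A"), c(100, 500)))
  # plant low expression in 30% of X genes, 5% of autosomal genes
  low <- c(runif(100) < 0.3, runif(500) < 0.05)
  me <- tibble::tibble(gene = asn$gene,
                       total_rpkm = ifelse(low, 0.01, 10),
                       rpkm_M = 1, log2_M = 1)
  res <- low_expression_test(me, asn, cutoff = 0.1)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$frac_low_X, res$frac_low_A)
  # no low genes at a tiny cutoff: graceful NA result
  res0 <- low_expression_test(me, asn, cutoff = 1e-6)
  expect_true(is.na(res0$p_value))
})
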